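## Shared fixtures and independent brute-force oracles.  Every oracle here
## is written as plain loops over the defining formulas, independent of the
## package's vectorised implementations.

## small custom alphabets keep q manageable in toy tests
smallAlphabet <- function(q) {
  stopifnot(q >= 2, q <= 21)
  new("PottsAlphabet",
      symbols = c("-", strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])[seq_len(q)],
      gapState = 1L)
}

## random symmetric Potts model with zero self-coupling blocks
randomModel <- function(L, q, seed = 1, couplingSD = 0.5, fieldSD = 0.5,
                        provenance = "synthetic") {
  set.seed(seed)
  E <- matrix(rnorm(L * q * L * q, sd = couplingSD), L * q, L * q)
  E <- (E + t(E)) / 2
  for (i in seq_len(L)) {
    bi <- ((i - 1) * q + 1):(i * q)
    E[bi, bi] <- 0
  }
  new("PottsModel", couplings = E,
      fields = matrix(rnorm(L * q, sd = fieldSD), L, q),
      L = as.integer(L), q = as.integer(q),
      gaugeTag = "reference-state", provenance = provenance)
}

randomMask <- function(LHK, LRR, nPairs, seed = 1) {
  set.seed(seed)
  all <- expand.grid(hk_col = seq_len(LHK), rr_col = LHK + seq_len(LRR))
  sel <- all[sample.int(nrow(all), nPairs), ]
  sel <- sel[order(sel$hk_col, sel$rr_col), ]
  rownames(sel) <- NULL
  new("ContactMask", pairs = cbind(sel, min_dist = NA_real_),
      cutoffA = 12, metricTag = "min-heavy-atom",
      LHK = as.integer(LHK), LRR = as.integer(LRR))
}

## -- brute-force oracles -----------------------------------------------------

bfHamiltonian <- function(model, s) {
  L <- model@L
  en <- 0
  for (i in seq_len(L)) en <- en - model@fields[i, s[i]]
  for (i in seq_len(L - 1)) for (j in (i + 1):L)
    en <- en - couplingBlock(model, i, j)[s[i], s[j]]
  en
}

bfHtcs <- function(model, mask, hk, rr) {
  s <- c(hk, rr)
  en <- 0
  mp <- maskPairs(mask)
  for (k in seq_len(nrow(mp)))
    en <- en - couplingBlock(model, mp$hk_col[k], mp$rr_col[k])[
      s[mp$hk_col[k]], s[mp$rr_col[k]]]
  for (i in seq_along(s)) en <- en - model@fields[i, s[i]]
  en
}

bfWeights <- function(states, thr) {
  M <- nrow(states); L <- ncol(states)
  n <- integer(M)
  for (a in seq_len(M)) for (b in seq_len(M)) {
    id <- sum(states[a, ] == states[b, ]) / L
    if (id >= thr - 1e-12) n[a] <- n[a] + 1L
  }
  1 / n
}

bfFrequencies <- function(states, weights, lambda, q) {
  M <- nrow(states); L <- ncol(states)
  Meff <- sum(weights)
  f1 <- matrix(lambda / q, L, q)
  for (s in seq_len(M)) for (i in seq_len(L))
    f1[i, states[s, i]] <- f1[i, states[s, i]] + weights[s]
  f1 <- f1 / (lambda + Meff)
  f2 <- array(lambda / q^2, c(L, L, q, q))
  for (s in seq_len(M)) for (i in seq_len(L)) for (j in seq_len(L))
    f2[i, j, states[s, i], states[s, j]] <-
      f2[i, j, states[s, i], states[s, j]] + weights[s]
  f2 <- f2 / (lambda + Meff)
  for (i in seq_len(L)) f2[i, i, , ] <- diag(f1[i, ], nrow = q)
  list(f1 = f1, f2 = f2)
}

bfLongestGapRun <- function(row) {
  best <- 0L; cur <- 0L
  for (ch in strsplit(row, "")[[1]]) {
    if (ch == "-") { cur <- cur + 1L; best <- max(best, cur) } else cur <- 0L
  }
  best
}

bfContacts <- function(xyzA, resA, xyzB, resB, cutoff) {
  out <- NULL
  for (ra in unique(resA)) for (rb in unique(resB)) {
    da <- xyzA[resA == ra, , drop = FALSE]
    db <- xyzB[resB == rb, , drop = FALSE]
    dmin <- Inf
    for (u in seq_len(nrow(da))) for (v in seq_len(nrow(db)))
      dmin <- min(dmin, sqrt(sum((da[u, ] - db[v, ])^2)))
    if (dmin < cutoff) out <- rbind(out, data.frame(res_a = ra, res_b = rb,
                                                    dist = dmin))
  }
  if (is.null(out)) data.frame(res_a = integer(0), res_b = integer(0),
                               dist = numeric(0))
  else out[order(out$res_a, out$res_b), , drop = FALSE]
}

bfClassify <- function(scoreMat, cognates) {
  r <- round(scoreMat, 9)
  out <- NULL
  for (k in seq_len(nrow(cognates))) {
    h <- cognates$hk_id[k]; rr <- cognates$rr_id[k]
    pos <- all(r[h, rr] < r[h, setdiff(colnames(r), rr)])
    neg <- all(r[h, rr] < r[setdiff(rownames(r), h), rr])
    out <- rbind(out, data.frame(hk_id = h, rr_id = rr, positive = pos,
                                 negative = neg,
                                 verdict = if (pos || neg) "true_positive"
                                           else "false_negative"))
  }
  out
}

## Sinkhorn matrix scaling: the unique P = D1 W D2 with marginals fi, fj --
## an independent route to the two-site direct distribution
sinkhornDirect <- function(W, fi, fj, iters = 5000) {
  r <- rep(1, length(fi)); cc <- rep(1, length(fj))
  for (t in seq_len(iters)) {
    r <- fi / as.vector(W %*% cc)
    cc <- fj / as.vector(crossprod(W, r))
  }
  P <- r * W * rep(cc, each = length(fi))
  P / sum(P)
}

## SiteFrequencies built directly from given f1 (product-form f2 off the
## diagonal): enough for direct-information inputs
freqsFromF1 <- function(f1, refState = 1L) {
  L <- nrow(f1); q <- ncol(f1)
  f1v <- as.vector(t(f1))
  f2 <- tcrossprod(f1v)
  for (i in seq_len(L)) {
    bi <- ((i - 1) * q + 1):(i * q)
    f2[bi, bi] <- diag(f1v[bi], nrow = q)
  }
  new("SiteFrequencies", f1 = f1, f2 = f2, Meff = 1, lambda = 0,
      weights = 1, refState = as.integer(refState))
}

## hand-written 2-chain PDB fixture; coords is a data.frame with columns
## chain, resno, resname, atom, x, y, z, and optional alt, occ
writeTinyPDB <- function(coords, path) {
  lines <- character(nrow(coords))
  for (k in seq_len(nrow(coords))) {
    r <- coords[k, ]
    alt <- if (!is.null(r$alt)) r$alt else " "
    occ <- if (!is.null(r$occ)) r$occ else 1.0
    elem <- substr(trimws(r$atom), 1, 1)
    lines[k] <- sprintf(
      "ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      k, r$atom, alt, r$resname, r$chain, r$resno, r$x, r$y, r$z, occ, 0,
      elem)
  }
  writeLines(c(lines, "END"), path)
  path
}

## deterministic random encoded rows
randomStates <- function(M, L, q, seed) {
  set.seed(seed)
  matrix(sample.int(q, M * L, replace = TRUE), M, L,
         dimnames = list(paste0("s", seq_len(M)), NULL))
}

encFromStates <- function(states, alphabet) {
  new("EncodedAlignment", states = states, alphabet = alphabet)
}

## mixed-radix key of configurations (rows of a state matrix)
configKey <- function(m, q) {
  L <- ncol(m)
  as.vector((m - 1) %*% q^((L - 1):0)) + 1
}

## chi-square statistic of sampled rows against exact Boltzmann enumeration
chiVsBoltzmann <- function(states, bz, q) {
  L <- ncol(states)
  M <- nrow(states)
  expv <- numeric(q^L)
  expv[configKey(bz$configs, q)] <- M * bz$prob
  obs <- tabulate(configKey(states, q), nbins = q^L)
  sum((obs - expv)^2 / expv)
}

## total-variation distance of sampled rows against the exact distribution
tvVsBoltzmann <- function(states, bz, q) {
  L <- ncol(states)
  pv <- numeric(q^L)
  pv[configKey(bz$configs, q)] <- bz$prob
  emp <- tabulate(configKey(states, q), nbins = q^L) / nrow(states)
  0.5 * sum(abs(emp - pv))
}
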