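## Mean-field Direct Coupling Analysis: reweighting, frequency counting,
## correlation-matrix inversion, direct information, Hamiltonian evaluation.

## sparse M x (Lq) one-hot indicator of an encoded state matrix
oneHot <- function(states, q) {
  M <- nrow(states); L <- ncol(states)
  cols <- as.vector(t(t(states) + (seq_len(L) - 1L) * q))  # column-shifted states
  Matrix::sparseMatrix(i = rep(seq_len(M), times = L),
                       j = cols, x = 1,
                       dims = c(M, L * q))
}

#' Identity-based sequence reweighting
#'
#' Each sequence gets weight 1 / (number of sequences, itself included,
#' whose fractional identity to it is >= `identityThreshold`).  The sum of
#' weights is the effective sequence number M_eff.  The default threshold of
#' 0.8 is the standard mean-field DCA choice.
#'
#' @param enc an [EncodedAlignment-class].
#' @param identityThreshold fraction in (0, 1].
#' @param chunk rows per block in the pairwise identity scan (memory knob).
#' @return list with `weights` (numeric, length M) and `Meff`.
#' @export
computeWeights <- function(enc, identityThreshold = 0.8, chunk = 4096L) {
  stopifnot(identityThreshold > 0, identityThreshold <= 1)
  s <- encodedStates(enc)
  M <- nrow(s); L <- ncol(s)
  if (M == 0L) stop("empty alignment")
  X <- oneHot(s, nStates(enc@alphabet))
  thr <- identityThreshold * L
  nNeighbors <- integer(M)
  for (start in seq(1L, M, by = chunk)) {
    idx <- start:min(start + chunk - 1L, M)
    sim <- as.matrix(Matrix::tcrossprod(X[idx, , drop = FALSE], X))
    nNeighbors[idx] <- rowSums(sim >= thr - 1e-9)
  }
  w <- 1 / nNeighbors
  list(weights = w, Meff = sum(w))
}

#' Reweighted, pseudocounted site frequencies
#'
#' Computes f1(i,a) = (lambda/q + sum_s w_s [x_si = a]) / (lambda + Meff)
#' and the analogous pair frequencies with pseudocount lambda/q^2; diagonal
#' blocks of f2 are set to diag(f1(i,.)) so that f2(i,i)(a,b) =
#' f1(i,a) delta(a,b).  The default pseudocount lambda = Meff (relative
#' weight 0.5) is the standard choice for stable mean-field inversion.
#'
#' @param enc an [EncodedAlignment-class].
#' @param weights per-sequence weights (default: uniform 1).
#' @param lambda pseudocount weight >= 0; default `Meff`.
#' @return a [SiteFrequencies-class].
#' @export
countFrequencies <- function(enc, weights = NULL, lambda = NULL) {
  s <- encodedStates(enc)
  M <- nrow(s); L <- ncol(s); q <- nStates(enc@alphabet)
  if (M == 0L) stop("empty alignment")
  if (is.null(weights)) weights <- rep(1, M)
  stopifnot(length(weights) == M)
  Meff <- sum(weights)
  if (is.null(lambda)) lambda <- Meff
  stopifnot(lambda >= 0)
  X <- oneHot(s, q)
  denom <- lambda + Meff
  f1v <- (lambda / q + as.vector(Matrix::crossprod(X, weights))) / denom
  f2 <- (lambda / q^2 +
         as.matrix(Matrix::crossprod(X, weights * X))) / denom
  # diagonal blocks: f2(i,i)(a,b) = f1(i,a) delta(a,b)
  for (i in seq_len(L)) {
    bi <- ((i - 1L) * q + 1L):(i * q)
    f2[bi, bi] <- diag(f1v[bi], nrow = q)
  }
  f1 <- matrix(f1v, nrow = L, ncol = q, byrow = TRUE)
  new("SiteFrequencies", f1 = f1, f2 = f2, Meff = Meff, lambda = lambda,
      weights = as.numeric(weights),
      refState = gapState(enc@alphabet))
}

## sparse block-averaging operator: (I_L kron J_q / q)
blockAverager <- function(L, q) {
  Matrix::bdiag(replicate(L, Matrix::Matrix(1 / q, q, q), simplify = FALSE))
}

#' Fit a Potts model by mean-field DCA
#'
#' Inverts the pseudocounted connected-correlation matrix
#' C(i,a)(j,b) = f2 - f1 f1 over the q-1 non-reference states per site
#' (reference state = gap, which removes the exact linear dependency among
#' the q states); couplings are e_ij(a,b) = -(C^-1)(i,a)(j,b), extended to
#' q states and re-expressed in the zero-sum gauge.  Fields come from the
#' mean-field self-consistency
#' h_i(a) = ln f1(i,a)/f1(i,ref) - sum_{j != i} sum_b e_ij(a,b) f1(j,b),
#' then absorb the gauge shift and are centred per site.
#'
#' @param freqs a [SiteFrequencies-class].
#' @param provenance recorded on the model (`"cognate"`, `"scrambled"`, ...).
#' @return a [PottsModel-class] in the zero-sum gauge.
#' @export
fitMFDCA <- function(freqs, provenance = "cognate") {
  f1 <- freqs@f1
  L <- nrow(f1); q <- ncol(f1)
  red <- setdiff(seq_len(q), freqs@refState)
  ridx <- as.vector(outer(red, (seq_len(L) - 1L) * q, `+`))
  f1v <- as.vector(t(f1))                    # site-major, (i-1)q + a
  C <- freqs@f2[ridx, ridx] - tcrossprod(f1v[ridx])
  Jred <- tryCatch(-solve(C), error = function(e)
    stop("connected-correlation matrix is singular (", conditionMessage(e),
         "); raise the pseudocount lambda"))
  E <- matrix(0, L * q, L * q)
  E[ridx, ridx] <- (Jred + t(Jred)) / 2
  for (i in seq_len(L)) {                    # zero self-couplings
    bi <- ((i - 1L) * q + 1L):(i * q)
    E[bi, bi] <- 0
  }
  # fields in the reference gauge
  ref <- freqs@refState
  fref <- rep(f1[, ref], each = q)
  h <- log(f1v / fref) - as.vector(E %*% f1v)
  # zero-sum gauge: e' = e - rowMean - colMean + blockMean, fields absorb
  # the per-row block means so H changes only by a sequence-independent
  # constant
  P <- blockAverager(L, q)
  Erow <- as.matrix(E %*% P)
  Ecol <- as.matrix(P %*% E)
  Eboth <- as.matrix(P %*% Erow)
  hAdd <- rowSums(Erow[, seq(1L, L * q, by = q), drop = FALSE])
  E <- E - Erow - Ecol + Eboth
  h <- h + hAdd
  fieldsM <- matrix(h, nrow = L, ncol = q, byrow = TRUE)
  fieldsM <- fieldsM - rowMeans(fieldsM)     # centred fields
  new("PottsModel", couplings = E, fields = fieldsM,
      L = as.integer(L), q = as.integer(q), gaugeTag = "zero-sum",
      provenance = provenance,
      metadata = list(lambda = freqs@lambda, Meff = freqs@Meff,
                      refState = freqs@refState))
}

## two-site direct distribution for one coupling block, by marginal matching
directPair <- function(W, fi, fj, tol = 1e-6, maxSweeps = 200L) {
  q <- length(fi)
  mu1 <- rep(1 / q, q); mu2 <- rep(1 / q, q)
  iter <- 0L; converged <- FALSE
  while (iter < maxSweeps) {
    iter <- iter + 1L
    new1 <- fi / as.vector(W %*% mu2);  new1 <- new1 / sum(new1)
    new2 <- fj / as.vector(crossprod(W, mu1)); new2 <- new2 / sum(new2)
    d <- max(0.5 * sum(abs(new1 - mu1)), 0.5 * sum(abs(new2 - mu2)))
    mu1 <- new1; mu2 <- new2
    if (d < tol) { converged <- TRUE; break }
  }
  P <- W * outer(mu1, mu2)
  list(P = P / sum(P), iter = iter, converged = converged)
}

#' Direct information of coupled column pairs
#'
#' For each column pair the two-site "direct" distribution
#' P_dir(a,b) proportional to exp(e_ij(a,b)) mu_i(a) mu_j(b) is built with
#' auxiliary fields mu fixed by iterative matching of its marginals to the
#' single-site frequencies (total-variation tolerance `tol`, at most
#' `maxSweeps` sweeps); DI is its mutual information against the product of
#' marginals.  DI is non-negative, symmetric, and zero for uncoupled pairs.
#'
#' @param model a [PottsModel-class].
#' @param freqs the [SiteFrequencies-class] the model was fit from.
#' @param pairs optional 2-column matrix/data.frame of (i, j) pairs to score;
#'   default all i < j.
#' @param tol marginal-matching tolerance (total variation).
#' @param maxSweeps iteration cap; non-converged pairs are reported in the
#'   `convergence` slot and a warning.
#' @return a [DIMatrix-class].
#' @export
directInformation <- function(model, freqs, pairs = NULL,
                              tol = 1e-6, maxSweeps = 200L) {
  L <- model@L; q <- model@q
  stopifnot(nrow(freqs@f1) == L, ncol(freqs@f1) == q)
  if (is.null(pairs)) {
    pairs <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
    pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  } else {
    pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  }
  di <- matrix(0, L, L)
  iters <- integer(nrow(pairs)); bad <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    W <- exp(couplingBlock(model, i, j))
    fi <- freqs@f1[i, ]; fj <- freqs@f1[j, ]
    dp <- directPair(W, fi, fj, tol = tol, maxSweeps = maxSweeps)
    iters[k] <- dp$iter; bad[k] <- !dp$converged
    P <- dp$P
    val <- sum(P * log(P / outer(fi, fj)))
    di[i, j] <- di[j, i] <- max(val, 0)
  }
  if (any(bad))
    warning(sum(bad), " pair(s) did not reach marginal-matching tolerance ",
            tol, " in ", maxSweeps, " sweeps (e.g. pair ",
            paste(pairs[which(bad)[1L], ], collapse = ","), ")")
  ranking <- data.frame(i = pairs[, 1L], j = pairs[, 2L],
                        di = di[pairs])
  ranking <- ranking[order(-ranking$di, ranking$i, ranking$j), ]
  rownames(ranking) <- NULL
  new("DIMatrix", di = di, ranking = ranking,
      convergence = list(iterations = iters,
                         nonConverged = pairs[bad, , drop = FALSE]))
}

#' Potts Hamiltonian of one encoded sequence
#'
#' H(s) = -sum_{i<j} e_ij(s_i, s_j) - sum_i h_i(s_i).  Only relative values
#' are meaningful: the normalisation Z of the Boltzmann distribution is
#' never computed.
#'
#' @param model a [PottsModel-class].
#' @param seq integer state vector of length `model@L` (values in 1..q).
#' @return scalar energy.
#' @export
hamiltonian <- function(model, seq) {
  L <- model@L; q <- model@q
  seq <- as.integer(seq)
  if (length(seq) != L) stop("sequence length ", length(seq), " != L = ", L)
  if (anyNA(seq) || min(seq) < 1L || max(seq) > q)
    stop("encoded states must lie in 1..q")
  sidx <- (seq_len(L) - 1L) * q + seq
  Esub <- model@couplings[sidx, sidx]
  coup <- sum(Esub[upper.tri(Esub)])
  fld <- sum(model@fields[cbind(seq_len(L), seq)])
  -coup - fld
}

#' Serialize a Potts model with a JSON sidecar
#'
#' Writes the model as an RDS archive plus `<path>.json` recording L, q,
#' gauge, provenance and fit metadata.
#'
#' @param model a [PottsModel-class].
#' @param path output path (e.g. `model.rds`).
#' @return `path`, invisibly.
#' @export
writePottsModel <- function(model, path) {
  saveRDS(model, path)
  side <- c(list(L = model@L, q = model@q, gauge = model@gaugeTag,
                 provenance = model@provenance), model@metadata)
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writePottsModel
#' @export
readPottsModel <- function(path) {
  m <- readRDS(path)
  stopifnot(is(m, "PottsModel"))
  m
}

#' Write a DI matrix as TSV
#'
#' Columns `i`, `j`, `di` with 1-based positions, in ranking order.
#'
#' @param di a [DIMatrix-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDITable <- function(di, path) {
  utils::write.table(di@ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
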