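## Potts sampling and planted-coupling toy two-component worlds.

## categorical sampling per chain from a q x M logit matrix (Gumbel-max)
sampleLogits <- function(logits) {
  q <- nrow(logits); M <- ncol(logits)
  g <- -log(-log(matrix(runif(q * M), q, M)))
  max.col(t(logits + g))
}

#' Sample sequences from a Potts model
#'
#' `method = "exact"` enumerates all q^L configurations (feasible for
#' q^L <= 1e6), computes Boltzmann weights exp(-H) and samples rows
#' directly.  `method = "gibbs"` runs one vectorised random-scan Gibbs chain
#' per requested row (default) or a smaller number of thinned chains; with
#' sparse coupling graphs each sweep only visits coupled neighbours.
#'
#' @param model a [PottsModel-class].
#' @param M number of rows to draw.
#' @param seed integer seed.
#' @param method `"gibbs"` (default) or `"exact"`.
#' @param burnin Gibbs burn-in sweeps (default 1000).
#' @param thin sweeps between retained samples when `nChains < M`
#'   (default 10).
#' @param nChains number of parallel chains (default `M`: one independent
#'   chain per row, each contributing its post-burn-in state).
#' @param alphabet alphabet attached to the output.
#' @return an [EncodedAlignment-class] with rows `s1..sM`.
#' @export
samplePotts <- function(model, M, seed = 1L, method = c("gibbs", "exact"),
                        burnin = 1000L, thin = 10L, nChains = M,
                        alphabet = pottsAlphabet()) {
  method <- match.arg(method)
  L <- model@L; q <- model@q
  stopifnot(M >= 1L)
  set.seed(seed)
  if (method == "exact") {
    nconf <- q^L
    if (nconf > 1e6)
      stop("exact enumeration infeasible: q^L = ", format(nconf, digits = 3),
           " configurations (> 1e6); use method = 'gibbs'")
    grid <- as.matrix(expand.grid(rep(list(seq_len(q)), L)))[, , drop = FALSE]
    en <- enumerateEnergies(model, grid)
    p <- exp(-(en - min(en)))
    rows <- grid[sample.int(nrow(grid), M, replace = TRUE, prob = p), ,
                 drop = FALSE]
  } else {
    nChains <- min(nChains, M)
    states <- matrix(sample.int(q, nChains * L, replace = TRUE), nChains, L)
    nbrs <- couplingNeighbours(model)
    sweep1 <- function(states) {
      for (i in sample.int(L)) {
        logits <- matrix(model@fields[i, ], q, nrow(states))
        for (j in nbrs[[i]]) {
          blk <- couplingBlock(model, i, j)
          logits <- logits + blk[, states[, j], drop = FALSE]
        }
        states[, i] <- sampleLogits(logits)
      }
      states
    }
    for (s in seq_len(burnin)) states <- sweep1(states)
    if (nChains == M) {
      rows <- states
    } else {
      rows <- matrix(0L, M, L)
      taken <- 0L
      while (taken < M) {
        take <- min(nChains, M - taken)
        rows[taken + seq_len(take), ] <- states[seq_len(take), , drop = FALSE]
        taken <- taken + take
        if (taken < M) for (s in seq_len(thin)) states <- sweep1(states)
      }
    }
  }
  rownames(rows) <- paste0("s", seq_len(M))
  new("EncodedAlignment", states = rows, alphabet = alphabet)
}

## energies of explicit configurations (rows of `grid`), vectorised over rows
enumerateEnergies <- function(model, grid) {
  L <- model@L; q <- model@q
  en <- numeric(nrow(grid))
  for (i in seq_len(L)) en <- en - model@fields[i, grid[, i]]
  for (i in seq_len(L - 1L)) for (j in (i + 1L):L) {
    blk <- couplingBlock(model, i, j)
    if (any(blk != 0)) en <- en - blk[cbind(grid[, i], grid[, j])]
  }
  en
}

## exact Boltzmann probabilities of all q^L configurations (small models)
#' Exact Boltzmann distribution of a small Potts model
#' @param model a [PottsModel-class] with q^L <= 1e6.
#' @return list with `configs` (matrix of states) and `prob`.
#' @export
enumerateBoltzmann <- function(model) {
  L <- model@L; q <- model@q
  if (q^L > 1e6) stop("q^L too large to enumerate: ", format(q^L))
  grid <- as.matrix(expand.grid(rep(list(seq_len(q)), L)))
  en <- enumerateEnergies(model, grid)
  w <- exp(-(en - min(en)))
  list(configs = grid, prob = w / sum(w))
}

couplingNeighbours <- function(model) {
  L <- model@L; q <- model@q
  lapply(seq_len(L), function(i) {
    bi <- ((i - 1L) * q + 1L):(i * q)
    js <- setdiff(seq_len(L), i)
    js[vapply(js, function(j)
      any(model@couplings[bi, ((j - 1L) * q + 1L):(j * q)] != 0),
      logical(1))]
  })
}

#' Build a planted-coupling toy two-component world
#'
#' Emulates the statistical structure the specificity model assumes: HK and
#' RR domain families whose concatenated sequences follow a q=21-state Potts
#' distribution with inter-domain couplings concentrated on a planted
#' interface mask.  `nInterfacePairs` disjoint column pairs (one HK column,
#' one RR column each) carry couplings of size `couplingStrength` on one
#' matched state combination per cognate family; each HK family additionally
#' prefers its own HK-side interface states through a field bias, so family
#' f's kinases co-vary with family f's regulators exactly at the interface.
#' Because planted pairs are disjoint the Boltzmann distribution factorises
#' into independent two-site joints plus independent columns, and sampling
#' is exact.
#'
#' Defaults mirror the real HisKA/REC setting (67 + 112 columns, q = 21)
#' with 5 cognate families of 500 sequence pairs each and strong planted
#' interface couplings.
#'
#' @param nFamilies number of cognate HK/RR families.
#' @param LHK,LRR domain block widths.
#' @param nInterfacePairs planted interface column pairs
#'   (<= min(LHK, LRR) so pairs can be disjoint).
#' @param couplingStrength coupling energy on matched state combinations
#'   (0 = no planted signal; classification then falls to chance).
#' @param fieldBias per-family HK-side field bonus at planted columns.
#' @param MPerFamily sampled sequence pairs per family.
#' @param backgroundFieldSD spread of the iid background fields.
#' @param seed master seed; all randomness (layout, model, sampling) flows
#'   from it.
#' @param alphabet the state alphabet (q taken from it).
#' @return a [ToyWorld-class].
#' @export
makeToyWorld <- function(nFamilies = 5L, LHK = 67L, LRR = 112L,
                         nInterfacePairs = 10L, couplingStrength = 3,
                         fieldBias = 2, MPerFamily = 500L,
                         backgroundFieldSD = 0.3, seed = 1L,
                         alphabet = pottsAlphabet()) {
  q <- nStates(alphabet)
  gap <- gapState(alphabet)
  stopifnot(nInterfacePairs <= LHK * LRR,
            nInterfacePairs <= min(LHK, LRR),  # disjoint layout
            nFamilies <= q - 1L)
  set.seed(seed)
  L <- LHK + LRR
  # planted layout: disjoint column pairs straddling the domain boundary
  hkCols <- sort(sample.int(LHK, nInterfacePairs))
  rrCols <- LHK + sort(sample.int(LRR, nInterfacePairs))
  # per-pair, per-family matched state combinations (non-gap states)
  nonGap <- setdiff(seq_len(q), gap)
  combosHK <- matrix(0L, nInterfacePairs, nFamilies)
  combosRR <- matrix(0L, nInterfacePairs, nFamilies)
  for (p in seq_len(nInterfacePairs)) {
    combosHK[p, ] <- sample(nonGap, nFamilies)
    combosRR[p, ] <- sample(nonGap, nFamilies)
  }
  # shared generating model
  fieldsM <- matrix(rnorm(L * q, sd = backgroundFieldSD), L, q)
  fieldsM[, gap] <- fieldsM[, gap] - 1     # gaps mildly disfavoured
  E <- matrix(0, L * q, L * q)
  for (p in seq_len(nInterfacePairs)) {
    i <- hkCols[p]; j <- rrCols[p]
    blk <- matrix(0, q, q)
    blk[cbind(combosHK[p, ], combosRR[p, ])] <- couplingStrength
    bi <- ((i - 1L) * q + 1L):(i * q); bj <- ((j - 1L) * q + 1L):(j * q)
    E[bi, bj] <- blk
    E[bj, bi] <- t(blk)
  }
  model <- new("PottsModel", couplings = E, fields = fieldsM,
               L = as.integer(L), q = as.integer(q),
               gaugeTag = "reference-state", provenance = "synthetic",
               metadata = list(seed = seed,
                               couplingStrength = couplingStrength,
                               fieldBias = fieldBias))
  # per-family HK field biases at planted columns
  familyBias <- lapply(seq_len(nFamilies), function(f) {
    b <- matrix(0, L, q)
    b[cbind(hkCols, combosHK[, f])] <- fieldBias
    b
  })
  # exact factorised sampling, family by family
  M <- MPerFamily * nFamilies
  paired <- matrix(0L, M, L)
  fam <- rep(seq_len(nFamilies), each = MPerFamily)
  freeCols <- setdiff(seq_len(L), c(hkCols, rrCols))
  for (i in freeCols) {
    p <- exp(fieldsM[i, ]); p <- p / sum(p)
    paired[, i] <- sample.int(q, M, replace = TRUE, prob = p)
  }
  for (f in seq_len(nFamilies)) {
    rows <- which(fam == f)
    for (p in seq_len(nInterfacePairs)) {
      i <- hkCols[p]; j <- rrCols[p]
      logits <- outer(fieldsM[i, ] + familyBias[[f]][i, ], fieldsM[j, ], `+`)
      logits[cbind(combosHK[p, ], combosRR[p, ])] <-
        logits[cbind(combosHK[p, ], combosRR[p, ])] + couplingStrength
      pr <- exp(logits - max(logits)); pr <- pr / sum(pr)
      draw <- sample.int(q * q, length(rows), replace = TRUE, prob = as.vector(pr))
      paired[rows, i] <- ((draw - 1L) %% q) + 1L
      paired[rows, j] <- ((draw - 1L) %/% q) + 1L
    }
  }
  ids <- sprintf("fam%d_seq%d", fam, sequence(rep(MPerFamily, nFamilies)))
  syms <- alphabetSymbols(alphabet)
  hkRows <- apply(paired[, seq_len(LHK), drop = FALSE], 1L,
                  function(r) paste(syms[r], collapse = ""))
  rrRows <- apply(paired[, LHK + seq_len(LRR), drop = FALSE], 1L,
                  function(r) paste(syms[r], collapse = ""))
  hkIds <- paste0(ids, "_hk"); rrIds <- paste0(ids, "_rr")
  mask <- new("ContactMask",
              pairs = data.frame(hk_col = hkCols, rr_col = rrCols,
                                 min_dist = NA_real_),
              cutoffA = Inf, metricTag = "planted",
              LHK = as.integer(LHK), LRR = as.integer(LRR))
  new("ToyWorld",
      hkAlignment = DomainAlignment(hkRows, ids = hkIds, domainTag = "HK"),
      rrAlignment = DomainAlignment(rrRows, ids = rrIds, domainTag = "RR"),
      pairs = data.frame(hk_id = hkIds, rr_id = rrIds,
                         stringsAsFactors = FALSE),
      mask = mask, model = model, familyBias = familyBias,
      families = data.frame(hk_id = hkIds, rr_id = rrIds, family = fam,
                            stringsAsFactors = FALSE),
      seed = as.integer(seed),
      params = list(nFamilies = nFamilies, LHK = LHK, LRR = LRR,
                    nInterfacePairs = nInterfacePairs,
                    couplingStrength = couplingStrength,
                    fieldBias = fieldBias, MPerFamily = MPerFamily,
                    backgroundFieldSD = backgroundFieldSD))
}

#' Family-consensus evaluation sets of a toy world
#'
#' Builds one representative HK and RR per family (column-wise modal state)
#' and the cognate map between them -- the organism-level inputs for
#' [specificityMatrix()] and [classifySelection()].
#'
#' @param world a [ToyWorld-class].
#' @return list: `hk`, `rr` ([DomainAlignment-class]s of one consensus row
#'   per family, ids `HK1..`, `RR1..`) and `cognates` (data.frame).
#' @export
toyConsensusSets <- function(world) {
  ab <- pottsAlphabet()
  consensusRows <- function(aln, famIds) {
    enc <- encodedStates(encodeAlignment(aln, ab))
    fams <- sort(unique(famIds))
    rows <- vapply(fams, function(f) {
      sub <- enc[famIds == f, , drop = FALSE]
      modal <- apply(sub, 2L, function(col) {
        tb <- tabulate(col, nbins = nStates(ab))
        which.max(tb)
      })
      paste(alphabetSymbols(ab)[modal], collapse = "")
    }, character(1))
    rows
  }
  famHK <- world@families$family[match(alnIds(world@hkAlignment),
                                       world@families$hk_id)]
  famRR <- world@families$family[match(alnIds(world@rrAlignment),
                                       world@families$rr_id)]
  fams <- sort(unique(world@families$family))
  hk <- DomainAlignment(consensusRows(world@hkAlignment, famHK),
                        ids = paste0("HK", fams), domainTag = "HK")
  rr <- DomainAlignment(consensusRows(world@rrAlignment, famRR),
                        ids = paste0("RR", fams), domainTag = "RR")
  list(hk = hk, rr = rr,
       cognates = data.frame(hk_id = paste0("HK", fams),
                             rr_id = paste0("RR", fams),
                             stringsAsFactors = FALSE))
}

#' Write a toy world to a directory
#'
#' FASTA alignments, TSV pair table, TSV planted mask and a JSON sidecar of
#' the generator parameters.
#'
#' @param world a [ToyWorld-class].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeToyWorld <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeAlignmentFasta(world@hkAlignment, file.path(dir, "hk.fasta"))
  writeAlignmentFasta(world@rrAlignment, file.path(dir, "rr.fasta"))
  writePairTable(world@pairs, file.path(dir, "pairs.tsv"))
  writeContactMask(world@mask, file.path(dir, "mask.tsv"))
  jsonlite::write_json(c(world@params, list(seed = world@seed)),
                       file.path(dir, "world.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
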