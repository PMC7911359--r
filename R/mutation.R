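## In-silico mutation of HK/RR sequences and incremental network rescoring.

#' Parse mutation specifications
#'
#' Text format `"<seq_id>:<pos><new_char>"`, e.g. `"cusR:74Q"` or
#' `"envZ:12-"` (gap introduction).  Positions are 1-based within the
#' concatenated HK+RR frame; the frame width never changes, so an
#' "insertion" is a substitution into a gap column.
#'
#' @param specs character vector of mutation strings.
#' @return data.frame (seq_id, position, new_char).
#' @export
parseMutationSpec <- function(specs) {
  m <- regmatches(specs, regexec("^([^:]+):([0-9]+)([A-Z-])$", specs))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad))
    stop("malformed mutation spec: ", specs[bad][1L],
         " (expected <seq_id>:<pos><new_char>)")
  data.frame(seq_id = vapply(m, `[`, "", 2L),
             position = as.integer(vapply(m, `[`, "", 3L)),
             new_char = vapply(m, `[`, "", 4L),
             stringsAsFactors = FALSE)
}

#' Apply substitutions to an encoded sequence row
#'
#' Width-preserving substitution-only semantics: `positions` index the row
#' (1-based), `newChars` are alphabet symbols (`-` introduces a gap).
#' Disjoint positions commute; a repeated position applies in order.
#'
#' @param row integer state vector (one encoded paired row, or a single
#'   domain row).
#' @param positions integer positions within the row.
#' @param newChars replacement characters (or integer states).
#' @param alphabet the [PottsAlphabet-class].
#' @return the mutated integer state vector (same width).
#' @export
applyMutations <- function(row, positions, newChars,
                           alphabet = pottsAlphabet()) {
  row <- as.integer(row)
  stopifnot(length(positions) == length(newChars))
  if (length(positions) == 0L) return(row)
  if (any(positions < 1L | positions > length(row)))
    stop("mutation position out of range 1..", length(row), ": ",
         positions[positions < 1L | positions > length(row)][1L])
  states <- if (is.numeric(newChars)) as.integer(newChars)
            else match(as.character(newChars), alphabetSymbols(alphabet))
  if (anyNA(states) || any(states < 1L | states > nStates(alphabet)))
    stop("mutation to a character outside the alphabet: ",
         paste(newChars[is.na(states)], collapse = ", "))
  for (k in seq_along(positions)) row[positions[k]] <- states[k]
  row
}

#' Exact H_TCS change of a single-position mutation
#'
#' Computed from only the terms that touch the mutated position:
#' Delta = -(h_i(b) - h_i(a)) - sum over mask pairs containing i of
#' (e(b, s_partner) - e(a, s_partner)).  Positions outside every mask pair
#' change the field term only.
#'
#' @param model a [PottsModel-class] on the concatenated frame.
#' @param mask a [ContactMask-class].
#' @param pairRow encoded concatenated wild-type row (length LHK + LRR).
#' @param position 1-based position in the concatenated frame.
#' @param newState integer state or alphabet character.
#' @param alphabet used when `newState` is a character.
#' @return scalar energy change H_TCS(mutant) - H_TCS(wild type).
#' @export
deltaHamiltonian <- function(model, mask, pairRow, position, newState,
                             alphabet = pottsAlphabet()) {
  pairRow <- as.integer(pairRow)
  L <- model@L; q <- model@q
  if (length(pairRow) != L) stop("row width ", length(pairRow), " != L = ", L)
  if (position < 1L || position > L)
    stop("position out of range 1..", L, ": ", position)
  b <- if (is.numeric(newState)) as.integer(newState)
       else match(as.character(newState), alphabetSymbols(alphabet))
  if (is.na(b) || b < 1L || b > q) stop("invalid new state: ", newState)
  a <- pairRow[position]
  if (a == b) return(0)
  d <- -(model@fields[position, b] - model@fields[position, a])
  mp <- maskPairs(mask)
  onHK <- mp[mp$hk_col == position, , drop = FALSE]
  for (j in onHK$rr_col) {
    blk <- couplingBlock(model, position, j)
    d <- d - (blk[b, pairRow[j]] - blk[a, pairRow[j]])
  }
  onRR <- mp[mp$rr_col == position, , drop = FALSE]
  for (i in onRR$hk_col) {
    blk <- couplingBlock(model, i, position)
    d <- d - (blk[pairRow[i], b] - blk[pairRow[i], a])
  }
  d
}

#' Rescore the specificity network after mutations
#'
#' Applies mutations to the named HK and/or RR sequences and recomputes only
#' the affected rows/columns of the wild-type [SpecificityMatrix-class];
#' every recomputed cell equals a from-scratch evaluation and untouched
#' cells are copied unchanged (delta exactly 0).  Multi-mutation changes are
#' evaluated by full re-evaluation of the affected row/column, since deltas
#' are not additive when mutated columns share a mask pair.
#'
#' @param wt wild-type [SpecificityMatrix-class].
#' @param cognate,null the models used to build `wt`.
#' @param mask the [ContactMask-class] used to build `wt`.
#' @param hkSet,rrSet the sequence sets used to build `wt`.
#' @param mutations data.frame (seq_id, position, new_char) from
#'   [parseMutationSpec()]; positions are in the concatenated frame for both
#'   HK and RR targets.
#' @param alphabet encoding alphabet.
#' @return a [MutationResult-class].
#' @export
rescoreAfterMutation <- function(wt, cognate, null, mask, hkSet, rrSet,
                                 mutations, alphabet = pottsAlphabet()) {
  hkStates <- asStateMatrix(hkSet, alphabet)
  rrStates <- asStateMatrix(rrSet, alphabet)
  LHK <- mask@LHK
  ids <- unique(mutations$seq_id)
  unknown <- setdiff(ids, c(rownames(hkStates), rownames(rrStates)))
  if (length(unknown)) stop("unknown sequence id: ", unknown[1L])
  for (id in ids) {
    mu <- mutations[mutations$seq_id == id, , drop = FALSE]
    if (id %in% rownames(hkStates)) {
      if (any(mu$position > LHK))
        stop("mutation position ", mu$position[mu$position > LHK][1L],
             " lies outside the HK block (1..", LHK, ") for HK ", id)
      hkStates[id, ] <- applyMutations(hkStates[id, ], mu$position,
                                       mu$new_char, alphabet)
    } else {
      if (any(mu$position <= LHK))
        stop("mutation position ", mu$position[mu$position <= LHK][1L],
             " lies inside the HK block for RR ", id,
             " (positions are in the concatenated frame)")
      rrStates[id, ] <- applyMutations(rrStates[id, ], mu$position - LHK,
                                       mu$new_char, alphabet)
    }
  }
  mutScores <- scores(wt)
  mutHK <- intersect(ids, rownames(hkStates))
  mutRR <- intersect(ids, rownames(rrStates))
  prov <- wt@provenance
  est <- if (!is.null(prov$nullEstimator)) prov$nullEstimator
         else "scrambled_model"
  rescore <- function(hs, rs) {
    sm <- specificityMatrix(cognate, null, mask,
                            hkStates[hs, , drop = FALSE],
                            rrStates[rs, , drop = FALSE],
                            nullEstimator = est,
                            repairRounds = prov$nullMeta$repairRounds %||% 25L,
                            repairSeed = prov$nullMeta$repairSeed %||% 1L,
                            checkProvenance = "none")
    scores(sm)
  }
  if (est == "empirical_repairing") {
    # the empirical null constant depends on the whole sequence sets, so a
    # mutation can shift every cell: recompute the full matrix
    mutScores <- rescore(rownames(mutScores), colnames(mutScores))
  } else {
    if (length(mutHK))
      mutScores[mutHK, ] <- rescore(mutHK, colnames(mutScores))
    if (length(mutRR))
      mutScores[, mutRR] <- rescore(rownames(mutScores), mutRR)
  }
  new("MutationResult",
      mutated = new("SpecificityMatrix", scores = mutScores,
                    provenance = c(prov, list(mutations = mutations))),
      deltas = mutScores - scores(wt), wt = wt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a mutation rescoring report as TSV
#'
#' One row per affected cell: hk_id, rr_id, wt_score, mut_score, delta.
#'
#' @param result a [MutationResult-class].
#' @param path output file.
#' @param allCells report every cell (default: changed cells only).
#' @return `path`, invisibly.
#' @export
writeMutationReport <- function(result, path, allCells = FALSE) {
  d <- result@deltas
  idx <- if (allCells) which(d == d, arr.ind = TRUE)
         else which(d != 0, arr.ind = TRUE)
  df <- data.frame(hk_id = rownames(d)[idx[, 1L]],
                   rr_id = colnames(d)[idx[, 2L]],
                   wt_score = scores(result@wt)[idx],
                   mut_score = scores(result@mutated)[idx],
                   delta = d[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
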