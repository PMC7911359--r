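## Interface-masked Hamiltonian specificity scores and selection
## classification.

checkPairWidths <- function(model, mask, hkSeq, rrSeq) {
  if (length(hkSeq) != mask@LHK)
    stop("HK sequence width ", length(hkSeq), " != LHK = ", mask@LHK)
  if (length(rrSeq) != mask@LRR)
    stop("RR sequence width ", length(rrSeq), " != LRR = ", mask@LRR)
  if (model@L != mask@LHK + mask@LRR)
    stop("model frame L = ", model@L, " does not match mask frame ",
         mask@LHK + mask@LRR)
}

#' Interface-masked Hamiltonian score H_TCS of one HK-RR pair
#'
#' The coupling term sums e_ij only over the inter-domain column pairs of
#' the structural contact mask, evaluated at the concatenated states; the
#' field term sums h_i over every concatenated position:
#' H_TCS = -sum_mask e_ij(A_i, A_j) - sum_i h_i(A_i).
#'
#' @param model a [PottsModel-class] on the concatenated frame.
#' @param mask a [ContactMask-class].
#' @param hkSeq,rrSeq integer state vectors of widths LHK and LRR (encode
#'   with [encodeAlignment()]).
#' @return a [ScoreComponents-class].
#' @export
htcs <- function(model, mask, hkSeq, rrSeq) {
  hkSeq <- as.integer(hkSeq); rrSeq <- as.integer(rrSeq)
  checkPairWidths(model, mask, hkSeq, rrSeq)
  q <- model@q
  s <- c(hkSeq, rrSeq)
  if (anyNA(s) || min(s) < 1L || max(s) > q)
    stop("encoded states must lie in 1..q")
  mp <- maskPairs(mask)
  coup <- if (nrow(mp)) {
    ii <- (mp$hk_col - 1L) * q + s[mp$hk_col]
    jj <- (mp$rr_col - 1L) * q + s[mp$rr_col]
    sum(model@couplings[cbind(ii, jj)])
  } else 0
  fld <- sum(model@fields[cbind(seq_len(model@L), s)])
  new("ScoreComponents", couplingSum = coup, fieldSum = fld,
      total = -coup - fld)
}

#' Specificity score H_TCS^specific of one HK-RR pair
#'
#' H_TCS evaluated with the cognate-trained model minus the null score of
#' the same pair, removing Hamiltonian contributions shared by all HK-RR
#' pairs.  Negative values indicate encoded interaction specificity, values
#' near zero shared attributes only, positive values loss of shared
#' attributes.  The default null evaluates the scrambled-trained model on
#' the same sequence pair.
#'
#' @param cognate cognate-trained [PottsModel-class].
#' @param null scrambled-trained null [PottsModel-class] (same L, q).
#' @param mask a [ContactMask-class].
#' @param hkSeq,rrSeq encoded sequences.
#' @param checkProvenance `"warn"` (default), `"error"` or `"none"` when the
#'   null model's provenance is not `"scrambled"`.
#' @return scalar H_TCS^specific.
#' @export
htcsSpecific <- function(cognate, null, mask, hkSeq, rrSeq,
                         checkProvenance = c("warn", "error", "none")) {
  checkProvenance <- match.arg(checkProvenance)
  if (null@provenance != "scrambled" && checkProvenance != "none") {
    msg <- paste0("null model provenance is '", null@provenance,
                  "', expected 'scrambled'")
    if (checkProvenance == "error") stop(msg) else warning(msg)
  }
  if (cognate@L != null@L || cognate@q != null@q)
    stop("cognate and null models must share L and q")
  htcs(cognate, mask, hkSeq, rrSeq)@total -
    htcs(null, mask, hkSeq, rrSeq)@total
}

## vectorised H_TCS of every HK x RR combination under one model:
## returns list(total = nHK x nRR matrix, fieldHK, fieldRR, coup)
htcsMatrixOneModel <- function(model, mask, hkStates, rrStates) {
  q <- model@q; LHK <- mask@LHK; LRR <- mask@LRR
  nH <- nrow(hkStates); nR <- nrow(rrStates)
  fHK <- vapply(seq_len(nH), function(h)
    sum(model@fields[cbind(seq_len(LHK), hkStates[h, ])]), numeric(1))
  fRR <- vapply(seq_len(nR), function(r)
    sum(model@fields[cbind(LHK + seq_len(LRR), rrStates[r, ])]), numeric(1))
  coup <- matrix(0, nH, nR)
  mp <- maskPairs(mask)
  for (k in seq_len(nrow(mp))) {
    i <- mp$hk_col[k]; j <- mp$rr_col[k]
    blk <- couplingBlock(model, i, j)
    coup <- coup + blk[hkStates[, i], rrStates[, j - LHK], drop = FALSE]
  }
  list(total = -coup - outer(fHK, fRR, `+`), coup = coup,
       fieldHK = fHK, fieldRR = fRR)
}

asStateMatrix <- function(x, alphabet = pottsAlphabet()) {
  if (is(x, "EncodedAlignment")) return(encodedStates(x))
  if (is(x, "DomainAlignment")) return(encodedStates(encodeAlignment(x, alphabet)))
  if (is.matrix(x)) return(x)
  stop("expected a DomainAlignment, EncodedAlignment or state matrix")
}

#' Organism-wide specificity matrix
#'
#' H_TCS^specific for every combination of the supplied HK and RR sequence
#' sets.  Deterministic given its inputs.  With
#' `nullEstimator = "empirical_repairing"` the null is instead the average
#' cognate-model H_TCS over `repairRounds` uniformly random HK-RR
#' re-pairings drawn from the supplied sets (one shared constant, seeded).
#'
#' @param cognate,null [PottsModel-class]s (null may be `NULL` for the
#'   empirical estimator).
#' @param mask a [ContactMask-class].
#' @param hkSet,rrSet [DomainAlignment-class]s / [EncodedAlignment-class]s /
#'   state matrices with row ids.
#' @param nullEstimator `"scrambled_model"` (default) or
#'   `"empirical_repairing"`.
#' @param repairRounds,repairSeed re-pairing draws and seed for the
#'   empirical estimator (default 25 draws).
#' @param checkProvenance see [htcsSpecific()].
#' @return a [SpecificityMatrix-class].
#' @export
specificityMatrix <- function(cognate, null, mask, hkSet, rrSet,
                              nullEstimator = c("scrambled_model",
                                                "empirical_repairing"),
                              repairRounds = 25L, repairSeed = 1L,
                              checkProvenance = "warn") {
  nullEstimator <- match.arg(nullEstimator)
  hkStates <- asStateMatrix(hkSet)
  rrStates <- asStateMatrix(rrSet)
  if (is.null(rownames(hkStates)) || is.null(rownames(rrStates)))
    stop("HK and RR sets must carry sequence ids")
  cog <- htcsMatrixOneModel(cognate, mask, hkStates, rrStates)
  if (nullEstimator == "scrambled_model") {
    if (!is(null, "PottsModel")) stop("null model required")
    if (null@provenance != "scrambled" && checkProvenance != "none") {
      msg <- paste0("null model provenance is '", null@provenance, "'")
      if (checkProvenance == "error") stop(msg) else warning(msg)
    }
    nul <- htcsMatrixOneModel(null, mask, hkStates, rrStates)$total
    sc <- cog$total - nul
  } else {
    set.seed(repairSeed)
    hs <- sample.int(nrow(hkStates), repairRounds, replace = TRUE)
    rs <- sample.int(nrow(rrStates), repairRounds, replace = TRUE)
    h0 <- mean(vapply(seq_len(repairRounds), function(k)
      htcs(cognate, mask, hkStates[hs[k], ], rrStates[rs[k], ])@total,
      numeric(1)))
    sc <- cog$total - h0
  }
  dimnames(sc) <- list(rownames(hkStates), rownames(rrStates))
  new("SpecificityMatrix", scores = sc,
      provenance = list(nullEstimator = nullEstimator,
                        cognateMeta = cognate@metadata,
                        nullMeta = if (is(null, "PottsModel"))
                          null@metadata else list(repairRounds = repairRounds,
                                                  repairSeed = repairSeed)))
}

#' Classify cognate pairs by positive / negative selection
#'
#' Highest specificity means the most negative score.  A cognate pair is
#' under positive selection iff the cognate RR is the strict row minimum of
#' its HK's scores, and under negative selection iff the cognate HK is the
#' strict column minimum of its RR's scores.  Either suffices for a
#' true-positive prediction; otherwise the pair is a false negative
#' (selection towards a non-cognate partner at least as strong).  Ties --
#' exact equality after rounding scores to 1e-9 -- defeat strictness and
#' thus never evidence selection.
#'
#' @param sm a non-empty [SpecificityMatrix-class].
#' @param cognates data.frame (hk_id, rr_id) or named character vector
#'   `rr_of_hk` (names = HK ids).
#' @return data.frame (hk_id, rr_id, positive, negative, verdict); cognate
#'   pairs whose ids are missing from the matrix are skipped and listed in
#'   `attr(, "skipped")`.
#' @export
classifySelection <- function(sm, cognates) {
  s <- scores(sm)
  if (length(s) == 0L) stop("empty specificity matrix")
  if (!is.data.frame(cognates))
    cognates <- data.frame(hk_id = names(cognates),
                           rr_id = as.character(cognates),
                           stringsAsFactors = FALSE)
  r <- round(s, 9)          # tie tolerance
  ok <- cognates$hk_id %in% rownames(s) & cognates$rr_id %in% colnames(s)
  skipped <- cognates[!ok, , drop = FALSE]
  cg <- cognates[ok, , drop = FALSE]
  pos <- logical(nrow(cg)); neg <- logical(nrow(cg))
  for (k in seq_len(nrow(cg))) {
    h <- cg$hk_id[k]; rr <- cg$rr_id[k]
    row <- r[h, ]; col <- r[, rr]
    pos[k] <- row[rr] < min(row[names(row) != rr], Inf)
    neg[k] <- col[h] < min(col[names(col) != h], Inf)
  }
  out <- data.frame(hk_id = cg$hk_id, rr_id = cg$rr_id,
                    positive = pos, negative = neg,
                    verdict = ifelse(pos | neg, "true_positive",
                                     "false_negative"),
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Sensitivity and selection-mode summary of classification calls
#'
#' Sensitivity = TP / (TP + FN) over the evaluated cognate pairs; the
#' reported "accuracy" equals the sensitivity because the scheme defines no
#' true negatives.  Selection-mode fractions (both, negative-only,
#' positive-only) are reported against both denominators: all evaluated
#' cognate pairs and the detected (true-positive) subset.
#'
#' @param calls data.frame from [classifySelection()].
#' @return named list: tp, fn, n_evaluated, sensitivity, accuracy,
#'   fraction_both, fraction_negative_only, fraction_positive_only (over
#'   evaluated pairs) and the `_of_detected` variants.
#' @export
validationMetrics <- function(calls) {
  stopifnot(nrow(calls) > 0L)
  tp <- sum(calls$verdict == "true_positive")
  fn <- sum(calls$verdict == "false_negative")
  n <- nrow(calls)
  both <- sum(calls$positive & calls$negative)
  negOnly <- sum(calls$negative & !calls$positive)
  posOnly <- sum(calls$positive & !calls$negative)
  sens <- tp / (tp + fn)
  list(tp = tp, fn = fn, n_evaluated = n,
       sensitivity = sens, accuracy = sens,
       fraction_both = both / n,
       fraction_negative_only = negOnly / n,
       fraction_positive_only = posOnly / n,
       fraction_both_of_detected = if (tp) both / tp else NA_real_,
       fraction_negative_only_of_detected = if (tp) negOnly / tp else NA_real_,
       fraction_positive_only_of_detected = if (tp) posOnly / tp else NA_real_)
}

#' Write selection calls as TSV
#' @param calls data.frame from [classifySelection()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSelectionCalls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
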