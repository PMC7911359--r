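## Alignment ingestion, encoding, filtering, pairing and scrambling.

#' Read a domain alignment from FASTA or Stockholm
#'
#' Pfam-style insert states -- lowercase letters and `.` -- are removed from
#' every row before the uniform-width check, so A2M/Stockholm dialect input
#' collapses to its match columns.  Gap characters `-` are preserved.
#'
#' @param path file path.
#' @param format `"auto"` (sniff the first non-blank line), `"fasta"` or
#'   `"stockholm"`.
#' @param domainTag tag for the resulting alignment (`"HK"`, `"RR"`,
#'   `"PAIRED"`).
#' @return a [DomainAlignment-class].
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "AC-DE", ">b", "ACGDE"), fa)
#' aln <- readAlignment(fa, domainTag = "HK")
#' alnWidth(aln)  # 5
#' @export
readAlignment <- function(path, format = c("auto", "fasta", "stockholm"),
                          domainTag = "HK") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 25L, warn = FALSE)
    first <- first[nzchar(trimws(first))]
    if (length(first) == 0L) stop("empty alignment file: ", path)
    format <- if (grepl("^# STOCKHOLM", first[1L])) "stockholm"
              else if (startsWith(first[1L], ">")) "fasta"
              else stop("unknown format: cannot sniff ", path)
  }
  rec <- switch(format,
    fasta = {
      ss <- Biostrings::readBStringSet(path)
      # keep only the first token of the description line as the id
      setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
    },
    stockholm = readStockholmRows(path))
  rows <- gsub("[a-z.]", "", rec)         # strip insert states
  rows <- chartr("~", "-", rows)          # rare gap dialect
  ids <- names(rec)
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ", ids[duplicated(ids)][1L])
  w <- nchar(rows)
  if (length(unique(w)) > 1L)
    stop("ragged alignment after insert removal; offending id: ",
         ids[w != w[1L]][1L])
  DomainAlignment(rows, ids = ids, domainTag = domainTag,
                  metadata = list(source = path, format = format))
}

## Minimal Stockholm parser: sequence lines only, multi-block aware.
## (Biostrings' Stockholm reader rejects the "." insert character of
## Pfam-dialect files, so rows are collected verbatim here.)
readStockholmRows <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^# STOCKHOLM", lines[1L]))
    stop("not a Stockholm file (missing '# STOCKHOLM' header): ", path)
  keep <- !grepl("^(#|//)", lines) & nzchar(trimws(lines))
  acc <- list()
  for (ln in lines[keep]) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) != 2L) stop("malformed Stockholm sequence line: ", ln)
    id <- parts[1L]
    acc[[id]] <- paste0(if (is.null(acc[[id]])) "" else acc[[id]], parts[2L])
  }
  if (length(acc) == 0L) stop("no sequences in Stockholm file: ", path)
  unlist(acc)
}

#' Write a domain alignment as FASTA
#' @param aln a [DomainAlignment-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAlignmentFasta <- function(aln, path) {
  Biostrings::writeXStringSet(aln@seqs, path)
  invisible(path)
}

#' Encode alignment rows to integer states
#'
#' Bijective on the 21 canonical symbols; every other character (ambiguous
#' residue codes B, Z, X, U, O, unknown letters) maps to the gap state so
#' that q stays at 21.
#'
#' @param aln a [DomainAlignment-class] or character vector of rows.
#' @param alphabet a [PottsAlphabet-class].
#' @return an [EncodedAlignment-class].
#' @export
encodeAlignment <- function(aln, alphabet = pottsAlphabet()) {
  rows <- if (is(aln, "DomainAlignment")) alnRows(aln) else aln
  ids <- names(rows)
  L <- if (length(rows)) nchar(rows[[1L]]) else 0L
  m <- matrix(gapState(alphabet), nrow = length(rows), ncol = L)
  if (length(rows)) {
    chars <- matrix(unlist(strsplit(rows, ""), use.names = FALSE),
                    nrow = length(rows), byrow = TRUE)
    idx <- match(chars, alphabetSymbols(alphabet))
    idx[is.na(idx)] <- gapState(alphabet)
    m[] <- idx
  }
  rownames(m) <- ids
  new("EncodedAlignment", states = m, alphabet = alphabet)
}

#' Decode integer states back to character rows
#' @param enc an [EncodedAlignment-class] or integer matrix/vector.
#' @param alphabet alphabet to use when `enc` is bare integers.
#' @return named character vector of rows.
#' @export
decodeAlignment <- function(enc, alphabet = pottsAlphabet()) {
  if (is(enc, "EncodedAlignment")) {
    alphabet <- enc@alphabet
    enc <- enc@states
  }
  if (is.null(dim(enc))) enc <- matrix(enc, nrow = 1L)
  syms <- alphabetSymbols(alphabet)
  out <- apply(enc, 1L, function(r) paste(syms[r], collapse = ""))
  setNames(out, rownames(enc))
}

#' Longest contiguous gap run per row
#' @param rows character vector of aligned rows.
#' @return integer vector of maximal `-` run lengths (0 if none).
#' @export
longestGapRun <- function(rows) {
  vapply(rows, function(r) {
    rl <- rle(strsplit(r, "")[[1L]] == "-")
    runs <- rl$lengths[rl$values]
    if (length(runs)) max(runs) else 0L
  }, integer(1), USE.NAMES = FALSE)
}

#' Exclude rows with long sequence gaps
#'
#' Removes every row whose gap content reaches `maxRun`: by default a
#' maximal contiguous run of `-` of length >= `maxRun` (reading "a sequence
#' gap of N residues" as one run); `mode = "total"` instead counts all gap
#' characters in the row.  The HisKA alignment of the reference pipeline
#' uses `maxRun = 5`, the REC alignment `maxRun = 6`.
#'
#' @param aln a [DomainAlignment-class].
#' @param maxRun integer >= 1; rows with gap run (or total) >= `maxRun` are
#'   removed.
#' @param mode `"run"` (contiguous, default) or `"total"`.
#' @return the filtered [DomainAlignment-class]; the removal report (id,
#'   longest_gap_run, n_gaps) is in `metadata(...)$removal_report`.
#' @export
filterByGapRun <- function(aln, maxRun, mode = c("run", "total")) {
  mode <- match.arg(mode)
  stopifnot(maxRun >= 1L)
  rows <- alnRows(aln)
  runs <- longestGapRun(rows)
  totals <- vapply(rows, function(r) sum(strsplit(r, "")[[1L]] == "-"),
                   integer(1), USE.NAMES = FALSE)
  crit <- if (mode == "run") runs else totals
  drop <- crit >= maxRun
  report <- data.frame(id = alnIds(aln)[drop],
                       longest_gap_run = runs[drop],
                       n_gaps = totals[drop],
                       stringsAsFactors = FALSE)
  md <- aln@metadata
  md$removal_report <- report
  md$gap_filter <- list(maxRun = maxRun, mode = mode)
  md$n_columns <- alnWidth(aln)
  DomainAlignment(rows[!drop], ids = alnIds(aln)[!drop],
                  domainTag = domainTag(aln), metadata = md)
}

#' Read / write a cognate pair table
#'
#' Two-column TSV (`hk_id`, `rr_id`); lines starting with `#` are comments.
#'
#' @param path file path.
#' @return data.frame with columns hk_id, rr_id.
#' @export
readPairTable <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("hk_id", "rr_id"))
  df$hk_id <- as.character(df$hk_id)
  df$rr_id <- as.character(df$rr_id)
  df
}

#' @rdname readPairTable
#' @param pairs data.frame with columns hk_id, rr_id.
#' @export
writePairTable <- function(pairs, path) {
  writeLines("# hk_id\trr_id", path)
  utils::write.table(pairs[, c("hk_id", "rr_id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE,
                     append = TRUE)
  invisible(path)
}

#' Concatenate cognate HK-RR pairs into the paired frame
#'
#' Row k of the output is the HK row named `pairs$hk_id[k]` followed by the
#' RR row named `pairs$rr_id[k]`; with the HisKA and REC domains this yields
#' the 67 + 112 = 179-column frame the couplings are inferred on.
#'
#' @param hk,rr [DomainAlignment-class]s of fixed width.
#' @param pairs data.frame (hk_id, rr_id); every id must resolve.
#' @param provenance `"cognate"` (default) or `"scrambled"`.
#' @return a [PairedAlignment-class]; row ids are `hk_id|rr_id`
#'   (made unique if the table repeats a combination).
#' @export
concatenatePairs <- function(hk, rr, pairs, provenance = "cognate") {
  hkRows <- alnRows(hk); rrRows <- alnRows(rr)
  badHK <- setdiff(pairs$hk_id, names(hkRows))
  if (length(badHK)) stop("unresolvable hk_id: ", badHK[1L])
  badRR <- setdiff(pairs$rr_id, names(rrRows))
  if (length(badRR)) stop("unresolvable rr_id: ", badRR[1L])
  LHK <- alnWidth(hk); LRR <- alnWidth(rr)
  rows <- paste0(hkRows[pairs$hk_id], rrRows[pairs$rr_id])
  ids <- make.unique(paste(pairs$hk_id, pairs$rr_id, sep = "|"), sep = "#")
  ss <- Biostrings::AAStringSet(if (length(rows)) rows else character(0))
  names(ss) <- ids
  new("PairedAlignment", seqs = ss, domainTag = "PAIRED",
      metadata = list(n_columns = LHK + LRR),
      LHK = as.integer(LHK), LRR = as.integer(LRR),
      pairTable = data.frame(hk_id = as.character(pairs$hk_id),
                             rr_id = as.character(pairs$rr_id),
                             stringsAsFactors = FALSE),
      provenance = provenance)
}

#' Build a scrambled (randomly re-paired) alignment
#'
#' In each of `rounds` passes every HK row appears exactly once, joined to
#' an RR drawn uniformly at random with replacement; the output therefore
#' has `rounds * nSequences(hk)` rows.  This is the null alignment the
#' scrambled Potts model (shared two-component attributes, no pair-specific
#' specificity) is trained on; the reference pipeline uses 25 rounds.
#'
#' @param hk,rr non-empty [DomainAlignment-class]s.
#' @param rounds number of passes (>= 1), default 25.
#' @param seed integer seed; recorded in the output metadata.
#' @return a [PairedAlignment-class] with `provenance = "scrambled"`.
#' @export
scramblePairs <- function(hk, rr, rounds = 25L, seed = 1L) {
  stopifnot(rounds >= 1L, nSequences(hk) > 0L, nSequences(rr) > 0L)
  set.seed(seed)
  hkIds <- alnIds(hk); rrIds <- alnIds(rr)
  pairs <- do.call(rbind, lapply(seq_len(rounds), function(r) {
    data.frame(hk_id = hkIds,
               rr_id = rrIds[sample.int(length(rrIds), length(hkIds),
                                        replace = TRUE)],
               stringsAsFactors = FALSE)
  }))
  out <- concatenatePairs(hk, rr, pairs, provenance = "scrambled")
  out@metadata$scramble <- list(rounds = rounds, seed = seed)
  out
}
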