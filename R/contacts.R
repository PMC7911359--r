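## Template-structure parsing and interface contact-mask construction.

#' Parse a template complex structure (PDB)
#'
#' Reads ATOM records (HETATM ignored by default), keeps the first MODEL
#' only, drops hydrogens, and resolves alternate locations to the
#' highest-occupancy conformer (ties go to altloc `A`).
#'
#' @param path PDB file.
#' @param includeHet also keep HETATM records.
#' @return named list of [StructureChain-class], one per chain.
#' @export
parseStructure <- function(path, includeHet = FALSE) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("malformed PDB file ", path, ": ",
                             conditionMessage(e)))
  at <- pdb$atom
  if (!includeHet) at <- at[at$type == "ATOM", , drop = FALSE]
  # drop hydrogens (element symbol H or D)
  elt <- toupper(trimws(at$elesy))
  unknown <- is.na(elt) | elt == ""
  if (any(unknown))    # fall back on atom-name heuristics
    elt[unknown] <- sub("^[0-9]*([A-Z]).*", "\\1", toupper(trimws(at$elety[unknown])))
  at <- at[!elt %in% c("H", "D"), , drop = FALSE]
  if (nrow(at) == 0L) stop("no heavy atoms in ", path)
  # altloc: keep highest occupancy per (chain, resno, atom name); ties -> 'A'
  alt <- at$alt; alt[is.na(alt)] <- ""
  occ <- at$o; occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$elety, sep = "\r")
  pos <- seq_len(nrow(at))
  ord <- order(key, -occ, alt)      # best conformer first within each key
  keep <- sort(pos[ord][!duplicated(key[ord])])   # original file order
  at <- at[keep, , drop = FALSE]
  chains <- split(at, at$chain)
  out <- lapply(names(chains), function(ch) {
    a <- chains[[ch]]
    a <- a[order(a$resno), , drop = FALSE]        # stable: file order within
    new("StructureChain", chainId = ch,
        atoms = data.frame(resno = a$resno, resid = a$resid,
                           atom = trimws(a$elety),
                           x = a$x, y = a$y, z = a$z,
                           stringsAsFactors = FALSE))
  })
  setNames(out, names(chains))
}

#' Interfacial residue contacts between two chains
#'
#' A residue pair is a contact iff its inter-residue distance is strictly
#' below `cutoffA` (the step function of the masking score is 0 at exactly
#' the cutoff).  The default distance is the minimum over heavy-atom pairs;
#' `metric = "ca"` / `"cb"` restrict to the respective backbone/side-chain
#' carbons (residues lacking the atom are skipped).  The reference template
#' is the HK853-RR468 complex with `cutoffA = 12`.
#'
#' @param a,b [StructureChain-class]s.
#' @param cutoffA positive distance cutoff in Angstrom.
#' @param metric `"min"` (heavy-atom minimum, default), `"ca"` or `"cb"`.
#' @return data.frame (res_a, res_b, dist) of contacting residue numbers.
#' @export
interfaceContacts <- function(a, b, cutoffA = 12, metric = c("min", "ca", "cb")) {
  metric <- match.arg(metric)
  stopifnot(cutoffA > 0)
  pick <- function(ch) {
    at <- ch@atoms
    if (metric == "ca") at <- at[at$atom == "CA", , drop = FALSE]
    if (metric == "cb") at <- at[at$atom == "CB", , drop = FALSE]
    at
  }
  atA <- pick(a); atB <- pick(b)
  if (nrow(atA) == 0L || nrow(atB) == 0L) {
    warning("empty chain (or no ", metric, " atoms); no contacts")
    return(data.frame(res_a = integer(0), res_b = integer(0),
                      dist = numeric(0)))
  }
  XA <- as.matrix(atA[, c("x", "y", "z")])
  XB <- as.matrix(atB[, c("x", "y", "z")])
  d2 <- outer(rowSums(XA^2), rowSums(XB^2), `+`) - 2 * tcrossprod(XA, XB)
  d2[d2 < 0] <- 0
  # minimum atom-atom distance per residue pair
  ra <- factor(atA$resno); rb <- factor(atB$resno)
  dmin <- matrix(Inf, nlevels(ra), nlevels(rb),
                 dimnames = list(levels(ra), levels(rb)))
  ia <- as.integer(ra); ib <- as.integer(rb)
  for (k in seq_len(nrow(XA))) {
    row <- sqrt(d2[k, ])
    agg <- tapply(row, ib, min)
    dmin[ia[k], ] <- pmin(dmin[ia[k], ], agg)
  }
  hit <- which(dmin < cutoffA, arr.ind = TRUE)
  out <- data.frame(res_a = as.integer(rownames(dmin)[hit[, 1L]]),
                    res_b = as.integer(colnames(dmin)[hit[, 2L]]),
                    dist = dmin[hit])
  out[order(out$res_a, out$res_b), , drop = FALSE]
}

#' Read a structure-residue to alignment-column mapping
#'
#' Two-column TSV `residue_number -> column` (1-based columns within the
#' domain block); `#` comments allowed.
#'
#' @param path TSV file.
#' @return named integer vector: names are residue numbers, values columns.
#' @export
readTemplateMapping <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          col.names = c("resno", "column"))
  map <- as.integer(df$column)
  names(map) <- as.character(df$resno)
  if (anyDuplicated(names(map)) || anyDuplicated(map))
    stop("template mapping must be injective: ", path)
  map
}

#' Project residue contacts onto paired-alignment columns
#'
#' HK-side residues map into columns 1..LHK, RR-side residues into
#' LHK+1..LHK+LRR of the concatenated frame (the RR mapping is given within
#' the RR block and offset here).  Contacts with an unmapped endpoint are
#' dropped and reported.
#'
#' @param contacts data.frame (res_a, res_b, dist) with res_a on the HK
#'   chain and res_b on the RR chain.
#' @param hkMap,rrMap named integer vectors from [readTemplateMapping()]
#'   (values are 1-based columns within each domain block).
#' @param LHK,LRR block widths of the target frame.
#' @param cutoffA,metricTag recorded on the mask.
#' @return a [ContactMask-class]; dropped contacts are in
#'   `metadata`-style attribute `attr(, "dropped")`.
#' @export
mapContactsToColumns <- function(contacts, hkMap, rrMap, LHK, LRR,
                                 cutoffA = 12, metricTag = "min-heavy-atom") {
  ci <- hkMap[as.character(contacts$res_a)]
  cj <- rrMap[as.character(contacts$res_b)]
  ok <- !is.na(ci) & !is.na(cj)
  pairs <- data.frame(hk_col = as.integer(ci[ok]),
                      rr_col = as.integer(cj[ok]) + as.integer(LHK),
                      min_dist = if ("dist" %in% names(contacts))
                        contacts$dist[ok] else NA_real_)
  pairs <- pairs[!duplicated(pairs[, c("hk_col", "rr_col")]), , drop = FALSE]
  pairs <- pairs[order(pairs$hk_col, pairs$rr_col), , drop = FALSE]
  rownames(pairs) <- NULL
  mask <- new("ContactMask", pairs = pairs, cutoffA = cutoffA,
              metricTag = metricTag, LHK = as.integer(LHK),
              LRR = as.integer(LRR))
  attr(mask, "dropped") <- contacts[!ok, , drop = FALSE]
  mask
}

#' Count top-k DI pairs inside the interface mask
#'
#' Restricts the DI ranking to inter-domain pairs (i <= LHK < j), takes the
#' top `k` by DI (ties lexicographic), and counts how many fall inside the
#' contact mask.
#'
#' @param mask a [ContactMask-class].
#' @param di a [DIMatrix-class] on the same concatenated frame.
#' @param k number of top pairs to test (>= 1).
#' @return integer in 0..k.
#' @export
overlapWithTopDI <- function(mask, di, k) {
  stopifnot(k >= 1L)
  r <- di@ranking
  r <- r[r$i <= mask@LHK & r$j > mask@LHK &
         r$j <= mask@LHK + mask@LRR, , drop = FALSE]
  top <- utils::head(r, k)
  mp <- maskPairs(mask)
  sum(paste(top$i, top$j) %in% paste(mp$hk_col, mp$rr_col))
}

#' Write / read a contact mask as TSV
#'
#' Columns `hk_col`, `rr_col`, `min_dist_A`, 1-based in the concatenated
#' frame; header comments record the cutoff, metric and frame widths.
#'
#' @param mask a [ContactMask-class].
#' @param path TSV file.
#' @return `path` (write) or a [ContactMask-class] (read).
#' @export
writeContactMask <- function(mask, path) {
  con <- file(path, "w")
  writeLines(sprintf("# cutoff_A=%s metric=%s LHK=%d LRR=%d",
                     format(mask@cutoffA), mask@metricTag, mask@LHK,
                     mask@LRR), con)
  writeLines("# hk_col\trr_col\tmin_dist_A", con)
  p <- maskPairs(mask)
  utils::write.table(data.frame(p$hk_col, p$rr_col,
                                if (is.null(p$min_dist)) NA else p$min_dist),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname writeContactMask
#' @export
readContactMask <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec(
    "cutoff_A=(\\S+) metric=(\\S+) LHK=([0-9]+) LRR=([0-9]+)", hdr))[[1L]]
  if (length(m) != 5L) stop("missing mask header in ", path)
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          col.names = c("hk_col", "rr_col", "min_dist"))
  new("ContactMask",
      pairs = data.frame(hk_col = as.integer(df$hk_col),
                         rr_col = as.integer(df$rr_col),
                         min_dist = as.numeric(df$min_dist)),
      cutoffA = as.numeric(m[2L]), metricTag = m[3L],
      LHK = as.integer(m[4L]), LRR = as.integer(m[5L]))
}
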