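## Config-driven pipeline and the CSV/PNG export surfaces.

#' Load and validate a pipeline run configuration
#'
#' A single YAML (or JSON) document with paths (`hk_alignment`,
#' `rr_alignment`, `pair_table`, and either `mask` or `structure` +
#' `hk_mapping` + `rr_mapping`), parameters (`identity_threshold`,
#' `lambda_relative`, `cutoff_A`, `scramble_rounds`, `seed`, `hk_max_gap_run`,
#' `rr_max_gap_run`, `null_estimator`) and an `output_dir`.  Optional
#' `hk_eval` / `rr_eval` alignments give the organism-level sequence sets the
#' specificity matrix is computed over (default: the filtered training
#' alignments), with `cognate_table` naming their cognate pairs (default:
#' `pair_table` restricted to the evaluation ids).  Unset parameters take
#' the documented defaults.
#'
#' @param path YAML/JSON config file, or a named list.
#' @return validated config list (class `tcsRunConfig`).
#' @export
readRunConfig <- function(path) {
  cfg <- if (is.list(path)) path
         else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  defaults <- list(identity_threshold = 0.8, lambda_relative = 1.0,
                   cutoff_A = 12, scramble_rounds = 25L, seed = 1L,
                   hk_max_gap_run = 5L, rr_max_gap_run = 6L,
                   contact_metric = "min",
                   null_estimator = "scrambled_model",
                   null_reweight = FALSE,
                   di_inter_domain_only = TRUE,
                   mutations = character(0))
  cfg <- utils::modifyList(defaults, cfg)
  for (p in c("hk_alignment", "rr_alignment", "pair_table"))
    if (is.null(cfg[[p]])) stop("config is missing required path: ", p)
  if (is.null(cfg$mask) &&
      (is.null(cfg$structure) || is.null(cfg$hk_mapping) ||
       is.null(cfg$rr_mapping)))
    stop("config needs either 'mask' or 'structure' + 'hk_mapping' + 'rr_mapping'")
  if (is.null(cfg$output_dir)) stop("config is missing output_dir")
  for (p in intersect(c("hk_alignment", "rr_alignment", "pair_table", "mask",
                        "structure", "hk_mapping", "rr_mapping",
                        "hk_eval", "rr_eval", "cognate_table"), names(cfg)))
    if (!file.exists(cfg[[p]])) stop("config path does not exist: ", cfg[[p]])
  stopifnot(cfg$identity_threshold > 0, cfg$identity_threshold <= 1,
            cfg$lambda_relative >= 0, cfg$cutoff_A > 0,
            cfg$scramble_rounds >= 1,
            cfg$null_estimator %in% c("scrambled_model", "empirical_repairing"))
  class(cfg) <- c("tcsRunConfig", "list")
  cfg
}

#' Run the full specificity pipeline from a config
#'
#' Reads and gap-filters the domain alignments, concatenates cognate pairs,
#' infers the cognate and scrambled-null Potts models by mean-field DCA,
#' builds (or loads) the interface contact mask, scores direct information,
#' computes the organism-wide specificity matrix, classifies cognate pairs
#' by positive/negative selection, applies any configured mutations, and
#' writes every artifact plus an effective-config snapshot and a plain-text
#' log to `output_dir`.  Re-running an identical config reproduces the
#' numeric artifacts byte for byte.
#'
#' @param config path to a YAML/JSON config or a list (see
#'   [readRunConfig()]).
#' @return invisibly, a list of the in-memory results
#'   (models, mask, di, specificity, calls, metrics, paths).
#' @export
runPipeline <- function(config) {
  cfg <- if (inherits(config, "tcsRunConfig")) config else readRunConfig(config)
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(out, "run.log")
  logCon <- file(logPath, "w")
  on.exit(close(logCon), add = TRUE)
  t0 <- proc.time()[["elapsed"]]
  logStage <- function(stage, ...) {
    msg <- sprintf("[%7.2fs] %s %s", proc.time()[["elapsed"]] - t0, stage,
                   paste0(..., collapse = ""))
    writeLines(msg, logCon); flush(logCon)
  }
  fail <- function(stage, e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  stage <- function(name, expr) {
    r <- tryCatch(expr, error = function(e) fail(name, e))
    logStage(name, "")
    r
  }
  logStage("start", sprintf("tcsdca %s, seed=%d",
                            as.character(utils::packageVersion("tcsdca")),
                            cfg$seed))
  yaml::write_yaml(unclass(cfg), file.path(out, "effective-config.yaml"))

  hk <- stage("read-hk", readAlignment(cfg$hk_alignment, domainTag = "HK"))
  rr <- stage("read-rr", readAlignment(cfg$rr_alignment, domainTag = "RR"))
  hk <- stage("filter-hk", filterByGapRun(hk, cfg$hk_max_gap_run))
  rr <- stage("filter-rr", filterByGapRun(rr, cfg$rr_max_gap_run))
  write.table(hk@metadata$removal_report, file.path(out, "hk_removed.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(rr@metadata$removal_report, file.path(out, "rr_removed.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  pairs <- stage("read-pairs", readPairTable(cfg$pair_table))
  pairs <- pairs[pairs$hk_id %in% alnIds(hk) & pairs$rr_id %in% alnIds(rr), ]
  paired <- stage("concatenate", concatenatePairs(hk, rr, pairs))
  ab <- pottsAlphabet()
  enc <- encodeAlignment(paired, ab)
  w <- stage("weights", computeWeights(enc, cfg$identity_threshold))
  logStage("weights", sprintf("Meff=%.1f of M=%d", w$Meff, nSequences(paired)))
  fr <- stage("frequencies",
              countFrequencies(enc, w$weights,
                               lambda = cfg$lambda_relative * w$Meff))
  cognate <- stage("fit-cognate", fitMFDCA(fr, provenance = "cognate"))
  scr <- stage("scramble", scramblePairs(hk, rr, rounds = cfg$scramble_rounds,
                                         seed = cfg$seed))
  encS <- encodeAlignment(scr, ab)
  wS <- if (isTRUE(cfg$null_reweight))
          stage("weights-null", computeWeights(encS, cfg$identity_threshold))
        else list(weights = rep(1, nSequences(scr)), Meff = nSequences(scr))
  frS <- stage("frequencies-null",
               countFrequencies(encS, wS$weights,
                                lambda = cfg$lambda_relative * wS$Meff))
  null <- stage("fit-null", fitMFDCA(frS, provenance = "scrambled"))
  writePottsModel(cognate, file.path(out, "model_cognate.rds"))
  writePottsModel(null, file.path(out, "model_scrambled.rds"))

  mask <- stage("mask", {
    if (!is.null(cfg$mask)) readContactMask(cfg$mask)
    else {
      chains <- parseStructure(cfg$structure)
      if (length(chains) < 2L) stop("structure must contain >= 2 chains")
      hkCh <- cfg$hk_chain %||% names(chains)[1L]
      rrCh <- cfg$rr_chain %||% names(chains)[2L]
      contacts <- interfaceContacts(chains[[hkCh]], chains[[rrCh]],
                                    cutoffA = cfg$cutoff_A,
                                    metric = cfg$contact_metric)
      mapContactsToColumns(contacts, readTemplateMapping(cfg$hk_mapping),
                           readTemplateMapping(cfg$rr_mapping),
                           LHK = alnWidth(hk), LRR = alnWidth(rr),
                           cutoffA = cfg$cutoff_A)
    }
  })
  writeContactMask(mask, file.path(out, "mask_used.tsv"))

  di <- stage("direct-information", {
    dipairs <- if (isTRUE(cfg$di_inter_domain_only)) {
      eg <- expand.grid(i = seq_len(mask@LHK),
                        j = mask@LHK + seq_len(mask@LRR))
      as.matrix(eg[order(eg$i, eg$j), ])
    } else NULL
    directInformation(cognate, fr, pairs = dipairs)
  })
  writeDITable(di, file.path(out, "di.tsv"))

  hkEval <- if (is.null(cfg$hk_eval)) hk
            else stage("read-hk-eval", readAlignment(cfg$hk_eval,
                                                     domainTag = "HK"))
  rrEval <- if (is.null(cfg$rr_eval)) rr
            else stage("read-rr-eval", readAlignment(cfg$rr_eval,
                                                     domainTag = "RR"))
  cognatePairs <- if (is.null(cfg$cognate_table)) pairs
                  else stage("read-cognates", readPairTable(cfg$cognate_table))
  sm <- stage("specificity",
              specificityMatrix(cognate, null, mask, hkEval, rrEval,
                                nullEstimator = cfg$null_estimator,
                                repairSeed = cfg$seed))
  writeSpecificityMatrix(sm, file.path(out, "specificity.csv"))
  writeSpecificityLong(sm, file.path(out, "specificity_long.tsv"))

  calls <- stage("classify", classifySelection(sm, cognatePairs))
  writeSelectionCalls(calls, file.path(out, "selection_calls.tsv"))
  metrics <- validationMetrics(calls)
  jsonlite::write_json(metrics, file.path(out, "validation_summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  mutResult <- NULL
  if (length(cfg$mutations)) {
    mutResult <- stage("mutate", {
      specs <- parseMutationSpec(unlist(cfg$mutations))
      rescoreAfterMutation(sm, cognate, null, mask, hkEval, rrEval, specs)
    })
    writeMutationReport(mutResult, file.path(out, "mutation_report.tsv"))
    writeSpecificityMatrix(mutResult@mutated,
                           file.path(out, "specificity_mutated.csv"))
  }
  logStage("done", "")
  invisible(list(config = cfg, cognate = cognate, null = null, mask = mask,
                 di = di, specificity = sm, calls = calls, metrics = metrics,
                 mutation = mutResult, outputDir = out))
}

#' Write a specificity matrix as wide CSV
#'
#' Header row = RR ids, first column = HK ids, values at 9 decimal places
#' (so CSV export/import is lossless at the 1e-9 score tolerance).
#'
#' @param sm a [SpecificityMatrix-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSpecificityMatrix <- function(sm, path) {
  s <- scores(sm)
  txt <- matrix(sprintf("%.9f", s), nrow(s), dimnames = dimnames(s))
  df <- data.frame(hk_id = rownames(s), txt, check.names = FALSE)
  colnames(df) <- c("hk_id", colnames(s))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpecificityMatrix
#' @export
writeSpecificityLong <- function(sm, path) {
  s <- scores(sm)
  df <- data.frame(hk_id = rep(rownames(s), times = ncol(s)),
                   rr_id = rep(colnames(s), each = nrow(s)),
                   score = sprintf("%.9f", as.vector(s)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export specificity scores as comma-delimited rows
#'
#' One data row `hk_id,rr_id,score` per exported cell (9 decimals); the full
#' matrix when no selection is given.  When a mutated matrix is supplied the
#' mutated values are exported.
#'
#' @param sm a [SpecificityMatrix-class] (wild-type or mutated).
#' @param path output CSV.
#' @param selection optional data.frame (hk_id, rr_id) of cells to export.
#' @return `path`, invisibly.
#' @export
exportCSV <- function(sm, path, selection = NULL) {
  s <- scores(sm)
  if (is.null(selection)) {
    selection <- expand.grid(hk_id = rownames(s), rr_id = colnames(s),
                             stringsAsFactors = FALSE)
    selection <- selection[order(match(selection$hk_id, rownames(s)),
                                 match(selection$rr_id, colnames(s))), ]
  }
  if (!all(selection$hk_id %in% rownames(s)) ||
      !all(selection$rr_id %in% colnames(s)))
    stop("selection refers to ids absent from the matrix")
  df <- data.frame(hk_id = selection$hk_id, rr_id = selection$rr_id,
                   score = sprintf("%.9f",
                                   s[cbind(selection$hk_id, selection$rr_id)]))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname exportCSV
#' @export
readSpecificityCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$score <- as.numeric(df$score)
  df
}

## diverging palette saturating symmetrically: strongly negative
## (favourable) and strongly positive (unfavourable) cells are emphasised
specificityPalette <- function(n = 255L) {
  grDevices::colorRampPalette(c("#08306b", "#4292c6", "#f7f7f7",
                                "#ef6548", "#7f0000"))(n)
}

#' Export the specificity heatmap as PNG
#'
#' Diverging colour scale, symmetric about zero and saturating at the
#' largest absolute score, with HK/RR labels and a legend strip.
#'
#' @param sm a non-empty [SpecificityMatrix-class].
#' @param path output PNG.
#' @param width,height device size in pixels.
#' @return `path`, invisibly.
#' @export
exportHeatmap <- function(sm, path, width = 800L, height = 600L) {
  s <- scores(sm)
  if (length(s) == 0L) stop("empty specificity matrix")
  lim <- max(abs(s), 1e-12)
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::layout(matrix(1:2, ncol = 2), widths = c(5, 1))
  graphics::par(mar = c(6, 6, 2, 1))
  graphics::image(seq_len(ncol(s)), seq_len(nrow(s)), t(s)[, rev(seq_len(nrow(s))), drop = FALSE],
                  col = specificityPalette(), zlim = c(-lim, lim),
                  axes = FALSE, xlab = "", ylab = "")
  graphics::axis(1, at = seq_len(ncol(s)), labels = colnames(s), las = 2)
  graphics::axis(2, at = seq_len(nrow(s)), labels = rev(rownames(s)), las = 1)
  graphics::title(main = "H_TCS specific")
  graphics::par(mar = c(6, 1, 2, 3))
  zseq <- seq(-lim, lim, length.out = 255L)
  graphics::image(1, zseq, matrix(zseq, nrow = 1),
                  col = specificityPalette(), axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4, las = 1)
  invisible(path)
}

#' Export the partner-score histogram of one protein as PNG
#'
#' For an HK id, bars show its specificity towards every RR (labelled by RR
#' id); for an RR id, towards every HK.
#'
#' @param sm a [SpecificityMatrix-class].
#' @param id an HK or RR identifier present in the matrix.
#' @param path output PNG.
#' @param width,height device size in pixels.
#' @return `path`, invisibly; partner labels are attached as
#'   `attr(, "labels")`.
#' @export
exportHistogram <- function(sm, id, path, width = 800L, height = 500L) {
  s <- scores(sm)
  if (id %in% rownames(s)) {
    vals <- s[id, ]; labs <- colnames(s)
  } else if (id %in% colnames(s)) {
    vals <- s[, id]; labs <- rownames(s)
  } else stop("unknown id: ", id)
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(7, 5, 3, 1))
  graphics::barplot(vals, names.arg = labs, las = 2,
                    col = ifelse(vals < 0, "#4292c6", "#ef6548"),
                    ylab = "H_TCS specific",
                    main = paste("Specificity of", id))
  graphics::abline(h = 0)
  out <- path
  attr(out, "labels") <- labs
  invisible(out)
}
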