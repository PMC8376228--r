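# File-based orchestration: read inputs named by a flat config, run the
# inference, write the scored table and reports plus a machine-readable
# run manifest.

#' Run the end-to-end inference pipeline from files
#'
#' Reads the per-source PPI tables, the annotation table and the
#' gold-standard DDI table named in `config`, runs [ddi_infer()], and
#' writes to `outdir`: `scored_ddis.tsv`, `calibration_report.tsv`,
#' `weights_report.tsv`, `category_summary.tsv` and `manifest.json`
#' (parameters, seeds and input checksums). A completed output directory
#' (one containing a manifest) is not recomputed unless `force = TRUE`.
#'
#' Recognised config keys: `sources` (named mapping source -> PPI file, or
#' `source_names` + `source_files` lists), `annotations`, `gold_standard`,
#' `alpha`, `half_cutoff`, `weights` (named mapping, optional),
#' `weight_strategy`, `restarts`, `negative_sample_size`, `folds`,
#' `train_fraction`, `seed`. Arguments passed directly to this function
#' override their config keys.
#'
#' @param config Path to a flat YAML config or an equivalent named list.
#' @param outdir Output directory.
#' @param force Recompute even when outputs already exist.
#' @param ... Overrides for individual config keys.
#' @return The `ddi_fit`, invisibly (or `NULL` when a completed run was
#'   skipped).
#' @export
run_pipeline <- function(config, outdir, force = FALSE, ...) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  over <- list(...)
  cfg[names(over)] <- over
  manifest_path <- file.path(outdir, "manifest.json")
  if (file.exists(manifest_path) && !force) {
    message("output directory already contains a completed run; use force = TRUE to recompute")
    return(invisible(NULL))
  }
  if (!is.null(cfg$source_names)) {
    cfg$sources <- stats::setNames(as.list(cfg$source_files), cfg$source_names)
  }
  req <- c("sources", "annotations", "gold_standard")
  miss <- setdiff(req, names(cfg))
  if (length(miss) > 0L) {
    stop("missing config keys: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  src_files <- unlist(cfg$sources)
  inputs <- c(src_files, annotations = cfg$annotations,
              gold_standard = cfg$gold_standard)
  absent <- inputs[!file.exists(inputs)]
  if (length(absent) > 0L) {
    stop("input file(s) not found: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  sources <- stage("read_sources",
                   lapply(cfg$sources, read_ppi_table))
  annotations <- stage("read_annotations", read_annotations(cfg$annotations))
  gold <- stage("read_gold_standard", read_ddi_table(cfg$gold_standard))
  arg <- function(key, default) if (is.null(cfg[[key]])) default else cfg[[key]]
  weights <- cfg$weights
  if (!is.null(weights)) weights <- unlist(weights)
  fit <- stage("infer", ddi_infer(
    sources, annotations, gold,
    alpha = arg("alpha", 0.05),
    weights = weights,
    weight_strategy = arg("weight_strategy", "coordinate_ascent"),
    restarts = arg("restarts", 3L),
    half_cutoff = cfg$half_cutoff,
    negative_sample_size = cfg$negative_sample_size,
    folds = arg("folds", 5L),
    train_fraction = arg("train_fraction", 2 / 3),
    seed = arg("seed", 1L)))

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage("write_outputs", {
    write_scored_ddis(fit$scored, file.path(outdir, "scored_ddis.tsv"))
    cal <- fit$calibration
    utils::write.table(
      data.frame(metric = c(paste0("fold_threshold_", seq_along(cal$fold_thresholds)),
                            "t_m", "f1_train", "f1_test",
                            "precision_test", "recall_test"),
                 value = c(cal$fold_thresholds, cal$t_m, cal$f1_train,
                           cal$f1_test, cal$precision_test, cal$recall_test)),
      file.path(outdir, "calibration_report.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(source = names(fit$weights), weight = as.numeric(fit$weights),
                 auc = fit$auc),
      file.path(outdir, "weights_report.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    smry <- attr(fit$scored, "summary")
    utils::write.table(
      data.frame(category = rownames(smry),
                 total = as.integer(rowSums(smry)),
                 in_gold_standard = as.integer(smry[, "in_gold_standard"])),
      file.path(outdir, "category_summary.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(
      package = "ddinfer",
      version = as.character(utils::packageVersion("ddinfer")),
      seed = arg("seed", 1L),
      alpha = arg("alpha", 0.05),
      weight_strategy = arg("weight_strategy", "coordinate_ascent"),
      weights = as.list(fit$weights),
      auc = fit$auc,
      t_m = fit$calibration$t_m,
      n_candidates = length(fit$consensus),
      n_retained = nrow(fit$scored),
      input_md5 = as.list(tools::md5sum(inputs))
    ), manifest_path, auto_unbox = TRUE, digits = NA)
  })
  invisible(fit)
}
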