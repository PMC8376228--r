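# The central estimator: from per-source PPI lists, protein-domain
# annotations and a gold-standard DDI set to a scored, thresholded and
# classified DDI table.

#' Infer domain-domain interactions from multi-source PPI data
#'
#' Runs the full inference procedure: builds the tripartite structure per
#' source, scores candidate domain pairs by cosine neighborhood
#' similarity, assesses them with the hypergeometric common-neighbor test
#' (Bonferroni-corrected over the merged candidate set), fuses sources by
#' the non-zero weighted average (weights tuned by ROC AUC against the
#' gold standard unless supplied), calibrates the consensus-score
#' threshold by cross-validated F1 on the gold-standard positives versus
#' degree-preserving shuffled negatives, filters the consensus matrix and
#' classifies the retained DDIs into Gold/Silver/Bronze tiers.
#'
#' When the learning set is too small for `folds`-fold cross-validation
#' (tiny inputs), the threshold falls back to the single F1-optimal grid
#' value on the whole learning set, with a warning.
#'
#' @param sources Named list of PPI tables (data frames whose first two
#'   columns are protein ids), or a `planted_world` (its sources, annotations
#'   and gold standard are then used and the remaining arguments may be
#'   omitted).
#' @param annotations Annotation map (named list, protein -> domains).
#' @param gold_standard Character vector of canonical gold-standard DDI keys.
#' @param alpha Family-wise error rate for the Bonferroni flags.
#' @param weights Optional fixed named weight vector; when `NULL` the
#'   weights are optimised.
#' @param weight_strategy Weight search strategy, see [optimize_weights()].
#' @param restarts Coordinate-ascent restarts.
#' @param half_cutoff Gold support cutoff override, see [classify()].
#' @param negative_sample_size Number of shuffled negatives to sample
#'   (default: as many as there are positives).
#' @param folds Cross-validation folds for threshold selection.
#' @param train_fraction Training fraction of the learning set.
#' @param shuffle_max_tries Proposal budget for the negative shuffle.
#' @param seed Integer master seed; the shuffle, the CV split and the
#'   weight search each draw a sub-seed derived from it.
#' @return An object of class `ddi_fit`; see [summary.ddi_fit()],
#'   [coef.ddi_fit()], [predict.ddi_fit()] and [plot.ddi_fit()].
#' @examples
#' world <- generate_world(world_config(n_domains = 20, n_proteins = 60,
#'                                      n_true_ddis = 10, n_sources = 2,
#'                                      n_ppis = 150, seed = 7))
#' fit <- ddi_infer(world, seed = 7)
#' summary(fit)
#' recovery_metrics(fit$scored$key, world$true_ddis, world$gold_standard)
#' @export
ddi_infer <- function(sources, annotations = NULL, gold_standard = NULL,
                      alpha = 0.05, weights = NULL,
                      weight_strategy = c("coordinate_ascent", "exhaustive"),
                      restarts = 3L, half_cutoff = NULL,
                      negative_sample_size = NULL,
                      folds = 5L, train_fraction = 2 / 3,
                      shuffle_max_tries = NULL, seed = 1L) {
  weight_strategy <- match.arg(weight_strategy)
  if (inherits(sources, "planted_world")) {
    world <- sources
    sources <- world$sources
    if (is.null(annotations)) annotations <- world$annotations
    if (is.null(gold_standard)) gold_standard <- world$gold_standard
  }
  if (is.null(names(sources)) || any(!nzchar(names(sources)))) {
    stop("sources must be a named list of PPI tables", call. = FALSE)
  }
  seed <- as.integer(seed)
  seed_shuffle <- seed + 101L
  seed_cv <- seed + 202L
  seed_opt <- seed + 303L

  graphs <- lapply(names(sources), function(s) {
    build_source_graph(s, sources[[s]], annotations)
  })
  names(graphs) <- names(sources)
  per_source <- lapply(graphs, score_source)
  per_source <- bonferroni_flags(per_source, alpha = alpha)
  for (s in names(per_source)) {
    message(sprintf("source '%s': %d candidate DDIs over %d PPIs",
                    s, nrow(per_source[[s]]), attr(per_source[[s]], "n_z")))
  }

  if (is.null(weights)) {
    if (length(per_source) == 1L) {
      opt <- optimize_weights(per_source, gold_standard, seed = seed_opt)
    } else {
      opt <- optimize_weights(per_source, gold_standard,
                              strategy = weight_strategy,
                              seed = seed_opt, restarts = restarts)
    }
    weights <- opt$weights
    auc <- opt$auc
  } else {
    consensus_tmp <- combine_scores(per_source, weights)
    auc <- roc_auc(consensus_tmp, gold_standard)
  }
  consensus <- combine_scores(per_source, weights)
  message(sprintf("consensus: %d merged candidates, AUC = %.4f",
                  length(consensus), auc))

  shuffled <- tryCatch(
    shuffle_negatives(gold_standard, seed = seed_shuffle,
                      max_tries = shuffle_max_tries),
    error = function(e) {
      warning("negative shuffle failed (", conditionMessage(e),
              "); calibrating on positives only", call. = FALSE)
      character(0)
    })
  if (!is.null(negative_sample_size) &&
      negative_sample_size < length(shuffled)) {
    shuffled <- with_seed(seed_shuffle + 1L,
                          sort_c(sample(shuffled, negative_sample_size)))
  }
  ls <- if (length(shuffled) > 0L) {
    build_learning_set(gold_standard, shuffled, consensus)
  } else {
    pos <- intersect(sort_c(gold_standard), names(consensus)[consensus > 0])
    if (length(pos) == 0L) stop("no positive example has a nonzero score",
                                call. = FALSE)
    structure(list(positives = pos, negatives = character(0),
                   scores = consensus[pos]),
              class = "learning_set")
  }
  calib <- if (length(ls$positives) >= folds && length(ls$negatives) >= folds) {
    select_threshold_cv(ls, k = folds, train_fraction = train_fraction,
                        seed = seed_cv)
  } else {
    warning("learning set too small for cross-validation; using the single ",
            "F1-optimal grid threshold on the whole learning set",
            call. = FALSE)
    lab <- c(rep(TRUE, length(ls$positives)), rep(FALSE, length(ls$negatives)))
    sc <- ls$scores[c(ls$positives, ls$negatives)]
    t1 <- best_grid_threshold(lab, sc)
    prf <- precision_recall_f1(lab, sc, t1)
    structure(list(fold_thresholds = t1, fold_f1 = prf[["f1"]], t_m = t1,
                   f1_train = prf[["f1"]], f1_test = prf[["f1"]],
                   precision_test = prf[["precision"]],
                   recall_test = prf[["recall"]]),
              class = "threshold_result")
  }
  filtered <- filter_matrix(consensus, calib$t_m)
  message(sprintf("threshold t_m = %.6g keeps %d of %d candidates",
                  calib$t_m, length(filtered), length(consensus)))
  scored <- classify_all(filtered, per_source, gold_standard,
                         n_sources_total = length(per_source),
                         half_cutoff = half_cutoff)
  structure(list(call = match.call(),
                 sources = names(per_source),
                 graphs = graphs,
                 candidates = per_source,
                 weights = weights, auc = auc,
                 consensus = consensus,
                 learning_set = ls,
                 shuffled_negatives = shuffled,
                 calibration = calib,
                 filtered = filtered,
                 scored = scored,
                 gold_standard = gold_standard,
                 alpha = alpha, half_cutoff = half_cutoff,
                 seed = seed),
            class = "ddi_fit")
}

#' @export
print.ddi_fit <- function(x, ...) {
  cat("Domain-domain interaction inference fit\n")
  cat(sprintf("  sources: %s\n", paste(x$sources, collapse = ", ")))
  cat(sprintf("  merged candidates: %d; AUC vs gold standard: %.4f\n",
              length(x$consensus), x$auc))
  cat(sprintf("  threshold t_m = %.6g; retained DDIs: %d\n",
              x$calibration$t_m, nrow(x$scored)))
  tab <- table(factor(x$scored$category, levels = c("Gold", "Silver", "Bronze")))
  cat(sprintf("  categories: Gold %d, Silver %d, Bronze %d\n",
              tab[["Gold"]], tab[["Silver"]], tab[["Bronze"]]))
  invisible(x)
}

#' Summarise a DDI inference fit
#'
#' @param object A `ddi_fit`.
#' @param ... Unused.
#' @return The fit, invisibly; prints per-source candidate counts, the
#'   fused weights and AUC, the calibration metrics and the category by
#'   gold-standard breakdown.
#' @export
summary.ddi_fit <- function(object, ...) {
  print(object)
  cat("\nPer-source candidates:\n")
  for (s in object$sources) {
    cm <- object$candidates[[s]]
    cat(sprintf("  %-12s %7d candidates, %6d significant, weight %.2f\n",
                s, nrow(cm), sum(cm$significant), object$weights[[s]]))
  }
  cat("\nCalibration:\n")
  print(object$calibration)
  cat("\nCategory x gold-standard table:\n")
  print(attr(object$scored, "summary"))
  invisible(object)
}

#' Source weights of a fit
#'
#' @param object A `ddi_fit`.
#' @param ... Unused.
#' @return The named per-source weight vector used in the consensus.
#' @export
coef.ddi_fit <- function(object, ...) object$weights

#' Look up domain pairs in a fitted DDI inference
#'
#' @param object A `ddi_fit`.
#' @param newdata Data frame whose first two columns are domain
#'   accessions (order within a pair is irrelevant); default: the fit's
#'   retained DDIs.
#' @param ... Unused.
#' @return A data frame with the canonical pair, its consensus score (0
#'   when unscored), whether it passed the threshold, and its category
#'   (NA when not retained).
#' @export
predict.ddi_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$scored)
  keys <- make_keys(as.character(newdata[[1L]]), as.character(newdata[[2L]]))
  ab <- split_keys(keys)
  sc <- object$consensus[keys]
  sc[is.na(sc)] <- 0
  cat_ <- object$scored$category[match(keys, object$scored$key)]
  data.frame(domain_a = ab$domain_a, domain_b = ab$domain_b,
             consensus = as.numeric(sc),
             retained = keys %in% object$scored$key,
             category = cat_, stringsAsFactors = FALSE)
}

#' Plot the consensus score distribution of a fit
#'
#' Shows the distribution of consensus scores for the calibration
#' positives and negatives with the selected threshold, next to the
#' distribution over all candidates.
#'
#' @param x A `ddi_fit`.
#' @param ... Passed to [graphics::hist()].
#' @return The fit, invisibly.
#' @export
plot.ddi_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::hist(x$consensus, breaks = 30, main = "All candidates",
                 xlab = "consensus score", col = "grey85", ...)
  graphics::abline(v = x$calibration$t_m, col = "red", lwd = 2)
  ls <- x$learning_set
  sp <- ls$scores[ls$positives]
  sn <- ls$scores[ls$negatives]
  brk <- pretty(range(c(sp, sn)), 20)
  hp <- graphics::hist(sp, breaks = brk, plot = FALSE)
  hn <- graphics::hist(sn, breaks = brk, plot = FALSE)
  ylim <- c(0, max(hp$counts, hn$counts))
  graphics::plot(hp, col = grDevices::adjustcolor("steelblue", 0.5),
                 ylim = ylim, main = "Learning set",
                 xlab = "consensus score")
  graphics::plot(hn, col = grDevices::adjustcolor("orange", 0.5), add = TRUE)
  graphics::abline(v = x$calibration$t_m, col = "red", lwd = 2)
  graphics::legend("topright", fill = c("steelblue", "orange"),
                   legend = c("positives", "negatives"), bty = "n")
  invisible(x)
}
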