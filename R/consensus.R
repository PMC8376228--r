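# Multi-source fusion: the consensus score of a domain pair is the
# weighted average of its per-source cosine scores over the sources where
# the score is nonzero; weights are tuned by ROC AUC against the gold
# standard.

# Dense (union-keys x sources) score matrix used by combine/optimize.
#' @noRd
align_scores <- function(per_source) {
  stopifnot(length(per_source) >= 1L)
  if (is.null(names(per_source)) || any(!nzchar(names(per_source)))) {
    names(per_source) <- vapply(per_source, function(m) attr(m, "source"),
                                character(1))
  }
  keys <- sort_c(unique(unlist(lapply(per_source, function(m) m$key),
                               use.names = FALSE)))
  C <- matrix(0, nrow = length(keys), ncol = length(per_source),
              dimnames = list(keys, names(per_source)))
  for (s in names(per_source)) {
    m <- per_source[[s]]
    C[m$key, s] <- m$cosine
  }
  C
}

#' @noRd
combine_aligned <- function(C, w) {
  num <- as.vector(C %*% w)
  den <- as.vector((C > 0) %*% w)
  out <- num / den
  names(out) <- rownames(C)
  out
}

#' Combine per-source candidate matrices into a consensus matrix
#'
#' For each domain pair in the union of candidates, the consensus score is
#' the weighted average of the per-source cosine scores over the sources
#' where the pair has a nonzero score; sources where the pair is absent
#' contribute to neither numerator nor denominator. The result is
#' invariant to rescaling all weights by a common factor, and with a
#' single source it reproduces that source's cosines.
#'
#' @param per_source Named list of `candidate_matrix` objects.
#' @param weights Named numeric vector of per-source weights covering
#'   every source (values conventionally on the grid 0.01..1).
#' @return A named numeric vector of consensus scores (all in `(0, 1]`),
#'   with attribute `weights`.
#' @export
combine_scores <- function(per_source, weights) {
  C <- align_scores(per_source)
  if (!all(colnames(C) %in% names(weights))) {
    stop("weights must cover every source", call. = FALSE)
  }
  w <- weights[colnames(C)]
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  out <- combine_aligned(C, w)
  attr(out, "weights") <- w
  out
}

#' ROC AUC of a DDI ranking against a positive set
#'
#' Positives are the gold-standard pairs among the scored keys; the
#' background is every other scored key. Ties are handled by the midrank
#' convention, so the value equals `P(score_pos > score_neg) +
#' 0.5 P(equal)` over random positive/background pairs.
#'
#' @param scores Named numeric vector of scores.
#' @param positives Character vector of canonical DDI keys.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, positives) {
  lab <- names(scores) %in% positives
  n_pos <- sum(lab)
  n_neg <- sum(!lab)
  if (n_pos == 0L || n_neg == 0L) {
    stop("need at least one positive and one background key among scored pairs",
         call. = FALSE)
  }
  r <- rank(scores)  # midranks
  (sum(r[lab]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @noRd
weight_grid <- function() (1:100) / 100

#' Optimise source weights by ROC AUC
#'
#' Searches the per-source weight grid 0.01, 0.02, ..., 1.00 for the
#' combination maximising the AUC of the consensus ranking against the
#' gold standard. `"exhaustive"` enumerates every combination and is only
#' permitted for up to 3 sources; `"coordinate_ascent"` starts from
#' `restarts` seeded random grid points and repeatedly sets each source's
#' weight to its best grid value with the others held fixed until a full
#' sweep yields no improvement. Ties between weight vectors of equal AUC
#' are broken by the lexicographically smallest weight tuple in source
#' order.
#'
#' @param per_source Named list of `candidate_matrix` objects.
#' @param positives Character vector of gold-standard DDI keys.
#' @param strategy `"coordinate_ascent"` (default) or `"exhaustive"`.
#' @param seed Integer seed for the random restarts.
#' @param restarts Number of coordinate-ascent restarts (default 3).
#' @return A list with `weights` (named vector) and `auc`.
#' @export
optimize_weights <- function(per_source, positives,
                             strategy = c("coordinate_ascent", "exhaustive"),
                             seed = 1L, restarts = 3L) {
  strategy <- match.arg(strategy)
  C <- align_scores(per_source)
  D <- ncol(C)
  lab <- rownames(C) %in% positives
  if (!any(lab) || all(lab)) {
    stop("gold standard must split the scored pairs into positives and background",
         call. = FALSE)
  }
  n_pos <- sum(lab); n_neg <- sum(!lab)
  auc_of <- function(w) {
    r <- rank(combine_aligned(C, w))
    (sum(r[lab]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  grid <- weight_grid()
  if (D == 1L) {
    w <- stats::setNames(grid[1L], colnames(C))
    return(list(weights = w, auc = auc_of(w)))
  }
  if (strategy == "exhaustive") {
    if (D > 3L) {
      stop("exhaustive weight search is only supported for <= 3 sources",
           call. = FALSE)
    }
    combos <- as.matrix(expand.grid(rev(replicate(D, grid, simplify = FALSE))))
    combos <- combos[, rev(seq_len(D)), drop = FALSE]  # lexicographic row order
    best_auc <- -Inf; best_w <- NULL
    for (i in seq_len(nrow(combos))) {
      a <- auc_of(combos[i, ])
      if (a > best_auc + 1e-15) {  # strict improvement keeps the lexicographically first
        best_auc <- a
        best_w <- combos[i, ]
      }
    }
    return(list(weights = stats::setNames(best_w, colnames(C)), auc = best_auc))
  }
  lex_lt <- function(w1, w2) {
    d <- which(w1 != w2)
    length(d) > 0L && w1[d[1L]] < w2[d[1L]]
  }
  # deterministic starts (equal weights, then one emphasis start per source)
  # precede the seeded random restarts; plateaus in the AUC landscape make
  # single random starts unreliable
  starts <- c(list(rep(1, D)),
              lapply(seq_len(D), function(d) {
                w <- rep(0.01, D); w[d] <- 1; w
              }))
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      starts <- c(starts, list(grid[sample.int(length(grid), D, replace = TRUE)]))
    }
    best_auc <- -Inf; best_w <- NULL
    for (w in starts) {
      cur <- auc_of(w)
      repeat {
        improved <- FALSE
        for (d in seq_len(D)) {
          aucs <- vapply(grid, function(g) {
            wd <- w; wd[d] <- g; auc_of(wd)
          }, numeric(1))
          gbest <- grid[which.max(aucs)]  # smallest grid value among maximisers
          if (max(aucs) > cur + 1e-15 ||
              (max(aucs) >= cur - 1e-15 && gbest < w[d])) {
            if (max(aucs) > cur + 1e-15) improved <- TRUE
            else if (gbest < w[d]) improved <- TRUE
            w[d] <- gbest
            cur <- max(aucs)
          }
        }
        if (!improved) break
      }
      if (cur > best_auc + 1e-15 ||
          (cur >= best_auc - 1e-15 && (is.null(best_w) || lex_lt(w, best_w)))) {
        best_auc <- max(cur, best_auc)
        best_w <- w
      }
    }
    list(weights = stats::setNames(best_w, colnames(C)), auc = best_auc)
  })
}
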