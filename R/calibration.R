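# Threshold calibration: degree-preserving shuffled negatives, a three-phase
# threshold grid, and 5-fold cross-validated F1 selection.

#' Degree-preserving shuffle of a DDI set
#'
#' Produces a negative example set of the same size as `positives` by
#' repeated double-edge swaps on the positive edge multigraph. Each
#' domain's degree is conserved exactly (a homo-DDI contributes 2 to its
#' domain), no returned edge is an original positive edge, no duplicate
#' edges are produced, and no new self-edge is created. If some original
#' edges cannot be rewired within `max_tries` proposals they are dropped
#' from the output with a message.
#'
#' @param positives Character vector of canonical DDI keys (>= 2).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param max_tries Maximum number of swap proposals (default
#'   `1000 * length(positives)`).
#' @return A character vector of canonical DDI keys, disjoint from
#'   `positives`, with the same degree multiset.
#' @export
shuffle_negatives <- function(positives, seed, max_tries = NULL) {
  positives <- unique(positives)
  n <- length(positives)
  if (n < 2L) stop("need at least 2 positive edges to shuffle", call. = FALSE)
  if (is.null(max_tries)) max_tries <- 1000L * n
  ed <- split_keys(positives)
  a <- ed$domain_a
  b <- ed$domain_b
  orig <- positives
  with_seed(seed, {
    cur_keys <- positives
    tries <- 0L
    n_swaps <- 0L
    target_swaps <- max(10L * n, 100L)
    propose <- function(i, j) {
      # two matchings of endpoints {a_i,b_i} x {a_j,b_j}; pick one at random
      if (stats::runif(1) < 0.5) {
        list(c(a[i], a[j]), c(b[i], b[j]))
      } else {
        list(c(a[i], b[j]), c(b[i], a[j]))
      }
    }
    try_swap <- function(i, j) {
      pr <- propose(i, j)
      e1 <- sort_c(pr[[1L]]); e2 <- sort_c(pr[[2L]])
      if (e1[1L] == e1[2L] || e2[1L] == e2[2L]) return(FALSE) # new self-edge
      k1 <- paste(e1[1L], e1[2L], sep = KEY_SEP)
      k2 <- paste(e2[1L], e2[2L], sep = KEY_SEP)
      if (k1 == k2) return(FALSE)
      # duplicates within the current edge set
      others <- cur_keys[-c(i, j)]
      if (k1 %in% others || k2 %in% others) return(FALSE)
      a[i] <<- e1[1L]; b[i] <<- e1[2L]
      a[j] <<- e2[1L]; b[j] <<- e2[2L]
      cur_keys[i] <<- k1; cur_keys[j] <<- k2
      TRUE
    }
    # phase 1: randomise
    while (n_swaps < target_swaps && tries < max_tries) {
      ij <- sample.int(n, 2L)
      tries <- tries + 1L
      if (try_swap(ij[1L], ij[2L])) n_swaps <- n_swaps + 1L
    }
    # phase 2: rewire any edges still equal to an original edge
    repeat {
      stuck <- which(cur_keys %in% orig)
      if (length(stuck) == 0L || tries >= max_tries) break
      i <- if (length(stuck) == 1L) stuck else sample(stuck, 1L)
      j <- sample.int(n, 1L)
      tries <- tries + 1L
      if (j != i) try_swap(i, j)
    }
    leftover <- cur_keys %in% orig
    if (any(leftover)) {
      message(sprintf("shuffle: %d original edge(s) could not be rewired and were dropped",
                      sum(leftover)))
    }
    sort_c(unique(cur_keys[!leftover]))
  })
}

#' Assemble the calibration learning set
#'
#' Keeps only the positives and shuffled negatives that have a nonzero
#' consensus score (the others cannot be placed on the score axis), and
#' drops any shuffled edge that coincides with a positive.
#'
#' @param positives,shuffled Character vectors of canonical DDI keys.
#' @param consensus Named numeric vector of consensus scores.
#' @return A `learning_set`: list with `positives`, `negatives` (scored
#'   keys) and `scores` (named vector covering both).
#' @export
build_learning_set <- function(positives, shuffled, consensus) {
  if (length(shuffled) == 0L) stop("empty shuffled negative set", call. = FALSE)
  shuffled <- setdiff(shuffled, positives)
  scored <- names(consensus)[consensus > 0]
  pos <- intersect(positives, scored)
  neg <- intersect(shuffled, scored)
  if (length(pos) == 0L) stop("no positive example has a nonzero score", call. = FALSE)
  if (length(pos) < length(positives)) {
    message(sprintf("learning set: %d of %d positives unscored and dropped",
                    length(positives) - length(pos), length(positives)))
  }
  message(sprintf("learning set: %d positives, %d negatives (%d shuffled unscored)",
                  length(pos), length(neg), length(shuffled) - length(neg)))
  structure(list(positives = sort_c(pos), negatives = sort_c(neg),
                 scores = consensus[c(sort_c(pos), sort_c(neg))]),
            class = "learning_set")
}

#' Precision, recall and F1 at a score threshold
#'
#' An example is predicted positive when its score is strictly greater
#' than `t`. Precision is 0 when nothing is predicted positive; F1 is 0
#' when precision + recall is 0.
#'
#' @param labels Logical vector (TRUE = positive) or character
#'   (`"pos"`/`"neg"`), aligned with `scores`.
#' @param scores Numeric score vector.
#' @param t Threshold.
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(labels, scores, t) {
  if (is.character(labels)) labels <- labels == "pos"
  stopifnot(length(labels) == length(scores))
  pred <- scores > t
  tp <- sum(pred & labels)
  fp <- sum(pred & !labels)
  fn <- sum(!pred & labels)
  p <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}

#' Three-phase threshold grid
#'
#' The union of three inclusive grids of increasing resolution: 0 to 1 in
#' steps of 0.01, 0 to 0.04 in steps of 0.001, and 0.01 to 0.02 in steps
#' of 0.0001; deduplicated and sorted.
#'
#' @return A strictly increasing numeric vector.
#' @export
threshold_grid <- function() {
  # grids built over integer multiples of 1e-4 to avoid floating-point
  # near-duplicates
  u <- sort(unique(c((0:100) * 100L, (0:40) * 10L, 100:200)))
  u / 1e4
}

# F1 over a whole grid for one labelled score set; returns the vector of F1s.
#' @noRd
f1_over_grid <- function(labels, scores, grid) {
  vapply(grid, function(t) precision_recall_f1(labels, scores, t)[["f1"]],
         numeric(1))
}

# Smallest grid threshold maximising F1.
#' @noRd
best_grid_threshold <- function(labels, scores, grid = threshold_grid()) {
  f1 <- f1_over_grid(labels, scores, grid)
  grid[which.max(f1)]  # which.max returns the first (= smallest) maximiser
}

#' Select the consensus-score threshold by cross-validated F1
#'
#' Splits the learning set into stratified Training (`train_fraction`) and
#' Test subsets, runs k-fold cross-validation on Training (for each fold,
#' the smallest grid threshold maximising F1 on the other folds is
#' recorded and validated on the held-out fold), and averages the k fold
#' thresholds into the working threshold `t_m`. F1 at `t_m` is reported on
#' the full Training set and, as the final check, on the untouched Test
#' set.
#'
#' @param ls A `learning_set` from [build_learning_set()].
#' @param k Number of folds (default 5).
#' @param train_fraction Fraction of the learning set used for Training
#'   (default 2/3).
#' @param seed Integer seed driving the split and fold assignment.
#' @return A `threshold_result`: list with `fold_thresholds`, `fold_f1`
#'   (held-out F1 per fold), `t_m`, `f1_train`, `f1_test`,
#'   `precision_test`, `recall_test`.
#' @export
select_threshold_cv <- function(ls, k = 5L, train_fraction = 2 / 3, seed) {
  stopifnot(inherits(ls, "learning_set"))
  pos <- sort_c(ls$positives)
  neg <- sort_c(ls$negatives)
  if (length(pos) < k || length(neg) < k) {
    stop(sprintf("need at least %d positives and %d negatives for %d-fold CV",
                 k, k, k), call. = FALSE)
  }
  grid <- threshold_grid()
  with_seed(seed, {
    take <- function(x, frac) sample(x, round(frac * length(x)))
    tr_pos <- take(pos, train_fraction); te_pos <- setdiff(pos, tr_pos)
    tr_neg <- take(neg, train_fraction); te_neg <- setdiff(neg, tr_neg)
    fold_of <- function(x) sample(rep_len(seq_len(k), length(x)))
    fp <- fold_of(tr_pos); fn_ <- fold_of(tr_neg)
    keys_tr <- c(tr_pos, tr_neg)
    lab_tr <- c(rep(TRUE, length(tr_pos)), rep(FALSE, length(tr_neg)))
    sc_tr <- ls$scores[keys_tr]
    folds <- c(fp, fn_)
    fold_thresholds <- numeric(k)
    fold_f1 <- numeric(k)
    for (f in seq_len(k)) {
      inb <- folds != f
      fold_thresholds[f] <- best_grid_threshold(lab_tr[inb], sc_tr[inb], grid)
      fold_f1[f] <- precision_recall_f1(lab_tr[!inb], sc_tr[!inb],
                                        fold_thresholds[f])[["f1"]]
    }
    t_m <- mean(fold_thresholds)
    f1_train <- precision_recall_f1(lab_tr, sc_tr, t_m)[["f1"]]
    keys_te <- c(te_pos, te_neg)
    lab_te <- c(rep(TRUE, length(te_pos)), rep(FALSE, length(te_neg)))
    te <- precision_recall_f1(lab_te, ls$scores[keys_te], t_m)
    structure(list(fold_thresholds = fold_thresholds, fold_f1 = fold_f1,
                   t_m = t_m, f1_train = f1_train,
                   f1_test = te[["f1"]], precision_test = te[["precision"]],
                   recall_test = te[["recall"]]),
              class = "threshold_result")
  })
}

#' @export
print.threshold_result <- function(x, ...) {
  cat("Cross-validated threshold selection\n")
  cat("  fold thresholds:", paste(format(x$fold_thresholds), collapse = " "), "\n")
  cat(sprintf("  t_m = %.6g  F1(train) = %.4f  F1(test) = %.4f  P(test) = %.4f  R(test) = %.4f\n",
              x$t_m, x$f1_train, x$f1_test, x$precision_test, x$recall_test))
  invisible(x)
}

#' Filter a consensus matrix at a threshold
#'
#' Keeps entries whose score is strictly greater than `t_m`; everything
#' else becomes an implicit zero.
#'
#' @param consensus Named numeric vector of consensus scores.
#' @param t_m Threshold.
#' @return The filtered named numeric vector.
#' @export
filter_matrix <- function(consensus, t_m) {
  consensus[consensus > t_m]
}
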