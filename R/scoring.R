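# Per-source candidate scoring: cosine neighborhood similarity between the
# incidence rows of a left domain and a right domain, plus a hypergeometric
# test on the number of shared PPI neighbors.

#' Cosine similarity of two incidence rows
#'
#' For binary rows this is the common-neighbor count divided by the
#' geometric mean of the two neighbor counts.
#'
#' @param row_x,row_y Numeric vectors of equal length, each with at least
#'   one nonzero entry.
#' @return The cosine similarity, in `[0, 1]` for nonnegative input.
#' @export
cosine_score <- function(row_x, row_y) {
  if (length(row_x) != length(row_y)) {
    stop("rows must have equal length", call. = FALSE)
  }
  nx <- sqrt(sum(row_x^2))
  ny <- sqrt(sum(row_y^2))
  if (nx == 0 || ny == 0) stop("all-zero incidence row", call. = FALSE)
  sum(row_x * row_y) / (nx * ny)
}

#' Upper-tail hypergeometric p-value for a common-neighbor count
#'
#' Probability that two items with `n_x` and `n_y` neighbors among `n_z`
#' middle-layer items share at least `k_xy` neighbors by chance:
#' `P(K >= k_xy)` under the hypergeometric distribution. Computed via the
#' survival function, so it is stable for large `n_z`. The sum starts at
#' the observed count (greater-or-equal, not strictly greater).
#'
#' @param k_xy Observed common-neighbor count(s).
#' @param n_x,n_y Neighbor counts of the two items.
#' @param n_z Total number of middle-layer items.
#' @return p-value(s) in `[0, 1]`. Vectorised.
#' @export
hypergeom_pvalue <- function(k_xy, n_x, n_y, n_z) {
  if (any(k_xy < 0) || any(k_xy > pmin(n_x, n_y)) ||
      any(n_x > n_z) || any(n_y > n_z) || any(n_x < 0) || any(n_y < 0)) {
    stop("invalid hypergeometric arguments: need 0 <= k <= min(n_x, n_y) <= n_z",
         call. = FALSE)
  }
  p <- stats::phyper(k_xy - 1, n_x, n_z - n_x, n_y, lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

#' Score all candidate domain pairs of one source
#'
#' Computes, for every (left domain, right domain) pair sharing at least
#' one PPI, the cosine similarity of their incidence rows, the common-
#' neighbor count and the hypergeometric p-value. Pairs with no common
#' neighbor are implicitly zero and not stored. Keys are canonical
#' unordered pairs; when both orientations of the same unordered pair are
#' scoreable, the orientation with the larger cosine is kept (ties: larger
#' common-neighbor count, then the orientation whose left-role domain is
#' the smaller identifier).
#'
#' @param g A `source_graph` from [build_source_graph()].
#' @return A `candidate_matrix`: data frame with columns `key`, `domain_a`,
#'   `domain_b`, `cosine`, `k_xy`, `n_x`, `n_y`, `n_z`, `p_value`,
#'   `significant` (NA until [bonferroni_flags()] is applied), with
#'   attributes `source` and `n_z`.
#' @export
score_source <- function(g) {
  stopifnot(inherits(g, "source_graph"))
  K <- Matrix::tcrossprod(g$m_left, g$m_right)  # common-neighbor counts
  tri <- Matrix::summary(K)
  n_x_all <- Matrix::rowSums(g$m_left)
  n_y_all <- Matrix::rowSums(g$m_right)
  dx <- g$d_left[tri$i]
  dy <- g$d_right[tri$j]
  k <- as.integer(tri$x)
  n_x <- as.integer(n_x_all[tri$i])
  n_y <- as.integer(n_y_all[tri$j])
  cosine <- k / sqrt(n_x * n_y)
  key <- make_keys(dx, dy)
  df <- data.frame(key = key, cosine = cosine, k_xy = k,
                   n_x = n_x, n_y = n_y,
                   left_role = dx, stringsAsFactors = FALSE)
  # resolve orientation duplicates per canonical key
  is_first <- !str_lt(split_keys(key)$domain_a, df$left_role) # left_role == smaller id
  ord <- order(df$key, -df$cosine, -df$k_xy, !is_first, method = "radix")
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(df$key), , drop = FALSE]
  ab <- split_keys(df$key)
  out <- data.frame(key = df$key,
                    domain_a = ab$domain_a, domain_b = ab$domain_b,
                    cosine = df$cosine, k_xy = df$k_xy,
                    n_x = df$n_x, n_y = df$n_y, n_z = g$n_z,
                    stringsAsFactors = FALSE)
  out$p_value <- hypergeom_pvalue(out$k_xy, out$n_x, out$n_y, out$n_z)
  out$significant <- NA
  out <- out[order(out$key, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, source = g$name, n_z = g$n_z,
            class = c("candidate_matrix", "data.frame"))
}

#' Set Bonferroni significance flags across all sources
#'
#' The family size is the number of distinct candidate pairs in the union
#' across all sources (the merged candidate set); every per-source p-value
#' is compared against `alpha / n_tests` with a strict less-than.
#'
#' @param matrices A (named) list of `candidate_matrix` objects.
#' @param alpha Family-wise error rate (default 0.05).
#' @return The list with each matrix's `significant` column set; the family
#'   size is attached to each as attribute `n_tests`.
#' @export
bonferroni_flags <- function(matrices, alpha = 0.05) {
  stopifnot(length(matrices) >= 1L)
  n_tests <- length(unique(unlist(lapply(matrices, function(m) m$key),
                                  use.names = FALSE)))
  if (n_tests == 0L) {
    warning("no candidate pairs in any source; nothing to flag", call. = FALSE)
    return(matrices)
  }
  thr <- alpha / n_tests
  lapply(matrices, function(m) {
    m$significant <- m$p_value < thr
    attr(m, "n_tests") <- n_tests
    m
  })
}
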