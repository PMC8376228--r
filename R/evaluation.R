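# Evaluation of a DDI set against interactomes and other DDI sets:
# PPI coverage, set overlap, and network statistics.

#' Domain-level coverage of an interactome by a DDI set
#'
#' A PPI (L, R) is covered when some domain of L and some domain of R form
#' (as an unordered pair) a DDI of the set; only cross-protein domain
#' pairs are considered, since those are the pairs a physical DDI can
#' mediate in a binary interaction. PPIs where either protein has no
#' domain annotation are excluded from the total. A "useful" DDI is one
#' covering at least one PPI.
#'
#' @param ppis Data frame whose first two columns are protein ids (raw or
#'   canonical; pairs are canonicalized and deduplicated first).
#' @param annotations Annotation map (named list).
#' @param ddis Character vector of canonical DDI keys.
#' @return A `coverage_report`: list with `n_ppis_total`, `n_ppis_covered`,
#'   `n_useful_ddis` and `per_ddi_cover_counts` (named integer vector over
#'   `ddis`).
#' @export
coverage <- function(ppis, annotations, ddis) {
  cp <- canonical_ppi(as.character(ppis[[1L]]), as.character(ppis[[2L]]))
  cp <- cp[!duplicated(paste(cp$left, cp$right, sep = "\t")), , drop = FALSE]
  dl <- annotations[cp$left]
  dr <- annotations[cp$right]
  keep <- lengths(dl) > 0L & lengths(dr) > 0L
  cp <- cp[keep, , drop = FALSE]
  dl <- dl[keep]; dr <- dr[keep]
  n_total <- nrow(cp)
  counts <- stats::setNames(integer(length(ddis)), ddis)
  covered <- logical(n_total)
  for (i in seq_len(n_total)) {
    keys <- unique(make_keys(rep(dl[[i]], each = length(dr[[i]])),
                             rep(dr[[i]], times = length(dl[[i]]))))
    hit <- keys[keys %in% ddis]
    if (length(hit) > 0L) {
      covered[i] <- TRUE
      counts[hit] <- counts[hit] + 1L
    }
  }
  structure(list(n_ppis_total = n_total,
                 n_ppis_covered = sum(covered),
                 n_useful_ddis = sum(counts >= 1L),
                 per_ddi_cover_counts = counts),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("coverage: %d / %d annotated PPIs covered (%.1f%%), %d useful DDIs\n",
              x$n_ppis_covered, x$n_ppis_total,
              if (x$n_ppis_total > 0) 100 * x$n_ppis_covered / x$n_ppis_total else 0,
              x$n_useful_ddis))
  invisible(x)
}

#' Three-way overlap of DDI sets
#'
#' Counts the 7 regions of the three-set Venn partition on canonical keys.
#'
#' @param a,b,c Character vectors of canonical DDI keys.
#' @return Named integer vector with elements `a_only`, `b_only`, `c_only`,
#'   `ab_only`, `ac_only`, `bc_only`, `abc`.
#' @export
overlap3 <- function(a, b, c) {
  a <- unique(a); b <- unique(b); c <- unique(c)
  u <- unique(c(a, b, c))
  ina <- u %in% a; inb <- u %in% b; inc <- u %in% c
  c(a_only = sum(ina & !inb & !inc),
    b_only = sum(!ina & inb & !inc),
    c_only = sum(!ina & !inb & inc),
    ab_only = sum(ina & inb & !inc),
    ac_only = sum(ina & !inb & inc),
    bc_only = sum(!ina & inb & inc),
    abc = sum(ina & inb & inc))
}

#' Network statistics of a DDI set
#'
#' Treats the DDI set as an undirected graph over domains, homo-DDIs being
#' self-loops. A domain interacting only with itself forms a 1-node
#' connected component. The degree of a domain is its number of distinct
#' partners, a self-loop adding 1. `degree_sup_99` is the degree of the
#' node at rank `ceiling(0.99 n)` when nodes are sorted by increasing
#' degree (the degree bounding 99% of nodes from above).
#'
#' @param ddis Non-empty character vector of canonical DDI keys.
#' @return A `network_stats` list: `n_nodes`, `n_edges`, `n_ccs`,
#'   `giant_cc_size`, `pct_nodes_in_giant`, `n_1node_ccs`, `n_2node_ccs`,
#'   `degree_histogram` (table), `pct_degree_gt3`, `degree_sup_99`,
#'   `degree_max`, `argmax_node`, `n_homo_ddis`.
#' @export
network_stats <- function(ddis) {
  ddis <- unique(ddis)
  if (length(ddis) == 0L) stop("empty DDI set", call. = FALSE)
  ed <- split_keys(ddis)
  nodes <- sort_c(unique(c(ed$domain_a, ed$domain_b)))
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  sizes <- as.integer(comp$csize)
  # degree: distinct partners, self-loop adds 1
  self <- ed$domain_a == ed$domain_b
  het <- ed[!self, , drop = FALSE]
  deg <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(het) > 0L) {
    tab <- table(c(het$domain_a, het$domain_b))
    deg[names(tab)] <- as.integer(tab)
  }
  if (any(self)) {
    deg[ed$domain_a[self]] <- deg[ed$domain_a[self]] + 1L
  }
  n <- length(nodes)
  deg_sorted <- sort(deg)  # ascending; names irrelevant here
  degree_max <- max(deg)
  cand <- names(deg)[deg == degree_max]
  structure(list(
    n_nodes = n,
    n_edges = length(ddis),
    n_ccs = comp$no,
    giant_cc_size = max(sizes),
    pct_nodes_in_giant = 100 * max(sizes) / n,
    n_1node_ccs = sum(sizes == 1L),
    n_2node_ccs = sum(sizes == 2L),
    degree_histogram = table(deg),
    pct_degree_gt3 = 100 * mean(deg > 3L),
    degree_sup_99 = as.integer(deg_sorted[ceiling(0.99 * n)]),
    degree_max = as.integer(degree_max),
    argmax_node = sort_c(cand)[1L],
    n_homo_ddis = sum(self)
  ), class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf("network: %d nodes, %d edges, %d components (giant %d = %.1f%%)\n",
              x$n_nodes, x$n_edges, x$n_ccs, x$giant_cc_size,
              x$pct_nodes_in_giant))
  cat(sprintf("  1-node CCs %d, 2-node CCs %d, homo-DDIs %d\n",
              x$n_1node_ccs, x$n_2node_ccs, x$n_homo_ddis))
  cat(sprintf("  degree: max %d at %s, 99%%-sup %d, %%>3 %.1f\n",
              x$degree_max, x$argmax_node, x$degree_sup_99, x$pct_degree_gt3))
  invisible(x)
}
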