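# Shared fixtures and independent brute-force oracles.

# Canonical three-PPI fixture: two left proteins share d1/d3, the third
# carries d3 only; the right proteins carry d2, d2/d4, d4. Gives the
# candidate pairs (d1,d2) cosine 1, (d2,d3) and (d3,d4) cosine 2/sqrt(6),
# (d1,d4) cosine 1/2.
fig_pairs <- function() {
  data.frame(protein_a = c("La", "Lb", "Lc"),
             protein_b = c("Ra", "Rb", "Rc"),
             stringsAsFactors = FALSE)
}

fig_annotations <- function() {
  list(La = c("d1", "d3"), Lb = c("d1", "d3"), Lc = "d3",
       Ra = "d2", Rb = c("d2", "d4"), Rc = "d4")
}

fig_graph <- function() {
  build_source_graph("fig", fig_pairs(), fig_annotations())
}

# Independent hypergeometric oracle: enumerate every size-n_y draw from
# n_z items and count overlaps with the first n_x items. Returns the
# whole upper-tail function P(K >= k) for k = 0..min(n_x, n_y).
bf_hyper_tail <- function(n_x, n_y, n_z) {
  draws <- utils::combn(n_z, n_y)
  k <- colSums(draws <= n_x)
  kmax <- min(n_x, n_y)
  vapply(0:kmax, function(v) mean(k >= v), numeric(1))
}

# Independent AUC oracle: average over all positive/negative pairs of
# 1, 1/2 or 0 for win/tie/loss.
bf_auc <- function(scores, positives) {
  lab <- names(scores) %in% positives
  sp <- scores[lab]
  sn <- scores[!lab]
  tot <- 0
  for (p in sp) for (q in sn) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(sp) * length(sn))
}

# Independent coverage oracle: double loop over PPIs x DDIs.
bf_coverage <- function(ppis, annotations, ddis) {
  cp <- canonical_ppi(as.character(ppis[[1]]), as.character(ppis[[2]]))
  cp <- cp[!duplicated(paste(cp$left, cp$right)), , drop = FALSE]
  dl <- annotations[cp$left]
  dr <- annotations[cp$right]
  keep <- lengths(dl) > 0 & lengths(dr) > 0
  cp <- cp[keep, , drop = FALSE]; dl <- dl[keep]; dr <- dr[keep]
  counts <- setNames(integer(length(ddis)), ddis)
  covered <- logical(nrow(cp))
  for (i in seq_len(nrow(cp))) {
    for (d in ddis) {
      ab <- strsplit(d, "|", fixed = TRUE)[[1]]
      hit <- (ab[1] %in% dl[[i]] && ab[2] %in% dr[[i]]) ||
             (ab[2] %in% dl[[i]] && ab[1] %in% dr[[i]])
      if (hit) {
        covered[i] <- TRUE
        counts[d] <- counts[d] + 1L
      }
    }
  }
  list(n_ppis_total = nrow(cp), n_ppis_covered = sum(covered),
       n_useful_ddis = sum(counts >= 1), per_ddi_cover_counts = counts)
}

# Independent connected-component oracle: flood fill on an adjacency list.
bf_components <- function(keys) {
  ed <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  nodes <- sort(unique(c(ed[, 1], ed[, 2])), method = "radix")
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(ed))) {
    adj[[ed[i, 1]]] <- c(adj[[ed[i, 1]]], ed[i, 2])
    adj[[ed[i, 2]]] <- c(adj[[ed[i, 2]]], ed[i, 1])
  }
  seen <- setNames(rep(FALSE, length(nodes)), nodes)
  sizes <- integer(0)
  for (v in nodes) {
    if (seen[v]) next
    stack <- v
    size <- 0L
    while (length(stack) > 0) {
      u <- stack[1]
      stack <- stack[-1]
      if (seen[u]) next
      seen[u] <- TRUE
      size <- size + 1L
      stack <- c(stack, adj[[u]])
    }
    sizes <- c(sizes, size)
  }
  sort(sizes, decreasing = TRUE)
}

# Degree multiset of an edge-key set (a homo edge contributes 2).
degree_multiset <- function(keys) {
  ed <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  sort(table(c(ed[, 1], ed[, 2])))
}

# Random bipartite edge set: n_edges distinct pairs between two disjoint
# 2*n_edges-node sides. Sparse enough that a degree-preserving rewiring
# avoiding all original edges always exists.
random_bipartite <- function(n_edges, seed) {
  set.seed(seed)
  m <- max(4, ceiling(0.6 * n_edges))
  L <- sprintf("L%02d", seq_len(m))
  R <- sprintf("R%02d", seq_len(m))
  keys <- character(0)
  while (length(keys) < n_edges) {
    keys <- unique(c(keys, paste(sample(L), sample(R), sep = "|")))
  }
  keys[seq_len(n_edges)]
}

# Random simple edge set over a lettered node pool (no self-loops).
random_edges <- function(n_edges, n_nodes, seed) {
  set.seed(seed)
  pool <- sprintf("n%02d", seq_len(n_nodes))
  keys <- character(0)
  while (length(keys) < n_edges) {
    i <- sample(pool, 1)
    j <- sample(setdiff(pool, i), 1)
    k <- paste(sort(c(i, j), method = "radix"), collapse = "|")
    keys <- unique(c(keys, k))
  }
  keys
}

# Minimal candidate-matrix stand-in for consensus-layer tests.
fake_matrix <- function(source, keys, cosines, p = NULL, sig = NA) {
  df <- data.frame(key = keys, cosine = cosines, stringsAsFactors = FALSE)
  if (!is.null(p)) df$p_value <- p
  df$significant <- rep(sig, length.out = nrow(df))
  structure(df, source = source, class = c("candidate_matrix", "data.frame"))
}

# Learning set built directly from score vectors.
make_learning_set <- function(pos_scores, neg_scores) {
  pos <- sprintf("p%03d|q%03d", seq_along(pos_scores), seq_along(pos_scores))
  neg <- sprintf("u%03d|v%03d", seq_along(neg_scores), seq_along(neg_scores))
  scores <- setNames(c(pos_scores, neg_scores), c(pos, neg))
  structure(list(positives = pos, negatives = neg, scores = scores),
            class = "learning_set")
}
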