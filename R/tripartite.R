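# Per-source tripartite structure: the middle layer is the set of ordered
# PPIs; the outer layers are the domains of the left and right proteins.
# The two bipartite incidence relations are stored as sparse binary
# matrices (domains x PPIs).

#' Canonically order a protein pair
#'
#' Orders a protein pair alphanumerically (byte order) so that each
#' interaction is represented once: the left protein always precedes the
#' right one. Self-interactions are allowed.
#'
#' @param a,b Protein identifiers (non-empty, no whitespace). Vectorised.
#' @return A data frame with columns `left` and `right`, `left <= right`.
#' @export
canonical_ppi <- function(a, b) {
  check_ids(a, "protein id")
  check_ids(b, "protein id")
  p <- order_pair(a, b)
  data.frame(left = p$first, right = p$second, stringsAsFactors = FALSE)
}

#' Build the tripartite structure for one PPI source
#'
#' Canonicalizes and deduplicates the raw pairs, drops PPIs whose two
#' proteins both lack domain annotations (they cannot contribute any
#' domain-level evidence), and builds the left and right domain-by-PPI
#' binary incidence matrices. A PPI with only one annotated protein is kept
#' and contributes incidence rows on that side only. Domains with no
#' incident PPI are not rows.
#'
#' @param name Source label.
#' @param pairs A data frame whose first two columns are protein ids (as
#'   from [read_ppi_table()]).
#' @param annotations Annotation map (named list, protein -> domains), as
#'   from [read_annotations()].
#' @return An object of class `source_graph`: list with `name`, `ppis`
#'   (data frame `left`/`right`), `d_left`, `d_right` (sorted domain
#'   vectors), `m_left`, `m_right` (sparse binary incidence, domains x
#'   PPIs), `n_z` (number of PPIs) and `n_dropped` (both-unannotated PPIs
#'   removed).
#' @export
build_source_graph <- function(name, pairs, annotations) {
  if (length(annotations) == 0L) stop("annotations must be non-empty", call. = FALSE)
  a <- as.character(pairs[[1L]])
  b <- as.character(pairs[[2L]])
  cp <- canonical_ppi(a, b)
  dup <- duplicated(paste(cp$left, cp$right, sep = "\t"))
  cp <- cp[!dup, , drop = FALSE]
  ann_l <- annotations[cp$left]
  ann_r <- annotations[cp$right]
  has_l <- lengths(ann_l) > 0L
  has_r <- lengths(ann_r) > 0L
  drop <- !has_l & !has_r
  n_dropped <- sum(drop)
  if (n_dropped > 0L) {
    message(sprintf("source '%s': dropped %d PPI(s) with no annotated protein",
                    name, n_dropped))
  }
  cp <- cp[!drop, , drop = FALSE]
  if (nrow(cp) == 0L) {
    stop(sprintf("source '%s': no PPIs survive annotation filtering", name),
         call. = FALSE)
  }
  n_z <- nrow(cp)
  inc <- function(proteins) {
    doms <- annotations[proteins]
    nd <- lengths(doms)
    col <- rep.int(seq_len(n_z), nd)
    dom <- as.character(unlist(doms, use.names = FALSE))
    rows <- sort_c(unique(dom))
    m <- Matrix::sparseMatrix(i = match(dom, rows), j = col, x = 1,
                              dims = c(length(rows), n_z),
                              dimnames = list(rows, NULL))
    # duplicate (domain, ppi) entries cannot arise: annotation sets are
    # deduplicated per protein
    m
  }
  m_left <- inc(cp$left)
  m_right <- inc(cp$right)
  structure(list(name = name, ppis = cp,
                 d_left = rownames(m_left), d_right = rownames(m_right),
                 m_left = m_left, m_right = m_right,
                 n_z = n_z, n_dropped = n_dropped),
            class = "source_graph")
}

#' @export
print.source_graph <- function(x, ...) {
  cat(sprintf("source_graph '%s': %d PPIs, %d left domains, %d right domains\n",
              x$name, x$n_z, length(x$d_left), length(x$d_right)))
  invisible(x)
}
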