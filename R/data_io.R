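# Flat-file readers and writers. All formats are plain TSV; no numerical
# logic lives here.

#' Read a two-column protein-protein interaction table
#'
#' Reads a tab-separated file with two columns of protein identifiers.
#' Lines starting with `#` and blank lines are skipped. Pairs are returned
#' in file order, unvalidated: no canonical ordering and no deduplication
#' is applied (see [build_source_graph()] for both).
#'
#' @param path Path to a TSV file.
#' @return A data frame with character columns `protein_a` and `protein_b`.
#' @seealso [read_annotations()], [read_ddi_table()]
#' @export
read_ppi_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[[:space:]]+$", "", lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.frame(protein_a = character(), protein_b = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L)) {
    bad <- idx[which(nf != 2L)[1L]]
    stop(sprintf("parse error in '%s' at line %d: expected 2 tab-separated columns",
                 path, bad), call. = FALSE)
  }
  data.frame(protein_a = vapply(parts, `[`, "", 1L),
             protein_b = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Read a protein-to-domain annotation table
#'
#' Each line maps one protein identifier to a comma-separated list of domain
#' accessions. Duplicate protein lines are merged by set union; lines whose
#' domain field is empty are dropped with a warning (an unannotated protein
#' cannot support any domain-level inference).
#'
#' @param path Path to a TSV file (protein, comma-separated domains).
#' @return A named list mapping protein id to a character vector of distinct
#'   domain accessions (an annotation map).
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[[:space:]]+$", "", lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  idx <- which(keep)
  ann <- list()
  n_empty <- 0L
  for (i in idx) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 1L || length(parts) > 2L || !nzchar(parts[1L])) {
      stop(sprintf("parse error in '%s' at line %d: expected protein<TAB>domains",
                   path, i), call. = FALSE)
    }
    doms <- if (length(parts) == 2L) parts[2L] else ""
    doms <- strsplit(doms, ",", fixed = TRUE)[[1L]]
    doms <- doms[nzchar(doms)]
    if (length(doms) == 0L) {
      n_empty <- n_empty + 1L
      next
    }
    p <- parts[1L]
    ann[[p]] <- unique(c(ann[[p]], doms))
  }
  if (n_empty > 0L) {
    warning(sprintf("%d line(s) with an empty domain set dropped from '%s'",
                    n_empty, path), call. = FALSE)
  }
  ann
}

#' Read a domain-domain interaction table
#'
#' Reads a two-column TSV of domain accessions. Each pair is canonicalized
#' (sorted within the pair, byte order) and duplicates are collapsed, so the
#' result is a set of unordered domain pairs. A pair with two identical
#' domains is a homo-DDI and is kept.
#'
#' @param path Path to a TSV file.
#' @return A character vector of canonical DDI keys (`"A|B"` with `A <= B`),
#'   sorted.
#' @export
read_ddi_table <- function(path) {
  tab <- read_ppi_table(path)
  if (nrow(tab) == 0L) return(character())
  check_ids(tab$protein_a, "domain accession")
  check_ids(tab$protein_b, "domain accession")
  sort_c(unique(make_keys(tab$protein_a, tab$protein_b)))
}

#' Write a scored DDI table
#'
#' Writes the classified DDI table produced by [classify_all()] (or taken
#' from a fitted [ddi_infer()] object) as TSV: `domain_a`, `domain_b`, one
#' score and one p-value column per source, `consensus_score`, `category`.
#' Rows are sorted by descending consensus score, ties broken by the domain
#' pair. Scores absent for a source are written as `0`, absent p-values as
#' `NA`; floating-point values carry 6 significant digits.
#'
#' @param ddis A `scored_ddis` data frame from [classify_all()].
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @export
write_scored_ddis <- function(ddis, path) {
  sources <- attr(ddis, "sources")
  if (is.null(sources)) {
    sources <- sub("^score\\.", "", grep("^score\\.", names(ddis), value = TRUE))
  }
  hdr <- c("domain_a", "domain_b",
           as.vector(rbind(paste0(sources, "_score"), paste0(sources, "_pvalue"))),
           "consensus_score", "category")
  fmt <- function(x) {
    out <- ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
    out[!is.na(x) & x == 0] <- "0"
    out
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = "\t"), con)
  if (nrow(ddis) > 0L) {
    ord <- order(-ddis$consensus, ddis$domain_a, ddis$domain_b, method = "radix")
    d <- ddis[ord, , drop = FALSE]
    cols <- list(d$domain_a, d$domain_b)
    for (s in sources) {
      sc <- d[[paste0("score.", s)]]
      pv <- d[[paste0("pvalue.", s)]]
      sc[is.na(sc)] <- 0
      cols <- c(cols, list(fmt(sc), fmt(pv)))
    }
    cols <- c(cols, list(fmt(d$consensus), as.character(d$category)))
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Write a DDI set as a two-column TSV
#'
#' @param ddis Character vector of canonical DDI keys.
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @export
write_ddi_table <- function(ddis, path) {
  d <- split_keys(sort_c(ddis))
  writeLines(paste(d$domain_a, d$domain_b, sep = "\t"), path)
  invisible(path)
}

#' Read a flat run configuration file
#'
#' The run configuration is a flat YAML mapping naming the per-source PPI
#' files, the annotation and gold-standard files, seeds, and algorithm
#' parameters. See [run_pipeline()] for the recognised keys.
#'
#' @param path Path to a YAML file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("run config must be a YAML mapping", call. = FALSE)
  cfg
}
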