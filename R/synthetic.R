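# Planted-truth synthetic data: a hidden DDI set over a domain universe,
# annotated proteins, and several noisy PPI sources generated from it.
# This is the package's benchmarking surface: parameter recovery on a
# planted world exercises the full inference pipeline with no external
# downloads.

#' Configuration for a planted synthetic world
#'
#' Defaults describe a small benchmark world: 50 domain families, 200
#' proteins carrying on average three domains, 30 planted true DDIs (10%
#' of them homotypic, in line with the homo-DDI share of curated DDI
#' resources), half of the truth revealed as the gold standard, and three
#' PPI sources of 500 interactions each in which 80% of pairs are
#' generated from a planted DDI and 20% are uniform random protein pairs.
#'
#' @param n_domains Number of domain families (named PF0001, ...).
#' @param n_proteins Number of proteins (named PR0001, ...).
#' @param domains_per_protein_mean Poisson mean; each protein carries
#'   `1 + Poisson(mean)` distinct domains (capped at `n_domains`).
#' @param n_true_ddis Number of planted true DDIs.
#' @param gold_fraction Fraction of the truth revealed as gold standard.
#' @param homo_ddi_fraction Fraction of planted DDIs that are homotypic.
#' @param n_sources Number of PPI sources.
#' @param n_ppis Interactions drawn per source (before deduplication).
#' @param signal_fraction Fraction of each source's pairs generated from a
#'   planted DDI rather than uniformly at random.
#' @param seed Integer seed; the world is fully reproducible from it.
#' @return A `world_config` list.
#' @export
world_config <- function(n_domains = 50L, n_proteins = 200L,
                         domains_per_protein_mean = 2,
                         n_true_ddis = 30L, gold_fraction = 0.5,
                         homo_ddi_fraction = 0.1,
                         n_sources = 3L, n_ppis = 500L,
                         signal_fraction = 0.8, seed = 1L) {
  cfg <- list(n_domains = as.integer(n_domains),
              n_proteins = as.integer(n_proteins),
              domains_per_protein_mean = domains_per_protein_mean,
              n_true_ddis = as.integer(n_true_ddis),
              gold_fraction = gold_fraction,
              homo_ddi_fraction = homo_ddi_fraction,
              n_sources = as.integer(n_sources),
              n_ppis = as.integer(n_ppis),
              signal_fraction = signal_fraction,
              seed = as.integer(seed))
  fr <- c(cfg$gold_fraction, cfg$homo_ddi_fraction, cfg$signal_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0, 1]", call. = FALSE)
  if (cfg$n_domains < 1L || cfg$n_proteins < 1L || cfg$n_sources < 1L ||
      cfg$n_ppis < 1L || cfg$n_true_ddis < 0L) {
    stop("counts must be positive", call. = FALSE)
  }
  structure(cfg, class = "world_config")
}

#' Generate a planted synthetic world
#'
#' Builds the domain universe, random protein annotations, a planted true
#' DDI set with its gold-standard subset, and per-source PPI lists. Signal
#' PPIs are built by sampling a planted DDI and then one carrier protein
#' for each of its two domains (planted DDIs with no carrier on either
#' side are never sampled); noise PPIs are uniform random protein pairs.
#' Pairs are canonicalized and deduplicated within each source. The world
#' is byte-reproducible from `cfg$seed`.
#'
#' @param cfg A [world_config()].
#' @return A `planted_world`: list with `domains`, `proteins`,
#'   `annotations` (named list), `true_ddis`, `gold_standard` (key
#'   vectors), `sources` (named list of data frames `left`/`right`),
#'   `provenance` (per-source data frame of generated raw pairs with an
#'   `origin` column, before deduplication), `config` and `seed`.
#' @export
generate_world <- function(cfg = world_config()) {
  stopifnot(inherits(cfg, "world_config"))
  with_seed(cfg$seed, {
    domains <- sprintf("PF%04d", seq_len(cfg$n_domains))
    proteins <- sprintf("PR%04d", seq_len(cfg$n_proteins))
    sizes <- pmin(1L + stats::rpois(cfg$n_proteins, cfg$domains_per_protein_mean),
                  cfg$n_domains)
    annotations <- stats::setNames(
      lapply(sizes, function(s) sample(domains, s)), proteins)
    # planted truth
    n_homo <- round(cfg$homo_ddi_fraction * cfg$n_true_ddis)
    n_het <- cfg$n_true_ddis - n_homo
    max_het <- cfg$n_domains * (cfg$n_domains - 1) / 2
    if (n_het > max_het || n_homo > cfg$n_domains) {
      stop("n_true_ddis too large for the domain universe", call. = FALSE)
    }
    homo <- if (n_homo > 0L) {
      d <- sample(domains, n_homo)
      paste(d, d, sep = KEY_SEP)
    } else character()
    het <- character()
    tries <- 0L
    while (length(het) < n_het) {
      need <- n_het - length(het)
      i <- sample.int(cfg$n_domains, 2L * need, replace = TRUE)
      j <- sample.int(cfg$n_domains, 2L * need, replace = TRUE)
      ok <- i != j
      het <- unique(c(het, make_keys(domains[i[ok]], domains[j[ok]])))
      het <- utils::head(het, n_het)
      tries <- tries + 1L
      if (tries > 1000L) stop("could not sample distinct true DDIs", call. = FALSE)
    }
    true_ddis <- sort_c(c(homo, het))
    gold_standard <- if (length(true_ddis) > 0L) {
      sort_c(sample(true_ddis, ceiling(cfg$gold_fraction * length(true_ddis))))
    } else character()
    # carrier index: domain -> proteins containing it
    carrier <- split(rep(proteins, sizes), unlist(annotations, use.names = FALSE))
    td <- split_keys(true_ddis)
    viable <- which(td$domain_a %in% names(carrier) &
                      td$domain_b %in% names(carrier))
    n_signal <- round(cfg$signal_fraction * cfg$n_ppis)
    if (n_signal > 0L && length(true_ddis) > 0L && length(viable) == 0L) {
      stop("no planted DDI has carrier proteins on both sides", call. = FALSE)
    }
    sources <- list()
    provenance <- list()
    for (s in seq_len(cfg$n_sources)) {
      ns <- if (length(viable) > 0L) n_signal else 0L
      sig_a <- character(ns); sig_b <- character(ns)
      if (ns > 0L) {
        pick <- viable[sample.int(length(viable), ns, replace = TRUE)]
        sig_a <- vapply(td$domain_a[pick], function(d) {
          cs <- carrier[[d]]; cs[sample.int(length(cs), 1L)]
        }, character(1))
        sig_b <- vapply(td$domain_b[pick], function(d) {
          cs <- carrier[[d]]; cs[sample.int(length(cs), 1L)]
        }, character(1))
      }
      nn <- cfg$n_ppis - ns
      noi_a <- proteins[sample.int(cfg$n_proteins, nn, replace = TRUE)]
      noi_b <- proteins[sample.int(cfg$n_proteins, nn, replace = TRUE)]
      raw <- data.frame(protein_a = c(sig_a, noi_a),
                        protein_b = c(sig_b, noi_b),
                        origin = rep(c("signal", "noise"), c(ns, nn)),
                        stringsAsFactors = FALSE)
      cp <- canonical_ppi(raw$protein_a, raw$protein_b)
      dup <- duplicated(paste(cp$left, cp$right, sep = "\t"))
      label <- paste0("S", s)
      sources[[label]] <- cp[!dup, , drop = FALSE]
      rownames(sources[[label]]) <- NULL
      provenance[[label]] <- raw
    }
    structure(list(domains = domains, proteins = proteins,
                   annotations = annotations,
                   true_ddis = true_ddis, gold_standard = gold_standard,
                   sources = sources, provenance = provenance,
                   config = cfg, seed = cfg$seed),
              class = "planted_world")
  })
}

#' @export
print.planted_world <- function(x, ...) {
  cat(sprintf("planted_world: %d domains, %d proteins, %d true DDIs (%d gold), %d source(s)\n",
              length(x$domains), length(x$proteins), length(x$true_ddis),
              length(x$gold_standard), length(x$sources)))
  for (s in names(x$sources)) {
    cat(sprintf("  %s: %d PPIs\n", s, nrow(x$sources[[s]])))
  }
  invisible(x)
}

#' Write a planted world as standard input files
#'
#' Writes one PPI TSV per source, the annotation TSV, the gold-standard
#' TSV, the full truth TSV, and a JSON echo of the generating
#' configuration, so the world can be consumed through the file-based
#' interface (or the command-line runner).
#'
#' @param world A `planted_world`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the paths written.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "planted_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (s in names(world$sources)) {
    p <- file.path(dir, paste0("ppis_", s, ".tsv"))
    writeLines(paste(world$sources[[s]]$left, world$sources[[s]]$right,
                     sep = "\t"), p)
    paths[[paste0("source_", s)]] <- p
  }
  p <- file.path(dir, "annotations.tsv")
  writeLines(paste(names(world$annotations),
                   vapply(world$annotations, paste, "", collapse = ","),
                   sep = "\t"), p)
  paths$annotations <- p
  paths$gold_standard <- write_ddi_table(world$gold_standard,
                                         file.path(dir, "gold_standard.tsv"))
  paths$true_ddis <- write_ddi_table(world$true_ddis,
                                     file.path(dir, "true_ddis.tsv"))
  p <- file.path(dir, "world_config.json")
  jsonlite::write_json(unclass(world$config), p, auto_unbox = TRUE, digits = NA)
  paths$config <- p
  invisible(paths)
}

#' Precision and recall of an inferred DDI set against the planted truth
#'
#' Both sets are reduced by `exclude` first (typically the gold-standard
#' subset used during calibration, so the metric reflects genuinely novel
#' inference). Empty denominators yield 0.
#'
#' @param inferred,planted Character vectors of canonical DDI keys.
#' @param exclude Keys removed from both sets before scoring.
#' @return Named numeric vector `c(precision, recall)`.
#' @export
recovery_metrics <- function(inferred, planted, exclude = character()) {
  inf <- setdiff(unique(inferred), exclude)
  pla <- setdiff(unique(planted), exclude)
  tp <- length(intersect(inf, pla))
  c(precision = if (length(inf) == 0L) 0 else tp / length(inf),
    recall = if (length(pla) == 0L) 0 else tp / length(pla))
}
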