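# Gold/Silver/Bronze classification from the per-source nonzero-score
# pattern and significance flags.

#' Classify one DDI's per-source evidence pattern
#'
#' Let `m` be the number of sources with a nonzero score for the pair and
#' `all_sig` whether every one of those sources flags the pair as
#' statistically significant. The pair is Gold when it is supported by at
#' least half of all sources (`m >= half_cutoff`) and all supporting
#' p-values are significant; Silver when it is supported by fewer than
#' half but still with uniformly significant p-values; and Bronze
#' otherwise (at least one supporting source not significant).
#'
#' @param m Number of sources with a nonzero score (vectorised).
#' @param all_sig Logical: every supporting source significant.
#' @param n_sources_total Total number of configured sources.
#' @param half_cutoff Support count needed for Gold; default
#'   `ceiling(n_sources_total / 2)`.
#' @return A character vector with values `"Gold"`, `"Silver"`, `"Bronze"`.
#' @export
classify <- function(m, all_sig, n_sources_total, half_cutoff = NULL) {
  if (any(m < 1L)) stop("a classified DDI must have at least one nonzero source",
                        call. = FALSE)
  if (any(m > n_sources_total)) {
    stop("support count exceeds the number of sources", call. = FALSE)
  }
  if (is.null(half_cutoff)) half_cutoff <- ceiling(n_sources_total / 2)
  ifelse(!all_sig, "Bronze", ifelse(m >= half_cutoff, "Gold", "Silver"))
}

#' Classify every filtered DDI
#'
#' Builds one row per filtered domain pair carrying the per-source cosine
#' scores and p-values (NA where a source has no score), the consensus
#' score, the Gold/Silver/Bronze category, and whether the pair belongs to
#' the gold standard. A category-by-gold-standard summary table is
#' attached as attribute `summary` and printed as a message.
#'
#' @param filtered_consensus Named numeric vector of filtered consensus
#'   scores (from [filter_matrix()]).
#' @param per_source Named list of `candidate_matrix` objects with
#'   significance flags set.
#' @param gold_standard Character vector of gold-standard DDI keys.
#' @param n_sources_total Total number of configured sources (default:
#'   `length(per_source)`).
#' @param half_cutoff Gold support cutoff, see [classify()].
#' @return A `scored_ddis` data frame: `key`, `domain_a`, `domain_b`,
#'   `score.<source>` and `pvalue.<source>` columns, `n_sources`,
#'   `all_significant`, `consensus`, `category`, `in_gold_standard`.
#' @export
classify_all <- function(filtered_consensus, per_source, gold_standard,
                         n_sources_total = length(per_source),
                         half_cutoff = NULL) {
  keys <- sort_c(names(filtered_consensus))
  sources <- names(per_source)
  if (is.null(sources)) {
    sources <- vapply(per_source, function(m) attr(m, "source"), character(1))
    names(per_source) <- sources
  }
  ab <- split_keys(keys)
  out <- data.frame(key = keys, domain_a = ab$domain_a, domain_b = ab$domain_b,
                    stringsAsFactors = FALSE)
  m_count <- integer(length(keys))
  all_sig <- rep(TRUE, length(keys))
  for (s in sources) {
    cm <- per_source[[s]]
    ix <- match(keys, cm$key)
    sc <- cm$cosine[ix]
    pv <- cm$p_value[ix]
    sg <- cm$significant[ix]
    out[[paste0("score.", s)]] <- sc
    out[[paste0("pvalue.", s)]] <- pv
    present <- !is.na(sc) & sc > 0
    m_count <- m_count + present
    all_sig <- all_sig & (!present | (!is.na(sg) & sg))
  }
  out$n_sources <- m_count
  out$all_significant <- all_sig
  out$consensus <- as.numeric(filtered_consensus[keys])
  if (length(keys) > 0L) {
    out$category <- classify(m_count, all_sig, n_sources_total, half_cutoff)
  } else {
    out$category <- character()
  }
  out$in_gold_standard <- keys %in% gold_standard
  rownames(out) <- NULL
  lev <- c("Gold", "Silver", "Bronze")
  smry <- table(factor(out$category, levels = lev),
                factor(ifelse(out$in_gold_standard, "in_gold_standard", "novel"),
                       levels = c("in_gold_standard", "novel")))
  for (l in lev) {
    message(sprintf("classified %s: %d (of which %d in gold standard)",
                    l, sum(smry[l, ]), smry[l, "in_gold_standard"]))
  }
  structure(out, sources = sources, summary = smry,
            class = c("scored_ddis", "data.frame"))
}
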