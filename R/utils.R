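# Internal helpers shared across modules.

KEY_SEP <- "|"

#' @noRd
check_ids <- function(x, what = "identifier") {
  bad <- !nzchar(x) | grepl("[[:space:]]", x) | is.na(x)
  if (any(bad)) {
    stop(sprintf("invalid %s: %s", what,
                 paste(utils::head(unique(x[bad]), 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

# Byte-order (C locale) string comparison, independent of the session locale.
# Returns TRUE where a < b bytewise.
#' @noRd
str_lt <- function(a, b) {
  n <- length(a)
  stopifnot(length(b) == n)
  if (n == 0L) return(logical(0))
  both <- c(a, b)
  o <- order(both, method = "radix")
  r <- integer(2L * n)
  r[o] <- seq_along(o)
  (r[seq_len(n)] < r[n + seq_len(n)]) & (a != b)
}

# Canonical unordered pair: smaller id first by byte order.
#' @noRd
order_pair <- function(a, b) {
  swap <- str_lt(b, a)
  list(first = ifelse(swap, b, a), second = ifelse(swap, a, b))
}

#' @noRd
sort_c <- function(x) sort(x, method = "radix")

# A DDI key is "A|B" with A <= B bytewise; domains never contain whitespace
# or "|", so the key is unambiguous.
#' @noRd
make_keys <- function(a, b) {
  p <- order_pair(a, b)
  paste(p$first, p$second, sep = KEY_SEP)
}

#' @noRd
split_keys <- function(keys) {
  if (length(keys) == 0L) {
    return(data.frame(domain_a = character(), domain_b = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(keys, KEY_SEP, fixed = TRUE)
  data.frame(domain_a = vapply(parts, `[`, "", 1L),
             domain_b = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.  All stochastic operations in the package go
# through this so results are reproducible per call, not per session.
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
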