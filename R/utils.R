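# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' that deterministic generators never perturb user code.
#' @noRd
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had_old <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had_old) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had_old) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic 31-bit stream seed derived from a base seed plus labels.
# Gives every (genotype, replicate) its own reproducible RNG stream, so
# adding replicates never perturbs existing ones.
derive_seed <- function(...) {
  s <- paste(vapply(list(...), as.character, character(1L)), collapse = "")
  h <- 17
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483629
  as.integer(h)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be a single non-missing number", name)
  if (x < lower || x > upper)
    stopf("'%s' must be in [%s, %s] (got %s)", name, lower, upper, x)
  if (integerish && x != round(x))
    stopf("'%s' must be a whole number (got %s)", name, x)
  invisible(x)
}

check_fraction <- function(x, name) check_number(x, name, 0, 1)

# Site identity used for unions/intersections across replicates.
site_key <- function(records) {
  paste(records$chrom, records$start, records$strand, sep = ":")
}

check_records <- function(records, counts = TRUE) {
  need <- c("chrom", "start", "end", "strand", "context")
  if (counts) need <- c(need, "n_meth", "n_unmeth", "n_illegitimate")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stopf("records are missing column(s): %s", paste(miss, collapse = ", "))
  invisible(records)
}

empty_records <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), context = character(),
             n_meth = integer(), n_unmeth = integer(),
             n_illegitimate = integer(), stringsAsFactors = FALSE)
}

# Normal deviates truncated at zero (area measurements cannot be negative).
rnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}
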