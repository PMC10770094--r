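# Fixtures and independent oracles used across the suite. Oracles are
# deliberately written with different primitives than the implementation
# (string reversal, row-wise loops, sort-based statistics).

make_records <- function(chrom = "chr1", start, strand = "+",
                         context = "CG", n_meth, n_unmeth,
                         n_illegitimate = 0L) {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start) + 1L, strand = strand,
             context = context, n_meth = as.integer(n_meth),
             n_unmeth = as.integer(n_unmeth),
             n_illegitimate = as.integer(n_illegitimate),
             stringsAsFactors = FALSE)
}

random_records <- function(n, seed, contexts = c("CG", "CHG", "CHH")) {
  set.seed(seed)
  make_records(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
               start = sample.int(10 * n, n),
               strand = sample(c("+", "-"), n, replace = TRUE),
               context = sample(contexts, n, replace = TRUE),
               n_meth = rpois(n, 3), n_unmeth = rpois(n, 3),
               n_illegitimate = rbinom(n, 4, 0.2))
}

random_sequence <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# String-based context oracle: builds the literal trinucleotide read on the
# cytosine's own strand via reverse complementation, then looks it up.
reverse_complement <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

brute_context <- function(sequence, position, strand) {
  n <- nchar(sequence)
  tri <- if (strand == "+") {
    if (position + 3 > n) return("none")
    substr(sequence, position + 1, position + 3)
  } else {
    if (position - 2 < 0) return("none")
    reverse_complement(substr(sequence, position - 1, position + 1))
  }
  if (substr(tri, 1, 1) != "C" || grepl("N", tri)) return("none")
  b2 <- substr(tri, 2, 2)
  b3 <- substr(tri, 3, 3)
  if (b2 == "G") "CG"
  else if (b3 == "G") "CHG"
  else "CHH"
}

# Sort-based median and m.a.d., coded independently of stats::median/mad.
oracle_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

oracle_mad <- function(x, constant = 1.4826) {
  constant * oracle_median(abs(x - oracle_median(x)))
}

# Row-wise filter predicate, mirroring the documented rules literally.
oracle_filter_keep <- function(rec, params) {
  depth <- rec$n_meth + rec$n_unmeth
  if (depth < params$min_depth) return(FALSE)
  if (rec$n_illegitimate / (depth + rec$n_illegitimate) >=
      params$max_variant_frac) return(FALSE)
  ratio <- rec$n_meth / depth
  if (!(ratio > params$min_ratio_exclusive)) return(FALSE)
  if (!is.null(params$high_stringency_min_ratio) &&
      ratio < params$high_stringency_min_ratio) return(FALSE)
  TRUE
}

# Normal-approximation two-sided Mann-Whitney p with tie correction and
# continuity correction, coded from the textbook formula.
oracle_u_pvalue <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(a, b))
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (abs(u - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
  2 * pnorm(-z)
}

# A small two-group replicate set with planted per-site differences:
# group B is flat at `base`, group A is `base + d` (noise-free counts at
# high depth so observed ratios equal the planted values).
planted_groups <- function(d, base = 0.4, spacing = 50L, depth = 1000L,
                           n_reps = 2L) {
  n <- length(d)
  start <- seq(0L, by = spacing, length.out = n)
  rec <- function(r) make_records(start = start, context = "CG",
                                  n_meth = round(depth * r),
                                  n_unmeth = depth - round(depth * r))
  list(a = replicate(n_reps, rec(base + d), simplify = FALSE),
       b = replicate(n_reps, rec(rep(base, n)), simplify = FALSE))
}
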