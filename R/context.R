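#' Site filter parameters
#'
#' Defaults mirror a standard bisulfite extraction/summarization setup:
#' minimum depth 4, illegitimate-base (SNP) allelic fraction below 0.25,
#' and exclusion of ratio-0 sites (the "covered, non-zero" filter applied
#' before building violin matrices). `high_stringency_min_ratio`, when set
#' (conventionally 0.25), additionally removes the low-ratio artefact band
#' by requiring ratio >= that threshold.
#'
#' @param min_depth Minimum informative reads (`n_meth + n_unmeth`).
#' @param max_variant_frac Keep sites with
#'   `n_illegitimate / (n_meth + n_unmeth + n_illegitimate)` strictly below
#'   this fraction.
#' @param min_ratio_exclusive Keep sites with ratio strictly greater than
#'   this value (default 0: drop unmethylated sites). Set to a negative
#'   value to keep ratio-0 sites.
#' @param high_stringency_min_ratio Optional inclusive lower ratio bound.
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(min_depth = 4L, max_variant_frac = 0.25,
                          min_ratio_exclusive = 0,
                          high_stringency_min_ratio = NULL) {
  check_number(min_depth, "min_depth", lower = 1, integerish = TRUE)
  check_fraction(max_variant_frac, "max_variant_frac")
  check_number(min_ratio_exclusive, "min_ratio_exclusive", lower = -1,
               upper = 1)
  if (!is.null(high_stringency_min_ratio))
    check_fraction(high_stringency_min_ratio, "high_stringency_min_ratio")
  structure(list(min_depth = as.integer(min_depth),
                 max_variant_frac = max_variant_frac,
                 min_ratio_exclusive = min_ratio_exclusive,
                 high_stringency_min_ratio = high_stringency_min_ratio),
            class = "filter_params")
}

# Vectorized trinucleotide -> context rule. d1, d2 are the two bases
# downstream of the cytosine on its own strand; NA marks a sequence edge.
# H is A, C or T. Any N (or edge) in the window gives "none".
.context_from_downstream <- function(d1, d2) {
  ctx <- rep("none", length(d1))
  ok <- !is.na(d1) & !is.na(d2) & d1 != "N" & d2 != "N"
  ctx[ok & d1 == "G"] <- "CG"
  h <- ok & d1 %in% c("A", "C", "T")
  ctx[h & d2 == "G"] <- "CHG"
  ctx[h & d2 %in% c("A", "C", "T")] <- "CHH"
  ctx
}

.complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Classify the context of a single cytosine
#'
#' Reads the two bases downstream of the cytosine on its own strand (for
#' the minus strand, leftward on the reverse complement): `CG*` is CG,
#' `CHG` is CHG, `CHH` is CHH, with H one of A/C/T. Returns `"none"` when
#' fewer than two downstream bases exist or when an N falls in the window.
#'
#' @param reference Named character vector of sequences.
#' @param chrom Sequence name.
#' @param position 0-based position of the cytosine.
#' @param strand `"+"` (forward C) or `"-"` (forward G, i.e. a cytosine on
#'   the reverse strand).
#' @return One of `"CG"`, `"CHG"`, `"CHH"`, `"none"`.
#' @examples
#' classify_context(c(chr = "ACGT"), "chr", 1, "+")   # "CG"
#' classify_context(c(chr = "ACAGT"), "chr", 1, "+")  # "CHG"
#' @export
classify_context <- function(reference, chrom, position, strand) {
  if (!chrom %in% names(reference)) stopf("unknown sequence '%s'", chrom)
  seq <- toupper(reference[[chrom]])
  n <- nchar(seq)
  check_number(position, "position", lower = 0, upper = n - 1,
               integerish = TRUE)
  if (!strand %in% c("+", "-")) stopf("strand must be '+' or '-'")
  base_at <- function(p) if (p < 0 || p >= n) NA_character_ else
    substr(seq, p + 1, p + 1)
  b <- base_at(position)
  if (strand == "+") {
    if (!identical(b, "C"))
      stopf("base at %s:%d(+) is '%s', not a cytosine", chrom, position, b)
    .context_from_downstream(base_at(position + 1), base_at(position + 2))
  } else {
    if (!identical(b, "G"))
      stopf("base at %s:%d(-) is '%s', not a cytosine on the reverse strand",
            chrom, position, b)
    d1 <- base_at(position - 1)
    d2 <- base_at(position - 2)
    .context_from_downstream(
      if (is.na(d1)) NA_character_ else .complement[[d1]],
      if (is.na(d2)) NA_character_ else .complement[[d2]])
  }
}

#' Enumerate and classify every cytosine site in a reference
#'
#' Scans both strands; sites whose context is `"none"` (sequence edge or N
#' in the window) are excluded.
#'
#' @param reference Named character vector of sequences.
#' @return Data frame with columns `chrom`, `start` (0-based), `strand`,
#'   `context`, ordered by chromosome, position, strand.
#' @export
classify_cytosines <- function(reference) {
  if (!is.character(reference) || is.null(names(reference)))
    stopf("'reference' must be a named character vector of sequences")
  out <- lapply(names(reference), function(chrom) {
    b <- strsplit(toupper(reference[[chrom]]), "")[[1L]]
    n <- length(b)
    at <- function(i) ifelse(i >= 1 & i <= n, b[pmax(pmin(i, n), 1)],
                             NA_character_)
    fwd <- which(b == "C")
    rev <- which(b == "G")
    fwd_ctx <- .context_from_downstream(at(fwd + 1L), at(fwd + 2L))
    rev_ctx <- .context_from_downstream(
      unname(.complement[at(rev - 1L)]), unname(.complement[at(rev - 2L)]))
    df <- data.frame(
      chrom = chrom,
      start = c(fwd, rev) - 1L,
      strand = rep(c("+", "-"), c(length(fwd), length(rev))),
      context = c(fwd_ctx, rev_ctx),
      stringsAsFactors = FALSE)
    df <- df[df$context != "none", , drop = FALSE]
    df[order(df$start, df$strand), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Merge symmetric CG strand pairs
#'
#' Destrands CG records: each record is re-anchored at the forward-strand C
#' of its CG dinucleotide (`start` for `+` records, `start - 1` for `-`
#' records), pairs at the same anchor have their counts summed, and the
#' merged record spans the 2-bp dinucleotide `[anchor, anchor + 2)` on the
#' `+` strand. Records already spanning 2 bp are treated as merged, so the
#' operation is idempotent. CHG/CHH records are never merged.
#'
#' @param records Site record data frame (see [read_bedgraph()]).
#' @return Records with all CG entries destranded, sorted by position.
#' @export
merge_cg_strands <- function(records) {
  check_records(records)
  key <- paste(records$chrom, records$start, records$strand)
  if (anyDuplicated(key))
    stopf("duplicate records for the same (chrom, position, strand)")
  is_cg <- records$context == "CG"
  rest <- records[!is_cg, , drop = FALSE]
  cg <- records[is_cg, , drop = FALSE]
  if (nrow(cg)) {
    anchor <- ifelse(cg$strand == "+" | (cg$end - cg$start) == 2L,
                     cg$start, cg$start - 1L)
    gk <- paste(cg$chrom, anchor, sep = ":")
    sums <- rowsum(cbind(cg$n_meth, cg$n_unmeth, cg$n_illegitimate),
                   group = gk)
    m <- match(rownames(sums), gk)
    cg <- data.frame(chrom = cg$chrom[m], start = anchor[m],
                     end = anchor[m] + 2L, strand = "+", context = "CG",
                     n_meth = as.integer(sums[, 1L]),
                     n_unmeth = as.integer(sums[, 2L]),
                     n_illegitimate = as.integer(sums[, 3L]),
                     stringsAsFactors = FALSE)
  }
  out <- rbind(cg, rest)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Methylation ratio from read counts
#'
#' The exact rational ratio `n_meth / (n_meth + n_unmeth)`; never derived
#' from a file's rounded percent column.
#'
#' @param records Either a site record data frame or a numeric vector of
#'   methylated counts (with `n_unmeth` supplied).
#' @param n_unmeth Unmethylated counts when `records` is a numeric vector.
#' @return Numeric vector of ratios in `[0, 1]`.
#' @export
compute_ratio <- function(records, n_unmeth = NULL) {
  if (is.data.frame(records)) {
    n_meth <- records$n_meth
    n_unmeth <- records$n_unmeth
  } else {
    n_meth <- records
  }
  depth <- n_meth + n_unmeth
  if (any(depth <= 0)) stopf("zero-depth site: ratio undefined")
  n_meth / depth
}

#' Apply per-site quality filters
#'
#' Keeps records with depth `>= min_depth`, illegitimate-base fraction
#' strictly below `max_variant_frac` (denominator: all reads at the site),
#' ratio strictly above `min_ratio_exclusive`, and, when set, ratio
#' `>= high_stringency_min_ratio`. Input order is preserved; the predicates
#' commute, so the filter is idempotent and order-independent.
#'
#' @param records Site record data frame.
#' @param params A [filter_params()].
#' @return The qualifying subset of `records` (possibly empty).
#' @export
apply_site_filters <- function(records, params = filter_params()) {
  check_records(records)
  if (!inherits(params, "filter_params"))
    stopf("'params' must be filter_params()")
  if (nrow(records) == 0L) return(records)
  depth <- records$n_meth + records$n_unmeth
  total <- depth + records$n_illegitimate
  ratio <- ifelse(depth > 0, records$n_meth / depth, NA_real_)
  keep <- depth >= params$min_depth &
    records$n_illegitimate / total < params$max_variant_frac &
    ratio > params$min_ratio_exclusive
  if (!is.null(params$high_stringency_min_ratio))
    keep <- keep & ratio >= params$high_stringency_min_ratio
  out <- records[which(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the site-by-sample ratio matrix over the all-condition intersection
#'
#' Filters every replicate individually, then restricts to sites passing
#' the filters in every replicate of every condition, and returns one ratio
#' column per replicate. This is the joint matrix on which pooled ratio
#' statistics (and DMR calling) operate.
#'
#' @param groups Named list: condition -> list of replicate record data
#'   frames.
#' @param params A [filter_params()] applied per replicate before
#'   intersecting.
#' @return Numeric matrix (sites x samples) with row names
#'   `chrom:start:strand`, column names `<condition>.<replicate>`, and a
#'   `"sites"` attribute holding the site coordinate data frame. An empty
#'   intersection yields a 0-row matrix.
#' @export
intersect_sites <- function(groups, params = filter_params()) {
  if (!is.list(groups) || is.null(names(groups)) || length(groups) == 0L)
    stopf("'groups' must be a non-empty named list of replicate lists")
  filtered <- lapply(groups, function(reps) {
    if (length(reps) == 0L) stopf("every condition needs >= 1 replicate")
    lapply(reps, apply_site_filters, params = params)
  })
  keys <- unlist(lapply(filtered, function(reps) lapply(reps, site_key)),
                 recursive = FALSE)
  common <- Reduce(intersect, keys)
  first <- filtered[[1L]][[1L]]
  idx <- match(common, site_key(first))
  sites <- first[idx, c("chrom", "start", "end", "strand", "context"),
                 drop = FALSE]
  ord <- order(sites$chrom, sites$start, sites$strand)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  common <- common[ord]
  cols <- list()
  for (cond in names(filtered)) {
    reps <- filtered[[cond]]
    for (j in seq_along(reps)) {
      r <- reps[[j]]
      m <- match(common, site_key(r))
      cols[[paste(cond, j, sep = ".")]] <-
        r$n_meth[m] / (r$n_meth[m] + r$n_unmeth[m])
    }
  }
  mat <- do.call(cbind, cols)
  if (is.null(mat)) mat <- matrix(numeric(), nrow = 0L, ncol = 0L)
  rownames(mat) <- common
  attr(mat, "sites") <- sites
  mat
}
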