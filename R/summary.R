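#' Count distinct methylated sites per condition (replicate union)
#'
#' Applies the site filters to every replicate individually, then counts
#' distinct `(chrom, start, strand)` sites appearing in at least one
#' replicate of the condition. With the default non-zero ratio filter this
#' is the per-condition methylated-site count underlying normalized
#' site-count comparisons.
#'
#' @param groups Named list: condition -> list of replicate record data
#'   frames.
#' @param params A [filter_params()].
#' @return Named integer vector of union sizes.
#' @export
count_methylated_sites <- function(groups, params = filter_params()) {
  if (!is.list(groups) || is.null(names(groups)))
    stopf("'groups' must be a named list of replicate lists")
  vapply(groups, function(reps) {
    keys <- unlist(lapply(reps, function(r)
      site_key(apply_site_filters(r, params))))
    length(unique(keys))
  }, integer(1L))
}

#' Normalize per-condition counts to a reference condition
#'
#' The reference condition (conventionally wild type) is set to exactly
#' 100; every other condition is scaled linearly:
#' `100 * count / count_reference`.
#'
#' @param counts Named numeric vector of per-condition counts.
#' @param reference Name of the reference condition.
#' @return Named numeric vector of normalized counts.
#' @examples
#' normalize_counts(c(wt = 50, mut = 100, dbl = 25), "wt")
#' @export
normalize_counts <- function(counts, reference) {
  if (!reference %in% names(counts))
    stopf("reference condition '%s' not found", reference)
  ref <- counts[[reference]]
  if (!is.finite(ref) || ref <= 0)
    stopf("reference count must be positive (got %s)", ref)
  100 * counts / ref
}

#' Pooled ratio statistics per condition
#'
#' Pools the per-site ratios of all replicate columns belonging to each
#' condition (no per-replicate averaging) and reports mean, median, and
#' m.a.d. The even-length median is the mean of the two middle values; the
#' m.a.d. is `constant * median(|x - median(x)|)` with the 1.4826
#' normal-consistency constant by default (set `mad_constant = 1` for the
#' raw m.a.d.).
#'
#' @param mat Site-by-sample ratio matrix from [intersect_sites()].
#' @param grouping Named list condition -> column names/indices. Defaults
#'   to grouping columns by the `<condition>.<replicate>` prefix.
#' @param mad_constant Consistency constant for the m.a.d.
#' @return Data frame with one row per condition: `condition`, `n_values`,
#'   `mean_ratio`, `median_ratio`, `mad_ratio`.
#' @export
summarize_ratios <- function(mat, grouping = NULL, mad_constant = 1.4826) {
  if (!is.matrix(mat) || nrow(mat) == 0L)
    stopf("'mat' must be a non-empty site-by-sample matrix")
  if (is.null(grouping)) {
    cond <- sub("\\.[^.]*$", "", colnames(mat))
    grouping <- split(colnames(mat), factor(cond, unique(cond)))
  }
  rows <- lapply(names(grouping), function(g) {
    x <- as.vector(mat[, grouping[[g]], drop = FALSE])
    x <- x[!is.na(x)]
    if (length(x) == 0L) stopf("condition '%s' has no ratio values", g)
    data.frame(condition = g, n_values = length(x), mean_ratio = mean(x),
               median_ratio = stats::median(x),
               mad_ratio = stats::mad(x, constant = mad_constant),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Restoration fraction in a double mutant
#'
#' The proportion of the single-mutant-induced change in mean methylation
#' ratio that is reversed in the double mutant:
#' `(mean_double - mean_single) / (mean_wt - mean_single)`. Equals 0 for no
#' restoration and 1 for full restoration; values above 1 indicate
#' over-restoration (double mutant beyond wild-type levels). Invariant
#' under affine transformations of the ratio scale.
#'
#' @param mean_wt,mean_single,mean_double Mean methylation ratios.
#' @return The restoration fraction.
#' @examples
#' restoration_fraction(0.8, 0.4, 0.7)  # 0.75
#' @export
restoration_fraction <- function(mean_wt, mean_single, mean_double) {
  check_number(mean_wt, "mean_wt")
  check_number(mean_single, "mean_single")
  check_number(mean_double, "mean_double")
  if (mean_wt == mean_single)
    stopf("restoration undefined: wild-type and single-mutant means equal")
  (mean_double - mean_single) / (mean_wt - mean_single)
}

#' Methylation meta-profile around transcription start sites
#'
#' Assigns sites to fixed-width bins by signed distance to the TSS
#' (negative = upstream; minus-strand genes are mirrored before binning)
#' and averages ratios per bin over all contributing (site, TSS) pairs.
#' Bins are half-open `[a, a + bin_size)`; a site exactly at the TSS lands
#' in the first downstream bin.
#'
#' @param records Filtered site record data frame.
#' @param tss TSS data frame in BED6 layout (`chrom`, `start`, `end`,
#'   `name`, `score`, `strand`); the TSS coordinate is `start`.
#' @param upstream,downstream Window half-widths in bp (defaults 3000).
#' @param bin_size Bin width in bp; must divide the window exactly.
#' @return Data frame with `bin_start` (signed distance of the bin's left
#'   edge to the TSS), `mean_ratio` (NA for empty bins), `n_sites`.
#' @export
tss_profile <- function(records, tss, upstream = 3000, downstream = 3000,
                        bin_size = 100) {
  check_records(records)
  check_number(upstream, "upstream", lower = 1, integerish = TRUE)
  check_number(downstream, "downstream", lower = 1, integerish = TRUE)
  check_number(bin_size, "bin_size", lower = 1, integerish = TRUE)
  if ((upstream + downstream) %% bin_size != 0)
    stopf("bin_size must divide the %d bp window", upstream + downstream)
  if (!all(c("chrom", "start", "strand") %in% names(tss)))
    stopf("'tss' must carry chrom, start and strand columns")
  if (!all(tss$strand %in% c("+", "-")))
    stopf("TSS entries must carry strand '+' or '-'")
  nbins <- (upstream + downstream) %/% bin_size
  ratio <- compute_ratio(records)
  all_bins <- integer(0)
  all_ratios <- numeric(0)
  for (i in seq_len(nrow(tss))) {
    on_chrom <- which(records$chrom == tss$chrom[i])
    if (!length(on_chrom)) next
    d <- records$start[on_chrom] - tss$start[i]
    if (tss$strand[i] == "-") d <- -d
    in_win <- d >= -upstream & d < downstream
    if (!any(in_win)) next
    all_bins <- c(all_bins, (d[in_win] + upstream) %/% bin_size + 1L)
    all_ratios <- c(all_ratios, ratio[on_chrom][in_win])
  }
  counts <- tabulate(all_bins, nbins)
  sums <- numeric(nbins)
  if (length(all_bins)) {
    s <- rowsum(all_ratios, all_bins)
    sums[as.integer(rownames(s))] <- s[, 1L]
  }
  data.frame(bin_start = seq(-upstream, downstream - bin_size, by = bin_size),
             mean_ratio = ifelse(counts > 0, sums / counts, NA_real_),
             n_sites = counts)
}

#' Paired fraction-methylated vs mean-ratio coordinates
#'
#' Extracts, per genotype and context, the pair (fraction of assayable
#' sites methylated, mean methylation ratio) used for correlation plots.
#' No fitting is performed.
#'
#' @param summaries A context summary data frame from
#'   [summarize_contexts()].
#' @return Data frame with `genotype`, `context`,
#'   `frac_sites_methylated`, `mean_ratio`.
#' @export
fraction_vs_mean <- function(summaries) {
  need <- c("genotype", "context", "frac_sites_methylated", "mean_ratio")
  miss <- setdiff(need, names(summaries))
  if (length(miss))
    stopf("summaries missing column(s): %s", paste(miss, collapse = ", "))
  out <- summaries[, need, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-genotype, per-context methylome summary
#'
#' For every context (CG, CHG, CHH) computes per condition: the distinct
#' methylated-site count over the replicate union, that count normalized to
#' the reference condition (= 100), pooled mean/median/m.a.d. ratios over
#' the all-condition intersection, and the fraction of assayable sites
#' (depth- and variant-passing) with ratio > 0. Site counts use the union,
#' ratio statistics the intersection — deliberately asymmetric, matching
#' the way union site tallies and joint violin matrices are built.
#'
#' @param groups Named list: condition -> list of replicate record data
#'   frames (per-strand, unmerged records are expected).
#' @param reference Name of the reference condition (wild type).
#' @param params A [filter_params()].
#' @param mad_constant Consistency constant for the m.a.d.
#' @return Data frame with one row per condition x context: `genotype`,
#'   `context`, `n_sites_union`, `normalized_count`, `mean_ratio`,
#'   `median_ratio`, `mad_ratio`, `frac_sites_methylated`.
#' @export
summarize_contexts <- function(groups, reference, params = filter_params(),
                               mad_constant = 1.4826) {
  if (!reference %in% names(groups))
    stopf("reference condition '%s' not found", reference)
  assay_params <- params
  assay_params$min_ratio_exclusive <- -1   # keep ratio-0 sites
  assay_params$high_stringency_min_ratio <- NULL
  out <- lapply(c("CG", "CHG", "CHH"), function(ctx) {
    sub <- lapply(groups, function(reps)
      lapply(reps, function(r) r[r$context == ctx, , drop = FALSE]))
    counts <- count_methylated_sites(sub, params)
    norm <- normalize_counts(counts, reference)
    mat <- intersect_sites(sub, params)
    stats_df <- if (nrow(mat) > 0) {
      summarize_ratios(mat, mad_constant = mad_constant)
    } else {
      # no site passes the filters in every replicate of every condition
      data.frame(condition = names(groups), mean_ratio = NA_real_,
                 median_ratio = NA_real_, mad_ratio = NA_real_,
                 stringsAsFactors = FALSE)
    }
    frac <- vapply(sub, function(reps) {
      mean(vapply(reps, function(r) {
        a <- apply_site_filters(r, assay_params)
        if (nrow(a) == 0L) return(NA_real_)
        mean(compute_ratio(a) > 0)
      }, numeric(1L)), na.rm = TRUE)
    }, numeric(1L))
    m <- match(names(groups), stats_df$condition)
    data.frame(genotype = names(groups), context = ctx,
               n_sites_union = unname(counts),
               normalized_count = unname(norm),
               mean_ratio = stats_df$mean_ratio[m],
               median_ratio = stats_df$median_ratio[m],
               mad_ratio = stats_df$mad_ratio[m],
               frac_sites_methylated = unname(frac),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
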