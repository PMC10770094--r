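#' DMR calling parameters
#'
#' Defaults follow the standard segmentation thresholds for vertebrate
#' WGBS: candidate regions are runs of CG sites at most `max_dist` bp
#' apart, with at least `min_cpgs` sites, every site covered by at least
#' `min_coverage` reads in every sample, an absolute between-group mean
#' methylation difference of at least `min_meth_diff`, and a
#' Benjamini-Hochberg q-value at most `fdr`.
#'
#' @param max_dist Maximum distance between consecutive CG sites (bp).
#' @param min_cpgs Minimum CG sites per region.
#' @param min_coverage Minimum reads per site per sample.
#' @param min_meth_diff Minimum absolute mean methylation difference.
#' @param fdr q-value threshold.
#' @return An object of class `dmr_params`.
#' @export
dmr_params <- function(max_dist = 300L, min_cpgs = 10L, min_coverage = 5L,
                       min_meth_diff = 0.1, fdr = 0.1) {
  check_number(max_dist, "max_dist", lower = 1, integerish = TRUE)
  check_number(min_cpgs, "min_cpgs", lower = 1, integerish = TRUE)
  check_number(min_coverage, "min_coverage", lower = 1, integerish = TRUE)
  check_number(min_meth_diff, "min_meth_diff", lower = 1e-12, upper = 1)
  check_number(fdr, "fdr", lower = 1e-12, upper = 1)
  structure(list(max_dist = as.integer(max_dist),
                 min_cpgs = as.integer(min_cpgs),
                 min_coverage = as.integer(min_coverage),
                 min_meth_diff = min_meth_diff, fdr = fdr),
            class = "dmr_params")
}

#' Group CG sites into candidate blocks by proximity
#'
#' Partitions position-sorted CG sites into maximal runs in which
#' consecutive sites are at most `max_dist` bp apart (per chromosome);
#' runs with fewer than `min_cpgs` sites are discarded.
#'
#' @param sites Data frame with `chrom` and `start`, sorted by position,
#'   one row per site (row order must match the ratio matrix).
#' @param params A [dmr_params()].
#' @return List of integer vectors of row indices, one per block.
#' @export
build_candidate_blocks <- function(sites, params = dmr_params()) {
  n <- nrow(sites)
  if (n == 0L) return(list())
  new_block <- c(TRUE, sites$chrom[-1L] != sites$chrom[-n] |
                   diff(sites$start) > params$max_dist)
  blocks <- split(seq_len(n), cumsum(new_block))
  unname(blocks[lengths(blocks) >= params$min_cpgs])
}

#' Segment a block into candidate differential subregions
#'
#' Recursive top-down search on the per-site mean methylation differences
#' `d` (group A minus group B): if the whole block's `|mean(d)|` reaches
#' `min_meth_diff` it is emitted; otherwise the block is split at the site
#' maximizing the CUSUM contrast `|cumsum(d - mean(d))|` (leftmost index on
#' ties, and only at splits leaving at least `min_cpgs` sites on each
#' side), and both halves are searched recursively.
#'
#' @param d Numeric vector of per-site differences.
#' @param params A [dmr_params()].
#' @return List of integer vectors `c(first, last)` (1-based, inclusive)
#'   into `d`, in left-to-right order.
#' @export
segment_block <- function(d, params = dmr_params()) {
  recurse <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n < params$min_cpgs) return(list())
    dd <- d[lo:hi]
    if (abs(mean(dd)) >= params$min_meth_diff) return(list(c(lo, hi)))
    if (n < 2L * params$min_cpgs) return(list())
    ks <- params$min_cpgs:(n - params$min_cpgs)
    s <- cumsum(dd - mean(dd))
    k <- ks[which.max(abs(s[ks]))]
    c(recurse(lo, lo + k - 1L), recurse(lo + k, hi))
  }
  recurse(1L, length(d))
}

#' Test candidate regions and control the FDR
#'
#' Each candidate is tested with a two-sided Mann-Whitney U test comparing
#' the pooled per-site ratios of group A against group B at the
#' candidate's sites; p-values are corrected across all candidates with
#' Benjamini-Hochberg, and candidates with `q <= fdr` are retained.
#' Candidates with fewer than two values in either group are dropped with
#' a warning.
#'
#' @param candidates List of candidate descriptions, each a list with
#'   `chrom`, `start`, `end`, `n_cpgs`, `mean_diff`, `values_a`,
#'   `values_b`.
#' @param params A [dmr_params()].
#' @return A DMR data frame: `chrom`, `start`, `end`, `n_cpgs`,
#'   `mean_diff`, `p_value`, `q_value` (0-based half-open coordinates).
#' @export
test_and_correct <- function(candidates, params = dmr_params()) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpgs = integer(),
                      mean_diff = numeric(), p_value = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE)
  if (length(candidates) == 0L) return(empty)
  ok <- vapply(candidates, function(cand)
    length(cand$values_a) >= 2L && length(cand$values_b) >= 2L, logical(1L))
  if (any(!ok))
    warnf("dropping %d candidate(s) with < 2 values per group", sum(!ok))
  candidates <- candidates[ok]
  if (length(candidates) == 0L) return(empty)
  p <- vapply(candidates, function(cand) {
    suppressWarnings(stats::wilcox.test(cand$values_a, cand$values_b,
                                        exact = FALSE)$p.value)
  }, numeric(1L))
  q <- stats::p.adjust(p, method = "BH")
  keep <- which(q <= params$fdr)
  out <- do.call(rbind, lapply(keep, function(i) {
    cand <- candidates[[i]]
    data.frame(chrom = cand$chrom, start = cand$start, end = cand$end,
               n_cpgs = cand$n_cpgs, mean_diff = cand$mean_diff,
               p_value = p[i], q_value = q[i], stringsAsFactors = FALSE)
  }))
  if (is.null(out)) return(empty)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call differentially methylated regions between two groups
#'
#' End-to-end caller: builds the site-by-sample ratio matrix over CG sites
#' covered by at least `min_coverage` reads in every sample of both groups
#' (ratio-0 sites are retained), groups sites into proximity blocks,
#' segments each block on the per-site mean difference (group A minus
#' group B), and tests the candidates with FDR control. This is a
#' transparent CUSUM-split + rank-test caller honoring the standard
#' threshold semantics; it is deliberately not a reimplementation of any
#' published segmentation tool's internal statistic.
#'
#' @param group_a,group_b Lists of replicate record data frames
#'   (CG-context records; destrand with [merge_cg_strands()] first if
#'   desired).
#' @param params A [dmr_params()].
#' @param name_a,name_b Labels used for the matrix columns.
#' @return A DMR data frame (see [test_and_correct()]); `mean_diff` is
#'   signed as group A minus group B.
#' @export
call_dmrs <- function(group_a, group_b, params = dmr_params(),
                      name_a = "A", name_b = "B") {
  cov_filter <- filter_params(min_depth = params$min_coverage,
                              max_variant_frac = 1,
                              min_ratio_exclusive = -1)
  groups <- list(lapply(group_a, function(r)
                   r[r$context == "CG", , drop = FALSE]),
                 lapply(group_b, function(r)
                   r[r$context == "CG", , drop = FALSE]))
  names(groups) <- c(name_a, name_b)
  mat <- intersect_sites(groups, cov_filter)
  sites <- attr(mat, "sites")
  if (nrow(mat) == 0L) return(test_and_correct(list(), params))
  is_a <- sub("\\.[^.]*$", "", colnames(mat)) == name_a
  d <- rowMeans(mat[, is_a, drop = FALSE]) -
    rowMeans(mat[, !is_a, drop = FALSE])
  blocks <- build_candidate_blocks(sites, params)
  candidates <- list()
  for (block in blocks) {
    for (reg in segment_block(d[block], params)) {
      rows <- block[reg[1L]:reg[2L]]
      candidates[[length(candidates) + 1L]] <- list(
        chrom = sites$chrom[rows[1L]],
        start = sites$start[rows[1L]],
        end = sites$end[rows[length(rows)]],
        n_cpgs = length(rows),
        mean_diff = mean(d[rows]),
        values_a = as.vector(mat[rows, is_a, drop = FALSE]),
        values_b = as.vector(mat[rows, !is_a, drop = FALSE]))
    }
  }
  test_and_correct(candidates, params)
}
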