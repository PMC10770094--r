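test_that("single-site context classification follows the CG/CHG/CHH rule", {
  expect_equal(classify_context(c(chr = "ACGT"), "chr", 1, "+"), "CG")
  expect_equal(classify_context(c(chr = "ACAGT"), "chr", 1, "+"), "CHG")
  expect_equal(classify_context(c(chr = "ACAAT"), "chr", 1, "+"), "CHH")
  # reverse strand: forward G at 2 reads CG on the reverse complement
  expect_equal(classify_context(c(chr = "ACGT"), "chr", 2, "-"), "CG")
  # a reverse-strand cytosine reads leftward: CG even near the right edge
  expect_equal(classify_context(c(chr = "AACG"), "chr", 3, "-"), "CG")
  # edges and ambiguity bases give none
  expect_equal(classify_context(c(chr = "ACNGT"), "chr", 1, "+"), "none")
  expect_equal(classify_context(c(chr = "AAAC"), "chr", 3, "+"), "none")
  expect_equal(classify_context(c(chr = "AG"), "chr", 1, "-"), "none")
  expect_error(classify_context(c(chr = "ACGT"), "chr", 0, "+"),
               "not a cytosine")
  expect_error(classify_context(c(chr = "ACGT"), "chr", 1, "-"),
               "not a cytosine")
})

test_that("genome-wide classification agrees with the string oracle", {
  seq <- random_sequence(400, seed = 21)
  ref <- c(chr1 = seq)
  sites <- classify_cytosines(ref)
  # partition: every classified site has exactly one context
  expect_true(all(sites$context %in% c("CG", "CHG", "CHH")))
  expect_false(anyDuplicated(paste(sites$start, sites$strand)) > 0)
  for (i in seq_len(nrow(sites))) {
    expect_equal(sites$context[i],
                 brute_context(seq, sites$start[i], sites$strand[i]))
    expect_equal(sites$context[i],
                 classify_context(ref, "chr1", sites$start[i],
                                  sites$strand[i]))
  }
  # and the oracle finds nothing the scan missed
  keys <- paste(sites$start, sites$strand)
  for (pos in 0:(nchar(seq) - 1)) for (st in c("+", "-")) {
    base <- substr(seq, pos + 1, pos + 1)
    is_c <- (st == "+" && base == "C") || (st == "-" && base == "G")
    if (is_c && brute_context(seq, pos, st) != "none")
      expect_true(paste(pos, st) %in% keys)
  }
})

test_that("CG strand merging conserves counts and is idempotent", {
  # symmetric pair: forward C at 10, reverse C (forward G) at 11
  pair <- rbind(make_records(start = 10, strand = "+", n_meth = 3,
                             n_unmeth = 1),
                make_records(start = 11, strand = "-", n_meth = 1,
                             n_unmeth = 3))
  m <- merge_cg_strands(pair)
  expect_equal(nrow(m), 1L)
  expect_equal(m[, c("start", "end", "strand", "n_meth", "n_unmeth")],
               data.frame(start = 10L, end = 12L, strand = "+",
                          n_meth = 4L, n_unmeth = 4L))
  # unpaired forward records only widen to the dinucleotide
  solo <- make_records(start = c(5, 20), strand = "+",
                       n_meth = c(2, 0), n_unmeth = c(2, 5))
  ms <- merge_cg_strands(solo)
  expect_equal(ms$start, c(5L, 20L))
  expect_equal(ms$end, c(7L, 22L))
  expect_equal(ms$n_meth, solo$n_meth)
  # random toy genome: merging conserves total counts; CHG/CHH untouched
  ref <- c(chr1 = random_sequence(300, seed = 31))
  sites <- classify_cytosines(ref)
  set.seed(32)
  rec <- make_records(start = sites$start, strand = sites$strand,
                      context = sites$context,
                      n_meth = rpois(nrow(sites), 4),
                      n_unmeth = rpois(nrow(sites), 4))
  merged <- merge_cg_strands(rec)
  expect_equal(sum(merged$n_meth), sum(rec$n_meth))
  expect_equal(sum(merged$n_unmeth), sum(rec$n_unmeth))
  expect_identical(merge_cg_strands(merged), merged)
  non_cg_in <- rec[rec$context != "CG", ]
  non_cg_in <- non_cg_in[order(non_cg_in$chrom, non_cg_in$start,
                               non_cg_in$strand), ]
  expect_equal(merged[merged$context != "CG", ], non_cg_in,
               ignore_attr = TRUE)
  expect_error(merge_cg_strands(rbind(pair, pair)), "duplicate")
})

test_that("methylation ratios come from counts, exactly", {
  expect_equal(compute_ratio(0, 7), 0)
  expect_equal(compute_ratio(5, 0), 1)
  expect_equal(compute_ratio(3, 9), 0.25)
  expect_error(compute_ratio(0, 0), "zero-depth")
})

test_that("site filters equal the brute-force predicate", {
  params <- filter_params()
  expect_equal(nrow(apply_site_filters(
    make_records(start = 1, n_meth = 2, n_unmeth = 1), params)), 0L)
  expect_equal(nrow(apply_site_filters(
    make_records(start = 1, n_meth = 0, n_unmeth = 9), params)), 0L)
  for (p in list(params,
                 filter_params(min_depth = 2, max_variant_frac = 0.5,
                               min_ratio_exclusive = -1),
                 filter_params(high_stringency_min_ratio = 0.25))) {
    rec <- random_records(100, seed = 41)
    keep <- vapply(seq_len(nrow(rec)), function(i)
      oracle_filter_keep(rec[i, ], p), logical(1))
    got <- apply_site_filters(rec, p)
    expect_equal(got, rec[keep, ], ignore_attr = TRUE)
    # idempotent
    expect_equal(apply_site_filters(got, p), got)
  }
})

test_that("intersection matrix equals the brute-force set oracle", {
  params <- filter_params(min_depth = 1, min_ratio_exclusive = -1)
  set.seed(51)
  one <- make_records(start = 1:15, n_meth = rpois(15, 3),
                      n_unmeth = rpois(15, 3) + 1L)
  m <- intersect_sites(list(g = list(one)), params)
  expect_equal(nrow(m), nrow(one))
  expect_equal(unname(m[, 1]), one$n_meth / (one$n_meth + one$n_unmeth),
               ignore_attr = TRUE, tolerance = 1e-12)
  # a site absent from one replicate is excluded
  two <- one[-3, ]
  m2 <- intersect_sites(list(g = list(one, two)), params)
  expect_equal(nrow(m2), nrow(one) - 1L)
  expect_false(paste(one$chrom[3], one$start[3], one$strand[3], sep = ":")
               %in% rownames(m2))
  # toy 20-site universe, 2 conditions x 3 replicates holding random
  # 15-site subsets with fresh counts, vs brute force
  base <- make_records(start = seq(10, 200, by = 10), n_meth = 0,
                       n_unmeth = 0)
  reps <- lapply(1:6, function(i) {
    set.seed(52 + i)
    r <- base
    r$n_meth <- rpois(20, 4)
    r$n_unmeth <- rpois(20, 4)
    r$n_illegitimate <- rbinom(20, 3, 0.2)
    r[sort(sample.int(20, 15)), ]
  })
  groups <- list(a = reps[1:3], b = reps[4:6])
  mat <- intersect_sites(groups, filter_params())
  brute <- lapply(reps, function(r) {
    keep <- vapply(seq_len(nrow(r)), function(i)
      oracle_filter_keep(r[i, ], filter_params()), logical(1))
    paste(r$chrom[keep], r$start[keep], r$strand[keep], sep = ":")
  })
  expect_setequal(rownames(mat), Reduce(intersect, brute))
  expect_equal(colnames(mat), c("a.1", "a.2", "a.3", "b.1", "b.2", "b.3"))
})
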