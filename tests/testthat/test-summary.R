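test_that("union site counts match brute-force set unions", {
  params <- filter_params(min_depth = 1, min_ratio_exclusive = -1)
  a <- make_records(start = 1:10, n_meth = 1, n_unmeth = 1)
  b <- make_records(start = 11:25, n_meth = 1, n_unmeth = 1)
  expect_equal(unname(count_methylated_sites(list(g = list(a, a)), params)),
               10L)
  expect_equal(unname(count_methylated_sites(list(g = list(a, b)), params)),
               25L)
  # random overlapping replicates vs an explicit set union
  reps <- lapply(1:3, function(i) random_records(60, seed = 60 + i))
  got <- count_methylated_sites(list(g = reps))
  brute <- unique(unlist(lapply(reps, function(r) {
    keep <- vapply(seq_len(nrow(r)), function(i)
      oracle_filter_keep(r[i, ], filter_params()), logical(1))
    paste(r$chrom[keep], r$start[keep], r$strand[keep])
  })))
  expect_equal(unname(got), length(brute))
})

test_that("count normalization pins the reference at 100 and is linear", {
  expect_equal(unname(normalize_counts(c(wt = 731, mut = 731), "wt")),
               c(100, 100))
  expect_equal(unname(normalize_counts(c(wt = 10, mut = 20), "wt")[["mut"]]),
               200)
  expect_equal(unname(normalize_counts(c(a = 50, b = 100, c = 25), "a")),
               c(100, 200, 50))
  # scale invariance
  x <- c(wt = 120, m1 = 80, m2 = 150)
  expect_equal(normalize_counts(x, "wt"), normalize_counts(7 * x, "wt"))
  expect_error(normalize_counts(c(wt = 0, m = 5), "wt"), "positive")
})

test_that("pooled ratio statistics match independent median/m.a.d.", {
  m <- matrix(0.5, nrow = 4, ncol = 2,
              dimnames = list(NULL, c("g.1", "g.2")))
  s <- summarize_ratios(m)
  expect_equal(s$mean_ratio, 0.5)
  expect_equal(s$median_ratio, 0.5)
  expect_equal(s$mad_ratio, 0)
  # documented even-length convention: median of {0, 1} is 0.5
  m2 <- matrix(c(0, 1), nrow = 2, ncol = 1,
               dimnames = list(NULL, "g.1"))
  expect_equal(summarize_ratios(m2)$median_ratio, 0.5)
  # 1000 random ratios vs a sort-based reference implementation
  set.seed(71)
  x <- runif(1000)
  m3 <- matrix(x, ncol = 2, dimnames = list(NULL, c("g.1", "g.2")))
  s3 <- summarize_ratios(m3)
  expect_equal(s3$median_ratio, oracle_median(x))
  expect_equal(s3$mad_ratio, oracle_mad(x))
  expect_equal(summarize_ratios(m3, mad_constant = 1)$mad_ratio,
               oracle_mad(x, constant = 1))
  # permutation invariance in sites and replicates
  perm <- m3[sample.int(nrow(m3)), c(2, 1)]
  colnames(perm) <- c("g.1", "g.2")
  expect_equal(summarize_ratios(perm)[, -1], s3[, -1])
})

test_that("restoration fraction interpolates between single and wild type", {
  expect_equal(restoration_fraction(0.8, 0.4, 0.8), 1)
  expect_equal(restoration_fraction(0.8, 0.4, 0.4), 0)
  expect_equal(restoration_fraction(0.8, 0.4, 0.7), 0.75)
  # over-restoration beyond wild type exceeds 1 (hypermethylated doubles)
  expect_gt(restoration_fraction(0.3, 0.1, 0.4), 1)
  # affine invariance of the ratio scale
  a <- 0.2; b <- 3
  expect_equal(restoration_fraction(a + b * 0.8, a + b * 0.4, a + b * 0.7),
               0.75)
  expect_error(restoration_fraction(0.5, 0.5, 0.7), "undefined")
})

test_that("TSS profiles bin by signed, strand-aware distance", {
  tss <- data.frame(chrom = "chr1", start = 1000L, end = 1001L,
                    name = "g1", score = 0L, strand = "+")
  rec <- make_records(start = 1000, n_meth = 8, n_unmeth = 2)
  p <- tss_profile(rec, tss, upstream = 200, downstream = 200,
                   bin_size = 100)
  expect_equal(p$bin_start, c(-200, -100, 0, 100))
  expect_equal(p$n_sites, c(0L, 0L, 1L, 0L))   # site at TSS: first downstream bin
  expect_equal(p$mean_ratio[3], 0.8)
  # flat methylation gives a flat profile
  rec2 <- make_records(start = seq(0, 2000, by = 10), n_meth = 4,
                       n_unmeth = 1)
  p2 <- tss_profile(rec2, tss, upstream = 500, downstream = 500,
                    bin_size = 100)
  expect_true(all(abs(p2$mean_ratio - 0.8) < 1e-12))
  # a dip centred on the TSS puts the minimum at distance 0 +/- bin width
  d <- abs(seq(0, 2000, by = 10) - 1000)
  ratio <- pmin(0.8, 0.1 + d / 1000)
  rec3 <- make_records(start = seq(0, 2000, by = 10),
                       n_meth = round(1000 * ratio),
                       n_unmeth = 1000 - round(1000 * ratio))
  p3 <- tss_profile(rec3, tss, upstream = 500, downstream = 500,
                    bin_size = 100)
  expect_lte(abs(p3$bin_start[which.min(p3$mean_ratio)]), 100)
  # minus-strand genes are mirrored: upstream lies at larger coordinates
  tss_m <- transform(tss, strand = "-")
  up_site <- make_records(start = 1150, n_meth = 9, n_unmeth = 1)
  pm <- tss_profile(up_site, tss_m, upstream = 200, downstream = 200,
                    bin_size = 100)
  expect_equal(pm$n_sites[pm$bin_start == -200], 1L)
  expect_error(tss_profile(rec, tss, bin_size = 7), "divide")
})

test_that("fraction-vs-mean pairs reflect hypomethylation direction", {
  cfg <- synthetic_config(seed = 12, genome_length = 6000,
                          coverage_mean = 50)
  sim <- simulate_methylome_set(cfg, generate_reference(cfg))
  s <- summarize_contexts(sim$methylomes, "wt")
  pairs <- fraction_vs_mean(s)
  expect_equal(nrow(pairs), 12L)  # 4 genotypes x 3 contexts
  for (ctx in c("CG", "CHG", "CHH")) {
    wt <- pairs[pairs$genotype == "wt" & pairs$context == ctx, ]
    mut <- pairs[pairs$genotype == "dnmt1" & pairs$context == ctx, ]
    expect_lt(mut$mean_ratio, wt$mean_ratio)
    # site loss moves the mutant left of wild type at CHG/CHH; the CG
    # fraction barely moves because no CG sites are lost outright
    if (ctx != "CG")
      expect_lt(mut$frac_sites_methylated, wt$frac_sites_methylated)
  }
})

test_that("context summaries pin wild type at 100 and order genotypes", {
  cfg <- synthetic_config(seed = 13, genome_length = 6000,
                          coverage_mean = 30)
  sim <- simulate_methylome_set(cfg, generate_reference(cfg))
  s <- summarize_contexts(sim$methylomes, "wt")
  expect_equal(s$normalized_count[s$genotype == "wt"], rep(100, 3))
  cg <- s[s$context == "CG", ]
  means <- setNames(cg$mean_ratio, cg$genotype)
  expect_lt(means[["dnmt1"]], means[["wt"]])     # hypomethylated
  expect_gt(means[["pole1"]], means[["wt"]])     # hypermethylated
  expect_gt(means[["double"]], means[["dnmt1"]]) # partially restored
  expect_lt(means[["double"]], means[["wt"]])
})
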