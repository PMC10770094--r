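#' Configuration for the synthetic methylome generator
#'
#' Bundles every effect size, noise parameter and seed used to simulate
#' genotype-structured whole-genome bisulfite methylomes for four genotypes:
#' wild type, a maintenance-methylase hypomorph (`dnmt1`-like, globally
#' hypomethylated with context-specific site loss), a replicative-polymerase
#' hypomorph (`pole1`-like, hypermethylated with non-CG site gain), and the
#' double mutant, in which a fraction `rho` of the hypomethylation is
#' restored.
#'
#' @param seed Integer seed; identical configurations give bit-identical
#'   output.
#' @param genome_length Reference length in bp (>= 10).
#' @param gc_content Fraction of G+C bases in `(0, 1)`. The default 0.37
#'   approximates the zebrafish genome.
#' @param n_replicates_per_genotype Number of replicate methylomes per
#'   genotype (>= 1).
#' @param coverage_mean Mean sequencing depth per cytosine site; per-site
#'   coverage is Poisson with this mean, so zero-depth sites occur and are
#'   emitted (downstream depth filters must handle them).
#' @param baseline_meth Named list with elements `CG`, `CHG`, `CHH`, each a
#'   numeric vector `c(p_meth = , mu = )`: the fraction of sites methylated
#'   in wild type and the mean methylation ratio of methylated sites.
#' @param hypo_factor Multiplicative ratio scaling in `(0, 1]` applied to
#'   every methylated site in the hypomethylated (dnmt1-like) genotype.
#' @param p_loss_CHG,p_loss_CHH Probability that a methylated CHG/CHH site
#'   is lost entirely (ratio set to 0) in the dnmt1-like genotype.
#' @param hyper_factor Ratio scaling `>= 1` (capped at 1) for the
#'   hypermethylated (pole1-like) genotype.
#' @param p_gain_CHG,p_gain_CHH Probability that an unmethylated CHG/CHH
#'   site gains methylation (drawn from the methylated-site distribution)
#'   in the pole1-like genotype.
#' @param rho Restoration fraction in `[0, 1]`: the double mutant's latent
#'   ratio is `r_dnmt1 + rho * (r_wt - r_dnmt1)`, after which the CHH gain
#'   step is applied so doubles can exceed wild type at CHH.
#' @param conversion_failure Probability an unmethylated cytosine reads as
#'   methylated (incomplete bisulfite conversion).
#' @param overconversion Probability a methylated cytosine reads as
#'   unmethylated.
#' @param snp_site_frac Fraction of sites carrying illegitimate-base (SNP)
#'   contamination.
#' @param snp_allele_frac Per-read probability of an illegitimate base at a
#'   contaminated site.
#' @param beta_concentration Concentration of the Beta distribution used for
#'   methylated-site ratios (shape `mu * k`, `(1 - mu) * k`); 20 gives
#'   broad-but-unimodal per-site ratio distributions.
#' @return An object of class `synthetic_config` (a validated list).
#' @seealso [generate_reference()], [simulate_methylome_set()]
#' @export
synthetic_config <- function(seed = 1L,
                             genome_length = 20000L,
                             gc_content = 0.37,
                             n_replicates_per_genotype = 2L,
                             coverage_mean = 10,
                             baseline_meth = list(
                               CG  = c(p_meth = 0.80, mu = 0.80),
                               CHG = c(p_meth = 0.05, mu = 0.25),
                               CHH = c(p_meth = 0.05, mu = 0.25)),
                             hypo_factor = 0.5,
                             p_loss_CHG = 0.5,
                             p_loss_CHH = 0.3,
                             hyper_factor = 1.15,
                             p_gain_CHG = 0.02,
                             p_gain_CHH = 0.05,
                             rho = 0.75,
                             conversion_failure = 0.005,
                             overconversion = 0.005,
                             snp_site_frac = 0.01,
                             snp_allele_frac = 0.3,
                             beta_concentration = 20) {
  check_number(seed, "seed", integerish = TRUE)
  check_number(genome_length, "genome_length", lower = 10, integerish = TRUE)
  check_number(gc_content, "gc_content", lower = 1e-9, upper = 1 - 1e-9)
  check_number(n_replicates_per_genotype, "n_replicates_per_genotype",
               lower = 1, integerish = TRUE)
  check_number(coverage_mean, "coverage_mean", lower = 1e-9)
  if (!setequal(names(baseline_meth), c("CG", "CHG", "CHH")))
    stopf("'baseline_meth' must have elements CG, CHG, CHH")
  for (ctx in c("CG", "CHG", "CHH")) {
    check_fraction(baseline_meth[[ctx]][["p_meth"]],
                   paste0("baseline_meth$", ctx, "[p_meth]"))
    check_fraction(baseline_meth[[ctx]][["mu"]],
                   paste0("baseline_meth$", ctx, "[mu]"))
  }
  check_number(hypo_factor, "hypo_factor", lower = 1e-9, upper = 1)
  check_fraction(p_loss_CHG, "p_loss_CHG")
  check_fraction(p_loss_CHH, "p_loss_CHH")
  check_number(hyper_factor, "hyper_factor", lower = 1)
  check_fraction(p_gain_CHG, "p_gain_CHG")
  check_fraction(p_gain_CHH, "p_gain_CHH")
  check_fraction(rho, "rho")
  check_fraction(conversion_failure, "conversion_failure")
  check_fraction(overconversion, "overconversion")
  check_fraction(snp_site_frac, "snp_site_frac")
  check_fraction(snp_allele_frac, "snp_allele_frac")
  check_number(beta_concentration, "beta_concentration", lower = 1e-9)
  structure(list(
    seed = as.integer(seed), genome_length = as.integer(genome_length),
    gc_content = gc_content,
    n_replicates_per_genotype = as.integer(n_replicates_per_genotype),
    coverage_mean = coverage_mean, baseline_meth = baseline_meth,
    hypo_factor = hypo_factor, p_loss_CHG = p_loss_CHG,
    p_loss_CHH = p_loss_CHH, hyper_factor = hyper_factor,
    p_gain_CHG = p_gain_CHG, p_gain_CHH = p_gain_CHH, rho = rho,
    conversion_failure = conversion_failure, overconversion = overconversion,
    snp_site_frac = snp_site_frac, snp_allele_frac = snp_allele_frac,
    beta_concentration = beta_concentration),
    class = "synthetic_config")
}

#' Configuration for the synthetic phenotype generator
#'
#' Describes the per-fish measurement model behind the thymopoietic index
#' (rag1 in-situ area over the gh internal-control area) and eye size:
#' `gh_area ~ Normal(gh_mean, gh_sd)` truncated above zero, and
#' `rag1_area = gh_area * index_scale * W_g * LogNormal(0, sdlog)`, where
#' the genotype fitness is `W_wt = 1`, `W_x`, `W_y`, and
#' `W_xy = W_x * W_y * 2^epsilon_true` under the multiplicative model.
#' Eye size follows the same structure with its own base distribution and
#' fitness values.
#'
#' @param seed Integer seed.
#' @param n_fish_per_genotype Fish per genotype (>= 2).
#' @param gh_mean,gh_sd Mean and s.d. of the gh-positive control area
#'   (arbitrary area units).
#' @param index_scale Dimensionless scale `kappa` linking fitness to the
#'   rag1/gh ratio in wild type.
#' @param W_x,W_y True single-mutant fitness values in `(0, 1]`.
#' @param epsilon_true True log2 interaction: 0 means no interaction,
#'   positive alleviating, negative synthetic.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise (0 disables noise).
#' @param eye_mean,eye_sd Base distribution of eye size.
#' @param eye_W_x,eye_W_y,eye_epsilon_true Eye-size analogues of `W_x`,
#'   `W_y`, `epsilon_true`.
#' @return An object of class `phenotype_config`.
#' @seealso [simulate_phenotypes()], [interaction_analysis()]
#' @export
phenotype_config <- function(seed = 1L,
                             n_fish_per_genotype = 30L,
                             gh_mean = 100, gh_sd = 15,
                             index_scale = 0.8,
                             W_x = 0.4, W_y = 0.2,
                             epsilon_true = 1,
                             noise_cv = 0.2,
                             eye_mean = 50, eye_sd = 5,
                             eye_W_x = 1, eye_W_y = 0.7,
                             eye_epsilon_true = 0.3) {
  check_number(seed, "seed", integerish = TRUE)
  check_number(n_fish_per_genotype, "n_fish_per_genotype", lower = 2,
               integerish = TRUE)
  check_number(gh_mean, "gh_mean", lower = 1e-9)
  check_number(gh_sd, "gh_sd", lower = 0)
  check_number(index_scale, "index_scale", lower = 1e-9)
  check_number(W_x, "W_x", lower = 1e-9, upper = 1)
  check_number(W_y, "W_y", lower = 1e-9, upper = 1)
  check_number(epsilon_true, "epsilon_true")
  check_number(noise_cv, "noise_cv", lower = 0)
  check_number(eye_mean, "eye_mean", lower = 1e-9)
  check_number(eye_sd, "eye_sd", lower = 0)
  check_number(eye_W_x, "eye_W_x", lower = 1e-9, upper = 1)
  check_number(eye_W_y, "eye_W_y", lower = 1e-9, upper = 1)
  check_number(eye_epsilon_true, "eye_epsilon_true")
  structure(list(
    seed = as.integer(seed),
    n_fish_per_genotype = as.integer(n_fish_per_genotype),
    gh_mean = gh_mean, gh_sd = gh_sd, index_scale = index_scale,
    W_x = W_x, W_y = W_y, epsilon_true = epsilon_true, noise_cv = noise_cv,
    eye_mean = eye_mean, eye_sd = eye_sd, eye_W_x = eye_W_x,
    eye_W_y = eye_W_y, eye_epsilon_true = eye_epsilon_true),
    class = "phenotype_config")
}

#' Generate a random reference sequence
#'
#' @param config A [synthetic_config()].
#' @return Named character vector of length one (sequence name `"synth_1"`),
#'   over the alphabet A/C/G/T, with `P(G) = P(C) = gc_content / 2`.
#' @examples
#' ref <- generate_reference(synthetic_config(seed = 7, genome_length = 100))
#' nchar(ref)
#' @export
generate_reference <- function(config) {
  if (!inherits(config, "synthetic_config"))
    stopf("'config' must be a synthetic_config")
  gc <- config$gc_content
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq <- with_seed(derive_seed(config$seed, "reference"), {
    paste(sample(names(probs), config$genome_length, replace = TRUE,
                 prob = probs), collapse = "")
  })
  c(synth_1 = seq)
}

.genotypes <- c("wt", "dnmt1", "pole1", "double")

#' Simulate genotype-structured methylomes
#'
#' For every cytosine site on both strands of the reference, draws a latent
#' true methylation ratio per genotype and then, per replicate, observed
#' bisulfite read counts:
#' \itemize{
#'   \item wild type: a site is methylated with probability `p_meth` for its
#'     context and then has ratio drawn from a Beta centred on `mu`;
#'     otherwise ratio 0;
#'   \item dnmt1-like: wild-type ratio scaled by `hypo_factor`; methylated
#'     CHG/CHH sites additionally drop to 0 with probability
#'     `p_loss_CHG`/`p_loss_CHH`;
#'   \item pole1-like: ratio scaled by `hyper_factor` (capped at 1);
#'     unmethylated CHG/CHH sites gain a methylated-distribution draw with
#'     probability `p_gain_CHG`/`p_gain_CHH`;
#'   \item double: `r_dnmt1 + rho * (r_wt - r_dnmt1)`, then the pole1-like
#'     gain step applied to CHH only.
#' }
#' Observed counts per replicate: coverage is Poisson(`coverage_mean`);
#' methylated reads are Binomial(coverage,
#' `r * (1 - overconversion) + (1 - r) * conversion_failure`);
#' illegitimate-base reads are Binomial(coverage, `snp_allele_frac`) at the
#' `snp_site_frac` subset of sites. Each (genotype, replicate) pair has its
#' own RNG stream derived from the seed, so adding replicates never changes
#' existing ones.
#'
#' @param config A [synthetic_config()].
#' @param reference Named character vector as returned by
#'   [generate_reference()] (or [read_reference()]).
#' @return A list of class `methylome_set` with elements `truth` (site table
#'   with latent ratios `r_wt`, `r_dnmt1`, `r_pole1`, `r_double` and the SNP
#'   flag) and `methylomes` (named list genotype -> list of replicate record
#'   data frames).
#' @export
simulate_methylome_set <- function(config, reference) {
  if (!inherits(config, "synthetic_config"))
    stopf("'config' must be a synthetic_config")
  sites <- classify_cytosines(reference)
  n <- nrow(sites)
  if (n == 0L) stopf("reference contains no classifiable cytosine sites")

  pm <- vapply(config$baseline_meth, `[[`, numeric(1L), "p_meth")
  mu <- vapply(config$baseline_meth, `[[`, numeric(1L), "mu")
  k <- config$beta_concentration
  ctx <- sites$context

  draw_meth_ratio <- function(idx) {
    pmax(pmin(stats::rbeta(length(idx), mu[ctx[idx]] * k,
                           (1 - mu[ctx[idx]]) * k), 1), 1e-9)
  }

  truth <- with_seed(derive_seed(config$seed, "latent"), {
    methylated <- stats::runif(n) < pm[ctx]
    r_wt <- numeric(n)
    r_wt[methylated] <- draw_meth_ratio(which(methylated))

    # dnmt1-like: global scaling plus stochastic non-CG site loss
    r_dnmt1 <- r_wt * config$hypo_factor
    p_loss <- ifelse(ctx == "CHG", config$p_loss_CHG,
                     ifelse(ctx == "CHH", config$p_loss_CHH, 0))
    lost <- r_wt > 0 & stats::runif(n) < p_loss
    r_dnmt1[lost] <- 0

    # pole1-like: capped scaling plus stochastic non-CG site gain
    r_pole1 <- pmin(1, r_wt * config$hyper_factor)
    p_gain <- ifelse(ctx == "CHG", config$p_gain_CHG,
                     ifelse(ctx == "CHH", config$p_gain_CHH, 0))
    gained <- r_wt == 0 & stats::runif(n) < p_gain
    r_pole1[gained] <- draw_meth_ratio(which(gained))

    # double: partial restoration toward wild type, then CHH gain so the
    # double mutant can exceed wild-type CHH levels
    r_double <- r_dnmt1 + config$rho * (r_wt - r_dnmt1)
    g2 <- r_double == 0 & ctx == "CHH" &
      stats::runif(n) < config$p_gain_CHH
    r_double[g2] <- draw_meth_ratio(which(g2))

    is_snp <- stats::runif(n) < config$snp_site_frac
    cbind(sites, r_wt = r_wt, r_dnmt1 = r_dnmt1, r_pole1 = r_pole1,
          r_double = r_double, is_snp = is_snp)
  })

  latent <- list(wt = truth$r_wt, dnmt1 = truth$r_dnmt1,
                 pole1 = truth$r_pole1, double = truth$r_double)
  snp_idx <- which(truth$is_snp)

  methylomes <- lapply(.genotypes, function(g) {
    lapply(seq_len(config$n_replicates_per_genotype), function(j) {
      with_seed(derive_seed(config$seed, g, j), {
        r <- latent[[g]]
        coverage <- stats::rpois(n, config$coverage_mean)
        p_obs <- r * (1 - config$overconversion) +
          (1 - r) * config$conversion_failure
        n_meth <- stats::rbinom(n, coverage, p_obs)
        n_illegitimate <- integer(n)
        if (length(snp_idx))
          n_illegitimate[snp_idx] <- stats::rbinom(
            length(snp_idx), coverage[snp_idx], config$snp_allele_frac)
        data.frame(chrom = sites$chrom, start = sites$start,
                   end = sites$start + 1L, strand = sites$strand,
                   context = sites$context, n_meth = n_meth,
                   n_unmeth = coverage - n_meth,
                   n_illegitimate = n_illegitimate,
                   stringsAsFactors = FALSE)
      })
    })
  })
  names(methylomes) <- .genotypes
  structure(list(truth = truth, methylomes = methylomes, config = config),
            class = "methylome_set")
}

#' Simulate a per-fish phenotype table
#'
#' Draws, per genotype (`wt`, `x`, `y`, `xy`), the gh internal-control area,
#' the rag1 area (control area times `index_scale`, the genotype fitness and
#' multiplicative lognormal noise), and eye size (same structure with the
#' eye parameters). Under the multiplicative model the double mutant's true
#' fitness is `W_x * W_y * 2^epsilon_true`.
#'
#' @param config A [phenotype_config()].
#' @return Data frame with columns `fish_id`, `genotype`, `rag1_area`,
#'   `gh_area`, `eye_size`.
#' @examples
#' ph <- simulate_phenotypes(phenotype_config(seed = 1, noise_cv = 0))
#' head(ph)
#' @export
simulate_phenotypes <- function(config) {
  if (!inherits(config, "phenotype_config"))
    stopf("'config' must be a phenotype_config")
  W <- c(wt = 1, x = config$W_x, y = config$W_y,
         xy = config$W_x * config$W_y * 2^config$epsilon_true)
  W_eye <- c(wt = 1, x = config$eye_W_x, y = config$eye_W_y,
             xy = config$eye_W_x * config$eye_W_y * 2^config$eye_epsilon_true)
  sdlog <- sqrt(log1p(config$noise_cv^2))
  n <- config$n_fish_per_genotype
  with_seed(config$seed, {
    rows <- lapply(names(W), function(g) {
      gh <- rnorm_pos(n, config$gh_mean, config$gh_sd)
      noise <- if (sdlog > 0) exp(stats::rnorm(n, 0, sdlog)) else rep(1, n)
      rag1 <- gh * config$index_scale * W[[g]] * noise
      eye_base <- rnorm_pos(n, config$eye_mean, config$eye_sd)
      eye_noise <- if (sdlog > 0) exp(stats::rnorm(n, 0, sdlog)) else rep(1, n)
      data.frame(fish_id = sprintf("%s_%03d", g, seq_len(n)),
                 genotype = g, rag1_area = rag1, gh_area = gh,
                 eye_size = eye_base * W_eye[[g]] * eye_noise,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
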