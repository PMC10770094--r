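#' Thymopoietic index
#'
#' The rag1-positive in-situ signal area divided by the gh-positive
#' (hypophysis) area; gh serves as an internal technical and biological
#' control, making the index dimensionless and comparable across larvae.
#'
#' @param rag1_area Non-negative rag1 signal area(s).
#' @param gh_area Positive gh signal area(s).
#' @return `rag1_area / gh_area`, vectorized.
#' @examples
#' thymopoietic_index(2.4, 3.0)  # 0.8
#' @export
thymopoietic_index <- function(rag1_area, gh_area) {
  if (any(!is.finite(gh_area)) || any(gh_area <= 0))
    stopf("gh_area must be positive (internal-control failure)")
  if (any(!is.finite(rag1_area)) || any(rag1_area < 0))
    stopf("rag1_area must be non-negative")
  rag1_area / gh_area
}

.metric_values <- function(phenotypes, metric) {
  if (metric == "thymopoietic_index") {
    bad <- !is.finite(phenotypes$gh_area) | phenotypes$gh_area <= 0
    if (any(bad)) {
      warnf("excluding %d fish with gh_area <= 0 (control-channel failure)",
            sum(bad))
      phenotypes <- phenotypes[!bad, , drop = FALSE]
    }
    thymopoietic_index(phenotypes$rag1_area, phenotypes$gh_area)
  } else {
    phenotypes$eye_size
  }
}

#' Estimate genotype fitness from a phenotype table
#'
#' Divides every fish's metric value by the wild-type mean of that metric;
#' the fitness `W` is the mean of the normalized values and `delta` their
#' sample standard deviation (n - 1 denominator). The wild type's own
#' fitness is 1 by construction.
#'
#' @param phenotypes Data frame with `genotype`, `rag1_area`, `gh_area`
#'   and optionally `eye_size`.
#' @param genotype Genotype label to estimate.
#' @param wildtype Wild-type genotype label (default `"wt"`).
#' @param metric `"thymopoietic_index"` or `"eye_size"`.
#' @return An object of class `fitness_estimate`: list with `genotype`,
#'   `W`, `delta`, `n`, `metric`, `values` (the normalized per-fish
#'   values).
#' @export
estimate_fitness <- function(phenotypes, genotype, wildtype = "wt",
                             metric = c("thymopoietic_index", "eye_size")) {
  metric <- match.arg(metric)
  if (metric == "eye_size" && is.null(phenotypes$eye_size))
    stopf("phenotype table has no eye_size column")
  wt <- phenotypes[phenotypes$genotype == wildtype, , drop = FALSE]
  gt <- phenotypes[phenotypes$genotype == genotype, , drop = FALSE]
  if (nrow(wt) < 2L || nrow(gt) < 2L)
    stopf("need >= 2 fish in '%s' and '%s'", genotype, wildtype)
  wt_mean <- mean(.metric_values(wt, metric))
  if (!is.finite(wt_mean) || wt_mean <= 0)
    stopf("wild-type mean %s must be positive", metric)
  values <- .metric_values(gt, metric) / wt_mean
  structure(list(genotype = genotype, W = mean(values),
                 delta = stats::sd(values), n = length(values),
                 metric = metric, values = values),
            class = "fitness_estimate")
}

.as_W <- function(x) if (inherits(x, "fitness_estimate")) x$W else x

#' Expected double-mutant fitness under the multiplicative model
#'
#' @param W_x,W_y Single-mutant fitness values (numbers or
#'   [estimate_fitness()] results).
#' @return `W_x * W_y`. Commutative; returns `W` when one input is 1.
#' @examples
#' expected_fitness(0.2, 0.5)  # 0.1
#' @export
expected_fitness <- function(W_x, W_y) {
  W_x <- .as_W(W_x); W_y <- .as_W(W_y)
  if (W_x <= 0 || W_y <= 0) stopf("fitness values must be positive")
  W_x * W_y
}

#' Propagated error of the expected fitness
#'
#' Mode `"standard"` (default) is first-order error propagation for a
#' product: `W_x * W_y * sqrt((delta_x / W_x)^2 + (delta_y / W_y)^2)`,
#' returning the absolute error of `E = W_x * W_y`. Mode `"as_printed"`
#' evaluates the literal expression
#' `((delta_x / W_x)^2 + (delta_y / W_y)^2)^(-2)` and is provided for
#' auditability only: for typical 20-40 percent relative errors it yields
#' absurd magnitudes (for example 25), which is why it is not the default.
#'
#' @param W_x,delta_x,W_y,delta_y Single-mutant fitness values and their
#'   standard deviations.
#' @param mode `"standard"` or `"as_printed"`.
#' @return The propagated error.
#' @examples
#' propagate_error(0.5, 0.1, 0.5, 0.2)                      # ~0.1118
#' propagate_error(0.5, 0.1, 0.5, 0.2, mode = "as_printed") # 25
#' @export
propagate_error <- function(W_x, delta_x, W_y, delta_y,
                            mode = c("standard", "as_printed")) {
  mode <- match.arg(mode)
  if (W_x <= 0 || W_y <= 0) stopf("fitness values must be positive")
  if (delta_x < 0 || delta_y < 0) stopf("deltas must be non-negative")
  s <- (delta_x / W_x)^2 + (delta_y / W_y)^2
  if (mode == "standard") {
    W_x * W_y * sqrt(s)
  } else {
    if (s == 0)
      stopf("as_printed mode undefined when both deltas are 0")
    s^(-2)
  }
}

#' Log2 interaction score
#'
#' The log2 fold-change between observed and expected double-mutant
#' fitness. Zero means no interaction; positive scores are alleviating
#' (phenotype less severe than expected), negative synthetic.
#'
#' @param W_xy_observed Observed double-mutant fitness (> 0).
#' @param E_expected Expected fitness from [expected_fitness()] (> 0).
#' @return `log2(W_xy_observed / E_expected)`.
#' @examples
#' interaction_score(0.4, 0.1)  # 2
#' @export
interaction_score <- function(W_xy_observed, E_expected) {
  W_xy_observed <- .as_W(W_xy_observed)
  if (W_xy_observed <= 0 || E_expected <= 0)
    stopf("fitness values must be positive")
  log2(W_xy_observed / E_expected)
}

#' Classify a genetic interaction
#'
#' Compares the observed double-mutant fitness with the multiplicative
#' expectation using a z statistic that combines the double mutant's
#' standard error with the propagated error of the expectation:
#' `z = (W_xy - E) / sqrt(delta_xy^2 / n_xy + epsilon_prop^2)`, two-sided
#' normal p-value. The call is `alleviating` if `p <= alpha` and the
#' interaction score is positive, `synthetic` if `p <= alpha` and
#' negative, otherwise `non_interacting`. If the variance is fully
#' degenerate (identical values and zero propagated error), p is set by
#' exact equality (0 when means differ, 1 otherwise) and flagged.
#'
#' @param values_xy Normalized per-fish double-mutant values (length
#'   >= 2), e.g. `estimate_fitness(...)$values`.
#' @param E_expected Expected fitness.
#' @param epsilon_prop Propagated error of the expectation (standard
#'   mode).
#' @param alpha Significance level (default 0.05).
#' @return An object of class `interaction_result`: list with
#'   `W_xy_observed`, `delta_xy`, `n_xy`, `E_expected`, `epsilon_prop`,
#'   `I`, `z`, `p_value`, `classification`, `degenerate`.
#' @export
classify_interaction <- function(values_xy, E_expected, epsilon_prop,
                                 alpha = 0.05) {
  if (length(values_xy) < 2L) stopf("need >= 2 double-mutant values")
  check_number(E_expected, "E_expected", lower = 1e-12)
  check_number(epsilon_prop, "epsilon_prop", lower = 0)
  check_number(alpha, "alpha", lower = 1e-12, upper = 1)
  W_xy <- mean(values_xy)
  delta_xy <- stats::sd(values_xy)
  n_xy <- length(values_xy)
  I <- interaction_score(W_xy, E_expected)
  se2 <- delta_xy^2 / n_xy + epsilon_prop^2
  degenerate <- se2 == 0
  if (degenerate) {
    z <- NA_real_
    p <- if (W_xy == E_expected) 1 else 0
  } else {
    z <- (W_xy - E_expected) / sqrt(se2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  classification <- if (p <= alpha && I > 0) "alleviating"
    else if (p <= alpha && I < 0) "synthetic"
    else "non_interacting"
  structure(list(W_xy_observed = W_xy, delta_xy = delta_xy, n_xy = n_xy,
                 E_expected = E_expected, epsilon_prop = epsilon_prop,
                 I = I, z = z, p_value = p, classification = classification,
                 degenerate = degenerate),
            class = "interaction_result")
}

#' Full genetic-interaction analysis for one mutant pair
#'
#' Runs the whole chain on a phenotype table: fitness estimation for both
#' single mutants and the double mutant (normalized to wild type),
#' multiplicative expected fitness, propagated error, log2 interaction
#' score, and significance classification.
#'
#' @param phenotypes Phenotype data frame (`fish_id`, `genotype`,
#'   `rag1_area`, `gh_area`, optionally `eye_size`).
#' @param pair Named character vector with elements `x`, `y`, `xy` giving
#'   the genotype labels of the two single mutants and the double mutant.
#' @param wildtype Wild-type label.
#' @param metric `"thymopoietic_index"` or `"eye_size"`.
#' @param alpha Significance level.
#' @param error_mode Error-propagation mode; classification always uses
#'   the standard propagated error, but the requested mode's value is
#'   reported alongside.
#' @return An `interaction_result` with added fields `W_x`, `W_y`,
#'   `fitness` (the three `fitness_estimate`s), `metric`, `alpha`,
#'   `error_mode`.
#' @export
interaction_analysis <- function(phenotypes,
                                 pair = c(x = "x", y = "y", xy = "xy"),
                                 wildtype = "wt",
                                 metric = c("thymopoietic_index",
                                            "eye_size"),
                                 alpha = 0.05,
                                 error_mode = c("standard", "as_printed")) {
  metric <- match.arg(metric)
  error_mode <- match.arg(error_mode)
  if (!all(c("x", "y", "xy") %in% names(pair)))
    stopf("'pair' must name genotypes x, y and xy")
  fx <- estimate_fitness(phenotypes, pair[["x"]], wildtype, metric)
  fy <- estimate_fitness(phenotypes, pair[["y"]], wildtype, metric)
  fxy <- estimate_fitness(phenotypes, pair[["xy"]], wildtype, metric)
  E <- expected_fitness(fx$W, fy$W)
  eps <- propagate_error(fx$W, fx$delta, fy$W, fy$delta, mode = "standard")
  res <- classify_interaction(fxy$values, E, eps, alpha)
  res$W_x <- fx$W
  res$W_y <- fy$W
  res$epsilon_reported <- propagate_error(fx$W, fx$delta, fy$W, fy$delta,
                                          mode = error_mode)
  res$fitness <- list(x = fx, y = fy, xy = fxy)
  res$metric <- metric
  res$alpha <- alpha
  res$error_mode <- error_mode
  res
}

#' @export
print.interaction_result <- function(x, ...) {
  cat("Genetic interaction (multiplicative model)\n")
  if (!is.null(x$metric)) cat("  metric:        ", x$metric, "\n")
  if (!is.null(x$W_x))
    cat(sprintf("  W_x = %.4f, W_y = %.4f\n", x$W_x, x$W_y))
  cat(sprintf("  observed W_xy: %.4f (sd %.4f, n %d)\n",
              x$W_xy_observed, x$delta_xy, x$n_xy))
  cat(sprintf("  expected E:    %.4f (propagated error %.4f)\n",
              x$E_expected, x$epsilon_prop))
  cat(sprintf("  score I = log2(obs/exp) = %.4f, p = %.4g\n",
              x$I, x$p_value))
  cat("  classification:", x$classification, "\n")
  invisible(x)
}

#' @export
print.fitness_estimate <- function(x, ...) {
  cat(sprintf("Fitness estimate [%s] %s: W = %.4f, delta = %.4f, n = %d\n",
              x$metric, x$genotype, x$W, x$delta, x$n))
  invisible(x)
}
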