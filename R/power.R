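#' Closed-form power of the two-sample comparison
#'
#' Power of a two-sided two-sample test at level \code{alpha} to detect a
#' true mean difference \code{delta} when the change score has common
#' individual-level SD \code{sd} and each arm has \code{n_per_group}
#' subjects. \code{method = "t"} uses the noncentral t distribution with
#' \code{2n - 2} degrees of freedom; \code{"normal"} uses the Gaussian
#' shift approximation.
#'
#' @param delta True mean difference (kg, or any outcome unit).
#' @param sd Common SD of the outcome (same unit).
#' @param n_per_group Subjects per arm (>= 2).
#' @param alpha Two-sided significance level.
#' @param method \code{"t"} (exact) or \code{"normal"}.
#' @return Power, a probability.
#' @examples
#' two_sample_power(2.0, 2.8, 32)  # about 0.80
#' two_sample_power(2.0, 2.8, 64)  # above 0.95
#' @export
two_sample_power <- function(delta, sd, n_per_group, alpha = 0.05,
                             method = c("t", "normal")) {
  method <- match.arg(method)
  stopifnot(sd > 0, alpha > 0, alpha < 1, n_per_group >= 2)
  ncp <- delta / (sd * sqrt(2 / n_per_group))
  if (method == "t") {
    df <- 2 * n_per_group - 2
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(-tc, df, ncp) + 1 - stats::pt(tc, df, ncp)
  } else {
    zc <- stats::qnorm(1 - alpha / 2)
    stats::pnorm(-zc - ncp) + 1 - stats::pnorm(zc - ncp)
  }
}

#' Monte-Carlo power of the full analysis pipeline
#'
#' Simulates \code{reps} two-arm trials with the given effect and residual
#' SD, analyses each with [adjusted_difference()], and reports the
#' rejection fraction at level \code{alpha} with its binomial standard
#' error. By default the analysis is unadjusted, matching the assumptions
#' of the closed form it validates; \code{adjust = TRUE} adds the primary
#' analysis's sex/race/baseline covariates (pure noise in this generator,
#' so adjustment can only cost precision -- useful for quantifying that
#' cost).
#'
#' @inheritParams two_sample_power
#' @param reps Number of simulated trials (>= 100).
#' @param seed Integer seed.
#' @param adjust Include the sex/race/baseline covariates in the analysis.
#' @param cfg Optional [simulation_config()] supplying the covariate
#'   marginals; defaults to the standard configuration.
#' @return List with \code{power}, \code{se}, \code{reps},
#'   \code{n_per_group}.
#' @export
simulated_power <- function(delta, sd, n_per_group, alpha = 0.05,
                            reps = 1000, seed = 1, adjust = FALSE,
                            cfg = simulation_config()) {
  stopifnot(reps >= 100)
  set.seed(as.integer(seed))
  n <- 2L * n_per_group
  rejected <- logical(reps)
  for (r in seq_len(reps)) {
    d <- data.frame(
      arm = rep(c("a", "b"), each = n_per_group),
      sex = ifelse(stats::runif(n) < cfg$female_fraction, "female", "male"),
      race = sample(cfg$race_levels, n, TRUE, cfg$race_probs),
      baseline_weight = stats::rnorm(n, 94, 15),
      stringsAsFactors = FALSE)
    d$change <- delta * (d$arm == "b") + stats::rnorm(n, 0, sd)
    est <- if (adjust) {
      adjusted_difference(d, "change", "arm",
                          covariates = c("sex", "race"),
                          baseline = "baseline_weight")
    } else {
      adjusted_difference(d, "change", "arm", covariates = character(0))
    }
    rejected[r] <- !is.na(est$p_value) && est$p_value < alpha
  }
  p_hat <- mean(rejected)
  list(power = p_hat, se = sqrt(p_hat * (1 - p_hat) / reps),
       reps = reps, n_per_group = n_per_group)
}
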