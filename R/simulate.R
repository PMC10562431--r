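#' Default effect-allele frequencies for the synthetic panel
#'
#' Frequencies paired with the shipped synthetic score table. They were
#' calibrated once with [calibrate_allele_freqs()] so the exact class
#' probabilities are approximately 0.41 fat-responder, 0.20
#' carbohydrate-responder, 0.39 neither-or-both -- the screening split the
#' generator is meant to emulate.
#'
#' @return Named numeric vector of effect-allele frequencies.
#' @export
default_allele_freqs <- function() {
  c(rs5082 = 0.421, rs894160 = 0.318, rs662799 = 0.161, rs1801282 = 0.129,
    rs838147 = 0.471, rs12255372 = 0.308, rs9939609 = 0.426,
    rs2943641 = 0.355, rs10423928 = 0.204, rs1478290 = 0.456)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults
#' emulate the cohort the analysis is designed for: 275 genotyped
#' screenees; age 54.4 (SD 13.2) years truncated to the 18-75 eligibility
#' window; BMI 34.9 (SD 5.1) kg/m^2 truncated to 27.0-47.5; 84\% women;
#' race White/Black/other with probabilities 0.68/0.295/0.025; a weight-
#' change outcome with individual-level residual SD 2.8 kg, mean change
#' -4.8 kg on a discordant diet and a -0.6 kg concordance effect; 11\%
#' attrition at follow-up; and adherence macro percentages drawn around
#' the per-arm, per-week means actually reported by trial participants.
#'
#' The published change summaries (e.g. "-5.3 (SD 1.0)") are read here as
#' standard errors of group means; the individual-level SD used throughout
#' is the 2.8 kg the power analysis assumed. Set \code{residual_sd}
#' yourself for the other interpretation.
#'
#' @param n_screened Number of genotyped screenees.
#' @param allele_freqs Named effect-allele frequencies for the panel.
#' @param missing_call_rate Per-SNP no-call probability in exports.
#' @param strand_flip_rate Probability a non-ambiguous locus is reported on
#'   the opposite strand (exercises orientation; recoverable).
#' @param mu_change Mean weight change (kg) on a discordant diet.
#' @param concordance_effect Additional mean change (kg) on a concordant
#'   diet (negative = more loss).
#' @param residual_sd Individual-level SD of weight change, kg.
#' @param attrition_prob Probability a randomized subject is lost before
#'   the final visit (non-informative by default).
#' @param informative_attrition If \code{TRUE}, dropout probability
#'   increases for subjects losing the least weight (sensitivity switch).
#' @param pre_randomization_dropout Probability an eligible screenee never
#'   reaches randomization.
#' @param ... Overrides for the remaining demographic/lab/adherence
#'   defaults (see the returned list for names).
#' @return List of class \code{sim_config}.
#' @export
simulation_config <- function(n_screened = 275,
                              allele_freqs = default_allele_freqs(),
                              missing_call_rate = 0.005,
                              strand_flip_rate = 0.2,
                              mu_change = -4.8,
                              concordance_effect = -0.6,
                              residual_sd = 2.8,
                              attrition_prob = 0.11,
                              informative_attrition = FALSE,
                              pre_randomization_dropout = 0.142,
                              ...) {
  cfg <- list(
    n_screened = n_screened,
    allele_freqs = allele_freqs,
    missing_call_rate = missing_call_rate,
    strand_flip_rate = strand_flip_rate,
    # demographics (age in years, heights in cm, BMI in kg/m^2)
    age_mean = 54.4, age_sd = 13.2, age_range = c(18, 75),
    bmi_mean = 34.9, bmi_sd = 5.1, bmi_range = c(27.0, 47.5),
    female_fraction = 0.84,
    race_levels = c("white", "black", "other"),
    race_probs = c(0.68, 0.295, 0.025),
    height_mean = c(female = 162.6, male = 175.8),
    height_sd = c(female = 6.4, male = 7.0),
    # fasting labs: log-normal marginals (glucose mg/dL, insulin uU/mL)
    glucose_meanlog = log(93), glucose_sdlog = 0.10,
    insulin_meanlog = log(12), insulin_sdlog = 0.45,
    # outcome model
    mu_change = mu_change,
    concordance_effect = concordance_effect,
    residual_sd = residual_sd,
    baseline_weight_coef = 0.02,   # heavier subjects lose slightly more (kg per kg)
    attrition_prob = attrition_prob,
    informative_attrition = informative_attrition,
    pre_randomization_dropout = pre_randomization_dropout,
    # secondary outcomes: linear in weight change + residual noise
    bodyfat_coef = 0.25, bodyfat_sd = 1.5,
    sbp_coef = 0.8, sbp_sd = 9, dbp_coef = 0.4, dbp_sd = 6,
    fci_coef = 0.05, fci_sd = 0.8,
    adherence = default_adherence_model()
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown simulation_config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  if (any(cfg$allele_freqs < 0 | cfg$allele_freqs > 1)) {
    stop("allele frequencies must lie in [0,1]", call. = FALSE)
  }
  stopifnot(cfg$residual_sd >= 0,
            cfg$missing_call_rate >= 0, cfg$missing_call_rate <= 1,
            cfg$attrition_prob >= 0, cfg$attrition_prob <= 1)
  structure(cfg, class = "sim_config")
}

#' Per-arm adherence model defaults
#'
#' Mean (SD) percent energy from carbohydrate, fat, and protein by arm and
#' week, matching the self-reported adherence of trial participants: the
#' high-carbohydrate arm near its 65/20/15 targets, the high-fat arm near
#' 45/40/15.
#'
#' @return Data frame with columns \code{arm}, \code{week}, \code{macro},
#'   \code{mean}, \code{sd}.
#' @export
default_adherence_model <- function() {
  hc <- rbind(
    c(4, 63.4, 2.3, 20.9, 2.4, 16.0, 1.0),
    c(8, 63.3, 2.8, 20.5, 1.7, 15.9, 1.0),
    c(12, 62.7, 4.0, 20.5, 2.5, 15.7, 1.8))
  hf <- rbind(
    c(4, 45.4, 2.2, 39.4, 2.0, 15.8, 1.2),
    c(8, 44.7, 2.2, 40.5, 2.1, 15.7, 2.3),
    c(12, 44.5, 3.4, 39.9, 2.5, 16.1, 3.3))
  expand <- function(m, arm) {
    do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
      data.frame(arm = arm, week = m[i, 1],
                 macro = c("carb", "fat", "protein"),
                 mean = m[i, c(2, 4, 6)], sd = m[i, c(3, 5, 7)],
                 stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(expand(hc, "high_carb"), expand(hf, "high_fat"))
  rownames(out) <- NULL
  out
}

# truncated-normal draws by rejection; bounds are a few SD from the mean
# everywhere this is used, so rejection is cheap
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lower & x <= upper
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' Generate synthetic DTC genotype tables
#'
#' Draws panel genotypes per subject under Hardy-Weinberg proportions at
#' the configured effect-allele frequencies (SNPs independent -- no LD),
#' injects missing calls at \code{missing_call_rate}, and reports each
#' non-ambiguous locus on the opposite strand with probability
#' \code{strand_flip_rate} (as real mixed-strand exports do; orientation
#' recovers these). A few fixed non-panel filler records are included so
#' parsers see realistic surroundings.
#'
#' @param n Number of subjects.
#' @param cfg A [simulation_config()].
#' @param score_table A [score_table] giving panel loci and alleles.
#' @param seed Integer seed.
#' @param dialect Export dialect for the serialized form.
#' @return List of \code{genotype_table} objects, subject ids
#'   \code{"S0001"}...
#' @export
generate_genotypes <- function(n, cfg, score_table, seed,
                               dialect = c("23andme", "ancestry")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(score_table, "score_table"))
  set.seed(as.integer(seed))
  panel <- score_table$panel
  freqs <- cfg$allele_freqs[panel$rsid]
  if (anyNA(freqs)) stop("allele_freqs must cover the panel", call. = FALSE)

  filler <- data.frame(
    rsid = c("rs4477212", "rs3094315", "rs3131972"),
    chromosome = "1", position = c("82154", "752566", "752721"),
    allele1 = c("A", "A", "G"), allele2 = c("A", "G", "G"),
    stringsAsFactors = FALSE)

  lapply(seq_len(n), function(i) {
    k <- stats::rbinom(nrow(panel), 2L, freqs)  # effect-allele copies
    a1 <- ifelse(k >= 1, panel$allele1, panel$allele2)
    a2 <- ifelse(k == 2, panel$allele1, panel$allele2)
    flip <- !panel$ambiguous_strand &
      stats::runif(nrow(panel)) < cfg$strand_flip_rate
    a1[flip] <- unname(.complement[a1[flip]])
    a2[flip] <- unname(.complement[a2[flip]])
    pair <- t(mapply(function(x, y) sort(c(x, y)), a1, a2))
    miss <- stats::runif(nrow(panel)) < cfg$missing_call_rate
    calls <- data.frame(rsid = panel$rsid, chromosome = panel$chromosome,
                        position = as.character(seq_len(nrow(panel)) * 1e5L),
                        allele1 = ifelse(miss, NA_character_, pair[, 1L]),
                        allele2 = ifelse(miss, NA_character_, pair[, 2L]),
                        stringsAsFactors = FALSE)
    calls <- rbind(filler, calls)
    structure(list(subject_id = sprintf("S%04d", i), dialect = dialect,
                   calls = calls),
              class = "genotype_table")
  })
}

#' Write synthetic genotype exports to disk
#'
#' Serializes [generate_genotypes()] output in the requested dialect, one
#' file per subject. Identical config and seed give byte-identical files.
#'
#' @inheritParams generate_genotypes
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths.
#' @export
generate_genotype_files <- function(n, cfg, score_table, seed, dir,
                                    dialect = c("23andme", "ancestry")) {
  dialect <- match.arg(dialect)
  tabs <- generate_genotypes(n, cfg, score_table, seed, dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(tabs, function(tb) {
    p <- file.path(dir, paste0(tb$subject_id, ".txt"))
    writeLines(write_dtc_table(tb, dialect), p)
    p
  }, character(1))
  invisible(paths)
}

#' Generate a synthetic cohort of participants
#'
#' Draws demographics, anthropometrics, and fasting labs with the marginal
#' structure the trial cohort had: truncated-normal age and BMI, sex and
#' race categorical, height normal within sex, weight derived from BMI and
#' height, glucose and insulin log-normal.
#'
#' @param n Number of participants (0 gives an empty cohort).
#' @param cfg A [simulation_config()].
#' @param seed Integer seed.
#' @return Data frame with columns \code{subject_id}, \code{sex},
#'   \code{race}, \code{age_years}, \code{height_cm}, \code{weight_kg},
#'   \code{bmi}, \code{glucose}, \code{insulin}.
#' @export
generate_cohort <- function(n, cfg, seed) {
  set.seed(as.integer(seed))
  if (n == 0L) {
    return(data.frame(subject_id = character(0), sex = character(0),
                      race = character(0), age_years = numeric(0),
                      height_cm = numeric(0), weight_kg = numeric(0),
                      bmi = numeric(0), glucose = numeric(0),
                      insulin = numeric(0), stringsAsFactors = FALSE))
  }
  sex <- ifelse(stats::runif(n) < cfg$female_fraction, "female", "male")
  race <- sample(cfg$race_levels, n, replace = TRUE, prob = cfg$race_probs)
  age <- .rtruncnorm(n, cfg$age_mean, cfg$age_sd,
                     cfg$age_range[1L], cfg$age_range[2L])
  bmi <- .rtruncnorm(n, cfg$bmi_mean, cfg$bmi_sd,
                     cfg$bmi_range[1L], cfg$bmi_range[2L])
  height <- stats::rnorm(n, cfg$height_mean[sex], cfg$height_sd[sex])
  weight <- bmi * (height / 100)^2
  data.frame(subject_id = sprintf("S%04d", seq_len(n)),
             sex = sex, race = race, age_years = age,
             height_cm = height, weight_kg = weight, bmi = bmi,
             glucose = stats::rlnorm(n, cfg$glucose_meanlog, cfg$glucose_sdlog),
             insulin = stats::rlnorm(n, cfg$insulin_meanlog, cfg$insulin_sdlog),
             stringsAsFactors = FALSE)
}

#' Simulate week-12 outcomes for a randomized cohort
#'
#' Weight change (kg) is
#' \code{mu_change + concordance_effect * concordant +
#' baseline_weight_coef * (weight - mean weight) + Normal(0, residual_sd)}.
#' Secondary outcomes are linear in the weight change with their own
#' residual noise. Attrition flags are Bernoulli(\code{attrition_prob});
#' non-completers have all outcomes missing. Percent weight change is
#' \code{100 * change / baseline weight} for completers.
#'
#' @param cohort Output of [generate_cohort()] (rows = randomized
#'   subjects).
#' @param assignments Output of [randomize_cohort()] for the same
#'   subjects.
#' @param cfg A [simulation_config()].
#' @param seed Integer seed.
#' @return Data frame keyed by \code{subject_id} with \code{arm},
#'   \code{concordant}, \code{completed}, weight/body-fat/blood-pressure
#'   change scores, and six food-craving scale changes (\code{fci_*}).
#' @export
simulate_outcomes <- function(cohort, assignments, cfg, seed) {
  set.seed(as.integer(seed))
  m <- match(cohort$subject_id, assignments$subject_id)
  if (anyNA(m)) stop("assignments must cover the cohort", call. = FALSE)
  asg <- assignments[m, , drop = FALSE]
  n <- nrow(cohort)

  mu <- cfg$mu_change + cfg$concordance_effect * as.numeric(asg$concordant) +
    cfg$baseline_weight_coef * (cohort$weight_kg - mean(cohort$weight_kg))
  wc <- mu + stats::rnorm(n, 0, cfg$residual_sd)

  if (cfg$informative_attrition) {
    # subjects losing the least weight are likelier to drop out
    lp <- stats::qlogis(min(max(cfg$attrition_prob, 1e-6), 1 - 1e-6)) +
      0.3 * (wc - mean(wc))
    dropped <- stats::runif(n) < stats::plogis(lp)
  } else {
    dropped <- stats::runif(n) < cfg$attrition_prob
  }
  completed <- !dropped

  sec <- function(coef, sd) coef * wc + stats::rnorm(n, 0, sd)
  out <- data.frame(
    subject_id = cohort$subject_id,
    arm = asg$arm,
    concordant = asg$concordant,
    completed = completed,
    weight_change_kg = wc,
    pct_weight_change = 100 * wc / cohort$weight_kg,
    bodyfat_change_pct = sec(cfg$bodyfat_coef, cfg$bodyfat_sd),
    sbp_change = sec(cfg$sbp_coef, cfg$sbp_sd),
    dbp_change = sec(cfg$dbp_coef, cfg$dbp_sd),
    fci_highfat = sec(cfg$fci_coef, cfg$fci_sd),
    fci_sweets = sec(cfg$fci_coef, cfg$fci_sd),
    fci_carbs = sec(cfg$fci_coef, cfg$fci_sd),
    fci_fastfood = sec(cfg$fci_coef, cfg$fci_sd),
    fci_fruitveg = sec(cfg$fci_coef, cfg$fci_sd),
    stringsAsFactors = FALSE)
  out$fci_total <- rowMeans(out[, grep("^fci_", names(out))])
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "completed"
  out[!completed, num] <- NA_real_
  out
}

#' Simulate per-week diet-adherence records
#'
#' For each subject and reporting week, percent energy from carbohydrate,
#' fat, and protein is drawn Normal around the arm-specific means/SDs of
#' the adherence model and renormalized to sum to 100.
#'
#' @param assignments Output of [randomize_cohort()].
#' @param cfg A [simulation_config()] (its \code{adherence} element).
#' @param weeks Reporting weeks.
#' @param seed Integer seed.
#' @return Data frame: \code{subject_id}, \code{arm}, \code{week},
#'   \code{carb_pct}, \code{fat_pct}, \code{protein_pct}.
#' @export
simulate_adherence <- function(assignments, cfg, weeks = c(4, 8, 12), seed) {
  set.seed(as.integer(seed))
  adh <- cfg$adherence
  rows <- list()
  for (w in weeks) {
    for (i in seq_len(nrow(assignments))) {
      arm <- assignments$arm[i]
      sub <- adh[adh$arm == arm & adh$week == w, ]
      if (nrow(sub) != 3L) {
        stop(sprintf("adherence model lacks arm %s week %s", arm, w),
             call. = FALSE)
      }
      v <- stats::setNames(stats::rnorm(3L, sub$mean, sub$sd), sub$macro)
      v <- 100 * v / sum(v)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = assignments$subject_id[i], arm = arm, week = w,
        carb_pct = v[["carb"]], fat_pct = v[["fat"]],
        protein_pct = v[["protein"]], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
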