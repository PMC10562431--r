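#' Mifflin-St Jeor resting energy expenditure
#'
#' Linear resting-metabolic-rate equations in weight, height, and age with
#' a sex-specific intercept: males \eqn{10W + 6.25H - 5A + 5}, females
#' \eqn{10W + 6.25H - 5A - 161} (kcal/day).
#'
#' @param sex \code{"female"} or \code{"male"} (vectorized).
#' @param weight_kg Body weight in kg.
#' @param height_cm Height in cm.
#' @param age_years Age in years.
#' @return Resting energy expenditure, kcal/day.
#' @examples
#' mifflin_st_jeor("male", 90, 180, 55)    # 1755
#' mifflin_st_jeor("female", 80, 165, 50)  # 1420.25
#' @export
mifflin_st_jeor <- function(sex, weight_kg, height_cm, age_years) {
  sex <- tolower(as.character(sex))
  if (!all(sex %in% c("female", "male"))) {
    stop("sex must be 'female' or 'male'", call. = FALSE)
  }
  if (any(weight_kg <= 0) || any(height_cm <= 0) || any(age_years <= 0)) {
    stop("weight, height, and age must be positive", call. = FALSE)
  }
  intercept <- ifelse(sex == "male", 5, -161)
  10 * weight_kg + 6.25 * height_cm - 5 * age_years + intercept
}

#' Energy-tier meal-plan prescription
#'
#' Total energy target is resting expenditure times an activity factor
#' minus a daily deficit (default 750 kcal), snapped to the nearest tier of
#' the 1400-2800 kcal/day meal-plan series (200 kcal increments) and
#' clamped to its range. A target exactly halfway between tiers rounds up,
#' favoring adequacy of the meal plan.
#'
#' @param rmr Resting energy expenditure, kcal/day.
#' @param activity_factor Dimensionless multiplier, >= 1 (default 1.4,
#'   sedentary-to-light activity).
#' @param deficit Daily energy deficit, kcal (default 750).
#' @return Energy tier in \code{seq(1400, 2800, by = 200)} (vectorized).
#' @examples
#' prescribe_energy(1755, activity_factor = 1.4)  # target 1707 -> tier 1800
#' @export
prescribe_energy <- function(rmr, activity_factor = 1.4, deficit = 750) {
  if (any(rmr <= 0)) stop("rmr must be positive", call. = FALSE)
  if (any(activity_factor < 1)) stop("activity_factor must be >= 1", call. = FALSE)
  tiers <- seq(1400, 2800, by = 200)
  target <- rmr * activity_factor - deficit
  vapply(target, function(tg) {
    d <- abs(tiers - tg)
    # ties round up: among equally near tiers take the largest
    cand <- tiers[d == min(d)]
    max(cand)
  }, numeric(1))
}

#' Diet-arm macronutrient targets
#'
#' The high-carbohydrate diet targets 65\% of energy from carbohydrate,
#' 20\% from fat, 15\% from protein; the high-fat diet 45/40/15.
#'
#' @param arm \code{"high_carb"} or \code{"high_fat"}.
#' @return Named numeric vector \code{c(carb, fat, protein)} in \% energy.
#' @export
arm_macro_targets <- function(arm = c("high_carb", "high_fat")) {
  arm <- match.arg(arm)
  if (arm == "high_carb") c(carb = 65, fat = 20, protein = 15)
  else c(carb = 45, fat = 40, protein = 15)
}

#' Genotype-diet concordance
#'
#' A diet is concordant when it matches the responder class: fat-responder
#' on the high-fat diet or carbohydrate-responder on the high-carbohydrate
#' diet.
#'
#' @param class Responder class (\code{"fat_responder"} or
#'   \code{"carb_responder"}; vectorized).
#' @param arm Diet arm (\code{"high_fat"} or \code{"high_carb"}).
#' @return Logical.
#' @export
is_concordant <- function(class, arm) {
  if (!all(class %in% eligible_classes())) {
    stop("concordance is defined only for fat_responder / carb_responder",
         call. = FALSE)
  }
  if (!all(arm %in% c("high_fat", "high_carb"))) {
    stop("unknown diet arm", call. = FALSE)
  }
  (class == "fat_responder" & arm == "high_fat") |
    (class == "carb_responder" & arm == "high_carb")
}

#' Stratified permuted-block randomization with BMI balancing
#'
#' Allocates eligible participants 1:1 to the high-fat or high-carbohydrate
#' diet within strata defined by responder class and sex, using permuted
#' blocks. Block sizes start at 6 for female strata and 4 for male strata
#' and drop to 4 and 2 respectively once the stratum passes the
#' \code{switch_fraction} of its enrolment. Within a block, whenever both
#' arms still have open slots, a biased coin (probability
#' \code{biased_coin_p}) favors the arm that would bring the running
#' trial-wide between-arm mean-BMI difference closer to zero; while the
#' running difference is inside half of \code{bmi_tolerance} the coin is
#' fair, so balancing pressure engages before the difference can drift past
#' the tolerance itself. The exact balancing rule used in such trials is
#' rarely published, so the mechanism here is deliberately config-swappable;
#' block balance itself is always strict.
#'
#' @param participants Data frame with columns \code{subject_id},
#'   \code{sex}, \code{responder_class}, \code{bmi}, and (for energy
#'   prescription) \code{weight_kg}, \code{height_cm}, \code{age_years}.
#' @param seed Integer seed; the same cohort and seed always reproduce the
#'   same assignments.
#' @param block_sizes List with elements \code{female} and \code{male},
#'   each \code{c(start, end)} block size.
#' @param switch_fraction Fraction of a stratum's enrolment after which the
#'   end block size is used (default 0.5).
#' @param bmi_tolerance Running mean-BMI difference (kg/m^2) below which no
#'   balancing pressure is applied (default 1.5).
#' @param biased_coin_p Probability of choosing the balancing arm when the
#'   tolerance is exceeded (default 0.8).
#' @param activity_factor,deficit Passed to [prescribe_energy()].
#' @return Data frame with one row per participant: \code{subject_id},
#'   \code{stratum}, \code{responder_class}, \code{sex}, \code{arm},
#'   \code{block_index}, \code{block_size}, \code{concordant},
#'   \code{rmr}, \code{energy_tier}.
#' @export
randomize_cohort <- function(participants, seed,
                             block_sizes = list(female = c(6, 4),
                                                male = c(4, 2)),
                             switch_fraction = 0.5,
                             bmi_tolerance = 1.5,
                             biased_coin_p = 0.8,
                             activity_factor = 1.4,
                             deficit = 750) {
  if (nrow(participants) == 0L) {
    return(data.frame(subject_id = character(0), stratum = character(0),
                      responder_class = character(0), sex = character(0),
                      arm = character(0), block_index = integer(0),
                      block_size = integer(0), concordant = logical(0),
                      rmr = numeric(0), energy_tier = numeric(0),
                      stringsAsFactors = FALSE))
  }
  if (!all(participants$responder_class %in% eligible_classes())) {
    stop("all participants must be fat_responder or carb_responder",
         call. = FALSE)
  }
  arms <- c("high_fat", "high_carb")
  set.seed(as.integer(seed))

  participants$stratum <- paste(participants$responder_class,
                                participants$sex, sep = ".")
  out <- vector("list", length(unique(participants$stratum)))
  names(out) <- sort(unique(participants$stratum))

  # running BMI totals per arm, pooled over strata: the balancing signal is
  # the trial-wide between-arm mean difference
  bmi_sum <- c(high_fat = 0, high_carb = 0)
  bmi_n <- c(high_fat = 0L, high_carb = 0L)

  for (st in names(out)) {
    idx <- which(participants$stratum == st)
    n_st <- length(idx)
    sx <- participants$sex[idx[1L]]
    sizes <- block_sizes[[sx]]
    arm_assigned <- character(n_st)
    block_index <- integer(n_st)
    block_size <- integer(n_st)

    pos <- 1L
    blk <- 0L
    while (pos <= n_st) {
      blk <- blk + 1L
      size <- if ((pos - 1L) < switch_fraction * n_st) sizes[1L] else sizes[2L]
      quota <- c(high_fat = size / 2, high_carb = size / 2)
      for (j in seq_len(min(size, n_st - pos + 1L))) {
        i <- pos + j - 1L
        open <- names(quota)[quota > 0]
        if (length(open) == 1L) {
          arm <- open
        } else {
          bmi_i <- participants$bmi[idx[i]]
          # between-arm mean difference that would result from each choice
          post_diff <- vapply(arms, function(a) {
            s <- bmi_sum; k <- bmi_n
            s[a] <- s[a] + bmi_i; k[a] <- k[a] + 1L
            if (any(k == 0L)) return(0)
            s["high_fat"] / k["high_fat"] - s["high_carb"] / k["high_carb"]
          }, numeric(1))
          diff_now <- if (all(bmi_n > 0)) {
            bmi_sum["high_fat"] / bmi_n["high_fat"] -
              bmi_sum["high_carb"] / bmi_n["high_carb"]
          } else 0
          if (abs(diff_now) <= bmi_tolerance / 2 ||
              abs(diff(post_diff)) < 1e-12) {
            arm <- sample(arms, 1L)
          } else {
            balancing <- arms[which.min(abs(post_diff))]
            arm <- if (stats::runif(1L) < biased_coin_p) balancing
                   else setdiff(arms, balancing)
          }
        }
        quota[arm] <- quota[arm] - 1
        bmi_sum[arm] <- bmi_sum[arm] + participants$bmi[idx[i]]
        bmi_n[arm] <- bmi_n[arm] + 1L
        arm_assigned[i] <- arm
        block_index[i] <- blk
        block_size[i] <- size
      }
      pos <- pos + size
    }

    rmr <- mifflin_st_jeor(participants$sex[idx],
                           participants$weight_kg[idx],
                           participants$height_cm[idx],
                           participants$age_years[idx])
    out[[st]] <- data.frame(
      subject_id = participants$subject_id[idx],
      stratum = st,
      responder_class = participants$responder_class[idx],
      sex = participants$sex[idx],
      arm = arm_assigned,
      block_index = block_index,
      block_size = block_size,
      concordant = is_concordant(participants$responder_class[idx],
                                 arm_assigned),
      rmr = rmr,
      energy_tier = prescribe_energy(rmr, activity_factor, deficit),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  # restore enrolment order
  res <- res[match(participants$subject_id, res$subject_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
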