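#' HOMA-IR insulin-resistance index
#'
#' Homeostatic model assessment of insulin resistance from fasting values:
#' \code{glucose * insulin / constant}, with the mass-unit constant 405
#' (glucose in mg/dL, insulin in uU/mL). Use \code{constant = 22.5} for
#' molar glucose (mmol/L).
#'
#' @param glucose Fasting glucose, mg/dL (non-negative).
#' @param insulin Fasting insulin, uU/mL (non-negative).
#' @param constant Denominator; 405 for mass units.
#' @return Dimensionless index (vectorized).
#' @examples
#' homa_ir(100, 10)  # 2.469
#' @export
homa_ir <- function(glucose, insulin, constant = 405) {
  if (any(glucose < 0) || any(insulin < 0)) {
    stop("glucose and insulin must be non-negative", call. = FALSE)
  }
  glucose * insulin / constant
}

#' Baseline-adjusted between-group difference (ANCOVA on change scores)
#'
#' Fits a linear model of a change-score outcome on the two-level group
#' factor plus covariates (by default sex, race, and the baseline value of
#' the outcome) on complete cases, and returns the group coefficient --
#' the adjusted difference between least-squares group means -- with a
#' t-based 95\% confidence interval on residual degrees of freedom and a
#' two-sided p-value. This ANCOVA-on-change formulation is the standard
#' single-follow-up equivalent of a two-timepoint random-intercept model
#' (see the methods vignette).
#'
#' Covariates that are constant in the analysed rows would make the design
#' singular; they are dropped with a warning. If the residuals are exactly
#' degenerate (zero variance) the estimate is returned with
#' \code{degenerate = TRUE} and a missing p-value.
#'
#' @param data Data frame containing all referenced columns.
#' @param outcome Name of the change-score column.
#' @param group Name of a two-level grouping column; the estimate is
#'   level2 minus level1 in factor-level order (set factor levels to choose
#'   the direction).
#' @param covariates Character vector of covariate column names.
#' @param baseline Optional name of the baseline-value column (appended to
#'   the covariates).
#' @param conf_level Confidence level (default 0.95).
#' @return An \code{effect_estimate}: one-row data frame with
#'   \code{contrast}, \code{estimate}, \code{ci_low}, \code{ci_high},
#'   \code{p_value}, \code{n_used}, \code{degenerate}; the covariates
#'   actually used are kept in the \code{"covariates"} attribute.
#' @export
adjusted_difference <- function(data, outcome, group,
                                covariates = c("sex", "race"),
                                baseline = NULL,
                                conf_level = 0.95) {
  covs <- c(covariates, baseline)
  cols <- c(outcome, group, covs)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
            drop = FALSE]
  if (nrow(d) == 0L) stop("no complete cases for outcome ", outcome,
                          call. = FALSE)
  d[[group]] <- factor(d[[group]])
  if (nlevels(d[[group]]) != 2L) {
    stop("group must have exactly two observed levels", call. = FALSE)
  }
  if (min(table(d[[group]])) < 2L) {
    stop("need at least 2 subjects per group level", call. = FALSE)
  }

  keep <- character(0)
  for (cv in covs) {
    v <- d[[cv]]
    ok <- if (is.numeric(v)) stats::var(v) > 0 else length(unique(v)) > 1L
    if (ok) keep <- c(keep, cv) else
      warning(sprintf("covariate '%s' is constant; dropped", cv),
              call. = FALSE)
  }
  fml <- stats::reformulate(c(group, keep), response = outcome)
  fit <- stats::lm(fml, data = d)

  co <- stats::coef(summary(fit))
  term <- paste0(group, levels(d[[group]])[2L])
  est <- co[term, "Estimate"]
  se <- co[term, "Std. Error"]
  df <- fit$df.residual
  degenerate <- !is.finite(se) || stats::sigma(fit) < 1e-10
  if (degenerate) {
    ci <- c(est, est); p <- NA_real_
  } else {
    tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
    ci <- est + c(-1, 1) * tcrit * se
    p <- co[term, "Pr(>|t|)"]
  }
  out <- data.frame(
    contrast = paste(levels(d[[group]])[2L], "-", levels(d[[group]])[1L]),
    estimate = est, ci_low = ci[1L], ci_high = ci[2L],
    p_value = p, n_used = nrow(d), degenerate = degenerate,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "covariates") <- keep
  class(out) <- c("effect_estimate", class(out))
  out
}

#' Holm-Bonferroni step-down adjustment
#'
#' Familywise-error control for a family of secondary endpoints: the i-th
#' smallest p-value is multiplied by (m - i + 1), a running maximum
#' enforces monotonicity, and values are capped at 1 and mapped back to
#' input order (via [stats::p.adjust()]).
#'
#' @param raw_p Numeric vector of p-values in \[0, 1\].
#' @param family_label Optional label for the endpoint family.
#' @return A \code{holm_result}: list with \code{raw_p},
#'   \code{adjusted_p}, \code{family_label}.
#' @examples
#' holm_adjust(c(0.001, 0.2, 0.3, 0.4, 0.5, 0.6))$adjusted_p[1]  # 0.006
#' @export
holm_adjust <- function(raw_p, family_label = NA_character_) {
  if (any(!is.finite(raw_p)) || any(raw_p < 0 | raw_p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  structure(list(raw_p = raw_p,
                 adjusted_p = stats::p.adjust(raw_p, method = "holm"),
                 family_label = family_label),
            class = "holm_result")
}

#' Association of baseline insulin measures with weight change
#'
#' For each predictor (by default fasting insulin and HOMA-IR), fits a
#' linear model of weight change on the predictor adjusted for diet arm,
#' sex, and race, and reports the predictor slope with 95\% CI and p. A
#' second model adds the diet-by-predictor interaction and reports its
#' p-value, probing whether insulin-resistant subjects respond
#' differentially to the two diets.
#'
#' @param data Data frame with the outcome, predictors, and covariates.
#' @param predictors Character vector of predictor column names.
#' @param outcome Outcome column (default \code{"weight_change_kg"}).
#' @param group Diet-arm column (default \code{"arm"}).
#' @param covariates Additional adjustment covariates.
#' @return Data frame with one row per predictor: \code{predictor},
#'   \code{slope}, \code{ci_low}, \code{ci_high}, \code{p_value},
#'   \code{interaction_p}, \code{n_used}.
#' @export
insulin_association <- function(data,
                                predictors = c("insulin", "homa_ir"),
                                outcome = "weight_change_kg",
                                group = "arm",
                                covariates = c("sex", "race")) {
  out <- lapply(predictors, function(pr) {
    cols <- c(outcome, pr, group, covariates)
    d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
              drop = FALSE]
    if (stats::var(d[[pr]]) == 0) {
      stop(sprintf("predictor '%s' has zero variance", pr), call. = FALSE)
    }
    d[[group]] <- factor(d[[group]])
    covariates <- covariates[vapply(covariates, function(cv)
      length(unique(d[[cv]])) > 1L, logical(1))]
    fml <- stats::reformulate(c(pr, group, covariates), response = outcome)
    fit <- stats::lm(fml, data = d)
    co <- stats::coef(summary(fit))
    est <- co[pr, "Estimate"]; se <- co[pr, "Std. Error"]
    tcrit <- stats::qt(0.975, fit$df.residual)

    fml_int <- stats::update(fml, stats::as.formula(
      paste(". ~ . +", pr, ":", group)))
    fit_int <- stats::lm(fml_int, data = d)
    int_p <- stats::anova(fit, fit_int)[2L, "Pr(>F)"]

    data.frame(predictor = pr, slope = est,
               ci_low = est - tcrit * se, ci_high = est + tcrit * se,
               p_value = co[pr, "Pr(>|t|)"],
               interaction_p = int_p, n_used = nrow(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Summarize diet adherence by arm, week, and macronutrient
#'
#' Mean and SD of reported percent energy per macronutrient in each
#' arm-week cell, with the deviation from the arm's target. A cell with a
#' single record reports a missing SD; an empty cell is simply absent.
#'
#' @param records Adherence records as from [simulate_adherence()]
#'   (columns \code{arm}, \code{week}, \code{carb_pct}, \code{fat_pct},
#'   \code{protein_pct}).
#' @param targets Optional data frame \code{arm}, \code{macro},
#'   \code{target}; defaults to [arm_macro_targets()] for both arms.
#' @return Data frame: \code{arm}, \code{week}, \code{macro}, \code{n},
#'   \code{mean}, \code{sd}, \code{target}, \code{deviation}.
#' @export
summarize_adherence <- function(records, targets = NULL) {
  if (nrow(records) == 0L) stop("no adherence records", call. = FALSE)
  if (is.null(targets)) {
    targets <- do.call(rbind, lapply(c("high_carb", "high_fat"), function(a) {
      tg <- arm_macro_targets(a)
      data.frame(arm = a, macro = names(tg), target = unname(tg),
                 stringsAsFactors = FALSE)
    }))
  }
  long <- do.call(rbind, lapply(c("carb", "fat", "protein"), function(m) {
    data.frame(arm = records$arm, week = records$week, macro = m,
               pct = records[[paste0(m, "_pct")]], stringsAsFactors = FALSE)
  }))
  agg <- do.call(rbind, lapply(split(long, long[c("macro", "week", "arm")],
                                     drop = TRUE), function(g) {
    data.frame(arm = g$arm[1L], week = g$week[1L], macro = g$macro[1L],
               n = nrow(g), mean = mean(g$pct),
               sd = if (nrow(g) > 1L) stats::sd(g$pct) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  agg <- merge(agg, targets, by = c("arm", "macro"), all.x = TRUE)
  agg$deviation <- agg$mean - agg$target
  agg <- agg[order(agg$arm, agg$week, match(agg$macro, c("carb", "fat", "protein"))), ]
  rownames(agg) <- NULL
  agg
}

#' Participant-flow (CONSORT-style) accounting
#'
#' Counts subjects at each stage of a screening-to-analysis chain and the
#' exclusions between consecutive stages. Stage membership must be nested:
#' a subject at stage k must also be at every earlier stage, otherwise the
#' log is inconsistent and an error is raised. If a \code{class} column is
#' present, the fractions of responder classes among subjects at the
#' classification stage are attached.
#'
#' @param log Data frame with one row per subject and logical columns for
#'   the stages.
#' @param stages Character vector of stage column names, outermost first.
#' @param class_stage Stage at which responder class was determined
#'   (for the class-fraction summary); default the second stage.
#' @return Data frame \code{stage}, \code{n}, \code{n_excluded}, with
#'   attribute \code{class_fractions} when available.
#' @export
consort_accounting <- function(log, stages,
                               class_stage = stages[min(2L, length(stages))]) {
  for (s in stages) {
    if (!s %in% names(log) || !is.logical(log[[s]])) {
      stop(sprintf("stage column '%s' must be logical", s), call. = FALSE)
    }
  }
  for (i in seq_along(stages)[-1L]) {
    bad <- log[[stages[i]]] & !log[[stages[i - 1L]]]
    if (any(bad)) {
      stop(sprintf("inconsistent flow: %d subject(s) at stage '%s' but not '%s'",
                   sum(bad), stages[i], stages[i - 1L]), call. = FALSE)
    }
  }
  n <- vapply(stages, function(s) sum(log[[s]]), integer(1))
  out <- data.frame(stage = stages, n = n,
                    n_excluded = c(NA_integer_, -diff(n)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if ("class" %in% names(log)) {
    at <- log[[class_stage]] & !is.na(log$class)
    if (any(at)) {
      tab <- table(factor(log$class[at],
                          levels = c("fat_responder", "carb_responder",
                                     "both", "neither")))
      attr(out, "class_fractions") <- as.numeric(tab) / sum(at)
      names(attr(out, "class_fractions")) <- names(tab)
    }
  }
  out
}
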