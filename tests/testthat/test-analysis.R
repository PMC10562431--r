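test_that("HOMA-IR matches the mass-unit formula and is bilinear", {
  expect_equal(homa_ir(100, 10), 100 * 10 / 405, tolerance = 1e-12)
  expect_equal(round(homa_ir(100, 10), 3), 2.469)
  expect_equal(homa_ir(100, 0), 0)
  expect_equal(homa_ir(200, 10), 2 * homa_ir(100, 10))
  expect_equal(homa_ir(100, 20), 2 * homa_ir(100, 10))
  expect_error(homa_ir(-5, 10), "non-negative")
  # molar variant
  expect_equal(homa_ir(5.5, 10, constant = 22.5), 5.5 * 10 / 22.5)
})

test_that("Holm adjustment reproduces hand-run step-down values", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03))$adjusted_p,
               c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.03)$adjusted_p, 0.03)
  # a 6-endpoint family whose smallest raw p is 0.001 adjusts to 0.006
  fam <- holm_adjust(c(0.001, 0.21, 0.35, 0.48, 0.62, 0.77))
  expect_equal(fam$adjusted_p[1], 0.006)
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Holm output dominates raw p and is order-invariant", {
  # independent oracle: literal step-down rule run by hand
  holm_oracle <- function(p) {
    m <- length(p); o <- order(p)
    adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
    adj <- cummax(adj)
    out <- numeric(m); out[o] <- adj
    out
  }
  set.seed(51)
  for (rep in 1:50) {
    p <- stats::runif(sample(1:8, 1))
    got <- holm_adjust(p)$adjusted_p
    expect_equal(got, holm_oracle(p))
    expect_true(all(got >= p - 1e-12) && all(got <= 1))
    perm <- sample(length(p))
    expect_equal(holm_adjust(p[perm])$adjusted_p, got[perm])
  }
  # all-equal family: first adjusted value is min(1, m p)
  expect_equal(holm_adjust(rep(0.02, 5))$adjusted_p, rep(0.1, 5))
})

make_analysis_data <- function(n_per_group, delta, sd, seed) {
  set.seed(seed)
  n <- 2 * n_per_group
  d <- data.frame(
    group = rep(c("ctrl", "trt"), each = n_per_group),
    sex = sample(c("female", "male"), n, TRUE, c(0.84, 0.16)),
    race = sample(c("white", "black", "other"), n, TRUE, c(.68, .295, .025)),
    baseline = stats::rnorm(n, 94, 15), stringsAsFactors = FALSE)
  d$change <- delta * (d$group == "trt") + stats::rnorm(n, -5, sd)
  d
}

test_that("with no covariates the adjusted difference equals the pooled t-test", {
  d <- make_analysis_data(15, -1.5, 2.8, seed = 61)
  est <- adjusted_difference(d, "change", "group", covariates = character(0))
  tt <- stats::t.test(change ~ group, data = d, var.equal = TRUE)
  expect_equal(est$estimate, unname(diff(tt$estimate)), tolerance = 1e-10)
  expect_equal(est$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(c(est$ci_low, est$ci_high),
               unname(-rev(tt$conf.int)), tolerance = 1e-10)
})

test_that("adjusted differences are invariant to row order and race relabels", {
  d <- make_analysis_data(40, -2, 2.8, seed = 62)
  est <- adjusted_difference(d, "change", "group",
                             covariates = c("sex", "race"),
                             baseline = "baseline")
  shuf <- d[sample(nrow(d)), ]
  est2 <- adjusted_difference(shuf, "change", "group",
                              covariates = c("sex", "race"),
                              baseline = "baseline")
  expect_equal(est$estimate, est2$estimate, tolerance = 1e-10)
  expect_equal(est$p_value, est2$p_value, tolerance = 1e-10)

  relab <- d
  relab$race <- c(white = "Z_w", black = "A_b", other = "M_o")[relab$race]
  est3 <- adjusted_difference(relab, "change", "group",
                              covariates = c("sex", "race"),
                              baseline = "baseline")
  expect_equal(est$estimate, est3$estimate, tolerance = 1e-10)
  expect_equal(est$p_value, est3$p_value, tolerance = 1e-10)
})

test_that("constant covariates are dropped and degenerate fits flagged", {
  d <- make_analysis_data(10, 0, 1, seed = 63)
  d$race <- "white"
  expect_warning(
    est <- adjusted_difference(d, "change", "group",
                               covariates = c("sex", "race")),
    "constant")
  expect_false(est$degenerate)

  d2 <- data.frame(group = rep(c("a", "b"), each = 5), change = 3)
  est2 <- adjusted_difference(d2, "change", "group",
                              covariates = character(0))
  expect_true(est2$degenerate)
  expect_equal(est2$estimate, 0)
  expect_true(is.na(est2$p_value))

  d3 <- d; d3$change <- NA_real_
  expect_error(adjusted_difference(d3, "change", "group",
                                   covariates = character(0)),
               "complete cases")
})

test_that("an injected effect is recovered and missing outcomes excluded", {
  d <- make_analysis_data(2000, -2, 2.8, seed = 64)
  d$change[1:50] <- NA  # incomplete subjects are dropped, not imputed
  est <- adjusted_difference(d, "change", "group",
                             covariates = c("sex", "race"),
                             baseline = "baseline")
  expect_equal(est$n_used, 3950)
  expect_lt(abs(est$estimate - (-2)), 3 * 2.8 * sqrt(2 / 2000))
  expect_equal(est$contrast, "trt - ctrl")
})

test_that("insulin association slopes rescale exactly with the predictor", {
  set.seed(65)
  n <- 300
  d <- data.frame(
    arm = rep(c("high_carb", "high_fat"), each = n / 2),
    sex = sample(c("female", "male"), n, TRUE),
    race = sample(c("white", "black"), n, TRUE),
    insulin = stats::rlnorm(n, log(12), 0.4), stringsAsFactors = FALSE)
  d$homa_ir <- homa_ir(stats::rlnorm(n, log(93), .1), d$insulin)
  d$weight_change_kg <- -5 - 0.1 * d$insulin + stats::rnorm(n, 0, 2.8)
  res <- insulin_association(d)
  expect_equal(res$predictor, c("insulin", "homa_ir"))
  expect_true(all(res$ci_low <= res$slope & res$slope <= res$ci_high))

  d$insulin2 <- 2 * d$insulin
  res2 <- insulin_association(d, predictors = "insulin2")
  expect_equal(res2$slope, res$slope[1] / 2, tolerance = 1e-10)
  expect_equal(res2$p_value, res$p_value[1], tolerance = 1e-10)

  d$flat <- 1
  expect_error(insulin_association(d, predictors = "flat"), "zero variance")
})

test_that("adherence summaries report means, SDs, and target deviations", {
  rec <- data.frame(
    subject_id = c("a", "b", "c"),
    arm = c("high_carb", "high_carb", "high_fat"),
    week = 4,
    carb_pct = c(65, 63, 45), fat_pct = c(20, 21, 40),
    protein_pct = c(15, 16, 15), stringsAsFactors = FALSE)
  s <- summarize_adherence(rec)
  hc_carb <- s[s$arm == "high_carb" & s$macro == "carb", ]
  expect_equal(hc_carb$mean, 64)
  expect_equal(hc_carb$deviation, -1)
  expect_equal(hc_carb$n, 2L)
  # single-record cell: SD undefined, reported missing
  hf <- s[s$arm == "high_fat" & s$macro == "fat", ]
  expect_true(is.na(hf$sd))
  expect_equal(hf$deviation, 0)

  exact <- data.frame(subject_id = "x", arm = "high_fat", week = 8,
                      carb_pct = 45, fat_pct = 40, protein_pct = 15,
                      stringsAsFactors = FALSE)
  s2 <- summarize_adherence(exact)
  expect_true(all(s2$deviation == 0))
})

test_that("participant-flow accounting counts stages and rejects bad chains", {
  log <- data.frame(
    screened = rep(TRUE, 10),
    eligible = c(rep(TRUE, 8), FALSE, FALSE),
    completed = c(rep(TRUE, 7), rep(FALSE, 3)),
    class = c(rep("fat_responder", 5), rep("carb_responder", 3),
              "both", "neither"))
  tab <- consort_accounting(log, c("screened", "eligible", "completed"),
                            class_stage = "screened")
  expect_equal(tab$n, c(10L, 8L, 7L))
  expect_equal(tab$n_excluded, c(NA_integer_, 2L, 1L))
  cf <- attr(tab, "class_fractions")
  expect_equal(unname(cf["fat_responder"]), 0.5)

  bad <- log
  bad$eligible[9] <- TRUE
  bad$screened[9] <- FALSE
  expect_error(consort_accounting(bad, c("screened", "eligible", "completed")),
               "inconsistent")
})
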