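test_that("score-table configs load, validate, and reject placeholders", {
  st <- toy_score_table()
  expect_s3_class(st, "score_table")
  expect_equal(nrow(st$panel), 3L)
  expect_equal(length(st$points) * 3L, 9L)  # 3 genotypes per SNP

  full <- full_score_table()
  expect_equal(nrow(full$panel), 10L)
  expect_equal(full$version_tag, "UPDATED_10SNP")
  # ambiguous-strand loci are marked
  expect_true(full$panel$ambiguous_strand[full$panel$rsid == "rs9939609"])

  cfg <- make_config(list(rs5082 = c("C", "T")),
                     list(rs5082 = list(fat = 0:2, carb = c(0, 0, 0))))
  cfg$panel[[1]]$points[["CT"]] <- NULL  # drop the heterozygote entry
  expect_error(load_score_table(cfg), "rs5082")

  bad <- make_config(list(rs1 = c("A", "G")),
                     list(rs1 = list(fat = 0:2, carb = c(0, 0, 0))))
  bad$panel[[1]]$points[["AA"]]$fat <- "REQUIRED"
  expect_error(load_score_table(bad), "placeholder")

  unk <- cfg <- make_config(list(rs1 = c("A", "G")),
                            list(rs1 = list(fat = 0:2, carb = c(0, 0, 0))))
  unk$version_tag <- "V99"
  expect_error(load_score_table(unk), "version_tag")
})

test_that("a 6-SNP legacy config is accepted under its version tag", {
  alleles <- stats::setNames(
    rep(list(c("A", "G")), 6), paste0("rs", 1:6))
  points <- stats::setNames(
    rep(list(list(fat = 0:2, carb = c(0, 0, 0))), 6), paste0("rs", 1:6))
  cfg <- make_config(alleles, points)
  cfg$version_tag <- "ORIGINAL_6SNP"
  st <- load_score_table(cfg)
  expect_equal(st$version_tag, "ORIGINAL_6SNP")
  expect_error(load_score_table(modifyList(cfg, list(version_tag = "UPDATED_10SNP"))),
               "expects 10")
})

test_that("score_subject sums per-SNP points and honors missing policy", {
  st <- toy_score_table()
  # hom-effect / het / hom-effect on the toy 1 / 0.5 scale
  gt <- make_genotype_table(list(rs0000001 = c("A", "A"),
                                 rs0000002 = c("C", "T"),
                                 rs0000003 = c("G", "G")))
  pg <- normalize_panel(extract_panel(gt, st$panel), st$panel)
  sc <- score_subject(pg, st, missing_policy = "zero")
  expect_equal(sc$fat_points, 2.5)
  expect_equal(sc$carb_points, 0)
  expect_equal(sc$n_missing, 0L)

  all_missing <- make_genotype_table(list(rs0000001 = c(NA, NA),
                                          rs0000002 = c(NA, NA),
                                          rs0000003 = c(NA, NA)))
  pg0 <- extract_panel(all_missing, st$panel)
  sc0 <- score_subject(pg0, st, missing_policy = "zero")
  expect_equal(c(sc0$fat_points, sc0$carb_points), c(0, 0))
  expect_equal(sc0$n_missing, 3L)

  one_missing <- make_genotype_table(list(rs0000001 = c("A", "A"),
                                          rs0000002 = c(NA, NA),
                                          rs0000003 = c("G", "G")))
  pg1 <- extract_panel(one_missing, st$panel)
  expect_error(score_subject(pg1, st, missing_policy = "reject"),
               "unscorable")
})

test_that("score_subject matches a brute-force oracle on small panels", {
  set.seed(31)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:40) {
    n_snp <- sample(1:4, 1)
    rsids <- paste0("rs", 100 + seq_len(n_snp))
    alleles <- stats::setNames(lapply(rsids, function(x) {
      a <- sample(bases, 2)
      # avoid strand-ambiguous pairs so orientation stays trivial here
      while (setequal(a, c("A", "T")) || setequal(a, c("C", "G")))
        a <- sample(bases, 2)
      a
    }), rsids)
    points <- stats::setNames(lapply(rsids, function(x)
      list(fat = round(stats::runif(3, -1, 2), 2),
           carb = round(stats::runif(3, -1, 2), 2))), rsids)
    st <- load_score_table(make_config(alleles, points))

    counts <- sample(0:2, n_snp, replace = TRUE)
    genos <- stats::setNames(lapply(seq_len(n_snp), function(i) {
      eff <- alleles[[i]][1]; oth <- alleles[[i]][2]
      sort(c(rep(eff, counts[i]), rep(oth, 2 - counts[i])))
    }), rsids)
    pg <- extract_panel(make_genotype_table(genos), st$panel)
    sc <- score_subject(pg, st, missing_policy = "reject")

    # oracle: direct per-SNP lookup summed by hand
    exp_fat <- sum(vapply(seq_len(n_snp), function(i)
      points[[i]]$fat[counts[i] + 1], numeric(1)))
    exp_carb <- sum(vapply(seq_len(n_snp), function(i)
      points[[i]]$carb[counts[i] + 1], numeric(1)))
    expect_equal(sc$fat_points, exp_fat)
    expect_equal(sc$carb_points, exp_carb)
  }
})

test_that("classification is a partition with inclusive thresholds", {
  expect_equal(classify_responder(list(fat_points = 5, carb_points = 1),
                                  thresholds_only(4, 4)), "fat_responder")
  expect_equal(classify_responder(list(fat_points = 4, carb_points = 4),
                                  thresholds_only(4, 4)), "both")
  expect_equal(classify_responder(list(fat_points = 0, carb_points = 0),
                                  thresholds_only(4, 4)), "neither")

  set.seed(11)
  for (rep in 1:500) {
    st <- thresholds_only(stats::runif(1, -5, 5), stats::runif(1, -5, 5))
    sc <- list(fat_points = stats::runif(1, -10, 10),
               carb_points = stats::runif(1, -10, 10))
    cls <- classify_responder(sc, st)
    # exactly one of the four mutually exclusive predicates holds
    preds <- c(
      fat_responder = sc$fat_points >= st$fat_threshold &&
        sc$carb_points < st$carb_threshold,
      carb_responder = sc$carb_points >= st$carb_threshold &&
        sc$fat_points < st$fat_threshold,
      both = sc$fat_points >= st$fat_threshold &&
        sc$carb_points >= st$carb_threshold,
      neither = sc$fat_points < st$fat_threshold &&
        sc$carb_points < st$carb_threshold)
    expect_equal(sum(preds), 1L)
    expect_equal(cls, names(preds)[preds])
  }
})

test_that("raising fat points never demotes a fat-responder to neither", {
  set.seed(12)
  for (rep in 1:200) {
    st <- thresholds_only(stats::runif(1, 0, 5), stats::runif(1, 0, 5))
    f <- stats::runif(1, st$fat_threshold, st$fat_threshold + 5)
    cb <- stats::runif(1, -5, st$carb_threshold - 1e-9)
    cls1 <- classify_responder(list(fat_points = f, carb_points = cb), st)
    cls2 <- classify_responder(list(fat_points = f + stats::runif(1, 0, 5),
                                    carb_points = cb), st)
    expect_equal(cls1, "fat_responder")
    expect_equal(cls2, "fat_responder")
  }
})

test_that("scores and classes are invariant to panel SNP order", {
  st <- toy_score_table()
  gt <- make_genotype_table(list(rs0000001 = c("A", "G"),
                                 rs0000002 = c("C", "C"),
                                 rs0000003 = c("G", "T")))
  pg <- normalize_panel(extract_panel(gt, st$panel), st$panel)
  sc <- score_subject(pg, st, "zero")
  perm <- pg[c(3, 1, 2), ]
  attr(perm, "subject_id") <- attr(pg, "subject_id")
  sc_perm <- score_subject(perm, st, "zero")
  expect_equal(sc$fat_points, sc_perm$fat_points)
  expect_equal(sc$carb_points, sc_perm$carb_points)
  expect_equal(classify_responder(sc, st), classify_responder(sc_perm, st))
})

test_that("screen_cohort aggregates classes and isolates unscorable subjects", {
  st <- toy_score_table()
  mk <- function(g1, g2, g3, id) make_genotype_table(
    list(rs0000001 = g1, rs0000002 = g2, rs0000003 = g3), subject_id = id)
  tables <- list(
    mk(c("A", "A"), c("C", "C"), c("G", "G"), "fat"),      # fat 3, carb 0
    mk(c("G", "G"), c("T", "T"), c("T", "T"), "carb"),     # fat 0, carb 1
    mk(c("A", "A"), c("C", "C"), c("T", "T"), "both"),     # fat 2, carb 1
    mk(c("G", "G"), c("T", "T"), c("G", "G"), "neither"),  # fat 1, carb 0
    mk(c(NA, NA), c("C", "C"), c("G", "G"), "missing"))
  res <- screen_cohort(tables, st)
  expect_equal(res$class[1:4],
               c("fat_responder", "carb_responder", "both", "neither"))
  expect_equal(sum(res$eligible), 2L)
  expect_true(is.na(res$class[5]))
  expect_equal(attr(res, "n_unscorable"), 1L)
  smry <- attr(res, "summary")
  expect_equal(smry$n[smry$class == "fat_responder"], 1L)
  expect_equal(sum(smry$fraction), 1)
})

test_that("exact class probabilities match Monte-Carlo sampling", {
  st <- toy_score_table()
  freqs <- c(rs0000001 = 0.6, rs0000002 = 0.5, rs0000003 = 0.4)
  p <- responder_class_probabilities(st, freqs)
  expect_equal(sum(p), 1)

  cfg <- simulation_config(allele_freqs = freqs, missing_call_rate = 0,
                           strand_flip_rate = 0)
  g <- generate_genotypes(4000, cfg, st, seed = 5)
  res <- screen_cohort(g, st)
  obs <- prop.table(table(factor(res$class, levels = names(p))))
  for (cls in names(p)) {
    se <- sqrt(p[cls] * (1 - p[cls]) / 4000)
    expect_lt(abs(obs[[cls]] - p[[cls]]), 4 * se + 1e-9)
  }
})
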