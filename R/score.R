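#' Load a responder score table from a YAML config
#'
#' The responder score sums per-SNP points on two axes -- fat-diet
#' responsiveness and carbohydrate-diet responsiveness -- over a panel of
#' diet-response variants, and classifies a subject by comparing each axis
#' total to its threshold. The point values and thresholds live in a
#' versioned config so the scoring criteria are swappable and testable; the
#' engine itself is table-agnostic.
#'
#' The config must declare \code{version_tag} (one of
#' \code{"ORIGINAL_6SNP"}, \code{"UPDATED_10SNP"}, or \code{"TOY"}),
#' numeric \code{fat_threshold} and \code{carb_threshold}, and a
#' \code{panel} list in which every SNP gives its \code{rsid},
#' \code{chromosome}, \code{alleles} (effect allele first), and a
#' \code{points} map with one \code{\{fat, carb\}} entry per diploid
#' genotype of its allele pair. Incomplete genotype coverage or placeholder
#' (non-numeric) point values are rejected at load.
#'
#' The package ships two configs under \code{extdata}:
#' \code{score_table_10snp_synthetic.yaml}, a synthetic 10-variant table
#' whose point values and thresholds are this package's own construction
#' (calibrated so that population class probabilities under the default
#' allele frequencies are approximately 41\% fat-responder, 20\%
#' carbohydrate-responder, 39\% neither-or-both), and
#' \code{score_table_toy3.yaml}, a 3-SNP table used in examples and tests.
#'
#' @param config Path to a YAML file, or an already-parsed list.
#' @return A \code{score_table}: list with \code{version_tag},
#'   \code{fat_threshold}, \code{carb_threshold}, \code{panel} (data frame
#'   of SNP definitions with columns \code{rsid}, \code{chromosome},
#'   \code{allele1}, \code{allele2}, \code{ambiguous_strand}), and
#'   \code{points}, a per-rsid lookup of fat/carb points indexed by
#'   effect-allele count (0, 1, 2).
#' @examples
#' st <- load_score_table(system.file("extdata",
#'   "score_table_toy3.yaml", package = "genodiet"))
#' st$panel
#' @export
load_score_table <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  for (field in c("version_tag", "fat_threshold", "carb_threshold", "panel")) {
    if (is.null(cfg[[field]])) {
      stop(sprintf("score config is missing '%s'", field), call. = FALSE)
    }
  }
  if (!cfg$version_tag %in% c("ORIGINAL_6SNP", "UPDATED_10SNP", "TOY")) {
    stop(sprintf("unknown version_tag '%s'", cfg$version_tag), call. = FALSE)
  }
  fat_thr <- as.numeric(cfg$fat_threshold)
  carb_thr <- as.numeric(cfg$carb_threshold)
  if (!is.finite(fat_thr) || !is.finite(carb_thr)) {
    stop("thresholds must be finite numbers", call. = FALSE)
  }

  rsid <- chrom <- a1 <- a2 <- character(0)
  points <- list()
  for (snp in cfg$panel) {
    if (is.null(snp$rsid) || is.null(snp$alleles) || is.null(snp$points)) {
      stop("each panel SNP needs rsid, alleles, and points", call. = FALSE)
    }
    eff <- as.character(snp$alleles[[1L]])
    oth <- as.character(snp$alleles[[2L]])
    if (!all(c(eff, oth) %in% c("A", "C", "G", "T")) || eff == oth) {
      stop(sprintf("%s: alleles must be two distinct bases", snp$rsid),
           call. = FALSE)
    }
    # genotype keys accepted in either allele order; index by effect count
    keys <- list(`0` = paste0(oth, oth),
                 `1` = c(paste0(eff, oth), paste0(oth, eff)),
                 `2` = paste0(eff, eff))
    fat <- carb <- rep(NA_real_, 3L)
    for (k in 0:2) {
      hit <- intersect(keys[[as.character(k)]], names(snp$points))
      if (length(hit) == 0L) {
        stop(sprintf("score config incomplete: %s lacks a points entry for genotype %s",
                     snp$rsid, keys[[as.character(k)]][1L]), call. = FALSE)
      }
      entry <- snp$points[[hit[1L]]]
      fv <- suppressWarnings(as.numeric(entry$fat))
      cv <- suppressWarnings(as.numeric(entry$carb))
      if (length(fv) != 1L || length(cv) != 1L || is.na(fv) || is.na(cv)) {
        stop(sprintf("%s genotype %s: fat/carb points must be numeric (placeholders rejected)",
                     snp$rsid, hit[1L]), call. = FALSE)
      }
      fat[k + 1L] <- fv; carb[k + 1L] <- cv
    }
    if (snp$rsid %in% rsid) {
      stop(sprintf("duplicate rsid %s in panel", snp$rsid), call. = FALSE)
    }
    rsid <- c(rsid, snp$rsid)
    chrom <- c(chrom, as.character(snp$chromosome %||% NA))
    a1 <- c(a1, eff); a2 <- c(a2, oth)
    points[[snp$rsid]] <- list(fat = fat, carb = carb)
  }
  n_expect <- switch(cfg$version_tag, ORIGINAL_6SNP = 6L, UPDATED_10SNP = 10L, NA)
  if (!is.na(n_expect) && length(rsid) != n_expect) {
    stop(sprintf("version_tag %s expects %d panel SNPs, config has %d",
                 cfg$version_tag, n_expect, length(rsid)), call. = FALSE)
  }

  panel <- data.frame(rsid = rsid, chromosome = chrom,
                      allele1 = a1, allele2 = a2,
                      stringsAsFactors = FALSE)
  panel$ambiguous_strand <- mapply(
    function(x, y) setequal(c(x, y), unname(.complement[c(x, y)])),
    panel$allele1, panel$allele2, USE.NAMES = FALSE)
  structure(list(version_tag = cfg$version_tag,
                 fat_threshold = fat_thr, carb_threshold = carb_thr,
                 panel = panel, points = points),
            class = "score_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("score_table [%s]: %d SNPs, thresholds fat >= %g, carb >= %g\n",
              x$version_tag, nrow(x$panel), x$fat_threshold, x$carb_threshold))
  invisible(x)
}

#' Path to the shipped synthetic 10-SNP score table
#'
#' Convenience accessor for the default config. Its point values and
#' thresholds are synthetic (see [load_score_table()]).
#'
#' @return File path.
#' @export
default_score_config <- function() {
  system.file("extdata", "score_table_10snp_synthetic.yaml",
              package = "genodiet", mustWork = TRUE)
}

.effect_count <- function(alleles, effect) sum(alleles == effect)

#' Score one subject's panel genotypes
#'
#' Sums per-SNP fat and carbohydrate points over the non-missing panel
#' calls. With \code{missing_policy = "reject"} (the default, conservative
#' choice for eligibility screening) any missing panel SNP makes the
#' subject unscorable; \code{"zero"} lets missing SNPs contribute zero
#' points, for sensitivity analyses.
#'
#' @param panel_genotypes Output of [extract_panel()]/[normalize_panel()]:
#'   data frame with \code{rsid}, \code{allele1}, \code{allele2}.
#' @param table A [score_table].
#' @param missing_policy \code{"reject"} or \code{"zero"}.
#' @return A \code{responder_score}: list with \code{subject_id},
#'   \code{fat_points}, \code{carb_points}, \code{n_missing}.
#' @export
score_subject <- function(panel_genotypes, table,
                          missing_policy = c("reject", "zero")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(table, "score_table"))
  pg <- panel_genotypes
  miss <- is.na(pg$allele1)
  in_panel <- pg$rsid %in% table$panel$rsid
  # panel SNPs absent from the supplied genotype rows also count as missing
  absent <- setdiff(table$panel$rsid, pg$rsid)
  n_missing <- sum(miss & in_panel) + length(absent)
  if (missing_policy == "reject" && n_missing > 0L) {
    stop(sprintf("subject %s unscorable: %d panel SNP(s) without a call",
                 attr(pg, "subject_id") %||% "?", n_missing), call. = FALSE)
  }
  fat <- carb <- 0
  for (i in seq_len(nrow(pg))) {
    if (miss[i]) next
    rs <- pg$rsid[i]
    pts <- table$points[[rs]]
    if (is.null(pts)) next  # non-panel rows are ignored
    def <- table$panel[table$panel$rsid == rs, ]
    obs <- c(pg$allele1[i], pg$allele2[i])
    if (!all(obs %in% c(def$allele1, def$allele2))) {
      stop(sprintf("%s: alleles %s not oriented to panel alleles %s/%s (run normalize_panel first)",
                   rs, paste(obs, collapse = "/"), def$allele1, def$allele2),
           call. = FALSE)
    }
    k <- .effect_count(obs, def$allele1)
    fat <- fat + pts$fat[k + 1L]
    carb <- carb + pts$carb[k + 1L]
  }
  structure(list(subject_id = attr(pg, "subject_id") %||% NA_character_,
                 fat_points = fat, carb_points = carb,
                 n_missing = n_missing),
            class = "responder_score")
}

#' Four-way responder classification
#'
#' A subject is a fat-responder iff the fat axis meets its threshold and
#' the carbohydrate axis does not; symmetrically for carbohydrate-
#' responders. Meeting both thresholds is \code{"both"}, meeting neither is
#' \code{"neither"}; both of those states are ineligible for a concordant/
#' discordant diet assignment. Threshold comparisons are inclusive
#' (\code{>=}), so a boundary subject meeting both thresholds classifies as
#' \code{"both"} and is excluded.
#'
#' @param score A \code{responder_score}, or a list with numeric
#'   \code{fat_points} and \code{carb_points}.
#' @param table A [score_table] supplying the thresholds.
#' @return One of \code{"fat_responder"}, \code{"carb_responder"},
#'   \code{"both"}, \code{"neither"}.
#' @export
classify_responder <- function(score, table) {
  f <- score$fat_points >= table$fat_threshold
  c_ <- score$carb_points >= table$carb_threshold
  if (f && !c_) "fat_responder"
  else if (!f && c_) "carb_responder"
  else if (f && c_) "both"
  else "neither"
}

#' Responder classes eligible for randomization
#' @return Character vector of the two eligible classes.
#' @export
eligible_classes <- function() c("fat_responder", "carb_responder")

#' Screen a batch of genotype tables for diet-responder eligibility
#'
#' Runs panel extraction, strand orientation, scoring, and classification
#' for each subject. Unscorable subjects (under \code{"reject"}) are
#' recorded with a missing class rather than aborting the batch.
#'
#' @param tables List of \code{genotype_table} objects.
#' @param score_table A [score_table].
#' @param missing_policy Passed to [score_subject()].
#' @return Data frame with one row per subject: \code{subject_id},
#'   \code{fat_points}, \code{carb_points}, \code{n_missing},
#'   \code{class} (\code{NA} if unscorable), \code{eligible}. The attribute
#'   \code{summary} holds per-class counts and fractions among scored
#'   subjects.
#' @export
screen_cohort <- function(tables, score_table,
                          missing_policy = c("reject", "zero")) {
  missing_policy <- match.arg(missing_policy)
  if (length(tables) == 0L) stop("no genotype tables supplied", call. = FALSE)
  n <- length(tables)
  out <- data.frame(subject_id = character(n),
                    fat_points = NA_real_, carb_points = NA_real_,
                    n_missing = NA_integer_, class = NA_character_,
                    eligible = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    tb <- tables[[i]]
    out$subject_id[i] <- tb$subject_id
    res <- tryCatch({
      pg <- extract_panel(tb, score_table$panel)
      pg <- normalize_panel(pg, score_table$panel)
      sc <- score_subject(pg, score_table, missing_policy)
      list(sc = sc, cls = classify_responder(sc, score_table))
    }, error = function(e) e)
    if (inherits(res, "error")) next
    out$fat_points[i] <- res$sc$fat_points
    out$carb_points[i] <- res$sc$carb_points
    out$n_missing[i] <- res$sc$n_missing
    out$class[i] <- res$cls
    out$eligible[i] <- res$cls %in% eligible_classes()
  }
  scored <- !is.na(out$class)
  counts <- table(factor(out$class[scored],
                         levels = c("fat_responder", "carb_responder",
                                    "both", "neither")))
  attr(out, "summary") <- data.frame(
    class = names(counts),
    n = as.integer(counts),
    fraction = if (sum(scored)) as.numeric(counts) / sum(scored) else NA_real_,
    stringsAsFactors = FALSE)
  attr(out, "n_unscorable") <- sum(!scored)
  out
}

#' Exact responder-class probabilities under Hardy-Weinberg genotypes
#'
#' Computes the joint population distribution of the (fat, carb) score pair
#' by convolving the per-SNP point contributions under Hardy-Weinberg
#' genotype probabilities at the given effect-allele frequencies (panel
#' SNPs treated as independent), then applies the table's thresholds. Used
#' to calibrate generator allele frequencies against an observed screening
#' split, and as the analytic reference for the sampled class fractions.
#'
#' @param table A [score_table].
#' @param allele_freqs Named numeric vector of effect-allele frequencies,
#'   one per panel rsid, each in (0, 1).
#' @return Named numeric vector of probabilities for \code{fat_responder},
#'   \code{carb_responder}, \code{both}, \code{neither}.
#' @export
responder_class_probabilities <- function(table, allele_freqs) {
  stopifnot(inherits(table, "score_table"))
  rsids <- table$panel$rsid
  if (!all(rsids %in% names(allele_freqs))) {
    stop("allele_freqs must cover every panel rsid", call. = FALSE)
  }
  f <- allele_freqs[rsids]
  if (any(f <= 0 | f >= 1)) stop("allele frequencies must lie in (0,1)", call. = FALSE)

  # support of each axis: enumerate reachable scores by discrete convolution
  dist <- list(list(fat = 0, carb = 0, p = 1))
  for (rs in rsids) {
    pts <- table$points[[rs]]
    fq <- f[[rs]]
    gp <- c((1 - fq)^2, 2 * fq * (1 - fq), fq^2)
    nxt <- list()
    acc <- new.env(parent = emptyenv())
    for (cell in dist) {
      for (k in 0:2) {
        key <- paste(cell$fat + pts$fat[k + 1L],
                     cell$carb + pts$carb[k + 1L], sep = "|")
        acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) +
          cell$p * gp[k + 1L]
      }
    }
    dist <- lapply(ls(acc), function(key) {
      xy <- as.numeric(strsplit(key, "|", fixed = TRUE)[[1L]])
      list(fat = xy[1L], carb = xy[2L], p = acc[[key]])
    })
  }
  probs <- c(fat_responder = 0, carb_responder = 0, both = 0, neither = 0)
  for (cell in dist) {
    cls <- classify_responder(list(fat_points = cell$fat,
                                   carb_points = cell$carb), table)
    probs[[cls]] <- probs[[cls]] + cell$p
  }
  probs
}

#' Calibrate allele frequencies toward a target class split
#'
#' Shifts the supplied effect-allele frequencies on the log-odds scale --
#' one common shift for the SNPs feeding the fat axis and one for those
#' feeding the carbohydrate axis -- so the exact class probabilities from
#' [responder_class_probabilities()] approach the target fractions of
#' fat-responders and carbohydrate-responders.
#'
#' @param table A [score_table].
#' @param allele_freqs Starting frequencies (named, one per panel rsid).
#' @param target Numeric vector \code{c(fat, carb)} of target fractions.
#' @return Named numeric vector of calibrated frequencies.
#' @export
calibrate_allele_freqs <- function(table, allele_freqs,
                                   target = c(fat = 0.41, carb = 0.20)) {
  rsids <- table$panel$rsid
  fat_side <- vapply(rsids, function(rs) any(table$points[[rs]]$fat != 0), logical(1))
  carb_side <- vapply(rsids, function(rs) any(table$points[[rs]]$carb != 0), logical(1))
  f0 <- allele_freqs[rsids]
  obj <- function(par) {
    lo <- stats::qlogis(f0)
    lo[fat_side] <- lo[fat_side] + par[1L]
    lo[carb_side & !fat_side] <- lo[carb_side & !fat_side] + par[2L]
    p <- responder_class_probabilities(table, stats::setNames(stats::plogis(lo), rsids))
    sum((p[c("fat_responder", "carb_responder")] - target)^2)
  }
  opt <- stats::optim(c(0, 0), obj, method = "Nelder-Mead")
  lo <- stats::qlogis(f0)
  lo[fat_side] <- lo[fat_side] + opt$par[1L]
  lo[carb_side & !fat_side] <- lo[carb_side & !fat_side] + opt$par[2L]
  stats::setNames(stats::plogis(lo), rsids)
}
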