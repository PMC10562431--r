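# Fixtures built in code: toy score tables and hand-written export lines.

toy_score_table <- function() {
  load_score_table(system.file("extdata", "score_table_toy3.yaml",
                               package = "genodiet"))
}

full_score_table <- function() {
  load_score_table(default_score_config())
}

# a score_table carrying only thresholds, for classification tests
thresholds_only <- function(fat, carb) {
  structure(list(fat_threshold = fat, carb_threshold = carb),
            class = "score_table")
}

# build a score-table config list for an arbitrary small panel:
# points[[rsid]] = list(fat = c(k0,k1,k2), carb = c(k0,k1,k2))
make_config <- function(alleles, points, fat_thr = 1, carb_thr = 1) {
  panel <- lapply(names(alleles), function(rs) {
    eff <- alleles[[rs]][1L]; oth <- alleles[[rs]][2L]
    keys <- c(paste0(oth, oth), paste0(eff, oth), paste0(eff, eff))
    pts <- stats::setNames(lapply(1:3, function(k) {
      list(fat = points[[rs]]$fat[k], carb = points[[rs]]$carb[k])
    }), keys)
    list(rsid = rs, chromosome = "1", alleles = as.list(alleles[[rs]]),
         points = pts)
  })
  list(version_tag = "TOY", fat_threshold = fat_thr, carb_threshold = carb_thr,
       panel = panel)
}

# genotype_table from rsid -> c(a1, a2) (NA pair = missing call)
make_genotype_table <- function(genos, subject_id = "T1",
                                dialect = "23andme") {
  calls <- data.frame(
    rsid = names(genos), chromosome = "1",
    position = as.character(seq_along(genos)),
    allele1 = vapply(genos, function(g) as.character(g[1L]), character(1)),
    allele2 = vapply(genos, function(g) as.character(g[2L]), character(1)),
    stringsAsFactors = FALSE)
  structure(list(subject_id = subject_id, dialect = dialect, calls = calls),
            class = "genotype_table")
}

# small eligible cohort for randomization tests
make_cohort <- function(n, seed, classes = c("fat_responder", "carb_responder"),
                        class_probs = c(0.67, 0.33)) {
  cfg <- simulation_config()
  co <- generate_cohort(n, cfg, seed = seed)
  set.seed(seed + 1L)
  co$responder_class <- sample(classes, n, TRUE, class_probs)
  co
}
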