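test_that("shared-strain fraction multipliers display truncated", {
  # adult panel of 250 strains -> 0.004; pooled panel of 845 -> 0.0011
  expect_equal(related_fraction(1L, 250L)$multiplier_display, 0.004)
  expect_equal(related_fraction(1L, 845L)$multiplier_display, 0.0011)
  expect_equal(related_fraction(0L, 845L)$fraction, 0)
  expect_equal(related_fraction(3L, 250L)$fraction, 3 / 250)
  expect_error(related_fraction(5L, 4L), "n_related")
  expect_error(related_fraction(1L, 0L), "n_total")
})

test_that("separation years bin into the cohort's interval groups", {
  expect_equal(as.character(assign_separation_group(0L)), "no separation")
  expect_equal(as.character(assign_separation_group(1L)), "1-9")
  expect_equal(as.character(assign_separation_group(9L)), "1-9")
  expect_equal(as.character(assign_separation_group(10L)), "10-19")
  # a pair 19 years apart belongs to the 10-19 analyses
  expect_equal(as.character(assign_separation_group(19L)), "10-19")
  expect_equal(as.character(assign_separation_group(59L)), "50-59")
  expect_error(assign_separation_group(-1L))
  expect_error(assign_separation_group(60L))
  # partition property: every year maps to exactly one group
  g <- assign_separation_group(0:59)
  expect_false(anyNA(g))
  expect_equal(levels(g), separation_group_levels)
})

test_that("one-way ANOVA reproduces the hand-computed fixture", {
  # groups {1,2,3} and {2,3,4}: SSB = 1.5 (df 1), SSW = 4 (df 4) -> F = 1.5
  res <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(res$F, 1.5)
  expect_equal(res$df_between, 1L)
  expect_equal(res$df_within, 4L)
  # identical groups -> no between-group variance
  expect_equal(one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))$F, 0)
  # fully constant data -> undefined statistic
  expect_true(is.na(one_way_anova(list(c(2, 2), c(2, 2)))$F))
})

test_that("ANOVA matches stats::aov and the F = t^2 identity", {
  set.seed(81)
  for (i in 1:10) {
    groups <- lapply(1:3, function(g) rnorm(sample(3:9, 1L), mean = g / 2))
    res <- one_way_anova(groups)
    df <- data.frame(y = unlist(groups),
                     g = factor(rep(seq_along(groups), lengths(groups))))
    ref <- summary(stats::aov(y ~ g, data = df))[[1L]]
    expect_equal(res$F, ref[["F value"]][1L], tolerance = 1e-10)
    expect_equal(res$p, ref[["Pr(>F)"]][1L], tolerance = 1e-10)
  }
  # k = 2: F equals the square of the pooled-variance t statistic
  for (i in 1:10) {
    a <- rnorm(sample(3:8, 1L)); b <- rnorm(sample(3:8, 1L), 0.5)
    res <- one_way_anova(list(a, b))
    tt <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("Tukey HSD matches stats::TukeyHSD and its k = 2 reduction", {
  set.seed(91)
  for (i in 1:10) {
    k <- sample(3:5, 1L)
    groups <- lapply(seq_len(k), function(g)
      rnorm(sample(3:9, 1L), mean = g / 3))
    names(groups) <- paste0("g", seq_len(k))
    res <- tukey_hsd(groups)
    df <- data.frame(y = unlist(groups),
                     g = factor(rep(names(groups), lengths(groups)),
                                levels = names(groups)))
    ref <- stats::TukeyHSD(stats::aov(y ~ g, data = df))$g
    expect_equal(res$contrast, rownames(ref))
    expect_equal(res$mean_diff, unname(ref[, "diff"]), tolerance = 1e-8)
    expect_equal(res$adjusted_p, unname(ref[, "p adj"]), tolerance = 1e-8)
    # adjusted p never below the unadjusted pairwise p for k >= 3
    aovfit <- one_way_anova(groups)
    means <- vapply(groups, mean, numeric(1L))
    n_i <- lengths(groups)
    pairs <- utils::combn(k, 2L)
    for (c_i in seq_len(ncol(pairs))) {
      i1 <- pairs[1L, c_i]; i2 <- pairs[2L, c_i]
      se_t <- sqrt(aovfit$ms_within * (1 / n_i[i1] + 1 / n_i[i2]))
      p_unadj <- 2 * stats::pt(-abs((means[i2] - means[i1]) / se_t),
                               df = aovfit$df_within)
      expect_gte(res$adjusted_p[c_i] + 1e-12, p_unadj)
    }
  }
  # two groups: the Tukey-adjusted p equals the one-way ANOVA p
  for (i in 1:10) {
    groups <- list(rnorm(5), rnorm(6, 0.8))
    expect_equal(tukey_hsd(groups)$adjusted_p, one_way_anova(groups)$p,
                 tolerance = 1e-10)
  }
  # identical groups: zero difference, adjusted p of 1
  same <- tukey_hsd(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$mean_diff, 0)
  expect_equal(same$adjusted_p, 1, tolerance = 1e-9)
})

make_cohort <- function(n, separation_years) {
  twin_cohort(data.frame(
    pair_id = sprintf("P%02d", seq_len(n)),
    sample_a = sprintf("P%02d_T1", seq_len(n)),
    sample_b = sprintf("P%02d_T2", seq_len(n)),
    family_id = sprintf("F%02d", seq_len(n)),
    age_years = 40L, separation_years = separation_years,
    stringsAsFactors = FALSE))
}

test_that("summary matrix collects calls, scores and fractions", {
  cohort <- make_cohort(2L, c(0L, 25L))
  cls <- data.frame(
    species_id = c("sp1", "sp1", "sp2", "sp2"),
    pair_id = c("P01", "P02", "P01", "P02"),
    wss_score = c(99, 45, NA, 88),
    call = factor(c("related", "unrelated", "indeterminate",
                    "indeterminate"),
                  levels = c("related", "unrelated", "indeterminate")),
    stringsAsFactors = FALSE)
  s <- build_summary_matrix(cls, cohort, n_total_strains = 10L)
  expect_equal(s$matrix["sp1", "P01"], "related")
  expect_equal(s$display["sp1", "P01"], "R")
  # undefined score: indeterminate with no number shown
  expect_equal(s$display["sp2", "P01"], "I")
  # score computed but filters failed: indeterminate with the score shown
  expect_equal(s$display["sp2", "P02"], "I:88.0")
  expect_equal(s$fractions$n_related, c(1L, 0L))
  expect_equal(s$fractions$fraction, c(0.1, 0))
  # conservation: related cells in the matrix equal summed per-pair counts
  expect_equal(sum(s$matrix == "related"), sum(s$fractions$n_related))
  expect_error(build_summary_matrix(rbind(cls, cls[1L, ]), cohort, 10L),
               "duplicate")
})

test_that("per-pair fractions stay in [0,1] and groups partition pairs", {
  set.seed(111)
  n <- 12L
  cohort <- make_cohort(n, sample(0:59, n, replace = TRUE))
  species <- paste0("sp", 1:6)
  cls <- expand.grid(species_id = species, pair_id = cohort$pair_id,
                     stringsAsFactors = FALSE)
  cls$wss_score <- runif(nrow(cls), 0, 100)
  cls$call <- factor(sample(c("related", "unrelated", "indeterminate"),
                            nrow(cls), replace = TRUE),
                     levels = c("related", "unrelated", "indeterminate"))
  s <- build_summary_matrix(cls, cohort, n_total_strains = 6L)
  expect_true(all(s$fractions$fraction >= 0 & s$fractions$fraction <= 1))
  expect_equal(sum(s$matrix == "related"), sum(s$fractions$n_related))
  expect_false(anyNA(s$fractions$group))
  expect_equal(nrow(s$fractions), n)
})

test_that("simulated related counts match truth when drift is negligible", {
  params <- simulation_params(n_species = 3L, reference_length = 4e3,
                              population_size = 24L,
                              population_divergence = 2e-3,
                              drift_rate = 0, replacement_prob_per_year = 0.1,
                              n_pairs = 5L,
                              separation_years = c(0L, 3L, 10L, 25L, 40L),
                              depth_mean = 15, dropout_prob = 0.02,
                              seed = 77L)
  sim <- simulate_twin_cohort(params)
  res <- run_twin_pipeline(sim, window_length = 200L)
  s <- build_summary_matrix(res$within, sim$cohort, n_total_strains = 3L)
  truth_counts <- tapply(sim$truth$truth_label == "shared-lineage",
                         sim$truth$pair_id, sum)
  expect_equal(unname(s$fractions$n_related),
               as.integer(truth_counts[s$fractions$pair_id]))
})

test_that("concordance tallies agreement between two call sets", {
  calls <- data.frame(
    species_id = rep(c("sp1", "sp2"), each = 3L),
    pair_id = rep(c("P1", "P2", "P3"), 2L),
    call = c("related", "unrelated", "related",
             "unrelated", "unrelated", "indeterminate"),
    stringsAsFactors = FALSE)
  same <- concordance(calls, calls)
  expect_equal(same$disagree, 0L)
  expect_equal(same$agree_related, 2L)
  expect_equal(same$agree_unrelated, 3L)
  flipped <- calls
  flipped$call[1L] <- "unrelated"
  one <- concordance(calls, flipped)
  expect_equal(one$disagree, 1L)
  expect_equal(one$disagreements$species_id, "sp1")
  expect_equal(one$disagreements$pair_id, "P1")
  expect_warning(
    empty <- concordance(calls,
                         transform(calls, pair_id = paste0("X", pair_id))),
    "no overlapping")
  expect_equal(empty$disagree, 0L)
  # random fixtures against a brute-force tally
  set.seed(121)
  for (i in 1:20) {
    n <- sample(4:30, 1L)
    base <- data.frame(species_id = sample(paste0("s", 1:3), n, TRUE),
                       pair_id = sample(paste0("P", 1:8), n, TRUE),
                       stringsAsFactors = FALSE)
    base <- base[!duplicated(base), ]
    a <- base; a$call <- sample(c("related", "unrelated"), nrow(a), TRUE)
    b <- base; b$call <- sample(c("related", "unrelated"), nrow(b), TRUE)
    tab <- concordance(a, b)
    n_dis <- 0L
    for (r in seq_len(nrow(base))) if (a$call[r] != b$call[r])
      n_dis <- n_dis + 1L
    expect_equal(tab$disagree, n_dis)
    expect_equal(tab$agree_related + tab$agree_unrelated +
                   tab$agree_indeterminate + tab$disagree, nrow(base))
  }
})
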