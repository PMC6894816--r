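# symmetric difference between two pool strains (positions with different
# alleles), counted directly from their sparse SNV profiles
strain_divergence <- function(s1, s2) {
  only_1 <- setdiff(s1$pos, s2$pos)
  only_2 <- setdiff(s2$pos, s1$pos)
  shared <- intersect(s1$pos, s2$pos)
  diff_shared <- sum(s1$alt[match(shared, s1$pos)] !=
                       s2$alt[match(shared, s2$pos)])
  length(only_1) + length(only_2) + diff_shared
}

test_that("parameter validation catches degenerate settings", {
  expect_error(simulation_params(population_size = 1L), "population_size")
  expect_error(simulation_params(population_divergence = 1.5), "\\[0, 1\\]")
  expect_error(simulation_params(n_pairs = 3L, separation_years = c(1L, 2L)))
  expect_warning(simulation_params(drift_rate = 1e-3,
                                   population_divergence = 1e-3),
                 "identifiable")
})

test_that("strain pools are reproducible and divergence-calibrated", {
  params <- simulation_params(n_species = 1L, reference_length = 1e5,
                              population_size = 2L,
                              population_divergence = 1e-3, seed = 5L)
  # determinism: same params (incl. seed) give identical pools
  expect_identical(simulate_strain_pool(params), simulate_strain_pool(params))
  # zero divergence collapses the pool to identical strains
  p0 <- simulate_strain_pool(
    simulation_params(n_species = 1L, reference_length = 1e4,
                      population_divergence = 0, drift_rate = 0, seed = 5L))
  expect_true(all(vapply(p0[[1L]]$strains,
                         function(s) length(s$pos), integer(1L)) == 0L))
  # expected pairwise differing positions ~ divergence x length (= 100)
  divs <- vapply(1:30, function(s) {
    pool <- simulate_strain_pool(
      simulation_params(n_species = 1L, reference_length = 1e5,
                        population_size = 2L,
                        population_divergence = 1e-3, seed = s))
    strain_divergence(pool[[1L]]$strains[[1L]], pool[[1L]]$strains[[2L]])
  }, numeric(1L))
  # binomial sampling error over 30 seeds: SE ~ sqrt(100)/sqrt(30) ~ 1.8
  expect_lt(abs(mean(divs) - 100), 6)
})

test_that("simulated cohorts are deterministic down to the emitted bytes", {
  params <- simulation_params(n_species = 1L, reference_length = 800L,
                              population_size = 12L, n_pairs = 3L,
                              separation_years = c(0L, 5L, 30L), seed = 9L)
  d1 <- tempfile("sim1"); d2 <- tempfile("sim2")
  sim1 <- simulate_twin_cohort(params, dir = d1)
  sim2 <- simulate_twin_cohort(params, dir = d2)
  expect_identical(sim1$truth, sim2$truth)
  expect_identical(sim1$profiles, sim2$profiles)
  expect_identical(readLines(file.path(d1, "species_01.vcf")),
                   readLines(file.path(d2, "species_01.vcf")))
})

test_that("null drift with no replacement gives identical twins, WSS 100", {
  params <- simulation_params(n_species = 2L, reference_length = 2e3,
                              population_size = 8L,
                              drift_rate = 0, replacement_prob_per_year = 0,
                              n_pairs = 3L,
                              separation_years = c(0L, 10L, 50L),
                              depth_mean = 15, dropout_prob = 0.02,
                              seed = 31L)
  sim <- simulate_twin_cohort(params)
  expect_true(all(sim$truth$truth_label == "shared-lineage"))
  expect_true(all(sim$truth$n_divergent_positions == 0L))
  res <- run_twin_pipeline(sim, window_length = 100L)
  defined <- !is.na(res$within$wss_score)
  expect_true(any(defined))
  expect_true(all(res$within$wss_score[defined] == 100))
})

test_that("certain replacement marks every separated pair replaced", {
  params <- simulation_params(n_species = 1L, reference_length = 1e3,
                              population_size = 20L,
                              replacement_prob_per_year = 1,
                              n_pairs = 4L,
                              separation_years = c(1L, 2L, 10L, 40L),
                              seed = 13L)
  sim <- simulate_twin_cohort(params)
  expect_true(all(sim$truth$truth_label == "replaced"))
})

test_that("within-pair drift follows its Poisson expectation", {
  # drift 1e-6 /base/yr over 1e5 bases and 10 years: Poisson mean 1 per
  # twin, so ~2 new substitutions between twins per pair
  divs <- unlist(lapply(1:4, function(s) {
    params <- simulation_params(
      n_species = 1L, reference_length = 1e5, population_size = 32L,
      drift_rate = 1e-6, replacement_prob_per_year = 0,
      n_pairs = 25L, separation_years = rep(10L, 25L),
      depth_mean = 2, dropout_prob = 0, seed = 400L + s)
    simulate_twin_cohort(params)$truth$n_divergent_positions
  }))
  expect_length(divs, 100L)
  # mean of 100 Poisson(2) draws: SE ~ 0.14, allow 4 SE
  expect_lt(abs(mean(divs) - 2), 0.6)
})

test_that("twin discordance grows linearly with separation time", {
  seps <- c(5L, 10L, 20L, 40L)
  drift <- 1e-5
  L <- 5e4L
  means <- vapply(seps, function(sy) {
    divs <- vapply(1:15, function(s) {
      params <- suppressWarnings(simulation_params(
        n_species = 1L, reference_length = L, population_size = 8L,
        drift_rate = drift, replacement_prob_per_year = 0,
        n_pairs = 3L, separation_years = rep(sy, 3L),
        depth_mean = 2, dropout_prob = 0, seed = 900L + 17L * s + sy))
      mean(simulate_twin_cohort(params)$truth$n_divergent_positions)
    }, numeric(1L))
    mean(divs)
  }, numeric(1L))
  fit <- stats::lm(means ~ seps)
  slope <- unname(coef(fit)["seps"])
  # expected slope: 2 x drift x L = 1 divergent position per year
  expect_lt(abs(slope - 2 * drift * L) / (2 * drift * L), 0.3)
  expect_true(all(diff(means) > 0))
})

test_that("confusion against truth handles perfect and inverted callers", {
  truth <- data.frame(
    pair_id = rep(c("P1", "P2", "P3", "P4"), each = 1L),
    species_id = "sp",
    truth_label = c("shared-lineage", "shared-lineage", "replaced",
                    "replaced"),
    n_divergent_positions = c(0L, 1L, 40L, 60L),
    stringsAsFactors = FALSE)
  perfect <- data.frame(
    species_id = "sp", pair_id = c("P1", "P2", "P3", "P4"),
    call = c("related", "related", "unrelated", "unrelated"),
    stringsAsFactors = FALSE)
  cf <- truth_confusion(perfect, truth)
  expect_equal(cf$sensitivity, 1)
  expect_equal(cf$specificity, 1)
  inverted <- transform(perfect,
                        call = ifelse(call == "related", "unrelated",
                                      "related"))
  cf2 <- truth_confusion(inverted, truth)
  expect_equal(cf2$sensitivity, 0)
  expect_equal(cf2$specificity, 0)
  # indeterminate units are excluded but counted
  mixed <- perfect; mixed$call[2L] <- "indeterminate"
  cf3 <- truth_confusion(mixed, truth)
  expect_equal(cf3$n_indeterminate, 1L)
  expect_equal(cf3$n_shared, 1L)
  expect_error(truth_confusion(transform(perfect, pair_id = "none"), truth),
               "no overlap")
  # brute-force tally on random fixtures
  set.seed(141)
  for (i in 1:20) {
    n <- sample(4:40, 1L)
    tr <- data.frame(pair_id = paste0("P", seq_len(n)), species_id = "sp",
                     truth_label = sample(c("shared-lineage", "replaced"),
                                          n, TRUE),
                     n_divergent_positions = 0L, stringsAsFactors = FALSE)
    cl <- data.frame(species_id = "sp", pair_id = tr$pair_id,
                     call = sample(c("related", "unrelated",
                                     "indeterminate"), n, TRUE),
                     stringsAsFactors = FALSE)
    if (all(cl$call == "indeterminate")) next
    cf <- truth_confusion(cl, tr)
    tp <- fn <- tn <- fp <- 0L
    for (r in seq_len(n)) {
      if (cl$call[r] == "indeterminate") next
      if (tr$truth_label[r] == "shared-lineage") {
        if (cl$call[r] == "related") tp <- tp + 1L else fn <- fn + 1L
      } else {
        if (cl$call[r] == "unrelated") tn <- tn + 1L else fp <- fp + 1L
      }
    }
    if (tp + fn > 0L) expect_equal(cf$sensitivity, tp / (tp + fn))
    if (tn + fp > 0L) expect_equal(cf$specificity, tn / (tn + fp))
  }
})
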