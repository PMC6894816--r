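#' Run the full strain-tracking pipeline on a simulated (or loaded) cohort
#'
#' For every species: computes all-vs-all WSS comparisons, estimates the
#' per-species cut-off from the truth-unrelated comparisons (samples from
#' *different* twin pairs), classifies the within-pair comparisons against
#' the cut-offs, and assesses the misclassification rate of the unrelated
#' pairs. Cut-offs may instead be supplied externally.
#'
#' @param sim a [simulate_twin_cohort()] result, or a list with elements
#'   `profiles` (per species, named list of [sample_profile()]), `cohort`
#'   (a [twin_cohort()]) and optionally `truth`.
#' @param window_length window size in bases (default 1000).
#' @param cutoffs optional external [cutoff_table()]; when `NULL` cut-offs
#'   are estimated from the unrelated comparisons with `cutoff_rule`.
#' @param cutoff_rule rule passed to [estimate_cutoffs()] (default `"max"`).
#' @param min_breadth,min_depth sample-filter thresholds.
#' @param depth_floor,max_low_fraction window-usability parameters.
#' @return list of class `wss_pipeline`: `comparisons` (all pairs, all
#'   species), `within` (classified within-pair table with `pair_id`),
#'   `unrelated_scores` (per species), `cutoffs`, `metrics` (per-sample QC),
#'   `misclassification` (per species), and `confusion` when truth was
#'   available.
#' @export
run_twin_pipeline <- function(sim, window_length = 1000L, cutoffs = NULL,
                              cutoff_rule = "max",
                              min_breadth = 0.30, min_depth = 3.5,
                              depth_floor = 5L, max_low_fraction = 0.5) {
  cohort <- sim$cohort
  pair_of <- stats::setNames(
    rep(cohort$pair_id, 2L), c(cohort$sample_a, cohort$sample_b))

  all_cmp <- list()
  metrics <- list()
  for (species_id in names(sim$profiles)) {
    profiles <- sim$profiles[[species_id]]
    L <- profiles[[1L]]$reference_length
    spec <- partition_windows(L, window_length, species_id)
    cmp <- wss_pair_table(profiles, spec,
                          min_breadth = min_breadth, min_depth = min_depth,
                          depth_floor = depth_floor,
                          max_low_fraction = max_low_fraction)
    cmp$pair_a <- unname(pair_of[cmp$sample_a])
    cmp$pair_b <- unname(pair_of[cmp$sample_b])
    cmp$within_pair <- !is.na(cmp$pair_a) & !is.na(cmp$pair_b) &
      cmp$pair_a == cmp$pair_b
    all_cmp[[species_id]] <- cmp
    metrics[[species_id]] <- sample_metrics_table(profiles, min_breadth,
                                                  min_depth)
  }
  comparisons <- do.call(rbind, c(all_cmp, list(make.row.names = FALSE)))

  unrel <- comparisons[!comparisons$within_pair & comparisons$pass_filter, ]
  unrelated_scores <- split(unrel$wss_score, unrel$species_id)
  if (is.null(cutoffs)) {
    cutoffs <- estimate_cutoffs(unrelated_scores, rule = cutoff_rule)
  }

  within <- comparisons[comparisons$within_pair, , drop = FALSE]
  within$pair_id <- within$pair_a
  within <- classify_pairs(within, cutoffs)

  misclass <- lapply(names(unrelated_scores), function(sp) {
    s <- unrelated_scores[[sp]]
    if (all(is.na(s))) return(NULL)
    r <- misclassification_rate(s, cutoffs$cutoffs[[sp]])
    data.frame(species_id = sp, n_exceed = r$n_exceed, n_total = r$n_total,
               rate_percent = r$rate_percent, stringsAsFactors = FALSE)
  })
  misclass <- do.call(rbind, misclass)

  out <- list(comparisons = comparisons, within = within,
              unrelated_scores = unrelated_scores, cutoffs = cutoffs,
              metrics = do.call(rbind, c(metrics,
                                         list(make.row.names = FALSE))),
              misclassification = misclass)
  if (!is.null(sim$truth)) {
    out$confusion <- truth_confusion(within, sim$truth)
  }
  class(out) <- "wss_pipeline"
  out
}

#' Parameters of the end-to-end recovery scenario
#'
#' The calibration scenario used throughout the package's validation: a
#' 100 kb genome tiled into 100 windows of 1 kb, per-base depth mean 20,
#' within-lineage drift of 1e-6 substitutions/base/year over at most 10
#' years of separation, unrelated-strain divergence of 1e-3
#' substitutions/base, and enough strain replacement (8%/year) that both
#' truth classes occur.
#'
#' @param seed RNG seed for the replicate.
#' @return a [simulation_params()] object.
#' @export
recovery_scenario_params <- function(seed = 1L) {
  simulation_params(
    n_species = 2L, reference_length = 1e5, population_size = 20L,
    population_divergence = 1e-3, drift_rate = 1e-6,
    replacement_prob_per_year = 0.08,
    n_pairs = 6L, separation_years = c(1L, 3L, 5L, 7L, 9L, 10L),
    depth_mean = 20, dropout_prob = 0.02, seed = seed)
}

#' End-to-end classification recovery over seeded replicates
#'
#' Simulates `n_replicates` cohorts under the recovery scenario (or a
#' supplied parameter template), runs the full pipeline with empirically
#' estimated cut-offs on each, and pools the confusion counts over
#' replicates.
#'
#' @param n_replicates number of simulated cohorts.
#' @param base_seed base RNG seed; replicate `i` uses
#'   `base_seed + 7919 * i`.
#' @param params_fn function(seed) returning [simulation_params()];
#'   defaults to [recovery_scenario_params()].
#' @param window_length window size passed to the pipeline.
#' @return list: pooled `sensitivity`, `specificity`, unit counts
#'   `n_shared`, `n_replaced`, `n_indeterminate`, and the per-replicate
#'   results in `replicates`.
#' @export
evaluate_recovery <- function(n_replicates = 50L, base_seed = 1L,
                              params_fn = recovery_scenario_params,
                              window_length = 1000L) {
  tp <- fn <- tn <- fp <- ind <- 0L
  reps <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    sim <- simulate_twin_cohort(params_fn(base_seed + 7919L * i))
    res <- run_twin_pipeline(sim, window_length = window_length)
    merged <- merge(res$within[, c("species_id", "pair_id", "call")],
                    sim$truth, by = c("species_id", "pair_id"))
    det <- merged$call != "indeterminate"
    shared <- merged$truth_label == "shared-lineage"
    tp <- tp + sum(det & shared & merged$call == "related")
    fn <- fn + sum(det & shared & merged$call != "related")
    tn <- tn + sum(det & !shared & merged$call == "unrelated")
    fp <- fp + sum(det & !shared & merged$call != "unrelated")
    ind <- ind + sum(!det)
    reps[[i]] <- res$confusion
  }
  list(sensitivity = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0L) tn / (tn + fp) else NA_real_,
       n_shared = tp + fn, n_replaced = tn + fp, n_indeterminate = ind,
       replicates = reps)
}

#' Shared-strain fraction decay across separation intervals
#'
#' Simulates cohorts whose pairs span the separation bins with a drift rate
#' high enough that relatedness decays with time apart, runs the pipeline,
#' and regresses each pair's shared-strain fraction on its ordered bin
#' index. Under strain drift plus replacement the expected fraction is
#' non-increasing with separation, so the fitted slope should be negative.
#'
#' @param n_replicates number of simulated cohorts.
#' @param base_seed base RNG seed.
#' @return list: `slope`, `p_value` (one-sided, slope < 0), `group_means`
#'   (mean fraction per occupied bin, in bin order), `data` (per pair and
#'   replicate).
#' @export
evaluate_separation_trend <- function(n_replicates = 50L, base_seed = 1L) {
  rows <- list()
  for (i in seq_len(n_replicates)) {
    # drift deliberately fast relative to the pool divergence, so the
    # identifiability guard in simulation_params() is expected to fire
    params <- suppressWarnings(simulation_params(
      n_species = 3L, reference_length = 5e4, population_size = 24L,
      population_divergence = 1e-3, drift_rate = 2e-5,
      replacement_prob_per_year = 0.02,
      n_pairs = 7L,
      separation_years = c(0L, 5L, 15L, 25L, 35L, 45L, 55L),
      depth_mean = 20, dropout_prob = 0.02,
      seed = base_seed + 104729L + 7919L * i))
    sim <- simulate_twin_cohort(params)
    res <- run_twin_pipeline(sim)
    summ <- build_summary_matrix(res$within, sim$cohort,
                                 n_total_strains = params$n_species)
    fr <- summ$fractions
    fr$bin_index <- as.integer(fr$group)
    fr$replicate <- i
    rows[[i]] <- fr
  }
  dat <- do.call(rbind, rows)
  fit <- stats::lm(fraction ~ bin_index, data = dat)
  est <- summary(fit)$coefficients["bin_index", ]
  group_means <- tapply(dat$fraction, dat$group, mean)
  group_means <- group_means[!is.na(group_means)]
  list(slope = unname(est["Estimate"]),
       p_value = stats::pt(unname(est["t value"]), df = fit$df.residual),
       group_means = group_means,
       data = dat)
}
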