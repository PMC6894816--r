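#' Parameters for the synthetic twin-cohort simulator
#'
#' The simulator emulates the data a strain-tracking study consumes: for
#' each species, a population pool of strain SNV profiles relative to a
#' random reference; each twin pair is seeded with one shared pool strain
#' which drifts independently in the two twins at a per-base per-year
#' substitution rate and, with a per-year probability, is replaced outright
#' by an independent pool strain; and a per-base read-depth observation
#' layer (Poisson depth with dropout) so breadth, mean-depth and window
#' usability filters are all exercised.
#'
#' @param n_species number of reference species simulated.
#' @param reference_length reference length per species, bases.
#' @param population_size strains in the population pool per species (>= 2).
#' @param population_divergence expected pairwise divergence between
#'   unrelated pool strains, substitutions per base.
#' @param drift_rate within-lineage substitution rate, per base per year.
#' @param replacement_prob_per_year probability per year that a twin's
#'   strain is replaced from the pool.
#' @param n_pairs number of twin pairs.
#' @param separation_years integer vector of length `n_pairs`: years each
#'   pair has lived apart.
#' @param depth_mean mean of the per-base Poisson read-depth model.
#' @param dropout_prob probability a position is unobserved (depth set to 0).
#' @param seed RNG seed; identical parameter sets (including the seed)
#'   reproduce byte-identical output.
#' @return validated list of class `simulation_params`.
#' @export
simulation_params <- function(n_species = 3L,
                              reference_length = 1e5,
                              population_size = 32L,
                              population_divergence = 1e-3,
                              drift_rate = 1e-6,
                              replacement_prob_per_year = 0.05,
                              n_pairs = 10L,
                              separation_years = c(0L, 0L, 1L, 5L, 7L, 19L,
                                                   25L, 34L, 47L, 55L),
                              depth_mean = 20,
                              dropout_prob = 0.02,
                              seed = 1L) {
  p <- list(n_species = as.integer(n_species),
            reference_length = as.integer(reference_length),
            population_size = as.integer(population_size),
            population_divergence = population_divergence,
            drift_rate = drift_rate,
            replacement_prob_per_year = replacement_prob_per_year,
            n_pairs = as.integer(n_pairs),
            separation_years = as.integer(separation_years),
            depth_mean = depth_mean,
            dropout_prob = dropout_prob,
            seed = as.integer(seed))
  stopifnot(p$n_species >= 1L, p$reference_length >= 1L,
            p$n_pairs >= 1L, p$depth_mean >= 0,
            length(p$separation_years) == p$n_pairs,
            all(p$separation_years >= 0L))
  if (p$population_size < 2L) abort("population_size must be >= 2")
  probs <- c(p$population_divergence, p$replacement_prob_per_year,
             p$dropout_prob)
  if (any(probs < 0 | probs > 1)) {
    abort("divergence and probabilities must lie in [0, 1]")
  }
  max_drift <- p$drift_rate * max(c(p$separation_years, 0L))
  if (max_drift * 10 > p$population_divergence) {
    warning("drift_rate x separation is not small relative to ",
            "population_divergence; related and unrelated pairs may not ",
            "be identifiable")
  }
  structure(p, class = "simulation_params")
}

.bases <- c("A", "C", "G", "T")

# substitute each base by one of the three others, uniformly
mutate_base <- function(b) {
  idx <- match(b, .bases)
  shift <- sample.int(3L, length(b), replace = TRUE)
  .bases[(idx - 1L + shift) %% 4L + 1L]
}

# run code under a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# pool simulation without touching the seed (internal)
simulate_pool_impl <- function(params) {
  L <- params$reference_length
  per_strain_rate <- params$population_divergence / 2
  lapply(seq_len(params$n_species), function(sp) {
    reference <- sample(.bases, L, replace = TRUE)
    strains <- lapply(seq_len(params$population_size), function(s) {
      n_mut <- stats::rbinom(1L, L, per_strain_rate)
      pos <- sort(sample.int(L, n_mut))
      list(pos = pos, alt = mutate_base(reference[pos]))
    })
    list(species_id = sprintf("species_%02d", sp),
         reference = reference, strains = strains)
  })
}

#' Simulate the per-species population strain pool
#'
#' Each strain is an SNV profile relative to a random reference: mutated
#' positions are placed uniformly at random at a per-strain rate of half the
#' target pairwise divergence (two independent strains then differ at
#' approximately `population_divergence * reference_length` positions), with
#' alternate alleles drawn uniformly from the three non-reference bases.
#'
#' @param params a [simulation_params()] object.
#' @return list with one element per species: `species_id`, `reference`
#'   (character vector of bases), `strains` (list of `pos`/`alt` pairs).
#' @export
simulate_strain_pool <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  with_seed(params$seed, simulate_pool_impl(params))
}

# full (noise-free) allele vector of a strain
strain_alleles <- function(reference, strain) {
  a <- reference
  a[strain$pos] <- strain$alt
  a
}

#' Simulate a twin cohort with known strain-sharing truth
#'
#' For every pair and species, both twins start from one shared pool strain.
#' Each twin independently accumulates `Poisson(drift_rate * length *
#' separation_years)` substitutions and, with probability
#' `1 - (1 - replacement_prob_per_year)^separation_years`, has its strain
#' replaced by an independent pool draw (truth label `replaced`; the pair is
#' `shared-lineage` only if neither twin was replaced). Observation then
#' draws per-base depths from `Poisson(depth_mean)`, zeroes a `dropout_prob`
#' fraction of positions, and masks the allele call wherever depth is 0.
#'
#' Pool draws (seed strains and replacements) take distinct strains, in a
#' random order, so no two draws coincide: human-population strain diversity
#' is effectively unbounded and unrelated individuals essentially never
#' carry the identical strain. `population_size` must therefore be at least
#' `n_pairs` plus the number of replacement events; the simulator stops with
#' an instructive error if the pool is exhausted.
#'
#' @param params a [simulation_params()] object.
#' @param dir optional directory; when given, the cohort is written out as
#'   one multi-sample VCF per species (`<species>.vcf`), `metadata.tsv`,
#'   `truth.tsv` and `params.json`.
#' @return list of class `twin_cohort_sim`: `params`, `pool`, `profiles`
#'   (per species, a named list of [sample_profile()]), `metadata`
#'   (per-sample data.frame), `cohort` (a [twin_cohort()]), `truth`
#'   (data.frame pair_id, species_id, truth_label, n_divergent_positions).
#' @export
simulate_twin_cohort <- function(params, dir = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  with_seed(params$seed, {
    pool <- simulate_pool_impl(params)
    L <- params$reference_length
    pair_ids <- sprintf("P%02d", seq_len(params$n_pairs))
    sample_ids <- as.vector(t(outer(pair_ids, c("_T1", "_T2"), paste0)))
    if (anyDuplicated(sample_ids)) abort("conflicting sample ids")

    metadata <- data.frame(
      sample_id = sample_ids,
      pair_id = rep(pair_ids, each = 2L),
      family_id = rep(sprintf("F%02d", seq_len(params$n_pairs)), each = 2L),
      separation_years = rep(params$separation_years, each = 2L),
      age_years = rep(pmin(36L + params$separation_years, 80L), each = 2L),
      stringsAsFactors = FALSE
    )

    profiles <- vector("list", params$n_species)
    names(profiles) <- vapply(pool, `[[`, character(1L), "species_id")
    truth_rows <- list()

    for (sp in seq_len(params$n_species)) {
      species_id <- pool[[sp]]$species_id
      reference <- pool[[sp]]$reference
      strains <- pool[[sp]]$strains
      sp_profiles <- vector("list", length(sample_ids))
      names(sp_profiles) <- sample_ids

      draw_order <- sample.int(params$population_size)
      n_drawn <- 0L
      draw_strain <- function() {
        n_drawn <<- n_drawn + 1L
        if (n_drawn > params$population_size) {
          abort(paste0("population pool exhausted for %s; increase ",
                       "population_size beyond %d"),
                species_id, params$population_size)
        }
        draw_order[n_drawn]
      }

      for (p in seq_len(params$n_pairs)) {
        sep <- params$separation_years[p]
        p_replace <- 1 - (1 - params$replacement_prob_per_year)^sep
        seed_strain <- draw_strain()
        twin_alleles <- vector("list", 2L)
        replaced <- logical(2L)
        for (t in 1:2) {
          replaced[t] <- stats::runif(1L) < p_replace
          strain_idx <- if (replaced[t]) draw_strain() else seed_strain
          alleles <- strain_alleles(reference, strains[[strain_idx]])
          n_drift <- stats::rpois(1L, params$drift_rate * L * sep)
          if (n_drift > 0L) {
            dpos <- sample.int(L, min(n_drift, L))
            alleles[dpos] <- mutate_base(alleles[dpos])
          }
          twin_alleles[[t]] <- alleles
        }
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          pair_id = pair_ids[p],
          species_id = species_id,
          truth_label = if (any(replaced)) "replaced" else "shared-lineage",
          n_divergent_positions =
            sum(twin_alleles[[1L]] != twin_alleles[[2L]]),
          stringsAsFactors = FALSE
        )
        for (t in 1:2) {
          depth <- stats::rpois(L, params$depth_mean)
          depth[stats::runif(L) < params$dropout_prob] <- 0L
          obs <- twin_alleles[[t]]
          obs[depth == 0L] <- NA_character_
          sid <- paste0(pair_ids[p], "_T", t)
          sp_profiles[[sid]] <- sample_profile(sid, species_id, L, obs,
                                               depth)
        }
      }
      profiles[[species_id]] <- sp_profiles
    }

    truth <- do.call(rbind, truth_rows)
    sim <- structure(
      list(params = params, pool = pool, profiles = profiles,
           metadata = metadata, cohort = pairs_from_metadata(metadata),
           truth = truth),
      class = "twin_cohort_sim")
    if (!is.null(dir)) write_cohort(sim, dir)
    sim
  })
}

#' Write a simulated cohort to disk
#'
#' Emits one base-resolution multi-sample VCF per species plus
#' `metadata.tsv`, `truth.tsv` and a `params.json` echo of the simulation
#' parameters.
#'
#' @param sim a [simulate_twin_cohort()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "twin_cohort_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in seq_along(sim$pool)) {
    species_id <- sim$pool[[sp]]$species_id
    write_multisample_vcf(sim$profiles[[species_id]],
                          sim$pool[[sp]]$reference,
                          file.path(dir, paste0(species_id, ".vcf")))
  }
  write_tsv_table(sim$metadata, file.path(dir, "metadata.tsv"))
  write_tsv_table(sim$truth, file.path(dir, "truth.tsv"))
  jsonlite::write_json(unclass(sim$params),
                       file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Sensitivity and specificity against simulator truth
#'
#' Joins relatedness calls to the simulator's truth records by
#' (species, pair). Sensitivity is the fraction of truth `shared-lineage`
#' units called related; specificity the fraction of truth `replaced` units
#' called unrelated. Indeterminate calls are excluded from both and counted
#' separately.
#'
#' @param classifications data.frame from [classify_pairs()] with a
#'   `pair_id` column.
#' @param truth truth data.frame from [simulate_twin_cohort()].
#' @return list: `sensitivity`, `specificity`, `n_shared`, `n_replaced`
#'   (determinate unit counts), `n_indeterminate`.
#' @export
truth_confusion <- function(classifications, truth) {
  merged <- merge(classifications[, c("species_id", "pair_id", "call")],
                  truth, by = c("species_id", "pair_id"))
  if (nrow(merged) == 0L) {
    abort("no overlap between classifications and truth records")
  }
  det <- merged$call != "indeterminate"
  shared <- merged$truth_label == "shared-lineage"
  n_shared <- sum(det & shared)
  n_replaced <- sum(det & !shared)
  list(
    sensitivity = if (n_shared > 0L)
      sum(det & shared & merged$call == "related") / n_shared else NA_real_,
    specificity = if (n_replaced > 0L)
      sum(det & !shared & merged$call == "unrelated") / n_replaced
      else NA_real_,
    n_shared = n_shared,
    n_replaced = n_replaced,
    n_indeterminate = sum(!det)
  )
}
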