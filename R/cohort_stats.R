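#' Separation-interval labels
#'
#' Twin pairs are binned by the years they have lived apart: pairs still
#' cohabiting fall in "no separation", all others in the decade bin
#' containing their separation time.
#'
#' @export
separation_group_levels <- c("no separation", "1-9", "10-19", "20-29",
                             "30-39", "40-49", "50-59")

#' Assign a twin pair to its separation-interval group
#'
#' @param separation_years non-negative integer years apart, at most 59.
#' @return ordered factor over [separation_group_levels]; vectorised.
#' @export
assign_separation_group <- function(separation_years) {
  y <- as.integer(separation_years)
  if (anyNA(y) || any(y < 0L) || any(y > 59L)) {
    abort("separation_years must be integers in [0, 59]")
  }
  lab <- ifelse(y == 0L, "no separation",
                sprintf("%d-%d", (y %/% 10L) * 10L + ifelse(y < 10L, 1L, 0L),
                        (y %/% 10L) * 10L + 9L))
  factor(lab, levels = separation_group_levels, ordered = TRUE)
}

#' Twin-pair cohort table
#'
#' @param pairs data.frame with columns pair_id, sample_a, sample_b,
#'   family_id, age_years, separation_years. A `group` column with the
#'   separation interval is appended.
#' @return data.frame of class `twin_cohort`.
#' @export
twin_cohort <- function(pairs) {
  need <- c("pair_id", "sample_a", "sample_b", "family_id", "age_years",
            "separation_years")
  missing_cols <- setdiff(need, names(pairs))
  if (length(missing_cols) > 0L) {
    abort("cohort table missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(pairs$pair_id)) abort("duplicated pair_id")
  pairs$group <- assign_separation_group(pairs$separation_years)
  class(pairs) <- c("twin_cohort", class(pairs))
  pairs
}

#' Build a twin-pair cohort from per-sample metadata
#'
#' @param metadata data.frame with one row per sample (columns sample_id,
#'   pair_id, family_id, separation_years, age_years); each pair_id must
#'   appear exactly twice.
#' @return [twin_cohort()] data.frame, one row per pair.
#' @export
pairs_from_metadata <- function(metadata) {
  split_md <- split(metadata, metadata$pair_id)
  rows <- lapply(split_md, function(m) {
    if (nrow(m) != 2L) {
      abort("pair '%s' has %d samples; expected 2", m$pair_id[1L], nrow(m))
    }
    data.frame(pair_id = m$pair_id[1L],
               sample_a = m$sample_id[1L], sample_b = m$sample_id[2L],
               family_id = m$family_id[1L],
               age_years = m$age_years[1L],
               separation_years = m$separation_years[1L],
               stringsAsFactors = FALSE)
  })
  twin_cohort(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Shared-strain fraction for one twin pair
#'
#' The fraction of the strain panel called related for a pair:
#' `n_related / n_total_strains`. The reciprocal `1 / n_total_strains` is the
#' per-strain multiplier reported alongside cohort tables, displayed
#' truncated to four decimal places (1/845 displays as 0.0011, 1/250 as
#' 0.004); internal arithmetic keeps full precision.
#'
#' @param n_related number of related strain calls for the pair.
#' @param n_total_strains total strains in the analysis panel (a fixed
#'   configured constant, not recomputed from detected species).
#' @return list: `fraction` (exact), `multiplier` (exact reciprocal),
#'   `multiplier_display` (truncated to 4 decimals).
#' @export
related_fraction <- function(n_related, n_total_strains) {
  if (n_total_strains < 1L) abort("n_total_strains must be >= 1")
  if (n_related < 0L || n_related > n_total_strains) {
    abort("n_related must lie in [0, n_total_strains]")
  }
  mult <- 1 / n_total_strains
  list(fraction = n_related / n_total_strains,
       multiplier = mult,
       multiplier_display = trunc_decimal(mult, 4L))
}

#' One-way analysis of variance over group fractions
#'
#' Standard between/within sums-of-squares F statistic with its upper-tail
#' p-value from the F distribution. Each twin pair contributes one
#' observation (its shared-strain fraction). When every value is identical
#' across and within groups the statistic is undefined and returned as `NA`;
#' when groups differ but within-group variance is zero the statistic is
#' infinite with p = 0.
#'
#' @param groups list of numeric vectors, one per group; at least two
#'   groups, each non-empty, and at least one group with two values.
#' @return list: `F`, `p`, `df_between`, `df_within`, plus the pooled
#'   within-group mean square `ms_within` (used by [tukey_hsd()]).
#' @export
one_way_anova <- function(groups) {
  groups <- lapply(groups, as.numeric)
  k <- length(groups)
  n_i <- lengths(groups)
  if (k < 2L || any(n_i < 1L)) {
    abort("need >= 2 groups, each with >= 1 value")
  }
  n <- sum(n_i)
  if (n - k < 1L) abort("need at least one group with >= 2 values")
  all_vals <- unlist(groups, use.names = FALSE)
  grand <- mean(all_vals)
  means <- vapply(groups, mean, numeric(1L))
  ss_between <- sum(n_i * (means - grand)^2)
  ss_within <- sum(vapply(seq_len(k),
                          function(i) sum((groups[[i]] - means[i])^2),
                          numeric(1L)))
  df_b <- k - 1L
  df_w <- n - k
  ms_b <- ss_between / df_b
  ms_w <- ss_within / df_w
  if (ms_w == 0) {
    if (ss_between == 0) {
      f <- NA_real_; p <- NA_real_
    } else {
      f <- Inf; p <- 0
    }
  } else {
    f <- ms_b / ms_w
    p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  }
  list(F = f, p = p, df_between = df_b, df_within = df_w, ms_within = ms_w)
}

#' Tukey HSD post-hoc comparisons
#'
#' All unordered group contrasts with p-values adjusted via the studentized
#' range distribution, using the Tukey–Kramer standard error so unbalanced
#' groups are handled. With two groups the adjusted p equals the one-way
#' ANOVA p.
#'
#' @param groups list of numeric vectors, one per group.
#' @param labels optional group names (default `names(groups)` or
#'   `"g1"..."gk"`).
#' @return data.frame: `contrast` (as `"B-A"`), `mean_diff` (mean B minus
#'   mean A), `adjusted_p`.
#' @export
tukey_hsd <- function(groups, labels = NULL) {
  groups <- lapply(groups, as.numeric)
  k <- length(groups)
  if (is.null(labels)) {
    labels <- if (!is.null(names(groups)) && all(nzchar(names(groups)))) {
      names(groups)
    } else {
      paste0("g", seq_len(k))
    }
  }
  aov_fit <- one_way_anova(groups)
  ms_w <- aov_fit$ms_within
  df_w <- aov_fit$df_within
  means <- vapply(groups, mean, numeric(1L))
  n_i <- lengths(groups)
  idx <- utils::combn(k, 2L)
  rows <- lapply(seq_len(ncol(idx)), function(c_i) {
    i <- idx[1L, c_i]; j <- idx[2L, c_i]
    diff <- means[j] - means[i]
    se <- sqrt(ms_w / 2 * (1 / n_i[i] + 1 / n_i[j]))
    p <- if (se == 0) {
      if (diff == 0) 1 else 0
    } else {
      stats::ptukey(abs(diff) / se, nmeans = k, df = df_w,
                    lower.tail = FALSE)
    }
    data.frame(contrast = paste(labels[j], labels[i], sep = "-"),
               mean_diff = diff, adjusted_p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Species-by-pair cohort summary
#'
#' Collects per-pair classifications into the cohort summary matrix
#' (species rows, twin-pair columns) and the per-pair shared-strain
#' fractions. Matrix cells are `"related"`, `"unrelated"` or
#' `"indeterminate"`; a display matrix renders them as `R` / `U` / `I`, with
#' an indeterminate cell that nonetheless has a computed score shown as
#' `I:<score>` (the raw WSS is displayed for pairs failing the filters).
#'
#' @param classifications data.frame from [classify_pairs()] carrying a
#'   `pair_id` column; duplicate (species, pair) entries are an error.
#' @param cohort a [twin_cohort()].
#' @param n_total_strains fixed denominator for the shared-strain fraction
#'   (e.g. the full strain panel size of the analysis).
#' @return list of class `cohort_summary`: `matrix`, `display`,
#'   `fractions` (data.frame pair_id, group, n_related, fraction),
#'   `n_total_strains`.
#' @export
build_summary_matrix <- function(classifications, cohort, n_total_strains) {
  stopifnot(is.data.frame(classifications), "pair_id" %in%
              names(classifications))
  key <- paste(classifications$species_id, classifications$pair_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- classifications[duplicated(key), , drop = FALSE][1L, ]
    abort("duplicate entry for species '%s', pair '%s'",
          dup$species_id, dup$pair_id)
  }
  species <- sort(unique(classifications$species_id))
  pair_ids <- cohort$pair_id
  m <- matrix("indeterminate", nrow = length(species),
              ncol = length(pair_ids),
              dimnames = list(species, pair_ids))
  disp <- matrix("I", nrow = length(species), ncol = length(pair_ids),
                 dimnames = list(species, pair_ids))
  for (r in seq_len(nrow(classifications))) {
    row <- classifications[r, ]
    if (!row$pair_id %in% pair_ids) next
    cl <- as.character(row$call)
    m[row$species_id, row$pair_id] <- cl
    disp[row$species_id, row$pair_id] <- switch(
      cl,
      related = "R",
      unrelated = "U",
      indeterminate = if (is.na(row$wss_score)) "I" else
        sprintf("I:%.1f", row$wss_score))
  }
  n_related <- vapply(pair_ids,
                      function(p) sum(m[, p] == "related"), integer(1L))
  fractions <- data.frame(
    pair_id = pair_ids,
    group = cohort$group,
    n_related = unname(n_related),
    fraction = vapply(unname(n_related), function(nr)
      related_fraction(nr, n_total_strains)$fraction, numeric(1L)),
    stringsAsFactors = FALSE
  )
  structure(list(matrix = m, display = disp, fractions = fractions,
                 n_total_strains = n_total_strains),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d species x %d pairs (panel of %d strains)\n",
              nrow(x$matrix), ncol(x$matrix), x$n_total_strains))
  print(x$display, quote = FALSE)
  invisible(x)
}

#' Separation-group statistics over shared-strain fractions
#'
#' Runs the one-way ANOVA and Tukey HSD over the per-pair fractions grouped
#' by separation interval (groups with no pairs are dropped).
#'
#' @param summary a [build_summary_matrix()] result.
#' @return list: `groups` (named list of fractions), `anova`, `tukey`.
#' @export
cohort_group_stats <- function(summary) {
  stopifnot(inherits(summary, "cohort_summary"))
  fr <- summary$fractions
  groups <- split(fr$fraction, fr$group, drop = TRUE)
  if (length(groups) < 2L) {
    abort("need >= 2 non-empty separation groups for group statistics")
  }
  list(groups = groups,
       anova = one_way_anova(groups),
       tukey = tukey_hsd(groups, labels = names(groups)))
}

#' Concordance between two sets of relatedness calls
#'
#' Compares calls from two methods (e.g. window-based SNV similarity vs a
#' marker-gene method) on the shared (species, pair) keys.
#'
#' @param calls_a,calls_b data.frames with columns species_id, pair_id,
#'   call.
#' @return list: counts `agree_related`, `agree_unrelated`,
#'   `agree_indeterminate`, `disagree`, and a data.frame `disagreements`
#'   listing the differing keys with both calls. Non-overlapping keys give
#'   an empty table with a warning.
#' @export
concordance <- function(calls_a, calls_b) {
  merged <- merge(calls_a[, c("species_id", "pair_id", "call")],
                  calls_b[, c("species_id", "pair_id", "call")],
                  by = c("species_id", "pair_id"),
                  suffixes = c("_a", "_b"))
  if (nrow(merged) == 0L) {
    warning("no overlapping (species, pair) keys between the two call sets")
    return(list(agree_related = 0L, agree_unrelated = 0L,
                agree_indeterminate = 0L, disagree = 0L,
                disagreements = merged))
  }
  ca <- as.character(merged$call_a)
  cb <- as.character(merged$call_b)
  agree <- ca == cb
  list(
    agree_related = sum(agree & ca == "related"),
    agree_unrelated = sum(agree & ca == "unrelated"),
    agree_indeterminate = sum(agree & ca == "indeterminate"),
    disagree = sum(!agree),
    disagreements = merged[!agree, , drop = FALSE]
  )
}
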