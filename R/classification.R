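#' Per-species WSS relatedness cut-off table
#'
#' @param cutoffs named numeric vector, species_id -> cut-off percentage in
#'   \[0, 100\].
#' @param provenance single string recording where the cut-offs came from,
#'   e.g. `"external:HMP-derived"` or `"empirical:max"`.
#' @return object of class `cutoff_table`.
#' @export
cutoff_table <- function(cutoffs, provenance = "external") {
  if (is.null(names(cutoffs)) || any(!nzchar(names(cutoffs)))) {
    abort("cutoffs must be named by species_id")
  }
  if (any(cutoffs < 0 | cutoffs > 100)) {
    abort("cut-offs must lie in [0, 100]")
  }
  structure(list(cutoffs = cutoffs, provenance = as.character(provenance)),
            class = "cutoff_table")
}

#' @export
print.cutoff_table <- function(x, ...) {
  cat(sprintf("<cutoff_table> %d species (%s)\n",
              length(x$cutoffs), x$provenance))
  invisible(x)
}

#' Read / write a cut-off table as TSV
#'
#' Columns: species_id, cutoff, provenance.
#'
#' @param path file path.
#' @rdname cutoff_table_io
#' @return [cutoff_table()] for the reader; `path` invisibly for the writer.
#' @export
read_cutoff_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  cutoff_table(stats::setNames(df$cutoff, df$species_id),
               provenance = df$provenance[1L])
}

#' @param x a [cutoff_table()].
#' @rdname cutoff_table_io
#' @export
write_cutoff_table <- function(x, path) {
  stopifnot(inherits(x, "cutoff_table"))
  write_tsv_table(
    data.frame(species_id = names(x$cutoffs), cutoff = unname(x$cutoffs),
               provenance = x$provenance, stringsAsFactors = FALSE),
    path)
}

#' Classify sample pairs as related / unrelated / indeterminate
#'
#' A pair is called *related* when its WSS score strictly exceeds the
#' species' cut-off and *unrelated* when the score is less than or equal to
#' it (a score exactly at the cut-off is unrelated: relatedness is defined
#' strictly as score > cut-off). Pairs with an undefined score (no usable
#' window) or with a sample failing the breadth/depth filter are
#' *indeterminate*.
#'
#' @param comparisons data.frame as produced by [wss_pair_table()] (columns
#'   species_id, sample_a, sample_b, wss_score, optionally `pass_filter`,
#'   optionally `pair_id`).
#' @param cutoffs a [cutoff_table()] covering every species present.
#' @return the input data.frame with columns `cutoff` and
#'   `call` (factor: related / unrelated / indeterminate) appended.
#' @export
classify_pairs <- function(comparisons, cutoffs) {
  stopifnot(inherits(cutoffs, "cutoff_table"),
            is.data.frame(comparisons))
  missing_sp <- setdiff(unique(comparisons$species_id), names(cutoffs$cutoffs))
  if (length(missing_sp) > 0L) {
    abort("no cut-off for species: %s", paste(missing_sp, collapse = ", "))
  }
  co <- unname(cutoffs$cutoffs[comparisons$species_id])
  pass <- if ("pass_filter" %in% names(comparisons)) {
    comparisons$pass_filter
  } else {
    rep(TRUE, nrow(comparisons))
  }
  call <- ifelse(is.na(comparisons$wss_score) | !pass, "indeterminate",
                 ifelse(comparisons$wss_score > co, "related", "unrelated"))
  out <- comparisons
  out$cutoff <- co
  out$call <- factor(call, levels = c("related", "unrelated",
                                      "indeterminate"))
  out
}

#' Estimate per-species cut-offs from unrelated-pair score distributions
#'
#' Given WSS scores of truth-unrelated sample pairs (different individuals),
#' places the cut-off per species by one of three rules: the maximum
#' unrelated score (default; most conservative against false relatedness),
#' an upper quantile, or mean + k standard deviations.
#'
#' @param unrelated_scores named list, species_id -> numeric vector of WSS
#'   scores from truth-unrelated pairs (NA scores are dropped); at least two
#'   scores per species.
#' @param rule one of `"max"`, `"quantile"`, `"mean_plus_k_sd"`.
#' @param q quantile for `rule = "quantile"` (default 0.99).
#' @param k multiplier for `rule = "mean_plus_k_sd"` (default 3).
#' @return a [cutoff_table()] with provenance `"empirical:<rule>"`.
#' @export
estimate_cutoffs <- function(unrelated_scores,
                             rule = c("max", "quantile", "mean_plus_k_sd"),
                             q = 0.99, k = 3) {
  rule <- match.arg(rule)
  if (length(unrelated_scores) == 0L) abort("no unrelated scores supplied")
  cutoffs <- vapply(names(unrelated_scores), function(sp) {
    s <- unrelated_scores[[sp]]
    s <- s[!is.na(s)]
    if (length(s) == 0L) abort("empty score list for species '%s'", sp)
    if (length(s) < 2L) {
      abort("need >= 2 unrelated scores for species '%s', got %d",
            sp, length(s))
    }
    v <- switch(rule,
                max = max(s),
                quantile = unname(stats::quantile(s, q)),
                mean_plus_k_sd = mean(s) + k * stats::sd(s))
    min(max(v, 0), 100)  # cut-offs are percentages
  }, numeric(1L))
  prov <- switch(rule,
                 max = "empirical:max",
                 quantile = sprintf("empirical:quantile(q=%g)", q),
                 mean_plus_k_sd = sprintf("empirical:mean_plus_%g_sd", k))
  cutoff_table(cutoffs, provenance = prov)
}

#' Misclassification rate of unrelated pairs
#'
#' Among truth-unrelated sample pairs (all-vs-all across different
#' individuals), counts those whose WSS score exceeds the cut-off — i.e.
#' would be miscalled related — and reports the rate as a percentage
#' truncated to two decimal places (2 exceedances out of 1544 pairs prints
#' as 0.12). Pairs with an undefined (NA) score are indeterminate and
#' excluded from the denominator.
#'
#' @param scores numeric vector of WSS scores of truth-unrelated pairs.
#' @param cutoff the species cut-off (percentage).
#' @return list: `n_exceed`, `n_total`, `rate_percent` (truncated to two
#'   decimals).
#' @export
misclassification_rate <- function(scores, cutoff) {
  scores <- scores[!is.na(scores)]
  n_total <- length(scores)
  if (n_total == 0L) abort("no defined unrelated scores to assess")
  n_exceed <- sum(scores > cutoff)
  list(n_exceed = n_exceed,
       n_total = n_total,
       rate_percent = trunc_decimal(100 * n_exceed / n_total, 2L))
}
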