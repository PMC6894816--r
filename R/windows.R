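#' Partition a reference sequence into fixed-length windows
#'
#' Tiles `[0, reference_length)` with non-overlapping windows of
#' `window_length` bases; the final window may be shorter. Intervals are
#' 0-based half-open, the internal convention for all window arithmetic
#' (VCF positions are 1-based and converted on entry).
#'
#' @param reference_length reference length in bases (>= 1).
#' @param window_length window size in bases (>= 1); default 1000.
#' @param species_id optional species identifier carried on the spec.
#' @return object of class `window_spec` with fields `start` (0-based
#'   inclusive), `end` (exclusive), `size`, and `n_windows`.
#' @export
partition_windows <- function(reference_length, window_length = 1000L,
                              species_id = NA_character_) {
  reference_length <- as.integer(reference_length)
  window_length <- as.integer(window_length)
  if (is.na(reference_length) || reference_length < 1L) {
    abort("reference_length must be >= 1")
  }
  if (is.na(window_length) || window_length < 1L) {
    abort("window_length must be >= 1")
  }
  start <- seq.int(0L, reference_length - 1L, by = window_length)
  end <- pmin(start + window_length, reference_length)
  structure(
    list(species_id = species_id,
         reference_length = reference_length,
         window_length = window_length,
         start = start, end = end, size = end - start,
         n_windows = length(start)),
    class = "window_spec"
  )
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> %d windows of %d bases over %d bases\n",
              x$n_windows, x$window_length, x$reference_length))
  invisible(x)
}

# internal: window index (1-based) for each reference position 1..L
window_index <- function(spec) {
  rep.int(seq_len(spec$n_windows), spec$size)
}

#' Is a window usable for a pair of samples?
#'
#' A window is ignored for a pair when, in *either* sample, more than
#' `max_low_fraction` of its bases have read depth below `depth_floor`
#' (defaults: more than 50% of bases with depth < 5). Exactly half
#' low-depth bases is still usable. Absent positions count as depth 0.
#'
#' @param depths_a,depths_b per-base depth vectors spanning the same window.
#' @param depth_floor depth below which a base counts as low (default 5).
#' @param max_low_fraction maximum tolerated fraction of low bases
#'   (default 0.5, exceeded strictly).
#' @return logical.
#' @export
window_usable <- function(depths_a, depths_b, depth_floor = 5L,
                          max_low_fraction = 0.5) {
  if (length(depths_a) != length(depths_b)) {
    abort("depth vectors differ in length (%d vs %d)",
          length(depths_a), length(depths_b))
  }
  n <- length(depths_a)
  if (n == 0L) abort("empty window")
  low_a <- sum(depths_a < depth_floor)
  low_b <- sum(depths_b < depth_floor)
  !(low_a / n > max_low_fraction || low_b / n > max_low_fraction)
}

#' Do two samples show an identical SNV pattern in a window?
#'
#' `TRUE` iff at every position of the window where *both* samples carry a
#' non-missing allele call the allele strings are equal. Positions missing
#' in either sample are non-informative; a window with no both-called
#' positions therefore counts as identical (no observed difference).
#'
#' @param profile_a,profile_b [sample_profile()] objects on the same
#'   reference.
#' @param window integer pair `c(start, end)`, 0-based half-open, inside the
#'   reference.
#' @return logical.
#' @export
window_identical <- function(profile_a, profile_b, window) {
  stopifnot(inherits(profile_a, "sample_profile"),
            inherits(profile_b, "sample_profile"),
            length(window) == 2L)
  start <- as.integer(window[1L]); end <- as.integer(window[2L])
  if (start < 0L || end > profile_a$reference_length || start >= end) {
    abort("window [%d,%d) outside the reference", start, end)
  }
  idx <- (start + 1L):end
  a <- profile_a$allele[idx]
  b <- profile_b$allele[idx]
  both <- !is.na(a) & !is.na(b)
  !any(a[both] != b[both])
}

#' Window-based SNV similarity between two samples
#'
#' For one species, partitions the reference per `spec`, determines the
#' usable windows for the pair (per-sample depth rule, see
#' [window_usable()]), counts the usable windows with no SNV pattern
#' difference (see [window_identical()]), and scores the pair as
#'
#' \deqn{WSS = 100 \times n_{identical} / n_{usable}}
#'
#' The score is undefined (`NA`) when no window is usable; such pairs are
#' reported as indeterminate downstream, never as 0 or 100. The comparison
#' is exactly symmetric in the two samples.
#'
#' @param profile_a,profile_b [sample_profile()] objects for the same
#'   species.
#' @param spec [partition_windows()] result matching the reference length.
#' @param depth_floor,max_low_fraction window-usability parameters, see
#'   [window_usable()].
#' @return a one-row data.frame of class `pair_comparison`: species_id,
#'   sample_a, sample_b, n_windows_total, n_windows_usable,
#'   n_windows_identical, wss_score (percentage or `NA`).
#' @export
wss_score <- function(profile_a, profile_b, spec, depth_floor = 5L,
                      max_low_fraction = 0.5) {
  stopifnot(inherits(profile_a, "sample_profile"),
            inherits(profile_b, "sample_profile"),
            inherits(spec, "window_spec"))
  if (profile_a$species_id != profile_b$species_id) {
    abort("species mismatch: '%s' vs '%s'",
          profile_a$species_id, profile_b$species_id)
  }
  if (profile_a$reference_length != spec$reference_length ||
      profile_b$reference_length != spec$reference_length) {
    abort("profile reference length does not match the window spec")
  }
  widx <- window_index(spec)
  nw <- spec$n_windows

  low_a <- tabulate(widx[profile_a$depth < depth_floor], nbins = nw)
  low_b <- tabulate(widx[profile_b$depth < depth_floor], nbins = nw)
  usable <- low_a / spec$size <= max_low_fraction &
            low_b / spec$size <= max_low_fraction

  both <- !is.na(profile_a$allele) & !is.na(profile_b$allele)
  diff_pos <- both & (profile_a$allele != profile_b$allele)
  n_diff <- tabulate(widx[diff_pos], nbins = nw)
  identical_w <- n_diff == 0L

  n_usable <- sum(usable)
  n_ident <- sum(usable & identical_w)
  score <- if (n_usable > 0L) 100 * n_ident / n_usable else NA_real_
  out <- data.frame(
    species_id = profile_a$species_id,
    sample_a = profile_a$sample_id,
    sample_b = profile_b$sample_id,
    n_windows_total = nw,
    n_windows_usable = n_usable,
    n_windows_identical = n_ident,
    wss_score = score,
    stringsAsFactors = FALSE
  )
  class(out) <- c("pair_comparison", class(out))
  out
}

#' All-pairs WSS comparison table for one species
#'
#' Runs [wss_score()] over the requested sample pairs (all unordered pairs by
#' default), annotating each row with whether both samples pass the
#' breadth/depth sample filter. Pairs whose score is computed but whose
#' samples fail the filter are retained with `pass_filter = FALSE` so they
#' can be reported as indeterminate with the raw score shown.
#'
#' @param profiles named list of [sample_profile()] for one species.
#' @param spec [partition_windows()] result.
#' @param pairs optional two-column matrix / data.frame of sample ids; by
#'   default all unordered pairs of `profiles`.
#' @param min_breadth,min_depth sample-filter thresholds.
#' @param depth_floor,max_low_fraction window-usability parameters.
#' @return data.frame: one row per pair with WSS fields plus `pass_filter`.
#' @export
wss_pair_table <- function(profiles, spec, pairs = NULL,
                           min_breadth = 0.30, min_depth = 3.5,
                           depth_floor = 5L, max_low_fraction = 0.5) {
  ids <- vapply(profiles, `[[`, character(1L), "sample_id")
  names(profiles) <- ids
  if (is.null(pairs)) {
    pairs <- t(utils::combn(ids, 2L))
  }
  pairs <- as.matrix(pairs)
  metrics <- sample_metrics_table(profiles, min_breadth, min_depth)
  pass <- stats::setNames(metrics$pass_filter, metrics$sample_id)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1L]; b <- pairs[i, 2L]
    cmp <- wss_score(profiles[[a]], profiles[[b]], spec,
                     depth_floor, max_low_fraction)
    cmp$pass_filter <- unname(pass[a] & pass[b])
    cmp
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
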