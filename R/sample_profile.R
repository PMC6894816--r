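#' Per-sample base-resolution genomic profile
#'
#' A `sample_profile` holds one sample's allele calls and read depths against
#' one microbial reference sequence, at base resolution. Internally the calls
#' are dense vectors over the whole reference: `allele[i]` is the called
#' allele string at 1-based position `i` (`NA` where no call was made — zero
#' depth, dropout, or an explicit missing genotype) and `depth[i]` is the
#' per-base read depth (0 where the position is unobserved).
#'
#' @param sample_id sample identifier.
#' @param species_id reference species identifier.
#' @param reference_length length of the reference sequence in bases.
#' @param allele character vector of length `reference_length`; `NA` marks
#'   positions without a genotype call.
#' @param depth non-negative integer vector of length `reference_length`.
#' @return an object of class `sample_profile`.
#' @export
sample_profile <- function(sample_id, species_id, reference_length,
                           allele, depth) {
  reference_length <- as.integer(reference_length)
  if (length(reference_length) != 1L || is.na(reference_length) ||
      reference_length < 1L) {
    abort("reference_length must be a single positive integer")
  }
  if (length(allele) != reference_length || length(depth) != reference_length) {
    abort("allele and depth must have length reference_length (%d)",
          reference_length)
  }
  depth <- as.integer(depth)
  if (anyNA(depth) || any(depth < 0L)) {
    abort("depths must be non-negative integers")
  }
  structure(
    list(sample_id = as.character(sample_id),
         species_id = as.character(species_id),
         reference_length = reference_length,
         allele = as.character(allele),
         depth = depth),
    class = "sample_profile"
  )
}

#' @export
print.sample_profile <- function(x, ...) {
  m <- compute_sample_metrics(x)
  cat(sprintf(
    "<sample_profile> %s on %s: %d bases, breadth %.3f, mean depth %.2f\n",
    x$sample_id, x$species_id, x$reference_length, m$breadth, m$mean_depth))
  invisible(x)
}

#' Coverage breadth and mean depth of a sample profile
#'
#' Breadth is the fraction of reference positions with depth >= 1 (any mapped
#' evidence). Mean depth averages over the *whole* reference length, counting
#' unobserved positions as depth 0, so the two metrics are not redundant.
#'
#' @param profile a [sample_profile()].
#' @return list with elements `breadth` (fraction in \[0,1\]) and
#'   `mean_depth` (non-negative real).
#' @export
compute_sample_metrics <- function(profile) {
  stopifnot(inherits(profile, "sample_profile"))
  if (profile$reference_length < 1L) abort("reference_length must be >= 1")
  list(
    breadth = sum(profile$depth >= 1L) / profile$reference_length,
    mean_depth = sum(as.numeric(profile$depth)) / profile$reference_length
  )
}

#' Sample-level inclusion filter
#'
#' A sample is kept for pairwise comparison only if its coverage breadth and
#' mean depth both *strictly* exceed the thresholds; the defaults mirror the
#' exclusion of samples with coverage < 30% and depth < 3.5.
#'
#' @param breadth coverage breadth in \[0,1\].
#' @param mean_depth mean read depth over the reference.
#' @param min_breadth breadth threshold (default 0.30).
#' @param min_depth mean-depth threshold (default 3.5).
#' @return logical: `TRUE` iff both metrics strictly exceed their thresholds.
#' @export
passes_sample_filter <- function(breadth, mean_depth,
                                 min_breadth = 0.30, min_depth = 3.5) {
  breadth > min_breadth & mean_depth > min_depth
}

#' Tabulate metrics and filter status for a set of profiles
#'
#' @param profiles list of [sample_profile()] objects.
#' @param min_breadth,min_depth thresholds passed to
#'   [passes_sample_filter()].
#' @return data.frame with columns sample_id, species_id, breadth,
#'   mean_depth, pass_filter.
#' @export
sample_metrics_table <- function(profiles, min_breadth = 0.30,
                                 min_depth = 3.5) {
  stopifnot(length(profiles) > 0L)
  rows <- lapply(profiles, function(p) {
    m <- compute_sample_metrics(p)
    data.frame(sample_id = p$sample_id, species_id = p$species_id,
               breadth = m$breadth, mean_depth = m$mean_depth,
               pass_filter = passes_sample_filter(m$breadth, m$mean_depth,
                                                  min_breadth, min_depth),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cohort sequencing-read manifest
#'
#' Bookkeeping container for raw and quality-filtered read counts per sample
#' in a dataset, with dataset totals as sums over member samples.
#'
#' @param dataset_id dataset identifier.
#' @param read_counts_raw named integer-like vector, sample_id -> raw reads.
#' @param read_counts_filtered named vector, sample_id -> reads surviving
#'   quality filtering; must not exceed the raw count for any sample.
#' @return object of class `cohort_manifest` with `total_raw` and
#'   `total_filtered` fields.
#' @export
cohort_manifest <- function(dataset_id, read_counts_raw,
                            read_counts_filtered = read_counts_raw) {
  if (is.null(names(read_counts_raw)) ||
      !identical(sort(names(read_counts_raw)),
                 sort(names(read_counts_filtered)))) {
    abort("read count vectors must be named by the same sample ids")
  }
  read_counts_filtered <- read_counts_filtered[names(read_counts_raw)]
  if (any(read_counts_filtered > read_counts_raw)) {
    bad <- names(read_counts_raw)[read_counts_filtered > read_counts_raw][1L]
    abort("filtered read count exceeds raw count for sample '%s'", bad)
  }
  structure(
    list(dataset_id = as.character(dataset_id),
         samples = names(read_counts_raw),
         read_counts_raw = read_counts_raw,
         read_counts_filtered = read_counts_filtered,
         total_raw = sum(as.numeric(read_counts_raw)),
         total_filtered = sum(as.numeric(read_counts_filtered))),
    class = "cohort_manifest"
  )
}

#' Combine manifests from several datasets
#'
#' @param ... `cohort_manifest` objects.
#' @return list with `total_raw` and `total_filtered` summed across datasets.
#' @export
combine_manifests <- function(...) {
  ms <- list(...)
  stopifnot(length(ms) > 0L,
            all(vapply(ms, inherits, logical(1L), "cohort_manifest")))
  list(total_raw = sum(vapply(ms, `[[`, numeric(1L), "total_raw")),
       total_filtered = sum(vapply(ms, `[[`, numeric(1L), "total_filtered")))
}
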