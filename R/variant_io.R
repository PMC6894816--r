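#' Read a base-resolution multi-sample VCF into sample profiles
#'
#' Reads a (g)VCF with one or more sample columns, haploid genotype calls and
#' per-sample `DP` depth annotations, and returns one [sample_profile()] per
#' sample column. Non-variant (reference-called) sites are expected to be
#' present; a site with genotype `0` yields the REF allele, genotype `k > 0`
#' yields the k-th ALT allele, and a missing genotype (`.`) is recorded with
#' no allele call but with the reported depth, so it still contributes to
#' window-depth accounting. Positions absent from the file carry depth 0 and
#' no call.
#'
#' Parsing of the VCF container itself is done by \pkg{vcfR}; this function
#' adds the contracts the pipeline needs: a malformed body line is reported
#' with its line number, a sample column lacking a depth annotation is
#' reported by name, and any genotype with ploidy > 1 is an error (the
#' pipeline is defined for haploid calls only).
#'
#' @param path path to an (uncompressed or bgzipped) VCF file.
#' @param species_id species identifier stamped on every returned profile.
#' @param reference_length reference sequence length in bases; every POS in
#'   the file must lie in `[1, reference_length]`.
#' @return named list of [sample_profile()], one per sample column.
#' @export
read_multisample_vcf <- function(path, species_id, reference_length) {
  reference_length <- as.integer(reference_length)
  stopifnot(length(reference_length) == 1L, reference_length >= 1L)
  if (!file.exists(path)) abort("VCF file not found: %s", path)
  validate_vcf_lines(path)

  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix  # always a matrix, unlike getFIX() on single records
  if (is.null(fix) || nrow(fix) == 0L || nrow(vcf@gt) == 0L) {
    abort("VCF '%s' contains no records", path)
  }
  pos <- as.integer(fix[, "POS"])
  if (anyNA(pos) || any(pos < 1L) || any(pos > reference_length)) {
    abort("VCF positions outside [1, %d] in '%s'", reference_length, path)
  }
  ref <- fix[, "REF"]
  alt_split <- strsplit(ifelse(is.na(fix[, "ALT"]), ".", fix[, "ALT"]),
                        ",", fixed = TRUE)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  ploid <- array(grepl("[/|]", gt), dim = dim(gt))  # grepl drops dims
  if (any(ploid, na.rm = TRUE)) {
    bad <- which(ploid, arr.ind = TRUE)[1L, ]
    abort("ploidy > 1 genotype '%s' at position %d (sample '%s'): haploid calls required",
          gt[bad[1L], bad[2L]], pos[bad[1L]], samples[bad[2L]])
  }
  fmt <- sub(":.*$", "", vcf@gt[, "FORMAT"])
  has_dp <- grepl("(^|:)DP(:|$)", vcf@gt[, "FORMAT"])
  if (!all(has_dp)) {
    abort("VCF records without a DP depth annotation (first at position %d)",
          pos[which(!has_dp)[1L]])
  }
  dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP",
                                          as.numeric = TRUE))
  for (s in samples) {
    if (all(is.na(dp[, s]))) {
      abort("sample '%s' has no depth (DP) annotation", s)
    }
  }
  dp[is.na(dp)] <- 0

  # map genotype index -> allele string per record
  n_alt <- lengths(alt_split)
  allele_options <- matrix(NA_character_, nrow = length(pos),
                           ncol = 1L + max(n_alt))
  allele_options[, 1L] <- ref
  for (k in seq_len(max(n_alt))) {
    has_k <- n_alt >= k
    ak <- vapply(alt_split[has_k], `[`, character(1L), k)
    ak[ak == "."] <- NA_character_
    allele_options[has_k, k + 1L] <- ak
  }

  profiles <- vector("list", length(samples))
  names(profiles) <- samples
  for (s in samples) {
    gidx <- suppressWarnings(as.integer(gt[, s]))
    allele_here <- rep(NA_character_, length(pos))
    called <- !is.na(gidx)
    if (any(gidx[called] > n_alt[called] | gidx[called] < 0L)) {
      abort("genotype index out of range for sample '%s'", s)
    }
    allele_here[called] <- allele_options[cbind(which(called),
                                                gidx[called] + 1L)]
    allele <- rep(NA_character_, reference_length)
    depth <- integer(reference_length)
    allele[pos] <- allele_here
    depth[pos] <- as.integer(round(dp[, s]))
    # a position with zero depth cannot carry a reliable call
    allele[depth == 0L] <- NA_character_
    profiles[[s]] <- sample_profile(s, species_id, reference_length,
                                    allele, depth)
  }
  profiles
}

# internal: cheap structural scan so that malformed body lines are reported
# with their 1-based line number before the real parser runs
validate_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !startsWith(lines[1L], "##fileformat=VCF")) {
    abort("malformed VCF at line 1: missing ##fileformat header in '%s'", path)
  }
  hdr <- which(startsWith(lines, "#CHROM"))
  if (length(hdr) != 1L) {
    abort("malformed VCF: expected exactly one #CHROM header line in '%s'",
          path)
  }
  n_fields <- length(strsplit(lines[hdr], "\t", fixed = TRUE)[[1L]])
  if (n_fields < 10L) {
    abort("malformed VCF at line %d: no sample columns", hdr)
  }
  body <- seq.int(hdr + 1L, length.out = length(lines) - hdr)
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != n_fields) {
      abort("malformed VCF at line %d: %d fields where %d expected",
            i, length(f), n_fields)
    }
    if (is.na(suppressWarnings(as.integer(f[2L])))) {
      abort("malformed VCF at line %d: non-numeric POS '%s'", i, f[2L])
    }
  }
  invisible(TRUE)
}

#' Write sample profiles as a base-resolution multi-sample VCF
#'
#' Emits a gVCF-style file with one record per reference position (including
#' non-variant sites) and `GT:DP` sample fields, the layout
#' [read_multisample_vcf()] consumes. Positions without a call in a sample
#' get genotype `.`; sites where no sample carries a non-reference allele get
#' ALT `.`.
#'
#' @param profiles named list of [sample_profile()] for one species; all must
#'   share `species_id` and `reference_length`.
#' @param reference character vector of single-base reference alleles, length
#'   `reference_length`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_multisample_vcf <- function(profiles, reference, path) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1L), "sample_profile")))
  ids <- vapply(profiles, `[[`, character(1L), "sample_id")
  if (anyDuplicated(ids)) abort("conflicting (duplicated) sample ids")
  sp <- unique(vapply(profiles, `[[`, character(1L), "species_id"))
  L <- unique(vapply(profiles, `[[`, integer(1L), "reference_length"))
  if (length(sp) != 1L || length(L) != 1L) {
    abort("profiles must share one species_id and reference_length")
  }
  if (length(reference) != L) {
    abort("reference must have length %d", L)
  }

  allele_mat <- vapply(profiles, `[[`, character(L), "allele")
  depth_mat <- vapply(profiles, `[[`, integer(L), "depth")

  # per position: collect ALT alleles (unique non-ref calls), GT indices
  gt_mat <- matrix(".", nrow = L, ncol = length(profiles))
  alt_str <- rep(".", L)
  is_ref <- allele_mat == reference  # NA where no call
  gt_mat[which(is_ref)] <- "0"
  nonref <- which(!is_ref & !is.na(allele_mat), arr.ind = TRUE)
  if (nrow(nonref) > 0L) {
    by_pos <- split(seq_len(nrow(nonref)), nonref[, 1L])
    for (p_chr in names(by_pos)) {
      idx <- by_pos[[p_chr]]
      p <- nonref[idx[1L], 1L]
      alleles <- allele_mat[cbind(p, nonref[idx, 2L])]
      alts <- unique(alleles)
      alt_str[p] <- paste(alts, collapse = ",")
      gt_mat[cbind(p, nonref[idx, 2L])] <- as.character(match(alleles, alts))
    }
  }

  sample_fields <- matrix(paste(gt_mat, depth_mat, sep = ":"),
                          nrow = L, ncol = length(profiles))
  body <- paste(sp, seq_len(L), ".", reference, alt_str, ".", ".", ".",
                "GT:DP", sep = "\t")
  for (j in seq_along(profiles)) {
    body <- paste(body, sample_fields[, j], sep = "\t")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", sp, L),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a sample-metadata table
#'
#' Tab-separated file with columns `sample_id`, `pair_id`, `family_id`,
#' `separation_years`, `age_years`.
#'
#' @param path path to the TSV.
#' @return data.frame of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "pair_id", "family_id", "separation_years",
            "age_years")
  missing_cols <- setdiff(need, names(md))
  if (length(missing_cols) > 0L) {
    abort("metadata is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  md
}

#' Write a table as TSV
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
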