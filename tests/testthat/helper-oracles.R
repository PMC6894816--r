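# Independent straight-line reimplementations used as oracles. These loop
# over every base and window deliberately: they must stay structurally
# unrelated to the vectorised implementations they check.

bf_sample_metrics <- function(profile) {
  covered <- 0L
  total_depth <- 0
  for (i in seq_len(profile$reference_length)) {
    d <- profile$depth[i]
    if (d >= 1L) covered <- covered + 1L
    total_depth <- total_depth + d
  }
  list(breadth = covered / profile$reference_length,
       mean_depth = total_depth / profile$reference_length)
}

bf_window_usable <- function(depths_a, depths_b, depth_floor = 5,
                             max_low_fraction = 0.5) {
  n <- length(depths_a)
  for (d in list(depths_a, depths_b)) {
    n_low <- 0L
    for (i in seq_len(n)) if (d[i] < depth_floor) n_low <- n_low + 1L
    if (n_low / n > max_low_fraction) return(FALSE)
  }
  TRUE
}

bf_window_identical <- function(profile_a, profile_b, start, end) {
  for (i in (start + 1L):end) {
    a <- profile_a$allele[i]
    b <- profile_b$allele[i]
    if (!is.na(a) && !is.na(b) && a != b) return(FALSE)
  }
  TRUE
}

bf_wss <- function(profile_a, profile_b, window_length, depth_floor = 5,
                   max_low_fraction = 0.5) {
  L <- profile_a$reference_length
  starts <- seq(0L, L - 1L, by = window_length)
  n_usable <- 0L
  n_identical <- 0L
  for (s in starts) {
    e <- min(s + window_length, L)
    idx <- (s + 1L):e
    if (!bf_window_usable(profile_a$depth[idx], profile_b$depth[idx],
                          depth_floor, max_low_fraction)) next
    n_usable <- n_usable + 1L
    if (bf_window_identical(profile_a, profile_b, s, e)) {
      n_identical <- n_identical + 1L
    }
  }
  list(n_usable = n_usable, n_identical = n_identical,
       score = if (n_usable > 0L) 100 * n_identical / n_usable else NA_real_)
}

# random profile fixtures -----------------------------------------------

random_profile <- function(L, sample_id = "S", species_id = "sp",
                           max_depth = 12L, p_missing = 0.1) {
  depth <- sample(0:max_depth, L, replace = TRUE)
  allele <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  allele[depth == 0L | runif(L) < p_missing] <- NA_character_
  sample_profile(sample_id, species_id, L, allele, depth)
}

# a pair sharing a backbone, with sprinkled discordances and missingness
random_profile_pair <- function(L, n_discordant = NULL, max_depth = 12L) {
  a <- random_profile(L, "A", "sp", max_depth)
  allele_b <- a$allele
  depth_b <- sample(0:max_depth, L, replace = TRUE)
  allele_b[depth_b == 0L | runif(L) < 0.1] <- NA_character_
  if (is.null(n_discordant)) n_discordant <- sample(0:round(L / 20), 1L)
  if (n_discordant > 0L) {
    pos <- sample.int(L, n_discordant)
    allele_b[pos] <- ifelse(is.na(allele_b[pos]), allele_b[pos],
                            chartr("ACGT", "CGTA", allele_b[pos]))
  }
  list(a = a,
       b = sample_profile("B", "sp", L, allele_b, depth_b))
}

# uniform-depth profile from explicit alleles (small hand fixtures)
profile_from_alleles <- function(alleles, depth = 10L, sample_id = "S",
                                 species_id = "sp") {
  L <- length(alleles)
  sample_profile(sample_id, species_id, L, alleles, rep(depth, L))
}

write_vcf_fixture <- function(lines) {
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  path
}

# minimal well-formed two-sample VCF: `records` are preformatted body lines
vcf_fixture <- function(records, samples = c("S1", "S2"), contig = "sp",
                        L = 10L) {
  write_vcf_fixture(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contig, L),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records))
}
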