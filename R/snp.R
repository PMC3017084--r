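#' Pool parameters
#'
#' Bundles the parameters that define SNP calling and estimator correction in
#' a pooled sample: the number of chromosomes in the pool, the minimum minor
#' allele count among reads (the truncation bound of the allele frequency
#' spectrum), the base-quality filter and the admissible coverage range.
#'
#' @param pool_size Chromosomes in the pool (2x individuals for diploids),
#'   `>= 2`.
#' @param min_count Minimum allele count `b >= 1` among reads for an allele
#'   to be believed.
#' @param min_quality Minimum Phred base quality (applied when reading the
#'   pileup).
#' @param min_coverage Minimum effective coverage for a site to count as
#'   covered. A warning is issued when below `2 * min_count`, where the
#'   truncation correction is undefined (such sites are always excluded).
#' @param max_coverage Maximum effective coverage (repeat-region guard);
#'   `Inf` disables the upper bound.
#' @return List of class `pool_params`.
#' @export
pool_params <- function(pool_size, min_count = 2L, min_quality = 20L,
                        min_coverage = 4L, max_coverage = Inf) {
  stopifnot(pool_size >= 2, min_count >= 1, min_coverage <= max_coverage)
  if (min_coverage < 2 * min_count)
    warning("min_coverage < 2*min_count: sites with coverage below ",
            2 * min_count, " are excluded (correction undefined there)")
  structure(list(pool_size = as.integer(pool_size),
                 min_count = as.integer(min_count),
                 min_quality = as.integer(min_quality),
                 min_coverage = as.integer(min_coverage),
                 max_coverage = max_coverage),
            class = "pool_params")
}

#' Call a SNP at one site
#'
#' A site is eligible when its effective coverage lies in
#' `[min_coverage, max_coverage]` (and is at least `2 * min_count`, below
#' which the truncated-spectrum correction is undefined). It is a SNP when
#' eligible and at least two of the four base counts reach `min_count`;
#' triallelic and quadriallelic sites are retained, all alleles with count
#' `>= min_count` being reported in descending count order.
#'
#' @param counts Named A/C/G/T count vector (quality-filtered).
#' @param params A [pool_params()].
#' @return List with `is_snp`, `eligible`, `alleles` (bases with count
#'   `>= min_count`, by descending count) and `effective_coverage`.
#' @export
call_snp <- function(counts, params) {
  cov <- sum(counts)
  eligible <- cov >= max(params$min_coverage, 2L * params$min_count) &&
    cov <= params$max_coverage
  ok <- counts[counts >= params$min_count]
  alleles <- names(sort(ok, decreasing = TRUE))
  list(is_snp = eligible && length(alleles) >= 2,
       eligible = eligible,
       alleles = alleles,
       effective_coverage = cov)
}

#' Vectorised site annotation for a count table
#'
#' Adds SNP calls and per-site estimator ingredients to a site-count table:
#' eligibility, SNP status, heterozygosity `h`, and the number of alleles at
#' or above the minor-allele-count bound.
#'
#' @param counts `data.table` from [read_pileup()] (columns `A`, `C`, `G`,
#'   `T`, `cov`).
#' @param params A [pool_params()].
#' @return The table, copied, with logical `eligible`, `is_snp` and numeric
#'   `h` columns appended.
#' @export
annotate_sites <- function(counts, params) {
  dt <- data.table::copy(counts)
  mat <- as.matrix(dt[, c("A", "C", "G", "T"), with = FALSE])
  cov_v <- as.integer(rowSums(mat))
  lo <- max(params$min_coverage, 2L * params$min_count)
  elig <- cov_v >= lo & cov_v <= params$max_coverage
  data.table::set(dt, j = "cov", value = cov_v)
  data.table::set(dt, j = "eligible", value = elig)
  data.table::set(dt, j = "is_snp",
                  value = elig & rowSums(mat >= params$min_count) >= 2)
  data.table::set(dt, j = "h", value = site_heterozygosity(mat))
  dt[]
}

#' Table of polymorphic sites
#'
#' @param counts Site-count `data.table`.
#' @param params A [pool_params()].
#' @return `data.table` of SNP sites with allele counts and read-level allele
#'   frequencies.
#' @export
snp_table <- function(counts, params) {
  ann <- annotate_sites(counts, params)
  snp <- ann[ann$is_snp]
  for (b in c("A", "C", "G", "T"))
    snp[, (paste0("f", b)) := get(b) / cov]
  snp[, c("eligible", "is_snp", "h") := NULL]
  snp[]
}
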