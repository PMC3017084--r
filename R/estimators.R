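#' Probability of a read-level allele count given a pool allele count
#'
#' Reads sample the `n` chromosomes of a pool with replacement, so the number
#' of reads `m` (out of coverage `C`) carrying an allele present on `k` of the
#' `n` pooled chromosomes is binomial with success probability `k/n`.
#'
#' @param C Coverage (number of reads at the site).
#' @param m Read-level allele count, `0 <= m <= C`. Vectorised.
#' @param k Pool-level allele count, `1 <= k <= n - 1`.
#' @param n Pool size (number of chromosomes in the pool).
#' @return Probability `P(m | k) = choose(C, m) (k/n)^m (1 - k/n)^(C - m)`.
#' @examples
#' prob_reads_given_pool(2, 1, 1, 2) # 0.5
#' @export
prob_reads_given_pool <- function(C, m, k, n) {
  stopifnot(C >= 0, n >= 2)
  if (any(m < 0 | m > C)) stop("read allele count m must lie in [0, C]")
  if (any(k < 1 | k > n - 1)) stop("pool allele count k must lie in [1, n - 1]")
  stats::dbinom(m, size = C, prob = k / n)
}

#' Correction table cache for pooled theta estimators
#'
#' Holds the pool size `n` and minimum allele count `b` and memoises the
#' coverage-dependent denominators of the corrected Watterson and pi
#' estimators, keyed by coverage. Coverage varies along real data, so each
#' SNP's contribution uses the denominator evaluated at that site's effective
#' coverage; caching avoids recomputing the inner sums per site.
#'
#' @param n Pool size (chromosomes), `n >= 2`.
#' @param b Minimum minor allele count among reads, `b >= 1`.
#' @param max_entries Cache bound; the cache is flushed when it grows past
#'   this many coverages (coverage values recur heavily, so this is rarely hit).
#' @return An object of class `correction_tables`.
#' @export
correction_tables <- function(n, b = 2L, max_entries = 100000L) {
  stopifnot(n >= 2, b >= 1)
  obj <- list(n = as.integer(n), b = as.integer(b),
              cache = new.env(parent = emptyenv()),
              max_entries = as.integer(max_entries))
  class(obj) <- "correction_tables"
  obj
}

#' @export
print.correction_tables <- function(x, ...) {
  cat(sprintf("correction tables: pool size n=%d, min count b=%d, %d cached coverages\n",
              x$n, x$b, length(ls(x$cache))))
  invisible(x)
}

# shared inner machinery: both denominators sum over pool allele counts
# k = 1..n-1 with the neutral weight 1/k (the expected frequency spectrum of
# an allele segregating at count k in the pool), and over read allele counts
# m restricted to the truncated window [b, C-b].
.denom_one <- function(C, n, b, which) {
  if (C < 2 * b) stop("coverage C must be at least 2*b for the truncated correction")
  k <- seq_len(n - 1)
  p <- k / n
  if (which == "watterson") {
    # P(b <= m <= C-b | k), in closed form via the binomial CDF
    keep <- stats::pbinom(C - b, C, p) - stats::pbinom(b - 1, C, p)
    sum(keep / k)
  } else {
    # E[2m(C-m)/(C(C-1)); b <= m <= C-b | k]. The untruncated expectation is
    # exactly 2p(1-p) because E[m(C-m)] = C(C-1)p(1-p); subtract the (at most
    # 2(b-1) nonzero) tail terms, noting the m=0 and m=C weights vanish.
    full <- 2 * p * (1 - p)
    if (b > 1) {
      mt <- c(seq_len(b - 1), C - seq_len(b - 1))
      w <- 2 * mt * (C - mt) / (C * (C - 1))
      tails <- vapply(p, function(pp) sum(w * stats::dbinom(mt, C, pp)), 0)
      full <- full - tails
    }
    sum(full / k)
  }
}

.denom_cached <- function(tables, C, which) {
  key <- paste0(which, ".", C)
  env <- tables$cache
  val <- get0(key, envir = env, inherits = FALSE)
  if (is.null(val)) {
    val <- .denom_one(C, tables$n, tables$b, which)
    if (length(ls(env)) >= tables$max_entries) rm(list = ls(env), envir = env)
    assign(key, val, envir = env)
  }
  val
}

#' Denominator of the pooled Watterson estimator
#'
#' The corrected Watterson estimator divides each SNP's contribution by the
#' expected number of segregating sites per unit theta that survive the
#' pooled sampling and the minor-allele-count truncation at the site's
#' coverage:
#' \deqn{\sum_{m=b}^{C-b} \sum_{k=1}^{n-1} \frac{1}{k} P(m \mid k)}
#' where `P(m | k)` is [prob_reads_given_pool()]. As `C` grows with `b = 1`
#' this approaches the harmonic number `a_{n-1} = sum(1/(1:(n-1)))`, the
#' classical Watterson denominator.
#'
#' @param C Coverage (scalar or vector).
#' @param n Pool size.
#' @param b Minimum minor allele count.
#' @param tables Optional [correction_tables()] cache; `n`/`b` are taken from
#'   it when supplied.
#' @return The denominator (same length as `C`), strictly positive for
#'   `C >= 2b`.
#' @export
watterson_denominator <- function(C, n = NULL, b = NULL, tables = NULL) {
  if (is.null(tables)) tables <- correction_tables(n, b)
  vapply(as.integer(C), function(cc) .denom_cached(tables, cc, "watterson"), 0)
}

#' Denominator of the pooled pi estimator
#'
#' The corrected pi estimator divides each SNP's heterozygosity by
#' \deqn{\sum_{m=b}^{C-b} \frac{2m(C-m)}{C(C-1)} \sum_{k=1}^{n-1}
#'       \frac{1}{k} P(m \mid k)}
#' which for `b = 1` equals `(n-1)/n` exactly (at any coverage), the
#' classical finite-sample correction of pi.
#'
#' @inheritParams watterson_denominator
#' @return The denominator (same length as `C`).
#' @export
pi_denominator <- function(C, n = NULL, b = NULL, tables = NULL) {
  if (is.null(tables)) tables <- correction_tables(n, b)
  vapply(as.integer(C), function(cc) .denom_cached(tables, cc, "pi"), 0)
}

#' Per-site heterozygosity from allele counts
#'
#' `h = C/(C-1) * (1 - sum(f_a^2))` with `f_a = count_a / C`; equals
#' `sum over allele pairs of 2 n_a n_b / (C (C-1))`, the probability that two
#' reads drawn without replacement differ. Zero at monomorphic sites.
#'
#' @param counts Numeric matrix (sites x alleles) or vector of allele counts.
#' @return Heterozygosity per site.
#' @export
site_heterozygosity <- function(counts) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  C <- rowSums(counts)
  h <- ifelse(C > 1, (C^2 - rowSums(counts^2)) / (C * (C - 1)), 0)
  as.numeric(h)
}

#' Windowed pooled Watterson estimator
#'
#' Sums `1 / watterson_denominator(C_site)` over SNP sites (each SNP corrected
#' at its own effective coverage) and divides by the number of covered sites.
#'
#' @param snp_coverages Effective coverages of the SNP sites in the window.
#' @param covered_sites Number of sites in the window with admissible coverage.
#' @param tables A [correction_tables()] cache carrying `n` and `b`.
#' @return Per-site theta Watterson; `NA` if `covered_sites == 0`.
#' @export
theta_w_window <- function(snp_coverages, covered_sites, tables) {
  if (covered_sites <= 0) return(NA_real_)
  if (length(snp_coverages) == 0) return(0)
  sum(1 / watterson_denominator(snp_coverages, tables = tables)) / covered_sites
}

#' Windowed pooled pi estimator
#'
#' Sums `h_site / pi_denominator(C_site)` over SNP sites and divides by the
#' number of covered sites.
#'
#' @param snp_h Per-site heterozygosities of the SNP sites.
#' @param snp_coverages Effective coverages of the same sites.
#' @inheritParams theta_w_window
#' @return Per-site theta pi; `NA` if `covered_sites == 0`.
#' @export
theta_pi_window <- function(snp_h, snp_coverages, covered_sites, tables) {
  if (covered_sites <= 0) return(NA_real_)
  if (length(snp_h) == 0) return(0)
  stopifnot(length(snp_h) == length(snp_coverages))
  sum(snp_h / pi_denominator(snp_coverages, tables = tables)) / covered_sites
}

#' Classical Tajima variance constants
#'
#' The constants `a1, a2, b1, b2, c1, c2, e1, e2` of Tajima's (1989) variance
#' of `pi - S/a1`, evaluated at sample size `n`.
#'
#' @param n Sample size (here: the pool size).
#' @return Named list of the eight constants.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 3)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D for a window of pooled data
#'
#' `D = (theta_pi - theta_W) / sqrt(Var)` on the locus (window total) scale.
#' Because the minor-allele-count filter truncates the frequency spectrum, the
#' observed number of segregating sites under-counts the true one; the
#' variance is therefore evaluated at an effective segregating-site number
#' `S* = a1 * thetaW_locus` — i.e. theta is plugged in as the window's
#' corrected Watterson estimate, which is unbiased for the full (untruncated)
#' theta — using the classical constants at sample size `n`:
#' `Var = e1 S* + e2 S* (S* - 1)`. This variance form is a documented
#' reconstruction (validated by the neutral expectation E[D] ~ 0), not an
#' exact finite-sample result for the truncated spectrum.
#'
#' @param S Observed number of SNPs in the window.
#' @param theta_pi_locus Window-total corrected pi (per-site value times
#'   covered sites).
#' @param theta_w_locus Window-total corrected Watterson theta.
#' @param n Pool size.
#' @param constants Optional precomputed [tajima_constants()].
#' @return Tajima's D, or `NA` when `S == 0` or the variance is not positive.
#' @export
tajima_d_window <- function(S, theta_pi_locus, theta_w_locus, n,
                            constants = tajima_constants(n)) {
  if (is.na(S) || S <= 0 || is.na(theta_pi_locus) || is.na(theta_w_locus))
    return(NA_real_)
  s_eff <- constants$a1 * theta_w_locus
  v <- constants$e1 * s_eff + constants$e2 * s_eff * max(s_eff - 1, 0)
  if (!is.finite(v) || v <= 0) return(NA_real_)
  (theta_pi_locus - theta_w_locus) / sqrt(v)
}
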