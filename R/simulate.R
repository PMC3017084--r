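#' Simulation parameters
#'
#' Defaults are the validation study conditions: a neutral sample of 400
#' chromosomes over a 100 kb locus at theta = 0.005 per site (Drosophila-like
#' variability), 75 bp reads with per-base error rates in the 0.1-1% range
#' and target coverages of 50-250, five replicates.
#'
#' @param n_chromosomes Pool/sample size (chromosomes).
#' @param locus_length Locus length in bp.
#' @param theta_per_site Scaled mutation rate (4 N mu) per site.
#' @param error_rate Per-base probability that a read base is replaced by a
#'   uniformly chosen different base.
#' @param target_coverage Mean read depth aimed for.
#' @param read_length Read length in bp.
#' @param replicates Number of simulation replicates.
#' @param block_size Recombination is approximated by simulating independent
#'   coalescent trees for consecutive blocks of this many bp (high
#'   per-locus recombination makes distant sites quasi-independent; linkage
#'   affects replicate variance, not estimator bias).
#' @return List of class `sim_params`.
#' @export
sim_params <- function(n_chromosomes = 400L, locus_length = 100000L,
                       theta_per_site = 0.005, error_rate = 0.002,
                       target_coverage = 50, read_length = 75L,
                       replicates = 5L, block_size = 1000L) {
  stopifnot(n_chromosomes >= 2, locus_length >= 1, theta_per_site > 0,
            error_rate >= 0, error_rate < 1, target_coverage > 0,
            read_length >= 1, replicates >= 1, block_size >= 1)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 locus_length = as.integer(locus_length),
                 theta_per_site = theta_per_site,
                 error_rate = error_rate,
                 target_coverage = target_coverage,
                 read_length = as.integer(read_length),
                 replicates = as.integer(replicates),
                 block_size = as.integer(block_size)),
            class = "sim_params")
}

# one neutral coalescent tree (no recombination) for n chromosomes;
# returns branches as (leafset, length) with time in units of 2N generations,
# so E[total length] = 2 * a_{n-1} and S ~ Poisson(theta_locus/2 * length).
.coalescent_branches <- function(n) {
  lineages <- as.list(seq_len(n))
  blen <- numeric(n)
  sets <- vector("list", 2L * (n - 1L))
  lens <- numeric(2L * (n - 1L))
  nb <- 0L
  j <- n
  while (j > 1L) {
    blen <- blen + stats::rexp(1L, rate = j * (j - 1L) / 2)
    pair <- sort(sample.int(j, 2L))
    for (i in pair) {
      nb <- nb + 1L
      sets[[nb]] <- lineages[[i]]
      lens[nb] <- blen[i]
    }
    lineages[[pair[1]]] <- c(lineages[[pair[1]]], lineages[[pair[2]]])
    blen[pair[1]] <- 0
    lineages[[pair[2]]] <- NULL
    blen <- blen[-pair[2]]
    j <- j - 1L
  }
  list(sets = sets[seq_len(nb)], lens = lens[seq_len(nb)])
}

#' Simulate neutral haplotypes
#'
#' Constant-size neutral coalescent sample of `n_chromosomes` haplotypes.
#' Two modes: `"coalescent"` (default) simulates an independent Kingman
#' coalescent per `block_size` block and drops Poisson mutations on the
#' branches (the infinite-sites model); `"sfs"` samples the number of sites
#' in each derived-frequency class `k` directly from its neutral expectation
#' `Poisson(theta * L / k)` with carriers chosen uniformly (fully unlinked
#' sites).
#'
#' @param params A [sim_params()].
#' @param mode `"coalescent"` or `"sfs"`.
#' @return List of class `haplotype_set`: logical matrix `haps`
#'   (`n_chromosomes` x S, `TRUE` = derived allele), sorted unique integer
#'   `positions` in `[1, locus_length]`, and `n`, `L`.
#' @export
simulate_haplotypes <- function(params, mode = c("coalescent", "sfs")) {
  mode <- match.arg(mode)
  n <- params$n_chromosomes
  L <- params$locus_length
  pos_list <- list(); car_list <- list()
  if (mode == "coalescent") {
    b0 <- seq(1L, L, by = params$block_size)
    for (bs in b0) {
      be <- min(bs + params$block_size - 1L, L)
      blen <- be - bs + 1L
      theta_block <- params$theta_per_site * blen
      br <- .coalescent_branches(n)
      S <- stats::rpois(1L, theta_block / 2 * sum(br$lens))
      S <- min(S, blen)                 # infinite-sites on a finite block
      if (S == 0L) next
      which_br <- sample.int(length(br$lens), S, replace = TRUE,
                             prob = br$lens)
      pos_list[[length(pos_list) + 1L]] <-
        bs - 1L + sort(sample.int(blen, S))
      car_list <- c(car_list, br$sets[which_br])
    }
  } else {
    k <- seq_len(n - 1L)
    nk <- stats::rpois(n - 1L, params$theta_per_site * L / k)
    S <- sum(nk)
    S <- min(S, L)
    if (S > 0L) {
      kk <- rep(k, nk)[seq_len(S)]
      pos_list[[1]] <- sort(sample.int(L, S))
      car_list <- lapply(kk, function(x) sample.int(n, x))
    }
  }
  positions <- as.integer(unlist(pos_list, use.names = FALSE))
  S <- length(positions)
  haps <- matrix(FALSE, n, S)
  for (j in seq_len(S)) haps[car_list[[j]], j] <- TRUE
  o <- order(positions)
  structure(list(haps = haps[, o, drop = FALSE], positions = positions[o],
                 n = n, L = L), class = "haplotype_set")
}

#' Encode haplotypes to DNA sequences on a template
#'
#' Ancestral bases come from the template; at each segregating site the
#' derived base is drawn uniformly from the three alternatives (fixed per
#' site). The default template is a synthetic uniform-random ACGT sequence.
#'
#' @param haps A [simulate_haplotypes()] result.
#' @param template Character vector of single bases (length `>= L`) or a
#'   single string; `NULL` generates a random template. Templates containing
#'   `N` at a segregating site are rejected.
#' @return List with `sequences` (character vector of `n` DNA strings),
#'   `template` (character vector) and `derived_base` per segregating site.
#' @export
encode_to_dna <- function(haps, template = NULL) {
  L <- haps$L
  bases <- c("A", "C", "G", "T")
  if (is.null(template)) {
    template <- sample(bases, L, replace = TRUE)
  } else if (length(template) == 1L && nchar(template[1]) > 1L) {
    template <- strsplit(toupper(template), "", fixed = TRUE)[[1]]
  }
  if (length(template) < L) stop("template shorter than the locus")
  template <- template[seq_len(L)]
  if (any(!template[haps$positions] %in% bases))
    stop("template contains a non-ACGT base at a segregating site")
  oth <- rbind(c("C", "G", "T"), c("A", "G", "T"),
               c("A", "C", "T"), c("A", "C", "G"))
  rownames(oth) <- bases
  S <- length(haps$positions)
  anc <- template[haps$positions]
  derived <- oth[cbind(match(anc, bases),
                       sample.int(3L, S, replace = TRUE))]
  seqs <- character(haps$n)
  for (i in seq_len(haps$n)) {
    v <- template
    carry <- haps$haps[i, ]
    v[haps$positions[carry]] <- derived[carry]
    seqs[i] <- paste(v, collapse = "")
  }
  list(sequences = seqs, template = template, derived_base = derived)
}

#' Simulate pooled sequencing reads over a haplotype set
#'
#' Reads of `read_length` start at uniform positions on uniformly chosen
#' chromosomes until the mean depth reaches `target_coverage`; every base is
#' independently replaced by a uniformly chosen different base with
#' probability `error_rate`. Reads are placed at their true positions and
#' stacked directly into per-site allele counts (the pileup content at known
#' coordinates; mapping is bypassed). Simulated base qualities are constant
#' and above any filter threshold, so the error rate alone controls false
#' SNPs. Use [write_pileup()] to materialise the result as a pileup file.
#'
#' @param haps A [simulate_haplotypes()] result.
#' @param params A [sim_params()] (fields `target_coverage`, `error_rate`,
#'   `read_length` are used).
#' @param template Optional template passed to the base labelling; `NULL`
#'   draws a random one.
#' @param chrom Chromosome name in the output.
#' @return Site-count `data.table` (`chrom`, `pos`, `ref`, `A`, `C`, `G`,
#'   `T`, `cov`) for every position with nonzero depth.
#' @export
simulate_reads <- function(haps, params, template = NULL, chrom = "sim") {
  L <- haps$L; n <- haps$n
  rl <- min(params$read_length, L)
  e <- params$error_rate
  bases <- c("A", "C", "G", "T")
  if (is.null(template)) template <- sample(bases, L, replace = TRUE)
  tb <- match(template[seq_len(L)], bases)
  oth <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))

  n_reads <- max(1L, as.integer(round(params$target_coverage * L / rl)))
  starts <- sample.int(L - rl + 1L, n_reads, replace = TRUE)
  chroms <- sample.int(n, n_reads, replace = TRUE)
  add <- tabulate(starts, nbins = L)
  rem <- tabulate(starts + rl, nbins = L)
  depth <- cumsum(add - rem)

  # error bases at (mostly monomorphic) sites: depth split as ref-keeping
  # vs three alternative bases, each error base uniform among the three
  err <- stats::rbinom(L, depth, e)
  e1 <- stats::rbinom(L, err, 1 / 3)
  e2 <- stats::rbinom(L, err - e1, 1 / 2)
  e3 <- err - e1 - e2
  cnt <- matrix(0L, L, 4L)
  cnt[cbind(seq_len(L), tb)] <- depth - err
  cnt[cbind(seq_len(L), oth[tb, 1])] <- e1
  cnt[cbind(seq_len(L), oth[tb, 2])] <- e2
  cnt[cbind(seq_len(L), oth[tb, 3])] <- e3

  S <- length(haps$positions)
  if (S > 0L) {
    ord <- order(starts)
    sst <- starts[ord]; sch <- chroms[ord]
    p <- haps$positions
    lo <- findInterval(p - rl, sst) + 1L   # first read with start > p - rl
    hi <- findInterval(p, sst)             # last read with start <= p
    der <- integer(S); dep <- integer(S)
    for (j in seq_len(S)) {
      if (hi[j] < lo[j]) next
      cc <- sch[lo[j]:hi[j]]
      dep[j] <- length(cc)
      der[j] <- sum(haps$haps[cc, j])
    }
    anc <- dep - der
    # errors on ancestral-allele reads: 1/3 each to the three alternatives
    ae <- stats::rbinom(S, anc, e)
    a2d <- stats::rbinom(S, ae, 1 / 3)
    ao1 <- stats::rbinom(S, ae - a2d, 1 / 2)
    ao2 <- ae - a2d - ao1
    # errors on derived-allele reads: 1/3 back to ancestral, rest to others
    de <- stats::rbinom(S, der, e)
    d2a <- stats::rbinom(S, de, 1 / 3)
    do1 <- stats::rbinom(S, de - d2a, 1 / 2)
    do2 <- de - d2a - do1
    # base labels: derived is a random alternative; o1/o2 the remaining two
    der_idx <- sample.int(3L, S, replace = TRUE)
    alt <- oth[tb[p], , drop = FALSE]
    derb <- alt[cbind(seq_len(S), der_idx)]
    o1b <- alt[cbind(seq_len(S), ifelse(der_idx == 1L, 2L, 1L))]
    o2b <- alt[cbind(seq_len(S), ifelse(der_idx == 3L, 2L, 3L))]
    cnt[p, ] <- 0L
    cnt[cbind(p, tb[p])] <- anc - ae + d2a
    cnt[cbind(p, derb)] <- der - de + a2d
    cnt[cbind(p, o1b)] <- ao1 + do1
    cnt[cbind(p, o2b)] <- ao2 + do2
  }
  keep <- depth > 0L
  data.table::data.table(chrom = chrom, pos = which(keep),
                         ref = bases[tb[keep]],
                         A = cnt[keep, 1], C = cnt[keep, 2],
                         G = cnt[keep, 3], T = cnt[keep, 4],
                         cov = as.integer(rowSums(cnt[keep, , drop = FALSE])))
}

#' True summary statistics of a simulated haplotype set
#'
#' Classical (individual-sequencing) statistics computed directly from the
#' haplotype matrix: `theta_W = S / a_{n-1}`, `pi` from the unbiased per-site
#' heterozygosity `2 d (n - d) / (n (n - 1))` summed over sites, and
#' classical Tajima's D.
#'
#' @param haps A [simulate_haplotypes()] result.
#' @return List with locus-scale `S`, `theta_w`, `pi`, `tajima_d` and the
#'   per-site `theta_w_site`, `pi_site`.
#' @export
truth_stats <- function(haps) {
  n <- haps$n
  S <- ncol(haps$haps)
  a1 <- sum(1 / seq_len(n - 1))
  d <- colSums(haps$haps)
  pi_locus <- sum(2 * d * (n - d) / (n * (n - 1)))
  theta_w <- S / a1
  D <- NA_real_
  if (S > 0 && n >= 3) {
    k <- tajima_constants(n)
    v <- k$e1 * S + k$e2 * S * (S - 1)
    if (v > 0) D <- (pi_locus - theta_w) / sqrt(v)
  }
  list(S = S, theta_w = theta_w, pi = pi_locus, tajima_d = D,
       theta_w_site = theta_w / haps$L, pi_site = pi_locus / haps$L)
}

#' Pooled estimates over a whole simulated locus
#'
#' Runs the full estimation pipeline (site annotation, SNP calling,
#' per-coverage corrected contributions) on a simulated count table as a
#' single window spanning the locus.
#'
#' @param counts Site-count table from [simulate_reads()] or [read_pileup()].
#' @param params A [pool_params()].
#' @param L Locus length (for the window span).
#' @return One-row window statistics table (see [sliding_windows()]).
#' @export
locus_estimates <- function(counts, params, L) {
  sliding_windows(counts, window_spec(L, L, min_covered_fraction = 0),
                  params, chrom_lengths = stats::setNames(L, counts$chrom[1]))
}

#' Estimator bias experiment under sequencing error
#'
#' For each combination of target coverage, per-base error rate and minor
#' allele count, simulates `replicates` neutral haplotype sets (shared across
#' the grid within a replicate), samples error-bearing reads, runs the pooled
#' estimators over the full locus and reports the mean over replicates of the
#' relative absolute deviation `|observed - expected| / expected` against the
#' haplotype-truth values, for theta pi, theta Watterson and Tajima's D
#' (absolute deviation for D, whose truth can be near zero).
#'
#' @param params A [sim_params()]; its `target_coverage`/`error_rate` fields
#'   are overridden by the grid.
#' @param coverages,error_rates,min_counts Vectors whose full cross defines
#'   the grid (ignored when `grid` is given).
#' @param grid Optional `data.table` with columns `coverage`, `error_rate`,
#'   `min_count` listing exactly the cells to run.
#' @param verbose Print one line per cell.
#' @return `data.table` with one row per (coverage, error_rate, min_count):
#'   `dev_pi`, `dev_w` (mean relative absolute deviations) and `dev_d`
#'   (mean absolute deviation of D).
#' @export
run_bias_experiment <- function(params = sim_params(),
                                coverages = c(50, 100, 250),
                                error_rates = c(0.01, 0.002, 0.001),
                                min_counts = c(1L, 2L, 3L),
                                grid = NULL, verbose = FALSE) {
  if (is.null(grid))
    grid <- data.table::CJ(coverage = coverages, error_rate = error_rates,
                           min_count = as.integer(min_counts))
  grid <- data.table::as.data.table(grid)
  acc <- array(0, dim = c(nrow(grid), 3L))
  for (r in seq_len(params$replicates)) {
    haps <- simulate_haplotypes(params)
    truth <- truth_stats(haps)
    for (g in seq_len(nrow(grid))) {
      p2 <- params
      p2$target_coverage <- grid$coverage[g]
      p2$error_rate <- grid$error_rate[g]
      counts <- simulate_reads(haps, p2)
      pp <- suppressWarnings(pool_params(
        pool_size = params$n_chromosomes,
        min_count = grid$min_count[g],
        min_quality = 0L,
        min_coverage = 2L * grid$min_count[g]))
      est <- locus_estimates(counts, pp, haps$L)
      dev_pi <- abs(est$theta_pi - truth$pi_site) / truth$pi_site
      dev_w <- abs(est$theta_w - truth$theta_w_site) / truth$theta_w_site
      dev_d <- abs(est$tajima_d - truth$tajima_d)
      acc[g, ] <- acc[g, ] + c(dev_pi, dev_w, dev_d)
      if (verbose)
        message(sprintf("rep %d cov %g err %g b %d: dev_pi %.4f", r,
                        grid$coverage[g], grid$error_rate[g],
                        grid$min_count[g], dev_pi))
    }
  }
  grid[, `:=`(dev_pi = acc[, 1] / params$replicates,
              dev_w = acc[, 2] / params$replicates,
              dev_d = acc[, 3] / params$replicates)]
  grid[]
}
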