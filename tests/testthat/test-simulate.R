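test_that("segregating-site counts match the Watterson expectation", {
  set.seed(71)
  p <- sim_params(n_chromosomes = 20, locus_length = 20000,
                  theta_per_site = 0.005)
  a <- sum(1 / (1:19))
  expS <- 0.005 * 20000 * a
  S <- replicate(12, ncol(simulate_haplotypes(p)$haps))
  # S is a Poisson mixture with E[S] = theta * L * a_{n-1}
  expect_lt(abs(mean(S) - expS), 3 * sd(S) / sqrt(length(S)))
  # derived counts are polymorphic and positions unique and ordered
  h <- simulate_haplotypes(p)
  d <- colSums(h$haps)
  expect_true(all(d >= 1 & d <= 19))
  expect_true(!is.unsorted(h$positions) && !anyDuplicated(h$positions))
})

test_that("pairwise sample: every site is a singleton and pi estimates theta", {
  set.seed(72)
  p <- sim_params(n_chromosomes = 2, locus_length = 50000,
                  theta_per_site = 0.005)
  pis <- replicate(10, truth_stats(simulate_haplotypes(p))$pi_site)
  h <- simulate_haplotypes(p)
  expect_true(all(colSums(h$haps) == 1))
  expect_lt(abs(mean(pis) - 0.005), 3 * sd(pis) / sqrt(10))
})

test_that("direct SFS sampling matches the neutral theta/k expectation", {
  set.seed(73)
  n <- 10; L <- 10000; theta <- 0.005
  p <- sim_params(n_chromosomes = n, locus_length = L, theta_per_site = theta)
  counts <- integer(n - 1)
  reps <- 20
  for (r in 1:reps) {
    h <- simulate_haplotypes(p, mode = "sfs")
    counts <- counts + tabulate(colSums(h$haps), nbins = n - 1)
  }
  expected <- reps * theta * L / (1:(n - 1))
  # pooled over classes, Poisson: 3 SE on the total and per binned class
  expect_lt(abs(sum(counts) - sum(expected)), 3 * sqrt(sum(expected)))
  for (k in 1:3)
    expect_lt(abs(counts[k] - expected[k]), 3 * sqrt(expected[k]))
})

test_that("DNA encoding round-trips the haplotype matrix", {
  set.seed(74)
  p <- sim_params(n_chromosomes = 8, locus_length = 500,
                  theta_per_site = 0.02)
  h <- simulate_haplotypes(p)
  enc <- encode_to_dna(h)
  expect_equal(nchar(enc$sequences), rep(500L, 8))
  # decode: a sequence differs from the template exactly at carried sites
  mat <- do.call(rbind, strsplit(enc$sequences, ""))
  tmpl <- matrix(enc$template, nrow = 8, ncol = 500, byrow = TRUE)
  diffs <- mat != tmpl
  recovered <- diffs[, h$positions, drop = FALSE]
  expect_equal(recovered, unname(h$haps))
  expect_true(all(!diffs[, -h$positions]))

  # zero segregating sites -> all sequences equal the template
  p0 <- sim_params(n_chromosomes = 4, locus_length = 100,
                   theta_per_site = 1e-9)
  h0 <- simulate_haplotypes(p0)
  if (ncol(h0$haps) == 0) {
    e0 <- encode_to_dna(h0)
    expect_equal(unique(e0$sequences), paste(e0$template, collapse = ""))
  }
  expect_error(encode_to_dna(h, template = rep("A", 10)), "shorter")
})

test_that("read simulation reproduces depth and error-rate targets", {
  set.seed(75)
  p <- sim_params(n_chromosomes = 10, locus_length = 20000,
                  theta_per_site = 0.001, error_rate = 0.01,
                  target_coverage = 30, read_length = 50)
  h <- simulate_haplotypes(p)
  cnt <- simulate_reads(h, p)
  interior <- cnt[cnt$pos > 50 & cnt$pos < 19950]
  expect_lt(abs(mean(interior$cov) - 30), 1)
  # fraction of non-reference bases at monomorphic sites ~ error rate
  mono <- interior[!interior$pos %in% h$positions]
  mism <- sum(mono$cov) - sum(as.matrix(mono[, c("A", "C", "G", "T")])[
    cbind(seq_len(nrow(mono)), match(mono$ref, c("A", "C", "G", "T")))])
  frac <- mism / sum(mono$cov)
  se <- sqrt(0.01 * 0.99 / sum(mono$cov))
  expect_lt(abs(frac - 0.01), 3 * se)

  # error-free reads carry only the two true alleles
  p0 <- p; p0$error_rate <- 0
  cnt0 <- simulate_reads(h, p0)
  mono0 <- cnt0[!cnt0$pos %in% h$positions]
  refcol <- as.matrix(mono0[, c("A", "C", "G", "T")])[
    cbind(seq_len(nrow(mono0)), match(mono0$ref, c("A", "C", "G", "T")))]
  expect_equal(as.integer(refcol), mono0$cov)
})

test_that("pool allele counts at sites follow the binomial sampling model", {
  set.seed(76)
  # one site carried by k of n chromosomes: reads at that site are Binomial
  n <- 10; k <- 3
  p <- sim_params(n_chromosomes = n, locus_length = 300,
                  theta_per_site = 1e-9, error_rate = 0,
                  target_coverage = 40, read_length = 50)
  h <- simulate_haplotypes(p)
  h$haps <- matrix(seq_len(n) <= k, n, 1)
  h$positions <- 150L
  reps <- 300
  der <- dep <- numeric(reps)
  for (r in seq_len(reps)) {
    cnt <- simulate_reads(h, p)
    row <- cnt[cnt$pos == 150L]
    cc <- as.matrix(row[, c("A", "C", "G", "T")])
    dep[r] <- sum(cc)
    der[r] <- dep[r] - cc[match(row$ref, c("A", "C", "G", "T"))]
  }
  # conditional on depth, the derived read count is Binomial(depth, k/n)
  frac <- sum(der) / sum(dep)
  se <- sqrt((k / n) * (1 - k / n) / sum(dep))
  expect_lt(abs(frac - k / n), 3 * se)
})

test_that("truth statistics match brute-force pairwise comparison", {
  haps <- matrix(c(1, 0, 0, 0,
                   1, 1, 0, 0), nrow = 4)   # 4 chromosomes, 2 sites
  hs <- structure(list(haps = haps == 1, positions = c(10L, 20L),
                       n = 4L, L = 100L), class = "haplotype_set")
  ts <- truth_stats(hs)
  # exhaustive pairwise differences
  pd <- 0
  for (i in 1:3) for (j in (i + 1):4)
    pd <- pd + sum(haps[i, ] != haps[j, ])
  expect_equal(ts$pi, pd / choose(4, 2))
  expect_equal(ts$theta_w, 2 / sum(1 / (1:3)))
  expect_equal(ts$S, 2)

  # singletons only: positive-skewed spectrum, D < 0
  hs2 <- structure(list(haps = diag(8) == 1, positions = 1:8,
                        n = 8L, L = 100L), class = "haplotype_set")
  ts2 <- truth_stats(hs2)
  expect_gt(ts2$theta_w, ts2$pi)
  expect_lt(ts2$tajima_d, 0)

  # empty matrix: theta zero, D undefined
  hs0 <- structure(list(haps = matrix(FALSE, 4, 0), positions = integer(),
                        n = 4L, L = 100L), class = "haplotype_set")
  expect_equal(truth_stats(hs0)$theta_w, 0)
  expect_true(is.na(truth_stats(hs0)$tajima_d))
})

test_that("seeded simulations are reproducible", {
  p <- sim_params(n_chromosomes = 10, locus_length = 2000,
                  target_coverage = 20)
  set.seed(77); h1 <- simulate_haplotypes(p); c1 <- simulate_reads(h1, p)
  set.seed(77); h2 <- simulate_haplotypes(p); c2 <- simulate_reads(h2, p)
  expect_identical(h1$positions, h2$positions)
  expect_identical(h1$haps, h2$haps)
  expect_identical(c1, c2)
})

test_that("simulated counts survive the pileup text round trip", {
  set.seed(78)
  p <- sim_params(n_chromosomes = 10, locus_length = 1000,
                  theta_per_site = 0.01, error_rate = 0.01,
                  target_coverage = 20)
  h <- simulate_haplotypes(p)
  cnt <- simulate_reads(h, p)
  tmp <- tempfile(fileext = ".pileup")
  write_pileup(cnt, tmp)
  back <- read_pileup(tmp, min_base_quality = 0)
  expect_equal(back$pos, cnt$pos)
  expect_equal(back[, c("A", "C", "G", "T", "cov")],
               cnt[, c("A", "C", "G", "T", "cov")])
})
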