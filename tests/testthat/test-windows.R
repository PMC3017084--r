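pp_default <- function(n = 50, b = 2)
  suppressWarnings(pool_params(n, b, min_quality = 0, min_coverage = 4))

test_that("windows tile the chromosome and partition sites", {
  set.seed(51)
  counts <- random_counts(100, max_pos = 100)
  counts <- counts[1:100][, pos := 1:100]  # dense 1..100
  pp <- pp_default()
  w1 <- sliding_windows(counts, window_spec(50, 50, 0), pp)
  expect_equal(nrow(w1), 2)
  expect_equal(w1$start, c(1L, 51L))
  expect_equal(w1$end, c(50L, 100L))
  # non-overlapping windows partition the called SNPs
  ann <- annotate_sites(counts, pp)
  expect_equal(sum(w1$snp_count), sum(ann$is_snp))

  # overlapping windows: interior sites contribute to exactly 2 windows
  w2 <- sliding_windows(counts, window_spec(50, 25, 0), pp)
  brute <- sapply(seq_len(nrow(w2)), function(i)
    sum(ann$is_snp & ann$pos >= w2$start[i] & ann$pos <= w2$end[i]))
  expect_equal(w2$snp_count, brute)
  interior <- sum(ann$is_snp & ann$pos > 25 & ann$pos <= 75)
  expect_equal(sum(w2$snp_count) - sum(w1$snp_count), interior)

  expect_error(sliding_windows(counts[c(2, 1, 3:100)], window_spec(50), pp),
               "sorted")
})

test_that("window statistics match a direct single-window computation", {
  set.seed(52)
  counts <- random_counts(80, max_pos = 500)
  pp <- pp_default(n = 30)
  w <- sliding_windows(counts, window_spec(500, 500, 0), pp,
                       chrom_lengths = c(chr1 = 500))
  ann <- annotate_sites(counts, pp)
  tab <- correction_tables(30, 2)
  snp <- ann[ann$is_snp]
  expect_equal(w$theta_w,
               theta_w_window(snp$cov, sum(ann$eligible), tab))
  expect_equal(w$theta_pi,
               theta_pi_window(snp$h, snp$cov, sum(ann$eligible), tab))
  expect_equal(w$covered_fraction, sum(ann$eligible) / 500)
})

test_that("GTF regions merge and restrict/mask behave as complements", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t5\t20\t.\t+\t.\tgene_id "g1";',
    'chr1\tsrc\texon\t15\t30\t.\t+\t.\tgene_id "g1";',
    'chr1\tsrc\texon\t40\t60\t.\t-\t.\tgene_id "g2";',
    'chr2\tsrc\texon\t1\t10\t.\t+\t.\tgene_id "g3";'), gtf)
  rs <- load_gtf(gtf, "restrict")
  iv <- rs$intervals[rs$intervals$chrom == "chr1"]
  expect_equal(iv$start, c(5L, 40L))   # overlapping features merged
  expect_equal(iv$end, c(30L, 60L))
  expect_equal(in_regions(rs, "chr1", c(4, 5, 30, 31, 45)),
               c(FALSE, TRUE, TRUE, FALSE, TRUE))

  bad <- tempfile(); writeLines("chr1\ts\te\t10\t5\t.\t+\t.\tx", bad)
  expect_error(load_gtf(bad), "end < start")

  empty <- tempfile(); writeLines(character(0), empty)
  ers <- load_gtf(empty, "restrict")
  set.seed(53)
  counts <- random_counts(100, max_pos = 100)
  pp <- pp_default()
  wempty <- sliding_windows(counts, window_spec(50, 50, 0.1), pp,
                            regions = ers)
  expect_true(all(wempty$covered_fraction == 0))
  expect_true(all(is.na(wempty$theta_pi)))

  # masking R equals restricting to its complement
  mask <- region_set(data.table::data.table(chrom = "chr1",
                                            start = c(10L, 60L),
                                            end = c(30L, 80L)), "mask")
  comp <- region_set(data.table::data.table(chrom = "chr1",
                                            start = c(1L, 31L, 81L),
                                            end = c(9L, 59L, 100L)),
                     "restrict")
  wm <- sliding_windows(counts, window_spec(25, 25, 0), pp, regions = mask)
  wc <- sliding_windows(counts, window_spec(25, 25, 0), pp, regions = comp)
  expect_equal(wm, wc)
})

test_that("restrict mode counts only in-region sites as covered", {
  counts <- data.table::data.table(
    chrom = "chr1", pos = 1:100, ref = "A",
    A = 10L, C = 10L, G = 0L, T = 0L, cov = 20L)
  rs <- region_set(data.table::data.table(chrom = "chr1", start = 1L,
                                          end = 10L), "restrict")
  w <- sliding_windows(counts, window_spec(50, 50, 0), pp_default(),
                       regions = rs)
  expect_equal(w$covered_fraction, c(10 / 50, 0))
  expect_equal(w$snp_count, c(10L, 0L))
})

test_that("wiggle output follows the variableStep contract and round-trips", {
  set.seed(54)
  counts <- random_counts(200, max_pos = 200)
  pp <- pp_default()
  w <- sliding_windows(counts, window_spec(50, 50, 0), pp,
                       chrom_lengths = c(chr1 = 200))
  path <- tempfile(fileext = ".wig")
  write_wiggle(w, "theta_pi", path, span = 50)
  lines <- readLines(path)
  expect_equal(lines[1], "variableStep chrom=chr1 span=50")
  defined <- w[!is.na(w$theta_pi)]
  expect_equal(length(lines), 1 + nrow(defined))
  parsed <- read.table(text = lines[-1])
  expect_equal(parsed$V1, defined$start)
  expect_equal(parsed$V2, round(defined$theta_pi, 8))

  tsv <- tempfile(fileext = ".tsv")
  write_window_tsv(w, "theta_pi", tsv)
  back <- data.table::fread(tsv, na.strings = "na")
  expect_equal(back$value, w$theta_pi)

  png <- tempfile(fileext = ".png")
  pdat <- plot_windows(w, "theta_pi", png)
  expect_gt(file.size(png), 0)
  expect_equal(pdat$value, defined$theta_pi)
  expect_error(plot_windows(w[0], "theta_pi", png), "no defined windows")
})

test_that("windows below the covered-fraction cutoff are undefined", {
  counts <- data.table::data.table(
    chrom = "chr1", pos = c(1:30, 95:100), ref = "A",
    A = 10L, C = 10L, G = 0L, T = 0L, cov = 20L)
  w <- sliding_windows(counts, window_spec(50, 50, 0.6), pp_default(),
                       chrom_lengths = c(chr1 = 100))
  expect_false(is.na(w$theta_pi[1]))   # 30/50 covered
  expect_true(is.na(w$theta_pi[2]))    # 6/50 covered
  expect_equal(w$snp_count[2], 6L)     # counts still reported
})
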