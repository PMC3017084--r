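# shared fixture builders; everything is generated in code at test time

# random read with qualities in [0, 40] and occasional N bases
random_read <- function(len, n_prob = 0.05) {
  bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  if (n_prob > 0) {
    nn <- runif(len) < n_prob
    bases[nn] <- "N"
  }
  q <- sample(0:40, len, replace = TRUE)
  list(bases = paste(bases, collapse = ""),
       quals = intToUtf8(q + 33L), q = q)
}

# exhaustive maximum-sum substring over all O(L^2) substrings via prefix
# sums; tie-break: max sum, then smallest start, then largest end.
# Returns c(start0, end) half-open, or NULL if the best sum <= 0.
brute_max_substring <- function(scores) {
  L <- length(scores)
  P <- c(0, cumsum(scores))
  best <- NULL
  for (i in seq_len(L)) {
    for (j in i:L) {
      s <- P[j + 1] - P[i]
      if (s <= 0) next
      if (is.null(best) || s > best[1] ||
          (s == best[1] && (i - 1 < best[2] ||
                            (i - 1 == best[2] && j > best[3]))))
        best <- c(s, i - 1, j)
    }
  }
  if (is.null(best)) NULL else best[2:3]
}

# a random site-count table on distinct sorted positions
random_counts <- function(n_sites, chrom = "chr1", max_pos = n_sites * 3,
                          lambda = 30) {
  pos <- sort(sample.int(max_pos, n_sites))
  mat <- matrix(stats::rpois(n_sites * 4, lambda / 4), n_sites, 4)
  data.table::data.table(chrom = chrom, pos = pos,
                         ref = sample(c("A", "C", "G", "T"), n_sites,
                                      replace = TRUE),
                         A = mat[, 1], C = mat[, 2], G = mat[, 3],
                         T = mat[, 4], cov = as.integer(rowSums(mat)))
}

# synthesize a pileup line from explicit calls and qualities
make_pileup_line <- function(chrom, pos, ref, calls, quals_phred,
                             offset = 33L) {
  enc <- ifelse(calls == ref, ".", calls)
  paste(chrom, pos, ref, length(calls), paste(enc, collapse = ""),
        intToUtf8(quals_phred + offset), sep = "\t")
}

# Monte-Carlo estimate of the truncated correction denominators:
# k sampled from the normalized 1/k neutral spectrum, m ~ Binomial(C, k/n)
mc_denominators <- function(C, n, b, reps = 50000) {
  a <- sum(1 / seq_len(n - 1))
  k <- sample.int(n - 1, reps, replace = TRUE, prob = 1 / seq_len(n - 1))
  m <- stats::rbinom(reps, C, k / n)
  keep <- as.numeric(m >= b & m <= C - b)
  wgt <- keep * 2 * m * (C - m) / (C * (C - 1))
  list(w = a * mean(keep), w_se = a * stats::sd(keep) / sqrt(reps),
       p = a * mean(wgt), p_se = a * stats::sd(wgt) / sqrt(reps))
}
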