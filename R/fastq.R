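#' Read a FASTQ file
#'
#' Plain or gzipped four-line-record FASTQ. Identifiers keep everything after
#' the leading `@`.
#'
#' @param path FASTQ file.
#' @param offset Phred ASCII offset: 33 (Sanger/modern Illumina) or 64
#'   (Illumina 1.3-1.7 era).
#' @return A `data.table` with columns `id`, `bases`, `quals` (quality string)
#'   and attribute `offset`.
#' @export
read_fastq <- function(path, offset = 33L) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ (line count not a multiple of 4): ", path)
  ii <- seq(1, length(lines), by = 4)
  dt <- data.table::data.table(
    id = sub("^@", "", lines[ii]),
    bases = lines[ii + 1],
    quals = lines[ii + 3])
  if (any(nchar(dt$bases) != nchar(dt$quals)))
    stop("FASTQ record with differing sequence and quality lengths in ", path)
  data.table::setattr(dt, "offset", as.integer(offset))
  dt
}

#' Write a FASTQ file
#'
#' @param reads `data.table` with `id`, `bases`, `quals` columns.
#' @param path Output path (gzipped if it ends in `.gz`).
#' @export
write_fastq <- function(reads, path) {
  out <- as.vector(rbind(paste0("@", reads$id), reads$bases,
                         "+", reads$quals))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Decode a quality string to Phred scores
#'
#' @param qual Quality string.
#' @param offset ASCII offset (33 or 64).
#' @return Integer vector of Phred scores.
#' @export
phred_scores <- function(qual, offset = 33L) {
  utf8ToInt(qual) - as.integer(offset)
}

#' Trimming parameters
#'
#' @param quality_threshold Phred threshold subtracted from every base
#'   quality before scoring (0 disables quality trimming and only strips
#'   terminal N runs when `drop_trailing_N`).
#' @param min_length Minimum kept length for a read to survive.
#' @param drop_trailing_N Strip leading/trailing `N` runs before scoring.
#' @param offset Phred ASCII offset of the input.
#' @return List of class `trim_params`.
#' @export
trim_params <- function(quality_threshold = 20, min_length = 40,
                        drop_trailing_N = TRUE, offset = 33L) {
  stopifnot(quality_threshold >= 0, min_length >= 1)
  structure(list(quality_threshold = quality_threshold,
                 min_length = as.integer(min_length),
                 drop_trailing_N = isTRUE(drop_trailing_N),
                 offset = as.integer(offset)),
            class = "trim_params")
}

# maximum-sum contiguous substring of scores, leftmost-longest tie-break:
# among equal sums prefer the smallest start, then the largest end.
# Returns c(start, end) 0-based half-open, or NULL when the best sum <= 0.
.max_sum_substring <- function(scores) {
  L <- length(scores)
  if (L == 0) return(NULL)
  P <- c(0, cumsum(scores))            # P[t+1] = sum(scores[1:t])
  pre <- P[1:L]                        # prefixes available as start points
  cm <- cummin(pre)
  # index (1-based into pre) of the FIRST occurrence of the running minimum
  rec <- ifelse(pre < c(Inf, cm[-L]), seq_len(L), 0L)
  first_min <- cummax(rec)
  sums <- P[2:(L + 1)] - cm            # best sum ending at each position
  best <- max(sums)
  if (best <= 0) return(NULL)
  cand <- which(sums == best)
  starts <- first_min[cand]
  keep <- cand[starts == min(starts)]
  c(min(starts) - 1L, max(keep))       # 0-based half-open
}

#' Modified Mott quality trimming of one read
#'
#' Scores every base as `quality - quality_threshold` and keeps the contiguous
#' substring with the maximum score sum (ties broken leftmost, then longest),
#' trimming the read from either side. `N` bases carry quality 0; terminal `N`
#' runs are removed before scoring when `drop_trailing_N` is set. A read is
#' rejected when the best sum is not positive (no stretch of informative
#' bases) or the kept substring is shorter than `min_length`.
#'
#' @param bases Base string (may contain `N`).
#' @param quals Quality string, same length.
#' @param params A [trim_params()] object.
#' @param id Optional identifier carried through.
#' @return A list with `id`, `kept_start`, `kept_end` (0-based half-open
#'   coordinates into the original read), `bases`, `quals`; or `NULL` when
#'   the read is rejected.
#' @export
mott_trim <- function(bases, quals, params = trim_params(), id = NULL) {
  if (nchar(bases) != nchar(quals))
    stop("malformed read: bases and qualities differ in length")
  q <- phred_scores(quals, params$offset)
  if (any(q < 0)) stop("negative Phred score; check the quality offset")
  bvec <- strsplit(bases, "", fixed = TRUE)[[1]]
  is_n <- bvec == "N" | bvec == "n"
  q[is_n] <- 0L
  lo <- 1L; hi <- length(q)
  if (params$drop_trailing_N) {
    while (lo <= hi && is_n[lo]) lo <- lo + 1L
    while (hi >= lo && is_n[hi]) hi <- hi - 1L
  }
  if (hi < lo) return(NULL)
  span <- .max_sum_substring(q[lo:hi] - params$quality_threshold)
  if (is.null(span)) return(NULL)
  s <- span[1] + lo - 1L   # 0-based into original read
  e <- span[2] + lo - 1L
  if (e - s < params$min_length) return(NULL)
  list(id = id, kept_start = s, kept_end = e,
       bases = substr(bases, s + 1L, e),
       quals = substr(quals, s + 1L, e))
}

#' Trim a batch of reads and aggregate trimming statistics
#'
#' Applies [mott_trim()] to every read and summarises the survivors with the
#' four standard trimming statistics: percent of reads passing, total and mean
#' kept read length, and mean base quality over kept bases.
#'
#' @param reads `data.table` from [read_fastq()] (columns `id`, `bases`,
#'   `quals`).
#' @param params A [trim_params()].
#' @return List with `reads` (trimmed survivors, same columns plus
#'   `kept_start`, `kept_end`) and `stats` (list: `n_in`, `n_kept`,
#'   `pct_reads_passing`, `sum_read_length`, `mean_read_length`,
#'   `mean_quality`).
#' @export
trim_reads <- function(reads, params = trim_params()) {
  n_in <- nrow(reads)
  kept <- vector("list", n_in)
  for (i in seq_len(n_in)) {
    kept[[i]] <- mott_trim(reads$bases[i], reads$quals[i], params,
                           id = reads$id[i])
  }
  kept <- kept[!vapply(kept, is.null, TRUE)]
  out <- data.table::data.table(
    id = vapply(kept, `[[`, "", "id"),
    bases = vapply(kept, `[[`, "", "bases"),
    quals = vapply(kept, `[[`, "", "quals"),
    kept_start = vapply(kept, function(x) x$kept_start, 0L),
    kept_end = vapply(kept, function(x) x$kept_end, 0L))
  list(reads = out, stats = trim_stats(out, n_in, params$offset))
}

#' Trimming summary statistics
#'
#' @param kept `data.table` of surviving reads (`bases`, `quals`).
#' @param n_in Number of input reads.
#' @param offset Phred ASCII offset.
#' @return List with the four summary statistics; zero counts give a defined
#'   empty result (`NaN` means, 0 sums).
#' @export
trim_stats <- function(kept, n_in, offset = 33L) {
  lens <- nchar(kept$bases)
  qsum <- if (nrow(kept)) sum(vapply(kept$quals,
                                     function(s) sum(phred_scores(s, offset)),
                                     0, USE.NAMES = FALSE)) else 0
  list(n_in = n_in,
       n_kept = nrow(kept),
       pct_reads_passing = if (n_in > 0) 100 * nrow(kept) / n_in else 0,
       sum_read_length = sum(lens),
       mean_read_length = if (nrow(kept)) mean(lens) else NaN,
       mean_quality = if (sum(lens) > 0) qsum / sum(lens) else NaN)
}

#' Trim a FASTQ file end to end
#'
#' @param input,output FASTQ paths (gz accepted for input; output gz if the
#'   name ends in `.gz`).
#' @param params A [trim_params()].
#' @return The trimming statistics list, invisibly printed by the CLI.
#' @export
trim_fastq <- function(input, output, params = trim_params()) {
  res <- trim_reads(read_fastq(input, params$offset), params)
  write_fastq(res$reads, output)
  res$stats
}
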