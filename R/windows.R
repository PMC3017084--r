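#' Sliding-window specification
#'
#' @param window_size Window length in bp.
#' @param step_size Step between window starts in bp; equal to `window_size`
#'   for non-overlapping tiling, smaller for overlapping windows.
#' @param min_covered_fraction Minimum fraction of window sites that must be
#'   covered for the window's statistics to be reported (others get `NA`).
#' @return List of class `window_spec`.
#' @export
window_spec <- function(window_size, step_size = window_size,
                        min_covered_fraction = 0.6) {
  stopifnot(window_size >= 1, step_size >= 1,
            min_covered_fraction >= 0, min_covered_fraction <= 1)
  structure(list(window_size = as.integer(window_size),
                 step_size = as.integer(step_size),
                 min_covered_fraction = min_covered_fraction),
            class = "window_spec")
}

#' Load a GTF file as a region set
#'
#' Reads the chrom/start/end columns of a GTF (1-based inclusive
#' coordinates), merging overlapping or adjacent features per chromosome.
#' The region set either restricts the analysis to these intervals or masks
#' them out, depending on `mode`.
#'
#' @param path GTF file.
#' @param mode `"restrict"` (analyse only these regions) or `"mask"`
#'   (exclude them).
#' @return List of class `region_set` with a merged interval `data.table`
#'   (`chrom`, `start`, `end`) and the `mode`.
#' @export
load_gtf <- function(path, mode = c("restrict", "mask")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) return(region_set(data.table::data.table(
    chrom = character(), start = integer(), end = integer()), mode))
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  if (length(f) < 5) stop("malformed GTF: fewer than 5 tab-separated columns")
  dt <- data.table::data.table(chrom = f[[1]],
                               start = as.integer(f[[4]]),
                               end = as.integer(f[[5]]))
  if (any(is.na(dt$start) | is.na(dt$end)))
    stop("malformed GTF: non-numeric start/end")
  if (any(dt$end < dt$start)) stop("malformed GTF: end < start")
  region_set(dt, mode)
}

#' Build a region set from intervals
#'
#' Intervals are normalised (sorted and merged) per chromosome with
#' `IRanges::reduce`.
#'
#' @param intervals `data.table`/data.frame with `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param mode `"restrict"` or `"mask"`.
#' @return `region_set` object.
#' @export
region_set <- function(intervals, mode = c("restrict", "mask")) {
  mode <- match.arg(mode)
  dt <- data.table::as.data.table(intervals)
  if (nrow(dt)) {
    merged <- dt[, {
      r <- IRanges::reduce(IRanges::IRanges(start, end))
      list(start = IRanges::start(r), end = IRanges::end(r))
    }, by = "chrom"]
    data.table::setkeyv(merged, c("chrom", "start"))
  } else merged <- dt
  structure(list(intervals = merged, mode = mode), class = "region_set")
}

#' Test positions for membership in a region set's intervals
#'
#' @param regions A [region_set()].
#' @param chrom Chromosome (scalar).
#' @param pos Positions (vector).
#' @return Logical: `TRUE` where the position falls inside an interval.
#' @export
in_regions <- function(regions, chrom, pos) {
  sel <- which(regions$intervals$chrom == chrom)  # evaluate outside `[` NSE
  iv <- regions$intervals[sel]
  if (nrow(iv) == 0) return(rep(FALSE, length(pos)))
  idx <- findInterval(pos, iv$start)
  idx >= 1 & pos <= iv$end[pmax(idx, 1L)]
}

# logical keep-mask for sites given an optional region set
.region_keep <- function(regions, chrom, pos) {
  if (is.null(regions)) return(rep(TRUE, length(pos)))
  inr <- in_regions(regions, chrom, pos)
  if (regions$mode == "restrict") inr else !inr
}

#' Sliding-window population genetics scan
#'
#' Tiles every chromosome with windows of `window_size` starting every
#' `step_size` bp (1-based inclusive coordinates) and computes per window:
#' the SNP count S, the pooled corrected per-site Watterson theta and pi,
#' the truncated-spectrum Tajima's D, the covered fraction and the mean
#' coverage of covered sites. Sites outside a restrict-mode region set (or
#' inside a mask-mode one) are treated as uncovered, as are sites absent
#' from the table or with inadmissible coverage. Windows whose covered
#' fraction is below `spec$min_covered_fraction` report `NA` statistics.
#'
#' @param counts Site-count `data.table` (see [read_pileup()]), sorted by
#'   chromosome and position.
#' @param spec A [window_spec()].
#' @param params A [pool_params()].
#' @param regions Optional [region_set()].
#' @param chrom_lengths Optional named vector of chromosome lengths; defaults
#'   to the last covered position per chromosome. The final window is
#'   truncated at the chromosome end and flagged `partial`.
#' @param normalize `"covered"` divides window sums by the number of covered
#'   sites; `"length"` divides by the window span.
#' @return `data.table` with one row per window: `chrom`, `start`, `end`,
#'   `snp_count`, `theta_w`, `theta_pi`, `tajima_d`, `covered_fraction`,
#'   `mean_coverage`, `partial`.
#' @export
sliding_windows <- function(counts, spec, params, regions = NULL,
                            chrom_lengths = NULL,
                            normalize = c("covered", "length")) {
  normalize <- match.arg(normalize)
  dt <- data.table::as.data.table(counts)
  # enforce sorted input (streaming contract)
  bad <- dt[, which(diff(pos) <= 0)[1], by = "chrom"]$V1
  bad <- bad[!is.na(bad)]
  if (length(bad))
    stop("pileup sites not sorted by position (first offence after row ",
         bad[1], " within its chromosome)")
  tables <- correction_tables(params$pool_size, params$min_count)
  consts <- tajima_constants(params$pool_size)
  w <- spec$window_size; s <- spec$step_size
  out <- list()
  for (ch in unique(dt$chrom)) {
    d <- dt[dt$chrom == ch]
    d <- annotate_sites(d, params)
    keep <- .region_keep(regions, ch, d$pos)
    d[, covered := eligible & keep]
    clen <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      as.integer(chrom_lengths[[ch]]) else max(d$pos)
    n_win <- max(1L, as.integer(ceiling((clen - w) / s)) + 1L)
    if ((n_win - 1L) * s + 1L > clen) n_win <- max(1L, n_win - 1L)
    starts <- (seq_len(n_win) - 1L) * s + 1L
    ends <- pmin(starts + w - 1L, clen)
    # per-site estimator contributions on covered SNP sites
    wc <- pc <- numeric(nrow(d))
    sel <- which(d$covered & d$is_snp)
    if (length(sel)) {
      wc[sel] <- 1 / watterson_denominator(d$cov[sel], tables = tables)
      pc[sel] <- d$h[sel] / pi_denominator(d$cov[sel], tables = tables)
    }
    data.table::set(d, j = "wc", value = wc)
    data.table::set(d, j = "pc", value = pc)
    # expand each site to every window covering it
    w_hi <- pmin((d$pos - 1L) %/% s + 1L, n_win)
    w_lo <- pmax(1L, ((d$pos - w) %/% s) + 1L + as.integer((d$pos - w) %% s > 0))
    w_lo <- pmin(w_lo, w_hi)
    reps <- w_hi - w_lo + 1L
    idx <- rep(seq_len(nrow(d)), reps)
    wid <- rep(w_lo, reps) + sequence(reps) - 1L
    dd <- d[idx]
    dd[, win := wid]
    agg <- dd[, list(snp_count = sum(covered & is_snp),
                     wsum = sum(wc[covered]),
                     psum = sum(pc[covered]),
                     n_cov = sum(covered),
                     cov_sum = sum(cov[covered])), by = "win"]
    res <- data.table::data.table(chrom = ch, start = starts, end = ends,
                                  win = seq_len(n_win))
    res <- merge(res, agg, by = "win", all.x = TRUE)
    for (jj in c("snp_count", "wsum", "psum", "n_cov", "cov_sum"))
      res[is.na(get(jj)), (jj) := 0]
    span <- res$end - res$start + 1L
    denom <- if (normalize == "covered") res$n_cov else span
    res[, `:=`(covered_fraction = n_cov / span,
               mean_coverage = ifelse(n_cov > 0, cov_sum / n_cov, NA_real_),
               theta_w = ifelse(denom > 0, wsum / denom, NA_real_),
               theta_pi = ifelse(denom > 0, psum / denom, NA_real_),
               partial = span < w)]
    res[, tajima_d := mapply(tajima_d_window, snp_count, psum, wsum,
                             MoreArgs = list(n = params$pool_size,
                                             constants = consts))]
    low <- res$covered_fraction < spec$min_covered_fraction
    res[low, c("theta_w", "theta_pi", "tajima_d") := NA_real_]
    res[, c("win", "wsum", "psum", "cov_sum", "n_cov") := NULL]
    out[[ch]] <- res
  }
  data.table::rbindlist(out)[, c("chrom", "start", "end", "snp_count",
                                 "covered_fraction", "mean_coverage",
                                 "theta_w", "theta_pi", "tajima_d",
                                 "partial"), with = FALSE]
}

#' Write window statistics as UCSC wiggle
#'
#' One `variableStep chrom=<chrom> span=<step>` block per chromosome; one
#' `<window_start> <value>` line per defined window, values with 8 decimal
#' places. Windows with `NA` for the chosen measure are omitted.
#'
#' @param windows Output of [sliding_windows()].
#' @param measure Column to export: `"theta_w"`, `"theta_pi"` or
#'   `"tajima_d"`.
#' @param path Output file.
#' @param span Span written in the header (conventionally the step size).
#' @export
write_wiggle <- function(windows, measure, path, span = NULL) {
  stopifnot(measure %in% names(windows))
  if (is.null(span)) span <- windows$end[1] - windows$start[1] + 1L
  lines <- character()
  for (ch in unique(windows$chrom)) {
    d <- windows[windows$chrom == ch]
    d <- d[!is.na(d[[measure]])]
    if (nrow(d) == 0) next
    lines <- c(lines, sprintf("variableStep chrom=%s span=%d", ch,
                              as.integer(span)),
               sprintf("%d %.8f", d$start, d[[measure]]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write window statistics as TSV
#'
#' Columns chrom, start, end, snp_count, covered_fraction, mean_coverage and
#' the requested value; undefined entries written as `"na"`.
#'
#' @inheritParams write_wiggle
#' @export
write_window_tsv <- function(windows, measure, path) {
  stopifnot(measure %in% names(windows))
  out <- windows[, c("chrom", "start", "end", "snp_count", "covered_fraction",
                     "mean_coverage"), with = FALSE]
  out[, value := windows[[measure]]]
  data.table::fwrite(out, path, sep = "\t", na = "na", quote = FALSE)
  invisible(path)
}

#' Plot a windowed statistic along the genome
#'
#' Line plot of the chosen statistic against window midpoint, with an
#' optional second track (typically divergence) overlaid.
#'
#' @param windows Output of [sliding_windows()].
#' @param measure Column to plot.
#' @param path PNG output path.
#' @param overlay Optional `data.table` with `start`, `end` and `value`
#'   columns (e.g. windowed dxy) drawn as a second line.
#' @param main Plot title.
#' @return The plotted `(position, value)` data, invisibly.
#' @export
plot_windows <- function(windows, measure, path, overlay = NULL,
                         main = measure) {
  d <- windows[!is.na(windows[[measure]])]
  if (nrow(d) == 0) stop("no defined windows to plot")
  x <- (d$start + d$end) / 2
  y <- d[[measure]]
  grDevices::png(path, width = 900, height = 450)
  on.exit(grDevices::dev.off())
  ylim <- range(c(y, if (!is.null(overlay)) overlay$value), na.rm = TRUE)
  graphics::plot(x, y, type = "l", xlab = "position (bp)", ylab = measure,
                 main = main, ylim = ylim)
  if (!is.null(overlay)) {
    graphics::lines((overlay$start + overlay$end) / 2, overlay$value,
                    col = "red")
    graphics::legend("topright", legend = c(measure, "divergence"),
                     col = c("black", "red"), lty = 1)
  }
  invisible(data.table::data.table(pos = x, value = y))
}
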