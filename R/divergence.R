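#' Load a pairwise genome alignment from aligned FASTA
#'
#' Expects exactly two equal-length gapped sequences (the first is the
#' reference whose coordinates windows are expressed in). Columns where the
#' reference carries a gap have no reference coordinate and are dropped from
#' the coordinate map.
#'
#' @param path Aligned FASTA with two records.
#' @return List of class `pairwise_alignment` with per-column vectors
#'   `ref_char`, `other_char`, the reference position of each reference
#'   (non-gap) column, and the names of the two sequences.
#' @export
read_pairwise_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) != 2)
    stop("pairwise alignment must contain exactly 2 sequences, found ",
         length(ss))
  if (Biostrings::width(ss)[1] != Biostrings::width(ss)[2])
    stop("aligned sequences differ in length (", Biostrings::width(ss)[1],
         " vs ", Biostrings::width(ss)[2], ")")
  a <- strsplit(toupper(as.character(ss[[1]])), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(as.character(ss[[2]])), "", fixed = TRUE)[[1]]
  structure(list(ref_char = a, other_char = b,
                 names = names(ss)), class = "pairwise_alignment")
}

#' Windowed divergence (dxy) from a pairwise alignment
#'
#' Per window (in reference coordinates), dxy is the number of aligned
#' columns whose two bases are valid (A/C/G/T on both sequences: gaps and N
#' excluded) and differ, divided by the number of valid aligned columns.
#' Windows without any valid column are `NA`. Alignment columns where the
#' reference carries a gap belong to no reference position and are ignored,
#' making the statistic insensitive to gap-only insertions.
#'
#' @param aln A [read_pairwise_alignment()] object.
#' @param spec A [window_spec()].
#' @param chrom Chromosome name used in the output.
#' @return `data.table` with `chrom`, `start`, `end`, `valid_sites`,
#'   `value` (dxy).
#' @export
dxy_windows <- function(aln, spec, chrom = "ref") {
  acgt <- c("A", "C", "G", "T")
  ref_nogap <- aln$ref_char != "-"
  a <- aln$ref_char[ref_nogap]
  b <- aln$other_char[ref_nogap]
  pos <- seq_along(a)                       # reference coordinates
  valid <- a %in% acgt & b %in% acgt
  diffb <- valid & a != b
  L <- length(a)
  w <- spec$window_size; s <- spec$step_size
  n_win <- max(1L, (L - 1L) %/% s + 1L)
  starts <- (seq_len(n_win) - 1L) * s + 1L
  starts <- starts[starts <= L]
  ends <- pmin(starts + w - 1L, L)
  val <- nd <- nv <- numeric(length(starts))
  cs_valid <- c(0, cumsum(valid))
  cs_diff <- c(0, cumsum(diffb))
  nv <- cs_valid[ends + 1L] - cs_valid[starts]
  nd <- cs_diff[ends + 1L] - cs_diff[starts]
  data.table::data.table(chrom = chrom, start = starts, end = ends,
                         valid_sites = as.integer(nv),
                         value = ifelse(nv > 0, nd / nv, NA_real_))
}
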