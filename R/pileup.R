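#' Parse one SAMtools pileup line
#'
#' Classic 6-column pileup: chrom, 1-based position, reference base, read
#' depth, base column, quality column. The base column is decoded as follows:
#' `.`/`,` are the reference base; letters (either case, strands merged) are
#' that base; `^` consumes the following mapping-quality character; `$` is
#' consumed; `+n`/`-n` followed by n indel bases are consumed and ignored;
#' `*` is a deletion placeholder (paired with a quality, excluded from
#' counts); `N` is excluded. After decoding, one call character must remain
#' per quality character.
#'
#' @param line One pileup record.
#' @param lineno Line number used in error messages.
#' @return List with `chrom`, `pos`, `ref`, `coverage` (declared), `calls`
#'   (character vector of decoded call characters, including `*` and `N`),
#'   `quals` (integer Phred per call, offset already applied with
#'   `attr(,"offset")` unavailable here -- see `offset` argument of
#'   [filter_counts()]).
#' @export
parse_pileup_line <- function(line, lineno = NA_integer_) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) != 6)
    stop("pileup parse error at line ", lineno, ": expected 6 columns, got ",
         length(f))
  bases <- f[5]
  # strip read-start marker plus its mapping-quality char, then read ends
  bases <- gsub("\\^.", "", bases)
  bases <- gsub("$", "", bases, fixed = TRUE)
  # strip indels: sign, length, then that many sequence characters
  repeat {
    m <- regexpr("[+-][0-9]+", bases)
    if (m == -1) break
    nd <- as.integer(substr(bases, m + 1, m + attr(m, "match.length") - 1))
    if (!is.finite(nd) || nchar(bases) < m + attr(m, "match.length") + nd - 1)
      stop("pileup parse error at line ", lineno, ": malformed indel")
    bases <- paste0(substr(bases, 1, m - 1),
                    substr(bases, m + attr(m, "match.length") + nd,
                           nchar(bases)))
  }
  calls <- strsplit(bases, "", fixed = TRUE)[[1]]
  ref <- toupper(f[3])
  calls[calls == "." | calls == ","] <- ref
  calls <- toupper(calls)
  quals <- utf8ToInt(f[6])
  if (length(calls) != length(quals))
    stop("pileup parse error at line ", lineno,
         ": base and quality columns decode to different lengths (",
         length(calls), " vs ", length(quals), ")")
  cov <- as.integer(f[4])
  if (!is.na(cov) && cov != length(calls))
    stop("pileup parse error at line ", lineno,
         ": declared coverage ", cov, " != ", length(calls), " decoded calls")
  list(chrom = f[1], pos = as.integer(f[2]), ref = ref,
       coverage = length(calls), calls = calls, quals = quals)
}

#' Quality-filter a parsed pileup site into allele counts
#'
#' Only calls with Phred quality at or above `min_base_quality` contribute;
#' `N` calls and `*` deletion placeholders are excluded regardless, so the
#' effective coverage can be below the declared depth.
#'
#' @param site Output of [parse_pileup_line()].
#' @param min_base_quality Minimum Phred base quality.
#' @param offset Phred ASCII offset of the quality column.
#' @return List with `chrom`, `pos`, `ref`, `counts` (named A/C/G/T integer
#'   vector) and `effective_coverage`.
#' @export
filter_counts <- function(site, min_base_quality = 20L, offset = 33L) {
  q <- site$quals - as.integer(offset)
  ok <- q >= min_base_quality & site$calls %in% c("A", "C", "G", "T")
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  if (any(ok)) {
    tb <- table(factor(site$calls[ok], levels = c("A", "C", "G", "T")))
    counts[] <- as.integer(tb)
  }
  list(chrom = site$chrom, pos = site$pos, ref = site$ref, counts = counts,
       effective_coverage = sum(counts))
}

#' Read a pileup file into a table of quality-filtered site counts
#'
#' Streams a plain or gzipped 6-column pileup file in chunks (memory bounded
#' by the chunk size, not the file) and returns per-site allele counts after
#' base-quality filtering. Sites whose effective coverage is zero are kept
#' and flagged uncovered downstream via their zero `cov`.
#'
#' @param path Pileup file (`.gz` accepted).
#' @param min_base_quality Minimum Phred base quality per call.
#' @param offset Phred ASCII offset.
#' @param chunk_size Lines per chunk.
#' @return `data.table` with columns `chrom`, `pos`, `ref`, `A`, `C`, `G`,
#'   `T`, `cov` (effective coverage).
#' @export
read_pileup <- function(path, min_base_quality = 20L, offset = 33L,
                        chunk_size = 100000L) {
  if (!file.exists(path)) stop("pileup file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  chunks <- list()
  lineno <- 0L
  repeat {
    lines <- readLines(con, n = chunk_size)
    if (length(lines) == 0) break
    rows <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      sc <- filter_counts(parse_pileup_line(lines[i], lineno + i),
                          min_base_quality, offset)
      rows[[i]] <- list(chrom = sc$chrom, pos = sc$pos, ref = sc$ref,
                        A = sc$counts[["A"]], C = sc$counts[["C"]],
                        G = sc$counts[["G"]], T = sc$counts[["T"]],
                        cov = sc$effective_coverage)
    }
    chunks[[length(chunks) + 1L]] <- data.table::rbindlist(rows)
    lineno <- lineno + length(lines)
  }
  if (length(chunks) == 0)
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  ref = character(), A = integer(),
                                  C = integer(), G = integer(), T = integer(),
                                  cov = integer()))
  data.table::rbindlist(chunks)
}

#' Write a pileup file from a site-count table
#'
#' Inverse of [read_pileup()] for synthetic data: reference-matching calls
#' become `.`, others their base letter; all qualities are written as a single
#' constant character.
#'
#' @param counts `data.table` with `chrom`, `pos`, `ref`, `A`, `C`, `G`, `T`.
#' @param path Output path.
#' @param qual_char Quality character for every call (default `"I"`, Phred 40
#'   at offset 33).
#' @export
write_pileup <- function(counts, path, qual_char = "I") {
  bases <- c("A", "C", "G", "T")
  mat <- as.matrix(counts[, c("A", "C", "G", "T"), with = FALSE])
  col <- character(nrow(mat))
  for (j in seq_len(4)) {
    ch <- ifelse(counts$ref == bases[j], ".", bases[j])
    add <- strrep(ch, mat[, j])
    col <- paste0(col, add)
  }
  depth <- rowSums(mat)
  lines <- paste(counts$chrom, counts$pos, counts$ref, depth, col,
                 strrep(qual_char, depth), sep = "\t")
  writeLines(lines[depth > 0], path)
  invisible(path)
}
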