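# Readers and writers for the on-disk formats the pipeline touches:
# BED6 / narrowPeak peak files, bedGraph signal tracks, per-CpG methylation
# tables, RepeatMasker-style repeat annotation and expression matrices.
# All readers validate strictly and report offending line numbers rather
# than skipping malformed records.

#' Read a peak file (BED6 or narrowPeak)
#'
#' The dialect is auto-detected from the column count: 6 columns = BED6
#' (score column taken verbatim), 10 columns = narrowPeak (score is the
#' -log10 p value from column 8). Peaks are validated against the assembly
#' and returned sorted.
#'
#' @param path Path to the peak file.
#' @param assembly A `GenomeAssembly`.
#' @param mark Optional histone-mark label stored as an attribute.
#' @param sample Optional sample label stored as an attribute.
#' @return data.frame of class `PeakSet` with columns `chrom`, `start`,
#'   `end`, `name`, `score`; attributes `mark`, `sample` and `dialect`.
#' @export
read_peaks <- function(path, assembly, mark = NA_character_,
                       sample = NA_character_) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    warning("empty peak file: ", path)
    df <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                     name = character(), score = numeric(),
                     stringsAsFactors = FALSE)
    return(peak_set(df, mark, sample, dialect = "empty"))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = FALSE)
  nc <- ncol(dt)
  if (nc == 6L) {
    df <- data.frame(chrom = as.character(dt[[1]]), start = dt[[2]],
                     end = dt[[3]], name = as.character(dt[[4]]),
                     score = as.numeric(dt[[5]]), stringsAsFactors = FALSE)
    dialect <- "BED6"
  } else if (nc == 10L) {
    df <- data.frame(chrom = as.character(dt[[1]]), start = dt[[2]],
                     end = dt[[3]], name = as.character(dt[[4]]),
                     score = as.numeric(dt[[8]]), stringsAsFactors = FALSE)
    dialect <- "narrowPeak"
  } else {
    stop(basename(path), ": expected 6 (BED6) or 10 (narrowPeak) columns, found ", nc)
  }
  validate_intervals(df, assembly, what = basename(path))
  if (any(df$score < 0))
    stop(basename(path), " line ", which(df$score < 0)[1], ": negative score")
  df <- df[order(match(df$chrom, names(assembly$lengths)), df$start, df$end), ]
  rownames(df) <- NULL
  peak_set(df, mark, sample, dialect)
}

peak_set <- function(df, mark = NA_character_, sample = NA_character_,
                     dialect = "BED6") {
  structure(df, class = c("PeakSet", "data.frame"),
            mark = mark, sample = sample, dialect = dialect)
}

#' Write a peak set as BED6
#' @param peaks A `PeakSet` (or compatible data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  dt <- data.table::data.table(
    peaks$chrom, format_bp(peaks$start), format_bp(peaks$end),
    if (is.null(peaks$name)) paste0("peak", seq_len(nrow(peaks))) else peaks$name,
    format(signif(peaks$score, 6), scientific = FALSE, trim = TRUE), ".")
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-CpG methylation table
#'
#' Tab-delimited, no header: chrom, position (1-based, the common caller
#' convention — converted to 0-based on read), methylation level in
#' \[0, 1\], read coverage. Rows with coverage 0, out-of-range levels or
#' duplicate positions are rejected with the offending line number.
#'
#' @param path Path to the methylation table.
#' @param assembly A `GenomeAssembly`.
#' @param sample Optional sample label stored as an attribute.
#' @return data.frame of class `MethylomeTable` with columns `chrom`,
#'   `pos` (0-based), `level`, `coverage`.
#' @export
read_methylome <- function(path, assembly, sample = NA_character_) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "pos1", "level", "coverage"))
  df <- data.frame(chrom = as.character(dt$chrom), pos = dt$pos1 - 1,
                   level = dt$level, coverage = dt$coverage,
                   stringsAsFactors = FALSE)
  bad <- df$level < 0 | df$level > 1
  if (any(bad))
    stop(basename(path), " line ", which(bad)[1], ": methylation level ",
         df$level[which(bad)[1]], " outside [0, 1]")
  bad <- df$coverage < 1
  if (any(bad))
    stop(basename(path), " line ", which(bad)[1], ": coverage must be >= 1")
  bad <- !df$chrom %in% names(assembly$lengths)
  if (any(bad))
    stop(basename(path), " line ", which(bad)[1], ": unknown chromosome '",
         df$chrom[which(bad)[1]], "'")
  oob <- df$pos < 0 | df$pos >= assembly$lengths[df$chrom]
  if (any(oob))
    stop(basename(path), " line ", which(oob)[1], ": position out of bounds")
  key <- paste(df$chrom, df$pos)
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stop(basename(path), " line ", i, ": duplicate CpG position ",
         df$chrom[i], ":", format_bp(df$pos[i] + 1))
  }
  structure(df, class = c("MethylomeTable", "data.frame"), sample = sample)
}

#' Write a per-CpG methylation table (positions written 1-based)
#' @param meth A `MethylomeTable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_methylome <- function(meth, path) {
  dt <- data.table::data.table(
    meth$chrom, format_bp(meth$pos + 1),
    format(signif(meth$level, 6), scientific = FALSE, trim = TRUE),
    format_bp(meth$coverage))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a RepeatMasker-style repeat annotation
#'
#' Tab-delimited, no header: chrom, start, end (BED coordinates), strand,
#' family, subfamily. A subfamily must map to exactly one family.
#'
#' @param path Path to the repeat annotation.
#' @param assembly A `GenomeAssembly`.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `family`, `subfamily`.
#' @export
read_repeats <- function(path, assembly) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "strand",
                                        "family", "subfamily"))
  df <- as.data.frame(dt)
  df$chrom <- as.character(df$chrom)
  validate_intervals(df, assembly, what = basename(path))
  fam_per_sub <- tapply(df$family, df$subfamily, function(x) length(unique(x)))
  if (any(fam_per_sub > 1))
    stop(basename(path), ": subfamily '", names(fam_per_sub)[fam_per_sub > 1][1],
         "' maps to more than one family")
  df
}

#' Write a repeat annotation table
#' @param repeats Repeat table as returned by [read_repeats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeats <- function(repeats, path) {
  dt <- data.table::data.table(
    repeats$chrom, format_bp(repeats$start), format_bp(repeats$end),
    repeats$strand, repeats$family, repeats$subfamily)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an expression table
#'
#' Tab-delimited with a header; first column `feature` (gene_id or TE
#' subfamily), remaining columns one per sample. Values must be >= 0.
#'
#' @param path Path to the expression TSV.
#' @return Numeric matrix, features in rows, samples in columns.
#' @export
read_expression <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- as.character(dt[[1]])
  if (any(!is.finite(m)) || any(m < 0))
    stop(basename(path), ": expression values must be finite and >= 0")
  m
}

#' Write an expression table
#' @param mat Numeric matrix, features in rows, samples in columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  dt <- data.table::data.table(feature = rownames(mat))
  for (j in colnames(mat))
    dt[[j]] <- format(signif(mat[, j], 6), scientific = FALSE, trim = TRUE)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write a generic report table
#'
#' Deterministic column order, header row, UTF-8 with `\n` line endings;
#' numeric columns serialized with 6 significant digits. Optional header
#' comment lines (prefixed `#`) record the parameter values used.
#'
#' @param df data.frame of records.
#' @param path Output path.
#' @param params Optional named list of parameters recorded as `#`-prefixed
#'   header lines.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, params = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(params))
    writeLines(paste0("# ", names(params), " = ",
                      vapply(params, function(p) paste(format(p), collapse = ","), "")),
               con, sep = "\n")
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- format(signif(out[[j]], 6), scientific = FALSE, trim = TRUE)
  writeLines(paste(names(out), collapse = "\t"), con, sep = "\n")
  if (nrow(out))
    writeLines(do.call(paste, c(lapply(out, as.character), sep = "\t")),
               con, sep = "\n")
  invisible(path)
}

#' Read a report table written by [write_table()]
#' @param path Path to the TSV.
#' @return data.frame (comment lines skipped).
#' @export
read_table_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "# ")]
  if (length(lines) == 0L) stop(basename(path), ": no header line")
  as.data.frame(data.table::fread(text = paste(lines, collapse = "\n"),
                                  header = TRUE, sep = "\t"))
}
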