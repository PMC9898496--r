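# Interval plumbing. Public containers are plain data.frames with columns
# chrom / start / end in BED convention (0-based, half-open). The heavy
# operations (overlap, merging, coverage) are delegated to IRanges /
# GenomicRanges through the +1 shift at this boundary.

#' Validate a set of genomic intervals against an assembly
#'
#' Checks that every interval has 0 <= start < end <= chromosome length and
#' lies on a chromosome of the assembly. Used by all readers.
#'
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param assembly A `GenomeAssembly`.
#' @param what Label used in error messages (e.g. the file being read).
#' @return `df`, invisibly, if valid; otherwise an error naming the first
#'   offending row.
#' @export
validate_intervals <- function(df, assembly, what = "interval") {
  stopifnot(inherits(assembly, "GenomeAssembly"))
  if (nrow(df) == 0L) return(invisible(df))
  bad_chrom <- !df$chrom %in% names(assembly$lengths)
  if (any(bad_chrom)) {
    i <- which(bad_chrom)[1]
    stop(what, " line ", i, ": unknown chromosome '", df$chrom[i], "'")
  }
  bad_coord <- df$start < 0 | df$start >= df$end
  if (any(bad_coord)) {
    i <- which(bad_coord)[1]
    stop(what, " line ", i, ": invalid interval [", df$start[i], ", ",
         df$end[i], ")")
  }
  lens <- assembly$lengths[df$chrom]
  oob <- df$end > lens
  if (any(oob)) {
    i <- which(oob)[1]
    stop(what, " line ", i, ": interval end ", format_bp(df$end[i]),
         " exceeds length of ", df$chrom[i], " (", format_bp(lens[i]), ")")
  }
  invisible(df)
}

# 0-based half-open data.frame -> GRanges (1-based closed); `chroms`
# fixes a shared seqlevels universe so cross-set operations are silent
as_granges <- function(df, chroms = NULL) {
  strand <- if ("strand" %in% names(df)) {
    s <- df$strand
    s[!s %in% c("+", "-")] <- "*"
    s
  } else "*"
  seqnames <- if (is.null(chroms)) df$chrom
              else factor(df$chrom, levels = chroms)
  GenomicRanges::GRanges(
    seqnames = seqnames,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand)
}

# GRanges -> 0-based half-open data.frame
as_bed_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Merge genomic intervals
#'
#' Merges intervals on the same chromosome whose gap is at most `max_gap`
#' bp. With the half-open convention, abutting intervals (`end == start`)
#' have gap 0 and merge at the default. Used to assemble H3K4me3 domains
#' from called peaks.
#'
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param max_gap Maximum gap in bp bridged by a merge (default 0).
#' @return Sorted, non-overlapping data.frame of merged intervals.
#' @examples
#' merge_intervals(data.frame(chrom = "chr1", start = c(100, 200),
#'                            end = c(200, 300)))
#' @export
merge_intervals <- function(df, max_gap = 0) {
  stopifnot(max_gap >= 0)
  if (nrow(df) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  gr <- as_granges(df[, c("chrom", "start", "end")])
  merged <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1,
                                  ignore.strand = TRUE)
  merged <- GenomicRanges::sort(merged, ignore.strand = TRUE)
  as_bed_df(merged)
}

# total bases of `a` covered by the merged union of `b`; per-row of `a`
overlap_bases <- function(a, b) {
  if (nrow(a) == 0L) return(numeric(0))
  if (nrow(b) == 0L) return(rep(0, nrow(a)))
  chroms <- unique(c(a$chrom, b$chrom))
  gra <- as_granges(a[, c("chrom", "start", "end")], chroms)
  grb <- GenomicRanges::reduce(as_granges(b[, c("chrom", "start", "end")],
                                          chroms),
                               ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(gra, grb, ignore.strand = TRUE)
  ov <- IRanges::pintersect(gra[S4Vectors::queryHits(hits)],
                            grb[S4Vectors::subjectHits(hits)],
                            ignore.strand = TRUE)
  out <- rep(0, nrow(a))
  w <- tapply(IRanges::width(ov), S4Vectors::queryHits(hits), sum)
  out[as.integer(names(w))] <- as.numeric(w)
  out
}

# logical: does each row of `a` overlap >= min_bp bases of any row of `b`
overlaps_any <- function(a, b, min_bp = 1) {
  overlap_bases(a, b) >= min_bp
}

# total length of the merged union of a set of intervals
total_covered_bases <- function(df) {
  if (nrow(df) == 0L) return(0)
  m <- merge_intervals(df)
  sum(m$end - m$start)
}
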