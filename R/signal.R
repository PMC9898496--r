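# Binned signal tracks (RPM scale). A SignalTrack holds one dense numeric
# vector per chromosome, tiling it from 0 at a fixed bin width; the last
# bin of a chromosome may be shorter. On disk the track is a bedGraph.

#' Construct a signal track
#'
#' @param values Named list, one numeric vector per chromosome, in
#'   assembly order; element `i` covers `[(i-1)*bin_width, i*bin_width)`.
#' @param bin_width Bin width in bp.
#' @param assembly A `GenomeAssembly`.
#' @param mark,sample Optional labels stored as attributes.
#' @return Object of class `SignalTrack`.
#' @export
signal_track <- function(values, bin_width, assembly,
                         mark = NA_character_, sample = NA_character_) {
  stopifnot(inherits(assembly, "GenomeAssembly"), bin_width > 0)
  if (!setequal(names(values), names(assembly$lengths)))
    stop("track chromosomes do not match the assembly")
  values <- values[names(assembly$lengths)]
  for (ch in names(values)) {
    expect_n <- ceiling(assembly$lengths[[ch]] / bin_width)
    if (length(values[[ch]]) != expect_n)
      stop("chromosome ", ch, ": expected ", expect_n, " bins, got ",
           length(values[[ch]]))
    if (any(!is.finite(values[[ch]])) || any(values[[ch]] < 0))
      stop("chromosome ", ch, ": signal values must be finite and >= 0")
  }
  structure(list(values = values, bin_width = bin_width,
                 lengths = assembly$lengths),
            class = "SignalTrack", mark = mark, sample = sample)
}

#' @export
print.SignalTrack <- function(x, ...) {
  cat("SignalTrack:", length(x$values), "chromosomes at", x$bin_width,
      "bp bins")
  if (!is.na(attr(x, "mark"))) cat("; mark:", attr(x, "mark"))
  cat("\n")
  invisible(x)
}

#' Write a signal track as bedGraph
#'
#' Every bin is written, including zeros, so a read/write cycle is
#' lossless.
#'
#' @param track A `SignalTrack`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "SignalTrack"))
  pieces <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    starts <- (seq_along(v) - 1) * track$bin_width
    data.table::data.table(ch, format_bp(starts),
                           format_bp(pmin(starts + track$bin_width,
                                          track$lengths[[ch]])),
                           format(signif(v, 6), scientific = FALSE, trim = TRUE))
  })
  data.table::fwrite(data.table::rbindlist(pieces), path, sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' Expects fixed-width bins aligned to multiples of `bin_width`; bins not
#' present in the file are zero-filled, so sparse bedGraphs are accepted.
#'
#' @param path Path to the bedGraph file.
#' @param assembly A `GenomeAssembly`.
#' @param bin_width Bin width in bp (default 100).
#' @param mark,sample Optional labels.
#' @return A `SignalTrack`.
#' @export
read_bedgraph <- function(path, assembly, bin_width = 100,
                          mark = NA_character_, sample = NA_character_) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"))
  df <- as.data.frame(dt)
  df$chrom <- as.character(df$chrom)
  validate_intervals(df, assembly, what = basename(path))
  if (any(df$value < 0))
    stop(basename(path), " line ", which(df$value < 0)[1], ": negative signal")
  misaligned <- df$start %% bin_width != 0 |
    (df$end - df$start > bin_width) |
    (df$end != pmin(df$start + bin_width, assembly$lengths[df$chrom]))
  if (any(misaligned))
    stop(basename(path), " line ", which(misaligned)[1],
         ": bin not aligned to ", bin_width, " bp grid")
  values <- lapply(names(assembly$lengths), function(ch) {
    n <- ceiling(assembly$lengths[[ch]] / bin_width)
    v <- numeric(n)
    rows <- df$chrom == ch
    idx <- df$start[rows] %/% bin_width + 1
    if (anyDuplicated(idx))
      stop(basename(path), ": duplicate bin on ", ch)
    v[idx] <- df$value[rows]
    v
  })
  names(values) <- names(assembly$lengths)
  signal_track(values, bin_width, assembly, mark, sample)
}

# cumulative base-weighted signal per chromosome: C[i] = sum of
# value * bin_length over the first i bins. Lets any [s, e) sum be read
# off in O(1), with fractional end bins handled exactly.
track_cumsum <- function(track, chrom) {
  v <- track$values[[chrom]]
  w <- rep(track$bin_width, length(v))
  w[length(w)] <- track$lengths[[chrom]] - (length(v) - 1) * track$bin_width
  c(0, cumsum(v * w))
}

# base-weighted signal sum over [s, e) — vectorized over regions on one chrom
region_signal_sum_1chrom <- function(track, chrom, s, e) {
  v <- track$values[[chrom]]
  cum <- track_cumsum(track, chrom)
  at <- function(x) {
    # cumulative signal over [0, x)
    b <- pmin(x %/% track$bin_width, length(v))          # full bins below x
    cum[b + 1] + ifelse(b < length(v), v[pmin(b + 1, length(v))], 0) *
      (x - b * track$bin_width)
  }
  at(e) - at(s)
}

#' Mean signal (RPM) over regions
#'
#' Length-weighted mean of the per-base signal across each region; bins
#' partially overlapping a region contribute proportionally to the
#' overlapped bases.
#'
#' @param track A `SignalTrack`.
#' @param regions data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return Numeric vector of per-region mean RPM, in input order.
#' @export
rpm_over_region <- function(track, regions) {
  stopifnot(inherits(track, "SignalTrack"))
  if (nrow(regions) == 0L) return(numeric(0))
  unknown <- !regions$chrom %in% names(track$values)
  if (any(unknown))
    stop("region on chromosome absent from track: ",
         regions$chrom[which(unknown)[1]])
  if (any(regions$start < 0 | regions$start >= regions$end |
            regions$end > track$lengths[regions$chrom]))
    stop("region outside assembly bounds")
  out <- numeric(nrow(regions))
  for (ch in unique(regions$chrom)) {
    rows <- which(regions$chrom == ch)
    out[rows] <- region_signal_sum_1chrom(track, ch, regions$start[rows],
                                          regions$end[rows]) /
      (regions$end[rows] - regions$start[rows])
  }
  out
}

#' TSS-centered signal profile matrix
#'
#' Row g, column j holds the mean RPM over the window
#' `[tss - flank + (j-1)*step, tss - flank + j*step)`. Rows of minus-strand
#' genes are reversed so that columns always run 5' to 3'. Windows that
#' would extend beyond a chromosome end are clipped; a window fully
#' outside yields NA.
#'
#' @param track A `SignalTrack`.
#' @param genes Gene table (needs `gene_id`, `chrom`, `tss`, `strand`).
#' @param flank Half-width of the profiled window in bp (default 2000).
#' @param step Column width in bp; must divide `2 * flank` (default 100).
#' @return Numeric matrix, genes x (2*flank/step), rownames = gene_id.
#' @export
tss_profile_matrix <- function(track, genes, flank = 2000, step = 100) {
  if ((2 * flank) %% step != 0) stop("step must divide 2*flank")
  ncol <- 2 * flank / step
  m <- matrix(NA_real_, nrow = nrow(genes), ncol = ncol,
              dimnames = list(genes$gene_id, NULL))
  lens <- track$lengths[genes$chrom]
  for (j in seq_len(ncol)) {
    s <- genes$tss - flank + (j - 1) * step
    e <- s + step
    cs <- pmax(0, s); ce <- pmin(lens, e)
    ok <- which(cs < ce)
    if (length(ok)) {
      reg <- data.frame(chrom = genes$chrom[ok], start = cs[ok], end = ce[ok])
      m[ok, j] <- rpm_over_region(track, reg)
    }
  }
  neg <- genes$strand == "-"
  m[neg, ] <- m[neg, ncol:1, drop = FALSE]
  m
}

#' Smooth a signal track with a centered moving mean
#'
#' Window is in bins ("pixels"); edges use the truncated window. Smoothing
#' never crosses a chromosome boundary.
#'
#' @param track A `SignalTrack`.
#' @param window Odd window size in bins (default 3).
#' @return A smoothed `SignalTrack`.
#' @export
smooth_track <- function(track, window = 3) {
  stopifnot(inherits(track, "SignalTrack"))
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  h <- (window - 1) / 2
  values <- lapply(track$values, function(v) {
    n <- length(v)
    if (n == 0L || h == 0) return(v)
    cum <- c(0, cumsum(v))
    lo <- pmax(seq_len(n) - h, 1)
    hi <- pmin(seq_len(n) + h, n)
    (cum[hi + 1] - cum[lo]) / (hi - lo + 1)
  })
  out <- track
  out$values <- values
  out
}

#' H3K4me3 domain widths and width-class proportions
#'
#' Domains are formed by merging peaks (gap at most `max_gap` bp) and
#' classified as `<1kb`, `1-2kb` (both bounds inclusive) or `>2kb`.
#'
#' @param peaks A `PeakSet` or data.frame with `chrom`, `start`, `end`.
#' @param max_gap Merge gap in bp (default 0: only overlapping or abutting
#'   peaks join into one domain).
#' @return List with `domains` (merged intervals plus `width` and `class`)
#'   and `proportions` (named numeric over the three classes, summing
#'   to 1).
#' @export
domain_widths <- function(peaks, max_gap = 0) {
  if (nrow(peaks) == 0L) {
    warning("empty peak set: no domains")
    return(list(domains = data.frame(), proportions = c(`<1kb` = NA_real_,
                `1-2kb` = NA_real_, `>2kb` = NA_real_)))
  }
  dom <- merge_intervals(peaks[, c("chrom", "start", "end")], max_gap)
  dom$width <- dom$end - dom$start
  dom$class <- classify_domain_width(dom$width)
  prop <- table(dom$class) / nrow(dom)
  list(domains = dom, proportions = setNames(as.numeric(prop), names(prop)))
}

classify_domain_width <- function(width) {
  factor(ifelse(width < 1000, "<1kb",
                ifelse(width <= 2000, "1-2kb", ">2kb")),
         levels = c("<1kb", "1-2kb", ">2kb"))
}

#' Replicate correlation over promoters
#'
#' Pearson correlation of per-promoter mean RPM between two tracks — the
#' replicate-QC statistic computed on all annotated gene promoters
#' (TSS +/- 2 kb).
#'
#' @param track_a,track_b `SignalTrack`s on the same assembly.
#' @param promoters data.frame of promoter intervals.
#' @return Pearson r (numeric scalar).
#' @export
replicate_correlation <- function(track_a, track_b, promoters) {
  a <- rpm_over_region(track_a, promoters)
  b <- rpm_over_region(track_b, promoters)
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) stop("need at least 3 promoters with finite signal")
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
    stop("zero variance in promoter signal; correlation undefined")
  stats::cor(a[ok], b[ok])
}
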