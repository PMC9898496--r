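# Observed/expected enrichment of a peak set on a genomic region set:
#   R_observed = L_peak-overlapping-region / L_total-peak
#   R_expected = L_total-region / L_total-genome
#   E          = R_observed / R_expected
# Lengths are computed on merged interval sets, so a base overlapped by
# several regions or peaks is counted once.

#' Observed/expected genomic enrichment of a peak set
#'
#' @param peaks `PeakSet` or data.frame of peak intervals.
#' @param regions data.frame of region intervals (merged internally).
#' @param assembly A `GenomeAssembly` supplying the total genome length.
#' @return Object of class `EnrichmentResult`: list with `r_observed`
#'   (fraction of peak bases inside the region set), `r_expected`
#'   (fraction of the genome covered by the region set) and `enrichment`
#'   (their quotient).
#' @examples
#' asm <- assembly(c(chr1 = 1e6))
#' peaks <- data.frame(chrom = "chr1", start = c(0, 50000),
#'                     end = c(5000, 55000))
#' regions <- data.frame(chrom = "chr1", start = 0, end = 100000)
#' genomic_enrichment(peaks, regions, asm)
#' @export
genomic_enrichment <- function(peaks, regions, assembly) {
  stopifnot(inherits(assembly, "GenomeAssembly"))
  if (nrow(regions) == 0L)
    stop("empty region set: expected ratio undefined")
  peaks_m <- merge_intervals(as.data.frame(peaks)[, c("chrom", "start", "end")])
  regions_m <- merge_intervals(regions[, c("chrom", "start", "end")])
  l_peak <- sum(peaks_m$end - peaks_m$start)
  if (l_peak == 0) stop("total peak length is 0")
  l_region <- sum(regions_m$end - regions_m$start)
  l_overlap <- sum(overlap_bases(peaks_m, regions_m))
  r_obs <- l_overlap / l_peak
  r_exp <- l_region / genome_length(assembly)
  structure(list(r_observed = r_obs, r_expected = r_exp,
                 enrichment = r_obs / r_exp,
                 l_overlap = l_overlap, l_peak = l_peak,
                 l_region = l_region, l_genome = genome_length(assembly)),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("EnrichmentResult: R_obs = %.4g, R_exp = %.4g, E = %.4g\n",
              x$r_observed, x$r_expected, x$enrichment))
  invisible(x)
}

#' Two-group location test
#'
#' Two-sample t test, Welch (unequal variance) by default; set
#' `equal_var = TRUE` for the classical pooled-variance Student test.
#' When both groups have zero variance and equal means the test is
#' degenerate and `p = 1` is returned by convention.
#'
#' @param a,b Numeric vectors, each of length >= 2, finite values.
#' @param equal_var Use the pooled-variance test (default FALSE).
#' @return List with `statistic` (t), `p_value` (two-sided), `df`,
#'   `mean_a`, `mean_b`.
#' @export
two_group_test <- function(a, b, equal_var = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("groups must contain only finite values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(statistic = 0, p_value = 1, df = NA_real_,
                  mean_a = mean(a), mean_b = mean(b)))
    stop("both groups constant with different means; t undefined")
  }
  tt <- stats::t.test(a, b, var.equal = equal_var)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_a = mean(a), mean_b = mean(b))
}

#' Sample ordination by principal components
#'
#' Mean-centered PCA of a samples x features signal matrix (e.g.
#' per-promoter mean RPM per sample). Zero-variance features are dropped.
#' The sign of each component is fixed so that its largest-magnitude
#' loading is positive, making coordinates reproducible.
#'
#' @param mat Numeric matrix, samples in rows, features in columns; at
#'   least 3 rows.
#' @return List with `coords` (samples x 2), `explained` (variance
#'   fractions of the first two components) and `all_explained`.
#' @export
sample_ordination <- function(mat) {
  if (nrow(mat) < 3) stop("need at least 3 samples")
  keep <- apply(mat, 2, stats::sd) > 0
  if (!any(keep)) stop("all features have zero variance")
  pc <- stats::prcomp(mat[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(pc$x, 2, flip, `*`)
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(2, ncol(scores))
  coords <- scores[, seq_len(k), drop = FALSE]
  if (k == 1) coords <- cbind(coords, 0)
  list(coords = coords, explained = varfrac[seq_len(k)],
       all_explained = varfrac)
}
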