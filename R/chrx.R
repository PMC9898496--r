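# X-chromosome dosage. The dosage statistic is the fraction of total
# expression carried by chrX genes; the female/male ratio of that
# fraction quantifies how far the two active female X chromosomes rise
# above the male single-X output (2.0 = full double dose, values below 2
# indicate dampening).

#' Fraction of total expression on the X chromosome
#'
#' Sum of expression over chrX genes divided by the sum over all genes.
#' Scale-invariant: multiplying all values by a constant leaves it
#' unchanged.
#'
#' @param expr Numeric expression vector (e.g. FPKM) named by gene_id.
#' @param genes Gene table with a logical `chrx` column.
#' @return Numeric scalar in \[0, 1\].
#' @export
x_expression_fraction <- function(expr, genes) {
  shared <- intersect(names(expr), genes$gene_id)
  if (length(shared) == 0L) stop("expression and gene table share no genes")
  e <- expr[shared]
  total <- sum(e)
  if (total <= 0) stop("total expression is zero")
  on_x <- genes$chrx[match(shared, genes$gene_id)]
  sum(e[on_x]) / total
}

#' Estimate the female/male X-dosage factor
#'
#' Ratio of the female to the male X expression fraction, with a
#' percentile bootstrap confidence interval over genes (both samples
#' resampled on the same gene draw, preserving the pairing).
#' Alternatively (`method = "per_gene"`) the median female/male ratio of
#' expressed chrX genes.
#'
#' @param expr_female,expr_male Numeric expression vectors named by
#'   gene_id.
#' @param genes Gene table with `chrx`.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional RNG seed for the bootstrap.
#' @param method `"fraction_ratio"` (default) or `"per_gene"`.
#' @return List of class `DosageEstimate`: `factor` (the point estimate),
#'   `ci` (length-2 numeric), `x_fraction_female`, `x_fraction_male`,
#'   `n_genes`, `method`.
#' @export
estimate_dosage_factor <- function(expr_female, expr_male, genes,
                                   n_boot = 1000, conf = 0.95, seed = NULL,
                                   method = c("fraction_ratio", "per_gene")) {
  method <- match.arg(method)
  shared <- intersect(intersect(names(expr_female), names(expr_male)),
                      genes$gene_id)
  if (length(shared) == 0L) stop("no shared genes")
  f <- expr_female[shared]; m <- expr_male[shared]
  on_x <- genes$chrx[match(shared, genes$gene_id)]
  if (sum(m) <= 0 || sum(m[on_x]) <= 0)
    stop("male X expression fraction is zero; ratio undefined")
  frac <- function(e) sum(e[on_x]) / sum(e)
  if (method == "per_gene") {
    ok <- on_x & m > 0 & f > 0
    if (!any(ok)) stop("no expressed chrX genes in both sexes")
    est <- stats::median(f[ok] / m[ok])
  } else {
    est <- frac(f) / frac(m)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(shared)
  boot <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    if (method == "per_gene") {
      ok <- on_x[idx] & m[idx] > 0 & f[idx] > 0
      if (!any(ok)) return(NA_real_)
      stats::median(f[idx][ok] / m[idx][ok])
    } else {
      fx <- sum(f[idx][on_x[idx]]); mx <- sum(m[idx][on_x[idx]])
      if (mx <= 0 || sum(m[idx]) <= 0) return(NA_real_)
      (fx / sum(f[idx])) / (mx / sum(m[idx]))
    }
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  structure(list(factor = est, ci = ci, conf = conf,
                 x_fraction_female = frac(f), x_fraction_male = frac(m),
                 n_genes = n, n_chrx = sum(on_x), method = method),
            class = "DosageEstimate")
}

#' @export
print.DosageEstimate <- function(x, ...) {
  cat(sprintf(paste0("DosageEstimate: female/male X-dosage factor = %.3f ",
                     "(%g%% CI %.3f-%.3f; %d genes, %d on chrX)\n"),
              x$factor, 100 * x$conf, x$ci[1], x$ci[2],
              x$n_genes, x$n_chrx))
  invisible(x)
}

#' Compare chrX CGI promoters with other promoters
#'
#' Per mark, mean promoter RPM of chrX CpG-island promoters versus all
#' other promoters (optionally a seeded random subsample of them), with a
#' two-group test.
#'
#' @param tracks Named list of `SignalTrack`s (e.g. H3K4me3, H3K27me3,
#'   H3K9me3).
#' @param genes Gene table with `chrx` and `cgi_promoter`.
#' @param assembly A `GenomeAssembly`.
#' @param flank Promoter half-width (default 2000).
#' @param n_other Optional size of a random subsample of the comparison
#'   set; default uses all non-chrX-CGI promoters.
#' @param seed RNG seed for the subsample.
#' @return List with `summary` and `tests` keyed by mark; groups are
#'   `chrX-CGI` and `other`.
#' @export
cgi_promoter_compare <- function(tracks, genes, assembly, flank = 2000,
                                 n_other = NULL, seed = NULL) {
  is_xcgi <- genes$chrx & genes$cgi_promoter
  if (!any(is_xcgi)) stop("no chrX CGI promoters in the gene table")
  other_idx <- which(!is_xcgi)
  if (!is.null(n_other) && n_other < length(other_idx)) {
    if (!is.null(seed)) set.seed(seed)
    other_idx <- sort(sample(other_idx, n_other))
  }
  sel <- c(which(is_xcgi), other_idx)
  g <- genes[sel, ]
  grp <- factor(ifelse(g$chrx & g$cgi_promoter, "chrX-CGI", "other"),
                levels = c("chrX-CGI", "other"))
  prom <- make_promoter(g$tss, g$chrom, assembly, flank)
  quantities <- list()
  for (mk in names(tracks))
    quantities[[mk]] <- rpm_over_region(tracks[[mk]], prom)
  group_compare(quantities, grp)
}
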