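# Demethylation-escapee calling. The genome is tiled into non-overlapping
# 5-kb bins; the mean methylation of each bin across development is the
# average of per-sample bin means. Bins above 0.4 (strictly) are escapees;
# TE subfamilies are escapees at mean >= 0.35 (inclusive). The two rules
# carry the asymmetry exactly as printed in the source thresholds.

#' Aggregate per-CpG methylation into genome bins
#'
#' Per-bin unweighted mean of CpG site levels (optionally
#' coverage-weighted), per sample, plus the development average: the mean
#' of the per-sample bin means, samples equally weighted.
#'
#' @param methylomes Named list of `MethylomeTable`s (one per sample).
#' @param bins Bin table from [bin_genome()].
#' @param weight_by_coverage Weight CpG levels by read coverage within a
#'   bin (default FALSE: unweighted site mean).
#' @return data.frame of class `BinMethylation`: bin columns, `n_cpg`
#'   (distinct CpG positions seen in the bin), one `mean_<sample>` column
#'   per sample and `development_average`. Bins with no CpG carry NA and
#'   are excluded from downstream calls.
#' @export
bin_methylation <- function(methylomes, bins, weight_by_coverage = FALSE) {
  stopifnot(is.list(methylomes), length(methylomes) > 0)
  if (is.null(names(methylomes)))
    names(methylomes) <- paste0("sample", seq_along(methylomes))
  gr_bins <- as_granges(bins[, c("chrom", "start", "end")])
  out <- bins
  seen <- vector("list", length(methylomes))
  for (i in seq_along(methylomes)) {
    m <- methylomes[[i]]
    gr_cpg <- GenomicRanges::GRanges(m$chrom,
                                     IRanges::IRanges(m$pos + 1, m$pos + 1))
    hits <- GenomicRanges::findOverlaps(gr_cpg, gr_bins)
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    means <- rep(NA_real_, nrow(bins))
    if (length(qi)) {
      if (weight_by_coverage) {
        num <- tapply(m$level[qi] * m$coverage[qi], si, sum)
        den <- tapply(m$coverage[qi], si, sum)
        means[as.integer(names(num))] <- as.numeric(num) / as.numeric(den)
      } else {
        mm <- tapply(m$level[qi], si, mean)
        means[as.integer(names(mm))] <- as.numeric(mm)
      }
    }
    out[[paste0("mean_", names(methylomes)[i])]] <- means
    seen[[i]] <- unique(data.frame(bin = si, pos = m$pos[qi]))
  }
  allpos <- unique(do.call(rbind, seen))
  n_cpg <- integer(nrow(bins))
  if (nrow(allpos)) {
    cnt <- table(allpos$bin)
    n_cpg[as.integer(names(cnt))] <- as.integer(cnt)
  }
  out$n_cpg <- n_cpg
  mean_cols <- paste0("mean_", names(methylomes))
  out$development_average <-
    rowMeans(as.matrix(out[, mean_cols, drop = FALSE]), na.rm = TRUE)
  out$development_average[n_cpg == 0] <- NA_real_
  class(out) <- c("BinMethylation", "data.frame")
  out
}

#' Call demethylation-escapee bins
#'
#' A bin is an escapee when its development-average methylation is
#' strictly greater than `threshold` (default 0.4); otherwise it is
#' demethylated. Bins with no CpG (undefined level) are dropped.
#'
#' @param binmeth A `BinMethylation` table.
#' @param threshold Strict escapee threshold (default 0.4).
#' @return data.frame with bin columns, `development_average` and `label`
#'   (factor `escapee` / `demethylated`).
#' @export
call_escapee_bins <- function(binmeth, threshold = 0.4) {
  defined <- !is.na(binmeth$development_average)
  out <- binmeth[defined, c("chrom", "start", "end", "bin_id", "n_cpg",
                            "development_average")]
  out$label <- factor(ifelse(out$development_average > threshold,
                             "escapee", "demethylated"),
                      levels = c("escapee", "demethylated"))
  rownames(out) <- NULL
  out
}

#' Call escapee promoters
#'
#' A promoter inherits the escapee/demethylated label of the 5-kb bin
#' containing its TSS. Promoters whose TSS falls in a bin with no CpG are
#' excluded with a warning.
#'
#' @param genes Gene table ([read_genes()]).
#' @param bin_calls Output of [call_escapee_bins()].
#' @param bin_width Width of the bin tiling (default 5000).
#' @return data.frame `gene_id`, `bin_id`, `development_average`, `label`.
#' @export
call_escapee_promoters <- function(genes, bin_calls, bin_width = 5000) {
  key <- paste0(bin_calls$chrom, ":", bin_calls$start %/% bin_width)
  tss_key <- paste0(genes$chrom, ":", genes$tss %/% bin_width)
  idx <- match(tss_key, key)
  missing <- is.na(idx)
  if (any(missing))
    warning(sum(missing), " promoter(s) in bins with undefined methylation excluded")
  data.frame(gene_id = genes$gene_id[!missing],
             bin_id = bin_calls$bin_id[idx[!missing]],
             development_average = bin_calls$development_average[idx[!missing]],
             label = bin_calls$label[idx[!missing]],
             stringsAsFactors = FALSE)
}

#' Call escapee TE subfamilies
#'
#' Copy-level methylation is the mean CpG level over the copy (per sample,
#' then averaged across samples); the subfamily mean is the mean over its
#' covered copies. A subfamily is an escapee when its mean is at least
#' `threshold` (default 0.35, inclusive — deliberately asymmetric to the
#' strict 0.4 bin rule). Subfamilies with no CpG-covered copy are excluded
#' with a warning.
#'
#' @param repeats Repeat table ([read_repeats()]).
#' @param methylomes Named list of `MethylomeTable`s.
#' @param threshold Inclusive escapee threshold (default 0.35).
#' @return data.frame `subfamily`, `family`, `n_copies`, `n_covered`,
#'   `mean_methylation`, `label`.
#' @export
call_te_escapees <- function(repeats, methylomes, threshold = 0.35) {
  if (inherits(methylomes, "MethylomeTable")) methylomes <- list(methylomes)
  gr_rep <- as_granges(repeats[, c("chrom", "start", "end")])
  copy_means <- matrix(NA_real_, nrow = nrow(repeats), ncol = length(methylomes))
  for (i in seq_along(methylomes)) {
    m <- methylomes[[i]]
    gr_cpg <- GenomicRanges::GRanges(m$chrom,
                                     IRanges::IRanges(m$pos + 1, m$pos + 1))
    hits <- GenomicRanges::findOverlaps(gr_cpg, gr_rep)
    if (length(hits)) {
      mm <- tapply(m$level[S4Vectors::queryHits(hits)],
                   S4Vectors::subjectHits(hits), mean)
      copy_means[as.integer(names(mm)), i] <- as.numeric(mm)
    }
  }
  copy_mean <- rowMeans(copy_means, na.rm = TRUE)
  copy_mean[!is.finite(copy_mean)] <- NA_real_
  sub_mean <- tapply(copy_mean, repeats$subfamily,
                     function(x) mean(x, na.rm = TRUE))
  sub_mean[!is.finite(sub_mean)] <- NA_real_
  fam <- tapply(repeats$family, repeats$subfamily, function(x) x[1])
  n_copies <- tapply(rep(1, nrow(repeats)), repeats$subfamily, sum)
  n_covered <- tapply(!is.na(copy_mean), repeats$subfamily, sum)
  uncovered <- is.na(sub_mean)
  if (any(uncovered))
    warning("subfamilies with no CpG coverage excluded: ",
            paste(names(sub_mean)[uncovered], collapse = ", "))
  keep <- names(sub_mean)[!uncovered]
  data.frame(subfamily = keep, family = as.character(fam[keep]),
             n_copies = as.integer(n_copies[keep]),
             n_covered = as.integer(n_covered[keep]),
             mean_methylation = as.numeric(sub_mean[keep]),
             label = factor(ifelse(sub_mean[keep] >= threshold,
                                   "escapee", "demethylated"),
                            levels = c("escapee", "demethylated")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Partition escapee bins by repeat content
#'
#' A bin is repeat-rich when at least `rich_threshold` of its bases are
#' covered by the merged union of repeat copies, repeat-poor otherwise.
#'
#' @param bins data.frame of bins (e.g. escapee calls).
#' @param repeats Repeat table.
#' @param rich_threshold Covered-fraction cutoff (default 0.5).
#' @return `bins` with added `repeat_fraction` and `repeat_class` (factor
#'   `repeat-rich` / `repeat-poor`).
#' @export
partition_repeat_content <- function(bins, repeats, rich_threshold = 0.5) {
  frac <- if (nrow(bins) == 0L) numeric(0) else
    overlap_bases(bins, repeats) / (bins$end - bins$start)
  bins$repeat_fraction <- frac
  bins$repeat_class <- factor(ifelse(frac >= rich_threshold,
                                     "repeat-rich", "repeat-poor"),
                              levels = c("repeat-rich", "repeat-poor"))
  bins
}

# shared helper: per-group summaries + two-group tests over named
# quantities for a two-level grouping
group_compare <- function(quantities, group) {
  stopifnot(is.factor(group), nlevels(group) == 2)
  lv <- levels(group)
  rows <- list(); tests <- list()
  for (q in names(quantities)) {
    v <- quantities[[q]]
    a <- v[group == lv[1] & is.finite(v)]
    b <- v[group == lv[2] & is.finite(v)]
    rows[[q]] <- data.frame(quantity = q,
                            group = lv,
                            n = c(length(a), length(b)),
                            mean = c(mean(a), mean(b)),
                            median = c(stats::median(a), stats::median(b)),
                            stringsAsFactors = FALSE)
    if (length(a) >= 2 && length(b) >= 2) {
      tests[[q]] <- two_group_test(a, b)
    } else {
      warning("group with fewer than 2 members for '", q, "'; test skipped")
      tests[[q]] <- NULL
    }
  }
  list(summary = do.call(rbind, c(rows, make.row.names = FALSE)),
       tests = tests)
}

#' Chromatin and expression profile of escapee vs demethylated promoters
#'
#' Compares the five per-promoter quantities — H3K4me3, H3K27me3 and
#' H3K9me3 mean RPM over the promoter window, expression, and promoter
#' methylation — between escapee and demethylated promoters, with a
#' two-group test per quantity.
#'
#' @param promoter_calls Output of [call_escapee_promoters()].
#' @param genes Gene table.
#' @param tracks Named list of `SignalTrack`s, names among
#'   `H3K4me3`, `H3K27me3`, `H3K9me3`.
#' @param expr Numeric expression vector named by gene_id.
#' @param assembly A `GenomeAssembly`.
#' @param flank Promoter half-width (default 2000).
#' @return List with `summary` (per-group n/mean/median per quantity) and
#'   `tests` (named list of two-group tests).
#' @export
escapee_chromatin_profile <- function(promoter_calls, genes, tracks, expr,
                                      assembly, flank = 2000) {
  if (!all(levels(droplevels(promoter_calls$label)) %in%
             c("escapee", "demethylated")) ||
        length(unique(promoter_calls$label)) < 2)
    stop("both escapee and demethylated promoters are required")
  g <- genes[match(promoter_calls$gene_id, genes$gene_id), ]
  prom <- make_promoter(g$tss, g$chrom, assembly, flank)
  quantities <- list()
  for (mk in names(tracks))
    quantities[[mk]] <- rpm_over_region(tracks[[mk]], prom)
  quantities[["expression"]] <- unname(expr[promoter_calls$gene_id])
  quantities[["methylation"]] <- promoter_calls$development_average
  group_compare(quantities, factor(promoter_calls$label,
                                   levels = c("escapee", "demethylated")))
}
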