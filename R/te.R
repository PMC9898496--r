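# Transposable-element chromatin preference. Each repeat copy is scored
# by the ratio of its mean H3K4me3 to mean H3K9me3 signal (pseudocounted):
# above 1.33 it is H3K4me3-marked, below 0.66 H3K9me3-marked, otherwise
# ambiguous. Subfamilies are additionally ranked by methylation and
# expression, and genes are split into "around" (within +/- 10 kb of any
# copy) vs "distal" sets for positional-effect comparisons.

TE_LABELS <- c("H3K4me3-marked", "H3K9me3-marked", "ambiguous")

#' Chromatin-preference label for TE copies
#'
#' @param k4,k9 Numeric vectors of mean H3K4me3 / H3K9me3 RPM per copy.
#' @param pseudocount Added to both signals before the ratio (default
#'   0.01 RPM; guards zero H3K9me3 signal).
#' @param upper Ratio above which a copy is H3K4me3-marked (default 1.33).
#' @param lower Ratio below which a copy is H3K9me3-marked (default 0.66).
#' @return List with `ratio` and `label` (factor over the three classes).
#' @examples
#' copy_preference(c(2, 0.5, 1), c(1, 1, 1))
#' @export
copy_preference <- function(k4, k9, pseudocount = 0.01,
                            upper = 1.33, lower = 0.66) {
  stopifnot(length(k4) == length(k9))
  if (any(k4 < 0) || any(k9 < 0)) stop("signals must be >= 0")
  ratio <- (k4 + pseudocount) / (k9 + pseudocount)
  label <- factor(ifelse(ratio > upper, "H3K4me3-marked",
                         ifelse(ratio < lower, "H3K9me3-marked", "ambiguous")),
                  levels = TE_LABELS)
  list(ratio = ratio, label = label)
}

#' Preference calls for all copies of a repeat annotation
#'
#' Computes mean RPM of both marks over each copy and applies
#' [copy_preference()]. Copies shorter than `min_copy_len` are excluded
#' (their signal mean is unstable).
#'
#' @param repeats Repeat table ([read_repeats()]).
#' @param k4_track,k9_track `SignalTrack`s for H3K4me3 and H3K9me3.
#' @param pseudocount,upper,lower Passed to [copy_preference()].
#' @param min_copy_len Minimum copy length in bp (default 50).
#' @return data.frame: repeat columns plus `k4_signal`, `k9_signal`,
#'   `ratio`, `label`.
#' @export
te_copy_preferences <- function(repeats, k4_track, k9_track,
                                pseudocount = 0.01, upper = 1.33,
                                lower = 0.66, min_copy_len = 50) {
  keep <- (repeats$end - repeats$start) >= min_copy_len
  df <- repeats[keep, , drop = FALSE]
  df$k4_signal <- rpm_over_region(k4_track, df)
  df$k9_signal <- rpm_over_region(k9_track, df)
  pref <- copy_preference(df$k4_signal, df$k9_signal, pseudocount,
                          upper, lower)
  df$ratio <- pref$ratio
  df$label <- pref$label
  rownames(df) <- NULL
  df
}

#' Per-subfamily preference proportions
#'
#' @param prefs Output of [te_copy_preferences()].
#' @return data.frame `subfamily`, `family`, `n`, and one proportion
#'   column per label; proportions sum to 1 per subfamily.
#' @export
subfamily_preference_summary <- function(prefs) {
  tab <- table(prefs$subfamily, prefs$label)
  prop <- tab / rowSums(tab)
  fam <- tapply(prefs$family, prefs$subfamily, function(x) x[1])
  out <- data.frame(subfamily = rownames(tab),
                    family = as.character(fam[rownames(tab)]),
                    n = as.integer(rowSums(tab)),
                    stringsAsFactors = FALSE)
  for (lab in colnames(prop)) out[[lab]] <- as.numeric(prop[, lab])
  out$majority <- TE_LABELS[apply(prop, 1, which.max)]
  rownames(out) <- NULL
  out
}

#' Methylation + expression rank-sum score per TE subfamily
#'
#' Subfamilies are ranked ascending (rank 1 = lowest) on mean methylation
#' and on expression separately, with average ranks on ties; the score is
#' the sum of the two ranks, so a high score means both high methylation
#' and high expression.
#'
#' @param methylation Named numeric vector of subfamily mean methylation.
#' @param expression Named numeric vector of subfamily expression
#'   (per-million normalized counts), same names.
#' @return data.frame `subfamily`, `meth_rank`, `expr_rank`, `rank_sum`,
#'   sorted by descending `rank_sum`; subfamilies missing either quantity
#'   are excluded with a warning.
#' @export
rank_sum_score <- function(methylation, expression) {
  shared <- intersect(names(methylation), names(expression))
  dropped <- setdiff(union(names(methylation), names(expression)), shared)
  shared <- shared[is.finite(methylation[shared]) &
                     is.finite(expression[shared])]
  if (length(dropped))
    warning("subfamilies missing a quantity excluded: ",
            paste(dropped, collapse = ", "))
  if (length(shared) < 2) stop("need at least 2 subfamilies with both quantities")
  mr <- rank(methylation[shared], ties.method = "average")
  er <- rank(expression[shared], ties.method = "average")
  out <- data.frame(subfamily = shared, meth_rank = as.numeric(mr),
                    expr_rank = as.numeric(er), rank_sum = as.numeric(mr + er),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$rank_sum, out$subfamily), ]
  rownames(out) <- NULL
  out
}

#' Split genes into around vs distal sets for a TE subfamily
#'
#' A gene is "around" when the minimum distance between its gene body and
#' any copy of the subfamily is at most `window` bp (overlap counts as
#' distance 0); all other genes are "distal". The two sets partition the
#' gene universe.
#'
#' @param repeats Repeat table.
#' @param genes Gene table.
#' @param subfamily Subfamily name.
#' @param window Distance cutoff in bp (default 10000).
#' @return Factor (`around` / `distal`) named by gene_id.
#' @export
proximal_distal_split <- function(repeats, genes, subfamily, window = 10000) {
  copies <- repeats[repeats$subfamily == subfamily, , drop = FALSE]
  if (nrow(copies) == 0L) stop("no copies of subfamily '", subfamily, "'")
  # expand copies by window + 1; >= 1 bp overlap with the expansion is
  # then exactly gap <= window under the half-open convention (a gap of g
  # bases leaves g bases between the intervals)
  expanded <- data.frame(chrom = copies$chrom,
                         start = pmax(0, copies$start - window - 1),
                         end = copies$end + window + 1)
  around <- overlaps_any(genes[, c("chrom", "start", "end")], expanded)
  setNames(factor(ifelse(around, "around", "distal"),
                  levels = c("around", "distal")), genes$gene_id)
}

#' Positional-effect report for a TE subfamily
#'
#' Compares H3K4me3 / H3K27me3 / H3K9me3 promoter signal, expression and
#' promoter methylation between genes around the subfamily's copies and
#' distal genes, with a two-group test per quantity.
#'
#' @param split Factor from [proximal_distal_split()].
#' @param genes Gene table.
#' @param tracks Named list of `SignalTrack`s.
#' @param expr Numeric expression vector named by gene_id.
#' @param prom_meth Optional numeric promoter methylation named by
#'   gene_id.
#' @param assembly A `GenomeAssembly`.
#' @param flank Promoter half-width (default 2000).
#' @return List with `summary` and `tests` (see [escapee_chromatin_profile()]).
#' @export
positional_effect_report <- function(split, genes, tracks, expr,
                                     prom_meth = NULL, assembly,
                                     flank = 2000) {
  if (any(table(split) == 0)) stop("both around and distal sets must be non-empty")
  g <- genes[match(names(split), genes$gene_id), ]
  prom <- make_promoter(g$tss, g$chrom, assembly, flank)
  quantities <- list()
  for (mk in names(tracks))
    quantities[[mk]] <- rpm_over_region(tracks[[mk]], prom)
  quantities[["expression"]] <- unname(expr[names(split)])
  if (!is.null(prom_meth))
    quantities[["methylation"]] <- unname(prom_meth[names(split)])
  group_compare(quantities, split)
}
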