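# Four-state promoter chromatin classification and its dynamics across
# developmental stages. A promoter is "covered" by a mark when at least
# min_overlap_bp bases of a called peak fall inside the TSS +/- 2 kb
# window; carrying both H3K4me3 and H3K27me3 makes it bivalent.

PROMOTER_STATES <- c("H3K4me3-only", "H3K27me3-only", "bivalent", "unmarked")

#' Classify promoters into four chromatin states
#'
#' @param promoters data.frame of promoter windows with `gene_id`,
#'   `chrom`, `start`, `end` (see [gene_promoters()]).
#' @param k4_peaks,k27_peaks `PeakSet`s for H3K4me3 and H3K27me3.
#' @param min_overlap_bp Minimum peak/promoter overlap in bp counted as
#'   coverage (default 1, the most permissive reading).
#' @return Factor of states (`H3K4me3-only`, `H3K27me3-only`, `bivalent`,
#'   `unmarked`), named by `gene_id`. The four states partition the
#'   promoter universe.
#' @export
classify_promoters <- function(promoters, k4_peaks, k27_peaks,
                               min_overlap_bp = 1) {
  has_k4 <- overlaps_any(promoters, k4_peaks, min_overlap_bp)
  has_k27 <- overlaps_any(promoters, k27_peaks, min_overlap_bp)
  state <- ifelse(has_k4 & has_k27, "bivalent",
                  ifelse(has_k4, "H3K4me3-only",
                         ifelse(has_k27, "H3K27me3-only", "unmarked")))
  setNames(factor(state, levels = PROMOTER_STATES), promoters$gene_id)
}

#' Promoter-state dynamics across ordered stages
#'
#' Builds the per-transition 4x4 count matrix between each pair of
#' consecutive stages (the alluvial-plot bookkeeping) and, for each stage
#' after the first, the source-state composition of newly bivalent
#' promoters (bivalent now, not bivalent before).
#'
#' @param states_by_stage Named list (in stage order) of state factors as
#'   returned by [classify_promoters()]; every stage must cover the same
#'   promoter universe.
#' @return List of class `StateDynamics` with elements `stages`,
#'   `totals` (stage x state counts), `transitions` (list of 4x4 matrices,
#'   rows = state at the earlier stage) and `gained_bivalent` (stage x
#'   source-state counts).
#' @export
state_dynamics <- function(states_by_stage) {
  if (length(states_by_stage) < 2)
    stop("need at least two stages")
  stages <- names(states_by_stage)
  universe <- names(states_by_stage[[1]])
  for (s in stages) {
    diff <- c(setdiff(universe, names(states_by_stage[[s]])),
              setdiff(names(states_by_stage[[s]]), universe))
    if (length(diff))
      stop("promoter universe differs at stage '", s, "': ",
           paste(utils::head(diff, 5), collapse = ", "),
           if (length(diff) > 5) " ..." else "")
  }
  totals <- t(vapply(states_by_stage,
                     function(s) table(factor(s, levels = PROMOTER_STATES)),
                     numeric(4)))
  transitions <- list()
  gained <- matrix(0, nrow = length(stages) - 1, ncol = 4,
                   dimnames = list(stages[-1], PROMOTER_STATES))
  for (i in seq_len(length(stages) - 1)) {
    from <- states_by_stage[[i]][universe]
    to <- states_by_stage[[i + 1]][universe]
    tm <- table(factor(from, PROMOTER_STATES), factor(to, PROMOTER_STATES))
    transitions[[paste(stages[i], stages[i + 1], sep = "->")]] <-
      unclass(as.matrix(tm))
    new_biv <- to == "bivalent" & from != "bivalent"
    gained[i, ] <- table(factor(from[new_biv], PROMOTER_STATES))
  }
  structure(list(stages = stages, totals = totals, transitions = transitions,
                 gained_bivalent = gained),
            class = "StateDynamics")
}

#' @export
print.StateDynamics <- function(x, ...) {
  cat("StateDynamics over stages:", paste(x$stages, collapse = " -> "), "\n")
  print(x$totals)
  invisible(x)
}

#' Split genes into expression tertiles
#'
#' Genes are ranked by expression (ascending, ties broken by a stable sort
#' on gene id for determinism) and split at ranks ceiling(n/3) and
#' ceiling(2n/3) into low / medium / high groups; group sizes differ by at
#' most 1.
#'
#' @param expr Numeric vector of expression values (e.g. FPKM), named by
#'   gene id.
#' @return Factor with levels `L-exp`, `M-exp`, `H-exp`, named like
#'   `expr`.
#' @export
expression_tertiles <- function(expr) {
  n <- length(expr)
  if (n < 3) stop("need at least 3 genes")
  ord <- order(expr, names(expr), method = "radix")
  cut1 <- ceiling(n / 3); cut2 <- ceiling(2 * n / 3)
  grp <- character(n)
  grp[ord[seq_len(cut1)]] <- "L-exp"
  grp[ord[seq(cut1 + 1, cut2)]] <- "M-exp"
  grp[ord[seq(cut2 + 1, n)]] <- "H-exp"
  setNames(factor(grp, levels = c("L-exp", "M-exp", "H-exp")), names(expr))
}

#' Associate promoter states with expression
#'
#' Summarizes expression by chromatin state, tests expression between
#' promoters with and without H3K27me3 (H3K27me3-only or bivalent versus
#' the rest), and reports mean mark signal per expression tertile when a
#' track is supplied.
#'
#' @param states State factor named by gene_id ([classify_promoters()]).
#' @param expr Numeric expression vector named by gene_id.
#' @param track Optional `SignalTrack` for per-tertile mean mark signal.
#' @param genes Gene table; required when `track` is given.
#' @param flank Promoter half-width for the tertile signal (default 2000).
#' @return List with `by_state` (per-state n / mean / median expression),
#'   `k27_test` (two-group test of with- vs without-H3K27me3, or NULL if a
#'   group has < 2 members) and `tertile_signal` (per-tertile mean RPM, or
#'   NULL without a track).
#' @export
state_expression_association <- function(states, expr, track = NULL,
                                         genes = NULL, flank = 2000) {
  shared <- intersect(names(states), names(expr))
  if (length(shared) == 0L) stop("states and expression share no genes")
  st <- states[shared]; ex <- expr[shared]
  by_state <- data.frame(
    state = PROMOTER_STATES,
    n = as.integer(table(st)[PROMOTER_STATES]),
    mean_expr = as.numeric(tapply(ex, st, mean)[PROMOTER_STATES]),
    median_expr = as.numeric(tapply(ex, st, stats::median)[PROMOTER_STATES]),
    stringsAsFactors = FALSE)
  with_k27 <- ex[st %in% c("H3K27me3-only", "bivalent")]
  without_k27 <- ex[!st %in% c("H3K27me3-only", "bivalent")]
  k27_test <- if (length(with_k27) >= 2 && length(without_k27) >= 2) {
    two_group_test(with_k27, without_k27)
  } else {
    warning("a group has fewer than 2 members; H3K27me3 test skipped")
    NULL
  }
  tertile_signal <- NULL
  if (!is.null(track)) {
    stopifnot(!is.null(genes))
    g <- genes[match(shared, genes$gene_id), ]
    tert <- expression_tertiles(ex)
    asm <- assembly(track$lengths,
                    sex_chromosome = names(track$lengths)[length(track$lengths)])
    prom <- make_promoter(g$tss, g$chrom, asm, flank)
    sig <- rpm_over_region(track, prom)
    tertile_signal <- tapply(sig, tert, mean)
  }
  list(by_state = by_state, k27_test = k27_test,
       tertile_signal = tertile_signal)
}
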