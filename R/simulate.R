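# Synthetic epigenome generator. Emits a complete toy data set — assembly,
# gene and repeat annotation, per-sample peak files and signal tracks for
# three histone marks, per-CpG methylomes, gene and TE expression tables —
# with planted ground truth written alongside under truth/. The seed fully
# determines every output byte.
#
# Layout of the toy genome (per chromosome): the first 70% is gene
# territory holding evenly spaced genes; the remainder is repeat/escapee
# territory holding TE-proximal gene cassettes, standalone TE copies (one
# per 5-kb bin) and the planted hypermethylated escapee bins, separated by
# a guard gap so that planted effects never bleed across analyses.

#' Default transposable-element subfamily roster
#'
#' Planted H3K4me3:H3K9me3 signal ratios follow the three-class design
#' (2.0 = H3K4me3-marked, 0.5 = H3K9me3-marked, 1.0 = ambiguous);
#' methylation and expression are per-subfamily planted means.
#'
#' @return data.frame `subfamily`, `family`, `k4k9_ratio`, `methylation`,
#'   `expression`.
#' @export
default_te_roster <- function() {
  data.frame(
    subfamily = c("SVA_A", "SVA_B", "SVA_C", "SVA_D", "SVA_E", "SVA_F",
                  "LTR5_Hs", "LTR14", "L1HS", "L1PA2", "L1PA3"),
    family = c(rep("SVA", 6), "ERVK", "ERVK", "L1", "L1", "L1"),
    k4k9_ratio = c(0.5, 0.5, 0.5, 2.0, 2.0, 1.0, 2.0, 0.5, 1.0, 0.5, 0.5),
    methylation = c(0.55, 0.50, 0.48, 0.45, 0.42, 0.40, 0.38, 0.25,
                    0.15, 0.08, 0.05),
    expression = c(400, 500, 600, 3500, 3000, 1500, 5000, 700, 900,
                   300, 200),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults define the study conditions the generator emulates: a
#' 13-Mb toy genome (two 5-Mb autosomes plus a 3-Mb X), 2000 genes with
#' ~10% on chrX, a globally hypomethylated background (mean 0.03) with 2%
#' of 5-kb bins planted as hypermethylated escapees (true level ~
#' Beta(14, 6), mean 0.7, resampled above `escapee_level_min`), TE
#' subfamilies with distinct H3K4me3:H3K9me3 balances, promoter-enriched
#' H3K4me3 coupled to expression, sparse H3K27me3 marking lowly expressed
#' bivalent promoters, female-specific H3K27me3/H3K9me3 elevation on
#' chrX, and female X output dampened to `x_dosage_factor` times the male
#' single-X fraction.
#'
#' @param seed Integer seed; fully determines every output byte.
#' @param chrom_lengths Named chromosome lengths in bp.
#' @param sex_chromosome Name of the X-equivalent chromosome.
#' @param n_genes Total genes (grid + TE-cassette + escapee-bin genes).
#' @param frac_chrx Fraction of genes on the sex chromosome.
#' @param frac_cgi Fraction of promoters flagged as CpG-island promoters.
#' @param gene_territory_frac Fraction of each chromosome reserved for the
#'   regular gene grid; the rest hosts repeats and escapee bins.
#' @param cpg_spacing CpG grid spacing in bp (one CpG per `cpg_spacing`).
#' @param background_meth Background CpG methylation mean.
#' @param escapee_bin_fraction Fraction of genome bins planted as
#'   escapees.
#' @param escapee_level_shape Beta shape parameters of the true escapee
#'   bin level.
#' @param escapee_level_min Lower truncation of the true escapee level
#'   (resampled below it) so planted escapees stay identifiable.
#' @param meth_concentration Beta concentration of per-CpG noise around
#'   the planted mean.
#' @param bin_width Escapee bin width in bp.
#' @param track_bin_width Signal-track bin width in bp.
#' @param track_background Background track level (RPM).
#' @param track_noise_shape Gamma shape of track noise (mean preserved).
#' @param fpkm_sdlog Log-normal sigma of expression noise (mean
#'   preserved).
#' @param base_expr_meanlog,base_expr_sdlog Log-normal parameters of the
#'   per-gene baseline expression.
#' @param x_dosage_factor Planted female/male X expression-fraction ratio.
#' @param weeks_female,weeks_male Gestational weeks of the PGC samples.
#' @param te_roster TE subfamily roster (see [default_te_roster()]).
#' @param n_te_copies Copies per subfamily.
#' @param n_te_cassette Gene cassettes per positional-effect subfamily
#'   (LTR5_Hs and LTR14).
#' @param n_escapee_promoters Escapee bins hosting a gene promoter.
#' @param state_props Planted PGC promoter-state proportions, in the
#'   order H3K4me3-only, H3K27me3-only, bivalent, unmarked.
#' @param soma_state_props Same for somatic samples.
#' @param noise Emit sampling noise (FALSE gives the noise-free fixture
#'   in which every truth table is exactly recoverable).
#' @return List of class `SimConfig`.
#' @export
sim_config <- function(seed = 1,
                       chrom_lengths = c(chr1 = 5e6, chr2 = 5e6, chrX = 3e6),
                       sex_chromosome = "chrX",
                       n_genes = 2000, frac_chrx = 0.10, frac_cgi = 0.6,
                       gene_territory_frac = 0.7,
                       cpg_spacing = 100, background_meth = 0.03,
                       escapee_bin_fraction = 0.02,
                       escapee_level_shape = c(14, 6),
                       escapee_level_min = 0.45,
                       meth_concentration = 30,
                       bin_width = 5000, track_bin_width = 100,
                       track_background = 0.1, track_noise_shape = 4,
                       fpkm_sdlog = 0.12,
                       base_expr_meanlog = 1.5, base_expr_sdlog = 0.6,
                       x_dosage_factor = 1.6,
                       weeks_female = c(9, 14, 21),
                       weeks_male = c(9, 15, 23),
                       te_roster = default_te_roster(),
                       n_te_copies = 30, n_te_cassette = 12,
                       n_escapee_promoters = 20,
                       state_props = c(0.45, 0.05, 0.10, 0.40),
                       soma_state_props = c(0.35, 0.15, 0.03, 0.47),
                       noise = TRUE) {
  fracs <- c(frac_chrx, frac_cgi, gene_territory_frac, escapee_bin_fraction,
             background_meth, state_props, soma_state_props)
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must be in [0, 1]")
  if (abs(sum(state_props) - 1) > 1e-9 || abs(sum(soma_state_props) - 1) > 1e-9)
    stop("state proportions must sum to 1")
  if (x_dosage_factor <= 0) stop("x_dosage_factor must be > 0")
  cfg <- list(seed = seed, chrom_lengths = chrom_lengths,
              sex_chromosome = sex_chromosome, n_genes = n_genes,
              frac_chrx = frac_chrx, frac_cgi = frac_cgi,
              gene_territory_frac = gene_territory_frac,
              cpg_spacing = cpg_spacing, background_meth = background_meth,
              escapee_bin_fraction = escapee_bin_fraction,
              escapee_level_shape = escapee_level_shape,
              escapee_level_min = escapee_level_min,
              meth_concentration = meth_concentration,
              bin_width = bin_width, track_bin_width = track_bin_width,
              track_background = track_background,
              track_noise_shape = track_noise_shape,
              fpkm_sdlog = fpkm_sdlog,
              base_expr_meanlog = base_expr_meanlog,
              base_expr_sdlog = base_expr_sdlog,
              x_dosage_factor = x_dosage_factor,
              weeks_female = weeks_female, weeks_male = weeks_male,
              te_roster = te_roster, n_te_copies = n_te_copies,
              n_te_cassette = n_te_cassette,
              n_escapee_promoters = n_escapee_promoters,
              state_props = state_props,
              soma_state_props = soma_state_props, noise = noise)
  class(cfg) <- "SimConfig"
  cfg
}

# sample roster: 6 PGC samples (2 sexes x 3 stages) + 2 somatic controls
sim_samples <- function(config) {
  wf <- config$weeks_female; wm <- config$weeks_male
  df <- data.frame(
    sample = c(paste0("F_PGC_", as.character(assign_stage(wf))),
               paste0("M_PGC_", as.character(assign_stage(wm))),
               "F_soma_early", "M_soma_early"),
    sex = c(rep("F", length(wf)), rep("M", length(wm)), "F", "M"),
    lineage = c(rep("PGC", length(wf) + length(wm)), "soma", "soma"),
    week = c(wf, wm, 9, 9),
    stringsAsFactors = FALSE)
  df$stage <- as.character(assign_stage(df$week))
  df
}

# ---- layout construction (gene grid, TE placement, escapee bins) -------

build_layout <- function(config, asm) {
  bw <- config$bin_width
  chroms <- names(asm$lengths)
  autosomes <- setdiff(chroms, asm$sex_chromosome)
  guard_bins <- 3

  n_cassette_genes <- 2 * config$n_te_cassette
  n_grid <- config$n_genes - n_cassette_genes - config$n_escapee_promoters
  n_x <- round(config$n_genes * config$frac_chrx)
  n_auto <- n_grid - n_x
  per_auto <- diff(round(seq(0, n_auto, length.out = length(autosomes) + 1)))
  grid_counts <- setNames(c(per_auto, n_x), c(autosomes, asm$sex_chromosome))

  genes <- list()
  gid <- 0
  for (ch in chroms) {
    n <- grid_counts[[ch]]
    territory <- floor(asm$lengths[[ch]] * config$gene_territory_frac)
    centers <- territory * (seq_len(n) - 0.5) / n
    tss <- round(centers + stats::runif(n, -200, 200))
    tss <- pmax(2500, pmin(territory - 2500, tss))
    len <- sample(1000:3000, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    len <- ifelse(strand == "-", pmin(len, tss + 1), len)
    start <- ifelse(strand == "+", tss, tss + 1 - len)
    end <- ifelse(strand == "+", tss + len, tss + 1)
    genes[[ch]] <- data.frame(
      gene_id = sprintf("G%04d", gid + seq_len(n)), chrom = ch,
      start = start, end = end, strand = strand,
      cgi_promoter = stats::runif(n) < config$frac_cgi, tss = tss,
      role = "grid", cassette_subfamily = NA_character_,
      stringsAsFactors = FALSE)
    gid <- gid + n
  }
  genes <- do.call(rbind, genes)

  # repeat/escapee territory bin bookkeeping per chromosome
  first_bin <- function(ch) {
    floor(asm$lengths[[ch]] * config$gene_territory_frac / bw) + guard_bins
  }
  last_bin <- function(ch) floor((asm$lengths[[ch]] - 1) / bw)

  # TE cassettes: 6 consecutive bins each, at the start of the autosomal
  # repeat territory, alternating LTR5_Hs / LTR14
  cassette_subfams <- rep(c("LTR5_Hs", "LTR14"), config$n_te_cassette)
  per_chrom_cassettes <- split(seq_along(cassette_subfams),
                               rep(autosomes,
                                   length.out = length(cassette_subfams)))
  cassettes <- list(); cassette_genes <- list()
  used_bins <- list()
  for (ch in autosomes) used_bins[[ch]] <- integer(0)
  for (ch in names(per_chrom_cassettes)) {
    ids <- per_chrom_cassettes[[ch]]
    for (k in seq_along(ids)) {
      b0 <- first_bin(ch) + (k - 1) * 6
      used_bins[[ch]] <- c(used_bins[[ch]], b0 + 0:5)
      region_start <- b0 * bw
      copy_len <- round(stats::runif(1, 600, 1400))
      copy_start <- region_start + 7000
      gap <- round(stats::runif(1, 3000, 8000))
      g_tss <- copy_start + copy_len + gap
      g_len <- 1500
      cassettes[[length(cassettes) + 1]] <- data.frame(
        chrom = ch, start = copy_start, end = copy_start + copy_len,
        strand = "+", subfamily = cassette_subfams[ids[k]],
        stringsAsFactors = FALSE)
      cassette_genes[[length(cassette_genes) + 1]] <- data.frame(
        gene_id = NA_character_, chrom = ch, start = g_tss,
        end = g_tss + g_len, strand = "+",
        cgi_promoter = stats::runif(1) < config$frac_cgi, tss = g_tss,
        role = "te_cassette", cassette_subfamily = cassette_subfams[ids[k]],
        stringsAsFactors = FALSE)
    }
  }
  cassettes <- do.call(rbind, cassettes)
  cassette_genes <- do.call(rbind, cassette_genes)

  # standalone TE copies: one per free autosomal repeat-territory bin
  roster <- config$te_roster
  standalone <- list()
  need <- setNames(rep(config$n_te_copies, nrow(roster)), roster$subfamily)
  need["LTR5_Hs"] <- need["LTR5_Hs"] - config$n_te_cassette
  need["LTR14"] <- need["LTR14"] - config$n_te_cassette
  if (any(need < 0)) stop("n_te_cassette exceeds n_te_copies")
  sub_seq <- rep(roster$subfamily, times = need[roster$subfamily])
  free <- unlist(lapply(autosomes, function(ch) {
    b <- setdiff(seq(first_bin(ch), last_bin(ch)), used_bins[[ch]])
    paste0(ch, ":", b)
  }))
  if (length(sub_seq) > length(free))
    stop("not enough repeat-territory bins for TE copies")
  take <- free[seq_along(sub_seq)]
  te_chrom <- sub("^(.*):.*$", "\\1", take)
  te_bin <- as.integer(sub("^.*:", "", take))
  copy_len <- round(stats::runif(length(sub_seq), 600, 1800))
  offset <- round(stats::runif(length(sub_seq), 200,
                               bw - copy_len - 200))
  standalone <- data.frame(
    chrom = te_chrom, start = te_bin * bw + offset,
    end = te_bin * bw + offset + copy_len,
    strand = sample(c("+", "-"), length(sub_seq), replace = TRUE),
    subfamily = sub_seq, stringsAsFactors = FALSE)
  for (i in seq_along(te_chrom))
    used_bins[[te_chrom[i]]] <- c(used_bins[[te_chrom[i]]], te_bin[i])

  repeats <- rbind(cassettes, standalone)
  repeats$family <- roster$family[match(repeats$subfamily, roster$subfamily)]
  repeats <- repeats[order(match(repeats$chrom, chroms), repeats$start),
                     c("chrom", "start", "end", "strand", "family",
                       "subfamily")]
  rownames(repeats) <- NULL
  repeats$copy_id <- sprintf("%s_c%03d", repeats$subfamily,
                             stats::ave(seq_len(nrow(repeats)),
                                        repeats$subfamily,
                                        FUN = seq_along))

  # escapee bins from the remaining repeat-territory bins (incl. chrX)
  used_bins[[asm$sex_chromosome]] <- integer(0)
  pool <- unlist(lapply(chroms, function(ch) {
    b <- setdiff(seq(first_bin(ch), last_bin(ch)),
                 if (ch %in% names(used_bins)) used_bins[[ch]] else integer(0))
    paste0(ch, ":", b)
  }))
  n_bins_total <- sum(floor(asm$lengths / bw) + (asm$lengths %% bw > 0))
  n_esc <- floor(config$escapee_bin_fraction * n_bins_total)
  if (n_esc > length(pool)) stop("not enough free bins for escapee planting")
  esc <- sample(pool, n_esc)
  esc_chrom <- sub(":.*$", "", esc)
  esc_bin <- as.integer(sub("^.*:", "", esc))
  # true escapee level: Beta, resampled above the truncation point
  a <- config$escapee_level_shape[1]; b <- config$escapee_level_shape[2]
  lv <- stats::rbeta(n_esc, a, b)
  while (any(lv < config$escapee_level_min))
    lv[lv < config$escapee_level_min] <-
      stats::rbeta(sum(lv < config$escapee_level_min), a, b)
  escapee_bins <- data.frame(
    chrom = esc_chrom, start = esc_bin * bw,
    end = pmin(esc_bin * bw + bw, asm$lengths[esc_chrom]),
    level = lv, stringsAsFactors = FALSE)
  escapee_bins <- escapee_bins[order(match(escapee_bins$chrom, chroms),
                                     escapee_bins$start), ]
  rownames(escapee_bins) <- NULL
  escapee_bins$bin_id <- paste0(escapee_bins$chrom, ":",
                                format_bp(escapee_bins$start), "-",
                                format_bp(escapee_bins$end))

  # genes inside escapee bins (promoter fully within the 5-kb bin)
  k <- min(config$n_escapee_promoters, nrow(escapee_bins))
  host <- sort(sample(seq_len(nrow(escapee_bins)), k))
  esc_genes <- data.frame(
    gene_id = NA_character_, chrom = escapee_bins$chrom[host],
    start = escapee_bins$start[host] + 2500,
    end = escapee_bins$start[host] + 3500, strand = "+",
    cgi_promoter = FALSE, tss = escapee_bins$start[host] + 2500,
    role = "escapee_prom", cassette_subfamily = NA_character_,
    stringsAsFactors = FALSE)

  genes <- rbind(genes, cassette_genes, esc_genes)
  genes <- genes[order(match(genes$chrom, chroms), genes$start), ]
  rownames(genes) <- NULL
  genes$gene_id <- sprintf("G%04d", seq_len(nrow(genes)))
  genes$chrx <- genes$chrom == asm$sex_chromosome

  list(genes = genes, repeats = repeats, escapee_bins = escapee_bins)
}

# minimum gap (bp) between gene bodies and any copy of each subfamily —
# brute force, used only to write the around-genes truth table
around_truth <- function(genes, repeats, window = 10000) {
  out <- list()
  for (sf in unique(repeats$subfamily)) {
    copies <- repeats[repeats$subfamily == sf, ]
    near <- vapply(seq_len(nrow(genes)), function(i) {
      same <- copies$chrom == genes$chrom[i]
      if (!any(same)) return(FALSE)
      gap <- pmax(0, pmax(copies$start[same] - genes$end[i],
                          genes$start[i] - copies$end[same]))
      any(gap <= window)
    }, logical(1))
    if (any(near))
      out[[sf]] <- data.frame(subfamily = sf,
                              gene_id = genes$gene_id[near],
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

# ---- planted states and expression -------------------------------------

plant_states <- function(config, genes, samples) {
  m <- matrix(NA_character_, nrow = nrow(genes), ncol = nrow(samples),
              dimnames = list(genes$gene_id, samples$sample))
  for (j in seq_len(nrow(samples))) {
    props <- if (samples$lineage[j] == "PGC") config$state_props
             else config$soma_state_props
    m[, j] <- sample(PROMOTER_STATES, nrow(genes), replace = TRUE,
                     prob = props)
  }
  # forced roles: TE-proximal LTR5_Hs genes are active; genes in escapee
  # bins carry the bin's repressive marks (PGC samples only)
  ltr5 <- which(genes$role == "te_cassette" &
                  genes$cassette_subfamily == "LTR5_Hs")
  m[ltr5, ] <- "H3K4me3-only"
  escp <- which(genes$role == "escapee_prom")
  for (j in seq_len(nrow(samples)))
    m[escp, j] <- if (samples$lineage[j] == "PGC") "H3K27me3-only"
                  else "unmarked"
  m
}

plant_expression_means <- function(config, genes, samples, states,
                                   base_expr) {
  m <- matrix(0, nrow = nrow(genes), ncol = nrow(samples),
              dimnames = list(genes$gene_id, samples$sample))
  for (j in seq_len(nrow(samples))) {
    st <- states[, j]
    mu <- ifelse(st == "H3K4me3-only", base_expr,
                 ifelse(st == "bivalent", 0.05,
                        ifelse(st == "H3K27me3-only", 0.2, 0.5)))
    mu[genes$role == "te_cassette" &
         genes$cassette_subfamily == "LTR5_Hs"] <-
      5 * base_expr[genes$role == "te_cassette" &
                      genes$cassette_subfamily == "LTR5_Hs"]
    mu[genes$role == "escapee_prom"] <- 0.05
    m[, j] <- mu
  }
  # dampen/scale female PGC chrX output so the planted female/male ratio
  # of X expression fractions equals x_dosage_factor exactly
  f <- config$x_dosage_factor
  on_x <- genes$chrx
  for (j in which(samples$sex == "F" & samples$lineage == "PGC")) {
    jm <- which(samples$sex == "M" & samples$lineage == "PGC" &
                  samples$stage == samples$stage[j])[1]
    mu_m <- m[, jm]; mu_f <- m[, j]
    p_m <- sum(mu_m[on_x]) / sum(mu_m)
    p_f <- f * p_m
    if (p_f >= 1) stop("x_dosage_factor too large for this gene set")
    g <- p_f * sum(mu_f[!on_x]) / (sum(mu_f[on_x]) * (1 - p_f))
    m[on_x, j] <- g * mu_f[on_x]
  }
  m
}

# mean-preserving log-normal noise
lognoise <- function(mu, sdlog, noise) {
  if (!noise || sdlog == 0) return(mu)
  mu * stats::rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# ---- track assembly ----------------------------------------------------

# add `amp` to all track bins overlapping [start, end)
add_amp <- function(means, chrom, start, end, amp, bw) {
  for (i in seq_along(start)) {
    lo <- start[i] %/% bw + 1
    hi <- (end[i] - 1) %/% bw + 1
    v <- means[[chrom[i]]]
    hi <- min(hi, length(v))
    means[[chrom[i]]][lo:hi] <- v[lo:hi] + amp[i]
  }
  means
}

build_track_means <- function(config, asm, mark, sample_row, genes, states,
                              expr_means, repeats, escapee_bins) {
  bw <- config$track_bin_width
  means <- lapply(asm$lengths,
                  function(len) rep(config$track_background,
                                    ceiling(len / bw)))
  j <- sample_row$sample
  st <- states[, j]
  is_pgc <- sample_row$lineage == "PGC"
  prom <- data.frame(chrom = genes$chrom,
                     start = pmax(0, genes$tss - 2000),
                     end = pmin(asm$lengths[genes$chrom], genes$tss + 2000))
  if (mark == "H3K4me3") {
    cov <- st %in% c("H3K4me3-only", "bivalent")
    amp <- 0.3 + 0.6 * log1p(expr_means[, j])
    means <- add_amp(means, genes$chrom[cov], prom$start[cov],
                     prom$end[cov], amp[cov], bw)
    if (is_pgc) {
      r <- config$te_roster
      k4 <- 2 * r$k4k9_ratio[match(repeats$subfamily, r$subfamily)]
      means <- add_amp(means, repeats$chrom, repeats$start, repeats$end,
                       k4, bw)
      if (sample_row$sex == "F") {
        xcgi <- genes$chrx & genes$cgi_promoter
        means <- add_amp(means, genes$chrom[xcgi], prom$start[xcgi],
                         prom$end[xcgi], rep(1.0, sum(xcgi)), bw)
      }
    }
  } else if (mark == "H3K27me3") {
    cov <- st %in% c("H3K27me3-only", "bivalent")
    means <- add_amp(means, genes$chrom[cov], prom$start[cov],
                     prom$end[cov], rep(1.5, sum(cov)), bw)
    if (is_pgc) {
      means <- add_amp(means, escapee_bins$chrom, escapee_bins$start,
                       escapee_bins$end, rep(2.5, nrow(escapee_bins)), bw)
      if (sample_row$sex == "F")
        means[[asm$sex_chromosome]] <- means[[asm$sex_chromosome]] + 1.2
    }
  } else if (mark == "H3K9me3") {
    if (is_pgc) {
      means <- add_amp(means, escapee_bins$chrom, escapee_bins$start,
                       escapee_bins$end, rep(2.5, nrow(escapee_bins)), bw)
      means <- add_amp(means, repeats$chrom, repeats$start, repeats$end,
                       rep(2.0, nrow(repeats)), bw)
      if (sample_row$sex == "F")
        means[[asm$sex_chromosome]] <- means[[asm$sex_chromosome]] + 1.2
    }
  }
  means
}

gamma_noise <- function(means, shape, noise) {
  if (!noise) return(means)
  lapply(means, function(v) stats::rgamma(length(v), shape = shape,
                                          rate = shape / v))
}

# ---- peak emission -----------------------------------------------------

build_peaks <- function(config, asm, mark, sample_row, genes, states,
                        expr_means, repeats, escapee_bins) {
  j <- sample_row$sample
  st <- states[, j]
  is_pgc <- sample_row$lineage == "PGC"
  noise <- config$noise
  rows <- list()
  if (mark %in% c("H3K4me3", "H3K27me3")) {
    cov <- which(st %in% if (mark == "H3K4me3")
                   c("H3K4me3-only", "bivalent")
                 else c("H3K27me3-only", "bivalent"))
    if (length(cov)) {
      hw <- if (noise) round(stats::runif(length(cov), 500, 1200))
            else rep(1000, length(cov))
      score <- if (mark == "H3K4me3")
        10 + 30 * log1p(expr_means[cov, j]) else rep(20, length(cov))
      if (noise) score <- pmax(0.1, score + stats::rnorm(length(cov), 0, 2))
      rows[[1]] <- data.frame(
        chrom = genes$chrom[cov],
        start = pmax(0, genes$tss[cov] - hw),
        end = pmin(asm$lengths[genes$chrom[cov]], genes$tss[cov] + hw),
        name = paste0(genes$gene_id[cov], "_", mark),
        score = score, stringsAsFactors = FALSE)
    }
    if (mark == "H3K27me3" && is_pgc && nrow(escapee_bins))
      rows[[2]] <- data.frame(
        chrom = escapee_bins$chrom, start = escapee_bins$start,
        end = escapee_bins$end,
        name = paste0("esc_", seq_len(nrow(escapee_bins)), "_", mark),
        score = rep(15, nrow(escapee_bins)), stringsAsFactors = FALSE)
  } else if (mark == "H3K9me3" && is_pgc) {
    r <- config$te_roster
    k9marked <- repeats[r$k4k9_ratio[match(repeats$subfamily,
                                           r$subfamily)] < 0.66, ]
    rows[[1]] <- data.frame(
      chrom = c(escapee_bins$chrom, k9marked$chrom),
      start = c(escapee_bins$start, k9marked$start),
      end = c(escapee_bins$end, k9marked$end),
      name = c(paste0("esc_", seq_len(nrow(escapee_bins)), "_K9"),
               paste0(k9marked$copy_id, "_K9")),
      score = rep(15, nrow(escapee_bins) + nrow(k9marked)),
      stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               name = character(), score = numeric())
  df <- df[order(match(df$chrom, names(asm$lengths)), df$start, df$end), ]
  rownames(df) <- NULL
  peak_set(df, mark = mark, sample = j)
}

# ---- methylome emission ------------------------------------------------

# planted per-CpG mean levels (shared across samples)
cpg_grid <- function(config, asm, repeats, escapee_bins) {
  lapply(setNames(names(asm$lengths), names(asm$lengths)), function(ch) {
    len <- asm$lengths[[ch]]
    pos <- seq(config$cpg_spacing %/% 2, len - 1, by = config$cpg_spacing)
    mu <- rep(config$background_meth, length(pos))
    eb <- escapee_bins[escapee_bins$chrom == ch, ]
    for (i in seq_len(nrow(eb)))
      mu[pos >= eb$start[i] & pos < eb$end[i]] <- eb$level[i]
    rp <- repeats[repeats$chrom == ch, ]
    r <- config$te_roster
    rp_mu <- r$methylation[match(rp$subfamily, r$subfamily)]
    for (i in seq_len(nrow(rp)))
      mu[pos >= rp$start[i] & pos < rp$end[i]] <- rp_mu[i]
    list(pos = pos, mu = mu)
  })
}

emit_methylome <- function(config, grid, path) {
  pieces <- lapply(names(grid), function(ch) {
    g <- grid[[ch]]
    lv <- if (config$noise) {
      nu <- config$meth_concentration
      stats::rbeta(length(g$mu), g$mu * nu, (1 - g$mu) * nu)
    } else g$mu
    cov <- if (config$noise) stats::rpois(length(g$mu), 9) + 1
           else rep(10L, length(g$mu))
    data.table::data.table(ch, format_bp(g$pos + 1),
                           format(signif(pmin(pmax(lv, 0), 1), 6),
                                  scientific = FALSE, trim = TRUE),
                           format_bp(cov))
  })
  data.table::fwrite(data.table::rbindlist(pieces), path, sep = "\t",
                     col.names = FALSE, quote = FALSE)
}

# ---- main entry --------------------------------------------------------

#' Generate a complete synthetic fixture with planted truth
#'
#' Writes, under `outdir`: `chrom.sizes`, `genes.tsv`, `repeats.tsv`,
#' `samples.tsv`, per-sample peak BEDs (`peaks/`), bedGraph tracks
#' (`tracks/`) for H3K4me3/H3K27me3/H3K9me3, per-CpG methylomes of the
#' PGC samples (`methylation/`), gene-FPKM and TE expression tables
#' (`expression/`), and the planted truth tables (`truth/`). The same
#' seed produces byte-identical output trees.
#'
#' @param config A `SimConfig` (see [sim_config()]).
#' @param outdir Output directory (created if absent).
#' @param emit `"full"` (everything) or `"expression"` — a lightweight
#'   mode writing only annotation, expression and truth tables, for
#'   expression-level studies (e.g. dosage replicates) that do not need
#'   tracks, peaks or methylomes.
#' @return Invisibly, a list with the in-memory objects: `config`, `dir`,
#'   `assembly`, `genes`, `repeats`, `escapee_bins`, `samples`, `states`
#'   (planted state matrix), `expr_means` (planted FPKM means), `fpkm`
#'   (emitted noisy FPKM matrix), `around` (around-genes truth).
#' @export
simulate_fixture <- function(config = sim_config(), outdir,
                             emit = c("full", "expression")) {
  emit <- match.arg(emit)
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("peaks", "tracks", "methylation", "expression", "truth"))
    dir.create(file.path(outdir, d), showWarnings = FALSE)

  asm <- assembly(config$chrom_lengths, config$sex_chromosome)
  write_assembly(asm, file.path(outdir, "chrom.sizes"))
  samples <- sim_samples(config)

  layout <- build_layout(config, asm)
  genes <- layout$genes
  write_genes(genes, file.path(outdir, "genes.tsv"))
  write_repeats(layout$repeats, file.path(outdir, "repeats.tsv"))
  data.table::fwrite(data.table::as.data.table(samples),
                     file.path(outdir, "samples.tsv"), sep = "\t",
                     quote = FALSE)

  states <- plant_states(config, genes, samples)
  base_expr <- stats::rlnorm(nrow(genes), config$base_expr_meanlog,
                             config$base_expr_sdlog)
  expr_means <- plant_expression_means(config, genes, samples, states,
                                       base_expr)

  # peaks and tracks, per sample x mark (fixed order for determinism)
  marks <- c("H3K4me3", "H3K27me3", "H3K9me3")
  if (emit == "full") for (jj in seq_len(nrow(samples))) {
    srow <- samples[jj, ]
    for (mk in marks) {
      pk <- build_peaks(config, asm, mk, srow, genes, states, expr_means,
                        layout$repeats, layout$escapee_bins)
      write_peaks(pk, file.path(outdir, "peaks",
                                paste0(srow$sample, ".", mk, ".bed")))
      mu <- build_track_means(config, asm, mk, srow, genes, states,
                              expr_means, layout$repeats,
                              layout$escapee_bins)
      vals <- gamma_noise(mu, config$track_noise_shape, config$noise)
      tr <- signal_track(vals, config$track_bin_width, asm,
                         mark = mk, sample = srow$sample)
      write_bedgraph(tr, file.path(outdir, "tracks",
                                   paste0(srow$sample, ".", mk,
                                          ".bedGraph")))
    }
  }

  # methylomes (PGC samples only; escapee calling pools PGC development)
  if (emit == "full") {
    grid <- cpg_grid(config, asm, layout$repeats, layout$escapee_bins)
    pgc <- samples[samples$lineage == "PGC", ]
    for (jj in seq_len(nrow(pgc)))
      emit_methylome(config, grid,
                     file.path(outdir, "methylation",
                               paste0(pgc$sample[jj], ".meth.tsv")))
  }

  # expression tables
  fpkm <- expr_means
  for (j in seq_len(ncol(fpkm)))
    fpkm[, j] <- lognoise(expr_means[, j], config$fpkm_sdlog, config$noise)
  write_expression(fpkm, file.path(outdir, "expression", "gene_fpkm.tsv"))
  r <- config$te_roster
  te_expr <- matrix(rep(r$expression, nrow(samples)), ncol = nrow(samples),
                    dimnames = list(r$subfamily, samples$sample))
  for (j in seq_len(ncol(te_expr)))
    te_expr[, j] <- lognoise(te_expr[, j], 0.2 * (config$fpkm_sdlog > 0),
                             config$noise)
  write_expression(te_expr, file.path(outdir, "expression",
                                      "te_expression.tsv"))

  # truth tables
  st_df <- data.frame(gene_id = rownames(states), states,
                      check.names = FALSE, stringsAsFactors = FALSE)
  write_table(st_df, file.path(outdir, "truth", "promoter_states.tsv"))
  write_table(layout$escapee_bins[, c("bin_id", "chrom", "start", "end",
                                      "level")],
              file.path(outdir, "truth", "escapee_bins.tsv"))
  pref_truth <- ifelse(r$k4k9_ratio > 1.33, "H3K4me3-marked",
                       ifelse(r$k4k9_ratio < 0.66, "H3K9me3-marked",
                              "ambiguous"))
  copies <- layout$repeats
  write_table(data.frame(copy_id = copies$copy_id,
                         subfamily = copies$subfamily,
                         planted_ratio = r$k4k9_ratio[
                           match(copies$subfamily, r$subfamily)],
                         planted_label = pref_truth[
                           match(copies$subfamily, r$subfamily)],
                         stringsAsFactors = FALSE),
              file.path(outdir, "truth", "te_copies.tsv"))
  write_table(cbind(r, escapee = r$methylation >= 0.35),
              file.path(outdir, "truth", "te_subfamilies.tsv"))
  write_table(data.frame(x_dosage_factor = config$x_dosage_factor),
              file.path(outdir, "truth", "dosage.tsv"))
  around <- around_truth(genes, layout$repeats)
  write_table(around, file.path(outdir, "truth", "around_genes.tsv"))
  gene_roles <- genes[, c("gene_id", "role", "cassette_subfamily")]
  write_table(gene_roles, file.path(outdir, "truth", "gene_roles.tsv"))

  invisible(list(config = config, dir = outdir, assembly = asm,
                 genes = genes, repeats = layout$repeats,
                 escapee_bins = layout$escapee_bins, samples = samples,
                 states = states, expr_means = expr_means, fpkm = fpkm,
                 around = around))
}

#' Redraw the expression tables of a fixture
#'
#' Applies fresh mean-preserving log-normal noise to the planted FPKM
#' means — a lightweight path for replicate simulations (e.g. dosage
#' recovery and null-calibration studies) that do not need the tracks or
#' methylomes regenerated.
#'
#' @param fixture The list returned by [simulate_fixture()].
#' @param seed RNG seed for the redraw.
#' @return Numeric FPKM matrix (genes x samples).
#' @export
sim_expression <- function(fixture, seed) {
  set.seed(seed)
  m <- fixture$expr_means
  for (j in seq_len(ncol(m)))
    m[, j] <- lognoise(fixture$expr_means[, j], fixture$config$fpkm_sdlog,
                       fixture$config$noise)
  m
}

#' Inject a named defect into a generated fixture
#'
#' For negative-path testing of the readers and the dynamics checks.
#' Modes: `"bad-level"` (methylation level > 1), `"oob-interval"` (peak
#' beyond the chromosome end), `"duplicate-cpg"` (repeated CpG position),
#' `"universe-mismatch"` (drops one gene from one stage of the
#' promoter-state truth table).
#'
#' @param outdir Fixture directory.
#' @param mode Defect name.
#' @return The path of the modified file, invisibly.
#' @export
corrupt_fixture <- function(outdir, mode) {
  meth_files <- list.files(file.path(outdir, "methylation"),
                           full.names = TRUE)
  peak_files <- list.files(file.path(outdir, "peaks"), full.names = TRUE)
  if (mode == "bad-level") {
    f <- meth_files[1]
    lines <- readLines(f)
    parts <- strsplit(lines[1], "\t")[[1]]
    parts[3] <- "1.2"
    lines[1] <- paste(parts, collapse = "\t")
    writeLines(lines, f)
    invisible(f)
  } else if (mode == "duplicate-cpg") {
    f <- meth_files[1]
    lines <- readLines(f)
    writeLines(c(lines, lines[1]), f)
    invisible(f)
  } else if (mode == "oob-interval") {
    f <- peak_files[1]
    sizes <- utils::read.table(file.path(outdir, "chrom.sizes"),
                               sep = "\t", stringsAsFactors = FALSE)
    bad <- paste(sizes[1, 1], format_bp(sizes[1, 2] - 100),
                 format_bp(sizes[1, 2] + 500), "bad_peak", "10", ".",
                 sep = "\t")
    cat(bad, "\n", sep = "", file = f, append = TRUE)
    invisible(f)
  } else if (mode == "universe-mismatch") {
    f <- file.path(outdir, "truth", "promoter_states.tsv")
    lines <- readLines(f)
    # blank one stage's state for the first gene (drops it from that stage)
    parts <- strsplit(lines[2], "\t")[[1]]
    parts[2] <- "NA"
    lines[2] <- paste(parts, collapse = "\t")
    writeLines(lines, f)
    invisible(f)
  } else {
    stop("unknown corruption mode '", mode, "'")
  }
}
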