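# End-to-end orchestration over a fixture-layout input directory:
#   quantify -> classify-promoters -> escapees -> te-analysis -> chrx ->
#   enrich
# Every stage writes plain-text outputs under the output directory; the
# manifest records each file with its md5 content hash and the parameter
# set used, so reruns are verifiable byte-for-byte.

#' Pipeline run configuration
#'
#' Threshold defaults are the analysis constants used throughout the
#' package: 2000-bp promoter flank, 5000-bp methylation bins, escapee
#' thresholds 0.4 (bins, strict) and 0.35 (TE subfamilies, inclusive),
#' TE preference bounds 1.33/0.66, 10-kb around-gene window.
#'
#' @param input_dir Directory holding the input file set (the layout
#'   written by [simulate_fixture()]).
#' @param output_dir Output directory.
#' @param seed Seed for the stochastic steps (bootstrap CIs).
#' @param flank,bin_width,escapee_threshold,te_threshold,pref_upper,pref_lower,around_window,track_bin_width,pseudocount,min_copy_len,domain_gap
#'   Analysis parameters; defaults as above.
#' @return List of class `RunConfig`.
#' @export
run_config <- function(input_dir, output_dir, seed = 1,
                       flank = 2000, bin_width = 5000,
                       escapee_threshold = 0.4, te_threshold = 0.35,
                       pref_upper = 1.33, pref_lower = 0.66,
                       around_window = 10000, track_bin_width = 100,
                       pseudocount = 0.01, min_copy_len = 50,
                       domain_gap = 0) {
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 seed = seed, flank = flank, bin_width = bin_width,
                 escapee_threshold = escapee_threshold,
                 te_threshold = te_threshold, pref_upper = pref_upper,
                 pref_lower = pref_lower, around_window = around_window,
                 track_bin_width = track_bin_width,
                 pseudocount = pseudocount, min_copy_len = min_copy_len,
                 domain_gap = domain_gap),
            class = "RunConfig")
}

pipeline_params <- function(cfg) {
  cfg[c("seed", "flank", "bin_width", "escapee_threshold", "te_threshold",
        "pref_upper", "pref_lower", "around_window", "track_bin_width",
        "pseudocount", "min_copy_len", "domain_gap")]
}

read_fixture_inputs <- function(cfg) {
  ind <- cfg$input_dir
  need <- c("chrom.sizes", "genes.tsv", "repeats.tsv", "samples.tsv")
  missing <- need[!file.exists(file.path(ind, need))]
  if (length(missing))
    stop("input directory is missing: ", paste(missing, collapse = ", "))
  asm <- read_assembly(file.path(ind, "chrom.sizes"))
  genes <- read_genes(file.path(ind, "genes.tsv"), asm)
  repeats <- read_repeats(file.path(ind, "repeats.tsv"), asm)
  samples <- as.data.frame(data.table::fread(file.path(ind, "samples.tsv")))
  fpkm <- read_expression(file.path(ind, "expression", "gene_fpkm.tsv"))
  te_expr <- read_expression(file.path(ind, "expression",
                                       "te_expression.tsv"))
  list(asm = asm, genes = genes, repeats = repeats, samples = samples,
       fpkm = fpkm, te_expr = te_expr)
}

load_track <- function(cfg, sample, mark, asm) {
  read_bedgraph(file.path(cfg$input_dir, "tracks",
                          paste0(sample, ".", mark, ".bedGraph")),
                asm, bin_width = cfg$track_bin_width,
                mark = mark, sample = sample)
}

load_peaks <- function(cfg, sample, mark, asm) {
  read_peaks(file.path(cfg$input_dir, "peaks",
                       paste0(sample, ".", mark, ".bed")),
             asm, mark = mark, sample = sample)
}

#' Run the full analysis pipeline
#'
#' Executes quantify, classify-promoters, escapees, te-analysis, chrx and
#' enrich over the input directory, writing one TSV per product plus a
#' `manifest.tsv` listing every output with its md5 hash. All randomness
#' (bootstrap CIs) is governed by the config seed, so two runs with the
#' same inputs and seed produce identical manifests.
#'
#' @param cfg A `RunConfig`.
#' @param dry_run If TRUE, print the planned stages and write nothing.
#' @return data.frame manifest (file, md5), invisibly for normal runs.
#' @export
run_pipeline <- function(cfg, dry_run = FALSE) {
  stopifnot(inherits(cfg, "RunConfig"))
  stages <- c("quantify", "classify-promoters", "escapees", "te-analysis",
              "chrx", "enrich")
  if (dry_run) {
    cat("planned stages:", paste(stages, collapse = " -> "), "\n")
    return(invisible(NULL))
  }
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  params <- pipeline_params(cfg)
  inputs <- read_fixture_inputs(cfg)
  outputs <- character(0)
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(df, name) {
    p <- file.path(cfg$output_dir, name)
    write_table(df, p, params = params)
    outputs <<- c(outputs, p)
  }
  asm <- inputs$asm
  genes <- inputs$genes
  pgc <- inputs$samples[inputs$samples$lineage == "PGC", ]
  prom <- gene_promoters(genes, asm, cfg$flank)

  run_stage("quantify", function() {
    rows <- list(); dom_rows <- list()
    for (s in pgc$sample) {
      tr <- load_track(cfg, s, "H3K4me3", asm)
      rows[[s]] <- data.frame(sample = s, gene_id = prom$gene_id,
                              mean_rpm = rpm_over_region(tr, prom),
                              stringsAsFactors = FALSE)
      dw <- domain_widths(load_peaks(cfg, s, "H3K4me3", asm),
                          max_gap = cfg$domain_gap)
      dom_rows[[s]] <- data.frame(sample = s,
                                  class = names(dw$proportions),
                                  proportion = as.numeric(dw$proportions),
                                  n_domains = nrow(dw$domains),
                                  stringsAsFactors = FALSE)
    }
    emit(do.call(rbind, c(rows, make.row.names = FALSE)),
         "promoter_signal.tsv")
    emit(do.call(rbind, c(dom_rows, make.row.names = FALSE)),
         "domain_widths.tsv")
  })

  states_by_sample <- list()
  run_stage("classify-promoters", function() {
    rows <- list()
    for (s in pgc$sample) {
      st <- classify_promoters(prom, load_peaks(cfg, s, "H3K4me3", asm),
                               load_peaks(cfg, s, "H3K27me3", asm))
      states_by_sample[[s]] <<- st
      rows[[s]] <- data.frame(sample = s, gene_id = names(st),
                              state = as.character(st),
                              stringsAsFactors = FALSE)
    }
    emit(do.call(rbind, c(rows, make.row.names = FALSE)),
         "promoter_states.tsv")
    dyn_rows <- list()
    for (sex in unique(pgc$sex)) {
      ss <- pgc[pgc$sex == sex, ]
      ss <- ss[match(c("early", "middle", "late"), ss$stage), ]
      ss <- ss[!is.na(ss$sample), ]
      if (nrow(ss) < 2) next
      dyn <- state_dynamics(setNames(states_by_sample[ss$sample],
                                     ss$stage))
      for (tr_name in names(dyn$transitions)) {
        tm <- dyn$transitions[[tr_name]]
        long <- expand.grid(state_from = rownames(tm),
                            state_to = colnames(tm),
                            stringsAsFactors = FALSE)
        long$count <- as.vector(tm)
        long <- cbind(sex = sex,
                      stage_from = sub("->.*", "", tr_name),
                      stage_to = sub(".*->", "", tr_name), long,
                      stringsAsFactors = FALSE)
        dyn_rows[[paste(sex, tr_name)]] <- long
      }
    }
    emit(do.call(rbind, c(dyn_rows, make.row.names = FALSE)),
         "state_dynamics.tsv")
  })

  meth_paths <- file.path(cfg$input_dir, "methylation",
                          paste0(pgc$sample, ".meth.tsv"))
  if (!all(file.exists(meth_paths)))
    stop("methylation file missing: ",
         basename(meth_paths[!file.exists(meth_paths)][1]))
  methylomes <- lapply(meth_paths, read_methylome, assembly = asm)
  names(methylomes) <- pgc$sample

  run_stage("escapees", function() {
    bins <- bin_genome(asm, cfg$bin_width)
    bm <- bin_methylation(methylomes, bins)
    calls <- call_escapee_bins(bm, threshold = cfg$escapee_threshold)
    calls <- partition_repeat_content(calls, inputs$repeats)
    emit(calls[, c("chrom", "start", "end", "bin_id",
                   "development_average", "label", "repeat_fraction",
                   "repeat_class")], "escapee_bins.tsv")
    pcalls <- call_escapee_promoters(genes, calls,
                                     bin_width = cfg$bin_width)
    emit(pcalls, "escapee_promoters.tsv")
    te_calls <- call_te_escapees(inputs$repeats, methylomes,
                                 threshold = cfg$te_threshold)
    emit(te_calls, "escapee_te_subfamilies.tsv")
    # chromatin/expression contrast of escapee vs demethylated promoters,
    # per sex at the early stage
    prof_rows <- list()
    for (sex in unique(pgc$sex)) {
      s <- pgc$sample[pgc$sex == sex & pgc$stage == "early"][1]
      if (is.na(s) || length(unique(pcalls$label)) < 2) next
      tracks <- list(H3K4me3 = load_track(cfg, s, "H3K4me3", asm),
                     H3K27me3 = load_track(cfg, s, "H3K27me3", asm),
                     H3K9me3 = load_track(cfg, s, "H3K9me3", asm))
      prof <- escapee_chromatin_profile(pcalls, genes, tracks,
                                        inputs$fpkm[, s], asm, cfg$flank)
      prof_rows[[sex]] <- cbind(sex = sex, sample = s, prof$summary,
                                stringsAsFactors = FALSE)
    }
    if (length(prof_rows))
      emit(do.call(rbind, c(prof_rows, make.row.names = FALSE)),
           "escapee_profile.tsv")
  })

  run_stage("te-analysis", function() {
    rows_pref <- list(); rows_sum <- list(); rows_pos <- list()
    for (sex in unique(pgc$sex)) {
      s <- pgc$sample[pgc$sex == sex & pgc$stage == "early"][1]
      if (is.na(s)) next
      k4 <- load_track(cfg, s, "H3K4me3", asm)
      k9 <- load_track(cfg, s, "H3K9me3", asm)
      prefs <- te_copy_preferences(inputs$repeats, k4, k9,
                                   pseudocount = cfg$pseudocount,
                                   upper = cfg$pref_upper,
                                   lower = cfg$pref_lower,
                                   min_copy_len = cfg$min_copy_len)
      rows_pref[[sex]] <- cbind(sex = sex, sample = s,
                                subfamily_preference_summary(prefs),
                                stringsAsFactors = FALSE)
      for (sf in c("LTR5_Hs", "LTR14")) {
        split <- proximal_distal_split(inputs$repeats, genes, sf,
                                       window = cfg$around_window)
        rep_ <- positional_effect_report(
          split, genes,
          list(H3K4me3 = k4, H3K9me3 = k9), inputs$fpkm[, s],
          prom_meth = NULL, assembly = asm, flank = cfg$flank)
        rows_pos[[paste(sex, sf)]] <- cbind(sex = sex, subfamily = sf,
                                            rep_$summary,
                                            stringsAsFactors = FALSE)
      }
    }
    te_meth <- call_te_escapees(inputs$repeats, methylomes,
                                threshold = cfg$te_threshold)
    rs <- rank_sum_score(
      setNames(te_meth$mean_methylation, te_meth$subfamily),
      rowMeans(inputs$te_expr[, pgc$sample, drop = FALSE]))
    emit(do.call(rbind, c(rows_pref, make.row.names = FALSE)),
         "te_preference.tsv")
    emit(rs, "te_rank_sum.tsv")
    emit(do.call(rbind, c(rows_pos, make.row.names = FALSE)),
         "te_positional_effect.tsv")
  })

  run_stage("chrx", function() {
    xf <- vapply(colnames(inputs$fpkm),
                 function(s) x_expression_fraction(inputs$fpkm[, s], genes),
                 numeric(1))
    emit(data.frame(sample = colnames(inputs$fpkm), x_fraction = xf,
                    stringsAsFactors = FALSE), "x_fraction.tsv")
    rows <- list()
    for (stg in intersect(c("early", "middle", "late"), pgc$stage)) {
      sf <- pgc$sample[pgc$sex == "F" & pgc$stage == stg][1]
      sm <- pgc$sample[pgc$sex == "M" & pgc$stage == stg][1]
      if (is.na(sf) || is.na(sm)) next
      d <- estimate_dosage_factor(inputs$fpkm[, sf], inputs$fpkm[, sm],
                                  genes, seed = cfg$seed)
      rows[[stg]] <- data.frame(stage = stg, factor = d$factor,
                                ci_lo = d$ci[1], ci_hi = d$ci[2],
                                x_fraction_female = d$x_fraction_female,
                                x_fraction_male = d$x_fraction_male,
                                stringsAsFactors = FALSE)
    }
    emit(do.call(rbind, c(rows, make.row.names = FALSE)), "x_dosage.tsv")
    cgi_rows <- list()
    for (sex in unique(pgc$sex)) {
      s <- pgc$sample[pgc$sex == sex & pgc$stage == "early"][1]
      if (is.na(s)) next
      tracks <- list(H3K4me3 = load_track(cfg, s, "H3K4me3", asm),
                     H3K27me3 = load_track(cfg, s, "H3K27me3", asm),
                     H3K9me3 = load_track(cfg, s, "H3K9me3", asm))
      cc <- cgi_promoter_compare(tracks, genes, asm, flank = cfg$flank)
      cgi_rows[[sex]] <- cbind(sex = sex, sample = s, cc$summary,
                               stringsAsFactors = FALSE)
    }
    emit(do.call(rbind, c(cgi_rows, make.row.names = FALSE)),
         "chrx_cgi_compare.tsv")
  })

  run_stage("enrich", function() {
    region_sets <- list(promoters = prom[, c("chrom", "start", "end")],
                        repeats = inputs$repeats[, c("chrom", "start",
                                                     "end")])
    rows <- list()
    for (s in pgc$sample) {
      for (mk in c("H3K4me3", "H3K27me3", "H3K9me3")) {
        pk <- load_peaks(cfg, s, mk, asm)
        if (nrow(pk) == 0L) next
        for (rs_name in names(region_sets)) {
          e <- genomic_enrichment(pk, region_sets[[rs_name]], asm)
          rows[[paste(s, mk, rs_name)]] <-
            data.frame(sample = s, mark = mk, region_set = rs_name,
                       r_observed = e$r_observed,
                       r_expected = e$r_expected,
                       enrichment = e$enrichment, stringsAsFactors = FALSE)
        }
      }
    }
    emit(do.call(rbind, c(rows, make.row.names = FALSE)),
         "enrichment.tsv")
  })

  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  write_table(manifest, file.path(cfg$output_dir, "manifest.tsv"),
              params = params)
  invisible(manifest)
}
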