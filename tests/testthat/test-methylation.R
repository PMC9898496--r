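mk_methylome <- function(chrom, pos, level, coverage = 10,
                         sample = "s1") {
  structure(data.frame(chrom = chrom, pos = pos, level = level,
                       coverage = coverage, stringsAsFactors = FALSE),
            class = c("MethylomeTable", "data.frame"), sample = sample)
}

test_that("bin means are unweighted CpG averages, matching a direct oracle", {
  asm <- assembly(c(chr1 = 20000))
  bins <- bin_genome(asm, 5000)
  m <- mk_methylome("chr1", c(100, 3000, 6000), c(0.2, 0.4, 0.9))
  bm <- bin_methylation(list(s1 = m), bins)
  expect_equal(bm$mean_s1[1], 0.3)
  expect_equal(bm$mean_s1[2], 0.9)
  expect_true(is.na(bm$development_average[3]))  # no CpG -> undefined
  expect_equal(bm$n_cpg, c(2L, 1L, 0L, 0L))
  # development average pools per-sample means with equal weight
  m2 <- mk_methylome("chr1", c(200, 4000), c(0.6, 0.8), sample = "s2")
  bm2 <- bin_methylation(list(s1 = m, s2 = m2), bins)
  expect_equal(bm2$development_average[1], mean(c(0.3, 0.7)))
  # fuzzed sites against per-site brute-force averaging
  set.seed(6)
  pos <- sort(sample(0:19999, 60))
  lev <- runif(60)
  mf <- mk_methylome("chr1", pos, lev)
  bmf <- bin_methylation(list(s1 = mf), bins)
  for (b in 1:4) {
    inb <- pos >= (b - 1) * 5000 & pos < b * 5000
    if (any(inb))
      expect_equal(bmf$mean_s1[b], mean(lev[inb]), tolerance = 1e-12)
  }
  # coverage weighting is available as the documented alternative
  mw <- mk_methylome("chr1", c(100, 200), c(0, 1), coverage = c(1, 3))
  bmw <- bin_methylation(list(s1 = mw), bins, weight_by_coverage = TRUE)
  expect_equal(bmw$mean_s1[1], 0.75)
})

test_that("bin escapee calls use the strict > 0.4 rule", {
  calls <- data.frame(chrom = "chr1", start = c(0, 5000, 10000),
                      end = c(5000, 10000, 15000),
                      bin_id = c("b1", "b2", "b3"), n_cpg = 5L,
                      development_average = c(0.41, 0.40, 0.00))
  out <- call_escapee_bins(calls)
  expect_equal(as.character(out$label),
               c("escapee", "demethylated", "demethylated"))
  # escapee/demethylated is a partition of all defined bins
  expect_false(any(is.na(out$label)))
})

test_that("TE subfamily calls use the inclusive >= 0.35 rule", {
  asm <- assembly(c(chr1 = 50000))
  reps <- data.frame(chrom = "chr1", start = c(1000, 11000, 21000),
                     end = c(2000, 12000, 22000), strand = "+",
                     family = c("SVA", "SVA", "L1"),
                     subfamily = c("SVA_X", "SVA_Y", "L1_Z"))
  # plant copy means exactly at, just below, and far below the threshold
  m <- mk_methylome("chr1", c(1500, 11500, 21500), c(0.35, 0.349, 0.10))
  out <- call_te_escapees(reps, list(s1 = m))
  expect_equal(out$label[out$subfamily == "SVA_X"], factor("escapee",
               levels = c("escapee", "demethylated")))
  expect_equal(as.character(out$label[out$subfamily == "SVA_Y"]),
               "demethylated")
  # single-copy subfamily mean equals that copy's mean
  expect_equal(out$mean_methylation[out$subfamily == "L1_Z"], 0.10)
  # a subfamily with no CpG coverage is excluded with a warning
  reps2 <- rbind(reps, data.frame(chrom = "chr1", start = 40000,
                                  end = 41000, strand = "+",
                                  family = "L1", subfamily = "L1_W"))
  expect_warning(out2 <- call_te_escapees(reps2, list(s1 = m)), "L1_W")
  expect_false("L1_W" %in% out2$subfamily)
})

test_that("promoters inherit the label of their TSS bin only", {
  asm <- assembly(c(chr1 = 30000))
  calls <- data.frame(chrom = "chr1", start = c(0, 5000, 10000),
                      end = c(5000, 10000, 15000),
                      bin_id = c("b1", "b2", "b3"), n_cpg = 5L,
                      development_average = c(0.1, 0.7, 0.1))
  calls <- call_escapee_bins(calls)
  genes <- data.frame(gene_id = c("in_esc", "tail_reaches", "far"),
                      chrom = "chr1", start = c(7500, 4500, 12000),
                      end = c(8500, 5500, 13000), strand = "+",
                      tss = c(7500, 4500, 12000))
  out <- call_escapee_promoters(genes, calls)
  expect_equal(as.character(out$label),
               c("escapee", "demethylated", "demethylated"))
  # TSS in a bin with no methylation data -> excluded with a warning
  genes2 <- rbind(genes, data.frame(gene_id = "undef", chrom = "chr1",
                                    start = 16000, end = 17000,
                                    strand = "+", tss = 16000))
  expect_warning(out2 <- call_escapee_promoters(genes2, calls),
                 "excluded")
  expect_false("undef" %in% out2$gene_id)
})

test_that("repeat-content partition matches a base-union oracle", {
  bins <- data.frame(chrom = "chr1", start = c(0, 5000),
                     end = c(5000, 10000))
  reps <- data.frame(chrom = "chr1", start = c(0, 2000, 2500),
                     end = c(2500, 4000, 3000))
  out <- partition_repeat_content(bins, reps)
  # overlapping copies count each base once: union is [0,4000) = 80%
  expect_equal(out$repeat_fraction, c(0.8, 0))
  expect_equal(as.character(out$repeat_class),
               c("repeat-rich", "repeat-poor"))
  # fuzzed against explicit base membership
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(1:8, 1)
    r <- data.frame(chrom = "chr1",
                    start = sample(0:4900, n, replace = TRUE))
    r$end <- pmin(r$start + sample(50:2000, n, replace = TRUE), 5000)
    frac <- partition_repeat_content(bins[1, ], r)$repeat_fraction
    member <- logical(5000)
    for (i in seq_len(n)) member[(r$start[i] + 1):r$end[i]] <- TRUE
    expect_equal(frac, mean(member), tolerance = 1e-12)
  }
})

test_that("escapee promoters show the planted chromatin contrast", {
  fx <- default_fixture()
  asm <- fx$assembly
  bins <- bin_genome(asm, 5000)
  pgc <- fx$samples[fx$samples$lineage == "PGC", ]
  methylomes <- lapply(setNames(file.path(fx$dir, "methylation",
                                          paste0(pgc$sample, ".meth.tsv")),
                                pgc$sample),
                       read_methylome, assembly = asm)
  bm <- bin_methylation(methylomes, bins)
  calls <- call_escapee_bins(bm)
  pcalls <- call_escapee_promoters(fx$genes, calls)
  s <- "M_PGC_early"
  tracks <- list(
    H3K4me3 = read_bedgraph(file.path(fx$dir, "tracks",
                                      paste0(s, ".H3K4me3.bedGraph")), asm),
    H3K9me3 = read_bedgraph(file.path(fx$dir, "tracks",
                                      paste0(s, ".H3K9me3.bedGraph")), asm))
  fpkm <- read_expression(file.path(fx$dir, "expression",
                                    "gene_fpkm.tsv"))
  prof <- escapee_chromatin_profile(pcalls, fx$genes, tracks, fpkm[, s],
                                    asm)
  sm <- prof$summary
  esc <- function(q) sm$mean[sm$quantity == q & sm$group == "escapee"]
  dem <- function(q) sm$mean[sm$quantity == q & sm$group == "demethylated"]
  # planted directions: repressive H3K9me3 and methylation high, and
  # expression low, at escapee promoters
  expect_gt(esc("H3K9me3"), dem("H3K9me3"))
  expect_gt(esc("methylation"), dem("methylation"))
  expect_lt(esc("expression"), dem("expression"))
  # group means equal direct recomputation from the inputs
  g <- fx$genes[match(pcalls$gene_id, fx$genes$gene_id), ]
  prom <- make_promoter(g$tss, g$chrom, asm)
  k9 <- rpm_over_region(tracks$H3K9me3, prom)
  expect_equal(esc("H3K9me3"), mean(k9[pcalls$label == "escapee"]),
               tolerance = 1e-9)
})
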