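test_that("copy preference thresholds follow the 1.33 / 0.66 bounds", {
  out <- copy_preference(c(2.0, 0.5, 1.0), c(1.0, 1.0, 1.0))
  expect_equal(as.character(out$label),
               c("H3K4me3-marked", "H3K9me3-marked", "ambiguous"))
  expect_equal(out$ratio[1], 2.01 / 1.01)
  # pseudocount guards a zero H3K9me3 signal
  z <- copy_preference(1, 0)
  expect_true(is.finite(z$ratio))
  expect_equal(as.character(z$label), "H3K4me3-marked")
  expect_error(copy_preference(-1, 1), ">= 0")
  # monotone in k4 at fixed k9: labels never move toward H3K9me3-marked
  k4 <- seq(0, 5, by = 0.05)
  lab <- as.integer(copy_preference(k4, rep(1.5, length(k4)))$label)
  # levels: 1 = K4-marked, 2 = K9-marked, 3 = ambiguous; map to ordering
  ord <- c(3L, 1L, 2L)[lab]  # K9 < ambiguous < K4
  expect_true(all(diff(ord) >= 0))
})

test_that("subfamily proportions sum to one and match a counting oracle", {
  set.seed(4)
  n <- 90
  prefs <- data.frame(
    subfamily = sample(c("SVA_A", "SVA_D", "SVA_F"), n, replace = TRUE),
    family = "SVA",
    label = factor(sample(c("H3K4me3-marked", "H3K9me3-marked",
                            "ambiguous"), n, replace = TRUE),
                   levels = c("H3K4me3-marked", "H3K9me3-marked",
                              "ambiguous")))
  out <- subfamily_preference_summary(prefs)
  for (sf in out$subfamily) {
    rows <- prefs$subfamily == sf
    expect_equal(out[out$subfamily == sf, "H3K4me3-marked"],
                 mean(prefs$label[rows] == "H3K4me3-marked"),
                 tolerance = 1e-12)
    expect_equal(sum(out[out$subfamily == sf,
                         c("H3K4me3-marked", "H3K9me3-marked",
                           "ambiguous")]), 1)
  }
})

test_that("rank-sum scores rank both quantities ascending with tie means", {
  meth <- setNames(c(0.1, 0.2, 0.3), c("A", "B", "C"))
  expr <- setNames(c(5, 1, 10), c("A", "B", "C"))
  out <- rank_sum_score(meth, expr)
  expect_equal(setNames(out$rank_sum, out$subfamily)[c("A", "B", "C")],
               c(A = 3, B = 3, C = 6))
  # sorted descending by rank_sum
  expect_equal(out$subfamily[1], "C")
  # ties share the average rank
  m2 <- setNames(c(0.2, 0.2, 0.5), c("A", "B", "C"))
  out2 <- rank_sum_score(m2, expr)
  expect_equal(out2$meth_rank[out2$subfamily %in% c("A", "B")],
               c(1.5, 1.5))
  # a subfamily present in both and top-ranked in both hits 2K
  m3 <- setNames(c(0.1, 0.9), c("A", "B"))
  e3 <- setNames(c(1, 9), c("A", "B"))
  expect_equal(rank_sum_score(m3, e3)$rank_sum[1], 4)
  expect_warning(rank_sum_score(m3, setNames(c(1, 2, 3),
                                             c("A", "B", "D"))), "D")
})

test_that("around/distal split applies the 10-kb gap rule inclusively", {
  asm <- assembly(c(chr1 = 1e6))
  reps <- data.frame(chrom = "chr1", start = 10000, end = 10300,
                     strand = "+", family = "ERVK",
                     subfamily = "LTR5_Hs")
  mk_gene <- function(id, start, end)
    data.frame(gene_id = id, chrom = "chr1", start = start, end = end,
               strand = "+", tss = start)
  genes <- rbind(mk_gene("gap8000", 1000, 2000),      # gap 8000
                 mk_gene("gap10000", 20300, 21000),   # gap exactly 10000
                 mk_gene("gap10001", 20301, 21001),   # gap 10001
                 mk_gene("overlap", 10100, 10600))    # distance 0
  sp <- proximal_distal_split(reps, genes, "LTR5_Hs")
  expect_equal(as.character(sp[c("gap8000", "gap10000", "overlap")]),
               rep("around", 3))
  expect_equal(as.character(sp[["gap10001"]]), "distal")
  # the two sets partition the gene universe
  expect_equal(sort(names(sp)), sort(genes$gene_id))
  expect_false(any(is.na(sp)))
  expect_error(proximal_distal_split(reps, genes, "LTR99"), "no copies")
})

test_that("planted TE chromatin preferences are recovered per subfamily", {
  fx <- default_fixture()
  asm <- fx$assembly
  s <- "M_PGC_early"
  k4 <- read_bedgraph(file.path(fx$dir, "tracks",
                                paste0(s, ".H3K4me3.bedGraph")), asm)
  k9 <- read_bedgraph(file.path(fx$dir, "tracks",
                                paste0(s, ".H3K9me3.bedGraph")), asm)
  prefs <- te_copy_preferences(fx$repeats, k4, k9)
  sm <- subfamily_preference_summary(prefs)
  truth <- read_table_tsv(file.path(fx$dir, "truth",
                                    "te_subfamilies.tsv"))
  planted <- ifelse(truth$k4k9_ratio > 1.33, "H3K4me3-marked",
                    ifelse(truth$k4k9_ratio < 0.66, "H3K9me3-marked",
                           "ambiguous"))
  got <- sm$majority[match(truth$subfamily, sm$subfamily)]
  expect_equal(got, planted)
})

test_that("genes near active TE copies show the planted expression boost", {
  fx <- default_fixture()
  fpkm <- read_expression(file.path(fx$dir, "expression",
                                    "gene_fpkm.tsv"))
  sp <- proximal_distal_split(fx$repeats, fx$genes, "LTR5_Hs")
  s <- "M_PGC_early"
  rep_ <- positional_effect_report(sp, fx$genes,
                                   tracks = list(), fpkm[, s],
                                   assembly = fx$assembly)
  sm <- rep_$summary
  expect_gt(sm$mean[sm$quantity == "expression" & sm$group == "around"],
            sm$mean[sm$quantity == "expression" & sm$group == "distal"])
  expect_lt(rep_$tests$expression$p_value, 0.05)
  # group means equal direct recomputation
  expect_equal(sm$mean[sm$quantity == "expression" & sm$group == "around"],
               mean(fpkm[names(sp)[sp == "around"], s]), tolerance = 1e-9)
})
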