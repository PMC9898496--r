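test_that("promoter windows are symmetric TSS +/- flank, clipped at ends", {
  asm <- assembly(c(chr1 = 1e6))
  expect_equal(make_promoter(10000, "chr1", asm),
               data.frame(chrom = "chr1", start = 8000, end = 12000))
  # strand plays no role in a symmetric window
  expect_equal(make_promoter(50000, "chr1", asm),
               data.frame(chrom = "chr1", start = 48000, end = 52000))
  # left clip at the chromosome origin
  expect_equal(make_promoter(1000, "chr1", asm),
               data.frame(chrom = "chr1", start = 0, end = 3000))
  # right clip at the chromosome end
  expect_equal(make_promoter(999500, "chr1", asm)$end, 1e6)
  expect_error(make_promoter(100, "chrZ", asm), "chrZ")
  expect_error(make_promoter(2e6, "chr1", asm), "bounds")
})

test_that("gene promoters derive from the strand-aware TSS", {
  asm <- toy_assembly()
  genes <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                      start = c(10000, 30000), end = c(12000, 33000),
                      strand = c("+", "-"),
                      tss = c(10000, 32999), chrx = FALSE)
  p <- gene_promoters(genes, asm)
  expect_equal(p$start, c(8000, 30999))
  expect_equal(p$end, c(12000, 34999))
})

test_that("gestational weeks map to stages with an unassigned gap", {
  expect_equal(as.character(assign_stage(9)), "early")
  expect_equal(as.character(assign_stage(22)), "late")
  expect_equal(as.character(assign_stage(17)), "unassigned")
  expect_equal(as.character(assign_stage(c(8, 10, 11, 15, 16, 19, 20, 23,
                                           24))),
               c("early", "early", "middle", "middle", "unassigned",
                 "unassigned", "late", "late", "unassigned"))
  expect_error(assign_stage(-1), "non-negative")
})

test_that("genome binning is an exact partition with short tails", {
  asm <- assembly(c(chrA = 12000, chrB = 5000))
  b <- bin_genome(asm, 5000)
  expect_equal(b$start[b$chrom == "chrA"], c(0, 5000, 10000))
  expect_equal(b$end[b$chrom == "chrA"], c(5000, 10000, 12000))
  # conservation: bin lengths sum to the genome length
  expect_equal(sum(b$end - b$start), genome_length(asm))
  # bins never cross a chromosome boundary
  expect_true(all(b$end <= asm$lengths[b$chrom]))
  # pairwise disjoint within chromosome
  for (ch in names(asm$lengths)) {
    x <- b[b$chrom == ch, ]
    expect_true(all(x$start[-1] == x$end[-nrow(x)]))
  }
})

test_that("interval merging bridges gaps up to max_gap only", {
  m <- merge_intervals(data.frame(chrom = "chr1", start = c(100, 150),
                                  end = c(200, 300)))
  expect_equal(m, data.frame(chrom = "chr1", start = 100, end = 300))
  # abutting half-open intervals merge at gap 0
  m <- merge_intervals(data.frame(chrom = "chr1", start = c(100, 200),
                                  end = c(200, 300)))
  expect_equal(nrow(m), 1L)
  # disjoint intervals stay apart
  m <- merge_intervals(data.frame(chrom = "chr1", start = c(100, 250),
                                  end = c(200, 300)))
  expect_equal(nrow(m), 2L)
  # gap bridged when max_gap is large enough
  m <- merge_intervals(data.frame(chrom = "chr1", start = c(100, 250),
                                  end = c(200, 300)), max_gap = 50)
  expect_equal(m, data.frame(chrom = "chr1", start = 100, end = 300))
  # never across chromosomes
  m <- merge_intervals(data.frame(chrom = c("chr1", "chr2"),
                                  start = c(100, 100),
                                  end = c(200, 200)), max_gap = 1e6)
  expect_equal(nrow(m), 2L)
})

test_that("merged coverage matches a base-set union oracle on fuzzed sets", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(1:12, 1)
    df <- data.frame(chrom = "chr1",
                     start = sample(0:950, n, replace = TRUE))
    df$end <- df$start + sample(1:60, n, replace = TRUE)
    m <- merge_intervals(df)
    # oracle: count distinct covered bases directly
    covered <- unique(unlist(Map(function(s, e) seq(s, e - 1), df$start,
                                 df$end)))
    expect_equal(sum(m$end - m$start), length(covered))
    expect_true(all(m$start[-1] > m$end[-nrow(m)] - 1))
  }
})

test_that("interval validation reports the offending line", {
  asm <- toy_assembly()
  expect_error(validate_intervals(
    data.frame(chrom = c("chr1", "chrNope"), start = c(0, 0),
               end = c(10, 10)), asm), "line 2.*chrNope")
  expect_error(validate_intervals(
    data.frame(chrom = "chr1", start = 50, end = 50), asm),
    "invalid interval")
  expect_error(validate_intervals(
    data.frame(chrom = "chr2", start = 0, end = 6e5), asm), "exceeds")
})

test_that("assembly construction enforces its invariants", {
  expect_error(assembly(c(chr1 = 0)), "> 0")
  expect_error(assembly(c(100, 200)), "named")
  expect_error(assembly(c(chr1 = 100, chr1 = 200)), "duplicate")
  expect_error(assembly(c(chr1 = 100), sex_chromosome = "chrX"),
               "not a chromosome")
  asm <- assembly(c(chr1 = 100, chrX = 50))
  expect_equal(genome_length(asm), 150)
})
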