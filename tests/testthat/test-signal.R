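test_that("region means are length-weighted and match a per-base oracle", {
  asm <- assembly(c(chr1 = 1000))
  tr <- constant_track(asm, value = 2)
  expect_equal(rpm_over_region(tr, data.frame(chrom = "chr1", start = 137,
                                              end = 803)), 2)
  tr <- signal_track(list(chr1 = c(1, 3, rep(0, 8))), 100, asm)
  expect_equal(rpm_over_region(tr, data.frame(chrom = "chr1", start = 0,
                                              end = 200)), 2)
  # fractional bin overlap weighs proportionally
  expect_equal(rpm_over_region(tr, data.frame(chrom = "chr1", start = 50,
                                              end = 150)), 2)
  # fuzzed regions against the base-by-base oracle
  set.seed(21)
  asm2 <- assembly(c(chr1 = 5000, chr2 = 3100))
  tr2 <- random_track(asm2)
  for (rep in 1:50) {
    ch <- sample(names(asm2$lengths), 1)
    s <- sample(0:(asm2$lengths[[ch]] - 2), 1)
    e <- s + sample(1:(asm2$lengths[[ch]] - s), 1)
    got <- rpm_over_region(tr2, data.frame(chrom = ch, start = s, end = e))
    oracle <- mean(track_per_base(tr2, ch)[(s + 1):e])
    expect_equal(got, oracle, tolerance = 1e-9)
  }
  expect_error(rpm_over_region(tr, data.frame(chrom = "chrZ", start = 0,
                                              end = 10)), "absent")
})

test_that("TSS profile rows run 5'->3' and average to the window mean", {
  asm <- assembly(c(chr1 = 100000))
  set.seed(3)
  tr <- random_track(asm)
  # a minus-strand gene over a mirrored track equals the plus-strand row
  mirror <- signal_track(list(chr1 = rev(tr$values$chr1)), 100, asm)
  genes_p <- data.frame(gene_id = "p", chrom = "chr1", tss = 40000,
                        strand = "+")
  # per-base mirror of a half-open window: tss' = len - tss
  genes_m <- data.frame(gene_id = "m", chrom = "chr1",
                        tss = 100000 - 40000, strand = "-")
  mp <- tss_profile_matrix(tr, genes_p)
  mm <- tss_profile_matrix(mirror, genes_m)
  expect_equal(unname(mp[1, ]), unname(mm[1, ]), tolerance = 1e-9)
  # row mean equals the full-window region mean
  full <- rpm_over_region(tr, data.frame(chrom = "chr1", start = 38000,
                                         end = 42000))
  expect_equal(mean(mp[1, ]), full, tolerance = 1e-9)
  # constant track gives a constant matrix
  ct <- constant_track(asm, 1.5)
  expect_true(all(tss_profile_matrix(ct, genes_p) == 1.5))
  expect_error(tss_profile_matrix(tr, genes_p, flank = 2000, step = 300),
               "divide")
})

test_that("track smoothing truncates at edges and chromosome boundaries", {
  asm <- assembly(c(chrA = 300, chrB = 300))
  tr <- signal_track(list(chrA = c(0, 3, 0), chrB = c(9, 0, 0)), 100, asm)
  sm <- smooth_track(tr, 3)
  expect_equal(sm$values$chrA, c(1.5, 1.0, 1.5))
  # chrB's 9 must not bleed into chrA
  expect_equal(sm$values$chrB, c(4.5, 3.0, 0))
  # window 1 is the identity
  expect_equal(smooth_track(tr, 1)$values, tr$values)
  expect_error(smooth_track(tr, 4), "odd")
  # constant track conserved exactly
  ct <- constant_track(asm, 2)
  expect_equal(smooth_track(ct, 3)$values, ct$values)
})

test_that("domain width classes use inclusive 1-2 kb bounds", {
  peaks <- data.frame(chrom = "chr1",
                      start = c(0, 10000, 20000),
                      end = c(800, 11500, 22500))
  dw <- domain_widths(peaks)
  expect_equal(unname(dw$proportions), rep(1 / 3, 3))
  # boundary ties: exactly 1000 and exactly 2000 are both class 1-2kb
  dw <- domain_widths(data.frame(chrom = "chr1", start = c(0, 10000),
                                 end = c(1000, 12000)))
  expect_equal(unname(dw$proportions["1-2kb"]), 1)
  # proportions sum to 1 and are order-invariant
  set.seed(8)
  start <- sample(seq(0, 1e6, by = 5000), 30)
  peaks <- data.frame(chrom = "chr1", start = start,
                      end = start + sample(200:4000, 30, replace = TRUE))
  a <- domain_widths(peaks)$proportions
  b <- domain_widths(peaks[sample(30), ])$proportions
  expect_equal(a, b)
  expect_equal(sum(a), 1)
  expect_warning(domain_widths(peaks[0, ]), "empty")
})

test_that("merging peaks into domains respects the configured gap", {
  peaks <- data.frame(chrom = "chr1", start = c(0, 1100), end = c(1000,
                                                                  2000))
  expect_equal(nrow(domain_widths(peaks, max_gap = 0)$domains), 2L)
  expect_equal(nrow(domain_widths(peaks, max_gap = 100)$domains), 1L)
})

test_that("replicate correlation equals the textbook Pearson formula", {
  asm <- assembly(c(chr1 = 100000))
  set.seed(12)
  ta <- random_track(asm)
  tb <- random_track(asm)
  prom <- data.frame(chrom = "chr1", start = seq(0, 90000, by = 4000))
  prom$end <- prom$start + 4000
  r <- replicate_correlation(ta, tb, prom)
  a <- rpm_over_region(ta, prom); b <- rpm_over_region(tb, prom)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(r, oracle, tolerance = 1e-12)
  expect_equal(replicate_correlation(ta, ta, prom), 1.0)
  ct <- constant_track(asm, 1)
  expect_error(replicate_correlation(ct, ta, prom), "variance")
  expect_error(replicate_correlation(ta, tb, prom[1:2, ]), "at least 3")
})
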