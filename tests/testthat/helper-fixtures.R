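# Shared fixtures, generated once per test run and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

# small, fast simulation configuration for structural tests
small_sim_config <- function(seed = 42, ...) {
  sim_config(seed = seed,
             chrom_lengths = c(chr1 = 4e5, chr2 = 4e5, chrX = 2e5),
             n_genes = 120, n_te_copies = 2, n_te_cassette = 1,
             n_escapee_promoters = 4, ...)
}

cached_fixture <- function(key, maker) {
  if (!exists(key, envir = .fixture_cache)) {
    dir <- file.path(tempdir(), paste0("pgcepi_", key))
    assign(key, maker(dir), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# full-size noisy fixture (the default study conditions)
default_fixture <- function() {
  cached_fixture("default", function(d) {
    simulate_fixture(sim_config(seed = 101), d)
  })
}

# full-size noise-free fixture
noisefree_fixture <- function() {
  cached_fixture("noisefree", function(d) {
    simulate_fixture(sim_config(seed = 101, noise = FALSE), d)
  })
}

small_fixture <- function() {
  cached_fixture("small", function(d) {
    simulate_fixture(small_sim_config(), d)
  })
}

# toy assembly used across unit tests
toy_assembly <- function() assembly(c(chr1 = 1e6, chr2 = 5e5, chrX = 2e5))

# constant-value signal track on a toy assembly
constant_track <- function(asm, value = 2, bin_width = 100) {
  vals <- lapply(asm$lengths,
                 function(len) rep(value, ceiling(len / bin_width)))
  signal_track(vals, bin_width, asm)
}

# random track for oracle comparisons
random_track <- function(asm, bin_width = 100) {
  vals <- lapply(asm$lengths,
                 function(len) stats::runif(ceiling(len / bin_width), 0, 5))
  signal_track(vals, bin_width, asm)
}

# per-base expansion of a track: value at every base of a chromosome
track_per_base <- function(track, chrom) {
  len <- track$lengths[[chrom]]
  rep(track$values[[chrom]], each = track$bin_width)[seq_len(len)]
}

# load the truth state table of a fixture as per-sample factors
truth_states <- function(fixture_dir, samples) {
  tt <- read_table_tsv(file.path(fixture_dir, "truth",
                                 "promoter_states.tsv"))
  out <- lapply(samples, function(s) {
    st <- tt[[s]]
    keep <- !is.na(st) & st != "NA"
    setNames(factor(st[keep],
                    levels = c("H3K4me3-only", "H3K27me3-only",
                               "bivalent", "unmarked")),
             tt$gene_id[keep])
  })
  names(out) <- samples
  out
}

# classify all PGC samples of a fixture from its peak files
classify_fixture_states <- function(fx, flank = 2000) {
  prom <- gene_promoters(fx$genes, fx$assembly, flank)
  pgc <- fx$samples[fx$samples$lineage == "PGC", ]
  out <- lapply(pgc$sample, function(s) {
    k4 <- read_peaks(file.path(fx$dir, "peaks",
                               paste0(s, ".H3K4me3.bed")), fx$assembly)
    k27 <- read_peaks(file.path(fx$dir, "peaks",
                                paste0(s, ".H3K27me3.bed")), fx$assembly)
    classify_promoters(prom, k4, k27)
  })
  names(out) <- pgc$sample
  out
}
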