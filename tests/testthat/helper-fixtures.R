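# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, .fixture_env)) assign(name, build(), .fixture_env)
  get(name, .fixture_env)
}

# tiny two-chromosome map for fast unit tests
tiny_map <- function(n = 40, n_chr = 2, len_cm = 100, len_bp = 1e8) {
  rows <- lapply(seq_len(n_chr), function(ch) {
    bp <- sort(sample.int(len_bp - 2L, n - 2L)) + 1L
    bp <- unique(c(1L, bp, len_bp))
    data.frame(marker_id = sprintf("t%d_%d", ch, seq_along(bp)),
               chromosome = ch, position_bp = bp,
               position_cM = (bp - 1) / (len_bp - 1) * len_cm)
  })
  df <- do.call(rbind, rows)
  genetic_map(df$marker_id, df$chromosome, df$position_bp, df$position_cM)
}

# small end-to-end fixture: population + genotypes + reconstruction
small_fit <- function() memo("small_fit", function() {
  map <- magic_map_synthetic(800, seed = 11)
  founders <- simulate_founder_panel(map, seed = 12)
  pop <- simulate_funnel_population(funnel_design(), map, n_lines = 80, seed = 13)
  geno <- genotype_mosaics(pop, founders, error_rate = 0.01,
                           missing_rate = 0.15, seed = 14)
  recon <- magic_reconstruct(geno, founders, map)
  list(map = map, founders = founders, pop = pop, geno = geno, recon = recon)
})

# mid-sized fixture for calibration tests (fewer markers, more lines)
calib_fit <- function() memo("calib_fit", function() {
  map <- magic_map_synthetic(400, seed = 21)
  founders <- simulate_founder_panel(map, seed = 22)
  pop <- simulate_funnel_population(funnel_design(), map, n_lines = 120, seed = 23)
  geno <- genotype_mosaics(pop, founders, error_rate = 0.01,
                           missing_rate = 0.15, seed = 24)
  recon <- magic_reconstruct(geno, founders, map)
  list(map = map, founders = founders, pop = pop, geno = geno, recon = recon)
})

# full acceptance-scale fixture (built on first use; shared by the heavy
# acceptance blocks)
big_fit <- function() memo("big_fit", function() {
  map <- magic_map_synthetic(5000, seed = 101)
  founders <- simulate_founder_panel(map, seed = 102)
  pop <- simulate_funnel_population(funnel_design(), map, n_lines = 500, seed = 103)
  geno <- genotype_mosaics(pop, founders, error_rate = 0.01,
                           missing_rate = 0.15, seed = 104)
  recon <- magic_reconstruct(geno, founders, map)
  list(map = map, founders = founders, pop = pop, geno = geno, recon = recon)
})

# deterministic toy emission array builder: founder calls -> emissions
toy_emissions <- function(calls, smoothing = 0.01) {
  fp <- founder_panel(rbind(calls, matrix(0L, 8 - nrow(calls), ncol(calls))))
  E <- init_emissions(fp, smoothing)$probs
  E[, seq_len(nrow(calls)), , drop = FALSE]
}
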