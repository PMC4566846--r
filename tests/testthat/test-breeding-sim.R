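test_that("funnel cross counts match the closed forms and an exhaustive check", {
  d8 <- enumerate_design(8)
  expect_equal(d8$n_two_way, 28)
  expect_equal(d8$n_four_way_crosses, 210)
  expect_equal(d8$n_pools, 70)
  expect_equal(d8$n_funnel_pairs, 35)
  # n = 4: enumerate pairs-of-disjoint-pairs by brute force
  tw <- combn(4, 2, simplify = FALSE)
  fw <- 0
  for (i in seq_along(tw)) for (j in seq_along(tw))
    if (i < j && !length(intersect(tw[[i]], tw[[j]]))) fw <- fw + 1
  d4 <- enumerate_design(4)
  expect_equal(d4$n_two_way, 6)
  expect_equal(d4$n_four_way_crosses, fw)
  expect_equal(d4$n_pools, 1)
  expect_error(enumerate_design(2), "undefined")
  expect_error(enumerate_design(7), "undefined")
})

test_that("expected contributions are exactly the design rationals", {
  off <- expected_contributions(funnel_design(substitution = FALSE))
  expect_equal(as.numeric(off), rep(1 / 8, 8))
  on <- expected_contributions(funnel_design(substitution = TRUE))
  expect_equal(sum(on), 1)
  expect_equal(as.numeric(on["B"]), 1 / 7)       # B73
  expect_equal(as.numeric(on["I"]), 1 / 56)      # CML91
  expect_equal(as.numeric(on["C"]), 3 / 28)      # B96
  expect_equal(as.numeric(on["F"]), 3 / 28)      # HP301
  expect_equal(as.numeric(on[c("A", "D", "E", "G", "H")]), rep(1 / 8, 5))
  expect_equal(attr(on, "numerator") / attr(on, "denominator"), as.numeric(on))
})

test_that("analytic design expectations reproduce the printed values", {
  ex <- design_expectations(19.96, generation = 6, n_lines = 1636)
  expect_equal(ex$expected_junctions, 79.84)
  expect_equal(ex$expected_heterozygosity, 0.03125)
  expect_equal(ex$rix_count, 1337430)
  expect_equal(design_expectations(19.96, 6, 2)$rix_count, 1)
  expect_error(design_expectations(19.96, 1), "F2 or later")
})

test_that("meiosis respects null maps, homozygosity and the Poisson crossover mean", {
  # flat (0 cM) chromosome: gamete equals a parental homolog, no crossovers
  gm0 <- genetic_map(c("a", "b"), c(1, 1), c(1, 1000), c(0, 0))
  h1 <- list(end = 1000L, founder = 1L)
  h2 <- list(end = 1000L, founder = 2L)
  set.seed(5)
  g <- magicpop:::meiosis_chrom(h1, h2, 1L, 1000L, 0, 0, function(cm) cm)
  expect_true(identical(g, h1) || identical(g, h2))
  # homozygous parent: gamete identical regardless of crossovers
  g2 <- magicpop:::meiosis_chrom(h1, h1, 1L, 1000L, 0, 120, function(cm) cm * 8)
  expect_identical(g2, h1)
  # 1-Morgan chromosome: mean crossover count within 3 SE of 1
  set.seed(6)
  n_rep <- 4000
  h2b <- list(end = 10000000L, founder = 2L)
  h1b <- list(end = 10000000L, founder = 1L)
  counts <- vapply(seq_len(n_rep), function(i) {
    g <- magicpop:::meiosis_chrom(h1b, h2b, 1L, 10000000L, 0, 100,
                                  function(cm) 1 + cm * 1e5)
    length(g$end) - 1L  # junctions = realized (effective) crossovers
  }, 0L)
  # junctions undercount crossovers only through parity cancellation (rare)
  expect_lt(abs(mean(counts) - 1), 3 * sqrt(1 / n_rep) + 0.02)
})

test_that("a two-way F1 is fully heterozygous with equal founder shares", {
  set.seed(7)
  map <- tiny_map(30)
  chroms <- magicpop:::chrom_table(map)
  tw <- magicpop:::cross(magicpop:::founder_homologs(1, chroms),
                         magicpop:::founder_homologs(2, chroms))
  line <- list(genome = tw)
  expect_equal(mosaic_heterozygosity(line, chroms), 1)
  sh <- founder_shares(line, chroms)
  expect_equal(sh[1:2], c(0.5, 0.5))
  expect_equal(sum(sh), 1)
})

test_that("simulated F6 lines show SSD heterozygosity decay and junction accumulation", {
  fit <- small_fit()
  pop <- fit$pop
  het <- vapply(pop$lines, mosaic_heterozygosity, 0, chroms = pop$chroms)
  expect_equal(mean(het), 0.03125, tolerance = 0.35)
  # heterozygosity halves per selfing generation
  map <- fit$map
  d3 <- funnel_design(substitution = FALSE, ssd_generations = 2L)  # F3
  d4 <- funnel_design(substitution = FALSE, ssd_generations = 3L)  # F4
  p3 <- simulate_funnel_population(d3, map, n_lines = 60, seed = 31)
  p4 <- simulate_funnel_population(d4, map, n_lines = 60, seed = 32)
  h3 <- mean(vapply(p3$lines, mosaic_heterozygosity, 0, chroms = p3$chroms))
  h4 <- mean(vapply(p4$lines, mosaic_heterozygosity, 0, chroms = p4$chroms))
  expect_equal(h4 / h3, 0.5, tolerance = 0.25)
  # junctions at F6 slightly below the 4L inbred limit
  jn <- mean(vapply(pop$lines, count_true_junctions, 0, chroms = pop$chroms))
  expect_gt(jn, 0.9 * 4 * 19.96)
  expect_lt(jn, 1.05 * 4 * 19.96)
})

test_that("founder shares per line sum to one and average near the design expectation", {
  fit <- small_fit()
  sh <- vapply(fit$pop$lines, founder_shares, numeric(9), chroms = fit$pop$chroms)
  expect_equal(colSums(sh), rep(1, ncol(sh)), tolerance = 1e-12)
  exp_c <- as.numeric(expected_contributions(funnel_design()))
  se <- apply(sh, 1, sd) / sqrt(ncol(sh))
  expect_true(all(abs(rowMeans(sh) - exp_c) <= 4 * se + 0.01))
})

test_that("array genotyping reproduces founder calls, heterozygote coding and call rate", {
  set.seed(8)
  map <- tiny_map(60)
  founders <- simulate_founder_panel(map, seed = 41)
  chroms <- magicpop:::chrom_table(map)
  # fully inbred all-A line: calls equal founder A's row exactly
  lineA <- list(id = "A", funnel = 1L, pedigree_flag = "eight-founder",
                genome = magicpop:::founder_genome(1L, chroms))
  pop <- structure(list(lines = list(lineA), design = funnel_design(),
                        map = map, chroms = chroms), class = "magic_population")
  g0 <- genotype_mosaics(pop, founders, error_rate = 0, missing_rate = 0, seed = 42)
  expect_equal(unname(g0$calls[1, ]), unname(founders$calls[1, ]))
  # heterozygous segment pair codes as 1 where founder alleles differ
  hetline <- list(id = "H", funnel = 1L, pedigree_flag = "eight-founder",
                  genome = magicpop:::cross(magicpop:::founder_homologs(1, chroms),
                                            magicpop:::founder_homologs(2, chroms)))
  pop$lines <- list(hetline)
  gh <- genotype_mosaics(pop, founders, error_rate = 0, missing_rate = 0, seed = 43)
  diffm <- founders$calls[1, ] != founders$calls[2, ]
  expect_true(all(gh$calls[1, diffm] == 1L))
  expect_equal(unname(gh$calls[1, !diffm]), unname(founders$calls[1, !diffm]))
  # missing rate calibrated to the assay's 85% call rate
  fit <- small_fit()
  cr <- call_rate(fit$geno)
  expect_equal(mean(cr), 0.85, tolerance = 0.01)
})

test_that("RIL minor allele frequencies concentrate near multiples of 1/8", {
  fit <- small_fit()
  mh <- compute_maf_het(fit$geno, fit$founders)
  maf <- mh$line_maf[!is.na(mh$line_maf)]
  dist_to_grid <- abs(maf - round(maf * 8) / 8)
  expect_lt(mean(dist_to_grid), 0.035)
})
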