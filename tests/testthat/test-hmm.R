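test_that("transition probability matches the closed form and its limits", {
  expect_equal(transition_probability(0), 0)
  expect_equal(transition_probability(0.5), 7 / 8)
  expect_equal(transition_probability(0.25), 0.25 * 3.75 / 1.5)
  r <- seq(0, 0.5, length.out = 30)
  expect_true(all(diff(transition_probability(r)) > 0))
  expect_error(transition_probability(0.6), "0, 0.5")
  expect_error(transition_probability(-0.1), "0, 0.5")
})

test_that("transition formula equals the eight-way-selfing Markov-chain oracle", {
  for (r in c(0.01, 0.05, 0.1, 0.25, 0.5))
    expect_equal(transition_probability(r), oracle_selfing_nonidentity(r),
                 tolerance = 1e-12)
})

test_that("initial emissions encode founder calls with smoothing", {
  calls <- matrix(c(0L, 2L, 1L, -1L), 4, 1)
  rownames(calls) <- c("A", "B", "C", "D")
  fp <- founder_panel(rbind(calls, matrix(0L, 4, 1)))
  em <- init_emissions(fp, smoothing = 0.01)
  # homozygous call: ~0.98 on its own symbol, ~0.01 elsewhere
  expect_equal(em$probs[1, 1, ], c("0" = 1.01, "1" = 0.01, "2" = 0.01) / 1.03)
  expect_equal(em$probs[1, 2, ], c("0" = 0.01, "1" = 0.01, "2" = 1.01) / 1.03)
  # heterozygous founder: mass split between the homozygous symbols
  expect_equal(unname(em$probs[1, 3, c(1, 3)]), rep(0.51 / 1.03, 2))
  # missing founder: uniform
  expect_equal(unname(em$probs[1, 4, ]), rep(1 / 3, 3))
  # smoothing off: degenerate distribution
  em0 <- init_emissions(fp, smoothing = 0)
  expect_equal(unname(em0$probs[1, 2, ]), c(0, 0, 1))
  expect_true(all(abs(apply(em$probs, c(1, 2), sum) - 1) < 1e-12))
})

test_that("forward-backward matches exhaustive path enumeration on small HMMs", {
  cases <- list(
    list(calls = rbind(c(0L, 2L, 0L), c(2L, 0L, 2L), c(0L, 0L, 2L)),
         obs = c(0L, 0L, 2L), R = c(0.1, 0.3)),
    list(calls = rbind(c(0L, 2L, 0L, 2L), c(2L, 0L, 2L, 0L), c(0L, 0L, 2L, 2L)),
         obs = c(0L, -1L, 1L, 2L), R = c(0.05, 0.2, 0.4)),
    list(calls = rbind(c(0L, 2L), c(2L, 2L)), obs = c(2L, 2L), R = 0.25))
  for (cs in cases) {
    E <- toy_emissions(cs$calls)
    got <- forward_backward(matrix(cs$obs, 1), E, cs$R)
    want <- oracle_fb_enumeration(cs$obs, E, cs$R)
    expect_equal(unname(got$posterior[1, , ]), unname(t(want$posterior)),
                 tolerance = 1e-10)
    expect_equal(got$loglik, want$loglik, tolerance = 1e-10)
  }
})

test_that("forward-backward handles uninformative and forced cases", {
  # single marker, all founders identical: posterior uniform
  callsu <- matrix(rep(0L, 3), 3, 1)
  E <- toy_emissions(callsu)
  got <- forward_backward(matrix(0L, 1, 1), E, numeric(0))
  expect_equal(unname(got$posterior[1, , 1]), rep(1 / 3, 3))
  # all-missing line: posterior equals the prior everywhere
  callsd <- rbind(c(0L, 2L, 0L), c(2L, 0L, 2L))
  E2 <- toy_emissions(callsd)
  gotm <- forward_backward(matrix(-1L, 1, 3), E2, c(0.1, 0.1))
  expect_equal(unname(gotm$posterior[1, , ]), matrix(0.5, 2, 3))
  # error-free two-founder data forces the generating founder
  obs <- matrix(callsd[1, ], 1)
  gotf <- forward_backward(obs, E2, c(0.01, 0.01))
  expect_true(all(gotf$posterior[1, 1, ] > 0.99))
})

test_that("EM increases the likelihood and stays near a self-consistent start", {
  fit <- small_fit()
  expect_true(all(diff(fit$recon$trace) >= 0))
  # error-free, missing-free data: EM converges almost immediately
  clean <- genotype_mosaics(fit$pop, fit$founders, error_rate = 0,
                            missing_rate = 0, seed = 55)
  rc <- magic_reconstruct(clean, fit$founders, fit$map, max_iter = 10)
  expect_lt(rc$iterations, 10)   # stops by the 1/1000 log-likelihood rule
  expect_lt(abs(diff(utils::tail(rc$trace, 2))), abs(rc$trace[1]) / 1000)
  expect_true(all(diff(rc$trace) >= 0))
  # fitted emissions stay close to the founder-call initialization
  expect_gt(stats::cor(as.vector(rc$emissions),
                       as.vector(init_emissions(fit$founders)$probs)), 0.9)
})

test_that("posteriors are normalized and recover simulated mosaics", {
  fit <- small_fit()
  for (a in fit$recon$posteriors) {
    sums <- colSums(aperm(a, c(2, 1, 3)))
    expect_true(all(abs(sums - 1) < 1e-9))
  }
  truth1 <- t(vapply(fit$pop$lines, function(l)
    magicpop:::mosaic_at_markers(l, fit$map, fit$pop$chroms)[, 1],
    integer(nrow(fit$map))))
  truth2 <- t(vapply(fit$pop$lines, function(l)
    magicpop:::mosaic_at_markers(l, fit$map, fit$pop$chroms)[, 2],
    integer(nrow(fit$map))))
  hom <- truth1 == truth2
  acc <- mean(founder_assignment(fit$recon)[hom] == truth1[hom])
  expect_gt(acc, 0.85)  # 800-marker panel; the dense panel does better
})

test_that("reconstruction accuracy degrades monotonically with genotyping error", {
  fit <- small_fit()
  truth1 <- t(vapply(fit$pop$lines, function(l)
    magicpop:::mosaic_at_markers(l, fit$map, fit$pop$chroms)[, 1],
    integer(nrow(fit$map))))
  truth2 <- t(vapply(fit$pop$lines, function(l)
    magicpop:::mosaic_at_markers(l, fit$map, fit$pop$chroms)[, 2],
    integer(nrow(fit$map))))
  hom <- truth1 == truth2
  accs <- vapply(c(0, 0.05, 0.10), function(e) {
    g <- genotype_mosaics(fit$pop, fit$founders, error_rate = e,
                          missing_rate = 0.15, seed = 60)
    r <- magic_reconstruct(g, fit$founders, fit$map, max_iter = 3)
    mean(founder_assignment(r)[hom] == truth1[hom])
  }, 0)
  expect_true(all(diff(accs) < 0))
})

test_that("junction counting is zero for pure lines and capped by the confidence filter", {
  set.seed(9)
  map <- tiny_map(50)
  founders <- simulate_founder_panel(map, seed = 71)
  chroms <- magicpop:::chrom_table(map)
  pure <- list(id = "P", funnel = 1L, pedigree_flag = "eight-founder",
               genome = magicpop:::founder_genome(2L, chroms))
  pop <- structure(list(lines = list(pure), design = funnel_design(),
                        map = map, chroms = chroms), class = "magic_population")
  g <- genotype_mosaics(pop, founders, error_rate = 0, missing_rate = 0, seed = 72)
  r <- magic_reconstruct(g, founders, map, max_iter = 0)
  expect_equal(count_junctions(r), 0L)
  fit <- small_fit()
  expect_true(all(count_junctions(fit$recon, 1.0) <= count_junctions(fit$recon, 0.8)))
})

test_that("per-locus founder contributions are normalized and reflect the design", {
  fit <- small_fit()
  fc <- founder_contribution_per_locus(fit$recon)
  expect_equal(unname(rowSums(fc)), rep(1, nrow(fc)), tolerance = 1e-9)
  # B73 genome-wide mean is elevated by the substitution rule
  expect_gt(mean(fc[, "B"]), mean(fc[, "A"]))
  # single line: contribution equals that line's posterior
  r1 <- fit$recon
  keep <- 1L
  r1$posteriors <- lapply(r1$posteriors, function(a) a[keep, , , drop = FALSE])
  r1$line_ids <- r1$line_ids[keep]
  fc1 <- founder_contribution_per_locus(r1)
  pm <- posterior_matrix(fit$recon, keep)
  expect_equal(unname(fc1), unname(pm / rowSums(pm)), tolerance = 1e-12)
})

test_that("nine-founder lines use the nine-state model and others eight", {
  fit <- small_fit()
  nine <- fit$geno$pedigree_flag == "nine-founder"
  if (any(nine) && any(!nine)) {
    a <- fit$recon$posteriors[[1]]
    expect_true(all(a[!nine, 9, ] == 0))
    expect_true(any(a[nine, 9, ] > 0))
  }
})
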