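test_that("founder replicate merging fills missing and flags conflicts", {
  r1 <- matrix(c(0L, -1L, 0L, 2L), 1)
  r2 <- matrix(c(-1L, 0L, 0L, 0L), 1)
  out <- merge_founder_replicates(r1, r2)
  expect_equal(out$calls[1, ], c(0L, 0L, 0L, -1L))
  expect_equal(out$conflicts[1, ], c(FALSE, FALSE, FALSE, TRUE))
})

test_that("marker QC enforces a strict call-rate boundary and polymorphism", {
  # 100 lines: tune call rates precisely
  n <- 100
  mk <- function(call_rate, alleles) {
    v <- rep(-1L, n)
    ok <- seq_len(round(call_rate * n))
    v[ok] <- rep_len(alleles, length(ok))
    v
  }
  calls <- cbind(m79 = mk(0.79, c(0L, 2L)),
                 m80 = mk(0.80, c(0L, 2L)),
                 m81 = mk(0.81, c(0L, 2L)),
                 mono = mk(1.00, 0L),
                 het_only = mk(1.00, c(0L, 1L)))
  g <- genotype_matrix(calls)
  res <- qc_filter_markers(g, min_call_rate = 0.8)
  expect_equal(unname(res$kept),
               c(FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(res$n_monomorphic, 1)
  # hand filter on a small random panel agrees
  set.seed(50)
  calls2 <- matrix(sample(c(-1L, 0L, 1L, 2L), 200, TRUE,
                          prob = c(0.3, 0.3, 0.1, 0.3)), 20, 10)
  g2 <- genotype_matrix(calls2)
  res2 <- qc_filter_markers(g2, 0.8)
  hand <- vapply(seq_len(10), function(m) {
    v <- calls2[, m]
    cr <- mean(v != -1L)
    ref <- any(v %in% c(0L, 1L)); alt <- any(v %in% c(1L, 2L))
    cr > 0.8 && ref && alt
  }, TRUE)
  expect_equal(unname(res2$kept), hand)
})

test_that("MAF uses only fully homozygous founder markers; never reaches 0.5 with nine", {
  calls <- rbind(matrix(0L, 8, 3), c(2L, 2L, 2L))    # 9 founders
  calls[1, 2] <- 1L     # het founder disqualifies marker 2
  calls[1, 3] <- -1L    # missing founder disqualifies marker 3
  colnames(calls) <- paste0("m", 1:3)
  fp <- founder_panel(calls)
  g <- genotype_matrix(matrix(c(0L, 0L, 2L, 1L, 0L, 2L), 2, 3))
  mh <- compute_maf_het(g, fp)
  expect_equal(unname(mh$marker_subset), c(TRUE, FALSE, FALSE))
  expect_equal(mh$founder_maf[1], 1 / 9)
  expect_true(all(is.na(mh$founder_maf[2:3])))
  expect_true(all(mh$founder_maf <= 4 / 9, na.rm = TRUE))
  # line het: fraction of heterozygous calls
  expect_equal(unname(mh$line_het), c(0, 1 / 3))
  # simulated F6 panel sits near the SSD expectation
  fit <- small_fit()
  clean <- genotype_mosaics(fit$pop, fit$founders, 0, 0, seed = 90)
  mh2 <- compute_maf_het(clean, fit$founders)
  expect_equal(mean(mh2$line_het), 0.03125, tolerance = 0.35)
})

test_that("r-squared matches the direct formula, with symmetry and sign invariance", {
  g1 <- c(0L, 0L, 2L, 2L, 0L, 2L)
  g2 <- c(0L, 2L, 2L, 0L, 0L, 2L)
  hand <- cor(g1, g2)^2
  expect_equal(ld_r2(g1, g2), hand, tolerance = 1e-12)
  expect_equal(ld_r2(g2, g1), ld_r2(g1, g2))
  expect_equal(ld_r2(g1, g1), 1)
  expect_equal(ld_r2(g1, 2L - g1), 1)     # complementary coding
  expect_true(is.na(ld_r2(g1, rep(0L, 6))))
  # missing handled pairwise-complete
  g3 <- g2; g3[2] <- -1L
  ok <- g3 != -1L
  expect_equal(ld_r2(g1, g3), cor(g1[ok], g3[ok])^2, tolerance = 1e-12)
})

test_that("LD decays with distance and halving lands in the expected range", {
  fit <- small_fit()
  ld <- ld_decay(fit$geno, fit$map, max_dist_mb = 10, bin_kb = 500)
  first <- vapply(ld$per_chromosome, function(t) t$mean_r2[1], 0)
  last <- vapply(ld$per_chromosome, function(t) t$mean_r2[nrow(t)], 0)
  expect_true(mean(first) > mean(last))
  hv <- ld$halving_distance_bp / 1e6
  expect_true(median(hv, na.rm = TRUE) >= 0.5 && median(hv, na.rm = TRUE) <= 6)
  # permuting line labels destroys LD: flat profile at background
  set.seed(91)
  perm_calls <- apply(fit$geno$calls, 2, sample)
  rownames(perm_calls) <- rownames(fit$geno$calls)
  gp <- genotype_matrix(perm_calls, fit$geno$pedigree_flag)
  ldp <- ld_decay(gp, fit$map, max_dist_mb = 10, bin_kb = 500)
  firstp <- vapply(ldp$per_chromosome, function(t) t$mean_r2[1], 0)
  expect_lt(mean(firstp), 0.1)
})

test_that("duplicated markers give first-bin r-squared of one", {
  set.seed(92)
  base <- sample(c(0L, 2L), 30, TRUE)
  calls <- cbind(a = base, b = base, c = sample(c(0L, 2L), 30, TRUE))
  g <- genotype_matrix(calls)
  map <- genetic_map(c("a", "b", "c"), c(1, 1, 1), c(1e5, 1.5e5, 9e6),
                     c(0.1, 0.15, 9))
  ld <- ld_decay(g, map, max_dist_mb = 10, bin_kb = 100)
  expect_equal(ld$per_chromosome[["1"]]$mean_r2[1], 1)
})

test_that("local LD profiles are ordered and complete", {
  fit <- small_fit()
  sub <- fit$map$chromosome <= 2
  g <- genotype_matrix(fit$geno$calls[, sub], fit$geno$pedigree_flag)
  map2 <- genetic_map(fit$map$marker_id[sub], fit$map$chromosome[sub],
                      fit$map$position_bp[sub], fit$map$position_cM[sub])
  prof <- local_ld(g, map2, flank_mb = 2, window_markers = 30)
  expect_equal(nrow(prof), sum(sub))
  ok <- !is.na(prof$q25) & !is.na(prof$q75)
  expect_true(all(prof$q25[ok] <= prof$q75[ok]))
  expect_true(all(prof$q25_smoothed <= prof$q75_smoothed + 1e-12, na.rm = TRUE))
})

test_that("LD pruning is greedy, audited and idempotent", {
  set.seed(93)
  base <- sample(c(0L, 2L), 40, TRUE)
  noise <- function() sample(c(0L, 2L), 40, TRUE)
  calls <- cbind(base, base, base, noise(), noise())
  colnames(calls) <- paste0("m", 1:5)
  g <- genotype_matrix(calls)
  map <- genetic_map(paste0("m", 1:5), rep(1, 5),
                     c(1e5, 2e5, 3e5, 4e5, 5e5), 1:5 / 10)
  keep <- ld_prune(g, map, r2_threshold = 0.4, window_kb = 500)
  expect_equal(unname(keep[1:3]), c(TRUE, FALSE, FALSE))  # duplicates pruned
  # audit: retained set has no pair above threshold within the window
  kept_idx <- which(keep)
  for (i in kept_idx) for (j in kept_idx)
    if (i < j && abs(map$position_bp[i] - map$position_bp[j]) <= 5e5) {
      r2 <- ld_r2(calls[, i], calls[, j])
      if (!is.na(r2)) expect_lte(r2, 0.4)
    }
  # idempotent: pruning the pruned panel keeps everything
  g2 <- genotype_matrix(calls[, keep, drop = FALSE])
  map2 <- genetic_map(colnames(calls)[keep], rep(1, sum(keep)),
                      map$position_bp[keep], map$position_cM[keep])
  expect_true(all(ld_prune(g2, map2, 0.4, 500)))
  # independent markers: all retained
  set.seed(94)
  ind <- matrix(sample(c(0L, 2L), 40 * 6, TRUE), 40, 6)
  colnames(ind) <- paste0("x", 1:6)
  gi <- genotype_matrix(ind)
  mi <- genetic_map(paste0("x", 1:6), rep(1, 6),
                    seq(1e6, 6e6, 1e6), 1:6)
  expect_true(all(ld_prune(gi, mi, 0.9, 10000)))
})

test_that("an unrecombined block elevates the local LD profile", {
  fit <- small_fit()
  sub <- which(fit$map$chromosome == 3)
  calls <- fit$geno$calls[, sub]
  block <- 15:24
  for (k in block) calls[, k] <- calls[, block[1]]   # perfect local LD
  g <- genotype_matrix(calls, fit$geno$pedigree_flag)
  map3 <- genetic_map(fit$map$marker_id[sub], fit$map$chromosome[sub],
                      fit$map$position_bp[sub], fit$map$position_cM[sub])
  prof <- local_ld(g, map3, flank_mb = 3, window_markers = 10)
  inblock <- mean(prof$mean_r2[block], na.rm = TRUE)
  outside <- mean(prof$mean_r2[-c(block, 1:5)], na.rm = TRUE)
  expect_gt(inblock, outside + 0.2)
})
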