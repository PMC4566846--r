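#' Read founder SNP variants from a VCF
#'
#' Parses chrom/pos/ref/alt and per-founder genotypes from a (plain-text)
#' VCF of the inbred founder lines; GT 0/0 becomes allele dosage 0, 1/1
#' becomes 2, heterozygous calls 1, missing NA. Requires the vcfR package.
#'
#' @param path VCF file.
#' @param region optional `"chrom:start-end"` restriction.
#' @return A `founder_variants` object: `sites` data.frame (chrom, pos, ref,
#'   alt) and `alleles` matrix founders x sites.
#' @export
read_founder_variants <- function(path, region = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF founder variants requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  sites <- data.frame(chrom = as.integer(fix[, "CHROM"]),
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  dos <- function(g) {
    g <- gsub("\\|", "/", g)
    ifelse(is.na(g), NA_real_,
           ifelse(g %in% c("0/0", "0"), 0,
                  ifelse(g %in% c("1/1", "1"), 2,
                         ifelse(g %in% c("0/1", "1/0"), 1, NA_real_))))
  }
  alleles <- t(apply(gt, 2, dos))
  rownames(alleles) <- colnames(gt)
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([0-9]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4) stop("region must be 'chrom:start-end'")
    keep <- sites$chrom == as.integer(m[2]) &
      sites$pos >= as.integer(m[3]) & sites$pos <= as.integer(m[4])
    sites <- sites[keep, , drop = FALSE]
    alleles <- alleles[, keep, drop = FALSE]
  }
  structure(list(sites = sites, alleles = alleles), class = "founder_variants")
}

#' Construct founder variants from in-memory tables
#'
#' Convenience constructor (used by simulations and tests) mirroring
#' [read_founder_variants()].
#'
#' @param sites data.frame with `chrom` and `pos`.
#' @param alleles founders x sites dosage matrix (0/1/2/NA).
#' @export
founder_variants <- function(sites, alleles) {
  stopifnot(nrow(sites) == ncol(alleles))
  structure(list(sites = sites, alleles = as.matrix(alleles)),
            class = "founder_variants")
}

#' Impute founder SNP alleles onto reconstructed mosaics
#'
#' Each line's posterior founder-probability vector at the array marker
#' nearest to a variant site (ties broken leftward) is combined with the
#' founder allele dosages: dosage = sum_s P(s) a_s, a continuous value in
#' [0, 2]. A rounded haploid companion (0/1 minor-allele indicator) is kept
#' for LD computations. Sites with all-missing founder alleles are skipped.
#'
#' @param recon a `magic_reconstruction`.
#' @param variants a `founder_variants` (founder rows ordered as the
#'   reconstruction's founders).
#' @param region optional `"chrom:start-end"` restriction.
#' @return An `imputed_genotypes` object: `dosage` (lines x sites),
#'   `rounded` (0/1 haploid indicator), `sites`.
#' @export
impute_founder_snps <- function(recon, variants, region = NULL) {
  stopifnot(inherits(recon, "magic_reconstruction"),
            inherits(variants, "founder_variants"))
  sites <- variants$sites
  alleles <- variants$alleles
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([0-9]+):([0-9]+)-([0-9]+)$", region))[[1]]
    keep <- sites$chrom == as.integer(m[2]) &
      sites$pos >= as.integer(m[3]) & sites$pos <= as.integer(m[4])
    sites <- sites[keep, , drop = FALSE]
    alleles <- alleles[, keep, drop = FALSE]
  }
  ok <- colSums(!is.na(alleles)) > 0
  if (any(!ok)) {
    message(sum(!ok), " variant site(s) with all-missing founder alleles skipped")
    sites <- sites[ok, , drop = FALSE]
    alleles <- alleles[, ok, drop = FALSE]
  }
  post <- drop_ninth_founder(recon)
  map <- recon$map
  chroms <- recon$chromosomes
  G <- min(nrow(alleles), 8L)
  n <- length(recon$line_ids)
  dosage <- matrix(NA_real_, n, nrow(sites),
                   dimnames = list(recon$line_ids, NULL))
  for (ch in unique(sites$chrom)) {
    ci <- match(ch, chroms)
    if (is.na(ci)) stop("variant chromosome ", ch, " not on the map")
    midx <- which(map$chromosome == ch)
    mbp <- map$position_bp[midx]
    sidx <- which(sites$chrom == ch)
    # nearest array marker, ties -> left
    lo <- findInterval(sites$pos[sidx], mbp)
    lo[lo == 0L] <- 1L
    hi <- pmin(lo + 1L, length(mbp))
    d_lo <- abs(sites$pos[sidx] - mbp[lo])
    d_hi <- abs(mbp[hi] - sites$pos[sidx])
    nearest <- ifelse(d_hi < d_lo, hi, lo)
    Pch <- post[[ci]]
    for (k in seq_along(sidx)) {
      a <- alleles[seq_len(G), sidx[k]]
      a[is.na(a)] <- mean(a, na.rm = TRUE)   # neutral fill for missing founders
      dosage[, sidx[k]] <- matrix(Pch[, 1:G, nearest[k]], ncol = G) %*% a
    }
  }
  rounded <- ifelse(dosage >= 1, 1L, 0L)
  structure(list(dosage = dosage, rounded = rounded, sites = sites),
            class = "imputed_genotypes")
}

#' Association scan on imputed allele dosages
#'
#' Single-dosage mixed-model regression at every variant site:
#' y = g beta_g + polygenic + error, with the same EMMAX-style machinery as
#' the linkage scan. Monomorphic sites get LOD 0.
#'
#' @param y trait values.
#' @param imputed an `imputed_genotypes`.
#' @param K kinship matrix, or NULL for an i.i.d. model.
#' @return An `assoc_scan` data.frame: chrom, pos, lod, beta.
#' @export
association_scan <- function(y, imputed, K = NULL) {
  stopifnot(inherits(imputed, "imputed_genotypes"))
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(n == nrow(imputed$dosage))
  if (is.null(K)) { U <- NULL; d <- rep(1, n) }
  else { eig <- eigen(K, symmetric = TRUE); U <- eig$vectors; d <- pmax(eig$values, 0) }
  rot <- function(x) if (is.null(U)) x else crossprod(U, x)
  ystar <- rot(y); one_star <- rot(matrix(1, n, 1))
  lambda <- reml_lambda(ystar, one_star, d)
  sw <- sqrt(1 / (lambda * d + 1))
  yw <- ystar * sw; ow <- one_star * sw
  Gw <- rot(imputed$dosage) * as.vector(sw)
  # weighted simple regression, vectorized over sites
  Soo <- sum(ow^2); Soy <- sum(ow * yw); Syy <- sum(yw^2)
  Sog <- as.vector(crossprod(ow, Gw))
  Sgy <- as.vector(crossprod(Gw, yw))
  Sgg <- colSums(Gw^2)
  rss0 <- Syy - Soy^2 / Soo
  gg_r <- Sgg - Sog^2 / Soo               # dosage variance after intercept
  gy_r <- Sgy - Sog * Soy / Soo
  beta <- ifelse(gg_r > 1e-12, gy_r / gg_r, NA_real_)
  rss1 <- ifelse(gg_r > 1e-12, rss0 - gy_r^2 / gg_r, rss0)
  rss1 <- pmin(pmax(rss1, 1e-12), rss0)
  lod <- ifelse(gg_r > 1e-12, n / 2 * log10(rss0 / rss1), 0)
  out <- cbind(imputed$sites[, c("chrom", "pos")],
               data.frame(lod = pmax(lod, 0), beta = beta))
  structure(out, class = c("assoc_scan", "data.frame"), n = n, lambda = lambda)
}

#' Permutation threshold for the association scan
#'
#' 90th percentile of the per-permutation maximum LOD over the scanned
#' region.
#'
#' @inheritParams association_scan
#' @param n_perm permutations (>= 100; the reference analysis used 500).
#' @param seed integer seed.
#' @return list with `threshold` and the permutation `maxima`.
#' @export
association_threshold <- function(y, imputed, K = NULL, n_perm = 500L, seed = 1L) {
  local_rng(seed)
  maxima <- vapply(seq_len(n_perm), function(i)
    max(association_scan(sample(as.numeric(y)), imputed, K)$lod), 0)
  list(threshold = stats::quantile(maxima, 0.90, names = FALSE), maxima = maxima)
}

#' Windowed LD profile over imputed variant sites
#'
#' For each site, the mean pairwise r-squared (on the rounded haploid
#' alleles) with all sites within `window_kb` on each side, then smoothed
#' with a rolling mean whose span is the average site count per
#' 2 x `window_kb` interval.
#'
#' @param imputed an `imputed_genotypes` (single region/chromosome).
#' @param window_kb window half-width in kb.
#' @return data.frame: chrom, pos, mean_r2, smoothed.
#' @export
interval_ld_profile <- function(imputed, window_kb = 100) {
  sites <- imputed$sites
  S <- nrow(sites)
  if (S < 2) return(data.frame(chrom = integer(0), pos = integer(0),
                               mean_r2 = numeric(0), smoothed = numeric(0)))
  x <- imputed$rounded
  r2 <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))^2
  mean_r2 <- numeric(S)
  w <- window_kb * 1e3
  for (s in seq_len(S)) {
    nb <- which(sites$chrom == sites$chrom[s] &
                  abs(sites$pos - sites$pos[s]) <= w & seq_len(S) != s)
    mean_r2[s] <- if (length(nb)) mean(r2[s, nb], na.rm = TRUE) else NA_real_
  }
  span <- max(1L, round(mean(vapply(seq_len(S), function(s)
    sum(sites$chrom == sites$chrom[s] &
          abs(sites$pos - sites$pos[s]) <= 2 * w), 0))))
  data.frame(chrom = sites$chrom, pos = sites$pos, mean_r2 = mean_r2,
             smoothed = rolling_mean(mean_r2, span))
}

rolling_mean <- function(x, span) {
  n <- length(x)
  half <- span %/% 2
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi], na.rm = TRUE)
  }, 0)
}
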