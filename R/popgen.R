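#' Merge duplicate founder genotyping replicates
#'
#' A call missing in one replicate is filled from the other; conflicting
#' non-missing calls are set missing and flagged.
#'
#' @param rep1,rep2 integer call matrices over the same panel (0/1/2/-1).
#' @return list with `calls` (consensus matrix) and `conflicts` (logical
#'   matrix of flagged cells).
#' @export
merge_founder_replicates <- function(rep1, rep2) {
  rep1 <- as.matrix(rep1); rep2 <- as.matrix(rep2)
  stopifnot(identical(dim(rep1), dim(rep2)))
  out <- rep1
  out[rep1 == -1L] <- rep2[rep1 == -1L]
  conflict <- rep1 != -1L & rep2 != -1L & rep1 != rep2
  out[conflict] <- -1L
  list(calls = out, conflicts = conflict)
}

#' Marker QC filter
#'
#' Retains markers with call rate strictly over `min_call_rate` that are
#' polymorphic (at least two alleles observed) among the lines.
#'
#' @param genotypes a [genotype_matrix()].
#' @param min_call_rate call-rate threshold (strict >, default 0.8).
#' @return list with the filtered [genotype_matrix()], the logical `kept`
#'   vector, and dropped counts by reason.
#' @export
qc_filter_markers <- function(genotypes, min_call_rate = 0.8) {
  g <- genotypes$calls
  cr <- colMeans(g != -1L)
  has_ref <- colSums(g == 0L | g == 1L) > 0
  has_alt <- colSums(g == 2L | g == 1L) > 0
  poly <- has_ref & has_alt
  kept <- cr > min_call_rate & poly
  if (!any(kept)) warning("no markers pass QC")
  filtered <- genotype_matrix(g[, kept, drop = FALSE], genotypes$pedigree_flag)
  list(genotypes = filtered, kept = kept,
       n_low_call = sum(cr <= min_call_rate),
       n_monomorphic = sum(cr > min_call_rate & !poly))
}

#' Minor allele frequencies and heterozygosity
#'
#' MAF is computed only at markers where every founder is homozygous and
#' non-missing (so founder alleles are unambiguous): founder MAF is the minor
#' fraction of the founder alleles (with nine founders it can never reach
#' 0.5), line MAF the minor allele fraction over non-missing line calls.
#' Line heterozygosity is the fraction of (non-missing) calls equal to 1
#' over all markers.
#'
#' @param genotypes a [genotype_matrix()].
#' @param founders a [founder_panel()] on the same markers.
#' @return list: `marker_subset` (logical), `founder_maf`, `line_maf`
#'   (per qualifying marker), `line_het` (per line).
#' @export
compute_maf_het <- function(genotypes, founders) {
  fc <- founders$calls
  g <- genotypes$calls
  qual <- colSums(fc == 0L | fc == 2L) == nrow(fc)
  if (!any(qual)) warning("no markers homozygous and called in all founders")
  founder_maf <- rep(NA_real_, ncol(fc))
  p <- colMeans(fc[, qual, drop = FALSE] == 2L)
  founder_maf[qual] <- pmin(p, 1 - p)
  line_maf <- rep(NA_real_, ncol(g))
  gs <- g[, qual, drop = FALSE]
  n_obs <- colSums(gs != -1L)
  alt <- colSums((gs == 2L) * 2L + (gs == 1L))
  pa <- ifelse(n_obs > 0, alt / (2 * n_obs), NA_real_)
  line_maf[qual] <- pmin(pa, 1 - pa)
  het <- rowSums(g == 1L) / pmax(rowSums(g != -1L), 1L)
  list(marker_subset = qual, founder_maf = founder_maf, line_maf = line_maf,
       line_het = het)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of additive allele dosages over
#' pairwise-complete lines (heterozygous calls contribute dosage 1).
#'
#' @param g1,g2 integer call vectors (0/1/2/-1).
#' @return r-squared in [0,1], or NA when either vector has no variance.
#' @export
ld_r2 <- function(g1, g2) {
  x <- ifelse(g1 == -1L, NA_real_, as.numeric(g1))
  y <- ifelse(g2 == -1L, NA_real_, as.numeric(g2))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])^2
}

# NA-coded dosage matrix for correlation work
dosage_matrix <- function(genotypes) {
  m <- genotypes$calls
  m[m == -1L] <- NA_integer_
  storage.mode(m) <- "double"
  m
}

#' LD decay with distance and halving distance
#'
#' Per chromosome, all marker pairs within `max_dist_mb` are binned by
#' physical distance (`bin_kb` wide bins) and mean r-squared computed per
#' bin. The halving distance is the first bin midpoint at which the mean
#' falls to half the first bin's mean.
#'
#' @param genotypes a [genotype_matrix()].
#' @param map the [genetic_map()].
#' @param max_dist_mb maximum pair distance (default 10).
#' @param bin_kb bin width (default 100).
#' @param min_pairs bins with fewer pairs are flagged (default 10).
#' @return An `ld_decay` object: per-chromosome decay tables and halving
#'   distances, plus a pooled table.
#' @export
ld_decay <- function(genotypes, map, max_dist_mb = 10, bin_kb = 100,
                     min_pairs = 10L) {
  dm <- dosage_matrix(genotypes)
  max_d <- max_dist_mb * 1e6
  bw <- bin_kb * 1e3
  per_chr <- list()
  halving <- c()
  pooled <- list()
  for (ch in unique(map$chromosome)) {
    idx <- which(map$chromosome == ch)
    bp <- map$position_bp[idx]
    r2 <- suppressWarnings(stats::cor(dm[, idx, drop = FALSE],
                                      use = "pairwise.complete.obs"))^2
    pr <- which(upper.tri(r2), arr.ind = TRUE)
    d <- bp[pr[, 2]] - bp[pr[, 1]]
    keep <- d > 0 & d <= max_d & !is.na(r2[pr])
    d <- d[keep]; v <- r2[pr][keep]
    bin <- floor(d / bw)
    tab <- data.frame(
      dist_mid = (sort(unique(bin)) + 0.5) * bw,
      mean_r2 = as.numeric(tapply(v, bin, mean)),
      n_pairs = as.integer(tapply(v, bin, length)))
    tab$sparse <- tab$n_pairs < min_pairs
    base <- tab$mean_r2[1]
    cross <- which(tab$mean_r2 <= base / 2)
    halving[as.character(ch)] <- if (length(cross)) tab$dist_mid[cross[1]] else NA_real_
    per_chr[[as.character(ch)]] <- tab
    pooled[[length(pooled) + 1L]] <- data.frame(d = d, v = v)
  }
  all <- do.call(rbind, pooled)
  bin <- floor(all$d / bw)
  pooled_tab <- data.frame(dist_mid = (sort(unique(bin)) + 0.5) * bw,
                           mean_r2 = as.numeric(tapply(all$v, bin, mean)),
                           n_pairs = as.integer(tapply(all$v, bin, length)))
  structure(list(per_chromosome = per_chr, halving_distance_bp = halving,
                 pooled = pooled_tab),
            class = "ld_decay")
}

#' @export
print.ld_decay <- function(x, ...) {
  cat("LD decay over", length(x$per_chromosome), "chromosome(s)\n")
  cat("Halving distance (Mb):\n")
  print(round(x$halving_distance_bp / 1e6, 2))
  invisible(x)
}

#' Marker-centered local LD profile
#'
#' For each marker, the mean (and 25th/75th percentile) of pairwise
#' r-squared with all markers within `flank_mb`; each series is then
#' smoothed with a `window_markers`-wide sliding mean (step 1 marker;
#' windows shrink at chromosome ends and on short chromosomes).
#'
#' @param genotypes a [genotype_matrix()].
#' @param map the [genetic_map()].
#' @param flank_mb flank half-width in Mb (default 1).
#' @param window_markers sliding window size (default 100).
#' @return data.frame per marker: chromosome, position, local mean/quartiles
#'   and their smoothed series.
#' @export
local_ld <- function(genotypes, map, flank_mb = 1, window_markers = 100L) {
  dm <- dosage_matrix(genotypes)
  out <- list()
  for (ch in unique(map$chromosome)) {
    idx <- which(map$chromosome == ch)
    bp <- map$position_bp[idx]
    r2 <- suppressWarnings(stats::cor(dm[, idx, drop = FALSE],
                                      use = "pairwise.complete.obs"))^2
    k <- length(idx)
    mean_r2 <- q25 <- q75 <- rep(NA_real_, k)
    for (i in seq_len(k)) {
      nb <- which(abs(bp - bp[i]) <= flank_mb * 1e6 & seq_len(k) != i)
      vals <- r2[i, nb]
      vals <- vals[!is.na(vals)]
      if (length(vals)) {
        mean_r2[i] <- mean(vals)
        q <- stats::quantile(vals, c(0.25, 0.75), names = FALSE)
        q25[i] <- q[1]; q75[i] <- q[2]
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      chromosome = ch, marker_id = map$marker_id[idx], position_bp = bp,
      mean_r2 = mean_r2, q25 = q25, q75 = q75,
      smoothed = rolling_mean(mean_r2, min(window_markers, k)),
      q25_smoothed = rolling_mean(q25, min(window_markers, k)),
      q75_smoothed = rolling_mean(q75, min(window_markers, k)),
      window_shrunk = k < window_markers)
  }
  do.call(rbind, out)
}

#' Greedy LD pruning
#'
#' Left-to-right within each chromosome: a marker is dropped when its
#' r-squared with any already-retained marker within `window_kb` exceeds the
#' threshold; the pass repeats until the retained set is stable.
#'
#' @param genotypes a [genotype_matrix()].
#' @param map the [genetic_map()].
#' @param r2_threshold pruning threshold (default 0.4).
#' @param window_kb window half-width in kb (default 500).
#' @return logical vector over markers: TRUE = retained.
#' @export
ld_prune <- function(genotypes, map, r2_threshold = 0.4, window_kb = 500) {
  dm <- dosage_matrix(genotypes)
  keep <- rep(TRUE, nrow(map))
  w <- window_kb * 1e3
  for (ch in unique(map$chromosome)) {
    idx <- which(map$chromosome == ch)
    bp <- map$position_bp[idx]
    r2 <- suppressWarnings(stats::cor(dm[, idx, drop = FALSE],
                                      use = "pairwise.complete.obs"))^2
    kc <- rep(TRUE, length(idx))
    repeat {
      changed <- FALSE
      for (i in seq_along(idx)) {
        if (!kc[i]) next
        prev <- which(kc & seq_along(idx) < i & abs(bp - bp[i]) <= w)
        if (length(prev) && any(r2[i, prev] > r2_threshold, na.rm = TRUE)) {
          kc[i] <- FALSE
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    keep[idx] <- kc
  }
  keep
}
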