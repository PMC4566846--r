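#' Kinship from founder posterior probabilities
#'
#' K_ij is the mean over markers of the inner product of the two lines'
#' posterior founder-probability vectors. With `exclude_chromosome`, markers
#' on that chromosome are left out (the LOCO scheme, which avoids absorbing
#' the scanned chromosome's own QTL signal into the polygenic term).
#'
#' @param posteriors a `magic_reconstruction` or a list of per-chromosome
#'   posterior arrays (lines x states x markers).
#' @param exclude_chromosome chromosome index to leave out, or NULL.
#' @return symmetric lines x lines matrix.
#' @export
compute_kinship <- function(posteriors, exclude_chromosome = NULL) {
  comp <- kinship_components(posteriors)
  use <- rep(TRUE, length(comp$gram))
  if (!is.null(exclude_chromosome)) {
    use[comp$chromosomes == exclude_chromosome] <- FALSE
    if (!any(use)) stop("no markers left after excluding chromosome ",
                        exclude_chromosome)
  }
  Reduce(`+`, comp$gram[use]) / sum(comp$n_markers[use])
}

# per-chromosome Gram matrices of the posterior design, cached by the scan
kinship_components <- function(posteriors) {
  if (inherits(posteriors, "magic_reconstruction")) {
    chroms <- posteriors$chromosomes
    posteriors <- posteriors$posteriors
  } else chroms <- seq_along(posteriors)
  gram <- lapply(posteriors, function(a) {
    L <- dim(a)[1]
    X <- matrix(a, L, dim(a)[2] * dim(a)[3])
    tcrossprod(X)
  })
  list(gram = gram, n_markers = vapply(posteriors, function(a) dim(a)[3], 0L),
       chromosomes = chroms)
}

#' Drop the ninth founder and renormalize posteriors
#'
#' The substitute parent segregates at very low frequency, which makes its
#' mapping coefficients unstable; its posterior column is removed and the
#' remaining eight renormalized to sum to 1 line by line. Rows that were
#' entirely ninth-founder become uniform 1/8 and are flagged.
#'
#' @param posteriors list of per-chromosome arrays (lines x >=9 x markers) or
#'   a `magic_reconstruction`.
#' @return list of per-chromosome arrays with 8 state columns; attribute
#'   `flagged` counts the degenerate line-markers.
#' @export
drop_ninth_founder <- function(posteriors) {
  if (inherits(posteriors, "magic_reconstruction"))
    posteriors <- posteriors$posteriors
  flagged <- 0L
  out <- lapply(posteriors, function(a) {
    if (dim(a)[2] <= 8L) return(a)
    b <- a[, 1:8, , drop = FALSE]
    tot <- colSums(aperm(b, c(2, 1, 3)))            # lines x markers
    zero <- tot <= 0
    flagged <<- flagged + sum(zero)
    tot[zero] <- 1
    b <- sweep(b, c(1, 3), tot, "/")
    if (any(zero)) {
      for (m in which(colSums(zero) > 0)) b[zero[, m], , m] <- 1 / 8
    }
    b
  })
  structure(out, flagged = flagged)
}

#' Multi-founder mixed-model QTL scan
#'
#' Regresses a trait on the posterior founder probabilities at each marker
#' with a polygenic random effect: y = sum_s p(s) beta_s + g + e, where g has
#' covariance sigma_g^2 K. The variance ratio is estimated once per
#' chromosome under the null by REML on the eigendecomposition of the LOCO
#' kinship (EMMAX-style) and fixed across markers; each marker is then tested
#' by generalized least squares on the rotated data. LOD is
#' (n/2) log10(RSS0/RSS1). Because the eight posterior columns sum to one the
#' marker model carries no separate intercept, and founder effects are
#' reported as deviations from their mean.
#'
#' @param y named or ordered numeric trait vector, one value per line.
#' @param recon a `magic_reconstruction` (nine-state posteriors are reduced
#'   via [drop_ninth_founder()] automatically).
#' @param kinship `"loco"` (default), `"overall"`, `"none"`, or a precomputed
#'   lines x lines matrix.
#' @param covariate optional marker id whose founder probabilities are added
#'   to both null and alternative models (conditional scan).
#' @return A `magic_scan` object: data.frame with marker, chromosome,
#'   positions, `lod`, plus founder-coefficient columns `beta_*`; attributes
#'   carry per-marker RSS and the per-chromosome null RSS for
#'   variance-explained computation.
#' @export
magic_scan <- function(y, recon, kinship = c("loco", "overall", "none"),
                       covariate = NULL) {
  stopifnot(inherits(recon, "magic_reconstruction"))
  post <- drop_ninth_founder(recon)
  n <- length(recon$line_ids)
  if (!is.null(names(y))) y <- y[recon$line_ids]
  y <- as.numeric(y)
  if (length(y) != n) stop("trait length does not match line count")
  if (stats::var(y) == 0) y_const <- TRUE else y_const <- FALSE
  Kmat <- NULL
  if (is.matrix(kinship)) { Kmat <- kinship; kinship <- "matrix" }
  else kinship <- match.arg(kinship)
  comp <- if (kinship %in% c("loco", "overall")) kinship_components(post) else NULL
  map <- recon$map
  chroms <- recon$chromosomes
  cov_cols <- NULL
  if (!is.null(covariate)) {
    mi <- match(covariate, map$marker_id)
    if (is.na(mi)) stop("covariate marker not in panel: ", covariate)
    ci <- match(map$chromosome[mi], chroms)
    ki <- sum(map$chromosome[seq_len(mi)] == map$chromosome[mi])
    cov_cols <- matrix(post[[ci]][, , ki], n, 8)
  }
  lod <- numeric(nrow(map)); rss1 <- numeric(nrow(map))
  rss0_chr <- numeric(length(chroms))
  betas <- matrix(NA_real_, nrow(map), 8,
                  dimnames = list(NULL, paste0("beta_", recon$founder_ids[1:8])))
  lambda_chr <- numeric(length(chroms))
  for (ci in seq_along(chroms)) {
    idx <- which(map$chromosome == chroms[ci])
    K <- switch(kinship,
                loco = Reduce(`+`, comp$gram[-ci]) / sum(comp$n_markers[-ci]),
                overall = Reduce(`+`, comp$gram) / sum(comp$n_markers),
                matrix = Kmat,
                none = NULL)
    eig <- if (is.null(K)) list(vectors = diag(n), values = rep(1, n))
           else eigen(K, symmetric = TRUE)
    res <- scan_chromosome(y, post[[ci]], eig, cov_cols)
    lod[idx] <- res$lod
    rss1[idx] <- res$rss1
    rss0_chr[ci] <- res$rss0
    betas[idx, ] <- res$beta
    lambda_chr[ci] <- res$lambda
  }
  if (y_const) { lod[] <- 0; betas[] <- 0 }
  out <- data.frame(marker_id = map$marker_id, chromosome = map$chromosome,
                    position_bp = map$position_bp, position_cM = map$position_cM,
                    lod = lod)
  out <- cbind(out, betas)
  structure(out, class = c("magic_scan", "data.frame"),
            rss1 = rss1, rss0 = stats::setNames(rss0_chr, chroms),
            lambda = stats::setNames(lambda_chr, chroms),
            n = n, kinship = kinship, covariate = covariate)
}

# Weighted GLS scan of one chromosome on rotated data. Null: intercept (+
# covariate founder columns); alternative adds the marker's 8 posterior
# columns (which span the intercept).
scan_chromosome <- function(y, post_arr, eig, cov_cols = NULL) {
  n <- length(y); G <- 8L; M <- dim(post_arr)[3]
  U <- eig$vectors; d <- pmax(eig$values, 0)
  ystar <- crossprod(U, y)
  one_star <- crossprod(U, rep(1, n))
  X0 <- one_star
  cov_star <- NULL
  if (!is.null(cov_cols)) {
    cov_star <- crossprod(U, cov_cols)
    X0 <- cbind(one_star, cov_star)
  }
  lambda <- reml_lambda(ystar, X0, d)
  w <- 1 / (lambda * d + 1)
  sw <- sqrt(w)
  yw <- ystar * sw
  X0w <- X0 * sw
  f0 <- stats::lm.fit(X0w, yw)
  rss0 <- sum(f0$residuals^2)
  # base (alt-model nuisance) = covariate columns only; residualize
  if (!is.null(cov_star)) {
    Bw <- cov_star * sw
    qb <- qr(Bw)
    yr <- qr.resid(qb, yw)
  } else { qb <- NULL; yr <- yw }
  rss_base <- sum(yr^2)
  lod <- numeric(M); rss1 <- numeric(M); beta <- matrix(NA_real_, M, G)
  # rotate all marker columns at once, then apply the GLS weights
  Pr <- crossprod(U, matrix(post_arr, n, G * M)) * as.vector(sw)
  scale0 <- stats::median(colSums(Pr^2))   # typical design-column norm
  for (m in seq_len(M)) {
    Xm <- Pr[, ((m - 1L) * G + 1L):(m * G), drop = FALSE]
    if (!is.null(qb)) Xm <- qr.resid(qb, Xm)
    A <- crossprod(Xm)
    # markers whose columns vanish after residualization (e.g. the covariate
    # itself) carry no testable signal
    if (max(diag(A)) < scale0 * 1e-8) { lod[m] <- 0; rss1[m] <- rss0; next }
    b <- crossprod(Xm, yr)
    sol <- safe_solve(A, b)
    if (is.null(sol)) { lod[m] <- 0; rss1[m] <- rss0; next }
    delta <- sum(b * sol)
    r1 <- max(rss_base - delta, 1e-12)
    r1 <- min(r1, rss0)
    rss1[m] <- r1
    lod[m] <- max(0, n / 2 * log10(rss0 / r1))
    beta[m, ] <- sol - mean(sol)
  }
  list(lod = lod, rss1 = rss1, rss0 = rss0, beta = beta, lambda = lambda)
}

# rank-tolerant SPD solve; NULL if the system is effectively singular
safe_solve <- function(A, b, tol = 1e-9) {
  dA <- diag(A)
  if (any(!is.finite(dA))) return(NULL)
  ch <- tryCatch(chol(A + diag(ncol(A)) * max(dA) * 1e-10),
                 error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  backsolve(ch, forwardsolve(t(ch), b))
}

reml_lambda <- function(ystar, X0, d, lower = -10, upper = 12) {
  n <- length(ystar); p <- ncol(X0)
  nll <- function(loglam) {
    lam <- exp(loglam)
    w <- 1 / (lam * d + 1)
    sw <- sqrt(w)
    fit <- stats::lm.fit(X0 * sw, ystar * sw)
    rss <- max(sum(fit$residuals^2), 1e-300)
    xtx <- crossprod(X0 * sw)
    ld <- as.numeric(determinant(xtx, logarithm = TRUE)$modulus)
    val <- 0.5 * ((n - p) * log(rss) + sum(log(lam * d + 1)) + ld)
    if (!is.finite(val)) .Machine$double.xmax / 2 else val
  }
  if (max(d) - min(d) < 1e-12) return(0)   # K proportional to I: ratio immaterial
  opt <- stats::optimize(nll, c(lower, upper))
  # compare against the boundary (no polygenic effect)
  if (nll(lower) <= opt$objective) return(exp(lower))
  exp(opt$minimum)
}

#' Genome-wide permutation significance thresholds
#'
#' Permutes the trait across lines, rescans the genome, and records the
#' genome-wide maximum LOD of each permutation. The strong threshold is the
#' 99th percentile of the maxima (genome-wide P < 0.01) and the suggestive
#' threshold the 37th percentile (P < 0.63). Variance components are
#' re-estimated for each permutation unless `freeze_vc = TRUE`.
#'
#' @inheritParams magic_scan
#' @param n_perm number of permutations (>= 100; the reference analysis used
#'   1,000).
#' @param seed integer seed for the permutation order.
#' @param freeze_vc reuse each chromosome's variance ratio from the observed
#'   trait instead of re-estimating per permutation.
#' @return list with `strong`, `suggestive` and the vector of permutation
#'   `maxima`.
#' @export
permutation_thresholds <- function(y, recon, n_perm = 1000L, seed = 1L,
                                   kinship = c("loco", "overall", "none"),
                                   freeze_vc = FALSE) {
  kinship <- match.arg(kinship)
  local_rng(seed)
  maxima <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    yp <- sample(as.numeric(y))
    sc <- magic_scan(yp, recon, kinship = kinship)
    maxima[p] <- max(sc$lod)
  }
  list(strong = stats::quantile(maxima, 0.99, names = FALSE),
       suggestive = stats::quantile(maxima, 0.37, names = FALSE),
       maxima = maxima)
}

#' Call QTL peaks with -2 LOD support intervals
#'
#' Markers above the suggestive threshold are grouped into peaks; two local
#' maxima are reported as distinct peaks only when separated by at least
#' `split_markers` consecutive markers below the suggestive threshold. The
#' support interval runs to the closest flanking markers whose LOD drops 2
#' below the peak (or the chromosome ends). Variance explained is
#' 1 - RSS1/RSS0 at the peak marker.
#'
#' @param scan a `magic_scan`.
#' @param suggestive,strong thresholds from [permutation_thresholds()].
#' @param split_markers separation rule (default 50 markers).
#' @return data.frame of peaks (possibly empty): chromosome, marker, LOD,
#'   interval, variance explained, significance level, founder effects.
#' @export
call_peaks <- function(scan, suggestive, strong, split_markers = 50L) {
  stopifnot(inherits(scan, "magic_scan"))
  rss1 <- attr(scan, "rss1"); rss0 <- attr(scan, "rss0")
  peaks <- list()
  for (ch in unique(scan$chromosome)) {
    idx <- which(scan$chromosome == ch)
    lod <- scan$lod[idx]
    above <- lod > suggestive
    if (!any(above)) next
    # group above-threshold markers: a new group starts after a run of
    # >= split_markers consecutive sub-suggestive markers
    ai <- which(above)
    gaps <- c(0L, diff(ai) - 1L)           # sub-suggestive markers between
    grp <- cumsum(gaps >= split_markers)
    for (g in unique(grp)) {
      members <- ai[grp == g]
      pk <- members[which.max(lod[members])]
      target <- lod[pk] - 2
      lo <- pk; while (lo > 1 && lod[lo] > target) lo <- lo - 1L
      hi <- pk; while (hi < length(idx) && lod[hi] > target) hi <- hi + 1L
      gi <- idx[pk]
      ve <- 1 - rss1[gi] / rss0[as.character(ch)]
      eff <- as.numeric(scan[gi, grep("^beta_", names(scan))])
      peaks[[length(peaks) + 1L]] <- cbind(
        data.frame(chromosome = ch, marker_id = scan$marker_id[gi],
                   position_bp = scan$position_bp[gi], lod = lod[pk],
                   ci_lo_bp = scan$position_bp[idx[lo]],
                   ci_hi_bp = scan$position_bp[idx[hi]],
                   var_explained = ve,
                   significance = if (lod[pk] > strong) "strong" else "suggestive"),
        stats::setNames(as.data.frame(t(eff)), grep("^beta_", names(scan), value = TRUE)))
    }
  }
  if (!length(peaks))
    return(data.frame(chromosome = integer(0), marker_id = character(0),
                      position_bp = integer(0), lod = numeric(0),
                      ci_lo_bp = integer(0), ci_hi_bp = integer(0),
                      var_explained = numeric(0), significance = character(0)))
  do.call(rbind, peaks)
}

#' @export
print.magic_scan <- function(x, ...) {
  cat("QTL scan: ", nrow(x), " markers, ", length(unique(x$chromosome)),
      " chromosomes, n = ", attr(x, "n"), " lines, kinship = ",
      attr(x, "kinship"), "\n", sep = "")
  top <- x[which.max(x$lod), c("marker_id", "chromosome", "position_bp", "lod")]
  cat("Top marker: ", top$marker_id, " (chr ", top$chromosome, ", ",
      round(top$position_bp / 1e6, 2), " Mb), LOD ", round(top$lod, 2), "\n",
      sep = "")
  invisible(x)
}

#' @export
summary.magic_scan <- function(object, ...) {
  by_chr <- do.call(rbind, lapply(split(object, object$chromosome), function(s)
    s[which.max(s$lod), c("chromosome", "marker_id", "position_bp", "lod")]))
  rownames(by_chr) <- NULL
  by_chr
}

#' @export
plot.magic_scan <- function(x, thresholds = NULL, ...) {
  col <- 1 + x$chromosome %% 2
  graphics::plot(seq_len(nrow(x)), x$lod, col = c("grey30", "steelblue")[col],
                 pch = 16, cex = 0.4, xlab = "marker index", ylab = "LOD", ...)
  if (!is.null(thresholds)) {
    graphics::abline(h = thresholds$strong, col = "red")
    graphics::abline(h = thresholds$suggestive, col = "darkgreen", lty = 2)
  }
  invisible(x)
}
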