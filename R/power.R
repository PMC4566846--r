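#' QTL power-study scenario grid
#'
#' The reference power study crosses four minor-allele-frequency settings
#' (the minor allele carried by 1-4 of the 8 founders), five sample sizes and
#' two heritabilities, with 20 QTL per run whose effects follow the geometric
#' series 0.9^i.
#'
#' @param maf_founders founders carrying the minor allele per QTL.
#' @param n_lines sample sizes.
#' @param h2 additive heritabilities.
#' @param n_qtl QTL per simulated trait (two per chromosome).
#' @param effect_base base of the geometric effect series.
#' @return data.frame of scenarios (one row per MAF x n x h2 combination).
#' @export
power_scenarios <- function(maf_founders = 1:4,
                            n_lines = c(100, 200, 300, 400, 500),
                            h2 = c(0.4, 0.7), n_qtl = 20L, effect_base = 0.9) {
  g <- expand.grid(maf_founders = maf_founders, n_lines = n_lines, h2 = h2)
  g$n_qtl <- n_qtl
  g$effect_base <- effect_base
  g
}

#' Condense founder posteriors to a QTL genotype
#'
#' f = 2 * sum over founders in F of the posterior probability, minus 1:
#' +1 for a line wholly descended from the minor-allele founders F, -1 for a
#' line wholly outside F.
#'
#' @param posterior matrix lines x founders (rows sum to 1) or a single row.
#' @param F integer indices of the founders carrying the minor allele.
#' @return numeric in [-1, 1] per line.
#' @export
condense_founder_genotype <- function(posterior, F) {
  if (!length(F)) stop("founder set F must be non-empty")
  if (is.null(dim(posterior))) posterior <- matrix(posterior, nrow = 1)
  2 * rowSums(posterior[, F, drop = FALSE]) - 1
}

#' Posterior founder probabilities of all lines at one marker
#'
#' @param post list of per-chromosome posterior arrays (see
#'   [drop_ninth_founder()]).
#' @param map the [genetic_map()].
#' @param chroms the chromosome indices matching `post`.
#' @param m global marker index into `map`.
#' @return matrix lines x 8.
#' @export
posterior_at_marker <- function(post, map, chroms, m) {
  ch <- map$chromosome[m]
  ci <- match(ch, chroms)
  k <- sum(map$chromosome[seq_len(m)] == ch)
  matrix(post[[ci]][, 1:8, k], ncol = 8)
}

#' Simulate a 20-QTL geometric-effect phenotype
#'
#' Samples `n_lines` lines, picks `n_qtl` QTL markers (two per chromosome),
#' draws an independent minor-allele founder set F of size `maf_founders` per
#' QTL, and builds the genetic value g = sum_i base^i f_i from the condensed
#' genotypes. g is standardized to unit variance and combined with standard
#' normal noise as y = sqrt(h2) g + sqrt(1 - h2) e.
#'
#' @param post list of per-chromosome posterior arrays (8 founder columns;
#'   see [drop_ninth_founder()]).
#' @param map the marker [genetic_map()].
#' @param scenario one row of [power_scenarios()] (or a list with the same
#'   fields).
#' @param seed integer seed.
#' @return list with `y`, `rows` (sampled line indices) and `truth`
#'   (per-QTL marker index, founder set, effect, realized explained-variance
#'   fraction).
#' @export
simulate_phenotype <- function(post, map, scenario, seed = 1L) {
  local_rng(seed)
  chroms <- sort(unique(map$chromosome))
  per_chr <- table(map$chromosome)
  if (any(per_chr < 2)) stop("need at least 2 markers per chromosome")
  n_total <- dim(post[[1]])[1]
  n <- scenario$n_lines
  if (n > n_total) stop("fewer reconstructed lines than requested sample size")
  rows <- sort(sample.int(n_total, n))
  n_qtl <- scenario$n_qtl
  per <- n_qtl / length(chroms)
  qtl_m <- unlist(lapply(chroms, function(ch)
    sample(which(map$chromosome == ch), per)))
  qtl_m <- sample(qtl_m)     # shuffle so effect rank is independent of position
  effects <- scenario$effect_base^seq_len(n_qtl)
  Fsets <- lapply(seq_len(n_qtl), function(i) sample.int(8L, scenario$maf_founders))
  f <- matrix(0, n, n_qtl)
  for (i in seq_len(n_qtl)) {
    Pm <- posterior_at_marker(post, map, chroms, qtl_m[i])[rows, , drop = FALSE]
    f[, i] <- condense_founder_genotype(Pm, Fsets[[i]])
  }
  g <- as.vector(f %*% effects)
  sdg <- stats::sd(g)
  if (sdg == 0) sdg <- 1
  gs <- (g - mean(g)) / sdg
  e <- stats::rnorm(n)
  y <- sqrt(scenario$h2) * gs + sqrt(1 - scenario$h2) * e
  vy <- stats::var(y)
  vqtl <- vapply(seq_len(n_qtl), function(i)
    stats::var(effects[i] * f[, i]) * scenario$h2 / sdg^2 / vy, 0)
  list(y = y, rows = rows,
       truth = data.frame(qtl = seq_len(n_qtl), marker = qtl_m,
                          chromosome = map$chromosome[qtl_m],
                          position_bp = map$position_bp[qtl_m],
                          effect = effects, var_explained = vqtl,
                          founders = vapply(Fsets, paste, "", collapse = ",")))
}

#' Forward stepwise founder-regression mapping
#'
#' Repeatedly scans all markers with the current multi-marker founder
#' regression, adds the best marker if its 7-df likelihood-ratio test has
#' P <= `p_enter`, and stops otherwise. This is the engine of the power
#' study; the polygenic kinship term is off by default there because lines
#' are drawn at random from a structure-free population (set
#' `kinship` to a matrix to pre-whiten).
#'
#' @param y trait values for the sampled lines.
#' @param P design matrix lines x (8 * markers) of founder posteriors laid
#'   out marker-block by marker-block (see [posterior_design()]).
#' @param p_enter LRT entry threshold (default 0.01, genome-wide).
#' @param max_steps maximum markers added (default 30).
#' @param kinship optional kinship matrix for pre-whitening.
#' @param chi2_threshold optional fixed genome-wide entry threshold on the
#'   7-df LRT statistic (e.g. a permutation 99th percentile from
#'   [stepwise_entry_threshold()]); overrides the Sidak-adjusted `p_enter`
#'   rule.
#' @return integer vector of selected marker indices, in selection order.
#' @export
stepwise_map <- function(y, P, p_enter = 0.01, max_steps = 30L, kinship = NULL,
                         chi2_threshold = NULL) {
  n <- length(y)
  M <- ncol(P) / 8L
  if (!is.null(kinship)) {
    eig <- eigen(kinship, symmetric = TRUE)
    lam <- reml_lambda(crossprod(eig$vectors, y),
                       crossprod(eig$vectors, rep(1, n)), pmax(eig$values, 0))
    sw <- sqrt(1 / (lam * pmax(eig$values, 0) + 1))
    y <- as.vector(crossprod(eig$vectors, y)) * sw
    P <- crossprod(eig$vectors, P) * sw
    one <- as.vector(crossprod(eig$vectors, rep(1, n))) * sw
  } else one <- rep(1, n)
  # the 8 founder columns of a marker sum to the intercept, so markers are
  # tested through their first 7 columns (7 df) against a base model that
  # always carries the intercept
  XtX <- marker_blocks7(P, M)
  Q <- qr.Q(qr(matrix(one, ncol = 1)))
  CtC <- marker_blocks7(crossprod(Q, P), M)
  yr <- y - Q %*% crossprod(Q, y)
  rss <- sum(yr^2)
  selected <- integer(0)
  for (step in seq_len(max_steps)) {
    bmat <- matrix(crossprod(P, yr), 8L, M)[1:7, , drop = FALSE]
    delta <- batch_delta_rss(XtX - CtC, bmat)
    delta[selected] <- 0
    delta <- pmin(delta, rss * (1 - 1e-10))
    best <- which.max(delta)
    rss1 <- rss - delta[best]
    chi2 <- n * log(rss / rss1)
    if (!is.finite(chi2)) break
    if (!is.null(chi2_threshold)) {
      if (chi2 < chi2_threshold) break
    } else {
      # the tested marker is the genome-wide maximum, so its LRT P value is
      # Sidak-adjusted for the number of markers scanned before comparing
      # with the entry threshold (a nominal cut on the maximum never stops)
      pval <- stats::pchisq(chi2, df = 7, lower.tail = FALSE)
      pval <- -expm1(M * log1p(-min(pval, 1)))
      if (!is.finite(pval) || pval > p_enter) break
    }
    selected <- c(selected, best)
    # orthogonalize the new marker's 7 test columns against the model
    Xn <- P[, ((best - 1L) * 8L + 1L):((best - 1L) * 8L + 7L), drop = FALSE]
    Xn <- Xn - Q %*% crossprod(Q, Xn)
    qn <- qr(Xn)
    Qa <- qr.Q(qn)[, seq_len(qn$rank), drop = FALSE]
    Q <- cbind(Q, Qa)
    CtC <- CtC + marker_blocks7(crossprod(Qa, P), M)
    yr <- yr - Qa %*% crossprod(Qa, yr)
    rss <- sum(yr^2)
  }
  selected
}

#' Permutation entry threshold for the stepwise scan
#'
#' Genome-wide null calibration of the first stepwise step: for each of
#' `n_perm` replicates a standard-normal null trait is drawn for a random
#' subset of `n_lines` lines and the genome-wide maximum 7-df LRT statistic
#' recorded; the (1 - p) quantile is the entry threshold.
#'
#' @param P full posterior design matrix (lines x 8M).
#' @param n_lines sample size of the study the threshold will serve.
#' @param n_perm null replicates (default 100).
#' @param p genome-wide type-I level (default 0.01).
#' @param seed integer seed.
#' @param method `"gumbel"` (default) fits an extreme-value distribution to
#'   the null maxima by moments and reads the quantile off the fit, which is
#'   far more stable at moderate `n_perm` than the `"empirical"` sample
#'   quantile (the 99th percentile of 50-100 maxima is essentially their
#'   maximum).
#' @return numeric threshold on the LRT chi-square scale.
#' @export
stepwise_entry_threshold <- function(P, n_lines, n_perm = 100L, p = 0.01,
                                     seed = 1L, method = c("gumbel", "empirical")) {
  method <- match.arg(method)
  local_rng(seed)
  n_total <- nrow(P)
  M <- ncol(P) / 8L
  maxima <- vapply(seq_len(n_perm), function(i) {
    rows <- sample.int(n_total, n_lines)
    y <- stats::rnorm(n_lines)
    Ps <- P[rows, , drop = FALSE]
    XtX <- marker_blocks7(Ps, M)
    one <- matrix(1 / sqrt(n_lines), n_lines, 1)
    CtC <- marker_blocks7(crossprod(one, Ps), M)
    yr <- y - mean(y)
    rss <- sum(yr^2)
    delta <- batch_delta_rss(XtX - CtC, matrix(crossprod(Ps, yr), 8L, M)[1:7, , drop = FALSE])
    delta <- pmin(delta, rss * (1 - 1e-10))
    n_lines * log(rss / (rss - max(delta)))
  }, 0)
  if (method == "empirical") return(stats::quantile(maxima, 1 - p, names = FALSE))
  beta <- stats::sd(maxima) * sqrt(6) / pi
  mu <- mean(maxima) - 0.5772156649 * beta
  mu - beta * log(-log(1 - p))
}

# per-marker 7x7 cross-product blocks of a (rows x 8M) design, as (7,7,M)
marker_blocks7 <- function(X, M) {
  slices <- lapply(1:7, function(i)
    X[, seq.int(i, by = 8L, length.out = M), drop = FALSE])
  A <- array(0, c(7, 7, M))
  for (i in 1:7) for (j in i:7) {
    v <- colSums(slices[[i]] * slices[[j]])
    A[i, j, ] <- v
    A[j, i, ] <- v
  }
  A
}

# delta RSS = b' A^-1 b for M systems at once: vectorized Cholesky across the
# third array dimension, with deficient pivots dropped (pseudo-inverse
# behaviour for locally monomorphic founder columns)
batch_delta_rss <- function(A, bmat) {
  p <- dim(A)[1]; M <- dim(A)[3]
  tol <- numeric(M)
  for (i in seq_len(p)) tol <- pmax(tol, A[i, i, ])
  tol <- tol * 1e-9 + 1e-300
  L <- array(0, c(p, p, M))
  for (j in seq_len(p)) {
    acc <- A[j, j, ]
    for (k in seq_len(j - 1)) acc <- acc - L[j, k, ]^2
    piv <- rep(Inf, M)                         # Inf pivot drops the direction
    ok <- acc > tol
    piv[ok] <- sqrt(acc[ok])
    L[j, j, ] <- piv
    for (i in seq.int(j + 1, length.out = p - j)) {
      acc <- A[i, j, ]
      for (k in seq_len(j - 1)) acc <- acc - L[i, k, ] * L[j, k, ]
      L[i, j, ] <- acc / piv
    }
  }
  z <- matrix(0, p, M)
  delta <- numeric(M)
  for (i in seq_len(p)) {
    acc <- bmat[i, ]
    for (k in seq_len(i - 1)) acc <- acc - L[i, k, ] * z[k, ]
    z[i, ] <- acc / L[i, i, ]
    delta <- delta + z[i, ]^2
  }
  delta[!is.finite(delta)] <- 0
  pmax(delta, 0)
}

#' Stack per-chromosome posteriors into a scan design matrix
#'
#' @param post list of per-chromosome posterior arrays.
#' @return matrix lines x (8 * total markers), marker-major blocks of the 8
#'   founder columns.
#' @export
posterior_design <- function(post) {
  do.call(cbind, lapply(post, function(a) matrix(a[, 1:8, , drop = FALSE],
                                                 nrow = dim(a)[1])))
}

#' Match selected markers to simulated QTL
#'
#' Greedy nearest-first one-to-one matching: a selected marker detects a
#' simulated QTL if it lies within +/- `window_mb` on the same chromosome
#' (boundary inclusive); each QTL and each selected marker is used at most
#' once. Power is the detected fraction of simulated QTL; FDR the unmatched
#' fraction of selected markers (0 when nothing is selected).
#'
#' @param selected integer marker indices from [stepwise_map()].
#' @param truth the truth table from [simulate_phenotype()].
#' @param map the [genetic_map()].
#' @param window_mb detection window half-width in Mb.
#' @return list with `power`, `fdr` and `detected` (logical per QTL).
#' @export
evaluate_detection <- function(selected, truth, map, window_mb = 5) {
  n_qtl <- nrow(truth)
  detected <- logical(n_qtl)
  if (!length(selected))
    return(list(power = 0, fdr = 0, detected = detected))
  cand <- expand.grid(s = seq_along(selected), q = seq_len(n_qtl))
  sm <- selected[cand$s]
  same <- map$chromosome[sm] == truth$chromosome[cand$q]
  dist <- abs(map$position_bp[sm] - truth$position_bp[cand$q])
  ok <- same & dist <= window_mb * 1e6
  cand <- cand[ok, , drop = FALSE]
  dist <- dist[ok]
  used_s <- logical(length(selected))
  for (i in order(dist)) {
    s <- cand$s[i]; q <- cand$q[i]
    if (used_s[s] || detected[q]) next
    used_s[s] <- TRUE
    detected[q] <- TRUE
  }
  list(power = mean(detected),
       fdr = sum(!used_s) / length(selected),
       detected = detected)
}

#' Run the QTL power and FDR study
#'
#' For every scenario, repeats `n_runs` simulations of
#' [simulate_phenotype()] followed by [stepwise_map()] and
#' [evaluate_detection()]. Results are kept per QTL so power can be averaged
#' overall (over runs and the four MAF settings, as in the reference
#' analysis), binned by realized explained variance (2%-wide bins), or split
#' by effect-size quartile.
#'
#' @param recon a `magic_reconstruction` (or list of 8-column posterior
#'   arrays).
#' @param map the [genetic_map()]; taken from `recon` when available.
#' @param scenarios data.frame from [power_scenarios()].
#' @param n_runs simulations per scenario.
#' @param seed master seed; each run derives its own.
#' @param p_enter genome-wide entry level for the stepwise LRT.
#' @param entry how the genome-wide level is enforced: `"permutation"`
#'   (default; entry threshold is the permutation 99th-percentile of the
#'   null genome-wide maximum LRT, one threshold per sample size) or
#'   `"sidak"` (analytic adjustment by the marker count).
#' @param n_perm_entry null replicates for the permutation threshold.
#' @return A `magic_power` object with `runs` (per-run power/FDR) and `qtl`
#'   (per-QTL detection and realized variance) tables.
#' @export
run_power_study <- function(recon, scenarios = power_scenarios(), n_runs = 100L,
                            seed = 1L, map = NULL, p_enter = 0.01,
                            entry = c("permutation", "sidak"),
                            n_perm_entry = 100L) {
  entry <- match.arg(entry)
  if (inherits(recon, "magic_reconstruction")) {
    map <- recon$map
    post <- drop_ninth_founder(recon)
  } else post <- recon
  stopifnot(!is.null(map))
  P_full <- posterior_design(post)
  thresholds <- NULL
  if (entry == "permutation") {
    thresholds <- vapply(unique(scenarios$n_lines), function(nl)
      stepwise_entry_threshold(P_full, nl, n_perm = n_perm_entry, p = p_enter,
                               seed = derive_seed(seed, "entry", nl)), 0)
    names(thresholds) <- as.character(unique(scenarios$n_lines))
  }
  runs <- list(); qtl <- list()
  for (si in seq_len(nrow(scenarios))) {
    sc <- scenarios[si, ]
    for (r in seq_len(n_runs)) {
      sseed <- derive_seed(seed, paste0("power", si), r)
      sim <- simulate_phenotype(post, map, sc, seed = sseed)
      sel <- stepwise_map(sim$y, P_full[sim$rows, , drop = FALSE],
                          p_enter = p_enter,
                          chi2_threshold = thresholds[as.character(sc$n_lines)])
      ev <- evaluate_detection(sel, sim$truth, map)
      runs[[length(runs) + 1L]] <- data.frame(
        maf_founders = sc$maf_founders, n_lines = sc$n_lines, h2 = sc$h2,
        run = r, n_selected = length(sel), power = ev$power, fdr = ev$fdr)
      qtl[[length(qtl) + 1L]] <- data.frame(
        maf_founders = sc$maf_founders, n_lines = sc$n_lines, h2 = sc$h2,
        run = r, qtl = sim$truth$qtl, effect = sim$truth$effect,
        var_explained = sim$truth$var_explained, detected = ev$detected)
    }
  }
  structure(list(runs = do.call(rbind, runs), qtl = do.call(rbind, qtl),
                 scenarios = scenarios, n_runs = n_runs,
                 entry = entry, entry_thresholds = thresholds),
            class = "magic_power")
}

#' Power aggregated by realized explained-variance bin
#'
#' @param pw a `magic_power`.
#' @param n_lines,h2 scenario cell to aggregate (all MAF settings pooled).
#' @param bin_width bin width on the explained-variance axis (default 0.02).
#' @return data.frame with bin center, mean power and QTL count per bin.
#' @export
power_by_variance_bin <- function(pw, n_lines, h2, bin_width = 0.02) {
  q <- pw$qtl[pw$qtl$n_lines == n_lines & pw$qtl$h2 == h2, ]
  bin <- round(q$var_explained / bin_width) * bin_width
  agg <- stats::aggregate(detected ~ bin, data = cbind(q, bin = bin), mean)
  cnt <- stats::aggregate(detected ~ bin, data = cbind(q, bin = bin), length)
  data.frame(bin_center = agg$bin, power = agg$detected, n_qtl = cnt$detected)
}

#' Overall power and FDR per scenario cell
#' @param pw a `magic_power`.
#' @return data.frame per (n_lines, h2): mean power and FDR over runs and MAF
#'   settings.
#' @export
power_overall <- function(pw) {
  agg <- stats::aggregate(cbind(power, fdr) ~ n_lines + h2, data = pw$runs, mean)
  agg[order(agg$h2, agg$n_lines), ]
}

#' @export
print.magic_power <- function(x, ...) {
  cat("QTL power study: ", nrow(x$scenarios), " scenario(s) x ", x$n_runs,
      " runs\n", sep = "")
  print(power_overall(x), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.magic_power <- function(x, h2 = NULL, ...) {
  cells <- unique(x$qtl[, c("n_lines", "h2")])
  if (!is.null(h2)) cells <- cells[cells$h2 == h2, ]
  graphics::plot(NULL, xlim = c(0, 0.2), ylim = c(0, 1),
                 xlab = "QTL explained variance", ylab = "power", ...)
  for (i in seq_len(nrow(cells))) {
    b <- power_by_variance_bin(x, cells$n_lines[i], cells$h2[i])
    graphics::lines(b$bin_center, b$power, type = "b", col = i, pch = 16)
  }
  graphics::legend("bottomright",
                   legend = paste0("n=", cells$n_lines, " h2=", cells$h2),
                   col = seq_len(nrow(cells)), lty = 1, pch = 16, cex = 0.8)
  invisible(x)
}
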