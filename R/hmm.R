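#' State-change probability between adjacent markers
#'
#' For an eight-way cross advanced by selfing, the probability that the
#' founder state differs between two markers at recombination fraction r is
#' R = r(4 - r) / (1 + 2r) at the inbred limit. The change mass is split
#' equally among the G - 1 alternative founder states.
#'
#' @param r recombination fraction(s) in [0, 0.5].
#' @return state-change probability R in [0, 7/8].
#' @examples
#' transition_probability(0.5)  # 7/8: unlinked loci share a founder w.p. 1/8
#' @export
transition_probability <- function(r) {
  if (any(r < 0 | r > 0.5)) stop("r must lie in [0, 0.5]")
  r * (4 - r) / (1 + 2 * r)
}

#' Initial emission probabilities from founder calls
#'
#' Each hidden state is a homozygous founder genotype. A founder call of 0 or
#' 2 puts all emission mass on that symbol; a heterozygous founder call
#' splits the mass 0.5/0.5 between the two homozygous symbols; a missing
#' founder call gives a uniform (flagged) distribution. `smoothing` is then
#' added to every symbol and each state's distribution renormalized, so a
#' confident call emits its symbol with probability about 0.98 at the default
#' smoothing of 0.01. Missing observed calls are emitted uniformly by all
#' states (handled in the likelihood, not stored here).
#'
#' @param founders a [founder_panel()].
#' @param smoothing emission smoothing constant (default 0.01).
#' @return An `emission_model`: array markers x states x 3 symbols, plus the
#'   indices of markers where all founders were missing.
#' @export
init_emissions <- function(founders, smoothing = 0.01) {
  fc <- founders$calls
  G <- nrow(fc); M <- ncol(fc)
  E <- array(0, dim = c(M, G, 3),
             dimnames = list(colnames(fc), rownames(fc), c("0", "1", "2")))
  E[, , 1] <- t(fc == 0L) + 0.5 * t(fc == 1L)
  E[, , 3] <- t(fc == 2L) + 0.5 * t(fc == 1L)
  miss <- t(fc == -1L)
  for (o in 1:3) E[, , o][miss] <- 1 / 3
  if (smoothing > 0) E <- E + smoothing
  # renormalize each (marker, state) distribution
  tot <- E[, , 1] + E[, , 2] + E[, , 3]
  for (o in 1:3) E[, , o] <- E[, , o] / tot
  structure(list(probs = E, smoothing = smoothing,
                 flagged_markers = which(colSums(fc != -1L) == 0L)),
            class = "emission_model")
}

# per-marker likelihood matrix (lines x states) for observed symbols;
# missing observations emit 1 for every state
emission_likelihood <- function(Em, obs_col) {
  L <- length(obs_col); G <- nrow(Em)
  lik <- matrix(1, L, G)
  sel <- obs_col != -1L
  if (any(sel)) lik[sel, ] <- t(Em)[obs_col[sel] + 1L, , drop = FALSE]
  lik
}

#' Scaled forward-backward over one chromosome
#'
#' Exact posterior founder-state probabilities for a block of lines sharing
#' the same state space, computed with per-marker normalization; the
#' log-likelihood of each line is the sum of its log scaling factors.
#'
#' @param obs integer matrix lines x markers of calls (0/1/2/-1) for one
#'   chromosome, in map order.
#' @param E emission array markers x G x 3 for the same chromosome.
#' @param Rvec state-change probabilities between consecutive markers
#'   (length markers - 1).
#' @param prior initial state probabilities (default uniform 1/G).
#' @return list with `posterior` (array lines x G x markers) and `loglik`
#'   (per-line log-likelihood).
#' @export
forward_backward <- function(obs, E, Rvec, prior = NULL) {
  L <- nrow(obs); M <- ncol(obs); G <- dim(E)[2]
  stopifnot(dim(E)[1] == M, length(Rvec) == M - 1L)
  if (is.null(prior)) prior <- rep(1 / G, G)
  c1 <- 1 - Rvec * G / (G - 1)
  c2 <- Rvec / (G - 1)
  alpha <- array(0, c(L, G, M))
  loglik <- numeric(L)
  a <- sweep(emission_likelihood(matrix(E[1, , ], G, 3), obs[, 1]), 2, prior, "*")
  s <- rowSums(a); a <- a / s; loglik <- loglik + log(s)
  alpha[, , 1] <- a
  for (m in seq_len(M - 1L)) {
    pred <- c1[m] * a + c2[m]
    a <- pred * emission_likelihood(matrix(E[m + 1L, , ], G, 3), obs[, m + 1L])
    s <- rowSums(a); a <- a / s; loglik <- loglik + log(s)
    alpha[, , m + 1L] <- a
  }
  post <- array(0, c(L, G, M))
  b <- matrix(1, L, G)
  post[, , M] <- alpha[, , M]
  for (m in rev(seq_len(M - 1L))) {
    v <- b * emission_likelihood(matrix(E[m + 1L, , ], G, 3), obs[, m + 1L])
    b <- c1[m] * v + c2[m] * rowSums(v)
    b <- b / rowSums(b)
    p <- alpha[, , m] * b
    post[, , m] <- p / rowSums(p)
  }
  list(posterior = post, loglik = loglik)
}

#' Reconstruct founder mosaics by HMM with EM-updated emissions
#'
#' Fits the founder-mosaic hidden Markov model to a RIL genotype matrix: the
#' hidden states are the homozygous founder genotypes (eight, or nine for
#' lines carrying the substitute parent), transitions between adjacent
#' markers use the eight-way selfing change probability
#' [transition_probability()] on map-derived recombination fractions, and
#' emission probabilities start from the founder calls
#' ([init_emissions()]) and are re-estimated by expectation-maximization,
#' pooling posterior-weighted symbol counts across lines. Iteration stops
#' when the total log-likelihood changes by less than 1/1000 of its initial
#' magnitude.
#'
#' @param genotypes a [genotype_matrix()].
#' @param founders a [founder_panel()] on the same marker panel.
#' @param map an interpolated [genetic_map()] covering the same markers.
#' @param smoothing emission smoothing constant, re-applied each M-step
#'   unless `smooth_updates = FALSE`.
#' @param max_iter maximum EM iterations.
#' @param damping multiplicative shrink applied to recombination fractions
#'   (see [cm_to_recfrac()]).
#' @param rec_method cM-to-recombination-fraction mode for [cm_to_recfrac()].
#' @param smooth_updates re-apply smoothing after each M-step (default TRUE).
#' @return A `magic_reconstruction` object: per-chromosome posterior arrays
#'   (lines x 9 states x markers; the ninth column is zero for eight-founder
#'   lines), per-line log-likelihoods, EM trace, and the fitted emissions.
#' @export
magic_reconstruct <- function(genotypes, founders, map, smoothing = 0.01,
                              max_iter = 10L, damping = 1.0,
                              rec_method = "haldane", smooth_updates = TRUE) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(founders, "founder_panel"),
            inherits(map, "genetic_map"))
  if (anyNA(map$position_cM)) stop("map must be interpolated first")
  if (!identical(colnames(genotypes$calls), map$marker_id))
    genotypes$calls <- genotypes$calls[, map$marker_id, drop = FALSE]
  if (!identical(colnames(founders$calls), map$marker_id))
    founders$calls <- founders$calls[, map$marker_id, drop = FALSE]
  G_all <- nrow(founders$calls)
  nine <- genotypes$pedigree_flag == "nine-founder"
  if (any(nine) && G_all < 9L)
    stop("nine-founder lines present but founder panel has 8 founders")
  em <- init_emissions(founders, smoothing)
  chroms <- sort(unique(map$chromosome))
  chr_idx <- lapply(chroms, function(ch) which(map$chromosome == ch))
  Rs <- lapply(chr_idx, function(idx)
    transition_probability(cm_to_recfrac(diff(map$position_cM[idx]),
                                         method = rec_method, damping = damping)))
  n <- nrow(genotypes$calls)
  groups <- list()
  if (any(!nine)) groups$eight <- list(rows = which(!nine), G = 8L)
  if (any(nine))  groups$nine  <- list(rows = which(nine),  G = 9L)

  e_step <- function(E) {
    post <- lapply(chr_idx, function(idx) array(0, c(n, 9L, length(idx))))
    ll <- numeric(n)
    for (ci in seq_along(chr_idx)) {
      idx <- chr_idx[[ci]]
      for (gr in groups) {
        fb <- forward_backward(genotypes$calls[gr$rows, idx, drop = FALSE],
                               E[idx, seq_len(gr$G), , drop = FALSE],
                               Rs[[ci]])
        post[[ci]][gr$rows, seq_len(gr$G), ] <- fb$posterior
        ll[gr$rows] <- ll[gr$rows] + fb$loglik
      }
    }
    list(post = post, ll = ll)
  }

  E <- em$probs
  trace <- numeric(0)
  es <- e_step(E)
  ll_init <- sum(es$ll)
  trace <- ll_init
  tol <- abs(ll_init) / 1000
  for (it in seq_len(max_iter)) {
    E_new <- m_step(E, es$post, genotypes$calls, chr_idx,
                    if (smooth_updates) smoothing else 0)
    es_new <- e_step(E_new)
    ll_new <- sum(es_new$ll)
    if (ll_new < trace[length(trace)] - tol)
      stop("EM log-likelihood decreased (", trace[length(trace)], " -> ",
           ll_new, "); implementation invariant violated")
    E <- E_new; es <- es_new
    trace <- c(trace, ll_new)
    if (abs(ll_new - trace[length(trace) - 1L]) < tol) break
  }
  structure(list(posteriors = es$post, loglik = es$ll, trace = trace,
                 iterations = length(trace) - 1L, emissions = E,
                 line_ids = genotypes$line_ids,
                 pedigree_flag = genotypes$pedigree_flag,
                 founder_ids = rownames(founders$calls),
                 map = map, chromosomes = chroms),
            class = "magic_reconstruction")
}

# pooled M-step: emission of (marker, state, symbol) proportional to the
# posterior-weighted count of observed symbols, keeping the previous
# distribution where a state has no posterior weight at a marker
m_step <- function(E, post, calls, chr_idx, smoothing) {
  E_new <- E
  G <- dim(E)[2]
  for (ci in seq_along(chr_idx)) {
    idx <- chr_idx[[ci]]
    P <- post[[ci]]
    for (k in seq_along(idx)) {
      m <- idx[k]
      o <- calls[, m]
      sel <- o != -1L
      if (!any(sel)) next
      Pm <- matrix(P[sel, seq_len(G), k], ncol = G)
      cnt <- rowsum(Pm, o[sel])                       # observed symbols x G
      full <- matrix(0, 3, G)
      full[as.integer(rownames(cnt)) + 1L, ] <- cnt
      upd <- which(colSums(full) > 1e-8)
      if (!length(upd)) next
      p <- t(full[, upd, drop = FALSE]) + smoothing
      E_new[m, upd, ] <- p / rowSums(p)
    }
  }
  E_new
}

#' @export
print.magic_reconstruction <- function(x, ...) {
  cat("MAGIC mosaic reconstruction: ", length(x$line_ids), " lines, ",
      nrow(x$map), " markers, ", length(x$founder_ids), " founder states\n",
      sep = "")
  cat("EM iterations: ", x$iterations, "; total log-likelihood ",
      format(sum(x$loglik), digits = 8), "\n", sep = "")
  invisible(x)
}

#' @export
logLik.magic_reconstruction <- function(object, ...) {
  structure(sum(object$loglik), df = NA, class = "logLik")
}

#' @export
summary.magic_reconstruction <- function(object, min_prob = 0.8, ...) {
  j <- count_junctions(object, min_prob = min_prob)
  out <- data.frame(line_id = object$line_ids,
                    pedigree_flag = object$pedigree_flag,
                    loglik = object$loglik,
                    junctions = j)
  class(out) <- c("summary.magic_reconstruction", "data.frame")
  out
}

#' Posterior matrix of one line
#' @param recon a `magic_reconstruction`.
#' @param line line index or id.
#' @return matrix markers x 9 of posterior founder probabilities.
#' @export
posterior_matrix <- function(recon, line) {
  if (is.character(line)) line <- match(line, recon$line_ids)
  do.call(rbind, lapply(recon$posteriors, function(a) t(a[line, , ])))
}

#' Count reconstructed junctions per line
#'
#' A junction is a change of the maximum-posterior founder state between
#' consecutive confidently assigned markers on the same chromosome: markers
#' whose maximum posterior falls below `min_prob` (typically those straddling
#' the crossover itself, where the evidence is split between the two
#' founders) are skipped before adjacent assignments are compared.
#'
#' @param recon a `magic_reconstruction`.
#' @param min_prob confidence filter (default 0.8).
#' @return integer vector of junction counts per line.
#' @export
count_junctions <- function(recon, min_prob = 0.8) {
  n <- length(recon$line_ids)
  out <- integer(n)
  for (a in recon$posteriors) {
    M <- dim(a)[3]
    if (M < 2) next
    flat <- matrix(aperm(a, c(1, 3, 2)), n * M, dim(a)[2])  # (line,marker) x G
    am <- matrix(max.col(flat, ties.method = "first"), n, M)
    pm <- matrix(flat[cbind(seq_len(n * M), as.vector(am))], n, M)
    for (l in seq_len(n)) {
      keep <- pm[l, ] >= min_prob
      s <- am[l, keep]
      if (length(s) > 1) out[l] <- out[l] + sum(s[-1] != s[-length(s)])
    }
  }
  out
}

#' Mean posterior founder contribution per locus
#'
#' @param recon a `magic_reconstruction`.
#' @return matrix markers x founders of column means of the posteriors across
#'   lines; rows sum to 1.
#' @export
founder_contribution_per_locus <- function(recon) {
  out <- do.call(rbind, lapply(recon$posteriors, function(a)
    t(colMeans(a, dims = 1))))
  G <- length(recon$founder_ids)
  out <- out[, seq_len(G), drop = FALSE]
  out <- out / rowSums(out)
  dimnames(out) <- list(recon$map$marker_id, recon$founder_ids)
  out
}

#' Hard founder assignment per line and marker
#' @param recon a `magic_reconstruction`.
#' @return integer matrix lines x markers of maximum-posterior founder indices.
#' @export
founder_assignment <- function(recon) {
  n <- length(recon$line_ids)
  do.call(cbind, lapply(recon$posteriors, function(a) {
    M <- dim(a)[3]
    flat <- matrix(aperm(a, c(1, 3, 2)), n * M, dim(a)[2])
    matrix(max.col(flat, ties.method = "first"), n, M)
  }))
}

#' Plot mean founder contribution along the genome
#' @param x a `magic_reconstruction`.
#' @param ... passed to [matplot()].
#' @export
plot.magic_reconstruction <- function(x, ...) {
  fc <- founder_contribution_per_locus(x)
  graphics::matplot(fc, type = "l", lty = 1, xlab = "marker index",
                    ylab = "mean founder contribution", ...)
  graphics::abline(h = 1 / 8, lty = 2, col = "grey40")
  graphics::legend("topright", legend = colnames(fc), col = seq_len(ncol(fc)),
                   lty = 1, cex = 0.7, ncol = 3)
  invisible(x)
}
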