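# Independent oracles used to freeze expected values.

# Two-locus eight-way-selfing Markov chain: exact probability that, at the
# inbred limit, a line carries different founders at two loci separated by
# recombination fraction r. Haplotypes over (locus1, locus2) founder labels
# are coded h = (f1-1)*8 + f2; diploids as ordered haplotype pairs
# d = (h1-1)*64 + h2. Built from first principles (gamete distributions of
# each pedigree step), fully independent of the package's formula.
oracle_selfing_nonidentity <- function(r, n_gen = 80) {
  hid <- function(f1, f2) (f1 - 1L) * 8L + f2
  # gamete distribution (length-64 vector) of a diploid (h1, h2)
  gamete_dist <- function(h1, h2) {
    a1 <- (h1 - 1L) %/% 8L + 1L; a2 <- (h1 - 1L) %% 8L + 1L
    b1 <- (h2 - 1L) %/% 8L + 1L; b2 <- (h2 - 1L) %% 8L + 1L
    g <- numeric(64)
    g[hid(a1, a2)] <- g[hid(a1, a2)] + (1 - r) / 2
    g[hid(a1, b2)] <- g[hid(a1, b2)] + r / 2
    g[hid(b1, b2)] <- g[hid(b1, b2)] + (1 - r) / 2
    g[hid(b1, a2)] <- g[hid(b1, a2)] + r / 2
    g
  }
  # two-way F1 of founders (p, q): homologs pure p and pure q
  twoway_gamete <- function(p, q) gamete_dist(hid(p, p), hid(q, q))
  # four-way gamete: expectation over the four-way individual's two homologs
  # (independent gametes of the two two-ways)
  fourway_gamete <- function(g1, g2) {
    g <- numeric(64)
    for (h1 in which(g1 > 0)) for (h2 in which(g2 > 0))
      g <- g + g1[h1] * g2[h2] * gamete_dist(h1, h2)
    g
  }
  gA <- fourway_gamete(twoway_gamete(1, 2), twoway_gamete(3, 4))
  gB <- fourway_gamete(twoway_gamete(5, 6), twoway_gamete(7, 8))
  # eight-way diploid distribution: independent gametes from the two sides
  D <- outer(gA, gB)                      # 64 x 64, D[h1, h2]
  # selfing: offspring diploid = two gametes of the same parent
  sup <- which(D > 0, arr.ind = TRUE)
  for (gen in seq_len(n_gen)) {
    Dn <- matrix(0, 64, 64)
    sup <- which(D > 1e-18, arr.ind = TRUE)
    for (k in seq_len(nrow(sup))) {
      g <- gamete_dist(sup[k, 1], sup[k, 2])
      nz <- which(g > 0)
      Dn[nz, nz] <- Dn[nz, nz] + D[sup[k, 1], sup[k, 2]] * outer(g[nz], g[nz])
    }
    D <- Dn
  }
  marg <- rowSums(D)                      # homolog-1 haplotype marginal
  f1 <- (seq_len(64) - 1L) %/% 8L + 1L
  f2 <- (seq_len(64) - 1L) %% 8L + 1L
  sum(marg[f1 != f2])
}

# Exhaustive path-sum forward-backward oracle for small HMMs.
# obs: integer vector of calls (0/1/2/-1); E: markers x G x 3 emission array;
# Rvec: state-change probabilities between markers; prior: length G.
oracle_fb_enumeration <- function(obs, E, Rvec, prior = NULL) {
  M <- length(obs); G <- dim(E)[2]
  if (is.null(prior)) prior <- rep(1 / G, G)
  emis <- function(m, s) if (obs[m] == -1L) 1 else E[m, s, obs[m] + 1L]
  paths <- as.matrix(expand.grid(rep(list(seq_len(G)), M)))
  pp <- apply(paths, 1, function(s) {
    p <- prior[s[1]] * emis(1, s[1])
    for (m in seq_len(M - 1)) {
      tr <- if (s[m + 1] == s[m]) 1 - Rvec[m] else Rvec[m] / (G - 1)
      p <- p * tr * emis(m + 1, s[m + 1])
    }
    p
  })
  post <- matrix(0, M, G)
  for (m in seq_len(M)) for (g in seq_len(G))
    post[m, g] <- sum(pp[paths[, m] == g])
  list(posterior = post / sum(pp), loglik = log(sum(pp)))
}

# piecewise-linear interpolation oracle over anchor points
oracle_interp <- function(anchor_bp, anchor_cm, bp) {
  vapply(bp, function(x) {
    if (x <= anchor_bp[1]) return(anchor_cm[1])
    n <- length(anchor_bp)
    if (x >= anchor_bp[n]) return(anchor_cm[n])
    i <- max(which(anchor_bp <= x))
    if (anchor_bp[i] == x) return(anchor_cm[i])
    anchor_cm[i] + (anchor_cm[i + 1] - anchor_cm[i]) *
      (x - anchor_bp[i]) / (anchor_bp[i + 1] - anchor_bp[i])
  }, 0)
}

# brute-force nearest-first one-to-one matching for detection evaluation
oracle_match_detection <- function(sel_bp, sel_chr, qtl_bp, qtl_chr, window) {
  pairs <- expand.grid(s = seq_along(sel_bp), q = seq_along(qtl_bp))
  pairs$d <- abs(sel_bp[pairs$s] - qtl_bp[pairs$q])
  pairs <- pairs[sel_chr[pairs$s] == qtl_chr[pairs$q] & pairs$d <= window, ]
  pairs <- pairs[order(pairs$d), ]
  used_s <- logical(length(sel_bp)); used_q <- logical(length(qtl_bp))
  for (i in seq_len(nrow(pairs))) {
    if (used_s[pairs$s[i]] || used_q[pairs$q[i]]) next
    used_s[pairs$s[i]] <- TRUE; used_q[pairs$q[i]] <- TRUE
  }
  list(detected = used_q, matched_sel = used_s)
}
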