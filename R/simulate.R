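#' Synthetic maize-like genetic map
#'
#' Builds a 10-chromosome marker map emulating a maize SNP array: physical
#' chromosome sizes proportioned like the maize genome (~2.06 Gb total) and
#' genetic lengths summing to 1,996 cM (19.96 Morgans), with a constant
#' cM/bp rate per chromosome. Marker positions are uniform within each
#' chromosome, with the terminal markers pinned to the chromosome ends so the
#' realized map length equals the nominal one.
#'
#' @param n_markers total marker count (default 5,000; allocated across
#'   chromosomes proportional to physical length).
#' @param seed integer seed for marker placement.
#' @return an interpolated [genetic_map()].
#' @export
magic_map_synthetic <- function(n_markers = 5000L, seed = 1L) {
  chr_mb <- c(301, 237, 232, 242, 217, 169, 176, 175, 157, 149)
  chr_bp <- as.integer(chr_mb * 1e6)
  chr_cm <- 1996 * chr_mb / sum(chr_mb)
  n_chr <- length(chr_bp)
  per_chr <- pmax(2L, round(as.numeric(n_markers) * chr_bp / sum(chr_bp)))
  rng <- local_rng(seed)
  rows <- vector("list", n_chr)
  for (ch in seq_len(n_chr)) {
    k <- per_chr[ch]
    bp <- sort(sample.int(chr_bp[ch] - 2L, k - 2L)) + 1L
    bp <- unique(c(1L, bp, chr_bp[ch]))
    while (length(bp) < k) {   # resample collisions (rare)
      extra <- sample.int(chr_bp[ch] - 2L, k - length(bp)) + 1L
      bp <- sort(unique(c(bp, extra)))
    }
    cm <- (bp - 1) / (chr_bp[ch] - 1) * chr_cm[ch]
    rows[[ch]] <- data.frame(marker_id = sprintf("c%d_m%d", ch, seq_along(bp)),
                             chromosome = ch, position_bp = bp, position_cM = cm)
  }
  df <- do.call(rbind, rows)
  genetic_map(df$marker_id, df$chromosome, df$position_bp, df$position_cM)
}

#' Synthetic founder genotype panel
#'
#' Draws array-like biallelic founder calls: at each marker every founder
#' carries allele 0 or 2 independently with probability 1/2, redrawn until the
#' marker is polymorphic among the first eight founders (array markers were
#' ascertained to be polymorphic). Optionally injects residual heterozygosity
#' as random heterozygous calls per founder.
#'
#' @param map a [genetic_map()].
#' @param substitution include the ninth founder (CML91).
#' @param het_rate optional numeric vector (recycled over founders) of
#'   residual heterozygosity rates; default 0 (fully inbred founders).
#' @param seed integer seed.
#' @return a [founder_panel()].
#' @export
simulate_founder_panel <- function(map, substitution = TRUE, het_rate = 0,
                                   seed = 1L) {
  stopifnot(inherits(map, "genetic_map"))
  rng <- local_rng(seed)
  n_f <- if (substitution) 9L else 8L
  m <- nrow(map)
  calls <- matrix(2L * (stats::runif(n_f * m) < 0.5), nrow = n_f)
  mono <- colSums(calls[1:8, , drop = FALSE]) %in% c(0L, 16L)
  while (any(mono)) {
    k <- sum(mono)
    calls[, mono] <- matrix(2L * (stats::runif(n_f * k) < 0.5), nrow = n_f)
    mono <- colSums(calls[1:8, , drop = FALSE]) %in% c(0L, 16L)
  }
  het_rate <- rep_len(het_rate, n_f)
  for (f in which(het_rate > 0)) {
    hit <- stats::runif(m) < het_rate[f]
    calls[f, hit] <- 1L
  }
  rownames(calls) <- names(magic_founders(substitution))[seq_len(n_f)]
  colnames(calls) <- map$marker_id
  founder_panel(calls)
}

# --- mosaic genome representation -------------------------------------------
# A homolog is a list(end = integer vector of segment right edges (1-based,
# inclusive), founder = integer vector of founder indices); segments tile
# [chrom_start, chrom_end]. A diploid genome is, per chromosome, list(h1, h2).

chrom_table <- function(map) {
  chr <- sort(unique(map$chromosome))
  data.frame(chromosome = chr,
             start_bp = tapply(map$position_bp, map$chromosome, min)[as.character(chr)],
             end_bp = tapply(map$position_bp, map$chromosome, max)[as.character(chr)],
             start_cm = tapply(map$position_cM, map$chromosome, min)[as.character(chr)],
             end_cm = tapply(map$position_cM, map$chromosome, max)[as.character(chr)])
}

founder_genome <- function(f_idx, chroms) {
  lapply(seq_len(nrow(chroms)), function(i) {
    h <- list(end = chroms$end_bp[i], founder = f_idx)
    list(h1 = h, h2 = h)
  })
}

# sub-segments of homolog h covering (a, b] (bp); returns list(end, founder)
slice_homolog <- function(h, a, b) {
  i1 <- findInterval(a + 1L, c(-Inf, h$end[-length(h$end)] + 1L))
  i2 <- findInterval(b, c(-Inf, h$end[-length(h$end)] + 1L))
  end <- h$end[i1:i2]
  end[length(end)] <- b
  list(end = end, founder = h$founder[i1:i2])
}

merge_segments <- function(end, founder) {
  if (length(end) > 1L) {
    keep <- c(founder[-1] != founder[-length(founder)], TRUE)
    end <- end[keep]; founder <- founder[keep]
  }
  list(end = end, founder = founder)
}

#' Simulate one meiosis on a single chromosome
#'
#' Crossovers follow a no-interference process: the count is Poisson with
#' mean the chromosome's genetic length in Morgans, positions uniform on the
#' cM scale and mapped back to bp through the marker map; the gamete
#' alternates between the parental homologs at crossover points, starting
#' from a random homolog.
#'
#' @param h1,h2 parental homologs (segment lists).
#' @param chrom one row of the chromosome table (bp and cM span).
#' @param cm_to_bp function mapping cM to bp for this chromosome.
#' @return a gamete homolog (segment list).
#' @keywords internal
meiosis_chrom <- function(h1, h2, start_bp, end_bp, start_cm, end_cm, cm_to_bp) {
  # a fully homozygous chromosome transmits itself whatever the crossovers
  if (identical(h1$end, h2$end) && identical(h1$founder, h2$founder)) return(h1)
  L <- (end_cm - start_cm) / 100
  n_xo <- stats::rpois(1L, L)
  start_h <- stats::runif(1) < 0.5
  if (n_xo == 0L) return(if (start_h) h1 else h2)
  xo_cm <- stats::runif(n_xo, start_cm, end_cm)
  xo_bp <- pmin(pmax(as.integer(round(cm_to_bp(xo_cm))), start_bp), end_bp - 1L)
  xo_bp <- xo_bp[order(xo_bp)]
  xo_bp <- xo_bp[c(TRUE, diff(xo_bp) > 0L)]
  # combined breakpoints of both homologs and the crossovers; each resulting
  # segment takes its founder from the homolog given by crossover parity
  ends <- c(h1$end, h2$end, xo_bp)
  ends <- ends[order(ends)]
  ends <- ends[c(TRUE, diff(ends) > 0L)]
  starts <- c(start_bp, ends[-length(ends)] + 1L)
  use_h1 <- xor(findInterval(starts, xo_bp + 1L) %% 2L == 1L, start_h)
  f1 <- h1$founder[findInterval(starts, c(-Inf, h1$end[-length(h1$end)] + 1L))]
  f2 <- h2$founder[findInterval(starts, c(-Inf, h2$end[-length(h2$end)] + 1L))]
  f <- f2
  f[use_h1] <- f1[use_h1]
  merge_segments(ends, f)
}

make_cm_to_bp <- function(map) {
  chr <- sort(unique(map$chromosome))
  fns <- lapply(chr, function(ch) {
    sub <- map[map$chromosome == ch, ]
    cm <- sub$position_cM; bp <- sub$position_bp
    # strictly increasing cm grid for inversion (collapse flat stretches)
    keep <- !duplicated(cm)
    stats::approxfun(cm[keep], bp[keep], rule = 2)
  })
  names(fns) <- as.character(chr)
  fns
}

gamete <- function(genome, cinfo, cm2bp) {
  out <- vector("list", length(genome))
  for (i in seq_along(genome))
    out[[i]] <- meiosis_chrom(genome[[i]]$h1, genome[[i]]$h2,
                              cinfo$start_bp[i], cinfo$end_bp[i],
                              cinfo$start_cm[i], cinfo$end_cm[i], cm2bp[[i]])
  out
}

cross <- function(gA, gB) {
  lapply(seq_along(gA), function(i) list(h1 = gA[[i]], h2 = gB[[i]]))
}

#' Forward-simulate a MAGIC funnel population
#'
#' Implements the funnel breeding scheme: half-diallel two-way hybrids,
#' founder-disjoint two-ways crossed into pooled four-way collections, pools
#' crossed with their complements into eight-way hybrids, then single seed
#' descent. Pooling is modelled as a uniform draw of the contributing
#' component cross for each seed. When the substitution rule is active, the
#' component descending from the B96 x HP301 two-way is replaced by one
#' descending from B73 x CML91 wherever B96 and HP301 share a pool, and such
#' lines are flagged nine-founder.
#'
#' @param design a [funnel_design()].
#' @param map an interpolated [genetic_map()].
#' @param n_lines total lines to simulate (default
#'   `n_funnels * lines_per_funnel`), allocated round-robin over funnels.
#' @param seed integer seed.
#' @return A `magic_population`: list with `lines` (per line: `id`, `funnel`,
#'   `pedigree_flag`, `genome`), `design`, `map`, `chroms`.
#' @export
simulate_funnel_population <- function(design, map, n_lines = NULL, seed = 1L) {
  stopifnot(inherits(design, "funnel_design"), inherits(map, "genetic_map"))
  if (anyNA(map$position_cM)) stop("map must be interpolated first")
  rng <- local_rng(seed)
  chroms <- chrom_table(map)
  cinfo <- list(start_bp = as.integer(chroms$start_bp),
                end_bp = as.integer(chroms$end_bp),
                start_cm = as.numeric(chroms$start_cm),
                end_cm = as.numeric(chroms$end_cm))
  cm2bp <- make_cm_to_bp(map)
  parts <- pool_partitions(design$n_founders)[seq_len(design$n_funnels)]
  if (is.null(n_lines)) n_lines <- design$n_funnels * design$lines_per_funnel
  funnel_of <- rep_len(seq_len(design$n_funnels), n_lines)
  lines <- vector("list", n_lines)
  for (i in seq_len(n_lines)) {
    fu <- funnel_of[i]
    sides <- vector("list", 2L)
    nine <- FALSE
    for (p in 1:2) {
      pool <- parts[[fu]][[p]]
      comp <- pool_components(pool)[[sample.int(3L, 1L)]]
      if (design$substitution) {
        comp <- substitute_component(comp)
        if (attr(comp, "substituted")) nine <- TRUE
      }
      # two-way hybrids are founder x founder F1s; their gametes form the
      # four-way, whose gamete in turn enters the eight-way
      tw1 <- cross(founder_homologs(comp[[1]][1], chroms),
                   founder_homologs(comp[[1]][2], chroms))
      tw2 <- cross(founder_homologs(comp[[2]][1], chroms),
                   founder_homologs(comp[[2]][2], chroms))
      fourway <- cross(gamete(tw1, cinfo, cm2bp), gamete(tw2, cinfo, cm2bp))
      sides[[p]] <- gamete(fourway, cinfo, cm2bp)
    }
    ind <- cross(sides[[1]], sides[[2]])
    for (g in seq_len(design$ssd_generations))
      ind <- cross(gamete(ind, cinfo, cm2bp), gamete(ind, cinfo, cm2bp))
    lines[[i]] <- list(id = sprintf("%d_%d", fu, sum(funnel_of[seq_len(i)] == fu)),
                       funnel = fu,
                       pedigree_flag = if (nine) "nine-founder" else "eight-founder",
                       genome = ind)
  }
  structure(list(lines = lines, design = design, map = map, chroms = chroms),
            class = "magic_population")
}

founder_homologs <- function(f_idx, chroms) {
  lapply(seq_len(nrow(chroms)), function(i)
    list(end = chroms$end_bp[i], founder = as.integer(f_idx)))
}

#' @export
print.magic_population <- function(x, ...) {
  cat("MAGIC population: ", length(x$lines), " lines, ",
      nrow(x$chroms), " chromosomes, F", x$design$ssd_generations + 1,
      "\n", sep = "")
  cat("Nine-founder lines: ",
      sum(vapply(x$lines, function(l) l$pedigree_flag == "nine-founder", TRUE)),
      "\n", sep = "")
  invisible(x)
}

# --- truth summaries ---------------------------------------------------------

#' Genome-length founder shares of one simulated line
#' @param line one element of a `magic_population`'s `lines`.
#' @param chroms the population's chromosome table.
#' @param n_founders size of the returned share vector.
#' @return numeric vector summing to 1.
#' @export
founder_shares <- function(line, chroms, n_founders = 9L) {
  tot <- numeric(n_founders)
  for (i in seq_along(line$genome)) {
    for (h in line$genome[[i]]) {
      start <- c(chroms$start_bp[i], h$end[-length(h$end)] + 1L)
      len <- as.numeric(h$end - start + 1)
      for (k in seq_along(len)) tot[h$founder[k]] <- tot[h$founder[k]] + len[k]
    }
  }
  tot / sum(tot)
}

#' True heterozygosity of one simulated line
#'
#' Fraction of genome length where the two homologs carry different founder
#' labels.
#' @inheritParams founder_shares
#' @return fraction in [0,1].
#' @export
mosaic_heterozygosity <- function(line, chroms) {
  het <- 0; tot <- 0
  for (i in seq_along(line$genome)) {
    h1 <- line$genome[[i]]$h1; h2 <- line$genome[[i]]$h2
    ends <- sort(unique(c(h1$end, h2$end)))
    starts <- c(chroms$start_bp[i], ends[-length(ends)] + 1L)
    f1 <- h1$founder[findInterval(starts, c(-Inf, h1$end[-length(h1$end)] + 1L))]
    f2 <- h2$founder[findInterval(starts, c(-Inf, h2$end[-length(h2$end)] + 1L))]
    len <- ends - starts + 1
    het <- het + sum(len[f1 != f2])
    tot <- tot + sum(len)
  }
  het / tot
}

#' True junction count of one simulated line
#'
#' Number of founder switches along the genome, averaged over the two
#' homologs (at the inbred limit the homologs coincide and this is the
#' count a mosaic reconstruction should recover).
#' @inheritParams founder_shares
#' @return numeric junction count.
#' @export
count_true_junctions <- function(line, chroms) {
  mean(vapply(line$genome, function(ch)
    (length(ch$h1$end) - 1L) + (length(ch$h2$end) - 1L), 0L)) * length(line$genome) / 2
}

#' Founder labels of a line's homologs at given marker positions
#' @keywords internal
mosaic_at_markers <- function(line, map, chroms) {
  out1 <- integer(nrow(map)); out2 <- integer(nrow(map))
  for (i in seq_along(line$genome)) {
    idx <- which(map$chromosome == chroms$chromosome[i])
    bp <- map$position_bp[idx]
    h1 <- line$genome[[i]]$h1; h2 <- line$genome[[i]]$h2
    out1[idx] <- h1$founder[findInterval(bp, c(-Inf, h1$end[-length(h1$end)] + 1L))]
    out2[idx] <- h2$founder[findInterval(bp, c(-Inf, h2$end[-length(h2$end)] + 1L))]
  }
  cbind(h1 = out1, h2 = out2)
}

#' Genotype simulated mosaics on the marker panel
#'
#' Reads each line's founder pair at every marker off the true mosaic,
#' combines the founder panel alleles (heterozygous call where the homologs'
#' alleles differ), then applies array-style noise: with probability
#' `error_rate` a call is flipped to a random different call, and with
#' probability `missing_rate` it is set missing (the reference assay averaged
#' an 85% call rate, i.e. 15% missing).
#'
#' @param pop a `magic_population` from [simulate_funnel_population()].
#' @param founders a [founder_panel()] over the population's map.
#' @param error_rate per-call genotyping error probability.
#' @param missing_rate per-call missing probability.
#' @param seed integer seed.
#' @return a [genotype_matrix()] with pedigree flags from the simulation.
#' @export
genotype_mosaics <- function(pop, founders, error_rate = 0.01,
                             missing_rate = 0.15, seed = 1L) {
  stopifnot(inherits(pop, "magic_population"), inherits(founders, "founder_panel"))
  rng <- local_rng(seed)
  map <- pop$map
  n <- length(pop$lines); m <- nrow(map)
  calls <- matrix(-1L, n, m, dimnames = list(
    vapply(pop$lines, `[[`, "", "id"), map$marker_id))
  fc <- founders$calls
  for (i in seq_len(n)) {
    mos <- mosaic_at_markers(pop$lines[[i]], map, pop$chroms)
    a1 <- fc[cbind(mos[, 1], seq_len(m))]
    a2 <- fc[cbind(mos[, 2], seq_len(m))]
    call <- ifelse(a1 == a2, a1, 1L)
    call[a1 == -1L | a2 == -1L] <- -1L
    # founder residual het calls pass through as het
    call[a1 == 1L | a2 == 1L] <- 1L
    if (error_rate > 0) {
      err <- which(stats::runif(m) < error_rate & call != -1L)
      if (length(err))
        call[err] <- (call[err] + sample(c(1L, 2L), length(err), replace = TRUE)) %% 3L
    }
    if (missing_rate > 0) call[stats::runif(m) < missing_rate] <- -1L
    calls[i, ] <- call
  }
  genotype_matrix(calls, vapply(pop$lines, `[[`, "", "pedigree_flag"))
}

#' Write true mosaic segments as a BED-like TSV
#'
#' Columns: line, chrom, start, end, homolog, founder. File coordinates are
#' 0-based half-open (BED convention); internal segments are 1-based
#' inclusive.
#'
#' @param pop a `magic_population`.
#' @param path output file.
#' @export
write_truth_segments <- function(pop, path) {
  rows <- list()
  for (l in pop$lines) {
    for (i in seq_along(l$genome)) {
      for (hn in c("h1", "h2")) {
        h <- l$genome[[i]][[hn]]
        start <- c(pop$chroms$start_bp[i], h$end[-length(h$end)] + 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          line = l$id, chrom = pop$chroms$chromosome[i],
          start = start - 1L, end = h$end, homolog = hn,
          founder = names(magic_founders(TRUE))[h$founder])
      }
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

local_rng <- function(seed) {
  set.seed(as.integer(as.numeric(seed) %% 2147483647))
  invisible(seed)
}

#' Derive a stage seed from a master seed
#'
#' Stable per-stage seeds so pipeline stages are independently reproducible.
#' @param master integer master seed.
#' @param stage character stage name.
#' @param index optional integer (e.g. replicate number).
#' @return integer seed below 2^31.
#' @export
derive_seed <- function(master, stage, index = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 2654435 + h * 97 + index * 7919) %% 2147483647)
}
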