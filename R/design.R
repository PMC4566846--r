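#' Founder labels of the reference MAGIC maize design
#'
#' Eight inbred founders labelled A-H (A632, B73, B96, F7, H99, HP301, Mo17,
#' W153R) plus the optional substitute ninth parent I (CML91), introduced as a
#' B73 x CML91 two-way wherever the B96 x HP301 two-way failed.
#'
#' @param substitution include the ninth founder label.
#' @return named character vector of founder labels.
#' @export
magic_founders <- function(substitution = FALSE) {
  f <- c(A = "A632", B = "B73", C = "B96", D = "F7",
         E = "H99", F = "HP301", G = "Mo17", H = "W153R")
  if (substitution) f <- c(f, I = "CML91")
  f
}

# letter indices of the founders involved in the substitution rule
.SUB <- list(b96 = 3L, hp301 = 6L, b73 = 2L, cml91 = 9L)

#' Describe a funnel breeding design
#'
#' @param n_founders number of founders (8 for the reference design).
#' @param n_funnels number of independent funnels (subfamilies); at most the
#'   number of complementary pool partitions, C(n,4)/2.
#' @param lines_per_funnel RILs advanced per funnel.
#' @param ssd_generations selfing generations after the eight-way hybrid
#'   (5 advances the population to F6).
#' @param substitution apply the B73 x CML91 replacement of failed
#'   B96 x HP301 two-ways.
#' @return A `funnel_design` object.
#' @export
funnel_design <- function(n_founders = 8L, n_funnels = 35L,
                          lines_per_funnel = 15L, ssd_generations = 5L,
                          substitution = TRUE) {
  if (n_founders %% 2 != 0 || n_founders < 4)
    stop("funnel design requires an even number of founders >= 4")
  max_funnels <- choose(n_founders, n_founders / 2) / 2
  if (n_funnels > max_funnels)
    stop("at most ", max_funnels, " distinct funnels exist for ",
         n_founders, " founders")
  if (substitution && n_founders != 8)
    stop("the substitution rule is defined for the 8-founder design only")
  structure(list(n_founders = as.integer(n_founders),
                 n_funnels = as.integer(n_funnels),
                 lines_per_funnel = as.integer(lines_per_funnel),
                 ssd_generations = as.integer(ssd_generations),
                 substitution = substitution),
            class = "funnel_design")
}

#' Count the crosses of the funnel design
#'
#' For n founders: C(n,2) two-way hybrids from the half-diallel; four-way
#' crosses are unordered pairs of founder-disjoint two-ways,
#' C(n,2) C(n-2,2) / 2; pools collect the four-ways sharing a founder set,
#' one per 4-founder subset; funnels pair complementary pools.
#'
#' @param n_founders even integer >= 4.
#' @return list with `n_two_way`, `n_four_way_crosses`, `n_pools`,
#'   `n_funnel_pairs`.
#' @examples
#' enumerate_design(8)  # 28 two-ways, 210 four-way crosses, 70 pools
#' @export
enumerate_design <- function(n_founders) {
  if (n_founders %% 2 != 0 || n_founders < 4)
    stop("design undefined for odd or < 4 founders")
  n <- n_founders
  list(n_two_way = choose(n, 2),
       n_four_way_crosses = choose(n, 2) * choose(n - 2, 2) / 2,
       n_pools = choose(n, 4),
       n_funnel_pairs = choose(n, 4) / 2)
}

# All complementary pool partitions of 1..8: 35 unordered {S, complement} pairs
pool_partitions <- function(n_founders = 8L) {
  half <- n_founders / 2
  cmb <- utils::combn(n_founders, half)
  keep <- cmb[, cmb[1, ] == 1L, drop = FALSE]  # fix founder 1 to dedupe pairs
  lapply(seq_len(ncol(keep)), function(j) {
    s <- keep[, j]
    list(pool1 = s, pool2 = setdiff(seq_len(n_founders), s))
  })
}

# The 3 component four-way crosses of a 4-founder pool, as pairs of two-ways
pool_components <- function(pool) {
  p <- sort(pool)
  list(list(c(p[1], p[2]), c(p[3], p[4])),
       list(c(p[1], p[3]), c(p[2], p[4])),
       list(c(p[1], p[4]), c(p[2], p[3])))
}

# Apply the substitution rule to one component cross: a two-way equal to
# {B96, HP301} is replaced by {B73, CML91}
substitute_component <- function(comp) {
  failed <- c(.SUB$b96, .SUB$hp301)
  hit <- FALSE
  comp <- lapply(comp, function(tw) {
    if (setequal(tw, failed)) { hit <<- TRUE; c(.SUB$b73, .SUB$cml91) } else tw
  })
  attr(comp, "substituted") <- hit
  comp
}

#' Expected founder contributions under the funnel design
#'
#' Without the substitution rule every founder is expected to contribute 1/8
#' of the genome. With it, every four-way cross descending from the failed
#' B96 x HP301 two-way is replaced by one descending from B73 x CML91; the
#' expectation over all complementary pool partitions (enumerated exactly, in
#' integer arithmetic) gives B96 = HP301 = 3/28, B73 = 1/7, CML91 = 1/56 and
#' 1/8 for the remaining founders.
#'
#' @param design a [funnel_design()].
#' @return named numeric vector of expected genome fractions (sums to 1), with
#'   attributes `numerator` and `denominator` giving the exact rationals.
#' @export
expected_contributions <- function(design = funnel_design()) {
  stopifnot(inherits(design, "funnel_design"))
  n <- design$n_founders
  n_states <- if (design$substitution) 9L else n
  counts <- integer(n_states)
  parts <- pool_partitions(n)
  for (pt in parts) {
    for (pool in pt) {
      for (comp in pool_components(pool)) {
        if (design$substitution) comp <- substitute_component(comp)
        for (tw in comp) counts[tw] <- counts[tw] + 1L
      }
    }
  }
  # each membership is worth 1/4 (of a four-way) * 1/2 (of the eight-way
  # genome) * 1/3 (pool pick) per funnel: 1/24; averaged over all partitions
  den <- length(parts) * 24L
  labels <- names(magic_founders(design$substitution))[seq_len(n_states)]
  g <- gcd_vec(counts, den)
  out <- counts / den
  names(out) <- labels
  attr(out, "numerator") <- as.integer(counts / g)
  attr(out, "denominator") <- as.integer(den / g)
  out
}

gcd_vec <- function(x, d) {
  g <- d
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  for (v in x[x > 0]) g <- gcd2(g, v)
  g
}

#' Analytic expectations for junctions, heterozygosity and RIX count
#'
#' Junction expectation counts one effective round of recombination (L
#' Morgans each) for the two intercross meioses, the first selfing, and one
#' further round contributed by the whole of single seed descent as
#' heterozygosity halves, totalling 4L. Heterozygosity halves per selfing
#' generation from 1 at the eight-way F1. RIX counts the distinct F1s between
#' pairs of RILs.
#'
#' @param map an interpolated [genetic_map()] (or a map length in Morgans).
#' @param generation integer k of F_k, k >= 2.
#' @param n_lines number of RILs available for intercrossing.
#' @return list with `expected_junctions`, `expected_heterozygosity`,
#'   `rix_count`.
#' @examples
#' design_expectations(19.96, generation = 6, n_lines = 1636)
#' @export
design_expectations <- function(map, generation = 6L, n_lines = 2L) {
  L <- if (inherits(map, "genetic_map")) map_length_morgans(map) else as.numeric(map)
  k <- as.integer(generation)
  if (k < 2) stop("generation must be F2 or later")
  list(expected_junctions = 4 * L,
       expected_heterozygosity = 0.5^(k - 1),
       rix_count = n_lines * (n_lines - 1) / 2)
}

#' @export
print.funnel_design <- function(x, ...) {
  cnt <- enumerate_design(x$n_founders)
  cat("Funnel design: ", x$n_founders, " founders, ", x$n_funnels,
      " funnels x ", x$lines_per_funnel, " lines, SSD to F",
      x$ssd_generations + 1, "\n", sep = "")
  cat("Crosses: ", cnt$n_two_way, " two-way, ", cnt$n_four_way_crosses,
      " four-way, ", cnt$n_pools, " pools\n", sep = "")
  cat("Substitution rule (B73 x CML91): ",
      if (x$substitution) "on" else "off", "\n", sep = "")
  invisible(x)
}
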