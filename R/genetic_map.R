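#' Construct a genetic map
#'
#' A genetic map is the coordinate backbone shared by the simulator, the
#' haplotype-reconstruction HMM and the QTL mapping machinery: an ordered
#' marker table with chromosome, physical position (bp, 1-based) and genetic
#' position (cM). Genetic positions may be missing ("anchored" maps) until
#' filled in by [interpolate_cm()].
#'
#' @param marker_id character vector of marker names, unique within chromosome.
#' @param chromosome integer chromosome index (1..C).
#' @param position_bp integer physical position, strictly increasing within
#'   chromosome.
#' @param position_cM numeric genetic position or `NA` for unanchored markers.
#' @return A `genetic_map` object: a data.frame with the four columns above,
#'   sorted by chromosome then position.
#' @examples
#' gm <- genetic_map(paste0("m", 1:4), c(1, 1, 2, 2),
#'                   c(100, 200, 100, 300), c(0, 1, 0, 2.5))
#' map_length_morgans(gm)
#' @export
genetic_map <- function(marker_id, chromosome, position_bp, position_cM = NA_real_) {
  df <- data.frame(marker_id = as.character(marker_id),
                   chromosome = as.integer(chromosome),
                   position_bp = as.integer(position_bp),
                   position_cM = as.numeric(position_cM),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chromosome, df$position_bp), , drop = FALSE]
  rownames(df) <- NULL
  validate_genetic_map(df)
  class(df) <- c("genetic_map", "data.frame")
  df
}

validate_genetic_map <- function(df) {
  if (any(df$position_bp < 1L, na.rm = TRUE))
    stop("position_bp must be >= 1 (1-based coordinates)")
  for (ch in unique(df$chromosome)) {
    sub <- df[df$chromosome == ch, ]
    if (anyDuplicated(sub$marker_id))
      stop("duplicate marker_id on chromosome ", ch, ": ",
           sub$marker_id[duplicated(sub$marker_id)][1])
    d <- diff(sub$position_bp)
    if (length(d) && any(d <= 0)) {
      i <- which(d <= 0)[1]
      stop("position_bp not strictly increasing on chromosome ", ch,
           " between markers ", sub$marker_id[i], " and ", sub$marker_id[i + 1])
    }
    cm <- sub$position_cM[!is.na(sub$position_cM)]
    if (length(cm) > 1 && any(diff(cm) < 0)) {
      i <- which(diff(cm) < 0)[1]
      anch <- sub[!is.na(sub$position_cM), ]
      stop("anchored cM decreasing on chromosome ", ch, " between markers ",
           anch$marker_id[i], " and ", anch$marker_id[i + 1])
    }
  }
  invisible(df)
}

#' Interpolate missing cM positions proportional to physical distance
#'
#' Markers with known ("anchored") genetic positions define a piecewise-linear
#' cM/bp relationship per chromosome; unanchored markers between two anchors
#' get cM linear in bp, and markers beyond the terminal anchors are
#' extrapolated at the chromosome's mean cM/bp rate. Anchored values are
#' left untouched, so the operation is idempotent.
#'
#' @param map a [genetic_map()], possibly with `NA` in `position_cM`.
#' @return The map with `position_cM` defined (non-decreasing) for all markers.
#' @export
interpolate_cm <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  out <- map
  for (ch in unique(map$chromosome)) {
    idx <- which(map$chromosome == ch)
    bp <- map$position_bp[idx]
    cm <- map$position_cM[idx]
    anch <- which(!is.na(cm))
    if (length(anch) < 2)
      stop("chromosome ", ch, " has fewer than 2 anchored markers; cannot interpolate")
    # interior: linear in bp between flanking anchors (approx handles flat
    # segments by taking the mean of the tied anchor values)
    filled <- stats::approx(bp[anch], cm[anch], xout = bp, ties = mean)$y
    # beyond terminal anchors: extrapolate at the chromosome mean rate
    rate <- (cm[anch[length(anch)]] - cm[anch[1]]) / (bp[anch[length(anch)]] - bp[anch[1]])
    lo <- bp < bp[anch[1]]
    hi <- bp > bp[anch[length(anch)]]
    filled[lo] <- cm[anch[1]] - (bp[anch[1]] - bp[lo]) * rate
    filled[hi] <- cm[anch[length(anch)]] + (bp[hi] - bp[anch[length(anch)]]) * rate
    filled[anch] <- cm[anch]
    filled <- pmax(filled, 0)
    filled <- cummax(filled)   # guard against extrapolation below the first anchor
    filled[anch] <- cm[anch]
    out$position_cM[idx] <- filled
  }
  validate_genetic_map(out)
  out
}

#' Total map length in Morgans
#'
#' @param map an interpolated [genetic_map()].
#' @return Sum over chromosomes of (max cM - min cM) / 100.
#' @export
map_length_morgans <- function(map) {
  stopifnot(inherits(map, "genetic_map"), !anyNA(map$position_cM))
  sum(tapply(map$position_cM, map$chromosome, function(x) max(x) - min(x))) / 100
}

#' Convert a cM distance to a recombination fraction
#'
#' Default is the Haldane inverse r = 0.5 (1 - exp(-2 d / 100)), consistent
#' with the no-interference (Poisson) crossover process used by the breeding
#' simulator. A `"linear"` mode (r = d/100) is provided for strict map-distance
#' mimicry at short range. The result is multiplied by `damping` and clamped
#' to [1e-12, 0.499] so transition probabilities never degenerate.
#'
#' @param d_cM non-negative genetic distance(s) in centimorgans.
#' @param method `"haldane"` (default) or `"linear"`.
#' @param damping multiplicative shrink applied to r (default 1).
#' @return recombination fraction(s) in [1e-12, 0.499].
#' @export
cm_to_recfrac <- function(d_cM, method = c("haldane", "linear"), damping = 1.0) {
  method <- match.arg(method)
  if (any(!is.finite(d_cM)) || any(d_cM < 0))
    stop("d_cM must be finite and non-negative")
  r <- switch(method,
              haldane = 0.5 * (1 - exp(-2 * d_cM / 100)),
              linear  = d_cM / 100)
  pmin(pmax(r * damping, 1e-12), 0.499)
}

#' Read / write the genetic-map TSV format
#'
#' Tab-separated with header `marker_id chromosome position_bp position_cM`;
#' an empty or `NA` cM field marks an unanchored marker.
#'
#' @param path file path.
#' @return `read_genetic_map()` returns a [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer", "integer", "numeric"),
                          na.strings = c("NA", ""))
  need <- c("marker_id", "chromosome", "position_bp", "position_cM")
  if (!identical(names(df), need))
    stop("map file must have header: ", paste(need, collapse = " "))
  genetic_map(df$marker_id, df$chromosome, df$position_bp, df$position_cM)
}

#' @param map a [genetic_map()] to write.
#' @rdname read_genetic_map
#' @export
write_genetic_map <- function(map, path) {
  stopifnot(inherits(map, "genetic_map"))
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @export
print.genetic_map <- function(x, ...) {
  n_chr <- length(unique(x$chromosome))
  cat("Genetic map: ", nrow(x), " markers on ", n_chr, " chromosome(s)\n", sep = "")
  if (!anyNA(x$position_cM))
    cat("Total length: ", round(map_length_morgans(x), 3), " Morgans\n", sep = "")
  else
    cat("Unanchored markers: ", sum(is.na(x$position_cM)),
        " (run interpolate_cm())\n", sep = "")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... ", nrow(x) - 6, " more markers\n", sep = "")
  invisible(x)
}
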