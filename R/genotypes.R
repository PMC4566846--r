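#' Founder genotype panel
#'
#' Holds the biallelic SNP calls of the 8 (or 9, with the substitute parent)
#' inbred founder lines over the marker panel. Calls are coded 0 (homozygous
#' reference), 2 (homozygous alternate), 1 (heterozygous) and -1 (missing).
#'
#' @param calls integer matrix, founders x markers, values in {0,1,2,-1};
#'   rownames are founder labels, colnames marker ids.
#' @return A `founder_panel` object.
#' @export
founder_panel <- function(calls) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (!nrow(calls) %in% c(8L, 9L))
    stop("founder panel must have 8 or 9 founders, got ", nrow(calls))
  if (is.null(rownames(calls))) rownames(calls) <- LETTERS[seq_len(nrow(calls))]
  check_call_coding(calls)
  if (any(colSums(calls != -1L) == 0L))
    stop("every marker needs at least one non-missing founder call")
  structure(list(founder_ids = rownames(calls), calls = calls),
            class = "founder_panel")
}

#' RIL genotype matrix
#'
#' @param calls integer matrix, lines x markers, coding as [founder_panel()].
#' @param pedigree_flag per-line flag, `"eight-founder"` or `"nine-founder"`,
#'   recording whether the line's funnel received the substitute ninth parent.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(calls, pedigree_flag = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls))) rownames(calls) <- paste0("L", seq_len(nrow(calls)))
  check_call_coding(calls)
  if (is.null(pedigree_flag)) pedigree_flag <- "eight-founder"
  if (!all(pedigree_flag %in% c("eight-founder", "nine-founder")))
    stop("pedigree_flag must be 'eight-founder' or 'nine-founder'")
  pedigree_flag <- rep_len(as.character(pedigree_flag), nrow(calls))
  structure(list(line_ids = rownames(calls), calls = calls,
                 pedigree_flag = pedigree_flag),
            class = "genotype_matrix")
}

check_call_coding <- function(calls) {
  bad <- !calls %in% c(-1L, 0L, 1L, 2L)
  if (any(bad)) stop("genotype calls must be in {0,1,2,-1(missing)}; found ",
                     calls[which(bad)[1]])
  invisible(calls)
}

#' Per-line call rate
#' @param g a [genotype_matrix()].
#' @return numeric vector, fraction of non-missing calls per line.
#' @export
call_rate <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  rowMeans(g$calls != -1L)
}

#' @export
print.founder_panel <- function(x, ...) {
  cat("Founder panel: ", length(x$founder_ids), " founders (",
      paste(x$founder_ids, collapse = ", "), "), ",
      ncol(x$calls), " markers\n", sep = "")
  invisible(x)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix: ", nrow(x$calls), " lines x ", ncol(x$calls),
      " markers\n", sep = "")
  cat("Pedigree: ", sum(x$pedigree_flag == "nine-founder"),
      " nine-founder line(s)\n", sep = "")
  cat("Mean call rate: ", round(mean(call_rate(x)), 3), "\n", sep = "")
  invisible(x)
}

#' Read / write genotype TSV files
#'
#' Genotype files are tab-separated with lines (or founders) as rows and
#' markers as columns; cells are 0/1/2 or NA. A founder panel file carries an
#' extra first comment row `#founders<TAB>label1<TAB>...` naming the founders.
#'
#' @param path file path.
#' @return `read_genotype_matrix()` returns a [genotype_matrix()];
#'   `read_founder_panel()` a [founder_panel()].
#' @export
read_genotype_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, na.strings = c("NA", ""))
  m <- as.matrix(df)
  m[is.na(m)] <- -1L
  flag_file <- paste0(path, ".flags")
  flags <- if (file.exists(flag_file))
    utils::read.delim(flag_file, header = TRUE)$pedigree_flag else NULL
  genotype_matrix(m, flags)
}

#' @param g object to write.
#' @rdname read_genotype_matrix
#' @export
write_genotype_matrix <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  m <- g$calls
  m[m == -1L] <- NA_integer_
  df <- data.frame(line_id = rownames(g$calls), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(data.frame(line_id = g$line_ids, pedigree_flag = g$pedigree_flag),
                     paste0(path, ".flags"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_genotype_matrix
#' @export
read_founder_panel <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#founders"))
    stop("founder panel file must start with a '#founders' header row")
  labels <- strsplit(first, "\t", fixed = TRUE)[[1]][-1]
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                          skip = 1, check.names = FALSE, na.strings = c("NA", ""))
  m <- as.matrix(df)
  m[is.na(m)] <- -1L
  rownames(m) <- labels
  founder_panel(m)
}

#' @param fp a [founder_panel()] to write.
#' @rdname read_genotype_matrix
#' @export
write_founder_panel <- function(fp, path) {
  stopifnot(inherits(fp, "founder_panel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#founders", fp$founder_ids), collapse = "\t"), con)
  m <- fp$calls
  m[m == -1L] <- NA_integer_
  df <- data.frame(founder_id = fp$founder_ids, m, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
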