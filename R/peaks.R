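# ENCODE peak formats and threshold filtering.

#' Read an ENCODE narrowPeak or broadPeak file
#'
#' narrowPeak has 10 tab-separated columns, broadPeak 9. Column 7 is the fold
#' enrichment over input, columns 8/9 carry -log10 p and -log10 q (the ENCODE
#' sentinel -1 means missing). Column 10 (narrowPeak only) is the summit offset
#' from the interval start.
#'
#' @param path Path to the peak file.
#' @param dialect `"narrowPeak"` or `"broadPeak"`.
#' @param genome Optional named vector of chromosome lengths.
#' @return A `GRanges` with metadata columns `name`, `fold_enrichment`,
#'   `p_value`, `q_value` (probabilities, `NA` when missing) and, for
#'   narrowPeak, `summit_offset`.
#' @export
read_peaks <- function(path, dialect = c("narrowPeak", "broadPeak"),
                       genome = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  want <- if (dialect == "narrowPeak") 10L else 9L
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lines <- lines[keep]
  if (length(lines) == 0) {
    gr <- gr_from_bed0(character(), numeric(), numeric(), genome = genome)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      name = character(), fold_enrichment = numeric(),
      p_value = numeric(), q_value = numeric())
    return(gr)
  }
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(nf != want)) {
    stop("format error in ", path, ": line ", which(nf != want)[1], " has ",
         nf[nf != want][1], " columns, ", dialect, " requires ", want)
  }
  x <- utils::read.table(text = lines, sep = "\t",
                         colClasses = c("character", "numeric", "numeric",
                                        "character", "numeric", "character",
                                        rep("numeric", want - 6)))
  gr <- gr_from_bed0(x[[1]], x[[2]], x[[3]],
                     ifelse(x[[6]] %in% c("+", "-"), x[[6]], "*"), genome)
  delog <- function(v) ifelse(v < 0, NA_real_, 10^(-v))
  mc <- S4Vectors::DataFrame(name = x[[4]],
                             fold_enrichment = x[[7]],
                             p_value = delog(x[[8]]),
                             q_value = delog(x[[9]]))
  if (dialect == "narrowPeak") {
    mc$summit_offset <- ifelse(x[[10]] < 0, NA_integer_, as.integer(x[[10]]))
  }
  if (any(mc$fold_enrichment < 0, na.rm = TRUE)) {
    stop("negative fold enrichment in ", path)
  }
  S4Vectors::mcols(gr) <- mc
  gr
}

#' Write peaks in narrowPeak/broadPeak format
#'
#' Inverse of [read_peaks()]; missing p/q are written as the ENCODE sentinel
#' `-1`.
#'
#' @param peaks A peak `GRanges` (see [read_peaks()]).
#' @param path Output path.
#' @param dialect `"narrowPeak"` or `"broadPeak"`.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, dialect = c("narrowPeak", "broadPeak")) {
  dialect <- match.arg(dialect)
  mc <- S4Vectors::mcols(peaks)
  relog <- function(p) ifelse(is.na(p), -1,
                              signif(-log10(p), 12))  # round-trip safe
  nm <- if (is.null(mc$name)) sprintf("peak_%d", seq_along(peaks)) else mc$name
  st <- as.character(BiocGenerics::strand(peaks))
  st[st == "*"] <- "."
  cols <- list(as.character(GenomeInfoDb::seqnames(peaks)),
               BiocGenerics::start(peaks) - 1L,
               BiocGenerics::end(peaks), nm, 0L, st,
               format(mc$fold_enrichment, trim = TRUE, scientific = FALSE,
                      digits = 15),
               format(relog(mc$p_value), trim = TRUE, scientific = FALSE,
                      digits = 15),
               format(relog(mc$q_value), trim = TRUE, scientific = FALSE,
                      digits = 15))
  if (dialect == "narrowPeak") {
    so <- mc$summit_offset
    if (is.null(so)) so <- rep(-1L, length(peaks))
    cols <- c(cols, list(ifelse(is.na(so), -1L, so)))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Filter peaks by fold enrichment and significance
#'
#' Retains records with `fold_enrichment >= min_fold` and, when a significance
#' threshold is given, `q_value <= max_q` (or `p_value <= max_p`). All
#' comparisons are inclusive. Records missing the tested significance column
#' are dropped when a threshold is set.
#'
#' @param peaks A peak `GRanges`.
#' @param min_fold Minimum fold enrichment (inclusive), >= 0.
#' @param max_q,max_p Optional inclusive significance ceilings; give at most
#'   one.
#' @return The filtered `GRanges`; the number of dropped records is reported
#'   via `message()`.
#' @export
filter_peaks <- function(peaks, min_fold = 0, max_q = NULL, max_p = NULL) {
  stopifnot(min_fold >= 0, is.null(max_q) || is.null(max_p))
  if (length(peaks) == 0) return(peaks)
  mc <- S4Vectors::mcols(peaks)
  keep <- mc$fold_enrichment >= min_fold
  if (!is.null(max_q)) keep <- keep & !is.na(mc$q_value) & mc$q_value <= max_q
  if (!is.null(max_p)) keep <- keep & !is.na(mc$p_value) & mc$p_value <= max_p
  dropped <- sum(!keep)
  if (dropped > 0) message(dropped, " peak(s) dropped by filter")
  peaks[keep]
}
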