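# Tab-separated file formats:
#   site file:  header "physPos genPos x n" (genPos optional; x = allele
#               count k), one row per informative site, sorted by physPos
#   spect file: line 1 "#polarity=<derived|minor>", line 2 "n k count",
#               one row per (n, k) cell with a nonnegative integer count
#   scan file:  header "physPos genPos CLR x_hat A_hat n_sites",
#               floats at 6 significant digits

.read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a site file
#'
#' @param path path to a TSV with header `physPos genPos x n` (the `genPos`
#'   column, genetic position in cM, may be absent, in which case scans fall
#'   back to a uniform recombination rate).
#' @param polarity `"derived"` or `"minor"` interpretation of the counts.
#' @return A `bal_sites` table.
#' @export
read_sites <- function(path, polarity = "derived") {
  df <- .read_tsv(path)
  need <- c("physPos", "x", "n")
  if (!all(need %in% names(df))) {
    stop(path, ": site file needs columns physPos, x, n (and optionally ",
         "genPos)", call. = FALSE)
  }
  gp <- if ("genPos" %in% names(df)) df$genPos else NULL
  bad <- which(!is.finite(df$physPos) | !is.finite(df$x) | !is.finite(df$n))
  if (length(bad)) {
    stop(path, ": malformed row at line ", bad[1L] + 1L, call. = FALSE)
  }
  if (is.unsorted(df$physPos, strictly = TRUE)) {
    bad <- which(diff(df$physPos) <= 0)[1L]
    stop(path, ": positions not strictly increasing at line ", bad + 2L,
         call. = FALSE)
  }
  site_records(df$physPos, k = df$x, n = df$n, gen_pos = gp,
               polarity = polarity)
}

#' Write a site file
#'
#' If the table carries a `"truth"` attribute (from [synth_footprint()]),
#' the generating parameters are written to a `<path>.json` sidecar.
#'
#' @param sites a `bal_sites` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  .check_sites(sites)
  df <- data.frame(physPos = sites$phys_pos, genPos = sites$gen_pos,
                   x = sites$k, n = sites$n)
  if (all(is.na(df$genPos))) df$genPos <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- attr(sites, "truth", exact = TRUE)
  if (!is.null(truth)) {
    jsonlite::write_json(truth, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a background spectrum ("spect") file
#'
#' @param path TSV whose first line is `#polarity=<derived|minor>` followed
#'   by a `n k count` table of raw genome-wide tallies (raw counts, not
#'   probabilities, so any model variant can be normalized from one file).
#' @return A `bal_sfs`.
#' @export
read_spect <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^#polarity=(derived|minor)$", first)) {
    stop(path, ": line 1 must be '#polarity=derived' or '#polarity=minor'",
         call. = FALSE)
  }
  polarity <- sub("^#polarity=", "", first)
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                          stringsAsFactors = FALSE)
  if (!all(c("n", "k", "count") %in% names(df))) {
    stop(path, ": spect file needs columns n, k, count", call. = FALSE)
  }
  bad <- which(!is.finite(df$count) | df$count < 0 |
                 df$count != round(df$count))
  if (length(bad)) {
    stop(path, ": invalid count at line ", bad[1L] + 2L, call. = FALSE)
  }
  bad <- if (polarity == "derived") {
    which(df$k < 1 | df$k > df$n)
  } else {
    which(df$k < 0 | df$k > df$n %/% 2)
  }
  if (length(bad)) {
    stop(path, ": allele count outside ", polarity, " support at line ",
         bad[1L] + 2L, call. = FALSE)
  }
  out <- data.frame(n = as.integer(df$n), k = as.integer(df$k),
                    count = as.numeric(df$count))
  out <- out[order(out$n, out$k), ]
  rownames(out) <- NULL
  structure(out, polarity = polarity, class = c("bal_sfs", "data.frame"))
}

#' Write a background spectrum ("spect") file
#'
#' @param bg a `bal_sfs`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spect <- function(bg, path) {
  .check_sfs(bg)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#polarity=", attr(bg, "polarity")), con)
  utils::write.table(as.data.frame(bg), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write scan results
#'
#' @param rows a `bal_scan` table from [scan()].
#' @param path output path; floats are written at 6 significant digits.
#' @return `path`, invisibly.
#' @export
write_scan <- function(rows, path) {
  fmt <- function(v) ifelse(is.na(v), "NA", formatC(signif(v, 6), digits = 6,
                                                    format = "g"))
  xh <- if (is.numeric(rows$x_hat)) fmt(rows$x_hat) else
    ifelse(is.na(rows$x_hat), "NA", rows$x_hat)
  df <- data.frame(physPos = rows$phys_pos, genPos = fmt(rows$gen_pos),
                   CLR = fmt(rows$B), x_hat = xh, A_hat = fmt(rows$A_hat),
                   n_sites = rows$n_sites)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read scan results written by [write_scan()]
#'
#' @param path scan TSV path.
#' @return A `data.frame` with columns `physPos`, `genPos`, `CLR`, `x_hat`,
#'   `A_hat`, `n_sites`.
#' @export
read_scan <- function(path) {
  df <- .read_tsv(path)
  need <- c("physPos", "genPos", "CLR", "x_hat", "A_hat", "n_sites")
  if (!all(need %in% names(df))) {
    stop(path, ": scan file needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read a genotype-count table for HWE filtering
#'
#' @param path TSV with header `physPos nAA nAa naa`.
#' @return A `data.frame`.
#' @export
read_genotypes <- function(path) {
  df <- .read_tsv(path)
  need <- c("physPos", "nAA", "nAa", "naa")
  if (!all(need %in% names(df))) {
    stop(path, ": genotype table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  bad <- which(df$nAA < 0 | df$nAa < 0 | df$naa < 0)
  if (length(bad)) {
    stop(path, ": negative genotype count at line ", bad[1L] + 1L,
         call. = FALSE)
  }
  df
}
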