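#' Tally the genome-wide background site frequency spectrum
#'
#' Aggregates informative sites into per-sample-size allele-count tallies:
#' xi_n(k) (derived polarity) or eta_n(k) (minor polarity), the number of
#' informative sites genome-wide with k derived (minor) alleles out of n.
#' The background is kept conditional on the exact sample size n, since
#' missing genotype calls make n vary along the genome.
#'
#' @param sites a `bal_sites` table (or list of tables) as returned by
#'   [site_records()] or [read_sites()].
#' @param polarity `"derived"` or `"minor"`; must match the site tables.
#' @return A `data.frame` of class `bal_sfs` with columns `n`, `k`, `count`
#'   and a `polarity` attribute.
#' @seealso [normalize_background()], [fold_background()], [read_spect()]
#' @export
build_background <- function(sites, polarity = "derived") {
  polarity <- match.arg(polarity, c("derived", "minor"))
  if (inherits(sites, "bal_sites")) sites <- list(sites)
  if (length(sites) == 0L) stop("no informative sites", call. = FALSE)
  for (s in sites) {
    .check_sites(s)
    if (!identical(.sites_polarity(s), polarity)) {
      stop("site table polarity '", .sites_polarity(s),
           "' does not match requested polarity '", polarity, "'",
           call. = FALSE)
    }
  }
  nn <- unlist(lapply(sites, `[[`, "n"))
  kk <- unlist(lapply(sites, `[[`, "k"))
  tab <- as.data.frame(table(n = nn, k = kk), stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, ]
  out <- data.frame(n = as.integer(tab$n), k = as.integer(tab$k),
                    count = as.numeric(tab$Freq))
  out <- out[order(out$n, out$k), ]
  rownames(out) <- NULL
  structure(out, polarity = polarity, class = c("bal_sfs", "data.frame"))
}

.check_sfs <- function(bg) {
  if (!inherits(bg, "bal_sfs")) {
    stop("expected a 'bal_sfs' background (see build_background() or ",
         "read_spect())", call. = FALSE)
  }
  if (any(bg$count < 0)) stop("negative background count", call. = FALSE)
  invisible(bg)
}

#' Fold a derived-polarity background spectrum to minor-allele polarity
#'
#' eta_n(min(k, n - k)) accumulates xi_n(k); substitutions (k = n) land in
#' eta_n(0). Total counts are conserved.
#'
#' @param bg a derived-polarity `bal_sfs`.
#' @return A minor-polarity `bal_sfs`.
#' @export
fold_background <- function(bg) {
  .check_sfs(bg)
  if (!identical(attr(bg, "polarity"), "derived")) {
    stop("fold_background() expects a derived-polarity background",
         call. = FALSE)
  }
  kf <- pmin(bg$k, bg$n - bg$k)
  agg <- stats::aggregate(count ~ n + k, data = data.frame(n = bg$n, k = kf,
                                                           count = bg$count),
                          FUN = sum)
  agg <- agg[order(agg$n, agg$k), ]
  rownames(agg) <- NULL
  structure(agg[, c("n", "k", "count")], polarity = "minor",
            class = c("bal_sfs", "data.frame"))
}

#' Normalize a background spectrum into the neutral null distribution
#'
#' Produces the per-sample-size neutral probabilities g_n(k) used both as the
#' null model and as the unlinked mixture component of the alternative model.
#' The normalization depends on the model variant:
#' \describe{
#'   \item{`"2"`}{g_n(k) = xi_n(k) / sum_{j=1}^{n} xi_n(j), k = 1..n.}
#'   \item{`"0"`}{substitutions excluded: denominator sums j = 1..n-1.}
#'   \item{`"1"`}{dichotomized: P(substitution) = xi_n(n) / sum_j xi_n(j).}
#'   \item{`"2MAF"`}{g_n(k) = eta_n(k) / sum_{j=0}^{floor(n/2)} eta_n(j).}
#'   \item{`"0MAF"`}{substitutions (k = 0) excluded from the denominator.}
#' }
#'
#' @param bg a `bal_sfs` background of compatible polarity (derived for
#'   variants `"2"`, `"1"`, `"0"`; minor for `"2MAF"`, `"0MAF"`).
#' @param variant model variant code (`"2"`, `"2MAF"`, `"1"`, `"0"`,
#'   `"0MAF"`; the aliases `"B2"`, `"B2maf"`, ... are accepted).
#' @return An object of class `bal_spectrum`: per-`n` probability vectors
#'   over the variant support, each summing to one.
#' @export
normalize_background <- function(bg, variant = "2") {
  .check_sfs(bg)
  variant <- .normalize_variant(variant)
  pol <- .variant_polarity(variant)
  if (!identical(attr(bg, "polarity"), pol)) {
    stop("variant ", variant, " requires a ", pol,
         "-polarity background, got ", attr(bg, "polarity"), call. = FALSE)
  }
  strata <- list()
  for (n in sort(unique(bg$n))) {
    sub <- bg[bg$n == n, ]
    supp <- .variant_support(variant, n)
    if (variant == "1") {
      total <- sum(sub$count)
      if (total <= 0) stop("no informative sites at n = ", n, call. = FALSE)
      p_sub <- sum(sub$count[sub$k == n]) / total
      prob <- c(poly = 1 - p_sub, sub = p_sub)
    } else {
      counts <- stats::setNames(numeric(length(supp)), supp)
      keep <- sub$k %in% supp
      counts[as.character(sub$k[keep])] <- sub$count[keep]
      total <- sum(counts)
      if (total <= 0) {
        stop("variant ", variant, " normalization impossible at n = ", n,
             ": no sites in support (all polymorphic counts zero?)",
             call. = FALSE)
      }
      prob <- counts / total
    }
    strata[[as.character(n)]] <- list(k = supp, prob = unname(prob),
                                      total = total)
  }
  structure(list(variant = variant, polarity = pol, strata = strata),
            class = "bal_spectrum")
}

.check_spectrum <- function(g) {
  if (!inherits(g, "bal_spectrum")) {
    stop("expected a 'bal_spectrum' (see normalize_background())",
         call. = FALSE)
  }
  invisible(g)
}

# Neutral probability g_n(k) for raw allele counts k; hard errors on missing
# strata (no projection across n) and on zero-probability cells, which signal
# a background not built from the scanned dataset.
.spectrum_prob <- function(g, n, k) {
  out <- numeric(length(k))
  n <- rep_len(n, length(k))
  for (key in unique(as.character(n))) {
    st <- g$strata[[key]]
    if (is.null(st)) {
      stop("no background stratum for sample size n = ", key,
           "; build the background from the same dataset being scanned",
           call. = FALSE)
    }
    sel <- as.character(n) == key
    idx <- .support_index(g$variant, as.integer(key), k[sel])
    if (anyNA(idx)) {
      stop("allele count outside variant ", g$variant,
           " support at n = ", key, call. = FALSE)
    }
    out[sel] <- st$prob[idx]
  }
  if (any(out <= 0)) {
    stop("observed (n, k) cell has zero background probability; ",
         "build the background from the same dataset being scanned",
         call. = FALSE)
  }
  out
}

#' @export
print.bal_spectrum <- function(x, ...) {
  cat("Neutral spectrum, variant B", x$variant, " (", x$polarity,
      " polarity)\n", sep = "")
  for (nm in names(x$strata)) {
    st <- x$strata[[nm]]
    cat("  n = ", nm, ": ", length(st$prob), " classes, ",
        format(st$total), " sites\n", sep = "")
  }
  invisible(x)
}
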