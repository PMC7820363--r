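#' Construct a validated table of informative sites
#'
#' An informative site is a polymorphism or a substitution relative to an
#' outgroup. Each record carries its physical position (bp), optionally its
#' genetic position (cM), the allele count `k` and the sample size `n`
#' (number of sampled haploid alleles, which may vary site to site because of
#' missing genotypes). Under `polarity = "derived"`, `k` is the derived allele
#' count with `k = n` denoting a substitution; under `polarity = "minor"`,
#' `k` is the minor allele count with `k = 0` denoting a substitution.
#'
#' @param phys_pos integer vector of 1-based physical positions.
#' @param k integer vector of allele counts.
#' @param n integer vector (or scalar) of sample sizes, `n >= 2`.
#' @param gen_pos optional numeric vector of genetic positions in cM,
#'   nondecreasing with physical position.
#' @param polarity `"derived"` or `"minor"`.
#' @return A `data.frame` of class `bal_sites` with columns `phys_pos`,
#'   `gen_pos`, `k`, `n`, sorted by physical position, with a `polarity`
#'   attribute.
#' @examples
#' site_records(c(100, 200), k = c(3, 10), n = 10)
#' @export
site_records <- function(phys_pos, k, n, gen_pos = NULL, polarity = "derived") {
  polarity <- match.arg(polarity, c("derived", "minor"))
  L <- length(phys_pos)
  if (L == 0L) stop("no informative sites", call. = FALSE)
  n <- as.integer(rep_len(n, L))
  k <- as.integer(k)
  phys_pos <- as.integer(phys_pos)
  if (length(k) != L) stop("k and phys_pos lengths differ", call. = FALSE)
  if (is.null(gen_pos)) gen_pos <- rep(NA_real_, L)
  gen_pos <- as.numeric(gen_pos)
  if (length(gen_pos) != L) stop("gen_pos and phys_pos lengths differ", call. = FALSE)

  bad <- which(n < 2L)
  if (length(bad)) {
    stop("sample size n < 2 at position ", phys_pos[bad[1L]], call. = FALSE)
  }
  bad <- if (polarity == "derived") {
    which(k < 1L | k > n)
  } else {
    which(k < 0L | k > n %/% 2L)
  }
  if (length(bad)) {
    stop("allele count k = ", k[bad[1L]], " outside ", polarity,
         " support at position ", phys_pos[bad[1L]], call. = FALSE)
  }

  ord <- order(phys_pos)
  df <- data.frame(phys_pos = phys_pos[ord], gen_pos = gen_pos[ord],
                   k = k[ord], n = n[ord])
  gp <- df$gen_pos[!is.na(df$gen_pos)]
  if (length(gp) > 1L && any(diff(gp) < 0)) {
    stop("genetic positions must be nondecreasing with physical position",
         call. = FALSE)
  }
  structure(df, polarity = polarity, class = c("bal_sites", "data.frame"))
}

.check_sites <- function(sites) {
  if (!inherits(sites, "bal_sites")) {
    stop("expected a 'bal_sites' table (see site_records() or read_sites())",
         call. = FALSE)
  }
  if (nrow(sites) == 0L) stop("no informative sites", call. = FALSE)
  invisible(sites)
}

.sites_polarity <- function(sites) attr(sites, "polarity", exact = TRUE)

# Genetic positions in cM for a site table: recorded map positions when
# present, otherwise phys_pos * rec_rate (cM/bp).
.genetic_positions <- function(sites, rec_rate) {
  gp <- sites$gen_pos
  if (anyNA(gp)) {
    if (is.null(rec_rate) || !is.finite(rec_rate) || rec_rate <= 0) {
      stop("sites lack genetic positions and no positive rec_rate (cM/bp) ",
           "was configured", call. = FALSE)
    }
    gp <- sites$phys_pos * rec_rate
  }
  gp
}
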