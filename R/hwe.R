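#' One-tailed exact test for heterozygote excess
#'
#' Exact conditional test of Hardy-Weinberg equilibrium against an excess of
#' heterozygotes, used to flag genotyping artifacts before a scan. The
#' default method conditions on the allele-count margins (Levene/Haldane):
#' given nA copies of A and na copies of a among N diploids, the number of
#' heterozygotes H has
#' P(H = h) proportional to 2^h / \[((nA - h)/2)! h! ((na - h)/2)!\],
#' over h with the parity of nA, and the one-tailed P-value is
#' P(H >= observed). Monomorphic sites return 1. `method = "fisher2x2"`
#' instead runs a literal one-sided Fisher's exact test on the 2x2 table of
#' (first, second) allele per individual, splitting odd heterozygote counts
#' evenly.
#'
#' @param n_AA,n_Aa,n_aa nonnegative genotype counts (equal-length vectors).
#' @param method `"exact"` (conditional on allele counts; default) or
#'   `"fisher2x2"`.
#' @return One-tailed P-value(s) in (0, 1\].
#' @examples
#' hwe_excess_het_test(0, 2, 0)  # 2/3
#' @export
hwe_excess_het_test <- function(n_AA, n_Aa, n_aa,
                                method = c("exact", "fisher2x2")) {
  method <- match.arg(method)
  len <- max(length(n_AA), length(n_Aa), length(n_aa))
  n_AA <- rep_len(as.integer(n_AA), len)
  n_Aa <- rep_len(as.integer(n_Aa), len)
  n_aa <- rep_len(as.integer(n_aa), len)
  if (any(n_AA < 0 | n_Aa < 0 | n_aa < 0)) {
    stop("genotype counts must be nonnegative", call. = FALSE)
  }
  if (any(n_AA + n_Aa + n_aa < 1L)) {
    stop("at least one individual required", call. = FALSE)
  }
  fun <- if (method == "exact") .hwe_exact_one else .hwe_fisher_one
  vapply(seq_len(len), function(i) fun(n_AA[i], n_Aa[i], n_aa[i]),
         numeric(1))
}

.hwe_exact_one <- function(a, h, b) {
  nA <- 2L * a + h
  na <- 2L * b + h
  if (nA == 0L || na == 0L) return(1)
  hs <- seq.int(nA %% 2L, min(nA, na), by = 2L)
  logw <- hs * log(2) - lfactorial((nA - hs) / 2) - lfactorial(hs) -
    lfactorial((na - hs) / 2)
  w <- exp(logw - max(logw))
  sum(w[hs >= h]) / sum(w)
}

.hwe_fisher_one <- function(a, h, b) {
  if (2L * a + h == 0L || 2L * b + h == 0L) return(1)
  tab <- matrix(c(a, floor(h / 2), ceiling(h / 2), b), 2L, 2L)
  # heterozygote excess = deficit of same-allele pairing on the diagonal
  stats::fisher.test(tab, alternative = "less")$p.value
}

#' Filter polymorphic sites with a significant heterozygote excess
#'
#' Applies [hwe_excess_het_test()] to each row of a genotype-count table and
#' removes sites with P below `threshold` (artifact-prone sites: collapsed
#' paralogs and mapping errors inflate heterozygote calls).
#'
#' @param tab `data.frame` with columns `physPos`, `nAA`, `nAa`, `naa`.
#' @param threshold remove sites with `P < threshold` (common choices:
#'   1e-4 for large panels, 1e-2 for small ones).
#' @param method passed to [hwe_excess_het_test()].
#' @return List with `retained` and `removed` (each the input rows plus a
#'   `p` column) and `counts` (`c(retained=, removed=)`).
#' @export
filter_sites <- function(tab, threshold = 1e-4, method = "exact") {
  need <- c("physPos", "nAA", "nAa", "naa")
  if (!all(need %in% names(tab))) {
    stop("genotype table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  p <- hwe_excess_het_test(tab$nAA, tab$nAa, tab$naa, method = method)
  tab$p <- p
  drop <- p < threshold
  list(retained = tab[!drop, , drop = FALSE],
       removed = tab[drop, , drop = FALSE],
       counts = c(retained = sum(!drop), removed = sum(drop)))
}
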