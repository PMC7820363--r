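#' Deterministic overdominance equilibrium for a biallelic locus
#'
#' Iterates the infinite-population viability recursion
#' p' = p (p w_AA + q w_Aa) / wbar with genotype fitnesses w_aa = 1 (ancestral
#' homozygote), w_Aa = 1 + h_dom s (heterozygote), w_AA = 1 + s (mutant
#' homozygote) until the estimated distance to the fixed point falls below
#' `tol` (the per-generation step divided by the local contraction rate) or
#' the iteration reaches floating-point stationarity. With h_dom > 1 the
#' heterozygote is the fittest genotype and an interior equilibrium exists
#' at p* = h_dom / (2 h_dom - 1), independent of the magnitude of s.
#'
#' @param s selective coefficient, `s > 0`.
#' @param h_dom dominance coefficient, `h_dom > 1` for an interior
#'   (balanced) equilibrium.
#' @param p0 starting derived-allele frequency in (0, 1).
#' @param tol target accuracy of the equilibrium frequency.
#' @param max_iter iteration cap.
#' @return List with `derived` (equilibrium derived-allele frequency),
#'   `minor` (`min(p, 1 - p)`), and `iterations`.
#' @examples
#' overdominance_equilibrium(0.01, 3)$minor  # 0.4
#' @export
overdominance_equilibrium <- function(s, h_dom, p0 = 0.5, tol = 1e-12,
                                      max_iter = 5e6) {
  if (!is.finite(s) || s <= 0) stop("s must be positive", call. = FALSE)
  if (!is.finite(h_dom) || h_dom <= 1) {
    stop("no interior equilibrium: need dominance h_dom > 1 ",
         "(heterozygote advantage)", call. = FALSE)
  }
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)", call. = FALSE)
  wAA <- 1 + s
  wAa <- 1 + h_dom * s
  waa <- 1
  p <- p0
  delta_prev <- NA_real_
  for (it in seq_len(max_iter)) {
    q <- 1 - p
    wA <- p * wAA + q * wAa            # marginal fitness of the mutant allele
    wa <- p * wAa + q * waa
    wbar <- p * wA + q * wa
    p_new <- p * wA / wbar
    delta <- p_new - p
    # near the fixed point the step contracts the remaining distance by the
    # factor c = s pq (2 h_dom - 1) / wbar per generation, so |delta| / c
    # estimates the distance still to go; stop when that bound is below tol,
    # or when the iteration reaches floating-point stationarity (zero or
    # sign-flipping steps), which for weak selection precedes tol
    c_rate <- s * p * q * (2 * h_dom - 1) / wbar
    at_floor <- delta == 0 ||
      (!is.na(delta_prev) && sign(delta) != sign(delta_prev))
    if (abs(delta) <= tol * c_rate || at_floor) {
      return(list(derived = p_new, minor = min(p_new, 1 - p_new),
                  iterations = it))
    }
    delta_prev <- delta
    p <- p_new
  }
  stop("overdominance recursion did not converge in ", max_iter,
       " iterations", call. = FALSE)
}

#' Deterministic equilibrium for multiallelic balancing selection
#'
#' Viability recursion for one ancestral allele plus `m_alleles` mutant
#' alleles under the multiplicative multi-mutation fitness rule: genotype
#' fitness is the product over mutant alleles carried, with 1 + s for a
#' mutant homozygote and 1 + h_dom s per heterozygous mutant — so ancestral/
#' ancestral = 1, ancestral/mutant = 1 + h_dom s, mutant_i/mutant_i = 1 + s,
#' and mutant_i/mutant_j (i != j) = (1 + h_dom s)^2. Allele frequencies are
#' updated by marginal fitness, x_i' = x_i w_i / wbar, from a near-symmetric
#' start (mutants at (1 - eps)/m each, ancestral at eps), until
#' max |x_i' - x_i| < tol. With h_dom s small and h_dom > 1 the mutants
#' converge to 1/m each and the ancestral allele is lost.
#'
#' @param s selective coefficient per mutant allele, `s > 0`.
#' @param h_dom dominance coefficient, `h_dom > 1`.
#' @param m_alleles number of mutant alleles, `>= 2`.
#' @param eps initial ancestral-allele frequency.
#' @param tol convergence tolerance.
#' @param max_iter iteration cap.
#' @return List with `freqs` (equilibrium mutant-allele frequencies),
#'   `ancestral` (residual ancestral frequency), `ancestral_lost`
#'   (`ancestral < 1e-6`, i.e. far below one copy in any census-size
#'   population), and `iterations`.
#' @examples
#' multiallelic_equilibrium(0.001, 20, 3)$freqs  # ~ rep(1/3, 3)
#' @export
multiallelic_equilibrium <- function(s, h_dom, m_alleles, eps = 1e-3,
                                     tol = 1e-12, max_iter = 1000000L) {
  if (!is.finite(s) || s <= 0) stop("s must be positive", call. = FALSE)
  if (!is.finite(h_dom) || h_dom <= 1) {
    stop("no balanced equilibrium: need dominance h_dom > 1", call. = FALSE)
  }
  m <- as.integer(m_alleles)
  if (m < 2L) stop("m_alleles must be >= 2", call. = FALSE)

  # fitness matrix over alleles 1..m (mutants) and m+1 (ancestral)
  het <- 1 + h_dom * s
  W <- matrix(het^2, m + 1L, m + 1L)
  diag(W) <- 1 + s
  W[m + 1L, ] <- W[, m + 1L] <- het
  W[m + 1L, m + 1L] <- 1

  x <- c(rep((1 - eps) / m, m), eps)
  for (it in seq_len(max_iter)) {
    w_marg <- as.vector(W %*% x)
    wbar <- sum(x * w_marg)
    x_new <- x * w_marg / wbar
    if (max(abs(x_new - x)) < tol) {
      return(list(freqs = x_new[seq_len(m)], ancestral = x_new[m + 1L],
                  ancestral_lost = x_new[m + 1L] < 1e-6, iterations = it))
    }
    x <- x_new
  }
  stop("multiallelic recursion did not converge in ", max_iter,
       " iterations (last state: ",
       paste(signif(x, 6), collapse = ", "), ")", call. = FALSE)
}

#' Specification of a synthetic balancing-selection footprint
#'
#' @param x0 true equilibrium frequency: scalar in (0, 1) (biallelic) or a
#'   class-frequency vector on the simplex.
#' @param A0 true linkage-decay rate per cM, `> 0`.
#' @param center physical position (bp) of the selected locus.
#' @param n_sites number of informative sites to place.
#' @param n_samples haploid sample size at every site.
#' @param spacing distance between adjacent sites, bp.
#' @param rate recombination rate, cM per bp.
#' @param seed integer RNG seed (mandatory: datasets must be reproducible).
#' @return A `bal_footprint_spec` list.
#' @export
footprint_spec <- function(x0, A0, center = 25000L, n_sites = 2000L,
                           n_samples = 50L, spacing = 25L, rate = 1e-6,
                           seed) {
  if (missing(seed)) stop("an explicit integer seed is required",
                          call. = FALSE)
  if (!is.finite(A0) || A0 <= 0) stop("A0 must be positive", call. = FALSE)
  if (n_sites < 1L) stop("n_sites must be >= 1", call. = FALSE)
  structure(list(x0 = x0, A0 = A0, center = as.numeric(center),
                 n_sites = as.integer(n_sites),
                 n_samples = as.integer(n_samples),
                 spacing = as.numeric(spacing), rate = as.numeric(rate),
                 seed = as.integer(seed)),
            class = "bal_footprint_spec")
}

#' Generate a scan-ready dataset carrying a balancing-selection footprint
#'
#' Places `n_sites` informative sites at regular spacing around the selected
#' locus and draws each allele count from the exact mixture pmf
#' f_{n, x0, A0}(., d) at the site's recombination distance d from the
#' center. This samples from the model itself (no forward simulation), so
#' parameter-recovery of (x0, A0, center) by the scan is a well-posed check.
#' The generating truth is attached as the `"truth"` attribute and written
#' as a JSON sidecar by [write_sites()].
#'
#' @param spec a `bal_footprint_spec`.
#' @param g a `bal_spectrum` providing the neutral mixture component; must
#'   contain the stratum `n_samples`.
#' @return A `bal_sites` table with a `"truth"` attribute.
#' @export
synth_footprint <- function(spec, g) {
  stopifnot(inherits(spec, "bal_footprint_spec"))
  .check_spectrum(g)
  n <- spec$n_samples
  st <- g$strata[[as.character(n)]]
  if (is.null(st)) {
    stop("spectrum has no stratum for n = ", n, call. = FALSE)
  }
  m <- if (length(spec$x0) > 1L) length(spec$x0) else 2L
  comp <- balanced_component(n, spec$x0, g$variant, m)
  supp <- if (g$variant == "1") c(1L, n) else comp$k  # poly coded as k = 1

  offset <- (seq_len(spec$n_sites) - ceiling(spec$n_sites / 2)) * spec$spacing
  phys <- as.integer(round(spec$center + offset))
  d <- abs(offset) * spec$rate
  alpha <- exp(-spec$A0 * d)

  set.seed(spec$seed)
  k <- integer(spec$n_sites)
  for (i in seq_len(spec$n_sites)) {
    f <- alpha[i] * comp$probs + (1 - alpha[i]) * st$prob
    k[i] <- supp[sample.int(length(supp), 1L, prob = f)]
  }
  out <- site_records(phys, k = k, n = n, gen_pos = phys * spec$rate,
                      polarity = g$polarity)
  attr(out, "truth") <- list(x0 = spec$x0, A0 = spec$A0,
                             center = spec$center, variant = g$variant,
                             n_samples = n, spacing = spec$spacing,
                             rate = spec$rate, seed = spec$seed)
  out
}

#' Generate a neutral dataset by i.i.d. sampling from the background
#'
#' Each site's sample size is drawn in proportion to the per-stratum site
#' totals of the spectrum and its allele count from g_n; equivalent to
#' [synth_footprint()] in the limit A0 -> Inf.
#'
#' @param n_sites number of sites.
#' @param g a `bal_spectrum`.
#' @param seed integer RNG seed.
#' @param spacing distance between adjacent sites, bp.
#' @param start physical position of the first site.
#' @return A `bal_sites` table.
#' @export
neutral_dataset <- function(n_sites, g, seed, spacing = 25L, start = 1L) {
  .check_spectrum(g)
  if (missing(seed)) stop("an explicit integer seed is required",
                          call. = FALSE)
  n_sites <- as.integer(n_sites)
  if (n_sites < 1L) stop("n_sites must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  ns <- as.integer(names(g$strata))
  totals <- vapply(g$strata, `[[`, numeric(1), "total")
  which_n <- ns[sample.int(length(ns), n_sites, replace = TRUE,
                           prob = totals)]
  k <- integer(n_sites)
  for (n in unique(which_n)) {
    sel <- which_n == n
    st <- g$strata[[as.character(n)]]
    supp <- if (g$variant == "1") c(1L, n) else st$k
    k[sel] <- supp[sample.int(length(supp), sum(sel), replace = TRUE,
                              prob = st$prob)]
  }
  phys <- as.integer(start + (seq_len(n_sites) - 1L) * spacing)
  site_records(phys, k = k, n = which_n, polarity = g$polarity)
}

#' Synthetic genome-wide background spectrum with neutral structure
#'
#' Deterministic background tallies with the statistical shape expected of a
#' neutral equilibrium genome: polymorphic counts proportional to 1/k
#' (the standard neutral site frequency spectrum) for k = 1..n-1, plus a
#' substitution class (k = n). The default substitution load of 2.5x the
#' polymorphic total reflects a great-ape-like divergence-to-diversity
#' ratio; adjust it for other systems. Useful as the genome-wide null when
#' exercising the scan on synthetic datasets.
#'
#' @param n haploid sample size(s); one stratum per value.
#' @param poly_sites total polymorphic sites per stratum.
#' @param sub_sites substitution count per stratum (default
#'   `round(2.5 * poly_sites)`).
#' @return A derived-polarity `bal_sfs` (fold with [fold_background()] for
#'   the minor-allele variants).
#' @export
neutral_background <- function(n, poly_sites = 2e5,
                               sub_sites = round(2.5 * poly_sites)) {
  rows <- lapply(as.integer(n), function(nn) {
    if (nn < 2L) stop("sample size n must be >= 2", call. = FALSE)
    k <- seq_len(nn - 1L)
    cnt <- round(poly_sites * (1 / k) / sum(1 / k))
    data.frame(n = nn, k = c(k, nn), count = c(pmax(cnt, 1), sub_sites))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, polarity = "derived", class = c("bal_sfs", "data.frame"))
}
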