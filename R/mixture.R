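#' Exponential linkage-decay mixing weight
#'
#' The probability that a site d cM away from the test locus is completely
#' linked to one of the balanced allelic classes, alpha_A(d) = exp(-A d).
#' A (> 0, per cM) sets the footprint size: the half-width at which the
#' weight drops to 1/2 is ln(2)/A cM.
#'
#' @param A decay rate per cM, `A > 0`.
#' @param d recombination distance(s) in cM, `d >= 0`.
#' @return alpha in (0, 1], vectorized over `d`.
#' @examples
#' linkage_weight(100, log(2) / 100)  # 0.5
#' @export
linkage_weight <- function(A, d) {
  if (!is.numeric(A) || length(A) != 1L || !is.finite(A) || A <= 0) {
    stop("decay parameter A must be a positive scalar", call. = FALSE)
  }
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("distances d must be nonnegative and finite", call. = FALSE)
  }
  exp(-A * d)
}

# Normalized balanced component for a single allelic class at frequency x:
# a binomial Bin(.; n, x) truncated/folded to the variant support and
# renormalized to sum to one.  The folded variants renormalize by the actual
# numerator sum (the printed biallelic denominator 1 - (1-x)^n would leave a
# total of 1/(1 - (1-x)^n)); the deviation in shape is nil and the result is
# a proper distribution.
.class_component <- function(n, x, variant) {
  p <- stats::dbinom(0:n, n, x)  # index shift: p[k + 1] = Bin(k; n, x)
  fl <- n %/% 2L
  v <- switch(variant,
    "2" = p[2:(n + 1L)],
    "0" = p[2:n],
    "1" = {
      s <- p[n + 1L] / sum(p[2:(n + 1L)])
      c(1 - s, s)  # (polymorphic, substitution)
    },
    "2MAF" = {
      kk <- 0:fl
      p[kk + 1L] + ifelse(kk != n - kk, p[n - kk + 1L], 0)
    },
    "0MAF" = {
      kk <- seq_len(fl)
      p[kk + 1L] + ifelse(kk != n - kk, p[n - kk + 1L], 0)
    }
  )
  if (variant == "1") v else v / sum(v)
}

# Canonical class-frequency vector: biallelic scalar x -> (x, 1 - x);
# multiallelic vector on the open simplex.  Classes are exchangeable, so the
# vector is sorted nondecreasing.
.canonical_classes <- function(x, m = 2L) {
  x <- as.numeric(x)
  if (length(x) == 1L) {
    if (m != 2L) {
      stop("scalar x is biallelic; supply a frequency vector for m > 2",
           call. = FALSE)
    }
    if (!is.finite(x) || x <= 0 || x >= 1) {
      stop("equilibrium frequency x must lie strictly in (0, 1)",
           call. = FALSE)
    }
    x <- c(x, 1 - x)
  }
  if (length(x) != m) {
    stop("expected ", m, " class frequencies, got ", length(x), call. = FALSE)
  }
  if (any(x <= 0) || any(x >= 1)) {
    stop("class frequencies must lie strictly in (0, 1)", call. = FALSE)
  }
  if (abs(sum(x) - 1) > 1e-9) {
    stop("class frequencies must sum to 1", call. = FALSE)
  }
  sort(x)
}

#' Balanced allele-frequency component of the mixture model
#'
#' Distribution of the allele count k at a site completely linked to a locus
#' balancing m allelic classes at frequencies x = (x_1, ..., x_m). A site
#' linked to class i carries counts Bin(k; n, x_i) truncated/folded to the
#' variant support; classes are equally likely, so the component is the
#' uniform mixture over the m per-class normalized distributions. For m = 2
#' with classes (x, 1 - x) this is exactly the composed biallelic component
#' (h_{n,x} + h_{n,1-x}) / 2.
#'
#' @param n sample size (haploid), `n >= 2`.
#' @param x scalar equilibrium frequency in (0, 1) (biallelic), or a vector
#'   of m class frequencies on the open simplex.
#' @param variant model variant code (see [normalize_background()]).
#' @param m number of balanced allelic classes (default 2).
#' @return An object of class `bal_component`: list with the support `k`
#'   (`NULL` for variant `"1"`, whose classes are polymorphic/substitution)
#'   and probabilities `probs` summing to one.
#' @examples
#' balanced_component(2, 0.5, "2")$probs  # c(2/3, 1/3)
#' @export
balanced_component <- function(n, x, variant = "2", m = 2L) {
  variant <- .normalize_variant(variant)
  n <- as.integer(n)
  if (n < 2L) stop("sample size n must be >= 2", call. = FALSE)
  classes <- .canonical_classes(x, m)
  supp <- .variant_support(variant, n)
  if (variant != "1" && length(supp) == 0L) {
    stop("empty support for variant ", variant, " at n = ", n, call. = FALSE)
  }
  comp <- vapply(classes, function(xi) .class_component(n, xi, variant),
                 numeric(if (variant == "1") 2L else length(supp)))
  probs <- rowMeans(matrix(comp, ncol = length(classes)))
  structure(list(variant = variant, n = n, x = classes, k = supp,
                 probs = probs),
            class = "bal_component")
}

#' Mixture model parameters
#'
#' @param x equilibrium frequency (scalar, canonicalized to (0, 0.5] via the
#'   x <-> 1-x symmetry) or a vector of m class frequencies.
#' @param A linkage-decay rate per cM, `A > 0`.
#' @param variant model variant code.
#' @param m number of balanced allelic classes.
#' @return A `bal_params` list with canonical class frequencies.
#' @export
mixture_params <- function(x, A, variant = "2", m = 2L) {
  variant <- .normalize_variant(variant)
  if (!is.numeric(A) || length(A) != 1L || !is.finite(A) || A <= 0) {
    stop("decay parameter A must be a positive scalar", call. = FALSE)
  }
  classes <- .canonical_classes(x, m)
  structure(list(x = classes, A = A, variant = variant, m = as.integer(m)),
            class = "bal_params")
}

#' Per-site probability under the balancing-selection mixture
#'
#' f(k, d) = alpha_A(d) * h(k) + (1 - alpha_A(d)) * g_n(k), the marginal
#' probability of observing allele count k at a site d cM from the presumed
#' selected locus: a convex mixture of the balanced component h (see
#' [balanced_component()]) and the neutral background g_n.
#'
#' @param params a `bal_params` object from [mixture_params()].
#' @param g a `bal_spectrum` matching the params' variant.
#' @param n sample size of the site.
#' @param k allele count(s).
#' @param d recombination distance(s) from the test locus, cM.
#' @return Probability vector (recycled over `k`/`d`).
#' @export
site_probability <- function(params, g, n, k, d) {
  .check_spectrum(g)
  if (!inherits(params, "bal_params")) {
    stop("params must come from mixture_params()", call. = FALSE)
  }
  if (!identical(params$variant, g$variant)) {
    stop("params variant ", params$variant,
         " does not match spectrum variant ", g$variant, call. = FALSE)
  }
  len <- max(length(k), length(d))
  k <- rep_len(as.integer(k), len)
  d <- rep_len(as.numeric(d), len)
  gk <- .spectrum_prob(g, n, k)
  comp <- balanced_component(n, params$x, params$variant, params$m)
  idx <- .support_index(params$variant, as.integer(n), k)
  if (anyNA(idx)) {
    stop("allele count outside variant ", params$variant, " support",
         call. = FALSE)
  }
  alpha <- linkage_weight(params$A, d)
  alpha * comp$probs[idx] + (1 - alpha) * gk
}
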