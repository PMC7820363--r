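# Independent brute-force oracles and small fixtures shared across tests.
# The oracles deliberately avoid the package's internals: naive factorial
# binomials, explicit normalization sums, plain double loops over grids,
# and exhaustive enumeration for the exact HWE test.

make_sfs <- function(n, k, count, polarity = "derived") {
  structure(data.frame(n = as.integer(n), k = as.integer(k),
                       count = as.numeric(count)),
            polarity = polarity, class = c("bal_sfs", "data.frame"))
}

# toy background: 8 singleton-ish sites and 2 substitutions at n = 2
toy_bg <- make_sfs(2L, c(1L, 2L), c(8, 2))

# binomial pmf by naive factorial arithmetic (exact for small n)
naive_binom <- function(k, n, x) {
  factorial(n) / (factorial(k) * factorial(n - k)) * x^k * (1 - x)^(n - k)
}

naive_support <- function(variant, n) {
  switch(variant,
    "2" = 1:n, "0" = 1:(n - 1), "2MAF" = 0:(n %/% 2),
    "0MAF" = 1:(n %/% 2), "1" = c("poly", "sub"))
}

# one allelic class, truncated/folded to the variant support, normalized by
# the explicit numerator sum
naive_class_component <- function(n, x, variant) {
  if (variant == "1") {
    v2 <- naive_class_component(n, x, "2")
    s <- v2[n]
    return(c(poly = 1 - s, sub = s))
  }
  supp <- naive_support(variant, n)
  v <- vapply(supp, function(k) {
    out <- naive_binom(k, n, x)
    if (variant %in% c("2MAF", "0MAF") && k != n - k) {
      out <- out + naive_binom(n - k, n, x)
    }
    out
  }, numeric(1))
  v / sum(v)
}

naive_component <- function(n, classes, variant) {
  if (length(classes) == 1L) classes <- c(classes, 1 - classes)
  comps <- sapply(classes, function(x) naive_class_component(n, x, variant))
  rowMeans(matrix(comps, ncol = length(classes)))
}

# neutral probabilities straight from the raw counts
naive_g <- function(bg, variant, n) {
  sub <- bg[bg$n == n, ]
  cnt <- function(k) {
    s <- sub$count[sub$k == k]
    if (length(s)) sum(s) else 0
  }
  if (variant == "1") {
    tot <- sum(sub$count)
    return(c(poly = 1 - cnt(n) / tot, sub = cnt(n) / tot))
  }
  supp <- naive_support(variant, n)
  v <- vapply(supp, cnt, numeric(1))
  v / sum(v)
}

# variant "1" vectors are ordered (poly, sub) by construction
naive_g_lookup <- function(gtab, variant, n, k) {
  if (variant == "1") {
    return(unname(gtab[[as.character(n)]][if (k == n) 2L else 1L]))
  }
  supp <- naive_support(variant, n)
  unname(gtab[[as.character(n)]][match(k, supp)])
}

naive_h_lookup <- function(htab, variant, n, k) {
  if (variant == "1") {
    return(unname(htab[[as.character(n)]][if (k == n) 2L else 1L]))
  }
  supp <- naive_support(variant, n)
  unname(htab[[as.character(n)]][match(k, supp)])
}

# plain double-loop grid maximization of the composite likelihood ratio
naive_B <- function(test_pos, sites, bg, variant, x_grid, A_grid,
                    cutoff = 1e-8, rate = 1e-6, m = 2L) {
  gp <- if (all(!is.na(sites$gen_pos))) sites$gen_pos else
    sites$phys_pos * rate
  tg <- gp[match(test_pos, sites$phys_pos)]
  d <- abs(gp - tg)
  ns <- sort(unique(sites$n))
  gtab <- lapply(stats::setNames(ns, ns),
                 function(n) naive_g(bg, variant, n))
  best <- 0
  best_x <- NA
  best_a <- NA
  for (A in A_grid) {
    for (xg in x_grid) {
      htab <- lapply(stats::setNames(ns, ns),
                     function(n) naive_component(n, xg, variant))
      ll <- 0
      for (i in seq_len(nrow(sites))) {
        alpha <- exp(-A * d[i])
        if (alpha < cutoff) next
        gk <- naive_g_lookup(gtab, variant, sites$n[i], sites$k[i])
        hk <- naive_h_lookup(htab, variant, sites$n[i], sites$k[i])
        f <- alpha * hk + (1 - alpha) * gk
        ll <- ll + log(f) - log(gk)
      }
      if (ll > best) {
        best <- ll
        best_x <- if (length(xg) == 1L) xg else list(xg)
        best_a <- A
      }
    }
  }
  list(B = 2 * best, x_hat = best_x, A_hat = best_a)
}

# exact HWE heterozygote-excess tail by exhaustive enumeration of genotype
# assignments: each of the N individuals is AA/Aa/aa, weight 2^(#het) for
# the two allele orderings, conditioned on the total A-allele count
naive_hwe_tail <- function(n_AA, n_Aa, n_aa) {
  N <- n_AA + n_Aa + n_aa
  nA <- 2L * n_AA + n_Aa
  copies <- as.matrix(expand.grid(rep(list(0:2), N)))
  keep <- rowSums(copies) == nA
  if (!any(keep)) return(NA_real_)
  copies <- copies[keep, , drop = FALSE]
  hets <- rowSums(copies == 1L)
  w <- 2^hets
  sum(w[hets >= n_Aa]) / sum(w)
}

# moderately sized background fixture for scans (deterministic)
fixture_g <- function(variant = "2", n = 50L, poly = 2e4) {
  bg <- neutral_background(n, poly_sites = poly)
  if (balscan:::.variant_polarity(balscan:::.normalize_variant(variant)) ==
        "minor") {
    bg <- fold_background(bg)
  }
  normalize_background(bg, variant)
}
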