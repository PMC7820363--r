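test_that("overdominance recursion reproduces the reported equilibria", {
  # heterozygote advantage with fitnesses 1 : 1+hs : 1+s
  expect_equal(overdominance_equilibrium(0.01, 3)$minor, 0.4,
               tolerance = 1e-9)
  expect_equal(overdominance_equilibrium(0.01, 1.75)$minor, 0.3,
               tolerance = 1e-9)
  expect_equal(round(overdominance_equilibrium(0.01, 1.33)$minor, 1), 0.2)
  # strong dominance: symmetric overdominance limit
  expect_equal(overdominance_equilibrium(0.01, 1e6)$minor, 0.5,
               tolerance = 1e-4)
  expect_error(overdominance_equilibrium(0.01, 0.9), "h_dom > 1")
})

test_that("equilibrium matches the closed form and is independent of s", {
  for (h in c(1.2, 1.75, 3, 20)) {
    closed <- h / (2 * h - 1)
    eqs <- vapply(c(1e-4, 1e-3, 1e-2),
                  function(s) overdominance_equilibrium(s, h)$derived,
                  numeric(1))
    expect_equal(eqs, rep(closed, 3), tolerance = 1e-9)
    expect_lt(max(eqs) - min(eqs), 1e-9)
  }
})

test_that("mean fitness is nondecreasing along the recursion", {
  s <- 0.01
  h <- 3
  wAA <- 1 + s
  wAa <- 1 + h * s
  p <- 0.05
  wbars <- numeric(200)
  for (it in 1:200) {
    q <- 1 - p
    wA <- p * wAA + q * wAa
    wa <- p * wAa + q
    wbar <- p * wA + q * wa
    wbars[it] <- wbar
    p <- p * wA / wbar
  }
  expect_true(all(diff(wbars) >= -1e-15))
})

test_that("multiallelic recursion balances m mutants at 1/m, losing the
           ancestral allele", {
  for (m in 2:4) {
    eq <- multiallelic_equilibrium(0.001, 20, m)
    expect_equal(eq$freqs, rep(1 / m, m), tolerance = 1e-4)
    expect_true(eq$ancestral_lost)
  }
  expect_error(multiallelic_equilibrium(0.001, 0.5, 3), "h_dom > 1")
})

test_that("multiallelic m = 2 agrees with the biallelic calculator after
           ancestral loss, and the symmetric point is stable", {
  eq2 <- multiallelic_equilibrium(0.001, 20, 2)
  # post-ancestral-loss state: two balanced mutants; the biallelic
  # overdominance equilibrium between them is symmetric
  expect_equal(eq2$freqs[1], eq2$freqs[2], tolerance = 1e-9)
  expect_equal(eq2$freqs[1], 0.5, tolerance = 1e-6)

  # perturb the symmetric start: same fixed point
  base <- multiallelic_equilibrium(0.001, 20, 3)
  pert <- multiallelic_equilibrium(0.001, 20, 3, eps = 1e-3 + 1e-4)
  expect_equal(base$freqs, pert$freqs, tolerance = 1e-6)
})

test_that("synthetic footprints are reproducible and match the spectrum in
           the unlinked limit", {
  g <- fixture_g("2", n = 20L, poly = 2e4)
  spec <- footprint_spec(x0 = 0.3, A0 = 500, center = 5000, n_sites = 200,
                         n_samples = 20L, spacing = 25, seed = 21)
  a <- synth_footprint(spec, g)
  b <- synth_footprint(spec, g)
  expect_identical(a$k, b$k)
  expect_identical(attr(a, "truth")$x0, 0.3)

  # A0 -> Inf: i.i.d. draws from g; chi-square GOF should not reject
  far <- footprint_spec(x0 = 0.3, A0 = 1e12, center = 5000, n_sites = 400,
                        n_samples = 20L, spacing = 25, seed = 1)
  pvals <- vapply(1:10, function(s) {
    far$seed <- s
    ds <- synth_footprint(far, g)
    obs <- tabulate(ds$k, nbins = 20)
    expected <- g$strata[["20"]]$prob
    keep <- expected * nrow(ds) >= 1
    suppressWarnings(stats::chisq.test(obs[keep],
                                       p = expected[keep] / sum(expected[keep]))$p.value)
  }, numeric(1))
  expect_gt(min(pvals), 0.001)
  expect_gt(mean(pvals > 0.05), 0.5)
})

test_that("fully linked sites at the equilibrium frequency obey the law of
           large numbers", {
  g <- fixture_g("2", n = 2L, poly = 2e4)
  spec <- footprint_spec(x0 = 0.5, A0 = 1e-9, center = 5000,
                         n_sites = 4000, n_samples = 2L, spacing = 1,
                         seed = 9)
  ds <- synth_footprint(spec, g)
  # alpha ~ 1 everywhere: k = 1 occurs with probability h(1) = 2/3
  expect_equal(mean(ds$k == 1), 2 / 3, tolerance = 0.03)
})

test_that("neutral datasets reproduce the per-stratum weights of g", {
  bg <- neutral_background(c(10L, 20L), poly_sites = c(1e4))
  bg$count[bg$n == 20] <- bg$count[bg$n == 20] * 3  # unequal strata
  g <- normalize_background(bg, "2")
  ds <- neutral_dataset(3000L, g, seed = 2)
  tot <- vapply(g$strata, `[[`, numeric(1), "total")
  expect_equal(mean(ds$n == 20), tot[["20"]] / sum(tot), tolerance = 0.05)
  expect_identical(neutral_dataset(50L, g, seed = 3)$k,
                   neutral_dataset(50L, g, seed = 3)$k)
})
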