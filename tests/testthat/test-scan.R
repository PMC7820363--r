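test_that("null composite log-likelihood is the sum of log backgrounds", {
  g <- normalize_background(toy_bg, "2")
  one <- site_records(10L, k = 1L, n = 2L)
  expect_equal(null_loglik(one, g), log(0.8))
  two <- site_records(c(10L, 20L), k = c(1L, 1L), n = 2L)
  expect_equal(null_loglik(two, g), 2 * log(0.8))
  # order invariance
  mixed <- site_records(c(10L, 20L, 30L), k = c(1L, 2L, 1L), n = 2L)
  perm <- site_records(c(30L, 10L, 20L), k = c(1L, 1L, 2L), n = 2L)
  expect_equal(null_loglik(mixed, g), null_loglik(perm, g))
})

test_that("alternative log-likelihood matches hand values and the null limit", {
  g <- normalize_background(toy_bg, "2")
  one <- site_records(10L, k = 1L, n = 2L)
  p <- mixture_params(0.5, A = 100)
  expect_equal(alt_loglik(one, 0, p, g), log(2 / 3))
  # all mixing weights below the cutoff: identical to the null
  pfar <- mixture_params(0.5, A = 1e6)
  expect_equal(alt_loglik(one, 1, pfar, g, alpha_cutoff = 1e-8),
               null_loglik(one, g))
})

test_that("alt_loglik equals a naive per-site product oracle", {
  set.seed(42)
  g <- fixture_g("2", n = 20L)
  k <- sample(1:20, 100, replace = TRUE,
              prob = g$strata[["20"]]$prob)
  s <- site_records(seq(100L, by = 50L, length.out = 100L), k = k, n = 20L)
  d <- abs(seq_len(100) - 50) * 5e-5
  p <- mixture_params(0.25, A = 300)
  htab <- naive_component(20, 0.25, "2")
  gvec <- naive_g(neutral_background(20L, poly_sites = 2e4), "2", 20)
  oracle <- sum(log(exp(-300 * d) * htab[k] + (1 - exp(-300 * d)) * gvec[k]))
  expect_equal(alt_loglik(s, d, p, g), oracle, tolerance = 1e-9)
})

test_that("compute_B equals brute-force grid maximization for all variants", {
  x_grid <- seq(0.1, 0.5, by = 0.1)
  A_grid <- c(50, 500, 5000)
  set.seed(7)
  for (v in c("2", "1", "0", "2MAF", "0MAF")) {
    n <- 12L
    bg <- neutral_background(n, poly_sites = 1e4)
    if (grepl("MAF", v)) bg <- fold_background(bg)
    g <- normalize_background(bg, v)
    spec <- footprint_spec(x0 = 0.25, A0 = 500, center = 5000,
                           n_sites = 100, n_samples = n, spacing = 50,
                           rate = 1e-6, seed = 11)
    ds <- synth_footprint(spec, g)
    cfg <- scan_config(v, x_grid = x_grid, A_grid = A_grid)
    tp <- ds$phys_pos[50]
    got <- compute_B(tp, ds, g, cfg)
    want <- naive_B(tp, ds, bg, v, x_grid, A_grid)
    expect_equal(got$B, want$B, tolerance = 1e-9)
    if (want$B > 0) {
      expect_equal(min(got$x_hat, 1 - got$x_hat), want$x_hat)
      expect_equal(got$A_hat, want$A_hat)
    }
  }
})

test_that("multiallelic path with m = 3 matches the brute-force oracle", {
  n <- 10L
  bg <- neutral_background(n, poly_sites = 1e4)
  g <- normalize_background(bg, "2")
  x_grid3 <- list(c(0.2, 0.3, 0.5), c(1, 1, 1) / 3, c(0.1, 0.1, 0.8))
  A_grid <- c(100, 1000)
  spec <- footprint_spec(x0 = c(0.2, 0.3, 0.5), A0 = 1000, center = 2500,
                         n_sites = 100, n_samples = n, spacing = 50,
                         seed = 3)
  ds <- synth_footprint(spec, g)
  cfg <- scan_config("2", m = 3L, x_grid = x_grid3, A_grid = A_grid)
  tp <- ds$phys_pos[50]
  got <- compute_B(tp, ds, g, cfg)
  want <- naive_B(tp, ds, bg, "2", x_grid3, A_grid, m = 3L)
  expect_equal(got$B, want$B, tolerance = 1e-9)
})

test_that("m = 2 multiallelic grid reproduces the biallelic scan exactly", {
  g <- fixture_g("2", n = 20L, poly = 2e4)
  spec <- footprint_spec(x0 = 0.3, A0 = 800, center = 10000, n_sites = 300,
                         n_samples = 20L, spacing = 40, seed = 5)
  ds <- synth_footprint(spec, g)
  cfg2 <- scan_config("2", m = 2L, x_step = 0.05, test_every = 25L)
  grid_m <- lapply(seq(0.05, 0.5, 0.05), function(x) c(x, 1 - x))
  cfgm <- scan_config("2", m = 2L, x_grid = grid_m, test_every = 25L)
  r2 <- scan(ds, g, cfg2)
  rm_ <- scan(ds, g, cfgm)
  expect_equal(r2$B, rm_$B, tolerance = 1e-12)
  expect_equal(r2$x_hat, rm_$x_hat)
  expect_equal(r2$A_hat, rm_$A_hat)

  gmaf <- fixture_g("2MAF", n = 20L, poly = 2e4)
  dsm <- ds
  dsm$k <- pmin(dsm$k, dsm$n - dsm$k)
  attr(dsm, "polarity") <- "minor"
  cfg2m <- scan_config("2MAF", x_step = 0.05, test_every = 25L)
  cfgmm <- scan_config("2MAF", x_grid = grid_m, test_every = 25L)
  expect_equal(scan(dsm, gmaf, cfg2m)$B, scan(dsm, gmaf, cfgmm)$B,
               tolerance = 1e-12)
})

test_that("B is nonnegative on neutral data and zero rows carry sentinels", {
  g <- fixture_g("2", n = 10L)
  for (seed in 1:25) {
    ds <- neutral_dataset(40L, g, seed = seed, spacing = 100L)
    res <- scan(ds, g, scan_config("2", x_step = 0.1, test_every = 10L))
    expect_true(all(res$B >= 0))
    zero <- res$B == 0
    expect_true(all(is.na(res$x_hat[zero])))
    expect_true(all(is.na(res$A_hat[zero])))
    expect_true(all(!is.na(res$x_hat[!zero])))
  }
})

test_that("scan rows equal independent compute_B calls (caching is inert)", {
  g <- fixture_g("2", n = 10L)
  ds <- neutral_dataset(30L, g, seed = 99, spacing = 200L)
  cfg <- scan_config("2", x_step = 0.1)
  res <- scan(ds, g, cfg)
  for (i in seq(1, 30, by = 7)) {
    solo <- compute_B(ds$phys_pos[i], ds, g, cfg)
    expect_equal(res$B[i], solo$B)
    expect_equal(res$x_hat[i], solo$x_hat)
  }
})

test_that("translation of physical positions leaves B unchanged", {
  g <- fixture_g("2", n = 10L)
  ds <- neutral_dataset(30L, g, seed = 4, spacing = 100L)
  shifted <- site_records(ds$phys_pos + 70000L, k = ds$k, n = ds$n)
  cfg <- scan_config("2", x_step = 0.1, test_every = 5L)
  expect_equal(scan(ds, g, cfg)$B, scan(shifted, g, cfg)$B)
})

test_that("sites below the cutoff for every A do not change B", {
  g <- fixture_g("2", n = 10L)
  ds <- neutral_dataset(30L, g, seed = 12, spacing = 50L)
  cfg <- scan_config("2", x_step = 0.1, A_grid = c(100, 1000, 10000))
  base <- compute_B(ds$phys_pos[15], ds, g, cfg)
  # a site ~10 cM away: alpha < 1e-8 for every A in the grid
  far <- site_records(c(ds$phys_pos, 10100000L), k = c(ds$k, 5L),
                      n = 10L)
  with_far <- compute_B(ds$phys_pos[15], far, g, cfg)
  expect_equal(with_far$B, base$B, tolerance = 1e-9)
})

test_that("window radius shrinks as A grows", {
  cutoff <- 1e-8
  radii <- log(1 / cutoff) / 10^seq(0, 5, length.out = 20)
  expect_true(all(diff(radii) < 0))
})

test_that("test-site policies thin deterministically and reject bad input", {
  g <- fixture_g("2", n = 10L)
  ds <- neutral_dataset(10L, g, seed = 8, spacing = 100L)
  cfg <- scan_config("2", x_step = 0.1, test_every = 2L)
  res <- scan(ds, g, cfg)
  expect_equal(nrow(res), 5L)
  expect_equal(res$phys_pos, ds$phys_pos[c(1, 3, 5, 7, 9)])

  cfge <- scan_config("2", x_step = 0.1,
                      test_positions = ds$phys_pos[c(2, 4)])
  expect_equal(scan(ds, g, cfge)$phys_pos, ds$phys_pos[c(2, 4)])

  dup <- ds
  dup$phys_pos[2] <- dup$phys_pos[1]
  expect_error(scan(dup, g, cfg), "sorted")
})
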