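#' Configuration of a composite likelihood ratio scan
#'
#' @param variant model variant code (`"2"`, `"2MAF"`, `"1"`, `"0"`,
#'   `"0MAF"`, or the aliases `"B2"`, `"B2maf"`, ...).
#' @param m number of balanced allelic classes assumed by the alternative
#'   model (fixed, not optimized over).
#' @param x_step grid step for equilibrium frequencies; the default biallelic
#'   grid is `seq(x_step, 0.5, x_step)` (the composed component is symmetric
#'   under x <-> 1-x, so (0, 0.5] covers all models). For m > 2 the grid is
#'   all simplex compositions of 1 in multiples of `x_step` with every class
#'   `>= x_step`, deduplicated under permutation.
#' @param x_grid optional explicit frequency grid: numeric vector (biallelic)
#'   or list of class-frequency vectors (multiallelic); overrides `x_step`.
#' @param A_grid optional explicit decay grid (per cM); default 20 values
#'   log-uniform on \[1, 1e5\], spanning footprint half-widths ln(2)/A from
#'   about 0.7 cM down to 7e-6 cM. The degenerate null (alpha = 0) is always
#'   a candidate, so B >= 0.
#' @param alpha_cutoff minimum mixing weight for a site to enter the window
#'   of a candidate A (default 1e-8); sites below the cutoff contribute equal
#'   terms to both likelihoods and are skipped.
#' @param rec_rate recombination rate in cM per bp used when sites carry no
#'   genetic positions (default 1e-6, roughly 1 cM/Mb).
#' @param test_every compute the statistic at every `test_every`-th
#'   informative site (default 1: every site).
#' @param test_positions optional explicit physical test positions,
#'   overriding `test_every`.
#' @return A `bal_scan_config` list.
#' @export
scan_config <- function(variant = "2", m = 2L, x_step = 0.01, x_grid = NULL,
                        A_grid = NULL, alpha_cutoff = 1e-8, rec_rate = 1e-6,
                        test_every = 1L, test_positions = NULL) {
  variant <- .normalize_variant(variant)
  m <- as.integer(m)
  if (m < 2L) stop("m must be >= 2", call. = FALSE)
  if (!is.null(x_grid)) {
    grid <- if (is.list(x_grid)) x_grid else as.list(x_grid)
    grid <- lapply(grid, .canonical_classes, m = m)
  } else {
    if (x_step <= 0 || x_step > 0.5) stop("x_step must be in (0, 0.5]",
                                          call. = FALSE)
    grid <- if (m == 2L) {
      lapply(seq(x_step, 0.5 + 1e-12, by = x_step),
             function(x) sort(c(min(x, 0.5), 1 - min(x, 0.5))))
    } else {
      .simplex_grid(m, x_step)
    }
  }
  if (length(grid) == 0L) stop("empty x grid", call. = FALSE)
  # deterministic lexicographic order (tie-breaks pick the first maximum)
  ord <- do.call(order, as.data.frame(t(vapply(grid, identity,
                                               numeric(m)))))
  grid <- grid[ord]
  grid <- grid[!duplicated(vapply(grid, paste, "", collapse = ","))]
  if (is.null(A_grid)) A_grid <- 10^seq(0, 5, length.out = 20L)
  A_grid <- sort(as.numeric(A_grid))
  if (any(A_grid <= 0)) stop("A grid must be positive", call. = FALSE)
  if (alpha_cutoff <= 0 || alpha_cutoff >= 1) {
    stop("alpha_cutoff must be in (0, 1)", call. = FALSE)
  }
  structure(list(variant = variant, m = m, x_grid = grid, A_grid = A_grid,
                 alpha_cutoff = alpha_cutoff, rec_rate = rec_rate,
                 test_every = as.integer(test_every),
                 test_positions = test_positions),
            class = "bal_scan_config")
}

# All compositions of 1 into m parts in multiples of `step`, each part
# >= step, sorted nondecreasing within a composition, unique.
.simplex_grid <- function(m, step) {
  units <- round(1 / step)
  if (abs(units * step - 1) > 1e-9) {
    stop("x_step must divide 1 for a multiallelic grid", call. = FALSE)
  }
  rec <- function(parts_left, units_left, min_units) {
    if (parts_left == 1L) {
      if (units_left >= min_units) return(list(units_left))
      return(list())
    }
    out <- list()
    for (u in min_units:(units_left %/% parts_left)) {
      for (tail in rec(parts_left - 1L, units_left - u, u)) {
        out[[length(out) + 1L]] <- c(u, tail)
      }
    }
    out
  }
  lapply(rec(m, units, 1L), function(u) u * step)
}

#' Composite log-likelihood under neutrality
#'
#' ln L0 = sum_i ln g_{n_i}(k_i): the product over informative sites of the
#' genome-wide background probabilities, treating sites as independent.
#'
#' @param sites a `bal_sites` table.
#' @param g a `bal_spectrum`.
#' @return Scalar log composite likelihood.
#' @export
null_loglik <- function(sites, g) {
  .check_sites(sites)
  .check_spectrum(g)
  sum(log(.spectrum_prob(g, sites$n, sites$k)))
}

#' Composite log-likelihood under the balancing-selection mixture
#'
#' ln La(x, A) = sum_i ln f_{n_i, x, A}(k_i, d_i). With a positive
#' `alpha_cutoff`, sites whose mixing weight falls below the cutoff
#' contribute their neutral term ln g instead (numerically
#' indistinguishable, and identical to how the scan windows sites).
#'
#' @param sites a `bal_sites` table.
#' @param d distances (cM) from the test locus, one per site.
#' @param params a `bal_params` object.
#' @param g a `bal_spectrum`.
#' @param alpha_cutoff drop the balanced component below this mixing weight
#'   (default 0: never).
#' @return Scalar log composite likelihood.
#' @export
alt_loglik <- function(sites, d, params, g, alpha_cutoff = 0) {
  .check_sites(sites)
  .check_spectrum(g)
  if (length(d) != nrow(sites)) {
    stop("need one distance per site", call. = FALSE)
  }
  if (any(d < 0)) stop("distances must be nonnegative", call. = FALSE)
  ll <- 0
  for (n in unique(sites$n)) {
    sel <- sites$n == n
    f <- site_probability(params, g, n, sites$k[sel], d[sel])
    gk <- .spectrum_prob(g, n, sites$k[sel])
    alpha <- linkage_weight(params$A, d[sel])
    use_null <- alpha < alpha_cutoff
    ll <- ll + sum(log(ifelse(use_null, gk, f)))
  }
  ll
}

# Precompute the stacked balanced-component matrix H for a scan: one row per
# (n, support cell) across the strata present in `n_values`, one column per
# x-grid entry; plus per-site row offsets.  Reused across all test sites.
.scan_tables <- function(g, config, n_values) {
  ns <- sort(unique(as.integer(n_values)))
  offsets <- integer(0)
  blocks <- list()
  off <- 0L
  for (n in ns) {
    supp_len <- if (config$variant == "1") 2L else
      length(.variant_support(config$variant, n))
    block <- matrix(0, nrow = supp_len, ncol = length(config$x_grid))
    for (j in seq_along(config$x_grid)) {
      block[, j] <- balanced_component(n, config$x_grid[[j]], config$variant,
                                       config$m)$probs
    }
    blocks[[as.character(n)]] <- block
    offsets[as.character(n)] <- off
    off <- off + supp_len
  }
  list(H = do.call(rbind, blocks), offsets = offsets)
}

.site_rows <- function(variant, sites, offsets) {
  idx <- .support_index(variant, sites$n, sites$k)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop("allele count k = ", sites$k[bad], " outside variant ", variant,
         " support at position ", sites$phys_pos[bad], call. = FALSE)
  }
  offsets[as.character(sites$n)] + idx - 1L  # 0-based for the C++ core
}

.format_xhat <- function(classes, m) {
  if (is.null(classes)) return(if (m == 2L) NA_real_ else NA_character_)
  if (m == 2L) min(classes) else paste(signif(classes, 6), collapse = ",")
}

#' Composite likelihood ratio statistic at one test position
#'
#' Maximizes the alternative composite likelihood over the (x, A) grid and
#' returns B = 2 \[ln La(x^, A^) - ln L0\]. For each candidate A only sites
#' with mixing weight alpha_A(d) >= `alpha_cutoff` enter (sites beyond the
#' radius ln(1/cutoff)/A contribute equal terms to both likelihoods). The
#' candidate set always includes the degenerate neutral model, so B >= 0;
#' when no alternative beats the null the estimates are NA sentinels. Ties
#' resolve to the smallest A, then the lexicographically smallest x.
#'
#' @param test_pos physical test position (bp).
#' @param sites a `bal_sites` table, sorted, single scaffold.
#' @param g a `bal_spectrum` matching the config's variant.
#' @param config a `bal_scan_config`.
#' @return One-row `data.frame`: `phys_pos`, `gen_pos`, `B`, `x_hat`,
#'   `A_hat`, `n_sites` (informative sites in the window at A^).
#' @export
compute_B <- function(test_pos, sites, g, config = scan_config()) {
  .check_sites(sites)
  .check_spectrum(g)
  stopifnot(inherits(config, "bal_scan_config"))
  if (!identical(config$variant, g$variant)) {
    stop("config variant ", config$variant,
         " does not match spectrum variant ", g$variant, call. = FALSE)
  }
  gp <- .genetic_positions(sites, config$rec_rate)
  test_gen <- if (test_pos %in% sites$phys_pos) {
    gp[match(test_pos, sites$phys_pos)]
  } else {
    stats::approx(sites$phys_pos, gp, xout = test_pos, rule = 2)$y
  }
  tables <- .scan_tables(g, config, sites$n)
  .compute_B_core(test_pos, test_gen, sites, gp, g, config, tables)
}

.compute_B_core <- function(test_pos, test_gen, sites, gp, g, config,
                            tables) {
  dist <- abs(gp - test_gen)
  gk <- .spectrum_prob(g, sites$n, sites$k)
  rows <- .site_rows(config$variant, sites, tables$offsets)
  res <- scan_core_cpp(dist, rows, gk, tables$H, config$A_grid,
                       config$alpha_cutoff)
  if (res$best <= 0) {
    data.frame(phys_pos = test_pos, gen_pos = test_gen, B = 0,
               x_hat = .format_xhat(NULL, config$m), A_hat = NA_real_,
               n_sites = res$n_window, stringsAsFactors = FALSE)
  } else {
    data.frame(phys_pos = test_pos, gen_pos = test_gen, B = 2 * res$best,
               x_hat = .format_xhat(config$x_grid[[res$x_idx]], config$m),
               A_hat = config$A_grid[res$a_idx], n_sites = res$n_sites,
               stringsAsFactors = FALSE)
  }
}

#' Scan a scaffold for footprints of balancing selection
#'
#' Computes the B statistic at every informative site (or a thinned or
#' explicit set of test positions). Results are identical to independent
#' [compute_B()] calls; component tables are cached across test sites.
#'
#' @inheritParams compute_B
#' @return A `data.frame` of class `bal_scan`, one row per test position,
#'   ordered by position. No multiple-testing correction is applied; scores
#'   are meant to be ranked, with significance assessed externally.
#' @export
scan <- function(sites, g, config = scan_config()) {
  .check_sites(sites)
  .check_spectrum(g)
  stopifnot(inherits(config, "bal_scan_config"))
  if (!identical(config$variant, g$variant)) {
    stop("config variant ", config$variant,
         " does not match spectrum variant ", g$variant, call. = FALSE)
  }
  if (is.unsorted(sites$phys_pos, strictly = TRUE)) {
    stop("sites must be sorted by position without duplicates ",
         "(single scaffold per scan)", call. = FALSE)
  }
  gp <- .genetic_positions(sites, config$rec_rate)
  test_pos <- if (!is.null(config$test_positions)) {
    sort(unique(as.numeric(config$test_positions)))
  } else {
    sites$phys_pos[seq(1L, nrow(sites), by = config$test_every)]
  }
  tables <- .scan_tables(g, config, sites$n)
  rows <- lapply(test_pos, function(tp) {
    tg <- if (tp %in% sites$phys_pos) gp[match(tp, sites$phys_pos)] else
      stats::approx(sites$phys_pos, gp, xout = tp, rule = 2)$y
    .compute_B_core(tp, tg, sites, gp, g, config, tables)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("bal_scan", "data.frame")
  attr(out, "variant") <- config$variant
  attr(out, "m") <- config$m
  out
}
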