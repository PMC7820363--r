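---
title: "Mixture-model composite likelihood scans for balancing selection"
author: "balscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture-model composite likelihood scans for balancing selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(balscan)
```

## The model

Long-term balancing selection holds two or more alleles at a locus near an
equilibrium frequency for timescales long enough that linked neutral
variation accumulates an excess of intermediate-frequency polymorphism. The
scan statistic implemented here models the allele count $k$ (out of $n$
sampled alleles) at an informative site $d$ centimorgans from a putatively
selected test site as a two-component mixture:

$$f_{n,x,A}(k, d) \;=\; \alpha_A(d)\, h_{n,x}(k) \;+\;
  \bigl[1 - \alpha_A(d)\bigr]\, g_n(k),$$

where

* $g_n(k)$ is the *genome-wide* site frequency spectrum (SFS), normalized
  per sample size $n$ — the empirical distribution of allele counts under
  whatever demography, average mutation and recombination processes shaped
  the genome as a whole;
* $h_{n,x}(k)$ is the *balanced* component: a site completely linked to a
  balanced allelic class at equilibrium frequency $x$ carries $k \sim
  \mathrm{Bin}(n, x)$, truncated and renormalized to the observable support;
* $\alpha_A(d) = e^{-A d}$ is the probability that a site $d$ cM away is
  completely linked to one of the balanced classes. The free decay rate
  $A > 0$ (per cM) sets the footprint size: the weight halves every
  $\ln 2 / A$ cM, so small $A$ describes wide footprints and large $A$
  narrow ones.

Treating informative sites as independent (a composite-likelihood
simplification; neighboring sites are in reality correlated by linkage),
the null composite likelihood of a region is $L_0 = \prod_i g_{n_i}(k_i)$
and the alternative is $L_a(x, A) = \prod_i f_{n_i,x,A}(k_i, d_i)$. The
test statistic at a site is

$$B \;=\; 2\bigl[\ln L_a(\hat x, \hat A) - \ln L_0\bigr],$$

maximized over a grid of $(x, A)$ that always includes the degenerate
neutral model ($\alpha \equiv 0$), so $B \ge 0$ by construction. Because
the informative sites entering each test and their correlation structure
vary along the genome, $B$ does not follow a $\chi^2$ distribution;
scores are meant to be *ranked*, with significance assessed against
simulations under an explicit demographic model. The package deliberately
performs no $P$-value calibration or multiple-testing correction.

### Data-type variants

Five variants differ only in what the data provide; all share the mixture
construction. "Substitution" means the sample is fixed for an allele that
differs from the outgroup.

| variant | counts | support |
|---|---|---|
| `2` | derived, polymorphisms + substitutions | $k = 1..n$ |
| `0` | derived, polymorphisms only | $k = 1..n-1$ |
| `1` | polymorphism/substitution dichotomy | 2 classes |
| `2MAF` | minor (folded), polymorphisms + substitutions | $k = 0..\lfloor n/2\rfloor$ |
| `0MAF` | minor, polymorphisms only | $k = 1..\lfloor n/2\rfloor$ |

For the derived variants the balanced component composes the two allelic
classes symmetrically, $\tfrac12 h_{n,x} + \tfrac12 h_{n,1-x}$, which makes
it invariant under $x \leftrightarrow 1-x$; the $x$ grid therefore covers
$(0, 0.5]$ only. For the folded variants the binomial is folded onto minor
counts. One normalization choice deserves a note: the folded component is
renormalized by the actual sum of its folded numerator so that it is a
probability distribution exactly (summing the folded binomial over
$k = 0..\lfloor n/2\rfloor$ already yields 1; dividing instead by
$1-(1-x)^n$ would leave a total of $1/(1-(1-x)^n)$). The deviation from the
unrenormalized form is $O((1-x)^n)$ and vanishes for moderate $n$.

### Multiallelic loci

For a locus balancing $m > 2$ allelic classes at frequencies
$x_1, \dots, x_m$ (summing to 1), a linked neutral site hitchhikes with one
class, equally likely each, so the balanced component is the uniform
mixture of per-class components:

$$h^{(m)}_{n,\mathbf{x}}(k) \;=\; \frac1m \sum_{i=1}^m h_{n,x_i}(k).$$

Each class component is normalized *before* mixing. This is the design
choice that makes the extension exactly nested: with $m = 2$ and classes
$(x, 1-x)$ the expression reduces bit-for-bit to the composed biallelic
component above (mixing unnormalized binomial kernels first and normalizing
afterwards would not, because the per-class truncation denominators
differ). Class labels are exchangeable, so class vectors are canonicalized
in nondecreasing order, and the multiallelic grid enumerates simplex
compositions deduplicated under permutation. The class count $m$ is fixed
by the user, not optimized over; in practice a larger $m$ than the truth is
benign, as surplus classes are driven towards low frequencies.

## Parameters that matter

* **`x_step` / `x_grid`** — equilibrium-frequency grid, default
  $0.01, 0.02, \dots, 0.50$. A fine grid is cheap for biallelic scans; for
  $m \ge 3$ the number of simplex compositions grows quickly, and a step of
  0.05–0.1 is a practical choice.
* **`A_grid`** — default 20 values log-uniform on $[10^0, 10^5]$ per cM,
  i.e. footprint half-widths $\ln 2/A$ from $\approx 0.7$ cM down to
  $7\times 10^{-6}$ cM — sub-kilobase to multi-megabase at a typical
  1 cM/Mb. The degenerate null is always an implicit extra candidate.
* **`alpha_cutoff`** — sites with mixing weight below this (default
  $10^{-8}$) are skipped for that candidate $A$; they contribute equal
  terms to both likelihoods, so the truncation only saves time. The
  inclusion radius $\ln(1/\text{cutoff})/A$ shrinks as $A$ grows.
* **`rec_rate`** — cM per bp, used only when sites carry no genetic
  positions (default $10^{-6}$, i.e. 1 cM/Mb, a common genome-wide
  average in great apes).
* **HWE filter threshold** — sites with one-tailed heterozygote-excess
  $P$ below the threshold are removed before scanning (defaults offered:
  $10^{-4}$ for large panels; $10^{-2}$ for small panels where the
  genome-wide $P$ distribution is used to pick an outlier cutoff).

Ties in the grid maximization resolve deterministically to the smallest
$A$, then the lexicographically smallest $x$; iteration order is fixed, so
scans are exactly reproducible.

## Worked example

```{r example}
# genome-wide background: 1/k-shaped polymorphism spectrum plus
# substitutions, n = 50 sampled alleles
bg <- neutral_background(50L)
g <- normalize_background(bg, "2")

# a synthetic footprint: equilibrium frequency 0.3, decay 1000/cM
spec <- footprint_spec(x0 = 0.3, A0 = 1000, center = 25000, n_sites = 2000,
                       n_samples = 50, spacing = 25, rate = 1e-6, seed = 7)
ds <- synth_footprint(spec, g)

res <- scan(ds, g, scan_config("2", test_every = 10L))
res[which.max(res$B), ]
```

The peak localizes at the selected site and $(\hat x, \hat A)$ land on the
grid points nearest the generating truth.

## The selection-equilibrium calculators

The synthetic studies are parameterized by the equilibrium frequencies that
overdominance maintains. With genotype fitnesses $1$, $1 + hs$, $1 + s$
(ancestral homozygote, heterozygote, mutant homozygote) and $h > 1$, the
deterministic viability recursion $p' = p\,\bar w_A/\bar w$ converges to
$p^\ast = h/(2h - 1)$ — e.g. minor-allele equilibria 0.4, 0.3 and 0.2 for
$h = 3$, $1.75$ and $1.33$ — independent of the magnitude of $s$.

```{r equilibria}
c(h3 = overdominance_equilibrium(0.01, 3)$minor,
  h1.75 = overdominance_equilibrium(0.01, 1.75)$minor,
  h1.33 = overdominance_equilibrium(0.01, 1.33)$minor)
```

Numerically, weak selection makes the recursion contract slowly, so the
stopping rule bounds the *distance to the fixed point* (step size divided
by the local contraction rate $s\,pq(2h-1)/\bar w$) rather than the raw
step size, and also stops at floating-point stationarity; `tol` is thus
the accuracy of the returned frequency.

The multiallelic calculator adds $m$ mutant alleles under a multiplicative
multi-mutation rule (heterozygous at two distinct mutants:
$(1+hs)^2$), starting mutants near-symmetric at $(1-\varepsilon)/m$ with
the ancestral allele at $\varepsilon = 10^{-3}$. The ancestral allele is
driven out and the mutants balance at $1/m$ each; the residual ancestral
frequency is reported along with an explicit `ancestral_lost` flag
(threshold $10^{-6}$, far below one copy at any census size) rather than
silently folded into the result.

```{r multi}
multiallelic_equilibrium(0.001, 20, 3)$freqs
```

## What the synthetic generator does and does not emulate

`synth_footprint()` draws each site's allele count *from the mixture model
itself* at the site's distance from the selected locus, and
`neutral_dataset()` draws i.i.d. from the background spectrum. This makes
parameter recovery a well-posed internal check: the generating $(x_0, A_0,
\text{center})$ are exactly the quantities the scan estimates. What these
draws deliberately do **not** contain is everything the mixture model
itself ignores: linkage disequilibrium *between* neighboring informative
sites (real data are correlated; composite likelihoods overstate
information), coalescent noise around the equilibrium frequency, mutation
and recombination rate heterogeneity, and demography beyond what the
background SFS absorbs. Passing recovery tests therefore demonstrates
correctness of the implementation and internal consistency of the
estimator — not power on real genomes, which in the literature is assessed
with forward simulations under explicit demographic models.

The deterministic `neutral_background()` gives the background the standard
neutral $1/k$ polymorphism shape plus a substitution class at 2.5 times
the polymorphic total, a divergence-to-diversity ratio typical of a
great-ape-like comparison (split $\sim 2.5 \times 10^5$ generations,
$\mu = 2.5\times10^{-8}$, $N = 10^4$: expected divergence
$\approx 0.0125$/site against heterozygosity-driven polymorphism
$\approx 0.0045$/site). Real backgrounds should always be tallied from the
scanned dataset itself with `build_background()`.

## Numerical choices and degenerate inputs

* Binomial terms come from `dbinom()` (log-space internally), stable to
  sample sizes in the thousands; component normalizers are explicit sums
  over the support, never closed forms prone to cancellation.
* The grid maximization accumulates $\sum_i \ln(f_i/g_i)$ as a running
  product of per-site likelihood ratios with under/overflow guards at
  $10^{\pm 280}$, taking logarithms only when the guard trips; this agrees
  with the direct sum of logarithms to within $\sim L \cdot
  \varepsilon_{\text{machine}}$ and the unit tests hold it to $10^{-9}$
  relative against a naive reimplementation.
* The background is conditional on the exact sample size $n$. A scan site
  whose $n$ has no background stratum is a hard error (no hypergeometric
  projection across $n$; a documented possible extension), as is a site
  falling in an $(n, k)$ cell with zero background count — both indicate
  the background was not built from the dataset being scanned.
* Monomorphic genotype tables return $P = 1$ in the HWE filter; filtering
  removes sites with $P$ strictly below the threshold.
* Test positions need not coincide with informative sites; genetic
  positions of off-site test points are linearly interpolated.
* A test site with no informative site inside any candidate window yields
  $B = 0$ with `NA` estimates rather than an error.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run entirely from synthetic
data generated at run time: backgrounds of $10^4$–$7\times10^5$ tallied
sites, scan instances of 30–2000 sites, 1000 neutral datasets for the
nestedness property, and 50 footprint replicates (2000 sites each,
$n = 50$, $x_0 = 0.3$, $A_0 = 10^3$/cM, tested every 10th site — a 250 bp
test grid against a $\ln 2/A_0 \approx 693$ bp localization half-width).
These sizes were chosen so the full suite completes in minutes on a single
core while keeping every estimate's sampling noise far from its pass
threshold.

## Known limitations

* Composite likelihood: no between-site dependence, so $B$ has no
  analytical null distribution; use simulation-based significance.
* The exponential linkage weight is a proxy, not a coalescent-derived
  decay; $\hat A$ should be compared only among regions with similar
  scores, and neither $\hat A$ nor $\hat x$ maps to an explicit
  evolutionary model.
* No ancestral-state misidentification correction: use the folded
  (`MAF`) variants when polarization is unreliable.
* Single scaffold per scan; no projection across sample sizes.
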