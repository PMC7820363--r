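# balscan

Composite likelihood ratio scans for footprints of long-term balancing
selection in population genomic data.

## What it does

Balancing selection (heterozygote advantage, negative frequency dependence,
...) maintains alleles at intermediate frequency for long timescales,
dragging linked neutral variation towards the balanced equilibrium
frequency. `balscan` detects these footprints by modelling the allele
count *k* (of *n* sampled alleles) at an informative site *d* cM from a
candidate locus as a mixture

    f(k, d) = α_A(d) · h_{n,x}(k) + [1 − α_A(d)] · g_n(k),
    α_A(d) = exp(−A·d)

of a binomial "balanced" component `h` (success rate = equilibrium
frequency *x*) and the genome-wide site frequency spectrum `g`, with an
exponential linkage-decay weight whose rate *A* (per cM) sets the
footprint size. Each test site scores

    B = 2 [ ln L_a(x̂, Â) − ln L_0 ],

the composite likelihood ratio maximized over an (x, A) grid that always
contains the neutral model, so B ≥ 0. Variants handle derived or minor
(folded) allele counts, with or without substitutions (`B2`, `B2maf`,
`B1`, `B0`, `B0maf`), and a multiallelic extension scores loci balancing
m > 2 allelic classes, reducing exactly to the biallelic model at m = 2.

The package also provides:

* deterministic overdominance equilibrium calculators (biallelic closed
  form p\* = h/(2h−1) via the viability recursion, and the multiallelic
  analogue under a multiplicative fitness rule),
* a synthetic-footprint generator that samples scan-ready datasets from
  the mixture model itself (for calibration and parameter-recovery
  checks),
* an exact one-tailed Hardy–Weinberg heterozygote-excess test (Levene
  conditional distribution) for filtering genotyping artifacts,
* TSV readers/writers for site, spectrum ("spect") and scan files, and a
  small CLI (`inst/cli/balscan`) with `build-background`, `scan`,
  `simulate` and `filter` subcommands.

Scores are raw and meant to be ranked; significance should come from
simulations under an explicit demographic model (B does not follow a χ²
distribution), and no multiple-testing machinery is included by design.

## Worked example

```r
library(balscan)

# genome-wide background (here synthetic: 1/k polymorphism spectrum plus
# substitutions; on real data, tally it from the scanned dataset with
# build_background())
g <- normalize_background(neutral_background(50L), "2")

# dataset carrying a balancing-selection footprint at position 25000
# (equilibrium frequency 0.3, decay 1000/cM, n = 50, 2000 sites)
spec <- footprint_spec(x0 = 0.3, A0 = 1000, center = 25000, n_sites = 2000,
                       n_samples = 50, spacing = 25, rate = 1e-6, seed = 7)
ds <- synth_footprint(spec, g)

res <- scan(ds, g, scan_config("2", test_every = 10L))
res[which.max(res$B), ]
#>     phys_pos  gen_pos        B x_hat   A_hat n_sites
#> 101    25025 0.025025 88.58217  0.29 1438.45    1025
```

The peak B sits 25 bp from the true selected site (well inside the
ln2/A₀ ≈ 693 bp footprint half-width), x̂ = 0.29 is one grid step from the
generating equilibrium frequency 0.3, and Â = 1438/cM is the grid
neighbour of the true decay 1000/cM; `n_sites` is the number of
informative sites inside the inclusion window at Â.

The same pipeline from the shell:

```sh
cli=$(Rscript -e 'cat(system.file("cli", "balscan", package = "balscan"))')
$cli simulate --spect bg.spect --out sites.tsv --x0 0.3 --a0 1000 --seed 7
$cli scan --sites sites.tsv --spect bg.spect --out scan.tsv --model B2
$cli filter --genotypes geno.tsv --out kept.tsv --threshold 1e-4
```

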