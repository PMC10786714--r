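---
title: "Detecting IBD segments from imputed genotype probabilities"
author: "ibdscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting IBD segments from imputed genotype probabilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdscreen)
```

## The problem

Two individuals who share a recent common ancestor carry long chromosome
stretches that are identical by descent (IBD). Because recombination
breaks shared haplotypes at a rate of one crossover per Morgan per
meiosis, a segment of length $\ell$ cM survives $m$ further meioses with
probability $e^{-m\ell/100}$; long segments therefore indicate *recent*
common ancestry, and the count and length spectrum of segments between
two genomes measures their degree of relatedness up to roughly sixth
degree.

Low-coverage genomes — the typical situation for ancient DNA — cannot be
genotyped confidently site by site. Imputation against a reference panel
produces, per site, a posterior probability triple over the three diploid
genotypes (`GP`) and a phased best-guess genotype (`GT`). `ibdscreen`
detects IBD segments directly from this probabilistic output instead of
from hard genotype calls, which preserves power at coverages where hard
calls are mostly noise.

## The model

### Hidden states

For a pair of phased diploid genomes (haplotypes 1A/1B and 2A/2B) the
hidden chain has five states: state 0, "non-IBD", and four IBD states,
one per shared haplotype pair (1A–2A, 1A–2B, 1B–2A, 1B–2B). Keeping the
four IBD states separate lets the model ride through phase-switch errors
inside one true segment: a switch error just moves the chain to a
neighbouring IBD state instead of ending the segment.

### Transitions

The chain moves along the genetic map with an infinitesimal generator
defined by three rates per Morgan: `ibd_in` (0 → each IBD state),
`ibd_out` (IBD → 0), and `ibd_switch` (IBD → each other IBD state). The
transition matrix over a map distance $r$ Morgans is $e^{Qr}$.

The four IBD states are exchangeable, so $Q$ is invariant under
permutations of them. Internally the three "other IBD" states are pooled
into one, the resulting $3\times3$ generator is eigendecomposed *once*,
and $e^{Q_3 r}$ for all $L-1$ inter-marker distances is evaluated as a
sum of three rank-one terms scaled by $e^{\lambda_k r}$ — no per-interval
matrix exponential. The five distinct entries of the full $5\times5$
matrix are then reconstructed by symmetry. A dense matrix exponential
(`Matrix::expm`) serves as the test oracle and as a fallback if the
eigendecomposition is ever ill-conditioned (condition number $>10^{10}$);
the unit tests check agreement to $10^{-9}$ across the rate ranges used.

Distances are floored at $10^{-8}$ Morgan so duplicate map positions do
not create degenerate transitions.

### Emissions: haploid dosages

The observed data at each site are four *haploid dosages* — the
probability that each of the four haplotypes carries the alternative
allele — derived from GP and GT. Writing the genotype posterior as
$(p_0, p_1, p_2)$, the phased-genotype probabilities are approximated as
$P_{00}=p_0$, $P_{11}=p_2$, and the heterozygote mass $p_1$ is assigned
to the orientation reported by a phased heterozygous GT when the GP
argmax is also heterozygous; otherwise (homozygous argmax, unphased or
missing GT, or a GP/GT contradiction, which is counted and reported) the
mass splits evenly. The dosages are $x_A = P_{11}+P_{10}$ and
$x_B = P_{11}+P_{01}$.

For the state sharing haplotypes $h_1$ and $h_2$, summing the likelihood
over the 16 latent phased genotype configurations with Hardy–Weinberg
priors — where the shared pair counts as a *single* population draw —
collapses to the closed form

$$ e \;=\; \frac{x_{h_1} x_{h_2}}{p} \;+\;
   \frac{(1-x_{h_1})(1-x_{h_2})}{1-p}, $$

expressed relative to the non-IBD state (whose column is identically 1).
Here $p$ is the population frequency of the alternative allele, clamped
to $[10^{-4}, 1-10^{-4}]$ because the form divides by $p$ and $1-p$.
`emission_bruteforce_oracle()` implements the 16-term enumeration
explicitly and the tests require agreement to $10^{-10}$. Two easy
sanity points: when both dosages equal $p$ the ratio is exactly 1 (no
information), and matching confident rare alleles give a ratio near
$1/p$ — shared rare variants are the strongest IBD evidence.

### Decoding

Posterior state probabilities come from the rescaled (non-logarithmic)
forward–backward algorithm, implemented in C++ with the five-component
transition structure rather than full matrix products. A pure-R log-space
implementation in the test suite is the correctness oracle ($10^{-8}$
agreement on 200-site instances). Rescaling also yields the marginal
log-likelihood as a by-product.

## From posteriors to reported segments

Candidate segments are maximal runs with $P(\text{non-IBD}) < 0.5$
spanning at least 2 cM. Post-processing, in order:

1. **Gap merging** — adjacent candidates separated by at most 0.5 cM are
   merged when both flanks are at least 2 cM, iterated to a fixpoint;
   sporadic genotype errors inside a long segment otherwise split it.
2. **Density filter** — segments averaging fewer than
   `density_min_snps_per_cm` markers per cM are discarded; sparse regions
   produce false positives. The default (220/cM) is tuned to dense
   ~1.1M-site capture panels and should be scaled to the input density
   (the simulations here run at 150 markers/cM and use 75).
3. **Masks** — optional cM intervals (centromeres, known artefact
   regions). A segment overlapping masks on more than half its length is
   dropped; smaller overlaps truncate it to its longest unmasked piece.
4. **Report floor** — only segments of at least 8 cM are reported;
   below that length, detection from low-coverage data is unreliable and
   population background sharing dominates.

Indices are 0-based and half-open; cM bounds are the map positions of
the first and last marker in the run.

## Default parameters

`ibd_rates(ibd_in = 0.01, ibd_out = 5, ibd_switch = 7.5)` and the caller
defaults above were frozen from the package's own grid-search harness
(`grid_search_defaults()`): 108 cells over `ibd_in`
$\{0.01, 0.02, 0.05\}$ × `ibd_out` $\{5, 10, 15, 25\}$ × `ibd_switch`
$\{2, 7.5, 15\}$ × threshold $\{0.3, 0.5, 0.7\}$, scored on simulated
scenarios by recall on ≥ 8 cM truth with a false-positive ceiling and
mean absolute length error as tie-breaker. The surface is nearly flat —
posterior decoding is robust to the transition prior over an order of
magnitude — so the winner was adopted and not micro-tuned. `ibd_out = 5`
corresponds to a prior mean segment length of 20 cM, appropriate for the
close-relative sharing the screen targets; `ibd_in` sets the prior
fraction of the genome in IBD near $4 \cdot 0.01/5 \approx 1\%$.

## The simulator and its limits

Validation needs pairs with *known* IBD. `simulate_panel()` builds a
panel of binary haplotypes (default 200) over a frequency spectrum
$p = 0.05 + 0.9\,\mathrm{Beta}(0.7, 0.7)$; a third of the panel are
independent Bernoulli draws and the rest copy founder templates with
Poisson switch points (0.5/cM), inducing local linkage disequilibrium.
Test genomes are *mosaics*: chunks of 0.25 cM copied from random panel
haplotypes. Chunking destroys long-range sharing, so any long IBD
between two mosaic genomes is exactly what `make_mosaic_pair()` copies
in — a freshly stitched donor stretch written onto one haplotype of each
individual over the same interval.

Noise imitates imputation output parametrically: GP triples are
Dirichlet draws centred on the true genotype with a concentration
parameter, a miscall probability re-centres a site's GP on a wrong
genotype, and phase-switch points flip the reported GT haplotype order.
Named tiers (`"2x"`, `"1x"`, `"0.5x"`, `"0.25x"`) bundle
concentration/miscall pairs (200/0.002 … 8/0.15) that produce a clean
power gradient. Two honest caveats:

* The tiers are *calibration knobs*, not measurements of any specific
  pipeline; absolute power and false-positive numbers from these
  simulations characterise the method under this noise family, not any
  particular dataset.
* Mosaic genomes carry less long-range background LD than real human
  chromosomes, so background (false-positive) sharing is lower here than
  in real cohorts. False-positive behaviour should be re-measured on
  real panels before interpreting absolute rates.

Two numerical corners worth knowing:

* **8 cM knife edge.** A planted segment of exactly 8.0 cM has a
  marker-to-marker span slightly *below* 8 cM (the outermost markers sit
  inside the interval), so it straddles the report floor by
  construction. Recovery experiments therefore plant lengths in
  $[8.5, 20]$ cM; power *at* 8 cM is dominated by this discretisation,
  not by the decoder.
* **Panel size and boundary accuracy.** At copied-segment boundaries the
  flanking mosaic chunk can coincide with the donor's continuation by
  chance, extending the call by ~0.25 cM per matching chunk. The effect
  shrinks with panel diversity; with the default 200-haplotype panel
  (the scale of a typical reference panel) noiseless boundary errors
  stay below 0.5 cM.

## Pedigree expectations

`simulate_relatives()` tracks founder-haplotype descent through explicit
pedigrees (parent–offspring through third cousins) over 22 autosome-like
chromosomes (≈ 3545 cM), with crossovers as a Poisson process of 1 per
Morgan and no interference. It reproduces the textbook anchors used as
acceptance checks: a parent–offspring pair shares exactly one
full-length segment per chromosome (22 segments, IBD1 fraction 1), and
full siblings average IBD1 = 0.5 and IBD2 = 0.25. Note that the IBD1
*genome fraction* for half-siblings is 0.5 — the popular "25% shared
DNA" figure is the diploid allele fraction, half the IBD1 fraction.

`expected_ibd_constant_ne()` gives the coalescent density of IBD
segments under a constant population size: two haplotypes coalescing in
generation $t$ accumulate breakpoints at rate $2t$ per Morgan, giving
$(2t)^2 (G-u)\,e^{-2tu}$ interior segments of map length $u$ plus
$2\cdot 2t\,e^{-2tu}$ chromosome-edge terms. An internal forward
Wright–Fisher simulation validates this in a sparse-coalescence regime;
in drift-heavy populations maximal shared-ancestry runs merge across
re-coalescences and exceed the single-coalescence prediction — and a
diploid screen additionally reports the *union* over the four haplotype
pairs — so quantitative comparisons use the per-haplotype-pair basis.

## Screening cohorts

`screen_pairs()` processes every unordered pair exactly once in batches
(all within-batch plus all cross-batch pairs), with output canonically
ordered and therefore *identical for every batch size* — verified for
partitions {2, 10, 20} of a 20-sample cohort. `count_pairs()` walks the
same loops and confirms $\binom{n}{2}$ without materialising pairs
(9 020 628 for a 4248-sample cohort). Sample QC follows imputation
confidence: a sample passes when at least 70% of chromosome-3 markers
have a genotype posterior above 0.99. `summarize_pair()` counts segments
above strict thresholds (8, 12, 20 cM) and `annotate_relatives()` maps
these to coarse relationship labels.

## Worked example

```{r example, eval = FALSE}
library(ibdscreen)

sim <- simulate_ibd_pair(
  noise = noise_config(tier = "1x"),
  ibd = data.frame(start_cm = 40, length_cm = 12),
  seed = 1)

fit <- ibd_hmm(sim$gm, sim$sites, pair = c("ind1", "ind2"),
               caller = caller_params(density_min_snps_per_cm = 75))
summary(fit)
plot(fit)
```

The CLI wraps the same pipeline for file-based use:

```sh
Rscript inst/cli/ibd.R simulate --out sim/ --seed 3 --lengths 12,20
Rscript inst/cli/ibd.R run --vcf sim/sim.vcf --map sim/map.txt \
    --out run/ --density_min_snps_per_cm 75
Rscript inst/cli/ibd.R evaluate --called run/segments.tsv \
    --truth sim/truth.tsv --out eval.tsv
```

## Design notes

* **Formats and numerics from established packages; the model authored
  here.** VCF parsing uses `vcfR`, configuration files `yaml`, and
  `Matrix::expm` appears only as an oracle/fallback. The HMM — collapsed
  transition algebra, dosage emissions, C++ forward–backward — is the
  contribution and is therefore implemented, and oracle-tested, in this
  package.
* **One fitting function, classed result.** `ibd_hmm()` returns an
  `ibd_fit` with `print`, `summary`, `coef` and `plot` methods; internals
  are base R.
* **Determinism.** All simulators accept seeds; screening output is
  independent of batching; segment tables have canonical column and row
  order.

## Limitations

* Frequencies are taken as known; mis-specified allele frequencies bias
  the emission ratios (rare-allele matches are the main signal).
* The mosaic simulator under-represents long-range LD (see above), so
  absolute false-positive rates are optimistic.
* IBD2 regions (both haplotype pairs shared, as in full siblings) are
  modelled only as single-pair states; the screen reports them as
  overlapping/merged IBD1-style segments rather than a distinct state.
* Detection below ~8 cM is deliberately out of scope; the report floor
  enforces this.
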