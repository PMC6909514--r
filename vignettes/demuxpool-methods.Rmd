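---
title: "Demultiplexing pooled scRNA-seq without a genotype reference: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demultiplexing pooled scRNA-seq: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demuxpool)
```

## The problem

Pooling cells from several genetically distinct donors into a single
droplet-based scRNA-seq run reduces cost and removes batch effects between
the pooled samples, at the price of having to assign every cell back to
its donor afterwards. When the donors' genotypes have been assayed this is
a lookup problem; demuxpool addresses the harder and more common setting
where no genotype reference exists. The natural genetic variation between
donors is then the only signal: at common SNVs, reads covering the variant
carry the REF or ALT base in proportions set by the donor's genotype.

The observable evidence is a pair of sparse variants-by-cells matrices:
`A`, UMI counts supporting the ALT allele, and `D`, total UMI depth. A
typical droplet cell covers on the order of 100 expressed variants at a
depth of a few UMIs each — far too little to genotype a cell on its own,
but plenty once information is aggregated over the ~1000 cells that share
a donor.

## The model

Each cell `j` belongs to one of `K` donors (indicator `Z_j`), and each
donor `k` has a genotype `G[i,k]` in {0, 1, 2} (copies of the ALT allele)
at each variant `i`. Given the genotype `t` of the donor of cell `j`, the
ALT count is binomial:

    a[i,j] | d[i,j], t  ~  Binomial(d[i,j], theta_t)

The allele rates `theta_t` are shared across variants and carry beta
priors concentrated near the theoretical dosages t/2 but allowing for
sequencing error and allelic imbalance:
`theta_0 ~ beta(0.3, 29.7)`, `theta_1 ~ beta(3, 3)`,
`theta_2 ~ beta(29.7, 0.3)` (prior means 0.01, 0.5, 0.99). Cell
assignments have a uniform categorical prior `pi = 1/K`; genotypes have a
categorical prior `U` which is uniform when nothing is known and encodes
reference genotypes when they are supplied (below).

Both `Z` and `G` are latent; the model is a mixture over donors in which
the mixture components' parameters (the genotypes) are themselves
inferred. This is what removes the need for a reference panel of donor
genotypes.

### Variational inference

The exact posterior over `(Z, G, theta)` is intractable, so we use
mean-field variational Bayes with the factorization
`q(Z) q(G) q(theta)`: categorical `r[j,k]` per cell, categorical
`g[i,k,t]` per variant and donor, and `beta(alpha_t, beta_t)` per state.
Coordinate ascent cycles three closed-form updates (genotype, then allele
rates, then assignment) and each sweep provably increases the evidence
lower bound (ELBO). The expected log binomial kernel used in the softmax
updates is the complete expectation

    a * (psi(alpha_t) - psi(alpha_t + beta_t)) +
    b * (psi(beta_t)  - psi(alpha_t + beta_t)),    b = d - a,

including the `-(a+b) psi(alpha_t + beta_t)` part: because the posterior
concentration `alpha_t + beta_t` differs across states, that term does not
cancel in the normalization over components, and dropping it would break
the guarantee that every update increases the bound. The test suite
checks monotonicity on randomized instances and, on instances small
enough to enumerate every `(Z, G)` configuration exactly, that the
converged bound never exceeds the true marginal likelihood and that the
variational assignment argmax agrees with the exact posterior argmax.

All softmax normalizations are done in log space with max subtraction
(depths of hundreds of UMIs would overflow otherwise), and the binomial
coefficient `log C(d, a)` — constant in all latent variables — is added
once to the ELBO's data term so reported bound values are exact.

### Initialization, restarts, and pruning

The genotype-free posterior is highly multi-modal (any permutation of
donors is a mode, and partial label swaps are local optima). The fit
therefore runs a warm-up pre-search: 50 random initializations (genotype
posteriors drawn from Dirichlet(1,1,1) per variant and component), each
advanced 15 sweeps, keeping the run with the highest bound. The warm-up
searches `K + ceiling(sqrt(K))` components; afterwards only the `K`
components with the largest soft-assigned cell mass are kept (ties broken
by component index) and ascent continues to convergence, declared when
the absolute ELBO change drops below 0.01 (cap 200 iterations, with a
warning if hit). The surplus-component trick makes the search robust to
modes in which one true donor is split and another is missed. All
randomness derives from a single integer seed, and two runs with the same
seed are bit-identical.

When an informative genotype prior is supplied the surplus-component
pre-search is skipped (the prior's columns already pin component
identity, and re-ordering them during pruning would scramble the donor
labels); the restarts still run.

### Doublet detection

A droplet containing cells from two different donors shows, at every
variant, the average allele dosage of the two genotypes. The fitted `K`
donors are therefore augmented with `K(K-1)/2` pseudo-donors, one per
unordered donor pair. The pair's genotype distribution over the extended
states (0, 0.5, 1, 1.5, 2) is the product-convolution of the two donors'
3-state distributions (e.g. `p(1) = x1*y1 + x0*y2 + x2*y0`), and the
pseudo-states' allele rates get beta distributions pinned by two moment
constraints: mean equal to the arithmetic mean of the neighbouring
states' means, concentration equal to the geometric mean of their
concentrations. Doublets of two cells from the *same* donor are
indistinguishable from singlets by genotype and are not modelled.

The component prior splits mass `(1 - eta)/K` per donor and `eta/K2` per
pair, with the prior doublet probability `eta = M/100,000` by default
(`M` = number of cells), the standard loading-rate rule for droplet
platforms. After the singlet model converges, the assignment posterior is
recomputed once over the extended component space; the genotype and
allele-rate posteriors stay frozen, so this extended step is a single
closed-form update (it is already at its coordinate optimum). Re-updating
`q(G)` in the extended space was considered and rejected: the doublet
components are deterministic functions of the singlet genotypes, and
letting doublet pseudo-donors reshape the genotypes would let 8% of cells
distort the inference for the 92%.

Each cell reports `prob_max` (largest singlet posterior) and
`prob_doublet` (summed pair posterior). The recommended operating points
are `prob_max > 0.9` to accept a singlet assignment and
`prob_doublet > 0.9` to call a doublet; both are exposed as arguments.
Cells with no covered variant sit exactly at the prior, so their
`prob_doublet` equals `eta`.

## Reference genotypes, full and partial

If genotypes are available for all donors (VCF with `GT`, `GP`, or `GL`;
`GT` is the default tag), the data are restricted to variants with known
genotypes and `q(G)` is clamped: only allele rates and assignments
iterate. A hard genotype `t` is encoded with relax rate `xi = 0.05`:
probability `1 - xi` on state `t`. Stated that way the row does not
normalize, so the remaining `xi` is split equally over the two other
states — the stated confidence in the call is preserved exactly and the
row is a proper distribution. `GP` probabilities are renormalized and
used as-is; `GL` log10-likelihoods are exponentiated and renormalized.
Soft `GP`/`GL` inputs are deliberately *not* relaxed further: they
already encode their own uncertainty.

With genotypes for only `K0 < K` donors, a two-step procedure is used:
(1) a genotype-free fit; (2) each reference donor is aligned to an
inferred component by genotype concordance, using a globally optimal
one-to-one matching; (3) the genotype prior of matched components is
replaced by the relaxed reference genotypes (uniform elsewhere); (4) the
model is refit with this mixed prior, and the reference donors' names are
attached to their components. A reference donor whose best concordance
falls below 0.7 is reported unmatched and not anchored — the threshold is
a package decision (exposed as an argument) chosen to prevent silently
anchoring a donor that is absent from the pool; concordance between
matched profiles is typically > 0.9 while unrelated profiles sit near the
chance level of ~0.55 for Hardy-Weinberg genotypes.

## Choosing the pool size

The ELBO is a surrogate marginal likelihood, so candidate pool sizes can
be compared directly. `scan_n_donors()` fits each K with the same restart
seeds (so curves are comparable) and reports the raw curve plus a numeric
elbow: the last K before the per-step ELBO gain first drops below 10% of
the largest gain in the scan. The rule is a stated heuristic for reading
the elbow; the curve and the per-component soft cell masses are always
returned so the user can judge. Over-specified fits are themselves
informative: the variational model self-prunes, parking surplus
components at near-zero mass, so fitting with a generous K and discarding
empty components is a valid alternative strategy.

## Donor matching and discriminatory panels

Reconstructed genotypes are only available at expressed variants, but
they are accurate there (the package's own benchmark measures precision
above 0.96 overall at 10+ UMIs per donor), which makes them usable as a
linking key: across two runs of the same donors, the fraction of
concordant hard genotype calls over variants with at least 10 UMIs of
per-donor expected depth identifies matching donors. The one-to-one
matching maximizing total concordance is found exactly with a shortest
augmenting path (Jonker-Volgenant) solver written in the package — no
assignment solver is available among the supported dependencies — and is
verified against factorial brute force in the tests.

For follow-up genotyping (e.g. qPCR), `select_discriminatory_variants()`
designs a minimal panel: starting from the trivial one-block partition of
donors (entropy 0), it greedily adds the variant whose hard-genotype
pattern most increases the entropy of the joint partition (base 2,
block-size proportions — the standard information-gain weighting; the
donor-count weighting would coincide here anyway since every donor is one
unit), stopping at `log2(K)` bits when all donors are separated, or
earlier with a warning naming the unresolved donor blocks. Variants with
under 20 UMIs in any donor are excluded first, and variants
homozygous-ALT in every donor can optionally be dropped. Ties in gain are
broken by higher aggregate depth, then lower variant index.

## The simulator

The package ships a generative simulator rather than downsampled real
data, so every end-to-end property is testable offline. Its defaults are
the study conditions used throughout the tests:

| parameter | default | rationale |
|---|---|---|
| donors K | 8 | typical multiplexed design |
| cells per donor | 1000 | typical pool size |
| doublet rate | auto: `n_singlets/100,000` = 8% | droplet loading rule |
| variants | 2000 | enough that ~100 are covered per cell |
| ALT allele frequency | Uniform(0.05, 0.5) | common variants; genotypes drawn per donor under Hardy-Weinberg |
| covered variants per cell | Poisson(100), uniformly placed | order of 100 expressed variants per droplet cell |
| depth per covered variant | geometric on {1, 2, ...}, mean 2 | sparse UMI counts |
| allele rates | 0.01 / 0.5 / 0.99 | the model priors' means |

Doublets are sums of two independently drawn singlet profiles from
distinct donors, appended on top of the singlet cells. Read subsampling
is emulated by binomial thinning: every UMI is kept independently with a
configured probability, ALT and REF thinned separately.

What the simulator does *not* emulate: expression-weighted variant
coverage (real coverage concentrates on highly expressed genes),
ambient RNA contamination, allelic imbalance beyond the global rates,
variant-calling artifacts, and doublets whose two cells contribute
asymmetric read numbers. Generative pools are therefore *cleaner* than
real data, and the package's benchmark numbers should be read as upper
bounds on real-data performance — which is why the acceptance checks
treat published accuracies from read-level benchmarks as floors that the
cleaner generative data must exceed.

## Numerical choices and degenerate inputs

* Convergence: absolute ELBO change < 0.01; cap 200 iterations.
* Zero-coverage cells get the prior assignment; zero-coverage
  (variant, donor) pairs revert to the genotype prior; both fall out of
  the log-space updates without special-casing.
* `0 * log 0 = 0` throughout the entropy terms.
* Degenerate one-hot priors (`xi = 0`) clamp the genotype posterior
  exactly (the `-Inf` log-prior survives the max-subtracted softmax).
* `K = 1` is allowed; the doublet stage is skipped with a warning.
* Warm-up surplus clusters are capped at `M - K`.
* Matrix-Market files are 1-based on disk per the standard; all internal
  indexing is R's 1-based; VCF positions stay 1-based end to end.

## Problem sizes used by the tests

Unit tests run on pools of 2-6 donors with tens to hundreds of cells and
a few hundred variants; exactness oracles enumerate instances up to 3
variants x 3 cells x 2 donors, where the brute-force posterior
(3^(N·K) genotype configurations x K^M assignments, with the allele rates
integrated in closed form against their beta priors) is computable. For
the exact-argmax comparison, instances are additionally conditioned on
discernible donors (genotype columns differing at ≥ 2 of the 3 variants)
and guaranteed per-entry coverage: without that conditioning a fraction
of instances are genuinely ambiguous (exact top posterior below 0.6),
where the argmax is decided by hair-thin margins that a mean-field
approximation has no reason to reproduce. The headline benchmark runs
the full default design (5 replicate pools of 8640 cells) in both the
acceptance test and `scripts/acceptance.R`.

## Known limitations

* Donors are exchangeable without a reference: labels are arbitrary and
  only meaningful after anchoring to external genotypes or another run.
* Doublets of two cells from the same donor are invisible to the model.
* Triplets and higher multiplets are not modelled.
* The binomial likelihood ignores overdispersion (no beta-binomial) and
  shares allele rates across variants, so strong variant-specific allelic
  imbalance is absorbed rather than modelled.
* Only bi-allelic SNVs are supported; indels and multi-allelic sites are
  dropped on input.
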