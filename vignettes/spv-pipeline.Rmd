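---
title: "Strain-private variants and mutation spectra in inbred genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-private variants and mutation spectra in inbred genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spvspectra)
```

## The model

Classical inbred laboratory strains descend from a small founder
population, so each strain's genome is a mosaic of a handful of ancestral
haplotypes, and any genomic region is typically shared identical by
descent (IBD) between several strains. On a haplotype shared IBD by two or
more strains, an allele carried by exactly one strain — a strain-private
variant (SPV) — cannot be ancestral: the most parsimonious explanation is
a single de novo germline mutation during that strain's breeding history.
Because strain maintenance through small sibling-mating stocks approximates
a mutation-accumulation design, the SPVs of a strain approximate an
unselected sample of its germline mutation process, and their folded
substitution spectrum estimates the strain's mutation spectrum.

The pipeline implements this logic in stages:

1. **IBD detection** (`buildIbdPanel`, `detectIbdSegments`,
   `filterSegments`): pairwise scans over a SNP panel for maximal runs of
   identical, non-missing, homozygous genotypes. Runs spanning at least
   200 kb are segments; analyses of private variants are then restricted
   to segments of at least 5 Mb, far beyond the longest identical run
   expected between unrelated wild genomes.
2. **SPV calling** (`identifySingletons`, `applyFilterStack`): singleton
   candidates pass a stringent filter stack (site quality > 50, focal
   GQ > 60, depth > 10 and < 1.9x the strain mean, < 15% missing calls,
   outside repeat and segmental-duplication masks, likelihood margin > 20,
   absent from wild and wild-derived outgroup panels, located on retained
   IBD territory of the focal strain, and for heterozygous calls an
   allele-balance cutoff of 0.3 plus a strand/allele bias test at
   p > 0.05). Survivors are polarized (the non-private, major allele is
   ancestral) and annotated with reference-strand trinucleotide context,
   folded class and CpG status.
3. **Spectra** (`spectrumMatrix`): folded class counts are divided by the
   number of eligible bases in the strain's IBD territory (C/G bases for
   C-rooted classes, A/T for T-rooted, with an optional CpG split) and
   rescaled to sum to one.
4. **Neutrality diagnostics** (`classifyConsequence`,
   `nullConsequenceFractions`, `gTest`, `bootstrapFractionCI`,
   `conservationCdfCompare`) and **among-strain comparison**
   (`pairwiseSpectrumGTests`, `pcaSpectra`, `spearmanCor`, `oneWayAnova`,
   `traitSpectrumReport`).

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `mafMin` | 0.05 | Panel minor allele frequency cutoff for IBD inference |
| `minSeedBp` | 200,000 | Minimum IBD run length (bp) |
| `minLengthBp` | 5,000,000 | Retention threshold for analysed IBD segments (bp) |
| `qualMin`/`gqMin`/`dpMin` | 50 / 60 / 10 | Site quality, genotype quality and depth cutoffs (strict `>`) |
| `dpMaxFactor` | 1.9 | Upper depth bound as a multiple of the strain's mean depth |
| `missingMax` | 0.15 | Maximum fraction of missing genotypes at a site |
| `plMarginMin` | 20 | Phred margin between best and second-best genotype |
| `balanceMin` | 0.3 | Minor-read fraction for heterozygous candidates |
| `biasAlpha` | 0.05 | Strand/allele bias test threshold |

The MAF cutoff deserves a note. Its purpose, beyond enriching for
informative markers, is that private alleles must not enter the IBD panel:
a private variant sitting on a genuinely shared haplotype would otherwise
split the very IBD segment that identifies it as de novo. For a panel of
29 strains the conventional cutoff 0.05 lies between the singleton (1/29)
and doubleton (2/29) frequencies and achieves this automatically. The
bundled twelve-strain synthetic fixture uses `panelMafMin = 0.1` for the
same reason: it lies between 1/12 and 2/12, so private alleles are
excluded while doubleton founder variants are kept. This is a structural
scaling of the rule to panel size, not a tuning knob.

## Numerical and design choices

- **Missing annotations fail filters.** A record lacking GQ, DP, PL or
  allele-depth information fails any rule that needs it. This matches the
  conservative intent of the stack: a variant is private only when the
  evidence says so.
- **Filter order is fixed** (quality, genotype quality, depth,
  missingness, segmental duplications, repeats, likelihood margin,
  outgroups, IBD, balance, bias) so that the first-failing-rule audit is
  deterministic. The survivor set itself is order-independent.
- **Missingness denominator includes the focal strain**, and the IBD rule
  requires only that the site overlap a retained segment of the focal
  strain (the IBD partner's genotype at the site is not separately
  constrained); both choices are the simplest consistent readings and are
  fixed here.
- **Mean coverage** for the upper depth bound is the mean of the DP field
  across all processed sites of the strain, computed in a first pass.
- **Allele balance** is `min(adRef, adAlt) / (adRef + adAlt)`, so the
  cutoff 0.3 requires the rarer allele to carry more than 30% of reads —
  the standard heterozygous-call QC reading.
- **The bias test** is a goodness-of-fit chi-square with three degrees of
  freedom comparing the four per-strand allele counts to expectations
  under allele fraction 1/2 and the observed forward/reverse ratio. The
  published analyses name this null without fixing the statistic's form;
  this construction is the package's own definition.
- **Standardization** divides class counts by per-class opportunity and
  renormalizes ("rate then rescale"). No equation is fixed by the source
  analyses; this reading keeps frequencies invariant under uniform
  scaling of opportunities, and the raw count proportions are also kept
  for comparison with de novo mutation datasets. Opportunities are counted
  on the reference sequence of the IBD intervals rather than the strain's
  own alleles: private variants are vanishingly rare relative to interval
  length, and contexts are extracted from the reference as well.
- **Heterozygous and fixed SPVs weigh equally** (one mutational event
  each).
- **Pairwise spectrum G-tests run on raw counts**, not standardized
  frequencies, because a count-based likelihood-ratio test needs
  integers. No multiple-testing correction is applied; the summary
  reports the uncorrected significant fraction.
- **The spectrum PCA** centres and scales classes to unit variance, drops
  zero-variance classes with a warning, and fixes each component's sign
  so its largest-magnitude loading is positive. The default input is the
  six-class frequencies; the CpG-split seven-class variant is available
  for trait correlations.
- **Stop-loss changes count as missense** in the three-way consequence
  classification (protein-altering, not premature stop).
- **The uniform-mutation null** enumerates all nine single-base changes
  at every CDS position of the supplied gene models rather than assuming
  published constants, so it adapts to the fixture's codon usage.
- **Bootstrap intervals are percentile intervals**; the two-sample
  conservation comparison uses the asymptotic Kolmogorov–Smirnov
  p-value (scores are heavily tied, so exact small-sample p-values are
  out of scope).
- **G-tests** use `G = 2 * sum(O * ln(O / E))` with `0 ln 0 = 0` and a
  chi-square reference with `(r-1)(c-1)` degrees of freedom.

## What the simulator emulates — and what it does not

`simulateFixture()` generates, from one seed: a random reference sequence
(default 60 Mb, GC 0.42); eight founder haplotypes carrying a SNP panel
(one site per 2 kb, founder allele counts drawn with probability
proportional to 1/k as under neutrality); twelve inbred strains as
founder-block mosaics with exponential block lengths (mean 10 Mb); 300
planted private mutations per strain (8.3% heterozygous, the rest fixed)
drawn from configurable six-class spectra, at positions off the SNP panel
so privacy is guaranteed by construction; a 27-sample wild outgroup drawn
per-site from founder allele frequencies with extra outgroup-private
polymorphism; the founder haplotypes themselves as a wild-derived inbred
panel; and repeat/segmental-duplication masks covering 5% and 2% of the
chromosome. Planted records receive quality fields that pass all default
filters; `injectFilterFailures()` flips one named field per targeted
record to just beyond its threshold for per-filter tests.

The default parameter values are the package's fixed study conditions:
block and panel scales are chosen so that a twelve-strain panel yields
several >= 5 Mb shared segments per strain pair (about half of each
genome ends up in retained IBD territory) while the wild outgroup shows
no identical run approaching 5 Mb; the exponential renewal process for
block lengths is an artifact choice, not an inference about real strain
history. The simulator does not model recombination graphs, selection
during strain propagation, sequencing error beyond the corruption hooks,
recurrent mutation (excluded by construction, as the wild-panel filter
would absorb it), or sex chromosomes. Passing recovery tests on these
fixtures therefore demonstrates the correctness of the pipeline's logic
under its stated assumptions — not the calibration of any real-data
quality model. Gene models are non-overlapping forward-strand single-exon
ORFs embedded into the reference so the codon annotator is exact; real
gene architecture (splicing, strands, overlaps) is deliberately absent.

Conservation scores in emitted fixtures are sparse (panel sites, planted
sites and a random background sample) with panel-site scores drawn from a
conservation-depleted distribution, emulating the depletion of ancestral
variants at conserved sites; a dense wiggle-style track is out of scope.

## Problem sizes used in the checks

The test suite exercises the full default fixture (60 Mb, twelve strains,
300 mutations per strain) once, a smaller 8 Mb fixture for unit tests
(with retention threshold 2 Mb and `panelMafMin = 0.15`, the analogous
singleton/doubleton scaling for eight strains), and a 30 Mb, GC-0.5
fixture with 2,000 mutations per strain for spectrum recovery, where
equal C/G and A/T base availability makes the planted class probabilities
directly comparable to the opportunity-standardized output. Statistical
calibration uses 2,000 replicate G-tests, 1,000 replicate ANOVAs and 500
bootstrap-coverage datasets. Detector correctness is established by
equivalence with a naive scanning oracle on 200 random panels plus a
brute-force maximal-window oracle for the nonzero mismatch budget.

## Known limitations

- IBD detection assumes essentially homozygous genomes; heterozygous
  sites break runs rather than being phased. Outbred or phased IBD is out
  of scope.
- The 5 Mb retention rule makes SPV discovery blind in low-IBD strains;
  per-strain SPV yield scales with IBD coverage, and strains with little
  shared territory contribute few or no spectrum counts.
- Consequence annotation covers single-exon forward-strand CDS models
  only (synonymous/missense/nonsense/noncoding); splice, UTR and
  regulatory classes are not modelled.
- The folded spectrum uses six (or seven) classes; full 96-context
  spectra are recorded per SPV but not aggregated.
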