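---
title: "Tag-haplotype genotyping and nonparametric association mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tag-haplotype genotyping and nonparametric association mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagwas)
```

## The problem

Androgenesis — the induction of immature pollen to develop into embryos and
regenerate into fully homozygous, doubled-haploid plants — is a key enabling
technology for hybrid breeding in self-incompatible crops such as perennial
ryegrass (*Lolium perenne* L.). Androgenic capacity is highly
genotype-dependent, and mapping the loci that govern it requires (i) dense
genotyping of a heterozygous, multiparental population and (ii) statistics
that survive the extreme distributional pathology of anther-culture traits:
most genotypes produce nothing at all (mode 0), while a few produce hundreds
of embryos or plants. No transformation normalises such data, so the mapping
stage must be rank-based.

`tagwas` implements the complete analysis path for this setting:

1. **Read processing**: barcode demultiplexing (one mismatch allowed,
   ambiguous reads discarded), trimming to 100 bp, and collapsing to unique
   *tags* counted per individual and per pair-cross population.
2. **Tag-haplotype genotype calling**: tags are grouped by their unique
   alignment position (*Upos* — the exact triple of strand flag, scaffold
   and 1-based position), filtered for coverage and frequency, screened for
   informative polymorphic sites (*Isites*), and genotypes are called as
   unordered pairs of tag haplotypes under diploid constraints.
3. **Trait derivation**: the eight androgenic-capacity traits from raw
   anther-culture counts.
4. **Association mapping**: per locus and trait, the tie-corrected
   Kruskal–Wallis test with a permutation-validated significance rule,
   Bonferroni corrected Dunn post hoc letters, and scaffold-level
   collapsing of significant markers.
5. **Simulation**: a generator of multiparental pair-cross studies with
   planted ground truth, used by every test in the package.

## The genotype caller

GBS tags of one locus differ only at the positions where the sampled
haplotypes differ, so genotyping can work directly on tag sequences without
a conventional variant caller:

* A Upos group is retained only if at least one of its tags has a
  population-level count strictly greater than `maf_count` (default 100).
  This is an absolute-count screen against low-coverage positions.
* Within a group, tags at a frequency of at most 5% of the group total are
  removed (strictly greater than 5% retains). Frequencies are computed on
  population counts before any removal, within each pair-cross population
  whose coverage passes the screen; a tag survives if it passes in at least
  one such population. The `maf_scope = "joint"` flag pools all populations
  instead — which of the two the original protocol used is ambiguous, and
  the per-population reading follows its explicitly per-population count
  tables.
* Isites are the offsets at which the retained tags disagree; groups with
  no Isite are non-informative and dropped. A tag's *haplotype* is the
  concatenation of its bases at the Isite offsets, so a tag with three
  SNPs yields three-letter alleles such as `GAG`/`CGA`.
* Exclusion rules: a locus is excluded when an Isite carries more than
  `max_alleles` (4) distinct alleles across the population — the maximum
  possible in a pair-cross of two diploid parents — or when any individual
  presents more distinct haplotypes than its ploidy (2). The latter
  condition is our reading of "more unique Isites than the ploidy level";
  the alternative reading (more Isites per tag than the ploidy) is
  available as `exclusion_rule = "isites_per_ploidy"`. The default reading
  is preferred because observed multi-SNP haplotypes of three and four
  sites are part of the reported results, which the alternative reading
  would have excluded.
* Calls: two observed haplotypes → heterozygote; one observed haplotype →
  homozygote only if its count strictly exceeds `min_allele_count`
  (minAC, default 8), otherwise missing, because a shallow observation
  cannot exclude an unseen second allele; zero observations → missing.
  Heterozygous calls carry no count requirement by default (the count
  condition attaches to homozygous calls only); `het_min_count` adds an
  optional per-allele minimum for robustness studies.
* Genotype class labels sort the two haplotypes lexicographically and join
  them with `/` (`CGA/GAG`), making classes unordered.

Boundary semantics are strict inequalities throughout and are unit-tested
(a best tag count of exactly 100 is removed; a tag at exactly 5% is
removed; a single haplotype with count exactly 8 is missing).

## The association scan

* Loci enter the scan when they have at least `min_genotypes` non-missing
  calls (100 for the larger campaign, 50 for the smaller) and a minor
  haplotype frequency of at least 10%. For multiallelic haplotype loci the
  minor frequency is defined as the **second-highest** allele frequency:
  this coincides with the usual minor-allele frequency at biallelic loci
  and requires two common alleles at multiallelic ones, which is what
  class-based testing needs.
* The Kruskal–Wallis H statistic uses midranks and the standard tie
  correction; the asymptotic p-value comes from the chi-square distribution
  with k−1 degrees of freedom. The association **LOD** is defined as
  −log10 of this p-value — the term is never given a formula in the
  K-W QTL-mapping tradition this follows, so the definition is stated here
  prominently. When all observations are tied the tie correction
  degenerates and the locus carries no signal (LOD 0).
* The permutation p-value permutes the phenotype vector against the fixed
  class labels and uses the add-one estimator
  (1 + #{H\* ≥ H}) / (B + 1), which is never zero. The significance rule is
  a conjunction: LOD ≥ 3.0 **and** permutation p ≤ 1%. We read the
  "permutation threshold of 1%" as per-locus (permutations are described
  per test); an experiment-wise maximum-statistic mode is available as
  `perm_mode = "max_T"`.
* Classes smaller than `min_class_size = 2` are dropped before testing
  (the source protocol is silent; a single observation cannot inform a
  rank test).
* Dunn's post hoc z statistics on mean ranks use the same tie correction;
  two-sided normal p-values are Bonferroni-multiplied by k(k−1)/2. Compact
  letters are assigned by insert-and-absorb so that classes sharing a
  letter are not significantly different at 5%; letter `a` goes to the
  class with the highest median.
* Missing trait values are deleted pairwise per locus × trait, which is
  what produces differing n across traits.
* Several tags can map to one genome scaffold; significant records are
  collapsed to distinct scaffolds per trait and overall, with `_1`, `_2`
  suffixes (ordered by position) distinguishing co-located markers.
* `pca_check()` encodes calls as per-locus haplotype dosage columns
  (0/1/2 per retained haplotype — a one-hot encoding that needs no
  arbitrary numeric ordering of multiallelic haplotypes), drops
  invariant columns, imputes missing dosages with the column mean, and
  reports variance-explained proportions. It is a structure diagnostic
  only; no kinship or structure correction is applied downstream, and no
  multiple-testing layer beyond the LOD + permutation rule is added.

All of H, LOD, the permutation p and the Dunn letters are invariant under
strictly increasing transformations of the trait; this rank invariance is
verified in the test suite with exponential and logarithmic transforms.

## The simulator

The generator emulates the study design the package targets: nine
heterozygous founders pair-crossed into eleven populations (default
per-cross sizes sum to 351 genotypes, of which 313 are phenotyped in the
first campaign, 116 in the second and 78 in both), roughly 2,000 unlinked
100 bp tag loci with one to four alleles (defaults give ~55% polymorphic
loci, i.e. ~1,100 informative tags), about a quarter of polymorphic tags
carrying two or more SNPs, negative-binomial read depth, and per-base
sequencing error that spawns spurious low-count tags carrying the true
alignment key of their source locus.

Choices worth stating explicitly:

* **Unlinked loci.** Tags are independent loci; no recombination map is
  modelled. Association is single-marker, so linkage would only matter for
  joint analyses the package does not perform.
* **Traits are a hurdle model.** Only summary statistics of the real traits
  are published, so the generative model is the package's own: a genotype
  responds with logistic probability; conditional on response, embryo
  (ELS) counts are negative binomial (plus one guaranteed embryo), a
  binomial fraction of embryos is cultured on, green-plant production has
  its own hurdle with negative-binomial magnitude, and albino counts are
  negative binomial with EC-proportional mean. Defaults are calibrated once
  to the qualitative shape of the published campaign summaries: ~60%
  responders, median embryo production in the tens per 100 anthers, median
  green-plant regeneration of 0 per 100 cultured embryos with maxima above
  100, and common albino regeneration. The simulator reproduces the
  response shape and zero inflation of real anther-culture data but not
  its between-population heterogeneity or any environment effects, so
  passing tests demonstrate correctness of the statistical machinery, not
  biological realism of any particular effect size.
* **QTL act additively on the logit of each hurdle and multiplicatively on
  magnitudes**, letting one locus influence several correlated traits, as
  observed in practice.
* **Two campaigns** are simulated by drawing the second-year genotype set
  with a configurable overlap (default 78 of 313) and applying additive
  year effects on the response logit and the ELS log-mean.
* **Determinism.** A single global seed drives per-stage derived
  substreams (founders, campaign assignment, read depth, traits), so a
  configuration reproduces byte-identical outputs and partial stages can
  be rerun without disturbing one another.
* **Per-cross offspring counts** are not published beyond totals; the
  defaults are an arbitrary partition of those totals.

## Numerical and scale choices

* Quantiles (for the interquartile range) use linear interpolation between
  order statistics (R type 7), configurable via `quantile_type`; the
  convention used for the published tables is unstated.
* "Plants" is taken as green + albino exactly; chimeric regenerants are
  not modelled.
* Tie handling is midranks everywhere (test and post hoc).
* Permutation counts: the reference protocol uses 10,000 permutations per
  test, which is the package default. The test-suite and acceptance runs
  use 200 permutations and problem sizes of a few hundred individuals by a
  few hundred loci — sizes chosen so the whole validation battery runs on
  a laptop in minutes while leaving every Monte-Carlo check at least three
  standard errors of slack.
* The caller's truth-recovery validation uses error-free reads at a fixed
  depth of 30: with minAC 8, a homozygote is always callable and the
  probability that a heterozygote shows only one haplotype is 2·2⁻³⁰.

## Known limitations

* No imputation, no phasing across loci, and no polyploid support beyond
  the ploidy parameter in the exclusion rule.
* Effect sizes are not estimated — rank-based testing does not provide
  them; class medians with Dunn letters are reported instead.
* Scaffold positions are taken from the alignment references as given;
  comparative anchoring of scaffolds onto linkage groups is out of scope.
* The read simulator models substitution errors only (no indels, no
  adapter read-through, no restriction-site check), matching what the
  downstream exact-collapse tag logic can represent.
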