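---
title: "metlink: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{metlink: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
assumptions it makes, and where the design was genuinely open.  It states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The analysis model

The package targets matched cohorts: per patient a normal sample, 1–6
primary-tumour (PT) regions and one metastasis (MT), with somatic variant
calls per tumour sample (normal already subtracted by the caller) and a
gene × sample matrix of raw RNA-seq counts.

The chain of inference is deliberately simple and rank-based:

1. variants are reduced to a high-confidence "filtered" set by
   conjunctive evidence and population rules;
2. per tumour sample, genes are ordered by expression fold change against
   the matched normal;
3. for a mutation class, the positions of mutated ("altered") genes on
   that ordered list are compared with the positions of all other genes
   by a two-sample Kolmogorov–Smirnov (KS) test.

If mutations of a class systematically perturb expression, altered genes
concentrate in the tails of the fold-change ranking and the KS statistic
grows.  Because the test only uses list positions, it is invariant to any
strictly increasing transform of the fold changes — normalization scale,
log transforms, and so on cannot change the answer (property-tested).

## The filter cascade

Four rules, all conjunctive: tumour allele fraction ≥ `min_allele_fraction`
(default 0.1, inclusive, SNVs only — the rule descends from an SNV-scoped
false-positive filter, so indels bypass it); depth ≥ 20 and ≥ 4
non-reference reads on each strand (inclusive); homozygous calls with ExAC
frequency strictly above 50% removed as common germline; any panel
frequency (ExAC, ESP6500, 1000 Genomes global/European) strictly above 1%
removed.  Missing panel entries count as 0: absence from a panel is not
evidence of commonness.

Because the rules are conjunctive the final set is independent of stage
order (asserted by a property test over permuted orders); only the
per-stage log depends on it.  The implemented order — allele fraction,
depth/strand, common homozygotes, population frequency — runs the evidence
rules before the annotation-based ones, which is also the order consistent
with the stage-log conventions used in the acceptance fixture.

Threshold directions deserve a note: the depth/strand rules are stated as
"≥" and implemented inclusively; the population rules are stated as "more
than" and implemented strictly.  A variant at exactly 1% population
frequency is therefore kept.

## Exclusive metastatic variants and recurrence

Variant identity is the tuple (chrom, pos, ref, alt) — genotype is not
part of it, so a site heterozygous in a PT region and homozygous in the MT
counts as "seen in the primary" and is not exclusive.  EMV = MT set minus
the union of all PT sets of the same patient; the normal sample's calls
are assumed subtracted upstream, with `check_normal = TRUE` available to
re-subtract them when a normal set is supplied.  Recurrence counts
collapse per patient first, so neither sample order nor duplicated records
can inflate them.  Gene mutation rates divide distinct variant identities
per gene by gene length; the length table is a user input (exonic target
length if available, full span otherwise) because no canonical
normalization denominator exists.

## Expression and normalization

Size factors use the median-of-ratios method: for genes with all-positive
counts, the per-sample median of count / geometric-mean ratios.  Factors
are identified only up to a common scale; all downstream use is
scale-free.  Fold changes use a pseudocount of 0.5 on normalized counts —
the smallest symmetric stabilizer that keeps FC finite for zero counts and
rank-stable near zero.  Genes with zero counts in both samples of a pair
carry no information and are dropped (logged).  Ties in FC are broken
lexicographically by gene identifier: deterministic, and irrelevant to the
KS statistic beyond tie granularity.

PCA outlier QC operates on log2(normalized + 1) with gene centering;
samples whose Euclidean distance from the centroid in the first 4
components exceeds a robust z-score (median/MAD) threshold of 3.5 are
excluded from pairing.  A pure library-size outlier is *absorbed by
normalization* and intentionally not flagged; what the QC catches is
compositional deviation.

Term overrepresentation is a plain one-sided Fisher/hypergeometric test
per term, restricted to terms with more than `min_term − 1` and fewer than
2% of the observed genes, with BH adjustment — a deliberate simplification
of conditional GO testing, documented as such.  The "more than 2" bound is
read as term size > 2 genes (configurable), the 2% bound as strict.

## The KS association

`ks_two_sample()` computes D from the two empirical CDFs.  For a smaller
group of ≤ 10 the two-sided p-value is exact: integer lattice-path
counting over all label assignments (the band condition |i·m − j·n| < c is
evaluated in integer arithmetic, so the enumeration is exact to rounding
of the final ratio).  Otherwise the asymptotic Kolmogorov distribution at
effective size n_e = nm/(n+m) is used.  With ties in the pooled data the
exact path-count argument does not apply and the asymptotic (conservative)
branch is taken; rankings produced by `pair_fold_change()` are tie-free by
construction.

Design choices that were genuinely open:

* **Two-sample, not one-sample.**  Altered-versus-unaltered is the
  comparison stated for the published table this reproduces; a
  one-sample-against-uniform mode is available behind `one_sample = TRUE`
  for comparison (the two agree asymptotically when the altered set is
  small).
* **`min_altered = 3`.**  Cells with fewer than 3 altered genes are
  reported as not tested (blank), the natural mechanism for the blank
  cells seen in such tables.
* **Sentinel formatting.**  −log10 p > 10 is displayed as `"Inf"`; the
  numeric p is preserved in machine-readable output.  Significance is
  flagged at p < 0.05.
* **Both "homozygous non-silent" and "silent exonic"** are implemented as
  classes; the non-silent class includes splicing variants and frameshift
  indels but not non-frameshift indels (severity convention; the source
  analysis never defines it precisely).
* A sample/class cell whose altered set covers *every* ranked gene has no
  comparison group; `associate()` raises a usage error, and the matrix
  builder records the cell as not tested instead of aborting the grid.

## The synthetic cohort: what it emulates, what it does not

The generator states a world and the defaults stay fixed; they were chosen
once, before the acceptance measurements, to mirror the cohort structure
the analysis assumes:

* 7 patients, one normal + 1–6 PT regions + one MT each; per-sample
  filtered-burden targets drawn from a low (54–306) or high (1490–3029)
  regime;
* substitution spectrum with C:G-pair mutations 9× A:T-pair and
  transversions 3× transitions, split evenly within strata;
* functional-class mix echoing the observed composition (~46% exonic,
  29% nonsynonymous, 11.4% synonymous, 2.6% stopgain); region categories
  the generator does not model (upstream/downstream/ncRNA) are folded
  into "intergenic", which is why its default weight (0.214) exceeds the
  observed intergenic fraction alone;
* per-site depth NB(mean 100, size 8) matching typical exome coverage;
  strand split 0.5; allele fractions from a clonal/subclonal/homozygous
  beta mixture, with zygosity called homozygous above AF 0.8 (the
  conventional proxy; no calling rule is stated anywhere);
* 30% of MT variants are metastasis-private (the EMV fraction is not
  stated by any source; 30% spans the observed 26–2029 EMV range and is a
  free parameter, not a measured one);
* per sample, 30% extra variants with evidence designed to fail the
  cascade and 5% common population variants, so the filter has real work
  to do;
* expression: log-normal gene base means, log-normal patient effect
  (sd 0.25) as a multiplicative stand-in for a patient covariate,
  log-normal library factors (sd 0.3), NB dispersion 0.1, and a coupling
  that shifts the expected log2 tumour/normal ratio by `coupling_delta`
  for a fraction `coupling_fraction` of genes carrying a non-silent
  filter-passing mutation in that sample.

Coordinates are synthetic (one chromosome, gene blocks of 10 kb with 5 kb
gene spans); nothing downstream reads genomic context.  Population
frequencies are attached per variant rather than drawn from a panel,
because the filter only ever reads the annotation columns.

What the generator does **not** emulate: read-level noise and alignment
artefacts, tumour phylogeny beyond the trunk/private split, copy-number
change, gene–gene expression correlation, and GC or length biases.  A
green test therefore establishes that the *pipeline algebra and
statistics* behave as specified on data with the stated moments — not
that the cascade's thresholds are optimal for any particular sequencing
protocol.

## Numerical choices

* Exact KS path counting rescales the DP row at 1e250 to avoid overflow
  and assembles the final probability in log space; band membership is
  integer arithmetic.
* The asymptotic tail sums 100 alternating Kolmogorov terms (machine
  convergence for any practical n_e·D²).
* BH adjustment is the textbook step-up with cumulative minima; verified
  against the reference implementation to 1e-12 on random inputs.
* Determinism: all simulation flows from the single config seed
  (`simulate_counts` uses seed + 1 so variant tables and counts can be
  regenerated independently); pipeline outputs contain no timestamps, so
  a rerun is byte-identical, which the acceptance suite checks by MD5.

## Known limitations

* Group-level differential expression (the cohort-wide up/down gene
  lists) is out of scope by design: it would need the negative-binomial
  testing machinery with a patient covariate, and only per-pair fold
  changes feed the association matrix.
* The exact KS branch requires a tie-free pooled sample; tied inputs fall
  back to the conservative asymptotic p.
* With very small gene panels and high burden the altered set can swallow
  the whole ranking; such cells are reported untested rather than
  invented.
* The null calibration of the association test is slightly conservative
  (rejection ≈ 4% at α = 0.05 in the acceptance run), inherited from the
  KS test on discrete ranks.
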