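---
title: "Methods: meta-epigenomic analysis with metaepi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta-epigenomic analysis with metaepi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaepi)
```

## Scope and model

`metaepi` analyses prokaryotic and viral DNA methylation (m6A, m4C) in
metagenome-assembled genomes (MAGs) observed through single-molecule
sequencing kinetics. The pipeline runs from per-molecule interpulse-duration
(IPD) ratios to motif methylomes, methylome ordination, single-nucleotide
methylation variation (SNMV), population differentiation (π, F~ST~) versus
methylome divergence, replication-linked methylation gradients, motif
enrichment by genomic region, and bit-score Dice-distance clustering of
viral genomes with motif-depletion scoring.

Because the raw long-read data such analyses start from is far too large to
compute on casually, the package ships a synthetic-community generator
(`synth_config()`, `simulate_genome()`, `simulate_ipd_observations()`,
`simulate_population()`, `simulate_phage_set()`) that emits the same file
formats with known ground truth, so every downstream stage can be validated
by parameter recovery.

## Modification calling from IPD kinetics

A modified base slows the polymerase, raising the IPD ratio relative to an
in-silico control. Per position and strand, `detect_modified_position()`
applies a one-sample, upper-tail *t* test of the molecule-level IPD ratios
against the control mean µ~0~ (default 1). The modification quality value is
QV = −10·log~10~ *p*, capped at 1000 to avoid infinities when *p*
underflows. Degenerate zero-variance samples are handled deterministically:
a constant sample at µ~0~ is unmodified (*p* treated as 1); a constant
sample above µ~0~ with at least 10 molecules is reported at the QV cap.

A site needs ≥ 10× per-strand coverage to be *evaluable* at all, and an
evaluable site is called methylated at QV ≥ 30. The three-valued status
(methylated / unmethylated / unevaluable) is preserved through the whole
pipeline: an uncovered site is never counted as unmethylated.

Because each genomic position pools molecules from many cells, the mean IPD
ratio carries the fraction of cells methylated there. `estimate_fraction()`
uses the method of moments under a two-component mixture,
f = (mean − µ~0~)/(µ~m~ − µ~0~) clipped to [0, 1], with µ~m~ the
fully-modified mean (default 4 for m6A, 2 for m4C). Moment estimation was
chosen over mixture EM: at the 100×-scale coverages this data reaches, EM on
a two-lognormal mixture is unstable, while the moment estimator is unbiased
(mean absolute error ≈ 0.044 at depth 100 in the acceptance run) and has no
tuning. The per-molecule IPD model is lognormal with the arithmetic mean
pinned to µ (meanlog = log µ − σ²/2), so the moment estimator is unbiased by
construction rather than by cancellation.

## Motif methylomes

`scan_motif()` translates an IUPAC motif to a character-class regular
expression and scans both strands with overlapping matches, reporting sites
in plus-strand coordinates. Two conventions matter:

* N in the *genome* never matches any motif symbol — a conservative policy
  that avoids phantom sites in low-quality assembly regions.
* A self-complementary (palindromic) motif such as GANTC yields one site
  per strand per locus, so both-strand bookkeeping counts each locus twice.

The per-genome, per-sample motif methylation ratio
(`motif_methylation_ratio()`) is methylated / (methylated + unmethylated)
over evaluable sites only; a motif below a 20% ratio is treated as noise
and not a candidate methylation motif. Genome–sample pairs are dropped when
their 10× breadth of coverage falls below the kingdom threshold
(`breadth_filter()`: prokaryotes and giant viruses 20%, eukaryotes 10%,
viruses 60%, read as strict-less-than drops).

`build_5mer_profile()` summarises a methylome without motif knowledge: for
each of the 1024 5-mers, the fraction of occurrences whose centre base is
called methylated, among occurrences with an evaluable centre. Both strands
contribute (the minus-strand occurrence is the reverse-complement window)
and 5-mers with no evaluable occurrence are missing, not zero — the
missing/zero distinction is preserved into the dissimilarities, which are
computed over pairwise-complete features. Strand-pooled counting is used;
strand-separate profiles would double the feature space without changing
the ordination structure on palindromic methylomes.

`pair_palindromic_sites()` classifies each palindromic locus as fully
methylated (both strands), hemimethylated (one methylated, the other
unmethylated), unmethylated, or unevaluable (either strand unevaluable
without an unambiguous call).

`discover_context_motifs()` is a deliberately simple context-enrichment
discoverer, not a branch-and-bound motif search: k-mer windows (default
k = 7) centred on methylated bases are tested for enrichment over their
genome background frequency with a one-sided binomial test. Two choices
keep it calibrated: the correction multiplies *p* by the full 4^k
hypothesis space (testing only observed k-mers under-corrects, since with
~100 random windows a birthday-paradox pair collision is likely), and
k-mers supported by fewer than 3 windows are never tested. On random calls
the false-discovery rate across seeds is ≤ 5%; on a planted GANTC
methylome the collapsed consensus is exactly `GANTC`.

`depletion_score()` quantifies motif avoidance as observed/expected, the
expectation coming from an order-1 Markov model fitted to the genome
itself; scores below 1 indicate depletion, as in restriction-site avoidance
by phages.

## Methylome comparison and SNMV

Two bounded dissimilarities are provided with pairwise-complete handling of
missing features: Kulczynski, d = 1 − ½(Σmin/Σx + Σmin/Σy), the default
for 5-mer profiles, and Bray–Curtis, d = Σ|x−y| / Σ(x+y), used for SNMV
and SNV profiles. Both are exposed everywhere via a flag: the two halves of
the source analysis use each in different places, and the package surfaces
the choice rather than resolving it.

`pcoa()` is classical metric scaling: double-centre −½D², eigendecompose,
scale eigenvectors by √λ. Negative eigenvalues (non-Euclidean input) are
reported, not corrected (no Cailliez/Lingoes); axis signs are fixed by
forcing each axis's largest-magnitude loading positive so ordinations are
reproducible.

`build_snmv()` compares methylation fractions site by site across samples.
Only position-strands with ≥ 20× coverage in *every* sample enter the
matrix (complete rows only), so missingness cannot masquerade as
variation. The binary view applies the strict frac > 0.5 rule, and
`site_set_intersections()` reports exclusive (UpSet-style) intersection
cardinalities of the methylated site sets across samples.

## Population genetics

`call_snps()` implements the SNP rule on pileup allele counts: a locus is
polymorphic in a sample when a non-reference allele has frequency > 1% and
≥ 4 supporting reads (both boundaries exact); the SNP set is the union over
samples. Per-position diversity is π~j~ = n/(n−1) · (1 − Σ f²) and genome π
the mean over positions with ≥ 10× depth, monomorphic positions
contributing zero.

F~ST~ between two samples is the Hudson-style ratio of averages,
F~ST~ = 1 − mean(π~X~ + π~Y~) / (2·mean(π~between~)) with
π~between~ = 1 − Σ~a~ f~X,a~·f~Y,a~ per shared position; within-sample π keeps
the n/(n−1) correction, between-sample π needs none (draws are
independent). A ratio of averages is stable at the low per-site diversity
typical of these populations, where an average of ratios is dominated by
noise. `fst_from_frequencies()` evaluates the same estimator on known
allele frequencies; the generator records it as the analytic truth, and
recovery at depth 100 over 1000 loci is within |error| < 0.05 (observed
≈ 0.002). Shannon macrodiversity uses natural logs; `mappability()` is the
percentage of a fixed subsample (49 million read pairs) aligned.

`correlate_methylome_fst()` reports the Pearson correlation between
methylome dissimilarity and F~ST~ over sample pairs with its *t*-based
*p*, and a Mantel permutation *p* alongside, because distance-matrix pairs
are not independent observations.

## Replication structure and the methylation gradient

In many bacteria the leading strand carries a G excess, so the GC skew
(G−C)/(G+C) flips sign at the replication origin and terminus.
`gc_skew()` computes windowed skew (defaults window 1000 bp, step 100 bp)
and its cumulative sum; `locate_ori_ter()` places *ori* at the cumulative
minimum and *ter* at the maximum, ties to the lowest coordinate, with a
warning and missing result on flat profiles. Multi-contig MAGs must be
concatenated in a user-supplied order first — contig order is an input,
never guessed. On synthetic replicons with skew amplitude 0.1 the planted
origin is recovered within ±2 windows (±2000 bp at the defaults).

CcrM-type methyltransferases act after the replication fork, so in a
growing population positions near *ori* spend longer hemimethylated and
their pooled methylation fraction is depressed. The generator's gradient
model is the simplest monotone form consistent with that mechanism: the
hemimethylated cell fraction is h(d) = h~0~·(1−d) with d the relative
replichore position (`relative_position()`: 0 at *ori*, 1 at *ter*, linear
on each replichore, rotation-invariant), giving a per-strand methylated
fraction m(d) = 1 − h~0~(1−d)/2 at palindromic sites.
`methylation_gradient()` bins fractions over d (20 bins), compares the
*ori* region (d ≤ 0.1), *ter* region (d ≥ 0.9) and the rest with two-sided
rank-sum tests — the 10% region half-width is this package's default since
no standard width exists — and fits h~0~ by single-parameter least squares
(clamped to [0, 1]; a saturated methylome fits h~0~ = 0 exactly). Recovery
across h~0~ ∈ {0.2, 0.4, 0.6, 0.8} at depth 100 is within ±0.1. The fit
should be run over sites *called methylated*: loci the MTase never
methylates sit at fraction ≈ 0 regardless of replication timing, and
including them inflates the apparent gradient (the pipeline applies this
filter).

## Motif enrichment by region

`classify_regions()` partitions each contig into genic, regulatory and
intergenic classes with precedence genic > regulatory > intergenic. The
regulatory class is a strand-aware window of R = 100 bp immediately
upstream of each gene start (truncated at contig edges and neighbouring
genes); 100 bp covers typical bacterial promoter spacing, is configurable,
and is reported in output because no standard definition exists.

`shuffle_null()` builds the null by re-placing, per strand, the observed
number of genes at the observed mean gene length uniformly without overlap
(500 replicates by default), keeping motif sites fixed and recomputing the
three region densities. Uniform non-overlapping placement uses the exact
sorted-uniform construction on the compacted line, which is the same
distribution as rejection sampling without a retry cap. Gene lengths are
the fixed observed mean rather than resampled — the literal reading of an
average-length shuffle — with the empirical-resampling alternative left as
a flag-level extension. `enrichment_test()` converts the observed density
to a two-sided *p*: via z = (obs − mean)/sd and the normal tail when the
null passes a Shapiro–Wilk check (p > 0.05), otherwise via a two-sided
empirical *p* with the +1 correction. Two-sided, because both enrichment
and depletion are of interest. Under a uniform null the type-I error at
α = 0.05 is 0.066 over 1000 synthetic genomes (200 replicates each),
within the [0.03, 0.07] calibration band.

## Viral genome clustering

`bitscore_sums()` aggregates a pairwise hits table into AB = the bit-score
sum of all hits between genomes A and B, averaging the two directions when
both are present (translated-alignment scores are not symmetric; averaging
restores metric symmetry), and requiring a positive self sum AA for every
genome retained. The Dice distance is D(A,B) = 1 − 2·AB/(AA+BB), the only
parenthesisation of the source formula that is bounded in [0, 1] and
consistent with the Dice coefficient; it is clamped to [0, 1] and
D(A,A) = 0 exactly.

`neighbor_joining()` is the standard Saitou–Nei agglomeration with two
determinism rules: Q-matrix ties break to the lowest label-index pair, and
negative branch lengths are clamped to zero with the total deficit recorded
on the tree. It recovers random additive trees up to 12 taxa exactly
(path-length error < 1e−7) and matches `ape::nj` topologies, which serves
as the independent cross-check, never the implementation.
`clade_density_association()` closes the loop with a two-sided rank-sum
test of per-genome motif density between tree clades; on synthetic phage
sets with a 0.2 depletion factor the depleted clade separates at p < 0.01
and the NJ tree recovers both clades monophyletically.

## The synthetic generator: what it emulates, and what not

Defaults are fixed once to the study conditions the package targets:
10 samples (stations), ~100× per-strand depth at evaluable sites (the
source data averaged ≈ 113× at motif sites), a GANTC methylome at 90%
per-locus methylation probability (observed per-sample ratios span
71–95%), gradient amplitude h~0~ = 0.6, GC content 0.4 with skew amplitude
0.1, and phage sets of 10+10 genomes at 4 motif loci/kb with a ×0.2
depleted clade. Replicon length defaults to 50 kb and the test suite runs
smaller (5–20 kb) corpora — these are the package's simulation scales,
chosen so full parameter-recovery suites stay interactive; all lengths are
configurable upward. One master seed fans out into named substreams, so
adding a component never reshuffles another's draws and a fixed seed
reproduces the corpus byte for byte.

The generator emulates: per-replichore G/C composition bias flipping at
*ori*/*ter*; non-overlapping strand-assigned genes; planted motif loci
(background occurrences are first removed, so planted density is true
density); per-molecule lognormal IPD kinetics with binomial cell-fraction
mixing; binomial read counts at Poisson depth over designed two-group
allele frequencies; and a bit-score table realising designed within/between
Dice distances. It does not emulate: read-level sequence errors, mapping
bias, context-dependent kinetic signal (the µ~m~, σ defaults are plausible
stand-ins, not measured values), strain-linked methylation, or genome
rearrangements. Passing recovery suites therefore demonstrates estimator
correctness under the declared model, not robustness to assembly or
mapping artefacts in real data.

## Numerical and degenerate-input policies

* QV cap 1000; *p* = 0 reports the cap, never infinity.
* Zero-variance IPD samples: deterministic policy above.
* Zero evaluable motif sites → missing ratio, never 0; all-unevaluable
  loci → unevaluable, distinct from unmethylated.
* Zero-sum profile vectors → missing dissimilarity; all-zero pairs →
  missing Bray–Curtis.
* G+C = 0 windows → skew 0; flat cumulative skew → warning + missing
  ori/ter.
* mean π~between~ = 0 → missing F~ST~ (no divergence information);
  F~ST~(X,X) is 0 by definition.
* Empty region classes → missing density; sd = 0 nulls take the empirical
  branch with the +1-corrected *p*.

## Known limitations

* De novo discovery is a context-enrichment screen; it will not find
  bipartite motifs with long gaps (e.g. Type I recognition sites).
* The gradient model is linear in replichore position; richer
  replication-age models are an extension point.
* Ori/ter localisation assumes a single circular replicon with canonical
  leading-strand G excess; plasmids and heavily rearranged MAGs violate
  this.
* F~ST~ and π read depths are treated as independent draws; duplicated
  reads or strain-aware mapping filters must be applied upstream.
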