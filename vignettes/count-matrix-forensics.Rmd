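---
title: "Forensics for contaminated metagenomic count matrices and normalization leakage"
author: "leakforensics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forensics for contaminated metagenomic count matrices and normalization leakage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The two failure modes this package models

Metagenomic profiling of host-derived samples (tumor biopsies, tissue,
blood) classifies sequencing reads against a database of microbial
genomes. Two distinct mistakes can make such profiles — and any machine
learning built on them — look far more informative than they are:

1. **Database contamination.** Draft microbial assemblies often carry
   mislabeled host-derived contigs. If the classification database
   contains such a draft but *not* the host genome, then host reads
   matching the contaminated contig are confidently assigned to the
   microbe. Because host reads dominate these samples by orders of
   magnitude, a single contaminated draft can inflate a genus's read
   count a hundred-fold or more.

2. **Normalization label leakage.** A supervised normalization that is
   (mis)applied with the outcome label in the wrong role can imprint
   per-class values onto features — even features whose raw counts are
   identically zero. Classifiers trained on such data rediscover the
   imprinted label and report near-perfect accuracy on data that
   contains no biological signal at all.

`leakforensics` implements both mechanisms end to end on synthetic data,
plus the diagnostic statistics that expose them in a given pair of
raw/normalized matrices. Everything is generated in code; no external
data is required.

## The k-mer LCA classifier

The classifier is the standard exact-match scheme used by Kraken-family
tools. A database maps every *canonical* k-mer (the lexicographic
minimum of a k-mer and its reverse complement; k = 31 by default, odd so
a k-mer is never its own reverse complement) occurring in any source
genome to the lowest common ancestor (LCA) of all genomes containing
it. The taxonomy is a four-rank tree (root, domain, genus, genome)
built from the taxon paths carried in genome records. To classify a
read, hits are accumulated per taxon over the read's canonical k-mers,
every root-to-leaf path is scored by the sum of hits on its nodes, and
the read is assigned the leaf of the maximal path; tied leaves resolve
to their LCA; a read with no database hits is unclassified. K-mers
containing non-ACGT characters are skipped. Genus-level counts
aggregate reads assigned at or below genus rank; assignments above
genus rank (domain, root) count toward no genus.

Two choices deserve a note. The tie-break by LCA of tied leaves is the
classical behaviour of the original k-mer classifiers; it is what turns
"equally good sibling genomes" into a genus-level call. And the host is
modeled as a taxon under its own domain, so a k-mer shared between the
host genome and a contaminated draft has its LCA at the *root* — which
is exactly the mechanism by which adding the host genome to the
database collapses false genus assignments. An optional host pre-filter
(dropping reads whose fraction of host-lineage k-mer hits is at least
0.5) abstracts the common practice of re-aligning reads to a host
reference before microbial classification; it models the effect of that
screening on database hits, not the aligner itself.

The k-mer core (encoding, database construction, binary-search lookup,
path scoring) is in C++ via Rcpp, as is usual for k-mer tools; all
orchestration is plain R. Databases are held as sorted 62-bit codes
split into two 31-bit integer halves, which keeps them serializable as
plain JSON integers.

## The synthetic data generator

The generator produces exactly the inputs the two mechanisms need, with
provenance sufficient to audit every downstream claim:

* **Genomes** are i.i.d. base sequences at a chosen GC fraction. Host
  genomes default to GC 0.41 (the human value); microbial genomes to
  0.5. Real genomes have repeats, homopolymers and shared ancestry that
  random sequence lacks; random sequence is the *conservative* choice
  here, since spurious 31-mer matches between independent random
  megabase-scale genomes are essentially impossible — any cross-genus
  assignment observed in the experiments is therefore attributable to
  the engineered contamination, not to background similarity.
* **Contaminated drafts** append a contiguous host substring (uniform
  random start) to a microbe while keeping its taxon label. Appending
  rather than inserting keeps provenance bookkeeping trivial; position
  within the genome is irrelevant to exact k-mer classification.
* **Reads** are single-end, fixed-length (default 150 bp, a typical
  short-read length), drawn uniformly without wrapping the genome end,
  with i.i.d. substitution errors (default 0.1%) and no indels — indels
  would only dilute exact k-mer hits without changing any conclusion.
  Each read records its source genome, start position, and the
  provenance segment covering its start, so "how many reads assigned to
  genus X are actually host reads" is an exact bookkeeping query.
* **Count matrices** have no class signal by construction: common
  genera are negative binomial with variance `mu + phi * mu^2`
  (mean 50, dispersion phi = 0.5 by default — overdispersion typical of
  microbiome counts), rare genera are non-zero in a fixed handful of
  samples, and zero genera are identically zero. Library sizes are the
  row sum plus a host-read allowance (default one million), reflecting
  that nearly all reads in host-derived samples are host reads.
* **Fixtures** reconstruct published single-genus case studies from
  their printed descriptions: declarative per-class value generators
  (constant tags, distinct uniform fillers, normal noise) over a stated
  raw-zero mask. Fixture statistics (cluster sizes, rule sensitivities)
  are exact by construction; only the filler values are random.

All randomness flows from one integer seed through `child_seed()`, a
stable string hash of stage names, so adding a stage never perturbs
another stage's stream, and every report is byte-reproducible.

## Normalization and its leaky misuse modes

`voom_logcpm()` is the log2 counts-per-million transform with a 0.5
pseudo-count: `log2((c + 0.5) / (L + 1) * 1e6)`. Precision weights are
deliberately omitted — the leakage phenomena live in the values, not
the weights. A zero count maps to a value that depends only on the
library size; with a library size near one million that anchor sits
near −1.

`supervised_normalize()` fits, per feature, an ordinary least squares
model on a design with the biological covariate (effects retained) and
the adjustment covariate (effects removed), and subtracts the intercept
and adjustment components. Categorical covariates use sum-to-zero
contrasts so that, under balance, the intercept is the grand mean and
the output of a no-op adjustment is simply the centered input. A
rank-deficient design is an error naming the collinear columns. This
honest mode provably cannot create class structure on all-zero
features: with class-independent constant library sizes their values
are constant, and the pipeline invariant tests verify that the
downstream classifier stays at chance (median AUC in [0.4, 0.6]) even
with random library sizes.

Because the precise mechanism by which real published matrices acquired
their per-class tags is not knowable from the outside, the package
ships leakage as two *explicit, named misuse modes* rather than
claiming to replicate any particular code path:

* `leak_mode = "class_offsets"` adds to every all-zero-raw feature a
  per-class constant drawn `N(0, offset_sd^2)` plus within-class noise
  `N(0, noise_sd^2)` (defaults 1 and 0.05). With zero noise this
  produces identical repeated values within a class — the
  duplicate-value tag signature; with small noise it produces tight
  clusters. It emulates fitted class means being written back into
  features that contained no information.
* `leak_mode = "libsize_coupling"` multiplies library sizes by a
  per-class log-normal factor before the log-CPM transform, so the
  zero-count anchor alone separates classes. This demonstrates that
  leakage does not require touching the values directly — coupling any
  transform parameter to the label suffices.

Either mode suffices to drive the downstream classifiers to
near-perfect accuracy on information-free data; neither is asserted to
be *the* mechanism behind any particular published matrix.

## Forensic statistics

* `inflation_report(A, B)` compares two count matrices entry-wise. At
  threshold T, pairs with `A >= T` are considered; a pair is ten-fold
  inflated when `A >= 10 B` (with `B = 0` counting as inflated — the
  ratio is infinite); a pair is within-50% when `B >= 1` and
  `A` lies in `[0.5 B, 1.5 B]`. The within-50% column is defined
  relative to the re-analysis count `B` and computed over the `A >= T`
  pair universe at the smallest threshold; both choices are documented
  here precisely because published tables rarely state them. Fractions
  are exact ratios; rounding is display-only.
* `duplicate_value_clusters()` groups samples sharing a value after
  rounding to 9 significant digits — the precision at which published
  normalized matrices print their repeated tags. The tolerance is
  configurable; at coarser tolerance nearby tags merge.
* `threshold_rule_eval()` scores a one-feature decision rule in any of
  the four directions (`ge`, `gt`, `le`, `lt`). Inclusive directions
  matter: a tag value shared by most positive samples only yields its
  published sensitivity if samples *at* the threshold are counted as
  positive.
* `best_threshold_rule()` scans midpoints of consecutive sorted unique
  values in both inclusive orientations and maximizes balanced
  accuracy; scanning both orientations guarantees a result of at least
  0.5, and ties prefer the smallest threshold with direction `ge`.
* `discordance_scan()` flags features that are informationless in the
  raw matrix (all zero, or non-zero in under 1% of samples) yet support
  a threshold rule with balanced accuracy above 0.75 — the signature of
  values that can only discriminate through the normalization itself.
  These are diagnostics, not inference: no multiplicity correction is
  applied, by design.

### The reconstructed case-study fixtures

The adrenocortical-carcinoma fixture deserves a note on its exact
numbers, because the published description of this case is internally
inconsistent at the margin: a stated count of "other samples at or
below the tag value" and a stated total error count cannot both hold
for any single threshold rule once the eight positives above the tag
are counted as false negatives. The fixture here realizes the two
headline statistics exactly — 71 of 79 positives at the tag value
(sensitivity 90%) and 77 total errors among 17,625 samples (error rate
0.4%) — which places 69 non-positive samples at or below the tag and
the eight remaining positives above it. The tag sits at the low end of
the value range (as in the published figure), so the positive rule is
"value at or below the tag".

The head-and-neck fixture (906 samples: 70 normal, 693 tumor, 143
blood, raw counts all zero) puts every normal sample below every tumor
sample, with duplicated-value clusters of 38, 18 and 5 normals at the
three published tag values. The kidney-chromophobe fixture (51 tumor,
41 normal, seven raw counts of 1) gives tumor and normal disjoint
normalized ranges.

## The information-free classification experiment

`extract_empty_submatrix()` keeps genera non-zero in fewer than 50
samples, then drops samples with any non-zero retained genus; the
result is identically zero (asserted, not assumed).
`populate_from_normalized()` then substitutes, by sample/genus key, the
corresponding normalized values; `run_fig6_experiment()` restricts to
primary tumor samples and hands the populated matrix to
`one_vs_all_evaluate()`.

The evaluation trains, per class, gradient-boosted shallow trees
(xgboost: 150 trees, depth 3, learning rate 0.1, single-threaded for
determinism — the model family used by the studies this package
scrutinizes, with hyperparameters chosen once and logged in the result)
under stratified 10-fold cross-validation, and scores out-of-fold
probabilities: sensitivity, specificity, PPV and NPV at probability
0.5, and the threshold-free AUC by trapezoid integration of the ROC
(with tie handling; a constant score gives exactly 0.5). Undefined
ratios (0/0) are excluded from the across-class medians. The AUC
implementation is cross-checked against an independent ROC package in
the test suite.

## Problem sizes and numerical choices

The designed simulations run at deliberately modest scale, chosen so a
desk machine reproduces them in about a minute while every qualitative
mechanism operates far from its margins: the contamination experiment
uses a 1 Mbp host, ten 200 kbp microbes, a 100 kbp contaminant contig
and 100,050 error-free 150 bp reads (about a tenth of host reads fall
in the copied region, so the contaminated genus count collapses roughly
200-fold when the host genome enters the database — comfortably beyond
the 132-fold benchmark); the leakage experiment uses 32 classes × 100
samples × 66 all-zero features with offset-to-noise ratio 20, which is
separable enough that median sensitivity and specificity sit at 1.0.
Property tests run the same machinery at kilobase/handful scale, where
the k-mer database is checked verbatim against a brute-force
enumeration and the LCA against ancestor-set intersection.

Degenerate inputs are handled explicitly: genomes shorter than k
contribute no k-mers; reads shorter than k are unclassified; an empty
extracted submatrix warns rather than errors; one-class label vectors
are errors for rule evaluation and classification; `contig_length = 0`
returns the genome unchanged.

## What passing tests do and do not show

Everything here runs on synthetic sequence and synthetic counts. The
experiments demonstrate *mechanisms* — that database composition alone
can manufacture or erase six-figure genus counts, and that
label-coupled normalization alone can manufacture near-perfect
classifiers from all-zero data — under conditions where every read's
true origin is known. They do not estimate the contamination rate of
any real database, the leakage of any particular published matrix, or
classifier performance on real microbiome data; real genomes share
k-mers for legitimate biological reasons that random sequence does not
model, so absolute false-positive rates here are lower bounds. The
forensic statistics, by contrast, apply unchanged to real paired
raw/normalized matrices in TSV form.
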