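---
title: "Classifying coding potential from the Morse wavelet scalogram"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying coding potential from the Morse wavelet scalogram}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncwave)
```

## The problem

Long non-coding RNAs (lncRNAs) are transcripts, conventionally longer than
200 bp, with little or no protein-coding capability. Telling them apart from
protein-coding RNAs (pcRNAs/mRNAs) from sequence alone is the first screening
step in most lncRNA studies, and alignment-free tools are preferred when the
species is poorly annotated. `lncwave` implements a feature-based classifier
for this task: a transcript is turned into a numeric signal, analysed with a
continuous wavelet transform, summarised into seven multi-scale "energy
segment" features, combined with eight classic coding-potential features,
screened for redundancy, and classified with a random forest (lncRNA is the
positive class throughout).

## From sequence to scalogram

Each base is mapped to a real amplitude through an encoding table. The
mathematics downstream is invariant to the particular table (an overall
rescaling multiplies the scalogram by a constant, which the above-mean
segmentation cancels), so the table is a recorded configuration choice rather
than a tuned parameter. Two tables ship with the package:

* `pk_default` — the acid-dissociation constants (pKa) of the free
  nucleobases (A 3.5, C 4.2, G 9.2, T 9.7), a proxy for the local
  protonation/charge behaviour of the chain;
* `eiip` — the electron–ion interaction potentials
  (A 0.1260, C 0.1340, G 0.0806, T 0.1335), a common alternative in genomic
  signal processing.

The signal is zero-meaned, reflection-padded to the next power of two
(reducing edge artifacts in position-sensitive features; circular padding is
available and gives exact shift covariance), and transformed with the
analytic generalized Morse wavelet

$$\varphi(\beta,\gamma;\omega) = U(\omega)\, a_{\beta,\gamma}\,
  \omega^{\beta} e^{-\omega^{\gamma}},$$

with the widely used defaults $\beta = 20$, $\gamma = 3$. $U$ is the unit
step, so the wavelet is analytic and a constant signal has exactly zero
response. The peak angular frequency is
$\omega_p = (\beta/\gamma)^{1/\gamma}$, and $a_{\beta,\gamma}$ is fixed so the
frequency-domain peak value is 2, the usual analytic-wavelet convention; any
other positive constant would cancel downstream. Each of the 35 layers $j$ is
assigned the scale $s_j = j\,\omega_p/(2\pi)$, so layer $j$ responds
maximally to periodicities of $j$ bases and the layer axis reads directly as
a base-length footprint; the spacing is linear, not dyadic, because the
features treat layers as base-length units. L1 scale normalization keeps peak
magnitudes comparable across layers. Transforms are computed per layer in the
frequency domain via the FFT; the test suite checks this path against a
direct time-domain circular-convolution oracle to $10^{-8}$ relative error.

## The seven wavelet features

Coefficient magnitudes of layers 1–20 are summed column-wise into one power
value per base position (the column-sum profile, SCWS). The positions whose
power strictly exceeds the profile mean form maximal contiguous segments
(SCWSS) — the transcript's high-energy regions. Strict inequality makes a
constant profile featureless instead of one giant segment. From the segments:

| Feature | Definition |
|---|---|
| `Count` | number of segments |
| `LenMean` | mean segment length |
| `LenVar` | variance of segment lengths (population variance by default; configurable) |
| `MidMean` | mean of the corrected midpoint statistic below |
| `30Count` | segments in the top third by length that are longer than 30 bases |
| `30PwMean` | mean power of those same segments |
| `30LenCount` | mean length of all segments longer than 30 bases |

The corrected midpoint statistic of a segment spanning 0-based positions
$[P_{start}, P_{end})$ is

$$FMid = \tfrac12\,(P_{end}-P_{start})/P_{end} \in (0, 0.5],$$

a per-transcript-normalization-free position summary: a single transcript can
be scored without any dataset-level standardization. $P_{end}$ is the
segment's end coordinate, which is what makes a whole-prefix segment score
exactly 0.5.

Two filters make the `30*` features biologically meaningful and
length-robust: the 30-base floor is the nucleotide length of the shortest
known protein (shorter high-energy runs cannot encode anything), and the
top-third rank filter keeps the long, rare segments that the coarse layers
produce rather than the many short runs contributed by layers 1–6 (one third
of the 20 summed layers). The top third is read as the first
$\lceil Count/3 \rceil$ segments ranked by length descending, ties broken by
earlier start for determinism; the literal alternative (length $> Count/3$)
is available behind `third_rule = "length_vs_count"`. Means over empty
subsets are 0, never NaN, so feature vectors stay finite.

## The eight classic features

Sequence length; GC percentage; the population standard deviation of the
counts of TAA/TAG/TGA as overlapping substrings over the whole transcript;
ORF integrity (1 complete / 0.5 partial / 0 none) of the longest forward-
frame ATG-initiated ORF; a CDS score; ORF coverage percentage; the
theoretical isoelectric point of the longest-ORF peptide
(Henderson–Hasselbalch per ionizable group, EMBOSS pKa set, bisection to
$10^{-3}$ pH, sentinel 0 when no ORF); and the Fickett TESTCODE statistic
(codon-position asymmetry and composition of each base, mapped through the
published lookup tables shipped as a plain-text data file).

The CDS score is a self-contained surrogate for an external CDS predictor:
ORF span + 50 per terminal signal (start, stop) + 25 for a Kozak-consistent
start context (purine at −3, G at +4). It is deterministic, monotone in ORF
length, and recorded in the model bundle; an adapter that shells out to a
`txCdsPredict` binary is provided for users who have one, but scores from the
two modes are not comparable and a model trained under one mode refuses
features produced under the other.

The ORF search scans the three forward frames only (transcripts are assumed
sense-strand) with ATG as the only start codon; terminal ATG-runs without a
stop are kept as incomplete candidates so 5'-complete/3'-truncated
transcripts still score.

## Screening and classification

The 8 + 7 = 15 features are screened once, on training data only, by a
greedy Pearson correlation filter: scanning pairs in canonical column order,
the later-ordered member of any pair with $|r| > 0.8$ is dropped. Absolute
correlation is used because an anticorrelated duplicate is equally
redundant; the drop-later rule makes the screen deterministic; zero-variance
columns are treated as uncorrelated. The retained set is frozen into the
model bundle and reused verbatim at prediction time — test data is never
re-screened, preventing leakage.

The classifier is a random forest (500 trees, $\lfloor\sqrt p\rfloor$
features per split, fixed seed). The bundle snapshots the forest, retained
feature names, encoding table, wavelet parameters, CDS-score mode and seed,
and prediction refuses tables that do not match. Performance is reported as
ACC, SEN, SPE, MCC from the thresholded confusion matrix (threshold 0.5,
exposed as a flag) and the rank-form AUC

$$AUC = \frac{\sum_{+} rank_i - \tfrac12 M(1+M)}{M\,N},$$

with midranks for tied scores (equivalent to Mann–Whitney pair counting with
half credit for ties; the suite verifies the identity exactly).

## The synthetic data generator

Real training corpora for this problem are large downloads; the package
instead ships a seeded generator of two separable classes so every stage is
testable offline:

* **coding-like** (`pcRNA`): random 5' UTR, ATG, codons drawn from a fixed
  skewed codon-usage table (one preferred codon per amino acid at 6× weight,
  blended with uniform at strength 0.8), a stop, random 3' UTR. The planted
  ORF covers 60% of the transcript; an in-frame stop ends the 5' UTR so a
  chance upstream ATG cannot extend it.
* **noncoding-like** (`lncRNA`): i.i.d. bases with stop codons written every
  90 bp in all three frames, capping chance ORFs near the 30-codon floor.

Lengths are uniform on 250–3000 bp and both classes target 50% GC: UTR
composition compensates the codon-table GC on the coding side, and the
i.i.d. composition compensates the AT-rich planted stops on the noncoding
side, so the classes are GC-matched *by construction* (mean difference under
2 percentage points; GC alone scores an AUC near 0.5). Class separation must
therefore come from the ORF/periodicity structure that the wavelet and ORF
features measure — which is exactly what the end-to-end tests demonstrate
(5-fold CV accuracy ≥ 0.90 and AUC ≥ 0.95 on the default 500-per-class set).

What the generator does **not** emulate: splice isoforms, expression levels,
homology between transcripts, UTR composition biases, pseudogenes, or the
class imbalance of real annotation sets. Passing tests show the pipeline
recovers planted structure reproducibly; they do not certify accuracy on any
real transcriptome, which depends on training data the user supplies.

## Numerical and design choices

* Ambiguity codes: dropped by default before encoding (a seeded
  length-preserving random replacement and a strict error mode exist);
  U→T so one alphabet exists downstream. Sub-200 bp transcripts warn but are
  processed.
* Degenerate inputs: a homopolymer yields an exactly zero scalogram (the
  analytic wavelet has no zero-frequency response), hence zero wavelet
  features; no-ORF transcripts use 0 sentinels for ORF-derived features and
  pI. Every feature vector is finite.
* Population variance for `LenVar` (configurable to sample variance).
* Determinism: every stochastic step (generator, fold assignment, forest)
  is seeded; identical seeds give byte-identical FASTA, feature TSVs and
  predictions, and each artifact-producing CLI command writes a JSON
  manifest with the fully resolved configuration.
* Problem sizes in the shipped tests: oracle checks run at 1000 random
  profiles, 500 random sequences for the ORF oracle, signals ≤ 128 for the
  convolution oracle, and 500 transcripts per class end-to-end; these sizes
  make the properties sharp while keeping the default suite around two
  minutes on one CPU.

## Known limitations

* The Morlet wavelet, mentioned as an equally suitable analytic wavelet, is
  not implemented (the configuration hook is reserved).
* The wavelet features are computed from the collapsed column-sum profile
  only; per-layer (2-D) scalogram texture is deliberately out of scope.
* The surrogate CDS score is not on the scale of any external predictor's
  score; models must be trained and applied under one mode.
* No homology, structure or ribosome-profiling features: the package targets
  the annotation-free setting by design.
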