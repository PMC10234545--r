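# lncwave

Wavelet-based classification of transcripts into long non-coding RNAs
(lncRNAs) and protein-coding RNAs (pcRNAs).

## What it does and for whom

Screening assembled transcripts for coding potential is the first step of
most lncRNA studies, and tools that need genome annotation or homology
databases fail exactly where lncRNA discovery happens — poorly annotated
species. `lncwave` is an annotation-free, alignment-free classifier for that
setting: everything is computed from the transcript sequence itself.

The idea is to treat a transcript as a non-stationary signal. Each base is
mapped to a physicochemical amplitude (nucleobase pKa by default) and the
signal is analysed with the analytic **generalized Morse wavelet**

    φ(β, γ; ω) = U(ω) · a_{β,γ} · ω^β · e^(−ω^γ),    β = 20, γ = 3,

whose scalogram resolves charge/composition structure by *position* and
*scale* simultaneously — unlike k-mer counts or Fourier spectra, which
discard position. Coefficient magnitudes of layers 1–20 (layer *j* reads as a
*j*-base footprint) are summed column-wise into a per-position power profile
(SCWS); the maximal runs strictly above the profile mean (SCWSS) are the
transcript's high-energy segments. Seven features summarise those segments —
count, mean and variance of length, the normalization-free corrected midpoint
statistic FMid = ½(P_end − P_start)/P_end ∈ (0, 0.5], and three features of
the long (> 30 bases, the shortest known protein) top-third segments. Eight
classic features (length, GC%, stop-codon count dispersion, ORF integrity /
coverage / CDS score, peptide isoelectric point, Fickett TESTCODE statistic)
complete the 15-column table. A Pearson screen drops one member of every pair
with |r| > 0.8 (fit on training data, frozen into the model), and a seeded
random forest (500 trees) does the classification. Performance is reported as
ACC, SEN, SPE, MCC and the rank-form (Mann–Whitney) AUC with midrank ties.

## Worked example

The package ships a seeded two-class simulator (coding-like transcripts with
a planted, codon-biased ORF; GC-matched noncoding-like transcripts with
suppressed ORFs), so the full pipeline runs without any download:

```r
library(lncwave)

cfg   <- synth_config(n_per_class = 100, seed = 42)
seqs  <- simulate_transcripts(cfg)
features <- extract_features(seqs)
head(features[, c("seq_id", "seq_len", "GC_content", "CDS_percent",
                  "Fickett_Score", "Count", "MidMean", "30LenCount",
                  "label")], 4)
#>     seq_id seq_len GC_content CDS_percent Fickett_Score Count MidMean
#> 1 lnc_0001    2552      50.43       3.527        0.5542    55 0.02225
#> 2 lnc_0002    2047      49.19       4.397        0.4980    48 0.02209
#> 3 lnc_0003    2351      51.13       3.445        0.4456    51 0.01997
#> 4 lnc_0004     853      51.93       8.792        0.4862    23 0.05046
#>   30LenCount  label
#> 1      55.06 lncRNA
#> 2      54.89 lncRNA
#> 3      51.67 lncRNA
#> 4      51.25 lncRNA
```

Noncoding-like transcripts have near-zero ORF coverage and lower Fickett
scores despite matched GC. Five-fold cross-validation and a final model:

```r
cv <- lnc_cv(features, k = 5, seed = 42)
str(cv$metrics)
#> List of 9
#>  $ tp : int 100
#>  $ fp : int 0
#>  $ tn : int 100
#>  $ fn : int 0
#>  $ acc: num 1
#>  $ sen: num 1
#>  $ spe: num 1
#>  $ mcc: num 1
#>  $ auc: num 1

model <- lnc_train(features, seed = 42)
model
#> lncwave random-forest model (schema 1 )
#>   features: seq_len, GC_content, Stop_std, Orf_fullness, CDS_Score,
#>     CDS_percent, PI, Fickett_Score, LenMean, LenVar, MidMean, 30PwMean
#>   trees: 500; encoding: pk_default; CDS mode: surrogate; seed: 42

lnc_predict(model, features[1:3, ])
#>     seq_id prob_lncRNA  label
#> 1 lnc_0001       0.996 lncRNA
#> 2 lnc_0002       0.998 lncRNA
#> 3 lnc_0003       0.994 lncRNA
```

The two classes separate perfectly on this synthetic set (out-of-fold
accuracy and AUC = 1.0): the wavelet segment features and ORF features carry
the signal, while GC content alone is uninformative by construction (AUC
≈ 0.52). The correlation screen retained 12 of the 15 features here
(`Count`, `30Count` and `30LenCount` were collinear with retained columns);
the retained set is stored in the model and reused at prediction time.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/lncwave.R simulate --n 500 --seed 7 --out synth.fa --labels synth.tsv
Rscript inst/cli/lncwave.R extract  --fasta synth.fa --out features.tsv
Rscript inst/cli/lncwave.R train    --features features.tsv --out model.rds --seed 7
Rscript inst/cli/lncwave.R predict  --model model.rds --fasta synth.fa --out pred.tsv
Rscript inst/cli/lncwave.R evaluate --pred pred.tsv --labels synth.tsv
```

Every artifact-producing command writes a `<out>.manifest.json` with the
fully resolved configuration, seed and package version, so any artifact is
reproducible from its manifest alone.

## Documentation

The methods vignette (`vignettes/lncwave-methods.Rmd`) describes the model
and its assumptions, all tunable parameters with defaults and rationale, what
the synthetic generator does and does not emulate, numerical choices, and
known limitations.
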