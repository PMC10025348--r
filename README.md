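# courttone

Courtroom speech emotion analysis: does the vocal emotion a defendant hears
in court — the judge's voice, the plaintiff's voice — relate to the
defendant's own emotional state and to the logical clarity of their
argument?

`courttone` is an end-to-end, fully testable R implementation of that
analysis for researchers in affective computing and legal psychology. Real
hearing audio of this kind cannot be redistributed, so the package pairs the
analysis pipeline with a seeded synthetic courtroom generator that plants a
known emotion-influence structure, making every stage verifiable by
parameter recovery.

The pipeline:

1. **Synthetic corpus generator** — multi-utterance court sessions with
   three roles (judge, plaintiff, defendant), three vocal emotions (angry,
   neutral, fear) realised acoustically through pitch level/variability,
   jitter, loudness and syllable rate; a planted judge → defendant
   conditional emotion matrix; a per-record logic flag; three noisy
   simulated annotators; WAV + CSV export.
2. **Features** — log-Mel spectrogram front end: z-score normalization,
   25 ms / 10 ms Hamming framing, k triangular mel bands, natural log with
   a silence floor, plus regression delta and delta-delta channels,
   stacked into the t × k × 3 tensor **F**.
3. **Classifier** — a residual CNN + BiLSTM + attention network written
   from first principles (im2col/GEMM convolutions, hand-derived
   backpropagation, Adam): residual stages `maxpool(conv1 + conv3(conv2(conv1)))`,
   bidirectional LSTM states h_i, attention weights
   `alpha_i = softmax_i( sigmoid(W_a h_i + b) . W_b )`, pooled
   representation `r = sum_i alpha_i h_i`, two dense levels and a softmax
   over the three emotions, trained with cross-entropy.
4. **Preprocessing** — silence-based utterance segmentation with the 1 s
   gap rule and metadata-driven role typing.
5. **Annotation** — 2-of-3 expert consensus labelling and a record-level
   training/prediction split (10 of 50 records by default).
6. **Influence analysis** — record-level emotion aggregation, the three
   cross-tabulations (judge → defendant emotion, plaintiff → defendant
   emotion, court emotion → defendant logic), Pearson chi-square with
   `(r-1)(c-1)` degrees of freedom, odds ratios `ad/(bc)` for every 2×2
   collapse, Fisher exact p-values when expected counts fall below 5, and
   planted-vs-recovered conditional matrices.

See `vignettes/courttone-methods.Rmd` for the full methodological account.

## Worked example

Load the published 50-record cross-tabulation of judge emotion against
defendant emotion and test the association:

```r
library(courttone)

tabs <- court_tables()
tabs$judge
#> <contingency_table> judge (rows) x defendant_emotion (columns), n = 50
#>         angry neutral fear
#> angry      10       1   10
#> neutral     8      19    2

association_stats(tabs$judge)
#> chi-square = 21.014, df = 2, p = 2.735e-05
```

The judge's emotion and the defendant's emotion are strongly associated:
when the judge sounds angry the defendant is rarely neutral (1 of 21
records) and frequently afraid (10 of 21), while a neutral judge leaves the
defendant neutral in 19 of 29 records.

Generate a synthetic corpus of the same size with that structure planted,
and run the influence report on its record-level labels:

```r
p <- court_params(n_records = 50, seed = 7)
corp <- sample_corpus(p, audio = FALSE)
influence_report(corp$records, planted = p, quiet = TRUE)
#> <influence_report> 50 records
#>
#> -- judge -> defendant_emotion
#>         angry neutral fear
#> angry       8       1   10
#> neutral    11      20    0
#> chi-square = 26.299, df = 2, p = 1.946e-06 (small expected cells: see Fisher p)
#>
#> -- plaintiff -> defendant_emotion
#>         angry neutral fear
#> angry       4       9    4
#> neutral    15      12    5
#> fear        0       0    1
#> chi-square = 6.651, df = 4, p = 0.1555 (small expected cells: see Fisher p)
#>
#> -- court -> logic
#>         logical non-logical
#> angry         0          22
#> neutral      24           4
#> chi-square = 36.264, df = 1, p = 1.723e-09
#>
#> recovery: max |recovered - planted| = 0.0790
```

The planted pattern is recovered: the judge → defendant dependence is
detected, the plaintiff → defendant table (independent by construction)
is not significant, anger in the courtroom is associated with non-logical
defendant argumentation, and the recovered conditional rows sit within
Monte-Carlo error of the planted matrix (at n = 50 that error is still
large; at n = 500 it drops below 0.07).

The audio path works the same way on waveforms: `sample_corpus(p)` attaches
synthesized audio, `train_rescnn()` fits the classifier on consensus-labelled
utterances (see `training_split()`), `predict_utterances()` scores each
utterance, and `aggregate_record_emotions()` reduces predictions to the
record-level labels consumed above. `autoplot()` draws contingency bar
charts and training-loss curves; `tidy()`/`glance()` return tabular views
of tables, test results and fitted models.

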