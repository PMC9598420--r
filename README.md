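# trackcoloc

Colocalization analysis between two genome tracks — sets of genomic
intervals ("stretches") or positions ("points") such as CpG islands,
ChIP-seq peaks, DNase clusters or transcription start sites — for
epigenomics and regulatory-genomics work where the question is whether two
feature sets sit on top of each other more (or less) than chance allows.

Interval positions on real chromosomes are strongly inhomogeneous and
interval lengths follow no standard distribution, so raw-overlap statistics
are outlier-dominated and partial permutation nulls depend on arbitrary
sampling choices. `trackcoloc` instead scores each nearest-neighbor (A, B)
pair of features with a normalized index in (−1, 1) and tests significance
with a **complete** permutation test — all K(K−1)/2 length swaps between
pairs, no sampling parameters.

For a pair with center distance `L` and stretch lengths `a`, `b`:

    IO = (L − (a+b)/2) / (L + (a+b)/2)   overlap     (stretch–stretch)
    IA = (a − b) / (a + b)               asymmetry   (stretch–stretch)
    IC = (L − a/2) / (L + a/2)           coverage    (stretch–point)

−1 means complete colocalization (coincident centers), negative IO/IC means
physical overlap, values near +1 mean unrelated remote features. The test
statistic is

    zeta = (mean(I) − mean_permuted(I)) / sigma_eff

with an effective variance combining observed, permuted and covariance
terms; negative zeta = colocalized. Because zeta is not exactly standard
normal, |zeta| significance thresholds are calibrated by Monte-Carlo
simulation of random tracks as a function of the pair count K, fitted with a
saturating curve, and mapped onto Gaussian p-values via
`lambda(K) = 1.96 / thr_0.05(K)`. Nearest-neighbor pairs are analyzed in two
disjoint classes (ABA–BAB middles and AABB–BBAA run junctions) that are
reported separately, and per-chromosome results are aggregated genome-wide
with an exact binomial chance model. A spacing-entropy randomness screen on
center positions decides which track's lengths may be permuted (the united
criterion): permuting the lengths of a non-random, length–position-coupled
track breaks the null, permuting the random partner does not.

## Worked example

Calibrate thresholds, then test whether a point track planted inside a
stretch track is detected (coverage mode):

```r
library(trackcoloc)

tb <- calibrate_thresholds(k_grid = c(50, 100, 200, 400, 800),
                           n_realizations = 2000, seed = 20260923)

set.seed(77)
n <- 600
ctr <- runif(n, 0, 2e8)
len <- sample.int(1e4, n, replace = TRUE)
stretches <- coloc_track(data.frame(chrom = "chr1", start = ctr - len/2,
                                    end = ctr + len/2),
                         name = "stretches", role = "A")
pick <- sample(n, 400, replace = TRUE)
pos  <- ctr[pick] + (runif(400) - 0.5) * len[pick]   # inside the stretches
points <- coloc_track(data.frame(chrom = "chr1", start = pos, end = pos),
                      name = "points", role = "B")

res <- analyze_colocalization(stretches, points, thresholds = tb, seed = 5)
res$chromosomes[, c("pair_class", "K", "scheme", "mean_IC", "zeta",
                    "p_approx", "sig_flag")]
#>   pair_class   K  scheme    mean_IC      zeta     p_approx sig_flag
#> 1    ABA_BAB 254 perm_IC -0.3333865 -3.701545 2.816758e-08     0.01
#> 2  AABB_BBAA 101 perm_IC -0.2357071 -2.755303 1.035425e-05     0.01
```

Reading the output: in both pair classes the mean coverage index is
negative (points tend to fall inside the stretches), zeta is far below the
calibrated Pr = 0.01 threshold, and the mapped Gaussian p-values are tiny —
the planted colocalization is detected. For two independent random tracks
the same pipeline leaves zeta within the null band and flags nothing
(`run_fdr_experiment()` quantifies this: the flagged fraction at nominal
0.05 is 0.05 within binomial scatter).

`write_report_tsv()` / `write_report_html()` emit the per-chromosome table
plus the genome-wide summary (exceedance counts with binomial p, class
shares of the smaller track, KS/Mann–Whitney divergence between classes).

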