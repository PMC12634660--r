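# soseq

Downstream analysis of behavioral syllable sequences from solitary and
dyadic (social) open-field recordings of mice.

Unsupervised decomposition methods segment continuous animal behavior into a
vocabulary of short stereotyped motifs ("syllables", here ~400 ms at a 25 Hz
frame rate). `soseq` starts where the decomposition ends: given frame-wise
syllable labels, centroid tracks, and social-contact annotations, it
quantifies how a social partner restructures behavior at three levels.

* **Usage** — which syllables are used more or less in the dyadic context
  (the *dyadic-modulated*, DM, set), tested per syllable with Mann-Whitney U
  tests across animals and Benjamini-Hochberg correction.
* **Syntax** — how syllables are *sequenced*: bout-transition networks with
  left-eigenvector centrality, per-edge context modulation, sliding windows
  of three consecutive bouts ("syntaxes"), Hamming-distance syntax families,
  and contact-aligned composition divergence (Kullback-Leibler, with a
  bout-shuffle randomized control).
* **Kinematics** — egocentrically aligned mean trajectories per syllable,
  parametric social-behavior classes in the plane spanned by inter-mouse
  distance and its change (contact / approach / leave / far-stationary), and
  PCA of usage and syntax features to separate contexts.

A fully seeded synthetic-experiment generator with *planted, recoverable
effects* backs every statistical claim: the planted configuration must be
recovered and the matched null configuration must stay null.

## Worked example

Simulate a study-scale experiment (20 solitary + 20 dyadic animals, 20
minutes at 25 Hz) and run the usage analysis:

```r
library(soseq)
library(dplyr)

cfg <- synthetic_config(seed = 1L)
exp <- simulate_experiment(cfg)
exp
#> <soseq_experiment>
#>   40 sequences (20 solitary, 20 dyadic), 40 tracks, 1083 contact bouts
#>   planted DM syllables: 7, 10, 12, 13, 18, 23, 28, 30

bouts <- extract_bouts(exp$sequences)
props <- syllable_proportions(bouts, 32L)
mod <- compare_contexts(props)
mod
#> <context modulation: 11 DM, 21 DU syllables (alpha = 0.05)>
#> DM: 4, 7, 10, 12, 13, 18, 19, 23, 26, 28, 30
```

All eight planted syllables are recovered. The three extra detections
(4, 19, 26) are *network spillover*: modulating the planted columns of the
transition matrix necessarily shifts the stationary probability of a few
non-planted syllables, and the generator's ground truth records them
(`exp$ground_truth$spillover_ids`) along with the analytically expected
shift per syllable.

Sequencing level — centrality and contact-aligned composition divergence:

```r
nets <- transition_networks(bouts, 32L)
ct <- centrality_context_test(centrality_table(nets))
ct %>% filter(significant) %>% select(syllable, statistic, p_adjusted)
#> # A tibble: 9 × 3
#>   syllable statistic p_adjusted
#>      <int>     <dbl>      <dbl>
#> 1        4        82 0.0474
#> 2        7       396 0.00000395
#> 3       10       400 0.00000217
#> 4       12       400 0.00000217
#> 5       13       400 0.00000217
#> 6       18         0 0.00000217
#> 7       23         0 0.00000217
#> 8       28         0 0.00000217
#> 9       30         0 0.00000217

dseq <- exp$sequences %>% filter(context == "dyadic")
ann <- pool_annotations(exp$annotations)
tc <- aligned_timecourse(dseq, ann, 32L, "active", seed = 2L)
tc
#> <single-mouse D_KL time-course (active): 429 qualifying bouts,
#>  6/75 bins significant (6 post-onset)>
```

Syllable composition diverges from baseline only *after* active-contact
onset; repeating the analysis on bout-shuffled sequences
(`shuffle_control()`) yields no significant bins.

Syntax level — the planted contact syntax tops the contact-aligned ranking:

```r
sy <- extract_syntaxes(bouts %>% filter(context == "dyadic"))
ztc <- zscore_timecourse(sy, ann, "active")
glance(ztc)
#> # A tibble: 1 × 5
#>   contact_type n_qualifying n_syntaxes_tested n_syntaxes_significant top
#>   <chr>               <int>             <int>                  <int> <chr>
#> 1 active                429               227                     37 7,10,12 | …
```

The whole pipeline, with every stage written to CSV/JSON/GraphML/Newick plus
a run manifest, is one call:

```r
run_all(exp, "out/", seed = 1L)
```

Results objects follow broom conventions (`tidy()`, `glance()`) and the main
ones have `autoplot()` methods.

## Data formats

Plain-text artifacts throughout: `*.labels.csv` (frame, syllable; `-1` =
unassigned) with a JSON metadata sidecar, `*.track.csv` (frame, x_mm, y_mm),
`*.annotations.csv` (contact_type, start_frame, end_frame; half-open
0-based frame intervals), written and read by `write_experiment()` /
`read_experiment()`. See the vignette (`vignettes/soseq-methods.Rmd`) for
the full model of the generator and the statistical conventions.
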