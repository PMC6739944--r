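---
title: "Methods: multi-task sequence CNNs for histone marks and their interpretation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-task sequence CNNs for histone marks and their interpretation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`epimotif`, the assumptions behind them, the parameters that matter, and
the places where the design was genuinely open and a choice had to be
made. It states no measurement that the test suite or
`scripts/acceptance.R` does not itself compute.

## From peak calls to training examples

The input to everything is a set of ChIP-seq peak calls, one track per
(cell type, histone mark) pair, with replicates. Peaks are cleaned in a
fixed order:

1. **Quality filter.** Peaks with $-\log_{10}(q) < 2$ or longer than
   10,000 bp are discarded. Both boundaries are inclusive on the keep
   side: $-\log_{10}(q) = 2$ and length exactly 10,000 bp survive.
2. **Blacklist.** A peak sharing at least one base with a blacklisted
   region is removed whole — no trimming — because signal inside such
   regions is artifactual end to end.
3. **Replicate consensus.** With two or more replicates, only the
   maximal intervals covered by at least two replicates are kept; with a
   single replicate its merged peaks are used as-is.
4. **Merge.** Union semantics; abutting intervals are merged.

Whether the replicate intersection should run before or after the
quality filter is not fixed by convention; we filter first, so that a
peak failing QC in one replicate cannot lend support to the consensus.
The whole chain is idempotent on its own output (regression-tested).

Coordinates are 0-based half-open everywhere inside the package; BED is
read natively and 1-based formats (wiggle, IRanges) are converted at the
readers.

The genome is segmented into 200-bp bins (trailing partial bins
dropped). A bin is positive for a task when at least `overlap_fraction`
of its *bin length* is covered by the task's consolidated peaks
(boundary inclusive; candidate thresholds 0.5–0.9 are crossed into the
hyper-parameter search). Bins positive for no task are discarded — an
important modeling commitment inherited from the study design: the
model discriminates *which* mark a modified bin carries, not modified
from unmodified genome. Each kept bin is extended to a 1000-bp context
centered on the bin midpoint; contexts that would cross a chromosome
end are dropped rather than padded, because any padding convention would
have to invent sequence content. One-hot encoding maps `A/C/G/T` to unit
vectors and `N` to `[0.25 0.25 0.25 0.25]`. The dataset is split
2:1:1 into train/validation/test by a seeded random permutation at bin
level (floor rule, remainder to test); an optional chromosome-holdout
mode is provided for users who want to control the sequence-overlap
leakage of nearby bins (neighbouring bins share up to 80% of their
contexts), at the cost of confounding the split with chromosome
composition.

## The network

Both model flavours share one architecture: three units of

$$\text{conv}(k) \rightarrow \text{ReLU} \rightarrow \text{batch norm}
\rightarrow \text{max pool},$$

a sigmoid fully connected layer, and one sigmoid output unit per task.
The full-scale defaults are 320/300/300 filters and 1000 FC units;
filter widths (19, 11, 7) and pool sizes (4, 4, 4) with stride equal to
pool size are configurable defaults, since only the filter counts are
canonical. The unit order follows the textual definition
(normalization after the activation, pooling last); the alternative
conv–pool–norm ordering that sometimes appears in schematic summaries
is not used.

Training minimizes multi-task binary cross entropy with RMSprop
(learning rate 0.001, decay 0.9, epsilon 1e-8) on minibatches of 128,
for at most 20 epochs, with early stopping on validation loss
(patience counted in validation checks; one check per epoch at these
problem sizes) and best-validation weights restored. L1/L2 penalties
apply to the fully connected layer weights only, leaving the
convolution filters free to grow into motif detectors; the paired
candidate values (L1 1e-07…6e-07, L2 2e-08…8e-07) are sampled without
replacement by `random_search()`, which selects the configuration with
the highest mean validation accuracy at cutoff 0.5.

All parameters are He-initialized from a seeded RNG; shuffling orders
are drawn from the same root seed, and the C++ core contains no RNG of
its own, so a fixed seed gives bit-identical training runs on the same
machine. Inference uses batch-norm running statistics (momentum 0.9),
so predictions are deterministic and independent of batch composition.
The backward pass is verified against central finite differences in the
test suite.

### The desk-scale configuration

`desk_config()` is the reduced setting used by the benchmark, the
acceptance checks and the CLI defaults: 32/16/16 filters, pools
(4, 4, 12), 32 FC units, learning rate 0.01, batch 16, at most 10
epochs. Two of these deviate from a naive scale-down and deserve
justification:

* **Near-global final pooling (4, 4, 12).** At full scale the model
  sees millions of bins and can afford position-resolved features going
  into the FC layer. With a few thousand bins, a 13-position flattened
  map lets the FC layer memorize positional noise instead of relying on
  the convolution filters; collapsing the final pool to ~1 position
  forces position-invariant motif evidence. Pool geometry is an open
  architectural parameter, and this is our choice for small data.
* **Learning rate 0.01, batch 16.** Ten epochs over ~1,500 training
  bins is only a few hundred optimizer steps. RMSprop's effective step
  is approximately `lr` per parameter, so at 0.001 the filters cannot
  travel far enough from initialization to become motif detectors in
  the step budget; 0.01 with smaller batches (more steps) does, while
  the full-scale defaults remain `model_config()`'s defaults.

## Interpreting the first layer

**Filter → PWM.** The post-ReLU first-layer activation of filter $k$ at
position $i$ scores the k-mer starting there. Per filter we record the
extreme activations $\alpha_{max}, \alpha_{min}$ over all positions of
all test sequences, and for each ratio $\beta \in \{0.3,\dots,0.8\}$
collect every k-mer with activation above
$(\alpha_{max}-\alpha_{min})\cdot\beta$, accumulating their one-hot
submatrices (so `N` bases contribute fractionally) into a count matrix
normalized with a pseudocount of 0.5 per base. The $\beta$ whose PWM has
the highest information content
$\sum_{cols}(2 + \sum_b p\log_2 p)$ wins; filters whose best PWM has
zero information content, or that never exceed threshold, are dropped.
Extracted PWMs span the full filter width, so a learned motif is
usually flanked by near-uniform columns; `trim_pwm()` removes flanking
columns below 0.25 bits before any cross-motif comparison — without
trimming, the flanks dilute the column-correlation score enough to make
planted-motif recovery unstable.

**Influence.** Nullifying a filter replaces its post-ReLU activation map
by the scalar mean of its activations over all positions of all test
sequences; the per-task influence is the summed squared change of that
task's predicted probability over the test set, and the across-task sum
is the scalar ranking score. Influence scales with test-set size, so
records carry `n_sequences` and scores are comparable only within a
run. Nullifying the empty set is the identity and has influence exactly
zero.

An observation users should expect: in these multi-task models
influence is *not* task-diagonal. Because unmodified bins are excluded,
the negatives of each task are the positives of the others, so the
absence of another task's motif is itself evidence; the shared FC layer
therefore gives every informative filter genuine influence on every
task. The acceptance report quantifies this as the ratio between
matched filters' influence on their own task and unmatched filters'
influence on the same task.

**Interactions.** For a filter pair $(i, j)$ and a task, 2000 test
sequences are sampled (with replacement if the test set is smaller) and
the per-sequence squared prediction changes under nullifying $i$, $j$
and both are related by least squares without intercept:
$\Delta P_{ij} = \alpha\,\Delta P_i + \beta\,\Delta P_j +
\gamma\,(\Delta P_i \cdot \Delta P_j)$. The product implements the
cross term, and the regression has no intercept because the model is
exact (all terms zero) for sequences neither filter touches. $\gamma$
is symmetric in $(i,j)$ by construction, and its two-sided t-test
p-value is reported. Degenerate regressors (a nullification that
changes nothing) are flagged rather than fit. Whether the regression
quantities should be squared per-sequence changes or raw signed changes
is ambiguous; we use squared changes, and note that a saturating
conjunction makes $\gamma$ negative (joint nullification is
sub-additive) while redundant detectors make it positive.

**Merging and annotation.** Motif pairs are compared by the mean
per-column Pearson correlation of their frequency vectors over every
offset with at least 7 aligned columns, in both orientations
(reverse-complementing the target); zero-variance columns contribute 0.
Significance comes from a permutation null — the target's columns are
shuffled at least 1000 times and the best score recomputed — with
$E = p \times \#targets$. This is a deliberate functional substitute
for an exact-null comparison tool: the threshold semantics (merge at
E < 0.1, known-match at E ≤ 0.5) are preserved, and the granularity of
p is limited to $1/(n_{perm}+1)$. Best hits rank by E-value with ties
broken by longer overlap, then higher score, then name. Bidirectional
best hits below E < 0.1 form a graph whose connected components are the
merged motifs; a merged PWM pools the members' site counts after
aligning each member to the first at its best offset/orientation
(replacing a re-discovery step with count pooling, which needs no
external binary and uses the same inputs). Model-by-motif binary
presence profiles are clustered with Hamming distance and average
linkage (UPGMA), serialized as Newick.

**Conservation.** A Markov background of order 5 (add-one smoothing,
lower orders kept as a fallback chain) is fitted to the target genome.
Scanning uses the 0-order marginal for the log-odds score and its
p-value — the standard behaviour of score-based scanners, which treat
the high-order model as a sequence generator rather than a scoring
background — with p-values computed by dynamic programming over the
score distribution discretized into 1000 bins over the achievable range
(the discretization is exact on the integer lattice, which is how the
test suite can compare it to exhaustive enumeration at width ≤ 8 to
1e-9). Both strands are scanned; overlapping sites on opposite strands
are both reported. Sites at p ≤ 1e-5 get their per-base conservation
averaged, motifs average over their sites (sites not covered by the
track are skipped and counted), and influence versus conservation is a
Pearson correlation with the t-distribution two-tailed p.

## The synthetic study generator

`grammar_spec()`/`generate_study()` emulate the *structure* of a
multi-cell-type, multi-mark ChIP-seq peak study at desk scale: 2 cell
types × 3 marks over a 2-Mbp two-chromosome genome sampled from an
order-0 background at 41% GC; 350 consensus peaks per track (600–900
bp); six planted motifs of widths 9–12 built from consensus strings at
0.92 dominant-base probability (≈1.6 bits/column, the sharpness of a
well-defined TF motif); four sampled instances per peak per motif on
random strands. Per-track rules express the three grammar types: one
motif per (cell, mark), the mark-1 motif shared across cells (with 60%
of the second cell's mark-1 peaks reusing the first cell's regions, as
the same mark does across related cell types), and a cooperative
AND-pair on cell1/mark3 in which a quarter of the peaks carry only the
first member, a quarter only the second, and half carry both — each
member is individually necessary somewhere, so both must be learned,
while both-present peaks carry the redundancy that the interaction
coefficient detects. Realism decoys exercise the cleaning chain:
per-replicate q-value failures (5%), 12-kb over-length peaks, peaks
over blacklisted regions that carry implanted decoy signal, and
replicate-specific noise peaks killed by the two-replicate rule. The
conservation track is uniform noise in [0.05, 0.35] elevated to
[0.7, 0.95] at planted sites.

What the generator does *not* emulate — and what passing tests
therefore do not show about real data: read-level noise and peak-caller
artifacts (peaks are drawn directly), sequence composition structure
(repeats, CpG islands, higher-order dependence unless a higher-order
background is supplied), degenerate/multi-modal motifs, realistic motif
co-occurrence statistics, and conservation that varies by constraint
rather than by construction. Numbers obtained on bundles are
demonstrations of mechanism, not biological estimates.

The problem sizes used by the bundled benchmark and acceptance script —
2 Mbp, ~3,000 labeled bins, the reduced 32/16/16 model, 10 epochs, 1000
comparison permutations, 2000 regression sequences — were chosen so a
complete study runs in minutes on one CPU while leaving the recovery
properties comfortably reproducible across seeds.

## Known limitations

* The CNN core is plain C++/BLAS on one CPU; full-scale (hundreds of
  filters, millions of bins) training is out of reach here and the
  full-scale hyper-parameters are carried as defaults, not exercised.
* Influence and interaction are *model* diagnostics: they attribute
  behaviour of one trained network, and filters in small networks are
  entangled (single filters partially detect several motifs), which
  spreads influence and produces non-additive effects among non-planted
  filter pairs of the same magnitude as planted ones. The acceptance
  report exposes both effects rather than hiding them.
* The permutation-null E-values are conservative and granular at small
  `n_perm`; raising `n_perm` sharpens them at linear cost.
* `sample_background()` draws base by base in R; generating very long
  sequences from high-order backgrounds is slow (the default generator
  uses an order-0 background precisely so genome synthesis is
  vectorized).
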