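---
title: "Consensus peak fusion and TF candidate scoring: methods"
author: "peakfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus peak fusion and TF candidate scoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakfusion)
```

## The problem

ChIP-seq against a post-translational modification — SUMO-1 is the
motivating case — precipitates every chromatin-associated protein carrying
the mark, not one transcription factor (TF). The resulting peak landscape
is a superposition of many factors' binding events, and peak callers
disagree with each other far more than on a single-factor experiment.
Two consequences drive the design of this package:

1. **No single caller can be trusted.** Peak sets from several callers are
   therefore *fused*: by union (`+`) when sensitivity matters, by
   intersection (`*`) when specificity matters. Intersection demands that
   every caller agree on a base before it is reported, which filters
   caller-private false positives.
2. **Peaks must be attributed to factors indirectly.** Fused peaks are
   annotated against a catalog of known TF binding sites (TFBS; the UCSC
   `tfbsConsSites` track is the archetype, with roughly 5.8 million sites
   for 258 factors) and against promoter windows around transcription
   start sites (TSS), and each factor is scored by how strongly and how
   broadly the peaks cover its sites.

## Interval representation

Internally every interval lives in a `GRanges` (1-based, closed), the
standard Bioconductor container; the constructor `peak_set()` and all
readers/writers speak the BED convention (0-based half-open) and convert
at the boundary, so files round-trip exactly. Overlap everywhere in the
package means "shares at least one base": abutting intervals do not
overlap, a single shared base suffices, and no minimum-overlap fraction
or containment is required anywhere. Strand is ignored for peaks and
binding sites (ChIP peaks are unstranded).

`normalize_peaks()` merges overlapping peaks *within* one set so that
each set covers every base at most once; this is a precondition for the
set algebra. Abutting peaks are left separate (they share no base, and
merging them would erase caller-reported peak boundaries without changing
coverage). The merged height is the maximum of the contributors: heights
from one caller share a scale, and the maximum preserves the strongest
evidence without double-counting overlapping signal the way a sum would.
A `"sum"` rule is available for callers whose overlapping peak shards
genuinely partition one region's signal.

## Fusion semantics

Union and intersection act on *coverage* (sets of covered bases), not on
peak identities:

* `union_fuse(a, b)` covers every base covered by either input;
  cross-set overlapping peaks merge into compound regions (height = max),
  private peaks keep their positions.
* `intersect_fuse(a, b)` emits each maximal jointly-covered fragment as
  one peak. The fragment's height is the **minimum** over all source
  peaks overlapping the fragment — the conservative reading: joint
  evidence is only as strong as the weakest caller supporting it. (A
  fragment can span more than one peak of an input when that input has
  abutting peaks, so the minimum is taken over all contributors, not
  over exactly two.)

Coverage semantics were chosen deliberately: they make both operators
associative and commutative, so a three-way label such as `M*C*T` has a
well-defined meaning independent of evaluation order — which the test
suite asserts by permuting operands rather than assuming. An alternative
intersection semantics (emit one caller's full peak whenever another
caller touches it) is neither associative nor symmetric and was rejected.
Whether the original analyses emitted fragments or full peaks is not
documented; fragment emission is this package's choice.

## Promoter windows

A promoter is the window from `upstream` (default 5000) bases 5' of the
TSS to `downstream` (default 1000) bases starting at the TSS, oriented by
strand and clamped at the chromosome start. The implementation is
`GenomicRanges::promoters()`, the canonical Bioconductor definition, in
which the window always has width `upstream + downstream` with exactly
`upstream` bases strictly 5' of the TSS on either strand. Note one
convention subtlety: on the minus strand the window is
`[tss - downstream + 1, tss + upstream]`, i.e. the TSS base itself counts
as the first "downstream" base, mirroring the plus strand exactly. A
naive arithmetic window `[pos - downstream, pos + upstream)` differs by
one base on the minus strand; with 6 kb windows this is immaterial, and
the strand-symmetric convention was preferred.

Duplicate TSS records are collapsed before window construction. A peak
"is in a promoter" on any ≥1 bp overlap with any window.

## The per-factor score

For factor $i$ with catalog site set $TB_i$ and a fused peak set $D$,
let $P_i$ be the distinct peaks overlapping at least one site of $TB_i$
and $D_i$ the sites of $TB_i$ overlapped by at least one peak. Then

$$ S_i \;=\; \Big(\sum_{p \in P_i} h_p\Big)\times\frac{|D_i|}{|TB_i|} $$

with $h_p$ the peak height. The first factor rewards tall (well
supported) peaks over the factor's sites; the weight is the fraction of
the factor's genome-wide sites that are covered, which normalizes away
the catalog's very unequal site counts per factor.

The prose definition this implements ("the sum of the peak heights ...
weighted by the percentage of sites covered") admits a second reading in
which a peak spanning $k$ sites of one factor contributes its height $k$
times. Both are implemented (`peak_sum = "per_peak"` / `"per_site"`);
`per_peak` is the default because a single physical binding event should
not be counted once per database entry it happens to span — TFBS catalogs
routinely contain clustered near-duplicate sites. The weight's
denominator $|TB_i|$ is a *site* count, so the numerator $|D_i|$ counts
sites, not peaks.

Ranking is by descending score with lexicographic tie-break on the matrix
identifier, making ranks a deterministic permutation of $1..N$.

## Hampel identifier

Candidates are the outliers of the score distribution. With $M$ the
median score, $\mathrm{MAD}$ the median absolute deviation and
$\mathrm{MADN} = \mathrm{MAD}/0.6745$, factor $i$ is flagged when

$$ \frac{|S_i - M|}{\mathrm{MADN}} \;>\; 2.24 . $$

Both constants are *computed*, not hard-coded: $0.6745 = \Phi^{-1}(0.75)$
(4 dp), the divisor that makes MADN estimate the standard deviation under
normality, and $2.24 = \sqrt{\chi^2_{1,0.975}}$ (2 dp), a two-sided 5%
rule on the squared standardized deviation. Median/MAD resist masking:
one enormous score inflates a mean/sd z-score's own yardstick but leaves
the median and MAD untouched.

Numerical edge cases, decided and frozen:

* even-length collections use the mean of the two central values (R's
  default median);
* the comparison is strict (`>`); for continuous scores the boundary has
  probability zero;
* when $\mathrm{MAD} = 0$ (at least half the scores equal the median —
  typical after intersection fusion, where most factors score exactly 0)
  the statistic degenerates. The limit behaviour is used: any score
  different from the median is flagged (statistic reported as `Inf`),
  scores at the median are not (statistic 0). This is the $c \to 0^+$
  limit of adding noise of scale $c$, and it is what makes a lone planted
  signal detectable in an otherwise silent score vector.

Hampel flags are invariant under shifting all scores by a constant and
scaling by any positive factor (location/scale equivariance of median and
MAD); the suite checks this property directly.

## Evaluation indices

Without a gold standard, peak sets are compared by composition. From six
counts (total peaks, promoter peaks, TFBS peaks overall/in promoters,
distinct sites hit overall/by promoter peaks) four percentage indices are
formed: `f_prom` (promoter peaks / peaks), `f_tfbs` (TFBS peaks / peaks),
`f_tp_p` (TFBS promoter peaks / promoter peaks), `f_tp_t` (TFBS promoter
peaks / TFBS peaks), plus `ap`, their arithmetic mean. `ap` is always
computed on the unrounded indices and only rounded (half away from zero,
1 decimal) for display: averaging pre-rounded indices can differ by 0.1,
and the published tables this package reproduces are only matched by the
unrounded-then-round order of operations.

Two count conventions required a decision. The "sites in promoters"
column is read peak-centrically (distinct sites hit by promoter peaks);
the site-centric reading (hits whose site itself lies in a window) is
available via `count_summary(site_in_promoter = TRUE)`. And a site hit by
several peaks counts once. Restricting peaks to promoters before or
after site annotation gives identical promoter-site counts under the
≥1 bp rule; a property test confirms the orders agree.

The package ships the published benchmark count table
(`sumo1_benchmark_counts()`): twelve strategies — MACS (M), CisGenome
(C), T-PIC (T), BayesPeak (B) and eight fusions of the top three — from a
SUMO-1 ChIP-seq experiment in BCBL-1 cells. Recomputing the indices from
these counts reproduces the published precision tables to one decimal,
with a single exception: BayesPeak's published AP (23.3) is inconsistent
with its own four indices, which average to 23.1; the package treats the
printed cell as a typo and asserts the recomputed value's components
only.

## The synthetic generator

`generate_fixture()` defines the study conditions under which the
pipeline's claims are tested; its defaults are fixed and are not tuned
per test:

| parameter | default | rationale |
|---|---|---|
| genome | 2 × 1 Mb | large enough that uniform noise rarely collides three ways |
| TFs × sites | 20 × 50 | a scaled-down catalog with per-factor site sets |
| TSS | 100 | promoter windows cover ~30% of the genome, as in gene-dense regions |
| true regions | 30 | placed over sites of one planted factor, near TSSs |
| noise peaks/caller | 200 | caller-private uniform placements |
| heights | true 30–100, noise 1–20 | separated scales so the score stage has recoverable signal |
| peak width | 200–500 bp | typical ChIP-seq peak scale |
| boundary jitter | ±20 bp | caller disagreement on shared peaks |

Every caller reports every true region (with jittered boundaries and
caller-specific heights); noise is private to each caller. Three-way
intersection therefore retains a fragment of every true region (jitter
of ±20 bp cannot annihilate a ≥200 bp region) and retains a noise peak
only when three independent uniform placements collide, which at these
densities is rare. The planted factor accumulates tall peaks over a
large fraction of its 50 sites while other factors collect at most
stray noise overlap, so it should rank first and be Hampel-flagged; the
acceptance suite measures exactly this over 50 seeded replicates.

What the generator does *not* emulate: callers missing true peaks (in
real data intersection loses sensitivity, which is why union exists);
heavy-tailed height distributions; clustered or overlapping binding
sites across factors; chromatin-driven nonuniform noise. Passing tests
therefore demonstrate the pipeline's mechanics — set algebra,
annotation, scoring, outlier calling — not performance on real data.

## Problem sizes and determinism

The oracle-equivalence tests run the interval algebra against per-base
brute force on toy genomes of 5 kb + 3 kb (1000 random fusion instances,
100 random annotation scenes); planted-signal recovery uses 50 replicates
of the default fixture. All randomness is seeded: the generator takes an
explicit seed and the same seed yields byte-identical files on disk.

## Known limitations

* Heights are mixed across callers as-is; no cross-caller rescaling is
  applied (matching the original analysis). Callers whose signal scales
  differ wildly will bias min/max height rules.
* Mixed fusion expressions (`(M*C)+T`) are representable only by
  composing the binary functions; the label parser handles single-operator
  expressions, which is all the published comparisons use.
* The candidate table stops at flagging; literature verification of
  candidates is out of scope.
* Genome-scale results from the motivating experiment (raw read counts,
  the 258-factor catalog, published Hampel values) are not reproducible
  from public data; they enter only as the shipped count table and as
  printed constants the arithmetic is checked against.
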