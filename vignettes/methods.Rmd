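---
title: "Timing tumor progression from allele fractions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timing tumor progression from allele fractions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorclock)
```

## The generative picture

`tumorclock` treats a bulk tumor sample as a mixture of normal cells and
one or more tumor cell populations, each carrying an allele-specific copy
state per genomic region. Three observable summaries follow from the
mixture arithmetic alone:

* the **copy ratio** of a region, anchored so that a diploid region reads 1
  at any purity;
* the **B-allele fraction** of germline heterozygous SNPs, which reports
  allelic imbalance;
* the **mutant allele fraction** of a somatic SNV present on `m` of the
  region's copies in a fraction `phi` of tumor cells:

$$\mathrm{MAF} = \frac{p\,\phi\,m}{p\,(n_1+n_2) + c_N\,(1-p)}$$

with purity $p$, major/minor copies $n_1, n_2$, and normal copy number
$c_N$ (2 for autosomes and female X; 1 for male X/Y — a per-region context
field, because worked female-X cases need 2 while male cohorts need 1).
Copy ratios divide by $c_N$, so they stay anchored to the normal sample
rather than to average tumor ploidy; for autosomes this is exactly the
divide-by-two convention that yields the textbook one-copy-gain values 1.5
(pure tumor) and 1.25 (50% purity), while for a hemizygous male X region it
keeps the ratio a tumor/normal depth ratio.

The clock assumption: SNVs accrue at a constant rate **per chromosome
copy** along mutational time $t \in [0, 1]$, normalized over the sample's
total accrual. All times the package reports are relative orderings on this
axis; they are not convertible to years, since mutation rates differ
between tumors and over a tumor's lifetime.

## Evolutionary histories and their signatures

A region's history is an ordered list of loss/gain events from germline
(1,1). For total copy number up to 4 the package enumerates a catalog of
paths (copy loss, copy neutral, CN-LOH, one-copy gain and its LOH variant,
mono-/bi-allelic two-copy gains, two-copy gain with LOH), each annotated
with *multiplicity classes*: which final multiplicity an SNV acquires as a
function of when and on which copy it arose. Distinct paths to the same
state differ in their class sets — a (4,0) region reached by loss followed
by a three-copy gain shows peaks only at $m \in \{4, 1\}$, whereas CN-LOH
followed by a mono-allelic two-copy gain adds an interior $m = 3$ peak —
which is what lets MAF profiles discriminate them. Above total copy 4 the
path space explodes and only two simple representatives (a mono-allelic
maximal gain and, for even totals, a bi-allelic one) are offered.

Naming follows net gain over diploid: loss = 1 copy, neutral/CN-LOH = 2,
one-copy gain = 3, two-copy gains = 4 total; "one-copy gain with LOH" is
accordingly the (3,0) state. This is the convention that keeps the
eight-name list internally consistent.

## Peak detection and class assignment

Observed MAF distributions are binned at 0.01 and smoothed with a cubic
smoothing spline whose smoothness is chosen by generalized cross-validation
(`smooth_density`); the 0.01 bin matches the granularity of the
detection-power model. Peaks are local maxima with relative prominence at
least 10% of the tallest peak (the data give no reason for a different
default); valleys are the density minima between adjacent peaks, and SNVs
are assigned to the peak whose valley-bounded interval contains them. A
value exactly on a valley goes to the **lower** peak — conservative toward
the later/subclonal class — and the rule is configurable.

## Purity and ploidy

`fit_candidates` scans purities 0.10–1.00 in steps of 0.01 (an exhaustive
grid is cheap at segment counts of tens, and replaces any dependence on an
external initializer) and assigns each segment the integer state minimizing
a weighted squared deviation of ratio and BAF. Two numerical choices
matter:

* **Segment BAF estimation.** SNP BAFs mirror around 0.5 (unknown parental
  phase); folding and averaging biases balanced segments downward by about
  0.04 at 60x depth. The package instead fits the mirrored binomial mixture
  $\tfrac12 B(n, q) + \tfrac12 B(n, 1-q)$ by maximum likelihood
  (`estimate_segment_baf`), which is essentially unbiased across the range.
* **BAF weight 5.** A segment's BAF pools thousands of SNPs and is an order
  of magnitude more precise than its copy ratio, so it carries more weight
  in the fit.

Purity ranking uses **clonal-only** assignments. A subclonal
reinterpretation solves its carrier fraction from the observed ratio and
therefore fits any ratio perfectly; letting it into the purity score would
flatten the landscape. Only after ranking are segments whose ratio misses
the best integer expectation by more than 0.08 (≈1.6 noise SDs at the
simulated noise level) reinterpreted as subclonal changes, keeping every
tied interpretation — including the clonal one — ordered by the smallest
number of copy changes.

Ties are real: a one-copy gain in 80% of cells and a two-copy gain in 40%
produce identical ratios and BAFs. `validate_with_mafs` breaks them by
comparing observed MAF peaks with the peaks each interpretation's histories
predict (post-event SNVs exist only in the carrying cells, so the
interpretations differ in their low peaks), accepting a segment when the
best interpretation matches within 0.05 — a tolerance chosen because even
clean worked cases show observed peaks up to 0.04 from prediction.
Solutions where some validated segment fits no interpretation are reported
`"unresolved"`, not forced. When no segment departs from diploid, purity is
unidentifiable from segments and is taken as twice the right-most clonal
MAF peak of copy-neutral regions.

## Timing

The timing of a gain/CN-LOH event is based on the counts of SNVs in
amplified ($m > 1$) versus unamplified peaks. Two estimators are provided:

* `raw_proportion`: literally $n_{\text{before}} / (n_{\text{before}} +
  n_{\text{after}})$. Its expectation is biased on the mutational-time
  axis because copies accrue mutations at different rates before and after
  the event; for CN-LOH it converges to $t/(2-t)$.
* `per_copy_corrected`: inverts that bias using the history's class accrual
  rates, $\hat t = r\,C / (A - r\,(A + B - C))$ where $A$, $B$, $C$ are the
  copy counts accruing amplified-class, unamplified-class and post-event
  SNVs. This estimator recovers the generating event times in simulation
  and is the pipeline default; `time_copy_event` itself defaults to the
  literal raw proportion so the two conventions stay separately available.

Clonal expansion time is the clonal fraction of SNVs, computed only on
one- and two-copy regions, where subclonal peaks separate cleanly from
clonal ones. All intervals are 95% percentile bootstrap over 1000 label
resamples; regions with fewer than 20 SNVs are not timed (small-count
timings are unstable and real cohorts show the same failure on small
chromosomes). Degenerate counts (all before, or all after) return boundary
estimates flagged `"degenerate"`.

Genome duplication is called when duplicated regions (CN-LOH, one-copy
gain, bi-allelic gains) whose timings are synchronous — within 0.1
mutational time or with overlapping CIs, merged by single linkage — cover
more than half the genome, counting chromosomes 1–22 plus X with arms as
halves. The GD time is the inverse-variance-weighted mean of member
timings. Sequential per-chromosome duplications covering the same genome
fraction but spread in time are deliberately *not* GD.

Driver mutations are placed as **intervals**, never points: a mutation on
all copies of a gained/CN-LOH region predates the event, one on a single
copy postdates it, and zygosity (exact binomial CI against the expected
peaks) decides which. The progression map validates the clone tree with the
pigeonhole rule — sibling subclone fractions may not exceed their parent.

## Neutral evolution test

Under neutral subclonal growth the cumulative count of subclonal SNVs with
allele fraction at least $f$ is linear in $1/f$. The test window is
tumor-specific:

* **Lower bound**: the lowest 0.01 allele-fraction bin at which at least
  80% of SNVs are detectable, from a Monte-Carlo power model (depth Poisson
  around the sample coverage, variant reads binomial, detection = at least
  3 variant reads — the arithmetic a 60x, 50%-purity, 20%-cell-fraction
  variant reduces to). The curve is isotonized before thresholding so
  Monte-Carlo ripple cannot move the bound. The real pipeline's
  caller-specific power cannot be replicated without BAMs; the read-draw
  model with a configurable minimum-alt-reads rule is an explicit,
  documented stand-in.
* **Upper bound**: the MAF valley separating the subclonal mass from the
  clonal peak. A fixed window shared across tumors mixes clonal SNVs into
  the subclonal set whenever purity, ploidy or depth differ — on aneuploid
  regions at purity ≤ 0.6, fully clonal single-copy SNVs fall inside the
  often-used fixed 0.12–0.24 window.

$M(f)$ is evaluated at each **distinct** observed allele fraction (read
depths discretize MAFs; tied values must not contribute a vertical
staircase to the regression), OLS against $1/f$, neutral iff $R^2 \ge
0.98$. Verdicts require at least 500 SNVs in the window; fewer yields an
`insufficient_data` status, not a call.

## Kataegis

C>T/C>G SNVs (pyrimidine-normalized, so G>A counts as C>T) whose
inter-mutation distance falls in the genome-wide lowest 3% are "close";
each chromosome's close/not-close counts are contrasted against the rest of
the genome (disjoint table cells) by a two-sided Fisher's exact test,
Bonferroni-corrected over the chromosomes tested, significant below 0.01.
Closeness uses the **left** (previous-SNV) distance by default: it marks
one SNV per tight pair, and on 20-seed uniform-genome simulations it
produces zero false chromosome calls while detecting a 30-SNV/10-kb
injected cluster every time. The nearest-neighbor alternative marks both
members of a pair, overdisperses the table and inflates significance; it
remains available as `distance = "nearest"`.

## What the simulator does and does not emulate

`simulate_tumor` draws, per segment and multiplicity class, Poisson SNV
counts proportional to (copies accruing the class) × (accrual interval
length) × (segment megabases), gives each SNV its closed-form expected
allele fraction, and samples reads as depth ~ Poisson(coverage × copy
ratio), variant reads ~ Binomial(depth, VAF). SNP BAFs get a random
parental phase; segment ratios get Gaussian noise (default SD 0.05, a
typical WGS segment-level noise scale). Defaults mirror the canonical
worked case: purity 0.74, tumor coverage 60 (normal 30), clonal expansion
at 0.9, one 0.3-fraction subclone, and `example_config()` reproduces the
event layout 0.02/0.66/0.68/0.71 on realistically sized chromosomes at
12 SNVs per copy per unit time per Mb (a few tens of thousands of SNVs
genome-wide, matching typical chromosomally unstable tumors).

The mutation rate is homogeneous per copy within a run; real tumors have
signature- and time-varying rates, but recovery testing only requires
internal consistency. Not modeled: sequencing error beyond binomial
sampling, mapping artifacts, caller-specific detection, subclonal copy
events nested inside subclones, SVs/indels/transposon insertions, and
kataegis arising mechanistically from rearrangements (clusters are injected
explicitly). Passing the recovery suites therefore demonstrates the
estimators are correct under the stated generative model — not that every
real-data complication is handled.

## Problem sizes used in the test suite

Deterministic identities run at closed form. Stochastic suites use: 20-seed
end-to-end recovery on the genome-scale example configuration (about 36,000
SNVs per run), 20-seed kataegis null calibration at ~2,300 background SNVs,
20-seed neutrality classification at 2,000 subclonal SNVs and depth 100,
and 10-seed estimator-bias checks at 2,000 SNVs. These sizes were chosen to
make the pass criteria (rates of 80–95%) statistically meaningful while
keeping the full suite around a minute.

## Known limitations

* Bulk data cannot resolve subclone topology; the pigeonhole rule validates
  nesting but the package does not infer trees.
* Histories above total copy 4 are represented, not enumerated.
* The manual-curation step that real cohorts require (ambiguous segments,
  marginal kataegis calls) is exposed as candidate rankings and statuses
  rather than automated away.
* Multi-event histories are timed per event against the amplified/
  unamplified split; when two events are close in time their individual
  estimates share counts and the correction is approximate.
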