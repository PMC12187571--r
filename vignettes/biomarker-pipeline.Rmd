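---
title: "Nominating and validating a single-protein diagnostic biomarker from multi-omics evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nominating and validating a single-protein diagnostic biomarker from multi-omics evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Desmoplastic small round cell tumor (DSRCT) is a sarcoma defined by a single
driver, the chimeric transcription factor EWSR1::WT1, and is easily confused
histologically with a broad family of small-round-blue-cell tumors. A
diagnostic marker for such an entity should satisfy three independent lines
of evidence at once: the gene is overexpressed in the entity relative to
every morphological mimic; its product drops when the fusion is depleted,
in more than one cell-line model; and the fusion physically binds a
regulatory element of the locus. `sarcomark` implements that
triple-intersection nomination strategy, the downstream signature and
epigenetic analyses that characterize a nominated marker, and the
immunohistochemistry (IHC) decision rule that turns it into a diagnostic
test. Every stage runs on a bundled synthetic-data generator with planted
ground truth, so the whole pipeline is testable end to end without any
external cohort.

## The three nomination gates

**Differential expression (one-vs-rest).** For each gene,
$\log_2\mathrm{FC} = \bar{x}_{\text{target}} - \bar{x}_{\text{rest}}$ on the
log2 scale, with the rest of the cohort pooled across entities. The
per-gene p-value is a two-sided Mann–Whitney rank-sum test; adjustment is
Benjamini–Hochberg across all genes. The gate is
$\log_2\mathrm{FC} > 2.5$ and $P_\mathrm{adj} < 0.01$. The comparison "target
versus all other entities" is genuinely ambiguous between pooling the rest
and requiring the gate against every entity separately; we default to
pooling (it is the statistically better-behaved estimator with unequal
entity sizes) and expose `per_entity = TRUE` for the strict reading.

The rank-sum test uses midranks for ties. When both groups have at most 8
observations the two-sided p-value comes from exact enumeration of all
label assignments — valid under ties, where classical exact tables are not
— with $p = \min(1,\, 2\min(P(U \le u), P(U \ge u)))$. Larger groups use
the normal approximation with the variance tie correction and no continuity
correction (the approximation is symmetric around the gate sizes used
here). Adjusted p-values are computed by the standard step-up procedure;
Benjamini–Hochberg is the default because an otherwise-unspecified
"adjusted P" is near-universally BH in this literature, and a
Bonferroni-style alternative can be obtained by adjusting externally
before gating.

**Knockdown-proteomics concordance.** Per cell line,
$\log_2\mathrm{FC} = \bar{x}_{\mathrm{KD}} - \bar{x}_{\mathrm{ctrl}}$ over
replicate-level protein abundances, tested by Welch's t (rank tests are
unreliable at $n = 4$ replicates), BH-adjusted within the line. A protein
is concordant when $|\log_2\mathrm{FC}| > 1$ and $P_\mathrm{adj} < 0.01$ in
*every* line with the same sign throughout. Discordant signs are excluded
even when both lines are individually significant.

**Peak-to-gene assignment.** Coordinates are BED-convention 0-based
half-open throughout; the TSS of a minus-strand gene is its annotation
`end`. A peak is assigned to every gene whose TSS lies within
`max_tss_distance` (default 100 kb) of the peak's nearest edge, distance 0
if the TSS falls inside the peak: $d = \max(0,\ \mathrm{start} - p,\
p - \mathrm{end})$ for TSS position $p$. The 100 kb default covers the
promoter–enhancer span typical of fusion-driven loci (tens of kb) with
headroom; it is config-exposed. One convention everywhere prevents
off-by-one drift between BED inputs and annotation tables.

Candidates are the lexicographically sorted intersection of the three
survivor sets (proteins mapped to genes through an explicit table, identity
in the synthetic data; no identifier service, hence no network dependence).
Prioritization ranks candidates by median target-entity expression and
reports an adjacent-pair rank-sum p-value — the test one would use to argue
that the top candidate is the one worth validating.

## Super-enhancer calling

Stitching merges peaks whose gap is at most 12,500 bp (the canonical ROSE
constant; config-exposed) transitively per chromosome, tracking component
counts and summed signal. No TSS-exclusion zone is applied by default. The
ranked-signal cutoff scales ascending rank to $x_i = i/n$ and signal to
$y_i = s_i/s_\max$ — dividing by the maximum rather than min–max keeps an
all-positive vector inside $(0, 1]$ — and takes
$i^* = \arg\max_i (x_i - y_i)$, the point where the scaled curve's tangent
has slope 1 for a convex profile, with ties broken toward the larger index
(the conservative choice: fewer super-enhancers). Regions with
$s > s_{i^*}$ are super-enhancers. A profile with
$\max_i(x_i - y_i) < 0.1$ has no pronounced elbow; the result is still
returned but flagged `weak_elbow`, and an all-identical signal vector is an
error rather than an arbitrary cutoff.

## Signatures and enrichment scoring

**Anchor-correlation signature.** Pearson correlation of every gene against
the anchor across the *target entity's* samples only (between-entity
correlation would be dominated by the entity contrast itself); members are
the top 100 by $r$, optionally intersected with $\{r \ge r_\min\}$, anchor
excluded.

**Knockdown signature.** A gene is fusion-activated when it is
significantly down upon knockdown ($P_\mathrm{adj} < 0.01$,
$\log_2\mathrm{FC} < 0$) in at least `min_support` tables (default: all);
the repressed set is symmetric.

**ssGSEA.** For one sample, genes are ranked by expression descending with
average ranks for ties, and
$$\mathrm{ES} = \sum_{i=1}^{N} \left[P^w_{\mathrm{in}}(i) - P_{\mathrm{out}}(i)\right],$$
where $P^w_{\mathrm{in}}$ is the weighted in-set ECDF with member weight
$r_g^{\alpha}$ ($r_g$ the gene's ascending rank, so the highest-expressed
gene carries the largest weight — the direction used by the canonical
single-sample formulation) and $P_{\mathrm{out}}$ the unweighted out-of-set
ECDF. The score is the *sum* of running differences, not the maximum
deviation; $\alpha = 0.25$ by default. With $\alpha = 0$ the score is a
pure rank functional, hence invariant under strictly monotone transforms —
a property the test suite checks. Matrix-level normalization divides all
scores by the global max − min. A set covering the whole universe (or
missing it entirely) is an error: the out-of-set ECDF is undefined.

**Preranked GSEA.** The classical running sum: members increment by
$|s|^{p}$ normalized to total 1, non-members decrement by $1/(N - |S|)$;
ES is the signed maximum deviation. We do not reproduce the analytic
multilevel null of fgsea; the null is `n_permutations` random same-size
gene sets under a local seed, $\mathrm{NES} = \mathrm{ES} /
\overline{|\mathrm{ES}_{\mathrm{null}}|}$ over matching-sign permutations,
and $p = (1 + k)/(1 + m)$ with $k$ the matching-sign null scores at least
as extreme and $m$ the matching-sign count — so $p$ is never below the
resolution floor $1/(m+1)$. If no null score matches the observed sign the
result is flagged `degenerate_null`, NES is NA, and the floor is reported.
The ES computation itself walks member positions in $O(|S|)$ — between
members the running sum falls linearly, so extrema occur only adjacent to
member positions — and agrees with fgsea's enrichment statistic, which the
suite uses as an independent cross-check.

Single-cell scoring applies ssGSEA to log1p-transformed counts after
dropping cells with fewer than 200 detected genes — a deliberately minimal
quality gate, since cluster labels come from the generator, not from the
pipeline.

## Methylation separation

CpGs are selected in $[\mathrm{start} - f, \mathrm{end} + f)$ around the
gene with flank $f = 1500$ bp (promoter-inclusive; config-exposed). The
"dimensional reduction" is the first two principal components of the
centered beta submatrix, and the visual notion of "distinct clustering" is
quantified by the mean silhouette width of target vs rest on those two
coordinates — both declared substitutes for unnamed methods, chosen because
they are the simplest reproducible versions of what the analyses show. The
hypomethylation contrast is a two-sided rank-sum test on per-sample mean
beta; betas are used raw (no M-value transform) because the test is
rank-based.

## The IRS diagnostic rule

The immunoreactive score is staining intensity (0–3) times the
positive-cell proportion category banded as 0 for 0%, 1 for (0,10)%, 2 for
[10,50]%, 3 for (50,80]%, 4 for (80,100]% — the classical Remmele–Stegner
banding, with band edges config-exposed so a modified variant can be
dialled in. The curve tabulates TP/FP/TN/FN under "positive iff
IRS $\ge c$" for every integer cutoff $c \in 0..12$; sensitivity is
non-increasing and specificity non-decreasing in $c$ by construction, and
$c = 0$ gives the exact (100%, 0%) limit. The decision rule maps
"IRS > 1" to $c = 2$, and the statement that full sensitivity is kept "up
to a cutoff of 6" is resolved as: every threshold $c \le 6$ yields 100%
sensitivity, which is forced whenever all target-entity samples score in
[6, 12].

## What the synthetic generator emulates — and what it does not

The generator defines the study conditions: 8 entities (one target), 10
bulk samples per entity (the signature analyses raise the target entity to
32 samples, the cohort size they emulate), 2,000 genes. Background log2
expression is Normal(6, 1); the two planted biomarkers are shifted +4 in
the target entity; a 30-gene coexpression module is generated as anchor +
Normal(0, 0.5), so module genes inherit the anchor's target-entity shift
(they are overexpressed *and* knockdown-responsive, as an indirect
fusion-activated program would be) but receive no fusion-binding peaks —
direct binding is restricted to the planted biomarker loci, which is what
keeps the triple intersection sharp and mirrors the biology of indirect
targets. Knockdown proteomics uses two cell lines, 4 replicates per arm,
planted effects of −2 upon knockdown, background per-protein effects
Normal(0, 0.3), and replicate-level measurement noise of 0.15 log2 units —
a typical precision for well-quantified proteins and the level at which a
−2 effect is decisive at $n = 4$. The H3K27ac landscape is 500 regions
with gamma-distributed background signal and 12 planted regions at
super-enhancer scale (a hockey-stick tail). The methylation cohort is 24
target vs 192 mimic samples over 13 mimic entities, logit-normal betas with
the planted CpGs dropped by 0.3 in the target. Single cells are negative
binomial (dispersion 0.5), 200 tumor + 200 normal, with the planted program
elevated in tumor cells. The IHC cohort is 61 target samples scoring
uniformly over {6, 8, 9, 12} and 249 mimic samples over 18 entities,
negative except for a 2% contamination fraction with weak staining (IRS
2–4) — a deliberate mirror of the ~98%-specificity regime, documented as a
mirror, not a reproduction.

What it does not emulate: platform or batch effects, absolute expression
distributions, probe-level methylation artifacts, doublets or ambient RNA
in single cells, inter-rater variability in IHC scoring. Passing tests on
this generator therefore demonstrates that the pipeline's logic and
statistics behave as specified under clean planted truth — not that any
particular real cohort would reproduce the printed effect sizes.

## Numerical choices and degenerate inputs

Ranks use midranks everywhere; descending sorts break ties
lexicographically by gene name so scores are deterministic. Expression
readers reject missing values rather than imputing (no imputation rule is
defensible without platform knowledge). p-values are floored at the
smallest positive double before BH, which requires $p \in (0,1]$.
Seeded operations (permutation GSEA, the generator) save and restore the
caller's RNG state, so pipeline results cannot depend on call order.
Degenerate cases fail loudly: empty rank-sum groups, all-identical SE
signals, constant beta submatrices, gene sets equal to the universe,
zero-variance anchors, IRS inputs out of range.

Problem sizes used by the test suite and analysis scripts — 2,000 genes,
1,500 proteins, 500 enhancer regions, 400 CpGs, 400 cells, 20 generator
seeds for the recovery and methylation frequency checks, 200 calibration
trials at 1,000 permutations — were chosen once as the smallest sizes at
which every planted effect is decisively detectable and null calibration is
measurable; they keep a full run in the low minutes on one core.

## Known limitations

The pipeline consumes protein-level tables and called peaks; it does not
process raw spectra or alignments. The permutation NES is not numerically
comparable to fgsea's analytic NES (same sign and regime, different
normalization constant). The modified-IRS banding of the original
supplementary protocol is approximated by the classical banding with
configurable edges. The per-entity strict DEG mode and the Bonferroni
alternative are provided but not exercised by the default workflow.
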