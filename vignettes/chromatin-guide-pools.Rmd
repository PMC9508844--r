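---
title: "Designing chromatin-state CRISPR guide pools and analysing dropout screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing chromatin-state CRISPR guide pools and analysing dropout screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromguide)
```

# The question and the method

A single CRISPR/Cas9 double-strand break (DSB) is enough to arrest and
sometimes kill a cell. Whether the *chromatin context* of the break —
promoter vs heterochromatin, lamina-associated vs interior — modulates that
toxicity can be asked with a pooled dropout screen: express one
single-cutting sgRNA per cell, let toxic breaks deplete their guides from
the population, and sequence guide abundance over time. `chromguide`
implements the computational side of that experiment as four stages plus a
synthetic-data generator:

1. **Single-cutter design** (`scan_pam_sites()`, `random_candidates()`,
   `find_matches()`, `design_single_cutters()`, `assemble_library()`):
   retain only protospacers with exactly one perfect NGG-adjacent genomic
   target and no secondary site within a Hamming mismatch radius (default
   3), so that each guide induces one and only one DSB.
2. **Window annotation** (`annotate_guides()`): summarise chromatin tracks
   in a fixed window (default 4 kb) centred on each cut site — ChromHMM
   state fractions and breaksite state, LAD/iLAD fractions, DNaseI window
   maximum, H3K9me3 coverage-weighted mean, and gene context from gene
   models plus expression values.
3. **Pool filtering and selection** (`builtin_pools()`, `evaluate_rule()`,
   `design_pools()`): apply six published rule sets that each isolate one
   chromatin environment, then select k = 10 guides per pool with at most
   2 per chromosome.
4. **Screen analysis** (`control_size_factors()`, `log2_fold_change()`,
   `region_dose_comparison()`, `chromosome_summary()`): normalise counts,
   compute paired log2 fold changes between an early reference timepoint
   (day 4) and a late timepoint (day 8 or 16), and compare regions.

# Coordinate and sequence conventions

All coordinates are 0-based, half-open `[start, end)` (BED-native)
everywhere in memory and on disk; 1-based presentation is formatting only.
A single convention eliminates off-by-one drift between the interval
arithmetic, the sequence scans and the file formats.

The PAM is NGG placed 3' of the 20-nt protospacer, the standard SpCas9
geometry. The blunt cut sits between protospacer bases 17 and 18, i.e.
3 bp 5' of the PAM; `cut_pos` is that breakpoint coordinate
(`start + 17` for a + guide, `start + 3` for a − guide occupying
`[start, start + 20)` in + coordinates). For U6 expression an extra 5' G
is always prepended to the protospacer — even when base 1 is already G —
giving a 21-nt expressed sequence.

# Off-target search

`find_matches()` is an exact Hamming scan (no indels, no seed heuristics)
of the protospacer and its reverse complement over every position of every
chromosome, with a small compiled kernel that abandons a position as soon
as the mismatch budget is exceeded. Two policies are provided because the
original library's behaviour is not documented:

* `require_pam = TRUE` (default): a secondary site only disqualifies a
  guide if it carries an NGG PAM — the biologically conservative reading,
  since Cas9 cannot cut without a PAM;
* `require_pam = FALSE`: any sequence match within the radius disqualifies.

`design_single_cutters()` keeps a candidate iff its hit list within the
radius is exactly one perfect, PAM-adjacent placement. Non-targeting
controls are rejection-sampled random 20-mers verified to have *zero*
placements within the radius under the PAM-agnostic policy (the stricter
definition, appropriate for guides that must do nothing).

The scan is checked in the test suite against a naive character-level
all-positions oracle on twenty seeded genomes; the two must agree exactly.

# Window annotation choices

Several details of the published procedure are underdetermined; the
package fixes them as follows.

* **Anchor**: the window is centred on the *cut site*, not the protospacer
  midpoint or start. The break, not the binding footprint, is the
  biological event of interest.
* **Denominator**: fractions always divide by the nominal window length
  (4000 bp by default), even when the window is clipped at a chromosome
  end; clipping is flagged in the `clipped` column so filters can exclude
  such guides. This keeps a "65% of the window" threshold comparable
  across guides.
* **Uncovered bases**: state and lamina tracks need not tile the genome;
  uncovered (or clipped-away) base pairs accrue to an explicit
  `unannotated` fraction, so state fractions plus `unannotated` always sum
  to 1 (enforced to 1e-9 in tests).
* **Signal summaries**: the DNaseI feature is the *maximum* value among
  intervals overlapping the window ("highest peak in the window"); the
  H3K9me3 feature is the coverage-weighted mean, sum(value x overlap bp) /
  window length, with uncovered bases contributing zero. The source
  material describes the H3K9me3 statistic both as a "weighted peak
  height" and an "average peak height"; the coverage-weighted mean is the
  single well-defined statistic consistent with both phrasings.
* **Gene context**: a cut is `genic` if inside any gene span, `exonic` if
  inside an exon of such a gene, `intronic` if genic and not exonic, and
  `expressed` if an overlapping gene's expression exceeds
  `expression_threshold` (default 1 normalized-expression unit — a
  conventional expressed/silent cut-off; no value is published, and it is
  a user parameter).
* **Namespaces**: a guide on a chromosome missing from the supplied genome
  namespace is an error; a chromosome merely lacking track intervals
  yields unannotated fractions and zero signal. This distinguishes user
  error from sparse annotation.

# The six pools and their thresholds

| pool | state clause | DNaseI | lamina | gene context |
|------|--------------|--------|--------|--------------|
| pool2 (promoters) | state 2 >= 65% of window, breaksite in state 2 | max > 0.2 | iLAD > 90% | genic + intronic, expressed |
| pool4 (enhancers) | state 4 > 50% | — | iLAD > 99% | — |
| pool7 (gene bodies) | state 7 > 99% | max < 0.06 | iLAD > 90% | genic + intronic, expressed |
| pool8a (polycomb, iLAD) | state 8 > 99% | — | iLAD > 99% | non-genic |
| pool8b (polycomb, LAD) | state 8 > 99% | — | LAD > 99% | non-genic |
| pool9 (heterochromatin) | breaksite confirmed state 9 | — | LAD > 99% | non-genic, H3K9me3 weighted mean > 5.5 |

Inclusivity follows the published wording literally: "at least 65%" is
inclusive (a window at exactly 0.65 passes); every threshold printed with
">", "<" or "exceed" is strict (a DNaseI max of exactly 0.2 fails pool2).
The published description of pool7's DNaseI rule is self-contradictory
(a tabulated "< 0.06" vs a prose "had to exceed 6%"); the tabulated upper
bound is adopted — gene bodies as closed chromatin, distinct from
accessible promoters — and the clause can be overridden via
`pool_definition()`. Pool4's observed 2-genic/8-non-genic composition is
treated as an outcome of selection, not a constraint, since no gene-context
filter is listed for it.

Selection among passing candidates (`select_pool()`) is a seeded uniform
shuffle followed by a greedy scan that skips a guide once its chromosome
has contributed `max_per_chrom` (default 2) guides. How the original ten
were chosen from the filtered list is not documented; a seeded shuffle is
simple, unbiased and reproducible. The greedy scan attains the maximum
feasible pool size `sum(min(n_chrom, cap))`; when that is below k the
function raises a typed error reporting the maximum, which the test suite
confirms against brute-force subset enumeration on small instances. By
default a guide selected by an earlier pool is withheld from later pools
(`exclusive = TRUE`); sharing between pools is not documented either way
in the source material, and exclusivity matches pools meant to be
transfected as disjoint sets.

# Screen analysis

Counts are first normalised as reads-per-million per sample
(`total_count_normalize()`), the published first step. For fold changes,
per-sample library-size factors are estimated from non-targeting control
guides only, by median-of-ratios: each control is divided by its
geometric mean across samples and a sample's factor is the median ratio;
controls containing any zero are excluded. Anchoring on controls is what
makes "no change" well defined in a screen where much of the library
depletes: a depleting library inflates every surviving guide's share of
the reads, and control anchoring removes exactly that compositional
drift. The implementation is cross-checked in the tests against DESeq2's
`estimateSizeFactorsForMatrix()` on control-only matrices.

Per replicate pair (reference day 4, target day 8 or 16),

$$\mathrm{lfc}_{g,r} = \log_2\frac{c_{g,t}/s_t + 0.5}{c_{g,ref}/s_{ref} + 0.5}$$

with the pseudocount 0.5 applied symmetrically *after* size-factor
scaling, so zeros stay finite and swapping reference and target negates
every value exactly. Guide-level values are means over replicate pairs.

Dropout inference here is deliberately fold-change plus a two-sided
rank-sum (Wilcoxon) test for region contrasts
(`region_dose_comparison()`), e.g. guides inside vs outside an amplified
chromosome arm where extra copies mean extra breaks per cell. A
negative-binomial Wald test with multiplicity correction (DESeq2-style) is
established machinery, not this package's contribution, and is out of
scope; the rank-sum test is the distribution-free default for a two-group
shift when no test is named in the source material.

# What the synthetic fixtures emulate — and what they do not

`fixture_spec()` + `make_fixture()` generate: i.i.d. uniform-base
genomes; chromatin-state tracks tiling each chromosome with
exponential-length segments (mean 3 kb, floor 200 bp) over states
"1".."10"; alternating LAD/iLAD tracks (mean segment 12 kb); DNaseI peaks
(400 bp, heights 0.5–3) placed preferentially in state-2 segments;
H3K9me3 plateaus (heights 6–10) over state-9 segments; and non-overlapping
genes (spans 4–8 kb, 3 evenly spaced 200-bp exons, 70% expressed with
values 2–20). `plant_pool_sites()` additionally engineers regions that
satisfy exactly one pool's rule set each and writes a verified unique
20-mer + NGG at the centre, round-robin across chromosomes on a 6 kb slot
grid, so a k = 10 / cap = 2 pool is feasible with at least five
chromosomes. These defaults were chosen once as plausible magnitudes for
segment-structured chromatin annotation at desk scale.

`simulate_screen()` draws initial relative abundances from a flat
Dirichlet per replicate and evolves guide i's expected share as
$a_{0i}\,[(1-e_i) + e_i\,2^{-d_i t}]$ — a mixture of unedited (neutral)
and edited cells whose descendants halve every $1/d_i$ days. This is the
simplest mechanism coupling toxicity to editing efficiency
multiplicatively, giving the analysis stage a falsifiable recovery target:
with efficiency 0 a "toxic" guide is indistinguishable from a control.
Counts are negative binomial around depth x share with overdispersion
0.05 (a typical pooled-screen noise scale; configurable). Efficiency
defaults to 1 (idealised fully-editing guides) so that planted depletion
maps monotonically onto expected fold change; intermediate efficiencies
are exercised explicitly in the tests.

What the fixtures do **not** emulate: real human sequence composition
(repeats, GC isochores, segmental duplications — so the mismatch landscape
is far sparser than Hg19's), ChromHMM's empirical segment-length and
transition structure, correlated replicate infection bottlenecks, PCR
jackpotting, or guide-specific sequencing bias. Passing tests therefore
demonstrate correctness of the pipeline's logic and statistics under a
clean generative model, not performance on genome-scale real data.

# Numerical choices and degenerate inputs

* Fractions are compared to thresholds as plain doubles; built-in
  thresholds and test sweeps are constructed from integer ratios
  (e.g. `65/100`), which round to the same double as the literal, so
  boundary behaviour is exact.
* Readers reject rather than repair: `start >= end`, negative counts or
  expression, non-numeric signal, overlapping valued intervals and
  duplicate ids are format errors naming the offending line.
* Empty passing sets, infeasible pools and all-inside region partitions
  raise typed or descriptive errors rather than returning degenerate
  results; `design_pools()` collects per-pool selection errors instead of
  aborting the remaining pools.
* All randomised operations take explicit seeds and restore the caller's
  RNG state. User seeds for sequence sampling are internally hashed so
  that re-using the seed that generated a synthetic genome cannot
  regenerate the genome's own base stream as "random" candidates.

# Problem sizes used by the test suite

The suite runs entirely on generated data: oracle equivalence on twenty
2 x 2 kb genomes; single-cutter recovery on a 6 x 30 kb genome with six
unique and six shadowed guides; pool recovery on 6 x 80 kb fixtures with
12 planted sites per pool; screen recovery at 500 guides, 3 replicates
and 1e6 reads per sample (the control-bias estimate averages five
independent screens, since a single screen's control mean has Monte Carlo
sd comparable to the 0.05 acceptance band); and mass conservation on 1000
random 4 kb windows. These sizes were chosen so the complete suite runs
in about a minute on one core.

# Known limitations

* The Hamming scan deliberately ignores DNA/RNA bulges and indel
  off-targets, and provides no CFD/MIT-style scoring; it answers
  "is this guide unique within r mismatches", not "how active is each
  off-target".
* `find_matches()` is exhaustive; on mammalian-genome scale a k-mer
  index or aligner front-end would be needed.
* Screen inference stops at fold changes and rank-sum contrasts; no
  per-guide significance or multiple-testing machinery is provided.
* Gene context uses gene spans and exons only — no UTR/CDS distinction,
  no transcript isoforms.
* The guide-window anchor and fraction-denominator conventions are this
  package's resolutions of ambiguities in the published description (see
  above); both are parameters of interpretation, not of the code, and are
  documented rather than configurable.

# A worked example

```{r example}
spec <- fixture_spec(
  n_chromosomes = 6, chrom_length = 80000,
  planted = c(pool2 = 12, pool4 = 12, pool7 = 12,
              pool8a = 12, pool8b = 12, pool9 = 12),
  seed = 11)
fx <- make_fixture(spec)

ann <- annotate_guides(fx$truth, fx$tracks$states, fx$tracks$lads,
                       fx$tracks$dnase, fx$tracks$h3k9me3, fx$tracks$genes,
                       chrom_lengths = nchar(fx$genome))
design <- design_pools(ann, seed = 7)
design
```

```{r screen}
ids <- c(fx$truth$id, sprintf("CTRL_%03d", 1:100))
ctrl <- startsWith(ids, "CTRL")
set.seed(1)
depl <- ifelse(ctrl, 0, runif(length(ids), 0, 0.3))
cm <- simulate_screen(screen_sim_spec(ids, ctrl, depl, seed = 1))
sf <- control_size_factors(cm)
pairs <- data.frame(replicate = 1:3, reference = sprintf("d4_r%d", 1:3),
                    target = sprintf("d16_r%d", 1:3))
fc <- log2_fold_change(cm, sf, pairs)
cor(depl[!ctrl], fc$lfc[match(ids[!ctrl], fc$id)], method = "spearman")
head(chromosome_summary(fc, fx$truth))
```
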