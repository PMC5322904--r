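---
title: "Methods: calling and comparing miRNA 3' truncation and tailing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling and comparing miRNA 3' truncation and tailing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isotrim)
```

# The model

Mature plant miRNAs are protected by 3'-terminal 2'-*O*-methylation.
Degradation intermediates carry two 3'-end marks: loss of nucleotides from
the 3' end (truncation, attributed to SDN-family 3'-to-5' exonucleases)
and addition of non-templated, U-rich nucleotides (tailing, by the
HESO1/URT1 nucleotidyl transferases). isotrim models every read assigned
to a miRNA as

$$\mathrm{read} = \mathrm{mature}[1..L - tr] \,\Vert\, \mathrm{tail},$$

where $tr \ge 0$ is the truncation length, the tail is whatever the read
carries past the matched mature prefix, and $ta = |\mathrm{tail}|$. The
pair $(tr, ta)$ defines the four mutually exclusive categories FL,
TR-only, TA-only and TR+TA.

## Assignment algorithm

A read is assigned by **exact 5'-anchored prefix matching**: among
references whose mature 5' end equals the read 5' end over at least
`min_match` bases, the matched length is the longest common prefix of
read and mature (capped at the mature length); then $tr = L -
\mathrm{matched}$ and the remaining suffix is the tail. A read is
accepted for a reference iff $tr \le$ `max_tr` and $ta \le$ `max_ta`;
among accepting references the one with minimal $tr$ wins.

The choices behind this algorithm, where the design was genuinely open:

* **No internal mismatches, no 5' isomiRs.** The quantities of interest
  are purely 3'-end phenomena; allowing 5' offsets or mismatches would
  trade a well-defined decomposition for sensitivity this analysis does
  not need. A consequence worth knowing: a sequencing error downstream of
  the matched prefix converts an FL read into an apparent TR+TA read
  (measured in the test suite: at a 1% per-base substitution rate roughly
  9% of FL reads shift category, a maximum composition distortion of
  about 0.05).
* **Tail dialect.** Under the default `mature_anchored` dialect every
  base past the matched mature prefix counts as tail even if it matches
  the hairpin (genome-templated). Rationale: a hairpin-templated U
  downstream of the mature end would otherwise mask genuine uridylation.
  The alternative `template_extended` dialect lets the match continue
  along the hairpin and records the templated extension length in a
  `templated_ext` column, for sensitivity analysis.
* **Ambiguity.** Closely related families (e.g. miR165 vs miR166) differ
  at few positions, and deep truncation can erase the difference. Ties at
  equal minimal $tr$ are dropped by default (counted and reported);
  `ambiguous_policy = "fractional"` splits the count equally instead,
  yielding non-integer counts.

## Parameters

| parameter | default | unit | why |
|---|---|---|---|
| `max_tr`, `max_ta` | 8 | nt | covers the offsets visible on truncation-tailing matrix axes; configurable |
| `min_match` | 12 | nt | 5' anchor long enough that chance matches are improbable (kept >= 10) |
| `min_len`, `max_len` | 15, 30 | nt | small-RNA length filter; adapter trimming is assumed upstream |
| `tail_dialect` | `mature_anchored` | — | see above |
| `ambiguous_policy` | `drop` | — | conservative and reproducible |

`max_tr` must stay below the shortest mature length minus one; this is
checked at classification time. Note that on a 21-nt mature, truncations
of 7–8 nt with no tail produce 13–14-nt reads, which the length filter
removes: deep TR-only isoforms are systematically invisible, a property
shared by any pipeline with a minimum read length.

# Quantification

* **RPM** is `count / library_total * 1e6`. The denominator is, by
  default, all reads passing the length filter (assigned + unassigned);
  whether published RPM values used genome-matched or miRNA-matched
  totals is generally unstated, so `denominator = "assigned"` is also
  available.
* **Compositions** report per-group category counts, proportions and
  RPM. Groups with zero reads are omitted rather than emitted as NaN
  rows, so downstream statistics never see 0/0.
* **Truncation ratio** is $(n_{TR} + n_{TR+TA})/\mathrm{total}$; the
  **TR-only ratio** uses $n_{TR}$ alone.
* **Abundance filter**: groups with RPM > threshold (default 10) in
  *every* library, the convention for presenting "abundant" miRNAs; an
  any-library mode exists and always yields a superset.
* **Truncation-tailing matrices** put proportions on the
  $(tr, ta) \in [0..8]^2$ grid; composition proportions are exactly its
  margins (`p_FL` = cell (0,0), `p_TA` = rest of row 0, `p_TR` = rest of
  column 0), which the tests assert to 1e-9.
* **Percentage tables** (`percent_table`) round half-up to one decimal —
  the convention of printed tables — while all internal computation is
  full precision.

# Comparison procedures

* **Mock subtraction** for in vitro exonuclease assays subtracts the
  no-enzyme (or catalytically dead) control from the treatment entrywise,
  floored at zero. It operates on proportions by default (RPM also
  works); a group present only in the control is kept at zero and
  reported. Monotonicity and the adjusted <= treatment bound are asserted
  over randomized fixtures.
* **Replicate pooling** sums counts *before* any ratio is computed.
  Pool-then-ratio and mean-of-ratios genuinely differ (a regression test
  keeps a fixture where they do), and the TR/FL scatter logic uses the
  pooled form.
* **Two-group tests** are two-sided Welch t-tests on raw per-replicate
  proportions — robust to unequal variance at n = 2–3; the pooled-variance
  Student variant is selectable. Stars follow 0.05 / 0.01 / 0.001.
  Whether published asterisks derive from t-tests on proportions, counts
  or transformed values is usually not recoverable; this is an
  interpretation, not a fact. Degenerate inputs are handled outside
  `stats::t.test`, which errors on constant data: two constant, equal
  groups give p = 1; two constant, different groups give p = 0; fewer
  than two replicates in either group gives a missing p-value and empty
  stars. Raw p-values are reported (no correction) as is conventional for
  starred figures; Benjamini–Hochberg is available as an extra column.
* **The summed truncation test** applies the same test to the
  per-replicate sum `p_TR + p_TRTA` (identically the truncation ratio):
  a total-truncation reduction can be significant when neither component
  is.
* **Library clustering** computes Euclidean distances on
  `log2(RPM + 1)` profiles and agglomerates with average linkage
  (configurable: single, complete, ward). Distances are taken over
  (group x category) RPM by default: group-total RPM cannot see
  composition shifts at all, while the full (group, tr, ta) grid has many
  low-count cells whose sampling noise dominates distances in small
  libraries; the four category cells per group are the stable middle
  ground. The tree is serialized as Newick via `ape`.

# The synthetic generator

`generate_library()` draws, per group: a category from the profile's
(FL, TR-only, TA-only, TR+TA) mixture; truncation and tail lengths from
truncated geometric distributions on 1..8 (parameters `q_tr`, `q_ta`,
default 0.5 — short offsets dominate, matching the qualitative shape of
observed truncation-tailing matrices without claiming their exact form,
which is not recoverable from published figures); tail bases i.i.d. with
P(U) = 0.9 (uridylation-dominated tailing); then optional per-base
substitution errors. Background reads are random 15–30-nt hairpin
substrings. Reads are emitted with a per-read manifest of the true
(group, tr, ta, tail, category, error positions).

Preset profiles encode the genotype contrasts the analysis is designed to
detect, as category mixtures (FL / TR-only / TA-only / TR+TA):

| preset | mixture | encodes |
|---|---|---|
| `wildtype_like` | .94/.02/.02/.02 | methylated, stable miRNAs |
| `hen1_like` | .35/.20/.15/.30 | rampant truncation + uridylation |
| `hen1_sdn_like` | .60/.08/.20/.12 | SDN loss: truncation much reduced |
| `hen1_heso1_like` | .35/.40/.10/.15 | HESO1 loss: TR+TA mass shifts to TR-only |
| `ago10_oe_like` | wildtype, with miR165/166-pattern groups at .70/.15/.03/.12 and 0.4x abundance | truncation elevated for miR165/6 only |

Defaults: `background_fraction = 0.02`, `error_rate = 0`,
`library_size = 50000`, equal group abundances. These are fixed modeling
choices; the mixtures were chosen once to reproduce the qualitative
orderings (SDN loss lowers `p_TR + p_TRTA`; HESO1 loss lowers `p_TRTA`
while raising `p_TR`) with magnitudes typical of deep-sequencing isomiR
profiles.

**Determinism and matched seeds.** Each group draws from an RNG substream
derived from (library seed, group name), and per-group read counts are
apportioned deterministically (largest remainder). Two libraries built
with the same seed therefore emit byte-identical reads for every group
whose parameters agree — which is what makes matched-seed type-I checks
exact: groups with identical profiles across genotypes produce identical
per-replicate values and p = 1.

**Collision control.** By default the first tail base is drawn avoiding
the next templated base (the next mature base for truncated reads, the
first downstream hairpin base otherwise), so the generated (tr, ta) is
the unique decomposition and ground truth is unambiguous under either
dialect. Turn it off for realism runs; with it off, a tail that happens
to continue the template is *correctly* called with a smaller tr by the
classifier, and the manifest and calls legitimately disagree.

**What the generator does not emulate:** ligation and PCR bias, adapter
chemistry, quality-score structure, 5' heterogeneity, expression
correlation between miRNAs, and the true in vivo truncation/tail length
distributions (only depictable, not printed, in published figures).
Passing closed-loop tests therefore demonstrates the internal consistency
of generator + classifier + quantification under the stated model — not
performance on real libraries with features outside the model.

# Problem sizes and tolerances in the test suite

The suite runs the classifier/oracle comparison on 1,000 random
(mature, read) pairs; closed-loop recovery on one 100,000-read error-free
library over 8 groups (tolerance ±0.01 on every per-group category
proportion, with exact recovery for point-mass profiles); contrast
recovery on 2 genotypes x 3 replicates x 20,000 reads; and clustering
purity on 3 presets x 2 replicates x 8,000 reads over three seeds. These
sizes keep the full suite under a few minutes while leaving the sampling
error of each check an order of magnitude below its tolerance (a
20,000-read library gives per-group proportions a standard error of about
0.006; tested differences are 0.1–0.2).

# Known limitations

* Exact-match assignment will not recover reads from polymorphic or
  edited miRNAs; mismatch tolerance is deliberately out of scope.
* Collapsed groups keep a single representative hairpin context (the
  first member in sorted order). If member hairpins differ immediately
  downstream of the mature end, `template_extended` calls can depend on
  that choice; the mature-anchored default is unaffected.
* The RPM denominator convention matters when comparing against published
  numbers; both options are exposed but they are not interchangeable.
* p-values from n = 2 replicates have 1–2 degrees of freedom; stars at
  that depth are a reporting convention, not strong inference.
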