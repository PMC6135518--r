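---
title: "Designing vertebrate-specific COI primers and identifying mosquito blood meals with vertcoi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing vertebrate-specific COI primers and identifying mosquito blood meals with vertcoi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertcoi)
```

## The problem

A mosquito blood meal contains host DNA that identifies the vertebrate the
mosquito fed on, which is the raw material for reconstructing host-use
networks and the transmission ecology of mosquito-borne pathogens. The
standard workflow amplifies a fragment of the mitochondrial *COI* barcode
from the blood meal, sequences it, and assigns a species by similarity to a
reference library. Three constraints make primer design for this application
hard:

1. the primers must anneal across all terrestrial vertebrate classes
   (amphibians, birds, mammals, reptiles), which forces degenerate bases at
   variable positions;
2. they must *not* amplify the overwhelming excess of mosquito template in
   the same extract, which is achieved by placing primer-template mismatches
   against mosquito sequences at or near the primer 3' end, where they block
   extension;
3. the amplicon should be short, because digestion fragments host DNA and
   short fragments survive longer than long ones.

`vertcoi` implements this design procedure and the downstream
identification workflow as a tested, fully offline library: IUPAC
ambiguity-code algebra, priming-site discovery from a joint
vertebrate/mosquito alignment, in-silico PCR with a 3'-clamp mismatch
model, hierarchical amplification with a percent-identity assignment rule,
a seeded synthetic-data generator, and the product-concentration
statistics used to validate versatility and specificity. The package ships
the four published degenerate primers (`coi_primers()`), whose three
combinations amplify 664, 395 and 244 bp of the vertebrate barcode region
(`coi_primer_pairs()`).

## Priming-site discovery

`scan_priming_sites()` consumes a gapped multiple alignment whose rows are
labelled `target` (vertebrates) or `non-target` (mosquitoes) and slides
windows of 20-25 bp over every column in both orientations. Per column the
target group is summarised by the minimal IUPAC code covering every base at
within-group frequency at least `min_base_freq` (default 0.05, computed over
non-gap bases); rarer bases are dropped and recorded as tolerated target
mismatches. Against the non-target group each column is classified *full*
(no mosquito sequence matches the consensus code — the bolded positions of
the published primer table), *partial* (some do), or matching. A window
containing at least one full mismatch column is classed
`"vertebrate universal"`, otherwise `"universal"`.

Windows are ranked by

$$ S = w_1\,c + w_2 \sum_{j \in \text{full}} k(o_j)
     - w_3 \log_2 d - w_4 \sum_{j \in \text{dropped}} k(o_j), $$

where $c$ is target coverage (fraction of target sequences matched at every
column), $d$ the degeneracy fold, $o_j$ the 0-based offset of column $j$
from the 3' end, and $k(o) = 1/(1+o)$ a strictly decreasing 3'-proximity
kernel. Defaults $w = (1, 1, 0.1, 1)$ encode the published design
preferences — reward conservation and 3'-proximal mosquito mismatches,
penalise degeneracy mildly and tolerated target mismatches strongly — they
are deliberately a formalisation, not a fitted model, and are exposed as
arguments. The original procedure was manual inspection of the alignment;
the scoring function is this package's reproducible stand-in for it.

Numerical choices worth knowing:

* **Degeneracy cap.** Candidates above 512-fold degeneracy (the usual
  threshold past which non-specific amplification becomes likely) are
  discarded; the cap is configurable.
* **Gap rule.** Any window containing a column with more than 10% gaps in
  the target group is ineligible; `consensus_window()` separately refuses
  gap-majority columns.
* **Tie-breaks.** Equal scores are ordered by lower degeneracy, more
  3'-proximal full mismatch, leftmost start, then *longer window*. The last
  key is needed because a sub-window of a conserved site that retains the
  3'-terminal mismatch column ties exactly on all preceding keys in reverse
  orientation.
* **Coordinates.** All exported coordinates are 1-based inclusive
  `[start, end]`, the R/Bioconductor convention; mismatch offsets are
  0-based from the 3' end.

`pair_candidates()` maps forward/reverse windows through the alignment onto
an ungapped reference and emits primer pairs with primer-inclusive amplicon
lengths, the convention under which the published combinations measure
664/395/244 bp.

## In-silico PCR

`find_binding_sites()` scans both strands of a template for primer
annealing sites under a two-parameter model: at most `max_mismatches`
(default 3) mismatches per primer and none within the 3'-terminal `clamp`
bases (default 3). A mismatch is decided per position by strict
set-membership of the concrete template base in the IUPAC code's base set;
an ambiguity code on the template itself (an `N` in a deposited reference)
is matched leniently by set intersection so that sequencing ambiguity does
not abolish predicted binding. The published work gives no numeric
annealing model — only the rationale that 3' mismatches block extension —
so both knobs are configurable and recorded in every screen report.
`predict_amplicons()` combines all forward sites on the plus strand with
all downstream reverse sites on the minus strand and reports every product
within the length bounds; there is deliberately no "dominant product"
heuristic. `specificity_screen()` tallies amplified/none verdicts over
target and non-target panels, the in-silico analogue of gel-based
versatility/specificity scoring; an empty non-target panel yields an `NA`
fraction, never a spurious 0 or 100%.

## Identification workflow

`pairwise_identity()` is a deterministic, offline surrogate for the
two-sequence similarity scores of online barcode engines: a global
alignment with free end gaps (`Biostrings::pairwiseAlignment(type =
"overlap")`, match 1 / mismatch −1 / gap open 4 / extend 1), with identity
= matches over aligned columns excluding terminal gaps. Whether the
original engine's "% similarity" is numerically identical is unknowable;
this contract is fixed, symmetric and reproducible, and a query nested in
a longer reference scores 1.

`identify_host()` applies the barcode rule: assign the species of the best
hit if its identity reaches the threshold (default 0.98, *inclusive* — a
hit at exactly 98.0% is assigned); report `ambiguous` when two or more
species tie at or above threshold, where a tie means equality after
rounding to 0.01 percentage points (the source procedure never adjudicates
ties; this tolerance makes the rule deterministic); otherwise
`unassigned`. `resolve_external()` re-runs an unassigned query against
independently obtained references only — the fallback used in practice
when a local lineage or unreferenced species (green anole and marsh rabbit
in the original study) is absent from the public database — and marks
successes `resolved_by_external_reference`.

`hierarchical_identify()` mirrors the field protocol: ordered PCR attempts,
by default shortest amplicon first (244, then 395, then 664 bp), stopping
at the first combination that yields a product on any intact fragment of
the sample's template; total failure is `no_amplification`.
`tabulate_hosts()` cross-tabulates outcomes into the host-by-mosquito count
table, with explicit `Unidentified` and `No amplification` rows.

Mixed-template (double-peak) detection is out of scope; inputs are assumed
single-source, as accepted chromatograms in the original workflow were.

## The synthetic-data generator

All tests run on data from `make_alignment()` and `make_study()`, which
emulate the study's structure with known ground truth.

`make_alignment()` radiates 31 target and 12 non-target sequences from a
common ancestor (no indels — vertebrate COI is protein-coding and
effectively indel-free at this scale) and then implants priming sites:
windows held invariant across targets, with specified columns forced to
mismatch *every* non-target. Two generator choices matter for
interpretation:

* **Divergences.** Defaults are 0.15 within groups and 0.25 between the
  target and non-target ancestors. A cross-class panel of 31 vertebrate COI
  sequences is highly diverged (cross-class pairwise divergence typically
  exceeds 20%); at unrealistically low background divergence (a few
  percent) chance background columns are as discriminative as implanted
  ones and "the implanted window" stops being a meaningful ground truth.
* **Flanks.** The two columns flanking each implanted site are made
  polymorphic among targets (and kept matching in non-targets) so the site
  has well-defined ends; without this, one-column extensions of a
  conserved window tie with it and recovery becomes a coin flip among
  equivalent candidates.

`degrade_template()` implements the digestion model implied by the inverse
relationship between amplification success and amplicon length: each of
the $n-1$ internucleotide bonds breaks independently with probability
$\lambda$, so a fixed span of length $L$ survives intact with probability
$(1-\lambda)^{L-1}$. The BF digestion scores map to
$\lambda = 0, 0.002, 0.01$ for BF1/BF2/BF3. The source material gives only
the ordering fresh < digested; these values are a declared modelling
choice, selected once so that fresh scores essentially always amplify
while BF3 often fails the 664-bp combination yet frequently retains a
244-bp span — the qualitative pattern that motivates the
short-amplicon-first hierarchy.

`make_study()` ties everything together: host species radiated at 10%
divergence around a COI-like template that carries one concrete expansion
of each published primer at the published amplicon geometry (sites
conserved across hosts), mosquito references with two 3'-clamp mismatches
knocked into each vertebrate-universal site (the universal Mod_RepCOI_R
site stays intact, as in the published specificity table), and blood-meal
samples with known hosts, digestion scores and fragmented templates.

One non-obvious geometric fact is handled explicitly: VertCOI_7194_F and
VertCOI_7216_R address the same conserved motif on opposite strands (their
code sets are compatible over the full 23-position overlap), so any
template carrying both sites verbatim would also support cross-annealing
products (292 and 443 bp) beyond the three published lengths. The
synthetic template therefore places one mismatch per site that its own
primer tolerates at the 5' end but that falls inside the *other* primer's
3' clamp — exactly the published design rule of shifting unavoidable
mismatches 5'-ward — which suppresses the cross-products and realises
precisely the published product set.

What passing tests on these data do **not** show: performance on real
chromatograms (quality trimming, double peaks), NUMT co-amplification,
indel-containing or misaligned references, PCR stochasticity beyond binary
site intactness, and real cross-species identity structure (the generator's
uniform substitution model has no rate heterogeneity or codon structure).

## Concentration statistics

`ng_to_nM()` converts fluorometer readings with the community-standard
660 g·mol⁻¹ per double-stranded base pair (the constant is an argument; the
original analysis states the conversion but not the constant).
`classify_product()` applies the strict > 45 nM sequencing-sufficiency rule;
the gel band categories (none < 10 ≤ weak ≤ 45 < strong) are an invented
operationalisation of qualitative strong/weak/none calls and are labelled
as such.

`crossed_anova()` fits the fixed-effects primer × template ANOVA whose
df/SS/F structure the published results table reports (the text calls
template a random effect, but the printed table is the fixed-effects
decomposition; this package implements what the table shows and notes the
discrepancy). The design must be complete — an empty cell is an explicit
error — and with the published replicate counts (93 + 14 + 4 extracts × 3
combinations) the residual df is 315. A constant response yields `NaN` F
ratios rather than an error. `tukey_groups()` runs `stats::TukeyHSD`
(studentized range, as in the original analysis) and summarises pairwise
results as a compact letter display via the insert-and-absorb algorithm,
implemented here directly because no installed package provides letter
displays over `TukeyHSD` output. `oneway_anova()` reproduces the
vertebrate-only comparison (between df 2; with 93 × 3 records, within df
276 — the published denominator df of 267 is internally inconsistent with
the printed counts and is not targeted). `simulate_quant_records()`
generates complete designs for calibration; with all effects zero it
simulates the null under which the crossed ANOVA's type-I error is checked.

## Problem sizes and reproducibility

Every stochastic function takes a `seed` argument, restores the caller's
RNG state, and is byte-reproducible. The shipped test-suite sizes are the
package's chosen desk-scale conditions: oracle comparisons on 100 random
templates up to 2 kb, window recovery over 20 seeded alignments,
a 61-sample end-to-end study, fragment-survival calibration at n = 10,000
per break rate, and 1,000 null replicates for ANOVA calibration.
`scripts/acceptance.R` recomputes the headline quantities from scratch for
any seed.

## Known limitations

* Identification identity is alignment-based; heavily truncated queries
  (< 50 nt) are refused rather than scored.
* The in-silico PCR model is binary (site intact and within mismatch
  budget, or not); it does not grade amplification efficiency, so "weak"
  bands have no in-silico analogue beyond the invented concentration
  thresholds.
* The scanner enumerates windows exhaustively in O(lengths × columns);
  alignments of genome scale were not a design goal.
* `make_study()` draws each sample's template as the species reference
  itself; within-species polymorphism is not modelled, which is why
  100% assignment of undegraded samples is the expected (and tested)
  outcome rather than an empirical claim about field samples.
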