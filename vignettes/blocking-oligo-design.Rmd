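---
title: "Designing and evaluating blocking oligonucleotides for globin depletion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating blocking oligonucleotides for globin depletion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligolock)
```

## The problem

Whole-blood RNA-seq libraries primed with oligo-dT are dominated by globin
mRNA: erythrocytes outnumber leukocytes by roughly three orders of
magnitude, and in untreated libraries half or more of all reads can map to
the two globin transcripts (alpha and beta). A blocking oligonucleotide
("blocker") suppresses this at the priming step: it hybridizes to the
globin transcript's 3'-terminal coding sequence plus the first bases of the
poly-A tail, so that the anchored oligo-dT primer (T30-VN, whose degenerate
anchor fixes priming at the poly-A junction) finds its single binding site
occupied. The blocker's own 3' end is chemically blocked so it cannot prime
synthesis itself.

`oligolock` designs such blockers from target sequence, reasons about
whether the target's 3' end is structurally accessible, screens candidates
for off-target and spike-in binding, and computes the depletion statistics
used to judge the outcome from RNA-seq count tables and qPCR Ct tables. A
seeded synthetic-data layer generates every input the workflow needs, so
the full pipeline runs and is tested without any external data.

## Blocker architecture

A **linear** blocker is, 5' to 3': a poly-T tail (default 15 nt, pairing
with the target's poly-A), a specific arm complementary to the target's
3'-terminal sequence, and a 3' extension block (default recorded as
phosphate). The arm must sit flush with the poly-A junction — an arm ending
even a few nucleotides upstream leaves the anchored primer's site exposed —
and the tail must be at least 4 nt: shorter tails do not form a stable
masking complex before primer hybridization. Both rules are enforced by
`validate_design()`.

A **circular** blocker adds a second arm against the transcript's 5' end,
joined to the first by a nonspecific linker, exploiting the closed-loop
geometry of mRNA in which the 5' and 3' ends are spatially close. The two
arms are grown to similar melting temperatures. The 5'-to-3' segment order
used here — tail, 3' arm, linker, 5' arm, block — is a convention this
package fixes and documents (antiparallel pairing places the tail against
the poly-A and lets the oligo's 3' region reach the mRNA 5' end across the
loop); the underlying geometry does not dictate a unique layout.

Arms grow inward from the transcript termini one nucleotide at a time. The
3' arm is the shortest suffix whose duplex Tm reaches the design target
(default 70 °C), capped at 30 nt; hitting the cap emits the design with a
warning rather than failing, since an under-temperature arm may still be
usable. The 5' arm of a circular design is the shortest prefix whose Tm
falls within a tolerance band (default 2.5 °C) of the 3' arm's Tm — "similar
Tm" needs a quantitative band to be deterministic, and 2.5 °C is about one
GC step at these lengths. Minimal arms are preferred throughout because
every extra nucleotide adds off-target surface.

Backbone chemistries that raise duplex stability (LNA, ZNA) are carried as
annotations only; no predictive model for modified duplexes is in scope.

## Thermodynamic model

Duplex stability uses unified nearest-neighbor DNA/DNA parameters (ΔH°, ΔS°
per stacked dinucleotide plus terminal initiation and self-complementarity
terms), shipped as a plain-text table in `inst/extdata/nn_unified.tsv` so
that tests can sum the same source independently. The melting temperature
is the two-state bimolecular form under the excess-probe assumption,

$$T_m = \frac{1000\,\Delta H^\circ}{\Delta S^\circ_{salt} + R \ln C_{probe}} - 273.15,$$

with an entropic monovalent-salt correction
$\Delta S^\circ_{salt} = \Delta S^\circ + 0.368\,(n-1)\ln[\mathrm{mono}]$.
Defaults are 150 mM monovalent cation (potassium treated as sodium
equivalent; the blocking buffer used for RNA-seq) and 5 µM blocker, the
concentration at which masking saturates — the blocker is in vast molar
excess over its target, hence the excess-probe convention.

Two approximations are deliberate. First, the blocker:mRNA duplex is scored
with DNA:DNA parameters; DNA:RNA tables could be slotted in behind the same
interface, but rank order of candidate arms is what design needs, and the
70 °C target is itself a convention without a stated salt/concentration
context — both the target and the buffer are exposed as parameters rather
than hard-coded. Second, crowding agents present in real blocking buffers
(PEG, betaine) are not modeled; there are no usable parameters for them at
this level of description. Mismatched and dangling-end thermodynamics are
unsupported; `duplex_thermo()` insists on a perfect duplex.

## 3'-end accessibility

Whether a blocker can engage its target depends on the target's own 3'-end
structure: a transcript whose terminal ~26–28 nt are free of intramolecular
pairing (the beta-globin situation) is easy to mask, while a tight
self-binding 3' end (the alpha-globin situation) competes with the blocker.
`assess_accessibility()` extracts the 3'-terminal window (default 60 nt),
appends five A nucleotides to mimic the beginning of the poly-A strand,
folds the window, and calls the end accessible when at least 75% of the
terminal 28 native positions are unpaired. The 28 nt summary width matches
both the empirically free beta 3' region (26–28 nt) and typical 3'-arm
lengths; the window default of 60 nt keeps the fold local to the region a
blocker sees (full-transcript folding is available by passing a larger
window but is not the default, since the blocker competes only with local
structure at the hybridization step).

Folding is Nussinov-style maximum base pairing over Watson–Crick plus G:T
wobble pairs with a minimum hairpin loop of 3 nt — not free-energy
minimization. The choice is deliberate: structure is used qualitatively
(accessible vs self-binding), and a maximum-pairing model is exhaustively
verifiable — the test suite checks the dynamic program against a brute-force
enumeration of all non-crossing, loop-legal pairings. An energy-model
backend could replace it behind the same interface. Among co-optimal
structures the traceback deterministically prefers the one leaving the
longest unpaired 3' suffix: accessibility is the decision variable, so the
profile reports the most blocker-favorable co-optimal case. Pseudoknots and
base-pair probabilities are out of scope, and the closed-loop (5'–3'
proximity) biology is treated as motivation for the circular architecture,
not modeled.

## Specificity screening

`screen_offtargets()` is an exact-seed, ungapped-extension search: the
12-mer at an arm's 3'-proximal end (where extension blocking matters most)
is looked up exactly across the transcriptome, each occurrence is extended
over the full arm footprint counting mismatches, and hits are kept when the
perfect-match portion's Tm is within 15 °C of the on-target arm Tm. Poly-T
tails are never seeded — tail:poly-A binding is the intended mechanism, not
an off-target — and only the sense strand is searched, because the targets
are single-stranded mRNAs. The single-seed design has a documented blind
spot: a site mutated inside the seed region escapes detection. The screen
is used both for candidate QC and to certify spike-in sets
(`check_spikein_compatibility()`): a usable spike-in set must offer the
blockers no binding sites at all, so that spike-in recovery measures
specificity rather than blocker activity.

## Depletion statistics

"Normalized read count" is implemented as the fraction of a sample's total
counts. This is the simplest normalization that reproduces every prevalence
statement the evaluation needs (class prevalences are additive over the
disjoint class partition, and the control:treated prevalence ratio is the
reduction fold change); UMI-based pipelines are out of scope. Per-gene
fractions carry Wilson score 95% intervals — chosen over the Wald interval
because it behaves sensibly at zero counts. Detection in a condition means
at least one pooled read by default, consistent with the observation that
genes unique to one condition sit at vanishing normalized counts. Complete
depletion (zero treated counts) yields an infinite fold change, reported
with a flag rather than raised as an error.

For qPCR, the relative design quantifies the reduction as
`efficiency^(ΔCt)` between condition means of the undiluted replicates
(replicates are aggregated by arithmetic mean of Ct, the simplest
defensible choice, exposed as data rather than config). The amplification
efficiency comes from the dilution series: the least-squares slope of Ct
against log10 template amount gives `efficiency = 10^(-1/slope)`, so a
perfect doubling series has slope −3.32. Crucially, a dilution-limited
design has a bounded quantification range: with 10× dilutions, folds up to
10 are measured accurately and anything larger is reported but flagged out
of range. `qpcr_fold_change()` applies that cap against the largest
dilution factor present.

## What the synthetic data emulate — and what they do not

The generators (`make_globin_like()`, `make_spikein_set()`,
`simulate_counts()`, `simulate_ct()`) are first-class, seeded, and
bit-reproducible; each draws from a named stream derived from the user seed
so generators never share draws.

* `make_globin_like()` reproduces exactly one property of the real
  transcripts: the structural dichotomy of the 3' end. Beta-like ends draw
  their last 60 nt from an A/C alphabet, which admits no pairs at all
  (including against the appended poly-A mimic); alpha-like ends carry an
  engineered terminal stem (10 G:C pairs closing at the 3' terminus) whose
  pairing is forced — the upstream window contains no other pairing
  partners for the stem. These are synthetic sequences, not globin
  homologs: composition, codon structure and real structural ensembles are
  not emulated. Passing structure tests on them shows the folding and
  accessibility machinery is correct, not that real alpha-globin folds this
  way.
* `make_spikein_set()` produces 92 poly-adenylated species on a 23-level ×
  4-species geometric concentration ladder with a 1.25× step, rejection
  sampled to share no 12-mer with any blocker arm site. The step size is a
  calibration: it keeps the lowest rung well above the detection limit at
  the simulated depth of 10^6 reads, so the between-condition spike-in
  correlation is a pure sampling-noise readout (≥ 0.99) rather than a
  dropout readout. The true composition of commercial mixes is proprietary
  and wider-ranged; this ladder is explicitly artificial.
* `simulate_counts()` draws one multinomial per sample. Controls put 63.6%
  of expected mass on globin (21.4% alpha / 42.2% beta — the measured
  prevalences), 5% on spike-ins, and the rest on a fixed log-normal gene
  profile. Treatment multiplies globin mass by `1 − 0.9686` and
  renormalizes: 0.9686 is the per-molecule removal fraction that maps a
  63.6% control prevalence to a 5.2% treated prevalence, the measured
  outcome. Multinomial sampling captures only counting noise — no
  overdispersion, batch effects, library-size variation, or
  treatment-induced bias on non-globin genes. Recovery tests on these data
  validate the estimators, not the biology.
* `simulate_ct()` generates Ct tables in which the treated−control shift is
  exactly `log_efficiency(fold)` plus optional Gaussian noise; noiseless
  tables invert exactly through the qPCR estimators, which is the point —
  they test the arithmetic, not instrument behavior.

Problem sizes used by the test suite — 60 nt folding windows, oracle
equivalence at n ≤ 12, 100 simulation replicates at depth 10^6, 50-target
design-oracle sweeps — were chosen as the smallest scales at which each
property is meaningfully exercised.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open on the stored transcript; RNA input is
  normalized U→T at the boundary so all internal logic is DNA-alphabet.
* Poly-A tails already present in input FASTA are not trimmed, and the A5
  appendage is always added before folding; the FASTA 3' terminus is
  treated as the cleavage site.
* Duplexes shorter than 2 stacked pairs have no defined Tm; `tail_stability()`
  returns a "no duplex" sentinel for tails of 0–1 nt instead of an error.
* Arm growth starts at 2 nt (the shortest duplex with a stack) and
  tie-breaks toward shorter arms.
* Linkers are generated from low-complexity two-base repeat units and
  rejected if their binding site shares a 12-mer with the target; lengths
  55 (alpha) and 44 (beta) ship as presets because linker length is a
  recorded experimental choice, not a derived quantity.
* `fold_window()` on an empty sequence, duplicate FASTA ids, non-IUPAC
  characters, zero-total-count samples, and dilution series without two
  distinct dilutions are all hard errors with named offenders.

## Known limitations

The Tm model ranks candidates; its absolute temperatures inherit the
DNA:DNA approximation and ignore crowding agents, so the 70 °C target
should be read as a scale convention, not a prediction of bath behavior.
Maximum base pairing overestimates pairing relative to energy models and
has no notion of ensemble occupancy. The off-target screen is blind to
sites mutated within the seed and to gapped alignments. Realized depletion
efficiency of a design is a wet-lab measurement and is deliberately not
predicted from sequence. Species-specific 3'-end variation (terminal motif
insertions or deletions seen when re-sequencing globin ends in some model
organisms) can silently abolish masking; `design_for_variants()` flags
affected variants but designing degenerate multi-oligo sets is out of
scope.
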