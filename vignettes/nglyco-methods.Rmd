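---
title: "Models and methods behind nglyco"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nglyco}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nglyco)
```

# The experimental model

nglyco analyzes the output of glycopeptide-capture N-glycoproteomics. The wet
side — periodate oxidation, hydrazide coupling, tryptic digestion, PNGase F
release, LC-MS/MS, and the database search — is out of scope; the package
consumes the searched PSM table and the protein FASTA. Two facts of the
chemistry drive everything downstream:

1. N-linked glycans occur only at sequon asparagines, the consensus
   **N‑X‑S/T with X ≠ proline**. The scanner applies exactly this rule:
   overlapping sequons are independent sites, the S/T position is accepted
   even when followed by proline (stricter variants of the rule are not
   assumed), and an unknown residue `X` can never occupy the N or S/T slots
   (at the middle slot it is accepted, since only proline is excluded — an
   unknown is rarely proline and the alternative silently discards real
   sites).
2. PNGase F converts the occupied asparagine to aspartate, so occupancy
   evidence is a `D` in the peptide aligned to an `N` in the protein.
   Matching tolerates this substitution *only at sequon asparagines*;
   a `D` over any other `N` disqualifies the match.

# Site calling and the ambiguity rule

When a matched peptide span covers two or more sequons, a low-resolution
instrument cannot tell which asparagine carried the glycan (the 0.98 Da shift
does not localize it). The package emits **all** candidate sequons in the
span, flagged ambiguous, and credits each site 1/k by default. The crediting
rule is a deliberate design choice: the source analysis acknowledges the
ambiguity (about 5.6% of identified peptides) without stating a resolution,
and fractional crediting is the only option that conserves counts — an
ambiguous peptide always contributes exactly one glycan to the protein's
stoichiometry. `credit = "first"` and `credit = "all"` are provided for
sensitivity analysis. Whether the ambiguity denominator should be peptides or
PSMs is equally unstated, so `ambiguity_rate()` exposes both.

Identification filters mirror the published workflow: PSMs below probability
0.9 are dropped (implemented as *keep p ≥ threshold*; the text's "greater
than 0.9" differs only at the exact boundary value, on which no reported
number depends); proteins identified by an identical peptide set are merged
into a degenerate group represented by the first accession in input order;
and protein groups with a total spectral count of 1 ("single hits") are
removed. "Single hit" is read in spectral-count terms — one spectrum in
total — consistent with the framework's quantity unit; peptides shared
between non-identical groups are credited to every group and flagged.

# Quantification

Protein quantity is stoichiometry-normalized spectral counting:

$$\mathrm{protein\ spectra} = \frac{\sum \mathrm{peptide\ spectra}}{N},$$

with *N* the number of distinct detected glycosites. Fractional values are
preserved (no rounding before tiering). The tiers — low < 5, medium 5–12
inclusive, high > 12 — take both boundaries into the middle bin, the only
reading under which the three bins are exhaustive. `calibrate_copies()` is a
straight line through the origin anchored on one reference protein (the Lifr
anchor, 4.4 spectra ≈ 100 copies/cell, puts a single-spectrum identification
at ≈ 23 copies). Multi-run inputs are summed before normalization, matching
the "sum over all MS results" definition; per-run averaging would explain
some published fractional values but is not the stated procedure.

# Occupancy statistics

Per-protein occupancy is detected/putative sequons; a set's **glycosylation
rate is the unweighted mean of per-protein occupancies**, not a pooled ratio
of sites. The choice is validated by reproduction: the nine glycosyl
transferases of the bundled reference table give 28.1% under the unweighted
mean, exactly the published figure. The same oracle puts the fourteen
hydrolases at 58.1% while the narrative prints "~58.7%"; the table-derived
value is the one the tests assert, and the discrepancy is documented rather
than reconciled. Two further published numbers are knowingly not asserted:
the transferase mean sequon count (printed 3.8; the table gives 38/9 ≈ 4.2)
and the "2.1 glycans per protein" average (1182/468 ≈ 2.5 under the stated
ratio definition).

# The transmembrane surrogate

TM counts enter the complementarity analyses either as precomputed
annotations (two-column TSV or TMHMM short format, `PredHel=` field) or from
`predict_tm()`, a Kyte–Doolittle sliding-window scan: window 19 residues (a
typical membrane-spanning helix), threshold 1.6 mean hydropathy (a
conventional strong-signal cutoff for 19-residue windows), segments closer
than 5 residues merged. It is deterministic and position-covariant, and it
reliably finds planted hydrophobic stretches, but it is *not* an HMM
reimplementation: on real sequences it will disagree with TMHMM near
boundaries and on marginal helices, which is why every TM-dependent statistic
accepts supplied counts. The low/high TM split in `stoichiometry_groups()`
defaults to ≤ 2 vs ≥ 3 (the operative textual definition; the alternative
"more than 3" reading is reachable through the `tm_high` knob).

# What the synthetic generator emulates — and what it does not

`generate_proteome()` draws i.i.d. background residues (uniform over the 20
standard amino acids by default, overridable), plants class-specific numbers
of hydrophobic helices (receptors mostly 0–2, transporters ~7, mirroring the
published class contrast), and plants sequons at 0.016 per residue — about
7.5 sequons on a typical 470-residue protein, matching the identified
glycoproteome's 3553 sequons over 468 proteins. Sequons are kept 12 residues
clear of helices, honoring the observed minimum spacing required for the
oligosaccharyltransferase to reach a site. Class mix defaults to the
published 42/17/15/26 receptor/transporter/enzyme/miscellaneous split.
Planted helices are spaced ≥ 25 residues apart so the 19-residue window
cannot bridge them.

`simulate_psms()` layers on: log-normal abundance (copies/cell), per-sequon
Bernoulli occupancy with a global or per-class rate, peptide-level Bernoulli
detection attenuated per missed cleavage, and Poisson spectral counts with
mean proportional to abundance (a peptide with a zero draw is unobserved,
which keeps *expected* total spectra exactly linear in abundance while making
the *effective* detection probability abundance-dependent, as in real
DDA data). Deamidation is written only at truth-occupied sequons, so any
leakage is a pipeline bug by construction.

Features of real data deliberately not emulated: residue composition biases,
glycosylation-efficiency differences between NXT and NXS, biased peptide
detectability (length/charge/hydrophobicity), chimeric spectra, and decoy
false positives. A green synthetic test therefore establishes that the
*arithmetic* of the pipeline is right under the stated statistical model, not
that the model captures every property of an LTQ run.

Two estimation subtleties surfaced in testing and are worth recording.
First, occupancy recovery is conditioned on proteins whose sequons are all
*coverable* — reachable by a fully tryptic peptide of detectable length
(5–60 residues, ≤ 2 missed cleavages). Coverability is a property of the
sequence and digestion parameters, not of the hidden occupancy, so the
conditioning introduces no circularity; without it, digestion losses would
read as occupancy losses. Second, restricting the rate estimate to *observed*
glycoproteins (≥ 1 detected site) inflates it — E[X/n | X ≥ 1] > rate,
substantially so for proteins with few sequons — so recovery tests include
zero-detection proteins in the denominator.

The complementarity cohort (`generate_complementarity_cohort()`) draws TM
counts uniformly on 0–8 and plants sequon counts as `base + slope · TM` plus
Gaussian noise, floored at one; incidental background sequons are mutated
away (a glutamine substitution, which can neither seed nor complete a
sequon) so planted counts are exact. With slope −1 the high-TM percentage
across stoichiometry groups is expected to be monotone *non-increasing* —
adjacent low-stoichiometry groups tie at 100% before the decline — which is
how the recovery test phrases monotonicity.

# Numerical and degenerate-input choices

- Coordinates are 1-based and inclusive everywhere, stated in every output
  header.
- Site credit per protein site is capped at 1 before stoichiometry is summed,
  so repeated observation never counts a site twice.
- `protein_spectra` excludes zero-stoichiometry proteins with a warning
  rather than dividing by zero; `occupancy()` rejects detected > sequons as
  an impossible state rather than clamping.
- Sequences shorter than one hydropathy window predict zero helices;
  sequences shorter than three residues contain no sequons; empty sequences
  are errors, not empty results.
- Output writers emit no timestamps, so a fixed config and seed reproduce
  byte-identical files.
- All generators use R's seeded RNG exclusively; nothing is time- or
  platform-seeded.

# Known limitations

- The hydropathy TM surrogate under-counts helices split by short loops and
  can merge closely spaced ones; use supplied TMHMM counts for biological
  conclusions.
- Fractional ambiguity crediting can place fractional credit on a
  never-occupied candidate site of an ambiguous peptide; site-level
  *identities* should be read from the deamidation evidence
  (`deamidated == TRUE`), while stoichiometry totals are conserved by
  design.
- Study-scale checks (43% mono-glycosylated, 44.4% cohort occupancy, 37.7%
  receptor rate) need the study's supplementary tables, which exist only as
  binary spreadsheets; the corresponding acceptance test fails by design
  until a TSV export is supplied (see `inst/extdata/supplementary/README`).
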