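---
title: "Blocking-peptide panels, descriptors and inhibition statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blocking-peptide panels, descriptors and inhibition statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piakit)
```

## The assay this package accompanies

A peptide inhibitor assay (PIA) screens a protein for functionally
important, peptide-accessible sites by incubating the enzyme with a large
molar excess (typically 500x) of short synthetic peptides drawn from the
protein's own sequence ("blocking peptides", BPs) and measuring the loss of
enzymatic activity.  For the model system supported here — the restriction
endonuclease EcoRI digesting a plasmid substrate — activity is read out as
the fluorescence of the excised product band on a gel, normalized to a
no-peptide control run in the same batch.  A peptide that lowers the
relative fluorescence is a candidate inhibitor; the most effective peptides
(relative intensity below 0.3) mark putative functional or structurally
important accessible sites.

The package covers the four computational legs of that workflow: panel
design, physicochemical description, readout simulation, and inhibition
statistics.

## Panel design

All coordinates are 1-based and inclusive on the translated chain
*including* the initiator methionine: the EcoRI chain is numbered M1-K277
even though M1 is removed after translation, so the first window peptide
starts at position 2.  The chain itself is not printed machine-readably in
the source tables; `ecori_chain()` returns the reconstruction obtained by
stitching the 25 overlapping original window peptides (`stitch_chain()`),
which is unique and conflict-free.  The FASTA fixture is labelled
"reconstructed" for that reason.

Four peptide families tile the chain:

* **original** — one peptide per secondary-structure window (given
  externally; the package takes the windows as input).
* **staggered** — for consecutive windows ending at $e_i$ and starting at
  $s_{i+1}$, a peptide of length $L$ centred on the junction midpoint
  $c = (e_i + s_{i+1})/2$.  For odd $L$ the window is
  $[c - (L-1)/2,\, c + (L-1)/2]$; for even $L$ and half-integer $c$ it is
  the symmetric integer window; for even $L$ at an integer $c$ no symmetric
  window exists and the tie-break shifts one residue toward the C-terminus.
  The single published row exercising the tie-break matches this choice.
* **short N/M/C** — the N-terminal, middle and C-terminal $k$-mers
  (default $k = 6$) of a parent, the middle window starting at offset
  $\lfloor (L-k)/2 \rfloor$.  Four published rows deviate from this rule
  (BP12N, BP12M, BP22M, BP22C); they are reproduced through an explicit
  override fixture and reported with a message, never silently.
* **deletion pairs** — a parent split into two windows of `sub_len`
  residues overlapping by `overlap`.
* **randomized** — seeded Fisher-Yates shuffles preserving the residue
  multiset (`randomize_peptides()`).  The six published randomized
  sequences were drawn by hand and are therefore shipped verbatim as
  fixtures; derangement is not enforced.

Where a printed interval's width disagrees with its printed sequence
length, the sequence is authoritative: `stitch_chain()` places such
peptides at the unique position consistent with the assembled residues and
warns with the recomputed interval.  One staggered row (BP22.5) was
evidently designed from a typo'd printed coordinate; it is carried as the
single staggered override.  `build_paper_panel()` reassembles the full
85-peptide published panel (25 + 22 + 2 + 30 + 6) from these rules and
fails loudly if any sequence disagrees with the packaged golden table.

## Physicochemical descriptors

Nine per-peptide descriptors, matching the conventions of the calculators
the published tables were generated with:

* **Molecular weight** — sum of Expasy *average* residue masses plus one
  water (average, not monoisotopic, masses are required to match the tables
  at two decimals).
* **GRAVY** — mean Kyte-Doolittle hydropathy.
* **Isoelectric point** — zero of the Henderson-Hasselbalch net charge
  under the Bjellqvist pKa set with *residue-specific N-terminal amine*
  pKas (A 7.59, M 7.00, S 6.93, P 8.36, T 6.82, V 7.44, E 7.70, otherwise
  7.50).  The solver reproduces the ProtParam-style iteration exactly:
  bisection on [0, 14] starting from pH 7, terminating when both sides of
  the bracket are within $10^{-4}$, reporting the final bracket point.
  This detail matters: a converge-to-root bisection differs in the second
  decimal for a couple of peptides whose root sits within $10^{-3}$ of a
  rounding boundary.  Because the N-terminal pKa is residue-specific, pI is
  **not** a pure composition function — a shuffle that moves a different
  residue to position 1 can shift the pI by several hundredths, which is
  exactly what the published randomized-peptide rows show (6.73 and 6.80
  against the parent's 6.86).  All other descriptors except the instability
  index are composition-only.
* **Aliphatic index** — $X_A + 2.9\,X_V + 3.9\,(X_I + X_L)$ on mole
  percentages.
* **Instability index** — $(10/L)\sum_{i} \mathrm{DIWV}(s_i, s_{i+1})$ over
  adjacent pairs, using the Guruprasad dipeptide weights.  The packaged
  table sets the K→Q cell to 24.68; a widely redistributed copy of the
  table carries 24.64 there, which disagrees with ProtParam's output on
  KQ-containing peptides by a detectable 0.03.
* **Aromatic count** — residues in {F, H, W, Y}.
* **Hydrophilic percentage** — share of residues in {D, E, K, R, N, Q, S},
  the set that reproduces the Bachem-calculator column across all 85
  published rows.
* **Net charge at pH 7** — by default the Bachem-style increment model
  (+1 K/R and N-terminus, −1 D/E and C-terminus, +0.09 H, −0.05 C), an
  empirical reconstruction fitted to the published column; a fully
  pKa-based alternative is available via `charge_model = "pka"`.

Reported values are rounded half away from zero exactly as the tables
round (`round_half_up()`): MW/pI/AI/II/charge to 2 decimals, GRAVY to 3,
hydrophilic percentage to integers; full precision is kept internally and
available with `describe_panel(raw = TRUE)`.

A small whitelist of golden cells is excluded from reproduction tests, all
provably inconsistent within the source tables themselves: a four-row block
whose MW/pI/GRAVY values are cyclically shifted between adjacent rows, one
pI cell off by 0.04 from the value its own sequence yields, and five
manually counted aromatic cells that contradict the {F, H, W, Y} definition
(for example a printed count of 1 for a sequence containing both Y and F).

## Readout simulation

The synthetic generator emulates the quantitative behaviour reported for
the assay, not its mechanism.  The noise-free curve is a single-exponential
approach to saturation

$$F(t) = F_{\max}\, \pi\, (1 - e^{-k_{\mathrm{eff}} t}),
\qquad k_{\mathrm{eff}} = \frac{k_0}{1 + d/d_{50}},$$

which encodes the three observed facts: peptides delay the catalytic rate,
leave the saturation level unchanged ($\pi = 1$ by default), and act
concentration-dependently across the x5-x500 dose ladder.  $d_{50}$ is the
dose (in molar equivalents) halving the rate constant; $\pi = 0$ flags a
peptide with no measurable product band at all (the nuclease-induction
phenotype is not modelled beyond this flag).  Defaults: $F_{\max} = 100$
AU (arbitrary), $k_0 = 1\,\mathrm{h}^{-1}$ so the control is $\ge 95\%$
saturated at the 3 h reference time, hourly sampling over 0-5 h, three
replicates, single-dose runs at 500 molar equivalents.  Noise is
multiplicative Gaussian with a coefficient of variation of 0.05 by default
(band densitometry noise scales with signal), clamped at zero.  Every run
is reproducible from the config seed.

What the generator does **not** emulate: enzyme kinetics with explicit
Mg²⁺ dependence, gel imaging artefacts, batch-to-batch drift, or any
peptide-specific mechanism.  Passing tests on simulated data therefore
demonstrate the correctness of the statistical pipeline, not the biology of
any particular peptide.

## Inhibition statistics

* `relative_intensity()` divides each replicate at the reference time by
  the mean control fluorescence of its batch (normalization is
  within-batch because a control is run in every assay); per-replicate
  normalization, then mean/sd, is the implemented convention.
* `dunnett_test()` performs the many-to-one comparison of every peptide
  against the shared control: pooled error variance over all groups,
  adjusted p from the null distribution of the maximum absolute statistic
  (which carries the shared-control correlation), evaluated by seeded
  Monte Carlo with $10^5$ draws by default.  The published analysis used a
  "repeated measure mode" under a no-interaction assumption; the standard
  independent-groups form is implemented instead, and that deviation is
  deliberate.  The Monte Carlo route was chosen over multivariate-t
  quadrature because its correctness is directly checkable: with one group
  it collapses to the two-sample t-test, and its family-wise error rate
  calibrates to $\alpha$ in simulation.  A cross-check against the
  multivariate-t implementation in `multcomp` runs in the test suite.
* `t_test_summary()` is the unpaired two-sided pooled-variance t-test from
  summary statistics.
* `rank_and_classify()` sorts ascending by relative intensity (rank 1 =
  most inhibitory) with lexicographic id tie-break and flags peptides
  strictly below the 0.3 threshold.
* `correlate_descriptors()` reports Pearson r and its t-transform p for
  each descriptor against relative intensity, after removing peptides on
  an exclusion list; no multiple-testing correction is applied across the
  nine factors, matching the published analysis.

## Problem sizes and numerical tolerances

The test suite exercises the full 85-peptide panel for golden-table
reproduction (seconds); the statistical calibration uses $10^5$ Monte
Carlo null draws and $10^4$ simulated five-group null experiments
(family-wise error rate within $0.05 \pm 0.01$), and noise-free pipeline
recovery is asserted to $10^{-12}$.  The pI bisection terminates at a
bracket width of $10^{-4}$; descriptor comparisons against printed values
are exact at the printed rounding.

## Limitations

* The chain numbering convention and override fixtures are specific to
  published-panel reconstruction; designing panels for a new protein needs
  only a FASTA and a window list.
* The net-charge increment model is an empirical reconstruction of an
  online calculator whose pKa basis is unpublished.
* The simulator's exponential kinetics are the simplest form compatible
  with the reported qualitative behaviour; it is a test harness for the
  statistics, not a mechanistic enzymology model.
* Raw fluorescence values from the published figures are not reproducible
  (they exist only as plots), so statistical acceptance is property-based
  rather than value-based.
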