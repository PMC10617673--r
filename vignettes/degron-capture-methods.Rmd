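---
title: "Detecting beta-strand degrons in Catch-domain complexes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting beta-strand degrons in Catch-domain complexes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betacatch)
```

## The problem

Midnolin routes certain substrates to the proteasome without ubiquitination.
Its Catch domain presents an open edge of a beta sheet: two anchor strands
between which a short, intrinsically flexible region of the substrate can
fold as an extra beta strand, completing a five-stranded antiparallel sheet.
`betacatch` implements the computational side of characterizing this
mechanism at scale:

1. a **screen module** that turns six-bin GPS (global protein stability)
   reporter read counts into a protein stability index (PSI) per gene and a
   treatment-minus-control difference (delta PSI), with the strict
   delta PSI < -0.5 filter that defines a destabilized substrate set;
2. a **capture-detection module** that, given a predicted receptor-substrate
   complex structure, decides whether a substrate segment sits between the
   two Catch anchor strands in beta conformation, and which residues it
   comprises;
3. an **annotation module** that classifies captured-strand side chains as
   facing toward or away from the receptor and computes cohort statistics:
   positional amino-acid enrichment, hydrophobicity contrast, and a pLDDT
   disorder contrast;
4. a **synthetic-data module** that generates the idealized structures and
   simulated screens all of this is tested on.

## The capture-detection procedure

For one two-chain model the steps are, in order:

1. **Distance seeds.** A Calpha-Calpha distance matrix between substrate
   and receptor is scanned for substrate residues whose minimum distance to
   *both* anchor ranges (receptor author numbers 148-157 and 279-286, in
   the numbering of the folded receptor sequence) is below 5.5 Angstroms -
   beta sheets typically run below 5 Angstroms between strands, and the
   extra half Angstrom absorbs model noise. Qualifying residues must form
   consecutive runs of at least `min_run = 2` ("sequential" residues imply
   at least two). An explicit monotonicity check on the receptor-side
   residue index is not enforced: the anchor ranges are only 8-10 residues
   long, and geometry makes non-sequential matches implausible; both knobs
   are exposed in `capture_params()`.
2. **Secondary structure.** Extended-strand ("E") state is assigned by an
   internal Kabsch-Sander implementation (below), jointly over both chains
   so that substrate-receptor hydrogen bonds count. Seeds not coded E are
   dropped; the survivors are expanded by `pad = 7` positions in sequence
   space in each direction and intersected with E again; finally the
   longest contiguous E stretch is kept, ties resolving to the most
   N-terminal stretch (a deterministic convention).
3. **Aggregation.** A substrate is called captured when at least one model
   of its ranked set yields a strand; the representative interval is taken
   from the best-ranked qualifying model, rank 0 being the most confident
   prediction. All per-model calls are retained, but cohort statistics use
   one representative strand per substrate to avoid weighting substrates by
   their model count.

## The Kabsch-Sander assignment

Backbone hydrogen bonds are scored with the classic electrostatic form

$$E = 0.084 \cdot 332 \left( \frac{1}{r_{ON}} + \frac{1}{r_{CH}}
  - \frac{1}{r_{OH}} - \frac{1}{r_{CN}} \right)\ \text{kcal/mol},$$

with a bond declared below -0.5 kcal/mol. The amide hydrogen is
reconstructed 1.0 Angstrom from N, anti to the preceding residue's
carbonyl; prolines donate nothing; distances under 0.5 Angstrom clamp the
energy at -9.9 (the conventional minimum). Beta bridges follow the
standard parallel and antiparallel bond patterns, and only *ladders* of at
least two consecutive bridges are coded E - an isolated bridge is left
unassigned, a literal reading of "E coding" that excludes the single-bridge
"B" state. Alpha helices (two consecutive i to i+4 turns) are coded H and
take precedence. The implementation is internal rather than a wrapper
around a `dssp` executable so that behaviour is self-contained and
bit-stable; its contract is fixture-level agreement with direct evaluation
of the energy form, which the test suite enforces, not bitwise identity
with any particular DSSP binary.

Chain termini cannot be assigned (the algorithm needs flanking context), so
they carry "?" until `propagate_terminal_E()` resolves them: a terminal
residue becomes E exactly when its single neighbour is E, otherwise "-".
This keeps genuine strand ends from being clipped at chain boundaries.

## Facing annotation and parity

Side chains along a beta strand alternate sides. A captured-strand residue
is provisionally called receptor-facing when its Cbeta lies strictly closer
than its Calpha to a reference Calpha in the receptor core (isoleucine 309,
a buried Catch-domain position). Glycines make no raw call (no Cbeta), and
strand-end rotamers are unreliable, so raw calls are reconciled: whichever
of the odd-position or even-position sets overlaps the raw calls more
becomes the facing set wholesale. Positions are 1-based within the strand,
N to C. An exact tie (including the all-glycine degenerate case) is an
error asking for a manual parity, not a silent guess.

## Cohort statistics

**Enrichment.** For depth $n$ into the strand from either terminus, amino
acid frequencies are computed over strands of length at least $2n$ (so no
strand contributes the same residue to both termini) and divided by the
background frequency across the full substrate sequences. Flanking
positions are tabulated the same way, skipping strands that sit at the
protein's own terminus. Within every (side, depth) cell the identity
$\sum_{aa} \text{ratio} \times \text{background} = 1$ holds by
construction and is tested.

**Contrasts.** Hydrophobicity (per-residue index at pH 7; the shipped
default is the Monera normalized pH-7 scale, and every consumer accepts an
alternative table since published index values vary) and pLDDT are
compared between the captured region and the rest of the substrate with a
two-sided paired t-test implemented from the closed form (mean and SD of
the differences, $df = n - 1$), so the test itself is oracle-checkable
against `stats::t.test`. A degenerate all-zero difference vector returns
t = 0, p = 1. Lower pLDDT in the captured region (a negative mean
difference) reads as higher predicted disorder in the receptor-free state.

## The PSI screen model

Cells sorted into six stability bins by GFP/DsRed ratio give, per gene,
read counts per bin and condition. Barcodes are summed at the gene level.
Per-bin sequencing depth is corrected before proportions are computed;
then

$$\mathrm{PSI} = \sum_{i=1}^{6} R_i \, i \in [1, 6], \qquad
  \Delta\mathrm{PSI} = \mathrm{PSI}_{\text{treatment}} -
  \mathrm{PSI}_{\text{control}},$$

and genes with delta PSI strictly below -0.5 form the destabilized set.
Genes with zero reads in a condition get a missing PSI and are excluded
from filtering, with a logged count.

**Depth correction.** Plain total-count column scaling is exactly right
only when the bin populations are balanced; when a minority of the library
genuinely shifts bins, column totals absorb that shift and every other
gene inherits a small opposite bias. `depth_normalize()` therefore
defaults to median-of-ratios depth factors (the median, over genes with
complete rows, of the ratio to a geometric-mean reference), which is
driven by the unshifted majority and measured here to keep the estimator
bias under about 0.02 at realistic hit sparsity; `method = "total"`
remains available. With fewer than ten complete rows the median is not
trustworthy and the method falls back to column totals.

## What the synthetic data emulates - and what it does not

`build_capture_complex()` constructs a three-strand antiparallel sheet
from ideal extended dihedrals (phi = -139, psi = +135, omega = 180) and
standard bond geometry, with the substrate strand between anchor strands
author-numbered to the Catch ranges, at a default spacing of 4.8 Angstroms.
Strand registry is fixed by a deterministic grid search (x and z offsets,
two antiparallel orientations) that maximizes the number of hydrogen bonds
the package's own energy function declares, tie-breaking on the worst
Calpha rung distance so every rung stays sheet-like. The peptide unit
entering the strand is given strand geometry, since the strand's first
amide hydrogen is built from it. Flanks use polyproline-II dihedrals: they
continue along the strand axis without either clashing into the anchors or
forming spurious ladders. Cbeta atoms sit at ideal tetrahedral positions,
so facing alternation is geometrically true, and the reference residue is
placed on the Catch-core side of the sheet plane. A ground-truth record
(planted interval, inward positions, bond counts) accompanies every
fixture.

Because ideal strands still twist, the bridge pattern weakens at the ends
of long planted strands (the anchors are 8-10 residues), so detected
intervals can shave one or two edge residues off a planted strand of
length 8 or more while always containing its midpoint; recovery on the
test grid (lengths 4-12, spacings 4.6-5.0 Angstroms) is asserted as
midpoint recall with the detected interval inside the planted one. At
5.4 Angstroms spacing the seeds still fall inside the 5.5 cutoff but the
hydrogen bonds fail the -0.5 kcal/mol criterion, and detection correctly
returns nothing - the energy evaluation itself decides the expected
outcome. What these fixtures do *not* emulate: side-chain rotamers, model
noise, sheet curvature of real Catch domains, or partial-occupancy
captures; passing on them shows the algorithm implements its stated rules,
not that AlphaFold models of real substrates will behave.

`simulate_screen()` draws each gene's control bin distribution from a
Dirichlet around the uniform baseline (gates collect one sixth of the
control population per bin; concentration 50 gives a moderate spread of
basal stabilities), conditioned so the planted shift stays inside the bin
range, then tilts it exponentially along the bin axis so the expected PSI
difference equals the planted delta PSI exactly - an error is raised when
the target is unreachable. Sequencing is simulated per bin library
(multinomial across gene barcodes, deliberately unequal per-bin depths),
which is the coupling that makes depth correction matter. A consequence
worth knowing: a stability shift common to the whole library is invisible
to any within-library normalization - the screen measures *relative*
stability - so planted-effect recovery is always tested with sparse hits,
matching the few-percent hit rate of a real ORFeome screen.

## Problem sizes and numerical choices

The shipped tests run the capture grid at 20 specs (5 lengths x 4
spacings), decoy families of 5-6 seeds, 1000-replicate null calibrations
for the paired t-tests, and screen simulations of 400-2000 genes at depth
100-1000; these sizes give stable assertions at interactive runtimes.
Tolerances: distance matrices match a brute-force double loop to 1e-9;
PDB coordinate round-trips to 1e-3 Angstrom (fixed-width rounding);
proportion sums to 1e-6. Ties are never random: longest-stretch ties go
N-terminal, registry-search ties go to the smaller offset, facing-parity
ties are errors.

## Known limitations

* Receptor numbering is assumed to match the folded reference sequence
  (UniProt Q504T8 for midnolin); models with renumbered receptors need the
  anchor ranges overridden in `capture_params()`.
* Only the first altloc and the requested MODEL block of a PDB file are
  read; mmCIF is out of scope.
* The internal secondary-structure alphabet is E/H/- only; turns, bridges,
  3-10 and pi helices are not distinguished, which is all the detection
  rule needs.
* The 25-model aggregation trusts the upstream ranking; no capture
  confidence score is computed.
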