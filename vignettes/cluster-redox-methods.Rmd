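---
title: "Cluster models and thermodynamic-cycle redox potentials: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster models and thermodynamic-cycle redox potentials: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmredox)
```

## The model and its assumptions

A metalloenzyme's reduction potential is dominated by the immediate
environment of the redox-active metal. The cluster-model approximation
exploits this: a finite fragment — the metal, its first coordination
shell, and hand-picked second-shell residues — is cut out of an
equilibrated protein structure, the severed covalent bonds are healed
with hydrogen link atoms, and the boundary anchor atoms are frozen so
geometry optimisation cannot relax away the scaffold strain the protein
imposes. The fragment is then small enough for DFT with an implicit
(continuum) solvent standing in for the bulk protein/water environment.

The solution-phase reduction free energy is assembled from a Born–Haber
style cycle:

$$\Delta G = \Delta G_g + \Delta\Delta G_{sol}, \qquad
  \Delta G_g = G_g(\mathrm{red}) - G_g(\mathrm{ox}), \qquad
  \Delta\Delta G_{sol} = \Delta G_{sol}(\mathrm{red}) -
                         \Delta G_{sol}(\mathrm{ox})$$

$$\Delta E = -\,\Delta G / nF, \qquad E_{calc} = \Delta E - \Delta E_H$$

This package implements the carving, bookkeeping and arithmetic; it never
runs an electronic-structure program. The underlying assumptions the user
inherits: the hand-picked residue roster captures the electrostatics that
matter; freezing the alpha carbons is a sufficient scaffold constraint;
the continuum solvent absorbs everything outside the cluster; and the
redox event is a pure one-electron transfer (no coupled protonation).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| coordination cutoff | 2.6 | Å | spans typical Cu–N (≈2.0) and Cu–S(thiolate) (≈2.2) bonds while excluding the long axial Cu–S(thioether) contact (≈2.9–3.3) |
| donor elements | N, S, O | — | the protein-derived donor atoms of first shells |
| cap C–H length | 1.09 | Å | standard sp³ C–H bond length for link atoms |
| frozen atoms | `CA` | — | the alpha carbons are the residue anchors; caps are never frozen |
| Faraday factor | 23.060548 | kcal/mol per eV | makes a one-electron kcal/mol free energy divide directly into volts |
| SHE reference | 4.44 | V | IUPAC absolute SHE potential for water; literature range 4.28–4.74 V is exposed via `she_sweep()` |
| n electrons | 1 | — | one-electron couple; `oxidized_charge = reduced_charge + 1` is enforced |

Level-of-theory defaults (`default_levels()`) encode the protocol's three
jobs: B3LYP/6-311G* with D3(BJ) dispersion and SMD water for optimisation
and frequencies, M062X/def2TZVP gas-phase single points, and
M062X/6-311G* solvated single points.

## Carving rules

The truncation is the standard side-chain + C$_\alpha$ scheme. For each
amino-acid residue the backbone is severed at the C$_\alpha$–N and
C$_\alpha$–C(carbonyl) bonds; each severed bond is replaced by one
hydrogen placed along the original bond vector at 1.09 Å (named `HL1` /
`HL2` for the amino/carbonyl side); the backbone atoms beyond the cut (N,
amide hydrogens, C, O, OXT) are removed. The source never states the cut
explicitly — it draws whole truncated residues with starred (frozen)
anchors — so the cut placement and the frozen set were genuinely open
design choices. We chose the field-standard convention because it keeps
the frozen-C$_\alpha$ semantics intact, and exposed `frozen_names` as an
override for protocols that freeze additional boundary atoms.

Charge bookkeeping is by formal fragments: every standard residue is
neutral except a cysteine whose SG falls inside the coordination shell,
which is treated as a metal-bound thiolate — its HG is removed and the
fragment carries −1. Input protonation is otherwise trusted, not
modified: the reader never adds hydrogens, and a His tautomer is accepted
as given (the metal-coordinating ring nitrogen is expected bare). Total
state charges are metal formal charge plus the fragment sum; spin
multiplicities follow the metal d-count (Cu(II) d⁹ → doublet, Cu(I) d¹⁰ →
singlet), with an explicit override required for any other couple rather
than a guess.

## What the synthetic generator emulates — and what it does not

`make_t1_site()` builds a deterministic toy type-1 copper site: two
equatorial histidines (2.05 / 2.10 Å), an equatorial cysteine thiolate
(2.25 Å), a long axial methionine thioether (2.90 Å), and a
non-coordinating residue 502 (Leu, or Lys for the variant mimic) on the
opposite axis — distances chosen at typical T1-site values. Residue
geometry is idealised (fixed bond lengths, tetrahedral angles, pentagonal
imidazole) with full hydrogens, and each residue's spin about its
metal-anchor axis was tuned once so the assembled default site is
clash-free (minimum non-bonded separation 2.4 Å); `jitter = TRUE` adds
small (±π/16) seeded spins for property tests without disturbing anchor
distances.

The generator emulates topology and coordination geometry, not physics:
no rotamer realism, no electronic structure, no thermal ensemble. A green
test therefore establishes that carving, capping, charge/spin assignment,
deck emission and the cycle arithmetic are correct — it says nothing
about whether a DFT energy computed on such a cluster would be accurate.
Mock logs (`make_mock_log()`) likewise exercise the parser's format
contract, not any energy surface.

## Numerical choices

* Energies are carried internally in kcal/mol; Hartree is accepted at
  boundaries with 627.509474 kcal/mol per Hartree, eV at 23.060548 and
  kJ/mol at 4.184. Unit round trips are tested to 1e-9 relative.
* $\Delta G = \Delta G_g + \Delta\Delta G_{sol}$ is exact addition — no
  tolerance is involved anywhere in the cycle arithmetic.
* Reported tables round half-away-from-zero to 2 decimals
  (`round_half_up()`), mirroring how results tables are typeset; full
  precision is always retained in the result object.
* Kabsch superposition uses SVD with the proper-rotation constraint
  (determinant +1), so mirror images are never superposed; correspondence
  is by row order, not nearest-neighbour assignment.
* Alternate locations: the highest-occupancy conformer wins, ties broken
  by altloc letter; duplicate atom names without altloc letters are left
  untouched. Dropped conformers are counted and reported.
* Deck emission is byte-deterministic (`%.6f` coordinates, fixed
  ordering); the freeze flag is the Cartesian-line integer convention
  (−1 frozen, 0 free), which maps one-to-one onto the frozen set.
* When composing energy records from logs (`logs_to_record()`), the
  gas-phase Gibbs free energy is the gas single-point electronic energy
  plus the thermal correction of the frequency job (its G minus its own
  electronic energy), and the solvation free energy is solvated-minus-gas
  single points at the same geometry. The electronic-only composition is
  available (`thermal = FALSE`); the source protocol is silent on this
  composition, so both are supported with the thermally corrected one as
  default. Note the caller must supply a matched-level gas/solvent pair
  for the difference to be meaningful.

## A deliberate red test: the wild-type 2-dp potential

The embedded published energy table stores the per-state rows exactly as
printed. For the wild type those rows give
$\Delta\Delta G_{sol} = -82.05 + 122.04 = 39.99$ kcal/mol, where the
source's own (internally unrounded) value tabulates as 40.00. The
0.01 kcal/mol print-rounding quantum lands exactly on a rounding
boundary: $\Delta G = -92.36$ yields $E_{calc} = -0.4349 \to -0.43$ V,
while the source's $\Delta G = -92.35$ yields $-0.4353 \to -0.44$ V. No
faithful composition of the printed per-state inputs can produce −0.44,
so the acceptance test asserting the tabulated value is intentionally
left failing, with the computed −0.43 asserted (and explained) in the
regular suite. The variant potential (0.56 V), both free-energy
differences, the variant-minus-WT gap, and every other tabulated quantity
reproduce within the stated tolerances.

## Known limitations

* No automatic second-sphere selection: the residue roster is explicit,
  by design (the reference protocols hand-pick those residues).
* Trinuclear (T2/T3) copper clusters, proton-coupled or multi-electron
  cycles, and isodesmic referencing are out of scope.
* mmCIF, symmetry expansion, hydrogen addition and mutant side-chain
  building are out of scope; users supply protonated, equilibrated
  coordinates.
* The PDB writer targets the subset of the format the package produces
  and reads (ATOM/HETATM/TITLE/END); insertion codes and multi-model
  files are not handled.
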