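# qmredox

Cluster-model construction and thermodynamic-cycle reduction potentials
for metalloenzyme active sites, in R.

## The problem

The redox potential of a metalloenzyme — for example the type-1 ("blue")
copper site of a multicopper oxidase, which sets how strongly the enzyme
pulls electrons from its substrates — can be estimated quantum-mechanically
without treating the whole protein. The standard *cluster model* approach
carves a finite fragment around the metal (the metal ion, its ligating
residues, and selected second-shell residues), heals the cut covalent bonds
with hydrogen link atoms, freezes the backbone anchor atoms so the fragment
remembers the protein scaffold, and treats the result with DFT in an
implicit solvent.

The one-electron reduction potential then follows from the thermodynamic
cycle

```
ΔG      = ΔG_g + ΔΔG_sol
ΔG_g    = G_g(red) − G_g(ox)          (gas-phase Gibbs free energies)
ΔΔG_sol = ΔG_sol(red) − ΔG_sol(ox)    (implicit-solvent solvation energies)
ΔE      = −ΔG / nF                    (absolute potential, volts)
E_calc  = ΔE − ΔE_H                   (vs the standard hydrogen electrode)
```

with `F` carried as 23.060548 kcal/mol per eV and `ΔE_H = 4.44 V` (the
IUPAC absolute SHE potential for water; literature assignments span
4.28–4.74 V).

`qmredox` implements everything around the expensive step: it reads PDB
structures, finds the metal and its coordination shell, carves and caps the
cluster, assigns per-redox-state total charge and spin multiplicity
(Cu(II) d⁹ doublet / Cu(I) d¹⁰ singlet; a metal-bound cysteine thiolate
contributes −1), writes Gaussian-style input decks for the three job types
of the protocol (optimization + frequencies, gas-phase single point,
solvated single point), parses engine logs or plain energy tables, and
evaluates the cycle. The DFT itself is out of scope — mock-log and
energy-table fixtures make the full pipeline testable offline.

## Worked example

```r
library(qmredox)

# a synthetic type-1 Cu site: Cu + His/Cys/Leu/His/Met, full hydrogens
s <- make_t1_site()
site <- find_metal_sites(s)[[1]]
coordination_shell(s, site, cutoff = 2.6)
#>   serial name resname chain resseq element distance
#> 1      1  ND1     HIS     A    443       N     2.05
#> 2     48  ND1     HIS     A    505       N     2.10
#> 3     18   SG     CYS     A    500       S     2.25

cl <- carve_cluster(s, site, cueo_t1_preset())
cl
#> <qmx_cluster> 71 atoms (10 caps, 5 frozen), charge ox/red +1/+0, 2S+1 ox/red 2/1
#>     label charge
#>  HIS A443      0
#>  CYS A500     -1
#>  LEU A502      0
#>  HIS A505      0
#>  MET A510      0
```

Ten link atoms heal the ten severed Cα–N / Cα–C(carbonyl) bonds, the five
alpha carbons are frozen, and the metal-bound thiolate makes the oxidized
cluster a charge +1 doublet and the reduced cluster a neutral singlet —
exactly the states a Gaussian deck needs on its charge/multiplicity line
(`1 2` and `0 1`; see `cluster_decks()`).

Running the cycle on the package's embedded published energy table:

```r
recs <- read_energy_table(make_paper_energy_table())
run_cycle(recs[sapply(recs, function(r) r$system == "L502K")])
#> Thermodynamic cycle: L502K (n = 1, SHE = 4.44 V)
#>   dG_gas   =   -118.70 kcal/mol
#>   ddG_solv =      3.41 kcal/mol
#>   dG       =   -115.29 kcal/mol
#>   dE       =      5.00 V
#>   E_calc   =      0.56 V vs SHE
```

The wild-type system evaluates to `E_calc = -0.43` V from the same table
(its tabulated per-state rows carry 0.01 kcal/mol of print rounding that
sits exactly on the 2-dp rounding boundary of the reference value −0.44 V;
see the methods vignette). The gap between the two systems — the variant
site is ~22.9 kcal/mol more downhill to reduce, i.e. ~1 V more oxidizing —
is reproduced robustly.

## Command line

```sh
Rscript -e 'quit(status = qmredox::qmx_cli())' fixtures --output_dir fx
Rscript -e 'quit(status = qmredox::qmx_cli())' carve --structure fx/t1_site_wt.pdb --output_dir out
Rscript -e 'quit(status = qmredox::qmx_cli())' prep  --structure fx/t1_site_wt.pdb --output_dir decks
Rscript -e 'quit(status = qmredox::qmx_cli())' cycle --energy_table fx/energies.csv --output_dir cyc
```

Subcommands: `carve`, `prep`, `cycle`, `distances`, `fixtures`; a JSON
config (`--config run.json`) holds the same keys, with flags overriding
file values. Every output directory gets a `provenance.json`.

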