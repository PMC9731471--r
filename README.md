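# receptorclust

Platelet glycoprotein receptors such as GPVI, CLEC-2 and PEAR1 are monomeric
single-transmembrane receptors that signal only after they are clustered:
multivalent ligands gather receptors on the outside of the membrane, while a
cytosolic tandem-SH2 protein (Syk or PI 3-kinase) can bridge two
phosphorylated receptor tails on the inside. `receptorclust` implements the
three computational layers needed to study this process quantitatively:

1. **Mass-action equilibrium and kinetic models** of monovalent, divalent
   and tetravalent ligands binding a monomeric receptor.  For a monovalent
   ligand in excess the occupancy is `[LR]/Rtot = [L]/(KD + [L])` and the
   time course is `LR(t) = Rtot [L]/(KD+[L]) (1 - e^{-(k1[L] + k-1) t})`.
   Divalent binding is the coupled pair `L2 + R ⇌ L2R`, `L2R + R ⇌ L2RR`
   with `KD3 = KD1·KD2` and an optional cooperativity coefficient
   `α = α+/α-` rescaling the second step; the tetravalent system extends the
   ladder to `L4RRRR`.  Both ligand-excess and ligand-depletion
   (membrane-ligand) modes are available, solved by long-time ODE
   integration (deSolve) with an independent algebraic route used for
   cross-checking.
2. **An exact Gillespie simulator** of the same reaction networks in integer
   copy numbers (direct method: exponential waiting times, propensity-
   weighted reaction choice), with ensemble means and quantile bands.
3. **A lattice agent-based model (ABM)**: receptors, divalent ligands and
   divalent cytosolic crosslinkers on a 21×21 toroidal patch grid (441
   patches).  Receptors carry one dimerisation interface, one extracellular
   epitope-binding site and one cytosolic tail; crosslinkers bind only
   phosphorylated tails and protect them from dephosphorylation.  Cluster
   sizes are read off the receptor bond graph (dimer bonds, shared ligands,
   shared crosslinkers) as a census of complexes of size 1, 2, 3, 4 and >4.

The ABM's hot loop is C++ (Rcpp) driven by R's RNG, so runs are exactly
reproducible from a seed; a 30-replicate × 3000-tick ensemble takes a few
seconds.

## Worked example

```r
library(receptorclust)

## mass action: 95% occupancy needs a 19-fold excess over KD
fold_for_occupancy(0.95)
#> [1] 19

## time to 95% of equilibrium falls with ligand (KD = 1 uM, k1 = 1/uM/s)
r <- rate_constants(k_on = 1e6, k_off = 1)
round(sapply(c(1e-6/3, 1e-6, 3e-6), time_to_equilibrium_fraction,
             rates = r, frac = 0.95), 2)
#> [1] 2.25 1.50 0.75

## the doubly bound divalent species is bell-shaped, peaking at KD1
tab <- concentration_response(binding_scenario(valency = 2, 1e-6), rates = r)
find_curve_peak(tab$ligand_conc, tab$bound2)$ligand_at_max
#> [1] 1e-06

## basal ABM state: ~10% of receptors in dimers, ~10% phosphorylated
cfg <- abm_config(n_crosslinkers = 0, n_ligands = 0)
ens <- run_ensemble(cfg, n_replicates = 30, base_seed = 101)
subset(ens$final, field %in% c("frac_receptors_in_size_2",
                               "frac_phosphorylated"))
#>                       field      mean         sd
#> 10 frac_receptors_in_size_2 0.1006667 0.03841097
#> 14      frac_phosphorylated 0.1010000 0.02656806
```

The first two results are the closed-form mass-action predictions (50%
occupancy at KD; the approach to equilibrium accelerates with ligand).  The
peak location confirms numerically that the doubly bound divalent species is
maximal when the ligand concentration equals `KD1`.  The ensemble summary
shows the calibrated resting state of the lattice model: with no ligand and
no crosslinker, about 10% of receptors sit in dimers and about 10% are
phosphorylated, mimicking a resting platelet.

Scenario configurations for all the simulation experiments (receptor-number
sweeps, crosslinker-count sweeps at moderate/high affinity, phosphorylation
and dimerisation rate sweeps, divalent-ligand sweeps) ship as code:
`figure_scenarios()` returns them, `generate_fixtures(dir)` writes them as
annotated YAML.  A thin command-line front end is installed at
`inst/cli/receptorclust.R` (`ode`, `gillespie`, `abm`, `scenarios`,
`version` subcommands) writing tidy TSVs plus a JSON run manifest.

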