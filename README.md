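# sasamc

Coarse-grained, implicit-water/implicit-salt Monte Carlo simulation of
how salts modulate the association and solubility of small organic
solutes — caffeine by default — together with the analysis layers that
recover the full ternary (water–solute–salt) solution thermodynamics.

## Who this is for

Researchers studying Hofmeister (salting-in / salting-out) effects on
self-associating solutes who want a fast, transparent alternative to
all-atom simulation: the solvent and the salt are implicit, and the salt
enters the Hamiltonian only through a transfer-free-energy (TFE)
coefficient times its concentration.

## The model

A molecule is a rigid set of functional-group beads (for caffeine: two
heterocycle rings, three methyls, two carbonyl oxygens, one –N=CH–).
The potential energy of a configuration is

    U = sum_{pairs ij} [ u_WCA(r_ij; sigma_ij, eps_ij)
                       + (gamma_ij + eps_ij,TFE * c_s) * dA_ij(r_ij) ]
      + N * c_s * sum_i eps_i,TFE * A_i^ref

where `dA_ij(r) <= 0` is the buried lens area of the two probe-inflated
bead spheres (zero beyond contact, from the exact spherical-cap
formula), `gamma` is a calibrated microscopic surface tension carried by
the ring beads, `c_s` the molar salt concentration, and the last term is
the one-body transfer free energy of an isolated molecule (reference
areas `A_i^ref`), which matters in grand-canonical sampling.

Sampling is Metropolis–Hastings in the canonical or grand-canonical
ensemble (single-molecule, guarded cluster, and insertion/deletion
moves), with Widom chemical potentials, virtual-volume pressures and
osmotic coefficients, COM–COM radial distribution functions and
Kirkwood–Buff (KB) integrals as observables.  The analysis layers
implement Gibbs–Duhem-consistent activity models
(`ln gamma_2 = A2 m2 + B2 m2^2 + C1 m3 + C2 m2 m3`, so the salting-out
constant is `k_s(m2) = C1 + C2 m2`), closed-form ternary KB inversion,
preferential-binding coefficients, and a vapor-pressure-osmometry style
pipeline (residual osmolality `dOsm = (C1 + C2 m2) m2 m3`, weighted
fits with 95 % intervals) that treats experimental tables and
simulation output identically.

See the methods vignette (`vignettes/mc-sasa-methods.Rmd`) for the
bead-geometry construction, the calibration of `gamma` (0.0502
kJ/mol/Å² for the bundled geometry; the published 0.0572 belongs to a
different geometry), numerical choices and known limitations.

## Worked example

```r
library(sasamc)

tpl <- build_caffeine_template(gamma = calibrated_defaults$gamma_geometry)
print(tpl)

set.seed(1)
st  <- mc_state(tpl, box_length = 150, n = 40)   # 0.02 M caffeine
run <- run_mc(st, move_params(),
              run_protocol(equilibration = 1e5, production = 1e6,
                           rdf_stride = 20, widom_stride = 20, seed = 1))
print(run)
w <- widom_mu_ex(run)
cat(sprintf("mu_ex = %.2f +/- %.2f kT\n", w$mu_ex, w$se))

tab <- generate_synthetic_osm_table(C1 = 3.84, C2 = -28.59,
                                    sigma = 0.002, seed = 1)
fit <- fit_ks(residual_osmolality(tab))
print(fit)
```

which prints (elided):

```
Rigid CG molecule template: 8 beads
  probe radius  : 1.40 A
  monomer SASA  : 364.4 A^2
  attractive    : RING5, RING6
MC run: 40 -> 40 molecules, U = -130.842 kJ/mol
      move attempts accepts     ratio
 translate   916509  771183 0.8414353
   cluster   183491  178735 0.9740805
mu_ex = -0.20 +/- 0.03 kT
Salting-out constant fit: dOsm = (C1 + C2 m2) m2 m3
  C1 = 3.9302 +/- 0.2775 (95% CI 3.6527 - 4.2077) 1/molal
  C2 = -31.5778 +/- 4.2967 (95% CI -35.8745 - -27.2812) 1/molal^2
```

The template's 364 Å² monomer surface matches the atomistic caffeine
SASA; the negative Widom excess chemical potential at 0.02 M reflects
caffeine's face-to-face self-association; and the osmometry fit
recovers the generating salting-out coefficients (C1 = 3.84,
C2 = −28.59) within its confidence intervals from a noisy synthetic
table.

A thin command-line front end for config-driven runs and osmometry
tables lives at `inst/cli/sasamc.R` (`run`, `vpo` subcommands).

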