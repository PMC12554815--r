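# cloudpolymer

Thermochemical feasibility analysis for carbon-free condensation polymers
in concentrated sulfuric-acid cloud droplets.

## The problem

In the temperate altitude band of Venus-like cloud decks, droplets of
concentrated sulfuric acid offer a liquid medium with extremely low water
activity. Condensation (dehydration) polymerization — chain growth that
releases one water per bond formed — is penalized in water but can become
thermoneutral or favorable in a desiccated droplet. `cloudpolymer` is a
post-processing pipeline for asking, quantitatively, whether a hypothetical
phosphorus-sulfur-oxide heteropolymer could form, persist and be detected
in such an environment, starting from species-level quantum-chemistry
outputs (free energies, enthalpies, harmonic line lists, electronic
excitations).

The core model is the activity-corrected reaction Gibbs energy

ΔG_r = Σᵢ νᵢ (Gᵢ + RT ln(aᵢ / c°ᵢ)),

where each species' correction follows its phase class: solutes relative to
the 1 M standard, gas-referenced species moved from 1 atm onto the solution
standard via c°(gas) = P°/RT = 0.0409 M at 298.15 K, and fixed-activity
solvent components (water at a_w = 5.33×10⁻⁴ contributes RT ln a_w = −4.466
kcal/mol per water produced). On top of this sit:

* **Oligomer energetics** — sequential monomer insertion into cyclic
  oligomers (end-group-free chain proxies), per-repeat-unit free energies,
  ring-strain estimates and strain-minimal proxy selection, plus a fit of
  the insertion asymptote g∞;
* **Stability proxies** — homolytic/heterolytic bond-dissociation
  enthalpies (the enthalpy difference upper-bounds the free-energy
  barrier), ionization potential / electron affinity from charge-state
  energies;
* **Persistence timescales** — Eyring rates k = (k_B T/h)·exp(−ΔH‡/RT)
  and first-order half-lives, computed in log space;
* **Feedstock arithmetic** — single-molecule concentrations, droplet-volume
  trace-gas counts, and scavenged concentrations for μm-scale droplets;
* **Detectability** — Lorentzian-broadened IR spectra, diagnostic-band
  screening against reference absorbers, oscillator-strength-weighted
  UV-Vis convolution and window-fraction analysis;
* **A seeded synthetic generator** with embedded ground truth, so the whole
  pipeline is testable without any calculation outputs.

## Worked example

The package ships a small synthetic species library and reaction set (see
`inst/extdata/`, all files prefixed `synthetic_` — generated stand-ins, not
deposited calculation data) encoding the headline scenario.

```r
library(cloudpolymer)

cond <- venus_conditions()
cond
#> <venus_conditions> T = 298.15 K; c°(gas) = 0.0409 M
#>   activities:  h2o = 0.000533
#>   concentrations (M):  h2so4 = 16.3

lib  <- read_library(system.file("extdata", "synthetic_venus_library.json",
                                 package = "cloudpolymer"))
rxns <- read_reaction_set(system.file("extdata", "synthetic_reaction_set.json",
                                      package = "cloudpolymer"))
head(reaction_table(rxns, lib, cond), 4)
#>                                              label delta_g_raw correction   delta_g
#> 1     r1_ring_closure (2 monomer -> cyc_2 + 2 H2O)    7.531104  -8.931104 -1.400000
#> 2 r1_insertion_n2 (cyc_2 + monomer -> cyc_3 + H2O)    3.265552  -4.465552 -1.200000
#> 3 r1_insertion_n3 (cyc_3 + monomer -> cyc_4 + H2O)    3.365552  -4.465552 -1.100000
#> 4              r2 (H3PO4 + H2SO4 -> monomer + H2O)    3.465552  -6.119275 -2.653723
```

Raw (standard-state) free-energy sums for the insertion steps are uphill by
~3-4 kcal/mol — the familiar penalty of condensation in water — and the low
water activity correction of −4.466 kcal/mol per released water turns every
step mildly exergonic, approaching ≈ −1 kcal/mol at the largest ring.
Persistence of a bond with a 50 kcal/mol dissociation barrier:

```r
half_life(eyring_rate(50))           # ambient
#> <half_life> 1.58e+16 years (4.987e+23 s)
half_life(eyring_rate(50, 573.15))   # 300 °C
#> <half_life> 7.81 days (6.746e+05 s)
```

Feedstock availability for a 1 μm droplet in 150 ppm SO₂:

```r
feedstock_table(droplet_model())
#>     species mixing_ratio molecules_per_droplet_volume delivered_concentration_M
#> so2     so2      0.00015                     15466.01              6.131107e-06
```

A droplet-volume of gas holds ~1.5×10⁴ SO₂ molecules; dissolving that
inventory yields ~6 μM, and one single molecule in the droplet already
represents 0.40 nM (`single_molecule_concentration(droplet_model())`).

`run_pipeline(pipeline_config(...))` runs any subset of the analyses and
writes delimited tables, spectra and a `manifest.json` recording every
tunable used.

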