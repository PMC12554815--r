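---
title: "Methods: thermochemical feasibility of heteropolymers in acidic cloud droplets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermochemical feasibility of heteropolymers in acidic cloud droplets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloudpolymer)
```

# The problem

Could condensation polymers built on a phosphorus-sulfur-oxygen backbone
form and persist in the concentrated sulfuric-acid droplets of a planetary
cloud deck? `cloudpolymer` answers the tractable, quantitative slices of
that question by post-processing species-level quantum-chemistry
thermochemistry: activity-corrected reaction Gibbs energies at extremely low
water activity, cyclic-oligomer insertion energetics and ring strain, bond
dissociation and ionization/electron-attachment energy differences, Eyring
persistence timescales, droplet-scale feedstock arithmetic, and IR/UV-Vis
detectability analysis.

The package consumes *species records* — per-species Gibbs free energies
(the sum of electronic and thermal free energies from a frequency analysis),
enthalpies, harmonic line lists and electronic excitations — and never runs
electronic-structure calculations itself. Records come from a structured
JSON library format or from the bundled synthetic generator.

# Chemical-potential model

Tabulated free energies refer to the computational standard state. Moving a
species onto the working conditions adds an RT ln term per species, and the
reaction Gibbs energy is

$$\Delta G_r = \sum_i \nu_i \left( G_i + RT \ln \frac{a_i}{c^\circ_i} \right),$$

with $\nu_i$ negative for reactants and positive for products. Each species
carries a *phase class* deciding its correction:

* **solute** at concentration $c$: $RT\ln(c/c^\circ)$ with $c^\circ = 1$ M,
  zero on the standard state;
* **gas-referenced** (tabulated at 1 atm): $RT\ln(c_\text{target}/c^\circ_\text{gas})$
  with $c^\circ_\text{gas} = P^\circ/RT = 0.0409$ M at 298.15 K — the
  1 atm $\to$ 1 M move is $+1.894$ kcal/mol;
* **fixed-activity** (the droplet solvent components): $RT\ln a_i$.

The default `venus_conditions()` preset fixes $T = 298.15$ K, a water
activity $a_w = 5.33\times10^{-4}$, and sulfuric acid at 16.3 M. Because no
activity coefficient is available for the droplet medium, the acid's 16.3 M
is used directly on the 1 M solute standard (an effective activity of 16.3);
the conditions object records this as an approximation. The water activity
term contributes $RT \ln a_w = -4.466$ kcal/mol per water *produced*, which
is the entire thermodynamic advantage a desiccated droplet confers on
condensation (dehydration) chemistry: `water_activity_scan()` verifies the
exact $\nu_w RT$ slope in $\ln a_w$.

All energies are handled in kcal/mol (fixed conversion table for hartree,
kJ/mol, eV inputs) and all physical constants come from one table,
`constants_table()`, with $R = 1.987204\times10^{-3}$ kcal/(mol K).
Temperature is a free parameter; the preset pins it at 298.15 K because the
input thermal corrections are computed there, and the package deliberately
does **not** re-evaluate thermal corrections at other temperatures
(a non-goal — inputs are valid at their computed temperature).

# Oligomer insertion, ring strain, and the cyclic proxy

Chain growth is modelled as sequential insertion of a monomer into a cyclic
oligomer,

$$\text{cyc}_n + \text{monomer} \rightarrow \text{cyc}_{n+1} + \text{H}_2\text{O},$$

with cycles used as end-group-free proxies for long chains. The per-unit
free energy $G(\text{cyc}_n)/n$ decreases with ring size as strain relaxes;
`select_cyclic_proxy()` picks the argmin (ties toward the smallest ring),
mirroring the convention of screening several cycles and keeping the one
with the lowest Gibbs free energy per repeat unit. `ring_strain()` reports
per-unit strain against either an explicit strain-free reference or the
large-$n$ asymptote of a least-squares fit $u(n) = u_\infty + s/n^p$.

The $n = 1$ "cycle" of the insertion bookkeeping is interpreted as the free
monomer (series flag `monomer_is_cycle1`), so the first step is the ring
closure $2\,\text{monomer} \to \text{cyc}_2 + \text{H}_2\text{O}$ in the
energy bookkeeping. A free monomer carries no ring strain, which has a
physical consequence the tests pin down: the ring-closure step is *penalized*
by the nascent small ring's strain (it sits above the asymptote), while
every later insertion *relieves* strain and approaches the asymptote from
below. Small rings are therefore disfavoured exactly where a strain model
says they should be. `fit_insertion_asymptote()` fits
$\Delta G_r(n) = g_\infty + c/(n(n+1))$ — the exact closed form for
per-unit strain $s/n^2$ — over the steps with $n \ge 2$, excluding the
ring-closure point that the strain-free monomer removes from the model's
scope.

# Bond cleavage and redox proxies

`bond_dissociation()` scores each cleavage channel as
$\sum H(\text{fragments}) - H(\text{parent})$. Enthalpies, not free
energies, are the default barrier estimate: the entropic gain from the new
rotational and translational degrees of freedom is only fully realized once
the bond is broken, so the fragment enthalpy difference upper-bounds the
free-energy barrier. A free-energy mode exists behind a flag. Homolytic
channels must produce neutral fragments; heterolytic channels must conserve
the parent charge through oppositely charged fragments, whose stabilization
by the polar droplet environment is why heterolytic cleavage can undercut
homolysis in solution-referenced energies.

`ip_ea()` differences charge-state energies: IP $= E(+1) - E(0)$,
EA $= E(0) - E(-1)$, reported in eV and invariant under a common energy
shift.

# Persistence timescales

`eyring_rate()` applies transition-state theory,
$k = \kappa\,(k_B T/h)\,e^{-\Delta H^\ddagger/RT}$, with $\kappa = 1$ and
first-order kinetics fixed (an advanced `kappa` argument exists), and
`half_life()` converts to $t_{1/2} = \ln 2 / k$. Computation is carried in
log space so a barrier large enough to underflow $k$ as a double still
yields a finite log-half-life. For a 50 kcal/mol barrier the package
computes $t_{1/2} \approx 1.6\times10^{16}$ years at 298.15 K (far beyond
the $1.38\times10^{10}$-year age of the universe) and $\approx 7.8$ days at
573.15 K — the "stable at cloud temperatures, weeks at 300 °C" contrast
that motivates the kinetic-stability argument.

# Droplet feedstock arithmetic

Three order-of-magnitude quantities for a droplet of radius $r$ in an
ambient gas at $(T, P)$ with trace mole fraction $\chi$:

* $1/(N_A V)$, the concentration of a single molecule
  ($V = \tfrac{4}{3}\pi r^3$): 0.396 nM at $r = 1\ \mu$m;
* $\chi P V/(k_B T)$, the molecule count in a droplet-volume of gas:
  $1.55\times10^4$ at 150 ppm;
* $f \chi P/(RT)$, the concentration delivered by scavenging a fraction
  $f$ of that inventory (volume cancels): 6.1 $\mu$M at $f = 1$, 150 ppm.

The defaults (1 atm, 298.15 K) represent the Earth-like
pressure/temperature band of the cloud deck and jointly reproduce both
printed-order quantities above; they are explicit `droplet_model()`
parameters and are echoed into every report. Counts are reported as real
numbers because sub-unity counts are the message at ppb levels. Henry's-law
equilibria, droplet size distributions and time-dependent scavenging are
out of scope.

# Spectra and detectability

`broaden_ir()` sums unit-area lineshapes weighted by stick intensities;
the IR default is a Lorentzian of 20 cm$^{-1}$ FWHM and the UV-Vis
convolution is a Gaussian of $\sigma = 0.3$ eV in the energy domain
(`uvvis_spectrum()`), converted to wavelength via
$\lambda = 1239.842/E$. Neither width is dictated by the underlying data,
so both are explicit arguments recorded in the run manifest. Frequencies
are unscaled by default (`scale = 1`); a global scale factor exists for
comparison with experiment. One numerical caveat is documented rather than
hidden: Lorentzian wings carry $\sim 2\gamma/\pi R$ of mass beyond $\pm R$,
so the 0.1%-level integral conservation that tests assert requires a grid a
few hundred half-widths wide — `broaden_ir(range = ...)` exposes that
choice, while the default grid pads 5 widths for plotting-scale use.

`classify_intensity()` buckets intensities (in the source's own opaque
units) below 100 as weak, 100-300 inclusive as medium — both boundary
values read as inside the closed interval — and above 300 as strong.
`diagnostic_windows()` returns the target's bands of at least a minimum
class whose distance to *every* reference band exceeds a tolerance, with
strict inequality at the boundary and a default of 15 cm$^{-1}$ — the
largest round tolerance under which a pair of strong composite P-O-S
stretches at 845 and 861 cm$^{-1}$ remains clear of the reference
absorbers' bands. The tolerance is attached to every result.
`window_fraction()` integrates a spectrum over an axis window relative to
its total; a disjoint window returns 0 with a warning rather than an error,
since "no intensity there" is a meaningful negative result (it is exactly
how a far-UV absorber is excluded as a candidate for 320-400 nm extinction).

# The synthetic generator and what it does (not) show

`generate_series()` builds cycle records
$G(\text{cyc}_n) = n(u_\infty + s/n^p) + \varepsilon_n$,
$\varepsilon_n \sim N(0, \sigma^2)$, and back-solves the monomer and water
records *noiselessly* so the noiseless insertion energy approaches a target
$g_\infty$ under the stated conditions. Noise is placed on the stored free
energies, not on derived $\Delta G$, so error propagation through the
reaction bookkeeping is exercised realistically; putting noise on the
monomer/water anchors as well would add a coherent shift of every insertion
step — indistinguishable from a change in $g_\infty$ itself — which is why
the anchors are the generator's noiseless reference frame.
`generate_band_tables()` plants diagnostic bands clear of
literature-plausible reference bands (and decoy strong bands deliberately
near them); `generate_library()` adds cleavage fragments encoding a chosen
weakest-channel BDE, charge states encoding chosen IP/EA, and a
singlet/triplet excitation manifold with a controllable absorbance maximum.
Each generator call owns a private seeded RNG stream and leaves the global
RNG state untouched; identical specs give bit-identical output.

Defaults encode the headline scenario: $g_\infty = -1$ kcal/mol, a 50
kcal/mol weakest heterolytic P-O channel, IP/EA of 11.2/1.2 eV, planted
845/861 cm$^{-1}$ bands, and a far-UV absorbance maximum near 170 nm. The
frozen library under `inst/extdata/` (filenames prefixed `synthetic_`) is
one such generated scenario with hand-chosen feedstock energies; it is a
synthetic stand-in whose reaction set reconstructs plausible feedstock
chemistry (acid + oxide condensations, water-consuming hydrations, tetramer
hydrolysis), not deposited quantum-chemistry data. Passing tests therefore
demonstrate that the *pipeline arithmetic* is correct and self-consistent
on data with the right statistical shape; they say nothing about any real
molecule's energies, which must come from real calculation outputs read
through the same validated format.

Problem sizes used by the test-suite and the acceptance script — series to
$n \le 8$, 100 recovery seeds at $\sigma = 0.05$ kcal/mol, 2000-point
spectral grids — were chosen as the smallest sizes at which the estimators
visibly stabilize.

# Numerical and design choices

* Constants live in one table; derived quantities (0.0409 M, $-4.466$
  kcal/mol, $6.21\times10^{12}$ s$^{-1}$) are recomputed, never stored.
* Imaginary modes (negative wavenumbers) are hard validation errors — a
  non-minimum structure disqualifies a record — with an explicit
  `allow_imaginary` escape hatch for inspection.
* Reactions validate charge balance always and element balance whenever
  every participant declares a formula; fractional stoichiometries are
  allowed for per-unit normalization.
* Ties in proxy selection break toward the smallest ring, the cheaper
  structure to compute and interpret.
* `run_pipeline()` writes every tunable it used (lineshape widths,
  tolerance, droplet T/P, constants) into `manifest.json`; silent defaults
  are treated as a reporting bug. Reruns on identical config are
  byte-identical; a stage failure removes partial outputs.

# Known limitations

* No explicit-solvent or ion-pairing corrections, no activity coefficient
  for the concentrated acid, no temperature re-evaluation of thermal
  corrections: inputs are trusted at their computed conditions.
* Kinetics is single-barrier Eyring with $\kappa = 1$: no tunneling,
  no microkinetic networks, no hydrolysis mechanism.
* Spectra are harmonic sticks under a single global width: no anharmonic
  corrections, no vibronic structure, no radiative transfer.
* The importer accepts only the structured JSON library format; no
  quantum-chemistry log-file parser is bundled, so upstream outputs must be
  exported to the schema first.
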