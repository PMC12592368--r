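---
title: "Divalent-cation binding free energies from metadynamics: models, estimators, and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divalent-cation binding free energies from metadynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionbindr)
```

# Scope and design

`ionbindr` packages the computational workflow of a divalent-cation channel
study as reusable, testable components. Two workflows are covered:

1. **Structure geometry** — scanning coordinates for candidate Mg²⁺/Ca²⁺
   sites formed by pairs of acidic residues, comparing that geometry between
   gating states, side-chain dihedrals, and a simple pore-radius profile.
2. **Binding thermodynamics** — well-tempered metadynamics (WTMetaD)
   sampling, free-energy-surface (FES) reweighting, minimum free-energy
   paths (MFEP), and the standard binding free energy ΔG⁰ with volume and
   ionic-strength corrections and block-analysis errors.

A deliberate design decision runs through the whole package: the *sampling
problem* is replaced by analytically tractable model landscapes, while the
*estimators* are implemented exactly as they would be applied to atomistic
trajectories. Every estimator can therefore be checked against brute-force
quadrature ground truth on the same landscape. A green test establishes that
the estimator is correct; it says nothing about force fields, water models,
or the μs-scale sampling problem of the real systems, all of which are out
of scope here. In particular the package makes no attempt to reproduce
atomistic ΔG⁰ magnitudes from first principles.

The package is tidyverse-shaped: structures, trajectories, hills, PMFs,
paths, and block tables are tibbles; fitted results have `tidy()`/`glance()`
methods and each result type has an `autoplot()`.

# The site criterion

A divalent cation bound directly (not water-mediated) by two carboxyl groups
constrains the Cα–Cα distance of the contributing residues: each residue
contributes its Cα→carboxyl-carbon arm (0.25 nm for ASP, 0.35 nm for GLU)
and the cation sits ~0.3 nm from each carboxyl carbon, giving cutoffs of
1.1/1.2/1.3 nm for DD/DE/EE pairs (`pair_threshold()`). `scan_sites()`
enumerates all acidic pairs — intra- and inter-chain, since the scan's
originators do not restrict this — below the cutoff (strict inequality: a
pair exactly at the threshold has no room for direct coordination), and
merges pairs sharing residues by single linkage, which is what lets a
six-residue acidic cluster appear as one site. The "intracellular side" of a
channel is a user-supplied axial slab (`z_range`); no automatic membrane
detection is attempted because no quantitative boundary is defined for it.

Cryo-EM density support for a candidate site — the second filter an
experimental study would apply — cannot be evaluated from coordinates alone
and is deliberately not modelled.

# Model landscapes and their ground truth

`model_potential()` builds three landscape kinds: a 1D double well, a 3D
particle attracted to two "carboxyl" anchors inside a flat-bottom restraining
cylinder, and the same with an auxiliary hydration coordinate. Wells are
isotropic Gaussians (depth `well_depths`, width `well_widths`), optionally
with an r⁻¹² soft-core repulsion scaled to RT at `repulsion_radius`. The
defaults mirror the cation-binding setups: anchors 0.3 nm apart, cylinder
radius 0.9 nm (0.7 nm for the acetate-like system), K_res = 10⁵
kJ mol⁻¹ nm⁻², RT = 2.577 kJ/mol (310 K). The demo landscape's well depths
(20 and 16 kJ/mol) were chosen once so that the bound basin lies clearly
below bulk (quadrature ΔG⁰ ≈ −2 kJ/mol) while remaining crossable at desk
scale; they are not tuned to reproduce any published number.

Because a cylinder is non-confining along its axis (and a Gaussian double
well is non-confining in 1D), restraints close the sampling volume: the
cylinder takes an axial flat-bottom range, and 1D systems use a flat-bottom
*interval* restraint — an addition to the cylinder/point kinds, declared
here. The 1D test fixtures use softer interval walls (K = 2000) purely to
keep the stable timestep large; the cylinder used in every ΔG⁰-bearing
computation keeps the stated K_res = 10⁵.

The **hydration coordinate** h mimics partial dehydration on binding without
explicit solvent: h is tethered harmonically (k_h = 10 kJ/mol per unit²) to
a rest value h_bulk − c·Σᵢ exp(−rᵢ²/2wᵢ²) that decreases from h_bulk = 6 (an
octahedral Mg²⁺ shell) by `hydration_coupling` c = 2 at full binding — two
waters displaced, as in monodentate–monodentate coordination. CN_W-style
collective variables read h directly. For computing coordination numbers
from real distance sets, `coordination_number()` implements the rational
switching function (1−(r/r₀)⁶)/(1−(r/r₀)¹²), summed over the supplied
distances (the published formula leaves the sum implicit); each term equals
1/(1+(r/r₀)⁶) identically, so the removable singularity at r = r₀ is handled
algebraically (value exactly 1/2).

`reference_fes_by_quadrature()` integrates exp(−U/RT) on a dense Cartesian
grid and bins by the collective variables — no sampling anywhere — giving
the ground-truth FES to which sampled estimates are compared. When a CV grid
is too coarse to resolve the wells (bin width > width/2) a warning is raised
and recorded in the result's provenance.

# The sampler

`run_wtmetad()` is an Euler–Maruyama overdamped Langevin integrator
(compiled core) with Gaussian-hill bias on the CVs:

* **Well-tempered rule.** Hills of width 0.05 nm (distances) / 0.1 (CN-like)
  are deposited every `deposit_stride` steps with height
  h = h₀·exp(−V(s)/((γ−1)RT)), h₀ = 0.3 RT, γ = 5.
* **Multiple walkers.** All walkers read and deposit into one shared bias in
  a fixed round-robin order (the synchronisation scheme is not prescribed
  anywhere authoritative; round-robin is declared here and makes runs
  bit-for-bit reproducible given seed, walker count and strides).
* **Bias cache.** The bias is accumulated on a CV grid with hills truncated
  at 5σ; forces come from multilinear interpolation. An exact-summation mode
  exists for validation, and a test pins the cache against it.
* **Timestep.** Euler–Maruyama is unstable when K·dt/friction > 2; with
  K_res = 10⁵ this forces a very small step. By default the step is derived
  from the stiffest force constant in the system as dt = 0.5·friction/K_max,
  trading run length for unconditional stability. The friction sets the toy
  diffusion constant D = RT/friction; neither maps to physical time and
  nothing downstream depends on the time unit.
* **Determinism.** The noise comes from R's RNG; `sampler_params()` requires
  a seed. Changing only the walker count changes the trajectories — this is
  inherent to shared-bias metadynamics and documented rather than hidden.

Sampling records and hills interoperate with the PLUMED text dialect
(`read_colvar()`/`write_colvar()`, `read_hills()`/`write_hills()`), so
externally produced COLVAR/HILLS files can be fed straight into the
estimators, and unknown columns are preserved.

# Estimation

**Reweighting.** `reweight_to_fes()` uses time-independent *final-bias*
weights w ∝ exp(+V_final(s_t)/RT) after discarding a burn-in (default 1/4 of
the run, the fraction used for the protein-like systems; 1/3 for the
acetate-like fixture). The published analyses cite a reweighting procedure
without fully specifying it; the final-bias convention is declared here,
chosen for its simplicity and its exactness in the long-time limit of
well-tempered metadynamics. Two of its properties are pinned by tests: with
an identically zero bias it reduces *exactly* to the plain histogram, and
adding a constant to the bias changes nothing (gauge invariance). Histogram
bins are half-open [lo, hi) with the global top edge closed; unvisited cells
are `NA`, never zero, and are excluded — never imputed — by projections
(`project_fes()`, a Boltzmann-weighted marginalisation) and by
`pmf_along_cv()`, which zeroes the PMF over the unbound window (mean
convention).

When the bias lives on more CVs than the histogram grid keeps (e.g. a 1D PMF
from an (L₁, L₂)-biased run), weights are evaluated at each sample's full
biased-CV coordinates before binning.

**Block analysis.** `block_analysis()` splits a series into k contiguous
equal blocks (remainder truncated), applies the statistic per block, and
reports mean and SEM across blocks; for ΔG⁰ the per-block functional is the
whole reweight→PMF→ΔG⁰ chain with the (fixed) final-bias weights, and the
value and SEM at the largest block size are reported, with plateau detection
as SEM stabilisation across the largest block sizes.

**MFEP.** `string_minimize()` is the zero-temperature string method: interior
nodes descend the bilinearly interpolated FES gradient and the chain is
reparameterised to equal arclength each iteration until the maximum node
displacement falls below `tol` (default 1e-4 grid units; n_nodes = 100 —
both declared defaults, as no authoritative values exist). Per-iteration
node moves are capped at one grid cell, and the step is damped geometrically
when the displacement stops decreasing, which lets the string settle on the
noisy FES of a finite run; non-convergence at `max_iter` returns the current
path flagged `converged = FALSE`. If the straight-line initialisation
crosses unvisited cells, a lowest-cost path over finite cells (uniform-cost
search) seeds the string instead. Missing cells repel the string via a
high-energy plateau rather than being interpolated.

# The standard binding free energy

`standard_binding_free_energy()` assembles ΔG⁰ = ΔG_PMF + ΔG_V + ΔG_I as an
exact identity of its returned components:

* ΔG_PMF = RT·ln(∫_unbound e^(−PMF/RT) dx / ∫_bound e^(−PMF/RT) dx), with
  trapezoidal integration on the PMF grid; region edges are honoured exactly
  by interpolating the PMF at the interval ends (half-bin flat extrapolation
  at the grid border), so the flat-profile closed form RT·ln(l_u/l_b) is
  reproduced exactly. Defaults: bound L < 0.4 nm, unbound 2 < L < 2.5 nm,
  l_u = 0.5 nm.
* ΔG_V = −RT·ln(l_u·S_u/V⁰) with V⁰ = 1.661 nm³ and the closed-form
  restraint cross-section S_u = πR²_cyl + 2π(√(πRT/(2K_res))·R_cyl +
  RT/K_res), which a test verifies against its defining radial integral to
  four significant figures across R_cyl ∈ [0, 2] nm, K_res ∈ [10³, 10⁷].
* ΔG_I: the printed form of the ionic-strength correction defines
  γᵢ = −A·zᵢ²·√I, which cannot be an activity coefficient (it is negative);
  it is read here as the limiting Debye–Hückel law log₁₀ γᵢ = −A·zᵢ²·√I,
  giving ΔG_I = RT·ln10·(−A√I)(z²_cation + z²_site − z²_complex) with
  A = 0.519 M^(−1/2) at 310 K. The literal reading is kept behind
  `mode = "literal_ratio"` for audit and errors with an explanation.

For a two-distance protein-like site the PMF coordinate is configurable
(`pmf_cv`, default L₁); whether a published bound-region cutoff applies to
one or both distances simultaneously is not stated anywhere authoritative,
so the package treats the PMF CV as the binding coordinate and leaves the
choice explicit. ΔΔG follows the "a versus b" convention
(`delta_delta_g()`), and `fold_preference()` returns exp((ΔG⁰_b − ΔG⁰_a)/RT)
with SEMs combined in quadrature (the combination rule for published ±
values is not stated; independent-error quadrature is declared here).

ECC charge-scaling factors (0.8/0.85) from the atomistic protocol have no
role in the toy model and are treated as metadata only.

# The demo pipeline and what its green tests establish

`run_demo_pipeline()` chains landscape → quadrature ground truth → 4-walker
WTMetaD → 2D FES → MFEP → 1D PMF → ΔG⁰ + block SEM, writing CSV/JSON and
COLVAR/HILLS outputs with a provenance record (package version, config, and
a key-order-independent config hash). Configuration is YAML
(`write_config()`/`read_config()`).

The headline property test re-runs this pipeline at a fixed seed and
requires the sampled ΔG⁰ to recover the quadrature oracle within 1 kJ/mol.
The desk-scale run length (1.5×10⁷ steps per walker, hills every 10⁴ steps)
was chosen once as the scale at which the block-analysis SEM plateaus well
below that bound; it stands in for the μs-scale production runs the same
way the landscape stands in for the atomistic system. What the green test
establishes is that the estimator chain — biasing, reweighting, PMF
extraction, volume correction, error analysis — is internally consistent
and unbiased at its stated tolerance on a landscape with known truth; it
does not establish anything about real proteins.

# Numerical choices and known limitations

* Units: nm and kJ/mol internally; PDB/mmCIF I/O converts Å at the boundary.
  Author residue numbering throughout; altloc duplicates resolve to the
  highest occupancy (ties: first in file); only the first model is read
  unless asked otherwise.
* The pore profiler is a plane-wise largest-empty-sphere search with
  multi-start local optimisation (five starts around the axis), vdW radii
  C 1.70, N 1.55, O 1.52, S 1.80 Å by default, radii clipped at 0 and an
  explicit sentinel for empty slices. It is a simple stand-in for dedicated
  pore software: it assumes a roughly straight pore near the given axis and
  will not follow strongly curved channels.
* Published positional-restraint force constants printed as kJ mol⁻¹ nm⁻¹
  are dimensionally inconsistent for a harmonic restraint and are treated as
  kJ mol⁻¹ nm⁻² (metadata only here, since positional restraints of protein
  atoms do not occur in the toy model).
* Helix-rotation angles (~100°, ~11°) between gating states are not
  quantified: the axis conventions they depend on are unspecified, and
  `compare_states()` reports the distance/site-presence comparison instead.
* The string method is zero-temperature only; no climbing image, finite-T
  strings, transition tubes or committor analysis.
* Checks against deposited structures require downloads and are therefore
  exercised on toy fixtures built to the same printed geometry (closed/open
  DD pairs at 1.05/1.25 nm); the reader functions accept the deposited
  models unchanged when files are available locally.
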