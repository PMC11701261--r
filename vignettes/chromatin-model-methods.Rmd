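---
title: "Model and methods: heteromorphic chromatin simulation and topos mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: heteromorphic chromatin simulation and topos mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(chromotopos)
```

This vignette is the package's own account of the model it implements, the
choices that were genuinely open, and what its tests do and do not
establish.

## The physical model

A chromosome fragment is a chain of beads, one per kbp, with diameter σ
(the simulation length unit; its physical value, typically 20–30 nm, is
only fixed afterwards by fitting to FISH data). Energies are in kBT, time
in τ = σ√(m/kBT). The force field has five bonded/nonbonded terms, each a
pure function in `R/energies.R` with an analytic force in the compiled
engine:

* WCA excluded volume between **any** two beads (cutoff 2^{1/6} σ).
* FENE backbone springs (K_f = 30 kBT/σ², R₀ = 1.6 σ). A bond reaching R₀
  is treated as a fatal diagnostic, never clamped: silent clamping would
  hide timestep errors.
* Kratky–Porod bending, U = (l_p/σ)(1 − cos θ), l_p = 4 σ.
* A truncated-shifted Lennard-Jones attraction between binding proteins
  and marked beads (cutoff r_c = 1.8 σ), multiplied by a normalization N
  chosen so the minimum is exactly −ε. N is found by bracketed numerical
  minimization and cached per r_c (robust to any future r_c) rather than
  via the closed form; the same single formula is used below the minimum
  (no splice to WCA). With ε = 0 the term vanishes and the WCA term alone
  carries the steric limit — that convention is asserted in a test.
* Harmonic springs for loop-extruder anchors (k = 40 kBT/σ², r₀ = 1.5 σ;
  the WCA part of the extruder bond is carried by the global WCA term, so
  the pair is counted once) and for crumpling (k = 200 kBT/σ², r₀ = 1.1 σ
  on (i, i+2) pairs).

A bead may carry several marks. A binding protein sees the **maximum** ε
over the marks it recognizes on that bead, not the sum: one pairwise
potential needs one depth, and max preserves strong-site semantics (an
ATAC + H3K27ac bead binds active factors at 7 kBT, not 10). Chromatin
beads attract each other at 0.4 kBT through the same functional form and
cutoff unless either carries H3K27ac.

## Dynamics and numerics

The Langevin equation (friction γ = 2, so the Brownian time is 2 τ) is
integrated with the BAOAB splitting at dt = 0.01 τ. With the thermostat
off, BAOAB reduces exactly to velocity Verlet, which is the NVE validation
mode: the energy-conservation test measures the **secular slope** of the
total energy over many samples, because a symplectic integrator's energy
oscillates with bounded O(dt²) amplitude but does not drift. BAOAB was
chosen over naive velocity-Verlet-plus-noise because the latter has an
O(γ dt) kinetic-temperature bias (~1% at these parameters) that would
consume most of the ±2% equipartition budget.

Positions are never folded into the periodic box; the minimum-image
convention is applied to nonbonded pair vectors only. Bonds, angles and
centre-of-mass (FISH) measurements therefore always see real-space
coordinates, and a probe straddling a box face cannot produce a spurious
centre. Nonbonded interactions use cell lists when the box admits at least
three cells per dimension at the largest cutoff, otherwise an all-pairs
fallback; thermostat noise comes from a self-contained xoshiro256++ /
Box–Muller generator so trajectories are bit-reproducible under a seed
across platforms.

## Loop extrusion

Extrusion is event-driven on top of the dynamics: every `event_interval`
MD steps (default 100, i.e. 1 τ) each unblocked extruder end advances one
bead outward with probability v·Δt, so the *rates* (v = 4×10⁻³ kbp/τ,
k_off = 2.5×10⁻⁵ τ⁻¹, processivity λ = 160 kbp) are the contract, not the
sweep cadence. An end halts when the **next** bead is an active CTCF bead
of opposing orientation (anchors come to rest adjacent to the boundary;
arrest-on-bead would conflate anchor and boundary identity), a bead
occupied by another anchor (re-tested each sweep, since the obstacle can
move), or the chain end. A forward-strand motif blocks leftward-travelling
ends and vice versa, which yields convergent loops; this single most
error-prone convention has a dedicated fixture test. Unbound extruders
rebind instantly at a fresh uniform position, keeping the count constant.
With two independently moving ends, the realized steady-state loop length
on a boundary-free chain is the two-sided accounting, ≈2λ plus the 3 kbp
loading footprint; the kinetics test asserts it inside [λ, 2λ] with 15%
slack, and the mean residence time against 1/k_off.

## Annotation rules

Interval arithmetic is 0-based half-open throughout, on a fixed 1 kbp bead
grid. A bead carries a mark iff ≥ 1 bp of a peak overlaps it — peak calls
mark enrichment without an overlap fraction, and 1 bp is the simplest
monotone rule (echoed in the provenance sidecar). CTCF boundary beads
require a CTCF peak overlapping a RAD21 peak and containing a motif hit;
orientation follows the best-scoring motif, with opposite-strand hits
within 10% of the larger score (config-exposed) making the site
bidirectional. Activation probabilities are linear in peak score,
normalized by the fragment's maximum so p ∈ [0, 1]; when several peaks
share a bead, every activation pattern is enumerated (mixed active
orientations combine to bidirectional) and one outcome is drawn per run.
Promoter beads sit at the midpoint of the supplied promoter interval —
the interval file is an explicit input, so users control the promoter
definition (TSS-anchored intervals give TSS-anchored beads).

## The staged protocol

The initialization sequence — rosette start, 600 τ soft-potential
relaxation (amplitude ramped 0→500 kBT), z-compression to the density-
matched cube over 10⁴ τ, fixed- then periodic-boundary relaxation
(5×10³ τ, 2.5×10⁴ τ), CTCF-free extrusion at 7.5 extruders/Mbp for
2×10⁴ τ, crumple relaxation 10⁴ τ, protein equilibration 10³ τ — precedes
a 3×10⁵ τ production run in which chromatin–chromatin attraction switches
on at 10⁴ τ, protein–chromatin attraction at 5×10⁴ τ, and conformations
are sampled every 2×10³ τ over the final 10⁵ τ, with structures at 2×10⁵
and 3×10⁵ τ flagged as the retained, statistically uncorrelated set. A
two-tier scheme (`n_relax` relaxed states × `n_production` seeds) mirrors
the 10 × 30 → 600-structure design at full scale.

Open choices resolved here:

* **Rosette geometry.** Only the post-relaxation ensemble matters (memory
  is erased by the CTCF-free extrusion stage), so the rosette is any
  self-overlap-tolerant stack of petals. The curve is resampled by
  **chord** length, not arc length: petals pass through the axis, where an
  arc-length grid would put consecutive beads a fraction of σ apart on the
  doubled-back path. Geometric postconditions (spacing within [0.9, 1.3] σ,
  centred on the axis, fits the box) are what the tests assert.
* **Soft push-off.** U = A(1 + cos(π r/r_cut)) for r < 2^{1/6} σ — the
  standard bounded pre-equilibration form — with A ramped linearly.
* **Quench ramps.** Adding all crumple springs at full stiffness in one
  step injects ~10² kBT per spring and overstretches FENE bonds at
  dt = 0.01; the spring constant is therefore ramped in over the first half
  of the crumple stage. Final constants and all rates are unchanged.
* **Compression** is a linear rescaling of the z box dimension with affine
  coordinate remapping, applied in 50 increments; **fixed boundaries** are
  soft repulsive walls of the same functional family as the push-off.
* **Desk scale.** One scalar multiplies every stage duration (and the
  sampling cadence proportionally). The defaults are the cluster-scale
  protocol; the packaged tests and examples use 0.002–0.01 on a 100 kbp
  locus, i.e. ~3.7×10⁵ MD steps per run, which keeps a full pipeline run
  under half a minute on one CPU. Kinetic rates are never rescaled, so at
  strong desk scales extruders translocate only a few kbp during
  production: desk-scale ensembles exercise bridging, crumpling and
  boundary capture, but not full-λ loop growth.
* **CTCF activation** is resampled per production run (cell-to-cell
  variability); protein binding states start balanced and switch at k_sw.
* **Protein insertion** rejects positions within 0.9 σ of existing beads,
  because a protein dropped inside a bead's core would see a divergent WCA
  force at the first step.

## Phantom-chain persistence length

The bond-correlation check simulates a chain with connectivity and bending
only. Two numerical facts matter. First, the discrete Kratky–Porod chain
at stiffness K = l_p/σ has ⟨cos θ⟩ = coth K − 1/K exactly, so the decay
length of ⟨cos θ(s)⟩ = (coth K − 1/K)^s is −1/ln(coth K − 1/K) ≈ K − ½ =
3.49 bond lengths at K = 4 — the *fitted* persistence length of a
faithful simulation sits ~13% below the stiffness parameter, a discreteness
effect, not an integrator error. The package ships an exact equilibrium
sampler (`sample_kp_chain`, inverse-CDF draws of cos θ) that both
initializes these runs and serves as the independent oracle for this
value. Second, the log-linear fit over s = 1..10 is heavy-tailed: the
s ≈ 10 correlations average few effectively independent samples because
long-wavelength direction modes decorrelate over ~10² τ, giving per-run
fit scatter of order 15%; the acceptance script therefore integrates 3×10⁶
sampling steps. Third, the bonded pairs keep their WCA core even in
phantom mode ("no excluded volume" drops only non-neighbour pairs): a pure
FENE bond has its minimum at r = 0, where bending forces diverge and
dt = 0.01 is unstable, while the bond's equilibrium length (~0.97 σ) does
not enter the angle statistics at all.

## Analysis stack

In-silico reads are sampled by the crosslinking analogy: a uniform random
bead pair is registered with probability exp(−r/r_t). Self-pairs are
excluded (the diagonal is uninformative and the directionality score
ignores < 20 kbp anyway); adjacent pairs are retained; the sampler takes
an explicit read target rather than auto-matching an experimental total.
ICE balancing masks zero-marginal bins and iterates row/column scaling to
a marginal coefficient of variation below 10⁻⁸ by default. The
directionality score uses 20–500 kbp windows; edge-truncated windows are
computed but flagged, and D-profile correlations use untruncated bins
only. Direct map correlations default to no near-diagonal exclusion band
(config-exposed).

Topos statistics use strict `< 3.5 σ` centre-to-centre minimum-image
contact distances, with *inclusive* ≥ 10% (partner) and ≥ 50%
(influential) frequency thresholds — boundary behaviour (60/600 in,
59/600 out) is pinned by tests. Each ATAC bead is its own candidate (no
peak-level merging), the empty partner subset counts as a valid network
(it is one of the 2^q subsets; switchable), and the diversity
normalization 1/(q+1) keeps H defined at q = 0. The FISH bead-size fit
searches σ ∈ [10, 50] nm on a 0.5 nm grid with golden-section refinement —
a bracket comfortably containing the plausible 20–30 nm range.

## What the synthetic locus does and does not establish

The generator plants a single gene (promoter at 50 kbp, also accessible)
with strong enhancers at 40 and 65 kbp, a weak distal ATAC site at 93 kbp,
an acetylated block over the gene, repressed H3K27me3/H3K9me3 domains, and
a maximal-score convergent CTCF pair at 30/75 kbp, on a 100 kbp fragment.
It emulates the *file formats and logical structure* of real input stacks
and the qualitative physics (bridging enrichment, crumpling, boundary
capture); it does not emulate peak-calling noise, mappability artifacts,
replicate disagreement, or the megabase-scale context of real loci, so
passing tests demonstrate internal correctness and qualitative behaviour,
not genome-wide predictive accuracy. Problem sizes in the packaged tests —
100 kbp fragments, desk scale 0.01, ensembles of ~50 structures per seed,
20-seed replication for the ordering checks — were chosen as the smallest
sizes at which the tested effects are unambiguous.

## Known limitations

No electrostatics, hydrodynamics, or transcription-driven supercoiling; no
explicit cohesin chemistry (loading bias, bypass); a single generic active
factor species; trans and ultra-long-range cis contacts are out of reach
of single-fragment simulations; and desk-scale runs shorten equilibration
relative to the cluster-scale protocol in proportion to the desk factor.
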