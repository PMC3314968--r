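---
title: "Methods: mapping ubiquitin recognition by an overlapping-UBA solenoid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping ubiquitin recognition by an overlapping-UBA solenoid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubamap)
```

`ubamap` implements the computational half of a joint NMR/calorimetry/
modelling study of how a solenoid of overlapping UBA domains binds
ubiquitin. This vignette records the models behind each stage, the
parameters that matter, the numerical choices, and what the synthetic
generators do and do not emulate.

## The structural model

A SOUBA is a single rigid domain of seven α-helices in a right-handed
solenoid. Reading three helices at a time gives three UBA-like
three-helix bundles, with the third helix of each unit doubling as the
first helix of the next. `decompose_overlapping_ubas()` encodes exactly
this: an odd stack of *n* helices yields (n−1)/2 units, units *i* and
*i+1* sharing helix 2*i*+1.

Helix assignment works from Cα geometry alone: a residue window is
helical when d(Cα_i, Cα_{i+3}) ∈ [4.5, 5.6] Å and d(Cα_i, Cα_{i+4}) ∈
[5.8, 6.8] Å. These windows bracket the ideal α-helix values (≈5.1 and
≈6.2 Å) generously enough to absorb coordinate noise of a few tenths of
an Ångström while excluding extended and loop geometry, and they need no
hydrogen-bond calculation, so the criterion applies to Cα-only models.
Segments must span ≥ 6 residues (UBA helices are short); when two
detected runs would overlap, the N-terminal segment keeps the shared
residues — an arbitrary but deterministic tie-break.

## Chemical shift perturbation analysis

CSPs combine the amide proton and nitrogen shift changes as
Δδ = sqrt(ΔδH² + (ΔδN/5)²); the factor 5 compensates the larger ¹⁵N
dispersion. Residues missing from either peak list — prolines above all,
which have no backbone amide — are assigned Δδ = 0 and flagged, and
flagged residues are excluded from interface calls and fitting rather
than treated as genuine zeros. The interface threshold defaults to
0.2 ppm, the operative cutoff for calling UBA/ubiquitin interface
residues; it is a parameter of `map_interface_residues()`, not a
constant.

The titration fit assumes fast exchange: each responsive residue's CSP
is Δδ_max(r) · f_b(P, L, K_d) with one global K_d. Rather than a joint
trust-region fit over K_d plus one amplitude per residue, the package
profiles the amplitudes out: for fixed K_d the least-squares
Δδ_max(r) has the closed form (Σ_i f_b,i Δδ_{r,i}) / (Σ_i f_b,i²), so
the problem collapses to a 1-D search over log K_d (81-point coarse grid
on [0.1, 10⁵] μM, then golden-section refinement to 10⁻¹⁰ on the log
scale). This reaches the same optimum as the joint fit, cannot be
derailed by amplitude initialisation, and makes the noiseless-recovery
property (K_d reproduced to ~10⁻⁶ relative anywhere in [1, 5000] μM)
easy to verify. Residues whose largest CSP stays below `min_response`
(default 0.05 ppm, a few times the per-point noise of a typical series)
carry no K_d information and are dropped from the fit.

The fraction bound is always the closed-form root of the binding
quadratic, evaluated in the cancellation-free form
2L / (s + sqrt(s² − 4PL)) with s = P + L + K_d; the test suite keeps an
independent bisection solver of the equilibrium equation as an oracle.

## ITC

`simulate_itc()`/`fit_itc()` implement a single set of independent
sites. After injection *i* of volume dV both cell species are diluted by
(1 − dV/V₀) — the standard perfusion approximation used by instrument
software — the syringe species additionally gaining dV/V₀ of its stock.
The cumulative binding heat is Q(i) = n·M_t(i)·ΔH·V₀·Θ(i), and the
observed injection heat adds the displaced-volume correction
(dV/V₀)(Q(i)+Q(i−1))/2 plus a per-injection baseline offset. Units are
fixed internally (μM, μL, cal/mol, heats in μcal) with conversions only
at I/O.

Fitting is Levenberg–Marquardt over (n, K_d, ΔH, offset), with n and
K_d parameterised on the log scale to keep them positive; standard
errors come from the Jacobian at the optimum (delta method for the
log-scale parameters). A Wiseman parameter c = n·M_cell/K_d outside
[1, 1000] triggers a warning but not a refusal: the low-affinity design
(75 μM cell, c ≈ 0.5) is exactly the regime in which one still fits,
with honest uncertainty. Under that design the fitted K_d is noticeably
more variable between replicate simulations than at c ≈ 2, which is why
recovery is stated as a median over 20 seeds rather than per-run. The
first-injection artifact common in real data can be handled with
`discard_first = TRUE` (off by default — simulated data have no such
artifact). ΔH for simulations defaults to −2000 cal/mol, a typical
exothermic UBA/ubiquitin-scale enthalpy chosen because only K_d recovery
is ever asserted.

## Docking by template superposition

Each UBA unit receives one ubiquitin by superposing a template
UBA:ubiquitin complex onto it: helix *k* of the template is paired with
helix *k* of the unit, Cα pairs taken symmetrically about the helix
midpoints and trimmed to the shorter helix. This fixed correspondence
needs no sequence alignment and is deterministic; it requires ≥ 3
pairable residues per helix. The Kabsch superposition uses the SVD
construction with a sign flip of the smallest singular direction, so a
reflection can never be returned; degenerate (collinear, < 3 point)
inputs are rejected.

Clash detection reports all inter-chain heavy-atom pairs below 2.4 Å, a
conservative hard-sphere criterion. The contact footprint that the
template itself defines (UBA residues within 5 Å of the template
ubiquitin, mapped through the helix pairing) is excluded for each placed
copy by default: that contact *is* the modelled interface. The exclusion
can be turned off to audit it.

Isopeptide-linkage feasibility between adjacent copies is a thresholded
geometric test: the Lys48 (or Lys63) NZ of one copy must come within
9 Å of the Gly76 carbonyl carbon of the other (minimum over both
directions). The 9 Å default allows an isopeptide bond (~1.3 Å) plus
generous rearrangement of the flexible C-terminal tail (residues
72–76); the threshold is a parameter precisely so its sensitivity can be
reported. Adjacency means consecutive UBA unit indices, and placed
chains are named U1, U2, U3 in unit order.

## PRE prediction

The spin label is a single pseudo-atom 6 Å beyond Cβ along the Cα→Cβ
direction — a one-point stand-in for a nitroxide tether, with no rotamer
ensemble (the offset is configurable). The paramagnetic rate at distance
r is Γ₂ = K·r⁻⁶·(4τc + 3τc/(1 + ω_H²τc²)) with K = 1.23·10¹⁶ Å⁶ s⁻²
(the standard nitroxide electron–proton dipolar constant), τc = 10 ns,
and ω_H for a 700 MHz spectrometer; the intensity ratio is
R₂·exp(−Γ₂t)/(R₂ + Γ₂) with R₂ = 20 s⁻¹ and t = 10 ms. Setting K = 0
models the reduced (ascorbic-acid) control and returns ratio 1
everywhere. Amide protons are taken from the structure when present,
otherwise rebuilt 1.02 Å from N along the bisector of N→Cα and
N→C(i−1), falling back to the N position for chain-initial residues.

Attenuation regions are contiguous runs of ≥ 2 residues with ratio
below 0.7. Neither cutoff is physically forced; with the default
parameters the 0.7 ratio corresponds to a label–amide distance of about
20 Å, so region calls are essentially a thresholded distance field —
and the test suite checks exactly that equivalence. Observed and
predicted profiles are scored by the Jaccard index of their
region-residue sets (1 when both are empty). The prediction assumes the
fully bound complex; exchange and partial occupancy are out of scope and
listed as a limitation.

## What the generators emulate

`make_solenoid()` builds ideal α-helices (1.5 Å rise, 100°/residue) on
a superhelical path with exact per-helix screw symmetry (40° twist and
9 Å rise per helix, radius 14 Å, 15° helix tilt, by default), linear
loops bowed 4 Å outward so they clear the helix bodies, and 0.05 Å
seeded Gaussian jitter. The screw symmetry makes every UBA unit
congruent, which is what lets one template dock all three ubiquitins
with sub-Ångström RMSD — mirroring the rigidity of the real domain. The
generated sequence is polyalanine with one signature motif per unit
(`MGF`, `KGF`, `MGF`) in the α1/α2 loops, the middle unit carrying the
degenerate variant.

`make_ub_like_domain()` is explicitly a geometric decoy, not a fold:
76 residues in five short helical columns arranged so that the
hydrophobic-patch markers (Ile44, Val70) and spin-label positions 6 and
48 sit on the binding face while positions 39 and 57 face away, with
side-chain vectors pointing radially outward. That placement is what
reproduces, by construction, the qualitative spin-label dichotomy:
probes at 6/48 sit near the receptor in the docked model and bleach its
amides, probes at 39/57 end up > 20 Å away and leave no significant
region. The named atoms needed downstream (Lys48/Lys63 NZ, Gly76 C,
Cβ everywhere but glycine) are present at fixed relative geometry.

`make_template_complex()` poses the decoy against the helix-1/3 face of
a three-helix UBA (the first three helices of a default solenoid) by
bisection along the face normal until the minimum heavy-atom separation
is exactly 4.0 Å — in contact for footprint purposes, comfortably
clash-free at 2.4 Å, and fully deterministic.

`simulate_titration()` defaults to the experimental design of the
corresponding HSQC experiments: 500 μM labelled protein, ligand to
3 molar equivalents over 10 points, true K_d 70 μM, twelve perturbed
residues (the motif loops plus the preceding helix-end residue) with
Δδ_max 0.4 ppm split between ¹H and ¹⁵N by a random phase, 0.01 ppm
proton noise (¹⁵N noise 5×), and two prolines omitted from every list.
ITC simulations default to the matching calorimetric designs (150 or
75 μM cell, 3 mM syringe, 38 × 1 μL injections into 200 μL) with noise
set to 2% of the largest injection heat.

What the generators do **not** emulate: real side-chain packing,
spectral overlap and lineshapes, intermediate/slow exchange, label
rotamer distributions, partial occupancy of the three sites, and any
actual ubiquitin fold. Passing tests therefore demonstrate that the
analysis chain is internally correct and statistically calibrated on
data obeying its assumptions — not that those assumptions hold for any
particular real system.

## Numerical and reproducibility choices

* Every stochastic function takes an explicit seed; nothing draws from
  an unseeded global RNG. Rerunning `run_pipeline()` with the same
  config reproduces every output file byte for byte.
* Problem sizes are kept at desk scale throughout: 95-residue receptor,
  76-residue decoy, 10-point titrations, 38-injection isotherms, 20-seed
  recovery medians. The full test suite and the acceptance script each
  run in well under a minute on one CPU.
* Degenerate inputs fail loudly: collinear superposition targets, even
  helix counts, peak lists with duplicate residues, thermograms whose
  length disagrees with the protocol, missing NZ/C atoms in linkage
  assessment. A coincident spin label (r = 0) returns ratio 0 as the
  physical limit rather than an error.
* PDB coordinates are written at the format's native 3-decimal
  precision; round-trips are exact at that precision and identical
  thereafter, which is what the packaged fixtures (regenerable
  bit-for-bit from their specs) rely on.

## Known limitations

Single-model PDB handling only (no ensembles, no crystallographic
symmetry); no DSSP-style secondary-structure taxonomy beyond helices; no
peak picking or exchange-regime analysis; no flexible docking, scoring
or side-chain repacking; PRE back-calculation stops at prediction and
comparison — distances are never refined against observed ratios. The
decoy ubiquitin supports every geometric operation the package performs
but must not be mistaken for a structural model of ubiquitin.
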