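---
title: "Quantifying conservation of collective motion between paired MD ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying conservation of collective motion between paired MD ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motioncons)
```

## The question and the model

A chemical modification of a nucleic-acid backbone — here the motivating
case is a methyl phosphotriester linkage placed at a chosen position of a
primer bound to a DNA polymerase — can perturb a complex in two quite
different ways. It can destabilize the structure, which shows up in RMSD,
interaction energies and hydrogen-bond counts; or it can leave the average
structure alone and instead redirect the *slow collective motions* of the
protein, an allosteric-like effect invisible to static metrics. This
package implements the second kind of analysis around the standard
structural ones, so that one modified ensemble can be compared with a
wild-type reference on both axes.

The motion analysis is essential dynamics: over a trajectory window, the
positional covariance matrix of N selected atoms (one Cα per residue of
the domain of interest) is

$$C_{ij} = \langle (x_i - \langle x_i\rangle)(x_j - \langle x_j\rangle)\rangle,$$

a 3N × 3N symmetric matrix whose leading eigenvectors (principal
components) are the dominant collective motions and whose eigenvalues are
the mean-square fluctuations along them. Two systems are compared
mode-by-mode through the directional similarity

$$\sigma_{mn} = \frac{1}{N}\sum_{i=1}^{N}\left(1 - \frac{\theta_i^{mn}}{\pi}\right),
\qquad \theta_i^{mn} = \angle\!\left(r_i^{\mathrm{test},m},\; r_i^{\mathrm{ref},n}\right),$$

where $r_i$ is the per-atom 3-vector slice of a mode. The per-atom angle
ignores amplitude on purpose: it asks whether atom *i* moves in the same
*direction* in both systems. With the first two PCs this yields a 2 × 2
matrix, summarized as $\Sigma_C = \sigma_{11} + \sigma_{22}$ (the leading
modes correspond) versus $\Sigma_U = \sigma_{12} + \sigma_{21}$ (they are
swapped or altered); $\Sigma_C > \Sigma_U$ is labelled conserved,
$\Sigma_C < \Sigma_U$ unconserved. Restricting the classification to the
first two PCs is a deliberate model choice: in domain-scale protein
motion, PC1 and PC2 typically carry most of the variance and the
functional interpretation; higher modes are computed but not classified.

The assumptions worth stating plainly:

* the ensemble is equilibrated over the analysis window (windows are
  always explicit; `find_equilibration()` only *flags* a candidate start
  frame, it never discards frames on its own);
* a per-atom *direction* comparison is meaningful, i.e. the two systems
  share the same atoms in the same order (enforced);
* two modes suffice for the verdict — when $\lambda_1 \approx \lambda_2$
  the PC basis itself is ill-determined within the degenerate subspace,
  and σ between such systems is unstable even if the subspace is
  perfectly conserved. The σ matrix is always reported so this case can
  be recognized (all four entries intermediate).

## The sign problem

Eigenvectors are defined up to ±1, and σ is *not* sign-invariant:
$\sigma(v, -w) = 1 - \sigma(v, w)$. Left unhandled, the verdict would
depend on solver-internal sign conventions. Two layers deal with this:

1. `principal_modes()` canonicalizes every eigenvector (largest-magnitude
   component made positive), so results are reproducible across runs and
   LAPACK builds;
2. `directional_similarity()` defaults to `sign_policy = "maximize"`: the
   test mode is globally negated iff that raises σ, and the flip is
   recorded in the result. This treats the two orientations of a mode as
   the same physical motion, which is the interpretation under which a
   conservation verdict makes sense. `sign_policy = "off"` evaluates the
   formula literally for strict-formula work.

Since the maximize policy is applied per mode pair, every σ is ≥ 0.5 under
it; the classification compares diagonal against off-diagonal sums, which
the shared floor does not bias. The per-residue decomposition reuses the
flips chosen for σ₁₁ and σ₂₂, so its mean equals Σ_C exactly.

## Numerical choices

* Per-atom angles via `atan2(|a × b|, a·b)` rather than `acos` of a
  normalized dot product: exact at 0, π/2 and π, so the analytic anchor
  values (σ = 1, 0.5, 0) are hit to machine precision instead of to
  `acos`-rounding noise.
* Atoms whose mode slice has norm < 1e-12 contribute the uninformative
  midpoint 0.5 instead of being dropped, keeping N fixed across mode
  pairs.
* Ties ($|\Sigma_C - \Sigma_U| \le 10^{-12}$) are labelled `ambiguous`
  rather than forced into a class.
* Covariance uses the population estimator (divide by M frames), matching
  the ensemble-average definition of C.
* Before covariance, frames are Kabsch-superposed onto the running mean
  of the selection (two passes), because unfitted covariance conflates
  rigid-body and internal motion. This is configurable: off for ensembles
  known to carry no rigid-body component (the synthetic generator's
  output), or onto a fixed reference. Note the elementwise
  rigid-motion-invariance of the covariance holds for a fixed external
  reference; under the iterative-mean fit the matrix co-rotates with the
  frames and only its spectrum is invariant.
* Kabsch superposition computes the proper rotation (det = +1) via SVD
  and refuses collinear point sets, where the rotation is not unique.
* Both hydrogen-bond cutoffs and the energy cutoff are *inclusive* (≤),
  so boundary fixtures behave deterministically.
* `pair_energy` canonicalizes group order internally, making
  E(A,B) and E(B,A) bit-identical, and refuses pairs closer than 0.05 nm,
  where point-charge/LJ energies are numerically meaningless.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| H-bond donor–acceptor cutoff | 3.5 | Å | standard geometric criterion for N/O polar contacts |
| H-bond H–donor–acceptor angle | 30 | degrees | same criterion's angular part |
| nonbonded cutoff | 1.0 | nm | short-range cutoff of the underlying MD setup; hard truncation, no switch |
| contact-shell cutoff | 5.0 (linkage), 4.5 (methyl) | Å | heavy-atom neighbourhood shells |
| contact occupancy threshold | 0.5 | fraction of frames | a "surrounding" residue should be there at least half the time; configurable |
| modes classified | 2 | — | PC1/PC2 carry the dominant motions |
| sign policy | maximize | — | see above |
| covariance estimator | 1/M | — | population (ensemble-average) convention |

Internal units are nm, ps, kJ/mol and elementary charges throughout; Å
appears only at PDB boundaries and in reported distances/RMSDs, where Å is
what practitioners read.

Where a choice was genuinely open, the package picks a documented default
and exposes it: the RMSD atom set defaults to Cα (the fit selection
defaults to the measure selection); the active-site distance defaults to
the carboxylate carbon of the named Asp and the 3′-terminal O3′, both
overridable since the chemistry, not the PDB atom naming, defines the
measurement; per-group energies are short-range pairwise only, since a
per-group decomposition of a reciprocal-space lattice sum is not defined —
group energies therefore carry a systematic offset relative to full-Ewald
totals, which cancels to first order in modified-minus-reference deltas.

## What the synthetic generator emulates — and what it does not

`generate_gaussian_ensemble()` draws i.i.d. frames from
$\mathcal{N}\!\left(\mu,\; \Sigma\right)$ with
$\Sigma = \sum_k \lambda_k v_k v_k^\top + \sigma^2_{\mathrm{res}}(I - \sum_k v_k v_k^\top)$:
prescribed orthonormal modes with prescribed variances, isotropic noise in
the orthogonal complement. `perturb_modes()` then constructs paired
systems whose ground truth is known exactly — identical, swapped, rotated
in the PC1/PC2 plane, or fully randomized leading modes.

This emulates exactly the features the statistics consume: a mean
structure, a covariance with a controlled spectrum, and a known
relationship between two systems' leading modes. It does *not* emulate
temporal autocorrelation (every statistic here is a single-time-point
functional of the ensemble, so i.i.d. frames test correctness; on real
trajectories autocorrelation only reduces the effective sample size),
anharmonicity or multi-basin kinetics, solvent, or periodic-image effects
(the minimum-image code paths are tested with constructed boxed fixtures
instead). Passing tests therefore demonstrate that the estimators recover
planted truth from Gaussian ensembles — not that two 100 ns trajectories
of a real complex contain enough sampling for a stable verdict; that
remains the user's convergence question.

Fixture scale mirrors the motivating study: 128 pseudo-residues (one
Cα-like atom each) for motion analyses. Mode-recovery checks use
λ = 1.0/0.3 nm² over 0.01 nm² residual noise — widely separated scales, so
recovery failures indicate bugs, not sampling noise — at 5000 frames;
classifier-recovery checks run 100 seeded replicates at 2000 frames. The
packaged demo roster (`make_demo_dataset()`) uses 400-frame trajectories
of a 135-atom complex (the 128-residue chain plus a 6-atom pseudo-
nucleotide donating a hydrogen bond, so the energetic and H-bond analyses
have non-trivial signal) with mode variances 0.04/0.012 nm² and
4 × 10⁻⁴ nm² residual — Ångström-scale fluctuations and sub-2 Å RMSD, the
regime of a stable complex.

## Degenerate and edge inputs

Empty selections are errors everywhere (no analysis here is meaningful on
zero atoms). Covariance needs ≥ 2 frames; superposition needs ≥ 3
non-collinear atoms; active-site distances require single-atom selections.
Candidate H-bond donors without bonded hydrogens are skipped (with a
warning in direct calls; silently in per-frame censuses where "donor" is
just "group member"). A donor cannot accept from itself. Trajectory/
structure atom-count mismatches report both counts. In the pipeline, one
failing system is marked `failed` in the report and skipped, rather than
aborting the whole run.

## Known limitations

* σ compares directions only; a mode whose direction is conserved but
  whose amplitude collapses will still score high (the eigenvalue spectrum
  is reported alongside for exactly this reason).
* The maximize sign policy makes each σ the better of two orientations;
  when comparing against published values computed with a fixed unknown
  sign convention, use `sign_policy = "off"` and inspect both σ and 1 − σ.
* Near-degenerate eigenvalues make the individual-PC comparison
  ill-posed, as discussed above; subspace-overlap metrics would be the
  robust alternative and are deliberately out of scope.
* Per-group energies are short-range only (no reciprocal-space term).
* Supported trajectory formats are multi-model PDB and DCD; structure
  formats PDB and GRO; orthorhombic boxes only.
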