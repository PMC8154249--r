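---
title: "Ensemble thermodynamics, variational weighting and the interacting-solution SAXS model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble thermodynamics, variational weighting and the interacting-solution SAXS model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbwsas)
```

This vignette is the package's own account of the model it implements, of
the parameters that matter, and of the numerical and design choices made
where the design was genuinely open. It states no empirical result that the
test-suite and `scripts/acceptance.R` do not themselves compute.

## The model

### Populations from mass action

The ensemble is a fixed library of $N$ conformers; conformer $i$ is a
multimer of $m_i$ identical chains. The monomer population weight $w_i$ is
the fraction of protein chains residing in conformer $i$. Equating the
per-chain chemical potentials of an ideal solution, with the molarity of
the $i$-multimer $C_i = (c/M_1)(w_i/m_i)$, gives

$$ w_i \;=\; A_i\,w_1^{\,m_i}, \qquad
   A_i \;=\; m_i\,(c/M_1)^{m_i-1}\,e^{-m_i\,\Delta G^\circ_{i,1}/RT}, $$

relative to a reference conformer ($i=1$) that the package requires to be a
monomer — that choice makes $A_1 = 1$ and turns the normalization
$\sum_i w_i = 1$ into a polynomial of degree $\gamma=\max_i m_i$ in $w_1$
with exactly one root in $(0,1]$. Although $\gamma \le 4$ (tetramers) would
admit closed-form solutions, the root is found by bracketed Brent iteration
(`stats::uniroot`, tolerance near machine precision, residual
renormalization to $|\sum w - 1| < 10^{-12}$), which is equally exact and
does not break for future $\gamma > 4$.

Temperature enters through Gibbs–Helmholtz with constant $\Delta C_p$,
parameterized by the dimensionless $dH = \Delta H^\circ/RT_0$,
$dS = \Delta S^\circ/R$, $dC_p = \Delta C_p/R$ at $T_0 = 298.15$ K:

$$ \frac{\Delta G^\circ(T)}{RT} = dH\,\frac{T_0}{T} - dS
   + dC_p\!\left[\frac{T-T_0}{T} - \ln\frac{T}{T_0}\right]. $$

Concentration enters through $c(T)$, the nominal w/v concentration scaled
by the thermal expansion of water (Kell equation of state), so that a
sample prepared at $T_0$ is described consistently at every measurement
temperature.

### Variational Bayesian weighting

Weights inside a class of conformers (same $m$) are only weakly constrained
by one curve, so they are treated with a Dirichlet posterior per class,
$\boldsymbol\alpha_m = \alpha_{m,0}\langle \mathbf W_m\rangle$: the mean is
pinned to the thermodynamic prediction and the scalar concentration
$\alpha_{m,0}$ expresses how sharply the curve constrains the class. With
the unbiased prior $\alpha_j = 1/2$ (mean $1/N_m$, variance
$2N_m^{-2}(N_m-1)/(N_m+2)$), the per-curve functional is the negative
evidence bound

$$ L_c = \frac{N_{c,q}}{2}\,\mathrm E\!\left[\chi_c^2\right]
  + \sum_m \mathrm{KL}\!\left(\mathrm{Dir}(\alpha_{m,0}\langle \mathbf W_m\rangle)
   \,\|\, \mathrm{Dir}(1/2)\right). $$

Because the model intensity is linear in $\mathbf W_m$, the posterior
expectation of $\chi^2$ is the $\chi^2$ at the means plus a covariance
correction assembled from the Dirichlet pair moments
$\mathrm E[W_jW_k] = (\alpha_{m,0}\langle W_j\rangle\langle W_k\rangle +
\delta_{jk}\langle W_j\rangle)/(\alpha_{m,0}+1)$; the KL term carries the
digamma functions. Both $\alpha_{m,0}$-dependent pieces separate by class
into $D_m/(\alpha_{m,0}+1) + \mathrm{KL}_m(\alpha_{m,0})$, so the optimal
concentrations are profiled out by cheap one-dimensional minimizations in
$\log\alpha_{m,0}$ at every merit evaluation — they never inflate the
global search space. A finite-difference test against the analytic
$\alpha_{m,0}$-gradient guards this algebra.

### The forward model

$$ I(q) = n_0\Big[\sum_m \frac{\omega_m}{m}\sum_j W_{m,j}
   \langle|F_{m,j}(q)|^2\rangle\Big]\,S_M(q) + B $$

in absolute units (cm$^{-1}$): each multimer enters with its number
concentration $n_0\,\omega_m W_{m,j}/m$. There is deliberately no free
intensity scale — absolute calibration is what makes $n_0$, and hence the
oligomer populations, quantitative. $B$ is a flat incoherent background,
bounded tightly around zero.

Form factors are orientationally averaged Debye double sums over effective
scatterers: Cromer–Mann X-ray atomic factors minus displaced-solvent
Gaussian dummy terms (Fraser-style volumes), plus an optional first
hydration shell sampled on the solvent-accessible surface whose excess
amplitude is proportional to $d_h - 1$, the shell density relative to bulk
water ($d_h$ restricted to $[0.95, 1.05]$; $d_h = 1$ is exactly no shell).
Shell points are pooled per residue to keep the Debye sums tractable; a
`residue` granularity pools the protein atoms too (documented as accurate
to a few percent for $q \lesssim 0.25$ Å$^{-1}$ on the test fixtures).

The structure factor is a single effective-particle description:
Percus–Yevick hard spheres perturbed in the random phase approximation,
$S^{-1} = S_0^{-1} + n\,\tilde u(q)/k_BT$, with the pair potential outside
the hard core at $2R$ the sum of a DLVO screened-Coulomb Yukawa (strength
from $Z$, $\varepsilon_r(T)$, $\kappa_D$, with the $(1+\kappa_D R)^{-2}$
contact correction) and an attractive Yukawa with contact value $-J$ and
range $d$; $\tilde u$ is the analytic Fourier transform of the truncated
potentials. Anisometry is handled by the decoupling approximation,
$S_M = 1 + \beta_{\mathrm{ell}}(q)(S-1)$, with
$\beta_{\mathrm{ell}} = |\langle F_{\mathrm{ell}}\rangle|^2 /
\langle|F_{\mathrm{ell}}|^2\rangle$ for a biaxial ellipsoid of anisometry
$\nu$ whose volume is $(4/3)\pi R_1^3\langle m\rangle$. Effective
parameters scale with the average aggregation number: $n = n_0\langle
m^{-1}\rangle$, $Z = Z_1\langle m\rangle$ (charge proportional to chain
count), $J = J_1\langle m\rangle^{2/3}$ (surface scaling), $R = R_1\langle
m\rangle^{1/3}$ (volume scaling).

### Merit, regularization, optimization, errors

Several curves of one protein are analyzed together:
$\Lambda = \sum_c L_c$ with the thermodynamic parameters (and $d_h$) shared
and $\alpha_{m,0}$, $J_1$, $d$, $R_1$, $\nu$, $B$ allowed to be
curve-specific. To prevent unphysical oscillations of the curve-specific
parameters between neighboring conditions, the merit is
$F = \Lambda + \alpha_V V$ with
$V = \sum_k \sum_{\langle c,c'\rangle} [(X_{k,c} - X_{k,c'})/s_k]^2$ over
$k \in \{J_1, d, R_1, \nu\}$; neighbors are consecutive curves after
lexicographic ordering by (concentration, temperature) and $s_k$ is the
mid-range of each parameter's bound box. $\alpha_V$ is auto-tuned downward
at every annealing stage to keep $\alpha_V V$ below about 10 % of $F$.

$F$ is minimized by simulated annealing over box-scaled coordinates
(log-scale for the positive $J_1$, $d$, $R_1$, $\nu$) hybridized with
Nelder–Mead simplex polish. Three implementation choices proved decisive
and are part of the package's design:

* **$(\Delta G^\circ_{T_0}, \Delta H^\circ)$ coordinates.** Enthalpy and
  entropy compensate almost exactly at fixed $\Delta G^\circ$; fitting
  $dG_0 = dH - dS$ (pinned by the populations at $T_0$) and $dH$ (pinned
  only by the temperature trend) instead of $(dH, dS)$ aligns that flat
  valley with the coordinate axes, and the recovered $dS$ is $dH - dG_0$.
* **Staged, block-coordinate warm start and polish with basin hopping.**
  Before the joint anneal, the thermodynamic block (plus background) is
  first fitted against the high-$q$ window ($q \ge 0.12$ Å$^{-1}$) with
  the structure factor switched off — populations dominate the curve
  shapes there, interference reshapes low $q$ — and then the
  thermodynamic and interaction blocks are alternately polished by
  Nelder–Mead (each a small, well-conditioned subproblem), from several
  seeded starting points. After the anneal, alternating block/joint
  polish rounds are applied to both the annealing incumbent and the
  warm-start best (the anneal's raw best can sit in a worse basin than
  the warm start), and the winner is refined by basin hopping: a stalled
  incumbent is kicked by a small seeded perturbation and re-polished,
  the best point ever seen winning. A statistical stopping rule ends the
  exploration early when the merit falls below 0.65 × (total number of
  data points), i.e. when the mean reduced chi-square is within ~30 % of
  its noise floor and further basin exploration cannot pay off.
  Restarted simplices escape the collapsed configurations that plain
  Nelder–Mead is prone to in ten or more dimensions.
* **Profiled $\alpha_{m,0}$** (above), keeping the annealed space to the
  physically meaningful parameters.

Parameter uncertainties come from a parametric bootstrap: every curve point
is resampled from $N(I_{\mathrm{exp}}, \sigma^2)$, the fit is re-polished
from the converged optimum, and the per-parameter standard deviation across
replicates is reported (default $R = 20$ replicates; replicate seeds derive
deterministically from the master seed).

### Ramachandran propensities

Backbone dihedrals are computed per chain with the IUPAC sign convention
(verified against an independent torsion implementation). The Ramachandran
torus is partitioned into eight regions by contouring a backbone-dihedral
density (normalized to max 1) at 0.0005 (allowed) and 0.02 (favored),
subdividing $\varphi \le 0$ into the closed αR band
$-120^\circ \le \psi \le -50^\circ$, the β bands $\psi < -120^\circ$ or
$\psi > 50^\circ$, and a helical bridge $(-50^\circ, 50^\circ]$ assigned to
αR; $\varphi > 0$ is αL, and cells reaching the allowed level only in a
glycine-specific density are labeled `gly`; everything else is `uns`. The
propensity of residue $a$ for region $r$ is the chain-averaged,
ensemble-weighted indicator
$p_a(r) = \sum_i w_i\, m_i^{-1} \sum_g \delta(r_{i,g,a}, r)$, which sums to
1 over regions by construction; its variance is propagated linearly from
the Dirichlet weight covariance. Mutant-minus-WT profiles are filtered to
maximal runs of at least 8 consecutive strictly same-signed changes (a zero
breaks a run; 8 residues ≈ the persistence length of a polypeptide chain);
each kept run is reported as its mean ± sd on all its residues, everything
else as 0.

The packaged density is an analytic mixture of periodic 2-D Gaussians
placed on the canonical β/PPII/αR/αL lobes (plus glycine mirror lobes),
normalized to a maximum of 1. The contour-and-subdivision rules are exact;
the density source is a documented, swappable stand-in for an empirical
high-resolution backbone-dihedral density, which cannot be redistributed
here. Region boundaries therefore differ in detail from any particular
empirical map, but every property the package relies on (total cover,
disjoint labels, the closed-interval band edges, the αR peak at
$(-63^\circ, -43^\circ)$ being favored) is asserted by tests.

## Tunable parameters

| Parameter | Units | Default / bounds | Why |
|---|---|---|---|
| $dH_i, dS_i$ | dimensionless | box $[-20, 20]$ | $\pm 20$ spans $\pm\sim 50$ kJ/mol at $T_0$, generous for conformer free-energy differences near thermal energy |
| $dC_{p,i}$ | dimensionless | frozen at 0 (flag) | one parameter per conformer is rarely supportable at desk scale |
| $R_1$ | Å | $[5, 60]$ | generous around typical monomer radii of gyration |
| $Z_1$ | e | fixed from sequence | computed by Henderson–Hasselbalch at the solution pH, not fitted |
| $J_1$ | kJ/mol | $[10^{-3}, 2000]$, log scale | attraction magnitudes reported for IDPs span decades |
| $d$ | Å | $[0.5, 30]$, log scale | short-range attraction |
| $\nu$ | – | $[0.2, 10]$, log scale | oblate through prolate ellipsoids |
| $B$ | cm$^{-1}$ | $[-0.005, 0.005]$ | absolute calibration leaves only a small residual background |
| $d_h$ | – | 1.0, range $[0.95, 1.05]$ | hydration-shell contrast for unfolded chains is weak and of uncertain sign |
| pH | – | 7.0 | samples in pure water carry no stated pH; configurable |
| pKa table | – | packaged intrinsic values | standard side-chain and terminal pKa at $T_0$; no temperature correction of pKa is applied (the temperature dependence of the electrostatics enters through $\varepsilon_r(T)$ and $\kappa_D(T)$) |

## The synthetic-data generator

`synthetic_spec()` defines the desk-scale study conditions used by the
tests and the acceptance script: 4 conformers (2 monomers, 1 trimer, 1
tetramer; 30-residue poly-alanine chains built at helix
$(-60^\circ,-45^\circ)$, strand $(-120^\circ,130^\circ)$ or seeded-coil
dihedrals with ideal backbone geometry; multimers are rigid copies on a
ring, overlap-checked), 9 curves on the grid $T \in \{25, 37, 45\}$ °C
$\times$ $c \in \{2, 5, 10\}$ g/L matching a typical synchrotron series,
120 $q$-points over 0.022–0.41 Å$^{-1}$ (a typical instrument window), and
noise $\sigma(q) = 0.01\,I(q)$ emulating well-measured synchrotron
statistics. The generating thermodynamic parameters
($dH = (0, 1.5, -8, 2)$, $dS = (0, 1.2, -4.4, 5.97)$) were chosen once so
that the class populations move visibly across the grid (monomer fraction
roughly 0.7–1.0 between 10 and 2 g/L) with free-energy differences of a few
$RT$ — the regime the method targets; the interaction truth
($R_1 = 10$ Å, $Z_1 = -6$, $J_1 = 30$ kJ/mol, $d = 3$ Å, $\nu = 2$,
$B = 5\times 10^{-4}$ cm$^{-1}$, $I_S = 0.02$ M) yields a
repulsion-dominated structure factor with a visible interference peak at
the highest concentration.

With this machinery the blind fit of the default study (11 free model
parameters after profiling, 1080 data points) converges to the noise
floor in roughly 8–10 minutes on one core across the noise realizations
tested; the problem sizes were chosen so that the whole test-suite runs
at desk scale.

What the generator does *not* emulate: real conformer geometry (the toy
multimers are rings of identical chains, not folded interfaces), inter-atom
contrast detail (poly-alanine only), $q$-dependent instrumental smearing,
buffer-subtraction artifacts, and any mismatch between the ensemble and
the solution (the fitted library is exactly the generating library).
Passing the recovery test therefore demonstrates the correctness and
identifiability of the machinery under the stated conditions, not the
biological accuracy of fits to real data.

The desk-scale recovery experiment shares one interaction-parameter set
across the nine curves — the generator's truth is constant over the grid,
and nine times five free interaction parameters would be badly
over-parameterized at this problem size; the per-curve machinery with
adjacency regularization remains available (`interactions = "per_curve"`)
and is exercised by its own tests. $d_h$ is held at the generating value
1.0 in that experiment; it remains a configuration knob of the form-factor
engine.

## Numerical choices

* `sinc` and the sphere amplitude switch to series below $x = 10^{-4}$;
  the Percus–Yevick kernels below $x = 10^{-3}$ — all guard 0/0.
* Truncated-Yukawa Fourier transforms use one complex exponential
  ($\tilde u = 4\pi K\,\mathrm{Im}[e^{-s r_c}/s]/q$, $s = \kappa - iq$),
  verified against adaptive quadrature.
* $\beta_{\mathrm{ell}}$ uses 128-point Gauss–Legendre quadrature in
  $\cos\theta$ by default (nodes memoized); the fitting loop uses 64
  nodes, which agrees with a $10^4$-node reference to $10^{-15}$ over the
  instrument $q$-window.
* $|\Delta G^\circ/RT|$ is clipped at 500 (with a warning) before
  exponentiation; the RPA raises an error naming the offending parameters
  whenever $S(q) \le 0$, and the Percus–Yevick branch requires
  $\eta < 0.5$.
* Dihedrals of residues with missing backbone atoms are `NA`, never
  zero-filled; propensity calculations drop such chains per residue and
  renormalize.
* Contour ties resolve upward ($\ge$); the αR band edges at $-120^\circ$
  and $-50^\circ$ are closed; runs in the propensity filter break on
  exact zeros.
* Degenerate cases: a single-conformer class has a point-mass posterior
  (no KL term, zero covariance); a one-member ensemble fits only the
  interaction block; $\omega_m = 0$ classes get uniform within-class
  weights with a flag.

## Known limitations

* The effective structure factor is a one-component approximation: all
  conformers share one $S_M(q)$ built from mixture-averaged parameters;
  no per-class partial structure factors.
* RPA is perturbative; strongly coupled systems (large $|Z|$ at low ionic
  strength, deep attractions) will hit the $S \le 0$ error path before
  the physics degrades gracefully.
* The hydration-shell model is a coarse surface-shell dummy-atom scheme;
  exact parity with any particular published implementation is a
  non-goal.
* Simulated annealing is stochastic: the merit landscape has local minima
  and reproducibility is guaranteed only through the recorded seed.
  The shipped schedule is sized for the desk-scale problem; larger
  ensembles need more annealing and proportionally more time.
* The analytic Ramachandran density is a stand-in (above); propensity
  *differences* between weight sets are robust to its details, absolute
  region occupancies less so.
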