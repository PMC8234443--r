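---
title: "Methods: pulsatile Casson hybrid-nanofluid flow in a constricted channel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pulsatile Casson hybrid-nanofluid flow in a constricted channel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stenoflow)
```

## The physical model

`stenoflow` simulates two-dimensional, unsteady, incompressible flow of a
Casson (yield-stress) nanofluid through a plane channel of unit height
carrying one pair of symmetric cosine-shaped wall constrictions — a
standard idealization of an artery with stenosis. The suspended phase is
either a single nanoparticle species (Cu in water, a mono nanofluid) or two
species (Cu and single-wall carbon nanotubes, a hybrid nanofluid). The
momentum balance includes three body-force terms beyond viscous stress:

* **Lorentz drag** from a uniform transverse magnetic field, scaled by the
  Hartmann number $M$;
* **Darcy drag** from a saturated porous matrix, entering as a linear
  sink $Re\,Da^2\,u$;
* the **Casson rheology**, which in non-dimensional form multiplies every
  viscous term by $(1 + 1/\beta)$, $\beta$ being the Casson parameter
  (Newtonian flow is the limit $1/\beta = 0$, available as `beta = Inf`).

Heat transport carries a Rosseland radiative augmentation of the
wall-normal diffusivity (radiation parameter $Rd$), and solute transport is
coupled to the temperature field through the Soret effect
($Sr$): a thermal-gradient-driven mass flux. Advection-to-diffusion ratios
are set by the Peclet numbers $Pe_h = Pr\,Re$ and $Pe_m = Sc\,Re$; the
pulsation is a sinusoidal flow-rate modulation $1 + \epsilon\sin 2\pi t$
with period one in cycle time and Strouhal number $St$ scaling the time
derivative.

### Effective mixture properties

The five dimensionless coefficients that scale the governing equations are
algebraic mixture rules evaluated once per run
(`mixture_coefficients()`):

* density $c_1$ and volumetric heat capacity $c_4$: two-stage volumetric
  weighting (species 1 dispersed first, then species 2);
* viscosity $c_2$: Brinkman rule $(1-\phi_1)^{-2.5}(1-\phi_2)^{-2.5}$;
* momentum coefficient $c_3 = c_1/c_2$;
* conductivity $c_5$: a two-step Maxwell chain — species 1 in the base
  fluid, then species 2 in that mono nanofluid.

Two implementation notes. First, the Maxwell factors carry $2\phi$ in
**both** numerator and denominator — a variant of the classical
Maxwell–Garnett form, whose denominator carries $\phi$; the textbook
form is available via `maxwell_classic = TRUE` for comparison. Second, the
two-stage $c_1$, $c_4$ rules are *not* symmetric under exchanging the
species: the residual is exactly
$\phi_1\phi_2(\rho_{s2}-\rho_{s1})/\rho_f$, because stage-one particles
are diluted by the stage-two loading. The property tests assert this
exact asymmetry.

## Formulation and discretization

Pressure is eliminated with the stream-function/vorticity formulation
($u = \psi_y$, $v = -\psi_x$, $\omega = v_x - u_y$), and the constricted
strip is mapped onto a rectangle by $\xi = x$,
$\eta = (y - y_1(x))/(y_2(x) - y_1(x))$. The mapping's metric
coefficients $P$ (wall curvature), $Q$ (wall slope), $R$ (gap slope) and
$D$ (inverse gap) are closed-form in the cosine bump shape and evaluated
once per grid (`build_metrics()`); the bump is $C^1$ at its edges and the
one-sided second derivative is used there without smoothing. A useful
exact identity, $Q = R\eta + y_1' D$, is asserted at machine precision in
the tests.

The default grid covers $\xi \in [-10, 10]$, $\eta \in [0, 1]$ with
$401 \times 51$ nodes ($\Delta\xi = 0.05$, $\Delta\eta = 0.02$, i.e.
$400\times50$ cells), constriction height 0.35 on each wall and bump
half-length $x_0 = 1$ ($x_0$ is not fixed by the model description; the
value matches the span the flow geometry implies and is configurable).

### Time stepping

Each step advances, in order: (1) boundary values at the new time
(pulsating inlet, walls, zero-gradient outlet); (2) vorticity transport;
(3) the stream-function Poisson solve; (4) the wall-vorticity closure;
(5) velocity recovery; (6) temperature; (7) concentration with the
new-level temperature in the Soret source.

The three transport equations share one ADI kernel: a Douglas–Gunn
approximate factorization of backward Euler in delta (increment) form.
Both sweep operators are tridiagonal — a $\xi$-implicit line solve then an
$\eta$-implicit line solve, each by the Thomas algorithm — and both
advection directions are implicit in the increment; the mixed
$\xi\eta$ derivative and the metric first-order terms are explicit at the
old level. This choice is deliberate: a Peaceman–Rachford splitting, which
treats each direction's advection explicitly in the other half-step, is
unstable here because the wall-normal advective CFL of the explicit half
exceeds unity on coarse grids. The scheme is first order in time and
second order in space (central differences). A deferred-correction upwind
option (`upwind = TRUE`: first-order upwind implicit operators, central
fluxes kept in the explicit right-hand side) exists as a robustness escape
hatch for very coarse grids; it is off by default.

The linear porous sink is kept implicit in the diagonal. Its sign is the
derivation-consistent damping sign $-Re\,Da^2\,\omega$ (taking the curl of
the momentum equations turns a velocity drag into vorticity damping); the
opposite sign, which appears in some printed forms of the vorticity
equation but would make the porous matrix a vorticity *source*, is
available via `porous_vorticity_sign = +1` for literal replication.

### Poisson solve and wall closure

The mapped Poisson equation $L[\psi] = -\omega$ is solved by successive
$\eta$-line over-relaxation: each axial sweep solves every wall-normal
line by the Thomas algorithm, Gauss–Seidel in $\xi$, with the mixed
derivative lagged. The relaxation factor defaults to the model-problem
optimum $2/(1+\sqrt{1-\mu^2})$ estimated from the grid (plain
Gauss–Seidel needs roughly 100 sweeps per decade of residual on the
401-node axial grid; the estimated factor needs about 7); any fixed factor
can be supplied, and a non-converged over-relaxed iteration falls back to
Gauss–Seidel, which is slower but monotone. Convergence is declared when
the maximum residual of the discrete equation falls below `poisson_tol`
(default $10^{-6}$; the residual is checked after every sweep and the
tolerance is enforced at every accepted time step). Within the march the
solve is warm-started from the linear extrapolation
$2\psi^{l} - \psi^{l-1}$, which keeps the per-step sweep count near ten.

No-slip walls close the vorticity with the one-sided second-order
three-point formula that uses $\psi_\eta = 0$ at the wall,
$\psi''_w \approx (8\psi_2 - \psi_3 - 7\psi_w)/(2\Delta\eta^2)$, scaled by
$-(Q^2 + D^2)$. Wall values of $\psi$ are 0 (lower) and the instantaneous
flux (upper) — the stream-function jump across the channel *is* the volume
flux, so these Dirichlet values enforce mass conservation identically.
Temperature and concentration are held at 1 on the lower (heated,
solute-rich) wall and 0 on the upper wall.

### Inlet and outlet

The inlet carries the steady fully developed profile of the flow: the
closed-form solution of $g\,u'' - M_1^2 u = G$ with
$g = c_2(1 + 1/\beta)$ and $M_1^2 = M^2 + c_1 Re^2 Da^2$ — a hyperbolic
Hartmann-type profile that degenerates to a parabola as $M_1 \to 0$ (a
series branch below $M_1/\sqrt{g} = 10^{-2}$ avoids catastrophic
cancellation; both branches are checked against an independent
fourth-order dense boundary-value solve). The profile, its stream
function and its vorticity are multiplied by the pulsation factor each
step.

Two normalizations of the pressure-gradient constant are provided:

* `paper_literal` (default): $G = -2$, reproducing the classical cubic
  stream function $\psi = \tfrac{1}{6g}(3\eta^2 - 2\eta^3)$ in the
  $M_1 = 0$ limit. The inlet flux is then $1/(6g) \approx 0.05$ and
  *depends on* $\beta$, the volume fractions and the drag scale $M_1$.
* `unit_flux`: $G$ rescaled so the steady mean inlet speed is 1.

The default matters more than it may look. With the literal normalization
the mean speed is about 0.05, the effective (advective) Reynolds number is
of order 20, and the pulsatile solution locks onto a periodic cycle to
near machine precision within six cycles — the regime in which a central
difference scheme on a $400\times50$ grid is comfortable, and the regime in
which the package's periodicity and conservation checks are meaningful. At
unit mean speed the effective Reynolds number is two orders of magnitude
larger; the constricted flow then sheds vortices, is aperiodic from cycle
to cycle, and eventually breaks the wall layers on coarse grids. A
consequence worth stating explicitly: because the literal flux falls
roughly as $1/M_1^2$, the wall shear stress *decreases* as the Hartmann
or Darcy number grows through the inlet flux, while at fixed flux the
profile blunting would make it *increase* through the wall gradient. The
two responses cannot be separated by any single normalization; the
sweep-trend tests record which comparisons follow which behaviour.

Inlet temperature and concentration take the conduction profile
$1 - \eta$, consistent with the wall values (the model description leaves
them unspecified). The outlet applies a zero axial gradient to all four
fields (copy of the penultimate column). In the manufactured-solution
harness this outflow condition is the one deliberate departure from the
manufactured field: it induces a local boundary layer decaying like
$e^{-\pi(\xi_{max}-\xi)}$, so convergence orders are measured on
$\xi \le \xi_{max} - 2.5$, where its contribution is below the finest
grid's truncation error.

## Diagnostics

Wall series per snapshot: wall shear stress on both walls (wall vorticity
scaled by the Casson viscous factor $(1/(Re\,c_3))(1+1/\beta)$, signed so
forward flow gives positive shear on both walls), skin friction
$C_f = -\tfrac{1}{u_{ref}^2}\tfrac{1}{Re\,c_3}(1+1/\beta)D\,u_\eta|_{\eta=0}$,
Nusselt number $Nu = -c_5(1+Rd)\,\theta_\eta|_{\eta=0}$ and Sherwood
number $Sh = -D\,\varphi_\eta|_{\eta=0}$, all with one-sided second-order
wall gradients (exact for linear profiles). The reference speed in $C_f$
defaults to the *steady* mean inlet speed: the instantaneous mean speed
vanishes at the zero-flow phase $t = 0.75$ and would leave $C_f$
undefined there. Station profiles are extracted at the nearest grid
column ($x = 0$, the throat, and $x = 2$, the lee of the constriction,
are exact nodes on the default grid).

Cycle periodicity is measured as the maximum relative change of the
upper-wall shear curve at the peak-flow phase ($t = 0.25$) between
consecutive cycles; the zero-flow phase is excluded because its
near-zero shear makes a relative metric ill-posed. Mass conservation is
measured as the axial uniformity of the stream-function jump (exact by
construction of the wall values) and, informationally, of the
$\eta$-quadrature of $u$ — the latter carries an $O(\Delta\eta^2)$
trapezoidal profile-integration bias of order 2% at the throat on the
reduced grid, a quadrature artifact rather than a solver defect.

## Problem sizes and presets

Two presets are built in. The `full` preset is the fidelity
configuration: $401\times51$ nodes, $\Delta t = 5\times10^{-5}$, six pulse
cycles, snapshots at cycle phases $0, 0.25, 0.5, 0.75$ of the final cycle.
The `acceptance` preset ($201\times26$ nodes, $\Delta t = 5\times10^{-4}$,
three cycles) is the desk-scale configuration used by the test suite and
the sweep harness; at the default (literal) inlet normalization the
solution is periodic to $10^{-9}$ already within three cycles, so the
reduced preset loses resolution, not cycle convergence. Steady runs
(`eps = 0`) may stop early once the per-step relative field change falls
below `steady_tol`.

## What the baseline conditions do and do not emulate

The defaults ($Re = 800$, $St = 0.02$, $M = 5$, $Da = 0.002$,
$\beta = 0.5$, $Rd = 0.2$, $Pe_h = 490$, $Pe_m = 420$, $Sr = 0.8$,
$\phi_1 = \phi_2 = 0.03$, $\epsilon = 1$, constriction height 0.35) are
the baseline study conditions, and all tests run at them or at the
standard one-factor variations. They represent an idealized vessel: 2-D
plane geometry rather than an axisymmetric tube, rigid walls, a
single-harmonic flow-rate waveform rather than a physiological pulse,
Boussinesq-free (no buoyancy), homogeneous particle loading, and a
yield-stress rheology linearized into the constant $(1+1/\beta)$ factor.
Passing the suite therefore demonstrates the numerics (stable marching,
second-order operators, exact degenerate limits, periodic locking,
monotone parameter responses where the model implies them) — not
quantitative hemodynamic prediction for real arteries.

## Known limitations

* First-order temporal accuracy (by construction of the factored scheme);
  the time step is small enough that spatial error dominates at both
  presets.
* Central advection needs the gently convective regime of the literal
  inlet normalization; at unit flux the coarse-grid solution is aperiodic
  and can break down. The upwind option trades accuracy for robustness
  there.
* The zero-gradient outflow is first-order near the outlet and assumes no
  inflow there; strong recirculation reaching the outlet invalidates it.
* The wall-vorticity closure couples explicitly (one pass per step); no
  inner $\psi$–$\omega$ iteration is performed.
* Quantities tied to the inlet normalization (absolute WSS, $C_f$ scale)
  are only meaningful relative to the chosen mode.
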