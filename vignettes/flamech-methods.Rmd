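---
title: "Models and methods behind flamech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flamech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

flamech studies how the spatial partitioning of a bacterial flagellum into
two flagellins — FlaA forming a short proximal (motor-side) segment, FlaB
the remainder — shapes the filament's mechanical stability against screw
formation, the wrapping instability used by polarly flagellated bacteria to
back out of traps.  The package has two computational halves: a discrete
elastic-filament simulator with resistive-force-theory hydrodynamics, and a
3D swimming-trajectory analysis (holographic localization, track linking,
run–tumble statistics) validated end to end with synthetic data generators.
This vignette records the models, the parameter choices, and the reasoning
behind the numerical design, in that order.

## The filament model

### Geometry and elasticity

Each flagellin is characterized by the equilibrium helix it polymerizes
into: radius $R$ and pitch $P$, both in µm, plus a handedness.  FlaA forms
narrow elongated helices ($R = 0.175$, $P = 1.18$), FlaB wider ones
($R = 0.315$, $P = 1.91$); both native states are left-handed.  A helix maps
to a constant rotational strain vector
$\Omega_0 = (\kappa, 0, \sigma\tau)$ with $p = P/2\pi$,
$\kappa = R/(R^2+p^2)$, $\tau = p/(R^2+p^2)$, and $\sigma = -1$ for
left-handed helices (the sign convention of the package: left-handedness is
negative rest torsion).

The filament of contour length $L_c = 6$ µm is discretized into $N$
segments of rest length $h = L_c/N$ ($N = 40$ at the reference resolution),
carrying beads $r_0 \dots r_N$ and one orthonormal material frame per
segment, stored as a unit quaternion.  The strain of segment $i$ is the
rotation vector taking frame $i-1$ to frame $i$, divided by $h$.  Deviations
from the active rest strain contribute the bend/twist energy

$$ F_K = \sum_i h\left[\frac{A}{2}\left((\Omega_1-\Omega_{0,1})^2 +
(\Omega_2-\Omega_{0,2})^2\right) + \frac{C}{2}(\Omega_3-\Omega_{0,3})^2
\right], $$

with bending rigidity $A$ and torsional rigidity $C$, both defaulting to
3.5 pN µm² and shared by all polymorphic states and both flagellins.  A
harmonic bond spring $\frac{K}{2}\sum_i (\lVert r_{i+1}-r_i\rVert - h)^2/h$
keeps the bond lengths within 0.1% of rest; it is implemented as a penalty
on the deviation of local segment length from rest length because the
stated purpose of the stretching term is length conservation, and a literal
penalty on the squared tangent would penalize the rest state itself.  The
discretization adds a shear-alignment penalty
$\frac{G}{2h}(\xi_1^2+\xi_2^2)$, $\xi = R_i^\top(r_{i+1}-r_i)$, that ties
each frame's third director to its bond to within about $10^{-3}$ rad;
$G = 0.85\,K$ is chosen so this slaved constraint never becomes the
stiffest mode of the system.

### Polymorphism

FlaB has a second equilibrium state.  Its geometry is not known for this
organism, so the package defaults to a right-handed curly form
($R = 0.14$ µm, $P = 1.0$ µm, the classic curly-I geometry of enteric
flagella), configurable through `flaB()`.  After every accepted integration
step each segment's local quadratic energy density is evaluated against all
of its flagellin's rest states and the active index set to the minimizer;
exact ties keep the current index, so the relabeling is deterministic and
never increases the elastic energy.  The relabeling is applied between
steps rather than inside Runge–Kutta stages because state switching is a
discrete relabeling, not a smooth force.  The first segment is exempt: its
proximal junction is the hook (below), whose strain does not reflect the
filament's internal deformation.

### The base boundary condition (motor and hook)

The base bead is clamped at the origin — the motor plane — and an anchored
base frame ("tripod") spins about the lab z axis (the motor axis) under the
applied motor torque $M$.  The flexible hook joining motor and filament is
folded into the proximal junction: the relative rotation between the base
frame and the first segment frame is decomposed into swing and twist.
Twist about the filament axis is transmitted with the full torsional
rigidity $C$ (hooks are torsionally stiff — that is how they transmit motor
rotation), while the tilt carries only a hook bending stiffness of
0.6 pN µm/rad by default, the ratio of published hook bending rigidity
(~3.6 × 10⁻² pN µm²) to hook length (~60 nm).  Tilt beyond ~120° runs into
a soft quadratic barrier representing the cell pole the hook emerges from;
besides being physical (the filament cannot fold through the cell body),
the barrier keeps the swing–twist decomposition away from its 180°
coordinate singularity.  The motor torque acts about the instantaneous
axis of the proximal segment — the hook transmits full rotation whatever
the filament's tilt, as in driven-tripod filament models — because with
the alternative convention (torque about the fixed lab axis) the twist
injection decays with the cosine of the hook tilt and the wrapping
instability never completes at experimentally relevant torques; the
lab-axis variant remains available through `options(flamech.motorAxis)`.
A positive torque drives the rotation sense that compresses the helix and
twists FlaB toward its curly basin — the screw-forming (CW, pulling)
sense; negative torque is the opposite (pushing) sense.

### Hydrodynamics

The fluid acts through local resistive-force-theory drag with
per-unit-length coefficients

$$ \gamma_\perp = \frac{4\pi\eta}{\ln(0.09\,l/r_f)+1/2}, \qquad
   \gamma_\parallel = \frac{2\pi\eta}{\ln(0.09\,l/r_f)}, \qquad
   \gamma_r = 4\pi\eta r_f^2, $$

where $l = \sqrt{4\pi^2R^2+P^2}$ is the contour length of one helical turn
and $r_f = 0.01$ µm the filament radius.  The coefficients are evaluated
per segment from the local flagellin's native helix geometry, so a
composite filament feels FlaA drag proximally and FlaB drag distally.  The
unit system is µm, s, pN throughout; water is $\eta = 10^{-3}$ pN s/µm²
and elevated-viscosity media are modeled by scaling $\eta$.

### Time integration

The dynamics are overdamped: bead velocities follow from the instantaneous
balance of elastic forces against the anisotropic drag (each bead carries
the half-segments adjacent to it), frames spin against $\gamma_r h$ about
their axis and against a slaved pivot drag $\gamma_\perp h^3/6$
transversally, and the system is integrated with an embedded Cash–Karp
RK4(5) pair (relative tolerance $10^{-6}$, absolute $10^{-9}$).  The
elastic forces and torques are exact analytic gradients of the discrete
energy — verified in the test suite against central differences and by the
vanishing of total internal force and torque — so zero-torque relaxation
dissipates energy monotonically.  Quaternions are renormalized after every
accepted step (the frame re-orthonormalization of this representation).

Two stiff mode families bound the step size: axial twist diffusion
(rate $\sim 4C/(\gamma_r h^2)$, a physical consequence of the tiny spin
drag) and bond stretching ($\sim 4K/(\gamma_\parallel h^2)$).  The spring
constant is therefore calibrated per run: $K$ starts from an affine
estimate in the motor torque and, should the 0.1% bond-strain invariant
still trip (the strongly buckled states above the screw threshold develop
tension spikes), the run restarts with a stiffer spring.  Runs that violate
the invariant after the retry ladder abort with a diagnostic rather than
continue silently.

### Screw classification and the analysis pipeline

A run counts as screw formation when the free end sits below the motor
plane ($z < 0$) and stays there for the final 10% of the simulated window;
the persistence requirement rejects transient dips of the rotating tip.
Threshold searches exploit the verified monotonicity of this indicator in
torque: the grid is bisected rather than scanned, refined between
bracketing grid points to the requested resolution (0.25 pN µm by
default), and clearly wrapped runs may terminate early (tip persistently
below an exit depth), because wrapped configurations do not unwrap at
fixed torque.  The force–torque efficiency $\beta_{\rm eff}$ is the
least-squares slope through the origin of the mean axial force against
torque over pre-screw runs; the mean force is taken over exactly ten base
rotations to average out the oscillation tied to the motor's position
relative to the filament axis.  The linear regime is the window of
torques well below threshold — at higher pre-screw torques the helix
compresses noticeably and thrust grows sublinearly.

### Simulated problem sizes

The reference resolution is $N = 40$ segments.  The acceptance analyses
run the torque bisections at $N = 24$, the composition scan at $N = 25$
(where 4% composition steps are commensurate with the segment grid) and
the reversed-order scan at $N = 20$; a resolution-convergence check in the
test suite verifies that screw thresholds change only weakly with the
segment count, which is what makes the reduced resolutions representative
of the reference one.  The bond-strain invariant is checked at the
reference resolution.

## The tracking pipeline

### Holography

Holograms are normalized by the per-pixel temporal median of the movie (a
robust background that one transient cell or a single-frame outlier cannot
contaminate) and refocused by angular-spectrum back-propagation, the
standard numerical realization of Rayleigh–Sommerfeld refocusing:
$H(q; z) = \exp[i z(\sqrt{k^2 - q^2} - k)]$ with the axial carrier removed
and evanescent components suppressed.  A raised-cosine spatial bandpass
retaining features between 2 and 30 px is applied during reconstruction.
Localization applies a Sobel-type axial-gradient filter: with the carrier
removed, the phase of the scattered field rotates fastest at focus, so the
magnitude of the complex axial derivative (central differences with 3×3
lateral binomial smoothing) peaks at the particle, and sub-voxel positions
come from quadratic interpolation.  The detection threshold defaults to
mean + 5 sd of the response volume with a relative floor at 20% of the
strongest response, and close detections are pruned cylindrically (by
lateral distance) because residual axial sidelobes of a scatterer share
its lateral position.  Tracks are linked greedily frame to frame with a
displacement gate and bridging of short gaps, with interpolated rows
flagged.

### Run–tumble statistics

Tracks are smoothed with cubic smoothing splines at two levels, both set
by the track's noise scales rather than by eye.  White localization noise
of standard deviation $\sigma$ and translational Brownian motion of
diffusivity $D$, low-passed at cutoff $f_c$, leave an angular-speed noise
of variance

$$ (2\pi)^4\,\frac{2\sigma^2 f_c^5}{5 f_N v^2} \;+\;
   (2\pi)^2\,\frac{8 D f_c^3}{3 v^2}, $$

so the direction spline's cutoff is chosen to keep that floor at a third
of the 5°/s reorientation threshold; velocity and speed use a lighter
spline (localization term only) because the first derivative tolerates a
higher cutoff and heavier smoothing would bias speeds low through turn
rounding.  The angular-speed series is averaged over ~0.1 s before the
peak search so that sample-scale ripples of the spline derivative never
register as separate maxima; physical reorientations are much wider.
Events are local maxima above 5°/s separated by at least 0.5 s (twice the
±0.25 s angle window, so one turn is never counted twice), and the turning
angle compares the swimming direction 0.25 s before and after the peak.
Runs are the intervals between events of a track, counted only for tracks
with at least two events.  Motility classification thresholds the
short-time log-log MSD slope at 1.5 and the MSD at 2 s at 25 µm²,
defaults calibrated on the synthetic generator for ≥95% accuracy (the
original analysis does not print its values).

A consequence of noise-driven smoothing is a temporal resolution floor:
events closer than roughly a second merge, so measured rates
underestimate true rates at high tumbling frequencies.  At the reference
condition (0.5 s⁻¹) the closed-loop bias is well inside the validation
tolerance; the generator-based tests quantify it.

## The synthetic generators

`genRunTumbleTracks()` emulates the acquisition the analysis assumes:
50 Hz sampling for 60 s, lateral/axial localization noise of 0.5/1 µm,
piecewise-constant headings with exponential run durations, a two-component
swimming-speed mixture (a slow population near 5 µm/s and a fast one near
60 µm/s, echoing the bimodal populations seen in the organism), rotational
diffusion of the heading (0.05 rad²/s) and translational Brownian motion
(0.2 µm²/s).  The turning-angle law mixes a broad component over [0°, 180°]
with a near-reversal component at 160° ± 15° — a modeling choice to emulate
wide observed angle distributions, not a measured law.  Ground-truth event
logs make closed-loop recovery tests possible: the generator is the oracle
for speed, tumble-rate and classification accuracy checks.

What the generator deliberately does not emulate: cell body wobble and
flagellar unbundling kinematics within a turn, hydrodynamic wall effects,
cell-to-cell speed correlations, or the real optical point-spread function
of a cell (the hologram generator uses ideal point scatterers).  Passing
the closed-loop tests therefore demonstrates the internal consistency of
the pipeline under the stated noise model, not its accuracy on any
particular microscope.

`genPointHologram()` is the exact forward counterpart of the
reconstruction: point scatterers propagated to the detector with the
conjugate angular-spectrum kernel, recorded as $|1 + aE_s|^2$ plus
Gaussian noise, so localization accuracy can be measured against known
positions.

## Design decisions that were genuinely open

* **Hook representation.**  With the proximal junction carrying the full
  filament bending stiffness no wrapping occurs at experimentally relevant
  torques; the hook's compliance is what permits the filament to reorient
  at the base.  The swing–twist junction with literature-derived bending
  stiffness was chosen over an extra hook segment to keep the boundary
  condition local, and its pole barrier makes large-tilt states both
  physical and integrable.
* **Motor torque axis.**  Torque is applied about the instantaneous
  proximal-segment axis (see above); the fixed-lab-axis variant is kept
  as an option but stalls against the pole barrier at large hook tilts.
* **Stretching constant.**  $K$ is not a physical measurement but the
  enforcement of the 0.1% length-conservation statement; it is calibrated
  automatically per torque rather than fixed, because the tension scale
  varies by an order of magnitude between gentle rotation and buckled
  wrapping, and a worst-case constant would slow every run.
* **Friction of the deformed filament.**  Drag coefficients stay at each
  segment's native-state values during a run; re-evaluating $l$ from the
  instantaneous local geometry would couple the mobility to the strain
  state for a logarithmically weak effect.
* **Reorientation detection.**  The 5°/s threshold applies to the spline
  derivative after a short moving average (the derivative-smoothing option
  the method leaves open); pauses and noise bumps register as near-zero
  angle events by design, as in the original analysis.

## Known limitations

* The simulator models an anchored filament, not a swimming cell: no cell
  body, no thermal fluctuations, no motor torque-speed relation.  Screw
  calls are based on the free end crossing the motor plane, the
  simulation-side proxy for wrapping around the body.
* Resistive force theory neglects hydrodynamic interactions between
  distant filament parts; in tightly wrapped states those interactions
  are not small, so post-onset screw shapes are indicative rather than
  quantitative.
* The two-flagellin filament shares one set of elastic constants; any
  stiffness contrast between FlaA and FlaB is not represented, only their
  geometric contrast.
* Track statistics assume isotropic Gaussian localization noise with
  known scale; grossly misestimated noise moves the smoothing cutoff and
  with it the event statistics.
* Well above the screw threshold the fixed-window screw indicator is not
  monotone in torque: strongly driven filaments can enter tightly coiled
  states that wrap later than moderately driven ones.  Threshold searches
  therefore scan upward and bisect only the bracketing interval.
* The composition dependence of the threshold is weaker and differently
  shaped than the organism's reported behavior: in this model stability
  keeps rising beyond ~25% proximal FlaA rather than peaking there, and
  reversed-order (proximal FlaB) filaments wrap at accessible torques
  instead of staying stable.  Several inputs are uncertain at this level
  of detail -- the exact elastic constants, the second polymorphic state's
  geometry, and the hook treatment -- and the package reports what its
  stated defaults produce rather than fitting them.
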