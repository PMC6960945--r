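---
title: "Magnetometer-free spherical-joint angle estimation: model, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Magnetometer-free spherical-joint angle estimation: model, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imujoint)
```

## The problem

Two rigid links meet at a spherical (ball-and-socket) joint; each link
carries a strapdown IMU (triaxial gyroscope and accelerometer). The goal is
the 3D joint angle — the Z-Y-X Euler angles (yaw $\alpha$, pitch $\beta$,
roll $\gamma$) of the relative orientation $R_{ij} = R_i^\top R_j$ — in real
time and without a magnetometer, so that the estimate is unaffected by
magnetic disturbance (the dominant failure mode of conventional IMU+
magnetometer orientation filters indoors and near ferromagnetic objects).

Each link's orientation is factored into two unit vectors written in sensor
coordinates: the *attitude vector* $Z$ (the inertial vertical; fixes roll
and pitch) and the *heading vector* $X$ (the inertial x axis; fixes yaw),
the first and third rows of the link's direction cosine matrix
$R = [X\; Y\; Z]^\top$ with $Y = Z \times X$. The package estimates them in
two sequential Kalman filters per link.

## Sensor model

With gravity $g$ (inertial Z up), angular rate $\omega$, external (non-
gravitational) acceleration $a$ and white Gaussian noises $n_A$, $n_G$, all
in sensor coordinates:

$$ y_A = g\,Z + a + n_A, \qquad y_G = \omega + n_G. $$

Default 1-$\sigma$ noise levels are $\sigma_A = 14.8\times10^{-3}$ m/s²
and $\sigma_G = 1.5\times10^{-3}$ rad/s per axis at 100 Hz, the levels of
the commercial sensors the method was designed around; the differentiated
gyro signal is assigned $\sigma_{\dot G} = 25.3\times10^{-3}$ rad/s².

## Attitude filter

`attitude_predict()` rotates $Z$ by the exact per-step rotation
$\exp(-\Delta t\,[\tilde y_G])$ — first-order equivalent to the transition
matrix $I - \Delta t\,\tilde y_G$, but free of the systematic truncation
drift a 60-s trial would otherwise accumulate — and propagates the
covariance with process noise $\Delta t^2 \sigma_G^2 \tilde Z \tilde Z^\top$.
`attitude_update()` applies the accelerometer with the measurement model
$y_A - \hat a = g Z + n_A$, where the external-acceleration estimate
follows a first-order Gauss–Markov model, $\hat a^- = c_1 \hat a^+$ with
$\hat a^+ = y_A - g Z^+$, and the measurement noise is inflated
adaptively, $R = \sigma_A^2 I + c_2^2\,\lVert y_A - gZ^- - \hat a^-
\rVert^2 I$. Defaults $c_1 = 0.1$, $c_2 = 0.05$.

Two limitations are worth knowing. First, with $c_1 = 0.1$ at 100 Hz the
Gauss–Markov model treats external acceleration as nearly white, so a
*sustained* body-frame acceleration (e.g. the centripetal term $\tilde
\omega \tilde\omega\, p$ of steady rotation about a lever arm) is partly
indistinguishable from tilt; attitude accuracy is therefore best when the
external acceleration is translation-dominated (zero-mean in the body
frame). A 6-state filter estimating $(Z, a)$ jointly was evaluated and
does not improve this at these parameter values. Second, the adaptive $R$
slows the correction during high acceleration, so slowly varying gyro
errors (bias) are corrected with a time constant of several seconds.

## Heading filter with a kinematic constraint

Both links' headings are predicted by strapdown integration
(`heading_predict()`, same exact rotation map; process noise $\Delta
t^{q}\sigma_G^2 \tilde X \tilde X^\top$ — see *Numerical choices* for $q$).
The correction uses no magnetometer. For a spherical joint the joint-center
acceleration is the same whether computed from link $i$ or link $j$:

$$ R_i\big(a_i + (\tilde{\dot\omega}_i + \tilde\omega_i\tilde\omega_i)p_i\big)
 = R_j\big(a_j + (\tilde{\dot\omega}_j + \tilde\omega_j\tilde\omega_j)p_j\big), $$

where $p$ is the constant sensor-to-joint-center vector. Substituting the
sensor models gives a measurable per-link vector
$C = y_A + (\tilde{\dot y}_G + \tilde y_G \tilde y_G)\,p$
(`constraint_vector()`; note $C$ contains gravity, i.e. it is the joint
acceleration *plus* $gZ$ mapped to the joint) with error
$\varepsilon = n_A + \lambda_1 n_G + \lambda_2 \dot n_G$,
$\lambda_1 = \tilde p \tilde y_G - 2 \tilde y_G \tilde p$,
$\lambda_2 = -\tilde p$. Projecting the equality onto link $i$'s heading
axes $X_i$ and $Y_i = \tilde Z_i X_i$ yields two scalar equations linear in
$X_j$:

$$ z = \begin{bmatrix} C_i^\top X_i^- \\ C_i^\top \tilde Z_i^+ X_i^- \end{bmatrix},
\qquad H = \begin{bmatrix} C_j^\top \\ C_j^\top \tilde Z_j^+ \end{bmatrix},
\qquad z = H X_j + v, $$

(`constraint_measurement()`). The 2×2 covariance of $v$
(`constraint_noise_cov()`) collects the accelerometer, gyro and
differentiated-gyro noise through the $\lambda$ matrices plus the a
posteriori attitude covariances of both links through terms of the form
$(\tilde X C)^\top P_Z (\tilde X C)$; products of error terms are
neglected (first-order model). A standard Kalman correction updates link
$j$'s heading only (`heading_update()`); link $i$'s heading is never
corrected. Absolute headings therefore drift — by design — while the
*relative* orientation, hence the joint angle, stays driftless. The same
correction propagates down an $n$-link chain (`estimate_chain_angles()`):
each link's heading is corrected against its already-determined
predecessor.

The angular acceleration $\dot y_G$ is obtained by central differences
(`differentiate_gyro()`), which implies a one-sample (10 ms) latency: the
output at step $t$ depends on samples up to $t+1$ and on nothing later
(verified by a truncation test). At 100 Hz the differencing amplifies gyro
noise to $\approx 0.11$ rad/s², above the configured
$\sigma_{\dot G} = 25.3\times10^{-3}$; the filter follows the configured
value, which in practice makes the correction slightly over-confident and
is absorbed by the covariance terms above.

## When the constraint is informative: the excitation gate

The constraint carries heading information only through the component of
$C$ orthogonal to the attitude axis (the horizontal joint acceleration);
gravity contributes only along $Z$. When the joint is (nearly) static that
component is noise-level, the rows of $H$ become degenerate, and the
correction would inject attitude error into the heading. `heading_update()`
therefore skips the correction — flagging the sample and warning once per
run — when $\lVert \tilde Z^+ C \rVert$ of either link falls below
`min_excitation` (default 0.2 m/s², roughly 2× the gravity leakage of a
1° attitude error), or when the innovation covariance is numerically
singular (condition number above 1e12, the fully degenerate noiseless
case). During skipped stretches the heading coasts on the gyro; with white
noise only, the resulting joint-yaw wander is a slow random walk. This is
the method's stated operating limitation: it requires a dynamic joint.

## Joint-angle extraction

`dcm_from_attitude_heading()` rebuilds each link's DCM from $(Z^+, X)$: $Z$
is trusted and normalized first, $X$ is projected orthogonal to $Z$, and
$Y$ completes the right-handed triad. Euler angles come from
`euler_zyx_from_dcm()`; at gimbal lock ($|\beta| = \pi/2$, where only
$\alpha \mp \gamma$ is defined) the convention $\gamma = 0$ is applied and
flagged. Reported RMSEs use shortest-arc angle differences.

## The motion simulator

`simulate_chain()` emulates a hand-excited rigid-link chain. Each link's
orientation follows bounded sum-of-sinusoid Z-Y-X Euler-angle oscillations
about a home pose (defaults: 4 incommensurate sinusoids per angle,
0.15–0.8 Hz, total amplitudes 0.7 rad yaw and 0.25 rad pitch/roll,
successive home poses yawed 170° apart as two rods extending from the
joint); the first joint's center translates along an analytic
sum-of-sinusoids trajectory (default 0.4 m per-axis amplitude scale at
0.3–0.8 Hz). Angular velocity and acceleration come from the exact Euler-
rate kinematics, and each sensor's external acceleration is derived from
the joint-center acceleration propagated down the chain, so the spherical-
joint constraint holds on the truth to machine precision with *analytic*
$\dot\omega$ — the central correctness oracle for every downstream test.
Gaussian noise is added by `synthesize_imu()` at the configured levels.

Design rationale for the orientation-space (rather than rate-space)
profiles: integrating random rate profiles makes the orientation random-
walk without bound, eventually driving the joint pitch through the Euler
degeneracy at ±90° and tilting every sensor axis arbitrarily — neither
happens when an operator swings a hand-held rig, and Euler-angle error
reporting presupposes the non-degenerate envelope. With the defaults the
joint pitch stays within roughly ±45°, each sensor's vertical axis stays
within ~20–30° of vertical, mean angular rates are ~1 rad/s, and mean
external accelerations are 3.5–4.5 m/s² — the middle of the range spanned
by the rig experiments the simulator emulates. What the simulator does
*not* model: soft-tissue artefact, joint-center migration, sensor bias and
scale-factor errors (a constant bias can be injected explicitly with
`add_gyro_bias()`), magnetic fields, and sampling jitter. Passing tests on
this generator therefore demonstrate algorithmic correctness and noise
behaviour, not robustness to those real-world effects.

In drift studies a 0.2°/s bias is injected about the base link's sensor z
axis (near-vertical in this motion envelope): a vertical bias component
produces pure heading drift — the pattern of interest, since tilt
components are simply absorbed by the accelerometer correction. Without an
injected bias, prediction-only heading does not visibly drift at white-
noise levels over a few minutes, so bias injection is what reproduces the
unbounded Method-2-style drift seen with real sensors; noisy comparative
runs therefore include it.

## Calibration of the sensor-to-joint vectors

`estimate_joint_vectors()` identifies $p_i, p_j$ from a dynamic trial by
minimizing $\sum_t (\lVert C_i(t;p_i)\rVert - \lVert C_j(t;p_j)\rVert)^2$ —
the frame-invariant form of the constraint, requiring no orientation
estimates — with a Levenberg-damped Gauss–Newton iteration (analytic
Jacobian, zero initialization, multiplicative damping adaptation,
convergence when the step norm drops below 1e-6 m). Because the unknown
lever arms multiply the differentiated gyro signal, derivative noise acts
as error-in-variables and systematically shrinks the estimates; the
calibration (an offline procedure) therefore differentiates the gyro with
a local-cubic Savitzky–Golay window (half-width 10 samples, edges
discarded), whose noise amplification is an order of magnitude below
central differences while sub-Hz motion passes undistorted. A minimum mean
angular rate (default 0.3 rad/s) guards against unidentifiable, poorly
excited trials.

## Numerical choices

* **Process-noise $\Delta t$ power.** The white-noise derivation of the
  heading process noise gives $\Delta t^2 \sigma_G^2 \tilde X \tilde
  X^\top$ per step (validated against Monte-Carlo draws of
  $w=\Delta t(-\tilde X)n_G$); the filter's default uses the
  power-spectral-density convention $\Delta t^1$ (`q_dt_power = 1`), whose
  higher gain gives the constraint correction a sub-second time constant so
  that bias-induced drift of the base link is tracked with negligible lag.
  The attitude filter keeps $\Delta t^2$ (`att_q_dt_power = 2`): raising
  attitude gain increases external-acceleration leakage. Both are
  configurable.
* **$\lambda$ matrix of the $\sigma_{\dot G}^2$ term.** The error
  decomposition assigns $\dot n_G$ to $\lambda_2$; `gdot_lambda`
  (default `"lambda2"`) also offers `"lambda1"` for compatibility with the
  alternative printed expansion.
* **Renormalization.** $Z$ and $X$ are renormalized after every predict
  and update; covariances are symmetrized each step and the constraint
  covariance is eigenvalue-floored at $10^{-12}\times$trace. The vector-
  state filter does not preserve unit norm by itself; $P$ is left
  unrescaled.
* **Strapdown step.** The effective rotation vector per step is the
  trapezoidal average of consecutive gyro samples plus the two-sample
  coning correction $\tfrac{\Delta t}{12}\, y_{t-1}\times y_t$.
* **Initialization.** Attitude from the first accelerometer sample
  (5° 1-$\sigma$), heading from the sensor x axis projected orthogonal to
  $Z_0$ (10°): the base link's absolute heading is unobservable and only
  relative heading matters. `pipeline_config_from_truth(exact_init =
  TRUE)` initializes from the true state *with near-zero covariance*
  ((1e-5°)²): an exactly known start has no uncertainty, and a large
  initial attitude covariance would let the first accelerometer updates
  absorb external acceleration into the attitude.
* **Method 4 (oracle attitude).** Supplied reference attitudes are treated
  as exact ($P_Z = 0$ in the constraint covariance; switchable with
  `oracle_zero_att_cov`).

## Problem sizes used in the shipped checks

The test-suite and the acceptance script use: 20 s for the exactness
oracles; 60 s noiseless recovery; one 180 s drift trial; five 90 s seeds
for the method ordering; $10^5$ Monte-Carlo draws for the covariance
checks; one noiseless 60 s and ten 180 s trials for calibration recovery;
10 s for the static-degeneracy check — all at 100 Hz. These sizes give
each property comfortable statistical margin while keeping a full run in a
few minutes.

## Known limitations

* Static or low-excitation joints are not observable; the filter detects
  and skips, it does not solve this (zero-velocity updates or a
  magnetometer would be needed).
* Attitude accuracy — hence joint-angle accuracy via the gravity-leverage
  $g\,\delta Z/\lVert \tilde Z C\rVert$ — degrades under sustained
  body-frame DC acceleration and under large gyro bias; the constraint
  correction cannot distinguish base-link attitude error from genuine
  relative-heading error.
* The sensor-to-joint vectors are assumed constant; joint-center migration
  (soft tissue, loose mounting) is unmodeled.
* Euler-angle output degrades near $|\beta| = 90°$ (convention-flagged,
  not avoidable in any Euler parameterization).
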