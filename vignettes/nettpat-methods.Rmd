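---
title: "Learned NETT regularization for masked photoacoustic tomography: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learned NETT regularization for masked photoacoustic tomography: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nettpat)
```

# The problem

Photoacoustic tomography (PAT) recovers an initial acoustic pressure
distribution $f$ — a proxy for optical absorption in tissue — from pressure
traces recorded by sensors surrounding the object. `nettpat` treats the 2D
circular geometry: the object lives in the unit disc, point sensors sit on the
unit circle, and the sound speed is 1, so all acoustic activity is over by
time 2 (the diameter transit time).

The twist is *masked* limited data: a diagonal stripe $I$ through the object
produces no measurable signal at all. Pixels inside $I$ are invisible to the
data, so reconstruction couples a wave-equation inverse problem with an
inpainting problem — the missing stripe must be filled in from prior
knowledge, which here is *learned* from training images.

# Forward model

The image is expanded in generalized Kaiser–Bessel (KB) basis functions on an
$N \times N$ pixel lattice: radially symmetric blobs
$$
\psi(\rho) = \left(1 - \rho^2/R^2\right)^{m/2}
\frac{I_m\!\left(\gamma\sqrt{1-\rho^2/R^2}\right)}{I_m(\gamma)},
\qquad \rho \le R,
$$
with order $m$, taper $\gamma$ and support radius $R$ ($I_m$ is the modified
Bessel function of the first kind). KB functions are the standard
discretization choice in tomography because each blob has an *analytic*
pressure trace: writing $g(\rho) = \rho\,\psi(\rho)$ and extending $g$ oddly,
the 3D wave equation with radial initial pressure $\psi$ gives
$$
p(d, t) = \frac{g(d + t) - \operatorname{sign}(t - d)\, g(|d - t|)}{2d}
$$
at distance $d$ from the blob center (the classical $v = r\,p$ substitution
that turns the radial 3D wave equation into the 1D one). This "pseudo-3D"
trace is exact, fast, and vanishes outside the causal window
$[d - R,\, d + R]$. The test suite verifies it against an independent
spherical-mean quadrature plus finite-difference oracle to better than
$10^{-4}$ relative error.

Defaults: $m = 2$ (the profile is then $C^1$ at the support edge, keeping
traces smooth), $\gamma = 3$, $R$ twice the pixel spacing. All are
configurable; no result in the package depends on these choices beyond
resolution quality.

The system matrix $W$ samples each blob's trace on the sensor/time lattice
(row $N_t(k-1)+j$ is sensor $k$, time $j$; column $N(i_1-1)+i_2$ is pixel
$(i_1, i_2)$). Masking zeroes the columns of pixels inside the stripe
(diagonal matrix $M_I$), and the stabilized operator is the truncated SVD
$$
A = U \Sigma_\star V^\top, \qquad A^+ = V \Sigma_\star^+ U^\top,
$$
with singular values $\le \sigma_\star$ removed. Truncation removes the
near-null space the mask creates; the default threshold is
$\sigma_\star = 10^{-3} \sigma_{\max}$ (relative, configurable as absolute).
All downstream products ($A$, $A^\top$, $A^+$, and the solver's reused
inverse) are applied through the thin SVD factors, never as dense matrices.

A note on the pixel lattice: the lattice is centered, $c(i) = ((2i_1 - N -
1)/N,\ (2i_2 - N - 1)/N)$, so it covers $[-1, 1]^2 \supset D_1$
symmetrically with spacing $2/N$ — the natural discretization for supports
in the unit disc.

# Training data

Training images are square-shaped rings — square annuli with random side
length, thickness, intensity and position, always strictly inside the unit
disc. The intensity on a ring is a random base level in $[0.4, 1]$ modulated
by a random affine profile along the ring (clipped to $[0, 1]$): enough
variation that the network cannot memorize a constant, without committing to
a particular profile law. Ranges (side $[0.5, 1.0]$, thickness
$[0.08, 0.2]$, one ring per image by default) are chosen so rings routinely
straddle the masked stripe, which is what makes the inpainting half of the
problem learnable.

Each phantom $x_a$ is paired with its *basic reconstruction*
$$
h_a = A^+(A x_a + \eta_a), \qquad
\eta_a \sim \mathcal N\!\left(0,\ (\sigma \|A x_a\|_\infty)^2\right),
\quad \sigma = 0.01,
$$
i.e. the noisy pseudoinverse image carrying exactly the artifacts (masked
stripe, truncation ringing, noise amplification) the regularizer must learn
to recognize. The out-of-distribution test object is a superposition of
filled discs — structures absent from the ring corpus.

# The learned regularizer

The NETT regularizer is
$$
R(x) = \|x - \Phi(x)\|_2^2 + \beta \|\nabla x\|_{1,\epsilon},
\qquad
\|\nabla x\|_{1,\epsilon} = \sum_{i_1, i_2}
\sqrt{(\Delta_1 x)^2 + (\Delta_2 x)^2 + \epsilon^2},
$$
with forward differences and replicate boundary (differences across the last
row/column are zero, so constant images minimize the TV term). The square
root makes this a genuine smoothed isotropic total variation; $\epsilon > 0$
makes it differentiable everywhere. $\beta$ defaults to 15, matching the
weight used with the trained regularizers throughout.

The default $\epsilon = 0.25$ is dictated by the solver, not by smoothing
aesthetics. The forward–backward iteration takes *explicit* gradient steps
on $\alpha R$, and the smoothed-TV gradient has a Lipschitz constant of
order $8\beta/\epsilon$; stability of the explicit step requires
$s\,\alpha\, 8\beta/\epsilon \lesssim 2$, which at the default study settings
($s = 0.25$, $\alpha \approx 0.016$, $\beta = 15$) gives
$\epsilon \gtrsim 0.24$. With a much smaller $\epsilon$ (say $10^{-3}$) the
TV gradient is nearly sign-valued, the iteration oscillates, and the
objective trace rises instead of falling — observed, and predicted by the
bound. At $\epsilon = 0.25$ the penalty behaves like a Huber-type edge
penalty on unit-range images, and the objective trace is monotone at the
study settings. $\epsilon$ remains configurable for uses (e.g. pure
evaluation of $R$) where stiffness does not matter.

$\Phi$ is a residual U-Net: two 3×3 convolution + ReLU blocks per scale,
$m$ down-/upsampling stages ($2 \times 2$ mean pooling down,
nearest-neighbor upsampling with concatenating skips up), channels doubling
per scale, and a final 1×1 convolution whose output is *added* to the input.
$\|x - \Phi(x)\|^2$ is therefore the squared norm of the network's estimated
artifact, small on clean images, large on pseudoinverse reconstructions.
Pooling and upsampling are linear and the final layer starts at zero, so a
fresh network is exactly the identity and training starts from "no
correction".

Design notes:

* **Width.** The default is 8 base channels. This is deliberately narrow:
  the package targets interactive single-CPU experimentation, and at the
  study scale below an 8-channel $m=1$ network separates clean phantoms from
  artifact reconstructions reliably. Width and depth are `network_spec()`
  parameters; nothing in the package depends on a specific width.
* **Exact gradients.** The network engine (im2col convolutions over BLAS
  matmuls) implements exact reverse-mode differentiation for both parameters
  and inputs. The regularizer gradient
  $2(I - J_\Phi(x))^\top (x - \Phi(x)) + \beta \nabla \mathrm{TV}_\epsilon(x)$
  is therefore exact — the finite-difference agreement asserted in the tests
  is a check, not the implementation.

Training minimizes
$$
\sum_a \|\Phi(h_a) - x_a\|_1 + \gamma \|\Phi(x_a) - x_a\|_1
$$
over minibatches (batch 8) with Adam at learning rate 0.01 and
$\gamma = 0.1$: the network must map artifact images back to their phantoms
while leaving clean phantoms fixed. Epoch losses are evaluated on the full
corpus after each epoch and the best-epoch parameters are returned.
Everything — initialization, shuffling, noise — is seeded, and retraining
with the same seed is bit-identical.

One subtlety worth recording: "a single tiny step cannot increase the loss"
is *not* universally true here. The L1 loss is nondifferentiable wherever a
residual entry is exactly zero, and with a masked operator $h_a - x_a$ has
structural zeros (masked pixels of $A^+y$ are exactly 0), so at the identity
initialization the loss sits on a kink and an Adam step (which normalizes
per-parameter, i.e. steps by $\pm$ the learning rate) pays $|\delta|$ on
every kink pixel no matter how small the rate. The descent property holds,
and is tested, in the differentiable configuration (unmasked operator,
$\gamma = 0$).

# The NETT solver

Reconstruction minimizes the discrete NETT functional
$$
T(x) = \tfrac12 \|A x - y^\delta\|_2^2 + \alpha R(x)
$$
by forward–backward splitting with constant step $s$:
$$
x_{k+1} = (s A^\top A + I)^{-1}
\left( s A^\top y + x_k - s \alpha R'(x_k) \right),
$$
an implicit (proximal) step on the quadratic data term and an explicit
gradient step on the regularizer. Because $s$ is constant the linear solve
is identical in every iteration; it is realized once through the stored SVD
factors, $(sA^\top A + I)^{-1} = I + V \operatorname{diag}\!\big((s d_i^2 +
1)^{-1} - 1\big) V^\top$, after which each iteration costs two thin
matrix-vector products plus one network gradient. A dense fresh-solve path
(`reuse_inverse = FALSE`) exists purely for verification; the tests confirm
both paths agree to $10^{-10}$.

Defaults follow the study setup: $N_{\mathrm{iter}} = 15$, $s = 0.25$,
$x_0 = \Phi(A^+ y)$, and per-noise-level weights $\alpha = 0.015 / 0.016 /
0.02$ for $\sigma = 0 / 0.01 / 0.1$. The start $\Phi(A^+y)$ is chosen over
$\Phi(A^\top y)$ because the network is trained on $A^+$-scale inputs;
`init = "network-adjoint"` restores the alternative. In the convex
degenerate cases ($\Phi$ zero, identity or linear) the iteration provably
converges to the closed-form Tikhonov minimizer, which the tests assert to
$10^{-6}$ relative; with $\alpha = 0$ it recovers $A^+ y$.

The *post-processing baseline* is $\Phi(A^+ y)$: one network application,
no data consistency. NETT's advantage over it is precisely the data term —
off-distribution structures that the network mangles are pulled back toward
the measurements by the iteration.

# Convergence-rate experiment

The theory predicts, for the quadratic regularizer $R(x) = \|x\|^2$ under
the source condition $R'(x^+) = A^\top \eta$ and the rule
$\alpha \propto \varepsilon$ (noise norm $\varepsilon$, noise *level*
$\delta = \varepsilon^2$ since the discrepancy is a squared norm), an
absolute Bregman distance
$$
B_R(x_\alpha^\delta, x^+) = \left| R(x) - R(x^+) - \langle R'(x^+),
x - x^+\rangle \right| = \|x_\alpha^\delta - x^+\|^2 = O(\varepsilon),
$$
i.e. log–log slope 1 against the noise norm. `rates_experiment()` measures
this slope on a diagonal toy operator where the Tikhonov minimizer is in
closed form, so measured Bregman values carry no solver error.

Two design points deserve explanation:

* **Geometric spectrum.** The default spectrum is $d_i = 0.6^{\,i-1}$,
  $i = 1..30$. The classical rate rests on the noise amplification factor
  $\max_\sigma \sigma/(\sigma^2 + 2\alpha) \sim \alpha^{-1/2}$ being realized
  at every noise level in the schedule. For a *geometric* spectrum the mode
  sum $\sum_i \big(d_i/(d_i^2 + 2\alpha)\big)^2$ is dominated by the mode
  nearest $\sqrt{2\alpha}$ and scales like $\alpha^{-1}$, reproducing the
  continuum behavior; for a slowly decaying power-law spectrum
  ($d_i = i^{-p}$) the same sum scales like $\alpha^{-(2p+1)/(2p)}$ and the
  measured slope flattens to $(2p-1)/(2p)$ — e.g. 0.75 at $p = 2$ — which
  misrepresents the theory rather than testing it. The measured slope with
  the default configuration is ≈ 0.97 and is insensitive to the ratio
  (0.4–0.6) and mode count (25–40).
* **Source condition on/off.** `solution = "source"` draws
  $x^+ = A^\top\eta$, satisfying the condition exactly;
  `solution = "flat"` places equal mass on all modes, loading the tiny
  singular directions that $A^\top$ cannot reach — the measured slope then
  collapses toward 0, which is the experiment's negative control.

The schedule checker runs before any computation: $\alpha_k$ must decrease
to 0 and $(\delta_k + \text{discrepancy}_k)/\alpha_k$ must decrease along
the schedule (with the optional growing spectral-truncation dimension
`n_modes` contributing the discrepancy); inadmissible schedules are
configuration errors, not warnings.

# The reconstruction study

`reconstruction_study()` reproduces the comparison design at configurable
scale: for each test phantom and noise level it simulates data and
reconstructs with $A^+$, post-processing, and NETT, recording MSEs in a tidy
table (`tidy()`, `glance()`, `autoplot()`).

The package's documented study scale — used by the acceptance tests and
`scripts/acceptance.R` — is $N = N_t = 64$, $N_s = 75$, 200 training pairs,
an $m = 1$ network trained 5 epochs, 10 held-out test phantoms, noise levels
$\sigma \in \{0.01, 0.1\}$ against training noise 0.01, $N_{\mathrm{iter}} =
15$, $s = 0.25$. These sizes are the package's reduced-scale study design:
half the linear resolution and a fifth of the corpus of the full-scale
setup ($N = 128$, $N_s = 150$, 1000 phantoms), sized so a complete
train-and-evaluate cycle is comfortable on a single CPU. The qualitative
findings asserted at this scale are:

* matched noise: mean NETT MSE < mean pseudoinverse MSE;
* noise mismatch: NETT at $\sigma = 0.1$ with a $\sigma = 0.01$-trained
  regularizer is worse than at matched noise (regularizers are
  noise-level-specific).

The study also compares NETT with post-processing on the
out-of-distribution circles phantom — the data-consistency comparison. A
caveat discovered at this scale and worth stating: the full-size version of
this experiment relies on a *deep* network being so specialized to the
training shapes that it corrupts unseen structures, which data consistency
then repairs. The desk-scale $m = 1$, 8-channel network is essentially a
local artifact filter and generalizes to the circles phantom rather than
corrupting it, so post-processing remains strong there and NETT's
variational solution (whose TV term trades error for smoothness) does not
undercut it. The mechanism itself is intact — pure data-consistency
refinement ($\alpha \to 0$ in the same iteration) does improve on the
post-processed image — but the headline inequality "NETT at or below
post-processing off-distribution" should only be expected of
structure-specialized (deeper, longer-trained) regularizers.

# What the synthetic data does and does not show

The generator emulates the geometry of the problem (compact piecewise-smooth
absorbers inside a disc, a no-data stripe, peak-scaled Gaussian noise), not
real tissue: no anatomical texture, no acoustic heterogeneity or
attenuation, no detector impulse response or band-limiting, and the same
forward operator is used for simulation and inversion (no model mismatch,
i.e. an inverse crime the study design accepts deliberately, since its
purpose is comparing reconstruction strategies on a controlled problem).
Passing tests therefore demonstrate correctness of the machinery and the
*relative* behavior of the methods under the stated conditions — not
clinical image quality.

# Numerical choices and degenerate inputs

* Pixels outside the unit disc exist in the square lattice; phantom
  generators never populate them, but the operator handles them like any
  other pixel (sensors can sit arbitrarily close, so the trace formula
  guards $d < 10^{-9}$ with an error rather than implementing the removable
  singularity).
* `truncate_operator()` retains exactly the singular values
  $> \sigma_\star$; ties go to truncation.
* `smoothed_tv()` accepts $\epsilon = 0$ for values but requires
  $\epsilon > 0$ for gradients.
* Degenerate ring thickness 0 produces the empty image; an empty circle
  list produces the zero image; both are valid inputs downstream.
* The solver records the objective at $x_0$ and after each iteration
  (trace length $N_{\mathrm{iter}} + 1$) and fails loudly, naming the
  iteration, on non-finite iterates.
* Dense system-matrix assembly refuses $N > 192$ unless the cap is raised
  explicitly.

# Known limitations

* 2D circular geometry only; no 3D, partial-arc or integrating-detector
  physics.
* The dense-matrix/SVD pipeline is the point (reused inverse, exact
  pseudoinverse) but caps the practical resolution; matrix-free operators
  are out of scope.
* The Bregman distance for the trained (non-convex) regularizer can be
  computed via `bregman_distance()` but is diagnostic only; rate assertions
  use the quadratic regularizer where values are exact.
* Training at the full-scale design (1000 phantoms, $N = 128$, deep
  networks) is possible but slow in this CPU implementation; the study
  defaults are sized accordingly.
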