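# nettpat

Learned **Ne**twork **T**ikhonov (**NETT**) regularization for a masked
limited-data photoacoustic tomography (PAT) problem, in R.

## The problem

2D circular-geometry PAT: an initial pressure image $f$ supported in the
unit disc is to be recovered from acoustic traces recorded by sensors on the
unit circle. A diagonal stripe $I$ through the object generates **no data**
at all, so the reconstruction task combines wave inversion with inpainting —
the invisible stripe must be filled in from learned prior knowledge.

The package is for researchers in learned regularization and computational
imaging who want a complete, self-contained, CPU-scale instance of the NETT
pipeline: forward model, training-data generation, regularizer training,
variational reconstruction, and the convergence-rate diagnostics that back
the method theoretically.

## The method

The image is discretized in Kaiser–Bessel basis functions, whose pressure
traces are known in closed form, giving a dense system matrix $W$. Masking
($M_I$) and truncated SVD yield the stabilized forward operator
$A = U\Sigma_\star V^\top$ and pseudoinverse $A^+ = V\Sigma_\star^+U^\top$.
Reconstruction minimizes the NETT functional

$$
T(x) \;=\; \tfrac12\,\lVert Ax - y^\delta\rVert_2^2 \;+\;
\alpha \left( \lVert x - \Phi(x)\rVert_2^2 + \beta\,\lVert\nabla x\rVert_{1,\epsilon} \right),
$$

where $\Phi$ is a residual U-Net trained so that
$\lVert x - \Phi(x)\rVert^2$ is small on clean phantoms and large on
artifact-laden basic reconstructions $h_a = A^+(Ax_a + \eta_a)$, and
$\lVert\nabla x\rVert_{1,\epsilon}$ is a smoothed total variation. The
functional is minimized by forward–backward splitting,

$$
x_{k+1} = (sA^\top A + I)^{-1}\big(sA^\top y + x_k - s\alpha R'(x_k)\big),
$$

with the inverse realized once through the SVD factors and the regularizer
gradient computed by exact reverse-mode differentiation through the network
(the network engine, including backprop and Adam, is implemented in the
package on BLAS matrix products).

A toy-problem harness measures Bregman-distance convergence rates: with a
quadratic regularizer, a solution satisfying the source condition
$R'(x^+) = A^\top\eta$, and the rule $\alpha \propto \varepsilon$, the
distance $B_R(x_\alpha, x^+)$ decays like the noise norm $\varepsilon$
(log–log slope 1), and violating the source condition destroys the rate.

## Worked example

```r
library(nettpat)

# geometry, forward operator, truncated SVD
geo <- build_geometry(N = 32, Ns = 40, Nt = 32)
sm  <- assemble_system_matrix(geo$grid, geo$sensors)
op  <- truncate_operator(sm, mask_indicator(geo$grid, mask_spec(0.34)))
op
#> <truncated_operator> 1280 x 1024, rank 810 (sigma* = 0.001652)

# training pairs: phantoms and their artifact reconstructions
data <- generate_dataset(geo$grid, op, n = 50, sigma = 0.01, seed = 1)
reg  <- train_regularizer(data, spec = network_spec(m = 1, base_channels = 8),
                          cfg = train_config(epochs = 5, seed = 1))
tail(attr(reg, "history"), 3)
#>   epoch  loss
#> 1     3  80.2
#> 2     4  72.5
#> 3     5  62.7

# compare pseudoinverse, post-processing and NETT on held-out phantoms
test_ph <- vapply(1:5, function(a)
  square_ring_phantom(geo$grid, ring_phantom_config(), seed = 5000000 + a),
  numeric(op$n_coef))
study <- reconstruction_study(op, list(R1 = reg), test_ph,
                              noise_levels = c(0.01, 0.1), seed = 1)
glance(study)
#>   sigma method  mean_mse     n
#> 1  0.01 nett_R1   0.0219     5
#> 2  0.01 pinv      0.0534     5
#> 3  0.01 post_R1   0.0119     5
#> 4  0.1  nett_R1   0.0281     5
#> 5  0.1  pinv      6.37       5
#> 6  0.1  post_R1   0.567      5

# convergence-rate diagnostic on the quadratic toy problem
rates_experiment(rates_config(seed = 1))
#> <rates_result> fitted log-log slope 1.025 over eps in [1e-04, 0.1]
```

Reading the numbers: at matched noise ($\sigma = 0.01$) the learned methods
cut the pseudoinverse error roughly in half or better; at mismatched noise
($\sigma = 0.1$, regularizer trained at 0.01) the pseudoinverse collapses
(MSE 6.4) while NETT's data-consistent iteration degrades gracefully and is
an order of magnitude more robust than one-shot post-processing. The rate
slope ≈ 1.0 is the theoretically predicted decay of the Bregman distance
under the source condition.

`tidy()`, `glance()` and `autoplot()` methods are provided for
reconstruction results, study reports and rate experiments; a thin command
line (`inst/cli/nett-pat`, or `cli_main()`) exposes the pipeline as
`build-forward`, `simulate`, `train`, `reconstruct`, `study`, `rates`
subcommands with YAML configs.

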