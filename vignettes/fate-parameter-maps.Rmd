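---
title: "Mapping cell fates to parametric conditions by systematic perturbation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping cell fates to parametric conditions by systematic perturbation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A gene regulatory network with state vector $x \in \mathbb{R}^m$ and kinetic
parameters $p \in \mathbb{R}^s$ typically supports a small number of stable
steady states — cell fates — whose existence and identity depend on $p$ in a
way that bifurcation analysis can only chart for one or two parameters at a
time. `fatemap` builds the map in the other direction and for *all*
parameters at once: it perturbs every parameter randomly, records which
stable states the ODE system reaches, and learns statistical rules that
predict, for a new parameter set, which fate the cell will adopt and which
parameters matter most.

The pipeline is:

1. **Systematic perturbation.** Draw $n$ parameter sets, each coordinate
   uniform on its perturbation interval, giving $P_{n\times s}$. For every
   row, enumerate all stable steady states; stacking them gives
   $X_{q\times m}$ with $q \ge n$ because multistable rows contribute
   several states.
2. **Fate classes.** Split rows into monostable and multistable. Cluster the
   monostable states with average-linkage hierarchical clustering
   (Euclidean metric) into $k$ fate classes.
3. **Dimension reduction.** Principal component analysis of the states; in
   the bundled systems PC1 alone carries roughly 90% of the variance and
   serves as the scalar fate coordinate.
4. **Fitting analysis.** Partial least-squares (PLS1) regression of PC1 on
   the min–max–normalized parameters, fit on a stratified 70% training
   split. Per-class confidence intervals on the fitted response become a
   classification rule evaluated on the held-out 30%.
5. **Multistable states.** PCA over *all* states; a critical value $V_c$ on
   PC1 (two fates) or per-class confidence ellipses on PC1–PC2 (three
   fates, e.g. with a hybrid class) assign a fate to every state of a
   multistable row. A kernel SVM on the parameters predicts mono- versus
   multistability itself.
6. **Importance.** Variable importance in projection,
   $\mathrm{VIP}_j = \sqrt{\, s \sum_a SS_a (w_{ja}/\lVert w_a \rVert)^2 /
   \sum_a SS_a \,}$, ranks parameters; $\sum_j \mathrm{VIP}_j^2 = s$, so 1
   is the conventional relevance threshold. Per-class refits give per-fate
   rankings, and sorting $|\beta_j|$ with signs retained gives the
   direction of each parameter's influence.

## Built-in models

Both models ship with compiled right-hand sides (used by the `deSolve`
integrator) and a single authoritative definition shared with direct
evaluation from R. Their algebraic form and basal values are this package's
own reconstruction, chosen once so that the qualitative behaviour described
below holds, and not revisited.

**Toggle switch** (`toggle_switch_model()`): two mutually repressing
proteins with shifted-Hill kinetics,
$\dot A = g_a\,H(B;k_a,n_a,\lambda_a) - A/\tau_a$ (symmetrically for $B$),
$H(x) = \lambda + (1-\lambda)/(1+(x/k)^n)$. Units: $g$ in nmol l$^{-1}$
h$^{-1}$, $k$ in nmol l$^{-1}$, $\tau$ in h. Basal values
($g=65$, $\tau=1$, $k=34$, $\lambda=0.275$, $n=4$) put the cusp of the
bistable wedge at $g_a=g_b\approx 31$ nmol l$^{-1}$ h$^{-1}$, below the
default sampling square $[50,80]^2$, so that (i) roughly a quarter of the
square is bistable, (ii) at $g_b = 70$ a bistable window in $g_a$ opens and
closes inside $[50,80]$, and (iii) every monostable state has one clearly
dominant protein — state I ($B$ high) or state III ($A$ high). Default
intervals for the remaining parameters span 75–125% of basal.

**EMT core network** (`emt_model()`): nine species — endogenous TGF-β
(`T`), snail mRNA (`s`), SNAIL (`S`), miR-34 (`R3`), zeb mRNA (`z`), ZEB
(`Z`), miR-200 (`R2`), E-cadherin (`E`), N-cadherin (`N`) — wired as two
coupled double-negative switches (SNAIL⊣miR-34 and ZEB⊣miR-200) driven by
total TGF-β, with miR-200 repressing endogenous TGF-β production as an
outer positive feedback. The staggered switch thresholds create a stable
hybrid branch (SNAIL on, ZEB off) between the epithelial state (E-cadherin
high) and the mesenchymal state (N-cadherin high); over the exogenous-dose
window `TGF0` $\in [0,3]$, `kT` $\in [0.3, 0.5]$ the system passes E →
E+hybrid → hybrid (→ E+hybrid+M tristability for part of the range) → M.
All other 42 parameters sample 75–125% of basal. Under these defaults
roughly 54% of random parameter sets yield only E or M states (no hybrid
member), the quantity the hybrid filter reports.

## Steady-state enumeration

For each parameter set, `find_steady_states()` integrates from `n_starts`
(default 20) random nonnegative initial conditions with `deSolve::lsoda`
in chunks of 150 time units (horizon 3000) until the windowed state change
falls below `conv_tol` ($10^{-8}$), polishes each endpoint with damped
Newton iteration to $\lVert f \rVert_\infty < 10^{-9}$, keeps roots whose
Jacobian eigenvalues all have real part below $-10^{-8}$, and merges
duplicates at $10^{-3}$ relative tolerance against each variable's scale.
Defaults were chosen so that the toggle-switch bistable fraction is
insensitive to doubling any of them. Non-converged trajectories are dropped
silently (a limit cycle should not abort a 10 000-row sweep); a row errors
only when *no* start converges. Missed attractors bias multistable rows
toward "mono" — increasing `n_starts` is the mitigation, and the
solver-versus-enumeration property test quantifies the residual risk on
the toggle switch (at least 95% exact agreement with a brute-force
fixed-point enumeration over 200 random draws).

## Numerical and design choices

* **Clustering scale.** Fate clustering runs on raw states by default
  (`standardize` is a flag): the fate classes of both bundled systems are
  separated by large absolute expression differences. The *hybrid
  identification* cut used before hybrid filtering (`filter_hybrid_for_em`)
  instead uses standardized states and Ward linkage: average linkage chains
  the epithelial and hybrid clouds on this geometry and strands singleton
  clusters, while a Ward cut recovers the three phenotypes essentially
  exactly. The fate-clustering contract itself remains average-linkage.
* **PCA scale.** Raw for both models. For the EMT data this was a genuinely
  open choice; the deciding observation is that the snail-mRNA column is
  only weakly fate-correlated, and z-scoring inflates its weight, pulling
  the PC1 share from ≈0.91 (raw) to ≈0.83. PC1 orientation follows a fixed
  sign convention (largest-magnitude loading positive), so learned
  thresholds such as $V_c$ are orientation-consistent but their *sign* has
  no meaning across datasets.
* **Confidence intervals.** Class intervals on the fitted response are
  Gaussian, mean $\pm z_{(1+c)/2}\,\mathrm{sd}$ of the class's training
  fitted values (`interval_type = "quantile"` is available). Gaussian
  intervals reach through the low-density region between well-separated
  classes, so on cleanly bimodal data the per-class accuracy saturates and
  barely changes with the confidence level; empirical quantile intervals
  stop at the data's inner edge and mechanically leave $\ge (1-c)/2$ of
  each class unclassifiable however clean the data. Only the facing edges
  of the intervals decide: the lowest class claims everything below its
  upper edge, the highest everything above its lower edge; a value in the
  uncovered gap is unclassifiable and scored false, a value claimed by
  both classes goes to the nearer training median.
* **PLS rank.** `fit_pls()` defaults to 5-fold cross-validated selection of
  the component count (smallest count within 1% of the best RMSEP, capped
  at $\min(s, 10, n-2)$). The EMT preset pins the rank to one component:
  with a single fate axis as the response, later components mostly model
  within-fate state variance, which widens the fitted-value tails and
  costs classification accuracy even as it lowers RMSEP.
* **Seeding.** One master seed drives everything; per-row solver seeds are
  derived with a fixed integer recurrence so rows are independent and a
  run is reproducible bit for bit. Fixture generators and splitters save
  and restore the caller's RNG state.
* **Degenerate inputs.** Fixed (non-varying) parameters min–max–normalize
  to the constant 0.5 and are excluded from regression; a singular ellipse
  covariance is ridge-regularized with a logged epsilon; a constant state
  matrix is a PCA error; solver failure on a row drops the row with a
  message and a count, never silently.

## What the synthetic fixtures emulate

`make_two_blob_dataset()` mimics the *statistical* shape of a solved
bistable system — two Gaussian state clouds whose membership is a linear
function of a few parameter columns — and `make_sparse_pls_dataset()` the
sparse linear parameter-to-response structure behind the VIP recovery
property. They let every downstream stage be tested without ODE solving.
They do **not** emulate multistability, basin geometry, hybrid states, or
any nonlinear parameter-to-fate boundary, so tests passing on fixtures
demonstrate correctness of the statistical machinery, not fidelity of the
dynamical reconstruction; the model-level checks in the acceptance suite
carry that burden.

## Problem sizes

The test and acceptance runs use 2000 parameter sets for the toggle-switch
experiments and 500 for the EMT network; at these sizes the bistable
fraction carries a binomial standard error of about one percentage point
and each EMT phenotype keeps a two-digit test count. The presets default to
the full study sizes (10 000 / 5000) for real use.

## Known limitations

* Only fixed-point attractors are enumerated; limit cycles are dropped as
  non-converged starts.
* The per-class accuracy of the EMT interval rule at $n = 500$ rests on
  test sets of 30–45 rows per phenotype, so single boundary rows move it
  by several percentage points between seeds.
* The all-parameter toggle-switch map is, under this package's
  reconstruction, more linearly decodable than the reference behaviour it
  emulates; its confidence-interval accuracies land around 0.90–0.96
  across seeds rather than in the 0.85–0.87 range, because the
  reconstructed parameter intervals shift the bistable wedge in a way a
  linear rule can absorb.
* Hybrid identification assumes the hybrid cloud is *intermediate* along
  PC1; exotic networks whose intermediate class is extreme on PC1 need the
  explicit `is_hybrid` override.

## A worked sketch

```r
library(fatemap)

cfg <- preset_config("ts2", n = 2000, seed = 7)
bundle <- run_experiment(cfg)
print(bundle)                     # dataset summary, PC1 share, accuracies
vip_scores(bundle$pls)            # importance of ga, gb
bundle$critical_value             # Vc on the all-states PC1 axis
```

The same call with `preset_config("emt", n = 500, seed = 7)` runs the
three-phenotype analysis: hybrid filtering, E/M clustering, regression,
ellipse classification of multistable rows, and per-phenotype VIP
rankings in `bundle$per_class_vip`.
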