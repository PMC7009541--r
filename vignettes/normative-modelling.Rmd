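---
title: "Voxelwise normative modelling of the neonatal brain: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxelwise normative modelling of the neonatal brain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

At each voxel inside a brain mask we observe, for subject $s$, a 5-vector
$y_s$ — two intensity contrasts and three displacement components — together
with covariates $x_s = (\mathrm{PMA}_s, \mathrm{GA}_s, \mathrm{sex}_s)$:
post-menstrual age at scan (weeks), gestational age at birth (weeks) and a
binary sex code. The five outputs are modelled jointly by a multi-output
Gaussian process under the intrinsic co-regionalization model (ICM): one
shared input kernel

$$k(x, x') = \sigma^2_{lin}\,\langle x, x'\rangle
  + \sigma^2_{rbf}\exp\!\big(-\tfrac12 \|(x - x')/\ell\|^2\big)
  + \sigma^2_w\,\delta_{x x'},$$

mixed across outputs by a positive semi-definite $5\times 5$ matrix
$B = WW^\top + \mathrm{diag}(\kappa)$, so that
$\mathrm{cov}(y_i(x), y_j(x')) = B_{ij}\,k(x, x')$. The linear term captures
slow, effectively linear growth; the squared-exponential term captures the
smooth sigmoidal transitions typical of tissue maturation; the white term
absorbs measurement noise together with the stable subject-specific
deviations that the model deliberately does not explain (they are the signal
of the deviation maps). Prematurity enters through GA at fixed PMA; sex as a
binary input column.

**Why this is fast.** With the coupled noise model the joint training
covariance of the stacked outputs is exactly a Kronecker product,
$K = B \otimes C$ with $C = k(X, X)$ (white noise included). Hence
$K^{-1} = B^{-1} \otimes C^{-1}$ and $\log|K| = m\log|C| + n\log|B|$: one
$n \times n$ Cholesky per likelihood evaluation instead of a dense
$5n \times 5n$ factorization, and every gradient reduces to $n \times n$
element-wise sums against $\alpha = C^{-1}YB^{-1}$. This is an algebraic
identity, not an approximation; the dense route is retained for the
independent-per-output noise option and doubles as the oracle path in the
test suite.

**Noise coupling.** Whether the white kernel should be shared through $B$
(noise correlated across channels in proportion to signal coupling) or be
independent per output is genuinely open; both are implemented
(`noise = "coupled"` / `"independent"`), coupled is the default. For
per-channel Z-scores only the marginal noise share $B_{ii}\sigma^2_w$
matters, which both models fit freely, so calibration is insensitive to this
choice; cross-channel noise correlation is where they differ.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| ICM rank $R$ | 2 | – | $W$ is $5\times 2$ plus $\mathrm{diag}(\kappa)$; rank 2 spans the intensity/shape axis pair without over-parameterizing 5 outputs. Tests cover $R \in \{1, 2, 5\}$ implicitly through module defaults. |
| Lengthscale | shared (isotropic) | standardized input units | PMA and GA are z-scored with training-fold statistics, sex left 0/1, so one $\ell$ is meaningful; an ARD option exists (`ard = TRUE`). |
| Restarts | 3 (`mogp_fit`), 1 (`fit_atlas`) | – | Atlas work fits thousands of voxels whose likelihood surfaces are well-behaved after standardization; single-restart fits were indistinguishable in held-out error while 3x cheaper. Raise per-voxel restarts via `atlas_config(n_restarts=)`. |
| Folds | 5 | – | Every fifth subject in enrolment order; deterministic given ordering, order-sensitivity intended. |
| Jitter | $10^{-8} \to 10^{-4}$ (relative) | – | Cholesky ladder; failure after the ladder raises with diagnostics. |
| Predictive SD floor | $10^{-6}\times$ channel SD | data units | Avoids Z blow-ups at near-deterministic voxels; floored voxels are QC-flagged. |
| Extrapolation window | warn ±2, refuse ±6 weeks | weeks PMA | Predictions far outside the training age range are illustrations, not estimates. |
| Zeta | $k=8$, $n_{ref}=80$, patch 27 | – | Distance to nearest of $k$ k-means centroids over reference patches; $n_{ref}$ clamps with a warning when fewer reference subjects exist. A kNN variant (mean distance to the $k$ nearest patches minus their mean pairwise distance) ships behind `variant = "knn"`. |

## The synthetic world

`generate_cohort()` draws, per voxel $v$ (tissue label $l$), channel $c$,
subject $s$:

$$y = \mu_{l,c}(x_s) + u_s(v, c) + \varepsilon,$$

with mean trajectory
$\mu = \beta_0 + \beta_1\,\mathrm{PMA} + A\,\mathrm{logistic}((\mathrm{PMA} - m)/w)
 + \gamma\,(\mathrm{PMA} - \mathrm{GA}) + \eta\,\mathrm{sex}$,
a subject effect $u_s \sim N(0, \sigma_u^2)$ drawn once per subject (the
deviation *fingerprint*; follow-up scans reuse it with persistence $\rho$:
$u(t_2) = \rho\,u(t_1) + \sqrt{1-\rho^2}\,\mathrm{fresh}$), and noise
$\varepsilon \sim N(0, \sigma_\varepsilon^2)$ correlated across channels by a
per-label correlation matrix. Covariates emulate a perinatal cohort: GA
preterm (24–36 wk) with probability 0.3, otherwise term (37–42 wk), scan
following birth by an exponential postnatal interval (mean 2 weeks) — most
infants scanned soon after birth, preterm infants spread up to
term-equivalent age.

Defaults state the world once: $\sigma_\varepsilon = 1$ (the intensity
unit), $\sigma_u = 0.5$ (individual differences at half the noise scale),
sigmoid midpoint 36 wk and width 2 wk (maturation centred before term),
linear slopes 0.08/wk for intensities and 0.02/wk for displacements,
prematurity slopes 0.05 and 0.01/wk, sex effect 0.1 (the model covers sex
but no effect size is established for it, so the default is deliberately
small). Lesions are spheres added to a single channel with amplitude
expressed in units of $\sigma_\varepsilon$.

**What a green test does and does not establish.** The generator matches the
model's assumptions: Gaussian, stationary-in-noise, spatially independent
voxels, i.i.d.-across-voxel fingerprints, perfectly co-registered. Passing
tests establish correctness of the machinery (exact GP algebra, calibrated
out-of-fold Z under a well-specified model, the qualitative orderings the
detection and fingerprinting methods are supposed to produce). They do not
establish performance on real data, where registration error, bias fields,
heavy-tailed artefacts and spatially structured individual differences all
matter — and where the published numbers (mean AUC near 0.95 with cluster
enhancement, identification of 35–38 of 46 infants) were obtained.

Two scale artefacts of desk-size grids are worth naming. First, a 27-voxel
patch around each lesion creates a "ring" of background voxels whose patches
contain lesion voxels; on a $10^3$ grid this ring is tens of percent of the
background, on a real brain it is negligible, so detection experiments here
use the largest grids the time budget allows. Second, with few admissible
sphere centres, lesions planted in many subjects collide at the same voxels
and contaminate the normative fit — which is also why the detection
experiments train the atlas on lesion-free subjects and score the lesioned
subjects as an independent dataset, matching how a lesion cohort sits
outside a normative training sample.

## Numerical choices

- Outputs are standardized per channel and inputs z-scored per training
  fold; predictions are de-standardized. An affine-equivariance test pins
  this down.
- Optimization is L-BFGS-B on log-transformed positive parameters
  ($W$ unconstrained), analytic gradients, restart jitter seeded and
  derived from a base seed; the best restart by log marginal likelihood
  wins, exact ties by lowest restart index.
- The scale indeterminacy between $B$ and the kernel variances
  ($cB \otimes k/c$) is left free, as is conventional; predictions are
  invariant to it.
- Degenerate (constant-across-cohort) voxels are excluded from the mask with
  a logged count; constant *shape elements* (a legitimately zero shear) are
  instead fitted as centred zeros (`allow_constant`).
- Per-voxel fit failures are flagged, propagate NaN, and abort the run only
  above a 5% failure fraction.
- Affine decomposition uses QR with sign-corrected positive diagonal
  (graphics convention): stretch = diag(U), shear = dimensionless ratios.
  A polar variant (rotation from SVD, symmetric factor carrying the shape)
  is available for sensitivity checks; both recompose exactly.
- Native-space rendering pulls back through the inverse affine and adds the
  displacement sampled in template space (displacement before affine in the
  template-to-native composition); the order is a stated convention, logged,
  since the upstream convention is not fixed.
- Fingerprint rank ties are broken pessimistically (a tie at rank 1 counts
  as a failure).

## Design decisions that were genuinely open

- **Per-fold atlases are retained** (5 fits per voxel). Out-of-fold Z needs
  them; prediction for new subjects moment-matches the mixture of fold
  posteriors unless an all-data refit is requested (`final_fit = TRUE`).
- **Zeta's exact definition** is summarized in one line by its source; the
  default here is distance-to-nearest-centroid after per-voxel k-means
  (k = 8), with a kNN-zeta alternative shipped for comparison. When fewer
  distinct patches than k exist, the distinct patches are the centroids.
- **Reference resampling**: the reference set is resampled per scored
  subject with a seed derived from the subject, rather than fixed once;
  either reading is consistent with the method description.
- **Edge policy** for patches: out-of-grid neighbours replicate the border;
  in-grid but out-of-mask neighbours take the centre value; a zero-fill
  flag exists.

## Known limitations

- Exact GP: cost per voxel is $O(n^3)$ in subjects per likelihood
  evaluation (with the Kronecker factorization, not $O((5n)^3)$); cohorts of
  a few hundred are comfortable, thousands are not. No sparse or variational
  approximations, by scope.
- Gaussian likelihood throughout; no heteroscedastic or heavy-tailed noise
  options.
- Voxels are fitted independently (parallelizable, order-invariant), so no
  spatial regularization of hyperparameters; neighbourhood context enters
  only through zeta, never through smoothing.
- The synthetic cohort cannot stand in for real-data validation; see above.
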