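---
title: "Donor-lifetime FRET readout from time-gated FLIM plates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Donor-lifetime FRET readout from time-gated FLIM plates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimhca)
```

# Scope

`flimhca` turns per-field-of-view (FOV) stacks of time-gated fluorescence
images into per-strain donor-lifetime statistics and FRET calls. This
vignette is the package's own account of the science inside it: the decay
model and its assumptions, the segmentation and background model, the
fitting and quality-control choices, what the synthetic instrument does and
does not emulate, and the numerical decisions a maintainer would want
spelled out.

# The acquisition model

One FOV is a stack of `r acq_template()$n_frames` frames sharing the
temporal geometry of an `acq_template()`:

* excitation period `T = 12.5` ns (80 MHz pulsed source),
* rectangular detection gate of width `W = 4` ns,
* 5 *prebleach* frames acquired first, all with the gate at delay 0 —
  their purpose is to photobleach cellular autofluorescence before the
  decay is sampled,
* 7 *FLIM* frames at gate delays `r paste(acq_template()$delays_ns,
  collapse = ", ")` ns.

The default of delay 0 for every prebleach frame is a modeling decision —
published acquisition protocols do not pin the prebleach gate position:
the natural way to bleach quickly is to park the gate on the decay peak,
and making the choice explicit in the template keeps it out of the fitting
path entirely (prebleach frames are used only for intensity integration,
never for lifetime fitting — photobleaching transients are unsafe to
fit).

Intensities are kept in camera digital numbers (DN) end to end. The gain
chain of a gated optical intensifier plus CCD is not characterized here, so
no photon-count conversion is attempted; the practical consequence is that
least squares is unweighted by default (see Fitting).

# The gated decay model

Under periodic excitation, fluorescence from earlier pulses overlaps the
current period ("incomplete decays"). For a monoexponential lifetime
$\tau$ and per-period amplitude $A$, the per-period emission density is the
wrapped exponential

$$ f_p(t) = \frac{A}{\tau}\,\frac{e^{-t/\tau}}{1 - e^{-T/\tau}},
   \qquad t \in [0, T). $$

A gate signal is the integral of the IRF-convolved density over the
rectangular gate. For a delta-like IRF this is closed-form,

$$ G(d) = A\,e^{-d/\tau}\,
   \frac{1 - e^{-W/\tau}}{1 - e^{-T/\tau}}, $$

and the factor $1/(1-e^{-T/\tau})$ — about 1.046 at $\tau = 4$ ns — is the
incomplete-decay correction. `model_gated_decay()` treats a sampled IRF as
point masses and evaluates each mass's gate integral with the exact
cumulative of the wrapped exponential, so its only approximation is the
IRF sampling itself; against a brute-force 1 ps circular-convolution
oracle it agrees to better than $10^{-4}$ relative (this is one of the
package's acceptance checks).

Because the amplitude is normalized per period, early gates are *not*
monotone in $\tau$ (a longer lifetime spreads fixed total emission past
the gate), while gates starting at or beyond one gate width are strictly
increasing in $\tau$ on the fit range — that monotone tail is what makes
late gates a lifetime readout, and is verified numerically in the tests.

## Reference reconvolution

The instrument response function is never deconvolved explicitly. Given
the finely sampled decay $R(t)$ of a reference dye of known lifetime
$\tau_{ref}$ (25 ps sampling over the whole period is the canonical
acquisition; a Coumarin-6-like $\tau_{ref} = 2.5$ ns is the default), the
decay for any $\tau$ follows the identity

$$ D_\tau(t) = R(t) + \left(\tfrac{1}{\tau_{ref}} - \tfrac{1}{\tau}\right)
   (R \circledast e_\tau)(t), $$

with $e_\tau$ the period-wrapped exponential kernel and $\circledast$
circular convolution over the period. At $\tau = \tau_{ref}$ the second
term vanishes and the model *is* the reference — handled exactly as a
special case.

Numerically, the convolution treats $R$ as its piecewise-linear
interpolant (after 4× periodic-spline refinement) and integrates the
kernel against it exactly, via the second central difference of the
kernel's closed-form second antiderivative. This keeps the kernel's jump
at the wrap from polluting the quadrature: for references whose features
are resolved by their grid — every measured dye decay — accuracy is second
order in the spacing (measured: $<10^{-4}$ relative against the known-IRF
model at 25 ps). An idealized *discontinuous* reference (a synthetic
delta-IRF reference) is reproduced only to first order in its spacing,
because no sampled representation can localize a jump inside a cell; the
tests therefore exercise that case on a 1 ps grid.

A single global time-origin shift can be estimated from the reference
(`estimate_time_origin()`) and applied to the gate delays; the
short-lifetime (quenched, ~100 ps) reference is used for this diagnostic
role only. Per-pixel IRF drift across the FOV is a documented
simplification: it is not modeled.

# Segmentation and the time-varying background

The intensity image is the pixel-wise sum of all 12 frames minus
`frame count × fixed_background_dn` (camera offset + ambient), clamped at
zero for segmentation only.

**Dead cells** are excluded first: connected components of pixels above
`median + 8·MAD` with area ≥ 40 px (far larger than any focus footprint),
dilated by 2 px. Because the zero-clamp can concentrate half of the
background mass at exactly 0 and collapse the MAD, the robust scale falls
back on the upper-quartile spread when needed; an image with no robust
scale at all (noiseless or empty) excludes nothing, since "typically
brighter" is undefined there.

**Foci** are detected with a modified nonlinear top-hat: the score of a
pixel is its intensity minus the *maximum* over the 24-pixel boundary ring
of the surrounding 7×7 window, thresholded at `k_sigma = 4` robust noise
units (MAD of the score outside the exclusion mask), connected components
formed, and the brightest pixel per component kept (ties broken toward the
smallest row-major index). The threshold is scale-relative, so detection
is invariant to multiplying the image by any positive constant. Centers
within 3 px of the frame edge are discarded rather than given shrunken
windows — keeping every focus's geometry homogeneous matters for the
image-wise fit. The window sizes mirror the 3×3/7×7 geometry of the
downstream masks and are exposed as parameters.

**TVB subtraction**: each focus is the 3×3 square around its center; its
local background ring is the hollow 7×7 boundary, minus pixels in the
exclusion mask or in any focus's member square (overlapping kinetochore
pairs occur in metaphase cells and would contaminate each other's rings).
Per temporal frame, the time-varying background is the *median* over the
surviving ring pixels, subtracted from each member pixel. Foci with fewer
than 8 usable ring pixels are dropped with a warning. Negative subtracted
values are retained — clamping would bias low-signal decays upward. Since
the subtraction is a per-frame median of a local ring, any spatially
uniform per-frame background cancels *exactly*; this background-immunity
invariant is asserted to $10^{-9}$ relative in the tests.

# Image-wise fitting and QC

All focus decays in a FOV are summed frame-wise and fitted together
("image-wise" fitting): for regions sharing one true monoexponential
lifetime, the summed fit is the photon-optimal simple estimator, and the
tests verify that its variance beats single-region fits. Whether an
instrument-side implementation sums decays or jointly fits per-region
amplitudes is an open design choice; the summed variant is adopted here
and documented.

The fit minimizes squared deviation between the aggregate decay and
`model_via_reference(τ, A)`. $A$ is linear and solved in closed form at
each trial $\tau$; $\tau$ is found by bounded scalar minimization on
[0.2, 8] ns (bracketing the mTurquoise2 donor at ~4 ns and cellular
autofluorescence while excluding degenerate $\tau \to 0$ or $\tau \to T$
solutions) with tolerance $10^{-4}$ ns, seeded and sanity-checked by a
rapid-lifetime-determination (RLD) estimate
$\tau_0 = (d_j - d_i)/\ln(G_i/G_j)$ from the first and last
positive-valued gates. Weights are uniform by default — after intensifier
amplification and TVB subtraction the noise is neither Poisson nor of
known variance; an inverse-variance mode is available.

QC: the total signal of a FOV is the summed TVB-subtracted FLIM-frame
signal over all kinetochore pixels, and must *exceed* $1.2 \times 10^5$
DN (strict inequality; the boundary case fails). QC is evaluated after
TVB subtraction so the threshold measures signal, not background — the
alternative ordering is not stated by the acquisition convention this
package follows, and the post-TVB choice is the one that makes the
statistic meaningful.

# Strain statistics

QC-passing image-wise lifetimes are pooled per strain across runs. Each
strain is summarized by median and quartiles (linear interpolation, type-7
quantiles), IQR, and the 95% CI of the median by the box-plot notch
convention $\mathrm{median} \pm 1.57\,\mathrm{IQR}/\sqrt{n}$ — the
standard normal-assumption constant, fixed and documented so it is
auditable. Query strains are compared to their group's single negative
control with the two-sided Wilcoxon rank-sum test: the exact null
distribution when both samples have $n \le 10$ and no ties, a
tie-corrected normal approximation with continuity correction otherwise
(at $n = 8$ the two agree within 0.02, verified on random samples).
Bonferroni divides $\alpha = 0.05$ by the number of *query* strains in
the group; positive controls are tested identically but never counted in
that number. Comparisons never cross groups.

# The synthetic instrument

`render_gated_stack()` is the forward model the analysis assumes, plus the
nuisances it must survive: elliptical cells of autofluorescence
(default 20 DN per pixel per period at τ = 1.2 ns), 1–2 kinetochore foci
per cell rendered by analytic Gaussian-PSF integration over pixel areas
(σ = 0.35 px ≈ 215 nm at the 615 nm pixel pitch; sub-pixel positions are
integrated, not stamped), occasional large bright dead cells, a camera
offset (default 100 DN), and Poisson noise on a pseudo-photon scale with
configurable gain (default 1, making noisy frames integer DN that survive
the 16-bit TIFF round trip bit-exactly).

Bleaching is an exponential per-frame factor (default 1 % per frame)
applied cumulatively across the *prebleach* phase, with the FLIM frames
carrying the final accumulated factor. That places all bleaching where the
acquisition design concentrates it, makes the prebleach frames visibly
non-stationary — so the decision to exclude them from fitting is testable
— and leaves the FLIM-frame *shape* unbiased. A per-FLIM-frame varying
factor would instead inject a systematic ≈ −50 ps lifetime error at the
default rate; modeling photobleaching *during* the FLIM series is out of
scope.

Photon budgets: the default per-focus amplitude is 25 000 DN per period,
so one 9-pixel focus integrates ≈ 5.5 × 10⁴ DN over the 7 FLIM gates and
a two-focus FOV sits at ≈ 1.1 × 10⁵ DN — right at the QC threshold, which
is the regime the screen operates in and the regime where the stochastic
recovery checks are run. These budgets are simulator policy, not measured
fact; no published per-focus DN values exist to calibrate against.

What the simulator does **not** emulate: optical crosstalk of the
spinning-disc unit, vignetting, depth sectioning, acceptor-channel
imaging, per-pixel IRF drift, cell-to-cell lifetime heterogeneity, and
camera read noise as distinct from Poisson noise. Passing tests therefore
demonstrate correctness of the *analysis chain* under its own forward
model with realistic counting noise — not robustness to every artifact of
real instruments.

# Numerical and design choices, collected

* **Coordinates** are row-major and 0-based in all tables; R matrices are
  indexed `[row + 1, col + 1]` internally.
* **TIFF dialect**: frames are 16-bit unsigned integer DN (the CCD's
  native range); delay/role metadata live in a plain-text sidecar.
  `write_fov_stack()` refuses non-integer frames unless asked to
  quantize, so round-trip exactness is never silently lost.
* **Gate profile** is rectangular; the true gate shape of the intensifier
  is not public, and a measured profile can be substituted.
* **Discretization**: reference-grid spacing 25 ps by default; the
  reconvolution engine refines by 4× periodic spline and convolves the
  piecewise-linear interpolant exactly (see above). Gate integration of
  sampled curves uses the trapezoid cumulative with exact handling of
  off-grid gate edges.
* **Ties** in focus detection resolve to the smallest row-major index;
  degenerate (noiseless) images use "strictly positive score" as the
  detection rule since the robust noise scale is zero.
* **Unfittable FOVs** (no foci, or a non-positive aggregate) are flagged
  with infinite residual and fail QC; they never raise errors mid-plate.
* **Monte-Carlo problem sizes**: the heavy validation studies run at
  reduced frame geometry chosen to keep the full suite comfortably
  affordable on one CPU while preserving the full-plate *statistical*
  structure — 96×96 px frames for replicate-FOV and segmentation studies,
  80×80 px frames with 4 cells per FOV for the 200 simulated screening
  plates (2 strains × 3 wells × 15 FOVs, i.e. 45 FOVs per strain, the full
  plate design) behind the power and type-I rates. Frame size affects
  compute, not the per-focus photon budget or the per-FOV statistics that
  power depends on.
* **Type-I rate**: the null-plate study measures the rejection rate of a
  test whose true size is just under the nominal 0.05; over 100 seeded
  plates the observed count is binomial and can fluctuate a point or two
  around 5 % from seed to seed. The reported number is the honest
  measured rate, never adjusted.

# Known limitations

Monoexponential fitting only — with 7 gates there is no support for
resolving FRETing and non-FRETing donor subpopulations, so the screen
detects interactions rather than quantifying FRET efficiency or stoichiometry.
No pixel-wise lifetime maps. No phasor or Bayesian estimators. No
correction for static dipole orientation effects. Well/plate random
effects are not modeled (comparisons pool FOVs within strain). The
synthetic-data caveats above bound what the validation can claim about
real instrument data.
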