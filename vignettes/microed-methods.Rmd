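---
title: "Models and methods behind microedtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind microedtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette explains the models and numerical choices the package makes,
what the synthetic-data generator does and does not emulate, and where the
design was genuinely open.

## The conversion model

Integrating electron detectors report pixel values on an ADU scale that can
be negative: read noise fluctuates around a dark level, and the native
formats (MRC2014 movie stacks, TIA/SER series) store signed or floating
values. Crystallographic data-reduction suites consume SMV images with an
unsigned 16-bit payload, so negative excursions must be handled explicitly
rather than silently wrapped. The conversion adds a user-chosen per-data-set
**pedestal** to every pixel; pixels whose raw value is at or below the
negated pedestal are set to zero and *counted*, and the per-frame zeroed
fraction is reported so a mis-chosen pedestal is visible (with sane
pedestals — 8 ADU for a Falcon III-like detector, 128 ADU for a CetaD-like
one — these fractions are of order 10⁻⁴ or less). The counting criterion is
`raw <= -pedestal`: a pixel landing exactly at zero is a no-op numerically
but is still flagged, which keeps the audit conservative. No dark-current or
flat-field correction is applied anywhere; the conversion is intentionally a
pure re-encoding plus geometry derivation.

The SMV header is the ADXV/MOSFLM-common key set (`HEADER_BYTES`, `SIZE1/2`,
`TYPE`, `BYTE_ORDER`, `PIXEL_SIZE`, `DISTANCE`, `WAVELENGTH`, `OSC_START`,
`OSC_RANGE`, `PHI`, `TIME`, `BEAM_CENTER_X/Y`, `BIN`), serialized as
`KEY=value;` lines inside `{...}` padded to a 512-byte multiple. Everything
derivable is derived: the wavelength from the acceleration voltage, the
oscillation start from the frame index, the pixel size from the physical
pixel and binning. The virtual sample-to-detector distance is *not*
derivable from the movie metadata and must be supplied; the error message
says exactly that. The beam centre is written in mm (the unit the targeted
suites accept); a flag on the CLI could re-express it in pixels, but mm is
the default because the header's `PIXEL_SIZE` makes the conversion
unambiguous. Stages are rotated from high tilt towards zero, so the signed
per-frame oscillation is typically negative; `OSC_RANGE` is written as its
absolute value and `OSC_START` decreases monotonically, which downstream
suites accept.

Frames stored by a Falcon III-like camera are the *average* of 40 subframes.
Pixel values are written as read, with no rescaling to summed counts: the
detector's linearity rule (single-frame linear range ≈ 6000 ADU, hence
< 150 ADU on the 40-frame-averaged scale, `linear_adu_threshold`) is defined
on the averaged scale, and rescaling would break it.

## Geometry

All geometry uses exact relations, not small-angle shortcuts: the
relativistic electron wavelength
λ = h / √(2 m₀ e V (1 + eV / 2 m₀ c²)) with CODATA 2018 constants
(0.025079 Å at 200 kV), and d = λ / (2 sin θ) with 2θ = atan(r / D). The
differences from the small-angle form are below print precision at typical
camera lengths but grow at short distances, and exactness costs nothing.
"Detector edge" means the half-width of the frame's shorter axis, not the
corner diagonal — this is the convention that reproduces the published edge
resolutions (2.1 Å at D = 2380 mm, 2.3 Å at 2660 mm, 2.8 Å at 3200 mm for
2048 × 2048 frames of 28 µm binned pixels at 200 kV).

The exposure ledger assigns frame *i* the exposure accumulated by its end,
`i × rate × t_exp`. The alternative (frame midpoint) changes nothing
structurally; end-of-frame was chosen because the published "maximum
exposure of any merged frame" statistic is exactly the last merged frame's
end-of-frame exposure. The exposure rate itself is a user input: it is
measured, not derived, and instrument reports typically quote an estimate
(≈ 0.01 e⁻ Å⁻² s⁻¹); the camera presets carry that value with that caveat.

## Gain estimation

For a background of Poisson-distributed primary events recorded at G ADU
per event, recorded values have mean G·n and variance G²·n, so
**G = var/mean** (index of dispersion). This method-of-moments estimator is
used as-is rather than a maximum-likelihood scaled-Poisson fit: the extra
structure buys nothing at the pixel counts involved (≥ 10⁵), and var/mean is
the field's standard. Two background-selection paths are supported, because
practice varies: a dedicated flat exposure (use every pixel,
`spot_exclusion_quantile = 1`) or a diffraction image (exclude the brightest
1 % by default to suppress Bragg spots, or pass an explicit mask).
Quantile truncation of a genuine Poisson sample biases var/mean slightly low
(≈ 6 % at the default 0.99 on a λ = 50 background) — the mask path exists
precisely so that users who can predict spot positions avoid that bias.
Gaussian read noise inflates the variance; a known read-noise variance can
be subtracted. Constant frames yield G = 0 with a degenerate-statistics
warning rather than an error, since flat test inputs are common.

## Merging under 4/mmm

The asymmetric-unit map applies all 16 tetragonal Laue operations
(sign changes of h, k, l and the h↔k swap; Friedel inversion is contained in
them) and picks the lexicographically greatest image — a deterministic
canonical representative that needs no ASU boundary case analysis. Friedel
pairs merge, matching standard MicroED treatment. R_merge uses the classical
Σ|Iᵢ − ⟨I⟩| / ΣIᵢ over multiply-observed reflections; singleton groups carry
no spread information and are excluded from both sums (the common scaling
programs' convention). CC½ splits each multiply-observed group into random
halves and correlates the half means across groups; the split is seeded and
the caller's RNG state is restored afterwards, so results are reproducible
and the package never perturbs a session's random stream. Negative
intensities are retained throughout: the conversion deliberately preserves
negative pixels, and clipping negative integrated intensities would bias the
merged means upward.

## The shared decay fit and D50

Radiation damage shows first as an exponential falloff of mean diffracted
intensity with exposure x. Per-frame mean intensities (observations first
filtered to a closed tilt window, default [−30°, +30°], to suppress
path-length effects, and a closed resolution window, default 2.70–20 Å) are
modelled as `A_c · exp(−B · x)` with one amplitude per crystal and one decay
constant shared per camera. The fit minimises squared residuals in *linear*
intensity space: log-space fitting is biased under multiplicative noise and
cannot digest non-positive means, which genuinely occur in weak data.
Numerically the problem is solved by variable projection — for fixed B the
optimal amplitudes have the closed form A_c = Σyᵉ/Σe² with e = exp(−B·x) —
so only B is searched (bracketed 1-D minimisation to ~10⁻¹² followed by a
BFGS polish), initialised from pooled per-series log-linear regressions.
This is exact to optimizer tolerance on noiseless data and has no
multi-start fragility. A fitted B ≤ 0 raises a warning (no detectable decay)
and leaves D50 undefined; otherwise **D50 = ln 2 / B**, the exposure at
which intensity halves relative to the zero-dose extrapolation. Points are
unweighted by default; the per-frame observation counts are returned so a
caller can weight if desired.

Completeness versus exposure merges only frames with end-of-frame exposure
strictly below each cutoff. The exposure at a target completeness (e.g.
95 %) is linearly interpolated between bracketing cutoffs, since the
underlying quantity is continuous and snapping to knots would quantise the
answer by the cutoff spacing.

Rocking curves — one reflection's intensity against rotation angle — are fit
with a Gaussian `h·exp(−(φ−c)²/2w²)` by weighted least squares (weights
1/σ², unweighted if σ are absent), moment-initialised. If the intensity sits
on a single frame the width is unidentifiable below the sampling, so it is
floored at half the frame spacing with a warning.

## The simulator: what a green test establishes

`simulate_movie` generates frames as
`gain · Poisson(background) + spots + N(0, σ_read) − pedestal_truth`, with
each Bragg spot contributing Poisson-many photons scattered over a Gaussian
footprint at its (h,k,0)-zone position, intensities decaying as
`I₀ · exp(−B·x)` and modulated by a per-spot Gaussian rocking factor.
Subframe averaging is modelled by dividing the Poisson components by the
averaging count — valid because a sum of independent Poisson subframes is
one Poisson draw. Random streams are split per component (background /
spots / read noise), each seeded independently from the master seed, so
switching one component off leaves the others' draws untouched; all
generation preserves the caller's RNG state. Defaults state a plausible
world: gain 1 (direct-detector-like), background 20 events/pixel/frame,
B = 0.277 Å² e⁻ (D50 = 2.5 e⁻ Å⁻²), exposure rate 0.01 e⁻ Å⁻² s⁻¹, a
20 × 20 × 30 Å tetragonal toy cell, spot footprint σ = 1.5 px.

Deliberate non-physics: spot positions are static (a single zero-tilt zone
projection; the Ewald-sphere sweep is represented only by the rocking
*intensity* factor, which is all the downstream analytics consume), there
are no structure factors, no dynamical diffraction, no detector MTF/DQE,
and no dark-current drift. A green parameter-recovery test therefore
establishes that the estimators are correct *for the assumed statistical
model* — Poisson counting, exponential decay, Gaussian read noise — not
that they are robust to systematic effects real detectors add.
`simulate_reflection_table` skips images entirely and emits observation
tables whose frame means are exactly `A_c · exp(−B·x)` (times optional
multiplicative noise), with Miller indices cycling through a shuffled
unique set so completeness grows steadily; its default cycles the unique
set twice per movie, covering the ASU halfway through the scan.

For the CLI simulator preset the virtual distance defaults to 650 mm with a
256-px frame and a d_min of 2.5 Å for the toy cell — chosen once so the
spot-grid spacing and unique-set size resemble a real (downscaled)
experiment; these are synthetic-world constants, not calibrations.

## Numerical and degenerate-input policy

Tolerances: the decay fit's 1-D search runs to ~10⁻¹² in B and is polished
by BFGS (relative tolerance 10⁻¹⁴); the Gaussian rocking fit uses
`nls` with `scaleOffset = 1` so exact-fit (zero-residual) data converge
instead of erroring. Ties in the ASU map cannot occur (the lexicographic key
is injective on each orbit). Degenerate inputs follow one rule: impossible
requests error with instructions (missing distance, empty tables, targets
never reached — the error carries the maximum completeness attained);
identifiability failures warn and return a defined fallback (zero-variance
gain, B ≤ 0, width floor).

## Known limitations

MRC modes 0/1/2/6 only (no float16/4-bit); SER 2-D image series only; the
unique-set generator handles orthogonal cells (sufficient for the tetragonal
target symmetry plus the generic −1 path); no resolution-shell binning of
merge statistics (overall values only); no per-reflection damage modelling;
no electron-counting-mode formats. The Laue-group catalogue contains 4/mmm
and −1 — adding groups means adding operation sets, the canonicalisation is
generic.
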