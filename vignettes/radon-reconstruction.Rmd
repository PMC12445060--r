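---
title: "Reconstructing community radon exposure from a silo source term"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing community radon exposure from a silo source term}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radonrecon)
```

## The problem

The K-65 silos at the Fernald uranium-processing site stored high-radium
raffinate from 1952 to 1988 and leaked radon-222 continuously. No routine
radon monitoring existed before 1980, so exposure of the surrounding
community must be reconstructed: from an event-level release timeline, from
joint-frequency wind climatology, and from month-resolution residential
histories collected decades later by questionnaire. `radonrecon` implements
that reconstruction as a discrete (central-value) model on a polar receptor
grid, producing annual outdoor concentrations per sector, duration-weighted
per-subject exposures, and exceedance statistics against the EPA 4 pCi/L
action level. Everything reconstructed here is the increment **above**
natural background (0.24–0.58 pCi/L in the region); background is never
added.

## The model

For a receptor in compass octet $d$ at distance $x$ from the source centre,
the concentration in period $t$ is

$$
X_{d,t}(x) \;=\; K\left(\frac{x}{\rho}\right)^{c}
\cdot \sum_{q=1}^{6}\sum_{s=A}^{F}\frac{f_{q,d',s}}{u_q}
\cdot D_s(x) \cdot Q_t \cdot \varphi_{\mathrm{resid}}\,\varphi_{\mathrm{met}},
$$

with the terms:

* **Calibration factor** $K(x/\rho)^c$: an empirical power-law correction
  fitted against 1980s monitoring data, with $\ln K$ centred at $-0.44$
  (SD 0.69), $c$ centred at $0.19$ (SD 0.32), and source radius
  $\rho = 50$ m (the two silos treated as one circular area source). The
  discrete model fixes $K$ at its geometric mean $e^{-0.44}$ and $c$ at its
  mean; no sampling mode is provided. Receptors inside the source footprint
  ($x < \rho$) are rejected.
* **Wind ratio** $\sum_q \sum_s f_{q,d',s}/u_q$ (s/m): the joint frequency
  of speed class $q$, direction $d'$ and Pasquill–Gifford stability class
  $s$, divided by the class-representative speed
  $u_q \in \{1,3,5,7,9,11\}$ m/s (the open $>10$ m/s class is represented
  by 11; calms are absorbed by the 0–2 m/s class). $d'$ is the direction
  **reciprocal** to the receptor octet: wind is named by where it blows
  from, so a southwesterly exposes north-eastern receptors. Frequencies are
  stored factored as $f_{q,d,s} = h_s\, g_{q,d|s}$ with $\sum_s h_s = 1$
  per month and $\sum_{q,d} g_{q,d|s} = 1$ per class; both normalisations
  are validated on load. Sixteen-direction roses are consolidated to the
  octet grid by splitting every intermediate direction in half, which
  conserves totals exactly; annualisation is the unweighted mean over the
  12 monthly tables (month lengths differ by at most ~10%, well inside the
  other uncertainties).
* **Diffusion function** $D_s(x)$ (m$^{-2}$): the sector-averaged
  ground-level Gaussian plume with the wind speed factored out,
  $D_s(x) = \sqrt{2/\pi}\,/\,(\sigma_z(s,x)\cdot 2\pi x/8)$, using the
  45° octet sector width.
* **Source term** $Q_t$: the piecewise-constant release rate (Ci/y),
  converted to Ci/s with the Julian year ($3.1557\times 10^{7}$ s).
* **Residual factors** $\varphi$: lognormal corrections for terrain and for
  using a five-year composite climatology; both have geometric mean 1 and
  are fixed at 1 in discrete mode.
* A units factor $10^{12}\ \mathrm{pCi/Ci} \div 10^{3}\ \mathrm{L/m^3}$
  yields pCi/L.

Radioactive decay in transit is neglected (the 3.8-day half-life is long
against minutes of travel across an 8 km domain), and radon progeny are out
of scope.

## Design choices that were genuinely open

**Boundary months of the release timeline.** The published event table
prints each event's end month as the next event's start month (June 1953
closes silo-1 filling *and* opens the silo-2 era; September 1958 likewise).
The package assigns each shared month to the **earlier** event, i.e. the
transition happens on the first day of the following month. This yields a
contiguous, non-overlapping 438-month timeline whose median integral is
164,890 Ci — equal to the published headline total of 160,000 Ci at the two
significant figures to which it is printed. Assigning shared months to the
later event instead would give 165,248 Ci, which rounds to
$1.7\times 10^{5}$ and contradicts the printed total; that is why the
earlier-event rule was adopted. A consequence worth knowing: the mean rate
for 1953 is $(6\cdot 1900 + 6\cdot 4900)/12 = 3400$ Ci/y.

**Vertical dispersion scheme.** The original reconstruction used a
diffusion curve fitted to 1980s monitoring data that is published only as a
figure. Rather than digitise a plot, the package uses the Briggs
open-country interpolation formulas for $\sigma_z$ by stability class —
standard, closed-form, covering A–F over the 0.1–10 km range — as the
default scheme (`dispersion_config()` accepts a custom coefficient matrix).
The calibration power law $(x/\rho)^c$ is the model's own shape correction
on top of whatever scheme is used. The practical consequence is that
**absolute** concentrations differ from the originally published sector
tables (Briggs rural $\sigma_z$ is more dispersive than the
monitoring-fitted curve, so levels here are lower), while every **relative**
structure — sector rankings, octet footprint, year-to-year ratios, the
constant maximum/mean ratio — is preserved. The reconstructed
maximum-to-mean ratio per sector, `max(annual)/mean(annual)` over
1952–1988, is 1.391 here against 1.38–1.39 across the published top-ten
sector table.

**Area source vs point source.** The sector-averaged point-source formula
is evaluated at the receptor's distance from the source centre, with an
evaluation floor of $2\rho = 100$ m and no virtual-source offset. All
receptors of the default grid sit at 1600 m or farther, where the 50 m disk
is indistinguishable from a point: a brute-force 2-D quadrature of
point-source plumes over the disk, swept across the 45° sector, agrees with
the closed form within 10% for all six stability classes between 500 and
8000 m (worst case ≈ 6%, class A at 500 m, where the crosswind Gaussian
starts to leak out of the sector).

**Sector geometry.** The true sector-id-to-geometry mapping is not
published in full; the ids whose octet and ring appear in the published
exposure and population tables are pinned to that geometry, and the
remaining ids are assigned deterministically so that each of the 40
(octet, ring) cells is occupied and the grid has 100 sectors. One published
id appears with two different octets in the population table (NW in the
1950s block, SW in the 1980s block); the SW entry is used. Ring distances
are the rounded $1600 \cdot \mathrm{ring}$ m of the published tables, not
the exact mile.

## Residential histories and exposure aggregation

Cleaning follows the study's rules exactly: a missing FROM month becomes
1 July and a missing TO month 30 June (the mid-year default); records
missing either year are dropped; a FROM date before the subject's date of
birth is replaced by the DOB when the DOB lies inside the exposure window
(subjects born after the window are dropped); unmappable sector ids are
dropped; surviving intervals are clipped to July 1952 – December 1988.
Residence runs from the first day of the FROM month to the last day of the
TO month. Cleaning is idempotent, and an interval inverted by the defaults
(e.g. missing FROM month in the same year as a March TO date) is dropped
rather than silently repaired. Dates of birth are accepted as ISO strings
or SAS day counts (origin 1960-01-01). Overlapping residences of one
subject are kept and both contribute; the study data offer no basis for
splitting them.

Concentrations are computed per sector-month with that month's wind table
and that month's release rate; the annual sector value is defined as the
mean of its 12 monthly values, so the two resolutions are exactly
consistent. A subject's annual exposure is the mean over their resident
sector-months of the year, and their overall mean is the month-weighted
mean across years — equivalently the plain mean over all resident months —
which reproduces the study's worked example: 5 years at one sector plus 7
at another gives $(5\bar{x}_1 + 7\bar{x}_2)/12$. Every subject in a sector
receives the identical concentration for a given month. Year-level
separability (concentration ratios across years equal source-rate ratios in
every sector) holds exactly on a month-invariant climatology and to within
the seasonal modulation otherwise.

Geometric summary statistics are computed on logs of strictly positive
subject means; the count of skipped non-positive values is reported
alongside. Sector rankings break ties alphabetically by id. Reported CSVs
round to 6 decimals; full precision is kept internally.

## What the synthetic data emulate — and what they do not

The real cohort is consent-restricted and the tower joint-frequency tables
live in an out-of-print agency report, so the generator reproduces their
*statistical structure*:

* residence-level missingness at the published rates (8.49% FROM month,
  7.55% TO month, 0.49% FROM year, 0.72% TO year), plus a configurable
  rate of records starting before the subject's birth;
* moves concentrated mildly in June/July and depleted in
  February/March/November/December;
* prevailing winds from NW/W/SW, an excess in the calm (0–2 m/s) class,
  and a winter-fast/summer-calm seasonal cycle
  (`seasonal_amplitude`, with `month_variation` adding month-to-month
  jitter; both set to 0 give 12 identical tables, the configuration used
  when a test needs exact separability);
* decade-weighted entry into the study area with geometric stay lengths
  (`move_rate` = 0.08/y, mean stay ≈ 12 years — a plain choice documented
  here, not a claim about the real cohort).

Each generator stream derives its own sub-seed from the single scenario
seed, so adding a stream never perturbs existing draws, and the same seed
reproduces a scenario byte for byte. The generator does **not** emulate the
true 1987–1991 tower statistics, the cohort's actual spatial distribution,
or address-level geocoding: tests passing on synthetic data validate the
*pipeline arithmetic* (cleaning, aggregation, counting, conservation,
linearity), not the historical accuracy of any particular exposure value.
For the same reason the published cohort-level exposure tables and
exceedance counts (1019 subjects above 4 pCi/L, 3059 above 2 pCi/L) are not
reproducible here.

## Numerical checks and problem sizes

The test suite anchors every closed form by hand-derived values
($K$-factor at 50 and 1600 m, $\sigma_z$ for classes D and F, the diffusion
function at 1600 m, a fully chained 9.0 pCi/L toy concentration) and checks
each aggregation against an independent brute-force oracle (576-cell sums
for the wind algebra, disk quadrature for the plume, per-subject scans for
exceedance, month-by-month accumulation for the source integral).
Property checks run at fixed seeds with: 1000 random roses for
consolidation conservation (residual $\le 10^{-12}$), a 10,000-subject
cohort for missingness recovery (3 binomial SDs), and a 40-subject locked
scenario whose output files carry frozen md5 digests as a regression
tripwire. The acceptance script rebuilds a 9318-subject scenario — the size
of the retained study cohort — from its seed argument.

## Known limitations

* Absolute concentration levels depend on the $\sigma_z$ scheme (see
  above); comparisons against the original reconstruction should be made
  on relative structure, or after supplying a custom scheme calibrated to
  the original diffusion curve.
* Emission before July 1952 (drummed storage on site from late 1951) is
  taken as zero because the release table quantifies nothing earlier.
* No workplace/school time budgets, no indoor-infiltration model (outdoor
  and indoor levels are argued to equilibrate for an outdoor source), no
  radon-progeny dosimetry, and no probabilistic propagation of $K$, $c$ or
  the $\varphi$ factors — the model is deliberately the discrete
  central-value reconstruction.
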