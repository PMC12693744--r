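---
title: "Egg inspection by detection, voting and barcode positioning: methods"
author: "nestscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Egg inspection by detection, voting and barcode positioning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestscan)
```

## The problem

In caged squab (meat-pigeon) production, every nest must be checked daily:
which nests contain eggs, and how many. Done by hand this is slow and is a
major source of egg breakage. An automated inspection rig drives a camera
past the cages, photographs each nest a few times, detects the eggs, reads
a barcode label on the cage front to learn *where* it is, and writes one
"position–quantity" record per visit to a database.

`nestscan` implements that system at desk scale. The trained neural
detector that a production rig would use is out of scope (no farm imagery
is distributable); in its place the package provides (i) the two numeric
cores such a detector relies on — a parameter-free attention energy
function and a dynamically focused IoU loss — implemented and tested as
standalone numerics, and (ii) a deterministic classical detector behind a
pluggable provider contract, so the complete pipeline runs end to end on
synthetic scenes with known ground truth.

## SimAM: attention from an energy function

For a target neuron with activation $t$ in one channel of a feature map
with $M = H \times W$ neurons, define

$$
e_t(w, b) = (y_t - (wt + b))^2
  + \frac{1}{M-1}\sum_{i \ne t}\left(y_o - (w x_i + b)\right)^2
  + \lambda w^2,
$$

with binary labels $y_t = 1$ and $y_o = -1$: the linear transform is asked
to separate the target from every other neuron in its channel. Minimising
over $(w, b)$ has the closed form

$$
e_t^* = \frac{4(\hat\sigma^2 + \lambda)}
             {(t - \hat\mu)^2 + 2\hat\sigma^2 + 2\lambda},
$$

where $\hat\mu$ and $\hat\sigma^2$ are the mean and biased variance of the
*other* neurons. A neuron far from its channel mean attains low minimal
energy, and its attention weight $\mathrm{sigmoid}(1/e_t^*)$ approaches 1;
`apply_simam()` multiplies the feature map by these weights channel by
channel, with no learnable parameters anywhere.

Two choices were genuinely open and are fixed here as follows:

* **Labels and regulariser.** The energy function is only minimisable once
  $y_t, y_o$ and $\lambda$ are fixed; we use the conventional $y_t = 1$,
  $y_o = -1$ and $\lambda = 10^{-4}$ (configurable via `simam_config()`).
* **Channel statistics.** `simam_weights()` defaults to mean/variance over
  *all* $M$ neurons — the standard $O(M)$ fast approximation, which
  differs from the exact leave-one-out statistics by $O(1/M)$. The exact
  per-neuron form is available as `exact = TRUE`; it is the version the
  test suite checks against brute-force numerical minimisation of
  `neuron_energy()` (agreement to $10^{-5}$ on random $4\times4$
  channels, where the approximation error of the fast form would be
  orders of magnitude larger).

## WIoU-v3: dynamic non-monotonic focusing

The base quantity is the IoU loss $L_{IoU} = 1 - IoU$. WIoU-v1 amplifies
it by a center-distance term,
$L_{WIoU1} = L_{IoU}\exp\!\big(d^2 / (W_g^2 + H_g^2)\big)$, where $d$ is
the distance between the predicted and target box centers and $W_g, H_g$
are the sides of their smallest enclosing box (held constant under
differentiation). WIoU-v3 then scales by a focusing coefficient of the
anchor's *anomaly degree* $\beta = L_{IoU} / \bar L_{IoU}$, the ratio of
the anchor's loss to an exponential moving average of batch losses:

$$
r(\beta) = \frac{\beta}{\delta\,\alpha^{\beta - \delta}}, \qquad
L_{WIoU3} = r(\beta)\, L_{WIoU1}.
$$

This reading of the coefficient is pinned down by its published anchor
property — $r = 1$ exactly when $\beta = \delta$ — and gives a single
interior maximum at $\beta = 1/\ln\alpha$: ordinary anchors get gain
$\approx 1$, moderately hard anchors get the largest gain, and extreme
outliers are damped. Defaults are $\alpha = 1.9$, $\delta = 3$ and EMA
decay $0.9$, all configurable through `wiou_params()` since no canonical
values are fixed for this detector. The EMA (`update_ema()`) is seeded
with the first batch mean and then updated once per batch with the batch
mean; $\beta$ is computed against it as a detached constant.

## Temporal majority voting

Nest-level interference — a parent briefly covering the nest, eggs rolling
a few pixels, momentary blur — is transient, so the system photographs the
same nest $N = 3$ times at 10 s intervals (longer than typical
interference, making frame outcomes approximately independent) and
declares "egg present" when at least $T = 2$ frames detect an egg. With
per-frame detection probability $P_d$ the system-level reliability is the
binomial tail

$$
P_{system} = \sum_{k=T}^{N}\binom{N}{k} P_d^k (1 - P_d)^{N-k},
$$

which at $P_d = 0.8$, $N = 3$, $T = 2$ equals $0.896$ — well above the
single-frame rate. `system_reliability()` computes the sum exactly;
`simulate_cycles()` confirms it by seeded Monte-Carlo.

Whether the vote applies to nest-level presence only or to each egg
identity is ambiguous in the field, so both are provided. `fuse_presence()`
is the plain T-of-N vote. `fuse_count()` generalises it to per-egg
granularity: detections from all frames are clustered by greedy
nearest-center matching (descending confidence, ties to the lower frame
index, a cluster accepting at most one detection per frame within
`match_radius`, default 40 px at 1920×1080 to absorb egg rolling), and
each cluster supported by at least $T$ distinct frames contributes one
egg. A detection seen in a single frame only — a spurious false positive —
is thereby filtered out, which is exactly why the detector upstream is
tuned for recall (confidence threshold 0.25) rather than precision.
Frames whose provider fails are treated as "no detection" votes rather
than aborting the cycle.

## The barcode positioning chain

Each cage carries an EAN-13 label whose 12 data digits embed an 8-digit
position code (below). `read_cage_label()` runs the classical chain:

1. **Grayscale**, $Y = 0.299R + 0.587G + 0.114B$ rounded and clamped.
   These are the ITU-R BT.601 luma weights; a red weight of 0.229 is
   sometimes quoted for this pipeline alongside a BT.601 citation, which
   we read as a transcription slip — the coefficients are configurable
   (`grayscale_coeffs()`) but must sum to 1.
2. **3×3 median filter** (edge replication): removes impulse noise while
   preserving the bar/space step edges.
3. **Otsu threshold** from the 256-bin histogram: exhaustive scan of
   $t \in [0,255]$ maximising $\omega_0\omega_1(\mu_0-\mu_1)^2$ with
   class 0 defined as values $\le t$ and ties broken to the smallest $t$
   (both conventions are ours; the method itself does not fix them).
4. **Canny** on the binarised image — Gaussian smoothing
   ($\sigma = 1.4$), Sobel 3×3 gradients, 4-sector non-maximum
   suppression (strict against one neighbour so ideal two-pixel plateaus
   thin to one pixel), double threshold 50/150 with 8-connected
   hysteresis. Running the edge detector after binarisation follows the
   stage order of the chain and has a practical benefit: the
   low-contrast wire grid never reaches the contour stage.
5. **Contour screening**: one externally traced boundary per 8-connected
   component (Moore-neighbour tracing; contour points are pixel centers,
   so a filled $w \times h$ rectangle's boundary encloses shoelace area
   $(w-1)(h-1)$), followed by a minimum-area-rectangle filter — area at
   least 0.1% of the image and long/short ratio within $2\!:\!1 \pm 25\%$,
   the label shape that cage grids, nests and drinking cups do not share.
   Candidates are tried largest first.
6. **EAN-13 decoding** from the *median-filtered grayscale* (not the
   global binarisation): ≥5 scanlines parallel to the candidate's long
   axis, each binarised with its own Otsu threshold so uneven lighting is
   handled per line, run-length measured against the 95-module structure
   (3 guard + 42 + 5 center + 42 + 3 guard), left digits decoded through
   L/G parity (recovering the implicit 13th digit), right digits through
   R patterns, both reading directions tried (a located rectangle is
   orientation-ambiguous by 180°), majority vote across scanlines, and a
   mandatory check-digit verification. Decoding is implemented from the
   symbology definition rather than delegated to a library detector, so
   the chain is self-contained and each stage is testable; the matching
   renderer `render_ean13()` makes the decoder's inverse available to
   tests and to the scene generator.

Failures are typed: `nestscan_no_barcode` when no well-formed module
structure is found, `nestscan_corrupt_code` when structure is found but
the checksum fails. Everything in the chain is deterministic.

## Position codes and records

A nest is addressed by four zero-padded two-digit fields — house (1–25),
cage within the building (1–4), cage group (1–99), nest (1–6) — giving
59,400 valid 8-digit codes (`position_code()`, `parse_position()`,
`format_position()`). The distinction between the second and third fields
is kept exactly as the numbering scheme defines it, with deliberately
neutral field names. The 8-digit payload occupies EAN-13 data digits
5–12; digits 1–4 are a configurable prefix, default `2000`, chosen from
the restricted-distribution numbering space so farm labels cannot collide
with retail articles; the 13th digit is the standard checksum.

Completed inspections land in an append-only store (`record_store()`)
with gap-free integer ids, the uid as text (leading zeros preserved), the
fused count (zero counts are recorded — an empty nest is information),
and an `MM-DD HH:MM:SS` display timestamp alongside a full ISO timestamp.
Re-inspection appends rather than updates, so the table is an audit log;
persistence is lossless CSV (`export_records_csv()` /
`import_records_csv()`).

## The reference detector

`detect_eggs()` is a deterministic classical stand-in for the trained
network: grayscale → Otsu → 8-connected components → per-component
ellipse-likeness scoring. A component passes if its pixel area lies in
`[min_area, max_area]` (defaults 1500–30000 px², sized for eggs at
1920×1080) and its minimum-area-rectangle side ratio is at most 1.8.
The *fill ratio* is defined against the ellipse inscribed in the
rectangle — component area over $\tfrac{\pi}{4}$ of the rectangle area —
so a clean ellipse scores ≈ 1 (against the raw rectangle it could never
exceed $\pi/4 \approx 0.785$, which would make a 0.8 gate unusable).
Confidence is fill ratio × (short/long side); the default acceptance
threshold of 0.25 keeps recall high and leaves false-positive suppression
to the voting stage. `run_provider()` wraps any detector callable,
re-indexes frames 0..N−1, and converts per-frame exceptions into empty
results plus a warning.

## The synthetic scene generator

`scene_spec()` / `render_scene()` emulate the statistical structure the
system assumes at the acquisition resolution of 1920×1080: a dark
nest-floor background (gray 70) crossed by a darker wire grid (pitch 90
px, thickness 4 px), zero to six light egg ellipses (semi-axes ~38–52 by
~30–42 px, albedo 200–235, random orientation, mild radial shading,
placed without mutual overlap and clear of the label), a rendered EAN-13
label on a white backing at ≈2:1 aspect, and salt-and-pepper noise at 1%
density by default. The wire grid is drawn beneath the eggs — the camera
looks down onto the nest floor — while frontal interference is modelled
at the cycle level. `cycle_spec()` / `render_cycle()` produce N frames of
the same layout in which each frame is independently occluded with
probability `p_occlude` (a body-sized blob hides all eggs at once; the
label on the cage exterior stays visible) and egg centers drift by up to
`egg_jitter` (6 px) between frames. Optional per-frame Gaussian blur is
off by default: momentary blur alone is not a failure mode of the chain.
One seed drives layout, noise and occlusion through independent
sub-streams, so layouts are comparable across occlusion settings, and
every render is bit-reproducible.

What the generator does *not* emulate — and what passing tests therefore
do not show about farm data: feather/feed clutter and partial occlusion,
specular reflections and lighting gradients, perspective distortion of
the label, print wear, and eggs whose appearance changes late in
incubation. The generator's role is to validate the machinery (geometry,
decoding, voting, record-keeping) under known ground truth, not to
certify field accuracy.

## Numerical choices

* Coordinates are 0-based with origin top-left, x rightward, y downward;
  boxes are continuous real rectangles with no ±1 pixel area correction;
  zero-area boxes are rejected, not clamped.
* Border handling is edge replication in every raster operation.
* Otsu: class 0 is $\le t$; ties to the smallest $t$.
* Canny NMS: strict comparison against the second neighbour thins ideal
  step plateaus to single-pixel edges, biasing edges to the lower-index
  side by half a pixel.
* Module quantisation in decoding: each digit's four run widths are
  scaled to sum to 7 and rounded with largest-residual correction,
  clamped to 1–4 modules.
* Greedy count-fusion ties: descending confidence, then lower frame
  index; cluster centers are running means.
* All randomness flows through explicit integer seeds; there is no hidden
  global-RNG dependence, and the caller's RNG state is restored.

## Problem sizes in the test suite

Unit tests exercise the image chain on 640×360 scenes with
proportionally scaled geometry (module 2 px, eggs ~2× smaller), which
preserves every structural feature at a fraction of the cost. The
end-to-end acceptance property runs 100 seeded noise-free cycles at the
full 1920×1080 default. The occlusion/miss-rate property
(`simulate_presence_cycles()`) runs 10⁴ cycles at the Bernoulli level:
for noise-free scenes with a perfect-recall detector, a frame's presence
outcome is fully determined by its occlusion draw, so rasterising those
cycles would only re-sample the same binomial process; a separate
image-level test confirms that rendered occlusion induces exactly the
vote predicted by the occlusion flags.

## Known limitations

* The voting mechanism's stated boundary is persistent occlusion: when a
  parent sits through most sampling points, most frames fail and the nest
  is reported empty. The package reproduces this boundary
  (`p_occlude = 1` cycles) rather than solving it; thermal or other
  modalities would be needed.
* The decoder handles in-plane rotation but not perspective skew.
* The classical detector's thresholds are properties of the synthetic
  scenes; its recall/precision figures say nothing about farm imagery.
* The record store is single-process and in-memory with CSV persistence;
  a production deployment would write to a remote database instead.
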