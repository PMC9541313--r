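---
title: "Quantifying cell division in fern gametophyte apical meristems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell division in fern gametophyte apical meristems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prothallus)
```

## The biological problem

Fern gametophytes (prothalli) are free-living, haploid sheets of cells, one
cell thick. Their growth is driven by two successive apical meristems: first
a single wedge-shaped **apical initial** that renews itself by oblique
divisions through its centre, and later a **multicellular apical meristem**
of small rectangular cells that takes over after the apical initial
terminates itself with a periclinal division. In the multicellular meristem,
the repeating structural unit is a **three-celled packet**: two adjacent
rectangular cells in the marginal layer over one short rectangular cell in
the submarginal layer. Four elementary division patterns act on a packet:

* **Type I** — anticlinal division of an upper cell,
* **Type II** — periclinal division of an upper cell,
* **Type III** — anticlinal division of the lower cell,
* **Type IV** — periclinal division of the lower cell,

where *anticlinal* means the new wall is roughly perpendicular to the tissue
margin and *periclinal* roughly parallel to it. Trichomes — differentiated
hair cells — arise by asymmetric division of marginal or inner cells,
protrude from the sheet, and are excluded from all meristem statistics.

This package implements the full quantitative workflow for this system:
watershed segmentation of membrane-stained images, time-lapse lineage
tracking with division detection, orientation and packet classification,
and the layer-rate and size statistics, together with a cell-based growth
simulator that provides ground truth for every stage.

## The statistics computed

With time-lapse windows of 24 or 48 h, cells counted *before* imaging, and
per-window division events classified as anticlinal (a) or periclinal (p),
the package computes, per time-lapse set:

* **Packet type percentages.** Per packet, Type I % = (number of Type I
  divisions)/2 x 100 and likewise Type II (two upper cells); Type III % =
  (number of Type III)/1 x 100 and likewise Type IV (one lower cell). A
  packet in which any cell divides more than once in the window is
  *complex* and excluded. Because all three cells are scored, the four
  percentages can sum to more than 100.
* **Per-48-h layer division rates.** For each of
  marginal/submarginal x a/p: (number of divisions)/(number of layer cells
  before imaging)/(timeframe in h) x 48 x 100 %.
* **Dividing-cell orientation fractions.** Per layer: (number of a (or p)
  divisions)/(all division events in the layer) x 100, with every event of
  a multiply-dividing cell counted.
* **Size versus division.** Mean +/- SE cell area at window start for cells
  that divided versus cells that did not, trichomes excluded, compared with
  a Student's two-tailed t-test.
* **Growth rate.** Per gametophyte, area(48 h)/area(0 h), with a two-tailed
  t-test between treatment groups.

The unit of replication is the time-lapse set; SE is always SD/sqrt(n of
sets). "Student's two-tailed t-test" is implemented as the pooled-variance
test; Welch's correction is available behind the `welch` flag everywhere.
Oblique division events are excluded from the a/p layer rates (only a and p
are defined there) but are retained in all event tables, and the exclusion
count is reported.

## The synthetic gametophyte

No raw micrographs of this system are publicly deposited, so the package is
validated against its own growth simulator, which emits images *and* the
complete ground truth (polygons, lineage, labelled events).

**Geometry.** Cells are convex-ish polygons in a conforming planar
subdivision. A division inserts a chord through the (grown) parent:
anticlinal chords along the local margin normal through the centroid,
periclinal chords along the tangent, oblique chords at 45 degrees. Daughter
polygons tile the parent exactly, so area is conserved at division to
machine precision. T-junction vertices are propagated to neighbours after
every division round, keeping shared boundaries identical in both incident
cells.

**The grammar.** From a spore (or from a rectangular starting sheet,
`init_rows` x `init_cols`, standing for the established stage), the apical
initial self-renews obliquely with probability `p_oblique` per 48-h window
or terminates periclinally with `p_terminate`; its derivatives divide
anticlinally with `p_derivative`, widening the marginal row. After
termination, marginal cells within the apical sector act as packet upper
cells (Type I with `q1`, Type II with `q2` per window) and submarginal
cells adjacent to them as packet lower cells (`q3`, `q4`). Trichomes
initiate with probability `p_trichome` per eligible cell by cutting a
corner triangle off the margin-facing vertex; the spike apex is then
extruded outward by `trichome_elong` per window. Inner-origin trichomes are
flagged out-of-plane and rendered as a bright disk, as they appear in a
maximum projection.

**Growth.** Each window the whole tissue dilates uniformly about its
area-weighted centroid by `growth_factor` (linear). Cells that never divide
therefore compound growth while dividing lineages are reset by halving —
this, together with the `size_gate` (cells below it may not divide), is
what links small cell size to high division activity in the simulated
tissue. Two implementation notes matter here. Per-cell local expansion
proposals averaged at shared vertices do *not* integrate into tissue-level
growth (each vertex displacement is bounded by one cell radius), so the
dilation must be global. And the gate must sit *below* the typical daughter
area, otherwise fresh daughters are censored for several windows and the
size-division correlation inverts.

**Defaults and why.**

| parameter | default | rationale |
|---|---|---|
| `p_oblique`, `p_terminate` | 0.8, 0.2 | the apical packet divides in every observed 48-h window; self-renewal dominates for several windows before termination |
| `q1`, `q2` | 0.15, 0.35 | placeholder values reproducing the reported ordering II > I in upper cells; not literature estimates |
| `q3`, `q4` | 0.30, 0.10 | likewise III > IV in lower cells |
| `meristem_fraction` | 0.4 | division activity is restricted to the apical meristem domain; only the apical sector of the margin proliferates |
| `growth_factor` | 1.15 | non-dividing cells reach the 2000-3000 um^2 scale of the published colour maps within ~8 windows from ~250 um^2 founders |
| `size_gate` | 100 um^2 | blocks only extreme slivers; typical daughters (~130-170 um^2) stay eligible |
| `p_trichome` | 0.02 | a few trichomes per gametophyte over a multi-window series |
| `cell_w` x `cell_h` | 18 x 14 um | small rectangular meristem-stage cells |
| pixel size (render) | 0.7 um/px | a 512-px frame covering a few hundred um, as in confocal practice |

**What the simulator does not emulate.** Real confocal stacks have
depth-dependent signal loss, uneven staining, wall brightness variation and
out-of-focus light; the renderer uses uniform wall intensity, Gaussian blur
and additive Gaussian noise. Tissue mechanics (pressure, wall tension,
differential growth) are not modelled; expansion is a uniform dilation. The
24-h imaging interval is supported as window metadata with the x48/timeframe
normalization in the statistics, but no mid-window geometric interpolation
is generated. A green test therefore establishes that the pipeline recovers
truth under idealized-but-noisy imaging, not that it is robust to every
microscope artefact.

## Pipeline design choices

* **Segmentation** is marker-controlled watershed: Gaussian smoothing,
  percentile background subtraction, normalization to [0, 1]; a tissue mask
  by thresholding, hole filling and 1-px erosion (the erosion trims the
  blur halo that otherwise inflates edge cells); seeds from regional minima
  of the h-minima transform; flooding without watershed lines; regions
  below `min_cell_area` (20 um^2) merged into the neighbour with the
  longest shared boundary. Everything is deterministic; labels are
  renumbered in raster order.
* **Registration** estimates a similarity transform (rotation, translation,
  *and* isotropic scale). Samples are physically moved between imaging
  sessions, and the tissue measurably expands within a window; a rigid
  transform leaves a radial drift of (growth - 1) x radius at the margin —
  exactly where divisions happen — which pushes daughter overlap fractions
  below the matching criteria. The objective is mask IoU (raw overlap is
  degenerate in the scale direction); fine stages score the IoU of
  1-px-dilated wall masks because the outer mask of a blob-shaped tissue is
  nearly rotation-invariant while the internal wall pattern pins rotation.
  Grid ties from nearest-neighbour quantization resolve toward the
  incumbent (zero rotation, unit scale).
* **Lineage matching** assigns each t1 cell to the t0 cell containing the
  largest fraction of its transformed area (ties to the smaller label); a
  division is a t0 cell with at least two children at overlap fraction >=
  0.5; children below 0.25 are flagged unmatched rather than silently
  attached. Parents with several children get a +/-2 px local shift polish
  of their footprint before the 0.5 criterion is applied, mirroring the
  local correspondence a human tracker uses. Multi-time-point series are
  always decomposed into consecutive windows.
* **Orientation** is the acute angle between the new wall's principal
  direction (the daughters' shared boundary pixels) and the margin tangent
  at the margin point nearest the parent centroid: anticlinal above 60
  degrees, periclinal below 30, oblique between. The bands are symmetric
  about 45 degrees and configurable. Both the simulator and the pipeline
  estimate tangents on the margin resampled to uniform 2-um arc spacing
  (smoothing window 5 points for chord placement, 11 for the raster
  margin); without uniform resampling, corner cells get systematically
  discordant tangents between the polygon world and the pixel world.
* **Packets** require both rectangularity tests (solidity >= 0.9 and
  minimum-area-bounding-rectangle fill >= 0.8, computed from pixel
  coordinates with half-pixel rim corrections) on all three members;
  overlapping candidate triples are resolved greedily by mean
  rectangularity, each cell in at most one packet.
* **Trichome flagging** passes simulator truth through in synthetic runs.
  The rule mode (>= 60% of area outside the convex hull of the remaining
  tissue, or aspect ratio >= 3 along the outward normal *with at least 10%
  protrusion*) is an honest heuristic: freshly divided anticlinal daughters
  are thin and normal-aligned, and corner cells sit partly outside the
  hull of the others, so rule-mode precision plateaus around 0.85 in dense
  meristems even though recall of well-protruded spikes exceeds 0.9.
* **Statistics** drop undefined per-set values (empty layers, zero-event
  sets) listwise with reported counts.

## Degenerate inputs and tolerances

Constant images preprocess to all-zero wall probability with a
`constant_input` flag rather than an error. An empty tissue mask, an
unreadable transform (mask overlap below 50% of the smaller mask), a
non-viable simulation (`max_cells` exceeded) and a zero baseline area all
fail with explicit messages. Walls of fewer than 2 px leave the orientation
unassigned with a QC note, and the event is retained. Area conservation at
division is exact to 1e-6 relative tolerance (measured ~1e-16); equation
implementations are tested against brute-force recounts to 1e-12.

## Known limitations

* Rule-based trichome detection is bounded by hull-of-others artefacts
  (see above); use truth mode for synthetic data and expect ~0.85 precision
  on real-style images.
* The wedge/trapezoid shapes of the earliest phase are idealized; a spore
  start needs several windows before layer statistics are meaningful.
* Very small daughters (< ~30 um^2) at coarse pixel sizes (>= 0.7 um/px)
  can be merged by segmentation; use 0.5 um/px when late-stage meristems
  with several division rounds are analyzed.
* The simulator models only the one-cell-thick vegetative sheet: no
  gametangia, no 3D structure, no mechanics.
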