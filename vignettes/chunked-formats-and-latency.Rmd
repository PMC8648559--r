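---
title: "Chunked bioimage formats and the latency benchmark: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chunked bioimage formats and the latency benchmark: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ngffbench)
```

## The model

Every image handled by this package is five-dimensional with canonical axis
order `(t, c, z, y, x)`. Users construct geometry in the microscopy-facing
XYZCT order (`image_spec(x, y, z, c, t)`); the constructor reverses it, so
that a serialized chunk is C-order over `(t, c, z, y, x)` with x fastest —
the byte order of the chunked next-generation layout. In R, dense arrays are
held with `dim = (x, y, z, c, t)`, because R is column-major: the same
memory order, read from the other end.

A dataset is a **multiscale pyramid** of chunked arrays. Level 0 is the full
resolution; each subsequent level halves `y` and `x` with ceiling and leaves
`z`, `c`, `t` untouched; the pyramid stops at the first level whose `y` and
`x` both fit inside one chunk. Two presets define the benchmark conditions:

* `cycif` — whole-slide cyclic immunofluorescence, XYZCT
  64000×64000×1×8×1, chunks 256×256 (one z/c/t per chunk), 16-bit unsigned.
  One chunk is exactly 128 KB (binary KB throughout: 256·256·2 = 131072 B).
* `lsm` — light-sheet time-lapse volume, 1024×1024×1024×1×100, chunks
  32×32×32, 64 KB each.

The y/x-only halving policy and the stop rule are design choices: applied to
the full presets they give 9 and 6 levels and ≈668 k and ≈4.37 M chunk
files, the same order of magnitude as the published datasets
(≈700 k / ≈4.3 M, which also include converter-specific metadata and depend
on an unstated pyramid depth, so they serve as magnitude cross-checks, not
exact targets). Halving z as well misses those counts by a wide margin.
Chunk extents on `t` and `c` are fixed at 1, consistent with "2D chunks" and
"3D chunks" being per-plane and per-subvolume units.

Chunk grids are ceil-division: per axis, the grid size `g` satisfies
`(g−1)·chunk < size ≤ g·chunk`. Edge chunks are stored full size with fill
value 0 — the raw, uncompressed chunk encoding has no way to express a
partial chunk — and readers trim the fill on assembly.

## Synthetic data

The generator emulates the benchmark images as deterministic gradients
rather than noise:

\[ v(t,c,z,y,x) = (t + c + z + y + x) \bmod 2^{16}. \]

The exact formula is a design choice (the original generator is only
described as "gradient images"); this one was picked because it is a pure
function of the coordinates — any chunk can be rendered independently,
byte-identically, in any format — and because it gives the downsampling
operator a closed form. Downsampling is a 2×2 block mean over y/x with
flooring (blocks shrink at the image edge): a level-0 2×2 block holds
`v, v+1, v+1, v+2`, so away from the modular wrap the level-1 value equals
the level-0 top-left value plus one. Tests exploit this to verify whole
pyramids without a reference image.

Presets scale down by a linear divisor applied to `x, y` (cycif) or
`x, y, z, t` (lsm) with floor — `scale = 8` turns the LSM preset into
(t,c,z,y,x) = (12, 1, 128, 128, 128) — while chunk shapes never scale, so
chunk-level behaviour (requests, bytes per request) matches the full-size
conditions. Scaling an axis below one sample is an error, not a clamp.

What the generator does **not** emulate: realistic texture and noise,
compression behaviour (everything is stored uncompressed, deliberately —
chunk sizes stay constant), acquisition metadata beyond array geometry, and
multi-writer workloads. Passing tests therefore demonstrate correctness of
layout, conversion and access accounting, not image-analysis performance on
real data.

## Storage layouts

All I/O goes through a small key–value contract (`store_kv`: `get`,
ranged `get`, `put`, `list`, `exists`), mirroring object storage. Three
layouts sit on top of it:

* **NGFF** (Zarr v2 dialect): JSON metadata documents (`.zgroup`,
  `.zattrs`, one `.zarray` per level), chunk keys
  `level/t/c/z/y/x` with the "/" separator, compressor `null`, C order,
  fill 0. Multiscale group attributes use the early ("0.2"-era) form —
  dataset paths without per-level transforms — and the validator ignores
  unknown attribute fields. Labels live under `labels/<name>` as their own
  multiscale groups; high-content plates as `plate` attributes over
  row/column well groups, each field a multiscale image. JSON is written
  with a fixed key order so metadata bytes are stable across runs.
* **Chunked HDF5** (native subset): one dataset per level
  (`level0`, `level1`, …; link entries sorted bytewise as the format
  requires), classic version-0 superblock, version-1 object headers,
  symbol-table root group, and a version-1 B-tree chunk index with the
  format's default node capacity. The subset is sufficient for standard
  HDF5 tooling to open the files (h5py is the oracle in the tests). The
  reader issues one ranged read per B-tree node plus one for the payload:
  request count per chunk = tree depth + 1 ≥ 2, which is precisely the
  monolithic-format cost the benchmark quantifies.
* **Tiled pyramidal BigTIFF**: one tiled 2D image per (t, c, z) plane of
  every level, sub-resolutions flagged `NewSubfileType = 1`, tile size =
  the chunk's y/x face, a minimal OME-XML `ImageDescription` carrying the
  5D sizes (tifffile is the oracle). TIFF is planar, so a volumetric chunk
  is assembled from `z × ⌈y/tile⌉ × ⌈x/tile⌉` tile reads — 32 for the LSM
  chunk. The reader caches the IFD chain at open; per chunk it issues
  exactly the tile reads.

Converters stream chunk by chunk through a common reader interface
(`open_dataset`), so memory stays bounded by one chunk (plus one z-slab in
the TIFF writer) regardless of dataset size; `verify_equivalence` compares
level shapes and every voxel and reports the first mismatching coordinate.

## The benchmark

`sample_chunks` draws `n` (default 100) level-0 chunk locations uniformly
**with replacement** (the original description says only "random
sequence"), reproducibly from a seed; the identical sequence is issued to
every format. `time_chunk_reads` opens each dataset once, untimed — access
cost should not include the one-off open — and then times each retrieval
individually on a monotonic clock. The 1-byte probe read measures fixed
per-request overhead.

Remote regimes are modelled by a latency-injection backend: every read
request sleeps `per_request_delay + bytes × per_byte_delay` seconds and is
appended to a request log. This makes the central claim checkable as
arithmetic: per-chunk time ≈ (requests per chunk) × per-request delay, with
requests/chunk = 1 for NGFF, ≥ 2 for HDF5, 32 for volumetric TIFF. Real
networked deployments (web servers, cloud buckets) are deliberately out of
scope — their absolute numbers are hardware-bound, while the request-count
model is what transfers. The backend set is `local` plus the simulator; a
loopback HTTP backend was considered and dropped because no installed R
component provides an in-process HTTP server, and the simulator already
covers the deterministic part of that regime.

## Reporting

Rainclouds combine three layers, each recomputed directly from the CSV rows:
a Gaussian-KDE half-violin, a median/quartile box, and jittered raw points.
Conventions the original description leaves open were fixed as: Scott's
bandwidth rule `sd · n^{-1/5}` (exposed as a parameter), a grid spanning
the data ± 3 bandwidths (trapezoid integral within 1% of 1 by
construction), type-7 linear-interpolation quantiles, and uniform jitter on
`[−w/2, w/2]` from a seeded RNG. Zero-variance groups draw as a box with a
warning instead of a degenerate density spike. Figures are written as
vector SVG by default; tests assert on the returned layer data frames, not
on image bytes.

## Configuration and tooling choices

The command-line entry point (`cli_main`, installed as `inst/cli/ngffbench`)
uses YAML for configuration files (the natural choice among the installed
parsers; note the config key `n_chunks`, since a bare `n:` is boolean
shorthand in YAML 1.1) with flags taking precedence. Exit codes: 0 success,
1 operation failure, 2 usage error.

## Problem sizes and numerical choices in the test suite

The suite exercises the presets at 1/8 linear scale (LSM: 12×1×128³, 1008
chunk files) and 1/100 (CycIF: 1×8×1×640², 112 chunk files), where whole
datasets can be rebuilt, converted and compared voxel-exactly in seconds;
request-count and latency properties use a 64³ volume whose chunks have the
full 32-plane z-extent. Latency sweeps use injected delays of 0, 1, 10 and
50 ms. Timing assertions allow a ~10% slack below the injected floor for
sleep and clock granularity. Sample values are held as R integers
(16-bit-safe); byte totals as doubles, exact far beyond any size handled
here.

## Known limitations

* The HDF5 and TIFF implementations are subsets tailored to this layout:
  they do not aim to read arbitrary third-party files (no compression
  codecs, no variable-length types, no sharded/v3 Zarr, no consolidated
  metadata).
* Single-writer semantics only; no concurrent mutation.
* The size model counts full-size uncompressed chunks; it does not model
  compression.
* More than ten pyramid levels would interleave `level10` between `level1`
  and `level2` in bytewise link order inside the HDF5 layout; lookup is
  by name, so this is cosmetic, and no preset reaches that depth.
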