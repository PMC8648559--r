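#' Benchmark dataset presets
#'
#' Two modalities drive the benchmark: `"cycif"`, a whole-slide cyclic
#' immunofluorescence image (XYZCT 64000×64000×1×8×1, 256×256 chunks), and
#' `"lsm"`, a light-sheet time-lapse isotropic volume
#' (XYZCT 1024×1024×1024×1×100, 32×32×32 chunks). Both use 16-bit unsigned
#' samples stored uncompressed.
#'
#' `scale` is a linear divisor applied to the in-plane axes (and `z`, `t`
#' for the volumetric preset): `scale = 8` means every scaled axis is 1/8 of
#' the printed size (floor). Chunk shapes are never scaled, so chunk-level
#' behaviour matches the full-size benchmark.
#'
#' @param name `"cycif"` or `"lsm"`.
#' @param scale linear down-scale divisor (>= 1); 1 gives the full printed
#'   dimensions.
#' @param chunk_edge optional chunk edge override (default 256 for cycif,
#'   32 for lsm).
#' @return an [image_spec()].
#' @examples
#' preset_spec("cycif", scale = 100)$sizes  # t c z y x = 1 8 1 640 640
#' preset_spec("lsm", scale = 8)$sizes      # 12 1 128 128 128
#' @export
preset_spec <- function(name = c("cycif", "lsm"), scale = 1, chunk_edge = NULL) {
  name <- match.arg(name)
  if (scale < 1) stop("scale must be >= 1 (a linear divisor)")
  dims <- switch(name,
    cycif = list(x = 64000, y = 64000, z = 1, c = 8, t = 1, edge = 256L,
                 scaled = c("x", "y")),
    lsm   = list(x = 1024, y = 1024, z = 1024, c = 1, t = 100, edge = 32L,
                 scaled = c("x", "y", "z", "t")))
  for (ax in dims$scaled) {
    v <- floor(dims[[ax]] / scale)
    if (v < 1) stop("scale ", scale, " shrinks axis '", ax, "' below 1")
    dims[[ax]] <- v
  }
  image_spec(x = dims$x, y = dims$y, z = dims$z, c = dims$c, t = dims$t,
             bytes_per_sample = 2L,
             chunk_edge = chunk_edge %||% dims$edge)
}

#' Deterministic gradient sample value
#'
#' The synthetic images are gradients rather than noise:
#' `value = (x + y + z + c + t) mod 2^(8*bytes_per_sample)` at level-0
#' coordinates (0-based). The function is pure in the coordinates, so any
#' chunk can be rendered independently and identically across formats.
#'
#' @param t,c,z,y,x non-negative level-0 coordinates (vectors recycle).
#' @param bytes_per_sample sample width; 2 gives mod 65536.
#' @return integer sample value(s).
#' @examples
#' gradient_value(0, 0, 0, 2, 3)      # 5
#' gradient_value(0, 0, 0, 65535, 1)  # 0 (modular wrap)
#' @export
gradient_value <- function(t, c, z, y, x, bytes_per_sample = 2L) {
  (x + y + z + c + t) %% (2^(8L * bytes_per_sample))
}

# Dense render of a level-0 region, dims (x,y,z,c,t), half-open 0-based
# ranges given as named lists lo/hi in (t,c,z,y,x) names.
render_region_level0 <- function(spec, lo, hi) {
  m <- 2^(8L * spec$bytes_per_sample)
  xs <- if (hi[["x"]] > lo[["x"]]) seq(lo[["x"]], hi[["x"]] - 1) else numeric(0)
  ys <- if (hi[["y"]] > lo[["y"]]) seq(lo[["y"]], hi[["y"]] - 1) else numeric(0)
  zs <- if (hi[["z"]] > lo[["z"]]) seq(lo[["z"]], hi[["z"]] - 1) else numeric(0)
  cs <- if (hi[["c"]] > lo[["c"]]) seq(lo[["c"]], hi[["c"]] - 1) else numeric(0)
  ts <- if (hi[["t"]] > lo[["t"]]) seq(lo[["t"]], hi[["t"]] - 1) else numeric(0)
  arr <- outer(outer(outer(outer(xs, ys, "+"), zs, "+"), cs, "+"), ts, "+") %% m
  array(arr, dim = c(length(xs), length(ys), length(zs), length(cs), length(ts)))
}

# One factor-2 mean-floor downsampling step over y and x (array dims
# (x,y,z,c,t)). Edge blocks shrink; the mean is floored after summing the
# whole 2x2 (or smaller) block, i.e. floor(sum/count).
downsample_xy <- function(arr) {
  pair_sum <- function(a, axis) {
    n <- dim(a)[axis]
    odd <- seq(1, n, by = 2)
    even <- if (n >= 2) seq(2, n, by = 2) else integer(0)
    idx <- function(i) {
      args <- rep(list(quote(expr = )), 5)
      args[[axis]] <- i
      do.call(`[`, c(list(a), args, list(drop = FALSE)))
    }
    s <- idx(odd)
    cnt <- array(1, dim = dim(s))
    if (length(even)) {
      e <- idx(even)
      ne <- dim(e)[axis]
      args <- rep(list(quote(expr = )), 5)
      args[[axis]] <- seq_len(ne)
      sel <- do.call(`[`, c(list(s), args, list(drop = FALSE)))
      sel <- sel + e
      s <- do.call(`[<-`, c(list(s), args, list(value = sel)))
      cel <- do.call(`[`, c(list(cnt), args, list(drop = FALSE))) + 1
      cnt <- do.call(`[<-`, c(list(cnt), args, list(value = cel)))
    }
    list(sum = s, count = cnt)
  }
  px <- pair_sum(arr, 1L)
  sy <- pair_sum(px$sum, 2L)
  cy <- pair_sum(px$count, 2L)
  floor(sy$sum / cy$sum)
}

#' Render a dense region of any pyramid level
#'
#' Level 0 is the gradient itself; level `k` is defined by applying the
#' factor-2 y/x block-mean (floored) operator `k` times. The requested
#' region is mapped back to level 0, rendered, and downsampled; region
#' starts must be chunk-aligned or at least multiples of `2^level` on y/x
#' for the block structure to agree with a whole-level downsample (chunk
#' offsets always are).
#'
#' @param spec an [image_spec()].
#' @param level pyramid level (0-based).
#' @param lo,hi named (t,c,z,y,x) 0-based half-open bounds at that level.
#' @param pyramid optional [build_pyramid()] result (validated against).
#' @return array with dim `(x, y, z, c, t)` extents `hi - lo`.
#' @export
render_region <- function(spec, level, lo, hi, pyramid = NULL) {
  f <- 2^level
  if (level > 0 && (lo[["y"]] %% f != 0 || lo[["x"]] %% f != 0))
    stop("region start on y/x must be a multiple of 2^level")
  lsz <- if (!is.null(pyramid)) pyramid$levels[[level + 1L]] else
    level_sizes(spec, level)
  if (any(unlist(hi[c("t","c","z","y","x")]) >
          lsz[c("t","c","z","y","x")]) || any(unlist(lo) < 0))
    stop("region out of level extent")
  lo0 <- lo; hi0 <- hi
  lo0[["y"]] <- lo[["y"]] * f; lo0[["x"]] <- lo[["x"]] * f
  hi0[["y"]] <- min(hi[["y"]] * f, spec$sizes[["y"]])
  hi0[["x"]] <- min(hi[["x"]] * f, spec$sizes[["x"]])
  arr <- render_region_level0(spec, lo0, hi0)
  for (i in seq_len(level)) arr <- downsample_xy(arr)
  storage.mode(arr) <- "integer"
  arr
}

level_sizes <- function(spec, level) {
  s <- spec$sizes
  for (i in seq_len(level)) {
    s[["y"]] <- as.integer(ceiling(s[["y"]] / 2))
    s[["x"]] <- as.integer(ceiling(s[["x"]] / 2))
  }
  s
}

#' Render one chunk as stored (full-size, zero fill past the extent)
#'
#' @param spec an [image_spec()].
#' @param ref a [chunk_ref()].
#' @param pyramid a [build_pyramid()] result.
#' @return array with dim `(x, y, z, c, t)` equal to the chunk shape;
#'   positions beyond the level extent hold fill value 0.
#' @export
render_chunk <- function(spec, ref, pyramid) {
  lsz <- pyramid$levels[[ref$level + 1L]]
  if (is.null(lsz)) stop("level ", ref$level, " out of pyramid range")
  grid <- grid_shape(lsz, spec$chunk_shape)
  if (any(ref$indices >= grid))
    stop("chunk indices (", paste(ref$indices, collapse = ","),
         ") outside grid (", paste(grid, collapse = ","), ")")
  ck <- spec$chunk_shape
  lo <- as.list(ref$indices * ck)
  hi <- as.list(pmin(ref$indices * ck + ck, lsz))
  arr <- render_region(spec, ref$level, lo, hi, pyramid)
  full <- array(0L, dim = array_dim(ck))
  d <- dim(arr)
  if (all(d > 0))
    full[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), seq_len(d[4]),
         seq_len(d[5])] <- arr
  full
}

#' Full dense array of one pyramid level (small inputs only)
#'
#' Brute-force reference used by tests and by region assembly checks.
#'
#' @inheritParams render_region
#' @return array with dim `(x, y, z, c, t)`.
#' @export
render_level <- function(spec, level = 0L) {
  s <- level_sizes(spec, level)
  zero <- as.list(stats::setNames(rep(0, 5), c("t", "c", "z", "y", "x")))
  render_region(spec, level, zero, as.list(s))
}

#' A chunk source backed by the synthetic gradient
#'
#' Returns `function(ref) -> array`, the producer interface accepted by the
#' format writers, rendering chunks lazily so whole datasets never need to
#' fit in memory.
#'
#' @inheritParams render_chunk
#' @export
gradient_chunk_source <- function(spec, pyramid) {
  force(spec); force(pyramid)
  function(ref) render_chunk(spec, ref, pyramid)
}

#' Generate a complete synthetic multiscale dataset
#'
#' Builds the preset's pyramid and writes it in the requested container:
#' the chunked NGFF layout (`"ngff"`), a chunked multiscale HDF5 file
#' (`"hdf5"`), or a tiled pyramidal BigTIFF (`"ometiff"`). Voxel content is
#' identical across formats for the same spec.
#'
#' @param spec an [image_spec()], e.g. from [preset_spec()].
#' @param format one of `"ngff"`, `"hdf5"`, `"ometiff"`.
#' @param destination directory path for `"ngff"`, file path otherwise.
#' @return (invisibly) a list with `spec`, `pyramid`, `format`,
#'   `destination`.
#' @export
build_dataset <- function(spec, format = c("ngff", "hdf5", "ometiff"),
                          destination) {
  format <- match.arg(format)
  stopifnot(inherits(spec, "image_spec"))
  pyramid <- build_pyramid(spec)
  src <- gradient_chunk_source(spec, pyramid)
  switch(format,
    ngff = write_multiscale(local_store(destination), src, spec, pyramid),
    hdf5 = write_hdf5(destination, src, spec, pyramid),
    ometiff = write_ometiff(destination, src, spec, pyramid))
  invisible(list(spec = spec, pyramid = pyramid, format = format,
                 destination = destination))
}

#' Write the 1-byte overhead probe file
#'
#' A single-byte file read by the benchmark to measure fixed per-request
#' overhead, independent of payload size.
#'
#' @param destination file path.
#' @return the path, invisibly.
#' @export
write_dummy <- function(destination) {
  dir.create(dirname(destination), recursive = TRUE, showWarnings = FALSE)
  writeBin(as.raw(0L), destination)
  invisible(destination)
}
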