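#' Number of planar TIFF tiles covering one chunk
#'
#' TIFF is planar, so a volumetric chunk stored as 2D tiles must be
#' assembled from its z-extent worth of tile reads:
#' `z * ceil(y / tile_y) * ceil(x / tile_x)`. For the volumetric benchmark
#' preset (32x32x32 chunk, 32x32 tiles) this is 32 tile reads per chunk.
#'
#' @param chunk_shape chunk extents `(z, y, x)` (a 5-vector `(t,c,z,y,x)` is
#'   accepted; its last three entries are used).
#' @param tile_shape tile extents `(y, x)`.
#' @return integer tile count.
#' @examples
#' tiles_per_chunk(c(32, 32, 32), c(32, 32))   # 32
#' tiles_per_chunk(c(1, 256, 256), c(256, 256)) # 1
#' @export
tiles_per_chunk <- function(chunk_shape, tile_shape) {
  chunk_shape <- unname(chunk_shape)
  if (length(chunk_shape) == 5L) chunk_shape <- chunk_shape[3:5]
  if (length(chunk_shape) != 3L || length(tile_shape) != 2L)
    stop("chunk_shape must be (z,y,x) and tile_shape (y,x)")
  if (any(chunk_shape < 1) || any(tile_shape < 1))
    stop("extents must be positive")
  chunk_shape[1] * ceiling(chunk_shape[2] / tile_shape[1]) *
    ceiling(chunk_shape[3] / tile_shape[2])
}

#' Open any supported dataset under one reader interface
#'
#' Wraps [open_ngff()], [hdf5_open()] and [tiff_open()] behind a common
#' handle exposing the pyramid level sizes, the chunk shape, and a
#' per-chunk read. The benchmark and the converters are format-agnostic
#' through this interface.
#'
#' @param path dataset path: a directory for `"ngff"`, a file otherwise.
#' @param format one of `"ngff"`, `"hdf5"`, `"ometiff"`.
#' @param store optional [store_kv] backend to read through (e.g. a
#'   [sim_store()]); for `"ngff"` it must be rooted at the dataset, for the
#'   file formats at the file's directory. Defaults to a plain
#'   [local_store()].
#' @return a `dataset_reader`: list with `format`, `levels` (list of named
#'   size 5-vectors), `chunk_shape`, `bytes_per_sample`, and
#'   `read_chunk(ref)`.
#' @export
open_dataset <- function(path, format = c("ngff", "hdf5", "ometiff"),
                         store = NULL) {
  format <- match.arg(format)
  ax <- c("t", "c", "z", "y", "x")
  if (format == "ngff") {
    st <- store %||% local_store(path)
    img <- open_ngff(st)
    levels <- lapply(img$levels, function(z) stats::setNames(z$shape, ax))
    ck <- stats::setNames(img$levels[[1]]$chunks, ax)
    rd <- function(ref) ngff_read_chunk(img, ref)
    bps <- img$bytes_per_sample
  } else if (format == "hdf5") {
    st <- store %||% local_store(dirname(path))
    key <- if (is.null(store)) basename(path) else path
    h <- hdf5_open(st, key)
    levels <- lapply(h$datasets, function(d) stats::setNames(d$shape, ax))
    ck <- stats::setNames(h$datasets[[1]]$chunks, ax)
    rd <- function(ref) hdf5_read_chunk(h, ref)
    bps <- h$datasets[[1]]$bytes_per_sample
  } else {
    st <- store %||% local_store(dirname(path))
    key <- if (is.null(store)) basename(path) else path
    h <- tiff_open(st, key)
    levels <- lapply(h$levels, function(l) l$sizes)
    ck <- c(t = 1L, c = 1L, z = h$chunk_z, y = h$tile_shape[1],
            x = h$tile_shape[2])
    rd <- function(ref) tiff_read_chunk(h, ref)
    bps <- h$bytes_per_sample
  }
  structure(list(format = format, levels = levels,
                 chunk_shape = stats::setNames(as.integer(ck), ax),
                 bytes_per_sample = as.integer(bps), read_chunk = rd),
            class = "dataset_reader")
}

#' Chunk grid of one level of an opened dataset
#'
#' @param reader a [open_dataset()] handle.
#' @param level resolution level.
#' @return named integer 5-vector of per-axis chunk counts.
#' @export
reader_grid <- function(reader, level = 0L) {
  grid_shape(reader$levels[[level + 1L]], reader$chunk_shape)
}

# Dense array of one whole level, assembled chunk by chunk (small data only).
assemble_level <- function(reader, level) {
  lsz <- reader$levels[[level + 1L]]
  ck <- reader$chunk_shape
  g <- reader_grid(reader, level)
  out <- array(0L, dim = array_dim(lsz))
  idx <- expand.grid(x = seq_len(g[["x"]]) - 1L, y = seq_len(g[["y"]]) - 1L,
                     z = seq_len(g[["z"]]) - 1L, c = seq_len(g[["c"]]) - 1L,
                     t = seq_len(g[["t"]]) - 1L)
  for (r in seq_len(nrow(idx))) {
    i <- c(t = idx$t[r], c = idx$c[r], z = idx$z[r], y = idx$y[r], x = idx$x[r])
    arr <- reader$read_chunk(chunk_ref(level, i))
    lo <- i * ck; hi <- pmin(lo + ck, lsz)
    n <- hi - lo
    out[lo[["x"]] + seq_len(n[["x"]]), lo[["y"]] + seq_len(n[["y"]]),
        lo[["z"]] + seq_len(n[["z"]]), lo[["c"]] + seq_len(n[["c"]]),
        lo[["t"]] + seq_len(n[["t"]])] <-
      arr[seq_len(n[["x"]]), seq_len(n[["y"]]), seq_len(n[["z"]]),
          seq_len(n[["c"]]), seq_len(n[["t"]])]
  }
  out
}

reader_spec <- function(reader) {
  s <- reader$levels[[1]]
  image_spec(x = s[["x"]], y = s[["y"]], z = s[["z"]], c = s[["c"]],
             t = s[["t"]], bytes_per_sample = reader$bytes_per_sample,
             chunk_shape = reader$chunk_shape)
}

reader_pyramid <- function(reader) {
  structure(list(levels = reader$levels, policy_id = "xy"),
            class = "pyramid_spec")
}

#' Convert a chunked HDF5 pyramid to the NGFF layout
#'
#' Streams chunk by chunk (bounded memory); the output passes
#' [validate_ngff()] and is voxel-identical to the source.
#'
#' @param hdf5_path source file.
#' @param store destination [store_kv] backend.
#' @return the store, invisibly.
#' @export
hdf5_to_ngff <- function(hdf5_path, store) {
  r <- open_dataset(hdf5_path, "hdf5")
  write_multiscale(store, r$read_chunk, reader_spec(r), reader_pyramid(r))
  invisible(store)
}

#' Convert an NGFF store to a chunked HDF5 pyramid
#'
#' @param store source [store_kv] backend.
#' @param hdf5_path destination file.
#' @return the path, invisibly.
#' @export
ngff_to_hdf5 <- function(store, hdf5_path) {
  img <- open_ngff(store)
  r <- open_dataset("", "ngff", store = store)
  write_hdf5(hdf5_path, r$read_chunk, reader_spec(r), reader_pyramid(r))
  invisible(hdf5_path)
}

#' Convert an NGFF store to a tiled pyramidal BigTIFF
#'
#' @param store source [store_kv] backend (must validate).
#' @param tiff_path destination file.
#' @param tile_shape optional `(y, x)` tile override, as in
#'   [write_ometiff()].
#' @return the path, invisibly.
#' @export
ngff_to_ometiff <- function(store, tiff_path, tile_shape = NULL) {
  r <- open_dataset("", "ngff", store = store)
  write_ometiff(tiff_path, r$read_chunk, reader_spec(r), reader_pyramid(r),
                tile_shape = tile_shape)
  invisible(tiff_path)
}

#' Voxel-level equivalence of two datasets
#'
#' True iff both datasets have the same level count, identical per-level
#' shapes, and every voxel agrees; the first mismatch (level and t,c,z,y,x
#' coordinates) is reported otherwise.
#'
#' @param a,b [open_dataset()] handles, or `list(path =, format =)`
#'   descriptions.
#' @return list with `equal` flag and, on mismatch, `level`, `coord`,
#'   `values`; shape mismatches set `reason`.
#' @export
verify_equivalence <- function(a, b) {
  as_reader <- function(x)
    if (inherits(x, "dataset_reader")) x else open_dataset(x$path, x$format)
  a <- as_reader(a); b <- as_reader(b)
  if (length(a$levels) != length(b$levels))
    return(list(equal = FALSE, reason = sprintf(
      "level count %d vs %d", length(a$levels), length(b$levels))))
  for (l in seq_along(a$levels) - 1L) {
    if (any(a$levels[[l + 1L]] != b$levels[[l + 1L]]))
      return(list(equal = FALSE, reason = sprintf(
        "shape mismatch at level %d", l)))
    va <- assemble_level(a, l)
    vb <- assemble_level(b, l)
    if (!identical(va, vb)) {
      w <- unname(which(va != vb, arr.ind = TRUE)[1, ])  # dims (x,y,z,c,t)
      coord <- c(t = w[5] - 1L, c = w[4] - 1L, z = w[3] - 1L,
                 y = w[2] - 1L, x = w[1] - 1L)
      return(list(equal = FALSE, level = l, coord = coord,
                  values = c(va[w[1], w[2], w[3], w[4], w[5]],
                             vb[w[1], w[2], w[3], w[4], w[5]])))
    }
  }
  list(equal = TRUE)
}
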