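#' @title 5D image geometry
#' @name image_spec
#' @description
#' All images in this package are 5-dimensional with canonical axis order
#' `(t, c, z, y, x)`. The constructor takes sizes in the microscopy-facing
#' "XYZCT" order and reverses them on ingest, so that serialized chunks are
#' C-order over `(t, c, z, y, x)` (x fastest), matching the chunked
#' next-generation layout convention.
#'
#' Chunk extents on `t` and `c` are fixed at 1 unless an explicit
#' `chunk_shape` is supplied; a single `chunk_edge` is applied to `y` and `x`
#' (and to `z` when the image is a volume, i.e. `z > 1`).
#'
#' @param x,y,z,c,t positive integer sizes, XYZCT order.
#' @param bytes_per_sample bytes per sample; 2 (16-bit unsigned
#'   little-endian) is the default used throughout the benchmark presets.
#' @param chunk_edge positive integer edge length applied to the spatial
#'   axes as described above.
#' @param chunk_shape optional explicit 5-vector of chunk extents in
#'   `(t, c, z, y, x)` order, overriding `chunk_edge`.
#' @return an `image_spec` object: a list with `sizes` and `chunk_shape`
#'   (named integer 5-vectors in `(t, c, z, y, x)` order) and
#'   `bytes_per_sample`.
#' @examples
#' sp <- image_spec(64000, 64000, 1, 8, 1, chunk_edge = 256)
#' sp$sizes        # t c z y x
#' chunk_nbytes(sp$chunk_shape, sp$bytes_per_sample)  # 131072 bytes
#' @export
image_spec <- function(x, y, z = 1L, c = 1L, t = 1L, bytes_per_sample = 2L,
                       chunk_edge = 256L, chunk_shape = NULL) {
  sizes <- c(t = t, c = c, z = z, y = y, x = x)
  if (any(!is.finite(sizes)) || any(sizes < 1) || any(sizes != floor(sizes)))
    stop("image sizes must be positive integers, got (",
         paste(sizes, collapse = ","), ")")
  if (!bytes_per_sample %in% c(1L, 2L))
    stop("bytes_per_sample must be 1 or 2")
  if (is.null(chunk_shape)) {
    if (chunk_edge < 1 || chunk_edge != floor(chunk_edge))
      stop("chunk_edge must be a positive integer")
    chunk_shape <- c(t = 1L, c = 1L,
                     z = if (z > 1) as.integer(chunk_edge) else 1L,
                     y = as.integer(chunk_edge), x = as.integer(chunk_edge))
  } else {
    if (length(chunk_shape) != 5L || any(chunk_shape < 1) ||
        any(chunk_shape != floor(chunk_shape)))
      stop("chunk_shape must be 5 positive integers (t,c,z,y,x)")
    chunk_shape <- stats::setNames(as.integer(chunk_shape),
                                   c("t", "c", "z", "y", "x"))
  }
  structure(list(sizes = stats::setNames(as.integer(sizes),
                                         c("t", "c", "z", "y", "x")),
                 chunk_shape = chunk_shape,
                 bytes_per_sample = as.integer(bytes_per_sample)),
            class = "image_spec")
}

#' @export
print.image_spec <- function(x, ...) {
  cat("<image_spec> sizes (t,c,z,y,x):", paste(x$sizes, collapse = "×"),
      "| chunk:", paste(x$chunk_shape, collapse = "×"),
      "|", 8L * x$bytes_per_sample, "bit\n")
  invisible(x)
}

#' Uncompressed byte size of one chunk
#'
#' Product of the chunk extents times the sample width. Edge chunks are
#' stored full-size (zero fill), so this is the byte length of every chunk
#' file in the layout.
#'
#' @param chunk_shape integer vector of chunk extents (any rank).
#' @param bytes_per_sample bytes per sample.
#' @return byte count (double, to stay exact past 2^31).
#' @examples
#' chunk_nbytes(c(256, 256), 2)      # 131072 = 128 KB
#' chunk_nbytes(c(32, 32, 32), 2)    # 65536  = 64 KB
#' @export
chunk_nbytes <- function(chunk_shape, bytes_per_sample) {
  if (any(chunk_shape < 1)) stop("chunk extents must be positive")
  prod(as.numeric(chunk_shape)) * as.numeric(bytes_per_sample)
}

#' Chunk grid shape for one resolution level
#'
#' Ceil-division grid: per axis the count `g` satisfies
#' `(g - 1) * chunk < size <= g * chunk`. Chunk extents larger than the axis
#' size are allowed and give a one-chunk grid on that axis.
#'
#' @param level_sizes integer sizes in `(t, c, z, y, x)` order.
#' @param chunk_shape chunk extents in the same order.
#' @return named integer 5-vector of per-axis chunk counts.
#' @export
grid_shape <- function(level_sizes, chunk_shape) {
  if (any(level_sizes < 1) || any(chunk_shape < 1))
    stop("sizes and chunk extents must be positive")
  g <- as.integer(ceiling(as.numeric(level_sizes) / as.numeric(chunk_shape)))
  stats::setNames(g, names(level_sizes) %||% c("t", "c", "z", "y", "x"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multiscale pyramid of an image
#'
#' Builds the ordered list of per-level sizes: level 0 is the full
#' resolution; each subsequent level halves (with ceiling) the downsampled
#' axes. The default policy halves `y` and `x` only, which reproduces the
#' file-count scale of the benchmark datasets. The last level is the first
#' whose `y` and `x` sizes are both at most the corresponding chunk extents
#' (so the level-0-plane grid is 1 by 1 there).
#'
#' @param spec an [image_spec()].
#' @param policy downsampling policy; only `"xy"` (factor-2 ceil halving of
#'   y and x) is implemented.
#' @return a `pyramid_spec`: list with `levels` (list of named size
#'   5-vectors, full resolution first) and `policy_id`.
#' @examples
#' p <- build_pyramid(image_spec(1024, 1024, 1024, 1, 100, chunk_edge = 32))
#' length(p$levels)  # 6: x/y run 1024,512,256,128,64,32
#' @export
build_pyramid <- function(spec, policy = "xy") {
  stopifnot(inherits(spec, "image_spec"))
  policy <- match.arg(policy, "xy")
  levels <- list(spec$sizes)
  cur <- spec$sizes
  while (cur[["y"]] > spec$chunk_shape[["y"]] ||
         cur[["x"]] > spec$chunk_shape[["x"]]) {
    cur[["y"]] <- as.integer(ceiling(cur[["y"]] / 2))
    cur[["x"]] <- as.integer(ceiling(cur[["x"]] / 2))
    levels[[length(levels) + 1L]] <- cur
  }
  structure(list(levels = levels, policy_id = policy), class = "pyramid_spec")
}

#' @export
print.pyramid_spec <- function(x, ...) {
  cat("<pyramid_spec>", length(x$levels), "levels, policy", x$policy_id, "\n")
  for (i in seq_along(x$levels))
    cat(sprintf("  %d: %s\n", i - 1L, paste(x$levels[[i]], collapse = "×")))
  invisible(x)
}

#' Reference to one stored chunk
#'
#' @param level non-negative resolution level (0 = full resolution).
#' @param indices 5 non-negative per-axis chunk indices, `(t, c, z, y, x)`.
#' @return a `chunk_ref` object.
#' @export
chunk_ref <- function(level, indices) {
  if (length(indices) != 5L) stop("chunk indices must have rank 5")
  if (level < 0 || any(indices < 0)) stop("level and indices must be non-negative")
  structure(list(level = as.integer(level),
                 indices = stats::setNames(as.integer(indices),
                                           c("t", "c", "z", "y", "x"))),
            class = "chunk_ref")
}

#' Byte and file-count accounting for a chunked multiscale dataset
#'
#' Counts full-size uncompressed chunk files per level and in total, plus the
#' metadata documents (one array-metadata document per level and one group
#' attribute document).
#'
#' @param spec an [image_spec()].
#' @param pyramid a [build_pyramid()] result for `spec`.
#' @return a `size_report`: list with `per_level_chunk_counts`,
#'   `total_chunk_files`, `total_chunk_bytes`, `metadata_file_count`, and a
#'   `table` data.frame with columns `level`, `count`, `bytes`.
#' @export
size_model <- function(spec, pyramid) {
  stopifnot(inherits(spec, "image_spec"), inherits(pyramid, "pyramid_spec"))
  per_chunk <- chunk_nbytes(spec$chunk_shape, spec$bytes_per_sample)
  counts <- vapply(pyramid$levels,
                   function(s) prod(as.numeric(grid_shape(s, spec$chunk_shape))),
                   numeric(1))
  tab <- data.frame(level = seq_along(counts) - 1L, count = counts,
                    bytes = counts * per_chunk)
  structure(list(per_level_chunk_counts = counts,
                 total_chunk_files = sum(counts),
                 total_chunk_bytes = sum(counts) * per_chunk,
                 metadata_file_count = length(counts) + 1L,
                 table = tab),
            class = "size_report")
}

#' @export
print.size_report <- function(x, ...) {
  cat("<size_report>", format(x$total_chunk_files, big.mark = ","),
      "chunk files,", format(x$total_chunk_bytes, big.mark = ","),
      "bytes,", x$metadata_file_count, "metadata documents\n")
  invisible(x)
}

#' Write a size report to CSV
#'
#' Columns `level,count,bytes`, one row per pyramid level.
#'
#' @param report a [size_model()] result.
#' @param path output CSV path.
#' @export
write_size_report <- function(report, path) {
  utils::write.csv(report$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Chunk-edge trade-off: chunk size versus number of chunk files
#'
#' For each candidate chunk edge, rebuilds the chunk shape (spatial axes as
#' in [image_spec()]), the pyramid, and the size model, and reports the
#' per-chunk byte size against the total number of chunk files. This is the
#' compromise analysis used to pick 256 for the planar preset and 32 for the
#' volumetric one.
#'
#' @param spec an [image_spec()]; its `chunk_edge` is ignored.
#' @param candidate_edges positive integer chunk edges to evaluate.
#' @return data.frame with columns `edge`, `chunk_nbytes`,
#'   `total_chunk_count`.
#' @examples
#' chunk_tradeoff(preset_spec("lsm"), c(16, 32, 64, 128))
#' @export
chunk_tradeoff <- function(spec, candidate_edges) {
  stopifnot(inherits(spec, "image_spec"))
  if (any(candidate_edges < 1)) stop("candidate edges must be positive")
  rows <- lapply(candidate_edges, function(e) {
    sp <- image_spec(x = spec$sizes[["x"]], y = spec$sizes[["y"]],
                     z = spec$sizes[["z"]], c = spec$sizes[["c"]],
                     t = spec$sizes[["t"]],
                     bytes_per_sample = spec$bytes_per_sample, chunk_edge = e)
    sm <- size_model(sp, build_pyramid(sp))
    data.frame(edge = as.integer(e),
               chunk_nbytes = chunk_nbytes(sp$chunk_shape, sp$bytes_per_sample),
               total_chunk_count = sm$total_chunk_files)
  })
  do.call(rbind, rows)
}
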