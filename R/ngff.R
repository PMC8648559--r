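#' Storage key of one chunk
#'
#' Chunk keys use the "/" dimension separator:
#' `"<level>/<t>/<c>/<z>/<y>/<x>"`, which maps to nested directories on a
#' filesystem store and to flat keys on object storage.
#'
#' @param level resolution level (0-based).
#' @param indices 5 non-negative chunk indices `(t, c, z, y, x)`.
#' @return the relative key string.
#' @examples
#' chunk_key(0, c(0, 3, 0, 2, 1))  # "0/0/3/0/2/1"
#' @export
chunk_key <- function(level, indices) {
  if (length(indices) != 5L)
    stop("chunk indices must have rank 5, got ", length(indices))
  if (level < 0 || any(indices < 0))
    stop("level and chunk indices must be non-negative")
  paste(c(level, indices), collapse = "/")
}

key_join <- function(path, key) {
  if (is.null(path) || !nzchar(path)) key else paste0(path, "/", key)
}

json_bytes <- function(x) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", digits = NA,
                          pretty = 2)
  charToRaw(paste0(as.character(txt), "\n"))
}

dtype_code <- function(bytes_per_sample) {
  switch(as.character(bytes_per_sample), "1" = "|u1", "2" = "<u2",
         stop("unsupported sample width"))
}

dtype_nbytes <- function(code) {
  switch(code, "|u1" = 1L, "<u2" = 2L,
         stop("unsupported dtype code in .zarray: ", code))
}

zarray_doc <- function(shape_tczyx, chunks_tczyx, bytes_per_sample) {
  # alphabetical key order; compressor null, raw uncompressed chunks
  list(chunks = as.integer(unname(chunks_tczyx)),
       compressor = NULL,
       dimension_separator = "/",
       dtype = dtype_code(bytes_per_sample),
       fill_value = 0L,
       filters = NULL,
       order = "C",
       shape = as.integer(unname(shape_tczyx)),
       zarr_format = 2L)
}

#' Write a multiscale image in the chunked NGFF layout
#'
#' Emits the Zarr v2 dialect: a group document, a `multiscales` attribute
#' listing the level paths `"0", "1", ...` in order, one `.zarray` per
#' level, and all chunks as raw uncompressed C-order files with "/"
#' separated keys. Edge chunks are stored full-size with fill value 0.
#'
#' @param store a [store_kv] backend.
#' @param chunk_source `function(ref) -> array` producing each chunk (dim
#'   `(x, y, z, c, t)`), e.g. [gradient_chunk_source()].
#' @param spec an [image_spec()].
#' @param pyramid a [build_pyramid()] result.
#' @param path group prefix inside the store (`""` = root).
#' @return the store, invisibly.
#' @export
write_multiscale <- function(store, chunk_source, spec, pyramid, path = "") {
  stopifnot(inherits(spec, "image_spec"), inherits(pyramid, "pyramid_spec"))
  if (any(spec$sizes < 1)) stop("empty image: every size must be >= 1")
  nlev <- length(pyramid$levels)
  store_put(store, key_join(path, ".zgroup"), json_bytes(list(zarr_format = 2L)))
  attrs <- list(multiscales = list(list(
    axes = list("t", "c", "z", "y", "x"),
    datasets = lapply(seq_len(nlev) - 1L, function(i) list(path = as.character(i))),
    version = "0.2")))
  store_put(store, key_join(path, ".zattrs"), json_bytes(attrs))
  for (l in seq_len(nlev) - 1L) {
    lsz <- pyramid$levels[[l + 1L]]
    store_put(store, key_join(path, paste0(l, "/.zarray")),
              json_bytes(zarray_doc(lsz, spec$chunk_shape, spec$bytes_per_sample)))
    g <- grid_shape(lsz, spec$chunk_shape)
    idx <- expand.grid(x = seq_len(g[["x"]]) - 1L, y = seq_len(g[["y"]]) - 1L,
                       z = seq_len(g[["z"]]) - 1L, c = seq_len(g[["c"]]) - 1L,
                       t = seq_len(g[["t"]]) - 1L)
    for (r in seq_len(nrow(idx))) {
      ref <- chunk_ref(l, c(idx$t[r], idx$c[r], idx$z[r], idx$y[r], idx$x[r]))
      arr <- chunk_source(ref)
      store_put(store, key_join(path, chunk_key(l, ref$indices)),
                serialize_array(arr, spec$bytes_per_sample))
    }
  }
  invisible(store)
}

parse_json_key <- function(store, key) {
  raw <- store_get(store, key)
  out <- tryCatch(jsonlite::fromJSON(rawToChar(raw), simplifyVector = TRUE),
                  error = function(e) stop("malformed JSON in '", key, "': ",
                                           conditionMessage(e), call. = FALSE))
  out
}

parse_zarray <- function(store, key) {
  z <- parse_json_key(store, key)
  for (f in c("shape", "chunks", "dtype"))
    if (is.null(z[[f]]))
      stop("malformed .zarray at '", key, "': missing field '", f, "'",
           call. = FALSE)
  if (length(z$shape) != length(z$chunks))
    stop("malformed .zarray at '", key, "': shape/chunks rank mismatch",
         call. = FALSE)
  z
}

#' Open a multiscale NGFF image
#'
#' Reads and caches all metadata documents so that subsequent chunk reads
#' issue exactly one data request each.
#'
#' @param store a [store_kv] backend.
#' @param path group prefix (`""` = root).
#' @return an `ngff_image` handle.
#' @export
open_ngff <- function(store, path = "") {
  attrs <- parse_json_key(store, key_join(path, ".zattrs"))
  ms <- attrs$multiscales
  if (is.null(ms)) stop("no multiscales attribute at '", path, "'")
  paths <- ms$datasets[[1]]$path
  levels <- lapply(paths, function(p)
    parse_zarray(store, key_join(path, paste0(p, "/.zarray"))))
  structure(list(store = store, path = path, level_paths = paths,
                 levels = levels,
                 bytes_per_sample = dtype_nbytes(levels[[1]]$dtype)),
            class = "ngff_image")
}

#' Read one chunk from an opened NGFF image
#'
#' Issues exactly one store request (metadata was cached at open time).
#' Missing levels and missing chunk keys raise distinct errors; a chunk file
#' whose length disagrees with the chunk byte size raises a truncation
#' error.
#'
#' @param img an [open_ngff()] handle.
#' @param ref a [chunk_ref()].
#' @return dense array, dim `(x, y, z, c, t)` = chunk shape.
#' @export
ngff_read_chunk <- function(img, ref) {
  stopifnot(inherits(img, "ngff_image"))
  if (ref$level >= length(img$levels))
    stop("level ", ref$level, " absent: image has ", length(img$levels),
         " levels", call. = FALSE)
  meta <- img$levels[[ref$level + 1L]]
  g <- ceiling(meta$shape / meta$chunks)
  if (any(ref$indices >= g))
    stop("chunk indices out of grid at level ", ref$level, call. = FALSE)
  key <- key_join(img$path, chunk_key(ref$level, ref$indices))
  raw <- tryCatch(store_get(img$store, key), error = function(e)
    stop("chunk absent (level exists): ", key, call. = FALSE))
  want <- chunk_nbytes(meta$chunks, img$bytes_per_sample)
  if (length(raw) != want)
    stop("truncated chunk at ", key, ": ", length(raw), " bytes, expected ",
         want, call. = FALSE)
  deserialize_array(raw, meta$chunks, img$bytes_per_sample)
}

#' Read an arbitrary region of one level
#'
#' Assembles the overlapping chunks and trims fill to the requested extent.
#'
#' @param img an [open_ngff()] handle.
#' @param level resolution level.
#' @param lo,hi named (t,c,z,y,x) 0-based half-open bounds.
#' @return dense array, dim `(x, y, z, c, t)` = `hi - lo` (possibly 0).
#' @export
ngff_read_region <- function(img, level, lo, hi) {
  meta <- img$levels[[level + 1L]]
  if (is.null(meta)) stop("level ", level, " absent")
  shp <- stats::setNames(meta$shape, c("t", "c", "z", "y", "x"))
  ck <- stats::setNames(meta$chunks, c("t", "c", "z", "y", "x"))
  lo <- unlist(lo)[c("t", "c", "z", "y", "x")]
  hi <- unlist(hi)[c("t", "c", "z", "y", "x")]
  if (any(lo < 0) || any(hi > shp) || any(lo > hi))
    stop("region out of level extent")
  out <- array(0L, dim = array_dim(pmax(hi - lo, 0)))
  if (any(hi - lo == 0)) return(out)
  c0 <- floor(lo / ck); c1 <- ceiling(hi / ck) - 1
  for (it in c0[["t"]]:c1[["t"]]) for (ic in c0[["c"]]:c1[["c"]])
    for (iz in c0[["z"]]:c1[["z"]]) for (iy in c0[["y"]]:c1[["y"]])
      for (ix in c0[["x"]]:c1[["x"]]) {
        idx <- c(t = it, c = ic, z = iz, y = iy, x = ix)
        arr <- ngff_read_chunk(img, chunk_ref(level, idx))
        cl <- idx * ck                       # chunk origin, global coords
        s0 <- pmax(lo, cl); s1 <- pmin(hi, cl + ck, shp)
        src <- lapply(c("x", "y", "z", "c", "t"), function(a)
          (s0[[a]] - cl[[a]] + 1):(s1[[a]] - cl[[a]]))
        dst <- lapply(c("x", "y", "z", "c", "t"), function(a)
          (s0[[a]] - lo[[a]] + 1):(s1[[a]] - lo[[a]]))
        out[dst[[1]], dst[[2]], dst[[3]], dst[[4]], dst[[5]]] <-
          arr[src[[1]], src[[2]], src[[3]], src[[4]], src[[5]]]
      }
  out
}

#' Attach a label image to a multiscale image
#'
#' Writes the label as its own multiscale group under `labels/<name>`,
#' registers it in the `labels` listing attribute, and marks it with an
#' `image-label` attribute. Label spatial extents (z, y, x) must match the
#' base image at level 0.
#'
#' @param store a [store_kv] backend holding the base image at `base_path`.
#' @param name label name.
#' @param chunk_source producer for the label chunks (integer mask values).
#' @param label_spec,label_pyramid geometry of the label image.
#' @param base_path prefix of the base image (`""` = root).
#' @param overwrite if `FALSE` (default), attaching an existing name errors.
#' @return the store, invisibly.
#' @export
attach_labels <- function(store, name, chunk_source, label_spec, label_pyramid,
                          base_path = "", overwrite = FALSE) {
  base <- open_ngff(store, base_path)
  bshape <- stats::setNames(base$levels[[1]]$shape, c("t", "c", "z", "y", "x"))
  for (ax in c("z", "y", "x"))
    if (label_spec$sizes[[ax]] != bshape[[ax]])
      stop("label shape mismatch on axis '", ax, "': label ",
           label_spec$sizes[[ax]], " vs image ", bshape[[ax]])
  lbl_root <- key_join(base_path, "labels")
  listing_key <- key_join(lbl_root, ".zattrs")
  listing <- if (store_exists(store, listing_key))
    parse_json_key(store, listing_key)$labels else character(0)
  if (name %in% listing && !overwrite)
    stop("label '", name, "' already attached (set overwrite = TRUE)")
  store_put(store, key_join(lbl_root, ".zgroup"),
            json_bytes(list(zarr_format = 2L)))
  write_multiscale(store, chunk_source, label_spec, label_pyramid,
                   path = key_join(lbl_root, name))
  # mark the group as a label image (merge into the multiscale .zattrs)
  gkey <- key_join(key_join(lbl_root, name), ".zattrs")
  ga <- parse_json_key(store, gkey)
  ga[["image-label"]] <- list(version = "0.2")
  store_put(store, gkey, json_bytes(ga))
  store_put(store, listing_key,
            json_bytes(list(labels = as.list(unique(c(listing, name))))))
  invisible(store)
}

#' List attached labels
#'
#' @param store a [store_kv] backend.
#' @param base_path prefix of the base image.
#' @return character vector of label names (possibly empty).
#' @export
list_labels <- function(store, base_path = "") {
  k <- key_join(key_join(base_path, "labels"), ".zattrs")
  if (!store_exists(store, k)) return(character(0))
  unlist(parse_json_key(store, k)$labels) %||% character(0)
}

#' Build a high-content screening plate layout
#'
#' Plate group with row/column naming, one well group per (row, column),
#' and one multiscale field image per well field, all readable with
#' [open_ngff()] / [ngff_read_chunk()].
#'
#' @param store a [store_kv] backend.
#' @param rows,cols,fields counts (>= 1); rows are named "A", "B", ...,
#'   columns "1", "2", ....
#' @param well_spec an [image_spec()] for every field image.
#' @param chunk_source_factory `function(row, col, field) -> chunk source`;
#'   defaults to the gradient source for `well_spec`.
#' @return (invisibly) list with `well_paths` and `field_paths`.
#' @export
build_plate <- function(store, rows, cols, fields, well_spec,
                        chunk_source_factory = NULL) {
  if (rows < 1 || cols < 1 || fields < 1)
    stop("rows, cols and fields must all be >= 1")
  pyramid <- build_pyramid(well_spec)
  if (is.null(chunk_source_factory))
    chunk_source_factory <- function(row, col, field)
      gradient_chunk_source(well_spec, pyramid)
  row_names <- LETTERS[seq_len(rows)]
  col_names <- as.character(seq_len(cols))
  wells <- expand.grid(row = row_names, col = col_names,
                       stringsAsFactors = FALSE)
  wells <- wells[order(wells$row, wells$col), ]
  well_paths <- paste(wells$row, wells$col, sep = "/")
  if (anyDuplicated(well_paths)) stop("duplicate well path")
  store_put(store, ".zgroup", json_bytes(list(zarr_format = 2L)))
  plate_attr <- list(plate = list(
    columns = lapply(col_names, function(n) list(name = n)),
    field_count = as.integer(fields),
    rows = lapply(row_names, function(n) list(name = n)),
    version = "0.2",
    wells = lapply(well_paths, function(p) list(path = p))))
  store_put(store, ".zattrs", json_bytes(plate_attr))
  field_paths <- character(0)
  for (w in well_paths) {
    store_put(store, key_join(w, ".zgroup"), json_bytes(list(zarr_format = 2L)))
    imgs <- lapply(seq_len(fields) - 1L, function(f) list(path = as.character(f)))
    store_put(store, key_join(w, ".zattrs"),
              json_bytes(list(well = list(images = imgs, version = "0.2"))))
    parts <- strsplit(w, "/")[[1]]
    for (f in seq_len(fields) - 1L) {
      fp <- key_join(w, as.character(f))
      write_multiscale(store, chunk_source_factory(parts[1], parts[2], f),
                       well_spec, pyramid, path = fp)
      field_paths <- c(field_paths, fp)
    }
  }
  invisible(list(well_paths = well_paths, field_paths = field_paths))
}

validate_entry <- function(type, path, detail) {
  data.frame(type = type, path = path, detail = detail,
             stringsAsFactors = FALSE)
}

validate_image <- function(store, path) {
  rep <- validate_entry(character(0), character(0), character(0))
  zak <- key_join(path, ".zattrs")
  if (!store_exists(store, zak))
    return(validate_entry("missing_metadata", zak, "no .zattrs"))
  attrs <- parse_json_key(store, zak)
  ms <- attrs$multiscales
  if (is.null(ms))
    return(validate_entry("missing_metadata", zak, "no multiscales attribute"))
  paths <- ms$datasets[[1]]$path
  prev_yx <- NULL
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    ak <- key_join(path, paste0(p, "/.zarray"))
    if (!store_exists(store, ak)) {
      rep <- rbind(rep, validate_entry("missing_metadata", ak, "no .zarray"))
      next
    }
    z <- tryCatch(parse_zarray(store, ak), error = function(e) e)
    if (inherits(z, "error")) {
      rep <- rbind(rep, validate_entry("bad_metadata", ak, conditionMessage(z)))
      next
    }
    if (length(z$shape) != 5L) {
      rep <- rbind(rep, validate_entry("bad_metadata", ak, "rank != 5"))
      next
    }
    yx <- z$shape[4:5]
    if (!is.null(prev_yx) && any(yx > prev_yx))
      rep <- rbind(rep, validate_entry("level_order", ak,
        "level sizes increase down the pyramid"))
    prev_yx <- yx
    nb <- chunk_nbytes(z$chunks, dtype_nbytes(z$dtype))
    g <- ceiling(z$shape / z$chunks)
    expect <- apply(expand.grid(t = seq_len(g[1]) - 1, c = seq_len(g[2]) - 1,
                                z = seq_len(g[3]) - 1, y = seq_len(g[4]) - 1,
                                x = seq_len(g[5]) - 1), 1,
                    function(r) paste(c(p, r), collapse = "/"))
    lvl_prefix <- paste0(key_join(path, p), "/")
    keys <- store_list(store, lvl_prefix)
    keys <- keys[!endsWith(keys, ".zarray") & !endsWith(keys, ".zattrs") &
                 !endsWith(keys, ".zgroup")]
    rel <- substring(keys, nchar(key_join(path, "")) + 1L)
    orphan <- setdiff(rel, expect)
    for (o in orphan)
      rep <- rbind(rep, validate_entry("orphan_key", key_join(path, o),
                                       "key not on the chunk grid"))
    for (k in intersect(rel, expect)) {
      b <- store_get(store, key_join(path, k))
      if (length(b) != nb)
        rep <- rbind(rep, validate_entry("chunk_size", key_join(path, k),
          sprintf("%d bytes, expected %d", length(b), nb)))
    }
  }
  rep
}

#' Validate a chunked NGFF store
#'
#' Walks a multiscale image (or an HCS plate of them, or attached labels)
#' and reports missing metadata documents, orphan chunk keys, chunk files
#' of the wrong byte length, level-ordering violations, and label/image
#' shape mismatches. Unknown attribute fields are ignored. An empty report
#' means the store conforms.
#'
#' @param store a [store_kv] backend.
#' @param path group prefix to validate (`""` = root).
#' @return data.frame with columns `type`, `path`, `detail`; zero rows if
#'   conformant.
#' @export
validate_ngff <- function(store, path = "") {
  zak <- key_join(path, ".zattrs")
  if (!store_exists(store, zak))
    return(validate_entry("missing_metadata", zak, "no .zattrs"))
  attrs <- parse_json_key(store, zak)
  rep <- validate_entry(character(0), character(0), character(0))
  if (!is.null(attrs$plate)) {
    wells <- attrs$plate$wells$path
    fields <- attrs$plate$field_count %||% 1L
    for (w in wells) {
      wk <- key_join(path, w)
      if (!store_exists(store, key_join(wk, ".zattrs"))) {
        rep <- rbind(rep, validate_entry("missing_metadata",
                                         key_join(wk, ".zattrs"), "no well group"))
        next
      }
      for (f in seq_len(fields) - 1L)
        rep <- rbind(rep, validate_image(store, key_join(wk, as.character(f))))
    }
    return(rep)
  }
  rep <- rbind(rep, validate_image(store, path))
  lbl_listing <- key_join(key_join(path, "labels"), ".zattrs")
  if (store_exists(store, lbl_listing)) {
    base <- open_ngff(store, path)
    bshape <- base$levels[[1]]$shape
    for (nm in unlist(parse_json_key(store, lbl_listing)$labels)) {
      lp <- key_join(key_join(path, "labels"), nm)
      rep <- rbind(rep, validate_image(store, lp))
      lb <- tryCatch(open_ngff(store, lp), error = function(e) NULL)
      if (!is.null(lb) && any(lb$levels[[1]]$shape[3:5] != bshape[3:5]))
        rep <- rbind(rep, validate_entry("shape_mismatch", lp,
          "label z/y/x extents differ from base image"))
    }
  }
  rep
}

#' Summarize an NGFF store
#'
#' @param store a [store_kv] backend.
#' @param path group prefix.
#' @return list with `shape`, `chunks`, `levels`, `chunk_files`,
#'   `chunk_bytes` (printed by the `info` CLI subcommand).
#' @export
ngff_info <- function(store, path = "") {
  img <- open_ngff(store, path)
  counts <- vapply(img$levels, function(z)
    prod(ceiling(z$shape / z$chunks)), numeric(1))
  nb <- chunk_nbytes(img$levels[[1]]$chunks, img$bytes_per_sample)
  list(shape = img$levels[[1]]$shape, chunks = img$levels[[1]]$chunks,
       levels = length(img$levels), chunk_files = sum(counts),
       chunk_bytes = sum(counts) * nb)
}
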