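# Tiled pyramidal BigTIFF writer/reader over the StoreKV contract.
# One tiled 2D image (IFD) per (t, c, z) plane of every pyramid level, full
# resolution first, sub-resolutions flagged with NewSubfileType = 1. Tiles
# are the chunk's y/x face (256x256 for the planar preset, 32x32 for the
# volumetric one), uncompressed 16-bit little-endian, padded to full tile
# size as TIFF requires. A minimal OME-XML header on the first IFD carries
# the 5D sizes and axis order. Volumetric data appears only as stacks of 2D
# tiled planes, so reading one 3D chunk means reading its z-extent worth of
# planar tiles.

TIFF_TAG <- list(new_subfile_type = 254L, image_width = 256L,
                 image_length = 257L, bits_per_sample = 258L,
                 compression = 259L, photometric = 262L,
                 image_description = 270L, samples_per_pixel = 277L,
                 tile_width = 322L, tile_length = 323L, tile_offsets = 324L,
                 tile_byte_counts = 325L, sample_format = 339L)

tiff_entry <- function(tag, type, count, value_raw8) {
  c(u16le(tag), u16le(type), u64le(count), value_raw8)
}

ome_xml_header <- function(spec) {
  s <- spec$sizes
  paste0('<?xml version="1.0" encoding="UTF-8"?>',
         '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
         '<Image ID="Image:0"><Pixels ID="Pixels:0" DimensionOrder="XYZCT"',
         sprintf(' Type="uint%d"', 8L * spec$bytes_per_sample),
         sprintf(' SizeX="%d" SizeY="%d" SizeZ="%d" SizeC="%d" SizeT="%d"',
                 s[["x"]], s[["y"]], s[["z"]], s[["c"]], s[["t"]]),
         '><TiffData/></Pixels></Image></OME>')
}

#' Write a multiscale image as a tiled pyramidal BigTIFF
#'
#' @param path output file path.
#' @param chunk_source `function(ref) -> array`, as in [write_multiscale()].
#' @param spec an [image_spec()].
#' @param pyramid a [build_pyramid()] result.
#' @param tile_shape optional `(y, x)` tile extents; defaults to the chunk's
#'   y/x face and must divide it evenly otherwise.
#' @return the path, invisibly.
#' @export
write_ometiff <- function(path, chunk_source, spec, pyramid,
                          tile_shape = NULL) {
  stopifnot(inherits(spec, "image_spec"), inherits(pyramid, "pyramid_spec"))
  ck <- spec$chunk_shape
  if (is.null(tile_shape)) tile_shape <- c(ck[["y"]], ck[["x"]])
  if (ck[["y"]] %% tile_shape[1] != 0 || ck[["x"]] %% tile_shape[2] != 0)
    stop("tile shape (", paste(tile_shape, collapse = "x"),
         ") must divide the chunk's y/x face (", ck[["y"]], "x", ck[["x"]], ")")
  bps <- spec$bytes_per_sample
  tile_nb <- prod(tile_shape) * bps
  desc <- charToRaw(paste0(ome_xml_header(spec), rawToChar(as.raw(0L))))
  nlev <- length(pyramid$levels)

  # plane table: one row per IFD, order: level, then t, c, z (z fastest)
  planes <- do.call(rbind, lapply(seq_len(nlev) - 1L, function(l) {
    s <- pyramid$levels[[l + 1L]]
    g <- expand.grid(z = seq_len(s[["z"]]) - 1L, c = seq_len(s[["c"]]) - 1L,
                     t = seq_len(s[["t"]]) - 1L)
    data.frame(level = l, t = g$t, c = g$c, z = g$z,
               width = s[["x"]], height = s[["y"]])
  }))
  planes$tiles_x <- as.integer(ceiling(planes$width / tile_shape[2]))
  planes$tiles_y <- as.integer(ceiling(planes$height / tile_shape[1]))
  planes$ntiles <- planes$tiles_x * planes$tiles_y

  n_entries <- ifelse(seq_len(nrow(planes)) == 1L, 13L, 12L)
  ifd_sizes <- 8 + n_entries * 20 + 8
  aux_sizes <- ifelse(planes$ntiles > 1, 2 * 8 * planes$ntiles, 0) +
    ifelse(seq_len(nrow(planes)) == 1L, pad8len(length(desc)), 0)
  meta_sizes <- ifd_sizes + aux_sizes
  ifd_off <- 16 + cumsum(c(0, meta_sizes[-length(meta_sizes)]))
  aux_off <- ifd_off + ifd_sizes
  data_off <- 16 + sum(meta_sizes) +
    cumsum(c(0, (planes$ntiles * tile_nb)[-nrow(planes)]))

  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), u16le(43), u16le(8), u16le(0), u64le(16)), con)

  plc <- as.list(planes)
  for (p in seq_len(nrow(planes))) {
    pl <- lapply(plc, `[`, p)
    toff <- data_off[p] + (seq_len(pl$ntiles) - 1) * tile_nb
    aux <- aux_off[p]
    entries <- list(
      tiff_entry(254, 4, 1, u64le(if (pl$level > 0) 1 else 0)),
      tiff_entry(256, 4, 1, u64le(pl$width)),
      tiff_entry(257, 4, 1, u64le(pl$height)),
      tiff_entry(258, 3, 1, u64le(8 * bps)),
      tiff_entry(259, 3, 1, u64le(1)),
      tiff_entry(262, 3, 1, u64le(1)))
    if (p == 1L) {
      entries <- c(entries, list(
        tiff_entry(270, 2, length(desc), u64le(aux))))
      aux <- aux + pad8len(length(desc))
    }
    entries <- c(entries, list(
      tiff_entry(277, 3, 1, u64le(1)),
      tiff_entry(322, 3, 1, u64le(tile_shape[2])),
      tiff_entry(323, 3, 1, u64le(tile_shape[1]))))
    if (pl$ntiles > 1) {
      entries <- c(entries, list(
        tiff_entry(324, 16, pl$ntiles, u64le(aux)),
        tiff_entry(325, 16, pl$ntiles, u64le(aux + 8 * pl$ntiles))))
    } else {
      entries <- c(entries, list(
        tiff_entry(324, 16, 1, u64le(toff[1])),
        tiff_entry(325, 16, 1, u64le(tile_nb))))
    }
    entries <- c(entries, list(tiff_entry(339, 3, 1, u64le(1))))
    next_ifd <- if (p < nrow(planes)) ifd_off[p + 1] else 0
    writeBin(c(u64le(length(entries)), do.call(c, entries), u64le(next_ifd)),
             con)
    if (p == 1L) writeBin(c(desc, raw(pad8len(length(desc)) - length(desc))),
                          con)
    if (pl$ntiles > 1)
      writeBin(c(u64le(toff), u64le(rep(tile_nb, pl$ntiles))), con)
  }

  # tile payloads, rendered chunk-by-chunk and cached per z-slab
  slab <- NULL; slab_id <- c(-1L, -1L, -1L, -1L)
  pll <- as.list(planes)   # column access is much cheaper than row slicing
  for (p in seq_len(nrow(planes))) {
    pl <- lapply(pll, `[`, p)
    zc <- pl$z %/% ck[["z"]]
    for (ty in seq_len(pl$tiles_y) - 1L) for (tx in seq_len(pl$tiles_x) - 1L) {
      id <- c(pl$level, pl$t %/% ck[["t"]], pl$c %/% ck[["c"]], zc)
      # tiles map 1:1 onto chunk y/x faces when tile == chunk face; for
      # smaller tiles several tiles share one chunk
      cy <- (ty * tile_shape[1]) %/% ck[["y"]]
      cx <- (tx * tile_shape[2]) %/% ck[["x"]]
      key <- c(id, cy, cx)
      if (is.null(slab) || !identical(slab_id, key)) {
        slab <- chunk_source(chunk_ref(pl$level,
          c(pl$t %/% ck[["t"]], pl$c %/% ck[["c"]], zc, cy, cx)))
        slab_id <- key
      }
      zl <- pl$z %% ck[["z"]] + 1L
      tl <- pl$t %% ck[["t"]] + 1L
      cl <- pl$c %% ck[["c"]] + 1L
      y0 <- ty * tile_shape[1] - cy * ck[["y"]]
      x0 <- tx * tile_shape[2] - cx * ck[["x"]]
      tilearr <- slab[x0 + seq_len(tile_shape[2]), y0 + seq_len(tile_shape[1]),
                      zl, cl, tl]
      writeBin(encode_samples(as.vector(tilearr), bps), con)
    }
  }
  invisible(path)
}

# ---- reader ----

tiff_read_entry <- function(raw, pos) {
  list(tag = rd_uint(raw, pos, 2), type = rd_uint(raw, pos + 2, 2),
       count = rd_uint(raw, pos + 4, 8), value = rd_uint(raw, pos + 12, 8),
       value_raw = raw[(pos + 13):(pos + 20)])
}

#' Open a tiled pyramidal BigTIFF
#'
#' Parses the whole IFD chain once (header, tag tables, tile offset arrays,
#' OME-XML sizes) and caches it; subsequent chunk reads cost exactly one
#' ranged request per constituent tile.
#'
#' @param store a [store_kv] backend.
#' @param key key of the TIFF file inside the store.
#' @param chunk_z z-extent of one logical chunk; by default the tile edge
#'   when the image is a volume (isotropic chunks), else 1.
#' @return a `tiff_file` handle.
#' @export
tiff_open <- function(store, key, chunk_z = NULL) {
  hdr <- store_get_range(store, key, 0, 16)
  if (rawToChar(hdr[1:2]) != "II" || rd_uint(hdr, 2, 2) != 43)
    stop("not a little-endian BigTIFF: ", key)
  ifd_off <- rd_uint(hdr, 8, 8)
  ifds <- list()
  while (ifd_off != 0) {
    nraw <- store_get_range(store, key, ifd_off, 8)
    n <- rd_uint(nraw, 0, 8)
    body <- store_get_range(store, key, ifd_off + 8, n * 20 + 8)
    tags <- list()
    for (i in seq_len(n) - 1) {
      e <- tiff_read_entry(body, i * 20)
      tags[[as.character(e$tag)]] <- e
    }
    g <- function(tag, default = NULL) {
      e <- tags[[as.character(tag)]]
      if (is.null(e)) return(default)
      e$value
    }
    ntiles <- tags[["324"]]$count
    if (is.null(ntiles)) stop("IFD without tile offsets (not a tiled TIFF)")
    if (ntiles > 1) {
      offs_raw <- store_get_range(store, key, tags[["324"]]$value, 8 * ntiles)
      cnts_raw <- store_get_range(store, key, tags[["325"]]$value, 8 * ntiles)
      toffs <- vapply(seq_len(ntiles) - 1, function(i) rd_uint(offs_raw, 8 * i, 8),
                      numeric(1))
      tcnts <- vapply(seq_len(ntiles) - 1, function(i) rd_uint(cnts_raw, 8 * i, 8),
                      numeric(1))
    } else {
      toffs <- tags[["324"]]$value
      tcnts <- tags[["325"]]$value
    }
    desc <- NULL
    if (!is.null(tags[["270"]])) {
      draw <- store_get_range(store, key, tags[["270"]]$value,
                              tags[["270"]]$count)
      desc <- rawToChar(draw[draw != as.raw(0)])
    }
    ifds[[length(ifds) + 1L]] <- list(
      width = g(256), height = g(257), bits = g(258, 16),
      tile_w = g(322), tile_h = g(323), subtype = g(254, 0),
      tile_offsets = toffs, tile_counts = tcnts, desc = desc)
    ifd_off <- rd_uint(body, n * 20, 8)
  }
  desc <- ifds[[1]]$desc
  dim_of <- function(ax) {
    m <- regmatches(desc, regexpr(paste0("Size", ax, '="[0-9]+"'), desc))
    if (!length(m)) stop("OME-XML header lacks Size", ax)
    as.integer(gsub("[^0-9]", "", m))
  }
  sizes <- c(t = dim_of("T"), c = dim_of("C"), z = dim_of("Z"),
             y = dim_of("Y"), x = dim_of("X"))
  ppl <- sizes[["t"]] * sizes[["c"]] * sizes[["z"]]
  if (length(ifds) %% ppl != 0)
    stop("IFD count ", length(ifds), " is not a multiple of planes per level ",
         ppl)
  nlev <- length(ifds) %/% ppl
  bps <- ifds[[1]]$bits %/% 8L
  if (is.null(chunk_z)) chunk_z <- if (sizes[["z"]] > 1) ifds[[1]]$tile_h else 1L
  levels <- lapply(seq_len(nlev) - 1L, function(l) {
    first <- ifds[[l * ppl + 1L]]
    s <- sizes; s[["y"]] <- first$height; s[["x"]] <- first$width
    list(sizes = s, ifd0 = l * ppl)
  })
  structure(list(store = store, key = key, ifds = ifds, levels = levels,
                 sizes = sizes, bytes_per_sample = bps,
                 tile_shape = c(ifds[[1]]$tile_h, ifds[[1]]$tile_w),
                 chunk_z = as.integer(chunk_z)),
            class = "tiff_file")
}

tiff_plane_ifd <- function(h, level, t, c, z) {
  s <- h$sizes
  h$levels[[level + 1L]]$ifd0 + t * (s[["c"]] * s[["z"]]) + c * s[["z"]] + z + 1L
}

#' Read one logical chunk from a tiled pyramidal TIFF
#'
#' A chunk is the same unit the chunked layouts store: for volumetric data
#' it spans `chunk_z` planar tiles (32 for the benchmark preset), each
#' fetched with one ranged request, and the planes are stacked back into
#' the dense chunk array.
#'
#' @param h a [tiff_open()] handle.
#' @param ref a [chunk_ref()]; indices on the chunk grid implied by the
#'   tile shape and `chunk_z`.
#' @return dense array, dim `(x, y, z, c, t)` = chunk shape.
#' @export
tiff_read_chunk <- function(h, ref) {
  stopifnot(inherits(h, "tiff_file"))
  if (ref$level >= length(h$levels)) stop("level ", ref$level, " absent")
  lv <- h$levels[[ref$level + 1L]]
  ck <- c(t = 1L, c = 1L, z = h$chunk_z,
          y = h$tile_shape[1], x = h$tile_shape[2])
  g <- grid_shape(lv$sizes, ck)
  if (any(ref$indices >= g)) stop("chunk indices out of grid")
  bps <- h$bytes_per_sample
  out <- array(0L, dim = array_dim(ck))
  z0 <- ref$indices[["z"]] * ck[["z"]]
  z1 <- min(z0 + ck[["z"]], lv$sizes[["z"]])
  for (z in z0:(z1 - 1)) {
    pi <- tiff_plane_ifd(h, ref$level, ref$indices[["t"]], ref$indices[["c"]], z)
    ifd <- h$ifds[[pi]]
    tiles_x <- ceiling(ifd$width / ifd$tile_w)
    tix <- ref$indices[["y"]] * tiles_x + ref$indices[["x"]] + 1
    raw <- store_get_range(h$store, h$key, ifd$tile_offsets[tix],
                           ifd$tile_counts[tix])
    tile <- array(decode_samples(raw, bps), dim = c(ifd$tile_w, ifd$tile_h))
    out[, , z - z0 + 1L, 1L, 1L] <- tile
  }
  out
}
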