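test_that("the HDF5 layout round-trips chunks, including multi-node B-trees", {
  sp <- image_spec(128, 128, 64, 1, 3, chunk_edge = 32)  # 96 level-0 chunks
  py <- build_pyramid(sp)
  path <- file.path(tempdir(), "btree.h5")
  write_hdf5(path, gradient_chunk_source(sp, py), sp, py)
  h <- hdf5_open(local_store(dirname(path)), basename(path))
  expect_identical(names(h$datasets), c("level0", "level1", "level2"))
  set.seed(11)
  g <- grid_shape(sp$sizes, sp$chunk_shape)
  for (i in 1:20) {
    idx <- vapply(g, function(k) sample.int(k, 1) - 1L, integer(1))
    ref <- chunk_ref(0, idx)
    expect_identical(hdf5_read_chunk(h, ref), render_chunk(sp, ref, py))
  }
  ref1 <- chunk_ref(2, c(2, 0, 1, 0, 0))
  expect_identical(hdf5_read_chunk(h, ref1), render_chunk(sp, ref1, py))
  expect_error(hdf5_read_chunk(h, chunk_ref(7, rep(0, 5))), "absent")
  expect_error(hdf5_read_chunk(h, chunk_ref(0, c(0, 0, 0, 0, 99))),
               "out of grid")
})

test_that("h5py opens our HDF5 files and sees the gradient (oracle)", {
  sp <- tiny_spec()
  path <- fixture_dataset("tiny", sp, "hdf5")
  expect_python_ok(sprintf("
import h5py, numpy as np
f = h5py.File(%s, 'r')
assert list(f.keys()) == ['level0', 'level1', 'level2']
d = f['level0']
assert d.shape == (2, 2, 3, 40, 70) and d.chunks == (1, 1, 32, 32, 32)
assert d.dtype == np.uint16
a = d[:]
idx = np.indices(a.shape, dtype=np.int64)
assert np.array_equal(a, (idx.sum(axis=0) %% 65536).astype('u2'))
import json
meta = json.loads(f.attrs['multiscales'])
assert meta['datasets'] == ['level0', 'level1', 'level2']
", deparse(path)))
})

test_that("HDF5 chunk access costs one request per B-tree node plus payload", {
  sp <- tiny_spec()
  path <- fixture_dataset("tiny", sp, "hdf5")
  sim <- sim_store(local_store(dirname(path)))
  h <- hdf5_open(sim, basename(path))
  reset_request_log(sim)
  invisible(hdf5_read_chunk(h, chunk_ref(0, c(1, 1, 0, 1, 1))))
  expect_identical(request_count(sim), 2L)   # single-leaf tree: root + data
  lg <- request_log(sim)
  expect_identical(lg$op, c("get_range", "get_range"))
})

test_that("tifffile opens our tiled pyramidal BigTIFF (oracle)", {
  sp <- tiny_spec()
  path <- fixture_dataset("tiny", sp, "ometiff")
  # planes: level sizes z=3,c=2,t=2 -> 12 IFDs per level, 3 levels
  expect_python_ok(sprintf("
import tifffile, numpy as np
tf = tifffile.TiffFile(%s)
assert tf.is_bigtiff and len(tf.pages) == 36
p0 = tf.pages[0]
assert p0.shape == (40, 70) and p0.tilewidth == 32 and p0.tilelength == 32
assert 'SizeZ=\"3\"' in p0.description
y, x = np.meshgrid(np.arange(40), np.arange(70), indexing='ij')
# IFD order is z fastest, then c, then t: page 11 = (t=1, c=1, z=2)
a = tf.pages[11].asarray()
assert np.array_equal(a, ((x + y + 2 + 1 + 1) %% 65536).astype('u2'))
", deparse(path)))
})

test_that("a volumetric TIFF chunk is assembled from its planar tiles", {
  sp <- vol_spec()   # z = 64, chunks 32^3 -> 32 tiles per chunk
  py <- build_pyramid(sp)
  path <- file.path(tempdir(), "vol.tif")
  write_ometiff(path, gradient_chunk_source(sp, py), sp, py)
  sim <- sim_store(local_store(dirname(path)))
  h <- tiff_open(sim, basename(path))
  expect_identical(h$chunk_z, 32L)
  reset_request_log(sim)
  ref <- chunk_ref(0, c(1, 0, 1, 1, 0))
  arr <- tiff_read_chunk(h, ref)
  expect_identical(request_count(sim),
                   as.integer(tiles_per_chunk(c(32, 32, 32), c(32, 32))))
  expect_identical(arr, render_chunk(sp, ref, py))
})

test_that("tile accounting follows z * ceil(y/tile) * ceil(x/tile)", {
  expect_identical(tiles_per_chunk(c(32, 32, 32), c(32, 32)), 32)
  expect_identical(tiles_per_chunk(c(1, 256, 256), c(256, 256)), 1)
  expect_identical(tiles_per_chunk(c(4, 100, 100), c(32, 32)), 64)
  expect_identical(tiles_per_chunk(c(1, 1, 32, 32, 32), c(32, 32)), 32)
  expect_error(tiles_per_chunk(c(0, 32, 32), c(32, 32)), "positive")
  # tile accounting bound: tiles * tile bytes >= chunk bytes
  for (ck in list(c(32, 32, 32), c(4, 100, 100), c(1, 256, 256))) {
    tl <- c(32, 32)
    n <- tiles_per_chunk(ck, tl)
    expect_gte(n * prod(tl) * 2, chunk_nbytes(ck, 2))
  }
  expect_identical(tiles_per_chunk(c(32, 32, 32), c(32, 32)) *
                     chunk_nbytes(c(32, 32), 2),
                   chunk_nbytes(c(32, 32, 32), 2))
  expect_error(write_ometiff(file.path(tempdir(), "bad.tif"),
                             gradient_chunk_source(tiny_spec(),
                                                   build_pyramid(tiny_spec())),
                             tiny_spec(), build_pyramid(tiny_spec()),
                             tile_shape = c(48, 48)),
               "must divide")
})

test_that("conversion triangle: every converted copy is voxel-identical", {
  sp <- tiny_spec()
  py <- build_pyramid(sp)
  ng_path <- fixture_dataset("tiny", sp, "ngff")
  h5_path <- fixture_dataset("tiny", sp, "hdf5")
  ng <- open_dataset(ng_path, "ngff")

  expect_true(verify_equivalence(ng, ng)$equal)

  ng2 <- file.path(tempdir(), "tri-ngff")
  unlink(ng2, recursive = TRUE)
  hdf5_to_ngff(h5_path, local_store(ng2))
  expect_identical(nrow(validate_ngff(local_store(ng2))), 0L)
  expect_true(verify_equivalence(ng, open_dataset(ng2, "ngff"))$equal)

  h5b <- file.path(tempdir(), "tri.h5")
  ngff_to_hdf5(local_store(ng_path), h5b)
  rb <- open_dataset(h5b, "hdf5")
  expect_length(rb$levels, length(py$levels))
  expect_identical(rb$chunk_shape, sp$chunk_shape)
  expect_true(verify_equivalence(ng, rb)$equal)

  tifb <- file.path(tempdir(), "tri.tif")
  ngff_to_ometiff(local_store(ng_path), tifb)
  expect_true(verify_equivalence(ng, open_dataset(tifb, "ometiff"))$equal)

  # round trip ngff -> hdf5 -> ngff is byte-identical chunk for chunk
  ng3 <- file.path(tempdir(), "tri-ngff3")
  unlink(ng3, recursive = TRUE)
  hdf5_to_ngff(h5b, local_store(ng3))
  a <- local_store(ng_path); b <- local_store(ng3)
  for (k in store_list(a)) {
    if (grepl("\\.z", basename(k))) next
    expect_identical(store_get(b, k), store_get(a, k))
  }
})

test_that("equivalence detects a single flipped voxel with its coordinate", {
  sp <- image_spec(40, 40, 1, 1, 1, chunk_edge = 32)
  py <- build_pyramid(sp)
  st1 <- mem_store(); st2 <- mem_store()
  write_multiscale(st1, gradient_chunk_source(sp, py), sp, py)
  write_multiscale(st2, gradient_chunk_source(sp, py), sp, py)
  b <- store_get(st2, "0/0/0/0/1/0")
  b[5] <- xor(b[5], as.raw(1))
  store_put(st2, "0/0/0/0/1/0", b)
  r1 <- open_dataset("", "ngff", store = st1)
  r2 <- open_dataset("", "ngff", store = st2)
  v <- verify_equivalence(r1, r2)
  expect_false(v$equal)
  expect_identical(v$level, 0L)
  expect_identical(unname(v$coord[c("y", "x")]), c(32L, 2L))
})
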