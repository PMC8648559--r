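test_that("chunk keys use the '/' dimension separator in (level,t,c,z,y,x) order", {
  expect_identical(chunk_key(0, c(0, 3, 0, 2, 1)), "0/0/3/0/2/1")
  expect_identical(chunk_key(2, rep(0, 5)), "2/0/0/0/0/0")
  expect_error(chunk_key(0, c(0, 0, 0, -1, 0)), "non-negative")
  expect_error(chunk_key(0, c(1, 2, 3)), "rank 5")
})

test_that("write/read round-trips every chunk byte-identically, one request each", {
  sp <- tiny_spec()
  py <- build_pyramid(sp)
  sim <- sim_store(mem_store())
  write_multiscale(sim, gradient_chunk_source(sp, py), sp, py)
  img <- open_ngff(sim)
  reset_request_log(sim)
  nread <- 0L
  for (l in seq_along(py$levels) - 1L) {
    g <- grid_shape(py$levels[[l + 1L]], sp$chunk_shape)
    idx <- expand.grid(t = seq_len(g[["t"]]) - 1L, c = seq_len(g[["c"]]) - 1L,
                       z = seq_len(g[["z"]]) - 1L, y = seq_len(g[["y"]]) - 1L,
                       x = seq_len(g[["x"]]) - 1L)
    for (r in seq_len(nrow(idx))) {
      ref <- chunk_ref(l, unlist(idx[r, c("t", "c", "z", "y", "x")]))
      expect_identical(ngff_read_chunk(img, ref), render_chunk(sp, ref, py))
      nread <- nread + 1L
    }
  }
  expect_identical(request_count(sim), nread)  # exactly 1 get per chunk
  lg <- request_log(sim)
  expect_true(all(lg$op == "get"))
  # conservation: every chunk file has exactly chunk_nbytes bytes
  expect_true(all(lg$bytes == chunk_nbytes(sp$chunk_shape,
                                           sp$bytes_per_sample)))
})

test_that("missing level, missing chunk and truncation raise distinct errors", {
  sp <- image_spec(40, 40, chunk_edge = 32)
  py <- build_pyramid(sp)
  st <- mem_store()
  write_multiscale(st, gradient_chunk_source(sp, py), sp, py)
  img <- open_ngff(st)
  expect_error(ngff_read_chunk(img, chunk_ref(5, rep(0, 5))), "level 5 absent")
  store_delete(st, "0/0/0/0/1/1")
  expect_error(ngff_read_chunk(img, chunk_ref(0, c(0, 0, 0, 1, 1))),
               "chunk absent")
  store_put(st, "0/0/0/0/0/0", as.raw(1:10))
  expect_error(ngff_read_chunk(img, chunk_ref(0, rep(0, 5))), "truncated")
  store_put(st, "0/.zarray", charToRaw('{"shape": [1,1,1,40,40]}'))
  expect_error(open_ngff(st), "missing field 'chunks'")
})

test_that("region reads assemble chunks and equal the brute-force render", {
  sp <- tiny_spec()
  py <- build_pyramid(sp)
  st <- mem_store()
  write_multiscale(st, gradient_chunk_source(sp, py), sp, py)
  img <- open_ngff(st)
  full <- render_level(sp, 0)
  expect_identical(
    ngff_read_region(img, 0, list(t = 0, c = 0, z = 0, y = 0, x = 0),
                     as.list(sp$sizes)),
    full)
  # a region crossing 4 chunks on the y/x face
  r <- ngff_read_region(img, 0, list(t = 1, c = 0, z = 1, y = 20, x = 20),
                        list(t = 2, c = 2, z = 3, y = 40, x = 60))
  expect_identical(r, full[21:60, 21:40, 2:3, 1:2, 2, drop = FALSE])
  # zero-length range
  z <- ngff_read_region(img, 0, list(t = 0, c = 0, z = 0, y = 5, x = 5),
                        list(t = 2, c = 2, z = 3, y = 5, x = 70))
  expect_identical(dim(z), c(65L, 0L, 3L, 2L, 2L))
  expect_error(ngff_read_region(img, 0, list(t = 0, c = 0, z = 0, y = 0, x = 0),
                                list(t = 2, c = 2, z = 3, y = 41, x = 70)),
               "out of level extent")
})

test_that("zarr-python opens our store and sees the gradient (oracle interop)", {
  sp <- tiny_spec()
  path <- fixture_dataset("tiny", sp, "ngff")
  expect_python_ok(sprintf("
import zarr, numpy as np, sys
g = zarr.open_group(%s, mode='r')
assert sorted(k for k, _ in g.arrays()) == ['0', '1', '2']
a0 = np.asarray(g['0'])
assert a0.dtype == np.uint16 and a0.shape == (2, 2, 3, 40, 70)
idx = np.indices(a0.shape, dtype=np.int64)
assert np.array_equal(a0, (idx.sum(axis=0) %% 65536).astype('u2'))
prev = a0.astype(np.int64)
for k in ['1', '2']:
    al = np.asarray(g[k])
    t, c, z, y, x = prev.shape
    ds = prev[..., :y//2*2, :x//2*2].reshape(t, c, z, y//2, 2, x//2, 2)
    assert np.array_equal(al[..., :y//2, :x//2], ds.sum(axis=(4, 6)) // 4)
    prev = al.astype(np.int64)
", deparse(path)))
})

test_that("stores written by zarr-python are readable by our reader", {
  path <- file.path(tempdir(), "zarr-written")
  unlink(path, recursive = TRUE)
  expect_python_ok(sprintf("
import zarr, numpy as np
root = zarr.open_group(%s, mode='w', zarr_format=2)
a = root.create_array('0', shape=(2,1,3,5,7), chunks=(1,1,2,3,4), dtype='<u2',
                      compressors=None, fill_value=0,
                      chunk_key_encoding={'name': 'v2',
                                          'configuration': {'separator': '/'}})
a[:] = np.arange(2*1*3*5*7, dtype='<u2').reshape(2,1,3,5,7)
root.attrs['multiscales'] = [{'datasets': [{'path': '0'}], 'version': '0.2'}]
", deparse(path)))
  img <- open_ngff(local_store(path))
  arr <- ngff_read_region(img, 0, list(t = 0, c = 0, z = 0, y = 0, x = 0),
                          list(t = 2, c = 1, z = 3, y = 5, x = 7))
  # C-order arange: value at (t,c,z,y,x) = ((((t*1)+c)*3+z)*5+y)*7+x
  expect_identical(arr[3, 2, 1, 1, 2], as.integer((((1 * 1 + 0) * 3 + 0) * 5
                                                   + 1) * 7 + 2))
  want <- array(0L, dim = c(7, 5, 3, 1, 2))
  for (t in 0:1) for (z in 0:2) for (y in 0:4) for (x in 0:6)
    want[x + 1, y + 1, z + 1, 1, t + 1] <-
      as.integer((((t * 1 + 0) * 3 + z) * 5 + y) * 7 + x)
  expect_identical(arr, want)
})

test_that("validator is empty on conformant stores and itemizes defects", {
  sp <- image_spec(70, 40, 1, 2, 1, chunk_edge = 32)
  py <- build_pyramid(sp)
  st <- mem_store()
  write_multiscale(st, gradient_chunk_source(sp, py), sp, py)
  expect_identical(nrow(validate_ngff(st)), 0L)

  store_delete(st, "1/.zarray")
  rep <- validate_ngff(st)
  expect_identical(rep$type, "missing_metadata")
  write_multiscale(st, gradient_chunk_source(sp, py), sp, py)  # restore

  store_put(st, "0/9/9/9/9/9", raw(10))
  rep <- validate_ngff(st)
  expect_identical(rep$type, "orphan_key")
  store_delete(st, "0/9/9/9/9/9")

  store_put(st, "0/0/0/0/0/0", raw(10))
  rep <- validate_ngff(st)
  expect_identical(rep$type, "chunk_size")
})

test_that("labels attach as sub-multiscales and validate against the base", {
  sp <- image_spec(64, 64, 1, 1, 1, chunk_edge = 32)
  py <- build_pyramid(sp)
  st <- mem_store()
  write_multiscale(st, gradient_chunk_source(sp, py), sp, py)
  thr <- 64L
  lbl_spec <- image_spec(64, 64, 1, 1, 1, bytes_per_sample = 1,
                         chunk_edge = 32)
  mask_source <- function(ref) {
    arr <- render_chunk(sp, ref, py)
    array(as.integer(arr >= thr), dim = dim(arr))
  }
  attach_labels(st, "bright", mask_source, lbl_spec, py)
  expect_identical(list_labels(st), "bright")
  expect_identical(nrow(validate_ngff(st)), 0L)
  lbl <- open_ngff(st, "labels/bright")
  m <- ngff_read_chunk(lbl, chunk_ref(0, c(0, 0, 0, 1, 1)))
  base <- render_chunk(sp, chunk_ref(0, c(0, 0, 0, 1, 1)), py)
  expect_identical(m, array(as.integer(base >= thr), dim = dim(base)))

  expect_error(attach_labels(st, "bright", mask_source, lbl_spec, py),
               "already attached")
  expect_silent(attach_labels(st, "bright", mask_source, lbl_spec, py,
                              overwrite = TRUE))
  bad_spec <- image_spec(32, 64, 1, 1, 1, bytes_per_sample = 1,
                         chunk_edge = 32)
  expect_error(attach_labels(st, "bad", mask_source, bad_spec,
                             build_pyramid(bad_spec)),
               "shape mismatch on axis 'x'")
})

test_that("HCS plates lay out wells and fields that read back correctly", {
  well <- image_spec(48, 48, chunk_edge = 32)
  st <- mem_store()
  res <- build_plate(st, rows = 2, cols = 3, fields = 1, well_spec = well)
  expect_identical(res$well_paths,
                   c("A/1", "A/2", "A/3", "B/1", "B/2", "B/3"))
  expect_length(res$field_paths, 6)
  expect_identical(nrow(validate_ngff(st)), 0L)
  img <- open_ngff(st, "B/2/0")
  py <- build_pyramid(well)
  expect_identical(ngff_read_chunk(img, chunk_ref(0, c(0, 0, 0, 1, 0))),
                   render_chunk(well, chunk_ref(0, c(0, 0, 0, 1, 0)), py))

  st1 <- mem_store()
  r1 <- build_plate(st1, 1, 1, 1, well)
  expect_identical(r1$well_paths, "A/1")
  expect_error(build_plate(mem_store(), 0, 1, 1, well), ">= 1")
})
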