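test_that("chunk sampling is seeded, uniform, and grid-bounded", {
  grid <- c(t = 2, c = 1, z = 2, y = 4, x = 4)
  expect_identical(sample_chunks(grid, 0, 1), list())
  s1 <- sample_chunks(grid, 25, 7)
  s2 <- sample_chunks(grid, 25, 7)
  expect_identical(s1, s2)
  expect_false(identical(s1, sample_chunks(grid, 25, 8)))
  for (r in s1) expect_true(all(r$indices < grid))
  expect_error(sample_chunks(c(t = 0, c = 1, z = 1, y = 1, x = 1), 5, 1),
               "empty")

  # chi-square uniformity over a 2x2 y/x grid at alpha = 0.01
  g2 <- c(t = 1, c = 1, z = 1, y = 2, x = 2)
  draws <- sample_chunks(g2, 1e4, 123)
  cell <- vapply(draws, function(r) r$indices[["y"]] * 2 + r$indices[["x"]],
                 numeric(1))
  obs <- tabulate(cell + 1, nbins = 4)
  chisq <- sum((obs - 2500)^2 / 2500)
  expect_lt(chisq, qchisq(0.99, df = 3))
})

test_that("request counts per chunk: ngff 1, hdf5 >= 2, 3D tiff = tiles_per_chunk", {
  sp <- vol_spec()
  py <- build_pyramid(sp)
  paths <- list(ngff = fixture_dataset("vol", sp, "ngff"),
                hdf5 = fixture_dataset("vol", sp, "hdf5"),
                ometiff = fixture_dataset("vol", sp, "ometiff"))
  refs <- sample_chunks(grid_shape(sp$sizes, sp$chunk_shape), 8, 5)
  want_req <- c(ngff = 1L, hdf5 = 2L, ometiff = 32L)
  for (fmt in names(paths)) {
    st <- if (fmt == "ngff") sim_store(local_store(paths[[fmt]]))
          else sim_store(local_store(dirname(paths[[fmt]])))
    rd <- open_dataset(if (fmt == "ngff") paths[[fmt]]
                       else basename(paths[[fmt]]), fmt, store = st)
    reset_request_log(st)
    rec <- time_chunk_reads(rd, refs, st, format = fmt)
    expect_identical(nrow(rec), length(refs))
    expect_false(any(rec$failed))
    if (fmt == "hdf5") expect_true(all(rec$requests >= want_req[[fmt]]))
    else expect_true(all(rec$requests == want_req[[fmt]]))
  }
})

test_that("identical chunk order is issued to every format (request logs)", {
  sp <- vol_spec()
  py <- build_pyramid(sp)
  ng <- fixture_dataset("vol", sp, "ngff")
  tif <- fixture_dataset("vol", sp, "ometiff")
  refs <- sample_chunks(grid_shape(sp$sizes, sp$chunk_shape), 10, 21)

  st1 <- sim_store(local_store(ng))
  rd1 <- open_dataset(ng, "ngff", store = st1)
  reset_request_log(st1)
  time_chunk_reads(rd1, refs, st1)
  expect_identical(request_log(st1)$key,
                   vapply(refs, function(r) chunk_key(0, r$indices), ""))

  # the tiff reader sees the same sequence: its per-read request groups are
  # deterministic functions of the same refs, so two passes agree exactly
  st2 <- sim_store(local_store(dirname(tif)))
  rd2 <- open_dataset(basename(tif), "ometiff", store = st2)
  reset_request_log(st2)
  time_chunk_reads(rd2, refs, st2)
  lg1 <- request_log(st2)
  reset_request_log(st2)
  time_chunk_reads(rd2, refs, st2)
  expect_identical(request_log(st2), lg1)
  expect_identical(nrow(lg1), length(refs) * 32L)
})

test_that("overhead probe: one request, at least the injected latency", {
  probe <- file.path(tempdir(), "bench-dummy", "dummy")
  write_dummy(probe)
  st <- sim_store(local_store(dirname(probe)), per_request_delay = 0.02)
  rec <- measure_overhead(st, "dummy", backend_name = "sim")
  expect_identical(rec$requests, 1L)
  expect_gte(rec$seconds, 0.018)
  expect_identical(rec$probe, "dummy")
  expect_error(measure_overhead(st, "absent"), "probe missing")
})

test_that("per-chunk time tracks requests x injected latency, monotonically", {
  sp <- vol_spec()
  paths <- list(ngff = fixture_dataset("vol", sp, "ngff"),
                hdf5 = fixture_dataset("vol", sp, "hdf5"),
                ometiff = fixture_dataset("vol", sp, "ometiff"))
  refs <- sample_chunks(grid_shape(sp$sizes, sp$chunk_shape), 5, 9)
  lats <- c(0, 0.001, 0.01, 0.05)
  med <- matrix(NA_real_, length(lats), 3,
                dimnames = list(NULL, names(paths)))
  for (i in seq_along(lats)) {
    for (fmt in names(paths)) {
      st <- if (fmt == "ngff")
        sim_store(local_store(paths[[fmt]]), per_request_delay = lats[i])
      else sim_store(local_store(dirname(paths[[fmt]])),
                     per_request_delay = lats[i])
      rd <- open_dataset(if (fmt == "ngff") paths[[fmt]]
                         else basename(paths[[fmt]]), fmt, store = st)
      rec <- time_chunk_reads(rd, refs, st, format = fmt)
      med[i, fmt] <- median(rec$seconds)
      # chunked access pays ~1x the latency; monolithic readers pay
      # (requests per chunk) x latency (small slack for clock granularity)
      expect_true(all(rec$seconds >= 0.9 * lats[i] * rec$requests - 0.002))
    }
  }
  for (fmt in colnames(med)) expect_true(all(diff(med[, fmt]) >= 0))
  # qualitative separation at high latency: chunked << monolithic
  expect_lt(med[4, "ngff"], med[4, "hdf5"])
  expect_lt(med[4, "hdf5"], med[4, "ometiff"])
  # ngff per-chunk time is approximately L itself (single request)
  expect_lt(med[4, "ngff"], 2 * 0.05 + 0.01)
})

test_that("run_bench produces the full deterministic CSV matrix", {
  sp <- image_spec(96, 96, 1, 1, 1, chunk_edge = 32)
  py <- build_pyramid(sp)
  root <- file.path(tempdir(), "runbench")
  unlink(root, recursive = TRUE); dir.create(root)
  build_dataset(sp, "ngff", file.path(root, "ng"))
  build_dataset(sp, "hdf5", file.path(root, "a.h5"))
  probe <- file.path(root, "dummy")
  cfg <- bench_config(
    datasets = list(ngff = file.path(root, "ng"),
                    hdf5 = file.path(root, "a.h5")),
    backends = list(local = list(), sim = list(per_request_delay = 0.001)),
    n_chunks = 7, seed = 33, dummy = probe)
  res <- run_bench(cfg)
  expect_identical(nrow(res), 2L * (2L * 7L) + 2L)
  expect_identical(sum(res$probe == "dummy"), 2L)
  res2 <- run_bench(cfg)
  expect_identical(res[, c("format", "backend", "probe", "level",
                           "t", "c", "z", "y", "x", "requests")],
                   res2[, c("format", "backend", "probe", "level",
                            "t", "c", "z", "y", "x", "requests")])
  csv <- file.path(root, "res.csv")
  write_bench_csv(res, csv)
  back <- read_bench_csv(csv)
  expect_identical(attr(back, "seed"), 33L)
  expect_identical(nrow(back), nrow(res))
  expect_identical(back$requests, res$requests)

  cfg_bad <- bench_config(datasets = list(ngff = file.path(root, "missing")),
                          n_chunks = 1)
  expect_error(run_bench(cfg_bad), "dataset missing")
})
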