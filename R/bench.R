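# Chunk-access latency benchmark: a seeded random sequence of level-0 chunk
# locations is read, in the same order, from each format; each retrieval is
# timed on its own (dataset open and metadata parsing are excluded), and
# the instrumented backend prices and counts every byte-range request. A
# 1-byte probe read measures the fixed per-request overhead.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

#' Sample a random sequence of chunk locations
#'
#' Uniform with replacement over the level-0 chunk grid, reproducible for a
#' given seed. The benchmark default is 100 locations.
#'
#' @param grid named integer 5-vector of per-axis chunk counts (from
#'   [reader_grid()] or [grid_shape()]).
#' @param n number of locations (>= 0).
#' @param seed RNG seed.
#' @return list of [chunk_ref()]s (level 0), length `n`.
#' @export
sample_chunks <- function(grid, n = 100L, seed = 1L) {
  if (n < 0) stop("n must be >= 0")
  if (n == 0) return(list())
  if (any(grid < 1)) stop("empty chunk grid")
  with_seed(seed, {
    draws <- vapply(grid, function(g) sample.int(g, n, replace = TRUE) - 1L,
                    integer(n))
    draws <- matrix(draws, nrow = n)
    lapply(seq_len(n), function(i) chunk_ref(0L, draws[i, ]))
  })
}

timing_row <- function(format, backend, probe, ref, seconds, requests,
                       failed) {
  idx <- if (is.null(ref)) rep(NA_integer_, 5) else unname(ref$indices)
  data.frame(format = format, backend = backend, probe = probe,
             level = if (is.null(ref)) NA_integer_ else ref$level,
             t = idx[1], c = idx[2], z = idx[3], y = idx[4], x = idx[5],
             seconds = seconds, requests = requests, failed = failed,
             stringsAsFactors = FALSE)
}

#' Time individual chunk reads
#'
#' One record per reference, in order. The clock spans only the per-chunk
#' retrieval (the reader was opened, and its metadata cached, beforehand);
#' request counts come from the instrumented backend's log. Failed reads
#' are recorded and the run continues.
#'
#' @param reader an [open_dataset()] handle opened over `backend`.
#' @param refs list of [chunk_ref()]s.
#' @param backend the [sim_store()] the reader reads through (`NULL` to
#'   skip request counting).
#' @param format,backend_name labels for the output rows.
#' @return data.frame of timing records (bench CSV dialect).
#' @export
time_chunk_reads <- function(reader, refs, backend = NULL,
                             format = reader$format, backend_name = "local") {
  rows <- vector("list", length(refs))
  for (i in seq_along(refs)) {
    n0 <- if (is.null(backend)) 0L else request_count(backend)
    t0 <- proc.time()[["elapsed"]]
    ok <- tryCatch({ reader$read_chunk(refs[[i]]); TRUE },
                   error = function(e) FALSE)
    dt <- proc.time()[["elapsed"]] - t0
    n1 <- if (is.null(backend)) 0L else request_count(backend)
    rows[[i]] <- timing_row(format, backend_name, "chunk", refs[[i]],
                            dt, n1 - n0, !ok)
  }
  do.call(rbind, rows)
}

#' Time the 1-byte overhead probe
#'
#' Reads the 1-byte dummy file once through the backend: the recorded time
#' is pure per-request overhead, independent of payload size.
#'
#' @param backend a store holding the probe.
#' @param key probe key (default `"dummy"`).
#' @param backend_name label for the output row.
#' @return one-row timing data.frame (`probe = "dummy"`, `requests = 1`).
#' @export
measure_overhead <- function(backend, key = "dummy", backend_name = "local") {
  if (!store_exists(backend, key)) stop("overhead probe missing: ", key)
  n0 <- if (inherits(backend, "sim_store")) request_count(backend) else 0L
  t0 <- proc.time()[["elapsed"]]
  b <- store_get(backend, key)
  dt <- proc.time()[["elapsed"]] - t0
  n1 <- if (inherits(backend, "sim_store")) request_count(backend) else n0 + 1L
  timing_row("dummy", backend_name, "dummy", NULL, dt, n1 - n0, FALSE)
}

#' Benchmark configuration
#'
#' @param datasets named list mapping format (`"ngff"`, `"hdf5"`,
#'   `"ometiff"`) to its path.
#' @param backends named list of backend settings; each entry is a list
#'   with `per_request_delay` and `per_byte_delay` (seconds). An empty
#'   delay models local disk.
#' @param n_chunks chunk locations per format (default 100).
#' @param seed RNG seed for the location sequence.
#' @param dummy path of the 1-byte probe file (created if absent).
#' @return a `bench_config` list.
#' @export
bench_config <- function(datasets, backends = list(local = list()),
                         n_chunks = 100L, seed = 1L, dummy = NULL) {
  if (n_chunks < 0) stop("n_chunks must be >= 0")
  structure(list(datasets = datasets, backends = backends,
                 n_chunks = as.integer(n_chunks), seed = as.integer(seed),
                 dummy = dummy),
            class = "bench_config")
}

bench_backend_store <- function(root, settings) {
  sim_store(local_store(root),
            per_request_delay = settings$per_request_delay %||% 0,
            per_byte_delay = settings$per_byte_delay %||% 0)
}

#' Run the latency benchmark
#'
#' For every backend and every configured format: open the dataset once
#' (untimed), read the same seeded sequence of level-0 chunks, record one
#' timing row per read, and add the 1-byte probe row. All formats see the
#' identical chunk order; the grids must therefore agree across formats.
#'
#' @param config a [bench_config()].
#' @return data.frame of timing records with attribute `seed`; write it
#'   with [write_bench_csv()].
#' @export
run_bench <- function(config) {
  stopifnot(inherits(config, "bench_config"))
  for (p in unlist(config$datasets))
    if (!file.exists(p)) stop("dataset missing: ", p,
                              " (generate it first)", call. = FALSE)
  refs <- NULL
  out <- list()
  for (bk in names(config$backends)) {
    settings <- config$backends[[bk]]
    for (fmt in names(config$datasets)) {
      path <- config$datasets[[fmt]]
      if (fmt == "ngff") {
        st <- bench_backend_store(path, settings)
        reader <- open_dataset(path, fmt, store = st)
      } else {
        st <- bench_backend_store(dirname(path), settings)
        reader <- open_dataset(basename(path), fmt, store = st)
      }
      if (is.null(refs))
        refs <- sample_chunks(reader_grid(reader, 0L), config$n_chunks,
                              config$seed)
      else
        stopifnot(all(reader_grid(reader, 0L) ==
                      grid_shape(reader$levels[[1]], reader$chunk_shape)))
      reset_request_log(st)
      out[[length(out) + 1L]] <-
        time_chunk_reads(reader, refs, st, format = fmt, backend_name = bk)
    }
    if (!is.null(config$dummy)) {
      if (!file.exists(config$dummy)) write_dummy(config$dummy)
      dst <- bench_backend_store(dirname(config$dummy), settings)
      out[[length(out) + 1L]] <-
        measure_overhead(dst, basename(config$dummy), backend_name = bk)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "seed") <- config$seed
  res
}

#' Write / read the benchmark CSV dialect
#'
#' Columns `format,backend,probe,level,t,c,z,y,x,seconds,requests,failed`;
#' the seed is recorded on a leading comment line.
#'
#' @param results data.frame from [run_bench()].
#' @param path CSV path.
#' @return the path ([write_bench_csv()]) or the data.frame with a `seed`
#'   attribute ([read_bench_csv()]).
#' @export
write_bench_csv <- function(results, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d", attr(results, "seed") %||% NA_integer_), con)
  utils::write.csv(results, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bench_csv
#' @export
read_bench_csv <- function(path) {
  first <- readLines(path, n = 1L)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  seed <- if (grepl("^# seed=", first))
    as.integer(sub("^# seed=", "", first)) else NA_integer_
  attr(df, "seed") <- seed
  df
}
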