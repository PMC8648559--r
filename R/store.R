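#' Key-value store contract
#'
#' Every layout in the package (NGFF directory trees, single-file HDF5 and
#' TIFF containers, the overhead probe) is written and read through a small
#' key-to-bytes contract mirroring object storage: `store_get`,
#' `store_get_range`, `store_put`, `store_list`, `store_exists`,
#' `store_delete`. Keys are "/"-separated relative paths. Backends implement
#' the generics; [sim_store()] wraps any backend with latency injection and
#' a request log, which is how the benchmark counts and prices requests.
#'
#' @param store a store object.
#' @param key relative "/"-separated key.
#' @param offset 0-based byte offset for ranged reads.
#' @param length number of bytes for ranged reads.
#' @param bytes raw vector to write.
#' @param prefix key prefix filter for listing (`""` lists everything).
#' @name store_kv
NULL

#' @rdname store_kv
#' @export
store_get <- function(store, key) UseMethod("store_get")
#' @rdname store_kv
#' @export
store_get_range <- function(store, key, offset, length) UseMethod("store_get_range")
#' @rdname store_kv
#' @export
store_put <- function(store, key, bytes) UseMethod("store_put")
#' @rdname store_kv
#' @export
store_list <- function(store, prefix = "") UseMethod("store_list")
#' @rdname store_kv
#' @export
store_exists <- function(store, key) UseMethod("store_exists")
#' @rdname store_kv
#' @export
store_delete <- function(store, key) UseMethod("store_delete")

#' Local-directory store
#'
#' Keys map to files below `root`; `put` creates intermediate directories
#' ("/" separator becomes the directory tree, the nested chunk layout).
#'
#' @param root directory path (created on first write).
#' @return a store object of class `local_store`.
#' @export
local_store <- function(root) {
  structure(list(root = normalizePath(root, mustWork = FALSE)),
            class = c("local_store", "store_kv"))
}

loc_path <- function(store, key) file.path(store$root, key)

#' @export
store_get.local_store <- function(store, key) {
  p <- loc_path(store, key)
  if (!file.exists(p)) stop("key not found: ", key, call. = FALSE)
  readBin(p, raw(), n = file.size(p))
}

#' @export
store_get_range.local_store <- function(store, key, offset, length) {
  p <- loc_path(store, key)
  if (!file.exists(p)) stop("key not found: ", key, call. = FALSE)
  con <- file(p, "rb")
  on.exit(close(con))
  seek(con, where = offset, origin = "start")
  readBin(con, raw(), n = length)
}

#' @export
store_put.local_store <- function(store, key, bytes) {
  p <- loc_path(store, key)
  dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
  writeBin(bytes, p)
  invisible(store)
}

#' @export
store_list.local_store <- function(store, prefix = "") {
  if (!dir.exists(store$root)) return(character(0))
  all <- list.files(store$root, recursive = TRUE, all.files = TRUE,
                    no.. = TRUE)
  if (nzchar(prefix)) all <- all[startsWith(all, prefix)]
  sort(all)
}

#' @export
store_exists.local_store <- function(store, key) file.exists(loc_path(store, key))

#' @export
store_delete.local_store <- function(store, key) {
  unlink(loc_path(store, key))
  invisible(store)
}

#' In-memory store
#'
#' Backed by an environment; useful for tests and as the target of small
#' conversions.
#'
#' @return a store object of class `mem_store`.
#' @export
mem_store <- function() {
  structure(list(env = new.env(parent = emptyenv())),
            class = c("mem_store", "store_kv"))
}

#' @export
store_get.mem_store <- function(store, key) {
  if (!exists(key, envir = store$env, inherits = FALSE))
    stop("key not found: ", key, call. = FALSE)
  get(key, envir = store$env, inherits = FALSE)
}

#' @export
store_get_range.mem_store <- function(store, key, offset, length) {
  b <- store_get.mem_store(store, key)
  b[(offset + 1):(offset + length)]
}

#' @export
store_put.mem_store <- function(store, key, bytes) {
  assign(key, bytes, envir = store$env)
  invisible(store)
}

#' @export
store_list.mem_store <- function(store, prefix = "") {
  k <- ls(store$env, all.names = TRUE)
  if (nzchar(prefix)) k <- k[startsWith(k, prefix)]
  sort(k)
}

#' @export
store_exists.mem_store <- function(store, key)
  exists(key, envir = store$env, inherits = FALSE)

#' @export
store_delete.mem_store <- function(store, key) {
  if (exists(key, envir = store$env, inherits = FALSE))
    rm(list = key, envir = store$env)
  invisible(store)
}

#' Latency-injection / instrumentation backend
#'
#' Wraps another store. Every read request (`get` or ranged `get`) sleeps
#' `per_request_delay + nbytes * per_byte_delay` seconds and appends one
#' entry `(op, key, bytes)` to the request log. This models remote regimes
#' (HTTP server, object storage) deterministically: the injected
#' per-request delay plays the role of round-trip latency.
#'
#' @param inner the wrapped store.
#' @param per_request_delay seconds added to every read request.
#' @param per_byte_delay seconds per byte transferred.
#' @return a store of class `sim_store`.
#' @seealso [request_log()], [request_count()], [reset_request_log()]
#' @export
sim_store <- function(inner, per_request_delay = 0, per_byte_delay = 0) {
  log <- new.env(parent = emptyenv())
  log$entries <- list()
  structure(list(inner = inner, per_request_delay = per_request_delay,
                 per_byte_delay = per_byte_delay, log = log),
            class = c("sim_store", "store_kv"))
}

sim_record <- function(store, op, key, nbytes) {
  d <- store$per_request_delay + nbytes * store$per_byte_delay
  if (d > 0) Sys.sleep(d)
  store$log$entries[[length(store$log$entries) + 1L]] <-
    list(op = op, key = key, bytes = nbytes)
  invisible(NULL)
}

#' @export
store_get.sim_store <- function(store, key) {
  b <- store_get(store$inner, key)
  sim_record(store, "get", key, length(b))
  b
}

#' @export
store_get_range.sim_store <- function(store, key, offset, length) {
  b <- store_get_range(store$inner, key, offset, length)
  sim_record(store, "get_range", key, length(b))
  b
}

#' @export
store_put.sim_store <- function(store, key, bytes) {
  store_put(store$inner, key, bytes)
  invisible(store)
}

#' @export
store_list.sim_store <- function(store, prefix = "") store_list(store$inner, prefix)

#' @export
store_exists.sim_store <- function(store, key) store_exists(store$inner, key)

#' @export
store_delete.sim_store <- function(store, key) {
  store_delete(store$inner, key)
  invisible(store)
}

#' Request log of an instrumented store
#'
#' @param store a [sim_store()].
#' @return data.frame with columns `op`, `key`, `bytes`, one row per read
#'   request in issue order.
#' @export
request_log <- function(store) {
  stopifnot(inherits(store, "sim_store"))
  e <- store$log$entries
  data.frame(op = vapply(e, `[[`, "", "op"),
             key = vapply(e, `[[`, "", "key"),
             bytes = vapply(e, function(x) as.numeric(x$bytes), numeric(1)),
             stringsAsFactors = FALSE)
}

#' @rdname request_log
#' @export
request_count <- function(store) {
  stopifnot(inherits(store, "sim_store"))
  length(store$log$entries)
}

#' @rdname request_log
#' @export
reset_request_log <- function(store) {
  stopifnot(inherits(store, "sim_store"))
  store$log$entries <- list()
  invisible(store)
}
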