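# Shared fixtures. Datasets are generated in a per-session temp directory
# and memoised, so expensive builds happen once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture_root <- function() {
  if (is.null(.fixtures$root)) {
    .fixtures$root <- file.path(tempdir(), "ngffbench-fixtures")
    dir.create(.fixtures$root, showWarnings = FALSE, recursive = TRUE)
  }
  .fixtures$root
}

# A small anisotropic 5D image exercising edge chunks on y/x/z and
# non-trivial c/t: sizes (t,c,z,y,x) = (2,2,3,40,70), 32^3 chunks.
tiny_spec <- function() image_spec(70, 40, 3, 2, 2, chunk_edge = 32)

# A volumetric spec whose 3D chunks have full z-extent 32 (so one TIFF
# chunk read spans 32 planar tiles) and >1 chunk per axis.
vol_spec <- function() image_spec(64, 64, 64, 1, 2, chunk_edge = 32)

fixture_dataset <- function(name, spec, format) {
  key <- paste0(name, "-", format)
  if (is.null(.fixtures[[key]])) {
    dest <- file.path(fixture_root(),
                      paste0(name, switch(format, ngff = "",
                                          hdf5 = ".h5", ometiff = ".tif")))
    build_dataset(spec, format, dest)
    .fixtures[[key]] <- dest
  }
  .fixtures[[key]]
}

run_python <- function(code) {
  res <- suppressWarnings(
    system2("python", c("-"), input = code, stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status") %||% 0L
  list(status = status, output = paste(res, collapse = "\n"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_python_ok <- function(code, label = "python oracle") {
  r <- run_python(code)
  expect_identical(r$status, 0L,
                   label = paste0(label, " exit status (output: ", r$output, ")"))
  invisible(r)
}
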