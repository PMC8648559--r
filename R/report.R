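# Raincloud statistics and figures: a raincloud combines a half-violin
# (Gaussian kernel density estimate), a box (median and quartiles), and the
# jittered raw points, so the shape of a latency distribution and its
# summary statistics can be compared at a glance.

#' Gaussian kernel density estimate on a regular grid
#'
#' Scott's bandwidth rule (`sd * n^(-1/5)`) by default; the grid spans the
#' data plus three bandwidths on each side, and the trapezoid integral of
#' the returned curve is within 1% of 1.
#'
#' @param values numeric vector (>= 2 finite values with positive spread).
#' @param bandwidth kernel bandwidth; `NULL` for Scott's rule.
#' @param n_grid number of grid points.
#' @return data.frame with columns `x` (grid) and `density`.
#' @export
kde <- function(values, bandwidth = NULL, n_grid = 512L) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("kde needs at least 2 finite values")
  if (is.null(bandwidth))
    bandwidth <- stats::sd(values) * length(values)^(-1 / 5)
  if (!is.finite(bandwidth) || bandwidth <= 0)
    stop("zero-variance sample: no density curve (degenerate spike)",
         call. = FALSE)
  g <- seq(min(values) - 3 * bandwidth, max(values) + 3 * bandwidth,
           length.out = n_grid)
  dens <- vapply(g, function(p) mean(stats::dnorm(p, values, bandwidth)),
                 numeric(1))
  data.frame(x = g, density = dens)
}

#' Median and quartiles of a sample
#'
#' Linear-interpolation quantiles (type 7) of the sorted sample.
#'
#' @param values numeric vector (>= 1 value).
#' @return named vector `(median, q1, q3)`.
#' @export
box_stats <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("box_stats needs at least one value")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(median = q[2], q1 = q[1], q3 = q[3])
}

#' Reproducible jitter offsets for raw data points
#'
#' Offsets are uniform on `[-width/2, width/2]`, deterministic for a seed;
#' values are returned unchanged.
#'
#' @param values numeric vector.
#' @param seed RNG seed.
#' @param width full jitter width (>= 0).
#' @return data.frame with columns `value` and `offset`.
#' @export
jitter_points <- function(values, seed = 1L, width = 0.3) {
  if (width < 0) stop("width must be >= 0")
  off <- if (width == 0) rep(0, length(values)) else
    with_seed(seed, stats::runif(length(values), -width / 2, width / 2))
  data.frame(value = as.numeric(values), offset = off)
}

raincloud_layers <- function(df, value_col = "seconds", seed = 1L,
                             violin_width = 0.4, jitter_width = 0.25) {
  groups <- split(df, interaction(df$format, df$backend, drop = TRUE))
  out <- list(violin = NULL, box = NULL, points = NULL, dropped = character(0))
  gi <- 0
  for (gn in names(groups)) {
    v <- groups[[gn]][[value_col]]
    v <- v[is.finite(v)]
    gi <- gi + 1
    bs <- box_stats(v)
    out$box <- rbind(out$box, data.frame(group = gn, pos = gi,
      median = bs[["median"]], q1 = bs[["q1"]], q3 = bs[["q3"]]))
    kd <- tryCatch(kde(v), error = function(e) NULL)
    if (is.null(kd)) {
      warning("group '", gn, "': zero spread, box only (no violin)",
              call. = FALSE)
      out$dropped <- c(out$dropped, gn)
    } else {
      kd$height <- violin_width * kd$density / max(kd$density)
      out$violin <- rbind(out$violin,
        data.frame(group = gn, pos = gi, x = kd$x, density = kd$density,
                   height = kd$height))
    }
    jp <- jitter_points(v, seed = seed + gi, width = jitter_width)
    out$points <- rbind(out$points,
      data.frame(group = gn, pos = gi, value = jp$value, offset = jp$offset))
  }
  out
}

save_figure <- function(plot, out) {
  ext <- tolower(tools::file_ext(out))
  dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
  dev <- switch(ext,
    svg = function(f) grDevices::svg(f, width = 8, height = 5),
    pdf = function(f) grDevices::pdf(f, width = 8, height = 5),
    png = function(f) grDevices::png(f, width = 1600, height = 1000,
                                     res = 200),
    stop("unsupported figure format: .", ext))
  dev(out)
  on.exit(grDevices::dev.off())
  print(plot)
  invisible(out)
}

#' Raincloud figure of benchmark results
#'
#' One cloud per format-backend group: half-violin (KDE) above the group
#' line, the median/quartile box on it, and the jittered raw per-chunk
#' times below. All layers are recomputed from the CSV rows, so the drawn
#' medians are exactly [box_stats()] of the input.
#'
#' @param results benchmark results: a data.frame or a CSV path from
#'   [write_bench_csv()].
#' @param out figure file (`.svg`, `.pdf` or `.png`); `NULL` to skip
#'   writing.
#' @param seed jitter seed.
#' @param value_col column to summarize (default `"seconds"`).
#' @return (invisibly) list with `plot` (ggplot) and `layers` (the violin /
#'   box / points data frames).
#' @export
raincloud_figure <- function(results, out = NULL, seed = 1L,
                             value_col = "seconds") {
  if (is.character(results)) results <- read_bench_csv(results)
  df <- results[results$probe == "chunk" & !results$failed, ]
  if (!nrow(df)) stop("no chunk timing rows in input")
  ly <- raincloud_layers(df, value_col = value_col, seed = seed)
  p <- ggplot2::ggplot()
  if (!is.null(ly$violin))
    p <- p + ggplot2::geom_ribbon(
      data = ly$violin,
      ggplot2::aes(x = .data$x, ymin = .data$pos, ymax = .data$pos + .data$height,
                   group = .data$group, fill = .data$group),
      alpha = 0.6)
  p <- p +
    ggplot2::geom_point(
      data = ly$points,
      ggplot2::aes(x = .data$value, y = .data$pos - 0.35 + .data$offset,
                   colour = .data$group),
      size = 0.6, alpha = 0.6) +
    ggplot2::geom_errorbarh(
      data = ly$box,
      ggplot2::aes(xmin = .data$q1, xmax = .data$q3, y = .data$pos,
                   group = .data$group),
      height = 0.12) +
    ggplot2::geom_point(
      data = ly$box,
      ggplot2::aes(x = .data$median, y = .data$pos), shape = 18, size = 2.5) +
    ggplot2::scale_y_continuous(breaks = ly$box$pos, labels = ly$box$group) +
    ggplot2::labs(x = value_col, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
  if (!is.null(out)) save_figure(p, out)
  invisible(list(plot = p, layers = ly))
}

#' Chunk-size trade-off figure
#'
#' Per-chunk byte size against total chunk-file count for each candidate
#' edge, on log-log axes, with the edge chosen for the benchmark
#' highlighted (256 for the planar preset, 32 for the volumetric one).
#'
#' @param tradeoff data.frame from [chunk_tradeoff()].
#' @param chosen_edge edge to highlight (`NULL` for none).
#' @param out figure file or `NULL`.
#' @return (invisibly) list with `plot` and `data`.
#' @export
tradeoff_figure <- function(tradeoff, chosen_edge = NULL, out = NULL) {
  if (!nrow(tradeoff)) stop("empty trade-off table")
  tradeoff$chosen <- !is.null(chosen_edge) & tradeoff$edge %in% chosen_edge
  p <- ggplot2::ggplot(tradeoff,
         ggplot2::aes(x = .data$chunk_nbytes, y = .data$total_chunk_count)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chosen), size = 2.5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$edge), vjust = -0.8,
                       size = 3) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "chunk size (bytes)", y = "total chunk files") +
    ggplot2::theme_minimal() + ggplot2::theme(legend.position = "none")
  if (!is.null(out)) save_figure(p, out)
  invisible(list(plot = p, data = tradeoff))
}
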