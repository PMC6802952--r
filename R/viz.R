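# Time-resolved MDS visualization of RDM series and beta time courses.

#' Sliding-window smoothing of an RDM series
#'
#' Entrywise boxcar average over a centered window; at the series edges
#' the window is truncated. A window no wider than one time step is the
#' identity. Smoothing preserves the series mean entrywise.
#'
#' @param series An [rdm_series()].
#' @param window_ms Window width in ms (default 15 ms).
#' @return The smoothed [rdm_series()].
#' @export
smooth_series <- function(series, window_ms = 15) {
  stopifnot(inherits(series, "rdm_series"))
  step <- if (length(series$times) > 1) diff(series$times)[1] else window_ms
  if (window_ms < step) {
    stop("window must be at least one time step wide", call. = FALSE)
  }
  half <- floor((window_ms / step) / 2)
  if (half == 0) return(series)
  n_t <- length(series$times)
  out <- series$values
  for (t in seq_len(n_t)) {
    win <- max(1, t - half):min(n_t, t + half)
    out[, , t] <- apply(series$values[, , win, drop = FALSE], c(1, 2), mean)
  }
  series$values <- out
  series
}

#' Two-dimensional MDS embedding of one RDM
#'
#' Projects the conditions into a plane whose inter-point distances
#' approximate the dissimilarities. The default is metric
#' (classical/Torgerson) scaling, which is deterministic and robust to
#' tied or zero dissimilarities; `nonmetric = TRUE` refines it by
#' Kruskal's non-metric MDS. Cross-validated-correlation RDMs, which can
#' be negative, are shifted by their minimum first; decoding-accuracy
#' RDMs are used as-is.
#'
#' @param x An [rdm()].
#' @param n_dims Embedding dimensionality (default 2).
#' @param nonmetric Use non-metric MDS refinement.
#' @param seed Unused for the deterministic metric solution; kept so that
#'   callers can thread one seed through a frame sequence.
#' @return An `mds_frame`: tibble with columns `condition`, `dim1`,
#'   `dim2`, with attributes `stress` and `time`.
#' @export
mds_frame <- function(x, n_dims = 2, nonmetric = FALSE, seed = NULL) {
  m <- as.matrix(x)
  diag(m) <- 0
  off <- m[lower.tri(m)]
  if (min(off) < 0) m <- m - min(off) # shift negatives (crossval RDMs)
  diag(m) <- 0
  if (max(m) <= 0) {
    warning("constant RDM: degenerate MDS configuration", call. = FALSE)
    coords <- matrix(0, nrow(m), n_dims)
  } else {
    coords <- stats::cmdscale(stats::as.dist(m), k = n_dims)
    if (ncol(coords) < n_dims) { # rank-deficient configuration
      coords <- cbind(coords,
                      matrix(0, nrow(m), n_dims - ncol(coords)))
    }
    if (nonmetric) {
      d <- stats::as.dist(m)
      d[d <= 0] <- min(d[d > 0]) / 2 # isoMDS needs positive dissimilarities
      coords <- MASS::isoMDS(d, y = coords, k = n_dims, trace = FALSE)$points
    }
  }
  coords <- sweep(coords, 2, colMeans(coords), `-`)
  dd <- as.matrix(stats::dist(coords))
  stress <- sqrt(sum((dd[lower.tri(dd)] - m[lower.tri(m)])^2) /
                   max(sum(m[lower.tri(m)]^2), .Machine$double.eps))
  out <- tibble::tibble(condition = seq_len(nrow(m)),
                        dim1 = coords[, 1], dim2 = coords[, 2])
  attr(out, "stress") <- stress
  class(out) <- c("mds_frame", class(out))
  out
}

#' Time-resolved MDS of an RDM series with frame-to-frame alignment
#'
#' Computes one MDS configuration per time point and chains Procrustes
#' alignments (each frame rigidly rotated/reflected/translated onto its
#' aligned predecessor, no scaling) so the resulting movie is visually
#' continuous despite the rotation indeterminacy of MDS. The rigid
#' alignment never changes within-frame pairwise distances.
#'
#' @param series An [rdm_series()] (typically smoothed with
#'   [smooth_series()] and averaged across subjects).
#' @param set Optional stimulus set; its vertical level and scene type
#'   are joined onto the output for plotting.
#' @param nonmetric Passed to [mds_frame()].
#' @return An `mds_movie` object: tibble with columns `time`,
#'   `condition`, `dim1`, `dim2` (plus design columns when `set` is
#'   given).
#' @export
mds_series <- function(series, set = NULL, nonmetric = FALSE) {
  stopifnot(inherits(series, "rdm_series"))
  n_t <- length(series$times)
  if (dim(series$values)[1] < 2) {
    stop("MDS needs at least two conditions", call. = FALSE)
  }
  frames <- vector("list", n_t)
  prev <- NULL
  for (t in seq_len(n_t)) {
    fr <- suppressWarnings(
      mds_frame(rdm_from_slice(series, t), nonmetric = nonmetric))
    co <- cbind(fr$dim1, fr$dim2)
    if (!is.null(prev)) {
      pr <- vegan::procrustes(prev, co, scale = FALSE, symmetric = FALSE)
      co <- pr$Yrot
      co <- sweep(co, 2, colMeans(co), `-`)
    }
    prev <- co
    frames[[t]] <- tibble::tibble(time = series$times[t],
                                  condition = fr$condition,
                                  dim1 = unname(co[, 1]),
                                  dim2 = unname(co[, 2]))
  }
  out <- dplyr::bind_rows(frames)
  if (!is.null(set)) {
    assert_stimulus_set(set)
    out <- dplyr::left_join(
      out, set[, c("condition", "scene_type", "vertical", "scene_id")],
      by = "condition")
  }
  class(out) <- c("mds_movie", class(out))
  out
}

rdm_from_slice <- function(series, t) {
  rdm(series$values[, , t], kind = series$kind)
}

#' Write an MDS movie as per-frame images and a coordinate table
#'
#' Renders one PNG per time point (condition markers colored by vertical
#' level, shaped by scene type when the design is attached) and writes
#' all frame coordinates to a CSV. Assembling the frames into an MP4/GIF
#' is left to an external encoder (e.g. `ffmpeg -i frame_%04d.png`).
#'
#' @param series An [rdm_series()], or a precomputed `mds_movie`.
#' @param out_dir Output directory (created if missing).
#' @param set Optional stimulus set, see [mds_series()].
#' @param width,height,dpi PNG geometry.
#' @return Invisibly, the `mds_movie` tibble (also written to
#'   `coordinates.csv` in `out_dir`).
#' @export
mds_movie <- function(series, out_dir, set = NULL, width = 5, height = 5,
                      dpi = 96) {
  movie <- if (inherits(series, "mds_movie")) series else
    mds_series(series, set = set)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(movie),
                   file.path(out_dir, "coordinates.csv"), row.names = FALSE)
  lims <- c(-1, 1) * max(abs(c(movie$dim1, movie$dim2)))
  times <- unique(movie$time)
  for (k in seq_along(times)) {
    fr <- movie[movie$time == times[k], , drop = FALSE]
    p <- plot_mds_frame(fr, lims) +
      ggplot2::ggtitle(sprintf("%g ms", times[k]))
    file <- file.path(out_dir, sprintf("frame_%04d.png", k))
    tryCatch(
      ggplot2::ggsave(file, p, width = width, height = height, dpi = dpi),
      error = function(e) stop(sprintf("failed writing frame %d to %s: %s",
                                       k, file, conditionMessage(e)),
                               call. = FALSE))
  }
  invisible(movie)
}

plot_mds_frame <- function(fr, lims = NULL) {
  has_design <- all(c("vertical", "scene_type") %in% names(fr))
  p <- if (has_design) {
    ggplot2::ggplot(fr, ggplot2::aes(.data$dim1, .data$dim2,
                                     colour = factor(.data$vertical),
                                     shape = .data$scene_type))
  } else {
    ggplot2::ggplot(fr, ggplot2::aes(.data$dim1, .data$dim2))
  }
  p <- p + ggplot2::geom_point(size = 2.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "MDS dim 1", y = "MDS dim 2",
                  colour = "vertical", shape = "type") +
    ggplot2::theme_minimal()
  if (!is.null(lims)) {
    p <- p + ggplot2::lims(x = lims, y = lims)
  }
  p
}

#' @export
autoplot.mds_frame <- function(object, ...) {
  plot_mds_frame(object)
}

#' Group-average beta time courses
#'
#' @param betas Tidy tibble with columns `subject`, `unit` (time in ms),
#'   `predictor`, `beta`, e.g. from per-subject [run_glm_suite()] calls
#'   bound together.
#' @return A ggplot: mean beta per predictor over time with standard
#'   error ribbons.
#' @export
plot_betas <- function(betas) {
  df <- betas |>
    dplyr::group_by(.data$unit, .data$predictor) |>
    dplyr::summarise(mean = mean(.data$beta),
                     se = stats::sd(.data$beta) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$unit, .data$mean,
                                   colour = .data$predictor,
                                   fill = .data$predictor)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "beta (a.u.)") +
    ggplot2::theme_minimal()
}
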