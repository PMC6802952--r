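#' Build a factorial scene-fragment stimulus set
#'
#' Constructs the full factorial grid of scene fragments: scenes (half
#' indoor, half outdoor) crossed with vertical and horizontal fragment
#' positions. The default reproduces the 36-condition design of the
#' accompanying experiments: 6 scenes (3 indoor + 3 outdoor), each split
#' into 3 vertical x 2 horizontal fragments.
#'
#' Conditions are returned in a fixed canonical order — scene-major, then
#' vertical, then horizontal — which every RDM and pair mask built by this
#' package is index-aligned to. Vertical levels are coded 1 = top,
#' 2 = middle, 3 = bottom; horizontal 1 = left, 2 = right. Indoor scenes
#' come first.
#'
#' @param n_scenes_per_type Number of scenes per scene type (indoor and
#'   outdoor each contribute this many scenes).
#' @param n_vertical Number of vertical fragment positions.
#' @param n_horizontal Number of horizontal fragment positions.
#'
#' @return A tibble with class `stimulus_set` and columns `condition`
#'   (1-based canonical index), `scene_id`, `scene_type` (factor
#'   indoor/outdoor), `vertical`, `horizontal`, and `label`.
#' @export
#' @examples
#' set <- build_stimulus_set()
#' nrow(set) # 36
build_stimulus_set <- function(n_scenes_per_type = 3, n_vertical = 3,
                               n_horizontal = 2) {
  counts <- c(n_scenes_per_type, n_vertical, n_horizontal)
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != round(counts))) {
    stop("invalid design: all counts must be integers >= 1", call. = FALSE)
  }
  n_scenes <- 2L * as.integer(n_scenes_per_type)
  grid <- tidyr::expand_grid(
    scene_id = seq_len(n_scenes),
    vertical = seq_len(as.integer(n_vertical)),
    horizontal = seq_len(as.integer(n_horizontal))
  )
  set <- grid |>
    dplyr::mutate(
      scene_type = factor(
        ifelse(.data$scene_id <= n_scenes_per_type, "indoor", "outdoor"),
        levels = c("indoor", "outdoor")
      ),
      condition = dplyr::row_number(),
      label = sprintf("s%02d_v%d_h%d", .data$scene_id, .data$vertical,
                      .data$horizontal)
    ) |>
    dplyr::select("condition", "scene_id", "scene_type", "vertical",
                  "horizontal", "label")
  class(set) <- c("stimulus_set", class(set))
  set
}

assert_stimulus_set <- function(set) {
  needed <- c("condition", "scene_id", "scene_type", "vertical", "horizontal")
  if (!is.data.frame(set) || !all(needed %in% names(set)) || nrow(set) < 1) {
    stop("`set` must be a stimulus set built by build_stimulus_set()",
         call. = FALSE)
  }
  invisible(set)
}

#' Construct a model (predictor) RDM object
#'
#' Low-level constructor wrapping a square symmetric dissimilarity matrix.
#' The diagonal is stored as `NA` — it is undefined, never zero.
#'
#' @param values Square numeric matrix of dissimilarities.
#' @param kind Character tag, e.g. `"vertical"`, `"category"`,
#'   `"crossval_corr_diff"`, `"decoding_accuracy"`, `"custom"`.
#' @param labels Optional condition labels for dimnames.
#' @return A numeric matrix with class `rdm` and attribute `kind`.
#' @export
rdm <- function(values, kind = "custom", labels = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("an RDM must be square", call. = FALSE)
  }
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-8) {
    stop("an RDM must be symmetric", call. = FALSE)
  }
  diag(values) <- NA_real_
  if (!is.null(labels)) dimnames(values) <- list(labels, labels)
  structure(values, kind = kind, class = c("rdm", class(values)))
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm> kind=%s, %d x %d conditions\n", attr(x, "kind"),
              nrow(x), ncol(x)))
  off <- x[lower.tri(x)]
  cat(sprintf("  off-diagonal range: [%.4g, %.4g]\n",
              min(off, na.rm = TRUE), max(off, na.rm = TRUE)))
  invisible(x)
}

#' Kind tag of an RDM
#' @param x An `rdm` object.
#' @return Character scalar.
#' @export
rdm_kind <- function(x) attr(x, "kind")

#' Binary same/different location predictor RDM
#'
#' Entry (i, j) is 0 if conditions i and j share the level on the chosen
#' axis (same vertical or same horizontal fragment position) and 1
#' otherwise. Diagonal is undefined (`NA`).
#'
#' @param set A stimulus set from [build_stimulus_set()].
#' @param axis `"vertical"` or `"horizontal"`.
#' @return An [rdm()] of the matching kind.
#' @export
#' @examples
#' v <- build_location_rdm(build_stimulus_set(), "vertical")
#' sum(v[lower.tri(v)] == 0) # 198 same-vertical pairs
build_location_rdm <- function(set, axis = c("vertical", "horizontal")) {
  assert_stimulus_set(set)
  axis <- match.arg(axis)
  lev <- set[[axis]]
  rdm(outer(lev, lev, `!=`) * 1, kind = axis, labels = set$label)
}

#' Binary same/different scene (category) predictor RDM
#'
#' Entry (i, j) is 0 if both fragments stem from the same scene image and
#' 1 otherwise.
#'
#' @inheritParams build_location_rdm
#' @return An [rdm()] with kind `"category"`.
#' @export
build_category_rdm <- function(set) {
  assert_stimulus_set(set)
  rdm(outer(set$scene_id, set$scene_id, `!=`) * 1, kind = "category",
      labels = set$label)
}

#' Graded (Euclidean) vertical-location predictor RDM
#'
#' Alternative to the binary vertical predictor: entry (i, j) is the
#' absolute difference of the ordinal vertical levels, so top-vs-bottom
#' pairs (distance 2) count as more dissimilar than top-vs-middle
#' (distance 1).
#'
#' @inheritParams build_location_rdm
#' @return An [rdm()] with kind `"vertical_euclidean"`.
#' @export
build_vertical_euclidean_rdm <- function(set) {
  assert_stimulus_set(set)
  rdm(abs(outer(set$vertical, set$vertical, `-`)),
      kind = "vertical_euclidean", labels = set$label)
}

#' Cross-scene-type pair mask
#'
#' Retains only condition pairs spanning the two scene types (one indoor,
#' one outdoor fragment); all within-indoor and within-outdoor comparisons
#' are excluded. Used for the restricted GLM analysis in which location
#' coding must generalize across scene types (and a category predictor
#' cannot be constructed).
#'
#' @inheritParams build_location_rdm
#' @return A logical matrix with class `pair_mask`; `TRUE` marks retained
#'   pairs, the diagonal is always `FALSE`.
#' @export
#' @examples
#' m <- build_cross_type_mask(build_stimulus_set())
#' sum(m[lower.tri(m)]) # 324 = 18 indoor x 18 outdoor fragments
build_cross_type_mask <- function(set) {
  assert_stimulus_set(set)
  keep <- outer(set$scene_type, set$scene_type, `!=`)
  diag(keep) <- FALSE
  if (!any(keep)) {
    warning("stimulus set contains a single scene type: mask is empty",
            call. = FALSE)
  }
  structure(keep, class = c("pair_mask", class(keep)))
}

#' The 17 posterior/occipital channel names
#'
#' Standard 10-10-system names of the occipital and posterior sensors used
#' for time-resolved decoding.
#'
#' @return Character vector of length 17.
#' @export
posterior_channels <- function() {
  c("O1", "O2", "Oz", "PO3", "PO4", "PO7", "PO8", "POz",
    "P1", "P2", "P3", "P4", "P5", "P6", "P7", "P8", "Pz")
}

#' Heatmap of an RDM
#'
#' @param object An [rdm()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rdm <- function(object, ...) {
  df <- tibble::as_tibble(as.table(unclass(object)), .name_repair = "minimal")
  names(df) <- c("row", "col", "dissimilarity")
  df$row <- as.integer(factor(df$row, levels = unique(df$row)))
  df$col <- as.integer(factor(df$col, levels = unique(df$col)))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$dissimilarity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "condition", y = "condition",
                  title = sprintf("RDM (%s)", attr(object, "kind")),
                  fill = "dissimilarity") +
    ggplot2::theme_minimal()
}
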