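#' Correlation-distance RDM from layer activations
#'
#' Entry (i, j) is 1 minus the Pearson correlation between the two
#' conditions' activation vectors across all units of the layer, so
#' values lie in `[0, 2]`. Zero-variance activation vectors yield r = 0
#' (dissimilarity 1) with a warning, matching the degenerate-correlation
#' rule used throughout the package.
#'
#' @param activations Numeric matrix, condition x unit (>= 2 units).
#' @param labels Optional condition labels.
#' @return An [rdm()] with kind `"custom"`.
#' @export
layer_rdm <- function(activations, labels = NULL) {
  activations <- as.matrix(activations)
  if (ncol(activations) < 2) {
    stop("layer_rdm needs >= 2 units", call. = FALSE)
  }
  if (any(!is.finite(activations))) {
    stop("activations must be finite", call. = FALSE)
  }
  rdm(1 - safe_row_cor(activations, activations), kind = "custom",
      labels = labels)
}

#' RDMs for every layer of a feature bank
#'
#' @param bank A `feature_bank` (see [simulate_features()]), or a plain
#'   named list of condition x unit activation matrices in hierarchy
#'   order.
#' @param labels Optional condition labels.
#' @return Named list of [rdm()]s, one per layer, order preserved.
#' @export
bank_rdms <- function(bank, labels = NULL) {
  layers <- if (inherits(bank, "feature_bank")) bank$layers else bank
  if (length(layers) == 0) stop("empty feature bank", call. = FALSE)
  lapply(layers, layer_rdm, labels = labels)
}

#' Pixel-dissimilarity control RDM
#'
#' Low-level control model: dissimilarity between flattened pixel vectors
#' of the condition images. The default metric is correlation distance
#' (1 - Pearson r), the same metric as [layer_rdm()] applied to raw
#' pixels; Euclidean distance is available as an option.
#'
#' @param images Numeric matrix, condition x pixel (equal-length flattened
#'   images).
#' @param method `"correlation"` (default) or `"euclidean"`.
#' @param labels Optional condition labels.
#' @return An [rdm()] with kind `"custom"`.
#' @export
pixel_rdm <- function(images, method = c("correlation", "euclidean"),
                      labels = NULL) {
  method <- match.arg(method)
  images <- as.matrix(images)
  if (method == "correlation") {
    layer_rdm(images, labels = labels)
  } else {
    rdm(as.matrix(stats::dist(images)), kind = "custom", labels = labels)
  }
}

#' Build a feature bank through an extractor adapter
#'
#' Generic adapter: any callable mapping a stack of images to a named
#' list of per-layer condition x unit activation matrices can stand in
#' for a pretrained network. The package itself ships no trained weights;
#' tests and simulations use [simulate_features()].
#'
#' @param images Condition x pixel matrix (or any object the extractor
#'   understands).
#' @param extractor Function `images -> named list of activation
#'   matrices`.
#' @return A `feature_bank`.
#' @export
extract_feature_bank <- function(images, extractor) {
  layers <- extractor(images)
  if (!is.list(layers) || length(layers) == 0) {
    stop("extractor must return a non-empty list of activation matrices",
         call. = FALSE)
  }
  structure(list(layers = layers, set = NULL, category_gradient = NA,
                 seed = NA), class = "feature_bank")
}
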