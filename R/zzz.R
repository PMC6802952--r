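#' @keywords internal
#' @useDynLib scenersa, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang .data
#' @importFrom MASS isoMDS
"_PACKAGE"

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
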