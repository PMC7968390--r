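#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom stats predict
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# derive k reproducible sub-seeds (< 2^31) from one master seed
derive_seeds <- function(seed, k) {
  withr::with_seed(seed, sample.int(.Machine$integer.max, k))
}
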