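#' @useDynLib neurodyn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx coef residuals
#' @importFrom utils head read.csv tail write.csv
NULL

.onLoad <- function(libname, pkgname) {
  .registry_init()
  .register_builtin_channels()
  .register_builtin_synapses()
  .register_builtin_mechanisms()
}
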