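#' @useDynLib phenopet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats rpois runif sd var dist aggregate t.test dnorm
#' @importFrom utils combn
NULL

# session cache for expensive geometry objects (PET system matrices)
.phenopetCache <- new.env(parent = emptyenv())
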