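#' @useDynLib lessnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif quantile
#' @importFrom grDevices rgb
#' @importFrom utils head modifyList
#' @importFrom graphics matplot legend par axis
NULL
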