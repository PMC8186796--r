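#' @importFrom deSolve lsoda
#' @importFrom tiff readTIFF writeTIFF
#' @importFrom yaml read_yaml write_yaml
#' @importFrom EBImage otsu bwlabel dilate makeBrush
#' @importFrom stats sd median quantile lm coef aov shapiro.test t.test cor
#'   rnorm runif rpois dnorm fft mad aggregate
#' @importFrom graphics hist
#' @importFrom utils modifyList read.csv write.csv
NULL
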