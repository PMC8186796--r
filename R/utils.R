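#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can distinguish validation, geometry,
# tracking, fit, pipeline and I/O failures programmatically.
ss_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "spherosed_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

ss_check <- function(cond, msg, class = "spherosed_validation_error") {
  if (!isTRUE(cond)) ss_stop(msg, class)
  invisible(TRUE)
}

check_finite <- function(x, name) {
  ss_check(is.numeric(x) && all(is.finite(x)),
           sprintf("`%s` must be finite and numeric", name))
}

#' Evaluate an expression with a local, restorable RNG state
#'
#' All generators route their randomness through this helper so that a
#' generator call is a pure function of (scenario, seed) and never disturbs
#' the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  ss_check(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
           "`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Modal value of a (roughly continuous) intensity sample via histogram
# binning; robust against bit-depth differences because the binning is
# relative to the observed range.
modal_value <- function(x, bins = 256L) {
  x <- x[is.finite(x)]
  ss_check(length(x) > 0, "no finite values for mode estimation")
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  h <- graphics::hist(x, breaks = seq(r[1], r[2], length.out = bins + 1L),
                      plot = FALSE)
  h$mids[which.max(h$counts)]
}

# Otsu threshold on raw values (any range); used for 3D stacks where the
# 2D image-oriented EBImage::otsu does not apply directly.
otsu_threshold <- function(x, levels = 256L) {
  x <- x[is.finite(x)]
  ss_check(length(x) > 1, "need at least two values for Otsu thresholding")
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  brk <- seq(r[1], r[2], length.out = levels + 1L)
  cnt <- graphics::hist(x, breaks = brk, plot = FALSE)$counts
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  w <- cnt / sum(cnt)
  mu <- cumsum(w * mids)
  omega <- cumsum(w)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

# Quantize intensities to the 16-bit grid in [0, 1]; what the TIFF writer
# stores, so generator output survives a write/read round trip bit-exactly.
quantize16 <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  round(x * 65535) / 65535
}
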