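#' @keywords internal
"_PACKAGE"

# Convolution of two mass-isotopomer vectors (index 0..n).
mid_convolve <- function(x, y) {
  z <- numeric(length(x) + length(y) - 1L)
  for (i in seq_along(x)) {
    idx <- i:(i + length(y) - 1L)
    z[idx] <- z[idx] + x[i] * y
  }
  z
}

# Validate a MID vector: non-negative (to tol) and unit sum.
check_mid <- function(x, tol = 1e-9, what = "MID") {
  if (any(!is.finite(x))) stop(what, " contains non-finite values")
  if (any(x < -tol)) stop(what, " has negative fractions")
  if (abs(sum(x) - 1) > tol) stop(what, " does not sum to 1")
  invisible(x)
}

# Clip small negatives and renormalize to unit sum.
mid_clip <- function(x) {
  x <- pmax(x, 0)
  s <- sum(x)
  if (s <= 0) stop("MID is identically zero after clipping")
  x / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @useDynLib sliceMFA, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL
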