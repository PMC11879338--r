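#' @import methods
NULL

#' Wrap angles into (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped into the half-open interval (-pi, pi].
#' @keywords internal
wrapAngle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi  # map -pi to +pi so the interval is half-open at -pi
  y
}

# Smallest absolute angular difference between two angles (rad).
angDiff <- function(a, b) {
  d <- abs(wrapAngle(a - b))
  d
}

# Travel time in ms for a path of `len` mm at `cv` m/s.
# 1 mm / (1 m/s) = 1 ms, so the numeric conversion is the identity.
travelTimeMs <- function(lenMm, cvMps) {
  lenMm / cvMps
}

# Stable hash of an R object via serialization + md5 (provenance records).
configHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopIfNot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
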