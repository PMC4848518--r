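#' Calibrated molecular clock of domain structures
#'
#' A linear map from relative evolutionary age `nd` (node distance on a
#' 0-to-1 scale, 0 = oldest) to geological age in billions of years (Gy).
#' The default calibration, `t = -3.831 nd + 3.628`, anchors the origin of
#' the domain timeline at 3.628 Gy ago and is monotone decreasing in `nd`.
#'
#' @param slope Gy change per unit `nd`; must be negative.
#' @param intercept Gy at `nd = 0`.
#' @return An object of class `ef_clock`.
#' @examples
#' apply_clock(0, ef_clock())    # 3.628 Gy: origin of the timeline
#' apply_clock(0.5, ef_clock())
#' @export
ef_clock <- function(slope = -3.831, intercept = 3.628) {
  stopifnot(is.numeric(slope), is.numeric(intercept), length(slope) == 1,
            length(intercept) == 1)
  if (slope >= 0) abort("A molecular clock must be decreasing in nd (slope < 0).")
  structure(list(slope = slope, intercept = intercept), class = "ef_clock")
}

#' @export
print.ef_clock <- function(x, ...) {
  cat(sprintf("<ef_clock> t(Gy) = %g * nd + %g\n", x$slope, x$intercept))
  invisible(x)
}

#' Convert relative ages to geological ages
#'
#' @param nd Numeric vector of relative ages in `[0, 1]`.
#' @param clock An [ef_clock()].
#' @return Geological ages in Gy, same length as `nd`.
#' @export
apply_clock <- function(nd, clock = ef_clock()) {
  stopifnot(inherits(clock, "ef_clock"))
  if (any(nd < 0 | nd > 1, na.rm = TRUE)) {
    abort("Relative ages must lie in [0, 1].")
  }
  clock$slope * nd + clock$intercept
}
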