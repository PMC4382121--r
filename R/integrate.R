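# Trapezoidal integral of (time, intensity) between arbitrary bounds a < b.
# Intensity at the bounds is obtained by linear interpolation, so the
# integral is exactly additive over adjacent intervals: splitting [a, c]
# at any b reproduces the total to machine precision. That exactness is
# what makes perpendicular-drop areas partition the trace.
trapz_interval <- function(time, intensity, a, b) {
  n <- length(time)
  if (b <= a) return(0)
  a <- max(a, time[1L])
  b <- min(b, time[n])
  if (b <= a) return(0)
  ya <- stats::approx(time, intensity, xout = a, rule = 2L)$y
  yb <- stats::approx(time, intensity, xout = b, rule = 2L)$y
  inside <- which(time > a & time < b)
  xs <- c(a, time[inside], b)
  ys <- c(ya, intensity[inside], yb)
  sum((xs[-1L] - xs[-length(xs)]) * (ys[-1L] + ys[-length(ys)])) / 2
}
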