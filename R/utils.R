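# Internal numeric helpers shared across modules.

# Centred running mean with shrinking windows at the edges, O(n) via cumsum.
# k is the full window width in samples; the half-window is floor(k/2) so the
# effective width is always odd and the filter is symmetric (static + dynamic
# decompositions stay exact everywhere, including the first/last samples).
runmean_centred <- function(x, k) {
  n <- length(x)
  if (n == 0L) return(x)
  h <- max(0L, floor(k / 2))
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Wrap an angle in radians into [0, 2*pi).
wrap_2pi <- function(theta) {
  out <- theta %% (2 * pi)
  out[out < 0] <- out[out < 0] + 2 * pi
  out
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Great-circle distance in metres between lon/lat pairs (WGS84 sphere).
gc_dist <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2))
}

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

# Strictly increasing timestamp check naming the first offending row.
check_monotonic <- function(t, what) {
  bad <- which(diff(t) <= 0)
  stop_if(length(bad) > 0,
          sprintf("%s: timestamps not strictly increasing at row %d (t = %.3f)",
                  what, bad[1] + 1L, t[bad[1] + 1L]))
  invisible(TRUE)
}
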