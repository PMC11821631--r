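#' Zero-phase low-pass Butterworth filtering
#'
#' Designs a low-pass Butterworth filter with [signal::butter()] and applies
#' it forward and backward (zero-phase), so peak timing is preserved and the
#' effective magnitude response is the square of the single-pass response.
#' Edge transients are controlled the way scientific signal-processing
#' libraries do it: the trace is extended at both ends by odd reflection and
#' the filter state is initialised to its steady-state response, which makes
#' constant traces pass through exactly (DC gain 1).
#'
#' @param x Numeric trace.
#' @param sample_rate Sampling rate in Hz.
#' @param cutoff Cut-off frequency in Hz; must be below the Nyquist
#'   frequency `sample_rate / 2`.
#' @param order Filter order of the underlying one-pass design.
#'
#' @return Filtered numeric trace, same length as `x`.
#' @examples
#' t <- seq(0, 1, by = 1 / 1000)
#' x <- sin(2 * pi * 5 * t) + sin(2 * pi * 80 * t)
#' y <- filter_twitch(x, 1000, cutoff = 15)
#' @export
filter_twitch <- function(x, sample_rate, cutoff = 15, order = 4) {
  if (cutoff >= sample_rate / 2) {
    abort("`cutoff` must be below the Nyquist frequency.",
          class = "tmg_invalid_config")
  }
  bf <- signal::butter(order, cutoff / (sample_rate / 2), type = "low")
  filtfilt_zp(bf$b, bf$a, x)
}

# Steady-state initial filter state for a unit-step input (direct form II
# transposed), so that filtering a constant yields that constant exactly.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a))) / a[1]
  b <- c(b, rep(0, n - length(b)))
  # companion matrix of the denominator polynomial, transposed
  A <- matrix(0, n - 1, n - 1)
  A[1, ] <- -a[2:n]
  if (n > 2) A[cbind(2:(n - 1), 1:(n - 2))] <- 1
  B <- b[2:n] - a[2:n] * b[1]
  solve(diag(n - 1) - t(A), B)
}

# One-pass IIR filter, direct form II transposed, with initial state zi.
lfilter <- function(b, a, x, zi) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  z <- zi
  y <- numeric(length(x))
  nb <- n - 1
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (nb > 1) {
      z[1:(nb - 1)] <- b[2:nb] * xi + z[2:nb] - a[2:nb] * yi
    }
    z[nb] <- b[n] * xi - a[n] * yi
    y[i] <- yi
  }
  y
}

# Forward-backward filtering with odd-reflection padding and steady-state
# initial conditions at each pass.
filtfilt_zp <- function(b, a, x) {
  n <- max(length(a), length(b))
  padlen <- min(3L * n, length(x) - 1L)
  if (padlen < 1) abort("Trace too short to filter.",
                        class = "tmg_invalid_config")
  front <- 2 * x[1] - x[(padlen + 1):2]
  back <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - padlen)]
  ext <- c(front, x, back)
  zi <- lfilter_zi(b, a)
  y <- lfilter(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- lfilter(b, a, y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1):(padlen + length(x))]
}

#' Single-pass Butterworth magnitude response
#'
#' Closed-form magnitude of an analogue n-th order Butterworth low-pass at
#' frequency `f`: \eqn{1 / \sqrt{1 + (f/f_c)^{2n}}}. Useful as an analytic
#' bound when testing filtered signals (the zero-phase filter squares it).
#'
#' @param f Frequency in Hz.
#' @param cutoff Cut-off frequency in Hz.
#' @param order Filter order.
#' @return Magnitude gain in `[0, 1]`.
#' @export
butterworth_gain <- function(f, cutoff = 15, order = 4) {
  1 / sqrt(1 + (f / cutoff)^(2 * order))
}
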