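# Butterworth bandpass design and zero-phase (forward-backward) filtering.
# Implemented from the analog prototype via the lowpass->bandpass transform
# and the bilinear transform; no dedicated DSP package is available in the
# target stack. The recursion itself runs in C through stats::filter.

poly_from_roots <- function(roots) {
  coefs <- 1 + 0i
  for (r in roots) coefs <- c(coefs, 0) - c(0, coefs * r)
  coefs
}

#' Design a digital Butterworth bandpass filter
#'
#' Returns transfer-function coefficients of an order-`order` analog
#' Butterworth lowpass prototype transformed to a bandpass (so the digital
#' filter has `2 * order` poles), discretized with the bilinear transform and
#' frequency pre-warping.
#'
#' @param fs sampling rate in Hz.
#' @param low_hz,high_hz passband edges, `0 < low_hz < high_hz < fs/2`.
#' @param order prototype order (default 2, i.e. a 4-pole bandpass).
#' @return list with numerator `b` and denominator `a` (both length
#'   `2 * order + 1`, `a[1] == 1`).
#' @export
butter_bandpass_design <- function(fs, low_hz, high_hz, order = 2L) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2)) {
    stop("band edges must satisfy 0 < low_hz < high_hz < fs/2")
  }
  order <- as.integer(order)
  stopifnot(order >= 1L)
  fs2 <- 2 * fs
  # pre-warped analog edge frequencies (rad/s)
  w1 <- fs2 * tan(pi * low_hz / fs)
  w2 <- fs2 * tan(pi * high_hz / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # prototype lowpass poles on the unit circle, left half-plane
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # lowpass -> bandpass: each pole p maps to the two roots of
  # s^2 - p*bw*s + w0^2 = 0
  pb <- p_bp_roots(proto, bw, w0)
  za <- rep(0 + 0i, order)             # bandpass zeros at s = 0
  ka <- bw^order
  # bilinear transform
  zd <- (fs2 + za) / (fs2 - za)
  pd <- (fs2 + pb) / (fs2 - pb)
  zd <- c(zd, rep(-1 + 0i, length(pb) - length(za)))  # zeros from infinity
  kd <- ka * Re(prod(fs2 - za) / prod(fs2 - pb))
  b <- Re(poly_from_roots(zd)) * kd
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

p_bp_roots <- function(proto, bw, w0) {
  half <- proto * bw / 2
  disc <- sqrt(half^2 - w0^2 + 0i)
  c(half + disc, half - disc)
}

#' Magnitude response of a digital filter
#'
#' Evaluates `|B(e^{-i w}) / A(e^{-i w})|` at the requested frequencies.
#'
#' @param design list with `b` and `a` as from [butter_bandpass_design()].
#' @param freq_hz frequencies of interest (Hz).
#' @param fs sampling rate in Hz.
#' @return numeric vector of gains.
#' @export
filter_gain <- function(design, freq_hz, fs) {
  vapply(freq_hz, function(f) {
    w <- 2 * pi * f / fs
    z <- exp(-1i * w * (seq_along(design$b) - 1L))
    num <- sum(design$b * z)
    z <- exp(-1i * w * (seq_along(design$a) - 1L))
    Mod(num / sum(design$a * z))
  }, numeric(1))
}

# single-pass IIR filtering, zero initial conditions
iir_filter <- function(b, a, x) {
  v <- stats::filter(c(rep(0, length(b) - 1L), x), b, method = "convolution",
                     sides = 1L)
  v <- as.numeric(v[-seq_len(length(b) - 1L)])
  if (length(a) > 1L) {
    v <- as.numeric(stats::filter(v, -a[-1L], method = "recursive"))
  }
  v
}

# steady-state direct-form-II-transposed state for a unit step input
# (solves z = A z + B with A the transposed companion matrix of a)
lfilter_zi <- function(b, a) {
  n <- length(a)
  if (n == 1L) return(numeric(0))
  comp_t <- matrix(0, n - 1L, n - 1L)
  comp_t[, 1L] <- -a[-1L] / a[1L]
  if (n > 2L) comp_t[cbind(1:(n - 2L), 2:(n - 1L))] <- 1
  B <- b[-1L] - a[-1L] * b[1L]
  solve(diag(n - 1L) - comp_t, B)
}

# filtering with initial state zi (df2t): zero-IC response plus the
# zero-input response of the state, which is an AR recursion seeded by zi
iir_filter_ic <- function(b, a, x, zi) {
  y <- iir_filter(b, a, x)
  if (length(zi)) {
    e <- numeric(length(x))
    e[seq_along(zi)] <- zi
    y <- y + as.numeric(stats::filter(e, -a[-1L], method = "recursive"))
  }
  y
}

filtfilt_vec <- function(b, a, x) {
  n <- length(x)
  pad <- 3L * (max(length(b), length(a)) - 1L)
  if (n <= pad) stop("signal too short for zero-phase filtering (need > ",
                     pad, " samples)")
  zi <- lfilter_zi(b, a)
  # odd extension at both ends to suppress startup transients
  xp <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- iir_filter_ic(b, a, xp, zi * xp[1L])
  y <- rev(iir_filter_ic(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1L):(pad + n)]
}

#' Zero-phase Butterworth bandpass filtering
#'
#' Applies a Butterworth bandpass of the given order forward and backward
#' (zero phase distortion, squared magnitude response) to each channel
#' independently. Output has the shape of the input.
#'
#' @param signal numeric matrix (`n_samples x n_channels`) or vector.
#' @param fs sampling rate in Hz.
#' @param low_hz,high_hz passband edges, `0 < low_hz < high_hz < fs/2`.
#' @param order filter order (default 2).
#' @return filtered matrix (or vector) of the same shape.
#' @export
butterworth_bandpass <- function(signal, fs, low_hz = 0.5, high_hz = 40,
                                 order = 2L) {
  design <- butter_bandpass_design(fs, low_hz, high_hz, order)
  if (is.matrix(signal)) {
    out <- apply(signal, 2L, function(col) filtfilt_vec(design$b, design$a, col))
    dimnames(out) <- dimnames(signal)
    out
  } else {
    filtfilt_vec(design$b, design$a, as.numeric(signal))
  }
}
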