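# Threshold spiking encoder: binary spike matrices per EEG segment,
# per-channel spike statistics (count and mean run duration), the
# seizure-indicator rule, logical-AND fine tuning, and the fast-sigmoid
# surrogate gradient used to train the threshold offset.

#' Per-channel up/down encoding thresholds
#'
#' For each channel `q` of a segment, `up = mu_q + kappa * sigma_q` and
#' `down = mu_q - kappa * sigma_q` (population standard deviation over the
#' segment; `sigma = 0` is allowed). The encoding comparison point is their
#' mean, i.e. the channel mean `mu_q`, optionally shifted by a trainable
#' offset expressed in units of `sigma_q`.
#'
#' @param segment numeric matrix (`timesteps x channels`).
#' @param kappa threshold width multiplier (default 1).
#' @return list with numeric vectors `up`, `down`, `mean_point`, `mu`,
#'   `sigma`.
#' @export
compute_thresholds <- function(segment, kappa = 1.0) {
  segment <- as.matrix(segment)
  if (nrow(segment) < 1L) stop("segment is empty")
  mu <- colMeans(segment)
  sigma <- sqrt(colMeans(segment^2) - mu^2)
  sigma[sigma < 0] <- 0
  up <- mu + kappa * sigma
  down <- mu - kappa * sigma
  list(up = up, down = down, mean_point = (up + down) / 2, mu = mu,
       sigma = sigma)
}

#' Encode a segment as a binary spike matrix
#'
#' Literal threshold rule (`mode = "mean"`): a sample spikes (1) iff its
#' value is greater than or equal to the channel's mean point (values exactly
#' at the mean point take the "otherwise" branch and spike). The alternative
#' `mode = "crossing"` spikes iff the sample leaves the `[down, up]` band,
#' which makes the `kappa`-wide thresholds themselves active.
#'
#' A trainable `offset` (in units of the channel standard deviation) shifts
#' the comparison point; encoding is invariant to positive affine rescaling
#' of a channel in both modes.
#'
#' @param segment numeric matrix (`timesteps x channels`).
#' @param thresholds from [compute_thresholds()] on the same segment.
#' @param mode `"mean"` (default) or `"crossing"`.
#' @param offset threshold offset in sigma units (default 0).
#' @return binary integer matrix of the segment's shape.
#' @export
encode_spikes <- function(segment, thresholds = compute_thresholds(segment),
                          mode = c("mean", "crossing"), offset = 0.0) {
  mode <- match.arg(mode)
  segment <- as.matrix(segment)
  if (mode == "mean") {
    thr <- thresholds$mean_point + offset * thresholds$sigma
    E <- (segment >= rep(thr, each = nrow(segment))) * 1L
  } else {
    up <- thresholds$up + offset * thresholds$sigma
    down <- thresholds$down - offset * thresholds$sigma
    E <- ((segment >= rep(up, each = nrow(segment))) |
            (segment <= rep(down, each = nrow(segment)))) * 1L
  }
  dimnames(E) <- dimnames(segment)
  E
}

#' Per-channel spike statistics
#'
#' `spike_count` is the number of 1s per channel; `spike_duration` is the
#' mean run length of consecutive 1s (in samples; 0 when a channel never
#' spikes); `n_runs` the number of spike runs.
#'
#' @param encoded binary matrix (`timesteps x channels`).
#' @return list of numeric vectors `spike_count`, `spike_duration`, `n_runs`.
#' @export
spike_stats <- function(encoded) {
  encoded <- as.matrix(encoded)
  n <- nrow(encoded)
  count <- colSums(encoded)
  # a run starts where a 1 is not preceded by a 1 (vectorized over channels)
  prev <- rbind(0L, encoded[-n, , drop = FALSE])
  runs <- colSums(encoded == 1L & prev != 1L)
  duration <- ifelse(runs > 0, count / runs, 0)
  list(spike_count = count, spike_duration = duration, n_runs = runs)
}

#' Seizure indicator per channel and segment probability
#'
#' A channel is flagged High (1) iff it spikes more often than the
#' cross-channel average AND its spikes are shorter than the average spike
#' duration (both strict): many short spikes indicate likely seizure onset.
#' The segment-level probability is the fraction of High channels.
#'
#' @param stats from [spike_stats()] (or a list with `spike_count` and
#'   `spike_duration`).
#' @return list with integer vector `indicator` (1 = High, 0 = Low) and
#'   scalar `probability`.
#' @export
seizure_indicator <- function(stats) {
  count <- stats$spike_count
  duration <- stats$spike_duration
  m <- length(count)
  stopifnot(m >= 1L, length(duration) == m)
  high <- (mean(count) < count) & (mean(duration) > duration)
  list(indicator = as.integer(high), probability = mean(high))
}

#' Fine-tune a spike matrix with the seizure indicator
#'
#' Elementwise logical AND between the encoded spikes and the per-channel
#' indicator: channels flagged Low are silenced.
#'
#' @param encoded binary matrix (`timesteps x channels`).
#' @param indicator binary vector, one entry per channel.
#' @return binary integer matrix.
#' @export
fine_tune <- function(encoded, indicator) {
  encoded <- as.matrix(encoded)
  if (!all(encoded %in% c(0L, 1L))) stop("encoded matrix must be binary")
  if (!all(indicator %in% c(0L, 1L))) stop("indicator must be binary")
  if (length(indicator) != ncol(encoded)) {
    stop("indicator length must equal the channel count")
  }
  encoded * rep(as.integer(indicator), each = nrow(encoded))
}

#' Fast-sigmoid surrogate gradient for the spike threshold
#'
#' The spike non-linearity is a step function with zero gradient almost
#' everywhere; backpropagation through the encoder's trainable threshold
#' offset uses the derivative of the fast sigmoid instead:
#' `g(x) = beta / (1 + beta * |x|)^2`, peaked at the threshold.
#'
#' @param x distance from the threshold.
#' @param beta_slope surrogate sharpness (default 10).
#' @return numeric, same shape as `x`.
#' @export
surrogate_spike_gradient <- function(x, beta_slope = 10) {
  beta_slope / (1 + beta_slope * abs(x))^2
}

#' Full spike representation of a segment
#'
#' Runs the encoder, spike statistics, seizure indicator and fine tuning for
#' one segment, and (optionally) the surrogate-gradient sums needed to train
#' the threshold offset.
#'
#' @param segment numeric matrix (`timesteps x channels`).
#' @param kappa threshold width multiplier.
#' @param mode encoding mode, see [encode_spikes()].
#' @param offset threshold offset in sigma units.
#' @param beta_slope surrogate sharpness; set `NA` to skip gradient
#'   bookkeeping.
#' @return object of class `spike_representation`: `encoded`, `spike_count`,
#'   `spike_duration`, `n_runs`, `indicator`, `probability`, `fine_tuned`,
#'   and `dcount_doffset` (per-channel derivative of the spike count with
#'   respect to the offset, via the surrogate).
#' @export
spike_representation <- function(segment, kappa = 1.0, mode = "mean",
                                 offset = 0.0, beta_slope = 10) {
  segment <- as.matrix(segment)
  thr <- compute_thresholds(segment, kappa)
  E <- encode_spikes(segment, thr, mode = mode, offset = offset)
  st <- spike_stats(E)
  ind <- seizure_indicator(st)
  ft <- fine_tune(E, ind$indicator)
  dcount <- NULL
  if (!is.na(beta_slope)) {
    # raising the offset moves the comparison point(s) away from the data:
    # samples near a threshold stop spiking, with the step replaced by the
    # fast-sigmoid surrogate
    if (mode == "mean") {
      cmp <- thr$mean_point + offset * thr$sigma
      dist <- segment - rep(cmp, each = nrow(segment))
      dcount <- -colSums(surrogate_spike_gradient(dist, beta_slope)) *
        thr$sigma
    } else {
      up <- thr$up + offset * thr$sigma
      down <- thr$down - offset * thr$sigma
      d_up <- segment - rep(up, each = nrow(segment))
      d_dn <- rep(down, each = nrow(segment)) - segment
      dcount <- -(colSums(surrogate_spike_gradient(d_up, beta_slope)) +
                    colSums(surrogate_spike_gradient(d_dn, beta_slope))) *
        thr$sigma
    }
  }
  structure(
    list(encoded = E, spike_count = st$spike_count,
         spike_duration = st$spike_duration, n_runs = st$n_runs,
         indicator = ind$indicator, probability = ind$probability,
         fine_tuned = ft, dcount_doffset = dcount,
         timesteps = nrow(segment)),
    class = "spike_representation"
  )
}
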