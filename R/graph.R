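# Channel graph construction and the renormalized graph operator
# D^{-1/2} (A + I) D^{-1/2} used by the graph-convolutional layers.

#' Symmetric renormalization of an adjacency matrix
#'
#' Adds self-loops and applies the symmetric degree normalization
#' `Ahat = Dtilde^{-1/2} (A + I) Dtilde^{-1/2}` with
#' `Dtilde = diag(rowSums(A + I))`. All eigenvalues of `Ahat` lie in
#' \[-1, 1\], which keeps layer-wise propagation numerically stable.
#'
#' @param A square nonnegative symmetric adjacency matrix (zero diagonal).
#' @return the renormalized operator (symmetric).
#' @export
renormalize_adjacency <- function(A) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == ncol(A))
  if (max(abs(A - t(A))) > 1e-12) stop("adjacency must be symmetric")
  At <- A + diag(nrow(A))
  d <- rowSums(At)
  s <- 1 / sqrt(d)
  At * outer(s, s)
}

#' Build the channel correlation graph
#'
#' Edges connect channel pairs whose absolute Pearson correlation over the
#' training signal reaches `corr_threshold`; the edge weight is that
#' absolute correlation. Constant channels have all their correlations
#' defined as 0. The stored operator is the symmetric renormalization of the
#' thresholded adjacency.
#'
#' @param signal numeric matrix (`n_samples x n_channels`), at least 2
#'   samples and 2 channels, or an [eeg_recording()].
#' @param corr_threshold minimum absolute correlation for an edge
#'   (default 0.3).
#' @return object of class `channel_graph`: `n_nodes`, `adjacency`,
#'   `operator`.
#' @export
build_graph <- function(signal, corr_threshold = 0.3) {
  if (inherits(signal, "eeg_recording")) signal <- signal$signal
  signal <- as.matrix(signal)
  if (ncol(signal) < 2L || nrow(signal) < 2L) {
    stop("need at least 2 channels and 2 time samples")
  }
  sds <- apply(signal, 2L, stats::sd)
  C <- suppressWarnings(stats::cor(signal))
  C[is.na(C)] <- 0
  C[, sds == 0] <- 0
  C[sds == 0, ] <- 0
  A <- abs(C)
  A[A < corr_threshold] <- 0
  diag(A) <- 0
  structure(list(n_nodes = ncol(signal), adjacency = A,
                 operator = renormalize_adjacency(A)),
            class = "channel_graph")
}

#' @export
print.channel_graph <- function(x, ...) {
  cat(sprintf("<channel_graph> %d nodes, %d edges\n", x$n_nodes,
              sum(x$adjacency[upper.tri(x$adjacency)] > 0)))
  invisible(x)
}
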