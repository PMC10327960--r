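#' Continuous multichannel EEG container
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param srate sampling rate in Hz.
#' @param channels channel labels (default from rownames or \code{ch01}...).
#' @param bad_intervals list of \code{c(from, to)} sample ranges flagged bad;
#'   these are excluded from modeling by [zero_out_intervals()] on the
#'   design, never by cutting the recording.
#' @return object of class \code{continuous_eeg}.
#' @export
continuous_eeg <- function(data, srate, channels = NULL,
                           bad_intervals = list()) {
  stopifnot(is.matrix(data), srate > 0)
  if (any(!is.finite(data))) stop("EEG must be finite")
  if (is.null(channels))
    channels <- rownames(data) %||% sprintf("ch%02d", seq_len(nrow(data)))
  rownames(data) <- channels
  structure(list(data = data, srate = srate, channels = channels,
                 n_samples = ncol(data), bad_intervals = bad_intervals),
            class = "continuous_eeg")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Solver options for the deconvolution fit
#'
#' @param tolerance relative residual tolerance of the LSMR iterations.
#' @param max_iterations iteration cap (default \code{10 * ncol(design)}).
#' @export
solver_options <- function(tolerance = 1e-10, max_iterations = NULL) {
  stopifnot(tolerance > 0)
  list(tolerance = tolerance, max_iterations = max_iterations)
}

#' Fit the deconvolution model per channel
#'
#' Estimates, channel by channel, the coefficients of the time-expanded
#' design against the continuous EEG by iterative sparse least squares
#' ([lsmr()]). Channels are independent: fitting them jointly or one at a
#' time gives identical coefficients. Rank-deficient designs (e.g. an empty
#' category) yield the minimum-norm solution, flagged in the diagnostics.
#' Samples whose design rows were zeroed have no influence on the estimates.
#'
#' @param eeg a \code{continuous_eeg} with as many samples as design rows.
#' @param design an \code{frp_expanded_design} (bad intervals already zeroed).
#' @param opts see [solver_options()].
#' @param channels optional subset of channel labels to fit.
#' @return object of class \code{frp_betas}: coefficient matrix
#'   \code{channels x (P * L)}, the design metadata, and per-channel solver
#'   \code{diagnostics} (iterations, stop flag, residual norms,
#'   \code{converged}).
#' @export
fit_deconvolution <- function(eeg, design, opts = solver_options(),
                              channels = NULL) {
  stopifnot(inherits(eeg, "continuous_eeg"),
            inherits(design, "frp_expanded_design"))
  if (eeg$n_samples != nrow(design$X))
    stop("design rows (", nrow(design$X), ") must equal EEG samples (",
         eeg$n_samples, ")")
  channels <- channels %||% eeg$channels
  bad <- setdiff(channels, eeg$channels)
  if (length(bad)) stop("unknown channels: ", paste(bad, collapse = ", "))

  maxit <- opts$max_iterations %||% (10L * ncol(design$X))
  B <- matrix(0, length(channels), ncol(design$X),
              dimnames = list(channels, NULL))
  diag_rows <- vector("list", length(channels))
  for (k in seq_along(channels)) {
    fit <- lsmr(design$X, eeg$data[channels[k], ],
                atol = opts$tolerance, btol = opts$tolerance,
                maxiter = maxit)
    B[k, ] <- fit$x
    diag_rows[[k]] <- data.frame(channel = channels[k], itn = fit$itn,
                                 istop = fit$istop, normr = fit$normr,
                                 normar = fit$normar,
                                 converged = fit$istop < 7L)
  }
  diagnostics <- do.call(rbind, diag_rows)
  if (any(!diagnostics$converged))
    warning("LSMR hit the iteration cap for channel(s): ",
            paste(diagnostics$channel[!diagnostics$converged], collapse = ", "))
  structure(list(coefficients = B, design = design, channels = channels,
                 diagnostics = diagnostics),
            class = "frp_betas")
}

#' Predict the continuous model signal from fitted coefficients
#'
#' @param design an \code{frp_expanded_design} (shapes must match the betas).
#' @param betas an \code{frp_betas}.
#' @return matrix channels x samples of the model prediction; the residual is
#'   \code{eeg$data - predict_eeg(design, betas)}.
#' @export
predict_eeg <- function(design, betas) {
  stopifnot(inherits(design, "frp_expanded_design"),
            inherits(betas, "frp_betas"))
  if (ncol(betas$coefficients) != ncol(design$X))
    stop("design / beta shape mismatch")
  t(as.matrix(design$X %*% t(betas$coefficients)))
}

#' @export
print.frp_betas <- function(x, ...) {
  cat("Deconvolution coefficients:", nrow(x$coefficients), "channel(s) x",
      x$design$mass$P, "predictors x", x$design$L, "lags\n")
  cat("LSMR iterations:", paste(x$diagnostics$itn, collapse = ", "), "\n")
  invisible(x)
}
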