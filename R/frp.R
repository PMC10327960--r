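#' Reconstruct marginal per-category FRP waveforms
#'
#' Turns fitted deconvolution coefficients into average-like fixation-related
#' potentials that are comparable across categories: the reference-category
#' waveform is the fixation intercept plus every spline covariate evaluated
#' at a fixed (by default mean) predictor level; each non-reference category
#' adds its treatment-coded dummy coefficients. All categories therefore
#' share the identical covariate contribution, so category differences equal
#' the dummy coefficients exactly and are invariant to the reference level
#' and to which spline column was dropped.
#'
#' @param betas an \code{frp_betas} from [fit_deconvolution()].
#' @param covariate_means named vector of predictor levels at which the
#'   spline effects are evaluated; defaults to the per-participant means over
#'   the fixation events the design was built from. Values outside the spline
#'   boundary are clamped.
#' @param categories categories to reconstruct (default: reference plus all
#'   dummy levels).
#' @return object of class \code{marginal_frp}: named list \code{waves} of
#'   channels x L matrices, lag \code{times} (seconds), \code{channels},
#'   \code{covariate_levels}, \code{baseline} (none yet).
#' @export
reconstruct_marginal_frps <- function(betas, covariate_means = NULL,
                                      categories = NULL) {
  stopifnot(inherits(betas, "frp_betas"))
  design <- betas$design
  mass <- design$mass
  ci <- mass$colinfo
  B <- betas$coefficients
  L <- design$L
  nch <- nrow(B)

  beta_lags <- function(p) {
    # channels x L slice of expanded coefficients for mass predictor p
    B[, expanded_cols(design, p), drop = FALSE]
  }

  covariate_means <- covariate_means %||% mass$means
  missing_cov <- setdiff(names(mass$bases), names(covariate_means))
  if (length(missing_cov))
    stop("missing covariate mean(s): ", paste(missing_cov, collapse = ", "))

  ip <- ci$col[ci$event_type == "fixation" & ci$term == "intercept"]
  if (length(ip) != 1) stop("fixation intercept term required")
  base <- beta_lags(ip)

  for (nm in names(mass$bases)) {
    bs <- eval_spline_basis(mass$bases[[nm]], covariate_means[[nm]],
                            drop = TRUE)
    cols <- ci$col[ci$term == "spline" & ci$name == nm]
    for (j in seq_along(cols))
      base <- base + bs[1, j] * beta_lags(cols[j])
  }

  cat_term <- Filter(function(t) t$kind == "categorical",
                     design$mass$formula$fixation)
  if (length(cat_term)) {
    cat_term <- cat_term[[1]]
    ref <- cat_term$reference
    dummies <- setdiff(cat_term$levels, ref)
  } else {
    ref <- "(all)"
    dummies <- character(0)
  }
  categories <- categories %||% c(ref, dummies)

  waves <- list()
  for (cg in categories) {
    if (cg == ref) {
      waves[[cg]] <- base
    } else {
      if (!cg %in% dummies) stop("unknown category: ", cg)
      dc <- ci$col[ci$term == "categorical" & !is.na(ci$level) &
                     ci$level == cg]
      waves[[cg]] <- base + beta_lags(dc)
    }
  }
  waves <- lapply(waves, function(w) {
    rownames(w) <- betas$channels
    w
  })
  structure(list(waves = waves, times = design$lag_times,
                 channels = betas$channels,
                 covariate_levels = covariate_means, baseline = NULL,
                 factors = NULL),
            class = "marginal_frp")
}

#' Assemble a marginal-FRP object from raw waveforms
#'
#' Mostly used by the simulator (ground-truth waveforms) and by
#' [fixation_locked_average()].
#'
#' @param waves named list of channels x L matrices.
#' @param times lag times in seconds.
#' @export
marginal_frp <- function(waves, times) {
  stopifnot(is.list(waves), length(waves) > 0)
  L <- length(times)
  ok <- vapply(waves, function(w) is.matrix(w) && ncol(w) == L, TRUE)
  if (!all(ok)) stop("every waveform must be a channels x length(times) matrix")
  structure(list(waves = waves, times = times,
                 channels = rownames(waves[[1]]) %||%
                   sprintf("ch%02d", seq_len(nrow(waves[[1]]))),
                 covariate_levels = NULL, baseline = NULL, factors = NULL),
            class = "marginal_frp")
}

#' Baseline-correct marginal FRPs
#'
#' Subtracts, per channel and category, the mean over the baseline window.
#' Windows are half-open in time (\code{t0 <= t < t1}) at the recording's
#' sample grid, so the adopted 0-20 ms baseline covers exactly 5 samples at
#' 250 Hz. Idempotent.
#'
#' @param frp a \code{marginal_frp}.
#' @param window \code{c(t0, t1)} seconds relative to fixation onset.
#' @export
baseline_correct <- function(frp, window = c(0, 0.02)) {
  stopifnot(inherits(frp, "marginal_frp"))
  sel <- window_samples(frp$times, window)
  if (!length(sel)) stop("empty baseline window")
  frp$waves <- lapply(frp$waves, function(w)
    w - rowMeans(w[, sel, drop = FALSE]))
  frp$baseline <- window
  frp
}

window_samples <- function(times, window) {
  if (length(window) != 2 || window[1] >= window[2])
    stop("window must be c(t0, t1) with t0 < t1")
  which(times >= window[1] - 1e-9 & times < window[2] - 1e-9)
}

#' Region-of-interest specification
#'
#' Eight ROIs of seven electrodes each (one central, six surrounding) around
#' the landmark electrodes F3/F4/C3/C4/P3/P4/O1/O2, crossed as region
#' (frontal/central/parietal/occipital) x hemisphere (left/right).
#' [default_roi_spec()] names the surrounding electrodes
#' \code{<center>_1 ... <center>_6}, matching the synthetic 56-channel
#' montage; real montages supply their own channel lists.
#'
#' @param rois named list: ROI name -> character vector of 7 channel labels.
#' @param region,hemisphere factor level per ROI (same order as \code{rois}).
#' @return data.frame with columns \code{roi}, \code{region},
#'   \code{hemisphere}, \code{channel} (one row per member channel).
#' @export
roi_spec <- function(rois, region, hemisphere) {
  stopifnot(length(rois) == length(region),
            length(rois) == length(hemisphere))
  if (any(vapply(rois, length, 1L) != 7L))
    stop("each ROI must contain exactly 7 channels")
  all_ch <- unlist(rois, use.names = FALSE)
  if (anyDuplicated(all_ch)) stop("ROIs must be pairwise disjoint")
  data.frame(roi = rep(names(rois), each = 7L),
             region = rep(region, each = 7L),
             hemisphere = rep(hemisphere, each = 7L),
             channel = all_ch)
}

#' @rdname roi_spec
#' @export
default_roi_spec <- function() {
  centers <- c("F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2")
  region <- rep(c("frontal", "central", "parietal", "occipital"), each = 2)
  hemisphere <- rep(c("left", "right"), times = 4)
  rois <- lapply(centers, function(cc) c(cc, paste0(cc, "_", 1:6)))
  names(rois) <- centers
  roi_spec(rois, region, hemisphere)
}

#' Average waveforms over ROIs
#'
#' Unweighted mean over each ROI's seven channels, with region/hemisphere
#' factor labels attached. Baseline correction commutes with this averaging.
#'
#' @param frp a \code{marginal_frp}.
#' @param rois an ROI specification from [roi_spec()].
#' @return a \code{marginal_frp} whose "channels" are the ROI names.
#' @export
roi_average <- function(frp, rois) {
  stopifnot(inherits(frp, "marginal_frp"))
  missing_ch <- setdiff(rois$channel, frp$channels)
  if (length(missing_ch))
    stop("channel(s) missing from the waveforms: ",
         paste(missing_ch, collapse = ", "))
  roi_names <- unique(rois$roi)
  frp$waves <- lapply(frp$waves, function(w) {
    out <- t(vapply(roi_names, function(rn) {
      colMeans(w[rois$channel[rois$roi == rn], , drop = FALSE])
    }, numeric(ncol(w))))
    rownames(out) <- roi_names
    out
  })
  frp$channels <- roi_names
  frp$factors <- unique(rois[c("roi", "region", "hemisphere")])
  frp
}

#' Named analysis windows
#'
#' The lambda window is the 100 ms window centered on the 80 ms lambda peak;
#' the late window covers the late occipital negativity; the two baseline
#' candidates bracket fixation onset.
#'
#' @export
frp_windows <- function() {
  list(lambda = c(0.030, 0.130), late = c(0.200, 0.400),
       baseline_pre = c(-0.200, -0.100), baseline_post = c(0.000, 0.020))
}

#' Mean amplitude in named time windows
#'
#' Time-mean over the half-open window \code{[t0, t1)} per category and
#' channel (or ROI).
#'
#' @param frp a \code{marginal_frp} (typically after [roi_average()]).
#' @param windows named list of \code{c(t0, t1)} windows (see
#'   [frp_windows()]).
#' @param participant participant label attached to the output rows.
#' @return long data.frame: participant, category, channel (plus region /
#'   hemisphere when ROI factors are attached), window, value (microvolts).
#' @export
window_mean <- function(frp, windows = frp_windows()[c("lambda", "late")],
                        participant = 1L) {
  stopifnot(inherits(frp, "marginal_frp"))
  out <- list()
  for (wname in names(windows)) {
    sel <- window_samples(frp$times, windows[[wname]])
    if (!length(sel))
      stop("window ", wname, " lies outside the lag range")
    for (cg in names(frp$waves)) {
      vals <- rowMeans(frp$waves[[cg]][, sel, drop = FALSE])
      d <- data.frame(participant = participant, category = cg,
                      channel = frp$channels, window = wname,
                      value = unname(vals))
      if (!is.null(frp$factors)) {
        m <- match(d$channel, frp$factors$roi)
        d$region <- frp$factors$region[m]
        d$hemisphere <- frp$factors$hemisphere[m]
      }
      out[[length(out) + 1L]] <- d
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Naive fixation-locked averaging (no overlap correction)
#'
#' Event-locked average of raw EEG segments per category over the lag
#' window: the classical FRP estimate the deconvolution model is compared
#' against. Events whose segment extends beyond the recording are skipped.
#'
#' @param eeg a \code{continuous_eeg}.
#' @param event_samples 1-based sample index of each event.
#' @param categories category label per event.
#' @param window lag window in seconds.
#' @return a \code{marginal_frp} of the per-category averages.
#' @export
fixation_locked_average <- function(eeg, event_samples, categories,
                                    window = c(-0.2, 0.5)) {
  stopifnot(inherits(eeg, "continuous_eeg"),
            length(event_samples) == length(categories))
  lag0 <- round(window[1] * eeg$srate)
  lag1 <- round(window[2] * eeg$srate)
  lags <- lag0:(lag1 - 1L)
  waves <- list()
  for (cg in unique(categories)) {
    ev <- event_samples[categories == cg]
    ev <- ev[ev + lag0 >= 1L & ev + lag1 - 1L <= eeg$n_samples]
    if (!length(ev)) next
    acc <- matrix(0, nrow(eeg$data), length(lags))
    for (s in ev) acc <- acc + eeg$data[, s + lags, drop = FALSE]
    w <- acc / length(ev)
    rownames(w) <- eeg$channels
    waves[[cg]] <- w
  }
  marginal_frp(waves, lags / eeg$srate)
}

#' Fitted spline partial effect of a covariate
#'
#' Evaluates the estimated nonlinear partial effect of one spline covariate
#' on the FRP: the covariate's basis expansion times its fitted
#' coefficients, averaged over a lag window (and over channels). The curve
#' is identified up to an additive constant (one basis column is dropped
#' next to the intercept), so it is compared with generating effect
#' functions by shape (e.g. correlation over the covariate range).
#'
#' @param betas an \code{frp_betas}.
#' @param covariate spline covariate name.
#' @param at covariate values to evaluate (clamped to the fitting range).
#' @param window lag window (seconds) to average over, e.g. the lambda
#'   window for saccade-size effects.
#' @param channels channels to average over (default: all fitted).
#' @return data.frame with \code{value} (the covariate) and \code{effect}
#'   (microvolts).
#' @export
spline_partial_effect <- function(betas, covariate, at,
                                  window = c(0.03, 0.13), channels = NULL) {
  stopifnot(inherits(betas, "frp_betas"))
  design <- betas$design
  md <- design$mass
  if (!covariate %in% names(md$bases))
    stop("unknown spline covariate: ", covariate)
  channels <- channels %||% betas$channels
  lags <- window_samples(design$lag_times, window)
  ci <- md$colinfo
  cols <- ci$col[ci$term == "spline" & ci$name == covariate]
  coef_w <- vapply(cols, function(p) {
    idx <- (p - 1L) * design$L + lags
    mean(betas$coefficients[channels, idx, drop = FALSE])
  }, 0)
  B <- eval_spline_basis(md$bases[[covariate]], at, drop = TRUE)
  data.frame(value = at, effect = as.vector(B %*% coef_w))
}

#' Export FRP waveforms as a long-format table
#'
#' @param frp a \code{marginal_frp}.
#' @param path output CSV path.
#' @param participant participant label for the rows.
#' @export
write_frp_long <- function(frp, path, participant = 1L) {
  rows <- list()
  for (cg in names(frp$waves)) {
    w <- frp$waves[[cg]]
    rows[[cg]] <- data.frame(participant = participant, category = cg,
                             channel = rep(rownames(w), times = ncol(w)),
                             time = rep(frp$times, each = nrow(w)),
                             amplitude = as.vector(w))
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
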