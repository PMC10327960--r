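#' Scanpath simulation settings
#'
#' Defaults emulate an 8-second free-viewing search trial on a 30 x 30 degree
#' display: gamma-distributed fixation durations with a 247 ms mean (the
#' inter-fixation-onset scale that drives EEG overlap; saccade flight time is
#' folded into it), saccade amplitudes of a few degrees, and gaze revisits
#' that return to a stored earlier location after several intervening
#' fixations (target mean 9). New locations keep a minimum separation larger
#' than the 2-degree labeling radius so the revisit structure is controlled;
#' revisits land within a small jitter of their target.
#'
#' @param n_participants,n_trials study size.
#' @param trial_duration trial length in seconds.
#' @param screen_halfwidth half-width of the square display (degrees).
#' @param fixation_duration_mean,fixation_duration_shape gamma law of
#'   fixation durations (seconds; shape > 1).
#' @param saccade_amplitude_mean,saccade_amplitude_shape gamma law of
#'   ordinary saccade amplitudes (degrees).
#' @param revisit_prob probability that a fixation is a revisit of a stored
#'   earlier location (no two consecutive revisits).
#' @param min_intervening minimum intervening fixations between a precursor
#'   and its refixation; the intervening count is
#'   \code{min_intervening + Poisson(mean_intervening - min_intervening)}.
#' @param mean_intervening target mean intervening count.
#' @param revisit_jitter maximal radial displacement of a revisit from its
#'   target (degrees; keep below the labeling radius).
#' @param min_separation minimum distance of a new (non-revisit) fixation
#'   from every earlier fixation of the trial (degrees).
#' @param inter_trial_gap seconds between trials (no modeled events).
#' @param first_fixation_latency onset of the first fixation relative to the
#'   stimulus onset (seconds).
#' @param saccade_asymmetry give designated future revisit targets a larger
#'   incoming and smaller outgoing saccade (category-covariate confound
#'   preset; off by default).
#' @export
scanpath_config <- function(n_participants = 1, n_trials = 70,
                            trial_duration = 8, screen_halfwidth = 15,
                            fixation_duration_mean = 0.247,
                            fixation_duration_shape = 6,
                            saccade_amplitude_mean = 4.5,
                            saccade_amplitude_shape = 4,
                            revisit_prob = 0.14, min_intervening = 4,
                            mean_intervening = 9, revisit_jitter = 0.7,
                            min_separation = 2.5, inter_trial_gap = 2,
                            first_fixation_latency = 0,
                            saccade_asymmetry = FALSE) {
  cfg <- list(n_participants = n_participants, n_trials = n_trials,
              trial_duration = trial_duration,
              screen_halfwidth = screen_halfwidth,
              fixation_duration_mean = fixation_duration_mean,
              fixation_duration_shape = fixation_duration_shape,
              saccade_amplitude_mean = saccade_amplitude_mean,
              saccade_amplitude_shape = saccade_amplitude_shape,
              revisit_prob = revisit_prob,
              min_intervening = min_intervening,
              mean_intervening = mean_intervening,
              revisit_jitter = revisit_jitter,
              min_separation = min_separation,
              inter_trial_gap = inter_trial_gap,
              first_fixation_latency = first_fixation_latency,
              saccade_asymmetry = saccade_asymmetry)
  with(cfg, {
    stopifnot(n_participants >= 1, n_trials >= 1, trial_duration > 0,
              screen_halfwidth > 0, fixation_duration_mean > 0,
              fixation_duration_shape > 0, saccade_amplitude_mean > 0,
              revisit_prob >= 0, revisit_prob <= 1, min_intervening >= 1,
              mean_intervening >= min_intervening, revisit_jitter >= 0,
              min_separation >= 0, inter_trial_gap >= 0)
  })
  if (cfg$fixation_duration_mean > cfg$trial_duration)
    stop("infeasible config: mean fixation duration exceeds the trial duration")
  structure(cfg, class = "scanpath_config")
}

#' Simulate free-viewing scanpaths with revisit structure
#'
#' Generates, per trial, a stimulus-onset event followed by fixations filling
#' the trial duration. Revisits redirect the gaze to a stored earlier
#' location (within the jitter radius) after the configured number of
#' intervening fixations; all other fixations keep the minimum separation
#' from every earlier location. Saccade amplitudes equal the distance
#' between consecutive fixation positions. Fully reproducible from the seed.
#'
#' @param config a [scanpath_config()].
#' @param seed RNG seed.
#' @return list of data.frames: \code{fixations} (participant, trial, rank,
#'   onset, duration, x, y, planned_revisit_of), \code{saccades},
#'   \code{stimuli} (participant, trial, onset).
#' @export
simulate_scanpaths <- function(config = scanpath_config(), seed = 1) {
  stopifnot(inherits(config, "scanpath_config"))
  set.seed(seed)
  cf <- config
  hw <- cf$screen_halfwidth
  margin <- 0.5
  fix_rows <- list(); stim_rows <- list()

  for (pp in seq_len(cf$n_participants)) {
    for (tr in seq_len(cf$n_trials)) {
      t0 <- (cf$inter_trial_gap + cf$trial_duration) *
        ((pp - 1) * cf$n_trials + (tr - 1)) + cf$inter_trial_gap
      stim_rows[[length(stim_rows) + 1L]] <-
        data.frame(participant = pp, trial = tr, onset = t0)

      xs <- ys <- durs <- numeric(0)
      revisit_of <- integer(0)
      marked <- logical(0)      # designated future revisit targets
      t <- t0 + cf$first_fixation_latency
      last_was_revisit <- FALSE
      repeat {
        if (t >= t0 + cf$trial_duration) break
        n <- length(xs)
        dur <- stats::rgamma(1, shape = cf$fixation_duration_shape,
                             scale = cf$fixation_duration_mean /
                               cf$fixation_duration_shape)
        if (n == 0L) {
          pos <- stats::runif(2, -hw + margin, hw - margin)
          rev_of <- NA_integer_; mark <- FALSE
        } else {
          do_revisit <- !last_was_revisit &&
            n > cf$min_intervening &&
            stats::runif(1) < cf$revisit_prob
          if (do_revisit) {
            interv <- cf$min_intervening +
              stats::rpois(1, cf$mean_intervening - cf$min_intervening)
            p <- n - as.integer(interv)
            if (p < 1L) do_revisit <- FALSE
          }
          if (do_revisit) {
            if (cf$saccade_asymmetry && any(marked[seq_len(max(0, n -
                cf$min_intervening))])) {
              cand <- which(marked[seq_len(n - cf$min_intervening)])
              p <- cand[which.min(abs(cand - p))]
            }
            ang <- stats::runif(1, 0, 2 * pi)
            rad <- cf$revisit_jitter * sqrt(stats::runif(1))
            pos <- c(xs[p] + rad * cos(ang), ys[p] + rad * sin(ang))
            rev_of <- p; mark <- FALSE
            last_was_revisit <- TRUE
          } else {
            mark <- cf$saccade_asymmetry && stats::runif(1) < cf$revisit_prob
            scale_amp <- if (mark) 1.5
              else if (cf$saccade_asymmetry && isTRUE(marked[n])) 0.6
              else 1
            pos <- NULL
            best <- NULL; best_d <- -Inf
            for (try in seq_len(100L)) {
              amp <- scale_amp * stats::rgamma(1,
                shape = cf$saccade_amplitude_shape,
                scale = cf$saccade_amplitude_mean / cf$saccade_amplitude_shape)
              dirr <- stats::runif(1, 0, 2 * pi)
              cand <- c(xs[n] + amp * cos(dirr), ys[n] + amp * sin(dirr))
              cand <- reflect_into(cand, hw - margin)
              dmin <- min(sqrt((xs - cand[1])^2 + (ys - cand[2])^2))
              if (dmin > best_d) { best <- cand; best_d <- dmin }
              if (dmin >= cf$min_separation) { pos <- cand; break }
            }
            if (is.null(pos)) pos <- best
            rev_of <- NA_integer_
            last_was_revisit <- FALSE
          }
        }
        xs <- c(xs, pos[1]); ys <- c(ys, pos[2]); durs <- c(durs, dur)
        revisit_of <- c(revisit_of, rev_of)
        marked <- c(marked, mark)
        t <- t + dur
      }
      nfix <- length(xs)
      if (nfix)
        fix_rows[[length(fix_rows) + 1L]] <- data.frame(
          participant = pp, trial = tr, rank = seq_len(nfix),
          onset = t0 + cf$first_fixation_latency +
            cumsum(c(0, durs[-nfix])),
          duration = durs, x = xs, y = ys,
          planned_revisit_of = revisit_of)
    }
  }
  fixations <- do.call(rbind, fix_rows)
  rownames(fixations) <- NULL
  stimuli <- do.call(rbind, stim_rows)
  rownames(stimuli) <- NULL
  saccades <- saccades_from_fixations(fixations)
  list(fixations = fixations, saccades = saccades, stimuli = stimuli)
}

reflect_into <- function(pos, lim) {
  for (d in 1:2) {
    while (pos[d] > lim || pos[d] < -lim) {
      if (pos[d] > lim) pos[d] <- 2 * lim - pos[d]
      if (pos[d] < -lim) pos[d] <- -2 * lim - pos[d]
    }
  }
  pos
}

#' Ground-truth presets for the forward EEG model
#'
#' Event-locked kernels on the causal part of the analysis lag window,
#' sampled at 250 Hz:
#' \itemize{
#'   \item a lambda-like positive occipital wave peaking 100 ms after
#'     fixation onset, multiplicatively scaled by a saturating function of
#'     incoming saccade size;
#'   \item a late negativity around 300 ms, scaled by a monotone function of
#'     fixation rank;
#'   \item a precursor-specific late offset: a raised-cosine negativity
#'     supported exactly on 200-400 ms (zero elsewhere), so precursor
#'     fixations differ from every other category only in the late window;
#'   \item a stimulus-onset kernel.
#' }
#' Effect functions are normalized to 1 at a reference (sample-mean) value.
#' The \code{"null"} preset sets the precursor offset to zero. The
#' \code{group} block holds the between-participant model used for
#' group-level window-measure simulation: region topography weights of the
#' late effect, participant and participant-by-category standard deviations,
#' cell noise, and a measurement-noise term for single-participant
#' deconvolution estimation error.
#'
#' @param preset \code{"default"} or \code{"null"}.
#' @param noise_sd white-noise standard deviation of the continuous EEG
#'   (microvolts per sample).
#' @return object of class \code{frp_ground_truth}.
#' @export
make_default_truth <- function(preset = c("default", "null"), noise_sd = 5) {
  preset <- match.arg(preset)
  srate <- 250
  t <- (0:124) / srate
  lambda <- 8 * exp(-((t - 0.10) / 0.020)^2 / 2)
  late <- -2.5 * exp(-((t - 0.30) / 0.055)^2 / 2)
  prec_amp <- if (preset == "default") -3 else 0
  prec <- ifelse(t >= 0.2 & t <= 0.4,
                 prec_amp * 0.5 * (1 - cos(2 * pi * (t - 0.2) / 0.2)), 0)
  stim <- 5 * exp(-((t - 0.12) / 0.030)^2 / 2) -
    2 * exp(-((t - 0.30) / 0.080)^2 / 2)
  in_late <- t >= 0.2 & t < 0.4
  structure(list(
    preset = preset, srate = srate, kernel_times = t,
    kernels = list(lambda = lambda, late = late, precursor_offset = prec,
                   stimulus = stim),
    effect_saccade = function(v, ref) {
      (1 + 0.3 * (1 - exp(-v / 4))) / (1 + 0.3 * (1 - exp(-ref / 4)))
    },
    effect_rank = function(r, ref) 1 + 0.008 * (r - ref),
    noise_sd = noise_sd,
    late_window_offset = mean(prec[in_late]),
    group = list(
      region_weights = c(frontal = 0.1, central = 0.2, parietal = 0.5,
                         occipital = 1),
      region_baseline = c(frontal = -0.2, central = 0.25, parietal = 0.7,
                          occipital = 1) * mean(late[in_late]),
      sigma_subject = 1.5, sigma_subject_category = 0.35,
      sigma_resid = 1.0, sigma_measure = 0.2)),
    class = "frp_ground_truth")
}

#' Synthetic electrode montage with ROI structure
#'
#' Channels named after the eight ROI landmark electrodes
#' (F3/F4/C3/C4/P3/P4/O1/O2), optionally replicated into seven channels per
#' site (\code{<center>} plus \code{<center>_1..6}, the surrounding
#' electrodes tapered to 95 percent of the center weight) to form the
#' 56-channel montage matching [default_roi_spec()]. Each channel carries
#' forward-model topography weights for the lambda wave, the late
#' negativity (mirrored positive-to-negative from occipital to frontal) and
#' the stimulus response.
#'
#' @param per_roi 1 (8 channels, fitting-sized) or 7 (56 channels).
#' @return data.frame: channel, region, hemisphere, topo_lambda, topo_late,
#'   topo_stim.
#' @export
default_montage <- function(per_roi = 1) {
  stopifnot(per_roi %in% c(1L, 7L))
  centers <- c("F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2")
  region <- rep(c("frontal", "central", "parietal", "occipital"), each = 2)
  hemisphere <- rep(c("left", "right"), times = 4)
  w_lambda <- rep(c(0.05, 0.10, 0.50, 1.00), each = 2)
  w_late <- rep(c(-0.20, 0.25, 0.70, 1.00), each = 2)
  w_stim <- rep(c(0.10, 0.30, 0.70, 1.00), each = 2)
  base <- data.frame(channel = centers, region = region,
                     hemisphere = hemisphere, topo_lambda = w_lambda,
                     topo_late = w_late, topo_stim = w_stim)
  if (per_roi == 1L) return(base)
  out <- do.call(rbind, lapply(seq_len(nrow(base)), function(i) {
    ctr <- base[i, ]
    nb <- ctr[rep(1, 6), ]
    nb$channel <- paste0(ctr$channel, "_", 1:6)
    nb$topo_lambda <- nb$topo_lambda * 0.95
    nb$topo_late <- nb$topo_late * 0.95
    nb$topo_stim <- nb$topo_stim * 0.95
    rbind(ctr, nb)
  }))
  rownames(out) <- NULL
  out
}

#' Forward-simulate continuous EEG from labeled events
#'
#' Linear superposition: every fixation contributes its topography-weighted
#' kernels at its onset sample -- the lambda kernel scaled by the saturating
#' incoming-saccade-size effect, the late kernel scaled by the monotone
#' rank effect, plus the precursor offset kernel for precursor fixations --
#' and every stimulus onset contributes the stimulus kernel. Overlapping
#' responses sum; seeded white Gaussian noise is added. Effect functions are
#' normalized at the empirical mean of the respective covariate, so the
#' marginal category waveforms at mean covariate levels equal the raw
#' kernels (see [true_marginal_waveforms()]).
#'
#' @param fixations labeled fixation table (category column required).
#' @param stimuli stimulus-onset table.
#' @param covariates covariate table aligned with \code{fixations} (NAs are
#'   imputed at the median for the amplitude scaling).
#' @param truth a [make_default_truth()] preset.
#' @param montage a [default_montage()]-style data.frame.
#' @param noise_sd overrides the preset's noise level.
#' @param seed RNG seed for the noise.
#' @param n_samples recording length (default: 0.6 s past the last event).
#' @return list: \code{eeg} (a \code{continuous_eeg}),
#'   \code{event_samples} (fixation onset samples), \code{stim_samples}.
#' @export
simulate_eeg <- function(fixations, stimuli, covariates, truth,
                         montage = default_montage(), noise_sd = NULL,
                         seed = 1, n_samples = NULL,
                         lag_window = c(-0.2, 0.5)) {
  stopifnot(inherits(truth, "frp_ground_truth"))
  if (is.null(fixations$category)) stop("fixations must be labeled")
  srate <- truth$srate
  noise_sd <- noise_sd %||% truth$noise_sd
  kl <- max(vapply(truth$kernels, length, 1L))
  if (kl > round(lag_window[2] * srate))
    stop("kernel support exceeds the analysis lag window: recovery would be ",
         "ill-posed by construction")
  if (nrow(fixations)) covariates <- impute_covariates(covariates)

  fix_s <- round(fixations$onset * srate) + 1L
  stim_s <- round(stimuli$onset * srate) + 1L
  if (is.null(n_samples)) {
    if (!length(c(fix_s, stim_s)))
      stop("n_samples must be given when there are no events")
    n_samples <- max(fix_s, stim_s) + kl + as.integer(0.1 * srate)
  }
  if (length(c(fix_s, stim_s)) &&
      (any(c(fix_s, stim_s) < 1L) || any(c(fix_s, stim_s) > n_samples - kl)))
    stop("events (plus kernel support) must lie within the recording")

  if (nrow(fixations)) {
    a_lambda <- truth$effect_saccade(covariates$incoming_saccade_size,
                                     mean(covariates$incoming_saccade_size))
    a_late <- truth$effect_rank(covariates$fixation_rank,
                                mean(covariates$fixation_rank))
    a_prec <- as.numeric(fixations$category == "precursor")
  } else {
    a_lambda <- a_late <- a_prec <- numeric(0)
  }

  train <- function(samples, amps) {
    z <- numeric(n_samples)
    for (i in seq_along(samples)) z[samples[i]] <- z[samples[i]] + amps[i]
    z
  }
  convolve_causal <- function(z, k) {
    out <- stats::convolve(z, rev(k), type = "open")[seq_len(n_samples)]
    out
  }
  s_lambda <- convolve_causal(train(fix_s, a_lambda), truth$kernels$lambda)
  s_late <- convolve_causal(train(fix_s, a_late), truth$kernels$late)
  s_prec <- convolve_causal(train(fix_s, a_prec),
                            truth$kernels$precursor_offset)
  s_stim <- convolve_causal(train(stim_s, rep(1, length(stim_s))),
                            truth$kernels$stimulus)

  set.seed(seed)
  data <- outer(montage$topo_lambda, s_lambda) +
    outer(montage$topo_late, s_late + s_prec) +
    outer(montage$topo_stim, s_stim)
  if (noise_sd > 0)
    data <- data + matrix(stats::rnorm(length(data), sd = noise_sd),
                          nrow(data), ncol(data))
  rownames(data) <- montage$channel
  list(eeg = continuous_eeg(data, srate, channels = montage$channel),
       event_samples = fix_s, stim_samples = stim_s)
}

#' Ground-truth marginal category waveforms on the analysis lag grid
#'
#' The waveform each category should reconstruct to at mean covariate
#' levels: kernels embedded at nonnegative lags of the analysis window,
#' weighted by the montage topography; precursor fixations additionally
#' carry the offset kernel. Useful as the reference for recovery tests.
#'
#' @param truth,montage as in [simulate_eeg()].
#' @param window analysis lag window (seconds).
#' @param categories categories to emit.
#' @return a \code{marginal_frp}.
#' @export
true_marginal_waveforms <- function(truth, montage, window = c(-0.2, 0.5),
                                    categories = c("other", "precursor",
                                                   "refixation", "ordinary")) {
  srate <- truth$srate
  lag0 <- round(window[1] * srate)
  lag1 <- round(window[2] * srate)
  times <- (lag0:(lag1 - 1L)) / srate
  embed <- function(k) {
    out <- numeric(length(times))
    pos <- match(0L, lag0:(lag1 - 1L))
    out[seq.int(pos, length.out = length(k))] <- k
    out
  }
  base <- outer(montage$topo_lambda, embed(truth$kernels$lambda)) +
    outer(montage$topo_late, embed(truth$kernels$late))
  prec_extra <- outer(montage$topo_late,
                      embed(truth$kernels$precursor_offset))
  waves <- lapply(stats::setNames(categories, categories), function(cg) {
    w <- base + if (cg == "precursor") prec_extra else 0
    rownames(w) <- montage$channel
    w
  })
  marginal_frp(waves, times)
}

#' Group-level window-measure simulation
#'
#' Draws late-window ROI measures for virtual participants from the
#' generator's group model: region baseline plus the precursor-specific
#' late-window offset scaled by the region topography weights, a
#' participant random intercept, a participant-by-category random effect,
#' and cell noise (residual plus measurement error in quadrature).
#'
#' @param truth a [make_default_truth()] preset.
#' @param n_subjects number of virtual participants.
#' @param categories category levels (precursor carries the offset).
#' @return long data.frame: participant, category, region, hemisphere,
#'   value.
#' @export
simulate_group_measures <- function(truth, n_subjects = 21,
                                    categories = c("precursor", "refixation",
                                                   "ordinary")) {
  g <- truth$group
  regions <- names(g$region_weights)
  hemis <- c("left", "right")
  grid <- expand.grid(category = categories, region = regions,
                      hemisphere = hemis, stringsAsFactors = FALSE)
  sd_cell <- sqrt(g$sigma_resid^2 + g$sigma_measure^2)
  rows <- lapply(seq_len(n_subjects), function(s) {
    b_s <- stats::rnorm(1, sd = g$sigma_subject)
    b_sc <- stats::setNames(stats::rnorm(length(categories),
                                         sd = g$sigma_subject_category),
                            categories)
    val <- g$region_baseline[grid$region] +
      truth$late_window_offset * g$region_weights[grid$region] *
        (grid$category == "precursor") +
      b_s + b_sc[grid$category] +
      stats::rnorm(nrow(grid), sd = sd_cell)
    cbind(participant = s, grid, value = as.numeric(val))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the modeling event table from labeled fixations and stimuli
#'
#' One row per modeling event (fixation onsets and stimulus onsets) with the
#' covariates the default model formula uses; covariates are imputed at the
#' participant median where absent.
#'
#' @param fixations labeled fixation table.
#' @param covariates aligned covariate table.
#' @param stimuli stimulus table.
#' @return data.frame sorted by onset with an \code{event_type} column.
#' @export
build_model_events <- function(fixations, covariates, stimuli) {
  covariates <- impute_covariates(covariates)
  fix <- data.frame(event_type = "fixation", onset = fixations$onset,
                    category = as.character(fixations$category),
                    fixation_rank = covariates$fixation_rank,
                    fixation_duration = covariates$fixation_duration,
                    incoming_saccade_size = covariates$incoming_saccade_size,
                    outgoing_saccade_size = covariates$outgoing_saccade_size,
                    y_position = covariates$y_position)
  stim <- data.frame(event_type = "stimulus", onset = stimuli$onset,
                     category = NA_character_, fixation_rank = NA_real_,
                     fixation_duration = NA_real_,
                     incoming_saccade_size = NA_real_,
                     outgoing_saccade_size = NA_real_, y_position = NA_real_)
  ev <- rbind(fix, stim)
  ev[order(ev$onset), , drop = FALSE]
}

#' One-participant end-to-end synthetic dataset
#'
#' Convenience wrapper running scanpath simulation, labeling, covariate
#' extraction and forward EEG simulation with a single seed, returning every
#' intermediate product plus the ground truth needed for recovery checks.
#'
#' @param config a [scanpath_config()] (single participant).
#' @param truth ground-truth preset.
#' @param montage electrode montage.
#' @param seed RNG seed (scanpaths and noise).
#' @param radius labeling radius (degrees).
#' @export
simulate_participant <- function(config = scanpath_config(),
                                 truth = make_default_truth(),
                                 montage = default_montage(), seed = 1,
                                 radius = 2) {
  sp <- simulate_scanpaths(config, seed = seed)
  fix <- label_fixations(sp$fixations, radius = radius)
  cov <- compute_covariates(fix, sp$saccades)
  sim <- simulate_eeg(fix, sp$stimuli, cov, truth, montage,
                      seed = seed + 1000L)
  events <- build_model_events(fix, cov, sp$stimuli)
  list(fixations = fix, saccades = sp$saccades, stimuli = sp$stimuli,
       covariates = cov, events = events, eeg = sim$eeg,
       event_samples = sim$event_samples, stim_samples = sim$stim_samples,
       truth = truth, montage = montage, config = config)
}
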