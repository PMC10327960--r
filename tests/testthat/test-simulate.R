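test_that("scanpath simulation is reproducible and obeys its config", {
  cfg <- scanpath_config(n_trials = 5)
  a <- simulate_scanpaths(cfg, seed = 7)
  b <- simulate_scanpaths(cfg, seed = 7)
  expect_identical(a, b)
  c <- simulate_scanpaths(cfg, seed = 8)
  expect_false(identical(a$fixations$x, c$fixations$x))
  # saccade amplitude equals the distance between consecutive fixations
  f <- a$fixations[a$fixations$trial == 1, ]
  s <- a$saccades[a$saccades$trial == 1, ]
  expect_equal(s$amplitude,
               sqrt(diff(f$x)^2 + diff(f$y)^2))
  # positions bounded by the screen
  expect_true(all(abs(a$fixations$x) <= cfg$screen_halfwidth))
  expect_true(all(abs(a$fixations$y) <= cfg$screen_halfwidth))
  # one stimulus onset per trial, preceding its fixations
  expect_equal(nrow(a$stimuli), 5)
  expect_true(all(tapply(a$fixations$onset, a$fixations$trial, min) >=
                    a$stimuli$onset))
  expect_error(scanpath_config(fixation_duration_mean = 10), "infeasible")
})

test_that("no revisits plus wide spacing yields zero refixations", {
  cfg <- scanpath_config(n_trials = 12, revisit_prob = 0,
                         min_separation = 2.5)
  sp <- simulate_scanpaths(cfg, seed = 5)
  lab <- label_fixations(sp$fixations)
  expect_equal(sum(lab$category == "refixation"), 0)
  expect_equal(sum(lab$category == "precursor"), 0)
})

test_that("fixation counts and durations follow the renewal process", {
  cfg <- scanpath_config(n_trials = 100, revisit_prob = 0)
  sp <- simulate_scanpaths(cfg, seed = 13)
  counts <- tapply(sp$fixations$rank, sp$fixations$trial, max)
  # independent renewal-count oracle at the configured duration law
  set.seed(99)
  oracle_counts <- replicate(3000, {
    t <- 0; n <- 0
    while (t < cfg$trial_duration) {
      t <- t + rgamma(1, shape = cfg$fixation_duration_shape,
                      scale = cfg$fixation_duration_mean /
                        cfg$fixation_duration_shape)
      n <- n + 1
    }
    n
  })
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - mean(oracle_counts)), 3 * se + 3 *
              sd(oracle_counts) / sqrt(3000))
  # and the renewal mean sits near trial_duration / mean_duration
  expect_lt(abs(mean(counts) - cfg$trial_duration /
                  cfg$fixation_duration_mean), 1.5)
  # per-category mean duration within 3 SE of the configured mean
  lab <- label_fixations(sp$fixations)
  cov <- compute_covariates(lab, sp$saccades)
  s <- summarize_eye_movements(lab, cov)
  ord <- s$categories[s$categories$category == "ordinary", ]
  se_d <- cfg$fixation_duration_mean /
    sqrt(cfg$fixation_duration_shape * ord$n)
  expect_lt(abs(ord$mean_duration - cfg$fixation_duration_mean), 3 * se_d)
})

test_that("revisit structure reproduces the configured intervening lag", {
  sp <- simulate_scanpaths(scanpath_config(n_trials = 60), seed = 17)
  lab <- label_fixations(sp$fixations)
  cov <- compute_covariates(lab, sp$saccades)
  s <- summarize_eye_movements(lab, cov)
  expect_gt(s$revisits$n_pairs, 30)
  expect_gt(s$revisits$mean_intervening, 7)
  expect_lt(s$revisits$mean_intervening, 11)
})

test_that("saccade-asymmetry preset enlarges precursor incoming saccades", {
  cfg <- scanpath_config(n_trials = 60, saccade_asymmetry = TRUE)
  sp <- simulate_scanpaths(cfg, seed = 19)
  lab <- label_fixations(sp$fixations)
  cov <- compute_covariates(lab, sp$saccades)
  s <- summarize_eye_movements(lab, cov)
  g <- function(cat, col) s$categories[[col]][s$categories$category == cat]
  expect_gt(g("precursor", "mean_incoming_size"),
            g("ordinary", "mean_incoming_size"))
  expect_lt(g("precursor", "mean_outgoing_size"),
            g("ordinary", "mean_outgoing_size"))
})

test_that("forward EEG model: zero case, single kernel, superposition", {
  truth <- make_default_truth()
  mont <- default_montage()
  empty_fix <- data.frame(trial = integer(0), onset = numeric(0),
                          duration = numeric(0), x = numeric(0),
                          y = numeric(0),
                          category = factor(character(0)))
  empty_cov <- data.frame(fixation_rank = numeric(0),
                          incoming_saccade_size = numeric(0))
  no_stim <- data.frame(trial = integer(0), onset = numeric(0))
  sim0 <- simulate_eeg(empty_fix, no_stim, empty_cov, truth, mont,
                       noise_sd = 0, n_samples = 500L)
  expect_equal(max(abs(sim0$eeg$data)), 0)
  # one stimulus event: signal equals the topography-scaled kernel
  one_stim <- data.frame(trial = 1, onset = 1)
  sim1 <- simulate_eeg(empty_fix, one_stim, empty_cov, truth, mont,
                       noise_sd = 0, n_samples = 600L)
  s0 <- round(1 * truth$srate) + 1
  k <- truth$kernels$stimulus
  expect_equal(sim1$eeg$data["O1", s0 + seq_along(k) - 1],
               mont$topo_stim[mont$channel == "O1"] * k,
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(max(abs(sim1$eeg$data[, seq_len(s0 - 1)])), 0,
               tolerance = 1e-12)
  # superposition: EEG(A union B) = EEG(A) + EEG(B) at zero noise
  two_stim <- data.frame(trial = c(1, 2), onset = c(1, 1.3))
  sim2 <- simulate_eeg(empty_fix, two_stim, empty_cov, truth, mont,
                       noise_sd = 0, n_samples = 600L)
  simB <- simulate_eeg(empty_fix, data.frame(trial = 2, onset = 1.3),
                       empty_cov, truth, mont, noise_sd = 0,
                       n_samples = 600L)
  expect_equal(sim2$eeg$data, sim1$eeg$data + simB$eeg$data,
               tolerance = 1e-10)
  # kernels longer than the lag window are rejected
  long_truth <- truth
  long_truth$kernels$lambda <- rep(1, 200)
  expect_error(simulate_eeg(empty_fix, one_stim, empty_cov, long_truth,
                            mont, n_samples = 600L), "lag window")
})

test_that("ground-truth presets encode the precursor-specific late offset", {
  tru <- make_default_truth()
  nul <- make_default_truth("null")
  # null preset: all categories share identical kernels
  expect_equal(max(abs(nul$kernels$precursor_offset)), 0)
  wn <- true_marginal_waveforms(nul, default_montage())
  expect_equal(wn$waves$precursor, wn$waves$ordinary)
  # default preset: difference only within 200-400 ms
  wd <- true_marginal_waveforms(tru, default_montage())
  d <- wd$waves$precursor["O1", ] - wd$waves$refixation["O1", ]
  inside <- wd$times >= 0.2 & wd$times <= 0.4
  expect_true(any(d[inside] != 0))
  expect_equal(max(abs(d[!inside])), 0)
  # effect functions are 1 at the reference level
  expect_equal(tru$effect_saccade(4.2, 4.2), 1)
  expect_equal(tru$effect_rank(16, 16), 1)
  # the configured window offset matches the embedded kernel
  lw <- wd$times >= 0.2 - 1e-9 & wd$times < 0.4 - 1e-9
  expect_equal(mean(d[lw]), tru$late_window_offset, tolerance = 1e-9)
  expect_error(make_default_truth("bogus"))
})
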