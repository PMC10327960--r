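# Small fitted instance with categories and one spline covariate, reused
# across reconstruction tests.
frp_instance <- function(reference = "other", seed = 21, noise_sd = 0.2) {
  set.seed(seed)
  n <- 120
  onsets <- cumsum(runif(n, 0.35, 0.6)) + 0.5
  cats <- sample(c("other", "precursor", "ordinary"), n, replace = TRUE)
  sz <- runif(n, 1, 9)
  srate <- 100
  kb <- 2 * exp(-((seq(0, 0.29, by = 0.01) - 0.1) / 0.03)^2 / 2)
  kp <- -1.5 * exp(-((seq(0, 0.29, by = 0.01) - 0.2) / 0.04)^2 / 2)
  n_samp <- round(max(onsets) * srate) + 120
  sig <- numeric(n_samp)
  s <- round(onsets * srate) + 1L
  for (i in seq_len(n)) {
    idx <- s[i] + seq_along(kb) - 1
    sig[idx] <- sig[idx] + kb * (1 + 0.05 * (sz[i] - mean(sz))) +
      if (cats[i] == "precursor") kp else 0
  }
  sig <- sig + rnorm(n_samp, sd = noise_sd)
  ev <- data.frame(event_type = "fixation", onset = onsets, category = cats,
                   size = sz)
  fml <- model_formula(
    fixation = list(term_intercept(),
                    term_categorical("category",
                                     c("other", "precursor", "ordinary"),
                                     reference),
                    term_spline("size", 5)),
    stimulus = list())
  md <- build_mass_design(ev, fml)
  xd <- time_expand(md, s, c(-0.1, 0.3), srate, n_samp)
  eeg <- continuous_eeg(matrix(sig, 1), srate, channels = "oz")
  betas <- fit_deconvolution(eeg, xd)
  list(betas = betas, design = xd, kb = kb, kp = kp)
}

test_that("marginal reconstruction: intercept, dummies and spline levels", {
  inst <- frp_instance()
  betas <- inst$betas
  L <- inst$design$L
  frp <- reconstruct_marginal_frps(betas)
  expect_setequal(names(frp$waves), c("other", "precursor", "ordinary"))
  # category difference equals exactly the dummy betas
  ci <- inst$design$mass$colinfo
  dprec <- ci$col[ci$term == "categorical" & !is.na(ci$level) &
                    ci$level == "precursor"]
  dummy <- betas$coefficients[1, (dprec - 1) * L + seq_len(L)]
  expect_equal(unname(frp$waves$precursor[1, ] - frp$waves$other[1, ]),
               unname(dummy), tolerance = 1e-12)
  # intercept-plus-categories only: reference waveform = intercept betas
  ev2 <- data.frame(event_type = "fixation", onset = c(1, 3, 5, 7),
                    category = c("a", "b", "a", "b"))
  fml2 <- model_formula(fixation = list(
    term_intercept(), term_categorical("category", c("a", "b"), "a")),
    stimulus = list())
  md2 <- build_mass_design(ev2, fml2)
  xd2 <- time_expand(md2, round(c(1, 3, 5, 7) * 100) + 1L, c(-0.1, 0.3),
                     100, 900L)
  eeg2 <- continuous_eeg(matrix(rnorm(900), 1), 100)
  b2 <- fit_deconvolution(eeg2, xd2)
  frp2 <- reconstruct_marginal_frps(b2)
  expect_equal(unname(frp2$waves$a[1, ]),
               unname(b2$coefficients[1, seq_len(xd2$L)]))
  # changing the evaluation level changes the waveform by basis difference
  frp_a <- reconstruct_marginal_frps(betas, covariate_means = c(size = 3))
  frp_b <- reconstruct_marginal_frps(betas, covariate_means = c(size = 7))
  bs <- inst$design$mass$bases$size
  dB <- eval_spline_basis(bs, 3) - eval_spline_basis(bs, 7)
  cols <- ci$col[ci$term == "spline"]
  pred <- rowSums(vapply(seq_along(cols), function(j)
    dB[1, j] * betas$coefficients[1, (cols[j] - 1) * L + seq_len(L)],
    numeric(L)))
  expect_equal(unname(frp_a$waves$other[1, ] - frp_b$waves$other[1, ]),
               unname(pred), tolerance = 1e-10)
  expect_error(reconstruct_marginal_frps(betas,
                                         covariate_means = c(bogus = 1)),
               "missing covariate")
})

test_that("category differences are invariant to the reference level", {
  f1 <- frp_instance(reference = "other")
  f2 <- frp_instance(reference = "ordinary")
  w1 <- reconstruct_marginal_frps(f1$betas)
  w2 <- reconstruct_marginal_frps(f2$betas)
  d1 <- w1$waves$precursor[1, ] - w1$waves$ordinary[1, ]
  d2 <- w2$waves$precursor[1, ] - w2$waves$ordinary[1, ]
  expect_lt(max(abs(d1 - d2)), 1e-6)
})

test_that("baseline correction: zero mean, idempotent, 5 samples at 250 Hz", {
  times <- (-50:124) / 250
  const <- marginal_frp(list(a = matrix(3, 2, length(times))), times)
  bc <- baseline_correct(const, c(0, 0.02))
  expect_equal(unname(bc$waves$a), matrix(0, 2, length(times)))
  expect_equal(length(window_samples(times, c(0, 0.02))), 5)
  set.seed(2)
  w <- marginal_frp(list(a = matrix(rnorm(2 * 175), 2)), times)
  once <- baseline_correct(w)
  twice <- baseline_correct(once)
  expect_equal(once$waves, twice$waves)
  sel <- window_samples(times, c(0, 0.02))
  expect_equal(rowMeans(once$waves$a[, sel]), c(0, 0), ignore_attr = TRUE)
  expect_error(baseline_correct(w, c(0.9, 1)), "empty")
})

test_that("ROI averaging consumes 56 channels and is order-invariant", {
  rois <- default_roi_spec()
  expect_equal(nrow(rois), 56)
  expect_equal(length(unique(rois$channel)), 56)
  expect_equal(as.vector(table(rois$roi)), rep(7L, 8))
  times <- (-10:20) / 100
  set.seed(3)
  base <- matrix(rnorm(56 * length(times)), 56,
                 dimnames = list(rois$channel, NULL))
  frp <- marginal_frp(list(a = base), times)
  ra <- roi_average(frp, rois)
  expect_setequal(ra$channels, unique(rois$roi))
  # identical waveforms within an ROI average to that waveform
  same <- base
  same[rois$channel[rois$roi == "O1"], ] <-
    rep(base["O1", ], each = 7)
  ra2 <- roi_average(marginal_frp(list(a = same), times), rois)
  expect_equal(ra2$waves$a["O1", ], base["O1", ])
  # permuting channel rows leaves ROI means unchanged
  perm <- base[sample(56), ]
  ra3 <- roi_average(marginal_frp(list(a = perm), times), rois)
  expect_equal(ra3$waves$a, ra$waves$a)
  # missing channel is reported by name
  expect_error(roi_average(marginal_frp(list(a = base[-1, , drop = FALSE]),
                                        times), rois),
               rownames(base)[1])
})

test_that("baseline correction commutes with ROI averaging", {
  rois <- default_roi_spec()
  times <- (-50:124) / 250
  set.seed(4)
  w <- matrix(rnorm(56 * 175), 56, dimnames = list(rois$channel, NULL))
  frp <- marginal_frp(list(a = w), times)
  ab <- baseline_correct(roi_average(frp, rois))
  ba <- roi_average(baseline_correct(frp), rois)
  expect_equal(ab$waves$a, ba$waves$a, tolerance = 1e-12)
})

test_that("window means: constants, ramps and the lambda window", {
  times <- (-50:124) / 250
  const <- marginal_frp(list(a = matrix(2.5, 1, 175,
                                        dimnames = list("O1", NULL))), times)
  wm <- window_mean(const, list(late = c(0.2, 0.4)))
  expect_equal(wm$value, 2.5)
  # linear ramp 0 at 200 ms to 1 at 400 ms averages to ~ 1/2
  ramp <- pmin(pmax((times - 0.2) / 0.2, 0), 1)
  fr <- marginal_frp(list(a = matrix(ramp, 1, dimnames = list("O1", NULL))),
                     times)
  wmr <- window_mean(fr, list(late = c(0.2, 0.4)))
  expect_lt(abs(wmr$value - 0.5), 1 / (0.2 * 250))
  # the lambda window is the 100 ms window centered on the 80 ms peak
  expect_equal(frp_windows()$lambda, c(0.08 - 0.05, 0.08 + 0.05))
  expect_error(window_mean(fr, list(x = c(0.9, 1.2))), "outside")
})

test_that("spline partial effects reproduce shapes on noiseless fits", {
  inst <- frp_instance(noise_sd = 0)
  eff <- spline_partial_effect(inst$betas, "size", at = seq(1.5, 8.5, 0.25),
                               window = c(0.05, 0.15))
  # generating modulation is linear in size
  expect_gt(cor(eff$effect, eff$value), 0.999)
})
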