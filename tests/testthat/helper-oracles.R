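# Independent brute-force reference implementations and shared fixtures.

# Reference labeler: literal rule evaluation over all fixation pairs,
# written with plain loops, kept independent of the package's vectorized
# implementation.
oracle_label_trial <- function(x, y, radius, drop_pre_refixation = TRUE) {
  n <- length(x)
  dd <- function(i, j) sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
  near <- function(i, j) dd(i, j) < radius
  left_between <- function(i, j) {
    if (j - i < 2) return(FALSE)
    for (k in (i + 1):(j - 1)) if (!near(i, k)) return(TRUE)
    FALSE
  }
  refix <- logical(n)
  prec_of <- rep(NA_integer_, n)
  for (j in seq_len(n)) {
    if (j == 1) next
    if (near(j - 1, j)) next
    for (i in seq_len(j - 1)) {
      if (near(i, j) && left_between(i, j)) {
        refix[j] <- TRUE
        prec_of[j] <- i
        break
      }
    }
  }
  precursors <- integer(0)
  for (j in which(refix)) precursors <- union(precursors, prec_of[j])
  lab <- rep(NA_character_, n)
  for (f in seq_len(n)) {
    is_r <- refix[f]
    is_p <- f %in% precursors
    if (is_r && is_p) lab[f] <- "other"
    else if (is_r) lab[f] <- "refixation"
    else if (is_p) lab[f] <- "precursor"
    else {
      near_any <- FALSE
      for (g in seq_len(n)) if (g != f && near(f, g)) near_any <- TRUE
      lab[f] <- if (near_any) "other" else "ordinary"
    }
  }
  if (drop_pre_refixation) {
    for (f in seq_len(n)) {
      if (f < n && lab[f + 1] == "refixation" && lab[f] != "refixation")
        lab[f] <- "other"
    }
  }
  lab
}

# Random scanpath stressing chains, shared precursors and boundary cases:
# positions drawn in a box small enough that revisits happen by chance.
random_scanpath_df <- function(n, box = 6, trial = 1) {
  data.frame(trial = trial, onset = (seq_len(n) - 1) * 0.25,
             duration = rep(0.2, n),
             x = stats::runif(n, -box, box), y = stats::runif(n, -box, box))
}

# Dense minimum-norm least squares via SVD pseudoinverse.
dense_lstsq <- function(A, b, tol = 1e-10) {
  A <- as.matrix(A)
  sv <- svd(A)
  keep <- sv$d > tol * sv$d[1]
  dinv <- ifelse(keep, 1 / sv$d, 0)
  as.numeric(sv$v %*% (dinv * crossprod(sv$u, b)))
}

# Naive first-principles repeated-measures ANOVA for one within factor:
# explicit cell-means sums of squares plus the eigenvalue form of the
# Greenhouse-Geisser epsilon and the textbook Huynh-Feldt step-up.
oracle_rm_anova_1f <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  gm <- mean(Y)
  col_m <- colMeans(Y); row_m <- rowMeans(Y)
  ss_a <- n * sum((col_m - gm)^2)
  ss_s <- k * sum((row_m - gm)^2)
  ss_tot <- sum((Y - gm)^2)
  ss_err <- ss_tot - ss_a - ss_s
  df_a <- k - 1; df_err <- (n - 1) * (k - 1)
  Fv <- (ss_a / df_a) / (ss_err / df_err)
  # GG epsilon from the double-centered covariance spectrum
  S <- stats::cov(Y)
  Cm <- diag(k) - 1 / k
  Sc <- Cm %*% S %*% Cm
  lam <- eigen(Sc, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > 1e-12 * max(lam)]
  gg <- sum(lam)^2 / ((k - 1) * sum(lam^2))
  hf <- min(1, (n * (k - 1) * gg - 2) / ((k - 1) * (n - 1 - (k - 1) * gg)))
  hf <- max(hf, gg)
  list(F = Fv, df_num = df_a, df_den = df_err,
       p = stats::pf(Fv, df_a, df_err, lower.tail = FALSE),
       gg = gg, hf = hf,
       p_hf = stats::pf(Fv, hf * df_a, hf * df_err, lower.tail = FALSE))
}

# Naive two-factor within-subject ANOVA from cell means (loops, no
# contrast machinery): returns F for both mains and the interaction.
oracle_rm_anova_2f <- function(Y3) {   # array n x k1 x k2
  n <- dim(Y3)[1]; k1 <- dim(Y3)[2]; k2 <- dim(Y3)[3]
  gm <- mean(Y3)
  m_s <- apply(Y3, 1, mean); m_a <- apply(Y3, 2, mean); m_b <- apply(Y3, 3, mean)
  m_sa <- apply(Y3, c(1, 2), mean); m_sb <- apply(Y3, c(1, 3), mean)
  m_ab <- apply(Y3, c(2, 3), mean)
  ss_a <- n * k2 * sum((m_a - gm)^2)
  ss_b <- n * k1 * sum((m_b - gm)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, k2)) -
                      outer(rep(1, k1), m_b) + gm)^2)
  ss_sa <- k2 * sum((m_sa - outer(m_s, rep(1, k1)) -
                       outer(rep(1, n), m_a) + gm)^2)
  ss_sb <- k1 * sum((m_sb - outer(m_s, rep(1, k2)) -
                       outer(rep(1, n), m_b) + gm)^2)
  ss_tot <- sum((Y3 - gm)^2)
  ss_s <- k1 * k2 * sum((m_s - gm)^2)
  ss_sab <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_sa - ss_sb
  F_a <- (ss_a / (k1 - 1)) / (ss_sa / ((n - 1) * (k1 - 1)))
  F_b <- (ss_b / (k2 - 1)) / (ss_sb / ((n - 1) * (k2 - 1)))
  F_ab <- (ss_ab / ((k1 - 1) * (k2 - 1))) /
    (ss_sab / ((n - 1) * (k1 - 1) * (k2 - 1)))
  list(F_a = F_a, F_b = F_b, F_ab = F_ab)
}

# Tiny deconvolution instance: two event classes with distinct kernels,
# optionally overlapping, noiseless by default. Returns the pieces needed
# to cross-check the sparse solver against dense least squares and
# event-locked averaging.
tiny_deconv_instance <- function(n_events = 12, spacing = 60, offset = 25,
                                 srate = 100, L_window = c(-0.1, 0.3),
                                 noise_sd = 0, seed = 7) {
  set.seed(seed)
  s1 <- 100 + cumsum(c(0, spacing + sample(-12:12, n_events - 1, TRUE)))
  s2 <- s1 + offset + sample(-5:5, n_events, TRUE)
  n_samp <- max(s2) + 80
  k1 <- 3 * exp(-((seq(0, 0.29, by = 1 / srate) - 0.08) / 0.02)^2 / 2)
  k2 <- -2 * exp(-((seq(0, 0.29, by = 1 / srate) - 0.15) / 0.04)^2 / 2)
  sig <- numeric(n_samp)
  for (s in s1) sig[s + seq_along(k1) - 1] <- sig[s + seq_along(k1) - 1] + k1
  for (s in s2) sig[s + seq_along(k2) - 1] <- sig[s + seq_along(k2) - 1] + k2
  if (noise_sd > 0) sig <- sig + rnorm(n_samp, sd = noise_sd)
  events <- data.frame(
    event_type = c(rep("fixation", n_events), rep("stimulus", n_events)),
    onset = (c(s1, s2) - 1) / srate)
  events <- events[order(events$onset), , drop = FALSE]
  fml <- model_formula(fixation = list(term_intercept()),
                       stimulus = list(term_intercept()))
  md <- build_mass_design(events, fml)
  xd <- time_expand(md, round(events$onset * srate) + 1L, L_window, srate,
                    n_samp)
  eeg <- continuous_eeg(matrix(sig, 1), srate, channels = "cz")
  list(eeg = eeg, design = xd, k1 = k1, k2 = k2, s1 = s1, s2 = s2,
       srate = srate)
}

# Shared end-to-end recovery fixture (built once per test run; reused by
# the recovery properties and the acceptance checks).
.fixture_env <- new.env(parent = emptyenv())

recovery_fixture <- function() {
  if (!is.null(.fixture_env$recovery)) return(.fixture_env$recovery)
  sim <- simulate_participant(scanpath_config(n_trials = 70), seed = 11)
  ev <- sim$events
  samp <- round(ev$onset * 250) + 1L
  md <- build_mass_design(ev, default_model_formula())
  xd <- time_expand(md, samp, c(-0.2, 0.5), 250, sim$eeg$n_samples)
  betas <- fit_deconvolution(sim$eeg, xd,
                             channels = c("O1", "O2", "P3", "F3"))
  frp <- baseline_correct(reconstruct_marginal_frps(betas))
  truth_frp <- baseline_correct(true_marginal_waveforms(sim$truth,
                                                        sim$montage))
  naive <- baseline_correct(fixation_locked_average(
    sim$eeg, sim$event_samples, as.character(sim$fixations$category)))
  .fixture_env$recovery <- list(sim = sim, design = xd, betas = betas,
                                frp = frp, truth_frp = truth_frp,
                                naive = naive)
  .fixture_env$recovery
}

# Kernel-recovery error metrics on the occipital reference channel.
recovery_metrics <- function(fx) {
  cats <- c("precursor", "refixation", "ordinary")
  per_cat <- lapply(cats, function(cg) {
    tru <- fx$truth_frp$waves[[cg]]["O1", ]
    est <- fx$frp$waves[[cg]]["O1", ]
    nav <- fx$naive$waves[[cg]]["O1", ]
    list(nrmse = sqrt(mean((est - tru)^2)) / (max(tru) - min(tru)),
         rmse_deconv = sqrt(mean((est - tru)^2)),
         rmse_naive = sqrt(mean((nav - tru)^2)))
  })
  names(per_cat) <- cats
  pooled_deconv <- sqrt(mean(vapply(per_cat, function(z) z$rmse_deconv^2, 0)))
  pooled_naive <- sqrt(mean(vapply(per_cat, function(z) z$rmse_naive^2, 0)))
  lw <- which(fx$frp$times >= 0.2 - 1e-9 & fx$frp$times < 0.4 - 1e-9)
  occ <- c("O1", "O2")
  offset <- mean(fx$frp$waves$precursor[occ, lw] -
                   fx$frp$waves$ordinary[occ, lw])
  list(per_cat = per_cat, pooled_deconv = pooled_deconv,
       pooled_naive = pooled_naive, ratio = pooled_naive / pooled_deconv,
       offset = offset,
       offset_true = fx$sim$truth$late_window_offset)
}
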