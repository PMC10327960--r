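#' Repeated-measures ANOVA with Huynh-Feldt sphericity correction
#'
#' Classical within-subject decomposition for fully crossed designs with one
#' to three within-subject factors and one observation per participant and
#' cell. For every main effect and interaction, the effect is projected onto
#' orthonormal contrasts; the effect and error sums of squares, the F ratio
#' and the uncorrected p value follow from the projected scores. Sphericity
#' is handled by the Huynh-Feldt epsilon, obtained from the
#' Greenhouse-Geisser epsilon of the effect's contrast covariance via
#' \deqn{\epsilon_{HF} = \frac{n d \epsilon_{GG} - 2}{d (n - 1 - d
#' \epsilon_{GG})}}{eHF = (n*d*eGG - 2) / (d*(n - 1 - d*eGG))}
#' capped at 1 (d = numerator degrees of freedom, n = participants). The
#' correction multiplies both degrees of freedom; it is applied only to
#' effects with two or more numerator degrees of freedom (epsilon is forced
#' to 1 otherwise).
#'
#' @param data long-format data.frame with one row per participant x cell.
#' @param factors character vector of 1-3 within-subject factor columns.
#' @param dv name of the dependent-variable column.
#' @param participant name of the participant column.
#' @return object of class \code{rm_anova}: a data.frame with one row per
#'   effect (\code{effect}, \code{df_num}, \code{df_den}, \code{F},
#'   \code{p_uncorrected}, \code{epsilon_HF}, \code{p_corrected}), carrying
#'   the cell array and factor structure as attributes for post hoc tests.
#' @export
rm_anova <- function(data, factors, dv = "value",
                     participant = "participant") {
  stopifnot(is.data.frame(data), length(factors) >= 1, length(factors) <= 3)
  miss <- setdiff(c(factors, dv, participant), names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  fs <- lapply(factors, function(nm) factor(data[[nm]]))
  names(fs) <- factors
  subj <- factor(data[[participant]])
  cnt <- tapply(data[[dv]], c(list(subj), fs), length)
  if (anyNA(cnt))
    stop("missing cells: the design must be complete and balanced")
  if (any(cnt != 1L))
    stop("duplicated participant x cell combinations")
  Y <- tapply(data[[dv]], c(list(subj), fs), mean)
  k <- vapply(fs, nlevels, 1L)
  n <- nlevels(subj)
  Ymat <- matrix(as.numeric(Y), n, prod(k))  # factor 1 varies fastest
  res <- rm_anova_cells(Ymat, k, effect_names = factors)
  attr(res, "cells") <- Y
  attr(res, "levels") <- lapply(fs, levels)
  attr(res, "n_subjects") <- n
  res
}

# Core decomposition on an n x prod(k) cell matrix (first factor fastest).
rm_anova_cells <- function(Ymat, k, effect_names = paste0("f", seq_along(k))) {
  n <- nrow(Ymat)
  if (n < 2) stop("need at least 2 participants")
  m <- length(k)
  Qs <- lapply(k, orth_contrasts)
  ones <- lapply(k, function(kk) matrix(1 / sqrt(kk), kk, 1))

  rows <- list()
  details <- list()
  subsets <- unlist(lapply(seq_len(m), function(sz)
    utils::combn(m, sz, simplify = FALSE)), recursive = FALSE)
  for (E in subsets) {
    C <- matrix(1, 1, 1)
    for (f in seq_len(m)) {           # kron right-to-left: factor 1 fastest
      Cf <- if (f %in% E) Qs[[f]] else ones[[f]]
      C <- Cf %x% C
    }
    Z <- Ymat %*% C
    d <- ncol(Z)
    zbar <- colMeans(Z)
    ss_eff <- n * sum(zbar^2)
    S <- stats::cov(Z)
    ss_err <- (n - 1) * sum(diag(S))
    df_err <- (n - 1) * d
    Fv <- (ss_eff / d) / (ss_err / df_err)
    p_unc <- stats::pf(Fv, d, df_err, lower.tail = FALSE)
    if (d >= 2) {
      tr <- sum(diag(S))
      gg <- tr^2 / (d * sum(S^2))
      hf <- min(1, (n * d * gg - 2) / (d * (n - 1 - d * gg)))
      eps <- max(hf, gg)               # HF never below GG; cap at 1 above
      eps <- min(1, eps)
      p_cor <- stats::pf(Fv, eps * d, eps * df_err, lower.tail = FALSE)
    } else {
      eps <- 1
      p_cor <- p_unc
    }
    nm <- paste(effect_names[E], collapse = ":")
    rows[[nm]] <- data.frame(effect = nm, df_num = d, df_den = df_err,
                             F = Fv, p_uncorrected = p_unc,
                             epsilon_HF = eps, p_corrected = p_cor)
    details[[nm]] <- list(factors = E, d = d, ms_err = ss_err / df_err,
                          q_cells = prod(k) / prod(k[E]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rm_anova", "data.frame")
  attr(out, "k") <- k
  attr(out, "effect_details") <- details
  attr(out, "Ymat") <- Ymat
  attr(out, "effect_names") <- effect_names
  out
}

# Orthonormal contrasts spanning the complement of the constant vector.
orth_contrasts <- function(k) {
  qr.Q(qr(cbind(rep(1, k), stats::contr.helmert(k))))[, -1, drop = FALSE]
}

#' @export
print.rm_anova <- function(x, ...) {
  df <- as.data.frame(x)
  df$F <- round(df$F, 3)
  df$epsilon_HF <- round(df$epsilon_HF, 3)
  df$p_uncorrected <- signif(df$p_uncorrected, 3)
  df$p_corrected <- signif(df$p_corrected, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Newman-Keuls stepwise post hoc test
#'
#' Stepwise studentized-range comparisons on the (marginal or interaction)
#' cell means of a fitted repeated-measures ANOVA. Means are ranked; the
#' range statistic of a pair spanning r ordered means is referred to the
#' studentized-range distribution with parameter r and the error degrees of
#' freedom of the effect. Ranges are tested outside-in, and a nonsignificant
#' range gates all ranges nested inside it (their p values are monotonized
#' against the enclosing range and they are declared nonsignificant). The
#' error term is the effect's participant-by-effect mean square, on the
#' scale of means averaged over the effect's complementary cells.
#'
#' @param fit an \code{rm_anova} object.
#' @param effect effect name as printed in the fit (e.g. \code{"category"}
#'   or \code{"category:region"}).
#' @param alpha significance level for the stepwise gating.
#' @return data.frame of pairwise comparisons: levels, mean difference,
#'   span, critical range at \code{alpha}, p value (gated), significance.
#' @export
newman_keuls <- function(fit, effect, alpha = 0.05) {
  stopifnot(inherits(fit, "rm_anova"))
  details <- attr(fit, "effect_details")
  if (!effect %in% names(details)) stop("unknown effect: ", effect)
  det <- details[[effect]]
  k <- attr(fit, "k")
  Ymat <- attr(fit, "Ymat")
  n <- nrow(Ymat)
  if (n < 2) stop("need at least 2 participants")

  # cell means of the effect, averaged over complementary factors
  m <- length(k)
  idx <- arrayInd(seq_len(prod(k)), k)
  grp <- apply(idx[, det$factors, drop = FALSE], 1, paste, collapse = ".")
  means <- tapply(colMeans(Ymat), grp, mean)
  lev_names <- effect_level_names(fit, det$factors)
  names(means) <- lev_names[match(names(means), names(lev_names))]

  q_cells <- det$q_cells
  se_mean <- sqrt(det$ms_err / q_cells / n)   # SE unit of one mean
  df_err <- (n - 1) * det$d

  ord <- order(means)
  ms <- means[ord]
  kk <- length(ms)
  pairs <- list()
  for (i in seq_len(kk - 1L)) for (j in seq.int(i + 1L, kk)) {
    span <- j - i + 1L
    diffv <- ms[j] - ms[i]
    qv <- abs(diffv) / se_mean
    p <- stats::ptukey(qv, span, df_err, lower.tail = FALSE)
    crit <- stats::qtukey(1 - alpha, span, df_err) * se_mean
    pairs[[length(pairs) + 1L]] <- data.frame(
      level_low = names(ms)[i], level_high = names(ms)[j],
      i = i, j = j, span = span, difference = unname(diffv),
      critical_range = crit, p = p)
  }
  tab <- do.call(rbind, pairs)
  tab <- tab[order(-tab$span, tab$i), ]
  # stepwise gating: a nonsignificant range blocks everything nested in it
  tab$significant <- FALSE
  blocked <- matrix(FALSE, kk, kk)
  for (r in seq_len(nrow(tab))) {
    i <- tab$i[r]; j <- tab$j[r]
    if (blocked[i, j]) {
      encl <- which(tab$i <= i & tab$j >= j & (tab$i != i | tab$j != j))
      if (length(encl)) tab$p[r] <- max(tab$p[r], max(tab$p[encl]))
      tab$significant[r] <- FALSE
      ii <- seq.int(i, j)
      blocked[ii, ii] <- TRUE
      next
    }
    sig <- tab$p[r] <= alpha
    tab$significant[r] <- sig
    if (!sig) {
      ii <- seq.int(i, j)
      blocked[ii, ii] <- TRUE
    }
  }
  tab$i <- NULL; tab$j <- NULL
  rownames(tab) <- NULL
  tab
}

effect_level_names <- function(fit, which_factors) {
  k <- attr(fit, "k")
  levs <- attr(fit, "levels")
  enames <- attr(fit, "effect_names")
  grid <- do.call(expand.grid, lapply(k[which_factors], seq_len))
  keys <- apply(grid, 1, paste, collapse = ".")
  labs <- apply(grid, 1, function(g) {
    paste(vapply(seq_along(which_factors), function(t) {
      f <- which_factors[t]
      if (!is.null(levs)) levs[[f]][g[t]]
      else paste0(enames[f], g[t])
    }, ""), collapse = ":")
  })
  stats::setNames(labs, keys)
}

#' Type-I error of the corrected category test under a null
#'
#' Monte-Carlo calibration: single within-subject factor, compound-symmetric
#' null data (participant random intercept plus white noise, no effect);
#' reports the rejection rate of the Huynh-Feldt-corrected p value.
#'
#' @param n_subjects,n_levels design size.
#' @param n_reps Monte-Carlo replicates.
#' @param sd_subject,sd_noise standard deviations of the random intercept
#'   and the cell noise.
#' @param alpha nominal level.
#' @param seed RNG seed.
#' @return list: \code{rate}, \code{n_reps}, \code{alpha}.
#' @export
anova_type1_sim <- function(n_subjects = 21, n_levels = 3, n_reps = 2000,
                            sd_subject = 1, sd_noise = 1, alpha = 0.05,
                            seed = 1) {
  set.seed(seed)
  hits <- 0L
  for (r in seq_len(n_reps)) {
    Y <- matrix(stats::rnorm(n_subjects * n_levels, sd = sd_noise),
                n_subjects, n_levels) +
      stats::rnorm(n_subjects, sd = sd_subject)
    fit <- rm_anova_cells(Y, n_levels)
    if (fit$p_corrected[1] < alpha) hits <- hits + 1L
  }
  list(rate = hits / n_reps, n_reps = n_reps, alpha = alpha)
}

#' Power of the group-level category test for a configured precursor effect
#'
#' Monte-Carlo power of the fixation-category main effect in the late-window
#' repeated-measures ANOVA (category x region x hemisphere), with
#' window measures drawn from the generator's group-level model (see
#' [simulate_group_measures()]): the configured precursor late-window offset
#' scaled by the region topography, participant and participant-by-category
#' random effects, and measurement noise.
#'
#' @param truth a ground-truth preset from [make_default_truth()]; its
#'   \code{late_window_offset} and \code{group} block parameterize the
#'   simulation. Pass the \code{"null"} preset for a type-I check of the
#'   full three-factor design.
#' @param n_subjects virtual participants per replicate.
#' @param n_reps replicates.
#' @param alpha nominal level applied to the corrected p value.
#' @param seed RNG seed.
#' @return list: \code{power} (rejection rate of the category main effect),
#'   \code{n_reps}, \code{effect} (the offset used).
#' @export
category_power_sim <- function(truth, n_subjects = 21, n_reps = 200,
                               alpha = 0.05, seed = 1) {
  set.seed(seed)
  hits <- 0L
  for (r in seq_len(n_reps)) {
    meas <- simulate_group_measures(truth, n_subjects)
    fit <- rm_anova(meas, c("category", "region", "hemisphere"))
    p <- fit$p_corrected[fit$effect == "category"]
    if (p < alpha) hits <- hits + 1L
  }
  list(power = hits / n_reps, n_reps = n_reps,
       effect = truth$late_window_offset)
}
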