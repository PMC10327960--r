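fix_df <- function(x, y, trial = 1, dur = 0.25, gap = 0.05) {
  n <- length(x)
  data.frame(trial = trial, onset = (seq_len(n) - 1) * (dur + gap),
             duration = dur, x = x, y = y)
}

test_that("worked scanpath geometry labels precursor/other/refixation", {
  # fixations 3 and 5 each within 2 deg of fixation 1; all other pairs apart
  f <- fix_df(x = c(0, 5, 0.5, 10, -0.5), y = c(0, 5, 0.5, 10, 0.5))
  lab <- label_fixations(f)
  expect_equal(as.character(lab$category),
               c("precursor", "other", "refixation", "other", "refixation"))
  expect_equal(lab$linked_precursor_rank, c(NA, NA, 1L, NA, 1L))
  # without pre-refixation removal the interposed fixations stay ordinary
  lab2 <- label_fixations(f, drop_pre_refixation = FALSE)
  expect_equal(as.character(lab2$category),
               c("precursor", "ordinary", "refixation", "ordinary",
                 "refixation"))
  # merged-reference relabeling
  lab3 <- label_fixations(f, merge_ordinary_other = TRUE)
  expect_equal(levels(lab3$category),
               c("ordinary_other", "precursor", "refixation"))
  expect_equal(as.character(lab3$category),
               c("precursor", "ordinary_other", "refixation",
                 "ordinary_other", "refixation"))
})

test_that("isolated fixations are ordinary; same-spot chains go to other", {
  f <- fix_df(x = c(0, 5, 10, 15, 20), y = rep(0, 5))
  expect_equal(as.character(label_fixations(f)$category), rep("ordinary", 5))
  # three consecutive fixations within the radius of each other, then leave
  f2 <- fix_df(x = c(0, 0.5, 1.0, 10), y = rep(0, 4))
  expect_equal(as.character(label_fixations(f2)$category),
               c("other", "other", "other", "ordinary"))
})

test_that("returns without leaving the region are not refixations", {
  # gaze hovers near fixation 1 for fixations 2-3 (never leaves), then leaves
  f <- fix_df(x = c(0, 1.0, 0.3, 8, 0.2), y = rep(0, 5))
  lab <- label_fixations(f)
  # fixation 5 re-enters after leaving -> refixation; 2,3 are chain members
  expect_equal(as.character(lab$category)[5], "refixation")
  expect_true(all(as.character(lab$category)[2:3] == "other"))
})

test_that("labels match the brute-force pair-enumeration oracle", {
  set.seed(101)
  for (rep in 1:400) {
    n <- sample(3:30, 1)
    f <- random_scanpath_df(n, box = stats::runif(1, 2.5, 8))
    drop_pre <- rep %% 2 == 0
    lab <- label_fixations(f, drop_pre_refixation = drop_pre)
    expect_equal(as.character(lab$category),
                 oracle_label_trial(f$x, f$y, 2, drop_pre))
  }
})

test_that("labeling invariants hold on random scanpaths", {
  set.seed(202)
  for (rep in 1:100) {
    f <- random_scanpath_df(sample(5:30, 1), box = 5)
    lab <- label_fixations(f)
    tab <- table(lab$category)
    expect_equal(sum(tab), nrow(f))                       # partition
    expect_gte(tab[["refixation"]], 0)
    expect_gte(tab[["refixation"]], tab[["precursor"]] * 0)  # defined
    # refixations outnumber (or equal) precursors: shared precursors only
    expect_gte(tab[["refixation"]], tab[["precursor"]])
    d <- as.matrix(dist(cbind(f$x, f$y)))
    for (j in which(lab$category == "refixation")) {
      expect_true(any(d[j, seq_len(j - 1)] < 2))          # has an origin
      expect_gte(d[j, j - 1], 2)                          # region was left
    }
    # determinism
    lab2 <- label_fixations(f)
    expect_identical(lab$category, lab2$category)
  }
})

test_that("malformed fixation tables are rejected", {
  f <- fix_df(x = c(0, 5, 10), y = rep(0, 3))
  expect_error(label_fixations(f[c(2, 1, 3), ]), "sorted")
  f_overlap <- f
  f_overlap$duration[1] <- 0.5   # runs past the next onset
  expect_error(label_fixations(f_overlap), "overlap")
  f_bad <- f; f_bad$x[2] <- NA
  expect_error(label_fixations(f_bad), "finite")
})

test_that("covariates link saccades and respect the following-category rule", {
  f <- fix_df(x = c(0, 3, 0.4), y = c(0, 4, 0.3))
  f$x[2] <- 3; # fixation 3 returns near fixation 1
  lab <- label_fixations(f, drop_pre_refixation = FALSE)
  sac <- saccades_from_fixations(lab)
  cov <- compute_covariates(lab, sac)
  expect_equal(cov$fixation_rank, 1:3)
  expect_equal(cov$incoming_saccade_size[2],
               sqrt((3 - 0)^2 + (4 - 0)^2))
  expect_true(is.na(cov$incoming_saccade_size[1]))
  expect_true(is.na(cov$outgoing_saccade_size[3]))
  # next fixation is a refixation -> following duration withheld
  expect_equal(as.character(lab$category)[3], "refixation")
  expect_true(is.na(cov$following_fixation_duration[2]))
  # next fixation ordinary -> recorded
  f2 <- fix_df(x = c(0, 5, 10), y = rep(0, 3))
  lab2 <- label_fixations(f2)
  cov2 <- compute_covariates(lab2, saccades_from_fixations(lab2))
  expect_equal(cov2$following_fixation_duration[1], f2$duration[2])
  # imputation fills the trial edges at the median
  imp <- impute_covariates(cov2)
  expect_false(anyNA(imp$incoming_saccade_size))
  expect_equal(imp$incoming_saccade_size[1],
               median(cov2$incoming_saccade_size, na.rm = TRUE))
})

test_that("summaries count categories and intervening fixations", {
  # precursor at rank 1, refixation at rank 11 -> 9 intervening
  x <- c(0, seq(5, 45, by = 5), 0.3)
  f <- fix_df(x = x, y = rep(0, 11))
  lab <- label_fixations(f)
  cov <- compute_covariates(lab, saccades_from_fixations(lab))
  s <- summarize_eye_movements(lab, cov)
  expect_equal(s$revisits$mean_intervening, 9)
  expect_equal(s$revisits$n_pairs, 1)
  counts <- setNames(s$categories$n, s$categories$category)
  expect_equal(sum(counts), 11)
  # all-ordinary input: zero precursor/refixation counts, NA means
  f2 <- fix_df(x = seq(0, 40, by = 10), y = rep(0, 5))
  lab2 <- label_fixations(f2)
  s2 <- summarize_eye_movements(lab2,
                                compute_covariates(lab2,
                                  saccades_from_fixations(lab2)))
  c2 <- setNames(s2$categories$n, s2$categories$category)
  expect_equal(unname(c2[c("precursor", "refixation")]), c(0L, 0L))
  expect_true(is.na(s2$categories$mean_duration[
    s2$categories$category == "precursor"]))
})

test_that("event tables round-trip through the documented CSV format", {
  f <- fix_df(x = c(0, 5, 0.5), y = rep(0, 3))
  lab <- label_fixations(f)
  path <- tempfile(fileext = ".csv")
  write_labeled_fixations(lab, path)
  back <- read_fixation_table(path)
  expect_equal(back$x, lab$x)
  expect_equal(back$onset, lab$onset)
  # pixel conversion
  path2 <- tempfile(fileext = ".csv")
  write.csv(data.frame(trial = 1, onset_s = 0, duration_s = 0.2,
                       x_px = 150, y_px = -75), path2, row.names = FALSE)
  px <- read_fixation_table(path2, px_per_deg = 30)
  expect_equal(px$x, 5)
  expect_equal(px$y, -2.5)
})
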