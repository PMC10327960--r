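#' Categorize fixations of free-viewing scanpaths by revisit structure
#'
#' Assigns each fixation of each trial to one of four categories used in
#' refixation research:
#' \describe{
#'   \item{\code{refixation}}{a fixation landing within \code{radius} degrees
#'     of an earlier fixation of the same trial, after the gaze had left that
#'     earlier fixation's region (at least one intervening fixation outside
#'     the radius), and entering the region from outside (its immediate
#'     predecessor is not within the radius).}
#'   \item{\code{precursor}}{the earliest fixation an eventual refixation
#'     returns to. When a refixation is within the radius of several
#'     mutually close earlier fixations it is scored once and attributed to
#'     the earliest qualifying one.}
#'   \item{\code{ordinary}}{a fixation at a location visited exactly once:
#'     no other fixation of the trial lies within the radius.}
#'   \item{\code{other}}{everything else. This includes members of chains of
#'     consecutive fixations on the same spot (which qualify equally as
#'     refixation of the previous and precursor of the next fixation),
#'     non-first returns of a refixation chain, fixations that would carry
#'     both a precursor and a refixation label (neither is kept), revisited
#'     locations whose precursor role was not attributed, and -- when
#'     \code{drop_pre_refixation} is \code{TRUE} -- fixations immediately
#'     preceding a refixation, which carry preparatory EEG activity and are
#'     therefore reassigned (never deleted: every fixation must stay in the
#'     deconvolution model).}
#' }
#'
#' The distance criterion is strict (\code{< radius}) on the Euclidean
#' distance between fixation mean positions in degrees of visual angle.
#'
#' @param fixations data.frame with columns \code{trial}, \code{onset}
#'   (seconds), \code{duration} (seconds), \code{x}, \code{y} (degrees), and
#'   optionally \code{rank} (1-based order within trial; derived when absent)
#'   and \code{participant}. Must be sorted by trial and onset, without
#'   overlapping fixation intervals.
#' @param radius revisit radius in degrees of visual angle (default 2).
#' @param drop_pre_refixation reassign the fixation immediately preceding each
#'   refixation to \code{"other"} (default \code{TRUE}).
#' @param merge_ordinary_other relabel \code{ordinary} and \code{other} into a
#'   single \code{"ordinary_other"} level (the merged-reference model).
#' @return the input data.frame with columns \code{rank}, \code{category}
#'   (factor) and \code{linked_precursor_rank} (for refixations, the rank of
#'   the attributed precursor fixation) added.
#' @export
label_fixations <- function(fixations, radius = 2, drop_pre_refixation = TRUE,
                            merge_ordinary_other = FALSE) {
  stopifnot(is.data.frame(fixations), radius > 0)
  req <- c("trial", "onset", "duration", "x", "y")
  miss <- setdiff(req, names(fixations))
  if (length(miss))
    stop("fixation table lacks columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(fixations$x)) || any(!is.finite(fixations$y)))
    stop("fixation positions must be finite")
  if (any(fixations$duration <= 0)) stop("fixation durations must be > 0")

  fixations <- validate_fixation_order(fixations)
  out_cat <- character(nrow(fixations))
  out_link <- rep(NA_integer_, nrow(fixations))

  for (tr in split(seq_len(nrow(fixations)), trial_key(fixations))) {
    lab <- label_trial_scanpath(fixations$x[tr], fixations$y[tr], radius,
                                drop_pre_refixation)
    out_cat[tr] <- lab$category
    out_link[tr] <- lab$linked_precursor
  }

  if (merge_ordinary_other) {
    out_cat[out_cat %in% c("ordinary", "other")] <- "ordinary_other"
    lev <- c("ordinary_other", "precursor", "refixation")
  } else {
    lev <- c("other", "precursor", "refixation", "ordinary")
  }
  fixations$category <- factor(out_cat, levels = lev)
  fixations$linked_precursor_rank <- out_link
  fixations
}

# Participant-nested trial key used for all per-trial splits.
trial_key <- function(df) {
  if (!is.null(df$participant)) paste(df$participant, df$trial, sep = "\r")
  else as.character(df$trial)
}

# Rank bookkeeping + ordering checks shared by labeling and covariates.
validate_fixation_order <- function(fixations) {
  key <- trial_key(fixations)
  ord <- order(factor(key, levels = unique(key)), fixations$onset)
  if (any(ord != seq_along(ord)))
    stop("fixations must be sorted by trial and onset")
  ranks <- unlist(lapply(split(fixations$onset, factor(key, unique(key))),
                         seq_along), use.names = FALSE)
  if (is.null(fixations$rank)) {
    fixations$rank <- ranks
  } else if (any(fixations$rank != ranks)) {
    stop("fixation ranks must be consecutive from 1 within each trial, in onset order")
  }
  ends <- fixations$onset + fixations$duration
  same <- utils::head(key, -1) == utils::tail(key, -1)
  overlap <- utils::tail(fixations$onset, -1) < utils::head(ends, -1) - 1e-12
  if (any(same & overlap))
    stop("overlapping fixation intervals within a trial")
  fixations
}

# Core per-trial labeler (positions in degrees). Returns category strings and,
# for refixations, the index (rank) of the attributed precursor.
label_trial_scanpath <- function(x, y, radius, drop_pre_refixation) {
  n <- length(x)
  if (n == 0L)
    return(list(category = character(0), linked_precursor = integer(0)))
  near <- as.matrix(stats::dist(cbind(x, y))) < radius
  diag(near) <- TRUE

  refix_raw <- logical(n)
  prec_of <- rep(NA_integer_, n)
  for (j in seq_len(n)[-1L]) {
    if (near[j - 1L, j]) next                    # region not entered from outside
    for (i in seq_len(j - 1L)) {
      if (!near[i, j]) next
      if (j - i < 2L) next                       # no room for an intervening fixation
      if (any(!near[i, (i + 1L):(j - 1L)])) {    # gaze left i's region before j
        refix_raw[j] <- TRUE
        prec_of[j] <- i                          # earliest qualifying precursor
        break
      }
    }
  }

  prec_raw <- unique(prec_of[!is.na(prec_of)])
  idx <- seq_len(n)
  dual <- refix_raw & idx %in% prec_raw          # both roles: keep neither
  is_refix <- refix_raw & !dual
  is_prec <- idx %in% prec_raw & !refix_raw
  near_any <- rowSums(near) > 1                  # some *other* fixation within radius

  category <- ifelse(is_refix, "refixation",
              ifelse(is_prec, "precursor",
              ifelse(near_any, "other", "ordinary")))

  if (drop_pre_refixation) {
    pre <- which(is_refix) - 1L
    pre <- pre[pre >= 1L & !is_refix[pre]]
    category[pre] <- "other"
  }
  list(category = category, linked_precursor = prec_of)
}

#' Derive a saccade table from consecutive fixations
#'
#' Builds the incoming/outgoing saccade records linking consecutive fixations
#' of each trial: amplitude is the Euclidean distance between the fixation
#' mean positions (degrees), angle the direction of movement (degrees,
#' counterclockwise from rightward), onset the end of the departing fixation.
#'
#' @param fixations fixation table (see [label_fixations()]).
#' @return data.frame with columns \code{trial}, \code{onset},
#'   \code{amplitude}, \code{angle}, \code{from_rank}, \code{to_rank}.
#' @export
saccades_from_fixations <- function(fixations) {
  fixations <- validate_fixation_order(fixations)
  res <- lapply(split(fixations, factor(trial_key(fixations),
                                        unique(trial_key(fixations)))),
                function(f) {
    n <- nrow(f)
    if (n < 2L) return(NULL)
    dx <- diff(f$x); dy <- diff(f$y)
    out <- data.frame(trial = f$trial[-n],
                      onset = f$onset[-n] + f$duration[-n],
                      amplitude = sqrt(dx^2 + dy^2),
                      angle = atan2(dy, dx) * 180 / pi,
                      from_rank = f$rank[-n],
                      to_rank = f$rank[-1L])
    if (!is.null(f$participant)) out$participant <- f$participant[-n]
    out
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Extract per-fixation oculomotor covariates
#'
#' For each labeled fixation: rank, duration, x/y position, incoming and
#' outgoing saccade size and angle, and the duration of the immediately
#' following fixation. The following-fixation duration is recorded only when
#' that fixation belongs to the \code{ordinary} or \code{other} (or merged
#' \code{ordinary_other}) category; otherwise it is \code{NA}. Covariates
#' without a defining saccade (first/last fixation of a trial) are \code{NA};
#' [impute_covariates()] fills them at the participant median for modeling.
#'
#' @param fixations labeled fixation table from [label_fixations()].
#' @param saccades saccade table (see [saccades_from_fixations()]).
#' @return data.frame aligned row-for-row with \code{fixations}.
#' @export
compute_covariates <- function(fixations, saccades) {
  if (is.null(fixations$category))
    stop("fixations must be labeled first (see label_fixations)")
  key <- function(df, rank) paste(trial_key(df), rank, sep = "\r")
  s_in <- match(key(fixations, fixations$rank),
                key(saccades, saccades$to_rank))
  s_out <- match(key(fixations, fixations$rank),
                 key(saccades, saccades$from_rank))

  nxt <- match(key(fixations, fixations$rank + 1L),
               key(fixations, fixations$rank))
  nxt_cat <- as.character(fixations$category)[nxt]
  follow_ok <- !is.na(nxt) &
    nxt_cat %in% c("ordinary", "other", "ordinary_other")

  out <- data.frame(
    trial = fixations$trial,
    fixation_rank = fixations$rank,
    fixation_duration = fixations$duration,
    incoming_saccade_size = saccades$amplitude[s_in],
    outgoing_saccade_size = saccades$amplitude[s_out],
    incoming_saccade_angle = saccades$angle[s_in],
    outgoing_saccade_angle = saccades$angle[s_out],
    x_position = fixations$x,
    y_position = fixations$y,
    following_fixation_duration =
      ifelse(follow_ok, fixations$duration[nxt], NA_real_)
  )
  if (!is.null(fixations$participant)) out$participant <- fixations$participant
  out
}

#' Impute absent covariates at the participant median
#'
#' First fixations of a trial have no incoming saccade and last fixations no
#' outgoing saccade; their covariates are imputed at the median of the
#' observed values so every fixation can enter the deconvolution model.
#'
#' @param covariates data.frame from [compute_covariates()].
#' @param columns columns to impute.
#' @return the data.frame with \code{NA}s in \code{columns} replaced.
#' @export
impute_covariates <- function(covariates,
                              columns = c("incoming_saccade_size",
                                          "outgoing_saccade_size")) {
  for (cl in columns) {
    v <- covariates[[cl]]
    if (anyNA(v)) v[is.na(v)] <- stats::median(v, na.rm = TRUE)
    covariates[[cl]] <- v
  }
  covariates
}

#' Per-participant, per-category eye movement summaries
#'
#' Counts and mean oculomotor characteristics per fixation category, and the
#' mean number of intervening fixations between each precursor fixation and
#' its first refixation.
#'
#' @param fixations labeled fixation table (a \code{participant} column is
#'   honored; otherwise a single participant is assumed).
#' @param covariates matching covariate table from [compute_covariates()].
#' @return list with elements \code{categories} (one row per participant x
#'   category: \code{n}, \code{mean_duration}, \code{mean_following_duration},
#'   \code{mean_incoming_size}, \code{mean_outgoing_size}, \code{mean_rank};
#'   means are \code{NA} for empty categories) and \code{revisits} (one row
#'   per participant: \code{n_pairs}, \code{mean_intervening}).
#' @export
summarize_eye_movements <- function(fixations, covariates) {
  if (is.null(fixations$category)) stop("fixations must be labeled first")
  if (nrow(fixations) != nrow(covariates))
    stop("fixations and covariates must align row-for-row")
  if (is.null(fixations$participant)) fixations$participant <- 1L

  lev <- levels(fixations$category)
  mean_or_na <- function(v) if (length(v) && any(!is.na(v)))
    mean(v, na.rm = TRUE) else NA_real_

  cats <- do.call(rbind, lapply(split(seq_len(nrow(fixations)),
                                      fixations$participant), function(ix) {
    do.call(rbind, lapply(lev, function(cg) {
      sel <- ix[fixations$category[ix] == cg]
      data.frame(participant = fixations$participant[ix[1]], category = cg,
                 n = length(sel),
                 mean_duration = mean_or_na(fixations$duration[sel]),
                 mean_following_duration =
                   mean_or_na(covariates$following_fixation_duration[sel]),
                 mean_incoming_size =
                   mean_or_na(covariates$incoming_saccade_size[sel]),
                 mean_outgoing_size =
                   mean_or_na(covariates$outgoing_saccade_size[sel]),
                 mean_rank = mean_or_na(fixations$rank[sel]))
    }))
  }))
  rownames(cats) <- NULL

  revisits <- do.call(rbind, lapply(split(fixations, fixations$participant),
                                    function(f) {
    pairs <- precursor_refixation_pairs(f)
    data.frame(participant = f$participant[1], n_pairs = nrow(pairs),
               mean_intervening = mean_or_na(pairs$intervening))
  }))
  rownames(revisits) <- NULL
  list(categories = cats, revisits = revisits)
}

# Precursor -> first-refixation pairs (only precursors that kept their label).
precursor_refixation_pairs <- function(fixations) {
  res <- lapply(split(fixations, factor(trial_key(fixations),
                                        unique(trial_key(fixations)))),
                function(f) {
    rf <- f[f$category == "refixation" & !is.na(f$linked_precursor_rank), ,
            drop = FALSE]
    if (!nrow(rf)) return(NULL)
    prec_cat <- as.character(f$category[match(rf$linked_precursor_rank, f$rank)])
    rf <- rf[prec_cat == "precursor", , drop = FALSE]
    if (!nrow(rf)) return(NULL)
    first <- rf[!duplicated(rf$linked_precursor_rank), , drop = FALSE]
    data.frame(trial = first$trial,
               precursor_rank = first$linked_precursor_rank,
               refixation_rank = first$rank,
               intervening = first$rank - first$linked_precursor_rank - 1L)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(trial = integer(0), precursor_rank = integer(0),
                      refixation_rank = integer(0), intervening = integer(0))
  rownames(out) <- NULL
  out
}

#' Read / write fixation and saccade report tables
#'
#' Reads tab- or comma-separated event reports with the documented headers
#' \code{trial, onset_s, duration_s, x_deg, y_deg} (fixations) and
#' \code{trial, onset_s, amplitude_deg, angle_deg, from_rank, to_rank}
#' (saccades), compatible with exports derived from EyeLink-style fixation
#' reports. Pixel-based reports (\code{x_px}, \code{y_px}) are converted to
#' degrees when \code{px_per_deg} is given.
#'
#' @param path file path; the delimiter is inferred from the extension
#'   (".tsv"/".txt" tab, otherwise comma).
#' @param px_per_deg optional pixels-per-degree scale for pixel reports.
#' @param origin_px screen origin (pixels) subtracted before conversion.
#' @return data.frame in the package's internal column naming.
#' @export
read_fixation_table <- function(path, px_per_deg = NULL, origin_px = c(0, 0)) {
  d <- read_delim_auto(path)
  if (!is.null(px_per_deg)) {
    d$x_deg <- (d$x_px - origin_px[1]) / px_per_deg
    d$y_deg <- (d$y_px - origin_px[2]) / px_per_deg
  }
  req <- c("trial", "onset_s", "duration_s", "x_deg", "y_deg")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  out <- data.frame(trial = d$trial, onset = d$onset_s,
                    duration = d$duration_s, x = d$x_deg, y = d$y_deg)
  if (!is.null(d$participant)) out$participant <- d$participant
  out
}

#' @rdname read_fixation_table
#' @export
read_saccade_table <- function(path) {
  d <- read_delim_auto(path)
  req <- c("trial", "onset_s", "amplitude_deg", "angle_deg",
           "from_rank", "to_rank")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  data.frame(trial = d$trial, onset = d$onset_s, amplitude = d$amplitude_deg,
             angle = d$angle_deg, from_rank = d$from_rank,
             to_rank = d$to_rank)
}

#' @rdname read_fixation_table
#' @param events labeled fixation table to write (category column included).
#' @export
write_labeled_fixations <- function(events, path) {
  out <- data.frame(trial = events$trial, rank = events$rank,
                    onset_s = events$onset, duration_s = events$duration,
                    x_deg = events$x, y_deg = events$y,
                    category = as.character(events$category))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}
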