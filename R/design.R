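#' Model terms for the deconvolution design
#'
#' A model formula lists, per event type (\code{fixation}, \code{stimulus}),
#' an ordered set of terms: an intercept, a treatment-coded categorical
#' predictor, and/or quantile-knotted B-spline expansions of continuous
#' covariates. [default_model_formula()] builds the standard free-viewing
#' model: fixation events get an intercept, the fixation category
#' (treatment-coded against the leftover \code{"other"} category) and five
#' 5-function spline covariates (fixation rank, fixation duration, incoming
#' and outgoing saccade size, vertical fixation position), for a total of
#' 1 + 3 + 5x4 = 24 fixation predictors; stimulus onsets get an intercept
#' (25 predictors in all).
#'
#' @param name covariate / factor column name in the event table.
#' @param levels,reference category levels and reference level.
#' @param n_basis number of spline basis functions (>= 4; one is dropped for
#'   identifiability in the presence of an intercept).
#' @name model-terms
NULL

#' @rdname model-terms
#' @export
term_intercept <- function() structure(list(kind = "intercept"),
                                       class = "frp_term")

#' @rdname model-terms
#' @export
term_categorical <- function(name, levels, reference = levels[1]) {
  if (!reference %in% levels) stop("reference must be one of the levels")
  structure(list(kind = "categorical", name = name, levels = levels,
                 reference = reference), class = "frp_term")
}

#' @rdname model-terms
#' @export
term_spline <- function(name, n_basis = 5) {
  if (n_basis < 4)
    stop("n_basis must be >= 4 for the cubic B-spline family")
  structure(list(kind = "spline", name = name, n_basis = as.integer(n_basis)),
            class = "frp_term")
}

#' @rdname model-terms
#' @param fixation,stimulus lists of terms per event type.
#' @export
model_formula <- function(fixation, stimulus = list(term_intercept())) {
  chk <- function(terms, what) {
    if (sum(vapply(terms, function(t) t$kind == "intercept", TRUE)) > 1)
      stop("at most one intercept per event type (", what, ")")
    terms
  }
  structure(list(fixation = chk(fixation, "fixation"),
                 stimulus = chk(stimulus, "stimulus")),
            class = "frp_formula")
}

#' @rdname model-terms
#' @param category_levels,category_reference category coding for the default
#'   model; the default matches unmerged labeling output.
#' @export
default_model_formula <- function(category_levels = c("other", "precursor",
                                                      "refixation", "ordinary"),
                                  category_reference = category_levels[1]) {
  model_formula(
    fixation = list(
      term_intercept(),
      term_categorical("category", category_levels, category_reference),
      term_spline("fixation_rank", 5),
      term_spline("fixation_duration", 5),
      term_spline("incoming_saccade_size", 5),
      term_spline("outgoing_saccade_size", 5),
      term_spline("y_position", 5)
    ),
    stimulus = list(term_intercept())
  )
}

#' Quantile-knotted cubic B-spline basis
#'
#' Builds an \code{n_basis}-function cubic B-spline basis whose knots sit on
#' the \code{n_basis - 2} equally spaced quantiles of the fitting sample
#' (probabilities \code{seq(0, 1, length.out = n_basis - 2)}; the outermost
#' quantiles are the data range and are repeated to full cubic multiplicity).
#' Before any column is dropped the basis is a partition of unity at every
#' in-range point; for identifiability next to an intercept the first column
#' is marked for removal, so each covariate contributes \code{n_basis - 1}
#' design columns. Out-of-range values are clamped to the boundary.
#'
#' @param values covariate sample the knots are estimated from.
#' @param n_basis number of basis functions (>= 4).
#' @return an object of class \code{frp_spline_basis}.
#' @export
make_spline_basis <- function(values, n_basis = 5) {
  n_basis <- as.integer(n_basis)
  if (n_basis < 4)
    stop("n_basis must be >= 4 for the cubic B-spline family")
  values <- values[is.finite(values)]
  if (length(unique(values)) < n_basis)
    stop("need at least ", n_basis, " distinct covariate values, got ",
         length(unique(values)))
  probs <- seq(0, 1, length.out = n_basis - 2L)
  kn <- as.numeric(stats::quantile(values, probs, names = FALSE, type = 7))
  if (any(diff(kn) < 0)) stop("knots must be nondecreasing")
  knot_vector <- c(rep(kn[1], 4), kn[-c(1, length(kn))],
                   rep(kn[length(kn)], 4))
  structure(list(n_basis = n_basis, knots = kn,
                 boundary = range(values), knot_vector = knot_vector,
                 dropped_column = 1L),
            class = "frp_spline_basis")
}

#' Evaluate a spline basis
#'
#' @param basis an \code{frp_spline_basis}.
#' @param x points to evaluate at (clamped to the boundary knots).
#' @param drop drop the identifiability column (default \code{TRUE}).
#' @return matrix \code{length(x)} x (\code{n_basis} or \code{n_basis - 1}).
#' @export
eval_spline_basis <- function(basis, x, drop = TRUE) {
  x <- pmin(pmax(x, basis$boundary[1]), basis$boundary[2])
  B <- splines::splineDesign(basis$knot_vector, x, ord = 4, outer.ok = FALSE)
  if (drop) B <- B[, -basis$dropped_column, drop = FALSE]
  B
}

#' Build the mass-univariate design matrix
#'
#' One row per modeling event (fixation onsets and stimulus onsets), one
#' column per predictor: intercepts, treatment-coded category dummies
#' relative to the reference level, and spline columns (with the
#' identifiability column removed). Rows of one event type are zero in the
#' other event type's columns. Spline knots are estimated from the event
#' table itself (participant-specific when called per participant).
#'
#' @param events data.frame with a column \code{event_type}
#'   (\code{"fixation"}/\code{"stimulus"}), \code{onset} (seconds) and the
#'   covariate/factor columns named in the formula. Covariates must be
#'   numeric and complete (see [impute_covariates()]).
#' @param formula an \code{frp_formula}.
#' @return an object of class \code{frp_mass_design}: list with the dense
#'   matrix \code{X} (events x P), per-column descriptors \code{colinfo},
#'   fitted spline \code{bases}, covariate \code{means} over fixation events,
#'   and the formula.
#' @export
build_mass_design <- function(events, formula) {
  stopifnot(inherits(formula, "frp_formula"))
  if (is.null(events$event_type)) stop("events need an event_type column")
  if (!all(events$event_type %in% c("fixation", "stimulus")))
    stop("unknown event types: ",
         paste(setdiff(unique(events$event_type),
                       c("fixation", "stimulus")), collapse = ", "))

  blocks <- list(); info <- list(); bases <- list(); means <- list()
  for (etype in c("fixation", "stimulus")) {
    rows <- events$event_type == etype
    for (term in formula[[etype]]) {
      if (term$kind == "intercept") {
        cols <- matrix(as.numeric(rows), ncol = 1)
        ci <- data.frame(event_type = etype, term = "intercept",
                         name = "(Intercept)", level = NA, basis_index = NA)
      } else if (term$kind == "categorical") {
        v <- as.character(events[[term$name]][rows])
        bad <- setdiff(unique(v), term$levels)
        if (length(bad))
          stop("unknown category level(s): ", paste(bad, collapse = ", "))
        dum <- setdiff(term$levels, term$reference)
        cols <- matrix(0, nrow(events), length(dum))
        for (k in seq_along(dum)) cols[rows, k] <- as.numeric(v == dum[k])
        ci <- data.frame(event_type = etype, term = "categorical",
                         name = term$name, level = dum,
                         basis_index = NA)
      } else {
        v <- events[[term$name]][rows]
        if (anyNA(v)) stop("covariate ", term$name,
                           " has missing values; impute first")
        b <- make_spline_basis(v, term$n_basis)
        bases[[term$name]] <- b
        means[[term$name]] <- mean(v)
        B <- eval_spline_basis(b, v, drop = TRUE)
        cols <- matrix(0, nrow(events), ncol(B))
        cols[rows, ] <- B
        ci <- data.frame(event_type = etype, term = "spline",
                         name = term$name, level = NA,
                         basis_index = seq_len(ncol(B)))
      }
      blocks[[length(blocks) + 1L]] <- cols
      info[[length(info) + 1L]] <- ci
    }
  }
  X <- do.call(cbind, blocks)
  colinfo <- do.call(rbind, info)
  colinfo$col <- seq_len(nrow(colinfo))
  structure(list(X = X, colinfo = colinfo, bases = bases,
                 means = unlist(means), formula = formula,
                 P = ncol(X)),
            class = "frp_mass_design")
}

#' Time-expand a mass design over the continuous recording
#'
#' Replicates every predictor across a grid of time lags around its event so
#' a single linear model spans the continuous EEG. The lag grid follows the
#' half-open sample convention \code{round(t_min * fs) ... round(t_max * fs)
#' - 1}, so a -200 to +500 ms window at 250 Hz yields exactly 175 lags.
#' Column \code{(p, l)} of the result holds the mass-design entry of
#' predictor \code{p} placed at \code{event_sample + lag_l}; overlapping
#' events sum. Rows outside the recording are truncated.
#'
#' @param mass an \code{frp_mass_design}.
#' @param event_samples integer sample index (1-based) of each event, aligned
#'   with the mass-design rows; use \code{round(onset * srate) + 1}.
#' @param window lag window in seconds, \code{c(t_min, t_max)}.
#' @param srate sampling rate (Hz).
#' @param n_samples number of samples of the continuous recording.
#' @return an object of class \code{frp_expanded_design}: sparse matrix
#'   \code{X} (\code{n_samples} x \code{P * L}) plus lag metadata.
#' @export
time_expand <- function(mass, event_samples, window = c(-0.2, 0.5),
                        srate = 250, n_samples) {
  stopifnot(inherits(mass, "frp_mass_design"),
            length(event_samples) == nrow(mass$X),
            window[1] < window[2], srate > 0)
  if (any(event_samples < 1 | event_samples > n_samples))
    stop("event times outside the recording")
  lag0 <- round(window[1] * srate)
  lag1 <- round(window[2] * srate)
  L <- as.integer(lag1 - lag0)
  P <- mass$P

  nz <- which(mass$X != 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) {
    warning("empty design: no events contribute")
    X <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n_samples, P * L))
  } else {
    ev <- nz[, 1L]; pp <- nz[, 2L]; val <- mass$X[nz]
    lags <- lag0:(lag1 - 1L)
    i <- rep(event_samples[ev], each = L) + rep(lags, times = length(ev))
    j <- rep((pp - 1L) * L, each = L) + rep(seq_len(L), times = length(ev))
    x <- rep(val, each = L)
    keep <- i >= 1L & i <= n_samples
    X <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = x[keep],
                              dims = c(n_samples, P * L))
  }
  structure(list(X = X, mass = mass, L = L, lag0 = as.integer(lag0),
                 srate = srate, window = window, n_samples = n_samples,
                 lag_times = (lag0:(lag1 - 1L)) / srate,
                 zeroed = list()),
            class = "frp_expanded_design")
}

#' Exclude recording intervals by zeroing design rows
#'
#' Sets all entries of the listed sample ranges to zero so the corresponding
#' EEG samples have no influence on the fit, while preserving the timing of
#' the continuous recording (dimensions unchanged).
#'
#' @param expanded an \code{frp_expanded_design}.
#' @param intervals list of \code{c(from, to)} sample ranges (1-based,
#'   inclusive) or a 2-column matrix.
#' @return the design with the rows zeroed and the intervals recorded.
#' @export
zero_out_intervals <- function(expanded, intervals) {
  stopifnot(inherits(expanded, "frp_expanded_design"))
  if (is.matrix(intervals))
    intervals <- lapply(seq_len(nrow(intervals)),
                        function(k) intervals[k, ])
  keep <- rep(1, expanded$n_samples)
  for (iv in intervals) {
    if (length(iv) != 2 || iv[1] > iv[2]) stop("inverted or malformed interval")
    if (iv[1] < 1 || iv[2] > expanded$n_samples)
      stop("interval outside the recording")
    keep[iv[1]:iv[2]] <- 0
  }
  expanded$X <- Matrix::Diagonal(x = keep) %*% expanded$X
  expanded$X <- methods::as(Matrix::drop0(expanded$X), "CsparseMatrix")
  expanded$zeroed <- c(expanded$zeroed, intervals)
  expanded
}

#' Export an expanded design as sparse triplets (debugging aid)
#'
#' Writes the nonzero entries as a \code{row,col,value} CSV.
#'
#' @param expanded an \code{frp_expanded_design}.
#' @param path output file.
#' @export
write_design_triplets <- function(expanded, path) {
  T3 <- Matrix::summary(methods::as(expanded$X, "TsparseMatrix"))
  utils::write.csv(data.frame(row = T3$i, col = T3$j, value = T3$x),
                   path, row.names = FALSE)
  invisible(path)
}

# Column indices of expanded columns belonging to mass predictor p.
expanded_cols <- function(expanded, p) {
  (p - 1L) * expanded$L + seq_len(expanded$L)
}
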