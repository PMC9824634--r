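# Leave-one-fixation-out person identification: distance table between
# held-out test segments and persons, and greedy assignment with L1 row
# renormalization.

#' Person-by-test-segment distance table
#'
#' Cell `(r, c)` is the sum of segment distances between test segment `r`
#' and each of person `c`'s training segments. All features must be on the
#' training-derived normalization.
#'
#' @param train List of persons, each a list of segment feature matrices
#'   (the held-out fixation removed).
#' @param tests List of test segment feature matrices.
#' @param w Weight vector of length 91.
#' @param method,trim Segment distance selection (see [seg_dist_d3()]).
#' @return Numeric matrix, rows = test segments, columns = persons.
#' @export
distance_table <- function(train, tests, w, method = "d3", trim = 0.9) {
  if (!length(train) || !length(tests)) stop("train and tests must be non-empty")
  if (any(vapply(train, length, integer(1)) == 0L))
    stop("every training person needs at least one segment")
  d <- seg_dist_fn(method, trim)
  train <- lapply(train, function(p) lapply(p, as_feature_matrix))
  tests <- lapply(tests, as_feature_matrix)
  tab <- matrix(0, length(tests), length(train))
  for (r in seq_along(tests)) for (c in seq_along(train)) {
    tab[r, c] <- sum(vapply(train[[c]], function(Tseg)
      d(Tseg, tests[[r]], w), numeric(1)))
  }
  rownames(tab) <- names(tests) %||% paste0("S", seq_along(tests))
  colnames(tab) <- names(train) %||% paste0("P", seq_along(train))
  tab
}

#' Greedy assignment with L1 row renormalization
#'
#' The first pick takes the globally smallest cell of the raw table; its row
#' and column are removed. Each subsequent round first divides every
#' remaining row by its sum (L1 normalization; all-zero rows are kept as
#' they are) and then picks the smallest cell, until the table is exhausted.
#' Ties break to the lowest row index, then the lowest column index.
#'
#' @param tab Square numeric matrix with nonnegative finite entries
#'   (rows = test segments, columns = persons).
#' @return List of class `msacc_assignment`: `pairs` (data frame `test`,
#'   `person` in pick order), `n_correct` (same-index matches) and
#'   `accuracy`.
#' @export
greedy_assign <- function(tab) {
  if (!is.matrix(tab) || nrow(tab) != ncol(tab))
    stop("assignment requires a square distance table")
  if (any(!is.finite(tab)) || any(tab < 0))
    stop("distance table entries must be finite and nonnegative")
  n <- nrow(tab)
  if (is.null(rownames(tab))) rownames(tab) <- paste0("S", seq_len(n))
  if (is.null(colnames(tab))) colnames(tab) <- paste0("P", seq_len(n))
  rows_left <- seq_len(n); cols_left <- seq_len(n)
  picks_r <- integer(0); picks_c <- integer(0)
  cur <- tab
  first <- TRUE
  while (length(rows_left) > 0L) {
    if (!first) {
      sums <- rowSums(cur)
      norm <- ifelse(sums > 0, sums, 1)
      cur <- cur / norm
    }
    # lowest value; ties -> lowest row index, then lowest column index
    best <- which(cur == min(cur), arr.ind = TRUE)
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
    picks_r <- c(picks_r, rows_left[best[1L]])
    picks_c <- c(picks_c, cols_left[best[2L]])
    rows_left <- rows_left[-best[1L]]
    cols_left <- cols_left[-best[2L]]
    cur <- cur[-best[1L], -best[2L], drop = FALSE]
    first <- FALSE
  }
  pairs <- data.frame(test = rownames(tab)[picks_r],
                      person = colnames(tab)[picks_c])
  n_correct <- sum(picks_r == picks_c)
  structure(list(pairs = pairs, n_correct = n_correct, accuracy = n_correct / n),
            class = "msacc_assignment")
}

#' @export
print.msacc_assignment <- function(x, ...) {
  cat("<msacc_assignment>\n")
  print(x$pairs)
  cat(sprintf("accuracy: %d/%d\n", x$n_correct, nrow(x$pairs)))
  invisible(x)
}

#' Leave-one-fixation-out identification
#'
#' For every person the segment of the held-out fixation becomes test data;
#' the remaining segments train the system. Feature scales (unit-vector
#' normalization) are derived from the training events only and applied to
#' the test events; weights are either supplied or learned on the training
#' split by [multi_start()].
#'
#' @param fcohort List of persons, each a list of (unnormalized) segment
#'   feature matrices; every person must have the held-out index.
#' @param holdout Index of the held-out fixation (default: the last).
#' @param w Optional weight vector; if NULL, learned on the training split.
#' @param method,trim Segment distance selection.
#' @param n_starts,base_seed,... Passed to [multi_start()] when learning.
#' @return List: `assignment`, `accuracy`, `table`, `w`, `scales`, and
#'   `opt` (the multi-start result when weights were learned).
#' @export
loo_evaluate <- function(fcohort, holdout = NULL, w = NULL,
                         method = "d3", trim = 0.9,
                         n_starts = 30, base_seed = 1, ...) {
  fcohort <- lapply(fcohort, function(p) lapply(p, as_feature_matrix))
  n_seg <- vapply(fcohort, length, integer(1))
  if (is.null(holdout)) holdout <- n_seg[1L]
  if (any(n_seg < holdout)) stop("a person is missing the held-out fixation")
  split <- split_holdout(fcohort, holdout)
  opt <- NULL
  if (is.null(w)) {
    f <- make_err_fn(split$train, method, trim)
    opt <- multi_start(f, n_starts = n_starts, base_seed = base_seed, ...)
    w <- opt$best$w_star
  }
  tab <- distance_table(split$train, split$tests, w, method, trim)
  asg <- greedy_assign(tab)
  list(assignment = asg, accuracy = asg$accuracy, table = tab, w = w,
       scales = split$scales, opt = opt)
}

# Split a feature cohort at a held-out fixation index and normalize with
# train-derived unit-vector scales.
split_holdout <- function(fcohort, holdout) {
  train_raw <- lapply(fcohort, function(p) p[-holdout])
  tests_raw <- lapply(fcohort, function(p) p[[holdout]])
  stack <- do.call(rbind, unlist(train_raw, recursive = FALSE))
  scales <- normalize_features(stack)$scales
  rescale <- function(m) sweep(m, 2L, scales, "/")
  train <- lapply(train_raw, function(p) lapply(p, rescale))
  tests <- lapply(tests_raw, rescale)
  names(train) <- names(fcohort) %||% paste0("P", seq_along(fcohort))
  names(tests) <- names(train)
  list(train = train, tests = tests, scales = scales)
}

#' Feature cohort from simulated or recorded traces
#'
#' Runs the preprocessing pipeline and feature extraction over every
#' fixation trace of a cohort, producing the nested list of per-segment
#' feature matrices consumed by [make_err_fn()], [loo_evaluate()] and
#' [between_person_matrix()].
#'
#' @param cohort An `msacc_cohort` from [synth_cohort()], or a list of
#'   persons each holding a list of [gaze_trace()]s under `$fixations`
#'   (either `labeled_trace`s or bare traces).
#' @param ... Passed to [preprocess_trace()].
#' @return Named list of persons, each a list of n x 13 feature matrices.
#' @export
cohort_features <- function(cohort, ...) {
  out <- lapply(cohort, function(person) {
    lapply(person$fixations, function(fx) {
      tr <- if (inherits(fx, "labeled_trace")) fx$trace else fx
      pp <- preprocess_trace(tr, ...)
      if (is.null(pp$segment))
        stop("no microsaccades detected in a fixation of ",
             person$person_id %||% "person")
      segment_features(pp$segment)
    })
  })
  names(out) <- vapply(cohort, function(p) p$person_id %||% NA_character_,
                       character(1))
  out
}
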