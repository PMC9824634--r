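# Projected steepest descent on the unit-norm nonnegative weight simplex.
#
# The error ratio is scale-invariant, so the feasible set is the
# intersection of the nonnegative orthant with the unit sphere. Projection
# zeroes negative components and renormalizes; renormalization never changes
# the objective.

#' Random starting weight vector
#'
#' 91 i.i.d. Uniform(0, 1) draws normalized to unit Euclidean norm.
#'
#' @param seed Integer seed.
#' @return Weight vector of length 91, unit norm, all entries > 0.
#' @export
random_weights <- function(seed) {
  w <- with_seed(seed, stats::runif(N_WEIGHTS))
  w / sqrt(sum(w^2))
}

#' Project onto the feasible weight set
#'
#' Negative components are zeroed; the vector is then renormalized to unit
#' Euclidean norm. Errors if nothing positive remains.
#'
#' @param w Numeric vector of length 91.
#' @return Feasible weight vector.
#' @export
project_weights <- function(w) {
  check_weights(w)
  w <- pmax(w, 0)
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) stop("degenerate direction: all weights clipped to zero")
  w / nrm
}

#' Central-difference gradient
#'
#' Component `i` is `(f(w + h e_i) - f(w - h e_i)) / (2h)`; when the negative
#' probe would leave the nonnegative orthant (`w_i < h`) a one-sided forward
#' difference is used instead.
#'
#' @param f Objective function of a 91-vector.
#' @param w Evaluation point.
#' @param h Step size.
#' @param f_w Optional precomputed `f(w)` (reused by one-sided differences).
#' @return Numeric gradient of length `length(w)`.
#' @export
numeric_gradient <- function(f, w, h = 1e-4, f_w = NULL) {
  if (h <= 0) stop("h must be > 0")
  n <- length(w)
  g <- numeric(n)
  for (i in seq_len(n)) {
    wp <- w; wp[i] <- w[i] + h
    if (w[i] >= h) {
      wm <- w; wm[i] <- w[i] - h
      g[i] <- (f(wp) - f(wm)) / (2 * h)
    } else {
      if (is.null(f_w)) f_w <- f(w)
      g[i] <- (f(wp) - f_w) / h
    }
  }
  g
}

#' Projected steepest descent
#'
#' Iterates `w <- project(w + step * dir)` with `dir = -gradient`, the
#' gradient being evaluated once per outer iteration. Two line searches are
#' available: `"halving"` tries steps 1, 1/2, 1/4, ... and accepts the first
#' that decreases the objective; `"crawl"` walks forward in multiples of a
#' small step `xi` while the objective keeps improving and accepts the best
#' probed point. Terminates when the iterate displacement falls below `tol`,
#' when no decreasing step exists, or at `max_iter`. Accepted objective
#' values are non-increasing by construction.
#'
#' @param f Objective function (e.g. from [make_err_fn()]).
#' @param w0 Feasible starting point (see [random_weights()]).
#' @param mode `"halving"` or `"crawl"` line search.
#' @param tol Stop threshold on `||w_i - w_(i+1)||`.
#' @param xi Base step of the crawl search (also its cap).
#' @param max_iter Maximum outer iterations.
#' @param h Finite-difference step.
#' @param max_halvings Maximum halvings tried per iteration.
#' @param seed Seed recorded in the result (the descent itself is
#'   deterministic given `w0`).
#' @return List of class `msacc_opt`: `w_star`, `err_star`, `trajectory`
#'   (data frame iteration/err), `n_gradient_evals`, `converged`, `seed`.
#' @export
steepest_descent <- function(f, w0, mode = c("halving", "crawl"),
                             tol = 1e-6, xi = 1e-3, max_iter = 500,
                             h = 1e-4, max_halvings = 40, seed = NA_integer_) {
  mode <- match.arg(mode)
  if (tol <= 0 || xi <= 0) stop("tol and xi must be > 0")
  w <- project_weights(w0)
  f_w <- f(w)
  traj_err <- f_w
  n_grad <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- numeric_gradient(f, w, h = h, f_w = f_w)
    n_grad <- n_grad + 1L
    dir <- -g
    if (all(dir == 0)) { converged <- TRUE; break }
    w_new <- NULL; f_new <- f_w
    if (mode == "halving") {
      k <- 1
      for (try in seq_len(max_halvings)) {
        cand <- tryCatch(project_weights(w + k * dir), error = function(e) NULL)
        if (!is.null(cand)) {
          fc <- f(cand)
          if (fc < f_w) { w_new <- cand; f_new <- fc; break }
        }
        k <- k / 2
      }
    } else {
      # forward crawl: controlled steps of length s (at most xi) along the
      # unit descent direction, advancing l = 1, 2, ... while the objective
      # keeps improving; keeps the best probed point. If even one step of xi
      # does not improve (the objective is only piecewise smooth), the step
      # is halved before giving up. Controlled steps avoid projecting large
      # blocks of weights to zero at once.
      u <- dir / sqrt(sum(dir^2))
      best_f <- f_w; best_w <- NULL
      s <- xi
      for (try in seq_len(max_halvings)) {
        cand <- tryCatch(project_weights(w + s * u), error = function(e) NULL)
        if (!is.null(cand)) {
          fc <- f(cand)
          if (fc < f_w) {
            best_f <- fc; best_w <- cand
            l <- 2
            repeat {
              cand <- tryCatch(project_weights(w + l * s * u),
                               error = function(e) NULL)
              if (is.null(cand)) break
              fc <- f(cand)
              if (fc < best_f) { best_f <- fc; best_w <- cand; l <- l + 1 }
              else break
              if (l > 1e5) break
            }
            break
          }
        }
        s <- s / 2
      }
      if (!is.null(best_w)) { w_new <- best_w; f_new <- best_f }
    }
    if (is.null(w_new)) { converged <- TRUE; break }  # local minimum
    step_norm <- sqrt(sum((w - w_new)^2))
    w <- w_new; f_w <- f_new
    traj_err <- c(traj_err, f_w)
    if (step_norm < tol) { converged <- TRUE; break }
  }
  structure(list(w_star = w, err_star = f_w,
                 trajectory = data.frame(iteration = seq_along(traj_err) - 1L,
                                         err = traj_err),
                 n_gradient_evals = n_grad, converged = converged,
                 seed = seed),
            class = "msacc_opt")
}

#' @export
print.msacc_opt <- function(x, ...) {
  cat(sprintf("<msacc_opt> err* = %.6g after %d accepted steps (%d gradients)\n",
              x$err_star, nrow(x$trajectory) - 1L, x$n_gradient_evals))
  invisible(x)
}

#' Multi-start weight learning
#'
#' Runs [steepest_descent()] from `n_starts` seeded random starting points
#' (30 by default) and returns the run with the smallest final error along
#' with all runs.
#'
#' @param f Objective function.
#' @param n_starts Number of restarts.
#' @param base_seed Seed of the first start; run `k` uses `base_seed + k - 1`.
#' @param ... Passed to [steepest_descent()].
#' @return List: `best` (an `msacc_opt`), `runs` (all results),
#'   `errors_start` and `errors_final` (numeric vectors, one per start).
#' @export
multi_start <- function(f, n_starts = 30, base_seed = 1, ...) {
  if (n_starts < 1L) stop("n_starts must be >= 1")
  runs <- vector("list", n_starts)
  errors_start <- numeric(n_starts)
  for (k in seq_len(n_starts)) {
    seed_k <- as.integer(base_seed + k - 1L)
    w0 <- random_weights(seed_k)
    errors_start[k] <- f(w0)
    runs[[k]] <- steepest_descent(f, w0, seed = seed_k, ...)
  }
  errors_final <- vapply(runs, `[[`, numeric(1), "err_star")
  list(best = runs[[which.min(errors_final)]], runs = runs,
       errors_start = errors_start, errors_final = errors_final)
}
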