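# Entropy-regularized deconvolution.
#
# Objective:  J(f) = sum((A f - g)^2) + lambda * sum(T * log(1 + (Lf)^2 / T))
# where A f = IFFT(OTF * FFT(f)) (the OTF forward model) and L is a 27-point
# discrete Laplacian (mean of the 26 neighbours minus the centre) with
# periodic boundaries. The smoothing weight lambda scales the penalty; the
# nonlinearity scale T interpolates between edge-preserving behaviour
# (small T) and a Tikhonov quadratic penalty (T -> infinity), whose exact
# minimizer is available in closed form and serves as the solver's oracle.
# Positivity is enforced by the smooth reparameterization f = s^2.

#' Deconvolution parameters
#'
#' @param smoothing Regularization weight lambda (> 0, default 0.5).
#' @param nonlinearity Transition scale T of the log penalty (> 0,
#'   default 10000). Large values approach a quadratic (Tikhonov) penalty.
#' @param max_iter Iteration budget for the conjugate-gradient solver
#'   (default 100).
#' @param tol Relative objective-change stopping tolerance (default 1e-6).
#' @param positivity Enforce a nonnegative solution (default `TRUE`).
#' @param seed Seed for any randomized initialization (default 0; the
#'   default deterministic initialization does not consume it).
#' @return A `deconv_params` list.
#' @export
deconv_params <- function(smoothing = 0.5, nonlinearity = 10000,
                          max_iter = 100, tol = 1e-6, positivity = TRUE,
                          seed = 0) {
  stopifnot(smoothing > 0, nonlinearity > 0, max_iter >= 1, tol >= 0)
  structure(list(smoothing = smoothing, nonlinearity = nonlinearity,
                 max_iter = as.integer(max_iter), tol = tol,
                 positivity = isTRUE(positivity), seed = as.integer(seed)),
            class = "deconv_params")
}

# 27-point Laplacian transfer function (real, symmetric stencil):
# Lhat(k) = mean over the 26 neighbour offsets of exp(2 pi i k.n / N) - 1.
laplacian_transfer <- function(n) {
  kern <- array(0, dim = c(n, n, n))
  ix <- c(1L, 2L, n)  # offsets 0, +1, -1 in periodic index space
  kern[ix, ix, ix] <- 1 / 26
  kern[1, 1, 1] <- -1
  Re(fft_fwd(kern))
}

apply_transfer <- function(x, tf) Re(fft_inv(fft_fwd(x) * tf))

otf_transfer <- function(otf, n) {
  stopifnot(inherits(otf, "fourier_volume"))
  if (dim(otf$data)[1] != n) stop("OTF shape mismatch", call. = FALSE)
  fft_uncenter(otf$data)
}

#' Deconvolution objective value
#'
#' Evaluates the data-fidelity plus entropy-style smoothness objective (see
#' the package vignette for the functional form).
#'
#' @param f Candidate restored [volume3d()].
#' @param g Observed [volume3d()].
#' @param otf An `otf_volume` (DC-centred transfer function).
#' @param p A [deconv_params()].
#' @return Single numeric objective value.
#' @export
deconv_objective <- function(f, g, otf, p) {
  stopifnot(inherits(f, "volume3d"), inherits(g, "volume3d"))
  if (!identical(dim(f$data), dim(g$data))) {
    stop("shape mismatch between f and g", call. = FALSE)
  }
  n <- dim(g$data)[1]
  ot <- otf_transfer(otf, n)
  lt <- laplacian_transfer(n)
  obj_core(f$data, g$data, ot, lt, p$smoothing, p$nonlinearity)
}

obj_core <- function(f, g, ot, lt, lambda, Tn) {
  resid <- apply_transfer(f, ot) - g
  lf <- apply_transfer(f, lt)
  sum(resid^2) + lambda * Tn * sum(log1p(lf^2 / Tn))
}

grad_core <- function(f, g, ot, lt, lambda, Tn) {
  resid <- apply_transfer(f, ot) - g
  lf <- apply_transfer(f, lt)
  # A and L have real symmetric transfer functions, hence self-adjoint.
  2 * apply_transfer(resid, ot) +
    lambda * apply_transfer(2 * lf / (1 + lf^2 / Tn), lt)
}

#' Entropy-regularized deconvolution by nonlinear conjugate gradient
#'
#' Minimizes the regularized objective with Polak-Ribiere conjugate
#' gradient and a parabolic-fit line search with Armijo backtracking, so
#' the objective trace is nonincreasing by construction. With positivity
#' on, the solution is parameterized as `f = s^2` (initialized from
#' `s = sqrt(max(g, 0))`) which keeps the problem smooth; otherwise the
#' iteration starts from the observed map itself.
#'
#' @param g Observed [volume3d()] (the map to restore).
#' @param otf An `otf_volume`.
#' @param p A [deconv_params()].
#' @return A `deconv_result`: list with `volume` (restored [volume3d()]),
#'   `objective_trace`, `iterations_run`, `converged`.
#' @export
deconvolve <- function(g, otf, p = deconv_params()) {
  stopifnot(inherits(g, "volume3d"), inherits(p, "deconv_params"))
  n <- dim(g$data)[1]
  ot <- otf_transfer(otf, n)
  lt <- laplacian_transfer(n)
  lambda <- p$smoothing
  Tn <- p$nonlinearity

  if (p$positivity) {
    x <- sqrt(pmax(g$data, 0))
    fn <- function(x) obj_core(x^2, g$data, ot, lt, lambda, Tn)
    gr <- function(x) 2 * x * grad_core(x^2, g$data, ot, lt, lambda, Tn)
    to_f <- function(x) x^2
  } else {
    x <- g$data
    fn <- function(x) obj_core(x, g$data, ot, lt, lambda, Tn)
    gr <- function(x) grad_core(x, g$data, ot, lt, lambda, Tn)
    to_f <- function(x) x
  }

  jx <- fn(x)
  if (!is.finite(jx)) stop("non-finite objective at initialization",
                           call. = FALSE)
  trace <- jx
  gx <- gr(x)
  d <- -gx
  alpha_prev <- NA_real_
  iters <- 0L
  converged <- FALSE

  for (it in seq_len(p$max_iter)) {
    dd <- sum(d * gx)
    if (dd >= 0) {          # not a descent direction: restart
      d <- -gx
      dd <- sum(d * gx)
      if (dd >= 0) break    # gradient numerically zero
    }
    ls <- line_search(fn, x, d, jx, dd, alpha_prev)
    if (is.null(ls)) {      # no decrease possible along -grad either
      if (!identical(d, -gx)) {
        d <- -gx
        dd <- sum(d * gx)
        ls <- line_search(fn, x, d, jx, dd, alpha_prev)
      }
      if (is.null(ls)) { converged <- TRUE; break }
    }
    x_new <- x + ls$alpha * d
    j_new <- ls$value
    if (!is.finite(j_new)) {
      stop("non-finite objective during iteration ", it, call. = FALSE)
    }
    g_new <- gr(x_new)
    beta <- max(0, sum(g_new * (g_new - gx)) / max(sum(gx * gx),
                                                   .Machine$double.xmin))
    d <- -g_new + beta * d
    rel <- (jx - j_new) / max(abs(jx), .Machine$double.xmin)
    x <- x_new; gx <- g_new; jx <- j_new
    alpha_prev <- ls$alpha
    trace <- c(trace, jx)
    iters <- it
    if (rel < p$tol) { converged <- TRUE; break }
  }

  vol <- volume3d(to_f(x), g$voxel_size, g$origin)
  structure(list(volume = vol, objective_trace = trace,
                 iterations_run = iters, converged = converged,
                 params = p),
            class = "deconv_result")
}

# Parabolic-fit line search with Armijo backtracking. Exact for quadratic
# objectives (the T -> infinity limit), monotone always. Returns NULL when
# no decreasing step is found.
line_search <- function(fn, x, d, j0, dd, alpha_prev, c1 = 1e-4,
                        max_backtrack = 40L) {
  alpha <- if (is.finite(alpha_prev) && alpha_prev > 0) alpha_prev else
    min(1, 1 / sqrt(max(sum(d * d), .Machine$double.xmin)))
  j_t <- fn(x + alpha * d)
  denom <- j_t - j0 - dd * alpha
  if (is.finite(denom) && denom > 0) {
    a_star <- -dd * alpha^2 / (2 * denom)
    if (is.finite(a_star) && a_star > 0) {
      j_s <- fn(x + a_star * d)
      if (is.finite(j_s) && j_s < j_t) { alpha <- a_star; j_t <- j_s }
    }
  }
  for (k in seq_len(max_backtrack)) {
    if (is.finite(j_t) && j_t <= j0 + c1 * alpha * dd) {
      return(list(alpha = alpha, value = j_t))
    }
    alpha <- alpha / 2
    j_t <- fn(x + alpha * d)
  }
  NULL
}

#' Closed-form solution of the quadratic (Tikhonov) limit
#'
#' Exact minimizer of `sum((A f - g)^2) + lambda * sum((L f)^2)`, computed
#' per Fourier voxel as `F = O G / (O^2 + lambda |Lhat|^2)` with `Lhat` the
#' Laplacian stencil's transfer function. This is the `T -> infinity`,
#' positivity-off limit of [deconvolve()] and serves as its independent
#' oracle in tests.
#'
#' @param g Observed [volume3d()].
#' @param otf An `otf_volume`.
#' @param lambda Smoothing weight (>= 0).
#' @return Restored [volume3d()].
#' @export
quadratic_solution <- function(g, otf, lambda) {
  stopifnot(inherits(g, "volume3d"), lambda >= 0)
  n <- dim(g$data)[1]
  ot <- otf_transfer(otf, n)
  lt <- laplacian_transfer(n)
  denom <- ot^2 + lambda * lt^2
  gt <- fft_fwd(g$data)
  ft <- ifelse(denom > 0, ot * gt / denom, 0 + 0i)
  volume3d(Re(fft_inv(ft)), g$voxel_size, g$origin)
}

#' @export
print.deconv_result <- function(x, ...) {
  cat(sprintf("<deconv_result> %d iterations, %s, objective %.6g -> %.6g\n",
              x$iterations_run,
              if (x$converged) "converged" else "iteration budget reached",
              x$objective_trace[1], utils::tail(x$objective_trace, 1)))
  invisible(x)
}

#' Tidy the objective trace of a deconvolution run
#'
#' @param x A `deconv_result`.
#' @param ... Unused.
#' @return Tibble with `iteration` and `objective`.
#' @method tidy deconv_result
#' @export
tidy.deconv_result <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$objective_trace) - 1L,
                 objective = x$objective_trace)
}

#' Summarize a deconvolution run
#'
#' @param x A `deconv_result`.
#' @param ... Unused.
#' @return One-row tibble with iteration count, convergence flag, and the
#'   initial/final objective values.
#' @method glance deconv_result
#' @export
glance.deconv_result <- function(x, ...) {
  tibble::tibble(iterations = x$iterations_run, converged = x$converged,
                 objective_initial = x$objective_trace[1],
                 objective_final = utils::tail(x$objective_trace, 1),
                 smoothing = x$params$smoothing,
                 nonlinearity = x$params$nonlinearity)
}
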