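# Internal helpers shared across modules.

fm_error <- function(msg, class, call. = FALSE, ...) {
  stop(structure(
    class = c(class, "fm_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL, ...)
  ))
}

fm_warn <- function(msg, class = "fm_warning") {
  warning(structure(
    class = c(class, "fm_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
is_strictly_increasing <- function(x) all(diff(x) > 0)

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Forward/central numeric Jacobian of vector-valued f at x.
num_jacobian <- function(f, x, eps = NULL) {
  f0 <- f(x)
  p <- length(x)
  J <- matrix(0, length(f0), p)
  h <- eps %||% pmax(abs(x), 1) * sqrt(.Machine$double.eps)
  for (j in seq_len(p)) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + h[j]
    xm[j] <- xm[j] - h[j]
    J[, j] <- (f(xp) - f(xm)) / (2 * h[j])
  }
  J
}

# Nonlinear least squares via nlminb on 0.5 * sum(resid^2).
# resid_fn(par) returns the residual vector. Returns the optimum plus
# convergence diagnostics; covariance is computed by the caller in
# whatever parameterization is natural for reporting.
ls_minimize <- function(par, resid_fn, lower = -Inf, upper = Inf,
                        abs_tol = 1e-10, max_eval = 10000L) {
  obj <- function(p) {
    r <- resid_fn(p)
    if (any(!is.finite(r))) return(.Machine$double.xmax)
    0.5 * sum(r^2)
  }
  fit <- stats::nlminb(
    start = par, objective = obj, lower = lower, upper = upper,
    control = list(eval.max = max_eval, iter.max = max_eval,
                   abs.tol = abs_tol, rel.tol = 1e-14,
                   x.tol = 1e-12)
  )
  # Gauss-Newton polish: quadratic convergence near the optimum pushes
  # (near-)zero-residual fits to machine precision, which nlminb's
  # gradient-free stopping rules do not guarantee.
  p <- fit$par
  ssr <- 2 * fit$objective
  for (it in 1:4) {
    r <- resid_fn(p)
    J <- num_jacobian(resid_fn, p)
    step <- tryCatch(qr.solve(J, -r), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    cand <- pmin(pmax(p + step, lower), upper)
    r2 <- resid_fn(cand)
    if (!all(is.finite(r2)) || sum(r2^2) >= ssr) break
    p <- cand
    ssr <- sum(r2^2)
  }
  list(par = p, ssr = ssr,
       convergence = fit$convergence, message = fit$message,
       iterations = fit$iterations)
}

# Standard errors of natural parameters theta from residual function
# resid_nat(theta); sigma^2 = SSR / (n - p), cov = sigma^2 (J'J)^-1.
ls_std_errors <- function(resid_nat, theta) {
  r <- resid_nat(theta)
  n <- length(r)
  p <- length(theta)
  dof <- max(n - p, 1L)
  sigma2 <- sum(r^2) / dof
  J <- num_jacobian(resid_nat, theta)
  JtJ <- crossprod(J)
  cov <- tryCatch(sigma2 * solve(JtJ), error = function(e) {
    sigma2 * MASS_ginv(JtJ)
  })
  se <- sqrt(pmax(diag(cov), 0))
  list(se = se, cov = cov, sigma2 = sigma2, dof = dof)
}

# Tiny Moore-Penrose pseudo-inverse so a rank-deficient Jacobian (for
# example a perfect noiseless fit) does not abort error reporting.
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1], 0)
  if (!any(pos)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# Draw-and-restore RNG scoping: generators set the stream from their
# spec seed without clobbering the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Pearson correlation between data and model prediction; NA-safe guard
# for constant vectors (returns 0 rather than NA).
safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}
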