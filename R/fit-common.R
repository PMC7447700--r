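# Shared nonlinear least-squares machinery for the curve fitters.
#
# All fitters minimise a residual sum of squares over a bound box using
# bounded Levenberg-Marquardt (minpack.lm::nls.lm) started from a fixed,
# deterministic lattice of starting points: 3 levels per free parameter at
# 15%, 50% and 85% of the box (optionally log-spaced for parameters whose
# bounds span decades). Best final SSE wins; ties go to the earlier lattice
# point. No randomness, so fits are bit-reproducible.

start_lattice <- function(lower, upper, log_scale = NULL) {
  frac <- c(0.15, 0.5, 0.85)
  levels <- lapply(names(lower), function(p) {
    lo <- lower[[p]]; hi <- upper[[p]]
    if (!is.null(log_scale) && p %in% log_scale) {
      lo <- max(lo, hi * 1e-6)
      exp(log(lo) + frac * (log(hi) - log(lo)))
    } else {
      lo + frac * (hi - lo)
    }
  })
  names(levels) <- names(lower)
  as.matrix(expand.grid(levels, KEEP.OUT.ATTRS = FALSE))
}

fit_control <- function() minpack.lm::nls.lm.control(
  maxiter = 500, ftol = 1e-10, ptol = 1e-12)

# residual_fn(par) -> residual vector; returns best fit across starts
multistart_fit <- function(residual_fn, starts, lower, upper) {
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[s, ], fn = residual_fn,
                         lower = lower, upper = upper,
                         control = fit_control()),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse - 1e-15) {
      best <- list(par = fit$par, sse = sse, info = fit$info,
                   converged = fit$info %in% 1:3)
    }
  }
  if (is.null(best))
    stop("all optimizer starts failed")
  best
}

num_jacobian <- function(residual_fn, par) {
  p <- length(par)
  r0 <- residual_fn(par)
  J <- matrix(NA_real_, length(r0), p)
  for (j in seq_len(p)) {
    h <- max(1e-7, 1e-7 * abs(par[j]))
    up <- par; up[j] <- up[j] + h
    dn <- par; dn[j] <- dn[j] - h
    J[, j] <- (residual_fn(up) - residual_fn(dn)) / (2 * h)
  }
  J
}

# Gauss-Newton standard errors at the optimum; NA when J'J is singular
gauss_newton_se <- function(residual_fn, par, sse, n_obs) {
  p <- length(par)
  se <- rep(NA_real_, p)
  names(se) <- names(par)
  if (n_obs <= p) return(se)
  J <- num_jacobian(residual_fn, par)
  jtj <- crossprod(J)
  cv <- tryCatch(solve(jtj) * sse / (n_obs - p), error = function(e) NULL)
  if (is.null(cv)) return(se)
  d <- diag(cv)
  se[d >= 0] <- sqrt(d[d >= 0])
  se
}

new_photo_fit <- function(subclass, coef, se, sse, n_obs, converged, flags,
                          data, fitted, model_label, extra = list()) {
  structure(c(list(coefficients = coef, se = se, sse = sse, n_obs = n_obs,
                   converged = converged, flags = flags, data = data,
                   fitted.values = fitted, model = model_label),
              extra),
            class = c(subclass, "photo_fit"))
}

bound_flags <- function(par, lower, upper, tol = 1e-8) {
  at <- names(par)[par <= lower + tol * pmax(1, abs(lower)) |
                     par >= upper - tol * pmax(1, abs(upper))]
  if (length(at)) paste0("parameter at bound: ", paste(at, collapse = ", "))
  else character()
}
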