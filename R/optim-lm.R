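# Box-constrained Levenberg-Marquardt least squares.
#
# Parameters are mapped into their (lower, upper) boxes through a scaled
# logistic transform, so every iterate is feasible and boundary optima are
# approached asymptotically. Used by the NGIVIM, VFA, Tofts and FXR fitters,
# which all need the machine-precision residual floor on noiseless data that
# general quasi-Newton optimizers do not reliably reach here.

# residual_fn(par) -> residual vector (data - model)
# jac_fn(par) -> d model / d par (n x p), optional; numeric forward
#   differences in native parameter space otherwise.
.lm_box <- function(par, residual_fn, lower, upper, jac_fn = NULL,
                    maxit = 200L, rel_tol = 1e-14) {
  p_len <- length(par)
  to_t <- function(p) stats::qlogis((p - lower) / (upper - lower))
  to_p <- function(t) lower + (upper - lower) * stats::plogis(t)
  dp_dt <- function(t) {
    s <- stats::plogis(t)
    (upper - lower) * s * (1 - s)
  }
  num_jac <- function(p) {
    r0 <- residual_fn(p)
    J <- matrix(0, length(r0), p_len)
    h <- pmax(abs(p), 1e-8) * 1e-7
    for (j in seq_len(p_len)) {
      pj <- p
      pj[j] <- min(p[j] + h[j], upper[j])
      hj <- pj[j] - p[j]
      if (hj == 0) {
        pj[j] <- p[j] - h[j]
        hj <- -h[j]
      }
      J[, j] <- -(residual_fn(pj) - r0) / hj   # residual = data - model
    }
    J
  }
  get_jac <- if (is.null(jac_fn)) num_jac else jac_fn

  eps <- 1e-8 * (upper - lower)
  t <- to_t(pmin(pmax(par, lower + eps), upper - eps))
  p <- to_p(t)
  r <- residual_fn(p)
  rss <- sum(r * r)
  lam <- 1e-3
  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    J <- get_jac(p) %*% diag(dp_dt(t), p_len)
    g <- crossprod(J, r)
    A <- crossprod(J)
    stepped <- FALSE
    # Damping floor relative to the dominant curvature scale keeps dead
    # parameter directions (zero Jacobian columns at a pinned bound) from
    # producing unbounded steps.
    dA <- pmax(diag(A), max(diag(A), 1e-300) * 1e-10)
    for (k in 1:40) {
      dt <- tryCatch(drop(solve(A + lam * diag(dA, p_len), g)),
                     error = function(e) NULL)
      if (!is.null(dt) && all(is.finite(dt))) {
        t2 <- t + dt
        p2 <- to_p(t2)
        r2 <- residual_fn(p2)
        rss2 <- sum(r2 * r2)
        if (is.finite(rss2) && rss2 < rss) {
          converged <- (rss - rss2) < rel_tol * (rss2 + 1e-300)
          t <- t2; p <- p2; r <- r2; rss <- rss2
          lam <- max(lam / 3, 1e-12)
          stepped <- TRUE
          break
        }
      }
      lam <- lam * 4
    }
    if (!stepped || converged) break
  }
  list(par = p, rss = rss, iterations = it, converged = converged || !stepped)
}
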