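#' Univariate Cox proportional-hazards fit
#'
#' Newton-Raphson maximization of the Cox partial likelihood for a single
#' covariate, with Efron's approximation for tied event times. Written as a
#' lean scalar fitter because the resampling screen calls it tens of
#' thousands of times per run; it matches `survival::coxph` to numerical
#' precision (see the package tests).
#'
#' @param x Numeric covariate vector.
#' @param time Follow-up times.
#' @param event Event indicators (0 = censored, 1 = event).
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence tolerance on the score.
#' @return List with `beta`, `se`, `z`, `p` (Wald), `loglik`, `n_events`,
#'   `converged`.
#' @export
cox_univariate <- function(x, time, event, max_iter = 100L, tol = 1e-9) {
  if (length(x) != length(time) || length(x) != length(event))
    stop("covariate, time and event must have equal length")
  if (sum(event) < 2) stop("need at least 2 events")
  if (stats::sd(x) == 0) stop("constant covariate")
  ord <- order(time)
  x <- as.numeric(x[ord]); time <- time[ord]; event <- event[ord]
  n <- length(x)
  # Center for numerical stability; beta is translation-invariant.
  xc <- x - mean(x)
  ev_times <- unique(time[event == 1])
  # Precompute per event time: indices of deaths and the risk-set start.
  death_idx <- lapply(ev_times, function(t) which(time == t & event == 1))
  risk_start <- vapply(ev_times, function(t) match(TRUE, time >= t),
                       integer(1))

  partial <- function(beta) {
    w <- exp(beta * xc)
    # Suffix sums over the (time-ascending) ordering: risk set at t is all
    # subjects with time >= t, i.e. a suffix.
    c0 <- rev(cumsum(rev(w)))
    c1 <- rev(cumsum(rev(w * xc)))
    c2 <- rev(cumsum(rev(w * xc^2)))
    ll <- 0; grad <- 0; info <- 0
    for (k in seq_along(ev_times)) {
      D <- death_idx[[k]]
      d <- length(D)
      s0 <- c0[risk_start[k]]; s1 <- c1[risk_start[k]]; s2 <- c2[risk_start[k]]
      s0d <- sum(w[D]); s1d <- sum(w[D] * xc[D]); s2d <- sum(w[D] * xc[D]^2)
      l <- (seq_len(d) - 1) / d
      den <- s0 - l * s0d
      e1 <- (s1 - l * s1d) / den
      e2 <- (s2 - l * s2d) / den
      ll <- ll + beta * sum(xc[D]) - sum(log(den))
      grad <- grad + sum(xc[D]) - sum(e1)
      info <- info + sum(e2 - e1^2)
    }
    list(ll = ll, grad = grad, info = info)
  }

  beta <- 0
  cur <- partial(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (cur$info <= 0) break
    step <- cur$grad / cur$info
    cand <- beta + step
    nxt <- partial(cand)
    halvings <- 0
    while ((!is.finite(nxt$ll) || nxt$ll < cur$ll - 1e-12) && halvings < 30) {
      step <- step / 2
      cand <- beta + step
      nxt <- partial(cand)
      halvings <- halvings + 1
    }
    beta <- cand
    cur <- nxt
    if (abs(cur$grad) < tol || abs(step) < 1e-12) {
      converged <- TRUE
      break
    }
  }
  se <- if (cur$info > 0) 1 / sqrt(cur$info) else NA_real_
  z <- beta / se
  list(beta = beta, se = se, z = z,
       p = 2 * stats::pnorm(-abs(z)),
       loglik = cur$ll, n_events = sum(event), converged = converged)
}
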