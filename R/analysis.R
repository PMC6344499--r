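## EXSY lifetime fitting: the delayed-detection signal of hyperpolarized
## hydrides that exchanged into the free pool decays with both the exchange
## lifetime and the (fixed, independently measured) T1.

#' Fit the hydride exchange lifetime from DARTH-EXSY signals
#'
#' Least-squares fit of the forward model
#' \deqn{A(\tau) = A_0 \, e^{-\tau/\tau_{ex}} \, e^{-\tau/T_1}}
#' with T1 held fixed (it enters as a known weight, not a fit parameter).
#' The amplitude is profiled out analytically and the lifetime found by 1-D
#' minimization, which is robust even for noiseless (zero-residual) data;
#' the uncertainty comes from the linearized (Jacobian) covariance.
#'
#' @param signals `data.frame` (or list of pairs) with columns `delay` (s)
#'   and `amplitude`; at least 3 distinct delays.
#' @param T1 longitudinal relaxation time in s (> 0); `Inf` reduces the
#'   model to a single exponential.
#' @param interval search interval for the lifetime in s.
#' @return object of class `exsy_fit` with fields `lifetime`, `uncertainty`,
#'   `amplitude`, `residual_norm`, `covariance`.
#' @export
fit_exsy_lifetime <- function(signals, T1, interval = c(1e-4, 100)) {
  if (is.list(signals) && !is.data.frame(signals)) {
    signals <- do.call(rbind, lapply(signals, function(p) {
      data.frame(delay = p[[1]], amplitude = p[[2]])
    }))
  }
  d <- signals$delay
  y <- signals$amplitude
  if (length(unique(d)) < 3) {
    stop("need at least 3 distinct delays", call. = FALSE)
  }
  if (!(T1 > 0)) stop("T1 must be > 0", call. = FALSE)
  r1 <- if (is.finite(T1)) 1 / T1 else 0

  g <- function(tau) exp(-d * (1 / tau + r1))
  rss <- function(tau) {
    gv <- g(tau)
    A <- sum(y * gv) / sum(gv^2)
    sum((y - A * gv)^2)
  }
  opt <- stats::optimize(rss, interval = interval, tol = 1e-12)
  tau <- opt$minimum
  gv <- g(tau)
  A <- sum(y * gv) / sum(gv^2)

  # linearized covariance: J = [dA, dtau] columns
  J <- cbind(gv, A * gv * d / tau^2)
  n <- length(y); p <- 2
  res <- y - A * gv
  s2 <- sum(res^2) / max(1, n - p)
  JtJ <- crossprod(J)
  cov <- tryCatch(s2 * solve(JtJ), error = function(e) matrix(NA_real_, 2, 2))
  structure(list(lifetime = tau, uncertainty = sqrt(cov[2, 2]),
                 amplitude = A, residual_norm = sqrt(sum(res^2)),
                 covariance = cov, T1 = T1),
            class = "exsy_fit")
}

#' @export
print.exsy_fit <- function(x, ...) {
  cat(sprintf("<exsy_fit: lifetime %.4g +/- %.2g s (T1 fixed at %.4g s)>\n",
              x$lifetime, x$uncertainty, x$T1))
  invisible(x)
}

#' DARTH-EXSY signal from an ensemble
#'
#' The z-magnetization carried by the hydride pool that exchanged off the
#' catalyst, per trajectory: the per-event mean departed-hydride
#' magnetization times the mean number of hydride-exchange events.
#'
#' @param ensemble an `ensemble_result` from a single-pulse DARTH sequence.
#' @param system the `spin_system` used.
#' @return numeric scalar (summed hydride z-magnetization in the free pool).
#' @export
exsy_signal <- function(ensemble, system) {
  hyd <- which(system$role == "hydride")
  key <- as.character(system$ligand_group[hyd[1]])
  dep <- ensemble$departed[[key]]
  if (is.null(dep)) stop("no hydride-exchange events recorded", call. = FALSE)
  sz <- diag(c(0.5, -0.5) + 0i)
  Fz <- sz %x% eye(2) + eye(2) %x% sz
  Re(mat_trace(dep$state %*% Fz)) * dep$mean_events
}
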