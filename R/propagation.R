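## Coherent evolution under the Liouville-von Neumann equation.
##
## Every segment Hamiltonian is piecewise constant (or piecewise-constant
## after first-order Magnus averaging of a linear rf ramp), so propagation is
## rho -> U rho U* with U = exp(-i H dt) computed from one Hermitian
## eigendecomposition per distinct Hamiltonian.  Decompositions and ramp-step
## propagators are cached per segment signature and shared across an entire
## Monte Carlo ensemble, which is what makes 1e5-trajectory runs feasible.

#' Propagation control parameters
#'
#' @param max_step maximum Magnus step (s) used for rf-ramped segments
#'   (default `1e-4`; at ramp rates of tens of Hz/s the nutation frequency
#'   changes by < 0.005 Hz per step, far below any coupling).
#' @param tolerance relative accuracy target used by step-halving checks.
#' @return object of class `propagation_control`.
#' @export
propagation_control <- function(max_step = 1e-4, tolerance = 1e-8) {
  stopifnot(max_step > 0)
  structure(list(max_step = max_step, tolerance = tolerance),
            class = "propagation_control")
}

# U = exp(-i H dt) for Hermitian H (rad/s)
expm_herm <- function(H, dt) {
  e <- eigen(H, symmetric = TRUE)
  ph <- exp(-1i * e$values * dt)
  e$vectors %*% (ph * Conj(t(e$vectors)))
}

unitary_sandwich <- function(U, rho) U %*% rho %*% Conj(t(U))

# signature string identifying a segment's Hamiltonian content
segment_key <- function(segment) {
  paste(segment$mode, segment$B0,
        paste(names(segment$offsets), unlist(segment$offsets), collapse = ","),
        segment$rf_init, segment$rf_ramp, segment$rf_phase,
        segment$rf_species, segment$duration, sep = "|")
}

# Precompute the evolution machinery for one segment.  `cache` is an
# environment shared across trajectories of an ensemble.
make_seginfo <- function(system, segment, control = propagation_control(),
                         cache = NULL) {
  key <- segment_key(segment)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  ramped <- segment$mode == "high_field" && !is.null(segment$rf_species) &&
    segment$rf_ramp != 0
  if (!ramped) {
    H <- segment_hamiltonian(system, segment, 0)
    e <- eigen(H, symmetric = TRUE)
    si <- list(type = "const", duration = segment$duration,
               V = e$vectors, Vh = Conj(t(e$vectors)), lam = e$values)
  } else {
    seg0 <- segment
    seg0$rf_init <- 0; seg0$rf_ramp <- 0
    Hbase <- high_field_hamiltonian(system, seg0, 0)
    Sx <- species_operator(system, segment$rf_species, "x")
    Sy <- species_operator(system, segment$rf_species, "y")
    Hrf_unit <- cos(segment$rf_phase) * Sx + sin(segment$rf_phase) * Sy
    h <- control$max_step
    nstep <- max(1L, ceiling(segment$duration / h - 1e-12))
    si <- list(type = "ramp", duration = segment$duration,
               Hbase = Hbase, Hrf = Hrf_unit,
               rf_init = segment$rf_init, rf_ramp = segment$rf_ramp,
               h = segment$duration / nstep, nstep = nstep,
               stepU = new.env(parent = emptyenv()))
  }
  if (!is.null(cache)) cache[[key]] <- si
  si
}

# unitary for [a, b] inside a ramped segment, midpoint-averaged Hamiltonian
ramp_U <- function(si, a, b) {
  w_mid <- 2 * pi * (si$rf_init + si$rf_ramp * (a + b) / 2)
  expm_herm(si$Hbase + w_mid * si$Hrf, b - a)
}

# evolve rho over [t0, t1] measured from the segment start
evolve_interval <- function(rho, si, t0, t1) {
  dt <- t1 - t0
  if (dt <= 1e-15) return(rho)
  if (si$type == "const") {
    U <- si$V %*% (exp(-1i * si$lam * dt) * si$Vh)
    return(U %*% rho %*% Conj(t(U)))
  }
  # ramped: walk the segment's fixed step grid; full steps use cached
  # propagators, partial steps (event boundaries) are computed on the fly
  h <- si$h
  k0 <- floor(t0 / h + 1e-12)
  k1 <- ceiling(t1 / h - 1e-12)
  for (k in k0:(k1 - 1)) {
    a <- max(t0, k * h)
    b <- min(t1, (k + 1) * h)
    if (b - a <= 1e-15) next
    full <- (a <= k * h + 1e-15) && (b >= (k + 1) * h - 1e-15)
    if (full) {
      key <- as.character(k)
      U <- si$stepU[[key]]
      if (is.null(U)) {
        U <- ramp_U(si, k * h, (k + 1) * h)
        si$stepU[[key]] <- U
      }
    } else {
      U <- ramp_U(si, a, b)
    }
    rho <- U %*% rho %*% Conj(t(U))
  }
  rho
}

#' Propagate a density matrix through one field segment
#'
#' Unitary evolution \eqn{\rho \to U \rho U^\dagger} under the segment's
#' Hamiltonian.  Constant segments use a single cached matrix exponential;
#' rf-ramped segments use first-order Magnus (midpoint-averaged Hamiltonian)
#' steps of at most `control$max_step`.
#'
#' @param rho density matrix on the system space.
#' @param system a `spin_system`.
#' @param segment a `field_segment`.
#' @param control a `propagation_control`.
#' @return the evolved density matrix.
#' @export
propagate <- function(rho, system, segment, control = propagation_control()) {
  if (!all(dim(rho) == c(system$dim, system$dim))) {
    stop("dimension mismatch between rho and system", call. = FALSE)
  }
  si <- make_seginfo(system, segment, control)
  evolve_interval(rho, si, 0, segment$duration)
}

#' Ideal hard pulse on one species
#'
#' Zero-duration rotation of every spin of `species` by `angle` about the
#' axis at azimuth `phase` in the transverse plane (phase 0 = x).
#'
#' @param rho density matrix.
#' @param system a `spin_system`.
#' @param species isotope tag, e.g. `"1H"`.
#' @param angle flip angle in rad.
#' @param phase pulse phase in rad.
#' @return rotated density matrix.
#' @export
hard_pulse <- function(rho, system, species, angle, phase = 0) {
  Fx <- species_operator(system, species, "x")
  Fy <- species_operator(system, species, "y")
  U <- expm_herm(cos(phase) * Fx + sin(phase) * Fy, angle)
  unitary_sandwich(U, rho)
}

#' Phenomenological quadrupolar relaxation of an auxiliary spin
#'
#' Damps the auxiliary spin's reduced degrees of freedom toward the
#' maximally mixed state with time constant `T_Q`:
#' \deqn{\rho \to e^{-dt/T_Q}\rho + (1 - e^{-dt/T_Q})\,
#'       (\mathrm{Tr}_{spin}\rho) \otimes \mathbf{1}/d.}
#' Trace-preserving; interleave with coherent steps (first-order splitting).
#'
#' @param rho density matrix.
#' @param system a `spin_system`.
#' @param spin index of an `auxiliary`-role spin (e.g. the quadrupolar 14N).
#' @param T_Q relaxation time constant in s (> 0).
#' @param dt elapsed time in s.
#' @return damped density matrix.
#' @export
apply_quadrupolar_relaxation <- function(rho, system, spin, T_Q, dt) {
  spin <- as.integer(spin)
  if (system$role[spin] != "auxiliary") {
    stop("quadrupolar relaxation requires an auxiliary-role spin", call. = FALSE)
  }
  if (!(T_Q > 0)) stop("T_Q must be > 0", call. = FALSE)
  w <- exp(-dt / T_Q)
  if (w >= 1) return(rho)
  others <- setdiff(seq_along(system$dims), spin)
  red <- ptrace(rho, system$dims, keep = others)
  d <- system$dims[spin]
  relaxed <- embed_state(list(red, eye(d) / d), list(others, spin), system$dims)
  w * rho + (1 - w) * relaxed
}

# validate a density matrix (used by the engine's diagnostics)
check_density <- function(rho, tol_herm = 1e-9, tol_trace = 1e-9, tol_pos = 1e-8) {
  ok_h <- max(abs(rho - Conj(t(rho)))) <= tol_herm
  ok_t <- abs(mat_trace(rho) - 1) <= tol_trace
  ev <- eigen((rho + Conj(t(rho))) / 2, symmetric = TRUE, only.values = TRUE)$values
  ok_p <- min(ev) >= -tol_pos
  list(ok = ok_h && ok_t && ok_p, hermitian = ok_h, trace = ok_t, positive = ok_p,
       min_eigenvalue = min(ev))
}
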