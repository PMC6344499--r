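## Physical observables on states and ensembles.

#' z-magnetization of one spin
#'
#' \eqn{\langle \hat I_z \rangle = \mathrm{Tr}(\rho \hat I_{z})}, in
#' \[-1/2, +1/2\] for a spin-1/2.  Polarization as a fraction of maximum is
#' `2 * z_magnetization()` (multiply by 100 for percent).
#'
#' @param rho density matrix.
#' @param system a `spin_system`.
#' @param spin spin index.
#' @return numeric scalar.
#' @export
z_magnetization <- function(rho, system, spin) {
  Re(mat_trace(rho %*% spin_operator(system, spin, "z")))
}

#' Singlet population of a spin-1/2 pair
#'
#' @inheritParams z_magnetization
#' @param pair two spin indices.
#' @return population of the two-spin singlet state, in \[0, 1\].
#' @export
singlet_population <- function(rho, system, pair) {
  Re(mat_trace(rho %*% pair_projector(system, pair, "S0")))
}

#' Singlet population excess over a reference triplet state
#'
#' `population(S0) - population(T0)` (or `T-`), the conserved "fuel" whose
#' consumption by the transfer dynamics bounds how much magnetization a
#' bound complex can still create.  Optionally normalized to an initial
#' singlet population.
#'
#' @inheritParams singlet_population
#' @param reference `"T0"` or `"T_minus"`.
#' @param normalize optional initial S0 population to divide by.
#' @return numeric scalar.
#' @export
singlet_excess <- function(rho, system, pair, reference = c("T0", "T_minus"),
                           normalize = NULL) {
  reference <- match.arg(reference)
  ref_state <- if (reference == "T0") "T0" else "Tm"
  x <- Re(mat_trace(rho %*% (pair_projector(system, pair, "S0") -
                               pair_projector(system, pair, ref_state))))
  if (!is.null(normalize)) x <- x / normalize
  x
}

#' Exchange baseline of an ensemble trace
#'
#' The asymptotic polarization to which the ensemble dynamics converge as
#' successive unpolarized ligands bind and become polarized, estimated as
#' the mean of the ensemble-mean observable over a trailing window.
#'
#' @param ensemble an `ensemble_result` (needs >= 10 grid points).
#' @param window trailing fraction of the time grid to average (default 0.2).
#' @param observable column name or index (default 1).
#' @return `list(value, stderr)`.
#' @export
exchange_baseline <- function(ensemble, window = 0.2, observable = 1) {
  nt <- length(ensemble$time)
  if (nt < 10) stop("ensemble needs at least 10 grid points", call. = FALSE)
  k <- floor(window * nt)
  if (k < 1) stop("empty trailing window", call. = FALSE)
  idx <- seq(nt - k + 1, nt)
  m <- ensemble$mean[idx, observable]
  se <- ensemble$stderr[idx, observable]
  list(value = mean(m), stderr = sqrt(sum(se^2)) / length(idx))
}

#' Ensemble-average the dissociated-ligand density matrices
#'
#' Event-weighted average of the reduced density matrices of every ligand
#' that dissociated, across a set of trajectories (or one `ensemble_result`).
#' This is the experimentally detected free-ligand pool.
#'
#' @param trajectories list of [run_trajectory()] results, or a single
#'   `ensemble_result`.
#' @param ligand_group group id to accumulate.
#' @return unit-trace density matrix on the ligand subspace.
#' @export
accumulate_dissociated_density <- function(trajectories, ligand_group) {
  key <- as.character(ligand_group)
  if (inherits(trajectories, "ensemble_result")) {
    d <- trajectories$departed[[key]]
    if (is.null(d)) stop("no dissociation events recorded for group ",
                         ligand_group, call. = FALSE)
    return(d$state)
  }
  s <- NULL; n <- 0L
  for (tr in trajectories) {
    if (!is.null(tr$departed$sum[[key]])) {
      s <- if (is.null(s)) tr$departed$sum[[key]] else s + tr$departed$sum[[key]]
      n <- n + tr$departed$n[[key]]
    }
  }
  if (n == 0L) stop("no dissociation events recorded for group ",
                    ligand_group, call. = FALSE)
  s / n
}

#' Total and per-pulse signal of an ensemble
#'
#' Terminal accumulated ensemble-mean signal and its ratio to the number of
#' sequence repetitions — the per-pulse efficiency measure used to compare
#' delay settings at constant experiment length.
#'
#' @param ensemble an `ensemble_result`.
#' @param sequence the `spin_sequence` that produced it.
#' @param observable column name or index (default 1).
#' @return `list(total_signal, per_pulse_signal, n_pulses)`.
#' @export
signal_per_pulse <- function(ensemble, sequence, observable = 1) {
  stopifnot(sequence$n >= 1)
  total <- ensemble$mean[nrow(ensemble$mean), observable]
  list(total_signal = unname(total),
       per_pulse_signal = unname(total) / sequence$n,
       n_pulses = sequence$n)
}
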