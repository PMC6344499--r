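## Hamiltonian builders.  All Hamiltonians are returned in rad/s; interface
## frequencies (J, offsets, rf nutation) are Hz, static fields are microtesla.

#' Describe one segment of a field/pulse schedule
#'
#' A `field_segment` is a period of constant (or linearly rf-ramped)
#' Hamiltonian.  In `low_field` mode the full scalar-coupling Hamiltonian is
#' used with Zeeman terms at static field `B0`.  In `high_field` mode the
#' rotating-frame Hamiltonian applies: species offsets, full homonuclear
#' couplings, secular (z-z) heteronuclear couplings, and an optional rf
#' field on one species whose nutation frequency may ramp linearly.
#'
#' @param duration segment length in s (>= 0).
#' @param mode `"low_field"` or `"high_field"`.
#' @param B0 static field in uT (low-field mode).
#' @param offsets named numeric vector: rotating-frame offset in Hz per
#'   species, e.g. `c("15N" = 5)` (high-field mode).
#' @param rf_init initial rf nutation frequency in Hz.
#' @param rf_ramp linear ramp rate of the nutation frequency in Hz/s; the
#'   ramp restarts at every segment.
#' @param rf_phase rf phase in rad (0 = x).
#' @param rf_species isotope tag the rf addresses (e.g. `"15N"`).
#' @param label free-text tag (`"evolution"`, `"storage"`, ...).
#' @return an object of class `field_segment`.
#' @export
field_segment <- function(duration, mode = c("low_field", "high_field"),
                          B0 = 0, offsets = NULL, rf_init = 0, rf_ramp = 0,
                          rf_phase = 0, rf_species = NULL, label = "") {
  mode <- match.arg(mode)
  if (!is.numeric(duration) || duration < 0) stop("duration must be >= 0", call. = FALSE)
  if (mode == "low_field" && (rf_init != 0 || rf_ramp != 0)) {
    stop("rf fields must be zero in low_field mode", call. = FALSE)
  }
  structure(list(duration = duration, mode = mode, B0 = B0, offsets = offsets,
                 rf_init = rf_init, rf_ramp = rf_ramp, rf_phase = rf_phase,
                 rf_species = rf_species, label = label),
            class = "field_segment")
}

# zero-duration ideal pulse marker used inside sequences
hard_pulse_event <- function(species, angle, phase = 0) {
  structure(list(duration = 0, species = species, angle = angle, phase = phase),
            class = "hard_pulse_event")
}

# full scalar coupling 2*pi*J * (IxIx + IyIy + IzIz) summed over a pair set
scalar_coupling_term <- function(system, pairs) {
  H <- matrix(0 + 0i, system$dim, system$dim)
  for (p in pairs) {
    i <- p[1]; j <- p[2]; Jij <- system$J[i, j]
    if (Jij == 0) next
    H <- H + 2 * pi * Jij *
      (spin_operator(system, i, "x") %*% spin_operator(system, j, "x") +
       spin_operator(system, i, "y") %*% spin_operator(system, j, "y") +
       spin_operator(system, i, "z") %*% spin_operator(system, j, "z"))
  }
  H
}

all_pairs <- function(n) {
  out <- list()
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) out[[length(out) + 1]] <- c(i, j)
  out
}

#' Low-field (strong-coupling) Hamiltonian
#'
#' Zeeman terms for every spin at static field `B0` plus the full scalar
#' coupling for every pair, homonuclear and heteronuclear alike — the
#' strong-coupling limit appropriate at microtesla fields, where level
#' anti-crossings between hydride and heteronuclear manifolds drive
#' SHEATH-type polarization transfer.
#'
#' @param system a `spin_system`.
#' @param B0 static field in uT (>= 0).
#' @return Hermitian complex matrix in rad/s.
#' @export
low_field_hamiltonian <- function(system, B0) {
  if (B0 < 0) stop("B0 must be >= 0", call. = FALSE)
  n <- length(system$dims)
  H <- matrix(0 + 0i, system$dim, system$dim)
  for (i in seq_len(n)) {
    w <- 2 * pi * system$gamma[i] * B0          # signed Larmor, rad/s
    if (w != 0) H <- H + w * spin_operator(system, i, "z")
  }
  H + scalar_coupling_term(system, all_pairs(n))
}

#' High-field rotating-frame Hamiltonian
#'
#' Rotating-frame offsets per species, full homonuclear couplings, secular
#' (z-z truncated) heteronuclear couplings, and the rf term
#' \eqn{\omega_1(t) (\cos\phi \, S_x + \sin\phi \, S_y)} on the addressed
#' species, with \eqn{\omega_1(t)/2\pi} ramping linearly within the segment.
#'
#' @param system a `spin_system`.
#' @param segment a high-field `field_segment`.
#' @param t_within time inside the segment (s) at which to evaluate a ramped
#'   rf amplitude; ignored when the ramp rate is zero.
#' @param secular if `FALSE`, keep the full heteronuclear scalar coupling
#'   (consistency switch: with zero rf this reproduces the low-field form).
#' @return Hermitian complex matrix in rad/s.
#' @export
high_field_hamiltonian <- function(system, segment, t_within = 0, secular = TRUE) {
  stopifnot(inherits(segment, "field_segment"))
  if (segment$mode != "high_field") stop("segment is not high_field", call. = FALSE)
  if (t_within < 0 || t_within > segment$duration + 1e-12) {
    stop("t_within outside the segment", call. = FALSE)
  }
  n <- length(system$dims)
  H <- matrix(0 + 0i, system$dim, system$dim)
  offs <- segment$offsets
  if (!is.null(offs)) {
    for (i in seq_len(n)) {
      sp <- system$species[i]
      if (sp %in% names(offs) && offs[[sp]] != 0) {
        H <- H + 2 * pi * offs[[sp]] * spin_operator(system, i, "z")
      }
    }
  }
  pairs <- all_pairs(n)
  homo <- Filter(function(p) system$species[p[1]] == system$species[p[2]], pairs)
  hetero <- Filter(function(p) system$species[p[1]] != system$species[p[2]], pairs)
  H <- H + scalar_coupling_term(system, homo)
  if (secular) {
    for (p in hetero) {
      Jij <- system$J[p[1], p[2]]
      if (Jij == 0) next
      H <- H + 2 * pi * Jij * spin_operator(system, p[1], "z") %*%
        spin_operator(system, p[2], "z")
    }
  } else {
    H <- H + scalar_coupling_term(system, hetero)
  }
  if (!is.null(segment$rf_species) &&
      (segment$rf_init != 0 || segment$rf_ramp != 0)) {
    if (!segment$rf_species %in% system$species) {
      stop("rf_target_species ", segment$rf_species, " absent from system",
           call. = FALSE)
    }
    w1 <- 2 * pi * (segment$rf_init + segment$rf_ramp * t_within)
    Sx <- species_operator(system, segment$rf_species, "x")
    Sy <- species_operator(system, segment$rf_species, "y")
    H <- H + w1 * (cos(segment$rf_phase) * Sx + sin(segment$rf_phase) * Sy)
  }
  H
}

# Hamiltonian of a segment at a given time inside it
segment_hamiltonian <- function(system, segment, t_within = 0) {
  if (segment$mode == "low_field") low_field_hamiltonian(system, segment$B0)
  else high_field_hamiltonian(system, segment, t_within)
}
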