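## Pulse-acquire spectrum synthesis from a (dissociated-)ligand density
## matrix: 90-degree read pulse, FID sampling under the free-ligand
## high-field Hamiltonian, exponential apodization, discrete Fourier
## transform.

#' Synthesize a pulse-acquire NMR spectrum
#'
#' Seeds a simple pulse-acquire experiment with `rho_ligand` (typically the
#' ensemble-averaged dissociated-ligand density matrix): an ideal 90-degree
#' pulse on the detected species, then an FID
#' \eqn{s(t_k) = \mathrm{Tr}(\rho(t_k) \sum_i \hat I_i^+)} sampled at dwell
#' intervals under the ligand's free-evolution Hamiltonian (per-spin
#' chemical-shift offsets, full homonuclear J couplings, secular
#' heteronuclear couplings), apodized with `exp(-pi * lb * t)` and Fourier
#' transformed.
#'
#' @param rho_ligand density matrix on the ligand spin system.
#' @param ligand_system a `spin_system` describing the free ligand.
#' @param offsets numeric vector of per-spin chemical-shift offsets in Hz
#'   (length = number of spins).
#' @param acquisition list with `dwell` (s, > 0), `points` (power of 2) and
#'   `line_broadening` (Hz, default 1).
#' @param detect_species species detected (default `"1H"`).
#' @return `list(frequency, spectrum, fid, dwell)`: `frequency` in Hz
#'   (ascending, centered on 0), `spectrum` complex.
#' @export
simulate_spectrum <- function(rho_ligand, ligand_system, offsets,
                              acquisition = list(dwell = 5e-4, points = 1024,
                                                 line_broadening = 1),
                              detect_species = "1H") {
  dwell <- acquisition$dwell
  np <- acquisition$points
  lb <- acquisition$line_broadening %||% 1
  if (!(dwell > 0)) stop("dwell must be > 0", call. = FALSE)
  if (np < 2 || bitwAnd(np, np - 1L) != 0) {
    stop("acquisition points must be a power of 2", call. = FALSE)
  }
  n <- length(ligand_system$dims)
  if (length(offsets) != n) stop("offsets must have one entry per spin", call. = FALSE)
  if (!all(dim(rho_ligand) == c(ligand_system$dim, ligand_system$dim))) {
    stop("rho_ligand has wrong dimension", call. = FALSE)
  }

  # free-evolution Hamiltonian: offsets + homonuclear full / hetero secular J
  H <- matrix(0 + 0i, ligand_system$dim, ligand_system$dim)
  for (i in seq_len(n)) {
    if (offsets[i] != 0) H <- H + 2 * pi * offsets[i] * spin_operator(ligand_system, i, "z")
  }
  pairs <- all_pairs(n)
  homo <- Filter(function(p) ligand_system$species[p[1]] == ligand_system$species[p[2]], pairs)
  hetero <- setdiff(pairs, homo)
  H <- H + scalar_coupling_term(ligand_system, homo)
  for (p in hetero) {
    Jij <- ligand_system$J[p[1], p[2]]
    if (Jij != 0) {
      H <- H + 2 * pi * Jij * spin_operator(ligand_system, p[1], "z") %*%
        spin_operator(ligand_system, p[2], "z")
    }
  }

  rho <- hard_pulse(rho_ligand, ligand_system, detect_species, pi / 2, phase = pi / 2)
  det_idx <- which(ligand_system$species == detect_species)
  Fp <- Reduce(`+`, lapply(det_idx, function(i) spin_operator(ligand_system, i, "+")))
  tFp <- t(Fp)

  U <- expm_herm(H, dwell)
  Uh <- Conj(t(U))
  fid <- complex(np)
  t_axis <- (seq_len(np) - 1) * dwell
  for (k in seq_len(np)) {
    fid[k] <- sum(tFp * rho)
    if (k < np) rho <- U %*% rho %*% Uh
  }
  fid <- fid * exp(-pi * lb * t_axis)
  fid[1] <- fid[1] / 2            # half-first-point for flat baseline
  spec <- fft(fid)
  # reorder to an ascending frequency axis centered on zero
  half <- np / 2
  spec <- c(spec[(half + 1):np], spec[1:half])
  freq <- (seq_len(np) - 1 - half) / (np * dwell)
  list(frequency = freq, spectrum = spec, fid = fid, dwell = dwell)
}
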