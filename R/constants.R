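## Nuclear constants.  Gyromagnetic ratios are gamma / 2*pi in Hz per microtesla
## (signed).  Only nuclei that occur in SABRE systems supported here are listed;
## 14N is the single spin-1 species allowed (as a quadrupolar auxiliary).

.GYRO_HZ_PER_UT <- c(
  "1H"  = 42.57747892,
  "2H"  = 6.53590,
  "13C" = 10.70840,
  "15N" = -4.31627,
  "14N" = 3.07770,
  "19F" = 40.07757,
  "31P" = 17.25150
)

.SPIN_QUANTUM <- c(
  "1H" = 0.5, "2H" = 1, "13C" = 0.5, "15N" = 0.5,
  "14N" = 1, "19F" = 0.5, "31P" = 0.5
)

#' Gyromagnetic ratio of a nuclear species
#'
#' Signed ratio \eqn{\gamma/2\pi} in Hz per microtesla, so that the Larmor
#' frequency at a static field \eqn{B_0} (in uT) is \eqn{\nu = \gamma B_0}.
#' At 1 uT this gives \eqn{|\nu| \approx 42.6} Hz for 1H and
#' \eqn{\approx 4.3} Hz for 15N.
#'
#' @param species isotope tag, e.g. `"1H"`, `"15N"`, `"14N"`.
#' @return numeric scalar, Hz/uT (negative for nuclei such as 15N).
#' @export
#' @examples
#' gyromagnetic_ratio("1H")   #  42.577...
#' gyromagnetic_ratio("15N")  # -4.316...
gyromagnetic_ratio <- function(species) {
  if (!species %in% names(.GYRO_HZ_PER_UT)) {
    stop("unknown nuclear species: ", species, call. = FALSE)
  }
  unname(.GYRO_HZ_PER_UT[[species]])
}

# spin quantum number for a species (1/2 or 1)
species_spin <- function(species) {
  if (!species %in% names(.SPIN_QUANTUM)) {
    stop("unknown nuclear species: ", species, call. = FALSE)
  }
  unname(.SPIN_QUANTUM[[species]])
}
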