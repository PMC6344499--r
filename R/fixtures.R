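## Runnable fixture bundles: the four model systems, each with its exchange
## model, pulse sequence and (where needed) relaxation settings.  Lifetimes
## follow the fitted values of the experiments this engine models (target
## ligand 20 ms for the DARTH tris-pyridine complex, 50 ms for the SHEATH
## benzonitrile complex, hydride 547 ms); J couplings are the approximate
## built-in defaults.

.FIXTURES <- c("aaxx_darth", "aax_sheath", "aaxq_dilute", "eightspin_lineshape")

#' Generate a runnable SABRE fixture
#'
#' Returns a fully specified bundle (spin system + exchange model + pulse
#' sequence + optional relaxation + default observables) for one of the
#' four model systems:
#' \describe{
#'   \item{`aaxx_darth`}{4-spin AA'XX' (two hydrides, two 15N-pyridines),
#'     high-field DARTH sequence, target-ligand lifetime 20 ms.}
#'   \item{`aax_sheath`}{3-spin AA'X (two hydrides, one 15N-benzonitrile),
#'     pulsed SHEATH sequence, ligand lifetime 50 ms.}
#'   \item{`aaxq_dilute`}{4-spin AA'XQ with a quadrupolar 14N auxiliary
#'     (T_Q = 2.2 ms), isotopic enrichment zeta = 0.14 and the matching
#'     inactive period, DARTH with 600 ms delays.}
#'   \item{`eightspin_lineshape`}{8-spin AA'(XB2)(X'B'2) including the
#'     pyridine ortho protons; a single 25 ms DARTH pulse, used for
#'     dissociated-ligand spectrum synthesis.}
#' }
#' All J couplings are approximate (figure-only in their source) and
#' overridable by rebuilding the system.
#'
#' @param name one of `fixture_names()`.
#' @param n_rep override the number of sequence repetitions.
#' @return list with `name`, `system`, `model`, `sequence`, `relaxation`,
#'   `observables`, `description`.
#' @export
generate_fixture <- function(name, n_rep = NULL) {
  hydride_channel <- list(ligand_group = 1, mean_lifetime = 0.547)
  if (name == "aaxx_darth") {
    sys <- build_spin_system("AA'XX'")
    model <- exchange_model(
      channels = list(list(ligand_group = 2, mean_lifetime = 0.020),
                      list(ligand_group = 3, mean_lifetime = 0.020),
                      hydride_channel))
    seq_ <- sequence_preset("darth_fig2c", n = n_rep %||% 10)
    relax <- NULL
    desc <- "4-spin AA'XX' DARTH: 20 ms ligand lifetime, 25 ms ramped pulses"
  } else if (name == "aax_sheath") {
    sys <- build_spin_system("AA'X")
    model <- exchange_model(
      channels = list(list(ligand_group = 2, mean_lifetime = 0.050),
                      hydride_channel))
    seq_ <- sequence_preset("sheath_fig2d", n = n_rep %||% 6)
    relax <- NULL
    desc <- "3-spin AA'X pulsed SHEATH: 50 ms ligand lifetime, 350 ms storage"
  } else if (name == "aaxq_dilute") {
    sys <- build_spin_system("AA'XQ")
    model <- exchange_model(
      channels = list(list(ligand_group = 2, mean_lifetime = 0.020),
                      hydride_channel),
      zeta = 0.14, k_d_ligand = 20.4)
    seq_ <- sequence_preset("darth_fig3b", n = n_rep %||% 5)
    relax <- list(spin = which(sys$species == "14N")[1], T_Q = 0.0022)
    desc <- "4-spin AA'XQ, 14 percent enriched: T_Q = 2.2 ms 14N auxiliary"
  } else if (name == "eightspin_lineshape") {
    sys <- build_spin_system("AA'(XB2)(X'B'2)")
    model <- exchange_model(
      channels = list(list(ligand_group = 2, mean_lifetime = 0.020),
                      list(ligand_group = 3, mean_lifetime = 0.020),
                      hydride_channel))
    seq_ <- darth_sequence(tau_p = 0.025, tau_d = 0, n = n_rep %||% 1,
                           offset = 20)
    seq_$meta$name <- "eightspin_single_pulse"
    relax <- NULL
    desc <- "8-spin AA'(XB2)(X'B'2): single 25 ms DARTH pulse, lineshape seed"
  } else {
    stop("unknown fixture: ", name, " (see fixture_names())", call. = FALSE)
  }
  list(name = name, system = sys, model = model, sequence = seq_,
       relaxation = relax, observables = default_observables(sys),
       description = desc)
}

#' Names of the built-in fixtures
#' @return character vector of length 4.
#' @export
fixture_names <- function() .FIXTURES
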