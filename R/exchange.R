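## Discrete-event chemical exchange: event sampling, ligand replacement by
## partial trace + tensor insertion, and parahydrogen replenishment.

#' Describe the chemical-exchange model
#'
#' Each dissociation channel addresses one ligand group of the spin system
#' (the hydride pair's group models H2 exchange; target-ligand groups model
#' ligand exchange) with its own mean bound lifetime.  Events are sampled
#' either literally from a uniform distribution with a fixed count per
#' trajectory (`uniform_count`, the default, matching the Monte Carlo
#' recipe this engine reproduces) or as a Poisson process (`exponential`).
#'
#' @param channels list of `list(ligand_group =, mean_lifetime =)` entries;
#'   `mean_lifetime` in s, `Inf` disables a channel.
#' @param event_mode `"uniform_count"` or `"exponential"`.
#' @param replenish_fraction f in \[0,1\]: fraction of singlet order restored
#'   on each hydride exchange event.
#' @param para_enrichment fraction of fresh H2 in the singlet state.
#' @param zeta isotopic enrichment of the target ligand, in (0, 1].
#' @param k_d_ligand ligand dissociation rate constant in 1/s (used for the
#'   inactive period `1/(k_d * zeta)` when `zeta < 1`).
#' @param fresh_ligand_state `"maximally_mixed"` or
#'   `list(type = "thermal", polarization = p)`.
#' @param replenish_mode `"deterministic"` (mixture weight f) or
#'   `"stochastic"` (Bernoulli-f full replacement).
#' @return object of class `exchange_model`.
#' @export
exchange_model <- function(channels,
                           event_mode = c("uniform_count", "exponential"),
                           replenish_fraction = 1,
                           para_enrichment = 1,
                           zeta = 1,
                           k_d_ligand = NULL,
                           fresh_ligand_state = "maximally_mixed",
                           replenish_mode = c("deterministic", "stochastic")) {
  event_mode <- match.arg(event_mode)
  replenish_mode <- match.arg(replenish_mode)
  channels <- lapply(channels, function(ch) {
    if (is.null(ch$ligand_group) || is.null(ch$mean_lifetime)) {
      stop("each channel needs ligand_group and mean_lifetime", call. = FALSE)
    }
    if (!(ch$mean_lifetime > 0)) stop("lifetimes must be > 0", call. = FALSE)
    ch$ligand_group <- as.integer(ch$ligand_group)
    ch$mean_lifetime <- as.numeric(ch$mean_lifetime)
    ch
  })
  chk01 <- function(x, nm) if (x < 0 || x > 1) stop(nm, " must be in [0,1]", call. = FALSE)
  replenish_fraction <- as.numeric(replenish_fraction)
  para_enrichment <- as.numeric(para_enrichment)
  zeta <- as.numeric(zeta)
  chk01(replenish_fraction, "replenish_fraction")
  chk01(para_enrichment, "para_enrichment")
  if (!(zeta > 0 && zeta <= 1)) stop("zeta must be in (0, 1]", call. = FALSE)
  structure(list(channels = channels, event_mode = event_mode,
                 replenish_fraction = replenish_fraction,
                 para_enrichment = para_enrichment, zeta = zeta,
                 k_d_ligand = k_d_ligand,
                 fresh_ligand_state = fresh_ligand_state,
                 replenish_mode = replenish_mode),
            class = "exchange_model")
}

#' Sample dissociation events for one trajectory
#'
#' In `uniform_count` mode each channel contributes exactly
#' `round(T_sim / mean_lifetime)` event times drawn i.i.d. uniform on
#' `[0, T_sim]`; in `exponential` mode the count is Poisson with mean
#' `T_sim / mean_lifetime` (a homogeneous Poisson process).  Draws come from
#' R's current RNG stream — seed before calling for reproducibility.
#'
#' @param T_sim trajectory length in s (> 0).
#' @param model an `exchange_model`.
#' @return `data.frame(time, ligand_group)` sorted by time.
#' @export
sample_dissociation_events <- function(T_sim, model) {
  stopifnot(T_sim > 0)
  times <- numeric(0); groups <- integer(0)
  for (ch in model$channels) {
    if (!is.finite(ch$mean_lifetime)) next
    N <- if (model$event_mode == "uniform_count") {
      as.integer(round(T_sim / ch$mean_lifetime))
    } else {
      rpois(1, T_sim / ch$mean_lifetime)
    }
    if (N > 0) {
      times <- c(times, runif(N, 0, T_sim))
      groups <- c(groups, rep(as.integer(ch$ligand_group), N))
    }
  }
  ord <- order(times)
  data.frame(time = times[ord], ligand_group = groups[ord])
}

# density matrix of a fresh (unpolarized or weakly thermally polarized)
# ligand on the spins of `group`
fresh_ligand_dm <- function(system, group, spec) {
  dims <- system$dims[group]
  if (identical(spec, "maximally_mixed")) {
    d <- prod(dims)
    return(eye(d) / d)
  }
  if (is.list(spec) && identical(spec$type, "thermal")) {
    p <- spec$polarization
    blocks <- lapply(seq_along(group), function(k) {
      s <- system$s[group[k]]
      m <- seq(s, -s)
      pop <- 1 + 2 * m * p          # linearized high-temperature populations
      diag(as.complex(pop / sum(pop)), length(m))
    })
    return(kron_list(blocks))
  }
  stop("unknown fresh_ligand_state", call. = FALSE)
}

#' Dissociate a ligand group and bind a fresh one
#'
#' The departing group is removed by partial trace (tensor contraction in
#' the spin product basis) and a fresh ligand state is tensored back in at
#' the same tensor slots.  Coherences among the remaining spins are exactly
#' preserved: their reduced density matrix is identical before and after.
#'
#' @param rho density matrix on the full space.
#' @param system a `spin_system`.
#' @param ligand_group group id to dissociate.
#' @param model an `exchange_model` (supplies the fresh-ligand state).
#' @param fresh optional explicit fresh-state density matrix on the group.
#' @return `list(rho = new density matrix, departed = reduced density matrix
#'   of the departing ligand)`.
#' @export
dissociate_and_replace <- function(rho, system, ligand_group, model = NULL,
                                   fresh = NULL) {
  group <- which(system$ligand_group == ligand_group)
  if (length(group) == 0) stop("unknown ligand group ", ligand_group, call. = FALSE)
  rest <- setdiff(seq_along(system$dims), group)
  departed <- ptrace(rho, system$dims, keep = group)
  if (is.null(fresh)) {
    spec <- if (is.null(model)) "maximally_mixed" else model$fresh_ligand_state
    fresh <- fresh_ligand_dm(system, group, spec)
  }
  kept <- ptrace(rho, system$dims, keep = rest)
  new_rho <- embed_state(list(kept, fresh), list(rest, group), system$dims)
  list(rho = new_rho, departed = departed)
}

# density matrix of fresh hydrogen: para_enrichment-weighted singlet
fresh_h2_dm <- function(para_enrichment) {
  ps <- proj(pair_state_vectors()$S0)
  para_enrichment * ps + (1 - para_enrichment) * eye(4) / 4
}

#' Fractionally replenish parahydrogen singlet order
#'
#' Models a hydride/H2 exchange event.  With weight `replenish_fraction` f
#' the hydride pair is replaced (partial trace + tensor insertion) by fresh
#' hydrogen whose singlet content is `para_enrichment`; with weight 1-f the
#' state is unchanged.  `replenish_mode = "deterministic"` applies the
#' f-weighted mixture; `"stochastic"` makes a Bernoulli(f) choice using the
#' current RNG stream.
#'
#' @param rho density matrix.
#' @param system a `spin_system` with a hydride pair.
#' @param model an `exchange_model`.
#' @return `list(rho =, departed = reduced hydride state before the event)`.
#' @export
replenish_parahydrogen <- function(rho, system, model) {
  hyd <- which(system$role == "hydride")
  if (length(hyd) != 2) stop("system has no hydride pair", call. = FALSE)
  hgroup <- system$ligand_group[hyd[1]]
  f <- model$replenish_fraction
  departed <- ptrace(rho, system$dims, keep = hyd)
  if (f == 0) return(list(rho = rho, departed = departed))
  fresh <- fresh_h2_dm(model$para_enrichment)
  rep_ <- dissociate_and_replace(rho, system, hgroup, fresh = fresh)
  if (model$replenish_mode == "stochastic") {
    if (runif(1) < f) return(list(rho = rep_$rho, departed = departed))
    return(list(rho = rho, departed = departed))
  }
  list(rho = f * rep_$rho + (1 - f) * rho, departed = departed)
}

#' Hyperpolarization-inactive period for isotopically dilute samples
#'
#' Mean time during which a catalyst carries no polarizable (labeled)
#' ligand: \eqn{T_{inactive} = (k_d \zeta)^{-1}}.
#'
#' @param model an `exchange_model` with `k_d_ligand` and `zeta` set.
#' @return time in s.
#' @export
#' @examples
#' m <- exchange_model(list(list(ligand_group = 2, mean_lifetime = 0.02)),
#'                     zeta = 0.5, k_d_ligand = 10)
#' inactive_period(m)  # 0.2 s
inactive_period <- function(model) {
  if (is.null(model$k_d_ligand) || !(model$k_d_ligand > 0)) {
    stop("k_d_ligand must be set and > 0", call. = FALSE)
  }
  if (!(model$zeta > 0)) stop("zeta must be > 0", call. = FALSE)
  1 / (model$k_d_ligand * model$zeta)
}
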