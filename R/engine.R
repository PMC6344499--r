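## The quantum Monte Carlo engine: a single stochastic trajectory alternates
## coherent Liouville-von Neumann evolution through the pulse sequence with
## discrete dissociation events (partial trace + fresh-ligand insertion,
## fractional parahydrogen replenishment); the ensemble layer averages many
## trajectories run from independent RNG substreams.
##
## Performance notes: everything reusable across trajectories (segment
## eigendecompositions, hard-pulse unitaries, exchange-event tensor layouts,
## compiled observables, the initial state) lives in a cache environment
## shared across the ensemble; exchange events use precomputed contiguous-
## block reshapes rather than the generic ptrace()/embed_state() path.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default observables for a SABRE system
#'
#' Bound-complex z-magnetization of the first target heteronucleus
#' (`target_z`), the experimentally detected pool signal `target_pool_z`
#' (cumulative z-magnetization carried off by dissociated ligands plus the
#' currently bound contribution), and the hydride-pair singlet population.
#'
#' @param system a `spin_system`.
#' @return named list of observable specs (see [run_trajectory()]).
#' @export
default_observables <- function(system) {
  obs <- list()
  tgt <- which(system$role == "target" & system$s == 0.5 &
                 system$species != "1H")
  if (length(tgt) == 0) tgt <- which(system$role == "target")
  if (length(tgt) > 0) {
    obs$target_z <- list(kind = "z_magnetization", spin = tgt[1])
    obs$target_pool_z <- list(kind = "pool_z", spin = tgt[1])
  }
  hyd <- which(system$role == "hydride")
  if (length(hyd) == 2) {
    obs$hydride_singlet <- list(kind = "singlet_population", pair = hyd)
  }
  obs
}

# z operator on the subspace of one ligand group, for the spin at system
# index `spin` (which must belong to the group)
group_z_operator <- function(system, spin) {
  g <- system$ligand_group[spin]
  idx <- which(system$ligand_group == g)
  pos <- match(spin, idx)
  ops <- lapply(seq_along(idx), function(k) {
    if (k == pos) single_spin_ops(system$s[idx[k]])$z else eye(system$dims[idx[k]])
  })
  kron_list(ops)
}

# Compile observable specs.  Each compiled entry has:
#   top   - transposed full-space operator for the bound part (or NULL)
#   group - ligand group whose departed states feed a cumulative part (or NA)
#   gtop  - transposed group-subspace operator applied to departed states
compile_observables <- function(system, specs) {
  comp <- lapply(specs, function(sp) {
    switch(sp$kind,
      z_magnetization = list(top = t(spin_operator(system, sp$spin, "z")),
                             group = NA_integer_, gtop = NULL),
      singlet_population = list(top = t(pair_projector(system, sp$pair, "S0")),
                                group = NA_integer_, gtop = NULL),
      triplet_population = list(
        top = t(pair_projector(system, sp$pair, sp$state %||% "T0")),
        group = NA_integer_, gtop = NULL),
      singlet_excess = list(
        top = t(pair_projector(system, sp$pair, "S0") -
                  pair_projector(system, sp$pair,
                                 switch(sp$reference %||% "T0",
                                        T0 = "T0", T_minus = "Tm",
                                        T_plus = "Tp"))),
        group = NA_integer_, gtop = NULL),
      pool_z = list(top = t(spin_operator(system, sp$spin, "z")),
                    group = system$ligand_group[sp$spin],
                    gtop = t(group_z_operator(system, sp$spin))),
      departed_z = list(top = NULL,
                        group = system$ligand_group[sp$spin],
                        gtop = t(group_z_operator(system, sp$spin))),
      custom = list(top = t(sp$operator), group = NA_integer_, gtop = NULL),
      stop("unknown observable kind: ", sp$kind, call. = FALSE)
    )
  })
  list(names = names(specs), comp = comp)
}

# Exchange-event applier for one contiguous ligand group: dissociation
# (partial trace) and fresh-state insertion via precomputed linear-index
# tables over the (b, g, a, b2, g2, a2) tensor layout (group index g, spins
# before the group a, after it b; b fastest in column-major order).
make_group_applier <- function(system, group_id) {
  idx <- which(system$ligand_group == group_id)
  if (length(idx) == 0) stop("unknown ligand group ", group_id, call. = FALSE)
  n <- length(system$dims)
  da <- prod(system$dims[seq_len(n) < idx[1]])
  dg <- prod(system$dims[idx])
  db <- prod(system$dims[seq_len(n) > idx[length(idx)]])
  D <- system$dim
  D2 <- D * D
  dab <- db * da
  lin <- function(b, g, a, b2, g2, a2) {
    b + db * ((g - 1) + dg * ((a - 1) + da * ((b2 - 1) + db * ((g2 - 1) +
      dg * (a2 - 1)))))
  }
  ab <- expand.grid(b = seq_len(db), a = seq_len(da))
  gg <- expand.grid(g = seq_len(dg), g2 = seq_len(dg))
  abab <- expand.grid(b = seq_len(db), a = seq_len(da),
                      b2 = seq_len(db), a2 = seq_len(da))
  ng <- nrow(gg)
  dep_idx <- matrix(0L, dab, ng)
  pos_idx <- matrix(0L, dab * dab, ng)
  for (k in seq_len(ng)) {
    dep_idx[, k] <- lin(ab$b, gg$g[k], ab$a, ab$b, gg$g2[k], ab$a)
    pos_idx[, k] <- lin(abab$b, gg$g[k], abab$a, abab$b2, gg$g2[k], abab$a2)
  }
  kept_idx <- matrix(0L, dg, dab * dab)
  for (g in seq_len(dg)) {
    kept_idx[g, ] <- lin(abab$b, g, abab$a, abab$b2, g, abab$a2)
  }
  ones_ab <- matrix(1 + 0i, 1, dab)
  ones_g <- matrix(1 + 0i, 1, dg)
  list(
    group = group_id,
    departed = function(rho) {
      v <- rho[dep_idx]
      dim(v) <- c(dab, ng)
      dep <- ones_ab %*% v
      dim(dep) <- c(dg, dg)
      dep
    },
    replace = function(rho, fresh) {
      v <- rho[kept_idx]
      dim(v) <- c(dg, dab * dab)
      kept <- ones_g %*% v
      out <- vector("complex", D2)
      dim(kept) <- c(dab * dab, 1)
      dim(fresh) <- c(1, ng)
      out[pos_idx] <- kept %*% fresh
      dim(out) <- c(D, D)
      out
    }
  )
}

# fresh bound-complex state: para-enriched hydrogen on the hydride pair,
# fresh (unpolarized) ligands elsewhere, mixed auxiliaries
initial_state <- function(system, model = NULL) {
  pe <- if (is.null(model)) 1 else model$para_enrichment
  hyd <- which(system$role == "hydride")
  groups <- list(); states <- list()
  if (length(hyd) == 2) {
    groups <- c(groups, list(hyd))
    states <- c(states, list(fresh_h2_dm(pe)))
  }
  for (g in unique(system$ligand_group)) {
    idx <- which(system$ligand_group == g)
    if (length(hyd) == 2 && g == system$ligand_group[hyd[1]]) next
    spec <- if (is.null(model)) "maximally_mixed" else model$fresh_ligand_state
    groups <- c(groups, list(idx))
    states <- c(states, list(fresh_ligand_dm(system, idx, spec)))
  }
  embed_state(states, groups, system$dims)
}

# one-time per-ensemble preparation shared by all trajectories
trajectory_setup <- function(system, sequence, model, observables, relaxation,
                             control, cache) {
  su <- cache$.setup
  if (!is.null(su)) return(su)
  els <- sequence$elements
  durs <- vapply(els, function(e) e$duration, numeric(1))
  el_end <- cumsum(durs)
  el_start <- el_end - durs
  is_seg <- vapply(els, inherits, logical(1), "field_segment")
  seginfos <- vector("list", length(els))
  for (k in which(is_seg)) seginfos[[k]] <- make_seginfo(system, els[[k]], control, cache)
  pulse_idx <- which(vapply(els, inherits, logical(1), "hard_pulse_event"))
  pulse_U <- vector("list", length(els))
  for (k in pulse_idx) {
    p <- els[[k]]
    key <- paste("hp", p$species, p$angle, p$phase, sep = "|")
    if (is.null(cache[[key]])) {
      Fx <- species_operator(system, p$species, "x")
      Fy <- species_operator(system, p$species, "y")
      cache[[key]] <- expm_herm(cos(p$phase) * Fx + sin(p$phase) * Fy, p$angle)
    }
    pulse_U[[k]] <- cache[[key]]
  }
  cobs <- compile_observables(system, observables)
  groups <- unique(vapply(model$channels, function(ch) as.integer(ch$ligand_group),
                          integer(1)))
  appliers <- vector("list", max(groups))
  fresh <- vector("list", max(groups))
  for (g in groups) {
    appliers[[g]] <- make_group_applier(system, g)
    fresh[[g]] <- fresh_ligand_dm(system, which(system$ligand_group == g),
                                  model$fresh_ligand_state)
  }
  hyd <- which(system$role == "hydride")
  hyd_group <- if (length(hyd) == 2) system$ligand_group[hyd[1]] else NA_integer_
  su <- list(els = els, el_start = el_start, el_end = el_end,
             seginfos = seginfos, pulse_idx = pulse_idx, pulse_U = pulse_U,
             pulse_times = el_start[pulse_idx],
             cobs = cobs, appliers = appliers, fresh = fresh,
             fresh_h2 = fresh_h2_dm(model$para_enrichment),
             hyd_group = hyd_group,
             rho_init = initial_state(system, model))
  cache$.setup <- su
  su
}

#' Run one stochastic SABRE trajectory
#'
#' Alternates coherent propagation through the sequence with the sampled
#' dissociation events, in time order.  Hydride-group events fractionally
#' replenish parahydrogen singlet order; target-ligand events trace out the
#' departing ligand (its reduced density matrix is accumulated — the
#' experimentally detected free pool) and bind a fresh unpolarized one.
#' When `model$zeta < 1` the trajectory starts at a random offset within
#' `[0, T_inactive + T_sim]` (hyperpolarization-inactive periods) and is
#' frozen once its single active ligand departs.
#'
#' @param system a `spin_system`.
#' @param sequence a `spin_sequence`.
#' @param model an `exchange_model`.
#' @param seed integer seed for this trajectory (`NULL`: use current RNG state).
#' @param grid output time grid in s (default: 201 points over the sequence).
#' @param observables named list of observable specs, each a list with
#'   `kind` (`"z_magnetization"`, `"singlet_population"`,
#'   `"triplet_population"`, `"singlet_excess"`, `"pool_z"`, `"departed_z"`,
#'   `"custom"`) and the `spin` / `pair` indices it needs (a `custom` spec
#'   carries `operator`).  `pool_z` records cumulative dissociated-ligand
#'   z-magnetization plus the bound contribution; `departed_z` the
#'   cumulative part only.
#' @param rho0 initial density matrix (default: fresh bound complex).
#' @param relaxation optional `list(spin =, T_Q =)` quadrupolar damping of an
#'   auxiliary spin, first-order-split with coherent steps of `T_Q / 20`.
#' @param control a `propagation_control`.
#' @param cache environment shared across trajectories of an ensemble.
#' @param start_offset explicit activation time (overrides the random
#'   offset; only used when `zeta < 1`).
#' @return list with `time`, `obs` (matrix time x observable), `departed`
#'   (per ligand group: summed reduced density matrices and event count),
#'   `n_events`, `frozen_at` (`NA` unless a dilute trajectory froze) and
#'   `t_activation`.
#' @export
run_trajectory <- function(system, sequence, model, seed = NULL, grid = NULL,
                           observables = NULL, rho0 = NULL, relaxation = NULL,
                           control = propagation_control(), cache = NULL,
                           start_offset = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  T_total <- sequence$duration
  stopifnot(T_total > 0)
  if (is.null(grid)) grid <- seq(0, T_total, length.out = 201)
  grid <- sort(grid)
  if (grid[1] < -1e-12 || grid[length(grid)] > T_total + 1e-9) {
    stop("grid times outside the sequence", call. = FALSE)
  }
  specs <- observables %||% default_observables(system)
  su <- trajectory_setup(system, sequence, model, specs, relaxation, control,
                         cache)
  cobs <- su$cobs
  nobs <- length(cobs$comp)

  # dilution: random activation offset, single active binding
  dilute <- model$zeta < 1
  t_act <- 0
  if (dilute) {
    Tin <- inactive_period(model)
    t_act <- start_offset %||% runif(1, 0, Tin + T_total)
  }
  events <- sample_dissociation_events(T_total, model)
  if (dilute) events <- events[events$time >= t_act, , drop = FALSE]
  ev_time <- events$time
  ev_group <- events$ligand_group
  n_ev <- length(ev_time)

  relax_dt <- if (!is.null(relaxation)) relaxation$T_Q / 20 else Inf

  rho <- rho0 %||% su$rho_init
  if (!all(dim(rho) == c(system$dim, system$dim))) {
    stop("rho0 has wrong dimension", call. = FALSE)
  }

  ngroups <- length(su$appliers)
  dep_sum <- vector("list", ngroups)
  dep_n <- integer(ngroups)
  cum <- numeric(nobs)                     # cumulative departed parts
  out <- matrix(NA_real_, length(grid), nobs,
                dimnames = list(NULL, cobs$names))

  eps <- 1e-12
  bp <- sort(unique(c(0, grid, su$el_start, su$el_end, ev_time, T_total)))
  bp <- bp[bp >= -eps & bp <= T_total + eps]
  n_bp <- length(bp)
  # element covering each interval (bp[k-1], bp[k])
  mids <- (bp[-1] + bp[-n_bp]) / 2
  el_of <- findInterval(mids, su$el_start)
  el_of[el_of < 1L] <- 1L
  el_of[el_of > length(su$els)] <- length(su$els)

  comp <- cobs$comp
  jseq <- seq_len(nobs)
  f_rep <- model$replenish_fraction
  stoch <- model$replenish_mode == "stochastic"
  hyd_group <- su$hyd_group

  gi <- 1L; ei <- 1L; frozen <- FALSE; frozen_at <- NA_real_
  ngrid <- length(grid)
  while (gi <= ngrid && grid[gi] <= eps) {
    for (j in jseq) {
      cj <- comp[[j]]
      v <- cum[j]
      if (!is.null(cj$top)) v <- v + Re(sum(cj$top * rho))
      out[gi, j] <- v
    }
    gi <- gi + 1L
  }

  for (b_i in 2:n_bp) {
    a <- bp[b_i - 1]; b <- bp[b_i]
    if (b - a > eps && !frozen && (!dilute || b > t_act)) {
      a_eff <- if (dilute && a < t_act) t_act else a
      k <- el_of[b_i - 1]
      si <- su$seginfos[[k]]
      if (!is.null(si)) {
        t0 <- a_eff - su$el_start[k]; t1 <- b - su$el_start[k]
        if (is.null(relaxation)) {
          rho <- evolve_interval(rho, si, t0, t1)
        } else {
          m <- max(1L, ceiling((t1 - t0) / relax_dt))
          ts <- seq(t0, t1, length.out = m + 1)
          for (kk in seq_len(m)) {
            rho <- evolve_interval(rho, si, ts[kk], ts[kk + 1])
            rho <- apply_quadrupolar_relaxation(rho, system, relaxation$spin,
                                                relaxation$T_Q, ts[kk + 1] - ts[kk])
          }
        }
      }
    }
    if (!frozen) {
      for (k in su$pulse_idx[abs(su$pulse_times - b) <= eps]) {
        if (!dilute || b >= t_act) {
          U <- su$pulse_U[[k]]
          rho <- U %*% rho %*% Conj(t(U))
        }
      }
      while (ei <= n_ev && ev_time[ei] <= b + eps) {
        g <- ev_group[ei]
        ap <- su$appliers[[g]]
        dep <- ap$departed(rho)
        if (!is.na(hyd_group) && g == hyd_group) {
          if (f_rep > 0) {
            replaced <- ap$replace(rho, su$fresh_h2)
            if (stoch) {
              if (runif(1) < f_rep) rho <- replaced
            } else if (f_rep == 1) {
              rho <- replaced
            } else {
              rho <- f_rep * replaced + (1 - f_rep) * rho
            }
          }
        } else {
          rho <- ap$replace(rho, su$fresh[[g]])
          if (dilute) { frozen <- TRUE; frozen_at <- ev_time[ei] }
        }
        if (is.null(dep_sum[[g]])) dep_sum[[g]] <- dep
        else dep_sum[[g]] <- dep_sum[[g]] + dep
        dep_n[g] <- dep_n[g] + 1L
        for (j in jseq) {
          cj <- comp[[j]]
          if (!is.null(cj$gtop) && !is.na(cj$group) && cj$group == g) {
            cum[j] <- cum[j] + Re(sum(cj$gtop * dep))
          }
        }
        ei <- ei + 1L
        if (frozen) break
      }
    }
    while (gi <= ngrid && grid[gi] <= b + eps) {
      for (j in jseq) {
        cj <- comp[[j]]
        v <- cum[j]
        if (!is.null(cj$top)) v <- v + Re(sum(cj$top * rho))
        out[gi, j] <- v
      }
      gi <- gi + 1L
    }
  }
  nz <- which(!vapply(dep_sum, is.null, logical(1)))
  list(time = grid, obs = out,
       departed = list(sum = setNames(dep_sum[nz], as.character(nz)),
                       n = setNames(as.list(dep_n[nz]), as.character(nz))),
       n_events = n_ev, frozen_at = frozen_at, t_activation = t_act)
}

#' Run a Monte Carlo ensemble of SABRE trajectories
#'
#' Runs `n_iterations` independent trajectories, each seeded from its own
#' substream derived from `master_seed`, and accumulates per-time-point
#' means, standard errors, and the ensemble-summed reduced density matrices
#' of every dissociated ligand.
#'
#' @inheritParams run_trajectory
#' @param n_iterations number of trajectories (>= 1).
#' @param master_seed integer master seed; all randomness derives from it.
#' @param ... passed on to [run_trajectory()].
#' @return object of class `ensemble_result` with fields `time`, `mean`,
#'   `stderr` (matrices time x observable), `departed` (per-group averaged
#'   reduced density matrix, total and per-trajectory mean event counts),
#'   `n_iterations`, `master_seed`, `mean_events`.
#' @export
run_ensemble <- function(system, sequence, model, n_iterations,
                         master_seed = 1L, grid = NULL, observables = NULL,
                         control = propagation_control(), ...) {
  stopifnot(n_iterations >= 1)
  set.seed(master_seed)
  seeds <- sample.int(2147483646L, n_iterations, replace = FALSE)
  cache <- new.env(parent = emptyenv())
  s1 <- s2 <- NULL
  dep_sum <- list(); dep_n <- list()
  tot_events <- 0
  tgrid <- NULL
  for (i in seq_len(n_iterations)) {
    tr <- run_trajectory(system, sequence, model, seed = seeds[i], grid = grid,
                         observables = observables, control = control,
                         cache = cache, ...)
    if (is.null(s1)) {
      s1 <- tr$obs * 0; s2 <- s1; tgrid <- tr$time
    }
    s1 <- s1 + tr$obs
    s2 <- s2 + tr$obs^2
    tot_events <- tot_events + tr$n_events
    for (key in names(tr$departed$sum)) {
      if (is.null(dep_sum[[key]])) {
        dep_sum[[key]] <- tr$departed$sum[[key]]
        dep_n[[key]] <- tr$departed$n[[key]]
      } else {
        dep_sum[[key]] <- dep_sum[[key]] + tr$departed$sum[[key]]
        dep_n[[key]] <- dep_n[[key]] + tr$departed$n[[key]]
      }
    }
  }
  n <- n_iterations
  mean_ <- s1 / n
  var_ <- pmax(s2 / n - mean_^2, 0) * n / max(1, n - 1)
  stderr_ <- sqrt(var_ / n)
  departed <- lapply(names(dep_sum), function(key) {
    list(ligand_group = as.integer(key),
         state = dep_sum[[key]] / dep_n[[key]],
         total_events = dep_n[[key]],
         mean_events = dep_n[[key]] / n)
  })
  names(departed) <- names(dep_sum)
  structure(list(time = tgrid, mean = mean_, stderr = stderr_,
                 departed = departed, n_iterations = n,
                 master_seed = master_seed, mean_events = tot_events / n),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result: %d iterations, %d time points, seed %d>\n",
              x$n_iterations, length(x$time), x$master_seed))
  cat(sprintf("  observables: %s\n", paste(colnames(x$mean), collapse = ", ")))
  cat(sprintf("  mean dissociation events per trajectory: %.2f\n", x$mean_events))
  term <- x$mean[nrow(x$mean), ]
  cat("  terminal means: ",
      paste(sprintf("%s = %.5g", colnames(x$mean), term), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy data frame of an ensemble result
#'
#' @param x an `ensemble_result`.
#' @param ... unused.
#' @return `data.frame(time, observable, mean, stderr)` in long format.
#' @export
as.data.frame.ensemble_result <- function(x, ...) {
  obs <- colnames(x$mean)
  do.call(rbind, lapply(seq_along(obs), function(j) {
    data.frame(time = x$time, observable = obs[j],
               mean = x$mean[, j], stderr = x$stderr[, j])
  }))
}
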