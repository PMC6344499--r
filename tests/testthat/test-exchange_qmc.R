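sheath_bundle <- function() generate_fixture("aax_sheath")

test_that("dissociation event sampling has the documented statistics", {
  m <- exchange_model(list(list(ligand_group = 2, mean_lifetime = Inf)))
  set.seed(1)
  expect_equal(nrow(sample_dissociation_events(1, m)), 0)

  # uniform_count: exactly round(T/tau) events
  m2 <- exchange_model(list(list(ligand_group = 2, mean_lifetime = 0.05)))
  set.seed(2)
  ev <- sample_dissociation_events(1, m2)
  expect_equal(nrow(ev), 20)
  expect_true(all(diff(ev$time) >= 0))
  expect_true(all(ev$time >= 0 & ev$time <= 1))

  # exponential mode: Poisson(20) counts; mean over many draws within 3 SE
  m3 <- exchange_model(list(list(ligand_group = 2, mean_lifetime = 0.05)),
                       event_mode = "exponential")
  set.seed(3)
  counts <- replicate(3000, nrow(sample_dissociation_events(1, m3)))
  se <- sqrt(20 / 3000)
  expect_lt(abs(mean(counts) - 20), 3 * se)
  # variance consistent with Poisson (loose sanity band)
  expect_gt(var(counts), 20 * 0.8)
  expect_lt(var(counts), 20 * 1.2)
})

test_that("exchange model validates its parameters", {
  ch <- list(list(ligand_group = 2, mean_lifetime = 0.05))
  expect_error(exchange_model(list(list(ligand_group = 2))), "mean_lifetime")
  expect_error(exchange_model(list(list(ligand_group = 2, mean_lifetime = -1))),
               "> 0")
  expect_error(exchange_model(ch, replenish_fraction = 1.2), "0,1")
  expect_error(exchange_model(ch, zeta = 0), "zeta")
})

test_that("dissociation replaces the ligand but preserves the rest exactly", {
  sys <- build_spin_system("AA'X")
  rho <- propagate(singlet_state(sys), sys,
                   field_segment(0.06, "low_field", B0 = 0.6))
  r <- dissociate_and_replace(rho, sys, 2)
  # departing state is the reduced ligand state
  expect_lt(mat_dev(r$departed, ptrace(rho, sys$dims, keep = 3)), 1e-12)
  # coherences among remaining spins exactly preserved
  expect_lt(mat_dev(ptrace(r$rho, sys$dims, keep = c(1, 2)),
                    ptrace(rho, sys$dims, keep = c(1, 2))), 1e-13)
  # fresh ligand is maximally mixed and uncorrelated
  expect_lt(mat_dev(ptrace(r$rho, sys$dims, keep = 3), diag(0.5 + 0i, 2)), 1e-12)
  expect_equal(Re(sum(diag(r$rho))), 1, tolerance = 1e-12)
  expect_error(dissociate_and_replace(rho, sys, 9), "unknown ligand group")

  # singlet pair: trace out one member, replace -> both maximally mixed
  pair <- build_spin_system(
    data.frame(label = c("a", "b"), species = "1H",
               role = c("hydride", "hydride"), ligand_group = c(1L, 2L)),
    J = matrix(0, 2, 2))
  rs <- two_spin_singlet()
  out <- dissociate_and_replace(rs, pair, 2)
  expect_lt(mat_dev(out$rho, diag(0.25 + 0i, 4)), 1e-12)

  # departing state of an unevolved fresh ligand equals the fresh state
  fresh0 <- dissociate_and_replace(singlet_state(sys), sys, 2)
  expect_lt(mat_dev(fresh0$departed, diag(0.5 + 0i, 2)), 1e-12)
})

test_that("parahydrogen replenishment restores the stated singlet content", {
  sys <- build_spin_system("AA'X")
  rho <- propagate(singlet_state(sys), sys,
                   field_segment(0.08, "low_field", B0 = 0.6))

  m1 <- exchange_model(list(list(ligand_group = 1, mean_lifetime = 0.5)),
                       replenish_fraction = 1, para_enrichment = 1)
  out <- replenish_parahydrogen(rho, sys, m1)
  expect_equal(singlet_population(out$rho, sys, c(1, 2)), 1, tolerance = 1e-12)

  m0 <- exchange_model(list(list(ligand_group = 1, mean_lifetime = 0.5)),
                       replenish_fraction = 0)
  expect_lt(mat_dev(replenish_parahydrogen(rho, sys, m0)$rho, rho), 1e-13)

  # f = 1, 50% para: S0 = 0.5 + 0.5 * 1/4 = 0.625 whatever the prior state
  mh <- exchange_model(list(list(ligand_group = 1, mean_lifetime = 0.5)),
                       replenish_fraction = 1, para_enrichment = 0.5)
  out2 <- replenish_parahydrogen(rho, sys, mh)
  expect_equal(singlet_population(out2$rho, sys, c(1, 2)), 0.625,
               tolerance = 1e-12)
  # the 15N reduced state is untouched by hydride exchange
  expect_lt(mat_dev(ptrace(out2$rho, sys$dims, keep = 3),
                    ptrace(rho, sys$dims, keep = 3)), 1e-12)
})

test_that("the inactive period is (k_d * zeta)^-1", {
  ch <- list(list(ligand_group = 2, mean_lifetime = 0.02))
  expect_equal(inactive_period(exchange_model(ch, zeta = 0.5, k_d_ligand = 10)),
               0.2)
  expect_equal(inactive_period(exchange_model(ch, zeta = 1, k_d_ligand = 8)),
               1 / 8)
  # the 14%-enriched sample's ~350 ms inactive period
  expect_equal(inactive_period(exchange_model(ch, zeta = 0.14, k_d_ligand = 20.4)),
               0.35, tolerance = 0.01)
  expect_error(inactive_period(exchange_model(ch, zeta = 0.5)), "k_d_ligand")
})

test_that("trajectories with all channels disabled equal closed LvN evolution", {
  fx <- sheath_bundle()
  m0 <- exchange_model(list(list(ligand_group = 2, mean_lifetime = Inf)))
  grid <- cumsum(rep(c(0.05, 0.35), 6))
  tr <- run_trajectory(fx$system, fx$sequence, m0, seed = 4, grid = grid)
  # closed-form reference: segment-by-segment propagation
  rho <- singlet_state(fx$system)
  segE <- field_segment(0.05, "low_field", B0 = 0.6)
  segS <- field_segment(0.35, "low_field", B0 = 55)
  k <- 1
  for (cyc in 1:6) {
    rho <- propagate(rho, fx$system, segE)
    expect_lt(abs(tr$obs[k, "target_z"] - z_magnetization(rho, fx$system, 3)),
              1e-9)
    k <- k + 1
    rho <- propagate(rho, fx$system, segS)
    expect_lt(abs(tr$obs[k, "target_z"] - z_magnetization(rho, fx$system, 3)),
              1e-9)
    k <- k + 1
  }
})

test_that("identical seeds give bit-identical trajectories", {
  fx <- sheath_bundle()
  g <- seq(0, fx$sequence$duration, length.out = 7)
  t1 <- run_trajectory(fx$system, fx$sequence, fx$model, seed = 33, grid = g)
  t2 <- run_trajectory(fx$system, fx$sequence, fx$model, seed = 33, grid = g)
  expect_identical(t1$obs, t2$obs)
  expect_identical(t1$departed, t2$departed)
  e1 <- run_ensemble(fx$system, fx$sequence, fx$model, 5, master_seed = 9, grid = g)
  e2 <- run_ensemble(fx$system, fx$sequence, fx$model, 5, master_seed = 9, grid = g)
  expect_identical(e1$mean, e2$mean)
})

test_that("trace and Hermiticity survive event/propagation interleaving", {
  fx <- sheath_bundle()
  tr <- run_trajectory(fx$system, fx$sequence, fx$model, seed = 15,
                       grid = c(0, fx$sequence$duration))
  expect_true(all(is.finite(tr$obs)))
  # spot-check the departed accumulator: Hermitian, unit-trace average
  dep <- tr$departed$sum[["2"]] / tr$departed$n[["2"]]
  expect_lt(mat_dev(dep, Conj(t(dep))), 1e-10)
  expect_equal(Re(sum(diag(dep))), 1, tolerance = 1e-10)
})

test_that("dilute trajectories activate late and freeze after one ligand loss", {
  fx <- generate_fixture("aaxq_dilute", n_rep = 2)
  # forced activation at t = 0.1 s with a long-T_inactive model
  tr <- run_trajectory(fx$system, fx$sequence, fx$model, seed = 21,
                       relaxation = fx$relaxation, start_offset = 0.1,
                       grid = seq(0, fx$sequence$duration, length.out = 13))
  expect_equal(tr$t_activation, 0.1)
  # before activation nothing has happened: fresh-state observables
  expect_equal(unname(tr$obs[1, "target_z"]), 0, tolerance = 1e-9)
  if (!is.na(tr$frozen_at)) {
    expect_gte(tr$frozen_at, 0.1)
    # frozen state: bound ligand fresh, so late bound polarization ~ 0
    expect_lt(abs(tr$obs[13, "target_z"]), 1e-9)
  }
  # quasi-CW contract: T_inactive >> T_sim means most trajectories never activate
  mqcw <- exchange_model(fx$model$channels, zeta = 0.01, k_d_ligand = 8)
  expect_gt(inactive_period(mqcw), 12)
  set.seed(77)
  acts <- replicate(40, {
    t <- run_trajectory(fx$system, fx$sequence, mqcw,
                        relaxation = fx$relaxation,
                        grid = c(0, fx$sequence$duration))
    t$t_activation < fx$sequence$duration
  })
  expect_lt(mean(acts), 0.5)
})

test_that("ensembles report zero stderr without exchange randomness", {
  fx <- sheath_bundle()
  m0 <- exchange_model(list(list(ligand_group = 2, mean_lifetime = Inf)))
  ens <- run_ensemble(fx$system, fx$sequence, m0, 4, master_seed = 2,
                      grid = c(0, fx$sequence$duration))
  expect_true(all(ens$stderr == 0))
  expect_equal(ens$mean_events, 0)
})
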