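# Independent oracles and small generators used across the suite.
# These deliberately avoid the package's own tensor machinery.

# brute-force partial trace by explicit multi-index loops
brute_ptrace <- function(rho, dims, keep) {
  n <- length(dims)
  keep <- sort(keep)
  drop_ <- setdiff(seq_len(n), keep)
  dk <- prod(dims[keep])
  # multi-index (i1..in), spin 1 slowest, as in kron(A1, ..., An)
  idx_of <- function(multi) {
    i <- 0
    for (k in seq_len(n)) i <- i * dims[k] + (multi[k] - 1)
    i + 1
  }
  grids <- lapply(dims, seq_len)
  keep_states <- expand.grid(rev(grids[keep]))[, rev(seq_along(keep)), drop = FALSE]
  drop_states <- expand.grid(rev(grids[drop_]))[, rev(seq_along(drop_)), drop = FALSE]
  out <- matrix(0 + 0i, dk, dk)
  for (r in seq_len(nrow(keep_states))) for (cc in seq_len(nrow(keep_states))) {
    acc <- 0 + 0i
    for (d in seq_len(max(1, nrow(drop_states)))) {
      mr <- integer(n); mc <- integer(n)
      mr[keep] <- as.integer(keep_states[r, ]); mc[keep] <- as.integer(keep_states[cc, ])
      if (length(drop_) > 0) {
        mr[drop_] <- as.integer(drop_states[d, ]); mc[drop_] <- as.integer(drop_states[d, ])
      }
      acc <- acc + rho[idx_of(mr), idx_of(mc)]
    }
    out[r, cc] <- acc
  }
  out
}

# random density matrix (Hermitian, psd, unit trace)
rand_density <- function(d) {
  A <- matrix(complex(real = rnorm(d * d), imaginary = rnorm(d * d)), d, d)
  rho <- A %*% Conj(t(A))
  rho / Re(sum(diag(rho)))
}

# random unitary from a random Hermitian generator
rand_unitary <- function(d) {
  A <- matrix(complex(real = rnorm(d * d), imaginary = rnorm(d * d)), d, d)
  H <- (A + Conj(t(A))) / 2
  e <- eigen(H, symmetric = TRUE)
  e$vectors %*% (exp(-1i * e$values) * Conj(t(e$vectors)))
}

# classical 4th-order Runge-Kutta integration of the Liouville-von Neumann
# equation d rho/dt = -i [H, rho] -- the independent propagation oracle
rk4_lvn <- function(rho, H, t_total, dt) {
  f <- function(r) -1i * (H %*% r - r %*% H)
  nstep <- round(t_total / dt)
  for (k in seq_len(nstep)) {
    k1 <- f(rho)
    k2 <- f(rho + dt / 2 * k1)
    k3 <- f(rho + dt / 2 * k2)
    k4 <- f(rho + dt * k3)
    rho <- rho + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  rho
}

mat_dev <- function(a, b) max(abs(a - b))

# hydride-pair singlet density matrix helpers on a bare two-spin space
two_spin_singlet <- function() {
  v <- c(0, 1, -1, 0) / sqrt(2)
  outer(as.complex(v), Conj(as.complex(v)))
}
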