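## Tensor-product bookkeeping for multi-spin density matrices.
##
## Convention: the full Hilbert space is the Kronecker product of the
## single-spin spaces taken in spin order, kron(A1, A2, ..., An), so spin 1
## is the slowest-varying index.  In R's column-major array layout a D x D
## matrix reshaped to c(rev(dims), rev(dims)) therefore exposes spin k's row
## index on axis (n - k + 1) and its column index on axis (2n - k + 1).

# Kronecker product of a list of matrices, left to right.
kron_list <- function(mats) {
  Reduce(function(a, b) a %x% b, mats)
}

# identity on a subspace of dimension d
eye <- function(d) diag(1 + 0i, d)

mat_trace <- function(m) sum(diag(m))

is_hermitian <- function(m, tol = 1e-10) {
  s <- max(abs(m))
  if (s == 0) return(TRUE)
  max(abs(m - Conj(t(m)))) <= tol * max(1, s)
}

#' Partial trace of a multi-spin operator
#'
#' Traces out every subsystem not listed in `keep`, returning the reduced
#' operator on the kept subsystems (in ascending spin order).
#'
#' @param rho complex matrix on the full product space.
#' @param dims integer vector of subsystem dimensions, in spin order.
#' @param keep indices (into `dims`) of the subsystems to retain.
#' @return complex matrix of dimension `prod(dims[keep])`.
#' @export
ptrace <- function(rho, dims, keep) {
  n <- length(dims)
  keep <- sort(as.integer(keep))
  stopifnot(length(keep) >= 1, all(keep >= 1), all(keep <= n))
  if (length(keep) == n) return(rho)
  drop_ <- setdiff(seq_len(n), keep)
  dk <- prod(dims[keep])
  dd <- prod(dims[drop_])

  arr <- rho
  dim(arr) <- c(rev(dims), rev(dims))
  row_axis <- function(k) n - k + 1L
  perm <- c(sort(row_axis(keep)), sort(row_axis(keep)) + n,
            sort(row_axis(drop_)), sort(row_axis(drop_)) + n)
  arr <- aperm(arr, perm)
  dim(arr) <- c(dk, dk, dd, dd)
  out <- matrix(0 + 0i, dk, dk)
  for (i in seq_len(dd)) out <- out + arr[, , i, i]
  out
}

#' Reorder the subsystems of a multi-spin operator
#'
#' Returns the same operator expressed with subsystem `order[j]` of the
#' input as subsystem `j` of the output.
#'
#' @param rho complex matrix on the product space.
#' @param dims subsystem dimensions of `rho`, in its current spin order.
#' @param order permutation of `seq_along(dims)`.
#' @return complex matrix with permuted tensor factors.
#' @export
spin_permute <- function(rho, dims, order) {
  n <- length(dims)
  stopifnot(length(order) == n, all(sort(order) == seq_len(n)))
  if (all(order == seq_len(n))) return(rho)
  arr <- rho
  dim(arr) <- c(rev(dims), rev(dims))
  # output axis (fastest first) j holds output spin (n - j + 1) = input spin
  # order[n - j + 1], i.e. input row axis n - order[n - j + 1] + 1
  perm_row <- n - rev(order) + 1L
  arr <- aperm(arr, c(perm_row, perm_row + n))
  d <- prod(dims)
  dim(arr) <- c(d, d)
  arr
}

# Build a full-space state from block states living on groups of spins.
# `groups` is a list of ascending index vectors partitioning seq_along(dims);
# `states` the matching list of block operators.  The result carries spin i of
# the system on tensor slot i regardless of group order.
embed_state <- function(states, groups, dims) {
  ord <- unlist(groups)
  n <- length(dims)
  stopifnot(length(ord) == n, all(sort(ord) == seq_len(n)))
  K <- kron_list(states)
  spin_permute(K, dims[ord], match(seq_len(n), ord))
}
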