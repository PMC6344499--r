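## Spin systems: the ordered spin list, its J-coupling network, and the
## operator algebra on the product basis.

.ROLES <- c("hydride", "target", "auxiliary", "coligand")

# single-spin angular momentum matrices for arbitrary spin s (1/2 or 1 here).
# Basis ordering: m = +s, +s-1, ..., -s.
single_spin_ops <- function(s) {
  m <- seq(s, -s)
  d <- length(m)
  jz <- diag(m + 0i, d)
  jp <- matrix(0 + 0i, d, d)
  for (k in seq_len(d - 1)) {
    # raising: |m+1> <m|, with m = m[k + 1]
    jp[k, k + 1] <- sqrt(s * (s + 1) - m[k + 1] * (m[k + 1] + 1))
  }
  jm <- Conj(t(jp))
  list(
    x = (jp + jm) / 2,
    y = (jp - jm) / (2i),
    z = jz,
    `+` = jp,
    `-` = jm,
    e = diag(1 + 0i, d)
  )
}

#' Build a SABRE spin system
#'
#' Either from a built-in topology name or from an explicit spin table plus
#' J-coupling matrix.  Built-in topologies model the canonical SABRE
#' polarization-transfer-catalyst spin systems: two parahydrogen-derived
#' hydrides (the AA' pair) coupled to one or two exchangeable heteronuclear
#' targets and, optionally, a quadrupolar 14N auxiliary or the ortho protons
#' of the pyridine ring.  Their default J couplings are standard Ir-IMes
#' SABRE literature magnitudes and are *approximate* (the source systems
#' report them only graphically); every value can be overridden via `J`.
#'
#' Spins are ordered hydrides first, then targets (grouped per ligand), then
#' auxiliaries, so that every dissociation group is contiguous in the tensor
#' layout.  Internally indices are 1-based.
#'
#' @param descriptor topology name (`"AA'X"`, `"AA'XX'"`, `"AA'XQ"`,
#'   `"AA'(XB2)(X'B'2)"`) or a `data.frame` with columns `label`, `species`,
#'   `role`, `ligand_group`.
#' @param J optional symmetric J-coupling matrix in Hz (zero diagonal).  For
#'   built-in topologies it overrides the defaults; required for explicit
#'   tables.
#' @return an object of class `spin_system`.
#' @export
#' @examples
#' sys <- build_spin_system("AA'X")
#' sys$dim  # 8
build_spin_system <- function(descriptor, J = NULL) {
  if (is.character(descriptor) && length(descriptor) == 1) {
    built <- builtin_topology(descriptor)
    tab <- built$table
    Jmat <- if (is.null(J)) built$J else as.matrix(J)
    approx_flag <- is.null(J)
  } else if (is.data.frame(descriptor)) {
    tab <- descriptor
    if (is.null(J)) stop("explicit spin tables require a J matrix", call. = FALSE)
    Jmat <- as.matrix(J)
    approx_flag <- FALSE
  } else {
    stop("descriptor must be a topology name or a spin data.frame", call. = FALSE)
  }
  new_spin_system(tab, Jmat, approx_J = approx_flag)
}

new_spin_system <- function(tab, J, approx_J = FALSE) {
  need <- c("label", "species", "role", "ligand_group")
  if (!all(need %in% names(tab))) {
    stop("spin table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  n <- nrow(tab)
  species <- as.character(tab$species)
  role <- as.character(tab$role)
  if (!all(role %in% .ROLES)) {
    stop("unknown role(s): ", paste(setdiff(role, .ROLES), collapse = ", "), call. = FALSE)
  }
  s <- vapply(species, species_spin, numeric(1))
  if (any(s > 0.5 & !(species == "14N" & role == "auxiliary"))) {
    stop("spin > 1/2 supported only for auxiliary 14N", call. = FALSE)
  }
  nh <- sum(role == "hydride")
  if (!nh %in% c(0L, 2L)) {
    stop("a SABRE system carries exactly two hydride spins (found ", nh, ")",
         call. = FALSE)
  }
  dims <- as.integer(round(2 * s + 1))
  dim_total <- prod(dims)
  if (dim_total > 1024) {
    stop("Hilbert-space dimension ", dim_total, " exceeds the supported 1024",
         call. = FALSE)
  }
  J <- as.matrix(J)
  storage.mode(J) <- "double"
  if (!all(dim(J) == c(n, n))) stop("J must be ", n, " x ", n, call. = FALSE)
  if (max(abs(J - t(J))) > 1e-12) stop("J matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(J)) > 1e-12)) stop("J matrix must have zero diagonal", call. = FALSE)
  # dissociation groups must be contiguous for the partial-trace layout
  lg <- as.integer(tab$ligand_group)
  for (g in unique(lg)) {
    idx <- which(lg == g)
    if (any(diff(idx) != 1L)) {
      stop("ligand_group ", g, " is not contiguous in the spin ordering", call. = FALSE)
    }
  }
  sys <- list(
    labels = as.character(tab$label),
    species = species,
    gamma = vapply(species, gyromagnetic_ratio, numeric(1)),
    role = role,
    ligand_group = lg,
    s = s,
    dims = dims,
    dim = dim_total,
    J = unname(J),
    approx_J = approx_J,
    op_cache = new.env(parent = emptyenv())
  )
  class(sys) <- "spin_system"
  sys
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf("<spin_system: %d spins, Hilbert dimension %d>\n",
              length(x$species), x$dim))
  print(data.frame(label = x$labels, species = x$species, role = x$role,
                   group = x$ligand_group, s = x$s))
  if (isTRUE(x$approx_J)) {
    cat("J couplings: built-in defaults (approximate - figure-only in source)\n")
  }
  invisible(x)
}

# canonical spin table for round-tripping
spin_table <- function(system) {
  data.frame(label = system$labels, species = system$species,
              role = system$role, ligand_group = system$ligand_group,
              stringsAsFactors = FALSE)
}

builtin_topology <- function(name) {
  key <- toupper(gsub("[' ]", "", name))
  hyd <- function(lab) data.frame(label = lab, species = "1H", role = "hydride",
                                  ligand_group = 1L)
  jsym <- function(n, entries) {
    J <- matrix(0, n, n)
    for (e in entries) { J[e[[1]], e[[2]]] <- e[[3]]; J[e[[2]], e[[1]]] <- e[[3]] }
    J
  }
  # Approximate Ir-IMes SABRE couplings (Hz); trans 2J_NH dominates, cis small.
  J_HH <- -7; J_NH_t <- -23; J_NH_c <- -1
  scale14 <- gyromagnetic_ratio("14N") / gyromagnetic_ratio("15N")  # sign flip
  if (key %in% c("AAX", "AAX3SPIN")) {
    tab <- rbind(hyd("Ha"), hyd("Hb"),
                 data.frame(label = "N1", species = "15N", role = "target",
                            ligand_group = 2L))
    J <- jsym(3, list(list(1, 2, J_HH), list(1, 3, J_NH_t), list(2, 3, J_NH_c)))
  } else if (key %in% c("AAXX", "AAXX4SPIN")) {
    tab <- rbind(hyd("Ha"), hyd("Hb"),
                 data.frame(label = c("N1", "N2"), species = "15N",
                            role = "target", ligand_group = c(2L, 3L)))
    J <- jsym(4, list(list(1, 2, J_HH),
                      list(1, 3, J_NH_t), list(2, 3, J_NH_c),
                      list(2, 4, J_NH_t), list(1, 4, J_NH_c)))
  } else if (key %in% c("AAXQ")) {
    tab <- rbind(hyd("Ha"), hyd("Hb"),
                 data.frame(label = "N1", species = "15N", role = "target",
                            ligand_group = 2L),
                 data.frame(label = "Q1", species = "14N", role = "auxiliary",
                            ligand_group = 3L))
    # 14N couples only to the hydrides (relaxation sink), scaled by gamma ratio
    J <- jsym(4, list(list(1, 2, J_HH),
                      list(1, 3, J_NH_t), list(2, 3, J_NH_c),
                      list(2, 4, J_NH_t * scale14), list(1, 4, J_NH_c * scale14)))
  } else if (key %in% c("AA(XB2)(XB2)", "AAXB2XB2", "EIGHTSPIN")) {
    J_No <- -10.8   # pyridine 2J(15N - ortho H)
    J_4JHH <- 1.2   # long-range hydride <-> ortho-H
    tab <- rbind(hyd("Ha"), hyd("Hb"),
                 data.frame(label = c("N1", "Ho1a", "Ho1b"),
                            species = c("15N", "1H", "1H"), role = "target",
                            ligand_group = 2L),
                 data.frame(label = c("N2", "Ho2a", "Ho2b"),
                            species = c("15N", "1H", "1H"), role = "target",
                            ligand_group = 3L))
    J <- jsym(8, list(
      list(1, 2, J_HH),
      list(1, 3, J_NH_t), list(2, 3, J_NH_c),
      list(2, 6, J_NH_t), list(1, 6, J_NH_c),
      list(3, 4, J_No), list(3, 5, J_No),
      list(6, 7, J_No), list(6, 8, J_No),
      list(1, 4, J_4JHH), list(1, 5, J_4JHH),
      list(2, 7, J_4JHH), list(2, 8, J_4JHH)))
  } else {
    stop("unknown topology: ", name, call. = FALSE)
  }
  list(table = tab, J = J)
}

#' Embedded spin operator
#'
#' The single-spin operator of spin `index` (x, y, z, raising `+`, lowering
#' `-`) embedded in the full product space by Kronecker products with the
#' identity on every other spin.
#'
#' @param system a `spin_system`.
#' @param index spin index (1-based).
#' @param axis one of `"x"`, `"y"`, `"z"`, `"+"`, `"-"`.
#' @return dense complex matrix of dimension `system$dim`.
#' @export
spin_operator <- function(system, index, axis = c("x", "y", "z", "+", "-")) {
  axis <- match.arg(axis)
  n <- length(system$dims)
  if (!(is.numeric(index) && length(index) == 1 && index >= 1 && index <= n)) {
    stop("invalid spin index", call. = FALSE)
  }
  index <- as.integer(index)
  key <- paste0(index, axis)
  cache <- system$op_cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  op1 <- single_spin_ops(system$s[index])[[axis]]
  pre <- prod(system$dims[seq_len(index - 1)])
  post <- prod(system$dims[seq_len(n)[-seq_len(index)]])
  full <- eye(pre) %x% op1 %x% eye(post)
  cache[[key]] <- full
  full
}

# sum of an axis operator over all spins of one species
species_operator <- function(system, species, axis) {
  idx <- which(system$species == species)
  if (length(idx) == 0) stop("species ", species, " absent from system", call. = FALSE)
  Reduce(`+`, lapply(idx, function(i) spin_operator(system, i, axis)))
}

# embed an operator acting on the contiguous-or-not spin set `group`
# (ascending) with identity elsewhere
embed_operator <- function(system, op, group) {
  group <- sort(as.integer(group))
  rest <- setdiff(seq_along(system$dims), group)
  if (length(rest) == 0) return(op)
  embed_state(list(op, eye(prod(system$dims[rest]))),
              list(group, rest), system$dims)
}

## Two-spin singlet/triplet machinery --------------------------------------

# projectors onto the singlet and triplet states of a spin-1/2 pair,
# basis |aa>, |ab>, |ba>, |bb>
pair_state_vectors <- function() {
  s  <- c(0, 1, -1, 0) / sqrt(2)
  t0 <- c(0, 1, 1, 0) / sqrt(2)
  tp <- c(1, 0, 0, 0)
  tm <- c(0, 0, 0, 1)
  list(S0 = s, T0 = t0, Tp = tp, Tm = tm)
}

proj <- function(v) outer(as.complex(v), Conj(as.complex(v)))

# full-space projector onto a pair state ("S0", "T0", "Tp", "Tm")
pair_projector <- function(system, pair, state = "S0") {
  pair <- sort(as.integer(pair))
  stopifnot(length(pair) == 2, pair[1] != pair[2])
  if (any(system$s[pair] != 0.5)) stop("pair must be spin-1/2", call. = FALSE)
  v <- pair_state_vectors()[[state]]
  if (is.null(v)) stop("unknown pair state ", state, call. = FALSE)
  embed_operator(system, proj(v), pair)
}

#' Prepare a two-spin singlet density matrix
#'
#' Tensor product of the singlet projector on `pair` (the parahydrogen-derived
#' hydrides, in the SABRE context) with a state for the remaining spins
#' (default: maximally mixed, i.e. fully unpolarized ligands).
#'
#' @param system a `spin_system`.
#' @param pair two distinct spin-1/2 indices; default: the hydride pair.
#' @param rest optional density matrix for the remaining spins (unit trace).
#' @return unit-trace density matrix on the full space.
#' @export
singlet_state <- function(system, pair = NULL, rest = NULL) {
  if (is.null(pair)) pair <- which(system$role == "hydride")
  pair <- sort(as.integer(pair))
  if (length(pair) != 2 || pair[1] == pair[2]) {
    stop("pair must be two distinct spin indices", call. = FALSE)
  }
  if (any(system$s[pair] != 0.5)) stop("pair spins must be spin-1/2", call. = FALSE)
  others <- setdiff(seq_along(system$dims), pair)
  ps <- proj(pair_state_vectors()$S0)
  if (length(others) == 0) return(ps)
  dr <- prod(system$dims[others])
  if (is.null(rest)) {
    rest <- eye(dr) / dr
  } else {
    rest <- as.matrix(rest)
    if (!all(dim(rest) == c(dr, dr))) stop("rest has wrong dimension", call. = FALSE)
    if (abs(mat_trace(rest) - 1) > 1e-9) stop("rest must have unit trace", call. = FALSE)
  }
  embed_state(list(ps, rest), list(pair, others), system$dims)
}

# maximally mixed state on the full system
mixed_state <- function(system) eye(system$dim) / system$dim
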