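## Structured-text (JSON) run configuration: load, validate, fill defaults,
## round-trip, and the run manifest.

.CONFIG_DEFAULTS <- list(
  ensemble = list(iterations = 1600L, seed = 1L, grid_points = 201L)
)

#' Load and validate a run configuration
#'
#' The configuration is a JSON object with blocks `system` (either
#' `{"topology": name}` or `{"spins": [...], "J": [[...]]}`), `sequence`
#' (either `{"preset": name, "n": k}` or explicit builder parameters with a
#' `kind` of `"darth"` or `"sheath"`), `exchange` (the [exchange_model()]
#' fields), `ensemble` (`iterations`, `seed`, `grid_points`) and an optional
#' `relaxation` (`spin`, `T_Q`).  Alternatively a top-level
#' `{"fixture": name}` pulls a complete built-in bundle, with any other
#' blocks acting as overrides.  Missing fields are filled with defaults and
#' echoed back in the returned object.
#'
#' @param path path to a JSON configuration file.
#' @return object of class `sabre_config`: the filled configuration
#'   (`$spec`) plus built objects `$system`, `$sequence`, `$model`,
#'   `$relaxation`, `$ensemble`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  spec <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                             simplifyMatrix = TRUE)
  build_config(spec)
}

build_config <- function(spec) {
  bundle <- NULL
  if (!is.null(spec$fixture)) {
    if (!spec$fixture %in% fixture_names()) {
      stop("config error in 'fixture': unknown fixture ", spec$fixture,
           call. = FALSE)
    }
    bundle <- generate_fixture(spec$fixture)
  }

  # --- system ---
  if (!is.null(spec$system)) {
    sb <- spec$system
    if (!is.null(sb$topology)) {
      system <- build_spin_system(sb$topology, J = sb$J)
    } else if (!is.null(sb$spins)) {
      system <- build_spin_system(as.data.frame(sb$spins), J = sb$J)
    } else {
      stop("config error in 'system': need 'topology' or 'spins'", call. = FALSE)
    }
  } else if (!is.null(bundle)) {
    system <- bundle$system
  } else {
    stop("config error: missing required block 'system' (or 'fixture')",
         call. = FALSE)
  }

  # --- sequence ---
  if (!is.null(spec$sequence)) {
    sq <- spec$sequence
    if (!is.null(sq$preset)) {
      sequence <- sequence_preset(sq$preset, n = sq$n %||% 10)
    } else if (identical(sq$kind, "darth")) {
      sequence <- darth_sequence(sq$tau_p, sq$tau_d, sq$n %||% 1,
                                 rf_init = sq$rf_init %||% 32,
                                 ramp = sq$ramp %||% 42,
                                 offset = sq$offset %||% 0,
                                 refocus_1H = isTRUE(sq$refocus_1H))
    } else if (identical(sq$kind, "sheath")) {
      sequence <- sheath_sequence(sq$tau_p, sq$tau_d, sq$n %||% 1,
                                  B_evolution = sq$B_evolution %||% 0.6,
                                  B_storage = sq$B_storage %||% 55)
    } else {
      stop("config error in 'sequence': need 'preset' or kind darth/sheath",
           call. = FALSE)
    }
  } else if (!is.null(bundle)) {
    sequence <- bundle$sequence
  } else {
    stop("config error: missing required block 'sequence'", call. = FALSE)
  }

  # --- exchange ---
  if (!is.null(spec$exchange)) {
    ex <- spec$exchange
    if (is.null(ex$channels)) {
      stop("config error in 'exchange': missing 'channels'", call. = FALSE)
    }
    chans <- ex$channels
    if (is.data.frame(chans)) {
      chans <- lapply(seq_len(nrow(chans)), function(i) as.list(chans[i, ]))
    }
    model <- exchange_model(
      channels = chans,
      event_mode = ex$event_mode %||% "uniform_count",
      replenish_fraction = ex$replenish_fraction %||% 1,
      para_enrichment = ex$para_enrichment %||% 1,
      zeta = ex$zeta %||% 1,
      k_d_ligand = ex$k_d_ligand,
      fresh_ligand_state = ex$fresh_ligand_state %||% "maximally_mixed",
      replenish_mode = ex$replenish_mode %||% "deterministic")
  } else if (!is.null(bundle)) {
    model <- bundle$model
  } else {
    stop("config error: missing required block 'exchange'", call. = FALSE)
  }

  relaxation <- spec$relaxation %||% bundle$relaxation
  ens <- modifyList(.CONFIG_DEFAULTS$ensemble, spec$ensemble %||% list())
  ens <- lapply(ens, function(x) as.integer(x))

  filled <- list(
    fixture = spec$fixture,
    system = list(table = spin_table(system), J = system$J),
    sequence = c(sequence$meta, list(n = sequence$n)),
    exchange = unclass(model),
    relaxation = relaxation,
    ensemble = ens
  )
  filled <- filled[!vapply(filled, is.null, logical(1))]
  structure(list(spec = filled, system = system, sequence = sequence,
                 model = model, relaxation = relaxation, ensemble = ens),
            class = "sabre_config")
}

#' Write a configuration back to JSON
#'
#' `load_config(save_config(cfg, path))` reproduces `cfg$spec` exactly
#' (round-trip identity on the filled configuration).
#'
#' @param config a `sabre_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  spec <- config$spec
  out <- list(
    system = list(spins = spec$system$table, J = spec$system$J),
    sequence = sequence_spec_from_meta(spec$sequence),
    exchange = spec$exchange[!vapply(spec$exchange, is.null, logical(1))],
    relaxation = spec$relaxation,
    ensemble = spec$ensemble
  )
  out <- out[!vapply(out, is.null, logical(1))]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

sequence_spec_from_meta <- function(meta) {
  if (!is.null(meta$name)) return(list(preset = meta$name, n = meta$n))
  m <- meta
  if (identical(m$kind, "darth") || identical(m$kind, "darth_exsy")) {
    list(kind = "darth", tau_p = m$tau_p, tau_d = m$tau_d, n = m$n,
         rf_init = m$rf_init, ramp = m$ramp, offset = m$offset,
         refocus_1H = m$refocus_1H)
  } else {
    list(kind = "sheath", tau_p = m$tau_p, tau_d = m$tau_d, n = m$n,
         B_evolution = m$B_evolution, B_storage = m$B_storage)
  }
}

# small stable 31-bit polynomial hash for the manifest (no external digest
# dependency; only used to tag configs, not for security)
fnv1a <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a run manifest
#'
#' Records the configuration hash, master seed, package version and
#' wall-clock metadata next to a run's outputs; reruns with an identical
#' manifest reproduce identical outputs in deterministic modes.
#'
#' @param path output JSON path.
#' @param config a `sabre_config` (or NULL).
#' @param seed master seed used.
#' @param extra named list of additional entries.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = NULL, seed = NULL, extra = list()) {
  cfg_json <- if (!is.null(config)) {
    jsonlite::toJSON(config$spec, auto_unbox = TRUE, digits = NA, null = "null")
  } else ""
  man <- c(list(
    config_hash = fnv1a(as.character(cfg_json)),
    master_seed = seed,
    package_version = as.character(packageVersion("sabreqmc")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = if (!is.null(config)) config$spec else NULL
  ), extra)
  jsonlite::write_json(man[!vapply(man, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
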