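# Run configuration (YAML) and fixture generation.

config_error <- function(msg) {
  stop(structure(class = c("gasci_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

known_keys <- list(
  top = c("fcidump", "nelec", "ms2", "gas", "pchb", "dynamics", "seed",
          "output_dir", "log_level"),
  gas = c("spaces", "constraint_kind", "min", "max", "neutral", "n_exc"),
  pchb = c("gas", "p_double", "memory_cap_gb"),
  dynamics = c("time_step", "target_population", "initial_population",
               "shift_damping", "shift_interval", "initiator", "n_add",
               "adaptive", "adaptive_offset_frac", "f_halflife",
               "core_space_size", "ss_start", "max_iter", "equilibration",
               "generator", "rdm_sample", "rdm_start")
)

check_keys <- function(lst, allowed, where) {
  extra <- setdiff(names(lst), allowed)
  if (length(extra) > 0)
    config_error(paste0("unknown key(s) in ", where, ": ",
                        paste(extra, collapse = ", ")))
}

#' Build GAS objects from a configuration block
#'
#' @param gas_cfg A list with `spaces`, `constraint_kind` and either explicit
#'   `min`/`max` arrays or `neutral` plus `n_exc`.
#' @param nelec Total electron count.
#' @return A list: `partition`, `constraints`, `table`.
#' @export
gas_from_config <- function(gas_cfg, nelec) {
  check_keys(gas_cfg, known_keys$gas, "gas block")
  if (is.null(gas_cfg$spaces)) config_error("gas block: missing 'spaces'")
  partition <- gas_partition(unlist(gas_cfg$spaces))
  kind <- gas_cfg$constraint_kind
  if (is.null(kind) || !kind %in% c("local", "cumulative"))
    config_error("gas block: constraint_kind must be 'local' or 'cumulative'")
  if (!is.null(gas_cfg$neutral)) {
    if (is.null(gas_cfg$n_exc)) config_error("gas block: 'neutral' needs 'n_exc'")
    constraints <- band_constraints(partition, unlist(gas_cfg$neutral),
                                    gas_cfg$n_exc, kind)
  } else if (!is.null(gas_cfg$min) && !is.null(gas_cfg$max)) {
    constraints <- if (kind == "local")
      gas_local(unlist(gas_cfg$min), unlist(gas_cfg$max))
    else gas_cumulative(unlist(gas_cfg$min), unlist(gas_cfg$max))
  } else {
    config_error("gas block: give either min/max or neutral + n_exc")
  }
  diag <- validate_gas(partition, constraints, nelec)
  if (!diag$ok)
    config_error(paste0("invalid GAS constraints: ",
                        paste(diag$violations, collapse = "; ")))
  list(partition = partition, constraints = constraints,
       table = build_supergroup_table(partition, constraints, nelec))
}

#' Read and validate a run configuration file
#'
#' YAML with blocks `gas`, `pchb`, `dynamics` plus `fcidump`, `nelec`, `ms2`,
#' `seed`, `output_dir`.  Unknown keys are rejected before any computation.
#'
#' @param path YAML file path.
#' @return A validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) config_error(paste0("config file not found: ", path))
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) config_error(paste0("YAML parse error: ",
                                                          conditionMessage(e))))
  check_keys(cfg, known_keys$top, "config")
  for (f in c("fcidump", "nelec")) {
    if (is.null(cfg[[f]])) config_error(paste0("config: missing '", f, "'"))
  }
  if (is.null(cfg$ms2)) cfg$ms2 <- 0L
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$gas)) config_error("config: missing 'gas' block")
  if (!is.null(cfg$pchb)) check_keys(cfg$pchb, known_keys$pchb, "pchb block")
  if (!is.null(cfg$dynamics))
    check_keys(cfg$dynamics, known_keys$dynamics, "dynamics block")
  structure(cfg, class = "run_config")
}

# short content hash for provenance headers (FNV-1a over the deparsed object)
config_hash <- function(x) {
  s <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 2166136261
  for (b in s) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Write fixture files
#'
#' Writes reproducible test inputs: random FCIDUMPs (4, 6, 8 orbitals),
#' Hubbard chains (L = 2, 4, 6), GAS constraint specifications for the
#' worked supergroup-table example, the non-convertible cumulative example,
#' the five-fragment (6,6) occupation bands, the four-site (3,3) bands and a
#' RAS counting specification, plus a manifest of closed-form oracle values.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed controlling all random content.
#' @return Invisibly, the manifest list.
#' @export
make_fixtures <- function(outdir, seed = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(outdir, ...)
  for (n in c(4L, 6L, 8L)) {
    t <- synthetic_integrals(n, seed = seed + n)
    write_fcidump(t, fp(sprintf("random_%de%do.fcidump", n, n)),
                  nelec = n, ms2 = 0)
  }
  U <- 4; tt <- 1
  for (L in c(2L, 4L, 6L)) {
    write_fcidump(hubbard_integrals(L, U, tt), fp(sprintf("hubbard_L%d.fcidump", L)),
                  nelec = L, ms2 = 0)
  }
  specs <- list(
    table_example = list(spaces = c(2, 2, 2), nelec = 3,
                         constraint_kind = "cumulative",
                         min = c(0, 1, 3), max = c(2, 2, 3)),
    nonconvertible = list(spaces = c(2, 2, 2, 2), nelec = 8,
                          constraint_kind = "cumulative",
                          min = c(1, 4, 5, 8), max = c(3, 4, 7, 8)),
    benzene_local_1 = list(spaces = rep(6, 5), nelec = 30,
                           constraint_kind = "local",
                           neutral = rep(6, 5), n_exc = 1),
    benzene_cumulative_1 = list(spaces = rep(6, 5), nelec = 30,
                                constraint_kind = "cumulative",
                                neutral = rep(6, 5), n_exc = 1),
    n4_local_1 = list(spaces = rep(3, 4), nelec = 12,
                      constraint_kind = "local",
                      neutral = rep(3, 4), n_exc = 1),
    n4_local_2 = list(spaces = rep(3, 4), nelec = 12,
                      constraint_kind = "local",
                      neutral = rep(3, 4), n_exc = 2),
    ras_96 = list(spaces = c(32, 34, 93), nelec = 96,
                  constraint_kind = "cumulative",
                  min = c(62, 94, 96), max = c(64, 96, 96))
  )
  for (nm in names(specs)) yaml::write_yaml(specs[[nm]], fp(paste0(nm, ".yaml")))
  manifest <- list(
    seed = seed,
    hubbard = list(U = U, t = tt,
                   L2_ground_energy = (U - sqrt(U^2 + 16 * tt^2)) / 2),
    supergroup_counts = list(table_example = 5, benzene_local_1 = 51,
                             benzene_cumulative_1 = 81, n4_local_1 = 19,
                             n4_local_2 = 85, ras_96 = 9)
  )
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write / read an RDM set as structured JSON
#'
#' Plain-text interchange for RDMs: spin blocks as flattened arrays with
#' dimensions, plus sector metadata.
#'
#' @param rdms An `rdm_set`.
#' @param path Output path.
#' @return `path` (write) or an `rdm_set` (read).
#' @export
write_rdms <- function(rdms, path) {
  obj <- list(n_orb = rdms$n_orb, n_alpha = rdms$n_alpha, n_beta = rdms$n_beta,
              gamma_a = as.numeric(rdms$gamma_a),
              gamma_b = as.numeric(rdms$gamma_b),
              Gaa = as.numeric(rdms$Gaa), Gbb = as.numeric(rdms$Gbb),
              Gab = as.numeric(rdms$Gab))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_rdms
#' @export
read_rdms <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- o$n_orb
  structure(list(gamma_a = matrix(o$gamma_a, n, n),
                 gamma_b = matrix(o$gamma_b, n, n),
                 Gaa = array(o$Gaa, rep(n, 4)), Gbb = array(o$Gbb, rep(n, 4)),
                 Gab = array(o$Gab, rep(n, 4)),
                 n_alpha = o$n_alpha, n_beta = o$n_beta, n_orb = n),
            class = "rdm_set")
}
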