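#' Load a run configuration from a YAML file
#'
#' Reads a structured config describing a full experiment: per-species,
#' per-strain parameter blocks (keys exactly `r, d, b, b_prime, c, c_prime,
#' p, q, u, v`), lattice geometry, protocol constants, rate mode and seed.
#' Omitted fields take the standard defaults (`L = 25`, 1000 + 1000
#' generations, 100 replicates, introduction frequency 0.04, base rates
#' 0.5 and 0.2, mode `"corrected"`). Unknown keys are rejected so that typos
#' cannot silently revert a parameter to its default.
#'
#' @param path Path to a YAML file (or a list already parsed from one).
#' @return A validated object of class `run_config`: list with `scenario`,
#'   `seed`, `mode`, and an [experiment_config()] in `$experiment`.
#' @examples
#' cfg <- load_config(system.file("examples", "host_symbiont.yaml",
#'                                package = "duallattice"))
#' @export
load_config <- function(path) {
  raw <- if (is.list(path)) path else yaml::read_yaml(path)
  known_top <- c("scenario", "seed", "rate_mode", "lattice", "experiment",
                 "species")
  check_keys(raw, known_top, "top level")

  lat <- raw$lattice %||% list()
  check_keys(lat, "L", "lattice")
  lattice <- lattice_config(L = lat$L %||% 25)

  exp_raw <- raw$experiment %||% list()
  known_exp <- c("equilibration_generations", "post_generations", "replicates",
                 "introduction_frequency", "establishment_threshold",
                 "targets", "resident_strain", "mutant_strain")
  check_keys(exp_raw, known_exp, "experiment")

  species <- raw$species %||% list()
  check_keys(species, c("A", "B"), "species")
  params <- lapply(c(A = "A", B = "B"), function(sp) {
    blk <- species[[sp]] %||% list()
    check_keys(blk, c("parasite", "mutualist"), paste0("species ", sp))
    mk <- function(strain) {
      p <- blk[[strain]] %||% list()
      check_keys(p, c("r", "d", "b", "b_prime", "c", "c_prime",
                      "p", "q", "u", "v"),
                 paste("species", sp, strain))
      do.call(species_params, p)
    }
    strain_set(parasite = mk("parasite"), mutualist = mk("mutualist"))
  })

  resident <- exp_raw$resident_strain %||% list(A = "parasite", B = "parasite")
  experiment <- experiment_config(
    paramsA = params$A, paramsB = params$B,
    resident_strain = c(A = resident$A %||% "parasite",
                        B = resident$B %||% "parasite"),
    mutant_strain = exp_raw$mutant_strain %||% "mutualist",
    targets = unlist(exp_raw$targets %||% "B"),
    lattice = lattice,
    equilibration_generations = exp_raw$equilibration_generations %||% 1000,
    post_generations = exp_raw$post_generations %||% 1000,
    replicates = exp_raw$replicates %||% 100,
    introduction_frequency = exp_raw$introduction_frequency %||% 0.04,
    establishment_threshold = exp_raw$establishment_threshold %||%
      (exp_raw$introduction_frequency %||% 0.04),
    seed = raw$seed %||% 1,
    mode = raw$rate_mode %||% "corrected")

  structure(list(scenario = raw$scenario %||% "custom",
                 seed = experiment$seed, mode = experiment$mode,
                 experiment = experiment),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_keys <- function(x, known, where) {
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown key(s) in ", where, ": ", paste(unknown, collapse = ", "),
         call. = FALSE)
  invisible(x)
}

#' Write a run configuration back to YAML
#'
#' Serializes a `run_config` so that `load_config(write_config(cfg, path))`
#' round-trips to an equal configuration.
#'
#' @param cfg A `run_config` from [load_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  e <- cfg$experiment
  as_plain <- function(sp) lapply(unclass(sp), unclass)
  out <- list(
    scenario = cfg$scenario,
    seed = cfg$seed,
    rate_mode = cfg$mode,
    lattice = list(L = e$lattice$L),
    experiment = list(
      equilibration_generations = e$equilibration_generations,
      post_generations = e$post_generations,
      replicates = e$replicates,
      introduction_frequency = e$introduction_frequency,
      establishment_threshold = e$establishment_threshold,
      targets = as.list(e$targets),
      resident_strain = as.list(e$resident_strain),
      mutant_strain = e$mutant_strain),
    species = list(A = as_plain(e$paramsA), B = as_plain(e$paramsB)))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write experiment results as delimited text plus a metadata sidecar
#'
#' Emits a long-format tab-separated table (deterministic column order, full
#' numeric precision) and a JSON sidecar recording the seed, rate mode,
#' protocol constants and package version, so any result file identifies the
#' exact run that produced it.
#'
#' @param result An `invasion_result` or `sweep_result`.
#' @param path Output path for the table; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  if (inherits(result, "invasion_result")) {
    cfg <- result$cfg
    tab <- data.frame(
      replicate = rep(seq_len(nrow(result$freq)), 2),
      species = rep(c("A", "B"), each = nrow(result$freq)),
      strain = cfg$mutant_strain,
      frequency = c(result$freq[, "A"], result$freq[, "B"]))
    meta <- list(kind = "invasion", seed = cfg$seed, rate_mode = cfg$mode,
                 replicates = cfg$replicates,
                 equilibration_generations = cfg$equilibration_generations,
                 post_generations = cfg$post_generations,
                 introduction_frequency = cfg$introduction_frequency,
                 establishment_threshold = cfg$establishment_threshold,
                 ensemble_mean = as.list(result$ensemble_mean),
                 established = as.list(result$established))
  } else if (inherits(result, "sweep_result")) {
    tab <- as.data.frame(result)
    meta <- list(kind = "sweep", seed = attr(result, "seed"),
                 rate_mode = attr(result, "mode"),
                 scenario = attr(result, "scenario"),
                 replicates = attr(result, "replicates"))
  } else stop("unsupported result class: ", class(result)[1], call. = FALSE)
  meta$package_version <- as.character(utils::packageVersion("duallattice"))
  utils::write.table(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
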