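#' Invasion experiment configuration
#'
#' Bundles the full protocol of a mutant-invasion experiment: lattice
#' geometry, per-species strain parameters, which strain is resident and which
#' is introduced where, and the protocol constants. Defaults reproduce the
#' standard protocol: a 25 x 25 torus filled with residents, 1,000
#' equilibration generations, mutants introduced at frequency 0.04 (25
#' individuals per targeted lattice), 1,000 further generations, ensemble of
#' 100 replicates, establishment called when the ensemble-mean mutant
#' frequency strictly exceeds 0.04.
#'
#' @param paramsA,paramsB [strain_set()] objects for species A and B.
#' @param resident_strain Named character vector, resident strain per species,
#'   e.g. `c(A = "parasite", B = "parasite")`.
#' @param mutant_strain Strain introduced on the targeted lattices.
#' @param targets Which lattices receive mutants (`"A"`, `"B"` or both).
#' @param lattice A [lattice_config()].
#' @param equilibration_generations,post_generations Generations before /
#'   after introduction (each >= 1).
#' @param replicates Ensemble size (>= 1).
#' @param introduction_frequency Mutant introduction frequency in (0,1).
#' @param establishment_threshold Establishment cutoff in (0,1); by default the
#'   introduction frequency.
#' @param seed Root seed for [replicate_seeds()].
#' @param mode Rate mode, see [pair_rates()].
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(paramsA, paramsB,
                              resident_strain = c(A = "parasite", B = "parasite"),
                              mutant_strain = "mutualist",
                              targets = "B",
                              lattice = lattice_config(),
                              equilibration_generations = 1000,
                              post_generations = 1000,
                              replicates = 100,
                              introduction_frequency = 0.04,
                              establishment_threshold = introduction_frequency,
                              seed = 1,
                              mode = c("corrected", "as_printed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(paramsA, "strain_set"), inherits(paramsB, "strain_set"),
            inherits(lattice, "lattice_config"),
            equilibration_generations >= 1, post_generations >= 1,
            replicates >= 1,
            introduction_frequency > 0, introduction_frequency < 1,
            establishment_threshold > 0, establishment_threshold < 1)
  resident_strain <- vapply(resident_strain, match.arg,
                            "", choices = c("empty", "parasite", "mutualist"))
  if (!identical(sort(names(resident_strain)), c("A", "B")))
    stop("resident_strain must be named c(A = ..., B = ...)", call. = FALSE)
  mutant_strain <- match.arg(mutant_strain, c("parasite", "mutualist"))
  targets <- match.arg(targets, c("A", "B"), several.ok = TRUE)
  structure(list(paramsA = paramsA, paramsB = paramsB,
                 resident_strain = resident_strain,
                 mutant_strain = mutant_strain, targets = targets,
                 lattice = lattice,
                 equilibration_generations = as.integer(equilibration_generations),
                 post_generations = as.integer(post_generations),
                 replicates = as.integer(replicates),
                 introduction_frequency = introduction_frequency,
                 establishment_threshold = establishment_threshold,
                 seed = as.integer(seed), mode = mode),
            class = "experiment_config")
}

#' Run a mutant-invasion experiment
#'
#' Per replicate: fill both lattices with residents, equilibrate, introduce
#' mutants on the targeted lattice(s), run the post-introduction generations,
#' and record the final frequency of the mutant strain of each species (over
#' all cells). Replicates use independent seed substreams; the ensemble mean
#' and the establishment call (strict `>` against the threshold) summarize
#' them. Replicates in which a resident population (a species initialized with
#' individuals) is extinct at introduction time are flagged and contribute 0
#' to the ensemble mean: a collapsed resident system cannot be invaded, and a
#' mutant drifting through its remains is not an invasion.
#'
#' @param cfg An [experiment_config()].
#' @return An object of class `invasion_result`: list with `freq` (replicates
#'   x 2 matrix of final mutant-strain frequencies for species A and B),
#'   `ensemble_mean`, `established` (per species, `NA` for non-targeted
#'   species), `joint_mean` (ensemble-mean 3 x 3 joint cell-state frequencies
#'   at the final generation), `extinct_before_introduction` (logical per
#'   replicate), and the `cfg`.
#' @examples
#' \donttest{
#' host <- neutral_strain_set()
#' symb <- strain_set(parasite_params(b = 0.3),
#'                    mutualist_params(b = 0.3, c = 0.3))
#' cfg <- experiment_config(host, symb, targets = "B", replicates = 5,
#'                          equilibration_generations = 200,
#'                          post_generations = 200, seed = 42)
#' run_invasion(cfg)
#' }
#' @export
run_invasion <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  seeds <- replicate_seeds(cfg$seed, cfg$replicates)
  mut_col <- cfg$mutant_strain
  freq <- matrix(NA_real_, cfg$replicates, 2,
                 dimnames = list(NULL, c("A", "B")))
  extinct <- logical(cfg$replicates)
  joint_sum <- matrix(0, 3, 3)
  for (k in seq_len(cfg$replicates)) {
    set.seed(seeds[k])
    st <- dual_lattice(cfg$lattice,
                       strainA = cfg$resident_strain[["A"]],
                       strainB = cfg$resident_strain[["B"]])
    st <- step_generation(st, cfg$paramsA, cfg$paramsB,
                          cfg$equilibration_generations, mode = cfg$mode)
    f_pre <- state_frequencies(st)
    inhabited <- names(which(cfg$resident_strain != "empty"))
    extinct[k] <- any(f_pre[inhabited, "empty"] == 1)
    st <- introduce_mutants(st, targets = cfg$targets,
                            mutant_strain = cfg$mutant_strain,
                            frequency = cfg$introduction_frequency)
    st <- step_generation(st, cfg$paramsA, cfg$paramsB,
                          cfg$post_generations, mode = cfg$mode)
    f <- state_frequencies(st)
    freq[k, ] <- if (extinct[k]) c(0, 0) else f[, mut_col]
    joint_sum <- joint_sum + joint_state_frequencies(st)
  }
  ens <- colMeans(freq)
  established <- ens > cfg$establishment_threshold
  established[setdiff(c("A", "B"), cfg$targets)] <- NA
  joint_mean <- joint_sum / cfg$replicates
  dimnames(joint_mean) <- list(A = c("empty", "parasite", "mutualist"),
                               B = c("empty", "parasite", "mutualist"))
  structure(list(freq = freq, ensemble_mean = ens, established = established,
                 joint_mean = joint_mean,
                 extinct_before_introduction = extinct, cfg = cfg),
            class = "invasion_result")
}

#' @export
print.invasion_result <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf(
    "invasion_result: %s mutants into %s residents on lattice(s) %s\n",
    cfg$mutant_strain, paste(unique(cfg$resident_strain), collapse = "/"),
    paste(cfg$targets, collapse = ",")))
  cat(sprintf("  %d replicates, %d + %d generations, f = %g\n",
              cfg$replicates, cfg$equilibration_generations,
              cfg$post_generations, cfg$introduction_frequency))
  for (sp in cfg$targets)
    cat(sprintf("  Sp. %s: ensemble-mean mutant frequency %.4f -> %s\n",
                sp, x$ensemble_mean[[sp]],
                if (isTRUE(x$established[[sp]])) "ESTABLISHED" else "not established"))
  if (any(x$extinct_before_introduction))
    cat("  note:", sum(x$extinct_before_introduction),
        "replicate(s) lost a resident population before introduction",
        "(zero contribution)\n")
  invisible(x)
}

#' @export
summary.invasion_result <- function(object, ...) {
  se <- apply(object$freq, 2, stats::sd) / sqrt(nrow(object$freq))
  data.frame(species = colnames(object$freq),
             ensemble_mean = object$ensemble_mean,
             se = se, established = object$established,
             row.names = NULL)
}

#' Reciprocal invasion: residents and mutants exchange roles
#'
#' The robustness check of an established strain: the former mutant strain
#' becomes the resident on every targeted lattice and the former resident is
#' introduced as the rare mutant, with the protocol otherwise unchanged.
#'
#' @inheritParams run_invasion
#' @return An `invasion_result` for the reversed roles.
#' @export
run_reciprocal <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  rev_cfg <- cfg
  for (sp in cfg$targets) {
    rev_cfg$resident_strain[[sp]] <- cfg$mutant_strain
  }
  rev_cfg$mutant_strain <- setdiff(c("parasite", "mutualist"),
                                   cfg$mutant_strain)
  # non-targeted species keep their resident as-is
  run_invasion(rev_cfg)
}

#' Establishment call on an invasion result
#'
#' Establishment means the ensemble-mean mutant frequency strictly exceeds the
#' threshold (by default the introduction frequency): the mutant population
#' has grown beyond its introduced size.
#'
#' @param result An `invasion_result`.
#' @param threshold Cutoff frequency; default taken from the result's config.
#' @return Named logical per species (`NA` for non-targeted species).
#' @export
establishment_test <- function(result, threshold = NULL) {
  stopifnot(inherits(result, "invasion_result"))
  if (is.null(threshold)) threshold <- result$cfg$establishment_threshold
  out <- result$ensemble_mean > threshold
  out[setdiff(c("A", "B"), result$cfg$targets)] <- NA
  out
}

#' Host and symbiont population sizes relative to a non-interacting baseline
#'
#' Resident-only runs (no invasion): both lattices are equilibrated with the
#' given residents, then the occupied-cell count of each species is averaged
#' over the post-equilibration generations and over replicates. The same
#' quantity is computed with the symbiont's interaction switched off
#' (`b = c = 0`), and the ratio is returned per species. A host ratio below 1
#' means the symbiont plays a net parasitic role; above 1, a net mutualistic
#' role.
#'
#' @param cfg An [experiment_config()]; its `resident_strain` selects which
#'   strain of each species is present (no mutants are introduced).
#' @param symbiont A [strain_set()] for species B (the symbiont); overrides
#'   `cfg$paramsB`. Default: use `cfg$paramsB`.
#' @return A list of class `population_ratio` with `ratio` (named per
#'   species), and the mean occupied counts `with_symbiont` / `baseline`.
#' @export
population_ratio <- function(cfg, symbiont = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (!is.null(symbiont)) cfg$paramsB <- symbiont
  null_B <- neutral_strain_set(r = cfg$paramsB$parasite$r,
                               d = cfg$paramsB$parasite$d)

  mean_counts <- function(paramsB) {
    seeds <- replicate_seeds(cfg$seed, cfg$replicates)
    acc <- c(A = 0, B = 0)
    for (k in seq_len(cfg$replicates)) {
      set.seed(seeds[k])
      st <- dual_lattice(cfg$lattice,
                         strainA = cfg$resident_strain[["A"]],
                         strainB = cfg$resident_strain[["B"]])
      st <- step_generation(st, cfg$paramsA, paramsB,
                            cfg$equilibration_generations, mode = cfg$mode)
      st <- step_generation(st, cfg$paramsA, paramsB,
                            cfg$post_generations, mode = cfg$mode,
                            record_counts = TRUE)
      cnt <- attr(st, "counts")
      acc <- acc + c(A = mean(cnt[, "A_parasite"] + cnt[, "A_mutualist"]),
                     B = mean(cnt[, "B_parasite"] + cnt[, "B_mutualist"]))
    }
    acc / cfg$replicates
  }

  with_symb <- mean_counts(cfg$paramsB)
  baseline <- mean_counts(null_B)
  if (any(baseline == 0))
    stop("baseline population extinct; ratio undefined", call. = FALSE)
  structure(list(ratio = with_symb / baseline,
                 with_symbiont = with_symb, baseline = baseline),
            class = "population_ratio")
}

#' @export
print.population_ratio <- function(x, ...) {
  cat("population ratio relative to a non-interacting symbiont:\n")
  cat(sprintf("  Sp. %s: %.3f (%.1f vs %.1f occupied cells)\n",
              names(x$ratio), x$ratio, x$with_symbiont, x$baseline),
      sep = "")
  invisible(x)
}

#' Screen the binary resource-allocation strategies
#'
#' Enumerates the binary strategy combinations: the exploitation split
#' `(p, q)` (shared by the resident and mutant strains of the focal species)
#' and the mutant's donation split `(u, v)`, each in \{0, 1\}^2, giving 16
#' combinations. Each is run through [run_invasion()] and the establishment
#' call recorded. In the two-species symmetric scenario the same strategies
#' are mirrored onto both species.
#'
#' @param cfg An [experiment_config()]; its parameter sets supply `r, d, b, c`
#'   while the screened strategies overwrite `p, q, u, v`.
#' @param species `"B"` (host-symbiont scenario: only species B mutates) or
#'   `"both"` (symmetric two-species scenario).
#' @return A data.frame of class `strategy_screen` with columns
#'   `p, q, u, v`, the ensemble-mean mutant frequency per targeted species,
#'   and `established` (all targeted species established).
#' @export
strategy_screen <- function(cfg, species = c("B", "both")) {
  species <- match.arg(species)
  stopifnot(inherits(cfg, "experiment_config"))
  combos <- expand.grid(p = c(0, 1), q = c(0, 1), u = c(0, 1), v = c(0, 1))
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    s <- combos[i, ]
    cfg_i <- cfg
    apply_strategy <- function(ss) {
      ss$parasite$p <- s$p; ss$parasite$q <- s$q
      ss$mutualist$p <- s$p; ss$mutualist$q <- s$q
      ss$mutualist$u <- s$u; ss$mutualist$v <- s$v
      ss
    }
    if (species == "both") {
      cfg_i$paramsA <- apply_strategy(cfg$paramsA)
      cfg_i$paramsB <- apply_strategy(cfg$paramsB)
      cfg_i$targets <- c("A", "B")
    } else {
      cfg_i$paramsB <- apply_strategy(cfg$paramsB)
      cfg_i$targets <- "B"
    }
    res <- run_invasion(cfg_i)
    data.frame(s, mean_A = if ("A" %in% cfg_i$targets) res$ensemble_mean[["A"]] else NA,
               mean_B = if ("B" %in% cfg_i$targets) res$ensemble_mean[["B"]] else NA,
               established = all(res$established[cfg_i$targets]))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("strategy_screen", "data.frame")
  out
}

#' Sweep the exploitation/donation parameters
#'
#' Runs the invasion experiment (and optionally the reciprocal test) over a
#' grid of cost/benefit values.
#'
#' Two scenarios:
#' \describe{
#'   \item{`host_symbiont`}{Species A is a neutral host (`b_A = c_A = 0`);
#'     the grid is `(b_B, c_B)` from `axis1` x `axis2`, mutants introduced on
#'     lattice B only.}
#'   \item{`two_species_symmetric`}{Both species are active and mirrored;
#'     the diagonal `b_A = b_B` runs over `axis1` at fixed donation cost
#'     `c_A = c_B` (`axis2` must be a single value); mutants are introduced on
#'     both lattices.}
#' }
#'
#' @param cfg An [experiment_config()] supplying everything except the swept
#'   values (strategies, protocol constants, seed). Symmetric exchange
#'   (`b' = b`, `c' = c`) is applied at each grid point.
#' @param axis1 Values of the exploitation benefit `b` (strictly increasing).
#' @param axis2 Values of the donation cost `c` (strictly increasing; length 1
#'   in the symmetric scenario).
#' @param scenario `"host_symbiont"` or `"two_species_symmetric"`.
#' @param reciprocal Also run the reciprocal (parasite-into-mutualist) test at
#'   every grid point.
#' @return A data.frame of class `sweep_result`, one row per grid point:
#'   `b`, `c`, ensemble means and establishment calls per targeted species
#'   (`invasion_*`), the same for the reciprocal direction (`reciprocal_*`,
#'   if requested), and in the symmetric scenario the ensemble-mean joint
#'   frequencies of A-mutualists sharing a site with B-parasites
#'   (`AM_with_BP`) and with B-mutualists (`AM_with_BM`).
#' @export
parameter_sweep <- function(cfg, axis1, axis2,
                            scenario = c("host_symbiont", "two_species_symmetric"),
                            reciprocal = TRUE) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(cfg, "experiment_config"),
            length(axis1) >= 1, all(diff(axis1) > 0),
            length(axis2) >= 1, all(diff(axis2) > 0))
  if (scenario == "two_species_symmetric" && length(axis2) != 1)
    stop("the symmetric scenario sweeps the diagonal b_A = b_B at a single c",
         call. = FALSE)
  grid <- expand.grid(b = axis1, c = axis2)

  set_bc <- function(ss, b, c) {
    ss$parasite$b <- b; ss$parasite$b_prime <- b
    ss$mutualist$b <- b; ss$mutualist$b_prime <- b
    ss$mutualist$c <- c; ss$mutualist$c_prime <- c
    ss
  }

  rows <- lapply(seq_len(nrow(grid)), function(i) {
    b <- grid$b[i]; c <- grid$c[i]
    cfg_i <- cfg
    if (scenario == "host_symbiont") {
      cfg_i$paramsA <- neutral_strain_set(r = cfg$paramsA$parasite$r,
                                          d = cfg$paramsA$parasite$d)
      cfg_i$paramsB <- set_bc(cfg$paramsB, b, c)
      cfg_i$targets <- "B"
    } else {
      cfg_i$paramsA <- set_bc(cfg$paramsA, b, c)
      cfg_i$paramsB <- set_bc(cfg$paramsB, b, c)
      cfg_i$targets <- c("A", "B")
    }
    inv <- run_invasion(cfg_i)
    row <- data.frame(b = b, c = c,
                      invasion_mean_A = inv$ensemble_mean[["A"]],
                      invasion_mean_B = inv$ensemble_mean[["B"]],
                      invasion_established_A = inv$established[["A"]],
                      invasion_established_B = inv$established[["B"]],
                      AM_with_BP = inv$joint_mean["mutualist", "parasite"],
                      AM_with_BM = inv$joint_mean["mutualist", "mutualist"])
    if (reciprocal) {
      rec <- run_reciprocal(cfg_i)
      row$reciprocal_mean_A <- rec$ensemble_mean[["A"]]
      row$reciprocal_mean_B <- rec$ensemble_mean[["B"]]
      row$reciprocal_established_A <- rec$established[["A"]]
      row$reciprocal_established_B <- rec$established[["B"]]
    }
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "scenario") <- scenario
  attr(out, "seed") <- cfg$seed
  attr(out, "replicates") <- cfg$replicates
  attr(out, "mode") <- cfg$mode
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Establishment threshold along the exploitation axis
#'
#' Reads a [parameter_sweep()] result: the smallest swept `b` at which the
#' mutant established (`direction = "invasion"`), or the largest `b` at which
#' the reciprocal mutant established (`direction = "reciprocal"` -- above this
#' bound re-invasion always fails).
#'
#' @param sweep A `sweep_result`.
#' @param species `"A"` or `"B"`.
#' @param direction `"invasion"` or `"reciprocal"`.
#' @return The threshold `b` value, or `NA` if no grid point (for
#'   `"invasion"`) / every grid point (for `"reciprocal"`) established.
#' @export
establishment_threshold_b <- function(sweep, species = "A",
                                      direction = c("invasion", "reciprocal")) {
  direction <- match.arg(direction)
  species <- match.arg(species, c("A", "B"))
  col <- paste0(direction, "_established_", species)
  stopifnot(col %in% names(sweep))
  est <- sweep[[col]]
  if (direction == "invasion") {
    if (!any(est, na.rm = TRUE)) return(NA_real_)
    min(sweep$b[which(est)])
  } else {
    if (!any(est, na.rm = TRUE)) return(NA_real_)
    max(sweep$b[which(est)])
  }
}
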