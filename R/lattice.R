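#' Lattice geometry
#'
#' The spatial model lives on two parallel `L x L` square grids with periodic
#' (torus) boundaries; dispersal and interaction ranges are fixed: offspring
#' settle in the four orthogonal (Neumann) neighbours, and each individual
#' interacts only with the occupant of the same coordinates on the other grid.
#'
#' @param L Side length (>= 3); default 25.
#' @return An object of class `lattice_config`.
#' @export
lattice_config <- function(L = 25) {
  if (!is.numeric(L) || length(L) != 1L || L != round(L) || L < 3)
    stop("L must be a single integer >= 3", call. = FALSE)
  structure(list(L = as.integer(L)), class = "lattice_config")
}

#' Initialize a dual lattice filled with one strain per species
#'
#' Builds the coupled pair of grids, every cell of each grid set to the given
#' strain of its species (the standard starting condition: wild-type
#' individuals on all sites of both lattices).
#'
#' @param config A [lattice_config()] (or an integer side length).
#' @param strainA,strainB `"empty"`, `"parasite"` or `"mutualist"`.
#' @return An object of class `dual_lattice`: list with integer matrices
#'   `grid_A`, `grid_B` (0 empty, 1 parasite, 2 mutualist), side length `L`
#'   and a `generation` counter.
#' @examples
#' st <- dual_lattice(lattice_config(25), "parasite", "parasite")
#' state_frequencies(st)
#' @export
dual_lattice <- function(config = lattice_config(),
                         strainA = "parasite", strainB = "parasite") {
  if (is.numeric(config)) config <- lattice_config(config)
  stopifnot(inherits(config, "lattice_config"))
  L <- config$L
  structure(list(
    grid_A = matrix(strain_code(strainA), L, L),
    grid_B = matrix(strain_code(strainB), L, L),
    L = L, generation = 0L
  ), class = "dual_lattice")
}

#' @export
print.dual_lattice <- function(x, ...) {
  f <- state_frequencies(x)
  cat(sprintf("dual_lattice %dx%d (torus), generation %d\n",
              x$L, x$L, x$generation))
  print(round(f, 4))
  invisible(x)
}

#' @export
plot.dual_lattice <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(par(op))
  cols <- c("white", "firebrick", "steelblue")
  for (sp in c("A", "B")) {
    g <- x[[paste0("grid_", sp)]]
    image(seq_len(x$L), seq_len(x$L), t(g)[, rev(seq_len(x$L))],
          col = cols, zlim = c(0, 2), axes = FALSE, xlab = "", ylab = "",
          main = paste("Species", sp))
  }
  invisible(x)
}

check_state <- function(state) {
  stopifnot(inherits(state, "dual_lattice"))
  invisible(state)
}

#' One Monte-Carlo site event
#'
#' Executes the elementary update at one site, reading the lattice state as it
#' currently stands at each sub-step, strictly in order: (a) an occupant of
#' grid A at `coords` places offspring of its own strain on each empty Neumann
#' neighbour independently with probability `R/4`, where its rates come from
#' [pair_rates()] against the occupant of the same site on grid B; (b) the
#' grid-B occupant does the same against grid A; (c) the grid-A occupant dies
#' with probability `D`; (d) the grid-B occupant dies with probability `D`
#' evaluated against the current grid-A cell, which step (c) may just have
#' emptied. Empty focal cells skip their sub-steps and consume no random
#' draws.
#'
#' @param state A [dual_lattice()].
#' @param coords Integer vector `c(row, col)`, 1-based.
#' @param paramsA,paramsB [strain_set()] objects.
#' @inheritParams pair_rates
#' @return The updated `dual_lattice` (the generation counter is untouched;
#'   a generation is `L^2` site events, see [step_generation()]).
#' @export
site_event <- function(state, coords, paramsA, paramsB,
                       mode = c("corrected", "as_printed")) {
  mode <- match.arg(mode)
  check_state(state)
  stopifnot(length(coords) == 2L, all(coords >= 1), all(coords <= state$L))
  tb <- engine_tables(paramsA, paramsB, mode)
  res <- cpp_site_event(state$grid_A, state$grid_B,
                        tb$RpA, tb$DA, tb$RpB, tb$DB,
                        as.integer(coords[1]) - 1L, as.integer(coords[2]) - 1L)
  state$grid_A <- res$grid_A
  state$grid_B <- res$grid_B
  state
}

#' Advance the dual lattice by whole generations
#'
#' One generation is `L^2` site events at sites drawn uniformly at random with
#' replacement (some sites may be visited twice in a generation, others not at
#' all). All randomness uses R's generator: `set.seed()` before a run makes it
#' bit-reproducible.
#'
#' @inheritParams site_event
#' @param generations Number of generations to run (>= 0).
#' @param record_counts If `TRUE`, attach a `generations x 6` matrix of
#'   end-of-generation cell counts (`A_empty, A_parasite, A_mutualist,
#'   B_empty, B_parasite, B_mutualist`) as the `counts` attribute of the
#'   returned state.
#' @return The updated `dual_lattice`, generation counter advanced.
#' @examples
#' A <- neutral_strain_set()
#' set.seed(1)
#' st <- step_generation(dual_lattice(8), A, A, generations = 10)
#' @export
step_generation <- function(state, paramsA, paramsB, generations = 1,
                            mode = c("corrected", "as_printed"),
                            record_counts = FALSE) {
  mode <- match.arg(mode)
  check_state(state)
  stopifnot(generations >= 0)
  if (generations == 0) return(state)
  tb <- engine_tables(paramsA, paramsB, mode)
  res <- cpp_run(state$grid_A, state$grid_B,
                 tb$RpA, tb$DA, tb$RpB, tb$DB,
                 as.integer(generations), isTRUE(record_counts))
  state$grid_A <- res$grid_A
  state$grid_B <- res$grid_B
  state$generation <- state$generation + as.integer(generations)
  if (isTRUE(record_counts)) {
    colnames(res$counts) <- c("A_empty", "A_parasite", "A_mutualist",
                              "B_empty", "B_parasite", "B_mutualist")
    attr(state, "counts") <- res$counts
  }
  state
}

#' Introduce mutant individuals at a fixed frequency
#'
#' Selects exactly `round(frequency * L^2)` distinct cells uniformly at random
#' on each targeted lattice and sets each to the mutant strain, irrespective of
#' whether the cell was occupied: a resident individual there is replaced, an
#' empty cell gains a mutant. Lattices targeted together use independent cell
#' draws. With the defaults (`L = 25`, `frequency = 0.04`) this places exactly
#' 25 mutants per targeted lattice.
#'
#' @inheritParams site_event
#' @param targets Character subset of `c("A", "B")`: which lattices receive
#'   mutants.
#' @param mutant_strain Strain to introduce, default `"mutualist"`.
#' @param frequency Introduction frequency in \[0,1\], default 0.04.
#' @return The updated `dual_lattice`. If `round(frequency * L^2) == 0`, warns
#'   and returns the state unchanged.
#' @export
introduce_mutants <- function(state, targets = c("A", "B"),
                              mutant_strain = "mutualist", frequency = 0.04) {
  check_state(state)
  targets <- match.arg(targets, c("A", "B"), several.ok = TRUE)
  stopifnot(frequency >= 0, frequency <= 1)
  n_cells <- state$L^2
  n_mut <- round(frequency * n_cells)
  if (n_mut == 0) {
    warning("introduction frequency ", frequency, " rounds to 0 cells on a ",
            state$L, "x", state$L, " lattice; state unchanged")
    return(state)
  }
  code <- strain_code(mutant_strain)
  for (tg in targets) {
    nm <- paste0("grid_", tg)
    cells <- sample.int(n_cells, n_mut)
    state[[nm]][cells] <- code
  }
  state
}

#' Strain frequencies per species
#'
#' Counts over all `L^2` cells (empty cells included in the denominator, as in
#' the mean-field bookkeeping), so the three frequencies of each species sum
#' to 1 exactly.
#'
#' @inheritParams site_event
#' @return A 2 x 3 numeric matrix, rows `A`, `B`, columns
#'   `empty, parasite, mutualist`.
#' @export
state_frequencies <- function(state) {
  check_state(state)
  n <- state$L^2
  count3 <- function(g) tabulate(g + 1L, 3L) / n
  out <- rbind(A = count3(state$grid_A), B = count3(state$grid_B))
  colnames(out) <- c("empty", "parasite", "mutualist")
  out
}

#' Joint cell-state frequencies across the two lattices
#'
#' Each site carries one of nine combined states `(A_i, B_j)` with
#' `i, j` in (empty, parasite, mutualist). Returns their frequencies over all
#' cells; used to ask, e.g., how often the mutualistic strains of the two
#' species occupy the same position.
#'
#' @inheritParams site_event
#' @return A 3 x 3 matrix (rows: A state, columns: B state) summing to 1.
#' @export
joint_state_frequencies <- function(state) {
  check_state(state)
  lev <- c("empty", "parasite", "mutualist")
  tab <- table(factor(strain_name(state$grid_A), levels = lev),
               factor(strain_name(state$grid_B), levels = lev))
  m <- unclass(tab) / state$L^2
  names(dimnames(m)) <- c("A", "B")
  m
}

#' Derive independent per-replicate seeds from one root seed
#'
#' Replicated experiments draw one substream seed per replicate from the root
#' seed, so replicate `k` is reproducible in isolation and permuting replicate
#' order permutes, but does not change, the set of trajectories.
#'
#' @param seed Root seed (integer).
#' @param n Number of replicates.
#' @return Integer vector of `n` seeds.
#' @export
replicate_seeds <- function(seed, n) {
  stopifnot(n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}
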