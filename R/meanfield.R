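#' Mean-field state of the two-species strain frequencies
#'
#' Under unlimited dispersal the dual-lattice model reduces to frequency
#' dynamics over the six cell states. A state holds the occupied-strain
#' frequencies; the empty frequencies are derived so that
#' `A_E + A_P + A_M = 1` and `B_E + B_P + B_M = 1` hold exactly.
#'
#' @param A_P,A_M,B_P,B_M Parasite and mutualist frequencies per species,
#'   each in \[0,1\] with `A_P + A_M <= 1` and `B_P + B_M <= 1`.
#' @return An object of class `mf_state`: named numeric vector with components
#'   `A_E, A_P, A_M, B_E, B_P, B_M`.
#' @examples
#' mf_state(A_P = 0.5, A_M = 0.3, B_P = 0.4, B_M = 0.1)
#' @export
mf_state <- function(A_P = 0, A_M = 0, B_P = 0, B_M = 0) {
  x <- c(A_P = A_P, A_M = A_M, B_P = B_P, B_M = B_M)
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("strain frequencies must lie in [0, 1]", call. = FALSE)
  if (A_P + A_M > 1 + 1e-12 || B_P + B_M > 1 + 1e-12)
    stop("strain frequencies of one species must sum to <= 1", call. = FALSE)
  structure(c(A_E = 1 - A_P - A_M, A_P = A_P, A_M = A_M,
              B_E = 1 - B_P - B_M, B_P = B_P, B_M = B_M),
            class = "mf_state")
}

# Raw (unclamped) mean-field coefficients for one species' two strains.
# Returns list(R, D): 2x3 matrices as in engine_tables but unclamped --
# the ODE is the analytic object, negative mortalities are admissible.
mf_coefficients <- function(own, other, mode) {
  R <- D <- matrix(0, 2, 3, dimnames = list(c("parasite", "mutualist"),
                                            c("empty", "parasite", "mutualist")))
  for (fs in rownames(R)) for (ps in colnames(R)) {
    partner <- if (ps == "empty") other$parasite else other[[ps]]
    rp <- pair_rates(own[[fs]], fs, partner, ps, mode = mode)
    R[fs, ps] <- rp$R_raw
    D[fs, ps] <- rp$D_raw
  }
  list(R = R, D = D)
}

#' Mean-field time derivatives of the strain frequencies
#'
#' The rate of change of each occupied strain frequency under unlimited,
#' random dispersal. For the parasitic strain of species A:
#' `dA_P/dt = r_A B_E A_P A_E + R_PP B_P A_P A_E + R_MP B_M A_P A_E`
#' `          - d_A B_E A_P - D_PP B_P A_P - D_MP B_M A_P`,
#' where `R_PP, D_PP` are the rates of an A-parasite paired with a B-parasite,
#' `R_MP, D_MP` with a B-mutualist (raw, unclamped, from [pair_rates()]); the
#' mutualist strain and species B follow by exchanging strains and species
#' symbol for symbol. Empty-cell frequencies are conserved complements, so the
#' three derivatives of one species always sum to zero over (E, P, M).
#'
#' @param state An [mf_state()].
#' @param paramsA,paramsB [strain_set()] objects.
#' @inheritParams pair_rates
#' @return Named numeric vector `c(A_P, A_M, B_P, B_M)` of time derivatives.
#' @export
mf_derivatives <- function(state, paramsA, paramsB,
                           mode = c("corrected", "as_printed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(state, "mf_state"))
  mf_deriv_core(unclass(state),
                mf_coefficients(paramsA, paramsB, mode),
                mf_coefficients(paramsB, paramsA, mode),
                paramsA, paramsB)
}

mf_deriv_core <- function(s, cA, cB, paramsA, paramsB) {
  deriv_one <- function(co, fs, own_E, own_f, oth_E, oth_P, oth_M, r, d) {
    r * oth_E * own_f * own_E +
      co$R[fs, "parasite"]  * oth_P * own_f * own_E +
      co$R[fs, "mutualist"] * oth_M * own_f * own_E -
      d * oth_E * own_f -
      co$D[fs, "parasite"]  * oth_P * own_f -
      co$D[fs, "mutualist"] * oth_M * own_f
  }
  c(A_P = deriv_one(cA, "parasite", s[["A_E"]], s[["A_P"]],
                    s[["B_E"]], s[["B_P"]], s[["B_M"]],
                    paramsA$parasite$r, paramsA$parasite$d),
    A_M = deriv_one(cA, "mutualist", s[["A_E"]], s[["A_M"]],
                    s[["B_E"]], s[["B_P"]], s[["B_M"]],
                    paramsA$mutualist$r, paramsA$mutualist$d),
    B_P = deriv_one(cB, "parasite", s[["B_E"]], s[["B_P"]],
                    s[["A_E"]], s[["A_P"]], s[["A_M"]],
                    paramsB$parasite$r, paramsB$parasite$d),
    B_M = deriv_one(cB, "mutualist", s[["B_E"]], s[["B_M"]],
                    s[["A_E"]], s[["A_P"]], s[["A_M"]],
                    paramsB$mutualist$r, paramsB$mutualist$d))
}

#' Integrate the mean-field dynamics
#'
#' Explicit first-order (Euler) time stepping of [mf_derivatives()]. After each
#' step, components that exit \[0,1\] by no more than `tol` are projected back
#' and the state re-normalized through [mf_state()]; a larger excursion aborts
#' with an error naming the offending component (the remedy is a smaller `dt`).
#'
#' @inheritParams mf_derivatives
#' @param state0 Initial [mf_state()].
#' @param t_end End time (>= 0).
#' @param dt Step size (> 0), default 0.01.
#' @param tol Permitted out-of-range excursion per step, default `1e-8`.
#' @return A data.frame of class `mf_trajectory` with columns
#'   `t, A_E, A_P, A_M, B_E, B_P, B_M`, including the states at `t = 0` and
#'   `t = t_end`.
#' @examples
#' A <- neutral_strain_set()
#' tr <- mf_integrate(mf_state(A_P = 0.5), A, A, t_end = 50)
#' tail(tr, 1)  # approaches the single-species equilibrium 1 - d/r = 0.6
#' @export
mf_integrate <- function(state0, paramsA, paramsB, t_end, dt = 0.01,
                         mode = c("corrected", "as_printed"), tol = 1e-8) {
  mode <- match.arg(mode)
  stopifnot(inherits(state0, "mf_state"), dt > 0, t_end >= 0)
  n_steps <- ceiling(t_end / dt - 1e-9)
  times <- c(seq_len(n_steps) * dt)
  if (n_steps > 0) times[n_steps] <- t_end
  out <- matrix(NA_real_, n_steps + 1L, 7L,
                dimnames = list(NULL, c("t", names(state0))))
  out[1L, ] <- c(0, unclass(state0))
  state <- state0
  t_prev <- 0
  cA <- mf_coefficients(paramsA, paramsB, mode)
  cB <- mf_coefficients(paramsB, paramsA, mode)
  for (k in seq_len(n_steps)) {
    h <- times[k] - t_prev
    dv <- mf_deriv_core(unclass(state), cA, cB, paramsA, paramsB)
    new <- unclass(state)[c("A_P", "A_M", "B_P", "B_M")] + h * dv
    low <- new < 0
    high <- new > 1
    if (any(new[low] < -tol) || any(new[high] > 1 + tol)) {
      bad <- names(new)[which.max(abs(pmin(new, 0)) + pmax(new - 1, 0))]
      stop("step size too large: component ", bad, " left [0,1] (",
           format(new[[bad]]), ") at t = ", format(times[k]),
           "; reduce dt", call. = FALSE)
    }
    new[low] <- 0
    new[high] <- 1
    state <- mf_state(A_P = new[["A_P"]], A_M = new[["A_M"]],
                      B_P = new[["B_P"]], B_M = new[["B_M"]])
    out[k + 1L, ] <- c(times[k], unclass(state))
    t_prev <- times[k]
  }
  out <- as.data.frame(out)
  class(out) <- c("mf_trajectory", "data.frame")
  out
}

#' @export
plot.mf_trajectory <- function(x, ...) {
  cols <- c(A_P = "firebrick", A_M = "steelblue",
            B_P = "darkorange", B_M = "darkcyan")
  plot(NULL, xlim = range(x$t), ylim = c(0, 1), xlab = "time",
       ylab = "frequency", ...)
  for (nm in names(cols)) lines(x$t, x[[nm]], col = cols[[nm]], lwd = 2)
  legend("topright", legend = names(cols), col = cols, lwd = 2, bty = "n")
  invisible(x)
}

#' Mean-field selection differential of the mutualist strain
#'
#' The per-capita growth-rate difference between the mutualistic and parasitic
#' strains of species A, `(1/A_M) dA_M/dt - (1/A_P) dA_P/dt`, computed directly
#' from [mf_derivatives()]. Because only the donation-cost terms distinguish
#' the two strains (the delivered-benefit terms cancel), the difference reduces
#' to the closed form
#' `-c_A (B_P + B_M) (u_A A_E + (1 - u_A))`,
#' which is `<= 0` whenever partners exist and strictly negative for
#' `c_A > 0`: in a well-mixed population the mutualist always declines, for
#' every parameter value. An alternative algebraic arrangement,
#' `-c_A (u_A A_E + (1 - u_A)(B_P + B_M))`, circulates in print; it does not
#' equal the term-by-term derivative difference but shares its sign, so the
#' impossibility conclusion is unaffected. Both forms are returned read-only
#' for audit; the authoritative `value` is always the direct computation.
#'
#' @inheritParams mf_derivatives
#' @return A list of class `selection_differential` with elements `value`
#'   (direct derivative difference), `derived_form` and `printed_form` (the two
#'   closed forms evaluated on the same state).
#' @examples
#' A <- strain_set(parasite_params(b = 0), mutualist_params(b = 0, c = 0.1))
#' s <- mf_state(A_P = 0.5, A_M = 0.3, B_P = 0.4, B_M = 0.1)
#' selection_differential(s, A, neutral_strain_set())$value  # -0.01
#' @export
selection_differential <- function(state, paramsA, paramsB,
                                   mode = c("corrected", "as_printed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(state, "mf_state"))
  s <- unclass(state)
  if (s[["A_P"]] <= 0 || s[["A_M"]] <= 0)
    stop("selection differential undefined: A_P and A_M must be > 0",
         call. = FALSE)
  dv <- mf_derivatives(state, paramsA, paramsB, mode = mode)
  c_A <- paramsA$mutualist$c
  u_A <- paramsA$mutualist$u
  Bocc <- s[["B_P"]] + s[["B_M"]]
  structure(list(
    value = dv[["A_M"]] / s[["A_M"]] - dv[["A_P"]] / s[["A_P"]],
    derived_form = -c_A * Bocc * (u_A * s[["A_E"]] + (1 - u_A)),
    printed_form = -c_A * (u_A * s[["A_E"]] + (1 - u_A) * Bocc)
  ), class = "selection_differential")
}

#' @export
print.selection_differential <- function(x, ...) {
  cat(sprintf("selection differential (mutualist - parasite): %g\n", x$value))
  cat(sprintf("  closed forms: derived %g, as printed %g\n",
              x$derived_form, x$printed_form))
  invisible(x)
}

#' Single-species equilibrium occupancy under unlimited dispersal
#'
#' For one species alone (no interactions) the mean-field dynamics
#' `dA/dt = A (r (1 - A) - d)` equilibrate at occupancy `1 - d/r`. Used as an
#' analytic benchmark for the spatial engine (whose clustered equilibrium lies
#' below this well-mixed value).
#'
#' @param r Reproductive rate (> 0).
#' @param d Mortality rate (>= 0).
#' @return Equilibrium occupied frequency; 0 with a warning when the
#'   mortality rate reaches the reproductive rate (extinction).
#' @examples
#' equilibrium_occupancy(0.5, 0.2)  # 0.6
#' @export
equilibrium_occupancy <- function(r, d) {
  stopifnot(r > 0, d >= 0)
  if (r <= d) {
    warning("r <= d: the species goes extinct (occupancy 0)")
    return(0)
  }
  1 - d / r
}
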