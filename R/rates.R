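#' Realized rates of a focal individual given its lattice partner
#'
#' Computes the reproductive and mortality rates of a focal individual from its
#' strain, its parameters, and the occupant of the corresponding site on the
#' partner species' lattice. This is the interaction engine shared by the
#' mean-field equations and the spatial simulation.
#'
#' With focal species X and partner species Y the raw rates compose additively:
#' \itemize{
#'   \item partner empty: `R_raw = r_X`, `D_raw = d_X` (no interaction);
#'   \item partner occupied (either strain): the focal exploits, gaining
#'     `p_X b_X` fecundity and `(1-p_X) b_X` survival, and is exploited,
#'     losing `q_Y b'_Y` fecundity and `(1-q_Y) b'_Y` survival:
#'     `R_raw = r_X + p_X b_X - q_Y b'_Y`,
#'     `D_raw = d_X - (1-p_X) b_X + (1-q_Y) b'_Y`;
#'   \item focal mutualist: pays its donation cost,
#'     `R_raw - u_X c_X` and `D_raw + (1-u_X) c_X`;
#'   \item partner mutualist: delivers its donation,
#'     `R_raw + v_Y c'_Y` and `D_raw - (1-v_Y) c'_Y`.
#' }
#'
#' `mode` selects which allocation parameter splits the delivered benefit
#' `c'_Y` between the recipient's fecundity and survival. The default
#' `"corrected"` uses the donor's recipient-side allocation `v_Y`, consistent
#' with the parameter definitions (v is the donor's allocation *onto the
#' recipient*) and with the mortality threshold behaviour of the model (the
#' mutualist-mutualist mortality turns negative for exploitation above 0.1
#' when `d = 0.2`, `c = c' = 0.1`, `(u,v) = (1,0)`). `"as_printed"` instead
#' applies `u_Y`, reproducing the originally printed coefficient formulas
#' verbatim; it is retained for auditability. The two modes differ by exactly
#' `(v_Y - u_Y) c'_Y` in `R_raw` and `(u_Y - v_Y) c'_Y` in `D_raw`, and only
#' when the partner is a mutualist.
#'
#' In the spatial model `R` is a rate spread over the four neighbouring sites
#' (per-site colonization probability `R/4`), hence the clamp of `R` to
#' \[0, 4\]; `D` is a probability, clamped to \[0, 1\]. Raw values are kept
#' unclamped as diagnostics for the negative-mortality regime.
#'
#' @param focal `species_params` of the focal individual.
#' @param focal_strain `"parasite"` or `"mutualist"` (never `"empty"`).
#' @param partner `species_params` of the partner species' relevant strain.
#' @param partner_strain `"empty"`, `"parasite"` or `"mutualist"`.
#' @param mode `"corrected"` (default) or `"as_printed"`; see Details.
#' @return An object of class `rate_pair`: list with `R_raw`, `D_raw`, and the
#'   clamped `R` (in \[0,4\]) and `D` (in \[0,1\]).
#' @examples
#' pA <- parasite_params(b = 0.15)
#' pair_rates(pA, "parasite", pA, "parasite")  # R_raw = 0.35, D_raw = 0.05
#' @export
pair_rates <- function(focal, focal_strain, partner, partner_strain,
                       mode = c("corrected", "as_printed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(focal, "species_params"))
  focal_strain <- match.arg(focal_strain, c("parasite", "mutualist"))
  partner_strain <- match.arg(partner_strain,
                              c("empty", "parasite", "mutualist"))

  R_raw <- focal$r
  D_raw <- focal$d
  if (partner_strain != "empty") {
    stopifnot(inherits(partner, "species_params"))
    R_raw <- R_raw + focal$p * focal$b - partner$q * partner$b_prime
    D_raw <- D_raw - (1 - focal$p) * focal$b + (1 - partner$q) * partner$b_prime
    if (focal_strain == "mutualist") {
      R_raw <- R_raw - focal$u * focal$c
      D_raw <- D_raw + (1 - focal$u) * focal$c
    }
    if (partner_strain == "mutualist") {
      split <- if (mode == "corrected") partner$v else partner$u
      R_raw <- R_raw + split * partner$c_prime
      D_raw <- D_raw - (1 - split) * partner$c_prime
    }
  }
  structure(list(R_raw = R_raw, D_raw = D_raw,
                 R = min(max(R_raw, 0), 4), D = min(max(D_raw, 0), 1)),
            class = "rate_pair")
}

#' @export
print.rate_pair <- function(x, ...) {
  cat(sprintf("rate_pair: R = %g (raw %g), D = %g (raw %g)\n",
              x$R, x$R_raw, x$D, x$D_raw))
  invisible(x)
}

#' Exhaustive rate lookup for both species and all strain pairings
#'
#' Precomputes [pair_rates()] for every (species, focal strain, partner state)
#' combination: 2 species x 2 focal strains x 3 partner states. The mean-field
#' coefficients (the rates of a parasite or mutualist focal paired with a
#' parasite or mutualist partner) are the occupied-partner rows of this table.
#'
#' @param paramsA,paramsB [strain_set()] objects for species A and B.
#' @inheritParams pair_rates
#' @return A data.frame with columns `species`, `focal_strain`,
#'   `partner_strain`, `R_raw`, `D_raw`, `R`, `D`.
#' @export
rate_matrix <- function(paramsA, paramsB, mode = c("corrected", "as_printed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(paramsA, "strain_set"), inherits(paramsB, "strain_set"))
  grid <- expand.grid(species = c("A", "B"),
                      focal_strain = c("parasite", "mutualist"),
                      partner_strain = c("empty", "parasite", "mutualist"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    own <- if (g$species == "A") paramsA else paramsB
    other <- if (g$species == "A") paramsB else paramsA
    partner <- if (g$partner_strain == "empty") other$parasite
               else other[[g$partner_strain]]
    rp <- pair_rates(own[[g$focal_strain]], g$focal_strain,
                     partner, g$partner_strain, mode = mode)
    cbind(g, as.data.frame(unclass(rp)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# 2x3 matrices (rows: focal parasite/mutualist; cols: partner
# empty/parasite/mutualist) of per-neighbour colonization probability R/4 and
# death probability D, in the layout the C++ engine consumes.
engine_tables <- function(paramsA, paramsB, mode = "corrected") {
  tab <- rate_matrix(paramsA, paramsB, mode = mode)
  pick <- function(sp, what) {
    m <- matrix(0, 2, 3, dimnames = list(c("parasite", "mutualist"),
                                         c("empty", "parasite", "mutualist")))
    for (fs in rownames(m)) for (ps in colnames(m)) {
      row <- tab[tab$species == sp & tab$focal_strain == fs &
                 tab$partner_strain == ps, ]
      m[fs, ps] <- if (what == "Rp") row$R / 4 else row$D
    }
    m
  }
  list(RpA = pick("A", "Rp"), DA = pick("A", "D"),
       RpB = pick("B", "Rp"), DB = pick("B", "D"))
}
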