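#' Species parameters for one strain
#'
#' Bundles the demographic rates and resource-allocation strategy of one strain
#' of one species. Every individual is fundamentally parasitic: it extracts a
#' total resource `b_prime` from its lattice partner (split between the
#' partner's fecundity and survival by `q`) and gains `b` for itself (split by
#' `p`). A mutualistic strain additionally donates: it pays a total cost `c`
#' (split between its own fecundity and survival by `u`) and delivers `c_prime`
#' to the partner (split by `v`). A parasitic strain has `c = 0`; a neutral
#' host has `b = c = 0`.
#'
#' Allocation parameters route resources between the two fitness components:
#' a value of 1 puts 100% of the flow on fecundity, 0 puts it on survival.
#'
#' @param r Basic reproductive rate (per generation, >= 0).
#' @param d Basic mortality rate (probability-like, >= 0).
#' @param b Parasitic benefit gained by this strain from its partner (>= 0).
#' @param b_prime Parasitic cost inflicted on the partner (>= 0); defaults to
#'   `b` (the symmetric exchange assumption).
#' @param c Altruistic cost paid by a mutualist (>= 0); ignored for a focal
#'   individual of the parasitic strain.
#' @param c_prime Altruistic benefit delivered to the partner (>= 0); defaults
#'   to `c`.
#' @param p Allocation of the parasitic gain `b` to own fecundity, in \[0,1\].
#' @param q Allocation of the inflicted cost `b_prime` to the partner's
#'   fecundity, in \[0,1\].
#' @param u Allocation of the donation cost `c` to own fecundity, in \[0,1\].
#' @param v Allocation of the delivered benefit `c_prime` to the partner's
#'   fecundity, in \[0,1\].
#' @return An object of class `species_params` (a validated named list).
#' @examples
#' species_params()                   # neutral defaults r = 0.5, d = 0.2
#' species_params(b = 0.15)           # parasite exploiting 0.15
#' species_params(b = 0.15, c = 0.1)  # mutualist: exploits and donates
#' @seealso [parasite_params()], [mutualist_params()], [neutral_params()]
#' @export
species_params <- function(r = 0.5, d = 0.2, b = 0, b_prime = b,
                           c = 0, c_prime = c,
                           p = 0, q = 1, u = 1, v = 0) {
  x <- list(r = r, d = d, b = b, b_prime = b_prime, c = c, c_prime = c_prime,
            p = p, q = q, u = u, v = v)
  for (nm in names(x)) {
    val <- x[[nm]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    if (val < 0)
      stop("parameter '", nm, "' must be >= 0, got ", val, call. = FALSE)
  }
  for (nm in c("p", "q", "u", "v")) {
    if (x[[nm]] > 1)
      stop("allocation parameter '", nm, "' must lie in [0, 1], got ",
           x[[nm]], call. = FALSE)
  }
  structure(x, class = "species_params")
}

#' @rdname species_params
#' @export
parasite_params <- function(b, b_prime = b, r = 0.5, d = 0.2, p = 0, q = 1) {
  species_params(r = r, d = d, b = b, b_prime = b_prime, c = 0, c_prime = 0,
                 p = p, q = q)
}

#' @rdname species_params
#' @export
mutualist_params <- function(b, c, b_prime = b, c_prime = c,
                             r = 0.5, d = 0.2, p = 0, q = 1, u = 1, v = 0) {
  species_params(r = r, d = d, b = b, b_prime = b_prime,
                 c = c, c_prime = c_prime, p = p, q = q, u = u, v = v)
}

#' @rdname species_params
#' @export
neutral_params <- function(r = 0.5, d = 0.2) {
  species_params(r = r, d = d, b = 0, b_prime = 0, c = 0, c_prime = 0)
}

#' @export
print.species_params <- function(x, ...) {
  cat("species_params:",
      paste(names(x), vapply(x, format, ""), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Parameter sets for the two strains of one species
#'
#' A species carries two heritable strains on its lattice: a parasitic
#' wild type and a mutualistic type. `strain_set()` pairs their parameter
#' objects; the lattice engine and the mean-field equations look up rates by
#' (strain, partner-strain) from such a pair.
#'
#' @param parasite `species_params` of the parasitic strain (`c` forced to 0).
#' @param mutualist `species_params` of the mutualistic strain.
#' @return An object of class `strain_set`: `list(parasite, mutualist)`.
#' @examples
#' strain_set(parasite_params(b = 0.15), mutualist_params(b = 0.15, c = 0.1))
#' @export
strain_set <- function(parasite = parasite_params(b = 0),
                       mutualist = mutualist_params(b = 0, c = 0)) {
  stopifnot(inherits(parasite, "species_params"),
            inherits(mutualist, "species_params"))
  if (parasite$c != 0 || parasite$c_prime != 0)
    stop("the parasitic strain donates nothing: c and c_prime must be 0",
         call. = FALSE)
  structure(list(parasite = parasite, mutualist = mutualist),
            class = "strain_set")
}

#' @rdname strain_set
#' @param r,d Basic rates shared by both strains.
#' @export
neutral_strain_set <- function(r = 0.5, d = 0.2) {
  strain_set(parasite_params(b = 0, r = r, d = d),
             mutualist_params(b = 0, c = 0, r = r, d = d))
}

# Strain coding shared with the C++ engine: 0 empty, 1 parasite, 2 mutualist.
.strains <- c(empty = 0L, parasite = 1L, mutualist = 2L)

strain_code <- function(strain) {
  strain <- match.arg(strain, names(.strains))
  .strains[[strain]]
}

strain_name <- function(code) names(.strains)[match(code, .strains)]
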