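# Shared fixtures: standard parameterizations used throughout the suite.
# All simulation parameters (r = 0.5, d = 0.2, symmetric b' = b, c' = c) are
# the model's standard study conditions.

neutral_host <- function() neutral_strain_set()

# symmetric strain set: parasitic wild type plus a mutualist paying c,
# both with exploitation b, strategies (p,q) = (0,1), (u,v) = (1,0)
symmetric_set <- function(b, c = 0.1) {
  strain_set(parasite_params(b = b), mutualist_params(b = b, c = c))
}

random_species_params <- function() {
  species_params(r = runif(1, 0, 1), d = runif(1, 0, 0.5),
                 b = runif(1, 0, 0.5), b_prime = runif(1, 0, 0.5),
                 c = runif(1, 0, 0.5), c_prime = runif(1, 0, 0.5),
                 p = runif(1), q = runif(1), u = runif(1), v = runif(1))
}

# random strain set in which the mutualist differs from the parasite only by
# its donation (shared r, d, b, b', p, q) -- the model's definition of a
# mutualistic variant of a resident parasite
random_strain_set <- function() {
  base <- list(r = runif(1, 0.1, 1), d = runif(1, 0, 0.5),
               b = runif(1, 0, 0.5), b_prime = runif(1, 0, 0.5),
               p = runif(1), q = runif(1))
  strain_set(
    parasite = do.call(parasite_params, base[c("b", "b_prime", "r", "d", "p", "q")]),
    mutualist = do.call(mutualist_params,
                        c(base, list(c = runif(1, 0, 0.5),
                                     c_prime = runif(1, 0, 0.5),
                                     u = runif(1), v = runif(1)))))
}

random_interior_state <- function() {
  a <- runif(2, 0.05, 0.45)
  b <- runif(2, 0.05, 0.45)
  mf_state(A_P = a[1], A_M = a[2], B_P = b[1], B_M = b[2])
}
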