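test_that("an empty partner leaves the base rates untouched", {
  p <- parasite_params(b = 0.37)
  rp <- pair_rates(p, "parasite", p, "empty")
  expect_equal(c(rp$R_raw, rp$D_raw), c(0.5, 0.2))
  expect_equal(c(rp$R, rp$D), c(0.5, 0.2))
  m <- mutualist_params(b = 0.2, c = 0.4)
  rm <- pair_rates(m, "mutualist", m, "empty")
  expect_equal(c(rm$R_raw, rm$D_raw), c(0.5, 0.2))
})

test_that("two survival-allocating parasites exchange fecundity damage for survival gain", {
  # (p,q) = (0,1), b = b' = 0.15: gain routed to survival, damage to fecundity
  p <- parasite_params(b = 0.15)
  rp <- pair_rates(p, "parasite", p, "parasite")
  expect_equal(rp$R_raw, 0.5 - 0.15)
  expect_equal(rp$D_raw, 0.2 - 0.15)
})

test_that("mutualist-mutualist mortality goes negative and is clamped at zero", {
  m <- mutualist_params(b = 0.15, c = 0.1)
  rp <- pair_rates(m, "mutualist", m, "mutualist", mode = "corrected")
  expect_equal(rp$D_raw, -0.05)
  expect_identical(rp$D, 0)
  # printed coefficient formulas route the benefit with u_Y, so the survival
  # gift vanishes when u = 1 and the pair stays mortal
  rp2 <- pair_rates(m, "mutualist", m, "mutualist", mode = "as_printed")
  expect_equal(rp2$D_raw, 0.05)
})

test_that("the two rate modes differ by exactly (v - u) * c_prime, only for mutualist partners", {
  set.seed(401)
  for (i in 1:25) {
    f <- random_species_params()
    g <- random_species_params()
    for (fs in c("parasite", "mutualist")) {
      for (ps in c("empty", "parasite", "mutualist")) {
        a <- pair_rates(f, fs, g, ps, mode = "corrected")
        b <- pair_rates(f, fs, g, ps, mode = "as_printed")
        # moving delivered benefit from survival to fecundity raises both
        # R (adds the fecundity gift) and D (removes the mortality reduction)
        dR <- if (ps == "mutualist") (g$v - g$u) * g$c_prime else 0
        expect_equal(a$R_raw - b$R_raw, dR, tolerance = 1e-12)
        expect_equal(a$D_raw - b$D_raw, dR, tolerance = 1e-12)
      }
    }
  }
})

test_that("rates decompose additively into switchable interaction terms", {
  set.seed(402)
  for (i in 1:20) {
    f <- random_species_params()
    g <- random_species_params()
    rp <- pair_rates(f, "mutualist", g, "mutualist")
    expect_equal(rp$R_raw,
                 f$r + f$p * f$b - g$q * g$b_prime - f$u * f$c + g$v * g$c_prime,
                 tolerance = 1e-12)
    expect_equal(rp$D_raw,
                 f$d - (1 - f$p) * f$b + (1 - g$q) * g$b_prime +
                   (1 - f$u) * f$c - (1 - g$v) * g$c_prime,
                 tolerance = 1e-12)
    # each term is switchable to zero by its own parameter
    f0 <- f; f0$b <- 0; f0$c <- 0
    g0 <- g; g0$b_prime <- 0; g0$c_prime <- 0
    base <- pair_rates(f0, "mutualist", g0, "mutualist")
    expect_equal(c(base$R_raw, base$D_raw), c(f$r, f$d), tolerance = 1e-12)
  }
})

test_that("zero interaction strength reduces every pairing to the base rates", {
  f <- species_params(r = 0.7, d = 0.1)
  g <- species_params(r = 0.3, d = 0.25)
  for (fs in c("parasite", "mutualist"))
    for (ps in c("empty", "parasite", "mutualist")) {
      rp <- pair_rates(f, fs, g, ps)
      expect_equal(c(rp$R_raw, rp$D_raw), c(0.7, 0.1))
    }
})

test_that("a commensal mutualist's contributions to its partner cancel exactly", {
  set.seed(403)
  for (i in 1:10) {
    # actor A: q = v and c' = b' makes its net effect on the partner zero
    q <- runif(1)
    bp <- runif(1, 0, 0.5)
    actor <- mutualist_params(b = runif(1, 0, 0.5), b_prime = bp,
                              c = runif(1, 0, 0.5), c_prime = bp,
                              q = q, v = q, p = runif(1), u = runif(1))
    noop <- parasite_params(b = 0, b_prime = 0)
    focal <- random_species_params()
    for (fs in c("parasite", "mutualist")) {
      with_actor <- pair_rates(focal, fs, actor, "mutualist")
      with_noop <- pair_rates(focal, fs, noop, "parasite")
      expect_equal(with_actor$R_raw, with_noop$R_raw, tolerance = 1e-12)
      expect_equal(with_actor$D_raw, with_noop$D_raw, tolerance = 1e-12)
    }
  }
})

test_that("rate_matrix agrees with pair_rates entry by entry and is symmetric under relabeling", {
  set.seed(404)
  A <- random_strain_set()
  B <- random_strain_set()
  tab <- rate_matrix(A, B)
  expect_equal(nrow(tab), 12L)
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    own <- if (row$species == "A") A else B
    oth <- if (row$species == "A") B else A
    partner <- if (row$partner_strain == "empty") oth$parasite else oth[[row$partner_strain]]
    rp <- pair_rates(own[[row$focal_strain]], row$focal_strain,
                     partner, row$partner_strain)
    expect_equal(unlist(row[c("R_raw", "D_raw", "R", "D")]),
                 c(R_raw = rp$R_raw, D_raw = rp$D_raw, R = rp$R, D = rp$D),
                 tolerance = 1e-12)
  }
  # swapping the species labels swaps the table's species blocks exactly
  swapped <- rate_matrix(B, A)
  reord <- function(t, sp) {
    out <- t[t$species == sp, c("focal_strain", "partner_strain", "R_raw", "D_raw")]
    out[order(out$focal_strain, out$partner_strain), ]
  }
  expect_equal(reord(tab, "A")[, c("R_raw", "D_raw")],
               reord(swapped, "B")[, c("R_raw", "D_raw")],
               ignore_attr = TRUE)
})

test_that("invalid parameters are rejected at construction", {
  expect_error(species_params(p = 1.5), "'p'")
  expect_error(species_params(b = -0.1), "'b'")
  expect_error(species_params(d = NaN), "'d'")
  expect_error(strain_set(mutualist_params(b = 0.1, c = 0.1),
                          mutualist_params(b = 0.1, c = 0.1)),
               "parasitic strain")
  p <- parasite_params(b = 0.1)
  expect_error(pair_rates(p, "empty", p, "parasite"))
})
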