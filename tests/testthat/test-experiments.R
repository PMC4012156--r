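# Reduced-scale invasion experiments: the full protocol (1,000 + 1,000
# generations, 100 replicates) lives in the acceptance suite; unit tests use
# shorter runs that still exercise every code path.

test_that("a costless mutant label drifts neutrally around the introduction frequency", {
  host <- neutral_host()
  symb <- strain_set(parasite_params(b = 0.15),
                     mutualist_params(b = 0.15, c = 0))
  cfg <- experiment_config(host, symb, targets = "B", replicates = 50,
                           equilibration_generations = 200,
                           post_generations = 200, seed = 5)
  res <- run_invasion(cfg)
  se <- sd(res$freq[, "B"]) / sqrt(nrow(res$freq))
  expect_lt(abs(res$ensemble_mean[["B"]] - 0.04), 3 * se)
  expect_true(is.na(res$established[["A"]]))

  # reciprocal with a costless mutualist resident is the mirrored neutral test
  rec <- run_reciprocal(cfg)
  expect_identical(rec$cfg$resident_strain[["B"]], "mutualist")
  expect_identical(rec$cfg$mutant_strain, "parasite")
  se_r <- sd(rec$freq[, "B"]) / sqrt(nrow(rec$freq))
  expect_lt(abs(rec$ensemble_mean[["B"]] - 0.04), 3 * se_r)
})

test_that("establishment is a strict comparison against the threshold", {
  fake <- structure(list(
    ensemble_mean = c(A = 0.04, B = 0.30),
    cfg = list(establishment_threshold = 0.04, targets = c("A", "B"))),
    class = "invasion_result")
  est <- establishment_test(fake)
  expect_false(est[["A"]])   # exactly 0.04 is not establishment
  expect_true(est[["B"]])
  est2 <- establishment_test(fake, threshold = 0.1)
  expect_false(est2[["B"]] && est2[["A"]])
  expect_false(establishment_test(fake, threshold = 0.3)[["B"]])
})

test_that("survival-directed mutualists establish in a host-symbiont system at high b and c", {
  host <- neutral_host()
  symb <- strain_set(parasite_params(b = 0.2),
                     mutualist_params(b = 0.2, c = 0.3))
  cfg <- experiment_config(host, symb, targets = "B", replicates = 6,
                           equilibration_generations = 400,
                           post_generations = 400, seed = 42)
  inv <- run_invasion(cfg)
  expect_true(inv$established[["B"]])
  expect_gt(inv$ensemble_mean[["B"]], 0.04)
  # and the established mutualist resists re-invasion by the parasite
  rec <- run_reciprocal(cfg)
  expect_false(rec$established[["B"]])
})

test_that("resident collapse before introduction zeroes the replicate's contribution", {
  # at b = 0.5 with q = 1 the resident parasite strips half the host's
  # fecundity; the host collapses during equilibration
  host <- neutral_host()
  symb <- strain_set(parasite_params(b = 0.5),
                     mutualist_params(b = 0.5, c = 0.3))
  cfg <- experiment_config(host, symb, targets = "B", replicates = 4,
                           equilibration_generations = 600,
                           post_generations = 100, seed = 17)
  res <- run_invasion(cfg)
  expect_true(all(res$extinct_before_introduction))
  expect_equal(unname(res$ensemble_mean), c(0, 0))
  expect_false(res$established[["B"]])
})

test_that("a non-interacting symbiont leaves the host population ratio at one", {
  host <- neutral_host()
  cfg <- experiment_config(host, neutral_strain_set(), replicates = 3,
                           equilibration_generations = 150,
                           post_generations = 150, seed = 31)
  pr <- population_ratio(cfg)
  expect_equal(unname(pr$ratio), c(1, 1), tolerance = 1e-12)
  expect_gt(pr$baseline[["A"]], 0)
})

test_that("exploitation without donation never raises the host population", {
  host <- neutral_host()
  cfg <- experiment_config(host, neutral_strain_set(),
                           resident_strain = c(A = "parasite", B = "mutualist"),
                           replicates = 4, equilibration_generations = 300,
                           post_generations = 300, seed = 9)
  exploiter <- strain_set(parasite_params(b = 0.15),
                          mutualist_params(b = 0.15, c = 0))
  pr <- population_ratio(cfg, symbiont = exploiter)
  expect_lt(pr$ratio[["A"]], 1)
  # a strongly donating exploiter raises it instead
  donor <- strain_set(parasite_params(b = 0.3),
                      mutualist_params(b = 0.3, c = 0.3))
  pr2 <- population_ratio(cfg, symbiont = donor)
  expect_gt(pr2$ratio[["A"]], 1)
})

test_that("the binary strategy screen singles out exploit-for-survival, donate-to-survival", {
  host <- neutral_host()
  symb <- strain_set(parasite_params(b = 0.2),
                     mutualist_params(b = 0.2, c = 0.3))
  cfg <- experiment_config(host, symb, targets = "B", replicates = 6,
                           equilibration_generations = 400,
                           post_generations = 400, seed = 21)
  sc <- strategy_screen(cfg, species = "B")
  expect_equal(nrow(sc), 16L)
  # the canonical winning strategy: exploit the host's fecundity for own
  # survival, donate own fecundity to the host's survival
  winner <- sc$p == 0 & sc$q == 1 & sc$u == 1 & sc$v == 0
  expect_true(sc$established[winner])
  # establishment requires survival-directed, fecundity-funded donation and
  # survival-directed exploitation gain; every other routing fails
  survival_route <- sc$p == 0 & sc$u == 1 & sc$v == 0
  expect_false(any(sc$established[!survival_route]))
})

test_that("parameter sweeps record both directions and expose the threshold readers", {
  sym <- symmetric_set(0.1)
  cfg <- experiment_config(sym, sym, targets = c("A", "B"), replicates = 2,
                           equilibration_generations = 20,
                           post_generations = 20, seed = 2)
  sw <- parameter_sweep(cfg, axis1 = c(0.1, 0.2), axis2 = 0.1,
                        scenario = "two_species_symmetric", reciprocal = TRUE)
  expect_s3_class(sw, "sweep_result")
  expect_equal(sw$b, c(0.1, 0.2))
  expect_true(all(c("invasion_mean_A", "reciprocal_established_B",
                    "AM_with_BP", "AM_with_BM") %in% names(sw)))
  expect_error(parameter_sweep(cfg, axis1 = c(0.1, 0.2), axis2 = c(0.1, 0.2),
                               scenario = "two_species_symmetric"),
               "single c")

  # threshold extraction on a synthetic sweep table
  fake <- data.frame(b = c(0.05, 0.10, 0.15, 0.20),
                     invasion_established_A = c(FALSE, FALSE, TRUE, TRUE),
                     reciprocal_established_A = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(establishment_threshold_b(fake, "A", "invasion"), 0.15)
  expect_equal(establishment_threshold_b(fake, "A", "reciprocal"), 0.10)
  fake$invasion_established_A <- FALSE
  expect_true(is.na(establishment_threshold_b(fake, "A", "invasion")))
})
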