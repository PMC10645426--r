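lib <- demo_library()

# Counts with one informative variant against a reference, everything else
# well covered so min_reads never interferes.
two_variant_counts <- function(nb_x, nu_x, nb_ref = 100, nu_ref = 100) {
  nb <- rep(100, 64)
  nu <- rep(100, 64)
  names(nb) <- names(nu) <- lib$variants
  nb["TAAGGG"] <- nb_x
  nu["TAAGGG"] <- nu_x
  nb["TAATCC"] <- nb_ref
  nu["TAATCC"] <- nu_ref
  fraction_counts(lib, nb, nu)
}

test_that("relative energies follow the log odds-ratio against the reference", {
  fc <- two_variant_counts(50, 200)
  et <- relative_energies(fc, "TAATCC", pseudocount = 0, min_reads = 1)
  en <- stats::setNames(et$energies$ddG_kT, et$energies$variant)
  # ln((100/100) / (50/200)) = ln 4
  expect_equal(unname(en["TAAGGG"]), log(4), tolerance = 1e-12)
  # the reference anchors at exactly 0, weaker binders are positive
  expect_identical(unname(en["TAATCC"]), 0)
  expect_true(en["TAAGGG"] > 0)
  # counts identical to the reference's give 0
  expect_equal(unname(en["TAAAAA"]), 0, tolerance = 1e-12)
})

test_that("variants below the read floor are missing, not zero", {
  nb <- rep(100, 64); nu <- rep(100, 64)
  names(nb) <- names(nu) <- lib$variants
  nb["TAAGGG"] <- 3
  fc <- fraction_counts(lib, nb, nu)
  et <- relative_energies(fc, "TAATCC", min_reads = 10)
  en <- stats::setNames(et$energies$ddG_kT, et$energies$variant)
  expect_true(is.na(en["TAAGGG"]))
  expect_identical(et$n_used, 63L)
  expect_false(et$energies$in_fit[et$energies$variant == "TAAGGG"])
})

test_that("a reference below the read floor is a hard error", {
  nb <- rep(100, 64); nu <- rep(100, 64)
  names(nb) <- names(nu) <- lib$variants
  nb["TAATCC"] <- 2
  fc <- fraction_counts(lib, nb, nu)
  expect_error(relative_energies(fc, "TAATCC", min_reads = 10), "anchor")
})

test_that("pseudocount keeps energies finite for zero-count variants", {
  nb <- rep(100, 64); nu <- rep(100, 64)
  names(nb) <- names(nu) <- lib$variants
  nb["TAAGGG"] <- 0
  fc <- fraction_counts(lib, nb, nu)
  et <- relative_energies(fc, "TAATCC", pseudocount = 1, min_reads = 0)
  expect_true(all(is.finite(et$energies$ddG_kT)))
  expect_error(relative_energies(fc, "TAATCC", pseudocount = 0, min_reads = 0),
               "pseudocount")
})

test_that("changing the reference shifts energies by a constant", {
  truth <- wt_truth(lib)
  sim <- simulate_counts(simulation_config(truth, lib, seed = 9,
                                           reads_per_fraction = c(1e5, 1e5)))
  e1 <- relative_energies(sim$fc, "TAATCC", min_reads = 1)
  e2 <- relative_energies(sim$fc, "TAAGCA", min_reads = 1)
  d <- e1$energies$ddG_kT - e2$energies$ddG_kT
  expect_lt(diff(range(d, na.rm = TRUE)), 1e-10)
})

# --- ePWM regression ---------------------------------------------------------

exact_energy_table <- function(truth, min_reads = 0) {
  # an energy table holding the exact additive energies (no counting noise)
  en <- predict_energy(truth, lib$variants)
  structure(
    list(library = lib, reference_variant = truth$reference_variant,
         energies = data.frame(variant = lib$variants, ddG_kT = en,
                               n_bound = 1000, n_unbound = 1000,
                               in_fit = TRUE, stringsAsFactors = FALSE),
         pseudocount = 0, min_reads = min_reads, n_used = 64L),
    class = "energy_table"
  )
}

test_that("regression recovers an exactly additive model to numerical precision", {
  truth <- wt_truth(lib)
  pwm <- fit_epwm(exact_energy_table(truth), max_mismatch = 2)
  expect_lt(max(abs(pwm$beta - truth$beta)), 1e-9)
  expect_equal(pwm$fit$residual_sd, 0, tolerance = 1e-9)
  expect_equal(pwm$fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(predict_energy(pwm, "TAATCC"), 0, tolerance = 1e-12)
})

test_that("the fit equals a brute-force normal-equations solution", {
  set.seed(21)
  truth <- random_truth(lib, seed = 13)
  et <- exact_energy_table(truth)
  et$energies$ddG_kT <- et$energies$ddG_kT +
    stats::rnorm(64, 0, 0.1) * (et$energies$variant != "TAATCC")
  et$energies$ddG_kT[et$energies$variant == "TAATCC"] <- 0
  pwm <- fit_epwm(et, max_mismatch = 2)

  # independent oracle: explicit normal equations on the same neighborhood
  nb <- hamming_neighborhood("TAATCC", lib, 2)$members
  refc <- strsplit("TAATCC", "")[[1]]
  X <- NULL; cn <- character()
  for (p in 4:6) for (b in setdiff(c("A", "C", "G", "T"), refc[p])) {
    X <- cbind(X, as.numeric(substr(nb, p, p) == b))
    cn <- c(cn, paste0(p, b))
  }
  y <- et$energies$ddG_kT[match(nb, et$energies$variant)]
  beta_hat <- solve(t(X) %*% X, t(X) %*% y)[, 1]
  fitted <- stats::setNames(as.vector(pwm$beta), outer(c("A", "C", "G", "T"),
                                                       4:6, function(b, p)
                                                         paste0(p, b)))
  expect_equal(unname(fitted[cn]), unname(beta_hat), tolerance = 1e-9)
})

test_that("bases never observed in the neighborhood yield missing coefficients", {
  truth <- wt_truth(lib)
  et <- exact_energy_table(truth)
  # censor every variant carrying G at position 6
  keep <- substr(et$energies$variant, 6, 6) != "G"
  et$energies$ddG_kT[!keep] <- NA
  pwm <- fit_epwm(et, max_mismatch = 2)
  expect_true(is.na(pwm$beta["G", 3]))
  expect_true(is.na(predict_energy(pwm, "TAATCG")))
  # remaining coefficients are unaffected
  expect_lt(max(abs(pwm$beta[, 1] - truth$beta[, 1])), 1e-9)
})

test_that("predictions are additive across positions", {
  truth <- random_truth(lib, seed = 3)
  pwm <- fit_epwm(exact_energy_table(truth), max_mismatch = 2)
  single1 <- predict_energy(pwm, "TAAACC") # pos 4 mutant
  single2 <- predict_energy(pwm, "TAATGC") # pos 5 mutant
  double <- predict_energy(pwm, "TAAAGC")
  expect_equal(double, single1 + single2, tolerance = 1e-12)
  expect_error(predict_energy(pwm, "TTTTCC"), "fixed positions")
})

# --- logo normalization ------------------------------------------------------

test_that("logo columns are mean-centered and fixed positions flagged", {
  truth <- wt_truth(lib)
  truth$beta[, 1] <- c(0, 1, 2, 3)
  lg <- logo_matrix(truth)
  expect_equal(unname(lg$energies[4, ]), c(-1.5, -0.5, 0.5, 1.5))
  expect_equal(unname(lg$display[4, ]), c(1.5, 0.5, -0.5, -1.5))
  expect_identical(lg$fixed_positions, 1:3)
  expect_true(all(is.na(lg$energies[1:3, ])))
  # every variable column sums to zero
  expect_lt(max(abs(rowSums(lg$energies[4:6, ]))), 1e-12)
  # all-equal column centers to zero
  truth$beta[, 2] <- rep(2, 4)
  expect_equal(unname(logo_matrix(truth)$energies[5, ]), rep(0, 4))
})

test_that("centering is idempotent", {
  truth <- random_truth(lib, seed = 8)
  lg1 <- logo_matrix(truth)
  centered <- truth
  centered$beta <- sweep(truth$beta, 2, colMeans(truth$beta))
  lg2 <- logo_matrix(centered)
  expect_equal(lg1$energies, lg2$energies, tolerance = 1e-12)
})

# --- table comparison --------------------------------------------------------

test_that("comparison statistics behave on exact linear relations", {
  truth <- wt_truth(lib)
  a <- exact_energy_table(truth)
  cmp <- compare_energy_tables(a, a)
  expect_equal(cmp$pearson_r, 1, tolerance = 1e-12)
  expect_equal(cmp$rms_difference, 0)
  expect_equal(cmp$noise_level, 0)
  expect_equal(cmp$fit_slope, 1, tolerance = 1e-12)

  b <- a
  b$energies$ddG_kT <- 0.5 * a$energies$ddG_kT
  cmp2 <- compare_energy_tables(a, b)
  expect_equal(cmp2$fit_slope, 0.5, tolerance = 1e-12)
  expect_equal(cmp2$pearson_r, 1, tolerance = 1e-12)
  # total least squares agrees on noiseless data
  cmp3 <- compare_energy_tables(a, b, fit = "tls")
  expect_equal(cmp3$fit_slope, 0.5, tolerance = 1e-6)
})

test_that("comparison requires at least three shared measured variants", {
  truth <- wt_truth(lib)
  a <- exact_energy_table(truth)
  b <- a
  b$energies$ddG_kT[3:64] <- NA
  expect_error(compare_energy_tables(a, b), "at least 3")
})

test_that("kT energies convert to kcal/mol with the Boltzmann factor", {
  expect_equal(energy_kcal_per_mol(1), 0.593)
  expect_equal(energy_kcal_per_mol(c(0, 2)), c(0, 1.186))
})
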