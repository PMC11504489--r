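test_that("equilibrium solver handles limiting cases and the reference value", {
  # no protein: nothing binds
  eq <- solve_equilibrium(0, species_spec("L", 1.0, 1.0))
  expect_equal(unname(eq$complex), 0)
  expect_equal(unname(eq$free_ligand), 1.0)

  # non-binder limit
  eq <- solve_equilibrium(0.01, species_spec("L", 1.0, Inf))
  expect_equal(unname(eq$complex), 0)
  expect_equal(eq$free_protein, 0.01)

  # one-species reference value, frozen from the damped fixed-point
  # oracle (protein 0.01 mM, ligand 1.0 mM, kd 1.0 mM)
  p_oracle <- fp_free_protein(0.01, 1.0, 1.0)
  complex_oracle <- p_oracle * 1.0 / (1.0 + p_oracle)
  expect_equal(complex_oracle, 4.9875e-3, tolerance = 1e-4)
  eq <- solve_equilibrium(0.01, species_spec("L", 1.0, 1.0))
  expect_equal(unname(eq$complex), complex_oracle, tolerance = 1e-10)
})

test_that("solver rejects invalid inputs", {
  expect_error(solve_equilibrium(NA, species_spec("L", 1, 1)), "finite")
  expect_error(solve_equilibrium(-1, species_spec("L", 1, 1)), ">= 0")
  expect_error(species_spec("L", 1, 0), "positive")
  expect_error(species_spec("L", -1, 1), ">= 0")
  expect_error(species_spec("L", Inf, 1), "finite")
  expect_error(
    solve_equilibrium(0.01, list(species_spec("a", 1, 1),
                                 species_spec("a", 2, 1))),
    "duplicate")
})

test_that("protein and ligand mass balances hold on random instances", {
  set.seed(101)
  for (i in 1:300) {
    m <- sample(1:3, 1)
    sp <- lapply(seq_len(m), function(j)
      species_spec(paste0("s", j),
                   total_conc = 10^stats::runif(1, -2, 1),
                   kd = 10^stats::runif(1, -2, 2)))
    p_tot <- 10^stats::runif(1, -3, 0)
    eq <- solve_equilibrium(p_tot, sp)
    expect_lt(abs(eq$free_protein + sum(eq$complex) - p_tot) /
                max(p_tot, 1e-12), 1e-10)
    totals <- vapply(sp, `[[`, 0, "total_conc")
    expect_lt(max(abs(eq$free_ligand + eq$complex - totals) / totals),
              1e-10)
    expect_true(all(c(eq$free_protein, eq$free_ligand, eq$complex) >= 0))
  }
})

test_that("solver agrees with the damped fixed-point oracle", {
  set.seed(202)
  for (i in 1:200) {
    m <- sample(1:3, 1)
    L <- 10^stats::runif(m, -2, 1)
    K <- 10^stats::runif(m, -2, 2)
    p_tot <- 10^stats::runif(1, -3, 0)
    sp <- lapply(seq_len(m), function(j) species_spec(paste0("s", j), L[j], K[j]))
    eq <- solve_equilibrium(p_tot, sp)
    expect_equal(eq$free_protein, fp_free_protein(p_tot, L, K),
                 tolerance = 1e-8)
  }
})

test_that("bound fraction is monotone in total ligand and in own kd", {
  p <- binding_parameters(0.87, 0.76, 1310)
  conc <- c(0.25, 0.5, 0.8, 1.0, 1.5, 2.5, 4.0, 6.0)
  bound_frac <- function(kd_own, L_seq) {
    vapply(L_seq, function(L) {
      eq <- solve_equilibrium(0.01, list(
        species_spec("own", 0.4 * L, kd_own),
        species_spec("other", 0.6 * L, 0.76)))
      unname(eq$complex["own"] / (0.4 * L))
    }, 0)
  }
  # non-increasing in total ligand
  expect_true(all(diff(bound_frac(0.87, conc)) <= 1e-12))
  # non-increasing in own kd, others fixed
  at_kds <- vapply(c(0.1, 0.5, 1, 2, 5), function(k)
    bound_frac(k, 1.0)[1], 0)
  expect_true(all(diff(at_kds) <= 1e-12))
})

test_that("observed_rate mixes populations linearly and validates input", {
  expect_equal(observed_rate(0, r_free = 2.0, r_bound = 1310), 2.0)
  expect_equal(observed_rate(1, r_free = 2.0, r_bound = 3200), 3200)
  expect_equal(observed_rate(0.00499, 2.0, 1310),
               (1 - 0.00499) * 2 + 0.00499 * 1310)
  expect_error(observed_rate(-0.1, 2, 1310), "\\[0, 1\\]")
  expect_error(observed_rate(1.1, 2, 1310), "\\[0, 1\\]")
})

test_that("predict_titration has the right limits", {
  p <- binding_parameters(0.87, 0.76, 1310)
  # saturation: huge ligand dilutes the bound population
  pred <- predict_titration(p, 0.01, 5e4, 0.4)
  expect_lt(max(abs(pred$r2 - 2.0)), 1e-3)
  # no protein: exactly free rates
  pred <- predict_titration(p, 0, c(0.25, 1, 6), 0.4)
  expect_identical(pred$r2, rep(c(2.0, 2.0), 3))
  # strictly decreasing R2 for both anomers across the 8-point design
  conc <- c(0.25, 0.5, 0.8, 1.0, 1.5, 2.5, 4.0, 6.0)
  pred <- predict_titration(p, 0.01, conc, 0.4)
  for (an in c("alpha", "beta"))
    expect_true(all(diff(pred$r2[pred$anomer == an]) < 0))
})

test_that("a non-binding competitor leaves the prediction unchanged", {
  p <- binding_parameters(0.87, 0.76, 1310)
  conc <- c(0.25, 0.5, 1, 2, 6)
  base <- predict_titration(p, 0.01, conc, 0.4)
  with_inert <- predict_titration(p, 0.01, conc, 0.4,
                                  competitor = species_spec("c", 5, Inf))
  expect_identical(base$r2, with_inert$r2)
})

test_that("single-anomer prediction reduces to the closed-form one-site curve", {
  p <- binding_parameters(1.3, 0.9, 2000, r_free_alpha = 2.2,
                          r_free_beta = 2.4)
  conc <- c(0.25, 0.5, 0.8, 1.0, 1.5, 2.5, 4.0, 6.0)
  pred <- predict_titration(p, 0.01, conc, anomer_fraction_alpha = 1)
  exp_alpha <- vapply(conc, function(L)
    one_site_r2(0.01, L, 1.3, 2.2, 2000), 0)
  expect_equal(pred$r2[pred$anomer == "alpha"], exp_alpha,
               tolerance = 1e-10)
  # the empty beta pool reports its free rate
  expect_equal(unique(pred$r2[pred$anomer == "beta"]), 2.4)
})
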