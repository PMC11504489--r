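test_that("noiseless titrations recover the generating parameters", {
  truth <- binding_parameters(0.87, 0.76, 1310)
  fit <- fit_titration(simulate_titration(make_design(noise_sigma = 0), truth))
  expect_true(fit$converged)
  expect_equal(fit$params$k_alpha, 0.87, tolerance = 1e-4)
  expect_equal(fit$params$k_beta, 0.76, tolerance = 1e-4)
  expect_equal(fit$params$r_bound, 1310, tolerance = 1e-4)
  expect_false(fit$identifiability_warning)
})

test_that("equal-affinity anomers reduce to the closed-form one-site model", {
  # with k_alpha = k_beta = K the two anomer pools act as one species, so
  # the closed-form one-site quadratic solution generates the data
  K <- 1.2; rb <- 1800; rf <- 2.0
  conc <- c(0.25, 0.5, 0.8, 1.0, 1.5, 2.5, 4.0, 6.0)
  r2 <- vapply(conc, function(L) one_site_r2(0.01, L, K, rf, rb), 0)
  rec <- data.frame(ligand_total = rep(conc, each = 2),
                    anomer = rep(c("alpha", "beta"), length(conc)),
                    r2_obs = rep(r2, each = 2))
  ds <- titration_dataset(0.01, rec, c(alpha = rf, beta = rf), 0.5)
  fit <- fit_titration(ds)
  expect_equal(fit$params$k_alpha, K, tolerance = 1e-6)
  expect_equal(fit$params$k_beta, K, tolerance = 1e-6)
  expect_equal(fit$params$r_bound, rb, tolerance = 1e-6)
})

test_that("Monte-Carlo recovery at 2% noise is unbiased within tolerance", {
  truth <- binding_parameters(0.96, 1.49, 3200)
  des <- make_design(seed = 42)
  kb <- vapply(1:30, function(r)
    fit_titration(simulate_titration(des, truth, replicate = r))$params$k_beta,
    0)
  expect_lt(abs(mean(kb) - 1.49), 0.15)
})

test_that("the fit is invariant to record order and equivariant to rate scaling", {
  truth <- binding_parameters(1.1, 0.6, 2500)
  ds <- simulate_titration(make_design(seed = 5), truth)
  base <- fit_titration(ds)

  perm <- ds
  set.seed(9)
  perm$records <- perm$records[sample(nrow(perm$records)), ]
  fit_p <- fit_titration(perm)
  expect_equal(fit_p$params$k_alpha, base$params$k_alpha, tolerance = 1e-8)
  expect_equal(fit_p$params$r_bound, base$params$r_bound, tolerance = 1e-8)

  c_scale <- 3.7
  scaled <- ds
  scaled$records$r2_obs <- c_scale * scaled$records$r2_obs
  scaled$reference_rates <- c_scale * scaled$reference_rates
  fit_s <- fit_titration(scaled)
  expect_equal(fit_s$params$k_alpha, base$params$k_alpha, tolerance = 1e-6)
  expect_equal(fit_s$params$k_beta, base$params$k_beta, tolerance = 1e-6)
  expect_equal(fit_s$params$r_bound, c_scale * base$params$r_bound,
               tolerance = 1e-6)
})

test_that("the optimizer matches an exhaustive coarse-grid search", {
  set.seed(77)
  for (i in 1:20) {
    truth <- binding_parameters(10^stats::runif(1, -1, log10(5)),
                                10^stats::runif(1, -1, log10(5)),
                                stats::runif(1, 500, 5000))
    ds <- simulate_titration(make_design(seed = 1000 + i), truth)
    fit <- fit_titration(ds)
    grid <- grid_search_titration(ds)
    # optimizer objective at least as good as the best grid cell
    expect_lte(fit$rss, grid$rss + 1e-9)
    # and its optimum lies within one grid cell of the grid argmin
    expect_lt(abs(log(fit$params$r_bound / grid$r_bound)),
              log(grid$cell[["r"]]) * 1.0 + 1e-9)
  }
})

test_that("inverse-variance weighting and r_free co-fitting are available", {
  truth <- binding_parameters(0.9, 0.8, 1500)
  ds <- simulate_titration(make_design(seed = 21), truth)
  fw <- fit_titration(ds, weighted = TRUE)
  expect_true(fw$converged)
  ff <- fit_titration(simulate_titration(make_design(noise_sigma = 0), truth),
                      fit_r_free = TRUE)
  expect_equal(ff$params$r_free_alpha, 2.0, tolerance = 1e-3)
  expect_equal(ff$params$k_alpha, 0.9, tolerance = 1e-3)
})

test_that("degenerate titrations are rejected or flagged", {
  rec <- data.frame(ligand_total = rep(c(1, 2, 3), each = 2),
                    anomer = rep(c("alpha", "beta"), 3),
                    r2_obs = rep(5, 6))
  ds <- titration_dataset(0.01, rec, c(alpha = 2, beta = 2))
  expect_error(fit_titration(ds), ">= 4 distinct")
  expect_error(titration_dataset(0.01,
                                 data.frame(ligand_total = 1:4,
                                            anomer = "alpha",
                                            r2_obs = 1:4),
                                 c(alpha = 2, beta = 2)),
               "both anomers")
})

test_that("a strong competitor is detected and bounded", {
  probe <- binding_parameters(0.87, 0.76, 1310)
  des <- competition_design(competitor_kd = 1.0, seed = 3)
  cd <- simulate_competition(des, probe)
  fit <- fit_competition(cd, probe)
  expect_identical(fit$verdict, "bounded")
  expect_gt(fit$kd, 0.2)
  expect_lt(fit$kd, 5)
})

test_that("probe rates fall monotonically with a competitive binder", {
  probe <- binding_parameters(0.87, 0.76, 1310)
  des <- competition_design(competitor_kd = 0.87, noise_sigma = 0)
  cd <- simulate_competition(des, probe)
  for (an in c("alpha", "beta")) {
    r <- cd$records$r2_obs[cd$records$anomer == an]
    expect_true(all(diff(r) < 0))
  }
})

test_that("a weak competitor yields a flat profile and an unbounded verdict", {
  probe <- binding_parameters(0.87, 0.76, 1310)
  # noiseless: the weak binder barely moves the probe rates at all
  flat <- simulate_competition(
    competition_design(competitor_kd = 100, noise_sigma = 0), probe)
  base <- predict_titration(probe, 0.01, 2.0, 0.4)
  drift <- abs(flat$records$r2_obs -
                 base$r2[match(flat$records$anomer, base$anomer)])
  # detection floor for a change between two measurements at the
  # generator's noise level (sigma * sqrt(2))
  sd_abs <- 0.02 * diff(range(c(flat$records$r2_obs, 2.0)))
  expect_lt(max(drift), sqrt(2) * sd_abs)

  noisy <- simulate_competition(
    competition_design(competitor_kd = 100, seed = 8), probe)

  fit <- fit_competition(noisy, probe)
  expect_identical(fit$verdict, "unbounded")
  expect_true(is.na(fit$kd))
  expect_gt(fit$kd_lower, 0)
})

test_that("a competition series without competitor is rejected", {
  probe <- binding_parameters(0.87, 0.76, 1310)
  rec <- data.frame(competitor_total = rep(0, 4),
                    anomer = rep(c("alpha", "beta"), 2),
                    r2_obs = rep(10, 4))
  cd <- competition_dataset(0.01, 2, rec)
  expect_error(fit_competition(cd, probe), "no information")
})
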