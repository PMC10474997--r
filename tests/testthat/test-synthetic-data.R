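test_that("identical preset and seed regenerate a bit-identical dataset", {
  d1 <- make_scenario("paper_like", seed = 42)
  d2 <- make_scenario("paper_like", seed = 42)
  expect_identical(serialize(d1, NULL), serialize(d2, NULL))
  d3 <- make_scenario("paper_like", seed = 43)
  expect_false(identical(d1$wells, d3$wells))
})

test_that("unknown presets and invalid parameters error early", {
  expect_error(make_scenario("no_such_preset", seed = 1), "unknown preset")
  expect_error(occupancy_params(psi0 = 1.4), "\\[0, 1\\]")
  expect_error(occupancy_params(theta_col = -2), "non-negative")
  expect_error(species_roster("A1", role = "omnivore"), "unknown role")
  expect_error(observation_params(n_bio = 0), "n_bio")
})

test_that("the null preset has no interaction and the study's design dimensions", {
  ds <- make_scenario("null_model", seed = 7)
  p <- ds$params$occupancy
  expect_identical(c(p$theta_col, p$theta_ext, p$phi_pred), c(1, 1, 1))
  expect_identical(dim(ds$truth), c(4L, 31L, 3L))
  ds2 <- make_scenario("paper_like", seed = 7)
  expect_identical(dim(ds2$truth), c(4L, 31L, 3L))
})

test_that("frozen dynamics and a zeroed colonization multiplier are absorbing", {
  sp <- species_roster()
  frozen <- simulate_occupancy(sp, occupancy_params(gamma = 0, epsilon = 0),
                               n_sites = 50, n_months = 5, seed = 1)
  for (t in 2:5) expect_identical(frozen[, , t], frozen[, , 1])

  # prey start absent, predators everywhere, prey colonization fully
  # suppressed: prey never enter
  pars <- occupancy_params(psi0 = c(A1 = 0, A2 = 0, F1 = 1, F2 = 1),
                           gamma = 0.5, epsilon = 0, theta_col = 0)
  occ <- simulate_occupancy(sp, pars, n_sites = 200, n_months = 4, seed = 2)
  expect_true(all(occ[c("A1", "A2"), , ] == 0L))
})

test_that("without interaction, predator and prey states are uncorrelated", {
  sp <- species_roster(c("A1", "F1"), c("prey", "predator"))
  occ <- simulate_occupancy(sp, occupancy_params(psi0 = 0.5, gamma = 0.3, epsilon = 0.2),
                            n_sites = 10000, n_months = 2, seed = 77)
  r <- cor(occ["A1", , 2], occ["F1", , 2])
  expect_lt(abs(r), 0.03)
})

test_that("marginal occupancy converges to gamma / (gamma + epsilon)", {
  sp <- species_roster("A1", "prey")
  occ <- simulate_occupancy(sp, occupancy_params(psi0 = 0.05, gamma = 0.3, epsilon = 0.2),
                            n_sites = 10000, n_months = 15, seed = 31)
  expect_equal(mean(occ["A1", , 15]), 0.3 / (0.3 + 0.2), tolerance = 0.02 / 0.6)
})

test_that("interaction-multiplied probabilities are capped and counted", {
  sp <- species_roster()
  pars <- occupancy_params(psi0 = c(A1 = 1, A2 = 1, F1 = 1, F2 = 1),
                           epsilon = c(A1 = 0.4, A2 = 0.4, F1 = 0, F2 = 0),
                           theta_ext = 5)
  occ <- simulate_occupancy(sp, pars, n_sites = 30, n_months = 3, seed = 3)
  expect_gt(attr(occ, "n_capped"), 0)
  # epsilon capped at 1 with predators everywhere: prey all vanish by month 2
  expect_true(all(occ[c("A1", "A2"), , 2] == 0L))
})

test_that("noise-free wells carry exactly the curve-predicted Cq", {
  sp <- species_roster("A1", "prey")
  arr <- array(1L, dim = c(1, 1, 2), dimnames = list("A1", "P01", c("1", "2")))
  truth <- detection_matrix(arr)
  curve <- standard_curve(-1.526, 41.232, lod = 0.01)
  obs <- observation_params(p_rep = 1, p_fp = 0, cq_sd = 0)
  wells <- simulate_wells(truth, obs, curve, seed = 9)
  expect_identical(nrow(wells), 2L * 9L)  # n_bio x n_tech per sampled month
  expect_true(all(!is.na(wells$cq)))
  expect_equal(wells$cq, -1.526 * log(quantify_cq(curve, wells$cq)) + 41.232,
               tolerance = 1e-12)

  none <- simulate_wells(truth, observation_params(p_rep = 0, p_fp = 0), curve, seed = 9)
  expect_true(all(is.na(none$cq)))
})

test_that("replicate amplification matches the closed-form binomial tail", {
  # P(>= 2 of 9 replicates amplify | present, p_rep = 0.9)
  p_tail <- 1 - 0.1^9 - 9 * 0.9 * 0.1^8
  sp <- species_roster("A1", "prey")
  n <- 10000
  arr <- array(1L, dim = c(1, n, 2),
               dimnames = list("A1", sprintf("P%05d", 1:n), c("1", "2")))
  truth <- detection_matrix(arr)
  curve <- standard_curve(-1.526, 41.232, lod = 0.01)
  wells <- simulate_wells(truth, observation_params(p_rep = 0.9, p_fp = 0), curve,
                          seed = 101)
  amp <- tapply(!is.na(wells$cq), interaction(wells$site_id, wells$month), sum)
  rate <- mean(amp >= 2)
  expect_lt(abs(rate - p_tail), 3 * sqrt(p_tail * (1 - p_tail) / (2 * n)) + 1e-6)
})

test_that("missingness spares month 1 and wells are only emitted where sampled", {
  ds <- make_scenario("paper_like", seed = 11)
  expect_true(all(!is.na(ds$truth[, , 1])))
  sampled <- apply(!is.na(unclass(ds$truth)), c(2, 3), all)
  emitted <- unique(ds$wells[c("site_id", "month")])
  for (k in seq_len(nrow(emitted))) {
    expect_true(sampled[emitted$site_id[k], as.character(emitted$month[k])])
  }
  # every sampled site-month emits its full replicate complement
  expect_identical(nrow(ds$wells), sum(sampled) * 4L * 9L)
})

test_that("the dropout rate over later months matches the preset", {
  drop <- 0L; tot <- 0L
  for (s in 1:30) {
    ds <- make_scenario("paper_like", seed = 1000 + s)
    miss <- apply(is.na(unclass(ds$truth)), c(2, 3), all)
    drop <- drop + sum(miss[, -1])
    tot <- tot + length(miss[, -1])
  }
  expect_lt(abs(drop / tot - 0.15), 3 * sqrt(0.15 * 0.85 / tot))
})
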