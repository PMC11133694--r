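test_that("pattern energy matches hand evaluation", {
  zero <- mem_params(c(0, 0, 0), matrix(0, 3, 3))
  expect_equal(pattern_energy(zero, c(1, -1, 1)), 0)

  p <- mem_params(c(0.5, -0.5), matrix(c(0, 0.3, 0.3, 0), 2))
  expect_equal(pattern_energy(p, c(1, 1)), -0.3)
  expect_equal(pattern_energy(p, c(1, -1)), -0.7)
  # matrix form agrees with scalar form across all patterns
  S <- all_patterns(2)
  expect_equal(pattern_energy(p, S),
               apply(S, 1, function(s) pattern_energy(p, s)))
  expect_error(pattern_energy(p, c(1, 1, 1)), "length")
})

test_that("mem_params validates symmetry and zero diagonal", {
  expect_error(mem_params(c(0, 0), matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_error(mem_params(c(0, 0), matrix(c(1, 0, 0, 0), 2)), "diag")
  expect_error(mem_params(c(0, Inf), matrix(0, 2, 2)), "finite")
})

test_that("Boltzmann distribution is normalized, positive, gauge-invariant", {
  unif <- boltzmann_distribution(mem_params(rep(0, 9), matrix(0, 9, 9)))
  expect_equal(unif$probabilities, rep(1 / 512, 512))

  # N = 1 closed form: h = 0.5 ln 3 gives P(+1) = 0.75
  one <- boltzmann_distribution(mem_params(0.5 * log(3), matrix(0, 1, 1)))
  expect_equal(one$probabilities, c(0.25, 0.75))

  tb <- rand_mem_landscape(6, seed = 2)
  expect_equal(sum(tb$probabilities), 1)
  expect_true(all(tb$probabilities > 0))
  shifted <- landscape_from_energies(tb$energies + 37.5)
  expect_equal(shifted$probabilities, tb$probabilities)
})

test_that("empirical moments are plain time averages", {
  all_on <- matrix(1, 2, 4)
  m <- empirical_moments(all_on)
  expect_equal(m$mean_activity, c(1, 1))
  expect_equal(unclass(m$pairwise), matrix(1, 2, 2))

  anti <- cbind(c(1, 1), c(-1, -1))
  m2 <- empirical_moments(anti)
  expect_equal(m2$mean_activity, c(0, 0))
  expect_equal(m2$pairwise[1, 2], 1)

  opp <- cbind(c(1, -1), c(-1, 1))
  expect_equal(empirical_moments(opp)$pairwise[1, 2], -1)
  expect_equal(empirical_moments(opp)$mean_activity, c(0, 0))
})

test_that("model moments are exact expectations in [-1, 1]", {
  unif <- boltzmann_distribution(mem_params(rep(0, 4), matrix(0, 4, 4)))
  mm <- model_moments(unif)
  expect_equal(mm$mean_activity, rep(0, 4))
  expect_equal(mm$pairwise[upper.tri(mm$pairwise)], rep(0, 6))

  one <- boltzmann_distribution(mem_params(0.5 * log(3), matrix(0, 1, 1)))
  expect_equal(model_moments(one)$mean_activity, 0.5)

  tb <- rand_mem_landscape(5, seed = 8)
  mm2 <- model_moments(tb)
  expect_true(all(abs(mm2$mean_activity) <= 1))
  expect_true(all(abs(mm2$pairwise) <= 1 + 1e-12))
})

test_that("independent fit is the atanh closed form and self-consistent", {
  expect_equal(fit_independent_mem(c(0, 0))$h, c(0, 0))
  expect_equal(fit_independent_mem(c(0.5, 0.5))$h, rep(atanh(0.5), 2),
               tolerance = 1e-12)
  fit <- fit_independent_mem(c(0.3, -0.6, 0.1))
  mm <- model_moments(boltzmann_distribution(fit))
  expect_equal(mm$mean_activity, c(0.3, -0.6, 0.1), tolerance = 1e-12)
  expect_warning(fit_independent_mem(c(1, 0)), "clamped")
})

test_that("gradient ascent recovers a model from its exact moments", {
  truth <- make_ground_truth_mem(4, 0.5, 0.3, seed = 21)
  mm <- model_moments(boltzmann_distribution(truth))
  mm$pairwise <- as.matrix(mm$pairwise)
  diag(mm$pairwise) <- 1
  mm$source <- "empirical"
  fit <- fit_pairwise_mem(mm, tol = 1e-8)
  expect_true(fit$diagnostics$converged)
  expect_lt(max(abs(fit$params$h - truth$h)), 1e-4)
  expect_lt(max(abs(fit$params$J - truth$J)), 1e-4)
})

test_that("moment matching holds at the stopping tolerance", {
  truth <- make_ground_truth_mem(5, 0.3, 0.3, seed = 5)
  dat <- sample_patterns(truth, 3000, mode = "iid", seed = 6)
  emp <- empirical_moments(dat)
  fit <- fit_pairwise_mem(emp, tol = 1e-6)
  expect_true(fit$diagnostics$converged)
  expect_lt(fit$diagnostics$max_moment_gap, 1e-6)
  mm <- model_moments(boltzmann_distribution(fit$params))
  expect_lt(max(abs(mm$mean_activity - emp$mean_activity)), 1e-6)
})

test_that("fitting data from an independent model leaves J near zero", {
  truth <- fit_independent_mem(c(0.4, -0.2, 0.1, 0.3))
  dat <- sample_patterns(truth, 5e4, mode = "iid", seed = 31)
  fit <- fit_pairwise_mem(empirical_moments(dat), tol = 1e-6)
  # sampling error of a pairwise moment at T = 5e4 is about 1/sqrt(T);
  # 0.05 is a 3-sigma bound with ample room for the moment-to-J jacobian
  expect_lt(max(abs(fit$params$J)), 0.05)
})

test_that("divergent learning rates raise a convergence error", {
  truth <- make_ground_truth_mem(4, 0.05, 0.05, seed = 13)
  mm <- model_moments(boltzmann_distribution(truth))
  mm$source <- "empirical"
  # large fixed step with damping off: the gap blows up from its small
  # starting value and trips the tenfold-growth check
  expect_error(
    fit_pairwise_mem(mm, learning_rate = 50, tol = 1e-10, max_iter = 2000,
                     adapt_lr = FALSE),
    "diverging|learning")
})

test_that("fit accuracy hits its defining limits", {
  tb <- rand_mem_landscape(4, seed = 3, coupling = 0.5)
  indep <- boltzmann_distribution(
    fit_independent_mem(model_moments(tb)$mean_activity))
  # empirical distribution equal to the pairwise model: D2 = 0, R = 1
  acc1 <- fit_accuracy(tb$probabilities, indep, tb)
  expect_equal(acc1$D2, 0, tolerance = 1e-12)
  expect_equal(acc1$R, 1, tolerance = 1e-12)
  # pairwise model identical to the independent model: R = 0
  acc0 <- fit_accuracy(tb$probabilities, indep, indep)
  expect_equal(acc0$R, 0, tolerance = 1e-12)
  # D1 = 0 when the data match the independent model
  expect_warning(acc_na <- fit_accuracy(indep$probabilities, indep, indep),
                 "undefined")
  expect_true(is.na(acc_na$R))
})

test_that("strong couplings give high R and near-perfect probability correlation", {
  truth <- make_ground_truth_mem(4, 0.2, 0.6, seed = 17)
  tb <- boltzmann_distribution(truth)
  mm <- model_moments(tb)
  mm$source <- "empirical"
  fit <- fit_pairwise_mem(mm, tol = 1e-8)
  indep <- boltzmann_distribution(fit_independent_mem(mm$mean_activity))
  acc <- fit_accuracy(tb$probabilities, indep,
                      boltzmann_distribution(fit$params))
  expect_gt(acc$R, 0.9)
  expect_gt(acc$pearson_r, 0.99)
  expect_gte(acc$D1, acc$D2)
})

test_that("KL uses base-2 logs and ignores zero-frequency patterns", {
  e <- landscape_from_energies(c(0, 0, 0, 0))
  q <- landscape_from_energies(-log(c(0.4, 0.3, 0.2, 0.1)))
  f <- c(0.5, 0.5, 0, 0)   # zero-frequency patterns contribute nothing
  acc <- fit_accuracy(f, q, e)
  expect_equal(acc$D1, 0.5 * log2(0.5 / 0.4) + 0.5 * log2(0.5 / 0.3))
  expect_equal(acc$D2, 0.5 * log2(0.5 / 0.25) * 2)
})

test_that("accuracy R rises toward 1 with sample size", {
  truth <- make_ground_truth_mem(4, 0.2, 0.5, seed = 9)
  tb <- boltzmann_distribution(truth)
  sizes <- c(500, 5000, 50000)
  r_of <- function(T, seed) {
    dat <- sample_patterns(truth, T, mode = "iid", seed = seed)
    emp <- empirical_moments(dat)
    fit <- fit_pairwise_mem(emp, tol = 1e-6)
    indep <- boltzmann_distribution(fit_independent_mem(emp$mean_activity))
    fit_accuracy(empirical_pattern_frequencies(dat), indep,
                 boltzmann_distribution(fit$params))$R
  }
  med <- sapply(seq_along(sizes), function(i) {
    median(sapply(1:7, function(s) r_of(sizes[i], seed = 100 * i + s)))
  })
  expect_true(all(diff(med) > 0))
  expect_gt(med[3], 0.9)
})
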