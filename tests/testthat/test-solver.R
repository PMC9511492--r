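# The network inverse solver: training behaviour, sign enumeration, and
# magnitude-only inversion under the two-sheet constraint.

test_that("sign enumeration covers all 2^16 assignments", {
  set.seed(71)
  mags <- runif(16, 0.1, 1)
  en <- enumerate_signs(mags)
  expect_equal(en$n, 65536L)
  # stream in blocks; verify count, coverage and distinctness by hashing
  seen <- character(0)
  for (from in seq(0L, 65535L, by = 16384L)) {
    blk <- en$block(from, from + 16383L)
    expect_equal(abs(blk), matrix(mags, 16384, 16, byrow = TRUE),
                 tolerance = 1e-15, ignore_attr = TRUE)
    seen <- c(seen, apply(sign(blk), 1, paste, collapse = ""))
  }
  expect_equal(length(seen), 65536L)
  expect_equal(length(unique(seen)), 65536L)

  # degenerate cases: all-zero magnitudes collapse to one vector,
  # a single nonzero magnitude to exactly two
  z <- enumerate_signs(rep(0, 16))$block(0L, 65535L)
  expect_equal(nrow(unique(z)), 1L)
  one <- enumerate_signs(c(2, rep(0, 15)))$block(0L, 65535L)
  expect_equal(nrow(unique(one)), 2L)

  expect_error(enumerate_signs(c(-1, rep(1, 15))), "nonnegative")
  expect_error(enumerate_signs(rep(1, 8)), "16")
})

test_that("training learns a degenerate constant-output set to < 1e-4", {
  set.seed(81)
  X <- matrix(runif(500 * 16, -1, 1), 500, 16)
  Y <- matrix(rep(c(0.3, -0.2, 0.1, 0.5, 0, 0.4, 1, 0.7, 2, 0, 0), each = 500),
              500, 11)
  ts <- structure(list(inputs = X, outputs = Y, seed = 1,
                       ranges = training_ranges(), kind = "train"),
                  class = "vsfg_training_set")
  m <- train_solver(ts, solver_config(epochs = 60, batch_size = 50,
                                      lr = 5e-3, seed = 82))
  expect_lt(tail(m$history$train, 1), 1e-4)
  expect_equal(nrow(m$history), 60L)   # history length = epochs run
})

test_that("training loss trends down and validation tracks training", {
  m <- small_solver()
  h <- m$history
  # monotone trend allowing plateaus: smoothed loss decreases
  third <- floor(nrow(h) / 3)
  expect_lt(mean(tail(h$train, third)), mean(head(h$train, third)))
  expect_lt(tail(h$validation, 1), 2 * tail(h$train, 1))
  # deterministic retraining under the same seed
  ts <- gen_training_set(2000, seed = 403)
  cfg <- solver_config(epochs = 5, seed = 404)
  m1 <- train_solver(ts, cfg)
  m2 <- train_solver(ts, cfg)
  expect_identical(m1$weights, m2$weights)
})

test_that("solver predictions land near the identity on unseen data", {
  m <- small_solver()
  te <- gen_test_set(400, seed = 405)
  ev <- evaluate_solver(m, te)
  # a reduced training run cannot hit the full-recipe figures, but the
  # correlation structure must already be tight for the identifiable
  # in-plane rotation and clearly present for the prior-identified tilt
  expect_gt(cor(ev$scatter$phi_true, ev$scatter$phi_pred), 0.99)
  expect_gt(cor(ev$scatter$theta_true, ev$scatter$theta_pred), 0.85)
})

test_that("signed observations are inverted almost exactly", {
  # forward-generate a signed observation; the solver must identify the
  # true sign pattern (up to the global flip) and reconstruct with ~0 MSE
  m <- small_solver()
  set.seed(91)
  b <- random_beta(signed = FALSE)
  theta <- 23 * pi / 180; phi <- 10 * pi / 180
  chi1 <- lab_susceptibilities(b, phi, theta)
  chi2 <- lab_susceptibilities(b, phi + pi / 3, theta) * 1.4
  signed <- c(chi1, chi2)
  obs <- two_sheet_observation(abs(signed), delta_phi_deg = 60)
  sol <- solve_orientation(obs, m)
  expect_s3_class(sol, "orientation_solution")
  expect_lt(sol$susceptibility_mse, 1e-3)
  # in-plane rotation is exactly identifiable; tilt only up to the width
  # of the amplitude-prior posterior (see the methods vignette)
  expect_lt(abs(sol$phi1_deg - 10), 2)
  expect_lt(abs(sol$theta_deg - 23), 8)

  # the winning signs must match the true ones up to the global flip on
  # every component that carries appreciable magnitude (signs of
  # near-zero susceptibilities are unconstrained by construction)
  won <- ifelse(strsplit(sol$sign_pattern, "")[[1]] == "-", -1, 1)
  big <- abs(signed) > 0.05 * max(abs(signed))
  agree <- sign(signed)[big] * won[big]
  expect_true(all(agree == 1) || all(agree == -1))
})

test_that("global sign flips are exactly equivalent and solving is deterministic", {
  m <- small_solver()
  set.seed(92)
  b <- random_beta(signed = FALSE)
  chi1 <- lab_susceptibilities(b, 1.1, 0.5)
  chi2 <- lab_susceptibilities(b, 1.1 + pi / 3, 0.5) * 0.8
  obs <- two_sheet_observation(abs(c(chi1, chi2)))
  s1 <- solve_orientation(obs, m)
  s2 <- solve_orientation(obs, m)
  expect_identical(s1$sign_index, s2$sign_index)
  expect_identical(s1$susceptibility_mse, s2$susceptibility_mse)
  # the complement pattern is reported as the equivalent solution
  expect_identical(s1$equivalent_pattern, chartr("+-", "-+", s1$sign_pattern))
  expect_lte(s1$susceptibility_mse, min(s1$runner_ups$susceptibility_mse) + 1e-15)
  expect_equal(s1$theta_deg, s2$theta_deg)
})

test_that("solver rejects invalid observations and untrained models", {
  m <- small_solver()
  expect_error(two_sheet_observation(rep(-1, 16)), "nonnegative")
  expect_error(two_sheet_observation(rep(1, 5)), "16")
  expect_error(solve_orientation(two_sheet_observation(rep(0, 16)), m),
               "unidentifiable")
  expect_error(solve_orientation(two_sheet_observation(rep(1, 16)),
                                 list(weights = NULL)), "trained")
})

test_that("solver checkpoints round-trip with a JSON manifest", {
  m <- small_solver()
  path <- withr::local_tempfile(fileext = ".rds")
  save_solver(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  manifest <- jsonlite::read_json(paste0(path, ".json"),
                                  simplifyVector = TRUE)
  expect_equal(manifest$architecture$hidden, c(200, 100, 50))
  expect_equal(manifest$architecture$activation, "tanh")
  back <- load_solver(path)
  te <- gen_test_set(50, seed = 406)
  expect_identical(predict_solver(back, te$inputs),
                   predict_solver(m, te$inputs))
})
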