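# Shared fixtures: all synthetic, built in code under fixed seeds.

# signed draws exercise the forward map in full generality; unsigned draws
# stay inside the generator's positive sampling box (solver tests)
random_beta <- function(signed = TRUE) {
  b <- if (signed) runif(7, -1, 1) else runif(7, 0.05, 1)
  do.call(hyperpolarizability_c7, as.list(b))
}

# a small but non-trivial scene used across imaging tests; sheet geometry
# scales with the image so small fixtures stay in bounds
test_scene <- function(theta_deg = 23, snr = 56, dim = c(40, 56),
                       two_sheets = FALSE) {
  beta <- c(1, 0.45, 0.3, 0.25, 0.15, -0.1, 0.2)
  ny <- dim[1]; nx <- dim[2]
  side <- round(0.27 * min(dim))
  sheets <- list(list(center = c(0.32 * nx, 0.45 * ny), side = side,
                      phi_deg = 25, theta_deg = theta_deg, beta = beta,
                      scale = 1))
  if (two_sheets) {
    sheets[[2]] <- list(center = c(0.68 * nx, 0.5 * ny), side = side,
                        phi_deg = 85, theta_deg = theta_deg, beta = beta,
                        scale = 1.3)
  }
  sheet_scene(dim = dim, sheets = sheets, snr = snr, baseline = 10)
}

# one small trained solver shared by solver tests (cached per session)
small_solver <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ts <- gen_training_set(20000, seed = 401)
      cache <<- train_solver(ts, solver_config(epochs = 60, lr = 2e-3,
                                               lr_decay = 0.97, seed = 402))
    }
    cache
  }
})
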