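# Neural-network inverse solver: a 200-100-50 tanh regressor from the 16
# normalized two-sheet susceptibilities to the 11-value parameter encoding,
# plus magnitude-only inversion by sign enumeration and minimal forward-MSE
# selection.

#' Solver training configuration
#'
#' @param hidden hidden layer widths.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param val_frac fraction of the shuffled set held out for validation
#'   (the trailing fraction after a seeded shuffle).
#' @param lr Adam step size.
#' @param lr_decay per-epoch multiplicative step-size decay.
#' @param seed seed for initialization, shuffling and batching.
#' @param verbose_every print losses every this many epochs (0 = silent).
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(hidden = c(200, 100, 50), epochs = 1000,
                          batch_size = 100, val_frac = 0.1, lr = 1e-3,
                          lr_decay = 0.999, seed = 1, verbose_every = 0) {
  stopifnot(epochs >= 1, batch_size >= 1, val_frac >= 0, val_frac < 1,
            lr > 0, lr_decay > 0, lr_decay <= 1)
  structure(list(hidden = as.integer(hidden), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), val_frac = val_frac,
                 lr = lr, lr_decay = lr_decay, seed = as.integer(seed),
                 verbose_every = as.integer(verbose_every)),
            class = "solver_config")
}

#' Train the orientation solver network
#'
#' Fits the feed-forward network (hyperbolic-tangent activations between
#' layers, linear output of width 11) to a forward-model training set by
#' minibatch Adam on mean squared error. Training and validation losses are
#' recorded every epoch; training aborts with a diagnostic if the loss
#' becomes non-finite.
#'
#' @param training_set a [gen_training_set()] result.
#' @param config a [solver_config()].
#' @return A list of class `vsfg_solver`: `weights`, `biases`, `history`
#'   (data.frame epoch/train/validation), `config`, `ranges`.
#' @export
train_solver <- function(training_set, config = solver_config()) {
  stopifnot(inherits(training_set, "vsfg_training_set"),
            inherits(config, "solver_config"))
  fit <- mlp_train_cpp(training_set$inputs, training_set$outputs,
                       config$hidden, config$epochs, config$batch_size,
                       config$val_frac, config$lr, config$lr_decay,
                       config$seed, config$verbose_every)
  structure(list(weights = fit$weights, biases = fit$biases,
                 history = data.frame(epoch = seq_len(config$epochs),
                                      train = as.numeric(fit$train_loss),
                                      validation = as.numeric(fit$val_loss)),
                 n_train = fit$n_train, n_val = fit$n_val,
                 config = config, ranges = training_set$ranges),
            class = "vsfg_solver")
}

#' Predict encoded outputs for normalized susceptibility inputs
#'
#' @param model a trained [train_solver()] model.
#' @param X n x 16 matrix of unit-normalized signed susceptibilities.
#' @return n x 11 matrix in the training-output encoding.
#' @export
predict_solver <- function(model, X) {
  stopifnot(inherits(model, "vsfg_solver"))
  X <- matrix(as.numeric(X), ncol = 16)
  Y <- mlp_predict_cpp(model$weights, model$biases, X)
  colnames(Y) <- c(GROUPED_NAMES, "phi", "theta", "coverage",
                   "phi_interval", "theta_interval")
  Y
}

#' Evaluate angle recovery on a test set
#'
#' Decodes predictions on an independent test set and reports the mean
#' squared error of the in-plane rotation over all samples and of the tilt
#' over the subset with true tilt below `tilt_cut` degrees, both in
#' degrees.
#'
#' @param model a trained solver.
#' @param test_set a [gen_test_set()] result.
#' @param tilt_cut restrict the tilt MSE to true tilts below this, degrees.
#' @return List with `phi_mse_deg`, `theta_mse_deg`, `n_tilt_subset`, and a
#'   `scatter` data.frame of true/predicted angles in degrees.
#' @export
evaluate_solver <- function(model, test_set, tilt_cut = 30) {
  pred <- decode_outputs(predict_solver(model, test_set$inputs))
  true <- decode_outputs(test_set$outputs)
  r2d <- 180 / pi
  scatter <- data.frame(phi_true = true$phi * r2d,
                        phi_pred = pred$phi * r2d,
                        theta_true = true$theta * r2d,
                        theta_pred = pred$theta * r2d)
  sub <- scatter$theta_true < tilt_cut
  list(phi_mse_deg = mean((scatter$phi_pred - scatter$phi_true)^2),
       theta_mse_deg = mean((scatter$theta_pred[sub] -
                               scatter$theta_true[sub])^2),
       n_tilt_subset = sum(sub), scatter = scatter)
}

#' Two-sheet magnitude observation
#'
#' @param magnitudes the 16 nonnegative susceptibility magnitudes: a 2 x 8
#'   matrix (rows = sheets, columns in [POLARIZATIONS] order) or a
#'   16-vector (sheet 1 then sheet 2).
#' @param delta_phi_deg known in-plane rotation offset between the sheets,
#'   degrees.
#' @param sheet_ids,pixel_counts optional metadata.
#' @return A list of class `two_sheet_observation`.
#' @export
two_sheet_observation <- function(magnitudes, delta_phi_deg = 60,
                                  sheet_ids = c("sheet1", "sheet2"),
                                  pixel_counts = NULL) {
  m <- as.numeric(if (is.matrix(magnitudes)) t(magnitudes) else magnitudes)
  if (length(m) != 16) stop("an observation carries exactly 16 magnitudes")
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("susceptibility magnitudes must be finite and nonnegative")
  }
  structure(list(magnitudes = m, delta_phi_deg = delta_phi_deg,
                 sheet_ids = sheet_ids, pixel_counts = pixel_counts),
            class = "two_sheet_observation")
}

#' Enumerate sign assignments of 16 magnitudes
#'
#' Homodyne detection loses the susceptibility signs, so inversion
#' enumerates all `2^16 = 65536` assignments. To keep memory flat the
#' enumeration is exposed as an indexed accessor: pattern `i` (0-based)
#' applies sign `-1` where bit `b` of `i` is set (bit 0 = first magnitude).
#'
#' @param magnitudes 16 nonnegative values.
#' @return A list of class `sign_enumeration` with `n = 65536`, and
#'   `block(from, to)` returning the signed vectors for a 0-based index
#'   range as a matrix.
#' @export
enumerate_signs <- function(magnitudes) {
  magnitudes <- as.numeric(magnitudes)
  if (length(magnitudes) != 16) stop("expected 16 magnitudes")
  if (any(magnitudes < 0)) stop("magnitudes must be nonnegative")
  block <- function(from, to) {
    idx <- from:to
    signs <- matrix(1, length(idx), 16)
    for (b in 0:15) {
      signs[, b + 1] <- ifelse(bitwAnd(idx, bitwShiftL(1L, b)) > 0, -1, 1)
    }
    sweep(signs, 2, magnitudes, "*")
  }
  structure(list(n = 65536L, magnitudes = magnitudes, block = block),
            class = "sign_enumeration")
}

#' Invert a magnitude-only observation
#'
#' For every sign assignment the candidate signed vector is normalized and
#' passed through the network; the predicted parameters are decoded, pushed
#' back through the two-sheet forward model, normalized, and scored by the
#' mean squared error against the signed candidate. Because a global sign
#' flip of all 16 susceptibilities is physically unobservable (it
#' corresponds to flipping the hyperpolarizability sign convention), each
#' pattern is scored as the better of itself and its global flip, making
#' complementary patterns exactly equivalent; the reported solution is the
#' global minimum, ties broken by lowest pattern index.
#'
#' @param obs a [two_sheet_observation()].
#' @param model a trained [train_solver()] model.
#' @param n_runner_up number of ranked runner-up patterns to keep.
#' @param chunk internal enumeration block size.
#' @return A list of class `orientation_solution`: `theta_deg` (folded into
#'   `[0, 90]`), `phi1_deg` (reported modulo 180; the global-flip symmetry
#'   makes `phi` and `phi + 180` equivalent), `grouped_beta` (unit
#'   normalized), `coverage`, `sign_pattern` (16-character +/- string),
#'   `sign_index`, `equivalent_pattern` (the global flip), `susceptibility_mse`,
#'   `tied_indices`, and `runner_ups` (data.frame).
#' @export
solve_orientation <- function(obs, model, n_runner_up = 10, chunk = 8192L) {
  stopifnot(inherits(obs, "two_sheet_observation"))
  if (!inherits(model, "vsfg_solver")) stop("model is not a trained solver")
  if (all(obs$magnitudes == 0)) {
    stop("all-zero observation: orientation unidentifiable (theta = 0 family)")
  }
  enum <- enumerate_signs(obs$magnitudes)
  mse_raw <- numeric(enum$n)
  store <- matrix(NA_real_, enum$n, 11)
  for (from in seq(0L, enum$n - 1L, by = chunk)) {
    to <- min(from + chunk - 1L, enum$n - 1L)
    V <- enum$block(from, to)
    nrm <- row_norms(V)
    Xn <- V / nrm
    Y <- predict_solver(model, Xn)
    # clamp decoded parameters to their physical domains before re-forward
    Y[, 8] <- pmin(pmax(Y[, 8], 1e-3), pi / 2 - 1e-6)
    Y[, 9] <- pmax(Y[, 9], 1e-6)
    rec <- forward_from_outputs(Y, obs$delta_phi_deg)
    mse_raw[(from:to) + 1L] <- rowMeans((rec - Xn)^2)
    store[(from:to) + 1L, ] <- Y
  }
  # global-flip symmetrization: pattern i and its complement describe the
  # same physical state; score both with the better reconstruction
  comp <- bitwXor(0:(enum$n - 1L), 65535L) + 1L
  mse <- pmin(mse_raw, mse_raw[comp])

  ord <- order(mse, seq_along(mse))   # stable: lowest index wins ties
  best <- ord[1]
  best_raw <- if (mse_raw[best] <= mse_raw[comp[best]]) best else comp[best]
  dec <- decode_outputs(store[best_raw, , drop = FALSE])
  r2d <- 180 / pi
  theta_deg <- dec$theta * r2d
  theta_deg <- if (theta_deg > 90) 180 - theta_deg else theta_deg
  ties <- which(mse == mse[best])

  keep <- ord[seq_len(min(n_runner_up + 1, length(ord)))]
  runner <- data.frame(sign_index = keep - 1L,
                       susceptibility_mse = mse[keep],
                       theta_deg = pmin(store[keep, 8] * r2d,
                                        180 - store[keep, 8] * r2d))
  pat <- function(i0) {
    bits <- bitwAnd(bitwShiftR(i0, 0:15), 1L)
    paste(ifelse(bits > 0, "-", "+"), collapse = "")
  }
  structure(list(theta_deg = theta_deg,
                 phi1_deg = (dec$phi * r2d) %% 180,
                 grouped_beta = stats::setNames(as.numeric(dec$g),
                                                GROUPED_NAMES),
                 coverage = dec$coverage,
                 sign_pattern = pat(best_raw - 1L),
                 sign_index = best_raw - 1L,
                 equivalent_pattern = pat(bitwXor(best_raw - 1L, 65535L)),
                 susceptibility_mse = mse[best],
                 tied_indices = ties - 1L,
                 runner_ups = runner[-1, , drop = FALSE]),
            class = "orientation_solution")
}

#' @export
print.orientation_solution <- function(x, ...) {
  cat("Two-sheet orientation solution\n")
  cat(sprintf("  tilt theta      : %.2f deg (folded into [0, 90])\n",
              x$theta_deg))
  cat(sprintf("  in-plane phi1   : %.2f deg (mod 180)\n", x$phi1_deg))
  cat(sprintf("  coverage ratio N: %.3f\n", x$coverage))
  cat(sprintf("  min susceptibility MSE: %.3g\n", x$susceptibility_mse))
  cat(sprintf("  sign pattern    : %s (equivalent: %s)\n", x$sign_pattern,
              x$equivalent_pattern))
  invisible(x)
}

#' Solver checkpoint I/O
#'
#' Weights are stored as an RDS container next to a JSON architecture
#' manifest (`<path>.json`) recording the layer widths, activation and
#' training configuration.
#'
#' @param model a trained solver.
#' @param path checkpoint path (RDS).
#' @return `path` invisibly (writer); a `vsfg_solver` (reader).
#' @export
save_solver <- function(model, path) {
  stopifnot(inherits(model, "vsfg_solver"))
  saveRDS(unclass(model), path)
  manifest <- list(architecture = list(
    input = 16L, hidden = model$config$hidden, output = 11L,
    activation = "tanh", output_activation = "linear"),
    training = model$config[c("epochs", "batch_size", "val_frac", "lr",
                              "lr_decay", "seed")],
    final_train_loss = utils::tail(model$history$train, 1),
    final_validation_loss = utils::tail(model$history$validation, 1))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_solver
#' @export
load_solver <- function(path) {
  obj <- readRDS(path)
  stopifnot(is.list(obj), all(c("weights", "biases", "config") %in% names(obj)))
  class(obj$config) <- "solver_config"
  structure(obj, class = "vsfg_solver")
}

#' Solution JSON export
#'
#' @param solution an [solve_orientation()] result.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_solution <- function(solution, path) {
  stopifnot(inherits(solution, "orientation_solution"))
  jsonlite::write_json(unclass(solution), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}
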