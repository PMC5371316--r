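## Umbrella windows over the dRMSD coordinate with Hamiltonian replica
## exchange.

#' Build equally spaced umbrella windows
#'
#' Windows are endpoint-inclusive: `R0` runs from `r_min` to `r_max` in
#' `n_windows` equal steps of `(r_max - r_min) / (n_windows - 1)`. The
#' defaults reproduce the sampling protocol of 12 windows over 0.0-0.5 nm.
#'
#' @param n_windows Number of windows (>= 2).
#' @param r_min,r_max dRMSD range (nm), `r_max > r_min`.
#' @param k0 Restraint force constant, kJ mol^-1 nm^-2 (recycled; a
#'   per-window vector is allowed for poorly overlapping cases).
#' @return A tibble with columns `window`, `R0`, `k0`.
#' @export
build_windows <- function(n_windows = 12, r_min = 0, r_max = 0.5, k0 = 1000) {
  if (n_windows < 2) abort("`n_windows` must be >= 2.", class = "helixscan_invalid_config")
  if (r_max <= r_min) abort("`r_max` must exceed `r_min`.", class = "helixscan_invalid_config")
  tibble(window = seq_len(n_windows),
         R0 = seq(r_min, r_max, length.out = n_windows),
         k0 = rep_len(k0, n_windows))
}

#' Metropolis swap attempt between two umbrella windows
#'
#' Both replicas share one Hamiltonian and differ only in their bias, so the
#' unbiased energy cancels and the swap criterion involves bias energies
#' only: accept with probability
#' `min(1, exp(-beta * (Va(xb) + Vb(xa) - Va(xa) - Vb(xb))))`.
#'
#' @param state_a,state_b Lists with elements `R` (current dRMSD, nm) and
#'   `restraint` (list with `R0`, `k0` in kJ mol^-1 nm^-2), and optionally
#'   `conf`.
#' @param beta Inverse temperature 1/(kB T) in mol/kJ.
#' @param u Optional uniform deviate in [0,1) for the decision (drawn from
#'   the session RNG when `NULL`).
#' @return A list: `accepted` (logical), `delta` (dimensionless
#'   `beta * Delta`), and `state_a`, `state_b` after the swap (exchanged
#'   when accepted).
#' @export
attempt_exchange <- function(state_a, state_b, beta, u = NULL) {
  va <- function(R, r) restraint_energy(R, r$R0, r$k0)
  delta <- beta * (va(state_b$R, state_a$restraint) +
                   va(state_a$R, state_b$restraint) -
                   va(state_a$R, state_a$restraint) -
                   va(state_b$R, state_b$restraint))
  if (is.null(u)) u <- runif(1)
  accepted <- delta <= 0 || u < exp(-delta)
  if (accepted) {
    keep <- state_a[c("R", "conf")]
    state_a[c("R", "conf")] <- state_b[c("R", "conf")]
    state_b[c("R", "conf")] <- keep
  }
  list(accepted = accepted, delta = delta, state_a = state_a, state_b = state_b)
}

#' Restrained windowed sampling with Hamiltonian replica exchange
#'
#' Runs one Monte Carlo replica per umbrella window under the model energy
#' plus its window's dRMSD restraint; neighbour swaps are attempted every
#' `exchange_interval` sweeps, alternating even/odd pairs. One "step" is one
#' MC sweep (one attempted pivot per pseudo-dihedral plus crankshaft moves).
#' Fully deterministic under a fixed seed; per-replica random streams are
#' derived from the master seed by fixed offsets, so adding windows never
#' perturbs existing streams.
#'
#' @param params A [model_parameters()].
#' @param windows Tibble from [build_windows()].
#' @param n_steps MC sweeps per replica (>= `exchange_interval`).
#' @param exchange_interval Sweeps between swap attempts (default 500).
#' @param seed Master seed.
#' @param init Starting structure per replica (`"helix"`, `"extended"` or a
#'   [chain_conformation()]).
#' @param record_every Record every this many sweeps.
#' @param segment_id Label for conformations.
#' @return A `windowed_samples` object: `$samples` tibble (window, step, R,
#'   energy), `$conformations` (list per window of [chain_conformation()]),
#'   `$exchange_log` tibble, `$windows`, `$acceptance` per window, and the
#'   dRMSD `$reference`.
#' @export
run_hremd <- function(params, windows, n_steps, exchange_interval = 500,
                      seed = 1, init = "helix", record_every = 1,
                      segment_id = "segment") {
  if (is.null(windows) || nrow(windows) < 1) {
    abort("At least one window is required.", class = "helixscan_invalid_config")
  }
  if (nrow(windows) > 1 && n_steps < exchange_interval) {
    abort("`n_steps` must be at least `exchange_interval`.",
          class = "helixscan_invalid_config")
  }
  n <- length(params$helix_bias)
  X0 <- init_conformation(init, n)
  ref <- helical_reference(n)
  beta_kJ <- 1 / kBT(params$temperature)
  out <- .mc_run_cpp(coords_of(X0), params_list(params),
                     ref$pair_list - 1L, ref$d0,
                     R0s = windows$R0, k0s_kBT = windows$k0 * beta_kJ,
                     n_sweeps = as.integer(n_steps),
                     exchange_interval = as.integer(exchange_interval),
                     record_every = as.integer(record_every),
                     seed = as.numeric(seed), max_pivot = pi / 3,
                     max_crank = pi / 3, n_crank = 2L)
  W <- nrow(windows)
  samples <- tidyr::expand_grid(window = seq_len(W),
                                step = as.integer(out$step)) |>
    arrange(.data$window, .data$step)
  samples$R <- as.numeric(out$R[cbind(match(samples$step, out$step), samples$window)])
  samples$energy <- as.numeric(out$energy[cbind(match(samples$step, out$step), samples$window)]) *
    energy_scale(params)
  confs <- lapply(seq_len(W), function(w) {
    cube_to_conformations(out$conformations[[w]], segment_id)
  })
  structure(list(
    samples = samples,
    conformations = confs,
    exchange_log = as_tibble(out$exchange) |>
      mutate(accepted = as.logical(.data$accepted)),
    windows = windows,
    acceptance = as.numeric(out$acceptance),
    reference = ref, params = params, seed = seed,
    segment_id = segment_id
  ), class = "windowed_samples")
}

#' @export
print.windowed_samples <- function(x, ...) {
  cat(sprintf("<windowed_samples> %d windows x %d frames; move acceptance %.2f; swap acceptance %.2f\n",
              nrow(x$windows), nrow(x$samples) / nrow(x$windows),
              mean(x$acceptance),
              if (nrow(x$exchange_log)) mean(x$exchange_log$accepted) else NA_real_))
  invisible(x)
}

#' @rdname run_hremd
#' @param x A `windowed_samples` object.
#' @param ... Unused.
#' @export
glance.windowed_samples <- function(x, ...) {
  tibble(n_windows = nrow(x$windows),
         n_frames = nrow(x$samples) / nrow(x$windows),
         move_acceptance = mean(x$acceptance),
         swap_acceptance = if (nrow(x$exchange_log)) mean(x$exchange_log$accepted) else NA_real_,
         mean_R = mean(x$samples$R))
}

#' @rdname run_hremd
#' @export
tidy.windowed_samples <- function(x, ...) x$samples

#' One-dimensional umbrella-sampling harness
#'
#' Samples a scalar coordinate under `potential(x) + restraint` per window
#' with Metropolis Monte Carlo. This is the validation harness used to check
#' the umbrella/WHAM machinery against closed forms: with `potential = NULL`
#' (pure restraint) each window's marginal is Gaussian with variance
#' `1 / (beta * k0)`; with an analytic double-well the WHAM reconstruction
#' can be compared with the exact profile.
#'
#' @param windows Tibble from [build_windows()].
#' @param n_steps MC steps per window.
#' @param potential Function of `x` returning energy in kJ/mol, or `NULL`.
#' @param temperature Kelvin.
#' @param step_size Proposal half-width.
#' @param x0 Starting value(s), recycled over windows.
#' @param seed Seed for the session RNG.
#' @param burn_in Discarded initial fraction.
#' @return A tibble (window, step, R) of retained samples.
#' @export
sample_windows_1d <- function(windows, n_steps, potential = NULL,
                              temperature = 300, step_size = 0.05,
                              x0 = NULL, seed = 1, burn_in = 0.1) {
  set.seed(seed)
  beta <- 1 / kBT(temperature)
  W <- nrow(windows)
  x <- rep_len(x0 %||% windows$R0, W)
  pot <- if (is.null(potential)) function(x) 0 else potential
  etot <- function(x) pot(x) + 0.5 * windows$k0 * (x - windows$R0)^2
  e <- etot(x)
  keep <- matrix(NA_real_, n_steps, W)
  for (s in seq_len(n_steps)) {
    xp <- x + runif(W, -step_size, step_size)
    ep <- etot(xp)
    acc <- runif(W) < exp(-beta * (ep - e))
    x[acc] <- xp[acc]; e[acc] <- ep[acc]
    keep[s, ] <- x
  }
  drop <- seq_len(floor(burn_in * n_steps))
  keep <- if (length(drop)) keep[-drop, , drop = FALSE] else keep
  tibble(window = rep(seq_len(W), each = nrow(keep)),
         step = rep(seq_len(nrow(keep)), W),
         R = as.numeric(keep))
}
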