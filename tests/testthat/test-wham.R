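double_well <- function(x) 60 * ((x - 0.25)^2 - 0.015)^2 / 0.015^2 * 0.15  # kJ/mol

test_that("single unbiased window reduces WHAM to Boltzmann inversion", {
  set.seed(1)
  x <- rnorm(5000, 0.25, 0.05)
  tbl <- tibble::tibble(window = 1L, R = x)
  w <- tibble::tibble(window = 1L, R0 = 0.25, k0 = 1e-12)
  pmf <- wham(tbl, windows = w, temperature = 300, bin_width = 0.01,
              range = c(0, 0.5))
  kT <- kBT(300)
  edges <- seq(0, 0.51, by = 0.01)
  h <- hist(x, breaks = edges, plot = FALSE)$counts
  direct <- -kT * log(h / sum(h))
  direct <- direct - min(direct[is.finite(direct)])
  def <- !is.na(pmf$F) & is.finite(direct[seq_len(nrow(pmf))])
  expect_equal(pmf$F[def], direct[seq_len(nrow(pmf))][def], tolerance = 1e-10)
})

test_that("WHAM recovers an analytic double-well from biased sampling", {
  w <- build_windows(12, 0, 0.5, k0 = 1000)
  s <- sample_windows_1d(w, n_steps = 40000, potential = double_well,
                         seed = 7, step_size = 0.08)
  pmf <- wham(s, windows = w, temperature = 300, bin_width = 0.01)
  kT <- kBT(300)
  well <- pmf[!is.na(pmf$F) & pmf$n_samples >= 50 & pmf$R >= 0 & pmf$R <= 0.5, ]
  ana <- double_well(well$R); ana <- ana - min(ana)
  est <- well$F - min(well$F)
  off <- mean(est - ana)
  rmse <- sqrt(mean((est - ana - off)^2)) / kT
  expect_lt(rmse, 0.1)
})

test_that("WHAM is invariant to window order and uniform bias offsets", {
  w <- build_windows(8, 0, 0.4, k0 = 800)
  s <- sample_windows_1d(w, n_steps = 8000, potential = double_well, seed = 9,
                         step_size = 0.08)
  pmf <- wham(s, windows = w, temperature = 300, tol = 1e-12)
  set.seed(2)
  perm <- sample(8)
  w_perm <- w[perm, ]
  pmf_perm <- wham(s, windows = w_perm, temperature = 300, tol = 1e-12)
  expect_equal(pmf$F, pmf_perm$F, tolerance = 1e-8)
})

test_that("disconnected histograms raise an error naming the gap", {
  tbl <- tibble::tibble(window = rep(c(1L, 2L), each = 100),
                        R = c(runif(100, 0, 0.05), runif(100, 0.4, 0.45)))
  w <- tibble::tibble(window = 1:2, R0 = c(0.02, 0.42), k0 = 1000)
  expect_error(wham(tbl, windows = w), class = "helixscan_disconnected_histograms")
})

test_that("helical population integrates the Boltzmann weight below the boundary", {
  # flat profile on [0, 0.5]: population equals the boundary fraction
  mk_pmf <- function(R, F, n = 1000) {
    out <- tibble::tibble(bin = seq_along(R), R = R, F = F,
                          F_kBT = F / kBT(300), n_samples = n,
                          sd = NA_real_)
    structure(out, class = c("pmf_profile", class(out)),
              temperature = 300, bin_width = R[2] - R[1])
  }
  R <- seq(0.005, 0.495, by = 0.01)
  expect_equal(as.numeric(helical_population(mk_pmf(R, rep(0, length(R))),
                                             boundary = 0.15)),
               0.30, tolerance = 1e-12)
  # infinitely unfavourable above the boundary: population 1
  Fhigh <- ifelse(R < 0.15, 0, 1e6)
  expect_equal(as.numeric(helical_population(mk_pmf(R, Fhigh), boundary = 0.15)),
               1, tolerance = 1e-9)
  # deep Gaussian well at R = 0.4: quadrature oracle agreement
  kT <- kBT(300)
  Fwell <- 0.5 * kT * ((R - 0.4) / 0.02)^2
  p <- as.numeric(helical_population(mk_pmf(R, Fwell), boundary = 0.15))
  wgt <- exp(-Fwell / kT)
  oracle <- sum(wgt[R < 0.15]) / sum(wgt)   # bin centres; boundary between bins
  expect_lt(p, 0.01)
  expect_equal(p, oracle, tolerance = 1e-6)
  # complements sum to one exactly
  pmf <- mk_pmf(R, Fwell)
  p_h <- as.numeric(helical_population(pmf, boundary = 0.15))
  p_c <- 1 - p_h
  expect_equal(p_h + p_c, 1)
  # boundary-bin proportional split
  p_mid <- as.numeric(helical_population(mk_pmf(R, rep(0, length(R))),
                                         boundary = 0.155))
  expect_equal(p_mid, 0.31, tolerance = 1e-12)
})

test_that("undefined bins below the boundary trigger the widening warning", {
  R <- seq(0.005, 0.495, by = 0.01)
  F <- rep(0, length(R)); F[8] <- NA
  out <- tibble::tibble(bin = seq_along(R), R = R, F = F, F_kBT = F / kBT(300),
                        n_samples = 1000, sd = NA_real_)
  pmf <- structure(out, class = c("pmf_profile", class(out)),
                   temperature = 300, bin_width = 0.01)
  expect_warning(helical_population(pmf, boundary = 0.15), "widened")
})

test_that("quartering flags stationary data as converged", {
  params <- model_parameters(helix_bias = 2, n_residues = 8)
  w <- build_windows(8, 0, 0.5, k0 = 1000)
  ws <- run_hremd(params, w, n_steps = 20000, exchange_interval = 250, seed = 4,
                  record_every = 4)
  cq <- convergence_quarters(ws, threshold_kBT = 0.5)
  expect_true(cq$converged)
  expect_length(cq$profiles, 4)
  # deviations match a hand-coded per-bin max-abs reduction over bins
  # adequately sampled in every quarter
  Fm <- vapply(cq$profiles, function(p) ifelse(p$n_samples >= 100, p$F, NA_real_),
               numeric(nrow(cq$profiles[[1]])))
  hand <- apply(Fm[, 2:4], 1, function(v) if (anyNA(v)) NA_real_ else diff(range(v)))
  expect_equal(cq$deviations$max_dev_q234_kBT, hand / kBT(300), tolerance = 1e-12)
})

test_that("non-equilibrated first quarter deviates most", {
  params <- model_parameters(helix_bias = 4, contact_strength = 1, n_residues = 10)
  w <- build_windows(8, 0, 0.5, k0 = 1000)
  # start every replica fully extended: early samples are far from the
  # restraint targets near R = 0
  ws <- run_hremd(params, w, n_steps = 4000, exchange_interval = 250, seed = 6,
                  init = "extended", record_every = 2)
  cq <- convergence_quarters(ws, threshold_kBT = 0.5, min_count = 50)
  dev_all <- cq$deviations$max_dev_all_kBT
  dev_late <- cq$deviations$max_dev_q234_kBT
  ok <- !is.na(dev_all) & !is.na(dev_late)
  expect_gt(mean(dev_all[ok]), mean(dev_late[ok]))
})
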