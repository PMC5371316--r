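test_that("synthetic shift generation hits the packaged constants", {
  seqs <- "EAQRAELAKQ"
  # zero population, zero noise: exactly the random-coil table
  st <- generate_shift_table(seqs, p_helix = 0, noise_sd = 0)
  rc <- random_coil_shifts()
  i <- match(strsplit(seqs, "")[[1]], rc$residue_type)
  expect_equal(st$CA_shift_ppm, rc$CA_rc_ppm[i], tolerance = 1e-12)
  expect_equal(st$CB_shift_ppm, rc$CB_rc_ppm[i], tolerance = 1e-12)
  # full population: dCA - dCB = 3.5 ppm everywhere
  st1 <- generate_shift_table(seqs, p_helix = 1, noise_sd = 0)
  d <- secondary_shifts(st1)
  expect_equal(d$dCA_ppm - d$dCB_ppm, rep(3.5, 10), tolerance = 1e-12)
  expect_equal(d$dCA_ppm, rep(3.1, 10), tolerance = 1e-12)
  # p = 0.4: dCA = 1.24 ppm
  st04 <- generate_shift_table(seqs, p_helix = 0.4, noise_sd = 0)
  expect_equal(secondary_shifts(st04)$dCA_ppm, rep(0.4 * 3.1, 10),
               tolerance = 1e-12)
  expect_error(generate_shift_table("AXQ", 0.5), class = "helixscan_unknown_residue")
  expect_error(generate_shift_table(seqs, p_helix = 1.2), "0, 1")
})

test_that("glycine rows keep the Calpha term only; proline is flagged", {
  st <- generate_shift_table("AGPA", p_helix = 0.5, noise_sd = 0)
  expect_true(is.na(st$CB_shift_ppm[2]))
  d <- secondary_shifts(st)
  expect_true(is.na(d$dCB_ppm[2]))
  expect_false(is.na(d$dCA_ppm[2]))
  expect_equal(d$is_proline, c(FALSE, FALSE, TRUE, FALSE))
  prof <- ssp_profile(d, window = 1)
  expect_equal(prof$raw_ppm[2], d$dCA_ppm[2], tolerance = 1e-12)
})

test_that("SSP profile implements the shift difference with neighbour correction", {
  d <- tibble::tibble(residue_number = 1:5, residue_type = rep("A", 5),
                      dCA_ppm = c(2, 1, 0.5, 2, 1),
                      dCB_ppm = c(-0.5, 0, NA, -1, 0),
                      is_proline = FALSE)
  prof <- ssp_profile(d, window = 1)
  expect_equal(prof$raw_ppm[1], 2.5, tolerance = 1e-12)
  expect_equal(prof$raw_ppm[3], 0.5, tolerance = 1e-12)   # missing CB -> CA alone
  # window-3 smoothing matches the masked moving-average oracle
  prof3 <- ssp_profile(d, window = 3)
  expect_equal(prof3$smoothed_ppm, masked_ma_oracle(prof$raw_ppm, 3),
               tolerance = 1e-12)
  # random missing patterns
  set.seed(8)
  for (rep in 1:5) {
    n <- 20
    dd <- tibble::tibble(residue_number = 1:n, residue_type = "A",
                         dCA_ppm = rnorm(n), dCB_ppm = rnorm(n),
                         is_proline = FALSE)
    dd$dCB_ppm[sample(n, 6)] <- NA
    dd$dCA_ppm[sample(n, 2)] <- NA
    raw <- ifelse(is.na(dd$dCB_ppm), dd$dCA_ppm, dd$dCA_ppm - dd$dCB_ppm)
    p <- ssp_profile(dd, window = 3)
    expect_equal(p$smoothed_ppm, masked_ma_oracle(raw, 3), tolerance = 1e-12)
  }
  # linearity before clipping
  p1 <- ssp_profile(d, window = 3)
  d2 <- d; d2$dCA_ppm <- d$dCA_ppm * 0.4; d2$dCB_ppm <- d$dCB_ppm * 0.4
  p2 <- ssp_profile(d2, window = 3)
  expect_equal(p2$smoothed_ppm, 0.4 * p1$smoothed_ppm, tolerance = 1e-12)
  expect_error(ssp_profile(tibble::tibble(residue_number = 1:3,
                                          residue_type = "A",
                                          dCA_ppm = NA_real_,
                                          dCB_ppm = NA_real_,
                                          is_proline = FALSE)),
               class = "helixscan_empty_profile")
})

test_that("clipping is applied and reported", {
  d <- tibble::tibble(residue_number = 1:4, residue_type = "A",
                      dCA_ppm = c(6, 6, 6, 6), dCB_ppm = c(-2, -2, -2, -2),
                      is_proline = FALSE)
  expect_warning(p <- ssp_profile(d, window = 1), "clipped")
  expect_true(all(p$ssp <= 1))
  expect_true(all(p$clipped))
})

test_that("sign convention separates helix from sheet", {
  helix <- generate_shift_table("AEALKAQALE", p_helix = 0.8, noise_sd = 0)
  p_h <- ssp_profile(secondary_shifts(helix))
  expect_true(all(p_h$ssp > 0))
  # sheet-like synthetic shifts: negative dCA, positive dCB
  rc <- random_coil_shifts()
  i <- match(strsplit("AEALKAQALE", "")[[1]], rc$residue_type)
  sheet <- tibble::tibble(residue_number = 1:10,
                          residue_type = rc$residue_type[i],
                          CA_shift_ppm = rc$CA_rc_ppm[i] - 1.2,
                          CB_shift_ppm = rc$CB_rc_ppm[i] + 1.5)
  class(sheet) <- c("shift_table", class(sheet))
  p_s <- ssp_profile(secondary_shifts(sheet))
  expect_true(all(p_s$ssp < 0))
})

test_that("noise-free SSP round trip inverts the generator exactly", {
  seqs <- strrep("AELRKQMEAL", 3)   # no glycine: exact inversion holds
  p_true <- 0.4
  native <- ssp_profile(secondary_shifts(
    generate_shift_table(seqs, p_helix = p_true, noise_sd = 0)))
  reference <- ssp_profile(secondary_shifts(
    generate_shift_table(seqs, p_helix = 1, noise_sd = 0)))
  expect_equal(native$ssp, rep(p_true, 30), tolerance = 1e-12)
  h <- helicity_from_ssp(native, reference, regions = list(1:10, 11:30))
  expect_equal(h$helicity, c(0.4, 0.4), tolerance = 1e-6)
  # native equals reference -> 100%; native zero -> 0%
  h1 <- helicity_from_ssp(reference, reference, regions = list(5:25))
  expect_equal(h1$helicity, 1)
  zero <- ssp_profile(secondary_shifts(
    generate_shift_table(seqs, p_helix = 0, noise_sd = 0)))
  h0 <- helicity_from_ssp(zero, reference, regions = list(5:25))
  expect_equal(h0$helicity, 0)
  expect_error(helicity_from_ssp(native, zero, regions = list(1:10)),
               class = "helixscan_undefined_reference")
})

test_that("noisy round trip recovers the population profile within 0.02", {
  n <- 100
  seqs <- strrep("AELRKQMEAL", 10)
  p_true <- seq(0.2, 0.7, length.out = n)   # linear: centred smoothing is unbiased
  st <- generate_shift_table(seqs, p_helix = p_true, noise_sd = 0.1, seed = 99)
  ref <- generate_shift_table(seqs, p_helix = 1, noise_sd = 0)
  native <- ssp_profile(secondary_shifts(st))
  reference <- ssp_profile(secondary_shifts(ref))
  # per-residue error is bounded by the propagated noise level
  # (sd ~ 0.1*sqrt(2)/sqrt(3)/3.5 ~ 0.023 at the interior)
  err <- abs(native$ssp - p_true)
  expect_lt(mean(err), 0.03)
  h <- helicity_from_ssp(native, reference, regions = list(10:40, 60:90))
  truth <- c(mean(p_true[10:40]), mean(p_true[60:90]))
  expect_equal(h$helicity, truth, tolerance = 0.02)
})

test_that("shift tables round-trip through CSV", {
  st <- generate_shift_table("AGELK", p_helix = 0.3, noise_sd = 0.05, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_shift_table(st, f)
  back <- read_shift_table(f)
  expect_equal(as.data.frame(back), as.data.frame(st), tolerance = 1e-9)
})
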