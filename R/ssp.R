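## Secondary chemical shifts, SSP profiles and helicity estimation, plus
## the synthetic shift-table generator used to test the whole stage.

## Full-helix secondary-shift offsets (ppm): documented package constants.
SHIFT_OFFSET_CA <- 3.1
SHIFT_OFFSET_CB <- -0.4
SSP_NORM <- SHIFT_OFFSET_CA - SHIFT_OFFSET_CB   # 3.5 ppm

#' Random-coil Calpha/Cbeta chemical-shift reference
#'
#' The packaged random-coil reference table (ppm), in the style of the
#' Wishart random-coil sets; glycine has no Cbeta. Shipped as
#' `extdata/random_coil_ca_cb.csv`.
#'
#' @return A tibble with columns `residue_type`, `CA_rc_ppm`, `CB_rc_ppm`.
#' @export
random_coil_shifts <- function() {
  path <- system.file("extdata", "random_coil_ca_cb.csv", package = "helixscan")
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Generate a synthetic chemical-shift table
#'
#' The desk-scale stand-in for assigned experimental Calpha/Cbeta shifts:
#' for residue `j` with helical population `p_j`,
#' `dCA(j) = rc_CA(aa_j) + p_j * 3.1 ppm + noise` and
#' `dCB(j) = rc_CB(aa_j) - p_j * 0.4 ppm + noise` (glycine: no Cbeta).
#' With zero noise the generator is exactly invertible by the SSP stage.
#'
#' @param sequence One-letter amino-acid string.
#' @param p_helix Per-residue helical population in [0, 1] (recycled).
#' @param noise_sd Gaussian noise SD in ppm (>= 0).
#' @param seed Seed for the noise.
#' @param first_residue Number of the first residue.
#' @return A `shift_table` tibble: `residue_number`, `residue_type`,
#'   `CA_shift_ppm`, `CB_shift_ppm`.
#' @export
generate_shift_table <- function(sequence, p_helix, noise_sd = 0, seed = 1,
                                 first_residue = 1) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  n <- length(aa)
  p_helix <- rep_len(p_helix, n)
  if (any(p_helix < 0 | p_helix > 1)) abort("`p_helix` must lie in [0, 1].")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  rc <- random_coil_shifts()
  miss <- setdiff(aa, rc$residue_type)
  if (length(miss)) {
    abort(paste0("No random-coil reference for residue type(s): ",
                 paste(unique(miss), collapse = ", ")),
          class = "helixscan_unknown_residue")
  }
  i <- match(aa, rc$residue_type)
  set.seed(seed)
  ca <- rc$CA_rc_ppm[i] + p_helix * SHIFT_OFFSET_CA +
    (if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0)
  cb <- rc$CB_rc_ppm[i] + p_helix * SHIFT_OFFSET_CB +
    (if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0)
  cb[aa == "G"] <- NA_real_
  out <- tibble(residue_number = seq.int(first_residue, length.out = n),
                residue_type = aa, CA_shift_ppm = ca, CB_shift_ppm = cb)
  class(out) <- c("shift_table", class(out))
  out
}

#' Read / write shift tables as CSV
#'
#' Columns: `residue_number`, `residue_type`, `CA_shift_ppm`,
#' `CB_shift_ppm`.
#'
#' @param path CSV path.
#' @return For `read_shift_table()`, a `shift_table` tibble.
#' @export
read_shift_table <- function(path) {
  out <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("residue_number", "residue_type", "CA_shift_ppm", "CB_shift_ppm")
  if (!all(need %in% names(out))) {
    abort(paste0("Shift CSV must have columns: ", paste(need, collapse = ", ")))
  }
  if (is.unsorted(out$residue_number, strictly = TRUE)) {
    abort("Residue numbers must be strictly increasing.")
  }
  class(out) <- c("shift_table", class(out))
  out
}

#' @rdname read_shift_table
#' @param shifts A `shift_table`.
#' @export
write_shift_table <- function(shifts, path) {
  write.csv(as.data.frame(shifts), path, row.names = FALSE)
  invisible(path)
}

#' Secondary chemical shifts
#'
#' Observed minus random-coil reference per nucleus:
#' `dDelta = delta_obs - delta_rc`. Missing observations propagate as
#' missing; glycine keeps the Calpha term only. Proline rows are flagged
#' since amide-detected experiments often miss them.
#'
#' @param shifts A `shift_table`.
#' @param rc_table Random-coil reference (default: packaged table).
#' @return Tibble: `residue_number`, `residue_type`, `dCA_ppm`, `dCB_ppm`,
#'   `is_proline`.
#' @export
secondary_shifts <- function(shifts, rc_table = random_coil_shifts()) {
  miss <- setdiff(shifts$residue_type, rc_table$residue_type)
  if (length(miss)) {
    pos <- shifts$residue_number[shifts$residue_type %in% miss]
    abort(sprintf("Unknown residue type(s) %s at position(s) %s.",
                  paste(unique(miss), collapse = ", "),
                  paste(pos, collapse = ", ")),
          class = "helixscan_unknown_residue")
  }
  i <- match(shifts$residue_type, rc_table$residue_type)
  tibble(residue_number = shifts$residue_number,
         residue_type = shifts$residue_type,
         dCA_ppm = shifts$CA_shift_ppm - rc_table$CA_rc_ppm[i],
         dCB_ppm = shifts$CB_shift_ppm - rc_table$CB_rc_ppm[i],
         is_proline = shifts$residue_type == "P")
}

#' Secondary-structure propensity profile
#'
#' Raw per-residue SSP is `dCA - dCB` (helix: consecutive positive values;
#' sheet: negative); a residue missing its Cbeta term (glycine) keeps the
#' Calpha term alone. A neighbour correction is applied as a centred moving
#' average over `window` residues that skips missing entries, and the
#' smoothed value is normalised by the packaged full-helix difference of
#' 3.5 ppm and clipped to [-1, 1] (clipping is reported via the `clipped`
#' column).
#'
#' @param deltas Output of [secondary_shifts()].
#' @param window Neighbour-correction window (odd, default 3).
#' @param norm_ppm Full-helix normalisation constant (ppm).
#' @return An `ssp_profile` tibble: `residue_number`, `raw_ppm`,
#'   `smoothed_ppm`, `ssp`, `clipped`.
#' @export
ssp_profile <- function(deltas, window = 3, norm_ppm = SSP_NORM) {
  raw <- ifelse(is.na(deltas$dCB_ppm), deltas$dCA_ppm,
                deltas$dCA_ppm - deltas$dCB_ppm)
  if (all(is.na(raw))) {
    abort("All residues are missing: empty profile.",
          class = "helixscan_empty_profile")
  }
  n <- length(raw)
  half <- (window - 1) %/% 2
  smoothed <- vapply(seq_len(n), function(j) {
    idx <- max(1, j - half):min(n, j + half)
    v <- raw[idx]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  ssp <- smoothed / norm_ppm
  clipped <- !is.na(ssp) & abs(ssp) > 1 + 1e-9   # tolerance for exact p = 1
  if (any(clipped)) {
    warn(sprintf("%d SSP value(s) clipped to [-1, 1].", sum(clipped)))
  }
  ssp <- pmin(pmax(ssp, -1), 1)
  out <- tibble(residue_number = deltas$residue_number,
                raw_ppm = raw, smoothed_ppm = smoothed,
                ssp = ssp, clipped = clipped)
  class(out) <- c("ssp_profile", class(out))
  out
}

#' Per-region helicity from SSP against a helix-stabilised reference
#'
#' Estimates fractional helicity as the ratio of mean SSP in the native
#' state to mean SSP in a near-fully-helical reference state (the role the
#' TFE-stabilised sample plays experimentally), per residue region, clipped
#' to [0, 1].
#'
#' @param native,reference `ssp_profile` tibbles on overlapping residue
#'   numbering; the reference must average positive over every region.
#' @param regions A list of integer vectors (residue-number ranges), or a
#'   two-column data frame with `from`/`to`.
#' @return Tibble: `region`, `from`, `to`, `native_ssp`, `reference_ssp`,
#'   `helicity`.
#' @export
helicity_from_ssp <- function(native, reference, regions) {
  if (is.data.frame(regions)) {
    regions <- purrr::map2(regions$from, regions$to, seq)
  }
  purrr::map_dfr(seq_along(regions), function(k) {
    rr <- regions[[k]]
    nat <- native$ssp[native$residue_number %in% rr]
    ref <- reference$ssp[reference$residue_number %in% rr]
    if (!length(nat) || !length(ref)) {
      abort(sprintf("Region %d lies outside the profiles.", k),
            class = "helixscan_shape_error")
    }
    mref <- mean(ref, na.rm = TRUE)
    if (!is.finite(mref) || mref <= 0) {
      abort(sprintf("Reference SSP is not positive over region %d.", k),
            class = "helixscan_undefined_reference")
    }
    h <- mean(nat, na.rm = TRUE) / mref
    tibble(region = k, from = min(rr), to = max(rr),
           native_ssp = mean(nat, na.rm = TRUE), reference_ssp = mref,
           helicity = pmin(pmax(h, 0), 1))
  })
}
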