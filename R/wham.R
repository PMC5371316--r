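## WHAM reconstruction of the free-energy profile F(R), helical-state
## population, and the convergence-quartering check.

as_sample_tbl <- function(samples) {
  if (inherits(samples, "windowed_samples")) samples$samples else as_tibble(samples)
}

#' Weighted histogram analysis of umbrella windows
#'
#' Combines the biased R histograms of all umbrella windows into one
#' unbiased free-energy profile F(R) by iterating the standard
#' self-consistent WHAM equations until the maximum relative change of the
#' per-window free-energy constants falls below `tol`. The profile is
#' reported on a regular grid spanning `[r_min - 0.05, r_max + 0.1]` nm
#' around the window range; bins with zero total counts are left undefined
#' (`NA`), never interpolated. With a single unbiased window the estimator
#' reduces exactly to direct Boltzmann inversion of the histogram.
#'
#' Per-bin uncertainty comes from a Bayesian bootstrap over each window's
#' sample weights (`n_boot` replicates of Dirichlet-weighted WHAM).
#'
#' @param samples A `windowed_samples` object from [run_hremd()] or a tibble
#'   with columns `window` and `R`.
#' @param windows Window tibble ([build_windows()]); taken from `samples`
#'   when omitted.
#' @param temperature Kelvin.
#' @param bin_width Histogram bin width (nm).
#' @param tol Convergence tolerance on window free energies (relative).
#' @param max_iter Iteration cap.
#' @param n_boot Bayesian-bootstrap replicates for per-bin SD (0 = none).
#' @param boot_block Block length (in retained frames) for the bootstrap:
#'   consecutive samples within a window share one Dirichlet weight, so
#'   autocorrelated Monte Carlo output is not treated as independent.
#' @param range Optional c(min, max) grid override (nm).
#' @return A `pmf_profile` tibble: columns `bin`, `R` (bin centre, nm), `F`
#'   (kJ/mol, minimum shifted to 0), `F_kBT`, `n_samples`, `sd` (kJ/mol).
#'   Attributes carry the per-window bin counts, window constants,
#'   temperature and iteration diagnostics.
#' @export
wham <- function(samples, windows = NULL, temperature = 300, bin_width = 0.01,
                 tol = 1e-7, max_iter = 100000, n_boot = 0, boot_block = 20,
                 range = NULL) {
  if (inherits(samples, "windowed_samples") && is.null(windows)) {
    windows <- samples$windows
    temperature <- samples$params$temperature %||% temperature
  }
  tbl <- as_sample_tbl(samples)
  if (is.null(windows)) abort("`windows` must be supplied.", class = "helixscan_invalid_config")
  W <- nrow(windows)
  kT <- kBT(temperature)
  rng <- range %||% c(min(windows$R0) - 0.05, max(windows$R0) + 0.1)
  edges <- seq(rng[1], rng[2] + bin_width, by = bin_width)
  centers <- edges[-length(edges)] + bin_width / 2
  B <- length(centers)

  ## per-window histograms
  Hw <- matrix(0, B, W)
  idx <- findInterval(tbl$R, edges, rightmost.closed = TRUE)
  ok <- idx >= 1 & idx <= B
  for (w in seq_len(W)) {
    sel <- ok & tbl$window == windows$window[w]
    Hw[, w] <- tabulate(idx[sel], nbins = B)
  }
  Nw <- colSums(Hw)
  if (W >= 2) check_window_overlap(Hw, windows)

  fit <- wham_solve(Hw, Nw, windows, centers, kT, tol, max_iter)

  sd_kJ <- rep(NA_real_, B)
  boot_F <- NULL
  if (n_boot > 0) {
    tbl$bin <- idx
    boot_F <- matrix(NA_real_, B, n_boot)
    for (b in seq_len(n_boot)) {
      Hb <- matrix(0, B, W)
      for (w in seq_len(W)) {
        sel <- which(ok & tbl$window == windows$window[w])
        if (!length(sel)) next
        blk <- (seq_along(sel) - 1) %/% max(1, boot_block) + 1
        wb <- stats::rexp(max(blk))
        wt <- wb[blk]
        wt <- wt / sum(wt) * length(sel)        # Dirichlet over blocks, scaled to N_w
        Hb[, w] <- vapply(seq_len(B), function(k)
          sum(wt[tbl$bin[sel] == k]), numeric(1))
      }
      fb <- wham_solve(Hb, colSums(Hb), windows, centers, kT, tol, max_iter)
      boot_F[, b] <- fb$F
    }
    sd_kJ <- apply(boot_F, 1, sd, na.rm = TRUE)
    sd_kJ[is.na(fit$F)] <- NA_real_
  }

  out <- tibble(bin = seq_len(B), R = centers, F = fit$F, F_kBT = fit$F / kT,
                n_samples = rowSums(Hw), sd = sd_kJ)
  structure(out,
            class = c("pmf_profile", class(out)),
            counts = Hw, windows = windows, temperature = temperature,
            bin_width = bin_width, f_window = fit$f, iterations = fit$iter,
            converged = fit$converged, boot_F = boot_F)
}

## self-consistent WHAM core; histograms Hw (bins x windows), counts Nw
wham_solve <- function(Hw, Nw, windows, centers, kT, tol, max_iter) {
  B <- nrow(Hw); W <- ncol(Hw)
  M <- rowSums(Hw)
  ## bias Boltzmann factors per (bin, window)
  Cwb <- exp(-outer(centers, seq_len(W), function(r, w)
    restraint_energy(pmax(r, 0), windows$R0[w], windows$k0[w])) / kT)
  f <- rep(0, W)                       # exp(beta * f_w) handled in log space
  P <- rep(NA_real_, B)
  converged <- FALSE
  iter <- 0L
  live <- Nw > 0
  for (iter in seq_len(max_iter)) {
    denom <- as.numeric(Cwb[, live, drop = FALSE] %*% (Nw[live] * exp(f[live] / kT)))
    P <- ifelse(M > 0 & denom > 0, M / denom, 0)
    fz <- -kT * log(pmax(colSums(P * Cwb), 1e-300))
    fz <- fz - fz[which(live)[1]]
    drel <- max(abs(fz[live] - f[live]) / pmax(abs(fz[live]), 1))
    f <- fz
    if (drel < tol) { converged <- TRUE; break }
  }
  if (!converged && max_iter > 1) {
    abort(sprintf("WHAM did not converge in %d iterations (residual %.3g).",
                  max_iter, drel), class = "helixscan_wham_nonconvergence")
  }
  Fr <- ifelse(M > 0, -kT * log(pmax(P, 1e-300)), NA_real_)
  Fr <- Fr - min(Fr, na.rm = TRUE)
  list(F = Fr, f = f, iter = iter, converged = converged)
}

## disconnected-histogram detection: neighbouring (by R0) windows must share
## occupied bins, transitively covering all windows
check_window_overlap <- function(Hw, windows) {
  occ <- colSums(Hw) > 0
  Hw <- Hw[, occ, drop = FALSE]
  windows <- windows[occ, , drop = FALSE]
  W <- ncol(Hw)
  if (W < 2) return(invisible(TRUE))
  ord <- order(windows$R0)
  for (k in seq_len(W - 1)) {
    a <- ord[k]; b <- ord[k + 1]
    reach <- FALSE
    for (j in seq(k + 1, W)) {
      if (any(Hw[, a] > 0 & Hw[, ord[j]] > 0)) { reach <- TRUE; break }
    }
    if (!reach) {
      abort(sprintf(
        "Window histograms are disconnected between R0 = %.3f and R0 = %.3f nm.",
        windows$R0[a], windows$R0[b]),
        class = "helixscan_disconnected_histograms")
    }
  }
  invisible(TRUE)
}

#' @export
print.pmf_profile <- function(x, ...) {
  def <- !is.na(x$F)
  cat(sprintf("<pmf_profile> %d bins (%d defined), T = %g K, WHAM iterations = %d\n",
              nrow(x), sum(def), attr(x, "temperature"), attr(x, "iterations")))
  NextMethod()
}

#' @rdname wham
#' @param x A `pmf_profile`.
#' @param ... Unused.
#' @export
glance.pmf_profile <- function(x, ...) {
  tibble(n_bins = nrow(x), n_defined = sum(!is.na(x$F)),
         iterations = attr(x, "iterations"),
         converged = attr(x, "converged"),
         temperature = attr(x, "temperature"),
         min_R = x$R[which.min(x$F)])
}

#' Population of the helical state from a PMF
#'
#' Boltzmann-weights the profile and integrates below the helical boundary:
#' `p_helix = sum_(R < boundary) exp(-F/kT) / sum_all exp(-F/kT)`, splitting
#' the bin containing the boundary proportionally. The default boundary
#' R = 0.15 nm is where geometric helicity crosses 50%.
#'
#' @param pmf A `pmf_profile` from [wham()].
#' @param temperature Kelvin (default: the profile's).
#' @param boundary Upper dRMSD bound of the helical state (nm).
#' @return The helical population in [0, 1]. If the profile carries
#'   bootstrap replicates, attribute `"sd"` holds the bootstrap SD; if bins
#'   below the boundary are undefined, a warning is issued and attribute
#'   `"widened"` is set.
#' @export
helical_population <- function(pmf, temperature = NULL, boundary = 0.15) {
  temperature <- temperature %||% attr(pmf, "temperature")
  kT <- kBT(temperature)
  bw <- attr(pmf, "bin_width") %||% diff(pmf$R[1:2])
  if (boundary <= min(pmf$R) - bw / 2 || boundary >= max(pmf$R) + bw / 2) {
    abort("`boundary` must lie inside the profile grid.",
          class = "helixscan_invalid_config")
  }
  pop_of <- function(Fvals) {
    w <- ifelse(is.na(Fvals), 0, exp(-Fvals / kT))
    lo <- pmf$R - bw / 2
    frac_below <- pmin(pmax((boundary - lo) / bw, 0), 1)
    sum(w * frac_below) / sum(w)
  }
  p <- pop_of(pmf$F)
  ## interior undefined bins below the boundary degrade the estimate
  def <- which(!is.na(pmf$F))
  interior_na <- which(is.na(pmf$F) & (pmf$R - bw / 2) < boundary)
  interior_na <- interior_na[interior_na > min(def) & interior_na < max(def)]
  widened <- length(interior_na) > 0
  if (widened) {
    warn("Undefined bins below the helical boundary; population uncertainty widened.")
  }
  boot <- attr(pmf, "boot_F")
  s <- if (!is.null(boot)) sd(apply(boot, 2, pop_of), na.rm = TRUE) else NA_real_
  if (widened && !is.na(s)) s <- 2 * s
  structure(p, sd = s, widened = widened)
}

#' Convergence check by data quartering
#'
#' Splits every window's samples into four equal contiguous blocks, runs
#' WHAM on each quarter, and reports the per-bin maximum absolute deviation
#' between the quarter profiles after the first (profiles from
#' non-equilibrated early data shift; later quarters should not). The run is
#' flagged converged when that deviation stays below `threshold_kBT` over
#' bins defined in all compared quarters.
#'
#' @param samples A `windowed_samples` object.
#' @param windows Window tibble; defaults to the object's.
#' @param temperature Kelvin.
#' @param threshold_kBT Convergence threshold (kBT).
#' @param min_count A bin counts as defined in a quarter only with at least
#'   this many samples; the shot noise on a bin free energy is ~1/sqrt(n)
#'   kBT, so sparse bins cannot attest drift at sub-kBT thresholds.
#' @param ... Passed to [wham()].
#' @return A `pmf_convergence` object: `$profiles` (list of 4
#'   `pmf_profile`s), `$deviations` (tibble with per-bin max |dF| over
#'   quarters 2-4 and over all quarters), `$converged`.
#' @export
convergence_quarters <- function(samples, windows = NULL, temperature = 300,
                                 threshold_kBT = 0.5, min_count = 100, ...) {
  stopifnot(inherits(samples, "windowed_samples"))
  windows <- windows %||% samples$windows
  temperature <- samples$params$temperature %||% temperature
  tbl <- samples$samples
  n_frames <- length(unique(tbl$step))
  if (n_frames < 4) abort("Need at least 4 frames per window.", class = "helixscan_invalid_config")
  qtr <- function(step) pmin(4L, 1L + ((match(step, sort(unique(tbl$step))) - 1L) * 4L) %/% n_frames)
  tbl$quarter <- qtr(tbl$step)
  profiles <- lapply(1:4, function(q) {
    tryCatch(
      wham(tbl[tbl$quarter == q, c("window", "R")], windows = windows,
           temperature = temperature, ...),
      error = function(e) NULL)   # quarter undefined (e.g. empty window)
  })
  ok_q <- which(!vapply(profiles, is.null, logical(1)))
  if (!length(ok_q)) abort("No quarter produced a defined profile.")
  B <- nrow(profiles[[ok_q[1]]])
  kT <- kBT(temperature)
  Fm <- vapply(profiles, function(p) if (is.null(p)) rep(NA_real_, B) else {
    ifelse(p$n_samples >= min_count, p$F, NA_real_)
  }, numeric(B))
  max_dev <- function(cols) {
    sub <- Fm[, cols, drop = FALSE]
    apply(sub, 1, function(v) if (anyNA(v)) NA_real_ else diff(range(v)))
  }
  dev <- tibble(bin = profiles[[ok_q[1]]]$bin, R = profiles[[ok_q[1]]]$R,
                max_dev_q234_kBT = max_dev(2:4) / kT,
                max_dev_all_kBT = max_dev(1:4) / kT)
  converged <- all(dev$max_dev_q234_kBT < threshold_kBT, na.rm = TRUE)
  structure(list(profiles = profiles, deviations = dev, converged = converged,
                 threshold_kBT = threshold_kBT, temperature = temperature),
            class = "pmf_convergence")
}

#' @export
print.pmf_convergence <- function(x, ...) {
  cat(sprintf("<pmf_convergence> converged = %s (max |dF| quarters 2-4 = %.3f kBT, threshold %.2f)\n",
              x$converged, max(x$deviations$max_dev_q234_kBT, na.rm = TRUE),
              x$threshold_kBT))
  invisible(x)
}

#' @rdname convergence_quarters
#' @param x A `pmf_convergence` object.
#' @param ... Unused.
#' @export
tidy.pmf_convergence <- function(x, ...) {
  purrr::map_dfr(seq_along(x$profiles), function(q) {
    p <- x$profiles[[q]]
    if (is.null(p)) return(tibble())
    tibble(quarter = q, R = p$R, F = p$F, F_kBT = p$F_kBT)
  })
}

#' Write a PMF profile as TSV
#'
#' Columns: R (nm), F (kJ/mol), sd, n_samples.
#'
#' @param pmf A `pmf_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pmf_tsv <- function(pmf, path) {
  utils::write.table(as.data.frame(pmf[, c("R", "F", "sd", "n_samples")]),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
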