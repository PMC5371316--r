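## The dRMSD reaction coordinate, its gradient, and the harmonic restraint.

#' Helical dRMSD reference
#'
#' Builds the distance-RMSD reference for the helical state: all
#' Calpha(j)-Calpha(j+3) pairs with a common reference distance (0.5 nm for
#' the fully helical peptide), so `R = 0` represents the helix and growing
#' `R` measures unfolding.
#'
#' @param n_residues Chain length (>= 4).
#' @param d0 Reference distance in nm (recycled over pairs).
#' @return A `drmsd_reference`: list with `pair_list` (N x 2 integer matrix
#'   of (j, j+3) pairs, N = n_residues - 3) and `d0` (length-N numeric).
#' @export
helical_reference <- function(n_residues, d0 = 0.5) {
  if (!is.numeric(n_residues) || n_residues < 4) {
    abort("`n_residues` must be at least 4 (no i,i+3 pair exists below that).",
          class = "helixscan_invalid_length")
  }
  if (any(d0 <= 0)) abort("`d0` must be positive.")
  n_residues <- as.integer(n_residues)
  N <- n_residues - 3L
  pairs <- cbind(seq_len(N), seq_len(N) + 3L)
  structure(list(pair_list = pairs, d0 = rep_len(as.numeric(d0), N)),
            class = "drmsd_reference")
}

#' @export
print.drmsd_reference <- function(x, ...) {
  cat(sprintf("<drmsd_reference> %d pairs, d0 = %s nm\n",
              nrow(x$pair_list), paste(unique(x$d0), collapse = ", ")))
  invisible(x)
}

check_ref <- function(conf, ref) {
  X <- coords_of(conf)
  if (max(ref$pair_list) > nrow(X)) {
    abort("Reference pair indices exceed the chain length.",
          class = "helixscan_shape_error")
  }
  X
}

#' Distance RMSD against a reference
#'
#' `R = sqrt( (1/N) * sum_i (d_i - d0_i)^2 )` over the reference pair list:
#' zero exactly when every pair distance matches its reference.
#'
#' @param conf A [chain_conformation()] (or list of them, giving a vector).
#' @param ref A [helical_reference()].
#' @return dRMSD in nm (>= 0).
#' @export
drmsd <- function(conf, ref) {
  if (is.list(conf) && !inherits(conf, "chain_conformation")) {
    return(vapply(conf, drmsd, numeric(1), ref = ref))
  }
  X <- check_ref(conf, ref)
  .drmsd_cpp(X, ref$pair_list - 1L, ref$d0)
}

#' Analytic gradient of the dRMSD
#'
#' Per-residue gradient dR/dx. The square root is singular at `R = 0`; there
#' the well-defined quantity is the gradient of `R^2` (the restraint force
#' `k0 (R - R0) dR/dx` stays finite in the limit), exposed via
#' `squared = TRUE` as the documented fallback.
#'
#' @param conf A [chain_conformation()].
#' @param ref A [helical_reference()].
#' @param squared If `TRUE`, return the gradient of `R^2` instead (finite
#'   everywhere).
#' @return An n x 3 matrix (nm^-1 units for `R`); residues in no pair get
#'   zero rows.
#' @export
drmsd_gradient <- function(conf, ref, squared = FALSE) {
  X <- check_ref(conf, ref)
  n <- nrow(X)
  N <- nrow(ref$pair_list)
  G <- matrix(0, n, 3)
  R <- .drmsd_cpp(X, ref$pair_list - 1L, ref$d0)
  for (k in seq_len(N)) {
    i <- ref$pair_list[k, 1]; j <- ref$pair_list[k, 2]
    v <- X[i, ] - X[j, ]
    d <- sqrt(sum(v^2))
    w <- (2 / N) * (d - ref$d0[k]) * v / d   # gradient of R^2 contribution
    G[i, ] <- G[i, ] + w
    G[j, ] <- G[j, ] - w
  }
  if (squared) return(G)
  if (R < 1e-9) {
    abort("dRMSD gradient is singular at R = 0; use `squared = TRUE`.",
          class = "helixscan_singular_gradient")
  }
  G / (2 * R)
}

#' Harmonic dRMSD restraint energy
#'
#' The umbrella bias `V = 1/2 * k0 * (R - R0)^2` confining sampling around a
#' target dRMSD `R0`.
#'
#' @param R dRMSD value(s), nm (>= 0).
#' @param R0 Restraint centre, nm.
#' @param k0 Force constant, kJ mol^-1 nm^-2 (> 0).
#' @return Energy in kJ/mol (vectorised over `R`).
#' @export
restraint_energy <- function(R, R0, k0 = 1000) {
  if (any(R < 0)) abort("`R` must be >= 0.")
  if (any(R0 < 0)) abort("`R0` must be >= 0.")
  if (any(k0 <= 0)) abort("`k0` must be > 0.")
  0.5 * k0 * (R - R0)^2
}
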