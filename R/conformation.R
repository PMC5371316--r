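## Chain conformations: ordered Calpha coordinates (nm) of one peptide
## segment, stored as an n x 3 matrix with a fixed virtual bond length.

CA_BOND_NM <- 0.38      # virtual Calpha-Calpha bond length (nm)
THETA0_DEG <- 91        # reference pseudo-bond angle
PHI_HELIX_DEG <- 50     # helical pseudo-dihedral minimum
PHI_EXT_DEG <- -170     # extended pseudo-dihedral minimum

#' Create a chain conformation
#'
#' A `chain_conformation` holds the ordered Calpha trace of one peptide
#' segment as an n x 3 coordinate matrix in nanometres. Consecutive residues
#' must sit at the fixed virtual bond length of 0.38 nm (to within 1e-9 nm)
#' and the chain must have at least 4 residues, the minimum needed to define
#' a pseudo-dihedral and an i,i+3 distance.
#'
#' @param coords Numeric n x 3 matrix of Calpha positions (nm).
#' @param segment_id Text label for the segment (default `"segment"`).
#' @param tolerance Permitted deviation of virtual bond lengths (nm);
#'   the default is the exact-geometry contract, loosened only when
#'   re-reading rounded coordinates from PDB files.
#' @return An object of class `chain_conformation`.
#' @export
chain_conformation <- function(coords, segment_id = "segment",
                               tolerance = 1e-9) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3) {
    abort("`coords` must be a numeric n x 3 matrix.", class = "helixscan_shape_error")
  }
  if (nrow(coords) < 4) {
    abort("A chain conformation needs at least 4 residues.",
          class = "helixscan_invalid_length")
  }
  b <- sqrt(rowSums((coords[-1, , drop = FALSE] - coords[-nrow(coords), , drop = FALSE])^2))
  if (any(abs(b - CA_BOND_NM) > tolerance)) {
    abort(sprintf("Virtual bond lengths must equal %.2f nm (max deviation %.3g nm).",
                  CA_BOND_NM, max(abs(b - CA_BOND_NM))),
          class = "helixscan_bond_error")
  }
  structure(list(coords = unname(coords), segment_id = segment_id),
            class = "chain_conformation")
}

#' @export
print.chain_conformation <- function(x, ...) {
  cat(sprintf("<chain_conformation> %s: %d residues, Rg = %.3f nm\n",
              x$segment_id, nrow(x$coords), radius_of_gyration(x)))
  invisible(x)
}

#' @export
length.chain_conformation <- function(x) nrow(x$coords)

#' @rdname chain_conformation
#' @param x A `chain_conformation`.
#' @param ... Unused.
#' @export
as_tibble.chain_conformation <- function(x, ...) {
  X <- x$coords
  tibble(residue = seq_len(nrow(X)), x = X[, 1], y = X[, 2], z = X[, 3])
}

coords_of <- function(conf) {
  if (inherits(conf, "chain_conformation")) conf$coords else as.matrix(conf)
}

## Build a chain from internal coordinates (fixed bond length, per-residue
## pseudo-bond angles theta and pseudo-dihedrals phi), standard NeRF chain
## extension. theta: length n-2, phi: length n-3, radians.
chain_from_internal <- function(theta, phi, bond = CA_BOND_NM,
                                segment_id = "segment") {
  n <- length(theta) + 2
  stopifnot(length(phi) == n - 3)
  X <- matrix(0, n, 3)
  X[2, ] <- c(bond, 0, 0)
  X[3, ] <- X[2, ] + bond * c(cos(pi - theta[1]), sin(pi - theta[1]), 0)
  for (i in seq(4, n)) {
    bc <- X[i - 1, ] - X[i - 2, ]; bc <- bc / sqrt(sum(bc^2))
    ab <- X[i - 2, ] - X[i - 3, ]
    nn <- c(ab[2] * bc[3] - ab[3] * bc[2],
            ab[3] * bc[1] - ab[1] * bc[3],
            ab[1] * bc[2] - ab[2] * bc[1])
    nn <- nn / sqrt(sum(nn^2))
    m <- c(nn[2] * bc[3] - nn[3] * bc[2],
           nn[3] * bc[1] - nn[1] * bc[3],
           nn[1] * bc[2] - nn[2] * bc[1])
    th <- theta[i - 2]; ph <- phi[i - 3]
    d2 <- bond * c(-cos(th), cos(ph) * sin(th), sin(ph) * sin(th))
    X[i, ] <- X[i - 1, ] + d2[1] * bc + d2[2] * m + d2[3] * nn
  }
  chain_conformation(X, segment_id)
}

#' Build an ideal helical Calpha trace
#'
#' Constructs a peptide segment in the idealised helical conformation used as
#' the dRMSD reference state: fixed 0.38 nm virtual bonds, 91 degree
#' pseudo-bond angles and +50 degree pseudo-dihedrals. This geometry puts
#' every Calpha(j)-Calpha(j+3) distance at 0.508 nm, within 0.01 nm of the
#' 0.5 nm helical reference distance, so its dRMSD against the helical
#' reference is below 0.01 nm ("R = 0" is the fully helical state).
#'
#' @param n_residues Number of residues (at least 4).
#' @param segment_id Text label.
#' @return A [chain_conformation()].
#' @examples
#' helix <- build_ideal_helix(10)
#' drmsd(helix, helical_reference(10))   # < 0.01 nm
#' @export
build_ideal_helix <- function(n_residues, segment_id = "ideal_helix") {
  if (!is.numeric(n_residues) || n_residues < 4) {
    abort("`n_residues` must be at least 4.", class = "helixscan_invalid_length")
  }
  n_residues <- as.integer(n_residues)
  chain_from_internal(theta = rep(THETA0_DEG * pi / 180, n_residues - 2),
                      phi = rep(PHI_HELIX_DEG * pi / 180, n_residues - 3),
                      segment_id = segment_id)
}

#' Build a fully extended Calpha trace
#'
#' All pseudo-dihedrals at the extended minimum (-170 degrees), bond angles
#' at the 91 degree reference.
#'
#' @inheritParams build_ideal_helix
#' @return A [chain_conformation()].
#' @export
build_extended_chain <- function(n_residues, segment_id = "extended") {
  if (!is.numeric(n_residues) || n_residues < 4) {
    abort("`n_residues` must be at least 4.", class = "helixscan_invalid_length")
  }
  n_residues <- as.integer(n_residues)
  chain_from_internal(theta = rep(THETA0_DEG * pi / 180, n_residues - 2),
                      phi = rep(PHI_EXT_DEG * pi / 180, n_residues - 3),
                      segment_id = segment_id)
}

#' Pseudo-dihedral and pseudo-bond angles of a conformation
#'
#' @param conf A [chain_conformation()] or n x 3 matrix.
#' @return For `pseudo_dihedrals()`, the n-3 Calpha pseudo-dihedrals
#'   (radians); dihedral `d` spans residues `d..d+3`. For
#'   `pseudo_angles()`, the n-2 interior pseudo-bond angles (radians).
#' @export
pseudo_dihedrals <- function(conf) as.numeric(.dihedrals_cpp(coords_of(conf)))

#' @rdname pseudo_dihedrals
#' @export
pseudo_angles <- function(conf) as.numeric(.bond_angles_cpp(coords_of(conf)))

## ---------------------------------------------------------------------------
## I/O: Calpha-only PDB (one MODEL per frame) and plain XYZ

#' Write conformations as a Calpha-only PDB file
#'
#' Writes one MODEL per frame with a single CA atom per residue, coordinates
#' converted from nm to Angstrom. Multi-model output is written directly
#' (one fixed-width ATOM record per residue); reading goes through
#' [bio3d::read.pdb()].
#'
#' @param confs A [chain_conformation()] or list of them.
#' @param path Output file path.
#' @param sequence Optional one-letter sequence for residue names.
#' @return `path`, invisibly.
#' @export
write_ca_pdb <- function(confs, path, sequence = NULL) {
  if (inherits(confs, "chain_conformation")) confs <- list(confs)
  aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(confs)) {
    X <- coords_of(confs[[m]]) * 10  # nm -> Angstrom
    res <- if (is.null(sequence)) rep("GLY", nrow(X)) else
      aa3[strsplit(toupper(sequence), "")[[1]][seq_len(nrow(X))]]
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(sprintf(
      "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(nrow(X)), res, seq_len(nrow(X)), X[, 1], X[, 2], X[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read Calpha conformations from a PDB file
#'
#' Parses with [bio3d::read.pdb()], extracts CA atoms per model and converts
#' Angstrom to nm.
#'
#' @param path PDB file path.
#' @param segment_id Label applied to all frames.
#' @return A list of [chain_conformation()] objects, one per MODEL.
#' @export
read_ca_pdb <- function(path, segment_id = "pdb") {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  ca <- bio3d::atom.select(pdb, elety = "CA")
  xyz <- pdb$xyz[, ca$xyz, drop = FALSE]
  lapply(seq_len(nrow(xyz)), function(m) {
    X <- matrix(xyz[m, ], ncol = 3, byrow = TRUE) / 10
    chain_conformation(X, segment_id, tolerance = 1e-3)  # PDB rounds to 1e-4 nm
  })
}

#' Write conformations as plain XYZ
#'
#' @inheritParams write_ca_pdb
#' @return `path`, invisibly.
#' @export
write_xyz <- function(confs, path) {
  if (inherits(confs, "chain_conformation")) confs <- list(confs)
  con <- file(path, "w")
  on.exit(close(con))
  for (cf in confs) {
    X <- coords_of(cf)
    writeLines(as.character(nrow(X)), con)
    writeLines("CA trace (nm)", con)
    writeLines(sprintf("CA %12.6f %12.6f %12.6f", X[, 1], X[, 2], X[, 3]), con)
  }
  invisible(path)
}
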