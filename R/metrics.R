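## Structural observables on Calpha ensembles: geometric helicity, radius
## of gyration, an H-bond surrogate, Kabsch RMSD, Daura clustering and
## cross-variant dominance analysis.

#' Geometric helicity assignment
#'
#' A Calpha-only stand-in for DSSP: residue `j` (for `2 <= j <= n-2`) is
#' helical when its pseudo-dihedral (residues `j-1..j+2`) lies in
#' [30, 80] degrees and, where defined, its Calpha(j)-Calpha(j+3) distance
#' lies in [0.44, 0.56] nm. Terminal residues lack the geometric context and
#' are excluded from the denominator. The criterion is calibrated so the
#' ideal helix scores 1 and the extended chain 0.
#'
#' @param conf A [chain_conformation()].
#' @return A tibble with columns `residue`, `assignable`, `helical`;
#'   attribute `"fraction"` holds helical / assignable. See
#'   [helicity_fraction()] for the scalar shortcut.
#' @export
assign_helicity <- function(conf) {
  X <- coords_of(conf)
  n <- nrow(X)
  if (n < 4) abort("Chain must have >= 4 residues.", class = "helixscan_invalid_length")
  phi <- pseudo_dihedrals(conf) * 180 / pi      # dihedral d spans residues d..d+3
  helical <- rep(NA, n)
  for (j in 2:(n - 2)) {
    dih_ok <- phi[j - 1] >= 30 && phi[j - 1] <= 80
    d_ok <- TRUE
    if (j + 3 <= n) {
      d <- sqrt(sum((X[j, ] - X[j + 3, ])^2))
      d_ok <- d >= 0.44 && d <= 0.56
    }
    helical[j] <- dih_ok && d_ok
  }
  out <- tibble(residue = seq_len(n),
                assignable = !is.na(helical),
                helical = helical)
  structure(out, fraction = mean(helical, na.rm = TRUE),
            class = c("helicity_assignment", class(out)))
}

#' Helicity fraction of a conformation
#'
#' @param conf A [chain_conformation()] or a list of them (vectorised).
#' @return Fraction of assignable residues that are helical, in [0, 1].
#' @export
helicity_fraction <- function(conf) {
  if (is.list(conf) && !inherits(conf, "chain_conformation")) {
    return(vapply(conf, helicity_fraction, numeric(1)))
  }
  attr(assign_helicity(conf), "fraction")
}

#' Mean helicity as a function of R, and the 50% crossing
#'
#' Bins the pooled window samples on the dRMSD coordinate and averages the
#' geometric helicity fraction per bin; the dRMSD at which linear
#' interpolation crosses 50% helicity is reported, mirroring the
#' calibration that places the helical-state boundary at R = 0.15 nm where
#' helicity drops below 50%.
#'
#' @param samples A `windowed_samples` object from [run_hremd()].
#' @param bin_width R bin width (nm).
#' @return A tibble (`R`, `mean_helicity`, `n`); attribute `"crossing"`
#'   holds the interpolated 50% crossing in nm, or `NA` (with attribute
#'   `"no_crossing" = TRUE`) when the curve never crosses 0.5.
#' @export
helicity_vs_R <- function(samples, bin_width = 0.02) {
  stopifnot(inherits(samples, "windowed_samples"))
  tbl <- samples$samples
  tbl$helicity <- unlist(lapply(samples$conformations, helicity_fraction))
  tbl$bin <- floor(tbl$R / bin_width)
  curve <- tbl |>
    group_by(.data$bin) |>
    summarise(R = (.data$bin[1] + 0.5) * bin_width,
              mean_helicity = mean(.data$helicity), n = n(),
              .groups = "drop") |>
    arrange(.data$R)
  crossing <- crossing_50(curve$R, curve$mean_helicity)
  structure(curve, crossing = crossing, no_crossing = is.na(crossing),
            class = c("helicity_curve", class(curve)))
}

## first downward 50% crossing of a binned helicity curve, by linear
## interpolation between the flanking bin centres
crossing_50 <- function(R, h) {
  below <- which(h < 0.5)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  if (i == 1) return(R[1])
  if (h[i - 1] == h[i]) return(R[i])
  approx(h[(i - 1):i], R[(i - 1):i], xout = 0.5)$y
}

#' Radius of gyration
#'
#' `Rg = sqrt(mean |x - centroid|^2)` with unit masses.
#'
#' @param conf A [chain_conformation()], coordinate matrix, or list of
#'   either (vectorised).
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(conf) {
  if (is.list(conf) && !inherits(conf, "chain_conformation")) {
    return(vapply(conf, radius_of_gyration, numeric(1)))
  }
  X <- coords_of(conf)
  ctr <- colMeans(X)
  sqrt(mean(rowSums((X - matrix(ctr, nrow(X), 3, byrow = TRUE))^2)))
}

#' Intramolecular H-bond surrogate count
#'
#' At Calpha resolution hydrogen bonds are not resolvable; the surrogate
#' counts medium/long-range contacts: residue pairs (i, j) with
#' `j >= i + 4` closer than 0.62 nm. On the ideal helix every i,i+4 pair
#' sits just inside the cutoff, giving n - 4 counts.
#'
#' @param conf A [chain_conformation()] or list (vectorised).
#' @param cutoff Contact cutoff (nm).
#' @return Integer contact count.
#' @export
count_hbond_surrogate <- function(conf, cutoff = 0.62) {
  if (is.list(conf) && !inherits(conf, "chain_conformation")) {
    return(vapply(conf, count_hbond_surrogate, numeric(1), cutoff = cutoff))
  }
  X <- coords_of(conf)
  n <- nrow(X)
  if (n < 5) abort("Chain must have >= 5 residues.", class = "helixscan_invalid_length")
  D <- as.matrix(stats::dist(X))
  sum(D[outer(seq_len(n), seq_len(n), function(i, j) j >= i + 4)] < cutoff)
}

#' Kabsch least-RMSD between two conformations
#'
#' Optimal superposition by centroid removal and the Kabsch rotation
#' (proper rotations only, so mirror images retain a positive RMSD).
#'
#' @param a,b Conformations of equal length.
#' @return RMSD in nm after superposition.
#' @export
kabsch_rmsd <- function(a, b) {
  A <- coords_of(a); B <- coords_of(b)
  if (!all(dim(A) == dim(B))) {
    abort("Conformations must have equal lengths.", class = "helixscan_shape_error")
  }
  .kabsch_rmsd_cpp(A, B)
}

#' Daura (GROMOS) conformational clustering
#'
#' Greedy neighbour-count clustering: compute all pairwise Kabsch RMSDs;
#' repeatedly take the structure with the most neighbours within `cutoff`
#' (ties broken by lowest structure index) as a cluster centre, remove it
#' and its neighbours, and continue until all structures are assigned.
#'
#' @param structures List of conformations (equal lengths).
#' @param cutoff RMSD cutoff in nm.
#' @param labels Optional per-structure variant labels.
#' @return A `cluster_set`: `$membership` tibble (`structure`, `cluster`,
#'   `is_center`, `label`), `$clusters` tibble (`cluster`, `center`, `size`)
#'   with sizes non-increasing, and the cutoff.
#' @export
daura_cluster <- function(structures, cutoff = 0.1, labels = NULL) {
  N <- length(structures)
  if (N < 1) abort("Need at least one structure.", class = "helixscan_invalid_config")
  if (!is.null(labels) && length(labels) != N) {
    abort("`labels` must match the number of structures.", class = "helixscan_shape_error")
  }
  D <- .pairwise_rmsd_cpp(lapply(structures, coords_of))
  adj <- D <= cutoff
  remaining <- rep(TRUE, N)
  cl <- integer(N); centers <- integer(0)
  k <- 0L
  while (any(remaining)) {
    k <- k + 1L
    counts <- colSums(adj[remaining, , drop = FALSE]) * remaining
    center <- which.max(counts)             # ties: lowest index wins
    members <- which(remaining & adj[center, ])
    cl[members] <- k
    centers[k] <- center
    remaining[members] <- FALSE
  }
  sizes <- tabulate(cl, k)
  ord <- order(-sizes, centers[seq_len(k)])  # largest first, stable
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  cl <- relabel[cl]
  membership <- tibble(structure = seq_len(N), cluster = cl,
                       is_center = seq_len(N) %in% centers,
                       label = if (is.null(labels)) NA_character_ else as.character(labels))
  clusters <- tibble(cluster = seq_len(k), center = centers[ord],
                     size = sizes[ord])
  structure(list(membership = membership, clusters = clusters,
                 cutoff = cutoff), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d structures in %d clusters (cutoff %.3f nm); largest = %d\n",
              nrow(x$membership), nrow(x$clusters), x$cutoff, x$clusters$size[1]))
  invisible(x)
}

#' @rdname daura_cluster
#' @param x A `cluster_set`.
#' @param ... Unused.
#' @export
tidy.cluster_set <- function(x, ...) x$membership

#' @rdname daura_cluster
#' @export
glance.cluster_set <- function(x, ...) {
  tibble(n_structures = nrow(x$membership), n_clusters = nrow(x$clusters),
         largest = x$clusters$size[1], cutoff = x$cutoff)
}

#' Force-field-variant dominance analysis of clusters
#'
#' For every significant cluster (more than `min_size` structures) and
#' every variant: the cluster is `dominated` by a variant contributing more
#' than `dominate_frac` of its structures, the variant is `neglected` when
#' it contributes less than `neglect_frac`, otherwise `neutral`. The
#' expected share under uniform contribution is reported alongside.
#'
#' @param clusters A `cluster_set` whose membership carries variant labels
#'   covering at least two variants.
#' @param min_size Minimum cluster size (strict; default: more than 100
#'   structures).
#' @param dominate_frac Dominance threshold on the variant share (> 0.8).
#' @param neglect_frac Neglect threshold (< 0.01).
#' @return A tibble (`cluster`, `size`, `variant`, `n`, `share`,
#'   `expected_share`, `status`).
#' @export
dominance_analysis <- function(clusters, min_size = 100, dominate_frac = 0.8,
                               neglect_frac = 0.01) {
  mem <- clusters$membership
  if (all(is.na(mem$label)) || length(unique(mem$label)) < 2) {
    abort("Dominance analysis needs labels covering at least two variants.",
          class = "helixscan_invalid_config")
  }
  variants <- sort(unique(mem$label))
  overall <- table(factor(mem$label, levels = variants))
  expected <- as.numeric(overall) / sum(overall)
  sizes <- clusters$clusters
  keep <- sizes$cluster[sizes$size > min_size]
  empty <- tibble(cluster = integer(), size = integer(),
                  variant = character(), n = integer(), share = numeric(),
                  expected_share = numeric(), status = character())
  if (!length(keep)) return(empty)
  purrr::map_dfr(keep, function(k) {
    sub <- mem[mem$cluster == k, ]
    cnt <- table(factor(sub$label, levels = variants))
    share <- as.numeric(cnt) / nrow(sub)
    tibble(cluster = k, size = nrow(sub), variant = variants,
           n = as.integer(cnt), share = share,
           expected_share = expected,
           status = dplyr::case_when(
             share > dominate_frac ~ "dominated",
             share < neglect_frac ~ "neglected",
             TRUE ~ "neutral"))
  })
}
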