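## Coarse-grained Calpha helix-coil model: parameters, energy, and unbiased
## Metropolis Monte Carlo sampling.

#' Coarse-grained model parameters
#'
#' Parameters of the Calpha helix-coil surrogate. The potential (in kBT) is
#' a sum of (i) harmonic pseudo-bond-angle terms about 91 degrees, (ii) a
#' double-well pseudo-dihedral term with a helical minimum at +50 degrees
#' whose depth is the per-residue helix bias `h_j`, and an extended minimum
#' at -170 degrees of fixed depth, and (iii) for residue pairs at least 4
#' apart in sequence, a square-well attraction of depth `contact_strength`
#' inside 0.62 nm with soft-core repulsion inside `excluded_radius`.
#' Dihedral `d` (residues `d..d+3`) takes its well depth from residue
#' `d+1`, the residue the dihedral is assigned to throughout the package.
#'
#' Well depths are specified in kBT units at the 300 K reference
#' temperature; sampling at another temperature rescales the reduced
#' Hamiltonian by `300 / T`, so heating flattens the landscape and raises
#' the mean energy, as it must.
#'
#' @param helix_bias Per-residue helical well depth `h_j` in kBT (scalar is
#'   recycled); must be >= 0.
#' @param contact_strength Contact well depth `eps_c` in kBT, >= 0.
#' @param excluded_radius Soft-core repulsion onset (nm).
#' @param temperature Kelvin, > 0.
#' @param variant_name Optional variant label (see [variant_presets()]).
#' @param n_residues Chain length the parameters apply to.
#' @return A `model_parameters` object.
#' @export
model_parameters <- function(helix_bias = 1, contact_strength = 1,
                             excluded_radius = 0.30, temperature = 300,
                             variant_name = NULL, n_residues = 10) {
  if (any(helix_bias < 0)) abort("`helix_bias` must be >= 0.")
  if (contact_strength < 0) abort("`contact_strength` must be >= 0.")
  if (temperature <= 0) abort("`temperature` must be > 0.")
  if (length(helix_bias) == 1) helix_bias <- rep(helix_bias, n_residues)
  if (length(helix_bias) != n_residues) {
    abort("`helix_bias` must have length 1 or `n_residues`.")
  }
  structure(list(
    helix_bias = as.numeric(helix_bias),
    contact_strength = contact_strength,
    excluded_radius = excluded_radius,
    temperature = temperature,
    variant_name = variant_name,
    ## fixed surrogate constants (kBT / rad / nm); see the methods vignette
    k_angle = 300,
    extended_depth = 0.8,
    theta0 = THETA0_DEG * pi / 180,
    phi_helix = PHI_HELIX_DEG * pi / 180,
    phi_extended = PHI_EXT_DEG * pi / 180,
    dihedral_width = 0.25,
    k_repulsion = 50,
    contact_cutoff = 0.62
  ), class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat(sprintf("<model_parameters>%s %d residues, mean h = %.2f kBT, eps_c = %.2f kBT, T = %g K\n",
              if (is.null(x$variant_name)) "" else paste0(" [", x$variant_name, "]"),
              length(x$helix_bias), mean(x$helix_bias), x$contact_strength,
              x$temperature))
  invisible(x)
}

#' Water-model surrogate variant presets
#'
#' Four frozen parameter sets standing in for the four water force fields
#' compared in the study. They encode only the qualitative orderings the
#' comparison rests on: helix stabilisation
#' V-TIP4P-ws >= V-TIP3P > V-TIP4P-s > V-TIP4P-D (via a multiplier on the
#' sequence-derived helix bias) and compaction, with V-TIP4P-D the most
#' extended (weakest contacts). Magnitudes are surrogate choices, not fits.
#'
#' @return A tibble with columns `variant`, `helix_scale`,
#'   `contact_strength`, `excluded_radius`.
#' @export
variant_presets <- function() {
  tibble(
    variant = c("V-TIP3P", "V-TIP4P-s", "V-TIP4P-ws", "V-TIP4P-D"),
    helix_scale = c(1.00, 0.60, 1.10, 0.25),
    contact_strength = c(1.0, 0.7, 0.7, 0.2),
    excluded_radius = c(0.30, 0.30, 0.30, 0.30)
  )
}

## Helix-propensity penalties (kcal/mol relative to Ala), Pace & Scholtz-style
## scale; converted to a 0..1 score via exp(-dG / 0.6).
HELIX_DG <- c(A = 0.00, L = 0.21, R = 0.21, M = 0.24, K = 0.26, Q = 0.39,
              E = 0.40, I = 0.41, W = 0.49, S = 0.50, Y = 0.53, F = 0.54,
              H = 0.61, V = 0.61, N = 0.65, T = 0.66, C = 0.68, D = 0.69,
              G = 1.00, P = 3.16)

#' Sequence-derived helix propensity scores
#'
#' Maps one-letter residue codes to a 0..1 helix-propensity score
#' `exp(-dG / 0.6)` built on an experimental helix-propensity scale
#' (alanine = 1, glycine ~ 0.19, proline ~ 0.005).
#'
#' @param sequence One-letter amino-acid string.
#' @return Numeric vector of per-residue scores.
#' @export
helix_propensity <- function(sequence) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(aa, names(HELIX_DG))
  if (length(bad)) {
    abort(paste0("Unknown residue type(s): ", paste(unique(bad), collapse = ", ")),
          class = "helixscan_unknown_residue")
  }
  unname(exp(-HELIX_DG[aa] / 0.6))
}

#' Model parameters for a sequence under a named variant
#'
#' Builds per-residue helix bias `h_j = helix_scale * 5 kBT *
#' helix_propensity(aa_j)` and the variant's contact parameters.
#'
#' @param sequence One-letter amino-acid string.
#' @param variant One of `"V-TIP3P"`, `"V-TIP4P-s"`, `"V-TIP4P-ws"`,
#'   `"V-TIP4P-D"`.
#' @param temperature Kelvin.
#' @param base_depth Full helical well depth for alanine at scale 1 (kBT).
#' @return A [model_parameters()] object.
#' @export
variant_parameters <- function(sequence, variant = "V-TIP3P",
                               temperature = 300, base_depth = 5) {
  pre <- variant_presets()
  if (!variant %in% pre$variant) {
    abort(paste0("Unknown variant '", variant, "'."), class = "helixscan_unknown_variant")
  }
  row <- pre[pre$variant == variant, ]
  s <- helix_propensity(sequence)
  model_parameters(helix_bias = row$helix_scale * base_depth * s,
                   contact_strength = row$contact_strength,
                   excluded_radius = row$excluded_radius,
                   temperature = temperature, variant_name = variant,
                   n_residues = nchar(sequence))
}

## Well depths are specified in kBT units at the 300 K reference
## temperature; at simulation temperature T the dimensionless Hamiltonian
## used by Metropolis is U / (kB T) = E_300 * (300 / T).
REF_TEMPERATURE <- 300

params_list <- function(params) {
  stopifnot(inherits(params, "model_parameters"))
  p <- unclass(params)
  s <- REF_TEMPERATURE / p$temperature
  for (f in c("helix_bias", "contact_strength", "extended_depth",
              "k_angle", "k_repulsion")) {
    p[[f]] <- p[[f]] * s
  }
  p
}

## recorded reduced energies back to the 300 K-referenced scale
energy_scale <- function(params) params$temperature / REF_TEMPERATURE

#' Potential energy of a conformation (kBT)
#'
#' Evaluates the coarse-grained surrogate potential described in
#' [model_parameters()].
#'
#' @param conf A [chain_conformation()].
#' @param params A [model_parameters()] with matching length.
#' @return Energy in kBT units (finite).
#' @export
potential_energy <- function(conf, params) {
  X <- coords_of(conf)
  if (nrow(X) < 4) abort("Chain must have >= 4 residues.", class = "helixscan_invalid_length")
  if (length(params$helix_bias) != nrow(X)) {
    abort("`params$helix_bias` length must match the chain length.",
          class = "helixscan_shape_error")
  }
  D <- as.matrix(stats::dist(X))
  if (any(D[upper.tri(D)] < 1e-6)) {
    abort("Overlapping coordinates: singular geometry.",
          class = "helixscan_singular_geometry")
  }
  .chain_energy_cpp(X, unclass(params))   # 300 K-referenced depths as given
}

#' Unbiased Monte Carlo sampling of the surrogate model
#'
#' Metropolis Monte Carlo with local dihedral pivot moves (one attempt per
#' pseudo-dihedral per sweep) and crankshaft rotations. Deterministic for a
#' fixed seed: per-replica pseudo-random streams are derived from the master
#' seed by fixed offsets.
#'
#' @param params A [model_parameters()].
#' @param n_steps Number of MC sweeps (>= 1).
#' @param seed Master seed (non-negative integer).
#' @param init `"helix"` or `"extended"` starting structure, or a
#'   [chain_conformation()].
#' @param record_every Record every this many sweeps.
#' @param segment_id Label for recorded conformations.
#' @return A `cg_trajectory`: list with `$stats` (tibble: step, R, energy),
#'   `$conformations` (list of [chain_conformation()]), `$acceptance`
#'   (fraction of accepted moves), and the reference used for R.
#' @export
sample_unbiased <- function(params, n_steps, seed = 1, init = "helix",
                            record_every = 1, segment_id = "segment") {
  stopifnot(n_steps >= 1)
  n <- length(params$helix_bias)
  X0 <- init_conformation(init, n)
  ref <- helical_reference(n)
  out <- .mc_run_cpp(coords_of(X0), params_list(params),
                     ref$pair_list - 1L, ref$d0,
                     R0s = 0, k0s_kBT = 0,
                     n_sweeps = as.integer(n_steps), exchange_interval = 0L,
                     record_every = as.integer(record_every),
                     seed = as.numeric(seed), max_pivot = pi / 3,
                     max_crank = pi / 3, n_crank = 2L)
  confs <- cube_to_conformations(out$conformations[[1]], segment_id)
  structure(list(
    stats = tibble(step = as.integer(out$step),
                   R = as.numeric(out$R[, 1]),
                   energy = as.numeric(out$energy[, 1]) * energy_scale(params)),
    conformations = confs,
    acceptance = as.numeric(out$acceptance[1]),
    reference = ref, params = params, seed = seed
  ), class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("<cg_trajectory> %d frames, acceptance %.2f, mean R %.3f nm\n",
              nrow(x$stats), x$acceptance, mean(x$stats$R)))
  invisible(x)
}

init_conformation <- function(init, n) {
  if (inherits(init, "chain_conformation")) return(init)
  switch(init,
         helix = build_ideal_helix(n),
         extended = build_extended_chain(n),
         abort("`init` must be 'helix', 'extended' or a chain_conformation."))
}

cube_to_conformations <- function(cube, segment_id = "segment") {
  lapply(seq_len(dim(cube)[1]), function(k) {
    chain_conformation(matrix(cube[k, , ], ncol = 3), segment_id)
  })
}
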