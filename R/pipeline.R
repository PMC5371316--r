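## Orchestration: sequence segmentation, per-segment per-variant sampling
## and analysis, and report generation.

#' The packaged Axin-1-like scan sequence
#'
#' Loads the packaged FASTA covering residues 380-490 in full-length
#' numbering. The sequence is a synthetic, Axin-1-like stand-in (see the
#' fixture name): it carries helix-prone stretches around residues 391-420
#' (with Arg-Glu i,i+3/i,i+7 spacings) and 461-480, and a Pro/Gly-rich
#' linker over 431-460, the architecture of the protein's binding and
#' linker regions.
#'
#' @return A list with `sequence` (one-letter string) and `first_residue`
#'   (380).
#' @export
axin_scan_sequence <- function() {
  path <- system.file("extdata", "axin1_380_490_synthetic.fasta",
                      package = "helixscan")
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  list(sequence = toupper(as.character(fa[[1]])), first_residue = 380L)
}

#' Split a sequence into fixed-length segments
#'
#' Cuts the residue range `[first_residue, last_residue]` into windows of
#' `window` residues every `stride` residues (non-overlapping by default,
#' matching the 10-residue segmentation of the scanned region). A trailing
#' remainder shorter than `window` is dropped with a warning.
#'
#' @param sequence One-letter string covering the range (its first character
#'   is residue `numbering_start`).
#' @param first_residue,last_residue Residue range to segment, in
#'   full-length numbering.
#' @param window Segment length (default 10).
#' @param stride Offset between segment starts (default 10).
#' @param numbering_start Residue number of `sequence[1]` (default
#'   `first_residue`).
#' @return A tibble: `segment`, `start_residue`, `end_residue`, `sequence`.
#' @export
segment_sequence <- function(sequence, first_residue, last_residue,
                             window = 10, stride = 10,
                             numbering_start = first_residue) {
  n <- nchar(sequence)
  lo <- first_residue - numbering_start + 1
  hi <- last_residue - numbering_start + 1
  if (lo < 1 || hi > n || hi < lo) {
    abort("Residue range lies outside the supplied sequence.",
          class = "helixscan_bounds_error")
  }
  if (window > hi - lo + 1) {
    abort("`window` exceeds the residue range.", class = "helixscan_bounds_error")
  }
  starts <- seq(lo, hi - window + 1, by = stride)
  dropped <- (hi - (starts[length(starts)] + window - 1))
  if (dropped > 0) {
    warn(sprintf("Trailing remainder of %d residue(s) shorter than the window was dropped.",
                 dropped))
  }
  tibble(segment = seq_along(starts),
         start_residue = starts + numbering_start - 1,
         end_residue = starts + window - 1 + numbering_start - 1,
         sequence = vapply(starts, function(s)
           substr(sequence, s, s + window - 1), character(1)))
}

#' Scan configuration
#'
#' Bundles every knob of a helicity scan. Defaults follow the sampling
#' protocol (12 windows over 0.0-0.5 nm, exchange every 500 sweeps) at
#' desk-scale run lengths.
#'
#' @param sequence One-letter sequence to scan.
#' @param first_residue Number of the first residue of `sequence`.
#' @param variants Character vector of variant presets.
#' @param window,stride Segmentation parameters.
#' @param n_windows,r_min,r_max,k0 Umbrella window layout
#'   ([build_windows()]).
#' @param n_steps,exchange_interval,record_every Sampling lengths.
#' @param temperature Kelvin.
#' @param seed Master seed; per-(segment, variant) seeds are derived by
#'   fixed offsets.
#' @param equilibration Initial fraction of samples discarded before
#'   analysis.
#' @param bin_width,boundary PMF bin width and helical boundary (nm).
#' @param n_boot Bootstrap replicates for PMF uncertainty.
#' @param cluster Logical: run Daura clustering + dominance per segment.
#' @param cluster_cutoff,cluster_subsample,cluster_min_size Clustering
#'   controls.
#' @param helix_bias Optional explicit per-residue bias for the full
#'   sequence, overriding the sequence-derived bias (used by synthetic
#'   known-truth scans).
#' @return A `scan_config` list.
#' @export
scan_config <- function(sequence, first_residue = 1,
                        variants = c("V-TIP3P", "V-TIP4P-D"),
                        window = 10, stride = 10,
                        n_windows = 12, r_min = 0, r_max = 0.5, k0 = 1000,
                        n_steps = 3000, exchange_interval = 500,
                        record_every = 2, temperature = 300, seed = 1,
                        equilibration = 0.1, bin_width = 0.01,
                        boundary = 0.15, n_boot = 20,
                        cluster = FALSE, cluster_cutoff = 0.1,
                        cluster_subsample = 300, cluster_min_size = 100,
                        helix_bias = NULL) {
  if (!length(variants)) abort("At least one variant is required.",
                               class = "helixscan_invalid_config")
  cfg <- as.list(environment())
  class(cfg) <- "scan_config"
  cfg
}

#' Hash of the semantically meaningful scan configuration
#'
#' @param config A [scan_config()].
#' @return A short hash string; equal iff every meaningful field is equal.
#' @export
config_hash <- function(config) {
  rlang::hash(unclass(config))
}

#' Run a full helicity scan
#'
#' For every (segment, variant) cell: derive the per-residue helix bias
#' from the segment sequence and the variant preset, build umbrella
#' windows, run restrained replica-exchange sampling, discard the
#' equilibration fraction, reconstruct the PMF by WHAM and integrate the
#' helical population below the boundary, and collect ensemble observables
#' (mean helicity, radius of gyration, contact counts). Cell failures are
#' isolated and recorded; the scan is deterministic under the master seed.
#'
#' @param config A [scan_config()].
#' @return A `scan_result`: `$cells` tibble with one row per (segment,
#'   variant) carrying populations, observables and errors; `$pmfs`,
#'   `$samples` keyed lists; `$clusters` per-segment cluster/dominance
#'   results when requested; `$segments`, `$config`, `$hash`.
#' @export
run_scan <- function(config) {
  stopifnot(inherits(config, "scan_config"))
  segs <- segment_sequence(config$sequence, config$first_residue,
                           config$first_residue + nchar(config$sequence) - 1,
                           window = config$window, stride = config$stride,
                           numbering_start = config$first_residue)
  windows <- build_windows(config$n_windows, config$r_min, config$r_max,
                           config$k0)
  cells <- tidyr::expand_grid(segment = segs$segment, variant = config$variants)
  pmfs <- list(); samples_store <- list()
  rows <- purrr::pmap_dfr(cells, function(segment, variant) {
    seg <- segs[segs$segment == segment, ]
    key <- paste0("seg", seg$start_residue, "_", variant)
    cell_seed <- config$seed + 1000 * segment +
      131071 * match(variant, config$variants)
    res <- tryCatch({
      params <- variant_parameters(seg$sequence, variant,
                                   temperature = config$temperature)
      if (!is.null(config$helix_bias)) {
        off <- seg$start_residue - config$first_residue
        params$helix_bias <- config$helix_bias[off + seq_len(config$window)]
      }
      ws <- run_hremd(params, windows, n_steps = config$n_steps,
                      exchange_interval = config$exchange_interval,
                      seed = cell_seed, record_every = config$record_every,
                      segment_id = key)
      ws <- discard_equilibration(ws, config$equilibration)
      pmf <- wham(ws, temperature = config$temperature,
                  bin_width = config$bin_width, n_boot = config$n_boot)
      pop <- helical_population(pmf, boundary = config$boundary)
      obs <- pooled_observables(ws)
      pmfs[[key]] <<- pmf
      samples_store[[key]] <<- ws
      tibble(segment = segment, start_residue = seg$start_residue,
             variant = variant, seed = cell_seed,
             p_helix = as.numeric(pop), p_helix_sd = attr(pop, "sd"),
             mean_helicity = obs$mean_helicity,
             mean_rg = obs$mean_rg, mean_hbonds = obs$mean_hbonds,
             swap_acceptance = mean(ws$exchange_log$accepted),
             error = NA_character_)
    }, error = function(e) {
      tibble(segment = segment, start_residue = seg$start_residue,
             variant = variant, seed = cell_seed,
             p_helix = NA_real_, p_helix_sd = NA_real_,
             mean_helicity = NA_real_, mean_rg = NA_real_,
             mean_hbonds = NA_real_, swap_acceptance = NA_real_,
             error = conditionMessage(e))
    })
    res
  })
  clusters <- if (isTRUE(config$cluster)) {
    cluster_scan(samples_store, segs, config)
  } else NULL
  structure(list(cells = rows, pmfs = pmfs, samples = samples_store,
                 clusters = clusters, segments = segs, windows = windows,
                 config = config, hash = config_hash(config)),
            class = "scan_result")
}

discard_equilibration <- function(ws, fraction) {
  if (fraction <= 0) return(ws)
  steps <- sort(unique(ws$samples$step))
  keep_steps <- steps[-seq_len(floor(fraction * length(steps)))]
  keep_idx <- match(keep_steps, steps)
  ws$samples <- ws$samples[ws$samples$step %in% keep_steps, ]
  ws$conformations <- lapply(ws$conformations, function(cl) cl[keep_idx])
  ws
}

pooled_observables <- function(ws) {
  confs <- unlist(ws$conformations, recursive = FALSE)
  list(mean_helicity = mean(helicity_fraction(confs)),
       mean_rg = mean(radius_of_gyration(confs)),
       mean_hbonds = mean(count_hbond_surrogate(confs)))
}

## pooled per-segment clustering across variants, with dominance statuses
cluster_scan <- function(samples_store, segs, config) {
  lapply(stats::setNames(segs$segment, paste0("seg", segs$start_residue)),
         function(sg) {
    seg <- segs[segs$segment == sg, ]
    confs <- list(); labels <- character(0)
    for (v in config$variants) {
      key <- paste0("seg", seg$start_residue, "_", v)
      ws <- samples_store[[key]]
      if (is.null(ws)) next
      cs <- unlist(ws$conformations, recursive = FALSE)
      if (length(cs) > config$cluster_subsample) {
        idx <- round(seq(1, length(cs), length.out = config$cluster_subsample))
        cs <- cs[idx]
      }
      confs <- c(confs, cs)
      labels <- c(labels, rep(v, length(cs)))
    }
    if (!length(confs)) return(NULL)
    cl <- daura_cluster(confs, cutoff = config$cluster_cutoff, labels = labels)
    dom <- tryCatch(
      dominance_analysis(cl, min_size = config$cluster_min_size),
      error = function(e) NULL)
    centers <- mutate(cl$clusters,
                      center_rg = radius_of_gyration(confs[cl$clusters$center]),
                      center_hbonds = count_hbond_surrogate(confs[cl$clusters$center]))
    list(clusters = cl, dominance = dom, centers = centers)
  })
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %d segments x %d variants; %d cell(s) failed; hash %s\n",
              nrow(x$segments), length(x$config$variants),
              sum(!is.na(x$cells$error)), substr(x$hash, 1, 8)))
  invisible(x)
}

#' @rdname run_scan
#' @param x A `scan_result`.
#' @param ... Unused.
#' @export
tidy.scan_result <- function(x, ...) x$cells

#' @rdname run_scan
#' @export
glance.scan_result <- function(x, ...) {
  tibble(n_segments = nrow(x$segments),
         n_variants = length(x$config$variants),
         n_failed = sum(!is.na(x$cells$error)),
         mean_p_helix = mean(x$cells$p_helix, na.rm = TRUE),
         hash = x$hash)
}

#' Write a scan report
#'
#' Emits per-cell PMF TSVs, figure files (PMF panels, helicity-per-segment
#' bars, observable histograms, cluster-size curves and a dominance
#' scatter where clustering was run), a machine-readable JSON summary of
#' the cell table, and a run manifest with the configuration and seeds.
#'
#' @param result A `scan_result`.
#' @param out_dir Output directory (created if needed).
#' @return Tibble of written files, invisibly.
#' @export
write_report <- function(result, out_dir) {
  stopifnot(inherits(result, "scan_result"))
  if (!length(result$config$variants) || !nrow(result$cells)) {
    abort("Empty scan result: nothing to report.", class = "helixscan_invalid_config")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(paste0("Cannot create ", out_dir))
  files <- character(0)
  for (key in names(result$pmfs)) {
    f <- file.path(out_dir, paste0("pmf_", key, ".tsv"))
    write_pmf_tsv(result$pmfs[[key]], f)
    files <- c(files, f)
  }
  ## machine-readable summary + manifest
  f <- file.path(out_dir, "scan_summary.json")
  jsonlite::write_json(result$cells, f, digits = NA, na = "null")
  files <- c(files, f)
  f <- file.path(out_dir, "manifest.json")
  cfg <- unclass(result$config)
  cfg$sequence <- as.character(cfg$sequence)
  jsonlite::write_json(list(config = cfg, hash = result$hash,
                            seeds = result$cells[, c("segment", "variant", "seed")],
                            timestamp = format(Sys.time(), tz = "UTC")),
                       f, auto_unbox = TRUE, digits = NA, na = "null")
  files <- c(files, f)
  ## figures
  figs <- list(
    pmf_panels.pdf = autoplot_pmf_panels(result),
    helicity_bars.pdf = autoplot(result),
    observable_histograms.pdf = plot_observable_histograms(result))
  if (!is.null(result$clusters)) {
    figs$cluster_sizes.pdf <- plot_cluster_sizes(result)
    dom <- dominance_table(result)
    if (!is.null(dom) && nrow(dom)) {
      figs$dominance_scatter.pdf <- plot_dominance(result)
      f <- file.path(out_dir, "dominance.csv")
      write.csv(as.data.frame(dom), f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  for (nm in names(figs)) {
    f <- file.path(out_dir, nm)
    ggplot2::ggsave(f, figs[[nm]], width = 9, height = 6)
    files <- c(files, f)
  }
  invisible(tibble(file = files))
}

#' Dominance table across segments
#'
#' @param result A `scan_result` run with `cluster = TRUE`.
#' @return Combined dominance tibble with a `segment_key` column, or `NULL`.
#' @export
dominance_table <- function(result) {
  if (is.null(result$clusters)) return(NULL)
  purrr::imap_dfr(result$clusters, function(cl, key) {
    if (is.null(cl) || is.null(cl$dominance) || !nrow(cl$dominance)) return(tibble())
    mutate(cl$dominance, segment_key = key)
  })
}
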