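## ggplot2 displays for each result type.

#' @importFrom ggplot2 ggplot aes geom_line geom_ribbon geom_col geom_point
#'   geom_step geom_histogram facet_wrap labs theme_bw scale_colour_brewer
#'   geom_hline geom_vline position_dodge
NULL

#' Plot a free-energy profile
#'
#' @param object A `pmf_profile` from [wham()].
#' @param units `"kBT"` or `"kJ"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pmf_profile <- function(object, units = c("kBT", "kJ"), ...) {
  units <- match.arg(units)
  kT <- kBT(attr(object, "temperature"))
  df <- as_tibble(object) |> filter(!is.na(.data$F))
  df$y <- if (units == "kBT") df$F_kBT else df$F
  df$ysd <- if (units == "kBT") df$sd / kT else df$sd
  p <- ggplot(df, aes(x = .data$R, y = .data$y)) +
    geom_line(linewidth = 0.7) +
    labs(x = "R (nm)", y = sprintf("F(R) (%s)", if (units == "kBT") "kBT" else "kJ/mol")) +
    theme_bw()
  if (any(!is.na(df$ysd))) {
    p <- p + geom_ribbon(aes(ymin = .data$y - .data$ysd,
                             ymax = .data$y + .data$ysd), alpha = 0.25)
  }
  p
}

## multi-panel PMFs per segment, coloured by variant
autoplot_pmf_panels <- function(result) {
  df <- purrr::imap_dfr(result$pmfs, function(p, key) {
    kT <- kBT(attr(p, "temperature"))
    cell <- result$cells[paste0("seg", result$cells$start_residue, "_",
                                result$cells$variant) == key, ]
    tibble(segment = paste0("seg ", cell$start_residue[1]),
           variant = cell$variant[1], R = p$R, F_kBT = p$F_kBT)
  }) |> filter(!is.na(.data$F_kBT))
  ggplot(df, aes(x = .data$R, y = .data$F_kBT, colour = .data$variant)) +
    geom_line() + facet_wrap(~segment) +
    labs(x = "R (nm)", y = "F(R) (kBT)", colour = "variant") + theme_bw()
}

#' Helicity-per-segment bar plot of a scan
#'
#' @param object A `scan_result`.
#' @param ... Unused.
#' @return A ggplot of helical population per segment and variant.
#' @export
autoplot.scan_result <- function(object, ...) {
  ggplot(object$cells,
         aes(x = factor(.data$start_residue), y = .data$p_helix,
             fill = .data$variant)) +
    geom_col(position = position_dodge()) +
    labs(x = "segment start residue", y = "helical population",
         fill = "variant") +
    theme_bw()
}

## Rg / contact histograms pooled over segments, per variant
plot_observable_histograms <- function(result) {
  df <- purrr::imap_dfr(result$samples, function(ws, key) {
    confs <- unlist(ws$conformations, recursive = FALSE)
    cell <- result$cells[paste0("seg", result$cells$start_residue, "_",
                                result$cells$variant) == key, ]
    tibble(variant = cell$variant[1],
           rg = radius_of_gyration(confs),
           hbonds = count_hbond_surrogate(confs))
  })
  df <- tidyr::pivot_longer(df, c("rg", "hbonds"), names_to = "observable")
  ggplot(df, aes(x = .data$value, fill = .data$variant)) +
    geom_histogram(bins = 30, position = "identity", alpha = 0.5) +
    facet_wrap(~observable, scales = "free") +
    labs(x = NULL, y = "count", fill = "variant") + theme_bw()
}

## sorted cluster-size curves per segment
plot_cluster_sizes <- function(result) {
  df <- purrr::imap_dfr(result$clusters, function(cl, key) {
    if (is.null(cl)) return(tibble())
    tibble(segment = key, rank = seq_len(nrow(cl$clusters$clusters)),
           size = cl$clusters$clusters$size)
  })
  ggplot(df, aes(x = .data$rank, y = .data$size, colour = .data$segment)) +
    geom_step() + labs(x = "cluster rank (by size)", y = "cluster size") +
    theme_bw()
}

## dominance scatter: Rg vs contact count of cluster centres, by status
plot_dominance <- function(result) {
  dom <- dominance_table(result)
  dom <- dom[dom$status != "neutral", ]
  centers <- purrr::imap_dfr(result$clusters, function(cl, key) {
    if (is.null(cl)) return(tibble())
    mutate(cl$centers, segment_key = key)
  })
  df <- left_join(dom, centers[, c("segment_key", "cluster", "center_rg",
                                   "center_hbonds")],
                  by = c("segment_key", "cluster"))
  ggplot(df, aes(x = .data$center_rg, y = .data$center_hbonds,
                 colour = .data$variant, shape = .data$status)) +
    geom_point(size = 2) +
    labs(x = "Rg of centre (nm)", y = "contacts of centre",
         colour = "variant", shape = "status") +
    theme_bw()
}

#' Plot an SSP profile
#'
#' Bar plot of normalised SSP per residue: consecutive positive bars
#' indicate helix, negative bars sheet.
#'
#' @param object An `ssp_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ssp_profile <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$residue_number, y = .data$ssp)) +
    geom_col(fill = "steelblue") + geom_hline(yintercept = 0) +
    labs(x = "residue", y = "SSP") + theme_bw()
}

#' Plot mean helicity versus R
#'
#' @param object A `helicity_curve` from [helicity_vs_R()].
#' @param ... Unused.
#' @return A ggplot with the 50% line and the crossing marked.
#' @export
autoplot.helicity_curve <- function(object, ...) {
  p <- ggplot(as_tibble(object), aes(x = .data$R, y = .data$mean_helicity)) +
    geom_line() + geom_point() +
    geom_hline(yintercept = 0.5, linetype = 2) +
    labs(x = "R (nm)", y = "mean helicity") + theme_bw()
  cr <- attr(object, "crossing")
  if (!is.na(cr)) p <- p + geom_vline(xintercept = cr, linetype = 3)
  p
}

#' Plot quarter-wise PMFs from a convergence check
#'
#' @param object A `pmf_convergence`.
#' @param ... Unused.
#' @return A ggplot of the four quarter profiles.
#' @export
autoplot.pmf_convergence <- function(object, ...) {
  df <- tidy(object) |> filter(!is.na(.data$F_kBT))
  ggplot(df, aes(x = .data$R, y = .data$F_kBT,
                 colour = factor(.data$quarter))) +
    geom_line() + labs(x = "R (nm)", y = "F(R) (kBT)", colour = "quarter") +
    theme_bw()
}
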