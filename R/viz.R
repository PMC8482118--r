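#' Build the multimodal plot model
#'
#' Lays out the age-ordered spot-cloud visualisation without rendering it,
#' so every layout rule is testable: each participant occupies one
#' vertical line of up to 23 spots (one per plottable cycle), positioned
#' by the cycle's mean correct-action RT, sized by its error fraction
#' (area proportional to `error_fraction ^ size_power`), colour-coded by
#' mistake count (0-8), and flagged as a big spot when the cycle reaches
#' the mistake threshold. Participants are ranked 0..n-1 by the ordering
#' variable (stable by id on ties); with a stratification, strata blocks
#' are laid out sequentially (first stratum block first) with the
#' ordering applied inside each block. Unplottable cycles are omitted.
#'
#' Overlay series carry each participant's total mistakes and, when the
#' cohort provides them, the wave-1 MMSE and TUG values multiplied by 3
#' (the factor that makes them visible on the shared axis). Age ticks
#' mark the first participant at or past each 5-year boundary; with
#' age-ordering their spacing is non-uniform because most of the cohort
#' is between 50 and 65.
#'
#' @param metrics Cycle metrics from [cycle_metrics()].
#' @param features Participant features from [participant_features()].
#' @param cohort Cohort tibble with the ordering variable and overlay
#'   columns (`mmse_w1`, `tug_w1` used when present).
#' @param threshold A `"sart_threshold"` object.
#' @param order_by Name of the continuous ordering column in `cohort`
#'   (default `"age"`). Participants missing it are dropped with a
#'   warning.
#' @param strata Optional name of a cohort column to stratify by; numeric
#'   columns are split at `strata_cut` into `"low"` / `"high"` blocks.
#' @param strata_cut Cut point for a numeric `strata` column (e.g. 12 for
#'   baseline TUG).
#' @return A list of class `"sart_plot_model"`: `spots`, `overlays`,
#'   `age_ticks`, `threshold`, `order_by`, `strata`.
#' @export
build_plot_model <- function(metrics, features, cohort, threshold,
                             order_by = "age", strata = NULL,
                             strata_cut = NULL) {
  stopifnot(inherits(threshold, "sart_threshold"))
  if (!order_by %in% names(cohort))
    stop("ordering variable `", order_by, "` not in cohort", call. = FALSE)
  tab <- dplyr::inner_join(
    features, cohort, by = "participant_id",
    suffix = c("", ".cohort"))
  drop <- is.na(tab[[order_by]])
  if (any(drop)) {
    warning(sum(drop), " participant(s) missing `", order_by,
            "` dropped from the plot", call. = FALSE)
    tab <- tab[!drop, , drop = FALSE]
  }

  if (!is.null(strata)) {
    if (!strata %in% names(tab))
      stop("stratum variable `", strata, "` not in cohort", call. = FALSE)
    sv <- tab[[strata]]
    if (is.numeric(sv)) {
      if (is.null(strata_cut))
        stop("numeric strata need `strata_cut`", call. = FALSE)
      tab$stratum <- factor(ifelse(sv < strata_cut, "low", "high"),
                            c("low", "high"))
    } else {
      tab$stratum <- factor(sv)
    }
    keep <- !is.na(tab$stratum)
    if (any(!keep)) {
      warning(sum(!keep), " participant(s) missing stratum dropped",
              call. = FALSE)
      tab <- tab[keep, , drop = FALSE]
    }
  } else {
    tab$stratum <- factor("all")
  }

  ord <- order(as.integer(tab$stratum), tab[[order_by]],
               tab$participant_id)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab)) - 1L

  spots <- dplyr::inner_join(
    metrics[metrics$plottable, , drop = FALSE],
    tab[c("participant_id", "rank", "stratum")],
    by = "participant_id")
  spots$size <- spots$error_fraction^threshold$size_power
  spots$big_spot <- spots$n_mistakes >= threshold$mistake_threshold
  spots <- spots[c("participant_id", "rank", "cycle_index",
                   "mean_rt_correct_ms", "n_mistakes", "error_fraction",
                   "size", "big_spot", "stratum")]

  overlays <- tibble::tibble(
    participant_id = tab$participant_id,
    rank = tab$rank,
    stratum = tab$stratum,
    total_mistakes = tab$total_mistakes,
    mmse_scaled = if ("mmse_w1" %in% names(tab)) 3 * tab$mmse_w1 else
      NA_real_,
    tug_scaled = if ("tug_w1" %in% names(tab)) 3 * tab$tug_w1 else
      NA_real_
  )

  ticks <- NULL
  ov <- tab[[order_by]]
  if (is.numeric(ov) && nrow(tab) > 1) {
    bnd <- seq(5 * ceiling(min(ov) / 5), max(ov), by = 5)
    pos <- vapply(bnd, function(b) tab$rank[which(ov >= b)[1]], 0L)
    ticks <- tibble::tibble(rank = pos, value = bnd)
    ticks <- ticks[!duplicated(ticks$rank), , drop = FALSE]
  }

  structure(list(spots = spots, overlays = overlays, age_ticks = ticks,
                 threshold = threshold, order_by = order_by,
                 strata = strata),
            class = "sart_plot_model")
}

#' @export
print.sart_plot_model <- function(x, ...) {
  cat("<sart_plot_model> ", nrow(x$overlays), " participants, ",
      nrow(x$spots), " spots (", sum(x$spots$big_spot), " big)\n",
      sep = "")
  invisible(x)
}

# shared ggplot construction; thresholded = big spots only
sart_ggplot <- function(model, thresholded = FALSE) {
  spots <- model$spots
  overlays <- model$overlays
  if (thresholded) {
    spots <- spots[spots$big_spot, , drop = FALSE]
    keep <- unique(spots$participant_id)
    overlays <- overlays[overlays$participant_id %in% keep, , drop = FALSE]
    if (nrow(spots) == 0)
      warning("no big spots to draw; rendering an empty plot",
              call. = FALSE)
  }
  y_top <- if (nrow(spots) > 0)
    max(spots$mean_rt_correct_ms, na.rm = TRUE) else 800
  # overlays sit above the spot cloud on the shared axis
  overlay_long <- tidyr::pivot_longer(
    overlays, c("total_mistakes", "mmse_scaled", "tug_scaled"),
    names_to = "series", values_to = "value")
  overlay_long$value <- overlay_long$value + y_top

  gg <- ggplot2::ggplot()
  if (nrow(spots) > 0) {
    # flawless cycles keep a minimal visible dot
    spots$size_draw <- pmin(1, spots$size + 0.02)
    gg <- gg + ggplot2::geom_point(
      data = spots,
      ggplot2::aes(x = .data$rank, y = .data$mean_rt_correct_ms,
                   size = .data$size_draw, fill = .data$n_mistakes,
                   colour = .data$big_spot),
      shape = 21, stroke = 0.5, alpha = 0.9)
  }
  gg <- gg +
    ggplot2::geom_line(
      data = overlay_long[!is.na(overlay_long$value), ],
      ggplot2::aes(x = .data$rank, y = .data$value,
                   linetype = .data$series, group = .data$series),
      linewidth = 0.3, colour = "grey30") +
    ggplot2::scale_fill_gradient(
      low = "#C8A165", high = "black", limits = c(0, 8),
      name = "mistakes") +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "transparent", `TRUE` = "white"),
      guide = "none") +
    ggplot2::scale_size_area(max_size = 5, limits = c(0, 1),
                             guide = "none") +
    ggplot2::labs(
      x = paste0("participants ordered by ", model$order_by,
                 if (!is.null(model$strata))
                   paste0(" within ", model$strata)),
      y = "mean RT of correct actions (ms); overlays offset above") +
    ggplot2::theme_minimal()
  if (!is.null(model$age_ticks) && nrow(model$age_ticks) > 0) {
    gg <- gg + ggplot2::scale_x_continuous(
      breaks = model$age_ticks$rank,
      labels = model$age_ticks$value)
  }
  if (!is.null(model$strata)) {
    block <- tapply(overlays$rank, overlays$stratum, max)
    block <- block[-length(block)]
    if (length(block) > 0)
      gg <- gg + ggplot2::geom_vline(xintercept = block + 0.5,
                                     linetype = "dotted")
  }
  gg
}

#' Render the full multimodal visualisation
#'
#' Draws the complete spot cloud with overlays and writes it to `path`
#' (format by extension: png, pdf or svg).
#'
#' @param model A `"sart_plot_model"` from [build_plot_model()].
#' @param path Output image path; NULL returns the ggplot object without
#'   writing.
#' @param width,height,dpi Device size passed to [ggplot2::ggsave()].
#' @return The ggplot object, invisibly.
#' @export
render_sart_full <- function(model, path = NULL, width = 10, height = 6,
                             dpi = 150) {
  gg <- sart_ggplot(model, thresholded = FALSE)
  if (!is.null(path))
    ggplot2::ggsave(path, gg, width = width, height = height, dpi = dpi)
  invisible(gg)
}

#' Render the thresholded ("big spots only") visualisation
#'
#' As [render_sart_full()], but restricted to the big spots, with the
#' overlay curves limited to participants who have at least one big spot.
#' A model without big spots produces a warning and an empty plot; the
#' file is still written.
#'
#' @inheritParams render_sart_full
#' @return The ggplot object, invisibly.
#' @export
render_sart_thresholded <- function(model, path = NULL, width = 10,
                                    height = 6, dpi = 150) {
  gg <- sart_ggplot(model, thresholded = TRUE)
  if (!is.null(path))
    suppressWarnings(ggplot2::ggsave(path, gg, width = width,
                                     height = height, dpi = dpi))
  invisible(gg)
}
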