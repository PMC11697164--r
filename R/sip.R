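# Single-cell stable-isotope probing: enrichment calls against 0-h
# controls, isotope-based growth (Ka), per-cell assimilation rates,
# depth summaries and region-integrated rates.

#' Baseline isotope ratio from 0-h control cells
#'
#' Computes the unlabeled baseline (sample mean and n-1 standard
#' deviation of the ion ratio) from the 0-h cells of one site/substrate
#' group. Cells are later called enriched when their ratio exceeds
#' `mean + 2 * sd` (strictly).
#'
#' @param rois Data frame of ROI measurements with columns `site`,
#'   `substrate`, `timepoint_h` and the ratio column for `isotope`
#'   (`ratio_15N` or `ratio_13C`).
#' @param site,substrate Group selectors.
#' @param isotope `"15N"` or `"13C"`.
#' @return A list of class `control_baseline` with `site`, `substrate`,
#'   `isotope`, `mean_ratio`, `sd_ratio`, `n_cells`.
#' @export
compute_baseline <- function(rois, site, substrate, isotope = c("15N", "13C")) {
  isotope <- match.arg(isotope)
  col <- if (isotope == "15N") "ratio_15N" else "ratio_13C"
  sel <- rois$site == site & rois$substrate == substrate &
    rois$timepoint_h == 0 & !is.na(rois[[col]])
  ratios <- rois[[col]][sel]
  if (length(ratios) < 2) {
    stop(sprintf(
      "insufficient baseline: %d 0-h cell(s) for site=%s substrate=%s isotope=%s (need >= 2)",
      length(ratios), site, substrate, isotope
    ))
  }
  check_nonneg(ratios, col)
  structure(
    list(
      site = site, substrate = substrate, isotope = isotope,
      mean_ratio = mean(ratios), sd_ratio = stats::sd(ratios),
      n_cells = length(ratios)
    ),
    class = "control_baseline"
  )
}

#' Call isotopic enrichment of cells against a control baseline
#'
#' A cell is enriched iff its ion ratio is strictly greater than the 0-h
#' mean plus two standard deviations.
#'
#' @param ratio Numeric vector of measured ion ratios.
#' @param baseline A [compute_baseline()] result.
#' @return Logical vector.
#' @export
call_enrichment <- function(ratio, baseline) {
  stopifnot(inherits(baseline, "control_baseline"))
  ratio > baseline$mean_ratio + 2 * baseline$sd_ratio
}

#' Isotope-based growth coefficient Ka
#'
#' Linear isotope mass balance: the fraction of a cell's initial elemental
#' content replaced by substrate-derived atoms per day,
#' `Ka = (x_cell - x0) / ((x_sub - x0) * t)` with `t` in days. Negative
#' excess (measurement noise below baseline) is clamped to 0 with a
#' warning; the cell stays in denominator counts downstream.
#'
#' @param x_cell Measured atom fraction(s) of the cell(s).
#' @param x0 Baseline (unlabeled) atom fraction.
#' @param x_sub Labeled atom fraction of the substrate pool
#'   ([substrate_label_fraction()]).
#' @param t_h Incubation duration in hours.
#' @return Ka in per day.
#' @export
compute_ka <- function(x_cell, x0, x_sub, t_h) {
  if (x_sub <= x0) stop("no label contrast: x_sub must exceed the baseline x0")
  stopifnot(t_h > 0)
  ka <- (x_cell - x0) / ((x_sub - x0) * (t_h / 24))
  if (any(ka < 0)) {
    warning(sprintf("%d cell(s) with negative atom-fraction excess; Ka clamped to 0",
                    sum(ka < 0)))
    ka[ka < 0] <- 0
  }
  ka
}

#' Single-cell elemental assimilation rate
#'
#' Converts Ka (per day) and the cell's elemental content (fg N or fg C
#' per cell) into an hourly assimilation rate:
#' `rate = Ka * content / 24` in fg per cell per hour.
#'
#' @param ka_per_day Ka value(s) from [compute_ka()].
#' @param cell_content_fg Elemental content per cell in femtograms. The
#'   default (10 fg N) is a placeholder typical of small marine
#'   prokaryotes and should be set from study-specific biomass data.
#' @return Rate(s) in fg element per cell per hour.
#' @export
assimilation_rate <- function(ka_per_day, cell_content_fg = 10) {
  stopifnot(all(ka_per_day >= 0), cell_content_fg >= 0)
  ka_per_day * cell_content_fg / 24
}

#' Per-cell SIP results for a full ROI table
#'
#' For each site/substrate group: builds the 0-h baseline, converts ratios
#' of the labeled-timepoint cells to atom fractions, calls enrichment,
#' and computes Ka and the assimilation rate for every analyzed cell.
#'
#' @param rois ROI table with columns `roi_id`, `site`, `depth_m`,
#'   `substrate`, `timepoint_h`, `ratio_15N` (and optionally `ratio_13C`).
#' @param ctx A [labeling_context()], or a named list of contexts keyed by
#'   substrate (e.g. `list(urea = ..., ammonium = ...)`).
#' @param cell_content_fg Elemental content per cell (fg).
#' @param isotope `"15N"` or `"13C"`.
#' @return Data frame of per-cell results (labeled timepoints only) with
#'   the computed `atom_fraction`, `atom_fraction_excess`, `enriched`,
#'   `ka_per_day` and `rate_fg_per_cell_h`; the per-group baselines are
#'   attached as attribute `"baselines"`.
#' @export
sip_cell_rates <- function(rois, ctx, cell_content_fg = 10,
                           isotope = c("15N", "13C")) {
  isotope <- match.arg(isotope)
  col <- if (isotope == "15N") "ratio_15N" else "ratio_13C"
  to_x <- if (isotope == "15N") ratio15N_to_atom_fraction else ratio13C_to_atom_fraction
  stopifnot(is.data.frame(rois), col %in% names(rois))

  groups <- unique(rois[, c("site", "substrate")])
  out <- vector("list", nrow(groups))
  baselines <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    site <- groups$site[i]
    substrate <- groups$substrate[i]
    cctx <- if (inherits(ctx, "labeling_context")) ctx else ctx[[substrate]]
    if (is.null(cctx)) stop("no labeling context for substrate ", substrate)
    bl <- compute_baseline(rois, site, substrate, isotope)
    baselines[[i]] <- bl
    sub <- rois[rois$site == site & rois$substrate == substrate &
                  rois$timepoint_h > 0 & !is.na(rois[[col]]), , drop = FALSE]
    if (nrow(sub) == 0) next
    x_cell <- to_x(sub[[col]])
    x0 <- to_x(bl$mean_ratio)
    x_sub <- substrate_label_fraction(cctx)
    ka <- suppressWarnings(compute_ka(x_cell, x0, x_sub, sub$timepoint_h))
    out[[i]] <- data.frame(
      roi_id = sub$roi_id, site = site, depth_m = sub$depth_m,
      substrate = substrate, timepoint_h = sub$timepoint_h,
      ratio = sub[[col]],
      atom_fraction = x_cell,
      atom_fraction_excess = x_cell - x0,
      enriched = call_enrichment(sub[[col]], bl),
      ka_per_day = ka,
      rate_fg_per_cell_h = assimilation_rate(ka, cell_content_fg),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no labeled-timepoint cells in the ROI table")
  rownames(res) <- NULL
  attr(res, "baselines") <- baselines
  res
}

#' Per-depth SIP summary
#'
#' Proportion of enriched cells and mean Ka / mean assimilation rate among
#' the enriched cells for every site/depth/substrate group. The mean rate
#' is reported as `NA` where no cell is enriched.
#'
#' @param cells Per-cell results from [sip_cell_rates()].
#' @return Data frame with one row per site/depth/substrate:
#'   `pct_enriched`, `mean_rate_enriched`, `mean_ka_enriched`, `n_cells`.
#' @export
summarize_depths <- function(cells) {
  stopifnot(is.data.frame(cells), nrow(cells) > 0)
  key <- interaction(cells$site, cells$depth_m, cells$substrate, drop = TRUE)
  rows <- lapply(split(cells, key), function(g) {
    enr <- g[g$enriched, , drop = FALSE]
    data.frame(
      site = g$site[1], depth_m = g$depth_m[1], substrate = g$substrate[1],
      pct_enriched = 100 * nrow(enr) / nrow(g),
      mean_rate_enriched = if (nrow(enr)) mean(enr$rate_fg_per_cell_h) else NA_real_,
      mean_ka_enriched = if (nrow(enr)) mean(enr$ka_per_day) else NA_real_,
      n_cells = nrow(g),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$site, res$substrate, res$depth_m), , drop = FALSE]
}

#' Depth-region bounds (meters below surface)
#'
#' Epipelagic 0-200 m, mesopelagic 200-1000 m, bathypelagic 1000-4500 m;
#' assignment uses half-open intervals `[lower, upper)`.
#' @export
region_bounds <- c(0, 200, 1000, 4500)

#' Assign a depth to a pelagic region
#'
#' @param depth_m Depth(s) in meters below surface.
#' @param bounds Region boundary vector (4 increasing values).
#' @return Character vector: `"epipelagic"`, `"mesopelagic"` or
#'   `"bathypelagic"`; depths outside all regions are an error.
#' @export
assign_region <- function(depth_m, bounds = region_bounds) {
  stopifnot(length(bounds) == 4, !is.unsorted(bounds, strictly = TRUE))
  labs <- c("epipelagic", "mesopelagic", "bathypelagic")
  idx <- findInterval(depth_m, bounds, rightmost.closed = FALSE)
  if (any(idx < 1 | idx > 3 | depth_m >= bounds[4])) {
    stop("depth(s) outside the 0-4500 m region bounds: ",
         paste(depth_m[idx < 1 | idx > 3 | depth_m >= bounds[4]], collapse = ", "))
  }
  labs[idx]
}

#' Region-integrated assimilation rates
#'
#' Per depth, volumetric rate = cell density x fraction enriched x mean
#' per-cell rate of enriched cells (fg per liter per hour); per region,
#' total rate = arithmetic mean of the volumetric rates of the sampled
#' depths in that region x region volume.
#'
#' @param summaries Depth summaries from [summarize_depths()] (one
#'   substrate at a time).
#' @param cell_density Data frame with columns `depth_m`, `cells_per_L`.
#' @param region_volume_L Named vector of region volumes in liters
#'   (`epipelagic`, `mesopelagic`, `bathypelagic`).
#' @param bounds Region boundary depths.
#' @return Data frame with one row per region: `volumetric_rate_fg_L_h`
#'   (region mean) and `total_rate_fg_h`; regions with no sampled depth
#'   are `NA` with a warning.
#' @export
integrate_regions <- function(summaries, cell_density, region_volume_L,
                              bounds = region_bounds) {
  stopifnot(is.data.frame(summaries), is.data.frame(cell_density),
            all(c("depth_m", "cells_per_L") %in% names(cell_density)))
  labs <- c("epipelagic", "mesopelagic", "bathypelagic")
  stopifnot(all(labs %in% names(region_volume_L)))
  dens <- cell_density$cells_per_L[match(summaries$depth_m, cell_density$depth_m)]
  if (any(is.na(dens))) {
    stop("missing cell density for depth(s): ",
         paste(summaries$depth_m[is.na(dens)], collapse = ", "))
  }
  rate <- ifelse(summaries$pct_enriched == 0, 0, summaries$mean_rate_enriched)
  vol_rate <- dens * (summaries$pct_enriched / 100) * rate
  region <- assign_region(summaries$depth_m, bounds)
  res <- data.frame(
    region = labs,
    volumetric_rate_fg_L_h = NA_real_,
    total_rate_fg_h = NA_real_,
    n_depths = 0L,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(labs)) {
    sel <- region == labs[i]
    if (!any(sel)) {
      warning("no sampled depth in region ", labs[i])
      next
    }
    res$volumetric_rate_fg_L_h[i] <- mean(vol_rate[sel])
    res$total_rate_fg_h[i] <- mean(vol_rate[sel]) * region_volume_L[[labs[i]]]
    res$n_depths[i] <- sum(sel)
  }
  res
}

#' Compare single-cell rates between substrates
#'
#' Two-sided unpaired Wilcoxon rank-sum test on per-cell assimilation
#' rates from two incubations. Cells in separate incubations cannot be
#' paired, so the unpaired form is used.
#'
#' @param rates_a,rates_b Numeric vectors of per-cell rates (n >= 3 each).
#' @return List with `statistic` (W for the first sample), `p_value` and
#'   `significant` (p < 0.05). Fully tied degenerate samples give p = 1
#'   with a warning.
#' @export
compare_substrates <- function(rates_a, rates_b) {
  stopifnot(length(rates_a) >= 3, length(rates_b) >= 3)
  if (length(unique(c(rates_a, rates_b))) == 1) {
    warning("all observations tied; reporting p = 1")
    return(list(statistic = length(rates_a) * length(rates_b) / 2,
                p_value = 1, significant = FALSE))
  }
  wt <- suppressWarnings(stats::wilcox.test(rates_a, rates_b,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       significant = wt$p.value < 0.05)
}
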