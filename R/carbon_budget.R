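# Nitrification-fueled carbon-fixation budget vs gravitational POC flux.

#' Carbon export efficiency from sea-surface temperature
#'
#' `e_eff = 0.23 * exp(-0.08 * SST)`: the fraction of net primary
#' production exported as sinking particulate organic carbon from the
#' euphotic zone, strictly decreasing in SST.
#'
#' @param sst_C Sea-surface temperature(s) in degrees Celsius.
#' @return Export efficiency (fraction).
#' @examples
#' export_efficiency(0)   # 0.23
#' export_efficiency(10)  # ~0.103
#' @export
export_efficiency <- function(sst_C) {
  0.23 * exp(-0.08 * sst_C)
}

#' Gravitational POC flux at the base of the euphotic zone
#'
#' Net primary production times export efficiency.
#'
#' @param npp_mgC_m2_d Net primary production in mg C m^-2 d^-1 (>= 0).
#' @param e_eff Export efficiency (fraction).
#' @return POC flux in mg C m^-2 d^-1.
#' @export
poc_flux <- function(npp_mgC_m2_d, e_eff) {
  check_nonneg(npp_mgC_m2_d, "npp_mgC_m2_d")
  npp_mgC_m2_d * e_eff
}

#' Chemoautotrophic carbon fixation from a nitrification rate
#'
#' 1 nmol N L^-1 d^-1 is 1 umol N m^-3 d^-1; with a fixation yield of
#' `yield` mol C per mol N oxidized, fixation is
#' `rate * yield * 12.011` ug C m^-3 d^-1.
#'
#' @param rate_nmolN_L_d Nitrification rate(s), nmol N L^-1 d^-1 (>= 0).
#' @param yield_molC_per_molN DIC fixation yield (default 0.09).
#' @return Volumetric fixation in ug C m^-3 d^-1.
#' @export
nitrification_to_cfix <- function(rate_nmolN_L_d, yield_molC_per_molN = 0.09) {
  check_nonneg(rate_nmolN_L_d, "rate_nmolN_L_d")
  stopifnot(yield_molC_per_molN > 0)
  rate_nmolN_L_d * yield_molC_per_molN * 12.011
}

#' Depth-integrate a volumetric rate profile
#'
#' Trapezoidal integration of a volumetric rate (ug C m^-3 d^-1) against
#' depth between `z_top` and `z_bottom`, with constant extrapolation from
#' the nearest measured depth to each bound; the result is converted to
#' mg C m^-2 d^-1.
#'
#' @param depth_m Strictly increasing measurement depths (m).
#' @param rate_ugC_m3_d Volumetric rates at those depths.
#' @param z_top,z_bottom Integration bounds in meters (`z_top < z_bottom`).
#' @return Areal rate in mg C m^-2 d^-1.
#' @export
integrate_column <- function(depth_m, rate_ugC_m3_d, z_top = 100,
                             z_bottom = 3000) {
  stopifnot(length(depth_m) == length(rate_ugC_m3_d), length(depth_m) >= 1,
            z_top < z_bottom)
  if (is.unsorted(depth_m, strictly = TRUE)) stop("depths must be strictly increasing")
  # constant extrapolation to the bounds
  z <- depth_m
  r <- rate_ugC_m3_d
  if (min(z) > z_top) { z <- c(z_top, z); r <- c(r[1], r) }
  if (max(z) < z_bottom) { z <- c(z, z_bottom); r <- c(r, r[length(r)]) }
  keep <- z >= z_top & z <= z_bottom
  # add interpolated points exactly at the bounds if interior points straddle them
  zi <- z[keep]
  ri <- r[keep]
  if (zi[1] > z_top) {
    ri <- c(stats::approx(z, r, xout = z_top)$y, ri)
    zi <- c(z_top, zi)
  }
  if (zi[length(zi)] < z_bottom) {
    ri <- c(ri, stats::approx(z, r, xout = z_bottom)$y)
    zi <- c(zi, z_bottom)
  }
  if (length(zi) < 2) stop("profile does not span the integration bounds")
  integral_ug_m2 <- sum(diff(zi) * (utils::head(ri, -1) + utils::tail(ri, -1)) / 2)
  integral_ug_m2 / 1000
}

#' Fixation as a percentage of the POC flux
#'
#' @param cfix_mgC_m2_d Integrated fixation, mg C m^-2 d^-1.
#' @param poc_mgC_m2_d Gravitational POC flux, mg C m^-2 d^-1 (> 0).
#' @return Percentage (not rounded; the reporting layer rounds to the
#'   nearest integer percent).
#' @export
percent_of_poc <- function(cfix_mgC_m2_d, poc_mgC_m2_d) {
  if (any(poc_mgC_m2_d <= 0)) stop("POC flux must be > 0")
  100 * cfix_mgC_m2_d / poc_mgC_m2_d
}

#' Nitrification-fueled carbon budget for one site
#'
#' End-to-end budget: converts a depth profile of total nitrification
#' (ammonia- plus urea-based, summed per depth; non-detected rates enter
#' as 0) into volumetric DIC fixation, integrates it over the dark water
#' column, estimates the gravitational POC flux from NPP and SST, and
#' reports fixation as a percentage of that flux.
#'
#' @param nitrif_profile Data frame with columns `depth_m`, `rate_nh3`,
#'   `rate_urea` (nmol N L^-1 d^-1; `NA` treated as 0).
#' @param sst_C Sea-surface temperature (deg C).
#' @param npp_mgC_m2_d Net primary production (mg C m^-2 d^-1).
#' @param z_top_m,z_bottom_m Dark-column integration bounds (m).
#' @param yield_molC_per_molN DIC fixation yield (mol C per mol N).
#' @return Object of class `carbon_budget` with `e_eff`,
#'   `poc_flux_mgC_m2_d`, `cfix_mgC_m2_d`, `pct_of_poc` and
#'   `pct_of_poc_reported` (nearest integer percent).
#' @export
carbon_budget <- function(nitrif_profile, sst_C, npp_mgC_m2_d,
                          z_top_m = 100, z_bottom_m = 3000,
                          yield_molC_per_molN = 0.09) {
  stopifnot(is.data.frame(nitrif_profile),
            all(c("depth_m", "rate_nh3", "rate_urea") %in% names(nitrif_profile)))
  prof <- nitrif_profile[order(nitrif_profile$depth_m), , drop = FALSE]
  total <- ifelse(is.na(prof$rate_nh3), 0, prof$rate_nh3) +
    ifelse(is.na(prof$rate_urea), 0, prof$rate_urea)
  cfix_vol <- nitrification_to_cfix(total, yield_molC_per_molN)
  cfix <- integrate_column(prof$depth_m, cfix_vol, z_top_m, z_bottom_m)
  eff <- export_efficiency(sst_C)
  poc <- poc_flux(npp_mgC_m2_d, eff)
  pct <- percent_of_poc(cfix, poc)
  structure(
    list(
      e_eff = eff, poc_flux_mgC_m2_d = poc, cfix_mgC_m2_d = cfix,
      pct_of_poc = pct, pct_of_poc_reported = round(pct),
      z_top_m = z_top_m, z_bottom_m = z_bottom_m,
      yield_molC_per_molN = yield_molC_per_molN
    ),
    class = "carbon_budget"
  )
}

#' @export
print.carbon_budget <- function(x, ...) {
  cat(sprintf(
    paste0("Carbon budget (%g-%g m):\n",
           "  export efficiency      %.4f\n",
           "  POC flux               %.4g mg C m^-2 d^-1\n",
           "  integrated DIC fixation %.4g mg C m^-2 d^-1\n",
           "  fixation / POC flux    %.2f%% (reported %d%%)\n"),
    x$z_top_m, x$z_bottom_m, x$e_eff, x$poc_flux_mgC_m2_d,
    x$cfix_mgC_m2_d, x$pct_of_poc, x$pct_of_poc_reported
  ))
  invisible(x)
}
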