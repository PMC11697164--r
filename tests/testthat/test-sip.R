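make_roi <- function(ratios0, ratios_t, site = "S", substrate = "urea",
                     depth = 500, t_h = 72) {
  n0 <- length(ratios0)
  nt <- length(ratios_t)
  data.frame(
    roi_id = paste0("c", seq_len(n0 + nt)),
    site = site, depth_m = depth, substrate = substrate,
    timepoint_h = c(rep(0, n0), rep(t_h, nt)),
    ratio_15N = c(ratios0, ratios_t),
    stringsAsFactors = FALSE
  )
}

test_that("baseline uses sample mean and n-1 standard deviation", {
  roi <- make_roi(c(0.003, 0.003, 0.003), numeric(0))
  bl <- compute_baseline(roi, "S", "urea")
  expect_equal(bl$mean_ratio, 0.003)
  expect_equal(bl$sd_ratio, 0)
  expect_equal(bl$n_cells, 3)

  roi2 <- make_roi(c(0.002, 0.004), numeric(0))
  bl2 <- compute_baseline(roi2, "S", "urea")
  expect_equal(bl2$mean_ratio, 0.003)
  expect_equal(bl2$sd_ratio, sqrt(((0.002 - 0.003)^2 + (0.004 - 0.003)^2) / 1))

  expect_error(compute_baseline(make_roi(0.003, numeric(0)), "S", "urea"),
               "insufficient baseline")
  expect_error(compute_baseline(roi, "other_site", "urea"),
               "insufficient baseline")
})

test_that("enrichment call is strictly above mean + 2 sd", {
  bl <- structure(list(mean_ratio = 0.003, sd_ratio = 0.0005),
                  class = "control_baseline")
  expect_false(call_enrichment(0.003 + 2 * 0.0005, bl))
  expect_true(call_enrichment(0.003 + 2.01 * 0.0005, bl))
  expect_false(call_enrichment(0.0029, bl))
})

test_that("Ka follows the linear mass balance and clamps negative excess", {
  expect_equal(compute_ka(0.0037, 0.0037, 0.49, 72), 0)
  # full labeling in one day
  expect_equal(compute_ka(0.49, 0.0037, 0.49, 24), 1)
  expect_equal(compute_ka(0.0525, 0.0037, 0.49183, 72),
               (0.0525 - 0.0037) / ((0.49183 - 0.0037) * 3))
  expect_warning(ka <- compute_ka(0.0030, 0.0037, 0.49, 72), "clamped")
  expect_equal(ka, 0)
  expect_error(compute_ka(0.01, 0.5, 0.4, 72), "label contrast")
  # homogeneity: scaling both excesses by a common factor leaves Ka fixed
  x0 <- 0.004; xs <- 0.5; xc <- 0.05
  k1 <- compute_ka(xc, x0, xs, 72)
  f <- 0.37
  k2 <- compute_ka(x0 + f * (xc - x0), x0, x0 + f * (xs - x0), 72)
  expect_equal(k1, k2, tolerance = 1e-12)
})

test_that("assimilation rate converts Ka and cell content to fg per hour", {
  expect_equal(assimilation_rate(0, 10), 0)
  expect_equal(assimilation_rate(1, 24), 1)
  expect_equal(assimilation_rate(0.03333, 10), 0.03333 * 10 / 24)
})

test_that("depth summaries report percent enriched and enriched-only means", {
  cells <- data.frame(
    roi_id = paste0("c", 1:10), site = "S", depth_m = 500,
    substrate = "urea", timepoint_h = 72, ratio = 0.01,
    atom_fraction = 0.01, atom_fraction_excess = 0.005,
    enriched = c(rep(TRUE, 9), FALSE),
    ka_per_day = c(rep(0.05, 9), 0),
    rate_fg_per_cell_h = c(rep(0.02, 9), 0),
    stringsAsFactors = FALSE
  )
  s <- summarize_depths(cells)
  expect_equal(s$pct_enriched, 90)
  expect_equal(s$mean_rate_enriched, 0.02)
  expect_equal(s$mean_ka_enriched, 0.05)
  expect_equal(s$n_cells, 10)

  cells$enriched <- FALSE
  s0 <- summarize_depths(cells)
  expect_equal(s0$pct_enriched, 0)
  expect_true(is.na(s0$mean_rate_enriched))
})

test_that("region integration multiplies density, enriched fraction and volume", {
  summ <- data.frame(site = "S", depth_m = 500, substrate = "urea",
                     pct_enriched = 50, mean_rate_enriched = 0.01,
                     mean_ka_enriched = 0.05, n_cells = 10,
                     stringsAsFactors = FALSE)
  dens <- data.frame(depth_m = 500, cells_per_L = 1e5)
  vols <- c(epipelagic = 1, mesopelagic = 1e3, bathypelagic = 1)
  # unsampled regions (epi, bathy here) warn and come back as NA
  w <- capture_warnings(res <- integrate_regions(summ, dens, vols))
  expect_match(w, "no sampled depth", all = TRUE)
  expect_length(w, 2)
  expect_true(all(is.na(res$total_rate_fg_h[res$region != "mesopelagic"])))
  meso <- res[res$region == "mesopelagic", ]
  expect_equal(meso$total_rate_fg_h, 1e5 * 0.5 * 0.01 * 1e3)  # 500 fg/h
  # doubling the region volume doubles the total
  res2 <- suppressWarnings(integrate_regions(summ, dens, vols * 2))
  expect_equal(res2$total_rate_fg_h[res2$region == "mesopelagic"],
               2 * meso$total_rate_fg_h)
  # nothing enriched anywhere -> zero totals
  summ$pct_enriched <- 0
  summ$mean_rate_enriched <- NA_real_
  res0 <- suppressWarnings(integrate_regions(summ, dens, vols))
  expect_equal(res0$total_rate_fg_h[res0$region == "mesopelagic"], 0)
})

test_that("depths map to half-open pelagic regions and reject out-of-range", {
  expect_equal(assign_region(c(0, 199.9, 200, 999, 1000, 4499)),
               c("epipelagic", "epipelagic", "mesopelagic", "mesopelagic",
                 "bathypelagic", "bathypelagic"))
  expect_error(assign_region(4500), "outside")
  expect_error(assign_region(-5), "outside")
})

test_that("substrate comparison matches the exact rank-sum enumeration", {
  a <- c(1, 2, 3); b <- c(101, 102, 103)
  res <- compare_substrates(a, b)
  expect_equal(res$statistic, 0)      # W for the first sample, fully separated
  expect_equal(res$p_value, 0.1)      # minimal two-sided p for n = 3, 3
  expect_equal(res$p_value, oracle_ranksum_p(a, b))
  # symmetry under swapping
  expect_equal(compare_substrates(b, a)$p_value, res$p_value)
  # degenerate fully tied samples
  expect_warning(tied <- compare_substrates(rep(1, 4), rep(1, 4)), "tied")
  expect_equal(tied$p_value, 1)
})
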