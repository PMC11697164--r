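test_that("ROI simulator is deterministic and respects its edge cases", {
  p <- sip_sim_params(n_cells_per_depth = 100, frac_active = 0.5, seed = 7)
  t1 <- simulate_roi_table(p)
  t2 <- simulate_roi_table(p)
  expect_identical(t1, t2)
  expect_true(all(t1$ratio_15N >= 0))
  expect_true(all(t1$timepoint_h %in% c(0, p$incubation_h)))
  expect_error(simulate_roi_table(sip_sim_params(n_cells_per_depth = 0)),
               "n_cells_per_depth")
})

test_that("inactive communities are indistinguishable from the 0-h baseline", {
  p <- sip_sim_params(n_cells_per_depth = 400, frac_active = 0, seed = 21)
  roi <- simulate_roi_table(p)
  r0 <- roi$ratio_15N[roi$timepoint_h == 0]
  rt <- roi$ratio_15N[roi$timepoint_h > 0]
  # same distribution: two-sample test should be unremarkable
  expect_gt(suppressWarnings(wilcox.test(r0, rt)$p.value), 1e-3)
  expect_lt(abs(mean(rt) - mean(r0)), 4 * sd(r0) / sqrt(length(r0)))
})

test_that("saturating Ka drives cells to the substrate label fraction", {
  p <- sip_sim_params(n_cells_per_depth = 200, frac_active = 1,
                      ka_mean = 100, ka_sd = 1, baseline_cv = 0.001,
                      substrate = "urea", seed = 5)
  roi <- simulate_roi_table(p)
  x_sub <- substrate_label_fraction(labeling_context(
    p$amendment_nM, p$label_purity, p$ambient_nM, n_per_molecule = 2))
  x_t <- ratio15N_to_atom_fraction(roi$ratio_15N[roi$timepoint_h > 0])
  expect_equal(mean(x_t), x_sub, tolerance = 0.01)
})

test_that("incubation simulator grows excess linearly and reproducibly", {
  p0 <- nitrif_sim_params(true_rate = 0, noise_sd_delta = 0, seed = 3)
  flat <- simulate_incubation_series(p0)
  expect_equal(var(flat$delta15N_NOx_permil), 0, tolerance = 1e-18)

  p <- nitrif_sim_params(true_rate = 10, noise_sd_delta = 0, seed = 3)
  ser <- simulate_incubation_series(p)
  x0 <- ratio15N_to_atom_fraction(isotope_constants[["r_std_15N"]])
  exc <- excess_15N(delta15N_to_atom_fraction(ser$delta15N_NOx_permil),
                    x0, ser$nox_uM)
  e24 <- exc[ser$timepoint_h == 24][1]
  e72 <- exc[ser$timepoint_h == 72][1]
  expect_equal(e72, 3 * e24, tolerance = 1e-6)

  pn <- nitrif_sim_params(seed = 9)
  expect_identical(simulate_incubation_series(pn),
                   simulate_incubation_series(pn))
  bad <- nitrif_sim_params()
  bad$nox_uM <- 0
  expect_error(simulate_incubation_series(bad), "nox_uM")
})

test_that("coverage simulator plants recoverable carriage and taxonomy", {
  expect_error(
    simulate_gene_coverage(local({
      q <- metag_sim_params(); q$library_reads <- 0; q
    })),
    "library_reads"
  )
  # no carriers -> no ureC reads
  mg0 <- simulate_gene_coverage(metag_sim_params(frac_ureC = 0, seed = 2))
  expect_equal(sum(mg0$coverage$mapped_reads[mg0$coverage$gene == "ureC"]), 0)
  # full carriage at single copy with equal lengths: symmetric expectations
  mg1 <- simulate_gene_coverage(metag_sim_params(
    frac_ureC = 1, ureC_copy_mean = 1,
    gene_length_bp = c(ureC = 1000, recA = 1000), seed = 2))
  nU <- sum(mg1$coverage$mapped_reads[mg1$coverage$gene == "ureC"])
  nR <- sum(mg1$coverage$mapped_reads[mg1$coverage$gene == "recA"])
  expect_equal(nU / nR, 1, tolerance = 0.05)
  # determinism
  pm <- metag_sim_params(seed = 13)
  a <- simulate_gene_coverage(pm)
  b <- simulate_gene_coverage(pm)
  expect_identical(a, b)
  expect_true(all(a$coverage$mapped_reads >= 0))
  expect_true(all(a$coverage$breadth >= 0 & a$coverage$breadth <= 1))
  # planted contig taxonomy is recovered by the consensus caller
  hit <- a$contigs[1, ]
  cons <- contig_consensus_taxonomy(strsplit(hit$gene_taxa, "|", fixed = TRUE)[[1]])
  expect_true(startsWith(cons, strsplit(hit$true_taxon, ";")[[1]][1]))
})

test_that("demo fixtures write a complete, reloadable dataset", {
  dir <- withr::local_tempdir()
  paths <- write_demo_fixtures(dir, seed = 4)
  expect_true(all(file.exists(paths)))
  roi <- read_tsv(paths[["roi"]])
  expect_setequal(unique(roi$site), c("Slope", "OpenOcean"))
  expect_setequal(unique(roi$substrate), c("urea", "ammonium"))
  expect_equal(length(unique(roi$depth_m)), 7)
  val <- validate_inputs(list(
    roi = roi,
    incubation = read_tsv(paths[["incubation"]]),
    gene_coverage = read_tsv(paths[["gene_coverage"]]),
    contig_hits = read_tsv(paths[["contig_hits"]]),
    cell_density = read_tsv(paths[["cell_density"]])
  ))
  expect_equal(nrow(val), 0)
})
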