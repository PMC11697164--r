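test_that("RPKM normalizes by gene kilobases and library millions", {
  expect_equal(rpkm(1000, 1000, 1e6), 1000)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(250, 2000, 5e7), 2.5)
  # brute-force oracle on a random grid
  set.seed(4)
  reads <- rpois(20, 500)
  len <- sample(300:3000, 20)
  lib <- sample(1e6:1e8, 20)
  expect_equal(rpkm(reads, len, lib),
               reads * 1e9 / (as.numeric(len) * as.numeric(lib)),
               tolerance = 1e-12)
  # invariant to exact library subsampling
  expect_equal(rpkm(reads / 2, len, lib / 2), rpkm(reads, len, lib))
  expect_error(rpkm(10, 0, 1e6), "> 0")
  expect_error(rpkm(10, 1000, 0), "> 0")
})

test_that("marker ratios and copy-corrected prevalence behave as quotients", {
  expect_equal(marker_ratio(5, 5), 1)
  expect_equal(marker_ratio(0, 20), 0)
  expect_equal(marker_ratio(9, 20), 0.45)
  expect_error(marker_ratio(9, 0), "undefined")
  expect_equal(as.numeric(prevalence_from_ratio(1.1, 1.1)), 1)
  expect_equal(as.numeric(prevalence_from_ratio(0.45, 1.1)), 0.45 / 1.1)
  expect_equal(as.numeric(prevalence_from_ratio(0)), 0)
  over <- prevalence_from_ratio(1.6, 1.1)
  expect_true(attr(over, "flagged"))
  expect_gt(as.numeric(over), 1)  # retained, not clipped
  expect_error(prevalence_from_ratio(0.5, 0), "> 0")
})

test_that("per-sample prevalence sums genes across contigs before the ratio", {
  cov <- data.frame(
    sample_id = "s1",
    gene = c("ureC", "ureC", "recA", "amoA"),
    contig_id = c("c1", "c2", "c3", "c4"),
    mapped_reads = c(100, 80, 200, 50),
    gene_length_bp = c(1700, 1700, 1050, 750),
    library_mapped_reads = 1e6,
    stringsAsFactors = FALSE
  )
  res <- sample_prevalence(cov, copy_number = 1.1)
  r_ureC <- (100 + 80) / 1.7
  r_recA <- 200 / 1.05
  expect_equal(res$ratio_ureC_recA, r_ureC / r_recA)
  expect_equal(res$prevalence_ureC, r_ureC / r_recA / 1.1)
  expect_equal(res$ratio_amoA_recA, (50 / 0.75) / r_recA)
  cov_norec <- cov[cov$gene != "recA", ]
  expect_error(sample_prevalence(cov_norec), "recA")
})

test_that("contig consensus taxonomy walks ranks by strict majority", {
  nitro <- "Archaea;Nitrososphaerota;Nitrososphaeria"
  proteo <- "Bacteria;Proteobacteria;Gammaproteobacteria"
  expect_equal(contig_consensus_taxonomy(rep(nitro, 4)), nitro)
  expect_equal(contig_consensus_taxonomy(c(rep(nitro, 3), proteo)), nitro)
  # 2 vs 2 at domain: no strict majority anywhere
  expect_equal(contig_consensus_taxonomy(c(nitro, nitro, proteo, proteo)),
               "unclassified")
  # 2 vs 2 at phylum under a shared domain stops at the domain
  tie <- c("Bacteria;Proteobacteria", "Bacteria;Proteobacteria",
           "Bacteria;Nitrospinota", "Bacteria;Nitrospinota")
  expect_equal(contig_consensus_taxonomy(tie), "Bacteria")
  expect_equal(contig_consensus_taxonomy(character(0)), "unclassified")
  # order invariance
  genes <- c(rep(nitro, 3), proteo, "Bacteria;Chloroflexota")
  set.seed(1)
  for (i in 1:5) {
    expect_equal(contig_consensus_taxonomy(sample(genes)),
                 contig_consensus_taxonomy(genes))
  }
})

test_that("ureC taxon composition filters contigs and normalizes coverage", {
  contigs <- data.frame(
    contig_id = c("c1", "c2", "c3"),
    coverage = c(30, 10, 100),
    breadth = c(0.9, 0.8, 0.4),
    length_bp = c(5000, 4000, 8000),
    taxonomy = c("Archaea;Nitrososphaerota", "Bacteria;Proteobacteria",
                 "Bacteria;Chloroflexota"),
    stringsAsFactors = FALSE
  )
  res <- ureC_taxon_relabund(contigs)
  expect_equal(sum(res$fraction), 1, tolerance = 1e-9)
  expect_equal(res$fraction[res$taxonomy == "Archaea;Nitrososphaerota"], 0.75)
  expect_equal(res$fraction[res$taxonomy == "Bacteria;Proteobacteria"], 0.25)
  # the breadth-0.4 contig is out of numerator and denominator alike
  expect_false("Bacteria;Chloroflexota" %in% res$taxonomy)
  expect_equal(res, ureC_taxon_relabund(contigs[contigs$breadth >= 0.5, ]))
  # single passing contig carries fraction 1
  one <- ureC_taxon_relabund(contigs[1, ])
  expect_equal(one$fraction, 1)
  expect_warning(none <- ureC_taxon_relabund(contigs[3, ]), "no contig")
  expect_equal(nrow(none), 0)
})

test_that("depth trend ANOVA matches the closed-form F and handles degeneracy", {
  vals <- c(1.2, 1.4, 1.1, 2.3, 2.5, 2.2, 3.3, 3.6, 3.1)
  grp <- rep(c("epi", "meso", "bathy"), each = 3)
  res <- depth_trend_test(vals, grp)
  expect_equal(res$F, oracle_anova_F(vals, grp), tolerance = 1e-9)
  expect_lt(res$p_value, 0.05)
  expect_equal(nrow(res$tukey), 3)
  # separation with tiny jitter drives p toward 0
  set.seed(2)
  sep <- depth_trend_test(c(rep(1, 3), rep(2, 3)) + rnorm(6, 0, 1e-6),
                          rep(c("a", "b"), each = 3))
  expect_lt(sep$p_value, 1e-6)
  # constant response
  expect_warning(flat <- depth_trend_test(rep(2, 6), rep(c("a", "b"), each = 3)),
                 "zero variance")
  expect_equal(flat$p_value, 1)
  # undersized groups are excluded
  expect_warning(
    dropped <- depth_trend_test(vals[1:7], c(grp[1:6], "solo")),
    "excluding"
  )
  expect_equal(dropped$n_groups, 2)
  expect_error(
    suppressWarnings(depth_trend_test(c(1, 2, 3), c("a", "a", "b"))),
    ">= 2 regions"
  )
})
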