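# Synthetic-data generators for every input family the pipeline
# consumes: nanoSIMS ROI tables, 15N-NOx incubation series and
# metagenome gene-coverage / contig-hit tables. Defaults mirror the
# study conditions (50 nM amendments, 98%/99% label purity, 72 h
# incubations, 0/24/72 h sampling, duplicate bottles, 1.1 ureC copies
# per carrier genome).

#' Parameters for the single-cell SIP simulator
#'
#' @param n_cells_per_depth Cells analyzed per depth and timepoint.
#' @param frac_active Fraction of cells assimilating the substrate.
#' @param ka_mean,ka_sd Mean and sd (per day) of the lognormal Ka
#'   distribution of active cells; inactive cells have Ka = 0.
#' @param baseline_ratio_15N Natural-abundance ion ratio.
#' @param baseline_cv Coefficient of variation of the ratio measurement
#'   (Gaussian on the ratio scale).
#' @param substrate `"urea"` or `"ammonium"`.
#' @param amendment_nM Label amendment (nmol molecules per liter).
#' @param label_purity 15N atom fraction of the label; defaults to 0.98
#'   for urea and 0.99 for ammonium.
#' @param ambient_nM Ambient substrate concentration.
#' @param incubation_h Incubation duration (hours).
#' @param depths_m Depths simulated (one ROI set each).
#' @param site Site label.
#' @param seed Integer seed; fixed seed gives byte-identical tables.
#' @return A list of class `sip_sim_params`.
#' @export
sip_sim_params <- function(n_cells_per_depth = 100, frac_active = 0.5,
                           ka_mean = 0.05, ka_sd = 0.02,
                           baseline_ratio_15N = isotope_constants[["r_std_15N"]],
                           baseline_cv = 0.05,
                           substrate = c("urea", "ammonium"),
                           amendment_nM = 50,
                           label_purity = NULL,
                           ambient_nM = 50,
                           incubation_h = 72,
                           depths_m = 500,
                           site = "SiteA",
                           seed = 1L) {
  substrate <- match.arg(substrate)
  if (is.null(label_purity)) {
    label_purity <- if (substrate == "urea") 0.98 else 0.99
  }
  stopifnot(
    frac_active >= 0, frac_active <= 1,
    ka_mean >= 0, ka_sd >= 0,
    baseline_ratio_15N > 0, baseline_cv >= 0,
    amendment_nM >= 0, ambient_nM >= 0,
    label_purity >= 0, label_purity <= 1,
    incubation_h > 0
  )
  structure(as.list(environment()), class = "sip_sim_params")
}

# lognormal meanlog/sdlog from a target mean and sd
lognormal_pars <- function(mean, sd) {
  if (mean <= 0) return(c(meanlog = -Inf, sdlog = 0))
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate a nanoSIMS ROI table
#'
#' For each depth: 0-h control cells drawn around the natural-abundance
#' baseline ratio, and labeled-timepoint cells where a `frac_active`
#' subset carries a lognormal Ka. Cell atom fractions are obtained by
#' inverting the linear Ka mass balance
#' (`x = x0 + Ka * (x_sub - x0) * t`), capped at the substrate label
#' fraction, and converted back to ion ratios with additive Gaussian
#' measurement noise.
#'
#' @param params A [sip_sim_params()] object.
#' @return ROI data frame with columns `roi_id`, `site`, `depth_m`,
#'   `substrate`, `timepoint_h`, `ratio_15N`, `ratio_13C` (`NA` for
#'   ammonium incubations) and the hidden truth columns `true_active`,
#'   `true_ka` used by recovery tests.
#' @export
simulate_roi_table <- function(params) {
  stopifnot(inherits(params, "sip_sim_params"))
  p <- params
  if (p$n_cells_per_depth == 0) stop("n_cells_per_depth must be >= 1")
  set.seed(p$seed)

  n_per <- if (p$substrate == "urea") 2 else 1
  ctx <- labeling_context(
    amendment_nM = p$amendment_nM, label_purity = p$label_purity,
    ambient_nM = p$ambient_nM, incubation_h = p$incubation_h,
    n_per_molecule = n_per
  )
  x_sub <- substrate_label_fraction(ctx)
  x0 <- ratio15N_to_atom_fraction(p$baseline_ratio_15N)
  noise_sd <- p$baseline_cv * p$baseline_ratio_15N
  lp <- lognormal_pars(p$ka_mean, p$ka_sd)

  rows <- lapply(p$depths_m, function(depth) {
    n <- p$n_cells_per_depth
    # 0-h controls
    r0 <- pmax(stats::rnorm(n, p$baseline_ratio_15N, noise_sd), 0)
    # labeled timepoint
    active <- stats::runif(n) < p$frac_active
    ka <- ifelse(active & p$ka_mean > 0,
                 stats::rlnorm(n, lp["meanlog"], lp["sdlog"]), 0)
    x_cell <- pmin(x0 + ka * (x_sub - x0) * (p$incubation_h / 24), x_sub)
    rt <- pmax(atom_fraction_to_ratio15N(x_cell) + stats::rnorm(n, 0, noise_sd), 0)
    # 13C channel for dual-labeled urea (1 C atom, 99% 13C label)
    r13 <- if (p$substrate == "urea") {
      ctx13 <- labeling_context(
        amendment_nM = p$amendment_nM, label_purity = 0.99,
        ambient_nM = p$ambient_nM,
        natural_atom_fraction = isotope_constants[["x_nat_13C"]],
        incubation_h = p$incubation_h, n_per_molecule = 1
      )
      x_sub13 <- substrate_label_fraction(ctx13)
      x13nat <- isotope_constants[["x_nat_13C"]]
      x13 <- pmin(x13nat + ka * (x_sub13 - x13nat) * (p$incubation_h / 24), x_sub13)
      r13_noise <- p$baseline_cv * atom_fraction_to_ratio13C(x13nat)
      pmax(atom_fraction_to_ratio13C(x13) + stats::rnorm(n, 0, r13_noise), 0)
    } else rep(NA_real_, n)
    r13_0 <- if (p$substrate == "urea") {
      x13nat <- isotope_constants[["x_nat_13C"]]
      pmax(atom_fraction_to_ratio13C(x13nat) +
             stats::rnorm(n, 0, p$baseline_cv * atom_fraction_to_ratio13C(x13nat)), 0)
    } else rep(NA_real_, n)
    data.frame(
      roi_id = sprintf("%s_d%g_%s_%03d", p$site, depth,
                       rep(c("t0", "t1"), each = n), c(seq_len(n), seq_len(n))),
      site = p$site, depth_m = depth, substrate = p$substrate,
      timepoint_h = rep(c(0, p$incubation_h), each = n),
      ratio_15N = c(r0, rt),
      ratio_13C = c(r13_0, r13),
      true_active = c(rep(FALSE, n), active),
      true_ka = c(rep(0, n), ka),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Parameters for the nitrification incubation simulator
#'
#' @param true_rate Total N oxidation rate, nmol N L^-1 d^-1.
#' @param nox_uM Ambient NOx concentration (umol L^-1, > 0).
#' @param timepoints_h Sampling times, strictly increasing from 0.
#' @param n_replicates Incubation bottles.
#' @param noise_sd_delta Gaussian measurement noise on delta-15N (per
#'   mil); 0.2 reflects typical denitrifier-method precision.
#' @param substrate_label_fraction Labeled fraction of the substrate
#'   pool feeding NOx production.
#' @param site,depth_m,substrate Series labels.
#' @param seed Integer seed.
#' @return A list of class `nitrif_sim_params`.
#' @export
nitrif_sim_params <- function(true_rate = 16, nox_uM = 30,
                              timepoints_h = c(0, 24, 72),
                              n_replicates = 2, noise_sd_delta = 0.2,
                              substrate_label_fraction = 0.4918315,
                              site = "SiteA", depth_m = 150,
                              substrate = "ammonium", seed = 1L) {
  stopifnot(
    true_rate >= 0,
    length(timepoints_h) >= 2, timepoints_h[1] == 0,
    !is.unsorted(timepoints_h, strictly = TRUE),
    n_replicates >= 1, noise_sd_delta >= 0,
    substrate_label_fraction > 0, substrate_label_fraction <= 1
  )
  structure(as.list(environment()), class = "nitrif_sim_params")
}

#' Simulate a 15N-NOx incubation time series
#'
#' Excess 15N-NOx grows linearly at `true_rate * substrate_label_fraction`
#' nmol 15N L^-1 d^-1; measured delta-15N values are back-computed from
#' the implied atom fractions with additive Gaussian noise, independent
#' across replicates and timepoints.
#'
#' @param params A [nitrif_sim_params()] object.
#' @return Data frame with columns `site`, `depth_m`, `substrate`,
#'   `replicate_id`, `timepoint_h`, `delta15N_NOx_permil`, `nox_uM`.
#' @export
simulate_incubation_series <- function(params) {
  stopifnot(inherits(params, "nitrif_sim_params"))
  p <- params
  if (p$nox_uM <= 0) stop("nox_uM must be > 0 (delta undefined otherwise)")
  set.seed(p$seed)
  x0 <- ratio15N_to_atom_fraction(isotope_constants[["r_std_15N"]])
  grid <- expand.grid(replicate_id = seq_len(p$n_replicates),
                      timepoint_h = p$timepoints_h)
  t_d <- grid$timepoint_h / 24
  excess <- p$true_rate * p$substrate_label_fraction * t_d
  x_t <- x0 + excess / (p$nox_uM * 1000)
  delta <- atom_fraction_to_delta15N(x_t) +
    stats::rnorm(nrow(grid), 0, p$noise_sd_delta)
  out <- data.frame(
    site = p$site, depth_m = p$depth_m, substrate = p$substrate,
    replicate_id = paste0("rep", grid$replicate_id),
    timepoint_h = grid$timepoint_h,
    delta15N_NOx_permil = delta,
    nox_uM = p$nox_uM,
    stringsAsFactors = FALSE
  )
  out[order(out$replicate_id, out$timepoint_h), ]
}

#' Parameters for the metagenome coverage simulator
#'
#' @param n_genomes Genomes in the community.
#' @param frac_ureC Abundance-weighted fraction of cells carrying ureC.
#' @param ureC_copy_mean Average ureC copies per carrier genome (in
#'   `[1, 2]`; the abundance-weighted realized mean is matched to this).
#' @param gene_length_bp Named marker lengths in bp.
#' @param background_bp Non-marker assembled length per genome that
#'   absorbs the rest of the library.
#' @param library_reads Total mapped reads per sample.
#' @param depth_labels Sample labels (one library per label).
#' @param abund_sdlog Lognormal spread of genome abundances.
#' @param seed Integer seed.
#' @return A list of class `metag_sim_params`.
#' @export
metag_sim_params <- function(n_genomes = 200, frac_ureC = 0.39,
                             ureC_copy_mean = 1.1,
                             gene_length_bp = c(ureC = 1700, recA = 1050,
                                                amoA = 750),
                             background_bp = 20000,
                             library_reads = 1e6,
                             depth_labels = "s1",
                             abund_sdlog = 1,
                             seed = 1L) {
  stopifnot(
    n_genomes >= 1, frac_ureC >= 0, frac_ureC <= 1,
    ureC_copy_mean >= 1, ureC_copy_mean <= 2,
    all(gene_length_bp > 0), all(c("ureC", "recA") %in% names(gene_length_bp)),
    background_bp >= 0, abund_sdlog >= 0
  )
  structure(as.list(environment()), class = "metag_sim_params")
}

# pick a subset of indices whose weight share best matches `target`
# (greedy over decreasing weight); keeps planted fractions exact in
# abundance-weighted terms so recovery tests see read-sampling noise only
pick_weighted_subset <- function(w, target) {
  if (target <= 0) return(integer(0))
  share <- w / sum(w)
  ord <- order(share, decreasing = TRUE)
  acc <- 0
  keep <- logical(length(w))
  for (i in ord) {
    if (acc + share[i] <= target + 1e-12) {
      keep[i] <- TRUE
      acc <- acc + share[i]
    }
  }
  which(keep)
}

#' Simulate metagenome gene-coverage and contig-hit tables
#'
#' Builds a community of `n_genomes` genomes with lognormal abundances;
#' each genome carries one recA, ureC is planted on a subset chosen so
#' the abundance-weighted carrier fraction matches `frac_ureC` (and the
#' weighted mean copy number matches `ureC_copy_mean`), and amoA marks
#' the Nitrososphaerota genomes. Reads are drawn multinomially over
#' genes with weights abundance x length x copies.
#'
#' @param params A [metag_sim_params()] object.
#' @return List with `coverage` (per-gene mapping records) and `contigs`
#'   (per-contig gene-taxonomy hits for ureC-carrying contigs). Truth
#'   attributes `true_frac_ureC` and `true_copy_mean` record the
#'   realized abundance-weighted values.
#' @export
simulate_gene_coverage <- function(params) {
  stopifnot(inherits(params, "metag_sim_params"))
  p <- params
  if (p$library_reads <= 0) stop("library_reads must be > 0")
  set.seed(p$seed)

  taxa_pool <- c(
    "Archaea;Nitrososphaerota;Nitrososphaeria",
    "Bacteria;Proteobacteria;Gammaproteobacteria",
    "Bacteria;Verrucomicrobiota;Verrucomicrobiae",
    "Bacteria;Chloroflexota;Dehalococcoidia",
    "Bacteria;Nitrospinota;Nitrospinia",
    "Bacteria;Planctomycetota;Planctomycetia"
  )
  taxon <- sample(taxa_pool, p$n_genomes,
                  replace = TRUE, prob = c(0.3, 0.3, 0.1, 0.1, 0.1, 0.1))
  abund <- stats::rlnorm(p$n_genomes, 0, p$abund_sdlog)

  carriers <- pick_weighted_subset(abund, p$frac_ureC)
  copies <- integer(p$n_genomes)
  copies[carriers] <- 1L
  if (length(carriers) && p$ureC_copy_mean > 1) {
    two <- carriers[pick_weighted_subset(abund[carriers], p$ureC_copy_mean - 1)]
    copies[two] <- 2L
  }
  amoA_car <- grepl("Nitrososphaerota", taxon)

  read_len <- 150
  rows <- list()
  contig_rows <- list()
  for (s in p$depth_labels) {
    w_ureC <- abund * copies * p$gene_length_bp[["ureC"]]
    w_recA <- abund * p$gene_length_bp[["recA"]]
    w_amoA <- abund * as.numeric(amoA_car) *
      if ("amoA" %in% names(p$gene_length_bp)) p$gene_length_bp[["amoA"]] else 0
    w_bg <- abund * p$background_bp
    w <- c(w_ureC, w_recA, w_amoA, w_bg)
    counts <- as.vector(stats::rmultinom(1, p$library_reads, w))
    idx <- function(block) (block - 1) * p$n_genomes + seq_len(p$n_genomes)
    mk <- function(gene, len, cnt, sel) {
      if (!any(sel)) return(NULL)
      cov_depth <- cnt[sel] * read_len / len
      data.frame(
        sample_id = s, gene = gene,
        contig_id = sprintf("g%03d_ctg1", which(sel)),
        mapped_reads = cnt[sel], gene_length_bp = len,
        library_mapped_reads = p$library_reads,
        breadth = 1 - exp(-cov_depth),
        stringsAsFactors = FALSE
      )
    }
    rows[[s]] <- rbind(
      mk("ureC", p$gene_length_bp[["ureC"]], counts[idx(1)], copies > 0),
      mk("recA", p$gene_length_bp[["recA"]], counts[idx(2)],
         rep(TRUE, p$n_genomes)),
      if ("amoA" %in% names(p$gene_length_bp))
        mk("amoA", p$gene_length_bp[["amoA"]], counts[idx(3)], amoA_car),
      mk("other", p$background_bp, counts[idx(4)], rep(p$background_bp > 0,
                                                       p$n_genomes))
    )
    if (length(carriers)) {
      clen <- round(stats::runif(length(carriers), 4000, 20000))
      ureC_reads <- counts[idx(1)][carriers]
      cov_depth <- (ureC_reads + counts[idx(4)][carriers] *
                      pmin(1, clen / pmax(p$background_bp, 1))) * read_len / clen
      n_genes <- sample(3:6, length(carriers), replace = TRUE)
      gene_taxa <- vapply(seq_along(carriers), function(i) {
        tx <- rep(taxon[carriers[i]], n_genes[i])
        if (stats::runif(1) < 0.1) {  # occasional horizontally-acquired gene
          tx[n_genes[i]] <- sample(setdiff(taxa_pool, tx[1]), 1)
        }
        paste(tx, collapse = "|")
      }, character(1))
      contig_rows[[s]] <- data.frame(
        contig_id = sprintf("g%03d_ctg1", carriers),
        sample_id = s, length_bp = clen,
        gene_taxa = gene_taxa,
        coverage = cov_depth,
        breadth = 1 - exp(-pmax(cov_depth, 0)),
        true_taxon = taxon[carriers],
        stringsAsFactors = FALSE
      )
    }
  }
  coverage <- do.call(rbind, rows)
  contigs <- if (length(contig_rows)) do.call(rbind, contig_rows) else
    data.frame()
  rownames(coverage) <- NULL
  if (nrow(contigs)) rownames(contigs) <- NULL
  tot <- sum(abund)
  structure(
    list(coverage = coverage, contigs = contigs),
    true_frac_ureC = sum(abund[carriers]) / tot,
    true_copy_mean = if (length(carriers))
      sum(abund[carriers] * copies[carriers]) / sum(abund[carriers]) else NA_real_
  )
}

#' Write a small demo fixture dataset
#'
#' Generates and writes the complete set of input TSVs the pipeline
#' consumes: ROI tables for two sites and both substrates across seven
#' depths, incubation series, gene coverage/contig tables across depth
#' samples, and a cell-density profile.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_demo_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  depths <- c(50, 150, 500, 1000, 2000, 3000, 4000)
  rois <- list()
  k <- 0
  for (site in c("Slope", "OpenOcean")) {
    for (sub in c("urea", "ammonium")) {
      k <- k + 1
      rois[[k]] <- simulate_roi_table(sip_sim_params(
        n_cells_per_depth = 50, frac_active = 0.4, ka_mean = 0.05,
        ka_sd = 0.02, substrate = sub, depths_m = depths, site = site,
        seed = seed + k
      ))
    }
  }
  roi <- do.call(rbind, rois)
  roi$true_active <- NULL
  roi$true_ka <- NULL

  series <- list()
  k <- 0
  for (site in c("Slope", "OpenOcean")) {
    for (sub in c("urea", "ammonium")) {
      for (d in depths[-1]) {
        k <- k + 1
        rate <- if (d == 150) 14 else 2 * exp(-d / 2000) + 0.5
        series[[k]] <- simulate_incubation_series(nitrif_sim_params(
          true_rate = rate, nox_uM = 30, substrate = sub,
          site = site, depth_m = d, seed = seed + 100 + k
        ))
      }
    }
  }
  incub <- do.call(rbind, series)

  mg <- simulate_gene_coverage(metag_sim_params(
    n_genomes = 150, frac_ureC = 0.39, library_reads = 5e5,
    depth_labels = paste0("d", depths), seed = seed + 500
  ))

  dens <- data.frame(depth_m = depths,
                     cells_per_L = round(5e8 * exp(-depths / 900) + 1e7))

  paths <- c(
    roi = file.path(dir, "roi_measurements.tsv"),
    incubation = file.path(dir, "incubation_series.tsv"),
    gene_coverage = file.path(dir, "gene_coverage.tsv"),
    contig_hits = file.path(dir, "contig_hits.tsv"),
    cell_density = file.path(dir, "cell_density.tsv")
  )
  write_tsv(roi, paths[["roi"]])
  write_tsv(incub, paths[["incubation"]])
  write_tsv(mg$coverage, paths[["gene_coverage"]])
  write_tsv(mg$contigs, paths[["contig_hits"]])
  write_tsv(dens, paths[["cell_density"]])
  invisible(paths)
}
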