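# Pipeline orchestration: config handling, input validation, stage
# execution and report assembly.

#' Write and read tab-separated tables
#'
#' Thin wrappers fixing the dialect used throughout the pipeline: one
#' header line, tab separator, no quoting or row names.
#'
#' @param x Data frame.
#' @param path File path.
#' @return `read_tsv()` returns a data frame; `write_tsv()` its path,
#'   invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Default pipeline constants
#'
#' Study constants the analysis relies on, overridable through the
#' `constants` block of the pipeline config: label purities, natural
#' abundances, the ureC copy-number correction (1.1), the DIC fixation
#' yield (0.09 mol C per mol N), the placeholder cellular N content,
#' region bounds and the detection alpha.
#'
#' @return Named list of constants.
#' @export
default_constants <- function() {
  list(
    amendment_nM = 50,
    label_purity_urea_15N = 0.98,
    label_purity_ammonium_15N = 0.99,
    ambient_nM = 50,
    natural_atom_fraction_15N = isotope_constants[["x_nat_15N"]],
    incubation_h = 72,
    cell_content_fg_N = 10,
    copy_number_ureC = 1.1,
    yield_molC_per_molN = 0.09,
    region_bounds_m = c(0, 200, 1000, 4500),
    region_volume_L = c(epipelagic = 1e18, mesopelagic = 4e18,
                        bathypelagic = 1.5e19),
    alpha = 0.05,
    nox_floor_uM = 0.5,
    z_top_m = 100,
    z_bottom_m = 3000,
    sst_C = 10,
    npp_mgC_m2_d = 500
  )
}

#' Validate pipeline input tables
#'
#' Checks schema and invariants of any subset of the four input tables
#' and reports violations with row numbers, distinguishing warnings from
#' errors.
#'
#' @param tables Named list with any of `roi`, `incubation`,
#'   `gene_coverage`, `contig_hits`, `cell_density` (data frames).
#' @return Data frame with columns `table`, `row`, `severity`,
#'   `message`; zero rows when everything is clean.
#' @export
validate_inputs <- function(tables) {
  out <- list()
  add <- function(table, row, severity, message) {
    out[[length(out) + 1]] <<- data.frame(
      table = table, row = row, severity = severity, message = message,
      stringsAsFactors = FALSE
    )
  }
  need <- function(tbl, name, cols) {
    miss <- setdiff(cols, names(tbl))
    if (length(miss)) {
      add(name, NA_integer_, "error",
          paste("missing column(s):", paste(miss, collapse = ", ")))
      return(FALSE)
    }
    TRUE
  }
  flag_rows <- function(tbl, name, bad, msg, severity = "error") {
    for (i in which(bad)) add(name, i, severity, msg)
  }

  if (!is.null(tables$roi)) {
    tbl <- tables$roi
    if (need(tbl, "roi", c("roi_id", "site", "depth_m", "substrate",
                           "timepoint_h", "ratio_15N"))) {
      flag_rows(tbl, "roi", !is.na(tbl$ratio_15N) & tbl$ratio_15N < 0,
                "negative ratio_15N")
      flag_rows(tbl, "roi", tbl$timepoint_h < 0, "negative timepoint_h")
      flag_rows(tbl, "roi", !tbl$substrate %in% c("urea", "ammonium"),
                "unknown substrate", "warning")
    }
  }
  if (!is.null(tables$incubation)) {
    tbl <- tables$incubation
    if (need(tbl, "incubation", c("site", "depth_m", "substrate",
                                  "replicate_id", "timepoint_h",
                                  "delta15N_NOx_permil", "nox_uM"))) {
      flag_rows(tbl, "incubation",
                !is.na(tbl$delta15N_NOx_permil) & tbl$delta15N_NOx_permil <= -1000,
                "delta15N <= -1000 per mil")
      flag_rows(tbl, "incubation",
                !is.na(tbl$delta15N_NOx_permil) &
                  (is.na(tbl$nox_uM) | tbl$nox_uM <= 0),
                "nox_uM must be > 0 where delta is reported")
    }
  }
  if (!is.null(tables$gene_coverage)) {
    tbl <- tables$gene_coverage
    if (need(tbl, "gene_coverage", c("sample_id", "gene", "mapped_reads",
                                     "gene_length_bp", "library_mapped_reads"))) {
      flag_rows(tbl, "gene_coverage", tbl$mapped_reads < 0, "negative read count")
      flag_rows(tbl, "gene_coverage", tbl$gene_length_bp <= 0,
                "non-positive gene length")
      if ("breadth" %in% names(tbl)) {
        flag_rows(tbl, "gene_coverage",
                  !is.na(tbl$breadth) & (tbl$breadth < 0 | tbl$breadth > 1),
                  "breadth outside [0, 1]")
      }
    }
  }
  if (!is.null(tables$contig_hits)) {
    tbl <- tables$contig_hits
    if (need(tbl, "contig_hits", c("contig_id", "sample_id", "length_bp",
                                   "coverage", "breadth"))) {
      flag_rows(tbl, "contig_hits", tbl$breadth < 0 | tbl$breadth > 1,
                "breadth outside [0, 1]")
      flag_rows(tbl, "contig_hits", tbl$coverage < 0, "negative coverage")
    }
  }
  if (!is.null(tables$cell_density)) {
    tbl <- tables$cell_density
    if (need(tbl, "cell_density", c("depth_m", "cells_per_L"))) {
      flag_rows(tbl, "cell_density", tbl$cells_per_L < 0, "negative cell density")
    }
  }
  if (length(out) == 0) {
    return(data.frame(table = character(0), row = integer(0),
                      severity = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  constants <- utils::modifyList(default_constants(), config$constants %||% list())
  rv <- constants$region_volume_L
  if (!is.null(names(rv))) constants$region_volume_L <- unlist(rv)
  constants$region_bounds_m <- unlist(constants$region_bounds_m)
  list(inputs = config$inputs %||% list(),
       constants = constants,
       output_dir = config$output_dir %||% "darksip_out",
       seed = config$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_or_generate <- function(spec, seed, kind) {
  if (is.character(spec)) return(read_tsv(spec))
  if (is.list(spec) && identical(spec$synthetic, TRUE)) {
    args <- spec[setdiff(names(spec), "synthetic")]
    if (is.null(args$seed)) args$seed <- seed
    switch(kind,
      roi = simulate_roi_table(do.call(sip_sim_params, args)),
      incubation = simulate_incubation_series(do.call(nitrif_sim_params, args)),
      metagenome = simulate_gene_coverage(do.call(metag_sim_params, args)),
      stop("no generator for input kind ", kind)
    )
  } else {
    stop("input '", kind, "' must be a file path or a synthetic block")
  }
}

#' Run the full analysis pipeline
#'
#' Executes generator (for `synthetic:` input blocks) then the SIP,
#' nitrification, gene-prevalence and carbon-budget stages, writes every
#' stage table as TSV to the output directory, and returns a report.
#' Reruns with the same config and seed are byte-identical.
#'
#' @param config Path to a YAML config file or an equivalent list, with
#'   blocks `inputs` (paths or `synthetic:` blocks for `roi`,
#'   `incubation`, `gene_coverage`, `contig_hits`, `cell_density`),
#'   `constants` (overrides of [default_constants()]), `output_dir` and
#'   `seed`.
#' @return Object of class `darksip_report`: list of stage tables,
#'   comparison summaries, and a provenance block (config hash, seed,
#'   package version).
#' @export
run_pipeline <- function(config) {
  cfg <- read_config(config)
  cst <- cfg$constants
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message("[darksip] ", sprintf(...))
  tables <- list()
  written <- character(0)
  emit <- function(x, name) {
    num <- vapply(x, is.numeric, logical(1))
    x[num] <- lapply(x[num], signif, digits = 6)
    p <- write_tsv(x, file.path(cfg$output_dir, paste0(name, ".tsv")))
    written <<- c(written, p)
    x
  }
  run_stage <- function(name, expr) {
    log_stage("stage %s", name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # ---- inputs ---------------------------------------------------------
  inp <- cfg$inputs
  roi <- if (!is.null(inp$roi)) run_stage("inputs",
    load_or_generate(inp$roi, cfg$seed, "roi"))
  incub <- if (!is.null(inp$incubation)) run_stage("inputs",
    load_or_generate(inp$incubation, cfg$seed + 1L, "incubation"))
  coverage <- contigs <- NULL
  if (!is.null(inp$metagenome)) {
    mg <- run_stage("inputs", load_or_generate(inp$metagenome, cfg$seed + 2L,
                                               "metagenome"))
    coverage <- mg$coverage
    contigs <- mg$contigs
  }
  if (!is.null(inp$gene_coverage)) coverage <- read_tsv(inp$gene_coverage)
  if (!is.null(inp$contig_hits)) contigs <- read_tsv(inp$contig_hits)
  density <- if (!is.null(inp$cell_density)) read_tsv(inp$cell_density)

  val <- validate_inputs(list(roi = roi, incubation = incub,
                              gene_coverage = coverage,
                              contig_hits = contigs, cell_density = density))
  if (any(val$severity == "error")) {
    stop("stage 'validate' failed: ", nrow(val), " input violation(s); ",
         "first: ", val$message[1], call. = FALSE)
  }

  # ---- sip ------------------------------------------------------------
  substrate_tests <- NULL
  if (!is.null(roi)) {
    cells <- run_stage("sip", {
      ctxs <- list(
        urea = labeling_context(cst$amendment_nM, cst$label_purity_urea_15N,
                                cst$ambient_nM, cst$natural_atom_fraction_15N,
                                cst$incubation_h, n_per_molecule = 2),
        ammonium = labeling_context(cst$amendment_nM,
                                    cst$label_purity_ammonium_15N,
                                    cst$ambient_nM,
                                    cst$natural_atom_fraction_15N,
                                    cst$incubation_h, n_per_molecule = 1)
      )
      suppressWarnings(sip_cell_rates(roi, ctxs, cst$cell_content_fg_N))
    })
    tables$sip_cells <- emit(cells, "sip_cells")
    tables$sip_depth_summary <- emit(summarize_depths(cells), "sip_depth_summary")
    if (!is.null(density)) {
      per_sub <- lapply(split(tables$sip_depth_summary,
                              tables$sip_depth_summary$substrate),
        function(s) {
          r <- suppressWarnings(
            integrate_regions(s, density, cst$region_volume_L,
                              cst$region_bounds_m))
          r$substrate <- s$substrate[1]
          r
        })
      tables$sip_region_integration <- emit(do.call(rbind, per_sub),
                                            "sip_region_integration")
    }
    # urea vs ammonium per site/depth where both measured
    key <- unique(cells[, c("site", "depth_m")])
    cmp <- lapply(seq_len(nrow(key)), function(i) {
      a <- cells$rate_fg_per_cell_h[cells$site == key$site[i] &
                                      cells$depth_m == key$depth_m[i] &
                                      cells$substrate == "urea"]
      b <- cells$rate_fg_per_cell_h[cells$site == key$site[i] &
                                      cells$depth_m == key$depth_m[i] &
                                      cells$substrate == "ammonium"]
      if (length(a) < 3 || length(b) < 3) return(NULL)
      res <- suppressWarnings(compare_substrates(a, b))
      data.frame(site = key$site[i], depth_m = key$depth_m[i],
                 statistic = res$statistic, p_value = res$p_value,
                 significant = res$significant, stringsAsFactors = FALSE)
    })
    cmp <- do.call(rbind, cmp)
    if (!is.null(cmp)) {
      substrate_tests <- emit(cmp, "sip_substrate_tests")
      tables$sip_substrate_tests <- substrate_tests
    }
  }

  # ---- nitrification --------------------------------------------------
  nitrif_results <- NULL
  if (!is.null(incub)) {
    nitrif_results <- run_stage("nitrif", {
      keep <- stats::aggregate(nox_uM ~ site + depth_m + substrate, incub, mean)
      keep <- keep[keep$nox_uM >= cst$nox_floor_uM, 1:3]
      rows <- lapply(seq_len(nrow(keep)), function(i) {
        ser <- incub[incub$site == keep$site[i] &
                       incub$depth_m == keep$depth_m[i] &
                       incub$substrate == keep$substrate[i], , drop = FALSE]
        n_per <- if (keep$substrate[i] == "urea") 2 else 1
        purity <- if (keep$substrate[i] == "urea")
          cst$label_purity_urea_15N else cst$label_purity_ammonium_15N
        x_sub <- substrate_label_fraction(labeling_context(
          cst$amendment_nM, purity, cst$ambient_nM,
          cst$natural_atom_fraction_15N, cst$incubation_h, n_per))
        fit <- fit_nitrification(ser, x_sub, alpha = cst$alpha)
        data.frame(site = keep$site[i], depth_m = keep$depth_m[i],
                   substrate = keep$substrate[i], rate = fit$rate,
                   stderr = fit$stderr, p_slope = fit$p_slope,
                   detected = fit$detected, n_points = fit$n_points,
                   replicate_rates = paste(signif(fit$replicate_rates, 6),
                                           collapse = ","),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
    tables$nitrification <- emit(nitrif_results, "nitrification_rates")
    # urea vs ammonium Welch t on replicate rates per site/depth
    key <- unique(nitrif_results[, c("site", "depth_m")])
    cmp <- lapply(seq_len(nrow(key)), function(i) {
      get_reps <- function(sub) {
        r <- nitrif_results$replicate_rates[
          nitrif_results$site == key$site[i] &
            nitrif_results$depth_m == key$depth_m[i] &
            nitrif_results$substrate == sub]
        if (length(r) != 1 || !nzchar(r)) return(numeric(0))
        as.numeric(strsplit(r, ",")[[1]])
      }
      a <- get_reps("urea"); b <- get_reps("ammonium")
      if (length(a) < 2 || length(b) < 2) return(NULL)
      res <- compare_rates(a, b)
      data.frame(site = key$site[i], depth_m = key$depth_m[i],
                 t = res$statistic, p_value = res$p_value,
                 indistinguishable = res$indistinguishable,
                 stringsAsFactors = FALSE)
    })
    cmp <- do.call(rbind, cmp)
    if (!is.null(cmp)) tables$nitrif_substrate_tests <-
      emit(cmp, "nitrif_substrate_tests")
  }

  # ---- genes ----------------------------------------------------------
  if (!is.null(coverage)) {
    prev <- run_stage("genes",
      sample_prevalence(coverage, cst$copy_number_ureC))
    tables$prevalence <- emit(prev, "gene_prevalence")
    if (!is.null(contigs) && nrow(contigs)) {
      comp <- lapply(split(contigs, contigs$sample_id), function(cg) {
        r <- suppressWarnings(ureC_taxon_relabund(cg))
        if (nrow(r)) r$sample_id <- cg$sample_id[1]
        r
      })
      comp <- do.call(rbind, comp[vapply(comp, nrow, 1L) > 0])
      if (!is.null(comp)) {
        rownames(comp) <- NULL
        tables$ureC_taxon_composition <- emit(comp, "ureC_taxon_composition")
      }
    }
  }

  # ---- budget ---------------------------------------------------------
  if (!is.null(nitrif_results)) {
    budget <- run_stage("budget", {
      wide <- stats::reshape(
        nitrif_results[, c("site", "depth_m", "substrate", "rate")],
        idvar = c("site", "depth_m"), timevar = "substrate",
        direction = "wide")
      names(wide) <- sub("^rate\\.", "rate_", names(wide))
      rows <- lapply(split(wide, wide$site), function(w) {
        prof <- data.frame(depth_m = w$depth_m,
                           rate_nh3 = w$rate_ammonium %||% 0,
                           rate_urea = w$rate_urea %||% 0)
        b <- carbon_budget(prof, cst$sst_C, cst$npp_mgC_m2_d,
                           cst$z_top_m, cst$z_bottom_m,
                           cst$yield_molC_per_molN)
        data.frame(site = w$site[1], e_eff = b$e_eff,
                   poc_flux_mgC_m2_d = b$poc_flux_mgC_m2_d,
                   cfix_mgC_m2_d = b$cfix_mgC_m2_d,
                   pct_of_poc = b$pct_of_poc,
                   pct_of_poc_reported = b$pct_of_poc_reported,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
    tables$carbon_budget <- emit(budget, "carbon_budget")
  }

  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg[c("inputs", "constants", "seed")], cfg_file)
  provenance <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = cfg$seed,
    version = as.character(utils::packageVersion("darksip")),
    files = written
  )
  unlink(cfg_file)
  structure(list(tables = tables, validation = val, provenance = provenance,
                 output_dir = cfg$output_dir),
            class = "darksip_report")
}

#' @export
print.darksip_report <- function(x, ...) {
  cat("darksip pipeline report\n")
  cat("  output dir:", x$output_dir, "\n")
  cat("  seed:", x$provenance$seed, " config hash:",
      x$provenance$config_hash, "\n")
  for (nm in names(x$tables)) {
    cat(sprintf("  %-24s %d rows\n", nm, nrow(x$tables[[nm]])))
  }
  invisible(x)
}
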