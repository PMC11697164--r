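# Marker-gene prevalence from metagenome coverage tables: RPKM,
# copy-number-corrected ureC/recA ratios, contig consensus taxonomy and
# taxon-level ureC community composition.

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = reads / (gene_length_bp / 1000) / (library_mapped_reads / 1e6)`.
#'
#' @param mapped_reads Read count(s) mapped to the gene.
#' @param gene_length_bp Gene length(s) in bp (> 0).
#' @param library_mapped_reads Total mapped reads in the library (> 0).
#' @return RPKM value(s).
#' @export
rpkm <- function(mapped_reads, gene_length_bp, library_mapped_reads) {
  if (any(gene_length_bp <= 0)) stop("gene_length_bp must be > 0")
  if (any(library_mapped_reads <= 0)) stop("library_mapped_reads must be > 0")
  check_nonneg(mapped_reads, "mapped_reads")
  mapped_reads / (gene_length_bp / 1000) / (library_mapped_reads / 1e6)
}

#' Marker-to-recA abundance ratio
#'
#' Quotient of RPKM values; per-sample gene RPKMs are summed across
#' contigs before division.
#'
#' @param rpkm_gene RPKM of the marker gene (contig-summed).
#' @param rpkm_recA RPKM of recA (> 0).
#' @return Dimensionless ratio.
#' @export
marker_ratio <- function(rpkm_gene, rpkm_recA) {
  if (any(rpkm_recA <= 0)) stop("recA RPKM absent or zero; ratio undefined")
  rpkm_gene / rpkm_recA
}

#' Fraction of cells carrying a gene, from its recA ratio
#'
#' Divides the gene/recA RPKM ratio by the average gene copy number per
#' genome (1.1 ureC genes per genome for ureC, from the study's MAG set;
#' recA is treated as strictly single-copy). Values above 1 are retained
#' but flagged: they signal copy-number or mapping artifacts.
#'
#' @param ratio Gene/recA RPKM ratio.
#' @param copy_number Average copies per carrier genome (> 0).
#' @return Numeric prevalence with attribute `flagged` (logical vector,
#'   `TRUE` where prevalence > 1).
#' @export
prevalence_from_ratio <- function(ratio, copy_number = 1.1) {
  if (copy_number <= 0) stop("copy_number must be > 0")
  prev <- ratio / copy_number
  attr(prev, "flagged") <- prev > 1
  prev
}

#' Per-sample marker prevalence from a gene coverage table
#'
#' Sums mapped reads and kilobases per gene within each sample, computes
#' contig-summed RPKMs, the ureC/recA and amoA/recA ratios, and the
#' copy-number-corrected ureC prevalence.
#'
#' @param coverage Data frame with columns `sample_id`, `gene`,
#'   `mapped_reads`, `gene_length_bp`, `library_mapped_reads` (and
#'   optionally `contig_id`, `breadth`).
#' @param copy_number Average ureC copies per carrier genome.
#' @param genes Marker genes to report ratios for (recA always included).
#' @return Data frame with one row per sample: `rpkm_<gene>` columns,
#'   `ratio_<gene>_recA` columns, `prevalence_ureC` and `flagged`.
#' @export
sample_prevalence <- function(coverage, copy_number = 1.1,
                              genes = c("ureC", "amoA")) {
  stopifnot(is.data.frame(coverage),
            all(c("sample_id", "gene", "mapped_reads", "gene_length_bp",
                  "library_mapped_reads") %in% names(coverage)))
  samples <- unique(coverage$sample_id)
  rows <- lapply(samples, function(s) {
    cv <- coverage[coverage$sample_id == s, , drop = FALSE]
    gene_rpkm <- function(g) {
      sub <- cv[cv$gene == g, , drop = FALSE]
      if (nrow(sub) == 0) return(0)
      sum(rpkm(sub$mapped_reads, sub$gene_length_bp, sub$library_mapped_reads))
    }
    r_recA <- gene_rpkm("recA")
    if (r_recA <= 0) stop("recA coverage absent in sample ", s, "; ratios undefined")
    row <- data.frame(sample_id = s, rpkm_recA = r_recA, stringsAsFactors = FALSE)
    for (g in genes) {
      rg <- gene_rpkm(g)
      row[[paste0("rpkm_", g)]] <- rg
      row[[paste0("ratio_", g, "_recA")]] <- marker_ratio(rg, r_recA)
    }
    prev <- prevalence_from_ratio(row$ratio_ureC_recA, copy_number)
    row$prevalence_ureC <- as.numeric(prev)
    row$flagged <- attr(prev, "flagged")
    row
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Contig consensus taxonomy by per-rank majority vote
#'
#' Walks the taxonomy ranks root to leaf; at each rank keeps the taxon
#' carried by strictly more than `majority_threshold` of the classified
#' genes and stops at the first rank with no majority. Ties therefore
#' truncate the path.
#'
#' @param gene_taxa Character vector of per-gene taxonomy paths,
#'   semicolon-delimited from domain downwards
#'   (e.g. `"Archaea;Nitrososphaerota;Nitrososphaeria"`).
#' @param majority_threshold Required majority fraction (default 0.5).
#' @return Consensus path as one semicolon-delimited string;
#'   `"unclassified"` when no gene is classified or no rank reaches a
#'   majority.
#' @export
contig_consensus_taxonomy <- function(gene_taxa, majority_threshold = 0.5) {
  gene_taxa <- gene_taxa[!is.na(gene_taxa) & nzchar(gene_taxa)]
  if (length(gene_taxa) == 0) return("unclassified")
  paths <- strsplit(gene_taxa, ";", fixed = TRUE)
  n <- length(paths)
  depth <- max(lengths(paths))
  consensus <- character(0)
  for (rank in seq_len(depth)) {
    taxa <- vapply(paths, function(p) if (length(p) >= rank) p[rank] else NA_character_,
                   character(1))
    tab <- table(taxa[!is.na(taxa)])
    if (length(tab) == 0) break
    top <- names(tab)[which.max(tab)]
    if (max(tab) / n <= majority_threshold) break
    # require consistency with the retained parent path
    ok <- !is.na(taxa) & taxa == top
    if (rank > 1) {
      parent_ok <- vapply(paths, function(p) {
        length(p) >= rank && identical(p[seq_len(rank - 1)], consensus)
      }, logical(1))
      ok <- ok & parent_ok
    }
    if (sum(ok) / n <= majority_threshold) break
    consensus <- c(consensus, top)
  }
  if (length(consensus) == 0) "unclassified" else paste(consensus, collapse = ";")
}

#' Taxon-level relative abundance of ureC-encoding contigs
#'
#' Restricts to contigs passing the breadth and length filters, assigns
#' each a consensus taxonomy, and divides the summed sequencing coverage
#' of each taxon's contigs by the total coverage of all passing contigs
#' in the sample. Fractions sum to 1.
#'
#' @param contigs Data frame with one row per contig: `contig_id`,
#'   `coverage`, `breadth`, `length_bp`, and `gene_taxa` (semicolon-
#'   delimited paths, multiple genes separated by `"|"`) or a
#'   pre-computed `taxonomy` column.
#' @param min_breadth Minimum breadth (fraction of positions covered).
#' @param min_length_bp Minimum contig length for the taxonomy set.
#' @param majority_threshold Consensus majority threshold.
#' @return Data frame `taxonomy`, `coverage`, `fraction`, sorted by
#'   decreasing fraction; empty (with a warning) when nothing passes.
#' @export
ureC_taxon_relabund <- function(contigs, min_breadth = 0.5,
                                min_length_bp = 3000,
                                majority_threshold = 0.5) {
  stopifnot(is.data.frame(contigs),
            all(c("coverage", "breadth", "length_bp") %in% names(contigs)))
  pass <- contigs$breadth >= min_breadth & contigs$length_bp >= min_length_bp
  sub <- contigs[pass, , drop = FALSE]
  if (nrow(sub) == 0) {
    warning("no contig passes the breadth/length filters")
    return(data.frame(taxonomy = character(0), coverage = numeric(0),
                      fraction = numeric(0), stringsAsFactors = FALSE))
  }
  tax <- if ("taxonomy" %in% names(sub)) {
    sub$taxonomy
  } else {
    vapply(strsplit(sub$gene_taxa, "|", fixed = TRUE),
           contig_consensus_taxonomy, character(1),
           majority_threshold = majority_threshold)
  }
  cov <- tapply(sub$coverage, tax, sum)
  res <- data.frame(taxonomy = names(cov), coverage = as.numeric(cov),
                    fraction = as.numeric(cov) / sum(cov),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$fraction), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Depth-region trend in marker ratios
#'
#' One-way ANOVA of per-sample gene/recA ratios across pelagic regions
#' with Tukey honest-significant-difference pairwise comparisons.
#' Regions with fewer than 2 samples are excluded with a warning; a
#' response with zero variance gives p = 1 with a warning.
#'
#' @param ratios Numeric vector of per-sample ratios.
#' @param regions Region label per sample.
#' @return List with `F`, `p_value`, `tukey` (data frame of pairwise
#'   contrasts with adjusted p-values) and `n_groups`.
#' @export
depth_trend_test <- function(ratios, regions) {
  stopifnot(length(ratios) == length(regions))
  keep <- !is.na(ratios) & !is.na(regions)
  ratios <- ratios[keep]
  regions <- as.character(regions[keep])
  counts <- table(regions)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning("excluding region(s) with < 2 samples: ", paste(small, collapse = ", "))
    sel <- !(regions %in% small)
    ratios <- ratios[sel]
    regions <- regions[sel]
  }
  if (length(unique(regions)) < 2) stop("need >= 2 regions with >= 2 samples each")
  if (stats::var(ratios) == 0) {
    warning("zero variance in ratios; reporting p = 1")
    return(list(F = 0, p_value = 1,
                tukey = data.frame(), n_groups = length(unique(regions))))
  }
  grp <- factor(regions)
  fit <- stats::aov(ratios ~ grp)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$grp
  list(
    F = an[["F value"]][1],
    p_value = an[["Pr(>F)"]][1],
    tukey = data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                       p_adj = tk[, "p adj"], row.names = NULL,
                       stringsAsFactors = FALSE),
    n_groups = nlevels(grp)
  )
}
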