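#' Default planted miRNA effects for the demonstration pipeline
#'
#' Encodes the study-scale effect structure: against the CRX/NRL reference,
#' one shRNA condition perturbs 35 miRNAs (14 up, 21 down) and the other 17
#' (4 up, 13 down), with exactly two miRNAs -- hsa-miR-654-3p and
#' hsa-miR-760 -- downregulated by both, and hsa-miR-452 downregulated only
#' in the second condition. Planted magnitudes are 2-fold (up) and 0.5-fold
#' (down).
#'
#' @param cond_a,cond_b the two shRNA condition labels.
#' @return data.frame(feature, condition, fc).
#' @export
default_mirna_effects <- function(cond_a = "shPias2_50",
                                  cond_b = "shPias2_49") {
  gen <- function(i) sprintf("mir-%04d", i)
  rbind(
    data.frame(feature = gen(15:28), condition = cond_a, fc = 2,
               stringsAsFactors = FALSE),
    data.frame(feature = c("hsa-miR-654-3p", "hsa-miR-760", gen(29:47)),
               condition = cond_a, fc = 0.5, stringsAsFactors = FALSE),
    data.frame(feature = gen(1:4), condition = cond_b, fc = 2,
               stringsAsFactors = FALSE),
    data.frame(feature = c("hsa-miR-654-3p", "hsa-miR-760", "hsa-miR-452",
                           gen(5:14)),
               condition = cond_b, fc = 0.5, stringsAsFactors = FALSE)
  )
}

# miRNA identifier pool for the demonstration run: three named species the
# integration stage tracks plus generic ids.
default_mirna_ids <- function(n_mirnas) {
  named <- c("hsa-miR-654-3p", "hsa-miR-760", "hsa-miR-452")
  c(named, sprintf("mir-%04d", seq_len(n_mirnas - length(named))))
}

#' Default planted gene effects for the demonstration pipeline
#'
#' 320 genes perturbed in the shRNA condition: 103 up (including ST8SIA2,
#' ZNF532 and the interferon-response genes IFIT1/IFIT2) and 217 down
#' (including the seven histone genes HIST1H4C, HIST1H4E, HIST1H4I,
#' HIST1H2AE, HIST1H2BJ, HIST1H2BK, HIST2H2AB and the five miR-452 targets
#' CCNT2, MXD1, PKN2, RANBP9, SKP1).
#'
#' @param condition the shRNA condition label.
#' @return data.frame(feature, condition, fc).
#' @export
default_gene_effects <- function(condition = "shPias2_49") {
  up_named <- c("ST8SIA2", "ZNF532", "IFIT1", "IFIT2")
  down_named <- c(histone_gene_names(),
                  c("CCNT2", "MXD1", "PKN2", "RANBP9", "SKP1"))
  up <- c(up_named, sprintf("geneUP%03d", seq_len(103 - length(up_named))))
  down <- c(down_named, sprintf("geneDN%03d", seq_len(217 - length(down_named))))
  rbind(
    data.frame(feature = up, condition = condition, fc = 2,
               stringsAsFactors = FALSE),
    data.frame(feature = down, condition = condition, fc = 0.5,
               stringsAsFactors = FALSE)
  )
}

histone_gene_names <- function() {
  c("HIST1H4C", "HIST1H4E", "HIST1H4I", "HIST1H2AE", "HIST1H2BJ",
    "HIST1H2BK", "HIST2H2AB")
}

# Gene universe for the demonstration run: planted DE genes, a histone
# family of `family_size` members (7 perturbed + synthetic non-DE members),
# and generic filler genes up to n_genes.
default_gene_ids <- function(n_genes, planted, family_size = 70) {
  extra_hist <- sprintf("HISTsyn%03d",
                        seq_len(family_size - length(histone_gene_names())))
  named <- unique(c(planted$feature, extra_hist))
  if (n_genes < length(named) + 1)
    stop_config("n_genes", "too small for the planted gene structure")
  c(named, sprintf("gene%05d", seq_len(n_genes - length(named))))
}

# Histone family annotation over the simulated gene universe.
default_family_annotation <- function(gene_ids) {
  hist <- c(histone_gene_names(), grep("^HISTsyn", gene_ids, value = TRUE))
  data.frame(gene = gene_ids,
             family = ifelse(gene_ids %in% hist, "histone", "other"),
             stringsAsFactors = FALSE)
}

# Predicted-target map mirroring the integration the pipeline demonstrates:
# miR-760 targets three of the planted histone genes (plus non-DE decoys),
# miR-452 targets the two planted up genes and five planted down genes.
default_target_map <- function() {
  list(
    "hsa-miR-760" = c("HIST1H2AE", "HIST1H2BJ", "HIST2H2AB",
                      "gene00001", "gene00002"),
    "hsa-miR-452" = c("ST8SIA2", "ZNF532", "CCNT2", "MXD1", "PKN2",
                      "RANBP9", "SKP1", "gene00003")
  )
}

#' Configuration for the end-to-end demonstration pipeline
#'
#' Validates and bundles every stage parameter: the miRNA simulation (see
#' [sim_config()]), the summarized gene-expression simulation, the two
#' differential-expression threshold pairs (miRNA: p < 0.05, |FC| > 1.1;
#' genes: p < 0.1, |FC| > 1.25), and the integration annotations.
#'
#' @param seed master integer seed; stage seeds are derived from it.
#' @param n_mirnas,n_genes feature counts (defaults 541 and 18000).
#' @param noise_cv,sample_cv count-level and per-sample CV of the miRNA run.
#' @param gene_noise_cv CV of the summarized gene matrix.
#' @param mirna_p,mirna_fc,gene_p,gene_fc calling thresholds.
#' @param conditions miRNA conditions (reference first, then the two shRNA
#'   conditions compared against it).
#' @param timepoints,gene_timepoints time labels of the two designs.
#' @param mirna_effects,gene_effects planted effect tables (defaults
#'   [default_mirna_effects()] / [default_gene_effects()]).
#' @param target_map named list miRNA -> target genes (default
#'   `default_target_map()`).
#' @param family_label family scored by the enrichment stage.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_mirnas = 541,
                            n_genes = 18000,
                            noise_cv = 0.05,
                            sample_cv = 0.1,
                            gene_noise_cv = 0.03,
                            mirna_p = 0.05, mirna_fc = 1.1,
                            gene_p = 0.1, gene_fc = 1.25,
                            conditions = c("crxnrl", "shPias2_49",
                                           "shPias2_50"),
                            timepoints = c("15h", "24h", "48h"),
                            gene_timepoints = c("15h", "48h"),
                            mirna_effects = NULL,
                            gene_effects = NULL,
                            target_map = NULL,
                            family_label = "histone") {
  assert_scalar_num(mirna_p, "mirna_p", lower = 0, strict = TRUE)
  assert_scalar_num(gene_p, "gene_p", lower = 0, strict = TRUE)
  assert_scalar_num(mirna_fc, "mirna_fc", lower = 1)
  assert_scalar_num(gene_fc, "gene_fc", lower = 1)
  if (length(conditions) != 3)
    stop_config("conditions", "must name a reference and two shRNA conditions")
  cfg <- list(
    seed = as.integer(seed), n_mirnas = n_mirnas, n_genes = n_genes,
    noise_cv = noise_cv, sample_cv = sample_cv, gene_noise_cv = gene_noise_cv,
    mirna_p = mirna_p, mirna_fc = mirna_fc, gene_p = gene_p, gene_fc = gene_fc,
    conditions = conditions, timepoints = timepoints,
    gene_timepoints = gene_timepoints,
    mirna_effects = mirna_effects %||%
      default_mirna_effects(conditions[3], conditions[2]),
    gene_effects = gene_effects %||% default_gene_effects(conditions[2]),
    target_map = target_map %||% default_target_map(),
    family_label = family_label
  )
  class(cfg) <- "pipeline_config"
  cfg
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the end-to-end demonstration pipeline on synthetic data
#'
#' Orchestrates the full workflow: simulate an nCounter-style miRNA run with
#' planted effects, calibrate it against the spike-in controls and globally
#' normalize, call paired differential expression for each shRNA condition
#' against the reference (p < 0.05, |FC| > 1.1), simulate and test the
#' summarized gene matrix (p < 0.1, |FC| > 1.25), then integrate: overlap of
#' the two miRNA DE sets, miRNA-target/DE-gene intersection and histone
#' family enrichment. Identical configurations reproduce identical outputs,
#' and every written file carries the seed and a configuration fingerprint.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, the normalized matrix, fit
#'   report, DE tables, target-pair list and a JSON report are written there.
#' @return object of class `pipeline_report` (a list of stage outputs and
#'   the summary counts).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (!inherits(config, "pipeline_config"))
    stop("`config` must come from pipeline_config()", call. = FALSE)
  ref <- config$conditions[1]
  sh_a <- config$conditions[2]
  sh_b <- config$conditions[3]

  m <- with_stage("simulate_ncounter", simulate_ncounter(sim_config(
    n_mirnas = config$n_mirnas, noise_cv = config$noise_cv,
    sample_cv = config$sample_cv, conditions = config$conditions,
    timepoints = config$timepoints, planted_fc = config$mirna_effects,
    mirna_ids = default_mirna_ids(config$n_mirnas), seed = config$seed
  )))
  nm <- with_stage("normalize", global_normalize(normalize_spikein(m)))

  de_a <- with_stage("diffexp_mirna", run_diffexp(
    nm, paired_design(nm$meta, ref, sh_a),
    p_thresh = config$mirna_p, fc_thresh = config$mirna_fc))
  de_b <- with_stage("diffexp_mirna", run_diffexp(
    nm, paired_design(nm$meta, ref, sh_b),
    p_thresh = config$mirna_p, fc_thresh = config$mirna_fc))

  ge <- with_stage("simulate_genes", simulate_expression_matrix(
    n_genes = config$n_genes, conditions = c(ref, sh_a),
    timepoints = config$gene_timepoints, planted_fc = config$gene_effects,
    noise_cv = config$gene_noise_cv,
    gene_ids = default_gene_ids(config$n_genes, config$gene_effects),
    seed = config$seed + 1L
  ))
  de_g <- with_stage("diffexp_genes", run_diffexp(
    ge, paired_design(ge$meta, ref, sh_a),
    p_thresh = config$gene_p, fc_thresh = config$gene_fc))

  set_a <- de_feature_set(de_a, sh_a)
  set_b <- de_feature_set(de_b, sh_b)
  set_g <- de_feature_set(de_g, paste0(sh_a, "_genes"))
  overlap <- with_stage("integration", set_overlap(set_a, set_b))
  mirna_union <- feature_set("mirna_union",
                             union(set_a$members, set_b$members),
                             c(set_a$direction,
                               set_b$direction[setdiff(names(set_b$direction),
                                                       names(set_a$direction))]))
  pairs <- with_stage("integration",
                      target_intersect(mirna_union, config$target_map, set_g))
  fam <- default_family_annotation(rownames(ge$values))
  enr <- with_stage("integration", family_enrichment(
    set_g, fam, config$family_label, background = config$n_genes))

  report <- structure(list(
    seed = config$seed,
    config_hash = config_fingerprint(unclass(config)),
    config = config,
    normalized = nm,
    de_mirna = stats::setNames(list(de_a, de_b), c(sh_a, sh_b)),
    de_genes = de_g,
    overlap = overlap,
    target_pairs = pairs,
    enrichment = enr,
    counts = list(
      mirna = stats::setNames(list(summary(de_a), summary(de_b)),
                              c(sh_a, sh_b)),
      genes = summary(de_g),
      overlap_n = overlap$n,
      overlap_concordant = overlap$concordant,
      n_target_pairs = nrow(pairs),
      family = enr[c("k", "n", "percent", "p")]
    )
  ), class = "pipeline_report")

  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report (seed", x$seed, ", config", x$config_hash, ")\n")
  for (nm in names(x$counts$mirna)) {
    s <- x$counts$mirna[[nm]]
    cat(sprintf("  miRNA DE %s vs %s: %d (%d up, %d down) of %d\n",
                nm, x$config$conditions[1], s$n_de, s$n_up, s$n_down,
                s$n_tested))
  }
  s <- x$counts$genes
  cat(sprintf("  gene DE: %d (%d up, %d down) of %d\n",
              s$n_de, s$n_up, s$n_down, s$n_tested))
  cat(sprintf("  miRNA DE-set overlap: %d (%d direction-concordant)\n",
              x$counts$overlap_n, x$counts$overlap_concordant))
  cat(sprintf("  miRNA-target DE pairs: %d\n", x$counts$n_target_pairs))
  f <- x$counts$family
  cat(sprintf("  %s family: %d/%d DE genes (%.2f%%), hypergeometric p = %.3g\n",
              x$config$family_label, f$k, f$n, f$percent, f$p))
  invisible(x)
}

# CSV writer with a provenance comment header (seed + config fingerprint).
write_with_provenance <- function(df, path, report) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# shrnaoff pipeline output; seed=%d; config=%s",
                     report$seed, report$config_hash), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_pipeline_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  nm <- report$normalized
  lin <- nm$values
  l2 <- nm$log2_values
  colnames(l2) <- paste0("log2_", colnames(l2))
  write_with_provenance(
    data.frame(feature_id = rownames(lin), lin, l2, check.names = FALSE),
    file.path(out_dir, "normalized_mirna.csv"), report)
  write_with_provenance(nm$fits, file.path(out_dir, "spikein_fits.csv"),
                        report)
  for (cond in names(report$de_mirna))
    write_with_provenance(as.data.frame(report$de_mirna[[cond]]),
                          file.path(out_dir, paste0("de_mirna_", cond, ".csv")),
                          report)
  write_with_provenance(as.data.frame(report$de_genes),
                        file.path(out_dir, "de_genes.csv"), report)
  write_with_provenance(report$target_pairs,
                        file.path(out_dir, "target_pairs.csv"), report)
  jsonlite::write_json(
    list(seed = report$seed, config_hash = report$config_hash,
         counts = report$counts),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
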