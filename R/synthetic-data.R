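#' Simulation configuration for an nCounter-style miRNA run
#'
#' Bundles every parameter of the synthetic hybridization-count generator.
#' The defaults emulate the study design the package targets: 541 expressed
#' miRNA species profiled across three transfection conditions (a CRX/NRL
#' reference and two shRNA co-transfections) at 15, 24 and 48 hours, with
#' four positive spike-in controls (POS_B..POS_E) on a four-fold dilution
#' ladder.
#'
#' Every probe count follows
#' `count = background + slope * conc * noise`,
#' where `noise` is multiplicative lognormal with mean 1 and coefficient of
#' variation `noise_cv`, and `slope`/`background` are perturbed per sample by
#' a shared lognormal hybridization-efficiency factor with CV `sample_cv`.
#' Spike-in probes use their nominal concentration; miRNA probes use
#' `conc_B + abundance`, i.e. planted abundances are expressed relative to
#' the POS_B calibration level, which is the scale the downstream
#' normalization `Ei = (Ri - B)/slope` measures (B is the fitted POS_B
#' signal). With `noise_cv = 0` and `sample_cv = 0` the normalization
#' recovers planted abundances exactly.
#'
#' @param n_mirnas number of miRNA features.
#' @param n_spikeins number of positive-control rows (default 4, POS_B..POS_E).
#' @param spike_concs nominal spike-in concentrations (strictly decreasing,
#'   arbitrary concentration units); the first entry is the POS_B level.
#' @param hyb_slope expected counts per concentration unit per sample.
#' @param hyb_background additive count background per sample.
#' @param noise_cv coefficient of variation of the per-count lognormal noise.
#' @param sample_cv CV of the per-sample hybridization-efficiency factor
#'   (defaults to `noise_cv`).
#' @param conditions character vector of condition labels; the first is the
#'   reference condition for planted fold changes.
#' @param timepoints character vector of time labels shared by all conditions;
#'   samples from different conditions at the same time point are paired.
#' @param planted_fc `NULL` or a data.frame with columns `feature`,
#'   `condition`, `fc` (linear fold change > 0 applied to that feature's
#'   abundance in that condition).
#' @param baseline_abund optional numeric vector of baseline abundances, one
#'   per miRNA; by default drawn lognormal (median 100 concentration units).
#' @param mirna_ids optional feature names (default `mir-0001` ...).
#' @param seed integer random seed.
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_ncounter()]
#' @export
sim_config <- function(n_mirnas = 541,
                       n_spikeins = 4,
                       spike_concs = c(32, 8, 2, 0.5),
                       hyb_slope = 10,
                       hyb_background = 20,
                       noise_cv = 0.05,
                       sample_cv = NULL,
                       conditions = c("crxnrl", "shPias2_49", "shPias2_50"),
                       timepoints = c("15h", "24h", "48h"),
                       planted_fc = NULL,
                       baseline_abund = NULL,
                       mirna_ids = NULL,
                       seed = 1L) {
  cfg <- list(
    n_mirnas = n_mirnas, n_spikeins = n_spikeins, spike_concs = spike_concs,
    hyb_slope = hyb_slope, hyb_background = hyb_background,
    noise_cv = noise_cv, sample_cv = sample_cv %||% noise_cv,
    conditions = conditions, timepoints = timepoints,
    planted_fc = planted_fc, baseline_abund = baseline_abund,
    mirna_ids = mirna_ids, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  assert_scalar_num(cfg$n_mirnas, "n_mirnas", lower = 1)
  assert_scalar_num(cfg$n_spikeins, "n_spikeins", lower = 3)
  if (length(cfg$spike_concs) != cfg$n_spikeins)
    stop_config("spike_concs", "must have one entry per spike-in")
  if (any(cfg$spike_concs <= 0))
    stop_config("spike_concs", "must be strictly positive")
  if (any(diff(cfg$spike_concs) >= 0))
    stop_config("spike_concs", "must be strictly decreasing")
  assert_scalar_num(cfg$hyb_slope, "hyb_slope", lower = 0, strict = TRUE)
  assert_scalar_num(cfg$hyb_background, "hyb_background", lower = 0)
  assert_scalar_num(cfg$noise_cv, "noise_cv", lower = 0)
  assert_scalar_num(cfg$sample_cv, "sample_cv", lower = 0)
  if (length(cfg$conditions) < 1 || anyDuplicated(cfg$conditions))
    stop_config("conditions", "must be non-empty and unique")
  if (length(cfg$timepoints) < 1 || anyDuplicated(cfg$timepoints))
    stop_config("timepoints", "must be non-empty and unique")
  if (!is.null(cfg$planted_fc)) {
    pf <- cfg$planted_fc
    if (!is.data.frame(pf) || !all(c("feature", "condition", "fc") %in% names(pf)))
      stop_config("planted_fc", "must be a data.frame(feature, condition, fc)")
    if (any(!is.finite(pf$fc)) || any(pf$fc <= 0))
      stop_config("planted_fc", "fold changes must be finite and > 0")
    if (any(!pf$condition %in% cfg$conditions))
      stop_config("planted_fc", "names a condition not in `conditions`")
  }
  if (!is.null(cfg$baseline_abund)) {
    if (length(cfg$baseline_abund) != cfg$n_mirnas)
      stop_config("baseline_abund", "must have one value per miRNA")
    if (any(cfg$baseline_abund <= 0))
      stop_config("baseline_abund", "must be strictly positive")
  }
  cfg
}

default_spike_names <- function(n) {
  # POS_B, POS_C, ... following the platform's naming of positive controls.
  paste0("POS_", LETTERS[seq(2, 1 + n)])
}

#' Simulate an nCounter-style raw count matrix
#'
#' Generates raw hybridization counts for miRNA probes plus positive spike-in
#' control rows, one sample per condition x time point, under the generative
#' model described in [sim_config()]. Counts are rounded to integers and
#' floored at zero; the continuous pre-rounding values and the planted
#' abundances are attached as the `truth` attribute for use by oracles.
#'
#' @param config a [sim_config()] object.
#' @return a `count_matrix`: list with `counts` (integer matrix, features x
#'   samples, spike-ins prefixed `POS_`), `meta` (data.frame `sample_id`,
#'   `condition`, `timepoint`, `pair_id`), and `spike_concs` (named by spike-in
#'   row). Attribute `truth` holds `abundance` (expected normalized expression
#'   per miRNA and sample), `slope`, `background` and `counts_cont`.
#' @export
#' @examples
#' m <- simulate_ncounter(sim_config(n_mirnas = 20, seed = 7))
#' dim(m$counts)
simulate_ncounter <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)

  grid <- expand.grid(timepoint = config$timepoints,
                      condition = config$conditions,
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  meta <- data.frame(
    sample_id = paste(grid$condition, grid$timepoint, sep = "_"),
    condition = grid$condition,
    timepoint = grid$timepoint,
    pair_id = grid$timepoint,
    stringsAsFactors = FALSE
  )
  n_s <- nrow(meta)
  n_m <- config$n_mirnas

  mirna_ids <- config$mirna_ids %||% sprintf("mir-%04d", seq_len(n_m))
  if (length(mirna_ids) != n_m || anyDuplicated(mirna_ids))
    stop_config("mirna_ids", "must be unique, one per miRNA")
  spike_ids <- names(config$spike_concs) %||% default_spike_names(config$n_spikeins)
  spike_concs <- stats::setNames(as.numeric(config$spike_concs), spike_ids)

  baseline <- config$baseline_abund %||% stats::rlnorm(n_m, meanlog = log(100), sdlog = 1)

  # fold-change matrix (miRNA x sample), 1 unless planted for that condition
  fc <- matrix(1, n_m, n_s, dimnames = list(mirna_ids, meta$sample_id))
  if (!is.null(config$planted_fc)) {
    pf <- config$planted_fc
    unknown <- setdiff(pf$feature, mirna_ids)
    if (length(unknown))
      stop_config("planted_fc", paste("names unknown features:",
                                      paste(unknown, collapse = ", ")))
    for (i in seq_len(nrow(pf)))
      fc[pf$feature[i], meta$condition == pf$condition[i]] <- pf$fc[i]
  }

  eff <- lognorm_factor(n_s, config$sample_cv)
  slope_s <- config$hyb_slope * eff
  bg_s <- config$hyb_background * eff

  conc_b <- spike_concs[[1]]
  abundance <- baseline * fc                       # expected normalized value
  conc <- rbind(abundance + conc_b,
                matrix(spike_concs, config$n_spikeins, n_s,
                       dimnames = list(spike_ids, meta$sample_id)))

  noise <- matrix(lognorm_factor(length(conc), config$noise_cv),
                  nrow(conc), n_s)
  counts_cont <- sweep(sweep(conc * noise, 2, slope_s, `*`), 2, bg_s, `+`)
  counts <- pmax(round(counts_cont), 0)
  storage.mode(counts) <- "integer"
  rownames(counts) <- c(mirna_ids, spike_ids)
  colnames(counts) <- meta$sample_id

  m <- count_matrix(counts, meta, spike_concs = spike_concs)
  attr(m, "truth") <- list(abundance = abundance, slope = slope_s,
                           background = bg_s, counts_cont = counts_cont)
  m
}

#' Simulate a summarized gene expression matrix
#'
#' Direct simulation at the summarized (post-preprocessing) level: positive
#' linear expression values with multiplicative lognormal noise and planted
#' condition-specific fold changes. Used for the microarray arm of the
#' pipeline, where probe-level preprocessing is out of scope.
#'
#' @param n_genes number of genes.
#' @param conditions condition labels (first = reference).
#' @param timepoints time labels; samples are paired by time point.
#' @param planted_fc `NULL` or data.frame(feature, condition, fc).
#' @param noise_cv multiplicative lognormal CV (default 0.03, reflecting the
#'   lower technical variability of summarized array intensities compared to
#'   raw counts).
#' @param baseline optional per-gene baseline expression (default lognormal,
#'   median 500).
#' @param gene_ids optional gene identifiers (default `gene00001` ...).
#' @param seed integer random seed.
#' @return list with `values` (numeric matrix genes x samples), `meta`
#'   (sample_id, condition, timepoint, pair_id) and attribute `truth`.
#' @export
simulate_expression_matrix <- function(n_genes,
                                       conditions = c("crxnrl", "shPias2_49"),
                                       timepoints = c("15h", "48h"),
                                       planted_fc = NULL,
                                       noise_cv = 0.03,
                                       baseline = NULL,
                                       gene_ids = NULL,
                                       seed = 1L) {
  assert_scalar_num(n_genes, "n_genes", lower = 1)
  assert_scalar_num(noise_cv, "noise_cv", lower = 0)
  set.seed(as.integer(seed))

  grid <- expand.grid(timepoint = timepoints, condition = conditions,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  meta <- data.frame(
    sample_id = paste(grid$condition, grid$timepoint, sep = "_"),
    condition = grid$condition, timepoint = grid$timepoint,
    pair_id = grid$timepoint, stringsAsFactors = FALSE
  )
  n_s <- nrow(meta)
  gene_ids <- gene_ids %||% sprintf("gene%05d", seq_len(n_genes))
  if (length(gene_ids) != n_genes || anyDuplicated(gene_ids))
    stop_config("gene_ids", "must be unique, one per gene")
  baseline <- baseline %||% stats::rlnorm(n_genes, meanlog = log(500), sdlog = 1)

  fc <- matrix(1, n_genes, n_s, dimnames = list(gene_ids, meta$sample_id))
  if (!is.null(planted_fc)) {
    pf <- planted_fc
    if (!is.data.frame(pf) || !all(c("feature", "condition", "fc") %in% names(pf)))
      stop_config("planted_fc", "must be a data.frame(feature, condition, fc)")
    if (any(pf$fc <= 0)) stop_config("planted_fc", "fold changes must be > 0")
    unknown <- setdiff(pf$feature, gene_ids)
    if (length(unknown))
      stop_config("planted_fc", paste("names unknown features:",
                                      paste(unknown, collapse = ", ")))
    for (i in seq_len(nrow(pf)))
      fc[pf$feature[i], meta$condition == pf$condition[i]] <- pf$fc[i]
  }

  truth <- baseline * fc
  noise <- matrix(lognorm_factor(length(truth), noise_cv), n_genes, n_s)
  values <- truth * noise
  dimnames(values) <- list(gene_ids, meta$sample_id)
  structure(list(values = values, meta = meta),
            truth = list(expression = truth), class = "expr_matrix")
}

#' Simulate a reporter plate of relative light units
#'
#' Per-well RLU = `control_rlu * fold(condition) * lognormal noise`. A
#' `"control"` condition with fold 1 is always present (added if absent from
#' `effects`). Wells are replicated within each day stratum.
#'
#' @param effects named positive numeric vector, condition -> fold over control.
#' @param control_rlu expected control RLU (> 0).
#' @param noise_cv lognormal CV of well-to-well noise.
#' @param n_wells replicate wells per condition per day (>= 1).
#' @param days vector of day labels (default `1:2`, matching a day-1/day-2
#'   secreted-luciferase sampling design).
#' @param seed integer random seed.
#' @return data.frame (class `reporter_table`) with columns `well_id`,
#'   `condition`, `day`, `replicate`, `rlu`.
#' @export
#' @examples
#' p <- simulate_reporter_plate(c(crxnrl = 10.23, shPias2_49 = 88),
#'                              control_rlu = 100, noise_cv = 0,
#'                              n_wells = 3, seed = 1)
#' relative_activity(p, "shPias2_49", "crxnrl")
simulate_reporter_plate <- function(effects, control_rlu = 100,
                                    noise_cv = 0.15, n_wells = 3,
                                    days = 1:2, seed = 1L) {
  if (length(effects) < 1 || is.null(names(effects)) || any(names(effects) == ""))
    stop_config("effects", "must be a named condition -> fold vector")
  if (any(!is.finite(effects)) || any(effects <= 0))
    stop_config("effects", "folds must be finite and > 0")
  assert_scalar_num(control_rlu, "control_rlu", lower = 0, strict = TRUE)
  assert_scalar_num(noise_cv, "noise_cv", lower = 0)
  assert_scalar_num(n_wells, "n_wells", lower = 1)
  set.seed(as.integer(seed))

  if (!"control" %in% names(effects)) effects <- c(control = 1, effects)
  grid <- expand.grid(replicate = seq_len(n_wells),
                      condition = names(effects), day = days,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  rlu <- control_rlu * effects[grid$condition] *
    lognorm_factor(nrow(grid), noise_cv)
  out <- data.frame(
    well_id = sprintf("d%s_%s_r%d", grid$day, grid$condition, grid$replicate),
    condition = grid$condition, day = grid$day,
    replicate = grid$replicate, rlu = as.numeric(rlu),
    stringsAsFactors = FALSE
  )
  class(out) <- c("reporter_table", "data.frame")
  out
}

#' Simulate flow-cytometry events as a two-component lognormal mixture
#'
#' Event intensities are drawn from a lognormal negative population and, for
#' a binomially sampled fraction of events, a lognormal positive population.
#' The output row count is exactly `n_events`.
#'
#' @param n_events total number of events (>= 1).
#' @param frac_positive probability an event is positive, in \[0, 1\].
#' @param pos_median median intensity of the positive population
#'   (> `neg_median`).
#' @param neg_median median intensity of the negative population (> 0).
#' @param pos_sdlog,neg_sdlog lognormal shape parameters of the two
#'   populations (defaults 0.5 and 0.25).
#' @param sample label stored in the `sample` column.
#' @param seed integer random seed.
#' @return data.frame (class `flow_events`) with columns `sample`,
#'   `intensity`, `true_positive` (the simulation truth, for oracles).
#' @export
simulate_flow_events <- function(n_events, frac_positive, pos_median,
                                 neg_median, pos_sdlog = 0.5,
                                 neg_sdlog = 0.25, sample = "sample",
                                 seed = 1L) {
  assert_scalar_num(n_events, "n_events", lower = 1)
  if (!is.numeric(frac_positive) || length(frac_positive) != 1L ||
      is.na(frac_positive) || frac_positive < 0 || frac_positive > 1)
    stop_config("frac_positive", "must be in [0, 1]")
  assert_scalar_num(neg_median, "neg_median", lower = 0, strict = TRUE)
  assert_scalar_num(pos_median, "pos_median", lower = 0, strict = TRUE)
  if (pos_median <= neg_median)
    stop_config("pos_median", "must exceed neg_median")
  set.seed(as.integer(seed))

  pos <- stats::rbinom(n_events, 1L, frac_positive) == 1L
  intensity <- numeric(n_events)
  intensity[!pos] <- stats::rlnorm(sum(!pos), log(neg_median), neg_sdlog)
  intensity[pos] <- stats::rlnorm(sum(pos), log(pos_median), pos_sdlog)
  out <- data.frame(sample = sample, intensity = intensity,
                    true_positive = pos, stringsAsFactors = FALSE)
  class(out) <- c("flow_events", "data.frame")
  out
}

#' Simulate a qPCR Ct table
#'
#' For each target gene, `Ct = ref_ct + baseline_offset -
#' log_efficiency(true_rel_expr) + noise`; the reference gene is reported at
#' `ref_ct + noise`. The per-gene baseline offset is constant across samples,
#' so it cancels in the delta-delta-Ct computation; a calibrator sample with
#' relative expression 1 for every target is always included.
#'
#' @param true_rel_expr named positive numeric vector, gene -> true expression
#'   of the treated sample relative to the calibrator.
#' @param ref_ct reference-gene Ct (cycles).
#' @param efficiency amplification efficiency per cycle (> 1; 2 = perfect
#'   doubling).
#' @param noise_sd additive normal noise on each Ct, in cycles.
#' @param reference_gene label of the reference gene (default "GAPDH").
#' @param samples labels of the calibrator and treated samples.
#' @param n_replicates technical replicates per sample x gene.
#' @param baseline_offset optional named per-gene Ct offset (default 0).
#' @param seed integer random seed.
#' @return data.frame (class `qpcr_table`) with columns `sample`, `gene`,
#'   `replicate`, `ct`; attribute `reference_gene`.
#' @export
simulate_qpcr <- function(true_rel_expr, ref_ct = 20, efficiency = 2,
                          noise_sd = 0, reference_gene = "GAPDH",
                          samples = c(calibrator = "calibrator",
                                      treated = "treated"),
                          n_replicates = 3, baseline_offset = NULL,
                          seed = 1L) {
  if (length(true_rel_expr) < 1 || is.null(names(true_rel_expr)))
    stop_config("true_rel_expr", "must be a named gene -> expression vector")
  if (any(!is.finite(true_rel_expr)) || any(true_rel_expr <= 0))
    stop_config("true_rel_expr", "must be finite and > 0")
  assert_scalar_num(efficiency, "efficiency", lower = 1, strict = TRUE)
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  assert_scalar_num(n_replicates, "n_replicates", lower = 1)
  set.seed(as.integer(seed))

  genes <- names(true_rel_expr)
  offset <- baseline_offset %||% stats::setNames(rep(0, length(genes)), genes)
  rel <- rbind(calibrator = rep(1, length(genes)), treated = true_rel_expr)
  rows <- list()
  for (s in seq_len(2)) {
    sample_lab <- samples[[s]]
    for (g in seq_along(genes)) {
      ct <- ref_ct + offset[[genes[g]]] - log(rel[s, g], base = efficiency) +
        stats::rnorm(n_replicates, 0, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sample_lab, gene = genes[g],
        replicate = seq_len(n_replicates), ct = ct, stringsAsFactors = FALSE)
    }
    ct_ref <- ref_ct + stats::rnorm(n_replicates, 0, noise_sd)
    rows[[length(rows) + 1L]] <- data.frame(
      sample = sample_lab, gene = reference_gene,
      replicate = seq_len(n_replicates), ct = ct_ref, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "reference_gene") <- reference_gene
  class(out) <- c("qpcr_table", "data.frame")
  out
}

#' Simulate a differential-expression gene table (synthetic supplementary list)
#'
#' Builds a synthetic stand-in for a published differentially-expressed-gene
#' table: `n_genes` rows with signed linear fold changes (`|fc| > fc_min`) and
#' p-values below `p_max`, of which exactly `n_down` are downregulated.
#' Specific gene names can be pinned to the up or down strata so that
#' family-membership and target-overlap analyses have known truth. This is a
#' synthetic emulation of such a table, not the published data.
#'
#' @param n_genes total rows (default 320).
#' @param n_down number of rows with negative signed fold change (default 217).
#' @param down_genes,up_genes character vectors of gene ids guaranteed to be
#'   present in the down / up strata (defaults empty).
#' @param fc_min,p_max the calling thresholds the table is consistent with
#'   (defaults 1.25 and 0.1).
#' @param seed integer random seed.
#' @return data.frame with columns `gene_id`, `fc` (signed linear), `p`.
#' @export
simulate_deg_table <- function(n_genes = 320, n_down = 217,
                               down_genes = character(), up_genes = character(),
                               fc_min = 1.25, p_max = 0.1, seed = 1L) {
  assert_scalar_num(n_genes, "n_genes", lower = 1)
  assert_scalar_num(n_down, "n_down", lower = 0)
  if (n_down > n_genes) stop_config("n_down", "cannot exceed n_genes")
  if (length(down_genes) > n_down || length(up_genes) > n_genes - n_down)
    stop_config("down_genes", "more pinned genes than stratum slots")
  set.seed(as.integer(seed))

  n_up <- n_genes - n_down
  filler <- function(k, prefix) if (k > 0) sprintf("%s%04d", prefix, seq_len(k)) else character()
  ids_down <- c(down_genes, filler(n_down - length(down_genes), "DEGDN"))
  ids_up <- c(up_genes, filler(n_up - length(up_genes), "DEGUP"))
  mag <- fc_min + stats::rexp(n_genes, rate = 1.5)   # |fc| strictly > fc_min
  fc <- c(-mag[seq_len(n_down)], mag[n_down + seq_len(n_up)])
  p <- stats::runif(n_genes, 0, p_max * 0.999)
  data.frame(gene_id = c(ids_down, ids_up), fc = fc, p = p,
             stringsAsFactors = FALSE)
}
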