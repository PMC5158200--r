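#' Relative reporter activity between conditions
#'
#' Ratio of mean RLU between a condition and a reference condition, computed
#' separately within each day stratum (day-1 and day-2 measurements are never
#' pooled). The standard error is propagated from the replicate standard
#' errors by the delta method:
#' `se(ratio) = ratio * sqrt((se_x/mean_x)^2 + (se_ref/mean_ref)^2)`.
#'
#' Chaining is exact by construction: the vs-control ratio of a condition
#' divided by the vs-control ratio of a second condition equals the direct
#' ratio against that second condition, supporting double ratios such as
#' activity vs control and vs the CRX/NRL condition.
#'
#' @param t a reporter table: data.frame with columns `condition`, `rlu`
#'   (>= 0) and optionally `day` (e.g. from [simulate_reporter_plate()]).
#' @param condition condition of interest.
#' @param reference_condition condition the ratio is taken against.
#' @param day optional day label to restrict to a single stratum.
#' @return data.frame with one row per day stratum: `day`, `condition`,
#'   `reference`, `ratio`, `se`, `n`, `n_ref`.
#' @export
#' @examples
#' p <- simulate_reporter_plate(c(crxnrl = 10.23, shPias2_49 = 88),
#'                              noise_cv = 0, n_wells = 3, days = 1, seed = 1)
#' relative_activity(p, "shPias2_49", "control")$ratio  # 88
#' relative_activity(p, "shPias2_49", "crxnrl")$ratio   # 8.602...
relative_activity <- function(t, condition, reference_condition, day = NULL) {
  if (!all(c("condition", "rlu") %in% names(t)))
    stop("reporter table needs `condition` and `rlu` columns", call. = FALSE)
  if (any(t$rlu < 0)) stop("RLU values must be >= 0", call. = FALSE)
  if (!"day" %in% names(t)) t$day <- NA
  if (!is.null(day)) t <- t[t$day %in% day, , drop = FALSE]
  for (cond in c(condition, reference_condition))
    if (!cond %in% t$condition)
      stop(sprintf("condition '%s' not present", cond), call. = FALSE)

  one_stratum <- function(sub) {
    x <- sub$rlu[sub$condition == condition]
    r <- sub$rlu[sub$condition == reference_condition]
    if (length(x) < 1 || length(r) < 1) return(NULL)
    mr <- mean(r)
    if (mr == 0) stop("reference condition has zero mean RLU", call. = FALSE)
    mx <- mean(x)
    ratio <- mx / mr
    if (condition == reference_condition) {
      se <- 0
    } else {
      se_x <- if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
      se_r <- if (length(r) > 1) stats::sd(r) / sqrt(length(r)) else NA_real_
      se <- ratio * sqrt((se_x / mx)^2 + (se_r / mr)^2)
    }
    data.frame(day = sub$day[1], condition = condition,
               reference = reference_condition, ratio = ratio, se = se,
               n = length(x), n_ref = length(r), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(split(t, t$day), one_stratum))
  rownames(out) <- NULL
  out
}

#' Intensity threshold for positive events from an untransfected control
#'
#' The empirical quantile of the control population's intensity distribution;
#' events above it are scored positive. The default 0.999 quantile admits
#' roughly a 0.1% false-positive rate in the control.
#'
#' @param control numeric intensity vector or a `flow_events` data.frame
#'   (uses its `intensity` column); >= 100 events required.
#' @param quantile probability in \[0, 1\] (default 0.999); 1 returns the
#'   control maximum.
#' @return threshold intensity (scalar).
#' @export
flow_threshold <- function(control, quantile = 0.999) {
  x <- if (is.data.frame(control)) control$intensity else control
  if (length(x) < 100)
    stop("need >= 100 control events to set a threshold", call. = FALSE)
  if (quantile < 0 || quantile > 1)
    stop("quantile must be in [0, 1]", call. = FALSE)
  unname(stats::quantile(x, quantile, type = 7))
}

#' Composite flow-cytometry reporter score
#'
#' `percent_positive` is the percentage of events above the threshold;
#' `median_positive` is the median intensity among the positive events only
#' (for an even count, the mean of the two central order statistics). The
#' composite score is their product, and when a control score is supplied the
#' result also carries the relative ratio to it. With no positive events the
#' score is 0 and `no_positive` is flagged.
#'
#' @param sample numeric intensity vector or `flow_events` data.frame.
#' @param threshold intensity threshold from [flow_threshold()].
#' @param control_score optional positive composite score of the control
#'   sample; enables the `relative` field.
#' @return list of class `flow_score`: `percent_positive`, `median_positive`,
#'   `score`, `relative` (NA without a control score), `no_positive`.
#' @export
flow_reporter_score <- function(sample, threshold, control_score = NULL) {
  x <- if (is.data.frame(sample)) sample$intensity else sample
  if (!is.null(control_score) && control_score <= 0)
    stop("control_score must be > 0", call. = FALSE)
  pos <- x[x > threshold]
  if (length(pos) == 0) {
    warning("no positive events above threshold; score is 0")
    out <- list(percent_positive = 0, median_positive = NA_real_, score = 0,
                relative = if (is.null(control_score)) NA_real_ else 0,
                no_positive = TRUE)
  } else {
    pp <- 100 * length(pos) / length(x)
    med <- stats::median(pos)
    score <- pp * med
    out <- list(percent_positive = pp, median_positive = med, score = score,
                relative = if (is.null(control_score)) NA_real_ else
                  score / control_score,
                no_positive = FALSE)
  }
  class(out) <- "flow_score"
  out
}

#' @export
print.flow_score <- function(x, ...) {
  cat(sprintf("flow_score: %.2f%% positive, median %.4g, score %.6g",
              x$percent_positive, x$median_positive, x$score))
  if (!is.na(x$relative)) cat(sprintf(", relative %.4g", x$relative))
  cat("\n")
  invisible(x)
}

#' Relative qPCR expression by the delta-delta-Ct method
#'
#' `relative = efficiency^-((Ct_target - Ct_ref)_sample -
#' (Ct_target - Ct_ref)_calibrator)`, i.e. target expression normalized to the
#' reference gene and calibrated against a reference sample. Replicate Cts
#' within a sample x gene are averaged first. Adding a constant to all Cts of
#' a sample cancels in the delta-Ct and leaves the result unchanged.
#'
#' @param t qPCR table: data.frame with columns `sample`, `gene`, `ct`.
#' @param target_gene gene of interest.
#' @param sample sample to quantify.
#' @param calibrator_sample sample the result is relative to.
#' @param reference_gene normalization gene (default the table's
#'   `reference_gene` attribute, else `"GAPDH"`).
#' @param efficiency amplification efficiency per cycle (default 2).
#' @return relative expression (scalar).
#' @export
#' @examples
#' q <- simulate_qpcr(c(PIAS2 = 0.57), noise_sd = 0, seed = 1)
#' qpcr_relative(q, "PIAS2", "treated", "calibrator") # 0.57
qpcr_relative <- function(t, target_gene, sample, calibrator_sample,
                          reference_gene = NULL, efficiency = 2) {
  if (!all(c("sample", "gene", "ct") %in% names(t)))
    stop("qPCR table needs `sample`, `gene`, `ct` columns", call. = FALSE)
  if (any(!is.finite(t$ct))) stop("Ct values must be finite", call. = FALSE)
  assert_scalar_num(efficiency, "efficiency", lower = 1, strict = TRUE)
  reference_gene <- reference_gene %||% attr(t, "reference_gene") %||% "GAPDH"

  ct_of <- function(s, g) {
    v <- t$ct[t$sample == s & t$gene == g]
    if (length(v) == 0)
      stop(sprintf("missing Ct for gene '%s' in sample '%s'", g, s),
           call. = FALSE)
    mean(v)
  }
  dct_s <- ct_of(sample, target_gene) - ct_of(sample, reference_gene)
  dct_c <- ct_of(calibrator_sample, target_gene) -
    ct_of(calibrator_sample, reference_gene)
  efficiency^(-(dct_s - dct_c))
}
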