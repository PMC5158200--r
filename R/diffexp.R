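#' Build a paired design between two conditions
#'
#' Pairs each sample of `condition_a` with the sample of `condition_b` sharing
#' its time point. At least two pairs are required (the paired t-test needs
#' >= 2 differences); each sample enters at most one pair.
#'
#' @param meta sample metadata data.frame (`sample_id`, `condition`,
#'   `timepoint`, optional `pair_id`).
#' @param condition_a,condition_b condition labels; `condition_a` is the
#'   reference (fold changes are b over a).
#' @return object of class `paired_design`: list with `condition_a`,
#'   `condition_b` and `pairs` (data.frame `timepoint`, `sample_a`,
#'   `sample_b`).
#' @export
paired_design <- function(meta, condition_a, condition_b) {
  for (cond in c(condition_a, condition_b))
    if (!cond %in% meta$condition)
      stop(sprintf("condition '%s' not present in metadata", cond), call. = FALSE)
  a <- meta[meta$condition == condition_a, ]
  b <- meta[meta$condition == condition_b, ]
  if (anyDuplicated(a$timepoint) || anyDuplicated(b$timepoint))
    stop("more than one sample per condition x timepoint; cannot pair uniquely",
         call. = FALSE)
  tps <- intersect(a$timepoint, b$timepoint)
  if (length(tps) < 2)
    stop("need >= 2 shared time points to form a paired design", call. = FALSE)
  pairs <- data.frame(
    timepoint = tps,
    sample_a = a$sample_id[match(tps, a$timepoint)],
    sample_b = b$sample_id[match(tps, b$timepoint)],
    stringsAsFactors = FALSE
  )
  structure(list(condition_a = condition_a, condition_b = condition_b,
                 pairs = pairs),
            class = "paired_design")
}

#' @export
print.paired_design <- function(x, ...) {
  cat(sprintf("paired_design: %s (reference) vs %s, %d pairs by time point\n",
              x$condition_a, x$condition_b, nrow(x$pairs)))
  invisible(x)
}

#' Paired t-test on matched value lists
#'
#' Classical paired Student t on the differences `b - a` (two-sided, n - 1
#' degrees of freedom). When all differences are identical the statistic is
#' undefined (0/0): the p-value is returned as `NA` with `undefined = TRUE`
#' and is treated as 1 by the differential-expression caller, so such
#' features are never called.
#'
#' @param a,b numeric vectors of equal length >= 2 (typically log2 values);
#'   positive `t` means `b` exceeds `a`.
#' @return list(t, p, df, undefined).
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b))
    stop("paired vectors must have equal length", call. = FALSE)
  if (length(a) < 2)
    stop("paired t-test needs >= 2 pairs", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("paired t-test requires finite values", call. = FALSE)
  d <- b - a
  if (stats::sd(d) == 0)
    return(list(t = NA_real_, p = NA_real_, df = length(d) - 1L,
                undefined = TRUE))
  tt <- stats::t.test(b, a, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), undefined = FALSE)
}

#' Signed linear fold change
#'
#' Ratio `r = mean_b / mean_a`, reported as `r` when `r >= 1` and `-1/r`
#' otherwise, so that the magnitude is always >= 1 and the sign encodes
#' direction. An optional pseudocount protects against zero means; when both
#' means are zero the fold change is undefined (`NA`).
#'
#' @param mean_a,mean_b non-negative mean linear expression values
#'   (vectorized).
#' @param pseudocount added to both means before the ratio (default 0).
#' @return numeric vector of signed linear fold changes (NA where undefined).
#' @export
#' @examples
#' fold_change(10, 20) #  2
#' fold_change(20, 10) # -2
fold_change <- function(mean_a, mean_b, pseudocount = 0) {
  if (any(mean_a < 0, na.rm = TRUE) || any(mean_b < 0, na.rm = TRUE))
    stop("means must be >= 0", call. = FALSE)
  a <- mean_a + pseudocount
  b <- mean_b + pseudocount
  r <- b / a
  fc <- ifelse(r >= 1, r, -1 / r)
  fc[a == 0 & b == 0] <- NA_real_
  fc
}

#' Flag differentially expressed features by threshold
#'
#' Applies the calling rule with strict inequalities: a feature is
#' differentially expressed when `p < p_thresh` *and* `|fc| > fc_thresh`.
#' Undefined p-values or fold changes never yield a call.
#'
#' @param results data.frame with columns `p` and `fc` (e.g. from
#'   [run_diffexp()]).
#' @param p_thresh p-value threshold (> 0); 0.05 for the miRNA analysis,
#'   0.1 for the gene analysis.
#' @param fc_thresh linear fold-change magnitude threshold (>= 1); 1.1 for
#'   miRNA, 1.25 for genes.
#' @return `results` with `is_de` (logical) and `direction` ("up"/"down"/NA)
#'   set, and a `summary` attribute list(n_tested, n_de, n_up, n_down).
#' @export
call_de <- function(results, p_thresh, fc_thresh) {
  assert_scalar_num(p_thresh, "p_thresh", lower = 0, strict = TRUE)
  assert_scalar_num(fc_thresh, "fc_thresh", lower = 1)
  p_eff <- ifelse(is.na(results$p), 1, results$p)
  ok <- !is.na(results$fc)
  results$is_de <- ok & p_eff < p_thresh & abs(results$fc) > fc_thresh
  results$direction <- ifelse(results$is_de,
                              ifelse(results$fc > 0, "up", "down"),
                              NA_character_)
  attr(results, "summary") <- list(
    n_tested = nrow(results),
    n_de = sum(results$is_de),
    n_up = sum(results$is_de & results$fc > 0),
    n_down = sum(results$is_de & results$fc < 0)
  )
  results
}

#' Paired differential expression across time points
#'
#' Per feature: a paired t-test on log2 values across the time-point-matched
#' sample pairs, and a signed linear fold change from the mean linear values
#' of the paired samples (t-test in log space, fold change in linear space).
#' Rows are ordered by feature id.
#'
#' @param x a `normalized_matrix` (its `log2_values` feed the test and its
#'   `values` the fold change) or a plain non-negative numeric matrix of
#'   linear expression (log2(x + `pseudocount`) is used for the test).
#' @param design a [paired_design()]; its samples must exist in `x`.
#' @param p_thresh,fc_thresh calling thresholds, see [call_de()].
#' @param pseudocount log2 offset for plain matrices (default 1).
#' @param fc_method `"ratio_of_means"` (default) computes the fold change
#'   from condition means; `"mean_of_ratios"` averages the per-pair linear
#'   ratios first.
#' @param adjust `"none"` (default; raw p-values feed the calling rule) or
#'   `"BH"` for Benjamini-Hochberg adjustment before calling.
#' @return data.frame of class `de_result` with columns `feature_id`,
#'   `mean_a`, `mean_b`, `fc`, `p`, `t`, `is_de`, `direction`, ordered by
#'   feature id, with the [call_de()] `summary` attribute.
#' @export
run_diffexp <- function(x, design, p_thresh = 0.05, fc_thresh = 1.1,
                        pseudocount = 1,
                        fc_method = c("ratio_of_means", "mean_of_ratios"),
                        adjust = c("none", "BH")) {
  fc_method <- match.arg(fc_method)
  adjust <- match.arg(adjust)
  if (inherits(x, "normalized_matrix")) {
    lin <- x$values
    l2 <- x$log2_values
  } else if (is.matrix(x)) {
    if (any(x < 0)) stop("expression matrix must be non-negative", call. = FALSE)
    lin <- x
    l2 <- log2(x + pseudocount)
  } else if (inherits(x, "expr_matrix")) {
    lin <- x$values
    l2 <- log2(x$values + pseudocount)
  } else {
    stop("`x` must be a normalized_matrix, expr_matrix or numeric matrix",
         call. = FALSE)
  }
  need <- c(design$pairs$sample_a, design$pairs$sample_b)
  missing_s <- setdiff(need, colnames(lin))
  if (length(missing_s))
    stop("design samples missing from matrix: ",
         paste(missing_s, collapse = ", "), call. = FALSE)

  sa <- design$pairs$sample_a
  sb <- design$pairs$sample_b
  la <- l2[, sa, drop = FALSE]
  lb <- l2[, sb, drop = FALSE]
  tests <- lapply(seq_len(nrow(la)), function(i) paired_t_test(la[i, ], lb[i, ]))
  res <- data.frame(
    feature_id = rownames(lin),
    mean_a = rowMeans(lin[, sa, drop = FALSE]),
    mean_b = rowMeans(lin[, sb, drop = FALSE]),
    p = vapply(tests, `[[`, 0, "p"),
    t = vapply(tests, `[[`, 0, "t"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (fc_method == "ratio_of_means") {
    res$fc <- fold_change(res$mean_a, res$mean_b)
  } else {
    va <- lin[, sa, drop = FALSE]
    vb <- lin[, sb, drop = FALSE]
    r <- rowMeans(vb / va)
    res$fc <- ifelse(is.finite(r), ifelse(r >= 1, r, -1 / r), NA_real_)
  }
  if (adjust == "BH") res$p <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$feature_id), c("feature_id", "mean_a", "mean_b",
                                      "fc", "p", "t")]
  rownames(res) <- NULL
  res <- call_de(res, p_thresh, fc_thresh)
  class(res) <- c("de_result", "data.frame")
  res
}

#' Summarize a differential-expression result
#'
#' @param object a `de_result` from [run_diffexp()].
#' @param ... unused.
#' @return list(n_tested, n_de, n_up, n_down).
#' @export
summary.de_result <- function(object, ...) {
  attr(object, "summary")
}

#' @export
print.de_result <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("de_result: %d features tested, %d DE (%d up, %d down)\n",
              s$n_tested, s$n_de, s$n_up, s$n_down))
  utils::str(utils::head(as.data.frame(x)))
  invisible(x)
}

#' Write a DE table and its JSON summary
#'
#' @param res a `de_result`.
#' @param table_path CSV output path.
#' @param summary_path optional JSON output path for the
#'   n_tested/n_de/n_up/n_down summary.
#' @return invisibly, the paths written.
#' @export
write_de_result <- function(res, table_path, summary_path = NULL) {
  utils::write.csv(as.data.frame(res), table_path, row.names = FALSE,
                   quote = FALSE)
  if (!is.null(summary_path))
    jsonlite::write_json(attr(res, "summary"), summary_path,
                         auto_unbox = TRUE, digits = NA)
  invisible(c(table_path, summary_path))
}
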