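#' Construct and validate a raw count matrix
#'
#' The container for raw hybridization counts: a non-negative integer matrix
#' (features x samples, spike-in control rows identified by their `POS_` id
#' prefix) together with per-sample metadata. Fails with an informative error
#' on duplicate ids, negative or missing counts, or incomplete metadata.
#'
#' @param counts integer matrix with feature row names and sample column names.
#' @param meta data.frame with columns `sample_id`, `condition`, `timepoint`
#'   and optionally `pair_id` (defaults to the timepoint).
#' @param spike_concs optional named numeric vector of nominal spike-in
#'   concentrations (names matching spike-in rows).
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, meta, spike_concs = NULL) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have feature row names and sample column names", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "),
         call. = FALSE)
  bad <- which(is.na(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("negative or missing count at feature '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]),
         call. = FALSE)
  req <- c("sample_id", "condition", "timepoint")
  if (!is.data.frame(meta) || !all(req %in% names(meta)))
    stop("`meta` must be a data.frame with sample_id, condition, timepoint",
         call. = FALSE)
  if (!setequal(meta$sample_id, colnames(counts)) ||
      anyDuplicated(meta$sample_id))
    stop("metadata sample_ids must match count matrix columns exactly", call. = FALSE)
  missing_lab <- meta$sample_id[is.na(meta$condition) | is.na(meta$timepoint) |
                                  meta$condition == "" | meta$timepoint == ""]
  if (length(missing_lab))
    stop("samples missing condition/timepoint labels: ",
         paste(missing_lab, collapse = ", "), call. = FALSE)
  if (is.null(meta$pair_id)) meta$pair_id <- meta$timepoint
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = counts, meta = meta, spike_concs = spike_concs),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  sp <- grepl(getOption("shrnaoff.spike_pattern", "^POS_"), rownames(x$counts))
  cat(sprintf("count_matrix: %d features (%d spike-ins) x %d samples\n",
              nrow(x$counts), sum(sp), ncol(x$counts)))
  cat("conditions:", paste(unique(x$meta$condition), collapse = ", "), "\n")
  cat("timepoints:", paste(unique(x$meta$timepoint), collapse = ", "), "\n")
  invisible(x)
}

#' Read a raw count matrix from CSV or a minimal RCC dialect
#'
#' CSV format: counts file with feature ids in the first column and sample ids
#' in the header, plus a metadata CSV (`sample_id`, `condition`, `timepoint`,
#' optional `pair_id`). RCC dialect: one plain-text file per sample containing
#' a `<CodeSummary>` ... `</CodeSummary>` section of `Name,Count` lines (only
#' that section is read).
#'
#' @param path counts CSV path (for `format = "csv"`) or character vector of
#'   RCC file paths / a directory containing `.rcc` files (for
#'   `format = "rcc"`).
#' @param meta metadata CSV path or data.frame.
#' @param format `"csv"` or `"rcc"`.
#' @param spike_concs optional named spike-in concentration vector to attach.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, meta, format = c("csv", "rcc"),
                        spike_concs = NULL) {
  format <- match.arg(format)
  meta_df <- if (is.data.frame(meta)) meta else
    utils::read.csv(meta, stringsAsFactors = FALSE, comment.char = "#")
  counts <- switch(format,
    csv = {
      df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                            comment.char = "#")
      ids <- df[[1]]
      m <- as.matrix(df[, -1, drop = FALSE])
      if (!is.numeric(m))
        stop(sprintf("non-numeric count in '%s'", path), call. = FALSE)
      rownames(m) <- ids
      storage.mode(m) <- "integer"
      m
    },
    rcc = {
      files <- path
      if (length(files) == 1 && dir.exists(files))
        files <- sort(list.files(files, pattern = "\\.rcc$", full.names = TRUE))
      if (length(files) == 0) stop("no RCC files found", call. = FALSE)
      cols <- lapply(files, read_rcc_one)
      ids <- names(cols[[1]])
      for (cc in cols) {
        if (!identical(names(cc), ids))
          stop("RCC files disagree on probe names/order", call. = FALSE)
      }
      m <- do.call(cbind, lapply(cols, unname))
      rownames(m) <- ids
      colnames(m) <- sub("\\.rcc$", "", basename(files))
      storage.mode(m) <- "integer"
      m
    })
  count_matrix(counts, meta_df, spike_concs = spike_concs)
}

# Parse the CodeSummary section of a single minimal RCC file.
read_rcc_one <- function(file) {
  lines <- readLines(file, warn = FALSE)
  open <- which(lines == "<CodeSummary>")
  close <- which(lines == "</CodeSummary>")
  if (length(open) != 1 || length(close) != 1 || close <= open)
    stop(sprintf("'%s': no well-formed <CodeSummary> section", file), call. = FALSE)
  body <- lines[(open + 1):(close - 1)]
  body <- body[nzchar(body)]
  if (identical(tolower(body[1]), "name,count")) body <- body[-1]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad))
    stop(sprintf("'%s' line %d: expected 'Name,Count'", file, open + bad[1]),
         call. = FALSE)
  counts <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(counts))
    stop(sprintf("'%s': non-numeric count value", file), call. = FALSE)
  stats::setNames(counts, vapply(parts, `[[`, "", 1L))
}

#' Write a count matrix to CSV (+ metadata CSV)
#'
#' @param m a [count_matrix()].
#' @param counts_path,meta_path output file paths.
#' @return invisibly, the paths written.
#' @export
write_counts <- function(m, counts_path, meta_path) {
  df <- data.frame(feature_id = rownames(m$counts), m$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, counts_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(m$meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(c(counts_path, meta_path))
}

#' Write one minimal RCC-dialect file per sample
#'
#' Emits only a `<CodeSummary>` section of `Name,Count` lines per sample, the
#' subset of the RCC format this package reads back.
#'
#' @param m a [count_matrix()].
#' @param dir output directory (created if needed).
#' @return invisibly, the files written.
#' @export
write_rcc <- function(m, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- file.path(dir, paste0(colnames(m$counts), ".rcc"))
  for (j in seq_len(ncol(m$counts))) {
    writeLines(c("<CodeSummary>", "Name,Count",
                 paste(rownames(m$counts), m$counts[, j], sep = ","),
                 "</CodeSummary>"),
               files[j])
  }
  invisible(files)
}

#' Fit the linear response of positive spike-in controls for one sample
#'
#' Ordinary least squares of raw counts on nominal concentration across the
#' positive controls. The calibration signal `B` is the *fitted* value at the
#' POS_B concentration (robust to noise in the single POS_B observation), and
#' `slope` is the fitted slope. An optional log-space variant regresses log2
#' counts on log2 concentrations.
#'
#' @param counts raw spike-in counts for one sample.
#' @param concs nominal concentrations (same length, >= 3 distinct values).
#' @param conc_b concentration whose fitted signal defines `B` (default: the
#'   largest, i.e. POS_B on a decreasing ladder).
#' @param sample_id optional label carried into the result.
#' @param log_space if `TRUE`, fit log2(counts) ~ log2(concs) and report the
#'   back-transformed fitted value at `conc_b` as `B` and the log-log slope.
#' @return object of class `spikein_fit`: list(slope, B, r2, sample_id,
#'   log_space).
#' @export
#' @examples
#' fit_spikein_response(10 * c(32, 8, 2, 0.5) + 5, c(32, 8, 2, 0.5))
fit_spikein_response <- function(counts, concs, conc_b = max(concs),
                                 sample_id = NA_character_,
                                 log_space = FALSE) {
  if (length(counts) != length(concs))
    stop("counts and concs must have equal length", call. = FALSE)
  if (length(unique(concs)) < 3)
    stop("degenerate spike-in fit: need >= 3 distinct concentrations", call. = FALSE)
  if (log_space) {
    y <- log2(counts)
    fit <- stats::lm(y ~ log2(concs))
    slope <- unname(stats::coef(fit)[2])
    b <- 2^unname(stats::predict(fit, data.frame(concs = conc_b)))
  } else {
    y <- counts
    fit <- stats::lm(y ~ concs)
    slope <- unname(stats::coef(fit)[2])
    b <- unname(stats::predict(fit, data.frame(concs = conc_b)))
  }
  if (!is.finite(slope) || slope <= 0)
    stop(sprintf("degenerate spike-in fit: non-positive slope (%.4g)", slope),
         call. = FALSE)
  # computed directly: summary.lm() warns on exact zero-noise fits
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(slope = slope, B = b, r2 = r2, sample_id = sample_id,
                 log_space = log_space),
            class = "spikein_fit")
}

#' @export
print.spikein_fit <- function(x, ...) {
  cat(sprintf("spikein_fit%s: slope = %.6g, B = %.6g, r2 = %.4f\n",
              if (is.na(x$sample_id)) "" else paste0(" [", x$sample_id, "]"),
              x$slope, x$B, x$r2))
  invisible(x)
}

# Identify spike-in rows by id prefix (configurable regex).
spike_rows <- function(m, spike_pattern = "^POS_") {
  grepl(spike_pattern, rownames(m$counts))
}

#' Fit spike-in responses for every sample of a count matrix
#'
#' @param m a [count_matrix()].
#' @param spike_concs named concentrations for the spike-in rows (default:
#'   taken from `m`).
#' @param spike_pattern regex identifying spike-in rows (default `"^POS_"`).
#' @param spike_use optional character vector restricting which spike-ins
#'   enter the fit (e.g. exclude POS_A/POS_F when present).
#' @param log_space passed to [fit_spikein_response()].
#' @return list of `spikein_fit`, one per sample, named by sample id.
#' @export
fit_spikein_matrix <- function(m, spike_concs = NULL, spike_pattern = "^POS_",
                               spike_use = NULL, log_space = FALSE) {
  spike_concs <- spike_concs %||% m$spike_concs
  if (is.null(spike_concs) || is.null(names(spike_concs)))
    stop("named `spike_concs` required (none attached to the matrix)", call. = FALSE)
  sp <- rownames(m$counts)[spike_rows(m, spike_pattern)]
  use <- intersect(names(spike_concs), sp)
  if (!is.null(spike_use)) use <- intersect(use, spike_use)
  if (length(use) < 3)
    stop("fewer than 3 spike-in rows with known concentrations", call. = FALSE)
  concs <- spike_concs[use]
  conc_b <- max(concs)
  fits <- lapply(colnames(m$counts), function(s) {
    fit_spikein_response(m$counts[use, s], concs, conc_b = conc_b,
                         sample_id = s, log_space = log_space)
  })
  stats::setNames(fits, colnames(m$counts))
}

#' Spike-in normalization: Ei = (Ri - B) / slope
#'
#' Applies the per-sample affine calibration from the positive-control fit:
#' each raw count has the fitted POS_B signal subtracted and is divided by the
#' fitted slope, converting counts to concentration units. Negative values are
#' clipped to zero; spike-in rows are dropped from the output. The log2 layer
#' is `log2(E + pseudocount)`.
#'
#' @param m a [count_matrix()].
#' @param fits list of per-sample [fit_spikein_response()] results (default:
#'   computed internally via [fit_spikein_matrix()]).
#' @param spike_concs,spike_pattern,spike_use,log_space passed to
#'   [fit_spikein_matrix()] when `fits` is `NULL`.
#' @param pseudocount added before the log2 transform (default 1).
#' @return object of class `normalized_matrix`: list with `values` (linear,
#'   clipped at 0), `log2_values`, `meta`, `pseudocount` and `fits` (a
#'   data.frame sample_id, slope, B, r2).
#' @export
normalize_spikein <- function(m, fits = NULL, spike_concs = NULL,
                              spike_pattern = "^POS_", spike_use = NULL,
                              pseudocount = 1, log_space = FALSE) {
  fits <- fits %||% fit_spikein_matrix(m, spike_concs, spike_pattern,
                                       spike_use, log_space)
  missing_fit <- setdiff(colnames(m$counts), names(fits))
  if (length(missing_fit))
    stop("missing spike-in fit for sample(s): ",
         paste(missing_fit, collapse = ", "), call. = FALSE)
  keep <- !spike_rows(m, spike_pattern)
  raw <- m$counts[keep, , drop = FALSE]
  values <- vapply(colnames(raw), function(s) {
    f <- fits[[s]]
    (raw[, s] - f$B) / f$slope
  }, numeric(nrow(raw)))
  values <- pmax(values, 0)
  dimnames(values) <- dimnames(raw)
  fit_df <- data.frame(
    sample_id = names(fits),
    slope = vapply(fits, `[[`, 0, "slope"),
    B = vapply(fits, `[[`, 0, "B"),
    r2 = vapply(fits, `[[`, 0, "r2"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(values = values,
                 log2_values = log2(values + pseudocount),
                 meta = m$meta, pseudocount = pseudocount, fits = fit_df),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d features x %d samples (pseudocount %g)\n",
              nrow(x$values), ncol(x$values), x$pseudocount))
  invisible(x)
}

#' Global normalization to a common per-sample mean
#'
#' Rescales each sample multiplicatively so that its mean over all features
#' equals the grand mean of the input matrix across all conditions. The grand
#' mean is preserved and the operation is idempotent.
#'
#' @param nm a `normalized_matrix` from [normalize_spikein()] (or any list
#'   with `values`, `meta`, `pseudocount`).
#' @return the rescaled `normalized_matrix` (log2 layer recomputed).
#' @export
global_normalize <- function(nm) {
  v <- nm$values
  if (nrow(v) < 1 || ncol(v) < 2)
    stop("global normalization needs >= 1 feature and >= 2 samples", call. = FALSE)
  sample_means <- colMeans(v)
  zero <- names(sample_means)[sample_means == 0]
  if (length(zero))
    stop("cannot rescale sample(s) with all-zero values: ",
         paste(zero, collapse = ", "), call. = FALSE)
  grand <- mean(v)
  scaled <- sweep(v, 2, grand / sample_means, `*`)
  nm$values <- scaled
  nm$log2_values <- log2(scaled + nm$pseudocount)
  nm$scale_factors <- grand / sample_means
  nm
}

#' Write a normalized matrix (linear + log2 layers) and its fit report
#'
#' @param nm a `normalized_matrix`.
#' @param values_path CSV path for the linear and log2 values (long header:
#'   linear columns first, then `log2_` columns).
#' @param fits_path optional CSV path for the per-sample fit report.
#' @return invisibly, the paths written.
#' @export
write_normalized <- function(nm, values_path, fits_path = NULL) {
  lin <- nm$values
  l2 <- nm$log2_values
  colnames(l2) <- paste0("log2_", colnames(l2))
  df <- data.frame(feature_id = rownames(lin), lin, l2,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, values_path, row.names = FALSE, quote = FALSE)
  if (!is.null(fits_path))
    utils::write.csv(nm$fits, fits_path, row.names = FALSE, quote = FALSE)
  invisible(c(values_path, fits_path))
}
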