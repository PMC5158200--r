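#' Construct a feature set with optional directions
#'
#' @param label set label.
#' @param members character vector of feature ids (de-duplicated).
#' @param direction optional named character vector (`"up"`/`"down"`) giving
#'   the direction of each member.
#' @return object of class `feature_set`.
#' @export
feature_set <- function(label, members, direction = NULL) {
  members <- unique(as.character(members))
  if (!is.null(direction)) {
    if (is.null(names(direction)))
      stop("`direction` must be named by feature id", call. = FALSE)
    direction <- direction[intersect(names(direction), members)]
  }
  structure(list(label = label, members = members, direction = direction),
            class = "feature_set")
}

#' Extract the DE feature set from a differential-expression result
#'
#' @param res a `de_result` from [run_diffexp()].
#' @param label set label.
#' @return a [feature_set()] of the DE features, with directions.
#' @export
de_feature_set <- function(res, label) {
  de <- res[res$is_de, ]
  feature_set(label, de$feature_id,
              stats::setNames(de$direction, de$feature_id))
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set '%s': %d members\n", x$label, length(x$members)))
  invisible(x)
}

#' Intersection of two feature sets with direction concordance
#'
#' Exact set intersection; where both sets carry directions, members of the
#' intersection are additionally counted as concordant (same direction in
#' both sets) or discordant.
#'
#' @param a,b [feature_set()] objects.
#' @return list(intersection, n, concordant, discordant,
#'   concordant_members); the last three are `NA`/`NULL` when either set has
#'   no direction annotation.
#' @export
set_overlap <- function(a, b) {
  stopifnot(inherits(a, "feature_set"), inherits(b, "feature_set"))
  inter <- intersect(a$members, b$members)
  out <- list(intersection = inter, n = length(inter),
              concordant = NA_integer_, discordant = NA_integer_,
              concordant_members = NULL)
  if (!is.null(a$direction) && !is.null(b$direction)) {
    both <- inter[inter %in% names(a$direction) & inter %in% names(b$direction)]
    conc <- both[a$direction[both] == b$direction[both]]
    out$concordant <- length(conc)
    out$discordant <- length(both) - length(conc)
    out$concordant_members <- conc
  }
  out
}

#' Pair differentially expressed miRNAs with their DE predicted targets
#'
#' Enumerates every (miRNA, gene) pair where the miRNA is in the DE miRNA
#' set, the gene is among its predicted targets, and the gene is in the DE
#' gene set. Where directions are available, each pair is annotated with
#' whether it is consistent with relief of repression (miRNA down and target
#' up) or direct repression (miRNA up and target down).
#'
#' @param de_mirnas [feature_set()] of DE miRNAs.
#' @param tmap named list, miRNA id -> character vector of predicted target
#'   gene ids (no empty names).
#' @param de_genes [feature_set()] of DE genes.
#' @return data.frame with columns `mirna`, `gene`, `mirna_direction`,
#'   `gene_direction`, `repression_consistent` (zero rows when empty).
#' @export
target_intersect <- function(de_mirnas, tmap, de_genes) {
  stopifnot(inherits(de_mirnas, "feature_set"), inherits(de_genes, "feature_set"))
  if (length(tmap) && (is.null(names(tmap)) || any(names(tmap) == "")))
    stop("target map must be named by miRNA id", call. = FALSE)
  rows <- list()
  for (m in intersect(de_mirnas$members, names(tmap))) {
    hits <- intersect(tmap[[m]], de_genes$members)
    for (g in hits) {
      md <- if (!is.null(de_mirnas$direction) && m %in% names(de_mirnas$direction))
        de_mirnas$direction[[m]] else NA_character_
      gd <- if (!is.null(de_genes$direction) && g %in% names(de_genes$direction))
        de_genes$direction[[g]] else NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        mirna = m, gene = g,
        mirna_direction = md,
        gene_direction = gd,
        repression_consistent = if (is.na(md) || is.na(gd)) NA else
          (md == "down" & gd == "up") | (md == "up" & gd == "down"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(mirna = character(), gene = character(),
                      mirna_direction = character(),
                      gene_direction = character(),
                      repression_consistent = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gene-family over-representation in a DE list
#'
#' Counts the family's members in the DE gene list, reports them as a
#' percentage of the list (rounded half-up to two decimals) and computes the
#' upper-tail hypergeometric probability `P(X >= k)` of drawing at least that
#' many family members in `n` draws from the annotated background universe.
#'
#' @param de_genes [feature_set()] of DE genes (non-empty).
#' @param fam family annotation: data.frame with columns `gene`, `family`.
#' @param family_label family of interest (must exist in the annotation).
#' @param background size of the annotated gene universe (default: number of
#'   distinct genes in `fam`); must be at least the DE list size.
#' @return list(k, n, percent, p, family_size, background, members).
#' @export
#' @examples
#' fam <- data.frame(gene = sprintf("g%03d", 1:500),
#'                   family = rep(c("histone", "other"), c(20, 480)))
#' de <- feature_set("de", c(sprintf("g%03d", 1:7), sprintf("g%03d", 400:420)))
#' family_enrichment(de, fam, "histone")
family_enrichment <- function(de_genes, fam, family_label, background = NULL) {
  stopifnot(inherits(de_genes, "feature_set"))
  if (!is.data.frame(fam) || !all(c("gene", "family") %in% names(fam)))
    stop("family annotation needs `gene` and `family` columns", call. = FALSE)
  if (!family_label %in% fam$family)
    stop(sprintf("family '%s' absent from annotation", family_label),
         call. = FALSE)
  n <- length(de_genes$members)
  if (n == 0) stop("DE gene set is empty", call. = FALSE)
  background <- background %||% length(unique(fam$gene))
  if (background < n)
    stop("background universe smaller than the DE list", call. = FALSE)
  fam_genes <- unique(fam$gene[fam$family == family_label])
  k_genes <- intersect(de_genes$members, fam_genes)
  k <- length(k_genes)
  K <- length(fam_genes)
  list(k = k, n = n,
       percent = round_half_up(100 * k / n, 2),
       p = stats::phyper(k - 1, K, background - K, n, lower.tail = FALSE),
       family_size = K, background = background, members = k_genes)
}

#' Coefficient of determination between two numeric vectors
#'
#' The squared Pearson correlation. Returns `NA` with a warning when either
#' vector is constant (the correlation is undefined).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return R-squared in \[0, 1\], or `NA` when undefined.
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need >= 3 observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("values must be finite", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: R-squared undefined")
    return(NA_real_)
  }
  stats::cor(x, y)^2
}

#' Read a miRNA-to-target map from a two-column TSV
#'
#' @param path TSV with columns `mirna`, `gene` (header required).
#' @return named list, miRNA id -> character vector of target gene ids.
#' @export
read_target_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mirna", "gene") %in% names(df)))
    stop("target map TSV needs `mirna` and `gene` columns", call. = FALSE)
  if (any(df$mirna == "")) stop("empty miRNA id in target map", call. = FALSE)
  lapply(split(df$gene, df$mirna), unique)
}

#' Read a gene-to-family annotation from a two-column TSV
#'
#' @param path TSV with columns `gene`, `family` (header required).
#' @return data.frame with columns `gene`, `family`.
#' @export
read_family_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "family") %in% names(df)))
    stop("family TSV needs `gene` and `family` columns", call. = FALSE)
  df
}
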