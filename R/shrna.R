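#' Parse a pLKO.1-style shRNA oligo into its structural parts
#'
#' pLKO.1 hairpin oligos have the architecture
#' `CCGG` (cloning prefix) + sense arm + `CTCGAG` (loop) + antisense arm +
#' poly-T terminator. The decomposition is found by jointly searching loop
#' positions and terminator lengths: among all trailing T-runs of length >=
#' `min_terminator` and all occurrences of the loop motif in what remains,
#' the placement giving equal-length non-empty arms is selected. (The search
#' over terminator lengths matters because an antisense arm may itself end in
#' T, extending the apparent poly-T run.) If no placement or more than one
#' distinct placement satisfies the constraint, parsing fails loudly rather
#' than guessing.
#'
#' @param name construct name.
#' @param seq uppercase DNA sequence (A/C/G/T only).
#' @param prefix expected cloning prefix (default `"CCGG"`).
#' @param loop loop motif (default `"CTCGAG"`, an XhoI site).
#' @param min_terminator minimum trailing T-run length (default 5).
#' @return object of class `shrna_oligo`: list with `name`, `full_seq`,
#'   `prefix`, `sense`, `loop`, `antisense`, `terminator`. Joining the parts
#'   reproduces `full_seq` exactly.
#' @export
#' @examples
#' o <- parse_plko_oligo("shPias2_48",
#'   "CCGGGCCATGTTATTACAGAGATTACTCGAGTAATCTCTGTAATAACATGGCTTTTT")
#' o$sense
#' nchar(o$antisense)
parse_plko_oligo <- function(name, seq, prefix = "CCGG", loop = "CTCGAG",
                             min_terminator = 5) {
  check_dna(seq, what = sprintf("oligo '%s'", name))
  if (!startsWith(seq, prefix))
    stop_parse(name, sprintf("missing '%s' cloning prefix", prefix))
  body <- substring(seq, nchar(prefix) + 1)
  t_run <- nchar(body) - nchar(sub("T+$", "", body))
  if (t_run < min_terminator)
    stop_parse(name, sprintf("trailing T-run of length %d (< %d required)",
                             t_run, min_terminator))

  solutions <- list()
  for (term in seq(min_terminator, t_run)) {
    core <- substring(body, 1, nchar(body) - term)
    pos <- gregexpr(loop, core, fixed = TRUE)[[1]]
    if (pos[1] == -1L) next
    for (p in pos) {
      sense <- substring(core, 1, p - 1)
      antisense <- substring(core, p + nchar(loop))
      if (nchar(sense) > 0 && nchar(sense) == nchar(antisense))
        solutions[[length(solutions) + 1L]] <-
          list(sense = sense, antisense = antisense, term = term)
    }
  }
  if (length(solutions) == 0) {
    if (!grepl(loop, body, fixed = TRUE))
      stop_parse(name, sprintf("loop motif '%s' not found", loop))
    stop_parse(name, "no loop placement yields equal-length arms")
  }
  if (length(unique(vapply(solutions, function(s)
    paste(s$sense, s$term), ""))) > 1)
    stop_parse(name, "ambiguous decomposition: several loop/terminator placements yield equal-length arms")
  s <- solutions[[1]]
  out <- list(name = name, full_seq = seq, prefix = prefix, sense = s$sense,
              loop = loop, antisense = s$antisense,
              terminator = strrep("T", s$term))
  class(out) <- "shrna_oligo"
  stopifnot(identical(paste0(out$prefix, out$sense, out$loop, out$antisense,
                             out$terminator), seq))
  out
}

stop_parse <- function(name, msg) {
  stop(structure(class = c("shrna_parse_error", "error", "condition"),
                 list(message = sprintf("cannot parse oligo '%s': %s", name, msg),
                      call = NULL)))
}

check_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L)
    stop(sprintf("%s must be a single string", what), call. = FALSE)
  if (grepl("[^ACGT]", seq))
    stop(sprintf("%s contains non-ACGT characters", what), call. = FALSE)
  invisible(seq)
}

#' @export
print.shrna_oligo <- function(x, ...) {
  cat(sprintf("shrna_oligo %s (%d nt)\n", x$name, nchar(x$full_seq)))
  cat(sprintf("  %s | %s | %s | %s | %s\n", x$prefix, x$sense, x$loop,
              x$antisense, x$terminator))
  sc <- stem_complementarity(x)
  cat(if (sc$is_perfect) "  perfect stem\n" else
    sprintf("  %d stem mismatch(es) at arm position(s) %s\n",
            length(sc$mismatch_positions),
            paste(sc$mismatch_positions, collapse = ", ")))
  invisible(x)
}

#' Reverse complement of a DNA sequence
#'
#' @param seq DNA string (A/C/G/T; empty allowed).
#' @return the Watson-Crick reverse complement.
#' @export
#' @examples
#' reverse_complement("ACGT") # "ACGT"
reverse_complement <- function(seq) {
  if (identical(seq, "")) return("")
  check_dna(seq)
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "", fixed = TRUE)[[1]]),
        collapse = "")
}

#' Stem complementarity of a parsed hairpin
#'
#' Compares the antisense arm to the reverse complement of the sense arm.
#' Mismatch positions are reported along the antisense arm (1 = its 5' end).
#' The mismatch count is invariant under swapping which arm is labeled sense.
#'
#' @param o a `shrna_oligo` from [parse_plko_oligo()].
#' @return list(is_perfect, mismatch_positions).
#' @export
stem_complementarity <- function(o) {
  stopifnot(inherits(o, "shrna_oligo"))
  expected <- reverse_complement(o$sense)
  a <- strsplit(expected, "", fixed = TRUE)[[1]]
  b <- strsplit(o$antisense, "", fixed = TRUE)[[1]]
  mm <- which(a != b)
  list(is_perfect = length(mm) == 0, mismatch_positions = mm)
}

#' Hamming distance between the sense arms of two oligos
#'
#' Positionwise comparison of the two sense arms; used to characterize
#' mutant-series constructs against their parental hairpins.
#'
#' @param a,b `shrna_oligo` objects with equal arm lengths.
#' @return list(distance, positions).
#' @export
arm_mismatches <- function(a, b) {
  stopifnot(inherits(a, "shrna_oligo"), inherits(b, "shrna_oligo"))
  if (nchar(a$sense) != nchar(b$sense))
    stop("arm lengths differ; cannot compare positionwise", call. = FALSE)
  xa <- strsplit(a$sense, "", fixed = TRUE)[[1]]
  xb <- strsplit(b$sense, "", fixed = TRUE)[[1]]
  pos <- which(xa != xb)
  list(distance = length(pos), positions = pos)
}

#' GC content of a DNA sequence
#'
#' @param seq non-empty DNA string.
#' @return fraction of G or C bases, in \[0, 1\].
#' @export
gc_content <- function(seq) {
  check_dna(seq)
  if (nchar(seq) == 0) stop("empty sequence has no GC content", call. = FALSE)
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  sum(x %in% c("G", "C")) / length(x)
}

#' Read shRNA oligos from TSV or FASTA
#'
#' TSV input must carry `name` and `sequence` columns; FASTA input (requires
#' the Biostrings package) uses record names as construct names.
#'
#' @param path input file.
#' @param format `"tsv"` or `"fasta"` (default: guessed from the extension).
#' @return data.frame with columns `name`, `sequence` (plus any extra TSV
#'   columns).
#' @export
read_oligos <- function(path, format = NULL) {
  format <- format %||%
    (if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE)) "fasta" else "tsv")
  if (format == "fasta") {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("FASTA input requires the Biostrings package", call. = FALSE)
    ss <- Biostrings::readDNAStringSet(path)
    data.frame(name = names(ss), sequence = as.character(ss),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("name", "sequence") %in% names(df)))
      stop("oligo TSV needs `name` and `sequence` columns", call. = FALSE)
    df
  }
}

#' Parse a table of oligos and summarize their structure
#'
#' Runs [parse_plko_oligo()] over every row and tabulates the decomposition:
#' arm sequences, arm length, terminator length, sense-arm GC content and
#' whether the stem is perfectly complementary.
#'
#' @param oligos data.frame with `name` and `sequence` columns (e.g. from
#'   [read_oligos()] or [table1_oligos()]).
#' @param ... passed to [parse_plko_oligo()].
#' @return data.frame with one row per oligo: `name`, `sense`, `loop`,
#'   `antisense`, `terminator_len`, `arm_len`, `gc_sense`, `perfect_stem`,
#'   `n_stem_mismatches`. The parsed `shrna_oligo` objects are attached as
#'   the `oligos` attribute.
#' @export
parse_oligo_table <- function(oligos, ...) {
  parsed <- Map(parse_plko_oligo, oligos$name, oligos$sequence,
                MoreArgs = list(...))
  summ <- do.call(rbind, lapply(parsed, function(o) {
    sc <- stem_complementarity(o)
    data.frame(name = o$name, sense = o$sense, loop = o$loop,
               antisense = o$antisense,
               terminator_len = nchar(o$terminator),
               arm_len = nchar(o$sense),
               gc_sense = gc_content(o$sense),
               perfect_stem = sc$is_perfect,
               n_stem_mismatches = length(sc$mismatch_positions),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  attr(summ, "oligos") <- parsed
  summ
}

#' The packaged shRNA oligo table
#'
#' The 30 pLKO.1 hairpin constructs shipped with the package (five PIAS2
#' shRNAs, seven PIAS2 mutant-series constructs, eGFP and scrambled controls,
#' and GAPDH/HDAC/PPP2CA/Bcl2l11 shRNAs), as a name/sequence data.frame.
#'
#' @return data.frame with columns `name`, `gene`, `species`, `catalog`,
#'   `sequence`.
#' @export
table1_oligos <- function() {
  read_oligos(system.file("extdata", "table1_shrna_oligos.tsv",
                          package = "shrnaoff", mustWork = TRUE))
}
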