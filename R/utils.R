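# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Decimal rounding with ties going up in absolute value, the convention used
#' when reporting percentages such as "2.19%" (base R `round()` rounds ties to
#' even, which would give 2.18 for 2.1875).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(2.1875, 2) # 2.19
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x))
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Multiplicative lognormal factors with mean 1 and the given coefficient of
# variation; cv = 0 returns exact ones so zero-noise limits are exact.
lognorm_factor <- function(n, cv) {
  if (cv < 0) stop("coefficient of variation must be >= 0")
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Polynomial rolling hash of a string, returned as 8 hex digits (modulus
# 2^31 - 1 keeps everything in exact double arithmetic). Used only to
# fingerprint configurations in provenance headers; not cryptographic.
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 7
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# Stable JSON-ish serialization of a (possibly nested) config list for hashing.
config_fingerprint <- function(x) {
  flat <- function(v, prefix = "") {
    if (is.list(v)) {
      nms <- names(v) %||% as.character(seq_along(v))
      unlist(lapply(seq_along(v), function(i) {
        flat(v[[i]], paste0(prefix, nms[i], "."))
      }))
    } else if (is.data.frame(v)) {
      paste0(prefix, "=", paste(utils::capture.output(print(v)), collapse = ";"))
    } else {
      paste0(prefix, "=", paste(format(v, digits = 15), collapse = ","))
    }
  }
  fnv1a_hash(paste(flat(x), collapse = "|"))
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

assert_scalar_num <- function(x, field, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config(field, "must be a single finite number")
  if (strict && x <= lower) stop_config(field, sprintf("must be > %g", lower))
  if (!strict && x < lower) stop_config(field, sprintf("must be >= %g", lower))
  invisible(x)
}
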