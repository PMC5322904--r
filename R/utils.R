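# Shared low-level helpers. The internal alphabet is RNA: sequences are
# uppercased and T is rewritten to U on every input path.

RNA_BASES <- c("A", "C", "G", "U")

#' Normalize a character vector of sequences to the RNA alphabet
#'
#' Uppercases and converts T to U. With `strict = TRUE` any residual
#' character outside A/C/G/U is a hard error naming the offending record.
#'
#' @param x character vector of sequences.
#' @param ids optional record names used in error messages.
#' @param strict error on non-ACGU(T) characters (default TRUE).
#' @return character vector over {A,C,G,U}.
#' @export
normalize_rna <- function(x, ids = NULL, strict = TRUE) {
  out <- chartr("Tt", "Uu", toupper(x))
  out <- toupper(out)
  if (strict) {
    bad <- grepl("[^ACGU]", out)
    if (any(bad)) {
      who <- if (!is.null(ids)) paste(ids[bad], collapse = ", ") else
        paste(which(bad), collapse = ", ")
      stop("non-ACGU(T) characters in sequence record(s): ", who, call. = FALSE)
    }
  }
  out
}

# Length of the longest common prefix of two strings.
lcp_len <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  n <- min(length(ra), length(rb))
  if (n == 0L) return(0L)
  neq <- which(ra[seq_len(n)] != rb[seq_len(n)])
  if (length(neq)) neq[1L] - 1L else n
}

#' Half-up rounding
#'
#' Rounds halves away from zero (for non-negative input, upward), the
#' convention used for printed percentage tables; base `round()` rounds
#' halves to even.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic 31-bit seed derived from a root seed plus string tags.
# Keeps per-library / per-group RNG streams reproducible and independent of
# the order in which other streams are consumed.
derive_seed <- function(seed, ...) {
  tags <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- 0
  for (code in utf8ToInt(tags)) h <- (h * 31 + code) %% 2147483629
  as.integer((as.numeric(seed) %% 2147483629 + h) %% 2147483629)
}

# Significance stars at the conventional 0.05 / 0.01 / 0.001 thresholds.
star_for_p <- function(p) {
  ifelse(is.na(p), "",
    ifelse(p < 0.001, "***",
      ifelse(p < 0.01, "**",
        ifelse(p < 0.05, "*", ""))))
}

# Largest-remainder (Hamilton) apportionment of n among weights w.
# Deterministic: ties broken by index order.
apportion <- function(n, w) {
  stopifnot(n >= 0, all(w >= 0), sum(w) > 0)
  q <- n * w / sum(w)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
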