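# Internal helpers shared across modules.

AA_ALPHABET_EXT <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                     "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y",
                     "X", "B", "Z", "U", "O")

NS_LABELS_DEFAULT <- c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 10L, 12L)

#' Validate an amino-acid sequence
#'
#' Checks that a sequence uses the 20 standard residues plus the ambiguity
#' and rare-residue codes X, B, Z, U, O. Errors name the first offending
#' position.
#'
#' @param sequence Character scalar, amino-acid sequence.
#' @return The uppercased sequence, invisibly usable downstream.
#' @keywords internal
check_aa_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L) {
    stop("sequence must be a non-empty character scalar")
  }
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% AA_ALPHABET_EXT)
  if (length(bad) > 0L) {
    stop(sprintf("illegal residue '%s' at position %d", chars[bad[1L]], bad[1L]))
  }
  sequence
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic 31-bit polynomial hash of a string (used to key synthetic
# encoders and caches; not cryptographic).
string_hash <- function(x, mod = 2147483647) {
  codes <- utf8ToInt(x)
  h <- 0
  for (code in codes) h <- (h * 131 + code) %% mod
  as.integer(h)
}

# Mix several non-negative integers into one 31-bit seed.
mix_seed <- function(...) {
  parts <- c(...)
  h <- 17
  for (p in parts) h <- (h * 1009 + (as.numeric(p) %% 2147483647)) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
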