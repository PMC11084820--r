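# Sequence embedding behind a pluggable encoder contract.
#
# The classifier consumes a pooled 1 x n vector per protein, where n is the
# encoder width (1280 for the ESM2-class language models this interface is
# designed around). Encoders are plain R objects satisfying a small
# contract, so precomputed language-model embeddings and the seeded
# synthetic encoder used for testing are interchangeable.

#' Construct an encoder backend
#'
#' An encoder backend is a deterministic map from an amino-acid sequence to
#' an `l x width` per-residue embedding matrix. The contract: same sequence
#' in, same matrix out; constant `width`; sequences longer than
#' `max_length` are truncated (with a warning) by [embed_sequence()].
#'
#' @param name Identity string recorded in embedding stores.
#' @param width Embedding width (number of columns).
#' @param encode Function `sequence -> l x width numeric matrix`.
#' @param max_length Maximum sequence length accepted before truncation.
#' @return An object of class `encoder_backend`.
#' @export
encoder_backend <- function(name, width, encode, max_length = 4096L) {
  stopifnot(is.character(name), width >= 1L, is.function(encode))
  structure(list(name = name, width = as.integer(width),
                 encode = encode, max_length = as.integer(max_length),
                 cache = new.env(parent = emptyenv())),
            class = "encoder_backend")
}

#' Seeded synthetic encoder
#'
#' A deterministic stand-in encoder for pipeline development and testing.
#' Each (residue, position) pair maps to a fixed pseudo-random vector
#' (seeded Gaussian, scaled by `noise_sd`), so embeddings are reproducible,
#' positional, and sensitive to single-residue changes. When
#' `class_centers` is supplied, every row is additionally offset by the
#' center of the class that `class_fun` assigns to the whole sequence; the
#' pooled embedding of a sequence of class c then lies within
#' O(`noise_sd`) of `class_centers[c, ]`, which makes the generated data
#' separable by construction and gives the classifier a recoverable signal.
#'
#' @param width Embedding width; 1280 matches the language-model default,
#'   smaller widths keep tests fast.
#' @param seed Integer seed for the residue/position vector table.
#' @param noise_sd Scale of the per-residue pseudo-random component.
#' @param class_centers Optional `K x width` matrix of class centers.
#' @param class_fun Optional function `sequence -> class index in 1..K`;
#'   defaults to a deterministic hash of the sequence modulo K.
#' @param max_length Truncation limit.
#' @return An `encoder_backend`.
#' @examples
#' enc <- synthetic_encoder(width = 8, seed = 1)
#' dim(embed_sequence("MKV", enc))
#' @export
synthetic_encoder <- function(width = 1280L, seed = 1L, noise_sd = 1,
                              class_centers = NULL, class_fun = NULL,
                              max_length = 4096L) {
  if (!is.null(class_centers)) {
    class_centers <- as.matrix(class_centers)
    stopifnot(ncol(class_centers) == width)
    if (is.null(class_fun)) {
      k <- nrow(class_centers)
      class_fun <- function(sequence) (string_hash(sequence) %% k) + 1L
    }
  }
  encode <- function(sequence) {
    chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    codes <- match(chars, AA_ALPHABET_EXT)
    mat <- matrix(0, nrow = length(codes), ncol = width)
    for (p in seq_along(codes)) {
      mat[p, ] <- with_seed(mix_seed(seed, codes[p], p),
                            stats::rnorm(width)) * noise_sd
    }
    if (!is.null(class_centers)) {
      cls <- class_fun(sequence)
      mat <- sweep(mat, 2L, class_centers[cls, ], "+")
    }
    mat
  }
  encoder_backend(name = sprintf("synthetic-w%d-s%d", width, seed),
                  width = width, encode = encode, max_length = max_length)
}

#' Embed one sequence through an encoder backend
#'
#' Validates the sequence (20 standard residues plus X, B, Z, U, O; an
#' illegal character raises an error naming its position), truncates it at
#' the backend's context limit with a warning, and returns the per-residue
#' embedding matrix. Results are cached per (backend, sequence) so repeated
#' calls are free.
#'
#' @param sequence Amino-acid string.
#' @param backend An `encoder_backend`.
#' @return Numeric matrix of shape `l x backend$width`.
#' @export
embed_sequence <- function(sequence, backend) {
  stopifnot(inherits(backend, "encoder_backend"))
  sequence <- check_aa_sequence(sequence)
  if (nchar(sequence) > backend$max_length) {
    warning(sprintf("sequence of length %d truncated to backend limit %d",
                    nchar(sequence), backend$max_length), call. = FALSE)
    sequence <- substr(sequence, 1L, backend$max_length)
  }
  key <- paste0(backend$name, ":", string_hash(sequence), ":", nchar(sequence))
  cached <- backend$cache[[key]]
  if (!is.null(cached)) return(cached)
  mat <- backend$encode(sequence)
  if (!is.matrix(mat) || nrow(mat) != nchar(sequence) ||
      ncol(mat) != backend$width || any(!is.finite(mat))) {
    stop("encoder backend violated its contract (shape or finiteness)")
  }
  backend$cache[[key]] <- mat
  mat
}

#' Pool a per-residue embedding matrix to one vector per sequence
#'
#' Collapses the residue axis of an `l x n` embedding matrix to a `1 x n`
#' vector. Mean pooling is the default (standard for protein language-model
#' classifier heads); max pooling is available as an option. Pooling is
#' invariant under permutation of rows and each pooled coordinate lies
#' within the column range of the input.
#'
#' @param matrix Numeric `l x n` matrix.
#' @param method `"mean"` or `"max"`.
#' @return Numeric vector of length `n`.
#' @examples
#' pool_embedding(rbind(c(1, 0), c(3, 2)))  # c(2, 1)
#' @export
pool_embedding <- function(matrix, method = c("mean", "max")) {
  method <- match.arg(method)
  if (!is.matrix(matrix) || nrow(matrix) < 1L || any(!is.finite(matrix))) {
    stop("matrix must be a finite numeric matrix with at least one row")
  }
  switch(method,
         mean = colMeans(matrix),
         max = apply(matrix, 2L, max))
}

#' Embed a set of sequences to pooled vectors
#'
#' Convenience wrapper: embeds each sequence and pools it, returning a
#' sample-by-feature matrix ready for the classifier.
#'
#' @param sequences Named character vector (or `AAStringSet`) of sequences.
#' @param backend An `encoder_backend`.
#' @param pooling Pooling method, see [pool_embedding()].
#' @return Numeric matrix, one row per sequence, `backend$width` columns,
#'   row names taken from `sequences`.
#' @export
embed_pooled <- function(sequences, backend, pooling = "mean") {
  if (inherits(sequences, "AAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  out <- matrix(0, nrow = length(sequences), ncol = backend$width,
                dimnames = list(names(sequences), NULL))
  for (i in seq_along(sequences)) {
    out[i, ] <- pool_embedding(embed_sequence(sequences[[i]], backend),
                               method = pooling)
  }
  out
}

# ---- embedding store ---------------------------------------------------

#' Write / read a pooled-embedding store
#'
#' The store is a single self-describing TSV: comment header lines carry
#' the backend name, width and pooling method; the body has one row per
#' accession followed by the embedding coordinates. Plain text keeps the
#' store portable and diffable.
#'
#' @param embeddings Numeric matrix with row names (accessions).
#' @param path Output file.
#' @param backend_name,pooling Metadata recorded in the header.
#' @return `write_embedding_store()` returns `path` invisibly;
#'   `read_embedding_store()` returns a list with `embeddings` (matrix) and
#'   `meta` (list: `backend`, `width`, `pooling`).
#' @export
write_embedding_store <- function(embeddings, path, backend_name = "unknown",
                                  pooling = "mean") {
  stopifnot(is.matrix(embeddings), !is.null(rownames(embeddings)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#backend=%s", backend_name),
               sprintf("#width=%d", ncol(embeddings)),
               sprintf("#pooling=%s", pooling)), con)
  df <- data.frame(accession = rownames(embeddings), embeddings,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_embedding_store
#' @export
read_embedding_store <- function(path) {
  header <- character(0)
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, 1L)
    if (length(line) == 0L || !startsWith(line, "#")) break
    header <- c(header, line)
  }
  meta <- list()
  for (h in header) {
    kv <- strsplit(sub("^#", "", h), "=", fixed = TRUE)[[1L]]
    meta[[kv[1L]]] <- kv[2L]
  }
  meta$width <- as.integer(meta$width)
  df <- utils::read.delim(path, skip = length(header), stringsAsFactors = FALSE)
  emb <- as.matrix(df[, -1L, drop = FALSE])
  rownames(emb) <- df[[1L]]
  colnames(emb) <- NULL
  if (!is.null(meta$width) && ncol(emb) != meta$width) {
    stop("embedding store width metadata does not match the data")
  }
  list(embeddings = emb, meta = list(backend = meta$backend,
                                     width = meta$width,
                                     pooling = meta$pooling))
}
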