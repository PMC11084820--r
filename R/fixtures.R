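# Seeded synthetic-data generators. Every stage of the pipeline — XML
# curation, embedding, training, evaluation — can be exercised offline on
# data with known ground truth. The generators are pure functions of
# (spec, seed).

#' Specification for synthetic NS fixtures
#'
#' Describes a class-conditional Gaussian-cluster dataset: one center per
#' NS label, points drawn as `center + noise`, with the class centers
#' themselves generated from the seed. Because the centers are draws from a
#' standard Gaussian in `width` dimensions, their pairwise distances
#' concentrate around `sqrt(2 * width)`; with the default `noise_sd = 0.1`
#' the clusters are separated by a wide margin, so a correct learner must
#' recover the labels almost perfectly — failures indicate implementation
#' bugs, not hard data.
#'
#' @param n_per_class Points generated per NS label.
#' @param width Embedding width; a reduced width (default 32) keeps tests
#'   fast, the full 1280 contract is exercised separately.
#' @param noise_sd Standard deviation of the isotropic Gaussian noise
#'   around each class center.
#' @param seed Integer seed; all generator output is a pure function of
#'   the spec including this seed.
#' @param length_range Range of generated sequence lengths.
#' @param ns_labels NS label set (one cluster per label).
#' @return A list of class `fixture_spec`, including the generated
#'   `class_centers` matrix.
#' @export
fixture_spec <- function(n_per_class = 30L, width = 32L, noise_sd = 0.1,
                         seed = 1L, length_range = c(50L, 100L),
                         ns_labels = NS_LABELS_DEFAULT) {
  stopifnot(n_per_class >= 1L, width >= 2L, noise_sd >= 0,
            length(length_range) == 2L, length_range[1L] >= 1L,
            length_range[1L] <= length_range[2L])
  centers <- with_seed(mix_seed(seed, 7L),
                       matrix(stats::rnorm(length(ns_labels) * width),
                              nrow = length(ns_labels), ncol = width))
  if (any(dist(centers) == 0)) stop("class centers must be pairwise distinct")
  structure(list(n_per_class = as.integer(n_per_class),
                 width = as.integer(width), noise_sd = noise_sd,
                 seed = as.integer(seed),
                 length_range = as.integer(length_range),
                 ns_labels = sort(as.integer(ns_labels)),
                 class_centers = centers),
            class = "fixture_spec")
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Generate toy UniProt-dialect XML
#'
#' Writes a well-formed UniProt-style document from a table of entry
#' descriptors, suitable for exercising the curation pipeline end to end.
#' Evidence codes are emitted the way real entries carry them: the subunit
#' comment's `<text>` node references numeric keys that resolve through
#' entry-level `<evidence>` elements. Generated documents round-trip
#' losslessly through [parse_uniprot_xml()].
#'
#' @param entries Data frame of descriptors with columns `accession` and
#'   `sequence` (required) and optionally `subunit_text`, `evidence_codes`
#'   (semicolon-joined ECO ids), `ec_numbers` (semicolon-joined),
#'   `organism`, `protein_name`, `is_fragment`.
#' @param path Optional output file; when `NULL` the XML text is returned.
#' @param namespaced Emit the UniProt namespace declaration.
#' @return The XML text (invisibly when written to `path`).
#' @export
make_toy_xml <- function(entries, path = NULL, namespaced = TRUE) {
  stopifnot(is.data.frame(entries))
  if (nrow(entries) > 0L &&
      (!all(c("accession", "sequence") %in% names(entries)) ||
       any(is.na(entries$accession)) || any(!nzchar(entries$accession)) ||
       any(is.na(entries$sequence)) || any(!nzchar(entries$sequence)))) {
    stop("invalid descriptor: every entry needs a non-empty accession and sequence")
  }
  col <- function(name, default) {
    if (name %in% names(entries)) {
      v <- entries[[name]]
      v[is.na(v)] <- default
      v
    } else rep(default, nrow(entries))
  }
  subunit <- col("subunit_text", "")
  evidence <- col("evidence_codes", "")
  ec <- col("ec_numbers", "")
  organism <- col("organism", "synthetic organism")
  pname <- col("protein_name", "synthetic protein")
  fragment <- col("is_fragment", FALSE)
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             if (namespaced) '<uniprot xmlns="http://uniprot.org/uniprot">'
             else "<uniprot>")
  for (i in seq_len(nrow(entries))) {
    lines <- c(lines, '  <entry dataset="Swiss-Prot">',
               sprintf("    <accession>%s</accession>",
                       xml_escape(entries$accession[i])),
               "    <protein>", "      <recommendedName>",
               sprintf("        <fullName>%s</fullName>", xml_escape(pname[i])))
    for (e in strsplit(ec[i], ";", fixed = TRUE)[[1L]]) {
      if (nzchar(e)) lines <- c(lines,
                                sprintf("        <ecNumber>%s</ecNumber>",
                                        xml_escape(e)))
    }
    lines <- c(lines, "      </recommendedName>", "    </protein>",
               "    <organism>",
               sprintf('      <name type="scientific">%s</name>',
                       xml_escape(organism[i])),
               "    </organism>")
    codes <- strsplit(evidence[i], ";", fixed = TRUE)[[1L]]
    codes <- codes[nzchar(codes)]
    if (nzchar(subunit[i])) {
      keys <- if (length(codes) > 0L) {
        sprintf(' evidence="%s"', paste(seq_along(codes), collapse = " "))
      } else ""
      lines <- c(lines, '    <comment type="subunit">',
                 sprintf("      <text%s>%s</text>", keys,
                         xml_escape(subunit[i])),
                 "    </comment>")
    }
    for (k in seq_along(codes)) {
      lines <- c(lines, sprintf('    <evidence key="%d" type="%s"/>',
                                k, xml_escape(codes[k])))
    }
    frag_attr <- if (isTRUE(fragment[i])) ' fragment="single"' else ""
    lines <- c(lines,
               sprintf('    <sequence length="%d"%s>%s</sequence>',
                       nchar(entries$sequence[i]), frag_attr,
                       xml_escape(entries$sequence[i])),
               "  </entry>")
  }
  lines <- c(lines, "</uniprot>")
  xml <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(xml, path)
    return(invisible(xml))
  }
  xml
}

#' Generate class-conditional pooled embeddings
#'
#' Draws `n_per_class` points per NS label as `class center + Gaussian
#' noise` (standard deviation `spec$noise_sd`), seeded. With
#' `noise_sd = 0` every point equals its class center exactly; with noise
#' far below the inter-center distance the clusters remain linearly
#' separable and a nearest-centroid rule recovers every label.
#'
#' @param spec A [fixture_spec()].
#' @return List with `x` (matrix, one pooled embedding per row, row names
#'   `S1..Sn`), `labels` (integer NS labels), and `centers`.
#' @export
make_synthetic_embeddings <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  k <- length(spec$ns_labels)
  n <- k * spec$n_per_class
  with_seed(mix_seed(spec$seed, 11L), {
    labels <- rep(spec$ns_labels, each = spec$n_per_class)
    cls <- rep(seq_len(k), each = spec$n_per_class)
    noise <- matrix(stats::rnorm(n * spec$width, sd = spec$noise_sd),
                    nrow = n, ncol = spec$width)
    x <- spec$class_centers[cls, , drop = FALSE] + noise
    rownames(x) <- paste0("S", seq_len(n))
    list(x = x, labels = labels, centers = spec$class_centers)
  })
}

#' Generate synthetic FASTA sequences with hidden class assignments
#'
#' Produces random amino-acid sequences whose class is a deterministic
#' hash of the sequence itself — the same label function the synthetic
#' encoder uses to add class-center offsets. Embedding these sequences
#' with [make_fixture_encoder()] therefore yields class-conditional pooled
#' vectors, enabling end-to-end FASTA-to-prediction tests with known
#' ground truth. Sequences are drawn (rejection-sampled per class) until
#' each label has exactly `n_per_class` representatives.
#'
#' @param spec A [fixture_spec()].
#' @param path Optional FASTA output path.
#' @return List with `sequences` (named character vector, names
#'   `SYN0001..`), `labels` (hidden NS labels, parallel to `sequences`),
#'   and `fasta` (path, when written).
#' @export
make_synthetic_sequences <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  k <- length(spec$ns_labels)
  aa20 <- AA_ALPHABET_EXT[1:20]
  with_seed(mix_seed(spec$seed, 13L), {
    seqs <- character(0)
    labels <- integer(0)
    quota <- stats::setNames(rep(spec$n_per_class, k), seq_len(k))
    guard <- 0L
    while (any(quota > 0L)) {
      guard <- guard + 1L
      if (guard > 10000L * k * spec$n_per_class) {
        stop("sequence generation failed to fill the class quota")
      }
      len <- sample(spec$length_range[1L]:spec$length_range[2L], 1L)
      s <- paste(sample(aa20, len, replace = TRUE), collapse = "")
      cls <- (string_hash(s) %% k) + 1L
      if (quota[[cls]] > 0L && !s %in% seqs) {
        seqs <- c(seqs, s)
        labels <- c(labels, spec$ns_labels[cls])
        quota[[cls]] <- quota[[cls]] - 1L
      }
    }
    names(seqs) <- sprintf("SYN%04d", seq_along(seqs))
    if (!is.null(path)) {
      Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
    }
    list(sequences = seqs, labels = labels, fasta = path)
  })
}

#' Encoder matched to a fixture spec
#'
#' Builds the synthetic encoder whose class centers, width, noise level
#' and label function match `spec`, so sequences from
#' [make_synthetic_sequences()] embed into the clusters the spec
#' describes.
#'
#' @param spec A [fixture_spec()].
#' @return An `encoder_backend`.
#' @export
make_fixture_encoder <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  k <- length(spec$ns_labels)
  synthetic_encoder(width = spec$width, seed = spec$seed,
                    noise_sd = spec$noise_sd,
                    class_centers = spec$class_centers,
                    class_fun = function(sequence) {
                      (string_hash(sequence) %% k) + 1L
                    })
}

#' Nearest-centroid classification
#'
#' The construction oracle for the synthetic clusters: assigns each row of
#' `x` the label of the nearest class center (Euclidean distance). On
#' fixtures with noise well below the center separation this rule attains
#' 100% accuracy, which bounds what a correct classifier must achieve.
#'
#' @param x Matrix of points (rows).
#' @param centers Matrix of class centers (rows).
#' @param labels Labels parallel to the center rows.
#' @return Vector of predicted labels.
#' @export
nearest_centroid <- function(x, centers, labels) {
  stopifnot(ncol(x) == ncol(centers), nrow(centers) == length(labels))
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) -
    2 * x %*% t(centers) +
    outer(rep(1, nrow(x)), rowSums(centers^2))
  labels[apply(d2, 1L, which.min)]
}
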