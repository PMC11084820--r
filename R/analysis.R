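# Dataset characterization: NS label distributions, EC-number
# stoichiometry diversity, and pairwise-identity analysis partitioned by
# label agreement.

#' NS label distribution
#'
#' Counts labeled proteins per NS label, optionally broken down by
#' organism. Counts always sum to the dataset size.
#'
#' @param proteins Labeled-protein data frame (see [build_ns_dataset()]).
#' @param by_organism Group counts by the `organism` column.
#' @return Data frame with columns `ns_label`, `count` (and `organism`
#'   first when requested), plus `proportion`.
#' @export
label_distribution <- function(proteins, by_organism = FALSE) {
  if (nrow(proteins) == 0L) {
    out <- data.frame(ns_label = integer(0), count = integer(0),
                      proportion = numeric(0))
    if (by_organism) out <- cbind(organism = character(0), out)
    return(out)
  }
  if (by_organism) {
    tab <- as.data.frame(table(organism = proteins$organism,
                               ns_label = proteins$ns_label),
                         stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0L, ]
    out <- data.frame(organism = tab$organism,
                      ns_label = as.integer(tab$ns_label),
                      count = tab$Freq, stringsAsFactors = FALSE)
    out <- out[order(out$organism, out$ns_label), ]
  } else {
    tab <- table(proteins$ns_label)
    out <- data.frame(ns_label = as.integer(names(tab)),
                      count = as.integer(tab))
  }
  out$proportion <- out$count / nrow(proteins)
  rownames(out) <- NULL
  out
}

split_ecs <- function(ec_numbers) {
  lapply(strsplit(ec_numbers, ";", fixed = TRUE),
         function(e) e[nzchar(e)])
}

#' NS diversity per EC number
#'
#' Groups labeled proteins by EC number (entries without an EC are
#' ignored; entries with several ECs count in each) and reports, per EC,
#' the member count, the set of NS labels observed, and the diversity
#' (number of distinct labels). Enzymes sharing an EC number but adopting
#' different oligomeric states — e.g. superoxide dismutases spanning
#' monomers to hexamers — surface at the top of this table.
#'
#' @param proteins Labeled-protein data frame.
#' @return List with `groups` (data frame `ec_number`, `n_proteins`,
#'   `ns_labels` (comma-joined, sorted), `diversity`, sorted by decreasing
#'   diversity) and `histogram` (data frame `diversity`, `n_ec`; bin counts
#'   sum to the number of distinct ECs).
#' @export
ec_ns_diversity <- function(proteins) {
  ecs <- split_ecs(proteins$ec_numbers %||% character(0))
  long <- data.frame(
    ec = unlist(ecs),
    label = rep(proteins$ns_label, lengths(ecs)),
    stringsAsFactors = FALSE)
  if (nrow(long) == 0L) {
    return(list(groups = data.frame(ec_number = character(0),
                                    n_proteins = integer(0),
                                    ns_labels = character(0),
                                    diversity = integer(0)),
                histogram = data.frame(diversity = integer(0),
                                       n_ec = integer(0))))
  }
  groups <- do.call(rbind, lapply(split(long$label, long$ec), function(lbls) {
    u <- sort(unique(lbls))
    data.frame(n_proteins = length(lbls),
               ns_labels = paste(u, collapse = ", "),
               diversity = length(u), stringsAsFactors = FALSE)
  }))
  groups <- data.frame(ec_number = rownames(groups), groups,
                       stringsAsFactors = FALSE, row.names = NULL)
  groups <- groups[order(-groups$diversity, groups$ec_number), ]
  rownames(groups) <- NULL
  htab <- table(groups$diversity)
  histogram <- data.frame(diversity = as.integer(names(htab)),
                          n_ec = as.integer(htab))
  list(groups = groups, histogram = histogram)
}

#' Percent identity of two sequences under global alignment
#'
#' Needleman–Wunsch global alignment with BLOSUM62 and affine gap
#' penalties (a length-k gap costs `gap_opening + k * gap_extension`).
#' Identity is defined as the number of identical aligned positions
#' divided by the alignment length, gaps included, times 100. Identity is
#' symmetric and every sequence is 100% identical to itself.
#'
#' @param a,b Amino-acid strings.
#' @param gap_opening,gap_extension Affine gap parameters.
#' @param substitution_matrix Scoring matrix name (passed to the aligner).
#' @return Percent identity in `[0, 100]`.
#' @examples
#' percent_identity("ACDE", "ACDF")  # 75
#' @export
percent_identity <- function(a, b, gap_opening = 10, gap_extension = 0.5,
                             substitution_matrix = "BLOSUM62") {
  a <- check_aa_sequence(a)
  b <- check_aa_sequence(b)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension)
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  100 * sum(pat == sub & pat != "-") / length(pat)
}

#' Pairwise identity of proteins sharing an EC number
#'
#' Forms all unordered pairs of dataset proteins that share at least one
#' EC number, samples up to `max_pairs` of them (seeded), and computes
#' global-alignment percent identity plus whether the two NS labels agree.
#' The comparison of the identity distributions of label-matching versus
#' label-mismatching pairs is the basis for the observation that sequence
#' similarity alone does not determine oligomeric state.
#'
#' @param proteins Labeled-protein data frame with `ec_numbers` and
#'   `sequence` columns.
#' @param max_pairs Cap on the number of aligned pairs.
#' @param seed Sampling seed.
#' @param ... Passed to [percent_identity()].
#' @return Data frame with columns `accession_a`, `accession_b`,
#'   `shared_ec`, `identity`, `label_match`. Pairs whose sequences contain
#'   illegal characters are skipped with a warning.
#' @export
pairwise_identity <- function(proteins, max_pairs = 1000L, seed = 1L, ...) {
  ecs <- split_ecs(proteins$ec_numbers)
  n <- nrow(proteins)
  cand <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      if (length(ecs[[i]]) == 0L) next
      for (j in seq((i + 1L), n)) {
        shared <- intersect(ecs[[i]], ecs[[j]])
        if (length(shared) > 0L) {
          cand[[length(cand) + 1L]] <- c(i, j, shared[1L])
        }
      }
    }
  }
  if (length(cand) > max_pairs) {
    cand <- with_seed(seed, sample(cand, max_pairs))
  }
  rows <- list()
  for (p in cand) {
    i <- as.integer(p[1L]); j <- as.integer(p[2L])
    ident <- tryCatch(
      percent_identity(proteins$sequence[i], proteins$sequence[j], ...),
      error = function(e) {
        warning(sprintf("skipping pair %s/%s: %s", proteins$accession[i],
                        proteins$accession[j], conditionMessage(e)),
                call. = FALSE)
        NA_real_
      })
    if (is.na(ident)) next
    rows[[length(rows) + 1L]] <- data.frame(
      accession_a = proteins$accession[i],
      accession_b = proteins$accession[j],
      shared_ec = p[3L], identity = ident,
      label_match = proteins$ns_label[i] == proteins$ns_label[j],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(accession_a = character(0), accession_b = character(0),
                      shared_ec = character(0), identity = numeric(0),
                      label_match = logical(0)))
  }
  do.call(rbind, rows)
}
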