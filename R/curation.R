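# Curation of NS (number-of-subunits) annotations from UniProt-dialect XML.
#
# UniProt records the oligomeric state of a protein as free text in a
# comment of type "subunit", with ECO evidence codes attached. The curation
# pipeline is: parse XML -> drop entries whose annotation is absent,
# similarity-inferred (ECO:0000250) or hedged ("By similarity", "Probable",
# "Potential") -> map the remaining descriptions to NS labels with a
# keyword-rule table.

# ---- parsing -----------------------------------------------------------

entry_fields <- function(node) {
  accession <- xml2::xml_text(xml2::xml_find_first(node, "./accession"))
  protein_name <- xml2::xml_text(
    xml2::xml_find_first(node, "./protein//fullName"))
  organism <- xml2::xml_text(
    xml2::xml_find_first(node, "./organism/name[@type='scientific']"))
  if (is.na(organism)) {
    organism <- xml2::xml_text(xml2::xml_find_first(node, "./organism/name"))
  }
  seq_node <- xml2::xml_find_first(node, "./sequence")
  sequence <- if (inherits(seq_node, "xml_missing")) NA_character_ else {
    gsub("\\s", "", xml2::xml_text(seq_node))
  }
  is_fragment <- !inherits(seq_node, "xml_missing") &&
    !is.na(xml2::xml_attr(seq_node, "fragment"))
  ec <- unique(xml2::xml_text(xml2::xml_find_all(node, ".//ecNumber")))

  comment <- xml2::xml_find_first(node, "./comment[@type='subunit']")
  subunit_text <- ""
  evidence_codes <- character(0)
  if (!inherits(comment, "xml_missing")) {
    text_node <- xml2::xml_find_first(comment, "./text")
    subunit_text <- if (inherits(text_node, "xml_missing")) {
      trimws(xml2::xml_text(comment))
    } else {
      trimws(xml2::xml_text(text_node))
    }
    # Evidence may be attached as key references ("1 2") resolved through
    # the entry's <evidence key=... type="ECO:..."/> elements, or inline.
    keys <- c(xml2::xml_attr(comment, "evidence"),
              if (!inherits(text_node, "xml_missing"))
                xml2::xml_attr(text_node, "evidence"))
    keys <- unlist(strsplit(keys[!is.na(keys)], "\\s+"))
    if (length(keys) > 0L) {
      ev_nodes <- xml2::xml_find_all(node, "./evidence")
      ev_map <- stats::setNames(xml2::xml_attr(ev_nodes, "type"),
                                xml2::xml_attr(ev_nodes, "key"))
      evidence_codes <- unique(c(
        keys[grepl("^ECO:\\d{7}$", keys)],
        unname(ev_map[keys[keys %in% names(ev_map)]])
      ))
      evidence_codes <- evidence_codes[!is.na(evidence_codes)]
    }
  }

  list(accession = accession, protein_name = protein_name %||% NA_character_,
       organism = organism, sequence = sequence,
       ec_numbers = paste(ec, collapse = ";"),
       subunit_text = subunit_text,
       evidence_codes = paste(evidence_codes, collapse = ";"),
       is_fragment = is_fragment)
}

entries_to_df <- function(rows) {
  if (length(rows) == 0L) {
    return(data.frame(
      accession = character(0), protein_name = character(0),
      organism = character(0), sequence = character(0),
      ec_numbers = character(0), subunit_text = character(0),
      evidence_codes = character(0), is_fragment = logical(0),
      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(rows, function(r) {
    data.frame(r, stringsAsFactors = FALSE)
  }))
}

parse_entry_node <- function(node) {
  f <- entry_fields(node)
  if (is.na(f$accession) || !nzchar(f$accession) ||
      is.na(f$sequence) || !nzchar(f$sequence)) {
    warning(sprintf("skipping entry without accession or sequence%s",
                    if (!is.na(f$accession)) paste0(" (", f$accession, ")") else ""),
            call. = FALSE)
    return(NULL)
  }
  f
}

#' Parse UniProt-dialect XML into a table of entries
#'
#' Reads protein entries from a UniProt-style XML document (namespaced or
#' not, plain or gzip-compressed) and extracts the fields the NS curation
#' pipeline needs: accession, protein name, organism, sequence, EC numbers,
#' the free text of the `subunit` comment and its ECO evidence codes, and
#' the fragment flag of the sequence record.
#'
#' With `streaming = TRUE` (default) the file is scanned incrementally:
#' each `<entry>` element is parsed and released as soon as it is complete,
#' so memory use is bounded by the largest entry rather than the file size.
#' The streaming and whole-document parses produce identical tables.
#'
#' Entries lacking an accession or a sequence are skipped with a warning.
#' Malformed XML raises an error reporting the approximate byte offset.
#'
#' @param source Path to an XML file (optionally `.gz`), or a character
#'   scalar containing XML text.
#' @param streaming Logical; parse incrementally (bounded memory) or load
#'   the whole document.
#' @param chunk_size Bytes read per chunk in streaming mode.
#' @return A data frame with one row per entry and columns `accession`,
#'   `protein_name`, `organism`, `sequence`, `ec_numbers`
#'   (semicolon-joined), `subunit_text` (empty string when the entry has no
#'   subunit comment), `evidence_codes` (semicolon-joined ECO identifiers
#'   attached to that comment), and `is_fragment`.
#' @seealso [filter_ns_evidence()], [build_ns_dataset()]
#' @export
parse_uniprot_xml <- function(source, streaming = TRUE, chunk_size = 65536L) {
  is_literal <- length(source) == 1L && grepl("<", source, fixed = TRUE)
  if (!is_literal && !file.exists(source)) {
    stop(sprintf("file not found: %s", source))
  }
  if (!streaming) {
    doc <- tryCatch(xml2::read_xml(source),
                    error = function(e) stop(sprintf(
                      "malformed XML at byte offset 0: %s", conditionMessage(e)),
                      call. = FALSE))
    xml2::xml_ns_strip(doc)
    nodes <- xml2::xml_find_all(doc, "//entry")
    rows <- Filter(Negate(is.null), lapply(nodes, parse_entry_node))
    return(entries_to_df(rows))
  }

  if (is_literal) {
    lit_pos <- 1L
    next_chunk <- function() {
      if (lit_pos > nchar(source)) return("")
      out <- substr(source, lit_pos, lit_pos + chunk_size - 1L)
      lit_pos <<- lit_pos + chunk_size
      out
    }
  } else {
    con <- if (grepl("\\.gz$", source)) gzfile(source, "rb") else file(source, "rb")
    on.exit(close(con))
    next_chunk <- function() readChar(con, chunk_size, useBytes = TRUE)
  }
  buf <- ""
  consumed <- 0
  rows <- list()
  repeat {
    chunk <- next_chunk()
    if (length(chunk) == 0L || nchar(chunk) == 0L) break
    buf <- paste0(buf, chunk)
    repeat {
      close_at <- regexpr("</entry>", buf, fixed = TRUE)
      if (close_at < 0L) break
      open_at <- regexpr("<entry[ >]", buf)
      if (open_at < 0L || open_at > close_at) {
        stop(sprintf("malformed XML at byte offset %.0f: '</entry>' without '<entry>'",
                     consumed + close_at), call. = FALSE)
      }
      entry_xml <- substr(buf, open_at, close_at + attr(close_at, "match.length") - 1L)
      node <- tryCatch(xml2::read_xml(entry_xml),
                       error = function(e) stop(sprintf(
                         "malformed XML at byte offset %.0f: %s",
                         consumed + open_at, conditionMessage(e)), call. = FALSE))
      xml2::xml_ns_strip(node)
      row <- parse_entry_node(node)
      if (!is.null(row)) rows[[length(rows) + 1L]] <- row
      drop_n <- close_at + attr(close_at, "match.length") - 1L
      consumed <- consumed + drop_n
      buf <- substr(buf, drop_n + 1L, nchar(buf))
    }
  }
  # Whatever remains must be document framing only, not an unterminated entry.
  if (regexpr("<entry[ >]", buf) > 0L) {
    stop(sprintf("malformed XML at byte offset %.0f: unterminated <entry>",
                 consumed), call. = FALSE)
  }
  entries_to_df(rows)
}

# ---- evidence / qualifier filtering ------------------------------------

QUALIFIER_STRINGS <- c("By similarity", "Probable", "Potential")

#' Evidence and qualifier filtering of parsed entries
#'
#' Decides, entry by entry, whether a parsed record is reliable enough to
#' carry an NS label. An entry is discarded iff (checked in this order,
#' first match gives the reason):
#'
#' 1. `"no-subunit-description"` — the subunit comment is absent;
#' 2. `"similarity-evidence"` — the comment's evidence includes
#'    `ECO:0000250` (annotation inferred from sequence similarity rather
#'    than direct experiment);
#' 3. `"qualifier"` — the description contains one of the hedging phrases
#'    "By similarity", "Probable" or "Potential".
#'
#' @param entries Data frame from [parse_uniprot_xml()].
#' @return A data frame with columns `retain` (logical) and `reason`
#'   (`NA` for retained entries).
#' @export
filter_ns_evidence <- function(entries) {
  n <- nrow(entries)
  retain <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (!nzchar(entries$subunit_text[i])) {
      retain[i] <- FALSE; reason[i] <- "no-subunit-description"
    } else if ("ECO:0000250" %in% strsplit(entries$evidence_codes[i], ";")[[1L]]) {
      retain[i] <- FALSE; reason[i] <- "similarity-evidence"
    } else if (any(vapply(QUALIFIER_STRINGS, grepl, logical(1L),
                          x = entries$subunit_text[i], fixed = TRUE))) {
      retain[i] <- FALSE; reason[i] <- "qualifier"
    }
  }
  data.frame(retain = retain, reason = reason, stringsAsFactors = FALSE)
}

# ---- pipeline ----------------------------------------------------------

#' Build a labeled NS dataset from UniProt-dialect XML
#'
#' Runs the full curation pipeline: parse the XML, apply the evidence and
#' qualifier filters ([filter_ns_evidence()]), then assign NS labels with
#' the keyword-rule table ([assign_ns_label()]). Entries whose description
#' matches no rule, or several base keywords, are dropped as `"unlabeled"`.
#' Fragment sequences are retained by default; `drop_fragments = TRUE`
#' removes them (reason `"fragment"`, applied after the evidence filters).
#'
#' The companion report satisfies the conservation law
#' `parsed = retained + sum(per-reason discards)`.
#'
#' @param xml_source Path or XML text, as for [parse_uniprot_xml()].
#' @param rules Keyword-rule table.
#' @param drop_fragments Drop entries flagged as sequence fragments.
#' @param streaming Passed to [parse_uniprot_xml()].
#' @return A list of class `ns_dataset` with elements `proteins` (data
#'   frame: `accession`, `organism`, `ns_label`, `matched_rule`,
#'   `ec_numbers`, `sequence`) and `report` (named integer vector of
#'   counts: `parsed`, `retained`, and per-reason discards).
#' @examples
#' xml <- make_toy_xml(data.frame(
#'   accession = c("P1", "P2"),
#'   sequence = c("MKV", "MKL"),
#'   subunit_text = c("Homodimer.", "Monomer (By similarity).")))
#' build_ns_dataset(xml)
#' @export
build_ns_dataset <- function(xml_source, rules = default_keyword_rules(),
                             drop_fragments = FALSE, streaming = TRUE) {
  rules <- validate_keyword_rules(rules)
  entries <- parse_uniprot_xml(xml_source, streaming = streaming)
  report <- c("no-subunit-description" = 0L, "similarity-evidence" = 0L,
              "qualifier" = 0L, "fragment" = 0L, "unlabeled" = 0L)
  flt <- filter_ns_evidence(entries)
  for (r in flt$reason[!flt$retain]) report[r] <- report[r] + 1L
  kept <- entries[flt$retain, , drop = FALSE]
  if (drop_fragments && nrow(kept) > 0L) {
    report["fragment"] <- sum(kept$is_fragment)
    kept <- kept[!kept$is_fragment, , drop = FALSE]
  }
  labels <- integer(0); rules_fired <- character(0); keep_idx <- integer(0)
  for (i in seq_len(nrow(kept))) {
    res <- assign_ns_label(kept$subunit_text[i], rules)
    if (is.na(res$label)) {
      report["unlabeled"] <- report["unlabeled"] + 1L
    } else {
      keep_idx <- c(keep_idx, i)
      labels <- c(labels, res$label)
      rules_fired <- c(rules_fired, res$rule)
    }
  }
  kept <- kept[keep_idx, , drop = FALSE]
  proteins <- data.frame(
    accession = kept$accession, organism = kept$organism,
    ns_label = labels, matched_rule = rules_fired,
    ec_numbers = kept$ec_numbers, sequence = kept$sequence,
    stringsAsFactors = FALSE, row.names = NULL)
  report <- c(parsed = nrow(entries), retained = nrow(proteins), report)
  structure(list(proteins = proteins, report = report), class = "ns_dataset")
}

#' @export
print.ns_dataset <- function(x, ...) {
  cat(sprintf("NS dataset: %d labeled proteins (of %d parsed entries)\n",
              x$report[["retained"]], x$report[["parsed"]]))
  drops <- x$report[setdiff(names(x$report), c("parsed", "retained"))]
  drops <- drops[drops > 0L]
  if (length(drops) > 0L) {
    cat("discarded:", paste(sprintf("%s=%d", names(drops), drops), collapse = ", "),
        "\n")
  }
  if (x$report[["retained"]] > 0L) {
    print(table(NS = x$proteins$ns_label))
  }
  invisible(x)
}

#' Write a curated NS dataset to TSV + FASTA
#'
#' Writes `<prefix>.tsv` with columns `accession`, `organism`, `ns_label`,
#' `matched_rule`, `ec_numbers`, `sequence`, and `<prefix>.fasta` keyed by
#' accession.
#'
#' @param dataset An `ns_dataset` (or its `proteins` data frame).
#' @param prefix Output path prefix.
#' @return The two paths, invisibly.
#' @export
write_ns_dataset <- function(dataset, prefix) {
  proteins <- if (inherits(dataset, "ns_dataset")) dataset$proteins else dataset
  tsv <- paste0(prefix, ".tsv")
  fasta <- paste0(prefix, ".fasta")
  utils::write.table(proteins, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  seqs <- Biostrings::AAStringSet(stats::setNames(proteins$sequence,
                                                  proteins$accession))
  Biostrings::writeXStringSet(seqs, fasta)
  invisible(c(tsv, fasta))
}

#' Read a curated NS dataset written by [write_ns_dataset()]
#' @param path Path to the TSV file.
#' @return The `proteins` data frame.
#' @export
read_ns_dataset <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$ns_label <- as.integer(df$ns_label)
  # all-empty columns must stay character, not collapse to logical NA
  for (col in c("accession", "organism", "matched_rule", "ec_numbers",
                "sequence")) {
    if (col %in% names(df)) {
      df[[col]] <- as.character(df[[col]])
      df[[col]][is.na(df[[col]])] <- ""
    }
  }
  df
}
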