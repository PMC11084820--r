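# Keyword-rule tables mapping subunit-comment phrases to NS labels.

#' Default keyword-rule table for NS label assignment
#'
#' Returns the built-in mapping from subunit-comment keywords to the number
#' of subunits (NS). Two tiers exist:
#'
#' * *compound* rules such as `"homooctamer of"` (priority tier 1). These
#'   describe an assembly built from smaller units — e.g. retinoschisin,
#'   annotated "Homooctamer of 4 homodimers" — and must win over the base
#'   keywords they contain, so they are applied first and decide the label
#'   immediately.
#' * *base* keywords `monomer`, `homodimer`, ..., `homododecamer`
#'   (priority tier 2). A comment matching exactly one base keyword gets
#'   that label; zero or two or more distinct base keywords leave the entry
#'   unlabeled.
#'
#' The label set is \{1, 2, 3, 4, 5, 6, 7, 8, 10, 12\}. The table is plain
#' data so users can load a custom mapping with [read_keyword_rules()].
#'
#' @return A data frame with columns `pattern` (literal keyword phrase),
#'   `label` (NS integer), `priority` (lower = applied first, unique), and
#'   `compound` (logical).
#' @examples
#' default_keyword_rules()
#' @export
default_keyword_rules <- function() {
  base_words <- c(
    monomer = 1L, homodimer = 2L, homotrimer = 3L, homotetramer = 4L,
    homopentamer = 5L, homohexamer = 6L, homoheptamer = 7L,
    homooctamer = 8L, homodecamer = 10L, homododecamer = 12L
  )
  oligo <- base_words[base_words > 1L]
  rules <- rbind(
    data.frame(
      pattern = paste(names(oligo), "of"),
      label = unname(oligo),
      compound = TRUE,
      stringsAsFactors = FALSE
    ),
    data.frame(
      pattern = names(base_words),
      label = unname(base_words),
      compound = FALSE,
      stringsAsFactors = FALSE
    )
  )
  rules$priority <- seq_len(nrow(rules))
  rules[, c("pattern", "label", "priority", "compound")]
}

validate_keyword_rules <- function(rules) {
  needed <- c("pattern", "label", "priority", "compound")
  if (!is.data.frame(rules) || !all(needed %in% names(rules))) {
    stop("rules must be a data frame with columns pattern, label, priority, compound")
  }
  if (any(!nzchar(rules$pattern))) stop("rule patterns must be non-empty")
  if (anyDuplicated(rules$priority)) {
    stop("configuration error: duplicate priorities in rule table")
  }
  if (!all(rules$label %in% NS_LABELS_DEFAULT)) {
    stop("rule labels must lie in {1,2,3,4,5,6,7,8,10,12}")
  }
  rules[order(rules$priority), , drop = FALSE]
}

# Whole-word, case-insensitive regex for a keyword phrase. Words ending in
# "mer" accept an optional plural "s" ("homodimers" matches "homodimer").
rule_regex <- function(pattern) {
  words <- strsplit(tolower(pattern), "\\s+")[[1L]]
  words <- vapply(words, function(w) {
    w <- gsub("([.\\\\+*?\\[\\]$(){}=!<>|:#^-])", "\\\\\\1", w, perl = TRUE)
    if (grepl("mer$", w)) paste0(w, "s?") else w
  }, character(1L))
  paste0("\\b", paste(words, collapse = "\\s+"), "\\b")
}

#' Assign an NS label to a subunit description
#'
#' Applies a keyword-rule table to the free text of a subunit comment.
#' Compound rules (e.g. `"homooctamer of"`) are tested first in priority
#' order and decide the label immediately; otherwise the label of the single
#' matching base keyword is used. Zero or multiple distinct base keywords
#' yield no label (`NA`), keeping ambiguous descriptions such as
#' "Homodimer; can also form homotetramers." out of the dataset.
#' Matching is case-insensitive on whole words, with optional plurals.
#'
#' @param subunit_text Character scalar, the subunit comment text.
#' @param rules Rule table as returned by [default_keyword_rules()].
#' @return A list with `label` (NS integer, or `NA_integer_` if unlabeled)
#'   and `rule` (the pattern that fired, or `NA_character_`).
#' @examples
#' assign_ns_label("Homooctamer of 4 homodimers; disulfide-linked.")
#' assign_ns_label("Monomer.")
#' assign_ns_label("Homodimer; can also form homotetramers.")
#' @export
assign_ns_label <- function(subunit_text, rules = default_keyword_rules()) {
  rules <- validate_keyword_rules(rules)
  if (!is.character(subunit_text) || length(subunit_text) != 1L) {
    stop("subunit_text must be a character scalar")
  }
  text <- tolower(subunit_text)
  compound <- rules[rules$compound, , drop = FALSE]
  for (i in seq_len(nrow(compound))) {
    if (grepl(rule_regex(compound$pattern[i]), text, perl = TRUE)) {
      return(list(label = as.integer(compound$label[i]),
                  rule = compound$pattern[i]))
    }
  }
  base <- rules[!rules$compound, , drop = FALSE]
  hit <- vapply(base$pattern, function(p) grepl(rule_regex(p), text, perl = TRUE),
                logical(1L))
  if (sum(hit) == 1L) {
    list(label = as.integer(base$label[hit]), rule = base$pattern[hit])
  } else {
    list(label = NA_integer_, rule = NA_character_)
  }
}

#' Read or write a keyword-rule table
#'
#' Rule tables are stored either as TSV with columns
#' `pattern`, `label`, `priority`, `compound`, or as YAML (a list of records
#' with the same fields). The format is chosen from the file extension.
#'
#' @param path File path ending in `.tsv`, `.yml` or `.yaml`.
#' @return `read_keyword_rules()` returns a validated rule data frame;
#'   `write_keyword_rules()` returns `path` invisibly.
#' @export
read_keyword_rules <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    recs <- yaml::read_yaml(path)
    rules <- do.call(rbind, lapply(recs, function(r) {
      data.frame(pattern = r$pattern, label = as.integer(r$label),
                 priority = as.integer(r$priority),
                 compound = isTRUE(r$compound), stringsAsFactors = FALSE)
    }))
  } else {
    rules <- utils::read.delim(path, stringsAsFactors = FALSE)
    rules$label <- as.integer(rules$label)
    rules$priority <- as.integer(rules$priority)
    rules$compound <- as.logical(rules$compound)
  }
  validate_keyword_rules(rules)
}

#' @rdname read_keyword_rules
#' @param rules Rule data frame to write.
#' @export
write_keyword_rules <- function(rules, path) {
  rules <- validate_keyword_rules(rules)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    recs <- lapply(seq_len(nrow(rules)), function(i) {
      list(pattern = rules$pattern[i], label = rules$label[i],
           priority = rules$priority[i], compound = rules$compound[i])
    })
    yaml::write_yaml(recs, path)
  } else {
    utils::write.table(rules, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
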