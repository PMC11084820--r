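# UniProt-dialect XML parsing, evidence filtering and NS label assignment.

test_that("parsing extracts fields and handles absent subunit comments", {
  xml <- make_toy_xml(data.frame(
    accession = c("P10000", "P20000"),
    sequence = c("MKVLA", "MACDE"),
    subunit_text = c("Homodimer.", ""),
    evidence_codes = c("ECO:0000250", ""),
    ec_numbers = c("1.1.1.1;2.7.7.7", ""),
    organism = c("Escherichia coli", "Homo sapiens")))
  entries <- parse_uniprot_xml(xml)
  expect_equal(nrow(entries), 2L)
  expect_equal(entries$accession, c("P10000", "P20000"))
  expect_equal(entries$sequence, c("MKVLA", "MACDE"))
  expect_equal(entries$organism[1], "Escherichia coli")
  expect_equal(entries$ec_numbers[1], "1.1.1.1;2.7.7.7")
  expect_equal(entries$subunit_text, c("Homodimer.", ""))
  # evidence attached to the subunit comment resolves to ECO identifiers
  expect_true("ECO:0000250" %in% strsplit(entries$evidence_codes[1], ";")[[1]])
  expect_equal(entries$evidence_codes[2], "")
})

test_that("streaming parse equals whole-document parse field for field", {
  desc <- random_entry_descriptors(300, seed = 42)
  path <- withr::local_tempfile(fileext = ".xml")
  make_toy_xml(desc, path = path)
  dom <- parse_uniprot_xml(path, streaming = FALSE)
  for (chunk in c(256L, 4096L, 65536L)) {
    stream <- parse_uniprot_xml(path, streaming = TRUE, chunk_size = chunk)
    expect_equal(stream, dom, info = sprintf("chunk size %d", chunk))
  }
})

test_that("namespaced and namespace-free dialects parse identically", {
  desc <- toy_entries_six()
  a <- parse_uniprot_xml(make_toy_xml(desc, namespaced = TRUE))
  b <- parse_uniprot_xml(make_toy_xml(desc, namespaced = FALSE))
  expect_equal(a, b)
})

test_that("entries lacking accession or sequence are skipped with a warning", {
  xml <- paste0(
    "<uniprot><entry><accession>P1</accession>",
    "<sequence>MKV</sequence></entry>",
    "<entry><accession>P2</accession></entry></uniprot>")
  expect_warning(entries <- parse_uniprot_xml(xml), "skipping entry")
  expect_equal(entries$accession, "P1")
})

test_that("malformed XML raises an error naming a byte offset", {
  bad <- "<uniprot><entry><accession>P1</accession><sequence>MKV</entry></uniprot>"
  expect_error(parse_uniprot_xml(bad), "byte offset")
  expect_error(parse_uniprot_xml("<uniprot></entry></uniprot>"), "byte offset")
})

test_that("gzip-compressed input parses like plain text", {
  desc <- toy_entries_six()
  plain <- withr::local_tempfile(fileext = ".xml")
  make_toy_xml(desc, path = plain)
  gz <- withr::local_tempfile(fileext = ".xml.gz")
  con <- gzfile(gz, "w")
  writeLines(readLines(plain), con)
  close(con)
  expect_equal(parse_uniprot_xml(gz), parse_uniprot_xml(plain))
})

test_that("evidence filter discards with exactly one reason, in order", {
  entries <- parse_uniprot_xml(make_toy_xml(data.frame(
    accession = c("A1", "A2", "A3", "A4", "A5"),
    sequence = rep("MKV", 5),
    subunit_text = c("", "Homodimer (By similarity).", "Homodimer.",
                     "Monomer. Potential.",
                     "Homodimer (By similarity)."),
    evidence_codes = c("", "", "ECO:0000269", "ECO:0000269", "ECO:0000250"))))
  flt <- filter_ns_evidence(entries)
  expect_equal(flt$retain, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  # reason (a) no description, then (b) similarity evidence, then (c) qualifier
  expect_equal(flt$reason,
               c("no-subunit-description", "qualifier", NA,
                 "qualifier", "similarity-evidence"))
})

test_that("keyword rules assign labels with compound-first priority", {
  # compound phrase wins over both base keywords it contains
  res <- assign_ns_label("Homooctamer of 4 homodimers; disulfide-linked")
  expect_equal(res$label, 8L)
  expect_equal(res$rule, "homooctamer of")
  expect_equal(assign_ns_label("Monomer.")$label, 1L)
  expect_equal(assign_ns_label("Forms homotetramers in solution.")$label, 4L)
  # zero or >= 2 distinct base keywords -> unlabeled
  expect_true(is.na(assign_ns_label("Homodimer; can also form homotetramers.")$label))
  expect_true(is.na(assign_ns_label("Interacts with RAD51.")$label))
  # case-insensitive whole-word matching; "homodimers" is not "homodecamer"
  expect_equal(assign_ns_label("HOMODIMER.")$label, 2L)
  expect_equal(assign_ns_label("Homodecamer.")$label, 10L)
})

test_that("duplicate rule priorities are a configuration error", {
  rules <- default_keyword_rules()
  rules$priority[2] <- rules$priority[1]
  expect_error(assign_ns_label("Monomer.", rules), "duplicate priorities")
})

test_that("rule order in the table does not matter, only priority does", {
  rules <- default_keyword_rules()
  texts <- c("Monomer.", "Homooctamer of 4 homodimers.", "Homotetramer.",
             "Homodimer; can also form homotetramers.", "Homododecamer.")
  for (seed in 1:5) {
    set.seed(seed)
    shuffled <- rules[sample(nrow(rules)), ]
    for (tx in texts) {
      expect_identical(assign_ns_label(tx, shuffled)$label,
                       assign_ns_label(tx, rules)$label)
    }
  }
})

test_that("build_ns_dataset composes the pipeline and reports conservation", {
  ds <- build_ns_dataset(make_toy_xml(toy_entries_six()))
  expect_s3_class(ds, "ns_dataset")
  expect_equal(nrow(ds$proteins), 2L)
  expect_equal(sort(ds$proteins$ns_label), c(1L, 8L))
  expect_equal(ds$report[["no-subunit-description"]], 1L)
  expect_equal(ds$report[["similarity-evidence"]], 1L)
  expect_equal(ds$report[["qualifier"]], 1L)
  expect_equal(ds$report[["unlabeled"]], 1L)
  # conservation: parsed = retained + sum of per-reason discards
  drops <- ds$report[setdiff(names(ds$report), c("parsed", "retained"))]
  expect_equal(ds$report[["parsed"]], ds$report[["retained"]] + sum(drops))
})

test_that("empty XML yields an empty dataset and an all-zero report", {
  ds <- build_ns_dataset(make_toy_xml(data.frame()))
  expect_equal(nrow(ds$proteins), 0L)
  expect_true(all(ds$report == 0L))
})

test_that("conservation holds on random fixtures, with and without fragments", {
  for (seed in c(7, 19)) {
    desc <- random_entry_descriptors(60, seed = seed)
    for (drop_frag in c(FALSE, TRUE)) {
      ds <- build_ns_dataset(make_toy_xml(desc), drop_fragments = drop_frag)
      drops <- ds$report[setdiff(names(ds$report), c("parsed", "retained"))]
      expect_equal(ds$report[["parsed"]], ds$report[["retained"]] + sum(drops))
      expect_equal(ds$report[["parsed"]], 60L)
    }
  }
})

test_that("fragments are retained by default and dropped on request", {
  desc <- data.frame(accession = c("F1", "F2"), sequence = c("MKV", "MKL"),
                     subunit_text = c("Monomer.", "Monomer."),
                     evidence_codes = "ECO:0000269",
                     is_fragment = c(TRUE, FALSE))
  expect_equal(nrow(build_ns_dataset(make_toy_xml(desc))$proteins), 2L)
  ds <- build_ns_dataset(make_toy_xml(desc), drop_fragments = TRUE)
  expect_equal(ds$proteins$accession, "F2")
  expect_equal(ds$report[["fragment"]], 1L)
})

test_that("curated datasets round-trip through TSV + FASTA", {
  ds <- build_ns_dataset(make_toy_xml(toy_entries_six()))
  prefix <- file.path(withr::local_tempdir(), "curated")
  paths <- write_ns_dataset(ds, prefix)
  back <- read_ns_dataset(paste0(prefix, ".tsv"))
  expect_equal(back$accession, ds$proteins$accession)
  expect_equal(back$ns_label, ds$proteins$ns_label)
  fasta <- Biostrings::readAAStringSet(paste0(prefix, ".fasta"))
  expect_equal(names(fasta), ds$proteins$accession)
  expect_equal(as.character(fasta), setNames(ds$proteins$sequence,
                                             ds$proteins$accession))
})

test_that("rule tables round-trip through TSV and YAML", {
  rules <- default_keyword_rules()
  for (ext in c(".tsv", ".yaml")) {
    path <- withr::local_tempfile(fileext = ext)
    write_keyword_rules(rules, path)
    back <- read_keyword_rules(path)
    rownames(back) <- NULL
    expect_equal(back, rules)
  }
})
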