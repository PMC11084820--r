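# Independent oracles and small fixture builders used across the suite.
# Each oracle recomputes a quantity by a different route than the package
# (brute force, enumeration, or explicit scalar arithmetic) so agreement
# is evidence of correctness, not of shared code.

# ---- entry descriptors --------------------------------------------------

toy_entries_six <- function() {
  data.frame(
    accession = c("P1", "P2", "P3", "P4", "P5", "P6"),
    sequence = c("MKV", "MKL", "MKI", "MKT", "MKR", "MKW"),
    subunit_text = c("",
                     "Homodimer.",
                     "Monomer (Probable).",
                     "Homodimer; can also form homotetramers.",
                     "Homooctamer of 4 homodimers; disulfide-linked.",
                     "Monomer."),
    evidence_codes = c("", "ECO:0000250", "ECO:0000269", "",
                       "ECO:0000269", "ECO:0000305"),
    ec_numbers = c("", "1.1.1.1", "", "", "1.1.1.1", "2.2.2.2"),
    organism = c("Org A", "Org A", "Org B", "Org B", "Org C", "Org C"),
    stringsAsFactors = FALSE)
}

random_entry_descriptors <- function(n, seed) {
  set.seed(seed)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  texts <- c("", "Monomer.", "Homodimer.", "Homotetramer.",
             "Homooctamer of 4 homodimers.", "Monomer (By similarity).",
             "Binds DNA & RNA as a <dimer>.",
             "Homodimer; can also form homotetramers.")
  data.frame(
    accession = sprintf("Q%05d", seq_len(n)),
    sequence = vapply(seq_len(n), function(i) {
      paste(sample(aa, sample(5:40, 1), replace = TRUE), collapse = "")
    }, character(1)),
    subunit_text = sample(texts, n, replace = TRUE),
    evidence_codes = sample(c("", "ECO:0000250", "ECO:0000269",
                              "ECO:0000269;ECO:0000305"), n, replace = TRUE),
    ec_numbers = sample(c("", "1.1.1.1", "2.7.7.7", "1.1.1.1;2.7.7.7"),
                        n, replace = TRUE),
    organism = sample(c("Escherichia coli", "Homo sapiens"), n, replace = TRUE),
    is_fragment = sample(c(TRUE, FALSE), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# ---- macro-metrics brute force -----------------------------------------

# Per-class metrics computed scalar by scalar from first principles.
brute_macro_metrics <- function(counts) {
  total <- attr(counts, "total")
  n_cls <- nrow(counts)
  precs <- recs <- accs <- numeric(n_cls)
  for (i in seq_len(n_cls)) {
    tp <- counts$tp[i]; fp <- counts$fp[i]; fn <- counts$fn[i]; tn <- counts$tn[i]
    precs[i] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recs[i] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    accs[i] <- (tp + tn) / total
  }
  mp <- sum(precs) / n_cls
  mr <- sum(recs) / n_cls
  list(mACC = sum(accs) / n_cls, mPrecision = mp, mRecall = mr,
       mF1 = if (mp + mr == 0) 0 else 2 * mp * mr / (mp + mr))
}

# Random label pair over n_cls classes (for property checks).
random_label_pair <- function(n, n_cls) {
  labels <- seq_len(n_cls)
  list(truth = sample(labels, n, replace = TRUE),
       pred = sample(labels, n, replace = TRUE),
       labels = labels)
}

# ---- global-alignment brute force --------------------------------------

# Exhaustive enumeration of every global alignment of a and b under
# BLOSUM62 with affine gaps (a length-k run costs open + k * ext, terminal
# gaps included). Returns the optimal score and the percent identities of
# all score-optimal alignments. Pure recursion, no DP.
brute_force_alignment <- function(a, b, open = 10, ext = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  S <- get("BLOSUM62", envir = environment())
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  best <- list(score = -Inf, idents = numeric(0))
  rec <- function(i, j, last, score, matches, len) {
    if (i > n && j > m) {
      if (score > best$score + 1e-9) {
        best <<- list(score = score, idents = 100 * matches / len)
      } else if (abs(score - best$score) <= 1e-9) {
        best$idents <<- unique(c(best$idents, 100 * matches / len))
      }
      return(invisible())
    }
    if (i <= n && j <= m) {
      rec(i + 1, j + 1, 0L, score + S[av[i], bv[j]],
          matches + (av[i] == bv[j]), len + 1)
    }
    if (j <= m) {
      pen <- if (last == 1L) ext else open + ext
      rec(i, j + 1, 1L, score - pen, matches, len + 1)
    }
    if (i <= n) {
      pen <- if (last == 2L) ext else open + ext
      rec(i + 1, j, 2L, score - pen, matches, len + 1)
    }
  }
  rec(1L, 1L, -1L, 0, 0L, 0L)
  best
}

# ---- tiny fixed-weight classifier and its scalar-arithmetic oracle -----

# A width-4, hidden-2 (H = 4), 1-head, 3-class model with hand-set weights.
tiny_fixed_model <- function() {
  cfg <- ns_config(gru_hidden = 2, attention_heads = 1, dropout = 0,
                   learning_rate = 0.001, epochs = 1, batch_size = 4,
                   seed = 1, ns_labels = c(1, 2, 3))
  D <- 4; hh <- 2; H <- 4; C <- 3
  lin <- function(vals, nr, nc) matrix(vals, nr, nc)
  params <- list(
    Wz_f = lin(seq(-0.4, 0.3, by = 0.1), D, hh), bz_f = c(0.1, -0.2),
    Wn_f = lin(seq(0.05, 0.40, by = 0.05), D, hh), bn_f = c(-0.1, 0.3),
    Wz_b = lin(seq(0.3, -0.4, by = -0.1), D, hh), bz_b = c(0.0, 0.2),
    Wn_b = lin(seq(-0.2, 0.15, by = 0.05), D, hh), bn_b = c(0.2, -0.3),
    Wq = diag(H) * 0.5, bq = rep(0.1, H),
    Wk = diag(H) * 0.3, bk = rep(-0.1, H),
    Wv = lin(seq(-0.75, 0.75, by = 0.1), H, H), bv = seq(0.1, 0.4, by = 0.1),
    Wo = lin(seq(0.8, -0.7, by = -0.1), H, H), bo = seq(-0.2, 0.1, by = 0.1),
    Wf = lin(seq(-0.55, 0.55, by = 0.1), H, C), bf = c(0.05, -0.05, 0.1)
  )
  structure(list(params = params, config = cfg, label_map = c(1L, 2L, 3L),
                 history = numeric(0), width = D, schema = 1L),
            class = "ns_model")
}

# Scalar-level recomputation of the tiny model's forward pass: explicit
# loops, no matrix products shared with the implementation.
tiny_forward_oracle <- function(params, x) {
  dotcol <- function(W, j, v) {
    s <- 0
    for (r in seq_along(v)) s <- s + v[r] * W[r, j]
    s
  }
  sig <- function(t) 1 / (1 + exp(-t))
  hh <- length(params$bz_f)
  hf <- hb <- numeric(hh)
  for (j in seq_len(hh)) {
    zf <- sig(dotcol(params$Wz_f, j, x) + params$bz_f[j])
    nf <- tanh(dotcol(params$Wn_f, j, x) + params$bn_f[j])
    hf[j] <- (1 - zf) * nf
    zb <- sig(dotcol(params$Wz_b, j, x) + params$bz_b[j])
    nb <- tanh(dotcol(params$Wn_b, j, x) + params$bn_b[j])
    hb[j] <- (1 - zb) * nb
  }
  hg <- c(hf, hb)
  H <- length(hg)
  # single-key attention: weight 1 -> value projection then output projection
  v <- numeric(H)
  for (j in seq_len(H)) v[j] <- dotcol(params$Wv, j, hg) + params$bv[j]
  ha <- numeric(H)
  for (j in seq_len(H)) ha[j] <- dotcol(params$Wo, j, v) + params$bo[j]
  C <- length(params$bf)
  logits <- numeric(C)
  for (j in seq_len(C)) logits[j] <- dotcol(params$Wf, j, ha) + params$bf[j]
  e <- exp(logits - max(logits))
  e / sum(e)
}
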