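# The NS classifier head: bidirectional GRU + multi-head self-attention +
# fully connected softmax, trained with cross-entropy.
#
# The input is the pooled 1 x 1280 sequence embedding, fed to the GRU as a
# single timestep. With a zero initial hidden state, one GRU step per
# direction reduces to h = (1 - z) * tanh(W_n x + b_n) with update gate
# z = sigmoid(W_z x + b_z); the reset gate only modulates the (zero)
# previous state and therefore drops out of the computation, so it carries
# no parameters here. The two directional states are concatenated
# (H = 2 * gru_hidden). Multi-head self-attention over this length-one
# sequence assigns its single key attention weight 1, so the layer acts
# through its value and output projections; the query/key projections are
# kept for architectural fidelity but receive no gradient in this regime.
# A fully connected layer with softmax produces the class probabilities.
# Dropout is applied after the GRU output and after attention.

#' Configuration for the NS classifier
#'
#' Defaults follow the reference training recipe: 128 GRU hidden units per
#' direction, 32 attention heads, dropout 0.5, learning rate 0.001 (Adam),
#' 200 epochs, batch size 1024, and the 10-label NS set
#' \{1, 2, 3, 4, 5, 6, 7, 8, 10, 12\}.
#'
#' @param gru_hidden Hidden units per GRU direction; the concatenated
#'   bidirectional width is `2 * gru_hidden` and must be divisible by
#'   `attention_heads`.
#' @param attention_heads Number of self-attention heads.
#' @param dropout Dropout rate in `[0, 1)`, applied during training only.
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed governing initialization, shuffling and dropout.
#' @param ns_labels Ordered NS label set defining the output classes.
#' @return A list of class `ns_config`.
#' @export
ns_config <- function(gru_hidden = 128L, attention_heads = 32L,
                      dropout = 0.5, learning_rate = 0.001,
                      epochs = 200L, batch_size = 1024L, seed = 1L,
                      ns_labels = NS_LABELS_DEFAULT) {
  cfg <- list(gru_hidden = as.integer(gru_hidden),
              attention_heads = as.integer(attention_heads),
              n_classes = length(ns_labels),
              dropout = dropout, learning_rate = learning_rate,
              epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              seed = as.integer(seed), ns_labels = sort(as.integer(ns_labels)))
  if (cfg$gru_hidden < 1L || cfg$attention_heads < 1L || cfg$epochs < 1L ||
      cfg$batch_size < 1L || cfg$learning_rate <= 0)
    stop("all size and rate parameters must be positive")
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop("dropout must lie in [0, 1)")
  if ((2L * cfg$gru_hidden) %% cfg$attention_heads != 0L)
    stop("2 * gru_hidden must be divisible by attention_heads")
  if (anyDuplicated(cfg$ns_labels)) stop("ns_labels must be distinct")
  structure(cfg, class = "ns_config")
}

addb <- function(M, b) sweep(M, 2L, b, "+")
sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(L) {
  L <- L - apply(L, 1L, max)
  E <- exp(L)
  E / rowSums(E)
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

init_ns_params <- function(width, config) {
  hh <- config$gru_hidden
  H <- 2L * hh
  C <- config$n_classes
  list(
    Wz_f = glorot(width, hh), bz_f = numeric(hh),
    Wn_f = glorot(width, hh), bn_f = numeric(hh),
    Wz_b = glorot(width, hh), bz_b = numeric(hh),
    Wn_b = glorot(width, hh), bn_b = numeric(hh),
    Wq = glorot(H, H), bq = numeric(H),
    Wk = glorot(H, H), bk = numeric(H),
    Wv = glorot(H, H), bv = numeric(H),
    Wo = glorot(H, H), bo = numeric(H),
    Wf = glorot(H, C), bf = numeric(C)
  )
}

# Forward pass over a batch (rows of X). Returns probabilities plus the
# intermediate activations needed for backprop. Dropout masks (already
# scaled by 1/(1-p)) are supplied only during training.
ns_forward_pass <- function(params, X, masks = NULL) {
  Zf <- sigmoid(addb(X %*% params$Wz_f, params$bz_f))
  Nf <- tanh(addb(X %*% params$Wn_f, params$bn_f))
  Hf <- (1 - Zf) * Nf
  Zb <- sigmoid(addb(X %*% params$Wz_b, params$bz_b))
  Nb <- tanh(addb(X %*% params$Wn_b, params$bn_b))
  Hb <- (1 - Zb) * Nb
  Hg <- cbind(Hf, Hb)
  Hgd <- if (is.null(masks)) Hg else Hg * masks$m1
  # Self-attention over a single timestep: softmax over one key gives each
  # head attention weight 1, so the layer reduces to its value + output
  # projections; Q and K are computed for contract fidelity only.
  V <- addb(Hgd %*% params$Wv, params$bv)
  Ha <- addb(V %*% params$Wo, params$bo)
  Had <- if (is.null(masks)) Ha else Ha * masks$m2
  logits <- addb(Had %*% params$Wf, params$bf)
  Y <- softmax_rows(logits)
  list(Y = Y, X = X, Zf = Zf, Nf = Nf, Zb = Zb, Nb = Nb,
       Hgd = Hgd, V = V, Had = Had, masks = masks)
}

# Gradients of mean cross-entropy w.r.t. every parameter, given the cached
# forward pass and the one-hot target matrix.
ns_backward_pass <- function(params, cache, Tmat) {
  B <- nrow(Tmat)
  dlogits <- (cache$Y - Tmat) / B
  g <- list()
  g$Wf <- t(cache$Had) %*% dlogits
  g$bf <- colSums(dlogits)
  dHad <- dlogits %*% t(params$Wf)
  dHa <- if (is.null(cache$masks)) dHad else dHad * cache$masks$m2
  g$Wo <- t(cache$V) %*% dHa
  g$bo <- colSums(dHa)
  dV <- dHa %*% t(params$Wo)
  g$Wv <- t(cache$Hgd) %*% dV
  g$bv <- colSums(dV)
  dHgd <- dV %*% t(params$Wv)
  dHg <- if (is.null(cache$masks)) dHgd else dHgd * cache$masks$m1
  hh <- ncol(cache$Zf)
  dHf <- dHg[, seq_len(hh), drop = FALSE]
  dHb <- dHg[, hh + seq_len(hh), drop = FALSE]
  # h = (1 - z) * n
  for (dir in c("f", "b")) {
    dH <- if (dir == "f") dHf else dHb
    Z <- cache[[paste0("Z", dir)]]
    N <- cache[[paste0("N", dir)]]
    dN <- dH * (1 - Z)
    dZ <- -dH * N
    dpreZ <- dZ * Z * (1 - Z)
    dpreN <- dN * (1 - N^2)
    g[[paste0("Wz_", dir)]] <- t(cache$X) %*% dpreZ
    g[[paste0("bz_", dir)]] <- colSums(dpreZ)
    g[[paste0("Wn_", dir)]] <- t(cache$X) %*% dpreN
    g[[paste0("bn_", dir)]] <- colSums(dpreN)
  }
  # Query/key projections receive no gradient with a single attention key.
  g$Wq <- params$Wq * 0; g$bq <- params$bq * 0
  g$Wk <- params$Wk * 0; g$bk <- params$bk * 0
  g
}

#' Cross-entropy between a true and a predicted distribution
#'
#' Computes `H(p, q) = -sum(p * log(q))` over the class axis, the standard
#' multi-class loss. Predicted probabilities are clamped at `1e-12` before
#' the logarithm. For a one-hot `p` the loss is non-negative and zero
#' exactly when `q` puts all mass on the true class.
#'
#' @param p,q Numeric probability vectors of equal length.
#' @return Non-negative scalar loss.
#' @examples
#' cross_entropy(c(1, rep(0, 9)), rep(0.1, 10))  # log(10)
#' @export
cross_entropy <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have the same length")
  if (any(p < 0) || any(q < 0)) stop("p and q must be non-negative")
  -sum(p * log(pmax(q, 1e-12)))
}

batch_loss <- function(Y, Tmat) {
  -mean(log(pmax(rowSums(Y * Tmat), 1e-12)))
}

#' Train the NS classifier
#'
#' Minimizes the mean cross-entropy by mini-batch gradient descent with the
#' Adam optimizer, recording the per-epoch training loss. All randomness
#' (weight initialization, epoch shuffling, dropout) is driven by
#' `config$seed`, so the same data and seed reproduce the same model
#' exactly.
#'
#' @param x Numeric matrix of pooled embeddings, one sample per row.
#' @param labels Integer NS labels, all within `config$ns_labels`; at least
#'   two distinct classes must be present.
#' @param config An [ns_config()].
#' @return An object of class `ns_model`: list with `params`, `config`,
#'   `label_map` and `history` (per-epoch loss).
#' @seealso [predict.ns_model()], [save_ns_model()]
#' @export
train_ns_classifier <- function(x, labels, config = ns_config()) {
  stopifnot(inherits(config, "ns_config"))
  x <- as.matrix(x)
  labels <- as.integer(labels)
  if (nrow(x) != length(labels)) stop("x and labels disagree in length")
  label_map <- config$ns_labels
  yi <- match(labels, label_map)
  if (anyNA(yi)) stop(sprintf("label %s outside the configured label map",
                              labels[which(is.na(yi))[1L]]))
  if (length(unique(yi)) < 2L) stop("training requires at least two classes")
  n <- nrow(x)
  C <- config$n_classes
  Tall <- matrix(0, n, C)
  Tall[cbind(seq_len(n), yi)] <- 1
  p <- config$dropout

  with_seed(config$seed, {
    params <- init_ns_params(ncol(x), config)
    m1 <- lapply(params, function(w) w * 0)
    v1 <- lapply(params, function(w) w * 0)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    step <- 0L
    history <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, n)]
        Xb <- x[idx, , drop = FALSE]
        Tb <- Tall[idx, , drop = FALSE]
        masks <- NULL
        if (p > 0) {
          H <- 2L * config$gru_hidden
          masks <- list(
            m1 = (matrix(stats::runif(length(idx) * H), length(idx), H) >= p) / (1 - p),
            m2 = (matrix(stats::runif(length(idx) * H), length(idx), H) >= p) / (1 - p))
        }
        cache <- ns_forward_pass(params, Xb, masks)
        loss <- batch_loss(cache$Y, Tb)
        if (!is.finite(loss)) {
          stop(sprintf(
            "training aborted: non-finite loss at epoch %d (lr %.4g); %s",
            epoch, config$learning_rate,
            "consider lowering the learning rate or checking the inputs"))
        }
        ep_loss <- ep_loss + loss * length(idx)
        grads <- ns_backward_pass(params, cache, Tb)
        step <- step + 1L
        for (k in names(params)) {
          m1[[k]] <- b1 * m1[[k]] + (1 - b1) * grads[[k]]
          v1[[k]] <- b2 * v1[[k]] + (1 - b2) * grads[[k]]^2
          mhat <- m1[[k]] / (1 - b1^step)
          vhat <- v1[[k]] / (1 - b2^step)
          params[[k]] <- params[[k]] -
            config$learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
      history[epoch] <- ep_loss / n
    }
    structure(list(params = params, config = config, label_map = label_map,
                   history = history, width = ncol(x), schema = 1L),
              class = "ns_model")
  })
}

#' Class probabilities from a trained NS model
#'
#' Runs the forward pass (GRU, attention, fully connected softmax) without
#' dropout and returns one probability vector per input row. Each row is a
#' valid distribution over the NS label map.
#'
#' @param model An `ns_model`.
#' @param x Pooled-embedding matrix (or a single vector) whose width
#'   matches the model input width.
#' @return Numeric matrix, rows summing to one, columns named by NS label.
#' @export
ns_forward <- function(model, x) {
  stopifnot(inherits(model, "ns_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != model$width) {
    stop(sprintf("input width %d does not match model width %d",
                 ncol(x), model$width))
  }
  Y <- ns_forward_pass(model$params, x)$Y
  colnames(Y) <- model$label_map
  Y
}

#' Predict NS labels
#'
#' Maps each probability vector to the NS label with the highest
#' probability; exact ties are broken toward the smaller NS label.
#'
#' @param object An `ns_model`.
#' @param newdata Pooled-embedding matrix or single vector.
#' @param type `"label"` for NS integers, `"prob"` for the probability
#'   matrix.
#' @param ... Unused.
#' @return Integer vector of NS labels, or the probability matrix.
#' @export
predict.ns_model <- function(object, newdata, type = c("label", "prob"), ...) {
  type <- match.arg(type)
  Y <- ns_forward(object, newdata)
  if (type == "prob") return(Y)
  # label_map is ascending, so the first maximum is the smallest NS label
  idx <- apply(Y, 1L, which.max)
  object$label_map[idx]
}

#' @export
print.ns_model <- function(x, ...) {
  cat(sprintf(
    "NS classifier: input %d -> biGRU 2x%d -> attention (%d heads) -> %d classes\n",
    x$width, x$config$gru_hidden, x$config$attention_heads, x$config$n_classes))
  cat(sprintf("trained %d epochs, final loss %.4f\n",
              length(x$history), utils::tail(x$history, 1L)))
  invisible(x)
}

#' Save / load a trained NS model
#'
#' A checkpoint is a single-file archive holding the weights, the
#' configuration, the label map and a schema version; loading restores a
#' model whose predictions are identical to the saved one.
#'
#' @param model An `ns_model`.
#' @param path Checkpoint file path.
#' @return `save_ns_model()` returns `path` invisibly; `load_ns_model()`
#'   the restored model.
#' @export
save_ns_model <- function(model, path) {
  stopifnot(inherits(model, "ns_model"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_ns_model
#' @export
load_ns_model <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$schema) || obj$schema != 1L) {
    stop("unrecognized model checkpoint schema")
  }
  structure(obj, class = "ns_model")
}
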