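# Variational graph auto-encoder, implemented directly in R.
#
# Encoder: edge-conditioned graph convolutions (one weight matrix per bond
# type plus a self loop), ReLU, three layers of width 128, mean-pooled over
# real atoms to a graph vector, then linear heads for the 64-dim posterior
# mean and log-variance. Decoder: 2-layer perceptron from the latent vector
# to (i) a node feature map (element block soft-maxed per slot) and (ii) an
# edge logit map symmetrized as (L + t(L))/2 and squashed to [0, 1].
#
# Loss: element-wise binary cross-entropy on the edge-existence map (full
# grid, off-diagonal) + cross-entropy on node feature blocks (padding slots
# masked) + the closed-form KL divergence against N(0, I). Gradients are
# hand-derived; every activation used here has the convenient
# "(prediction - target)" backward form.

default_vgae_hyper <- function(latent_dim = 64L, hidden_dim = 128L,
                               n_layers = 3L, learning_rate = 0.001,
                               batch_size = 64L, epochs = 50L,
                               val_frac = 0.1) {
  list(latent_dim = as.integer(latent_dim),
       hidden_dim = as.integer(hidden_dim),
       n_layers = as.integer(n_layers),
       learning_rate = learning_rate,
       batch_size = as.integer(batch_size),
       epochs = as.integer(epochs),
       val_frac = val_frac)
}

# --- parameter initialization ------------------------------------------------

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

vgae_init_params <- function(config, hyper) {
  dn <- config$d_node
  db <- config$d_edge
  dh <- hyper$hidden_dim
  dz <- hyper$latent_dim
  M <- config$max_atoms
  enc <- vector("list", hyper$n_layers)
  d_in <- dn
  for (l in seq_len(hyper$n_layers)) {
    enc[[l]] <- list(Wb = lapply(seq_len(db), function(b) glorot(d_in, dh)),
                     Ws = glorot(d_in, dh),
                     b = numeric(dh))
    d_in <- dh
  }
  list(enc = enc,
       Wmu = glorot(dh, dz), bmu = numeric(dz),
       Wlv = glorot(dh, dz), blv = numeric(dz),
       W1 = glorot(dz, dh), b1 = numeric(dh),
       Wn = glorot(dh, M * dn), bn = numeric(M * dn),
       We = glorot(dh, M * M), be = numeric(M * M))
}

# flatten/unflatten parameter lists for the Adam state
param_walk <- function(params, f) {
  rec <- function(x) {
    if (is.list(x)) lapply(x, rec) else f(x)
  }
  rec(params)
}

param_map2 <- function(a, b, f) {
  rec <- function(x, y) {
    if (is.list(x)) Map(rec, x, y) else f(x, y)
  }
  rec(a, b)
}

# --- graph tensors -----------------------------------------------------------

# Pre-extract what the passes need from a molecular_graph.
graph_tensors <- function(graph, config) {
  check_graph(graph, config)
  M <- config$max_atoms
  A <- lapply(seq_len(config$d_edge),
              function(b) graph$edge_features[, , b])
  mask <- numeric(M)
  mask[seq_len(graph$n_atoms)] <- 1
  Tadj <- Reduce(`+`, A)
  Tadj[Tadj > 0] <- 1
  list(X = graph$node_features, A = A, mask = mask, n = graph$n_atoms,
       Tadj = Tadj)
}

check_graph <- function(graph, config) {
  if (!inherits(graph, "molecular_graph")) {
    abort_config("expected a molecular_graph")
  }
  d <- dim(graph$edge_features)
  if (nrow(graph$node_features) != config$max_atoms ||
      ncol(graph$node_features) != config$d_node ||
      !all(d == c(config$max_atoms, config$max_atoms, config$d_edge))) {
    abort_config("graph dimensions do not match the feature configuration")
  }
  for (b in seq_len(d[3L])) {
    sl <- graph$edge_features[, , b]
    if (!isTRUE(all.equal(sl, t(sl)))) {
      abort_config("edge feature tensor is not symmetric")
    }
  }
  invisible(TRUE)
}

# --- forward / backward ------------------------------------------------------

vgae_encode_forward <- function(gt, params, hyper) {
  H <- gt$X
  acts <- list(H)       # H_0 .. H_L
  msgs <- list()        # cached A_b %*% H_{l-1}
  for (l in seq_len(hyper$n_layers)) {
    lay <- params$enc[[l]]
    AH <- lapply(gt$A, function(Ab) Ab %*% H)
    pre <- H %*% lay$Ws + outer(gt$mask, lay$b)
    for (b in seq_along(AH)) pre <- pre + AH[[b]] %*% lay$Wb[[b]]
    H <- pmax(pre, 0) * gt$mask        # padding rows stay exactly zero
    msgs[[l]] <- AH
    acts[[l + 1L]] <- H
  }
  g <- crossprod(H, gt$mask) / gt$n    # column vector d_h x 1
  g <- t(g)                            # 1 x d_h
  mu <- g %*% params$Wmu + matrix(params$bmu, 1)
  lv <- g %*% params$Wlv + matrix(params$blv, 1)
  list(acts = acts, msgs = msgs, g = g, mu = mu, lv = lv)
}

# per-slot activation of raw node logits: softmax over one-hot blocks,
# sigmoid on binary flags, identity on the charge column
node_block_layout <- function(config) {
  spec <- config$node_feature_spec
  offs <- cumsum(c(0, unlist(spec)))
  list(element = offs[1] + seq_len(spec$element),
       degree = offs[2] + seq_len(spec$degree),
       charge = offs[3] + 1L,
       aromatic = offs[4] + 1L,
       hybridization = offs[5] + seq_len(spec$hybridization))
}

row_softmax <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

activate_node_map <- function(raw, config) {
  lay <- node_block_layout(config)
  out <- raw
  out[, lay$element] <- row_softmax(raw[, lay$element, drop = FALSE])
  out[, lay$degree] <- row_softmax(raw[, lay$degree, drop = FALSE])
  out[, lay$aromatic] <- stats::plogis(raw[, lay$aromatic])
  out[, lay$hybridization] <-
    row_softmax(raw[, lay$hybridization, drop = FALSE])
  out
}

vgae_decode_forward <- function(z, params, config) {
  M <- config$max_atoms
  h1 <- pmax(z %*% params$W1 + matrix(params$b1, 1), 0)
  nl <- h1 %*% params$Wn + matrix(params$bn, 1)
  el <- h1 %*% params$We + matrix(params$be, 1)
  E <- matrix(el, M, M)
  S <- (E + t(E)) / 2
  P <- stats::plogis(S)
  diag(P) <- 0
  node_raw <- matrix(nl, M, config$d_node)
  node_map <- activate_node_map(node_raw, config)
  list(h1 = h1, node_raw = node_raw, node_map = node_map, S = S, P = P)
}

.BCE_EPS <- 1e-12

edge_recon_loss <- function(P, Tadj) {
  M <- nrow(P)
  off <- row(P) != col(P)
  p <- pmin(pmax(P[off], .BCE_EPS), 1 - .BCE_EPS)
  t <- Tadj[off]
  -sum(t * log(p) + (1 - t) * log(1 - p)) / 2
}

node_recon_loss <- function(node_map, X, mask, config) {
  lay <- node_block_layout(config)
  real <- which(mask > 0)
  p <- node_map[real, , drop = FALSE]
  t <- X[real, , drop = FALSE]
  ce_block <- function(idx) {
    pp <- pmin(pmax(p[, idx, drop = FALSE], .BCE_EPS), 1)
    -sum(t[, idx, drop = FALSE] * log(pp))
  }
  bce <- function(idx) {
    pp <- pmin(pmax(p[, idx, drop = FALSE], .BCE_EPS), 1 - .BCE_EPS)
    tt <- t[, idx, drop = FALSE]
    -sum(tt * log(pp) + (1 - tt) * log(1 - pp))
  }
  se <- function(idx) 0.5 * sum((p[, idx] - t[, idx])^2)
  ce_block(lay$element) + ce_block(lay$degree) + se(lay$charge) +
    bce(lay$aromatic) + ce_block(lay$hybridization)
}

kl_closed_form <- function(mu, lv) {
  0.5 * sum(exp(lv) + mu^2 - 1 - lv)
}

# One full pass: returns loss pieces and parameter gradients.
vgae_grad <- function(gt, params, hyper, config, eps) {
  fwd <- vgae_encode_forward(gt, params, hyper)
  mu <- fwd$mu; lv <- fwd$lv
  z <- mu + exp(lv / 2) * eps
  dec <- vgae_decode_forward(z, params, config)
  M <- config$max_atoms

  l_edge <- edge_recon_loss(dec$P, gt$Tadj)
  l_node <- node_recon_loss(dec$node_map, gt$X, gt$mask, config)
  l_kl <- kl_closed_form(mu, lv)

  # ----- backward: decoder -----
  off <- row(dec$P) != col(dec$P)
  dS <- matrix(0, M, M)
  dS[off] <- (dec$P[off] - gt$Tadj[off]) / 2
  dE <- dS                       # symmetric, and dS/dE averages transpose
  del <- matrix(as.vector(dE), 1)

  lay <- node_block_layout(config)
  dnode <- dec$node_map - gt$X   # (p - t) for CE/BCE/SE alike
  dnode <- dnode * gt$mask       # padding slots masked out of the loss
  dnl <- matrix(as.vector(dnode), 1)

  dh1 <- del %*% t(params$We) + dnl %*% t(params$Wn)
  dh1 <- dh1 * (dec$h1 > 0)
  gWe <- crossprod(dec$h1, del); gbe <- as.numeric(del)
  gWn <- crossprod(dec$h1, dnl); gbn <- as.numeric(dnl)
  gW1 <- crossprod(z, dh1); gb1 <- as.numeric(dh1)
  dz <- dh1 %*% t(params$W1)

  # ----- backward: reparameterization + KL -----
  dmu <- dz + mu
  dlv <- dz * eps * 0.5 * exp(lv / 2) + 0.5 * (exp(lv) - 1)

  # ----- backward: encoder heads -----
  g <- fwd$g
  gWmu <- crossprod(g, dmu); gbmu <- as.numeric(dmu)
  gWlv <- crossprod(g, dlv); gblv <- as.numeric(dlv)
  dg <- dmu %*% t(params$Wmu) + dlv %*% t(params$Wlv)
  dH <- outer(gt$mask, as.numeric(dg)) / gt$n

  # ----- backward: conv stack -----
  genc <- vector("list", hyper$n_layers)
  for (l in rev(seq_len(hyper$n_layers))) {
    lay_p <- params$enc[[l]]
    Hl <- fwd$acts[[l + 1L]]
    Hprev <- fwd$acts[[l]]
    dpre <- dH * (Hl > 0)
    gWb <- lapply(seq_along(lay_p$Wb), function(b) {
      crossprod(fwd$msgs[[l]][[b]], dpre)
    })
    gWs <- crossprod(Hprev, dpre)
    gb <- as.numeric(crossprod(dpre, gt$mask))
    dH <- dpre %*% t(lay_p$Ws)
    for (b in seq_along(lay_p$Wb)) {
      dH <- dH + gt$A[[b]] %*% (dpre %*% t(lay_p$Wb[[b]]))
    }
    genc[[l]] <- list(Wb = gWb, Ws = gWs, b = gb)
  }

  grads <- list(enc = genc, Wmu = gWmu, bmu = gbmu, Wlv = gWlv, blv = gblv,
                W1 = gW1, b1 = gb1, Wn = gWn, bn = gbn, We = gWe, be = gbe)
  list(loss = c(recon = l_edge + l_node, kl = l_kl,
                total = l_edge + l_node + l_kl),
       grads = grads)
}

vgae_loss_only <- function(gt, params, hyper, config, eps) {
  fwd <- vgae_encode_forward(gt, params, hyper)
  z <- fwd$mu + exp(fwd$lv / 2) * eps
  dec <- vgae_decode_forward(z, params, config)
  l_edge <- edge_recon_loss(dec$P, gt$Tadj)
  l_node <- node_recon_loss(dec$node_map, gt$X, gt$mask, config)
  l_kl <- kl_closed_form(fwd$mu, fwd$lv)
  c(recon = l_edge + l_node, kl = l_kl, total = l_edge + l_node + l_kl)
}

# --- training ----------------------------------------------------------------

#' Train the variational graph auto-encoder
#'
#' Mini-batch Adam on the evidence lower bound (reconstruction
#' cross-entropy + closed-form KL against the standard-normal prior).
#' Fully reproducible under a fixed seed.
#'
#' @param dataset a non-empty list of [smiles_to_graph()] outputs sharing
#'   one [feature_config()].
#' @param config the shared [feature_config()].
#' @param hyper hyperparameters from [default_vgae_hyper()]; the defaults
#'   are latent 64, hidden 128, 3 conv layers, learning rate 0.001, batch
#'   size 64.
#' @param seed integer seed for initialization, shuffling and
#'   reparameterization noise.
#' @return an object of class `vgae_model`: parameters, configuration,
#'   hyperparameters and a per-epoch loss `history` data.frame.
#' @export
vgae_train <- function(dataset, config, hyper = default_vgae_hyper(),
                       seed = 1L) {
  if (!is.list(dataset) || length(dataset) == 0L) {
    abort_config("dataset must be a non-empty list of molecular graphs")
  }
  hyper <- utils::modifyList(default_vgae_hyper(), hyper)
  withr::with_seed(as.integer(seed), {
    params <- vgae_init_params(config, hyper)
    gts <- lapply(dataset, graph_tensors, config = config)
    n <- length(gts)
    n_val <- if (n >= 10L) max(1L, floor(hyper$val_frac * n)) else 0L
    idx <- sample.int(n)
    val_idx <- if (n_val > 0L) idx[seq_len(n_val)] else integer(0)
    train_idx <- setdiff(idx, val_idx)

    adam_m <- param_walk(params, function(x) x * 0)
    adam_v <- param_walk(params, function(x) x * 0)
    beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
    step <- 0L
    history <- data.frame(epoch = integer(0), train = numeric(0),
                          val = numeric(0))
    dz <- hyper$latent_dim

    for (epoch in seq_len(hyper$epochs)) {
      ord <- sample(train_idx)
      batches <- split(ord, ceiling(seq_along(ord) / hyper$batch_size))
      epoch_loss <- 0
      for (batch in batches) {
        acc <- NULL
        batch_loss <- 0
        for (i in batch) {
          eps <- matrix(stats::rnorm(dz), 1)
          res <- vgae_grad(gts[[i]], params, hyper, config, eps)
          batch_loss <- batch_loss + res$loss[["total"]]
          acc <- if (is.null(acc)) res$grads else {
            param_map2(acc, res$grads, `+`)
          }
        }
        k <- length(batch)
        acc <- param_walk(acc, function(x) x / k)
        step <- step + 1L
        lr_t <- hyper$learning_rate *
          sqrt(1 - beta2^step) / (1 - beta1^step)
        adam_m <- param_map2(adam_m, acc,
                             function(m, g) beta1 * m + (1 - beta1) * g)
        adam_v <- param_map2(adam_v, acc,
                             function(v, g) beta2 * v + (1 - beta2) * g^2)
        upd <- param_map2(adam_m, adam_v,
                          function(m, v) lr_t * m / (sqrt(v) + adam_eps))
        params <- param_map2(params, upd, `-`)
        epoch_loss <- epoch_loss + batch_loss
      }
      train_loss <- epoch_loss / length(train_idx)
      val_loss <- if (n_val > 0L) {
        mean(vapply(val_idx, function(i) {
          eps <- matrix(stats::rnorm(dz), 1)
          vgae_loss_only(gts[[i]], params, hyper, config, eps)[["total"]]
        }, numeric(1)))
      } else NA_real_
      history <- rbind(history, data.frame(epoch = epoch, train = train_loss,
                                           val = val_loss))
    }
    structure(list(params = params, config = config, hyper = hyper,
                   history = history, format_version = 1L),
              class = "vgae_model")
  })
}

#' @export
print.vgae_model <- function(x, ...) {
  cat("vgae_model: latent", x$hyper$latent_dim, "| hidden",
      x$hyper$hidden_dim, "x", x$hyper$n_layers, "layers | max_atoms",
      x$config$max_atoms, "\n")
  if (nrow(x$history) > 0L) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs; final train loss %.3f\n",
                last$epoch, last$train))
  }
  invisible(x)
}

# --- user-facing encode / decode / sampling ---------------------------------

#' Encode a molecular graph to its latent posterior
#'
#' @param graph a [smiles_to_graph()] output.
#' @param model a trained [vgae_train()] model.
#' @return an object of class `latent_posterior` with `mu` and `logvar`
#'   (each `latent_dim` long). Deterministic in `(graph, model)`.
#' @export
vgae_encode <- function(graph, model) {
  stopifnot(inherits(model, "vgae_model"))
  gt <- graph_tensors(graph, model$config)
  fwd <- vgae_encode_forward(gt, model$params, model$hyper)
  structure(list(mu = as.numeric(fwd$mu), logvar = as.numeric(fwd$lv)),
            class = "latent_posterior")
}

#' Sample a latent vector from a posterior (reparameterization)
#'
#' `z = mu + exp(logvar / 2) * eps` with standard-normal `eps`.
#'
#' @param posterior a [vgae_encode()] output.
#' @param seed optional integer seed for a reproducible draw.
#' @return numeric latent vector.
#' @export
sample_posterior <- function(posterior, seed = NULL) {
  stopifnot(inherits(posterior, "latent_posterior"))
  draw <- function() {
    eps <- stats::rnorm(length(posterior$mu))
    posterior$mu + exp(posterior$logvar / 2) * eps
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' Sample a latent vector from the standard-normal prior
#'
#' @param model a trained model (fixes the latent dimension).
#' @param seed optional integer seed.
#' @return numeric latent vector.
#' @export
sample_prior <- function(model, seed = NULL) {
  dz <- model$hyper$latent_dim
  if (is.null(seed)) stats::rnorm(dz)
  else withr::with_seed(as.integer(seed), stats::rnorm(dz))
}

#' Decode a latent vector into node/edge feature maps
#'
#' @param z numeric latent vector of length `latent_dim`.
#' @param model a trained model.
#' @return an object of class `decoded_feature_map`: `edge_prob`
#'   (`max_atoms x max_atoms`, symmetric, zero diagonal, entries in
#'   `[0, 1]`) and `node_map` (`max_atoms x d_node`, element block summing
#'   to one per slot).
#' @export
vgae_decode <- function(z, model) {
  stopifnot(inherits(model, "vgae_model"))
  if (length(z) != model$hyper$latent_dim) {
    abort_config(sprintf("latent vector has length %d, expected %d",
                         length(z), model$hyper$latent_dim))
  }
  dec <- vgae_decode_forward(matrix(as.numeric(z), 1), model$params,
                             model$config)
  structure(list(edge_prob = dec$P, node_map = dec$node_map,
                 config = model$config),
            class = "decoded_feature_map")
}

#' Evidence-lower-bound loss pieces for one graph
#'
#' `kl = 0.5 * sum(exp(logvar) + mu^2 - 1 - logvar)` (non-negative);
#' `reconstruction` is the edge-map binary cross-entropy plus the node
#' feature cross-entropy (padding masked); `total` is their sum.
#'
#' @param graph a [smiles_to_graph()] output.
#' @param decoded a [vgae_decode()] output of matching size.
#' @param posterior a [vgae_encode()] output.
#' @return named numeric vector `reconstruction`, `kl`, `total`.
#' @export
elbo_loss <- function(graph, decoded, posterior) {
  stopifnot(inherits(decoded, "decoded_feature_map"),
            inherits(posterior, "latent_posterior"))
  config <- decoded$config
  gt <- graph_tensors(graph, config)
  l_edge <- edge_recon_loss(decoded$edge_prob, gt$Tadj)
  l_node <- node_recon_loss(decoded$node_map, gt$X, gt$mask, config)
  l_kl <- kl_closed_form(posterior$mu, posterior$logvar)
  c(reconstruction = l_edge + l_node, kl = l_kl,
    total = l_edge + l_node + l_kl)
}

# --- checkpointing -----------------------------------------------------------

#' Save / load a trained model
#'
#' The checkpoint embeds the feature configuration and a format-version
#' tag; loading verifies both.
#'
#' @param model a `vgae_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "vgae_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @param config optional [feature_config()] the checkpoint must match.
#' @export
load_model <- function(path, config = NULL) {
  if (!file.exists(path)) abort_io(paste0("checkpoint not found: ", path))
  model <- readRDS(path)
  if (!inherits(model, "vgae_model") ||
      !identical(model$format_version, 1L)) {
    abort_config("not a compatible model checkpoint")
  }
  if (!is.null(config) && !feature_config_equal(model$config, config)) {
    abort_config("checkpoint feature configuration does not match")
  }
  model
}
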