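# The sequence-design network: DSSP-state + type embeddings -> 3-layer
# bidirectional LSTM encoder -> layer normalization -> 8-head self-attention
# with a residual connection -> two feedforward decoder stages (linear /
# ReLU / dropout) -> a 20-way residue classifier head and a 3-way continuous
# property head. The composite loss combines property MSE, temperature-scaled
# cross-entropy, entropy regularization, and an L2 penalty on logits.

#' Model configuration
#'
#' Defaults reproduce the published architecture: 64-dim DSSP-state
#' embedding plus 16-dim type embedding (80-dim combined input), three
#' bidirectional LSTM layers with 256 hidden features (512-wide output),
#' layer normalization, 8-head self-attention, and a two-stage feedforward
#' decoder. The decoder widths (279, 78) were resolved by exhaustive search
#' as the configuration whose trainable parameter inventory equals exactly
#' 5,065,280 (see the methods vignette). Both embedding tables carry one
#' extra padding row outside the content vocabularies.
#'
#' @param dssp_vocab,type_vocab Content vocabulary sizes (9 and 3).
#' @param dssp_embed_dim,type_embed_dim Embedding widths (64 and 16).
#' @param lstm_hidden Hidden features per LSTM direction (256).
#' @param lstm_layers Number of bidirectional LSTM layers (3).
#' @param attention_heads Self-attention heads (8); must divide
#'   `2 * lstm_hidden`.
#' @param decoder_dims Widths of the two decoder stages.
#' @param dropout_rate Dropout probability in the decoder (training only).
#' @param residue_vocab Classifier width (20).
#' @param property_dim Property-head width (3).
#' @return A validated config list.
#' @export
modelConfig <- function(dssp_vocab = 9L, type_vocab = 3L,
                        dssp_embed_dim = 64L, type_embed_dim = 16L,
                        lstm_hidden = 256L, lstm_layers = 3L,
                        attention_heads = 8L, decoder_dims = c(279L, 78L),
                        dropout_rate = 0.1, residue_vocab = 20L,
                        property_dim = 3L) {
  cfg <- list(dssp_vocab = as.integer(dssp_vocab),
              type_vocab = as.integer(type_vocab),
              dssp_embed_dim = as.integer(dssp_embed_dim),
              type_embed_dim = as.integer(type_embed_dim),
              lstm_hidden = as.integer(lstm_hidden),
              lstm_layers = as.integer(lstm_layers),
              attention_heads = as.integer(attention_heads),
              decoder_dims = as.integer(decoder_dims),
              dropout_rate = dropout_rate,
              residue_vocab = as.integer(residue_vocab),
              property_dim = as.integer(property_dim))
  .validateModelConfig(cfg)
  cfg
}

.validateModelConfig <- function(cfg) {
  if (any(unlist(cfg[c("dssp_embed_dim", "type_embed_dim", "lstm_hidden",
                       "lstm_layers", "attention_heads", "decoder_dims")]) <= 0))
    stop("model dimensions must be positive")
  width <- 2L * cfg$lstm_hidden
  if (width %% cfg$attention_heads != 0L)
    stop(sprintf("attention_heads (%d) must divide the encoder width (%d)",
                 cfg$attention_heads, width))
  if (length(cfg$decoder_dims) != 2L)
    stop("decoder_dims must hold exactly two widths")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  invisible(TRUE)
}

#' Combined input embedding width of a config
#' @param config From [modelConfig()].
#' @export
combinedInputDim <- function(config) {
  config$dssp_embed_dim + config$type_embed_dim
}

# ---- parameter tree helpers -------------------------------------------

.mapLeaves <- function(x, f) {
  if (is.list(x)) lapply(x, .mapLeaves, f) else f(x)
}
.zipLeaves <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- .zipLeaves(a[[i]], b[[i]], f)
    out
  } else f(a, b)
}
.sumLeaves <- function(x, f) {
  if (is.list(x)) sum(vapply(x, .sumLeaves, numeric(1), f = f)) else f(x)
}

#' Closed-form trainable parameter count for a config
#'
#' Sums the parameter inventory symbolically from the configuration
#' dimensions: embeddings (content rows plus one padding row each),
#' per-direction LSTM weight/bias blocks, layer-norm affine pair, packed
#' QKV and output attention projections with biases, decoder stages, and
#' the two heads.
#'
#' @param config From [modelConfig()].
#' @return Integer parameter count.
#' @export
parameterCountFromConfig <- function(config) {
  H <- config$lstm_hidden
  E <- 2L * H
  inp <- combinedInputDim(config)
  n <- (config$dssp_vocab + 1L) * config$dssp_embed_dim +
    (config$type_vocab + 1L) * config$type_embed_dim
  for (l in seq_len(config$lstm_layers)) {
    d_in <- if (l == 1L) inp else E
    n <- n + 2L * (4L * H * d_in + 4L * H * H + 8L * H)
  }
  n <- n + 2L * E                       # layer norm
  n <- n + 3L * E * E + 3L * E + E * E + E  # attention in/out projections
  d1 <- config$decoder_dims[1]; d2 <- config$decoder_dims[2]
  n <- n + d1 * E + d1 + d2 * d1 + d2
  n <- n + config$residue_vocab * d2 + config$residue_vocab +
    config$property_dim * d2 + config$property_dim
  as.integer(n)
}

# ---- model object ------------------------------------------------------

#' BlstmaModel: a built (possibly trained) design network
#'
#' @slot config Model configuration list (see [modelConfig()]).
#' @slot params Nested list of weight arrays.
#' @slot standardizer Property standardizer (`mean`, `sd`) or empty list
#'   before training.
#' @slot meta Bookkeeping: init seed, trained length envelope, state
#'   ordering.
#' @export
setClass("BlstmaModel",
         representation(config = "list", params = "list",
                        standardizer = "list", meta = "list"))

#' @rdname BlstmaModel-class
#' @param object A `BlstmaModel`.
#' @export
setMethod("show", "BlstmaModel", function(object) {
  cat(sprintf(paste0("BlstmaModel: %d-dim input, %d x biLSTM(%d), %d-head ",
                     "attention, decoder %s; %s parameters%s\n"),
              combinedInputDim(object@config), object@config$lstm_layers,
              object@config$lstm_hidden, object@config$attention_heads,
              paste(object@config$decoder_dims, collapse = "->"),
              format(countParameters(object), big.mark = ","),
              if (length(object@standardizer)) " [trained]" else ""))
})

#' Build a model from a configuration
#'
#' The classifier head is initialized Xavier-uniform with gain 0.1 and zero
#' bias; other layers use conventional defaults (uniform
#' \eqn{\pm 1/\sqrt{fan}} for LSTM and linear stages, Xavier for the
#' attention projections, standard normal embeddings with a zero padding
#' row).
#'
#' @param config From [modelConfig()].
#' @param seed Integer seed for initialization.
#' @return A [BlstmaModel-class].
#' @export
buildModel <- function(config, seed = 1L) {
  .validateModelConfig(config)
  H <- config$lstm_hidden
  E <- 2L * H
  inp <- combinedInputDim(config)
  d1 <- config$decoder_dims[1]; d2 <- config$decoder_dims[2]
  params <- withSeed(deriveSeed(seed, "init"), {
    emb_dssp <- matrix(rnorm((config$dssp_vocab + 1L) * config$dssp_embed_dim),
                       config$dssp_vocab + 1L, config$dssp_embed_dim)
    emb_dssp[config$dssp_vocab + 1L, ] <- 0
    emb_type <- matrix(rnorm((config$type_vocab + 1L) * config$type_embed_dim),
                       config$type_vocab + 1L, config$type_embed_dim)
    emb_type[config$type_vocab + 1L, ] <- 0
    k <- 1 / sqrt(H)
    lstm <- lapply(seq_len(config$lstm_layers), function(l) {
      d_in <- if (l == 1L) inp else E
      dir <- function() list(
        W_ih = matrix(runif(4L * H * d_in, -k, k), 4L * H, d_in),
        W_hh = matrix(runif(4L * H * H, -k, k), 4L * H, H),
        b_ih = runif(4L * H, -k, k),
        b_hh = runif(4L * H, -k, k))
      list(fwd = dir(), bwd = dir())
    })
    list(
      emb_dssp = emb_dssp,
      emb_type = emb_type,
      lstm = lstm,
      ln = list(gamma = rep(1, E), beta = rep(0, E)),
      attn = list(W_in = .xavierUniform(3L * E, E), b_in = rep(0, 3L * E),
                  W_out = .xavierUniform(E, E), b_out = rep(0, E)),
      dec1 = .linearDefault(d1, E),
      dec2 = .linearDefault(d2, d1),
      cls = list(W = .xavierUniform(config$residue_vocab, d2, gain = 0.1),
                 b = rep(0, config$residue_vocab)),
      prop = .linearDefault(config$property_dim, d2))
  })
  new("BlstmaModel", config = config, params = params,
      standardizer = list(),
      meta = list(init_seed = as.integer(seed),
                  state_order = DSSP_STATES,
                  trained_lengths = NULL))
}

#' Count trainable parameters of a built model
#'
#' @param model A [BlstmaModel-class] (or a raw parameter list).
#' @return Integer: sum of element counts over all weight arrays.
#' @export
countParameters <- function(model) {
  params <- if (is(model, "BlstmaModel")) model@params else model
  as.integer(.sumLeaves(params, length))
}

# ---- forward -----------------------------------------------------------

# Core forward pass over a padded batch. dssp/type: (B, L) 0-based token
# matrices (pad ids = vocab size); mask: (B, L) logical. Dropout is active
# only when training = TRUE (draws from the current RNG stream).
.forwardPass <- function(params, config, dssp, type, mask, training = FALSE,
                         keep_cache = FALSE) {
  if (!all(dim(dssp) == dim(type)))
    stop("dssp and type token tracks must have identical shape")
  if (!all(dim(dssp) == dim(mask)))
    stop("mask shape must match the token tracks")
  B <- nrow(dssp); L <- ncol(dssp)
  E <- 2L * config$lstm_hidden
  rate <- if (training) config$dropout_rate else 0
  x_d <- .embedForward(dssp, params$emb_dssp)
  x_t <- .embedForward(type, params$emb_type)
  x <- array(0, dim = c(B, L, dim(x_d)[3] + dim(x_t)[3]))
  x[, , seq_len(dim(x_d)[3])] <- x_d
  x[, , dim(x_d)[3] + seq_len(dim(x_t)[3])] <- x_t

  lstm_in <- vector("list", config$lstm_layers)
  lstm_cache <- vector("list", config$lstm_layers)
  cur <- x
  for (l in seq_len(config$lstm_layers)) {
    lstm_in[[l]] <- cur
    fw <- .lstmForward(cur, mask, params$lstm[[l]]$fwd$W_ih,
                       params$lstm[[l]]$fwd$W_hh, params$lstm[[l]]$fwd$b_ih,
                       params$lstm[[l]]$fwd$b_hh, reverse = FALSE,
                       keep_cache = keep_cache)
    bw <- .lstmForward(cur, mask, params$lstm[[l]]$bwd$W_ih,
                       params$lstm[[l]]$bwd$W_hh, params$lstm[[l]]$bwd$b_ih,
                       params$lstm[[l]]$bwd$b_hh, reverse = TRUE,
                       keep_cache = keep_cache)
    cur <- array(0, dim = c(B, L, E))
    cur[, , seq_len(config$lstm_hidden)] <- fw$out
    cur[, , config$lstm_hidden + seq_len(config$lstm_hidden)] <- bw$out
    lstm_cache[[l]] <- list(fwd = fw$cache, bwd = bw$cache)
  }

  ln <- .layerNormForward(cur, params$ln$gamma, params$ln$beta,
                          keep_cache = keep_cache)
  at <- .attentionForward(ln$out, mask, params$attn$W_in, params$attn$b_in,
                          params$attn$W_out, params$attn$b_out,
                          config$attention_heads, keep_cache = keep_cache)
  ctx <- ln$out + at$out   # residual connection

  z1_pre <- .linearForward(ctx, params$dec1$W, params$dec1$b)
  z1 <- pmax(z1_pre, 0)
  dm1 <- .dropoutMask(dim(z1), rate)
  if (!is.null(dm1)) z1 <- z1 * dm1
  z2_pre <- .linearForward(z1, params$dec2$W, params$dec2$b)
  z2 <- pmax(z2_pre, 0)
  dm2 <- .dropoutMask(dim(z2), rate)
  if (!is.null(dm2)) z2 <- z2 * dm2

  logits <- .linearForward(z2, params$cls$W, params$cls$b)
  props <- .linearForward(z2, params$prop$W, params$prop$b)
  list(residue_logits = logits, property_pred = props, mask = mask,
       cache = if (keep_cache)
         list(x = x, lstm_in = lstm_in, lstm_cache = lstm_cache,
              ln_out = ln$out, ln_cache = ln$cache, attn_cache = at$cache,
              ctx = ctx, z1_pre = z1_pre, z1 = z1, dm1 = dm1,
              z2_pre = z2_pre, z2 = z2, dm2 = dm2,
              dssp = dssp, type = type) else NULL)
}

#' Run the model forward over a padded batch
#'
#' @param model A [BlstmaModel-class].
#' @param dssp_tokens,type_tokens (B x L) 0-based token matrices (padding =
#'   vocabulary size).
#' @param mask (B x L) logical validity mask; defaults to all-valid.
#' @param training Enable dropout (default `FALSE`).
#' @return List with `residue_logits` (B x L x 20), `property_pred`
#'   (B x L x 3), `mask`.
#' @export
forwardModel <- function(model, dssp_tokens, type_tokens, mask = NULL,
                         training = FALSE) {
  if (is.vector(dssp_tokens)) dssp_tokens <- matrix(dssp_tokens, nrow = 1L)
  if (is.vector(type_tokens)) type_tokens <- matrix(type_tokens, nrow = 1L)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(dssp_tokens), ncol(dssp_tokens))
  out <- .forwardPass(model@params, model@config, dssp_tokens, type_tokens,
                      mask, training = training, keep_cache = FALSE)
  out["cache"] <- NULL
  out
}

# ---- loss --------------------------------------------------------------

#' Default composite-loss weights
#'
#' Property MSE weight `alpha` = 1.0, cross-entropy weight `beta` = 0.2,
#' entropy-regularization weight `gamma` = 0.01, logit L2 weight `lambda`
#' (default 1e-4), and the entropy sign convention (`entropy_sign` = -1
#' adds -gamma * mean entropy, i.e. encourages entropy).
#' @param alpha,beta,gamma,lambda,entropy_sign Component weights.
#' @export
lossWeights <- function(alpha = 1.0, beta = 0.2, gamma = 0.01,
                        lambda = 1e-4, entropy_sign = -1) {
  list(alpha = alpha, beta = beta, gamma = gamma, lambda = lambda,
       entropy_sign = entropy_sign)
}

# Shared machinery for the loss value and its gradient wrt the two heads.
# labels: (B, L) 0-based, -1 at padding; targets: (B, L, 3) standardized.
.lossCore <- function(logits, props, labels, targets, mask, temperature,
                      weights, want_grad = FALSE) {
  if (temperature <= 0) stop("temperature must be positive")
  B <- dim(logits)[1]; L <- dim(logits)[2]; K <- dim(logits)[3]
  P <- dim(props)[3]
  sel <- which(as.vector(mask))
  N <- length(sel)
  if (N == 0L) stop("empty mask: no real positions to score")
  logitM <- .mat3(logits)[sel, , drop = FALSE]
  propM <- .mat3(props)[sel, , drop = FALSE]
  tgtM <- .mat3(targets)[sel, , drop = FALSE]
  y <- as.vector(labels)[sel] + 1L

  u <- logitM / temperature
  umax <- apply(u, 1, max)
  eu <- exp(u - umax)
  Z <- rowSums(eu)
  p <- eu / Z
  lse <- log(Z) + umax
  ce <- mean(lse - u[cbind(seq_len(N), y)])
  logp <- (u - umax) - log(Z)
  Hrow <- -rowSums(p * logp)
  ent_mean <- mean(Hrow)
  mse <- mean((propM - tgtM)^2)
  l2 <- mean(logitM^2)
  entropy_term <- weights$entropy_sign * ent_mean
  total <- weights$alpha * mse + weights$beta * ce +
    weights$gamma * entropy_term + weights$lambda * l2
  breakdown <- list(property_mse = mse, cross_entropy = ce,
                    entropy_term = entropy_term, logit_l2 = l2,
                    total = total, weights = weights,
                    temperature = temperature, n_positions = N)
  if (!want_grad) return(breakdown)

  onehot <- matrix(0, N, K)
  onehot[cbind(seq_len(N), y)] <- 1
  du <- weights$beta * (p - onehot) / N +
    weights$gamma * weights$entropy_sign * (-p * (logp + Hrow)) / N
  dlogitM <- du / temperature + weights$lambda * 2 * logitM / (N * K)
  dpropM <- weights$alpha * 2 * (propM - tgtM) / (N * P)
  dlogits <- array(0, dim = dim(logits))
  dprops <- array(0, dim = dim(props))
  dlM <- .mat3(dlogits); dlM[sel, ] <- dlogitM
  dpM <- .mat3(dprops); dpM[sel, ] <- dpropM
  breakdown$dlogits <- .arr3(dlM, B, L)
  breakdown$dprops <- .arr3(dpM, B, L)
  breakdown
}

#' Composite training loss
#'
#' `total = alpha * property_mse + beta * cross_entropy + gamma *
#' entropy_term + lambda * logit_l2`, with the cross-entropy and prediction
#' entropy computed on temperature-scaled logits and every component
#' averaged over unmasked positions only.
#'
#' @param output Result of [forwardModel()].
#' @param residue_labels (B x L) 0-based labels (-1 at padding).
#' @param property_targets (B x L x 3) standardized property targets.
#' @param temperature Positive softmax temperature.
#' @param weights From [lossWeights()].
#' @return A loss-breakdown list (`property_mse`, `cross_entropy`,
#'   `entropy_term`, `logit_l2`, `total`, ...).
#' @export
computeLoss <- function(output, residue_labels, property_targets,
                        temperature = 1, weights = lossWeights()) {
  if (is.vector(residue_labels))
    residue_labels <- matrix(residue_labels, nrow = 1L)
  .lossCore(output$residue_logits, output$property_pred, residue_labels,
            property_targets, output$mask, temperature, weights)
}

# ---- backward ----------------------------------------------------------

.zeroLike <- function(params) .mapLeaves(params, function(x) x * 0)

# Full backward pass from head gradients to a gradient tree mirroring params.
.modelBackward <- function(params, config, cache, mask, dlogits, dprops) {
  g <- list()
  cls_b <- .linearBackward(dlogits, cache$z2, params$cls$W)
  prop_b <- .linearBackward(dprops, cache$z2, params$prop$W)
  g$cls <- list(W = cls_b$dW, b = cls_b$db)
  g$prop <- list(W = prop_b$dW, b = prop_b$db)
  dz2 <- cls_b$dx + prop_b$dx
  if (!is.null(cache$dm2)) dz2 <- dz2 * cache$dm2
  dz2 <- dz2 * (cache$z2_pre > 0)
  dec2_b <- .linearBackward(dz2, cache$z1, params$dec2$W)
  g$dec2 <- list(W = dec2_b$dW, b = dec2_b$db)
  dz1 <- dec2_b$dx
  if (!is.null(cache$dm1)) dz1 <- dz1 * cache$dm1
  dz1 <- dz1 * (cache$z1_pre > 0)
  dec1_b <- .linearBackward(dz1, cache$ctx, params$dec1$W)
  g$dec1 <- list(W = dec1_b$dW, b = dec1_b$db)
  dctx <- dec1_b$dx

  at_b <- .attentionBackward(dctx, cache$ln_out, mask, params$attn$W_in,
                             params$attn$W_out, config$attention_heads,
                             cache$attn_cache)
  g$attn <- list(W_in = at_b$dW_in, b_in = at_b$db_in,
                 W_out = at_b$dW_out, b_out = at_b$db_out)
  dln_out <- dctx + at_b$dx   # residual branch
  ln_b <- .layerNormBackward(dln_out, params$ln$gamma, cache$ln_cache)
  g$ln <- list(gamma = ln_b$dgamma, beta = ln_b$dbeta)

  H <- config$lstm_hidden
  dcur <- ln_b$dx
  g$lstm <- vector("list", config$lstm_layers)
  for (l in rev(seq_len(config$lstm_layers))) {
    d_fwd <- dcur[, , seq_len(H), drop = FALSE]
    d_bwd <- dcur[, , H + seq_len(H), drop = FALSE]
    xin <- cache$lstm_in[[l]]
    fb <- .lstmBackward(d_fwd, xin, mask, params$lstm[[l]]$fwd$W_ih,
                        params$lstm[[l]]$fwd$W_hh,
                        cache$lstm_cache[[l]]$fwd, reverse = FALSE)
    bb <- .lstmBackward(d_bwd, xin, mask, params$lstm[[l]]$bwd$W_ih,
                        params$lstm[[l]]$bwd$W_hh,
                        cache$lstm_cache[[l]]$bwd, reverse = TRUE)
    g$lstm[[l]] <- list(
      fwd = list(W_ih = fb$dW_ih, W_hh = fb$dW_hh, b_ih = fb$db_ih,
                 b_hh = fb$db_hh),
      bwd = list(W_ih = bb$dW_ih, W_hh = bb$dW_hh, b_ih = bb$db_ih,
                 b_hh = bb$db_hh))
    dcur <- fb$dx + bb$dx
  }

  dd <- config$dssp_embed_dim
  g$emb_dssp <- .embedBackward(dcur[, , seq_len(dd), drop = FALSE],
                               cache$dssp, nrow(params$emb_dssp))
  g$emb_type <- .embedBackward(
    dcur[, , dd + seq_len(config$type_embed_dim), drop = FALSE],
    cache$type, nrow(params$emb_type))
  g[names(params)]
}

# Loss + gradient tree on one batch (used by the trainer and in tests).
.lossAndGradients <- function(params, config, batch, temperature, weights,
                              training = FALSE) {
  out <- .forwardPass(params, config, batch$dssp, batch$type, batch$mask,
                      training = training, keep_cache = TRUE)
  lb <- .lossCore(out$residue_logits, out$property_pred, batch$labels,
                  batch$props, batch$mask, temperature, weights,
                  want_grad = TRUE)
  grads <- .modelBackward(params, config, out$cache, batch$mask,
                          lb$dlogits, lb$dprops)
  lb$dlogits <- NULL
  lb$dprops <- NULL
  list(loss = lb, grads = grads)
}
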