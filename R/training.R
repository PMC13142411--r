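# Optimization loop: AdamW with decoupled weight decay, cosine-annealing
# warm restarts (per-epoch steps), linear temperature annealing, global
# gradient-norm clipping, best-validation checkpointing, seeded and
# deterministic end to end.

#' Training configuration
#'
#' Defaults follow the published recipe: 50 epochs, batch size 8, AdamW with
#' learning rate 1e-3 and weight decay 0.01, cosine annealing warm restarts
#' with a first period of 20 epochs doubling at each restart, temperature
#' annealed linearly from 2.0 to 0.5, gradient clipping at max norm 1.0.
#'
#' @param epochs,batch_size,learning_rate,weight_decay Optimizer settings.
#' @param restart_period,restart_mult Warm-restart schedule (T, T_mult).
#' @param temp_start,temp_end Linear temperature annealing endpoints.
#' @param grad_clip_norm Maximum global gradient norm (must be > 0).
#' @param mixed_precision Accepted for configuration compatibility; this
#'   implementation computes in double precision and emits a message when
#'   the flag is set.
#' @param eta_min Learning-rate floor of the cosine schedule.
#' @param weights Loss weights, see [lossWeights()].
#' @param seed Root seed for the training stream.
#' @return A validated config list.
#' @export
trainingConfig <- function(epochs = 50L, batch_size = 8L,
                           learning_rate = 1e-3, weight_decay = 0.01,
                           restart_period = 20L, restart_mult = 2L,
                           temp_start = 2.0, temp_end = 0.5,
                           grad_clip_norm = 1.0, mixed_precision = FALSE,
                           eta_min = 0, weights = lossWeights(),
                           seed = 1L) {
  cfg <- list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              learning_rate = learning_rate, weight_decay = weight_decay,
              restart_period = as.integer(restart_period),
              restart_mult = as.integer(restart_mult),
              temp_start = temp_start, temp_end = temp_end,
              grad_clip_norm = grad_clip_norm,
              mixed_precision = isTRUE(mixed_precision), eta_min = eta_min,
              weights = weights, seed = as.integer(seed))
  if (!(cfg$temp_start >= cfg$temp_end && cfg$temp_end > 0))
    stop("temperature endpoints must satisfy temp_start >= temp_end > 0")
  if (cfg$learning_rate <= 0 || cfg$epochs < 1L || cfg$batch_size < 1L)
    stop("learning_rate, epochs and batch_size must be positive")
  if (cfg$grad_clip_norm <= 0)
    stop("grad_clip_norm must be positive")
  cfg
}

#' Annealed softmax temperature at a (0-based) epoch
#'
#' Linear interpolation with `temperatureAt(0) == temp_start` and
#' `temperatureAt(epochs - 1) == temp_end`.
#'
#' @param epoch Epoch index in `[0, epochs - 1]` (may be fractional).
#' @param config From [trainingConfig()].
#' @export
temperatureAt <- function(epoch, config) {
  if (epoch < 0 || epoch > config$epochs - 1L)
    stop(sprintf("epoch %s outside [0, %d]", format(epoch), config$epochs - 1L))
  if (config$epochs == 1L) return(config$temp_start)
  frac <- epoch / (config$epochs - 1L)
  config$temp_start + frac * (config$temp_end - config$temp_start)
}

#' Cosine-annealing warm-restart learning rate at a (0-based) epoch
#'
#' Cosine decay from `learning_rate` to `eta_min` within each cycle; the
#' first cycle lasts `restart_period` epochs and each subsequent cycle is
#' `restart_mult` times longer. The rate returns to the peak at every
#' restart boundary (epochs 0, 20, 60, ... under the defaults).
#'
#' @param epoch Epoch index >= 0 (may be fractional).
#' @param config From [trainingConfig()].
#' @export
learningRateAt <- function(epoch, config) {
  if (epoch < 0) stop("epoch must be >= 0")
  start <- 0
  Ti <- config$restart_period
  while (epoch >= start + Ti) {
    start <- start + Ti
    Ti <- Ti * config$restart_mult
  }
  tcur <- epoch - start
  config$eta_min + (config$learning_rate - config$eta_min) *
    (1 + cos(pi * tcur / Ti)) / 2
}

.globalNorm <- function(grads) {
  sqrt(.sumLeaves(grads, function(x) sum(x^2)))
}

.clipGrads <- function(grads, max_norm) {
  nrm <- .globalNorm(grads)
  if (is.finite(nrm) && nrm > max_norm)
    grads <- .mapLeaves(grads, function(x) x * (max_norm / nrm))
  list(grads = grads, norm = min(nrm, max_norm), raw_norm = nrm)
}

.checkFinite <- function(loss) {
  for (comp in c("property_mse", "cross_entropy", "entropy_term",
                 "logit_l2", "total")) {
    if (!is.finite(loss[[comp]]))
      stop(sprintf("non-finite loss component '%s' (%s); aborting training",
                   comp, format(loss[[comp]])))
  }
}

.meanLoss <- function(losses) {
  comps <- c("property_mse", "cross_entropy", "entropy_term", "logit_l2",
             "total")
  out <- lapply(comps, function(cn)
    mean(vapply(losses, `[[`, numeric(1), cn)))
  names(out) <- comps
  out
}

.evalSplit <- function(params, config, examples, batch_size, weights) {
  if (length(examples) == 0L) return(NULL)
  batches <- makeBatches(examples, batch_size)
  losses <- lapply(batches, function(b) {
    out <- .forwardPass(params, config, b$dssp, b$type, b$mask,
                        training = FALSE)
    .lossCore(out$residue_logits, out$property_pred, b$labels, b$props,
              b$mask, temperature = 1, weights = weights)
  })
  .meanLoss(losses)
}

#' Train a model on a dataset split
#'
#' Computes the property standardizer from the training split, then runs
#' `epochs` of gradient-clipped AdamW updates with the temperature and
#' learning-rate schedules. Validation loss is computed with dropout off at
#' temperature 1; the checkpoint with minimum validation total loss is
#' retained. Fully reproducible for a fixed `config$seed`.
#'
#' @param model A freshly built [BlstmaModel-class].
#' @param split Result of [splitDataset()] over raw (un-standardized)
#'   examples.
#' @param config From [trainingConfig()].
#' @param verbose Print one progress line per epoch.
#' @return List with `model` (best-validation weights, standardizer
#'   attached) and `history` (one row per epoch: losses, learning rate,
#'   temperature, post-clip gradient norm).
#' @export
trainModel <- function(model, split, config = trainingConfig(),
                       verbose = FALSE) {
  if (config$mixed_precision)
    message("mixed_precision requested: computation proceeds in double precision")
  stopifnot(length(split$train) > 0L)
  standardizer <- computeStandardizer(split$train)
  train_ex <- standardizeExamples(split$train, standardizer)
  val_ex <- standardizeExamples(split$validation, standardizer)
  params <- model@params
  mcfg <- model@config
  m_state <- .zeroLike(params)
  v_state <- .zeroLike(params)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  best_val <- Inf
  best_params <- params
  hist <- vector("list", config$epochs)

  withSeed(deriveSeed(config$seed, "training"), {
    for (epoch in seq_len(config$epochs)) {
      temp <- temperatureAt(epoch - 1L, config)
      lr <- learningRateAt(epoch - 1L, config)
      shuffle_seed <- deriveSeed(config$seed, paste0("shuffle-", epoch))
      batches <- makeBatches(train_ex, config$batch_size, shuffle_seed)
      train_losses <- vector("list", length(batches))
      max_norm_seen <- 0
      for (i in seq_along(batches)) {
        lg <- .lossAndGradients(params, mcfg, batches[[i]], temp,
                                config$weights, training = TRUE)
        .checkFinite(lg$loss)
        train_losses[[i]] <- lg$loss
        cl <- .clipGrads(lg$grads, config$grad_clip_norm)
        max_norm_seen <- max(max_norm_seen, cl$norm)
        step <- step + 1L
        bc1 <- 1 - b1^step
        bc2 <- 1 - b2^step
        m_state <- .zipLeaves(m_state, cl$grads,
                              function(m, g) b1 * m + (1 - b1) * g)
        v_state <- .zipLeaves(v_state, cl$grads,
                              function(v, g) b2 * v + (1 - b2) * g * g)
        upd <- .zipLeaves(m_state, v_state,
                          function(m, v) (m / bc1) / (sqrt(v / bc2) + eps))
        params <- .zipLeaves(params, upd,
                             function(p, u) p - lr * u - lr * config$weight_decay * p)
      }
      tr <- .meanLoss(train_losses)
      vl <- .evalSplit(params, mcfg, val_ex, config$batch_size,
                       config$weights)
      if (!is.null(vl) && vl$total < best_val) {
        best_val <- vl$total
        best_params <- params
      }
      hist[[epoch]] <- data.frame(
        epoch = epoch, lr = lr, temperature = temp,
        train_property_mse = tr$property_mse,
        train_cross_entropy = tr$cross_entropy,
        train_entropy_term = tr$entropy_term,
        train_logit_l2 = tr$logit_l2, train_total = tr$total,
        val_property_mse = if (is.null(vl)) NA else vl$property_mse,
        val_cross_entropy = if (is.null(vl)) NA else vl$cross_entropy,
        val_entropy_term = if (is.null(vl)) NA else vl$entropy_term,
        val_logit_l2 = if (is.null(vl)) NA else vl$logit_l2,
        val_total = if (is.null(vl)) NA else vl$total,
        grad_norm_postclip = max_norm_seen)
      if (verbose)
        message(sprintf("epoch %3d | lr %.2e | T %.3f | train %.4f | val %s",
                        epoch, lr, temp, tr$total,
                        if (is.null(vl)) "NA" else sprintf("%.4f", vl$total)))
    }
  })
  if (is.infinite(best_val)) best_params <- params
  lens <- vapply(split$train, function(e) length(e$dssp_ids), integer(1))
  model@params <- best_params
  model@standardizer <- standardizer
  model@meta$trained_lengths <- c(min(lens), max(lens))
  model@meta$training_seed <- config$seed
  list(model = model, history = do.call(rbind, hist))
}

#' Write a training history to CSV
#' @param history Data frame from [trainModel()].
#' @param path Output path.
#' @export
writeTrainingHistory <- function(history, path) {
  write.csv(history, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save a model checkpoint
#'
#' Serialized weights plus a human-readable JSON sidecar (`<path>.json`)
#' holding the model configuration, the property standardizer, the DSSP
#' state ordering, and the training seed.
#'
#' @param model A [BlstmaModel-class].
#' @param history Optional training history.
#' @param path Checkpoint path.
#' @export
saveCheckpoint <- function(model, history = NULL, path) {
  saveRDS(list(config = model@config, params = model@params,
               standardizer = model@standardizer, meta = model@meta,
               history = history), path)
  sidecar <- list(config = model@config, standardizer = model@standardizer,
                  state_order = model@meta$state_order,
                  trained_lengths = model@meta$trained_lengths,
                  init_seed = model@meta$init_seed,
                  training_seed = model@meta$training_seed)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint path from [saveCheckpoint()].
#' @param config Optional expected model configuration; a mismatch is an
#'   error.
#' @return A [BlstmaModel-class].
#' @export
loadCheckpoint <- function(path, config = NULL) {
  if (!file.exists(path)) stop(sprintf("checkpoint '%s' not found", path))
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop(sprintf("corrupt checkpoint '%s': %s",
                                                   path, conditionMessage(e))))
  if (!is.list(obj) || !all(c("config", "params") %in% names(obj)))
    stop(sprintf("corrupt checkpoint '%s': missing fields", path))
  if (!is.null(config) && !identical(config, obj$config))
    stop("checkpoint model configuration does not match the expected config")
  new("BlstmaModel", config = obj$config, params = obj$params,
      standardizer = if (is.null(obj$standardizer)) list() else obj$standardizer,
      meta = if (is.null(obj$meta)) list() else obj$meta)
}
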