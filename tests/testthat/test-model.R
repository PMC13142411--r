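test_that("the published configuration counts 5,065,280 trainable parameters", {
  cfg <- modelConfig()
  expect_identical(parameterCountFromConfig(cfg), 5065280L)
  model <- buildModel(cfg, seed = 1)
  expect_identical(countParameters(model), 5065280L)
  expect_identical(combinedInputDim(cfg), 80L)
})

test_that("closed-form count matches the built tensor inventory on toy configs", {
  for (cfg in list(tinyModelConfig(),
                   modelConfig(dssp_embed_dim = 4, type_embed_dim = 2,
                               lstm_hidden = 3, lstm_layers = 1,
                               attention_heads = 3, decoder_dims = c(5, 4)),
                   recoveryModelConfig())) {
    expect_identical(countParameters(buildModel(cfg, seed = 2)),
                     parameterCountFromConfig(cfg))
  }
  # removing the embedding tables removes exactly their rows (incl. padding)
  cfg <- modelConfig()
  m <- buildModel(cfg, seed = 1)
  p <- m@params
  p$emb_dssp <- NULL
  p$emb_type <- NULL
  expect_identical(countParameters(p), 5065280L - (10L * 64L + 4L * 16L))
  # count is an architecture property, independent of inputs
  expect_identical(countParameters(buildModel(cfg, seed = 99)), 5065280L)
})

test_that("invalid configurations are rejected", {
  expect_error(modelConfig(attention_heads = 7), "divide")
  expect_error(modelConfig(lstm_hidden = 0), "positive")
  expect_error(modelConfig(decoder_dims = c(10, 10, 10)), "two widths")
})

test_that("classifier head initializes with zero bias and small Xavier weights", {
  m <- buildModel(tinyModelConfig(), seed = 3)
  expect_true(all(m@params$cls$b == 0))
  d2 <- tinyModelConfig()$decoder_dims[2]
  bound <- 0.1 * sqrt(6 / (20 + d2))
  expect_true(all(abs(m@params$cls$W) <= bound))
  expect_true(any(m@params$cls$W != 0))
  # padding embedding rows start at zero
  expect_true(all(m@params$emb_dssp[10, ] == 0))
})

test_that("forward obeys the shape contract and batch equivariance", {
  cfg <- tinyModelConfig()
  m <- buildModel(cfg, seed = 4)
  withr::with_seed(8, {
    dssp <- matrix(sample(0:8, 14, replace = TRUE), 2, 7)
    type <- matrix(ssdesign:::typeIdsOf(as.vector(dssp)), 2, 7)
  })
  out <- forwardModel(m, dssp, type)
  expect_equal(dim(out$residue_logits), c(2L, 7L, 20L))
  expect_equal(dim(out$property_pred), c(2L, 7L, 3L))
  expect_true(all(is.finite(out$residue_logits)))
  # permuting the batch permutes outputs identically (dropout off)
  swapped <- forwardModel(m, dssp[2:1, ], type[2:1, ])
  expect_equal(swapped$residue_logits[1, , ], out$residue_logits[2, , ])
  expect_equal(swapped$property_pred[2, , ], out$property_pred[1, , ])
  expect_error(forwardModel(m, dssp, type[, 1:5]), "identical shape")
})

test_that("padding never leaks into real positions", {
  cfg <- tinyModelConfig()
  m <- buildModel(cfg, seed = 5)
  ids <- tokenizeDssp("HHEETTSC")
  types <- ssdesign:::typeIdsOf(ids)
  short <- forwardModel(m, matrix(ids, 1), matrix(types, 1))
  # same example padded by 4 extra positions
  pad <- function(v, id) matrix(c(v, rep(id, 4)), 1)
  mask <- matrix(c(rep(TRUE, 8), rep(FALSE, 4)), 1)
  long <- forwardModel(m, pad(ids, DSSP_PAD_ID), pad(types, TYPE_PAD_ID),
                       mask)
  expect_equal(long$residue_logits[1, 1:8, ], short$residue_logits[1, , ],
               tolerance = 1e-12)
  expect_equal(long$property_pred[1, 1:8, ], short$property_pred[1, , ],
               tolerance = 1e-12)
})

test_that("loss closed forms: zero MSE, ln(20) cross-entropy and entropy", {
  B <- 1L; L <- 4L
  out <- list(residue_logits = array(0, dim = c(B, L, 20)),
              property_pred = array(rnorm(B * L * 3), dim = c(B, L, 3)),
              mask = matrix(TRUE, B, L))
  labels <- matrix(sample(0:19, L, replace = TRUE), B, L)
  lb <- computeLoss(out, labels, out$property_pred, temperature = 1)
  expect_equal(lb$property_mse, 0)
  expect_equal(lb$cross_entropy, log(20), tolerance = 1e-12)
  # all-equal logits give maximal prediction entropy ln(20)
  expect_equal(abs(lb$entropy_term), log(20), tolerance = 1e-12)
  expect_equal(lb$logit_l2, 0)
  expect_equal(lb$total,
               lb$weights$alpha * lb$property_mse +
                 lb$weights$beta * lb$cross_entropy +
                 lb$weights$gamma * lb$entropy_term +
                 lb$weights$lambda * lb$logit_l2)
  expect_error(computeLoss(out, labels, out$property_pred, temperature = 0),
               "positive")
})

test_that("loss ignores padded positions entirely", {
  cfg <- tinyModelConfig()
  m <- buildModel(cfg, seed = 6)
  b <- raggedBatch()
  out <- forwardModel(m, b$dssp, b$type, b$mask)
  lb <- computeLoss(out, b$labels, b$props, temperature = 1.3)
  # re-pad the second example with 3 more columns: all components unchanged
  ext <- function(m2, fill) cbind(m2, matrix(fill, 2, 3))
  b2 <- list(dssp = ext(b$dssp, DSSP_PAD_ID), type = ext(b$type, TYPE_PAD_ID),
             labels = ext(b$labels, -1L),
             props = array(c(b$props, rnorm(2 * 3 * 3)), dim = c(2, 8, 3)),
             mask = ext(b$mask, FALSE))
  b2$props[, 1:5, ] <- b$props
  out2 <- forwardModel(m, b2$dssp, b2$type, b2$mask)
  lb2 <- computeLoss(out2, b2$labels, b2$props, temperature = 1.3)
  for (comp in c("property_mse", "cross_entropy", "entropy_term",
                 "logit_l2", "total"))
    expect_equal(lb2[[comp]], lb[[comp]], tolerance = 1e-10)
  # and batch order does not matter
  out3 <- forwardModel(m, b$dssp[2:1, ], b$type[2:1, ], b$mask[2:1, ])
  lb3 <- computeLoss(out3, b$labels[2:1, ], b$props[2:1, , , drop = FALSE],
                     temperature = 1.3)
  expect_equal(lb3$total, lb$total, tolerance = 1e-12)
})

test_that("cross-entropy sharpens for a confident correct prediction as T drops", {
  logits <- array(0, dim = c(1, 1, 20))
  logits[1, 1, 5] <- 4  # confident, correct
  out <- list(residue_logits = logits,
              property_pred = array(0, dim = c(1, 1, 3)),
              mask = matrix(TRUE, 1, 1))
  labels <- matrix(4L, 1, 1)  # 0-based id 4 = index 5
  ce <- vapply(c(1, 0.8, 0.5, 0.25), function(Tt)
    computeLoss(out, labels, out$property_pred, temperature = Tt)$cross_entropy,
    numeric(1))
  expect_true(all(diff(ce) <= 1e-12))
})

test_that("analytic gradients match central finite differences everywhere", {
  cfg <- tinyModelConfig()
  m <- buildModel(cfg, seed = 11)
  b <- raggedBatch()
  w <- lossWeights(lambda = 1e-3)
  lossAt <- function(params) {
    out <- ssdesign:::.forwardPass(params, cfg, b$dssp, b$type, b$mask)
    ssdesign:::.lossCore(out$residue_logits, out$property_pred, b$labels,
                         b$props, b$mask, temperature = 1.7, weights = w)$total
  }
  lg <- ssdesign:::.lossAndGradients(m@params, cfg, b, 1.7, w)
  eps <- 1e-6
  paths <- list(list("emb_dssp"), list("emb_type"),
                list("lstm", 1L, "fwd", "W_ih"), list("lstm", 1L, "bwd", "W_hh"),
                list("lstm", 2L, "fwd", "b_ih"), list("lstm", 2L, "bwd", "W_ih"),
                list("ln", "gamma"), list("ln", "beta"),
                list("attn", "W_in"), list("attn", "b_in"), list("attn", "W_out"),
                list("dec1", "W"), list("dec1", "b"), list("dec2", "W"),
                list("cls", "W"), list("cls", "b"), list("prop", "W"),
                list("prop", "b"))
  withr::with_seed(21, {
    for (path in paths) {
      arr <- getLeaf(m@params, path)
      grad <- getLeaf(lg$grads, path)
      idx <- if (length(arr) <= 4) seq_along(arr)
             else sample.int(length(arr), 4)
      for (i in idx) {
        p1 <- nudgeLeaf(m@params, path, i, eps)
        p2 <- nudgeLeaf(m@params, path, i, -eps)
        num <- (lossAt(p1) - lossAt(p2)) / (2 * eps)
        expect_equal(grad[i], num, tolerance = 1e-4,
                     label = sprintf("grad[%s][%d]",
                                     paste(path, collapse = "/"), i))
      }
    }
  })
})

test_that("gradient reaches every trainable tensor on a random batch", {
  cfg <- tinyModelConfig()
  m <- buildModel(cfg, seed = 12)
  b <- raggedBatch(7)
  lg <- ssdesign:::.lossAndGradients(m@params, cfg, b, 1.2, lossWeights())
  walk <- function(g, path) {
    if (is.list(g)) {
      for (i in seq_along(g))
        walk(g[[i]], paste(path, if (!is.null(names(g))) names(g)[i] else i))
    } else {
      expect_gt(sum(abs(g)), 0, label = paste("gradient at", path))
    }
  }
  # embeddings only receive gradient for observed tokens; check the rest
  grads <- lg$grads
  expect_gt(sum(abs(grads$emb_dssp)), 0)
  expect_gt(sum(abs(grads$emb_type)), 0)
  walk(grads[setdiff(names(grads), c("emb_dssp", "emb_type"))], "params")
})
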