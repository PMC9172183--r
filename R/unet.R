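# Compact residual U-Net for 2D lung segmentation, trained with the
# Soft-Jaccard loss. The network follows the winning configuration of the
# acquisition study: 3 downsampling stages, 1 bridge, 4 decoder stages
# (3 upsampling + 1 full-resolution block), each stage a residual block of
# two (batch norm, 3x3 convolution, leaky ReLU) cycles, and a final 1x1
# convolution with no output nonlinearity. The raw output is a logit map;
# probabilities are obtained by the logistic map when evaluating the loss or
# thresholding (threshold 0.5 on probability == 0 on logits).
#
# Convolution/pooling kernels live in src/unet_ops.cpp; everything else
# (batch norm, activations, Adam, the training loop) is plain R on
# (H, W, C, N) arrays.

#' Segmentation model configuration
#'
#' Fixed to the architecture that won the original hyperparameter sweep:
#' 3 downsampling layers, 1 bridge layer, 4 upsampling layers, blocks of two
#' (batch normalization, convolution, leaky ReLU) cycles, batch size 64.
#' Channel width and batch size may be overridden (smaller batches make CPU
#' training practical); the layer counts themselves are hard-coded.
#'
#' @param baseChannels channels of the first encoder stage (doubles per
#'   stage).
#' @param batchSize training batch size (default 64; use 8-16 on a laptop
#'   CPU).
#' @param threshold probability threshold turning the probability map into a
#'   mask.
#' @param epsilon Soft-Jaccard smoothing constant.
#' @param leakySlope negative slope of the leaky ReLU.
#' @param resampleMM in-plane working resolution in mm (inputs are resampled
#'   here before inference; within 1-1.5 mm by default).
#' @param maxEpochs default training epoch cap.
#' @return A list of class \code{SegModelConfig}.
#' @export
segModelConfig <- function(baseChannels = 8L, batchSize = 64L,
                           threshold = 0.5, epsilon = 1, leakySlope = 0.1,
                           resampleMM = 1.25, maxEpochs = 20L) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  structure(list(downLayers = 3L, bridgeLayers = 1L, upLayers = 4L,
                 blockCycles = 2L, baseChannels = as.integer(baseChannels),
                 batchSize = as.integer(batchSize), threshold = threshold,
                 epsilon = epsilon, leakySlope = leakySlope,
                 resampleMM = resampleMM, maxEpochs = as.integer(maxEpochs)),
            class = "SegModelConfig")
}

## ---- low-level layers -----------------------------------------------------

.bnFwd <- function(x, g, b, rm, rv, train, momentum = 0.1, eps = 1e-5) {
  if (train) {
    st <- cppChanStats(x)
    mu <- st$mean; v <- st$var
    invstd <- 1 / sqrt(v + eps)
    xhat <- cppChanScale(x, invstd, -mu * invstd)
    list(y = cppChanScale(xhat, g, b), xhat = xhat, invstd = invstd,
         rm = (1 - momentum) * rm + momentum * mu,
         rv = (1 - momentum) * rv + momentum * v)
  } else {
    invstd <- 1 / sqrt(rv + eps)
    xhat <- cppChanScale(x, invstd, -rm * invstd)
    list(y = cppChanScale(xhat, g, b), xhat = xhat, invstd = invstd,
         rm = rm, rv = rv)
  }
}

.bnBwd <- function(dy, xhat, invstd, g) {
  d <- dim(dy)
  M <- d[1] * d[2] * d[4]
  s <- cppChanSums(dy, xhat)
  dx <- cppBnBwdCore(dy, xhat, s$sdy, s$sdyx, g * invstd / M)
  list(dx = dx, dg = s$sdyx, db = s$sdy)
}

.ccat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

## ---- residual block -------------------------------------------------------

.blockInit <- function(cin, cout) {
  he <- function(k, ci, co) {
    array(rnorm(k * k * ci * co, 0, sqrt(2 / (k * k * ci))),
          dim = c(k, k, ci, co))
  }
  p <- list(bn1.g = rep(1, cin), bn1.b = rep(0, cin),
            w1 = he(3, cin, cout), b1 = rep(0, cout),
            bn2.g = rep(1, cout), bn2.b = rep(0, cout),
            w2 = he(3, cout, cout), b2 = rep(0, cout))
  if (cin != cout) {
    p$pw <- he(1, cin, cout)
    p$pb <- rep(0, cout)
  }
  r <- list(bn1.rm = rep(0, cin), bn1.rv = rep(1, cin),
            bn2.rm = rep(0, cout), bn2.rv = rep(1, cout))
  list(p = p, r = r)
}

.blockFwd <- function(p, r, x, train, slope) {
  b1 <- .bnFwd(x, p$bn1.g, p$bn1.b, r$bn1.rm, r$bn1.rv, train)
  c1 <- cppConvFwd(b1$y, p$w1, p$b1)
  a1 <- cppLrelu(c1, slope)
  b2 <- .bnFwd(a1, p$bn2.g, p$bn2.b, r$bn2.rm, r$bn2.rv, train)
  c2 <- cppConvFwd(b2$y, p$w2, p$b2)
  a2 <- cppLrelu(c2, slope)
  res <- if (is.null(p$pw)) x else cppConvFwd(x, p$pw, p$pb)
  rNew <- list(bn1.rm = b1$rm, bn1.rv = b1$rv, bn2.rm = b2$rm, bn2.rv = b2$rv)
  list(y = a2 + res,
       cache = list(x = x, b1y = b1$y, b1xhat = b1$xhat, b1inv = b1$invstd,
                    c1 = c1, b2y = b2$y,
                    b2xhat = b2$xhat, b2inv = b2$invstd, c2 = c2),
       r = rNew)
}

.blockBwd <- function(p, cache, dy, slope) {
  g <- list()
  dc2 <- cppLreluBwd(dy, cache$c2, slope)
  cb2 <- cppConvBwd(cache$b2y, p$w2, dc2)
  g$w2 <- cb2$gw; g$b2 <- cb2$gb
  bb2 <- .bnBwd(cb2$gx, cache$b2xhat, cache$b2inv, p$bn2.g)
  g$bn2.g <- bb2$dg; g$bn2.b <- bb2$db
  dc1 <- cppLreluBwd(bb2$dx, cache$c1, slope)
  cb1 <- cppConvBwd(cache$b1y, p$w1, dc1)
  g$w1 <- cb1$gw; g$b1 <- cb1$gb
  bb1 <- .bnBwd(cb1$gx, cache$b1xhat, cache$b1inv, p$bn1.g)
  g$bn1.g <- bb1$dg; g$bn1.b <- bb1$db
  dx <- bb1$dx
  if (is.null(p$pw)) {
    dx <- dx + dy
  } else {
    cbp <- cppConvBwd(cache$x, p$pw, dy)
    g$pw <- cbp$gw; g$pb <- cbp$gb
    dx <- dx + cbp$gx
  }
  list(dx = dx, g = g)
}

## ---- full network ---------------------------------------------------------

.unetBlocks <- function(cfg) {
  c0 <- cfg$baseChannels
  list(enc1 = c(1, c0), enc2 = c(c0, 2 * c0), enc3 = c(2 * c0, 4 * c0),
       bridge = c(4 * c0, 8 * c0),
       dec3 = c(12 * c0, 4 * c0), dec2 = c(6 * c0, 2 * c0),
       dec1 = c(3 * c0, c0), dec0 = c(c0, c0))
}

.unetInit <- function(cfg, seed = 1L) {
  .withSeed(seed, {
    specs <- .unetBlocks(cfg)
    P <- list(); R <- list()
    for (nm in names(specs)) {
      bi <- .blockInit(specs[[nm]][1], specs[[nm]][2])
      P[[nm]] <- bi$p
      R[[nm]] <- bi$r
    }
    P$out <- list(w = array(rnorm(cfg$baseChannels, 0,
                                  sqrt(2 / cfg$baseChannels)),
                            dim = c(1, 1, cfg$baseChannels, 1)),
                  b = 0)
    structure(list(params = P, running = R, cfg = cfg, trained = FALSE,
                   log = NULL), class = "UNetModel")
  })
}

.unetFwd <- function(P, R, cfg, x, train) {
  s <- cfg$leakySlope
  cc <- list()
  e1 <- .blockFwd(P$enc1, R$enc1, x, train, s)
  p1 <- cppMaxPool2(e1$y)
  e2 <- .blockFwd(P$enc2, R$enc2, p1$y, train, s)
  p2 <- cppMaxPool2(e2$y)
  e3 <- .blockFwd(P$enc3, R$enc3, p2$y, train, s)
  p3 <- cppMaxPool2(e3$y)
  br <- .blockFwd(P$bridge, R$bridge, p3$y, train, s)
  u3 <- cppUpsample2(br$y)
  d3in <- .ccat(u3, e3$y)
  d3 <- .blockFwd(P$dec3, R$dec3, d3in, train, s)
  u2 <- cppUpsample2(d3$y)
  d2in <- .ccat(u2, e2$y)
  d2 <- .blockFwd(P$dec2, R$dec2, d2in, train, s)
  u1 <- cppUpsample2(d2$y)
  d1in <- .ccat(u1, e1$y)
  d1 <- .blockFwd(P$dec1, R$dec1, d1in, train, s)
  d0 <- .blockFwd(P$dec0, R$dec0, d1$y, train, s)
  z <- cppConvFwd(d0$y, P$out$w, P$out$b)
  RNew <- list(enc1 = e1$r, enc2 = e2$r, enc3 = e3$r, bridge = br$r,
               dec3 = d3$r, dec2 = d2$r, dec1 = d1$r, dec0 = d0$r)
  cache <- list(e1 = e1$cache, e2 = e2$cache, e3 = e3$cache,
                bridge = br$cache, dec3 = d3$cache, dec2 = d2$cache,
                dec1 = d1$cache, dec0 = d0$cache,
                p1 = p1, p2 = p2, p3 = p3,
                e1y = e1$y, e2y = e2$y, e3y = e3$y,
                d3in = d3in, d2in = d2in, d1in = d1in, d0in = d1$y,
                d0y = d0$y)
  list(z = z, cache = cache, R = RNew)
}

.splitChannels <- function(x, c1) {
  d <- dim(x)
  list(a = x[, , seq_len(c1), , drop = FALSE],
       b = x[, , c1 + seq_len(d[3] - c1), , drop = FALSE])
}

.unetBwd <- function(P, cfg, cache, dz) {
  s <- cfg$leakySlope
  G <- list()
  co <- cppConvBwd(cache$d0y, P$out$w, dz)
  G$out <- list(w = co$gw, b = co$gb)
  bd0 <- .blockBwd(P$dec0, cache$dec0, co$gx, s)
  G$dec0 <- bd0$g
  bd1 <- .blockBwd(P$dec1, cache$dec1, bd0$dx, s)
  G$dec1 <- bd1$g
  sp1 <- .splitChannels(bd1$dx, dim(bd1$dx)[3] - dim(cache$e1y)[3])
  du1 <- cppUpsample2Bwd(sp1$a)
  de1skip <- sp1$b
  bd2 <- .blockBwd(P$dec2, cache$dec2, du1, s)
  G$dec2 <- bd2$g
  sp2 <- .splitChannels(bd2$dx, dim(bd2$dx)[3] - dim(cache$e2y)[3])
  du2 <- cppUpsample2Bwd(sp2$a)
  de2skip <- sp2$b
  bd3 <- .blockBwd(P$dec3, cache$dec3, du2, s)
  G$dec3 <- bd3$g
  sp3 <- .splitChannels(bd3$dx, dim(bd3$dx)[3] - dim(cache$e3y)[3])
  du3 <- cppUpsample2Bwd(sp3$a)
  de3skip <- sp3$b
  bbr <- .blockBwd(P$bridge, cache$bridge, du3, s)
  G$bridge <- bbr$g
  dp3 <- cppMaxUnpool2(bbr$dx, cache$p3$idx, dim(cache$e3y))
  be3 <- .blockBwd(P$enc3, cache$e3, dp3 + de3skip, s)
  G$enc3 <- be3$g
  dp2 <- cppMaxUnpool2(be3$dx, cache$p2$idx, dim(cache$e2y))
  be2 <- .blockBwd(P$enc2, cache$e2, dp2 + de2skip, s)
  G$enc2 <- be2$g
  dp1 <- cppMaxUnpool2(be2$dx, cache$p1$idx, dim(cache$e1y))
  be1 <- .blockBwd(P$enc1, cache$e1, dp1 + de1skip, s)
  G$enc1 <- be1$g
  G
}

## ---- loss and optimizer ---------------------------------------------------

.sigmoid <- function(z) 1 / (1 + exp(-z))

# aggregated Soft-Jaccard over the batch on probabilities sigmoid(z);
# returns loss and gradient w.r.t. z
.softJaccardGrad <- function(z, g, epsilon) {
  p <- .sigmoid(z)
  i <- sum(p * g)
  u <- sum(p) + sum(g) - i
  loss <- 1 - (i + epsilon) / (u + epsilon)
  dLdp <- -(g * (u + epsilon) - (i + epsilon) * (1 - g)) / (u + epsilon)^2
  list(loss = loss, dz = dLdp * p * (1 - p))
}

# training objective: Soft-Jaccard plus a binary cross-entropy term. The
# Jaccard gradient passes through p(1-p) and dies once logits saturate,
# which can freeze training on degenerate minima; the BCE gradient (p - g)
# has no such trap. Validation is scored with pure Soft-Jaccard.
.trainLossGrad <- function(z, g, epsilon, bceWeight = 0.5) {
  sj <- .softJaccardGrad(z, g, epsilon)
  p <- .sigmoid(z)
  n <- length(p)
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  bce <- -mean(g * log(pc) + (1 - g) * log(1 - pc))
  list(loss = sj$loss + bceWeight * bce,
       dz = sj$dz + bceWeight * (p - g) / n)
}

.adamStep <- function(P, G, state, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (blk in names(G)) {
    for (nm in names(G[[blk]])) {
      g <- G[[blk]][[nm]]
      key <- paste0(blk, ".", nm)
      if (is.null(state$m[[key]])) {
        state$m[[key]] <- g * 0
        state$v[[key]] <- g * 0
      }
      state$m[[key]] <- b1 * state$m[[key]] + (1 - b1) * g
      state$v[[key]] <- b2 * state$v[[key]] + (1 - b2) * g * g
      mhat <- state$m[[key]] / (1 - b1^t)
      vhat <- state$v[[key]] / (1 - b2^t)
      P[[blk]][[nm]] <- P[[blk]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(P = P, state = state)
}

.normSlice <- function(m) {
  s <- sd(m)
  if (s < 1e-12) s <- 1
  (m - mean(m)) / s
}

## ---- training and prediction ----------------------------------------------

#' Train the residual U-Net on image/mask slice pairs
#'
#' Slices should already be at the model's working resolution (1-1.5 mm
#' in-plane) with spatial dimensions divisible by 8. Each slice is
#' standardized (z-scored) before entering the network. Training minimizes
#' the batch-aggregated Soft-Jaccard loss with Adam; per-epoch training loss,
#' validation loss and validation Dice are logged, the best-validation-Dice
#' weights are kept, and training stops early once validation Dice is
#' essentially perfect or stops improving.
#'
#' @param images numeric array (H, W, N) of slices.
#' @param masks binary array (H, W, N) of lung masks.
#' @param cfg a \code{\link{segModelConfig}}.
#' @param augCfg an \code{\link{augmentationConfig}}, or NULL to disable
#'   augmentation.
#' @param split train/validation fractions (default 0.8/0.2).
#' @param seed RNG seed for the split, initialization, shuffling and
#'   augmentation.
#' @param batchSize override of \code{cfg$batchSize}.
#' @param lr Adam learning rate.
#' @param maxEpochs override of \code{cfg$maxEpochs}.
#' @param patience epochs without validation-Dice improvement before
#'   stopping.
#' @param targetDice validation Dice at which training stops early.
#' @param verbose print per-epoch progress.
#' @return A \code{UNetModel} list: \code{params}, \code{running} (batch-norm
#'   statistics), \code{cfg}, \code{log} (data.frame epoch/trainLoss/valLoss/
#'   valDice), \code{trained}.
#' @export
trainUnet <- function(images, masks, cfg = segModelConfig(),
                      augCfg = augmentationConfig(), split = c(0.8, 0.2),
                      seed = 1L, batchSize = NULL, lr = 2e-3,
                      maxEpochs = NULL, patience = 5, targetDice = 0.98,
                      verbose = FALSE) {
  if (is.list(images)) images <- simplify2array(images)
  if (is.list(masks)) masks <- simplify2array(masks)
  d <- dim(images)
  if (length(d) != 3L || d[3] < 2L)
    stop("need at least two image/mask slice pairs")
  if (!identical(dim(masks), d)) stop("image and mask arrays differ in shape")
  if (sum(masks) == 0) stop("all masks are empty; nothing to learn")
  if (any(d[1:2] %% 8 != 0))
    stop("slice dimensions must be divisible by 8")
  if (is.null(batchSize)) batchSize <- cfg$batchSize
  if (is.null(maxEpochs)) maxEpochs <- cfg$maxEpochs
  n <- d[3]

  model <- .unetInit(cfg, seed = seed)
  P <- model$params; R <- model$running

  .withSeed(seed + 1L, {
    perm <- sample.int(n)
    nTrain <- round(split[1] * n)
    trainIdx <- perm[seq_len(nTrain)]
    valIdx <- perm[(nTrain + 1):n]

    state <- list(m = list(), v = list())
    t <- 0
    bestDice <- -Inf; bestP <- P; bestR <- R; bestEpoch <- 0
    log <- NULL

    evalVal <- function(P, R) {
      losses <- numeric(0); dices <- numeric(0)
      for (b in split(valIdx, ceiling(seq_along(valIdx) / batchSize))) {
        x <- array(0, c(d[1], d[2], 1, length(b)))
        g <- array(0, c(d[1], d[2], 1, length(b)))
        for (k in seq_along(b)) {
          x[, , 1, k] <- .normSlice(images[, , b[k]])
          g[, , 1, k] <- masks[, , b[k]]
        }
        fw <- .unetFwd(P, R, cfg, x, train = FALSE)
        p <- .sigmoid(fw$z)
        for (k in seq_along(b)) {
          losses <- c(losses, softJaccardLoss(p[, , 1, k], g[, , 1, k],
                                              cfg$epsilon))
          dices <- c(dices, diceCoefficient(p[, , 1, k] >= cfg$threshold,
                                            g[, , 1, k] > 0.5))
        }
      }
      c(loss = mean(losses), dice = mean(dices))
    }

    for (epoch in seq_len(maxEpochs)) {
      order <- sample(trainIdx)
      epochLoss <- numeric(0)
      for (b in split(order, ceiling(seq_along(order) / batchSize))) {
        x <- array(0, c(d[1], d[2], 1, length(b)))
        g <- array(0, c(d[1], d[2], 1, length(b)))
        for (k in seq_along(b)) {
          img <- images[, , b[k]]; msk <- masks[, , b[k]]
          if (!is.null(augCfg)) {
            aug <- augmentPair(img, msk, augCfg,
                               seed = sample.int(.Machine$integer.max, 1))
            img <- aug$image; msk <- aug$mask
          }
          x[, , 1, k] <- .normSlice(img)
          g[, , 1, k] <- msk
        }
        fw <- .unetFwd(P, R, cfg, x, train = TRUE)
        R <- fw$R
        sj <- .trainLossGrad(fw$z, g, cfg$epsilon)
        epochLoss <- c(epochLoss, sj$loss)
        G <- .unetBwd(P, cfg, fw$cache, sj$dz)
        t <- t + 1
        st <- .adamStep(P, G, state, lr, t)
        P <- st$P; state <- st$state
      }
      ev <- evalVal(P, R)
      log <- rbind(log, data.frame(epoch = epoch,
                                   trainLoss = mean(epochLoss),
                                   valLoss = ev["loss"],
                                   valDice = ev["dice"]))
      if (verbose)
        message(sprintf("epoch %d: train loss %.4f, val loss %.4f, val Dice %.4f",
                        epoch, mean(epochLoss), ev["loss"], ev["dice"]))
      if (ev["dice"] > bestDice) {
        bestDice <- ev["dice"]; bestP <- P; bestR <- R; bestEpoch <- epoch
      }
      if (ev["dice"] >= targetDice) break
      if (epoch - bestEpoch >= patience) break
    }
    rownames(log) <- NULL
    structure(list(params = bestP, running = bestR, cfg = cfg, log = log,
                   trained = TRUE, valDice = bestDice), class = "UNetModel")
  })
}

.padTo8 <- function(m) {
  d <- dim(m)
  d2 <- ceiling(d / 8) * 8
  out <- matrix(0, d2[1], d2[2])
  out[seq_len(d[1]), seq_len(d[2])] <- m
  out
}

#' Predict lung masks for a volume with a trained U-Net
#'
#' Each coronal slice is resampled in-plane to the model's working
#' resolution, standardized, passed through the network, and the probability
#' map is resampled back and thresholded. Slices with no suprathreshold
#' pixels yield empty masks. 3D connected components of the stacked masks
#' are assigned to the right or left lung by centroid column relative to the
#' volume midline (ties toward right).
#'
#' @param model a trained \code{UNetModel}.
#' @param volume an \linkS4class{MRIVolume}.
#' @param cfg configuration override (defaults to the model's own).
#' @param batchSlices slices fed per forward pass.
#' @return A \linkS4class{LungSegmentation}.
#' @export
predictLungsUnet <- function(model, volume, cfg = model$cfg,
                             batchSlices = 16L) {
  if (!inherits(model, "UNetModel") || !isTRUE(model$trained))
    stop("model is not a trained UNetModel")
  dat <- volume@data
  d <- dim(dat)
  sp <- volume@spacing
  w2 <- round(d[2] * sp[2] / cfg$resampleMM)
  c2 <- round(d[3] * sp[3] / cfg$resampleMM)
  prob <- array(0, dim = d)
  sliceList <- lapply(seq_len(d[1]), function(s) {
    m <- dat[s, , ]
    if (!(w2 == d[2] && c2 == d[3])) m <- .resize2d(m, w2, c2)
    .padTo8(m)
  })
  pd <- dim(sliceList[[1]])
  for (b in split(seq_len(d[1]), ceiling(seq_len(d[1]) / batchSlices))) {
    x <- array(0, c(pd[1], pd[2], 1, length(b)))
    for (k in seq_along(b)) x[, , 1, k] <- .normSlice(sliceList[[b[k]]])
    fw <- .unetFwd(model$params, model$running, cfg, x, train = FALSE)
    p <- .sigmoid(fw$z)
    for (k in seq_along(b)) {
      ps <- p[seq_len(w2), seq_len(c2), 1, k]
      if (!(w2 == d[2] && c2 == d[3])) ps <- .resize2d(ps, d[2], d[3])
      prob[b[k], , ] <- ps
    }
  }
  mask <- prob >= cfg$threshold
  lab <- cppLabel3D(mask)
  right <- array(FALSE, d); left <- array(FALSE, d)
  if (max(lab) > 0) {
    mid <- (d[3] + 1) / 2
    for (cc in seq_len(max(lab))) {
      idx <- which(lab == cc, arr.ind = TRUE)
      if (mean(idx[, 3]) <= mid) right[idx] <- TRUE else left[idx] <- TRUE
    }
  }
  LungSegmentation(right, left, spacing = sp)
}

#' Save / load a trained segmentation model
#'
#' The model is written as a single serialized file; its configuration is
#' echoed alongside as a JSON sidecar for provenance.
#'
#' @param model a \code{UNetModel}.
#' @param path destination path (the sidecar gets extension .json).
#' @return \code{saveUNetModel}: invisibly, \code{path};
#'   \code{loadUNetModel}: the model.
#' @export
saveUNetModel <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(model$cfg[setdiff(names(model$cfg), character(0))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveUNetModel
#' @export
loadUNetModel <- function(path) readRDS(path)
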