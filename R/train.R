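# Seeded training loop for the segmentation network: Adam, composite
# cross-entropy + soft-Dice loss, per-epoch validation metrics and
# best-checkpoint tracking by validation mIoU.

#' Training configuration
#'
#' Defaults follow the production settings (640 px inputs, batch 8, 200
#' epochs, initial learning rate 0.001, constant schedule); the test suite
#' and desk-scale examples override them with small values.
#'
#' @param input_size Input size in pixels.
#' @param batch_size Batch size, >= 1.
#' @param epochs Number of epochs, >= 1.
#' @param lr Learning rate, > 0 (constant; Adam).
#' @param seed Integer seed covering shuffling and weight initialization.
#' @param w_ce,w_dice Loss weights of the cross-entropy and soft-Dice
#'   terms.
#' @param eval_every Validation-metric cadence in epochs.
#' @return Object of class `train_config`.
#' @export
train_config <- function(input_size = 640, batch_size = 8, epochs = 200,
                         lr = 0.001, seed = 1L, w_ce = 0.5, w_dice = 0.5,
                         eval_every = 1L) {
  if (lr <= 0) stop("learning rate must be > 0")
  if (batch_size < 1) stop("batch size must be >= 1")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(input_size = input_size, batch_size = batch_size,
                 epochs = epochs, lr = lr, seed = seed, w_ce = w_ce,
                 w_dice = w_dice, eval_every = eval_every),
            class = "train_config")
}

#' Composite segmentation loss
#'
#' Weighted sum of per-pixel softmax cross-entropy and soft multi-class
#' Dice loss. With uniform logits over `K` classes the cross-entropy term
#' equals `log(K)` per pixel.
#'
#' @param logits `H x W x K` (or `H x W x K x N`) array of class logits.
#' @param target Integer label matrix/array (`0..K-1`), matching shape.
#' @param w_ce,w_dice Term weights.
#' @return Non-negative scalar loss.
#' @export
composite_loss <- function(logits, target, w_ce = 0.5, w_dice = 0.5) {
  d <- dim(logits)
  if (length(d) == 3L) dim(logits) <- c(d[1], d[2], 1L, d[3])
  node <- ad_ce_dice_loss(ad_const(logits), target, w_ce, w_dice)
  as.numeric(node$value)
}

# One Adam step over all store parameters using accumulated gradients.
adam_state <- function(store) {
  e <- new.env(parent = emptyenv())
  e$m <- lapply(store$params, function(p) array(0, dim(p$value) %||%
                                                  length(p$value)))
  e$v <- e$m
  e$t <- 0L
  e
}

adam_step <- function(store, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(store$params)) {
    p <- store$params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    p$value <- p$value - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  invisible(NULL)
}

# Stack a list of (image, mask) samples into batch arrays.
.stack_batch <- function(samples) {
  H <- dim(samples[[1]]$image)[1]; W <- dim(samples[[1]]$image)[2]
  N <- length(samples)
  x <- array(0, c(H, W, N, 3L))
  y <- array(0L, c(H, W, N))
  for (i in seq_len(N)) {
    x[, , i, ] <- samples[[i]]$image / 255
    y[, , i] <- unclass(samples[[i]]$mask)
  }
  list(x = x, y = y)
}

#' Evaluate pooled segmentation metrics on a sample set
#'
#' @param model An `ar2u_model`.
#' @param samples List of `list(image, mask)` pairs.
#' @param categories mIoU category set (see [miou()]).
#' @return List with `miou`, `mean_dice`, `mean_f1` over pooled confusion
#'   counts.
#' @export
evaluate_model <- function(model, samples, categories = NULL) {
  K <- model$config$n_classes
  counts <- NULL
  for (s in samples) {
    pred <- predict_mask(model, s$image)
    cc <- confusion_counts(unclass(pred), unclass(s$mask), K)
    counts <- if (is.null(counts)) cc else add_confusion(counts, cc)
  }
  id <- iou_dice(counts)
  prf <- precision_recall_f1(counts)
  if (is.null(categories)) categories <- setdiff(id$class, 0L)
  sel <- id$class %in% categories
  list(miou = mean(id$iou[sel], na.rm = TRUE),
       mean_dice = mean(id$dice[sel], na.rm = TRUE),
       mean_f1 = mean(prf$f1[sel], na.rm = TRUE),
       counts = counts)
}

#' Train the segmentation model
#'
#' Seeded mini-batch training with Adam on the composite loss. Validation
#' metrics are computed every `eval_every` epochs; the parameter state with
#' the best validation mIoU is restored into the model at the end (when a
#' validation set is given).
#'
#' @param model An `ar2u_model` (modified in place).
#' @param train_samples List of `list(image, mask)` pairs.
#' @param val_samples Optional validation list.
#' @param cfg A [train_config()].
#' @param stop_miou Optional early-stop threshold: training halts once the
#'   validation mIoU reaches this value (checked at the `eval_every`
#'   cadence).
#' @param verbose Log per-epoch lines to stderr.
#' @return Object of class `train_history`: data.frame with one row per
#'   epoch (`epoch`, `loss`, `val_miou`, `val_dice`, `val_f1`) plus
#'   attributes `best_epoch` and `steps`.
#' @export
train_model <- function(model, train_samples, val_samples = NULL,
                        cfg = train_config(), stop_miou = NULL,
                        verbose = FALSE) {
  if (length(train_samples) == 0L) stop("empty training set")
  set.seed(cfg$seed)
  opt <- adam_state(model$store)
  n <- length(train_samples)
  bs <- min(cfg$batch_size, n)
  best_miou <- -Inf
  best_epoch <- NA_integer_
  best_params <- NULL
  hist <- vector("list", cfg$epochs)
  steps <- 0L
  step_losses <- numeric(0)
  for (epoch in seq_len(cfg$epochs)) {
    idx <- sample(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = bs)) {
      batch <- train_samples[idx[start:min(start + bs - 1L, n)]]
      dat <- .stack_batch(batch)
      ad_zero_grad(model$store$params)
      logits <- model$forward(ad_const(dat$x), training = TRUE)
      loss <- ad_ce_dice_loss(logits, dat$y, cfg$w_ce, cfg$w_dice)
      ad_backward(loss)
      adam_step(model$store, opt, cfg$lr)
      ep_loss <- ep_loss + as.numeric(loss$value)
      nb <- nb + 1L
      steps <- steps + 1L
      step_losses[steps] <- as.numeric(loss$value)
    }
    ep_loss <- ep_loss / nb
    vm <- vd <- vf <- NA_real_
    if (!is.null(val_samples) && (epoch %% cfg$eval_every == 0L ||
                                  epoch == cfg$epochs)) {
      ev <- evaluate_model(model, val_samples)
      vm <- ev$miou; vd <- ev$mean_dice; vf <- ev$mean_f1
      if (!is.na(vm) && vm > best_miou) {
        best_miou <- vm
        best_epoch <- epoch
        best_params <- lapply(model$store$params, function(p) p$value)
      }
    }
    if (verbose)
      message(sprintf("epoch %d/%d loss %.4f val_miou %.4f",
                      epoch, cfg$epochs, ep_loss, vm))
    hist[[epoch]] <- data.frame(epoch = epoch, loss = ep_loss,
                                val_miou = vm, val_dice = vd, val_f1 = vf)
    if (!is.null(stop_miou) && !is.na(vm) && vm >= stop_miou) break
  }
  hist <- hist[!vapply(hist, is.null, logical(1))]
  if (!is.null(best_params))
    for (nm in names(best_params))
      model$store$params[[nm]]$value <- best_params[[nm]]
  out <- do.call(rbind, hist)
  attr(out, "best_epoch") <- best_epoch
  attr(out, "steps") <- steps
  attr(out, "step_losses") <- step_losses
  class(out) <- c("train_history", "data.frame")
  out
}

#' Desk-scale overfit harness
#'
#' Trains a small network (depth 3, base width 8, both attention modules)
#' on a handful of 64 x 64 synthetic images until it fits them
#' (training-set mIoU at least `target_miou`) or the optimizer step budget
#' is exhausted — a sanity check that the full architecture and optimizer
#' can fit the data they are given. Training-set mIoU is evaluated every
#' few epochs; the budget caps total optimizer steps.
#'
#' @param n_images Number of training images.
#' @param steps Optimizer step budget.
#' @param seed Integer seed.
#' @param lr Learning rate.
#' @param batch_size Batch size.
#' @param target_miou Early-stop threshold on training-set mIoU.
#' @return List with `miou`, `steps` (steps actually taken), `history`,
#'   `model`, `samples`.
#' @export
overfit_harness <- function(n_images = 8, steps = 300, seed = 1L,
                            lr = 0.003, batch_size = 4,
                            target_miou = 0.90) {
  samples <- desk_samples(n_images, seed = seed)
  model <- build_model(net_config(depth = 3, base_width = 8,
                                  input_size = 64),
                       seed = seed)
  batches_per_epoch <- ceiling(n_images / batch_size)
  epochs <- ceiling(steps / batches_per_epoch)
  cfg <- train_config(input_size = 64, batch_size = batch_size,
                      epochs = epochs, lr = lr, seed = seed,
                      eval_every = 10L)
  history <- train_model(model, samples, val_samples = samples, cfg = cfg,
                         stop_miou = target_miou)
  ev <- evaluate_model(model, samples)
  list(miou = ev$miou, steps = attr(history, "steps"), history = history,
       model = model, samples = samples)
}

#' Desk-scale synthetic samples
#'
#' Renders small (64 x 64) single-view carcass images with ground-truth
#' masks, one per carcass, for fast experiments and tests.
#'
#' @param n Number of images.
#' @param seed Integer seed.
#' @param canvas Canvas size.
#' @return List of `list(image, mask)` pairs.
#' @export
desk_samples <- function(n, seed = 1L, canvas = c(64, 64)) {
  set.seed(derive_seed(seed, 3))
  s_draw <- pmin(pmax(stats::rnorm(n, 1, 0.08), 0.8), 1.15)
  lapply(seq_len(n), function(i) {
    sp <- carcass_spec(carcass_id = sprintf("D%03d", i), s = s_draw[i],
                       torso_a = 13, torso_b = 8.5, head_r = 4.5,
                       leg_len = 15, leg_w = 4.2, views = "ventral",
                       sigma_pos = 0.5, sigma_tex = 8, px_per_cm = 2,
                       canvas = canvas)
    car <- generate_carcass(sp, seed = derive_seed(seed, 300 + i),
                            replicates = 1)
    car$ventral$replicates[[1]]
  })
}
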