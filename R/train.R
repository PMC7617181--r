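# Training: voxel-wise categorical cross-entropy, Adam, early stopping.

#' Softmax cross-entropy over voxels
#'
#' @param logits (n_classes, D, H, W) array.
#' @param labels (D, H, W) integer array with values 0..n_classes-1.
#' @param class_weights optional per-class weights (length n_classes);
#'   the loss is the weighted mean of voxel losses.
#' @return list with `loss` (scalar) and `grad` (same shape as logits).
#' @export
softmax_cross_entropy <- function(logits, labels, class_weights = NULL) {
  C <- dim(logits)[1]; N <- prod(dim(logits)[-1])
  L <- matrix(logits, C, N)
  y <- as.integer(labels) + 1L
  m <- apply(L, 2, max)
  Ls <- sweep(L, 2, m)
  lse <- log(colSums(exp(Ls)))
  P <- exp(sweep(Ls, 2, lse))
  pick <- cbind(y, seq_len(N))
  nll <- -(Ls[cbind(y, seq_len(N))] - lse)
  w <- if (is.null(class_weights)) rep(1, N) else class_weights[y]
  wsum <- sum(w)
  loss <- sum(w * nll) / wsum
  G <- sweep(P, 2, w / wsum, "*")
  G[pick] <- G[pick] - w / wsum
  if (is.na(loss) || !is.finite(loss)) stop("NaN/Inf loss")
  list(loss = loss, grad = array(G, dim = dim(logits)))
}

## ---- Adam -------------------------------------------------------------------

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, theta, grad, lr = 5e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mh <- state$m / (1 - beta1^state$t)
  vh <- state$v / (1 - beta2^state$t)
  list(state = state, theta = theta - lr * mh / (sqrt(vh) + eps))
}

## ---- early stopping ---------------------------------------------------------

#' Early-stopping bookkeeping
#'
#' `early_stop_update` consumes one validation loss per epoch; `stop` is
#' set once `patience` epochs have passed without improving on the best
#' loss.
#'
#' @param patience epochs to wait after the best validation epoch.
#' @return a state list; update with [early_stop_update()].
#' @export
early_stop_state <- function(patience) {
  list(patience = patience, best = Inf, best_epoch = 0L, epoch = 0L,
       stop = FALSE)
}

#' @rdname early_stop_state
#' @param state the current state.
#' @param loss this epoch's validation loss.
#' @return the updated state; `state$improved` flags a new best epoch.
#' @export
early_stop_update <- function(state, loss) {
  state$epoch <- state$epoch + 1L
  state$improved <- loss < state$best
  if (state$improved) {
    state$best <- loss
    state$best_epoch <- state$epoch
  }
  state$stop <- (state$epoch - state$best_epoch) >= state$patience
  state
}

## ---- patch sampling ---------------------------------------------------------

# random patch origin; with probability fg_prob the patch is centered on a
# random foreground voxel (small structures occupy a few percent of the
# volume, so unbiased patches would rarely carry gradient signal)
sample_patch <- function(image, labels, patch, fg_prob = 0.5) {
  sp <- dim(labels)
  if (is.null(patch) || all(patch >= sp)) {
    return(list(image = image, labels = labels))
  }
  patch <- rep(patch, length.out = 3)
  orig <- integer(3)
  if (stats::runif(1) < fg_prob && any(labels > 0)) {
    fg <- which(labels > 0)
    v <- fg[sample.int(length(fg), 1)]
    cen <- arrayInd(v, sp)
    for (a in 1:3)
      orig[a] <- min(max(cen[a] - patch[a] %/% 2, 1L), sp[a] - patch[a] + 1L)
  } else {
    for (a in 1:3) orig[a] <- sample.int(sp[a] - patch[a] + 1L, 1)
  }
  ix <- orig[1] + seq_len(patch[1]) - 1L
  iy <- orig[2] + seq_len(patch[2]) - 1L
  iz <- orig[3] + seq_len(patch[3]) - 1L
  list(image = image[, ix, iy, iz, drop = FALSE], labels = labels[ix, iy, iz])
}

balanced_class_weights <- function(train_set, n_classes, power = 0.5) {
  counts <- numeric(n_classes)
  for (ph in train_set)
    counts <- counts + tabulate(as.integer(ph$labels) + 1L, n_classes)
  w <- 1 / pmax(counts, 1)^power
  w * n_classes / sum(w)
}

## ---- training loop ----------------------------------------------------------

#' Train a U-Net on labeled volumes
#'
#' Minimizes voxel-wise categorical cross-entropy with Adam (learning rate
#' 5e-3 by default) and early stopping on the validation loss; the weights
#' of the best validation epoch are kept. Optional rotational data
#' augmentation (for baseline runs) rotates each training volume through a
#' uniform angle in a random anatomical plane with cubic (image) /
#' nearest (labels) interpolation before patch extraction.
#'
#' @param model a `unet_model`.
#' @param train_set,val_set lists of `list(image, labels)`.
#' @param epochs maximum epochs.
#' @param patience early-stopping patience in epochs (full-scale presets:
#'   25 and 150; scaled-down demos use less).
#' @param lr Adam learning rate.
#' @param patch_size training patch side (NULL: whole volumes); must be
#'   divisible by `2^levels`.
#' @param fg_prob fraction of patches centered on a foreground voxel.
#' @param augment_rot NULL, or a length-2 numeric range of rotation angles
#'   in degrees, e.g. `c(0, 360)`, applied in a random plane per sample.
#' @param class_weights `"none"`, `"balanced"` (inverse square-root
#'   frequency), `"inverse"` (inverse frequency; appropriate when
#'   structures occupy a small fraction of the volume), or a numeric
#'   vector of length n_classes.
#' @param val_crop side of the central crop used for validation loss
#'   (NULL: whole volumes).
#' @param seed master seed for all randomness of the run.
#' @param verbose print one line per epoch.
#' @return list with `model` (best weights), `history` (data.frame of
#'   epoch losses) and `best_epoch`.
#' @export
train_unet <- function(model, train_set, val_set, epochs = 50L,
                       patience = 25L, lr = 5e-3, patch_size = NULL,
                       fg_prob = 0.5, augment_rot = NULL,
                       class_weights = "none", val_crop = NULL,
                       seed = 1L, verbose = FALSE) {
  set.seed(seed)
  n_classes <- model$n_classes
  cw <- NULL
  if (is.numeric(class_weights)) cw <- class_weights
  else if (identical(class_weights, "balanced"))
    cw <- balanced_class_weights(train_set, n_classes)
  else if (identical(class_weights, "inverse"))
    cw <- balanced_class_weights(train_set, n_classes, power = 1)
  theta <- model_parameters(model)
  opt <- adam_init(length(theta))
  es <- early_stop_state(patience)
  best_theta <- theta
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  crop_center <- function(ph) {
    if (is.null(val_crop)) return(ph)
    sp <- dim(ph$labels)
    if (all(sp <= val_crop)) return(ph)
    o <- pmax((sp - val_crop) %/% 2, 0L)
    ix <- o[1] + seq_len(min(val_crop, sp[1]))
    iy <- o[2] + seq_len(min(val_crop, sp[2]))
    iz <- o[3] + seq_len(min(val_crop, sp[3]))
    list(image = ph$image[, ix, iy, iz, drop = FALSE],
         labels = ph$labels[ix, iy, iz])
  }
  val_cropped <- lapply(val_set, crop_center)
  for (epoch in seq_len(epochs)) {
    ord <- sample(length(train_set))
    tl <- 0
    for (i in ord) {
      ph <- train_set[[i]]
      if (!is.null(augment_rot)) {
        ang <- stats::runif(1, augment_rot[1], augment_rot[2])
        pl <- sample(c("axial", "coronal", "sagittal"), 1)
        R <- plane_rotation(ang, pl)
        ph <- list(image = rotate_volume(ph$image, R, "cubic"),
                   labels = array(as.integer(
                     rotate_volume(ph$labels, R, "nearest")),
                     dim = dim(ph$labels)))
      }
      pt <- sample_patch(ph$image, ph$labels, patch_size, fg_prob)
      model <- model_set_parameters(model, theta)
      fw <- unet_forward(model, pt$image, with_cache = TRUE)
      ce <- softmax_cross_entropy(fw$logits, pt$labels, cw)
      tl <- tl + ce$loss
      grads <- unet_backward(model, fw, ce$grad)
      g <- model_gradients(model, grads)
      st <- adam_step(opt, theta, g, lr = lr)
      opt <- st$state; theta <- st$theta
    }
    tl <- tl / length(train_set)
    model <- model_set_parameters(model, theta)
    vl <- mean(vapply(val_cropped, function(ph) {
      fw <- unet_forward(model, ph$image)
      softmax_cross_entropy(fw$logits, ph$labels, cw)$loss
    }, 0))
    history <- rbind(history, data.frame(epoch = epoch, train_loss = tl,
                                         val_loss = vl))
    es <- early_stop_update(es, vl)
    if (es$improved) best_theta <- theta
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f%s", epoch, tl, vl,
                      if (es$improved) " *" else ""))
    if (es$stop) break
  }
  list(model = model_set_parameters(model, best_theta), history = history,
       best_epoch = es$best_epoch)
}
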