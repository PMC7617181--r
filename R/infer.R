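# Patch-wise Gaussian-weighted inference and Dice evaluation.

gaussian_window <- function(patch, sigma) {
  g1 <- function(n) {
    c0 <- (n + 1) / 2
    exp(-((seq_len(n) - c0)^2) / (2 * sigma^2))
  }
  wx <- g1(patch[1]); wy <- g1(patch[2]); wz <- g1(patch[3])
  outer(outer(wx, wy), wz)
}

patch_origins <- function(n, patch, stride) {
  if (patch >= n) return(1L)
  o <- seq.int(1L, n - patch + 1L, by = stride)
  if (o[length(o)] != n - patch + 1L) o <- c(o, n - patch + 1L)
  o
}

#' Patch-wise prediction with overlapping patches and Gaussian weighting
#'
#' The volume is covered by overlapping patches; per-patch softmax
#' probabilities are blended with a centered Gaussian weight window and
#' normalized by the accumulated weights. Volumes smaller than the patch
#' in any axis are zero-padded symmetrically and the result cropped back.
#'
#' @param model a `unet_model`.
#' @param volume (C, D, H, W) or (D, H, W) array.
#' @param patch_size patch side (default: the whole volume, rounded up to
#'   divisibility by `2^levels`); must be divisible by `2^levels`.
#' @param stride patch stride (default `patch_size / 2`).
#' @param gaussian_sigma Gaussian window sigma (default `patch_size / 8`).
#' @return list with `labels` (D, H, W) integer array of argmax classes
#'   (0-based) and `probs` (n_classes, D, H, W).
#' @export
predict_patchwise <- function(model, volume, patch_size = NULL,
                              stride = NULL, gaussian_sigma = NULL) {
  if (length(dim(volume)) == 3) volume <- array(volume, dim = c(1, dim(volume)))
  sp <- dim(volume)[-1]
  div <- 2^model$config$levels
  if (is.null(patch_size)) patch_size <- min(ceiling(sp / div) * div)
  if (patch_size %% div != 0)
    stop("patch_size must be divisible by 2^levels = ", div)
  pad <- pmax(patch_size - sp, 0)
  lo <- pad %/% 2
  if (any(pad > 0)) {
    padded <- array(0, dim = c(dim(volume)[1], sp + pad))
    padded[, lo[1] + seq_len(sp[1]), lo[2] + seq_len(sp[2]),
           lo[3] + seq_len(sp[3])] <- volume
    volume <- padded
  }
  spp <- dim(volume)[-1]
  if (is.null(stride)) stride <- max(patch_size %/% 2, 1L)
  if (is.null(gaussian_sigma)) gaussian_sigma <- patch_size / 8
  win <- gaussian_window(rep(patch_size, 3), gaussian_sigma)
  nc <- model$n_classes
  acc <- array(0, dim = c(nc, spp))
  wacc <- array(0, dim = spp)
  ox <- patch_origins(spp[1], patch_size, stride)
  oy <- patch_origins(spp[2], patch_size, stride)
  oz <- patch_origins(spp[3], patch_size, stride)
  for (x0 in ox) for (y0 in oy) for (z0 in oz) {
    ix <- x0 + seq_len(patch_size) - 1L
    iy <- y0 + seq_len(patch_size) - 1L
    iz <- z0 + seq_len(patch_size) - 1L
    logits <- unet_forward(model, volume[, ix, iy, iz, drop = FALSE])$logits
    L <- matrix(logits, nc)
    Ls <- sweep(L, 2, apply(L, 2, max))
    P <- sweep(exp(Ls), 2, colSums(exp(Ls)), "/")
    acc[, ix, iy, iz] <- acc[, ix, iy, iz, drop = FALSE] +
      array(sweep(P, 2, as.vector(win), "*"), dim = c(nc, rep(patch_size, 3)))
    wacc[ix, iy, iz] <- wacc[ix, iy, iz] + win
  }
  probs <- sweep(acc, 2:4, wacc, "/")
  if (any(pad > 0)) {
    probs <- probs[, lo[1] + seq_len(sp[1]), lo[2] + seq_len(sp[2]),
                   lo[3] + seq_len(sp[3]), drop = FALSE]
  }
  lab <- array(max.col(t(matrix(probs, nc)), ties.method = "first") - 1L,
               dim = sp)
  list(labels = lab, probs = probs)
}

#' Dice similarity coefficient for one label
#'
#' `2|A intersect B| / (|A| + |B|)`, defined as 1 when both masks are
#' empty.
#'
#' @param pred_labels,ref_labels integer arrays of equal shape.
#' @param label the label value to score.
#' @return Dice in [0, 1].
#' @export
dice_score <- function(pred_labels, ref_labels, label) {
  if (!all(dim(pred_labels) == dim(ref_labels)))
    stop("shape mismatch between prediction and reference")
  a <- pred_labels == label
  b <- ref_labels == label
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Per-structure Dice table over a dataset
#'
#' @param model a trained `unet_model`.
#' @param dataset list of `list(image, labels)`.
#' @param structures label values to score (default: all nonzero labels of
#'   the first volume).
#' @param ... passed to [predict_patchwise()].
#' @return data.frame with columns `volume`, `structure`, `dice`.
#' @export
evaluate_model <- function(model, dataset, structures = NULL, ...) {
  if (length(dataset) == 0) stop("empty dataset")
  if (is.null(structures))
    structures <- sort(setdiff(unique(as.vector(dataset[[1]]$labels)), 0))
  rows <- list()
  for (v in seq_along(dataset)) {
    pred <- predict_patchwise(model, dataset[[v]]$image, ...)
    rows[[v]] <- data.frame(volume = v, structure = structures,
                            dice = vapply(structures, function(s)
                              dice_score(pred$labels, dataset[[v]]$labels, s),
                              0))
  }
  do.call(rbind, rows)
}
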