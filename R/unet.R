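#' U-Net architecture configuration
#'
#' Shared by the equivariant and the reference (plain) 3D U-Net. The
#' equivariant net carries a direct sum of irreps per level, starting from
#' `base_irreps` (default ratio 8:4:2 of orders 0:1:2, equivalent scalar
#' depth 30) with multiplicities doubling at every max-pooling and halving
#' at every upsampling. The reference net mirrors the layout with ordinary
#' convolutions of depth `ref_depth` at the top level, instance
#' normalization and leaky ReLU.
#'
#' @param base_irreps top-level feature irreps (default `"8x0+4x1+2x2"`).
#' @param levels number of pooling (and upsampling) operations, default 3.
#' @param kernel_size odd convolution kernel size, default 5.
#' @param n_radial radial basis functions per kernel, default 5.
#' @param l_max maximum harmonic order of kernel paths, default 4.
#' @param in_channels scalar input image channels, default 1.
#' @param n_classes output classes (scalar logit channels).
#' @param ref_depth top-level feature depth of the reference net,
#'   default 30.
#' @return a `unet_config` object.
#' @export
unet_config <- function(base_irreps = "8x0+4x1+2x2", levels = 3L,
                        kernel_size = 5L, n_radial = 5L, l_max = 4L,
                        in_channels = 1L, n_classes = 2L, ref_depth = 30L) {
  stopifnot(levels >= 1, kernel_size %% 2 == 1, n_radial >= 1,
            in_channels >= 1, n_classes >= 2)
  structure(list(base_irreps = format(irreps_canonical(irreps(base_irreps))),
                 levels = as.integer(levels),
                 kernel_size = as.integer(kernel_size),
                 n_radial = as.integer(n_radial), l_max = as.integer(l_max),
                 in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 ref_depth = as.integer(ref_depth)),
            class = "unet_config")
}

# multiply all multiplicities of an irreps by an integer factor
scale_irreps <- function(ir, factor) {
  e <- irreps(ir)$entries
  irreps(data.frame(mul = e$mul * factor, l = e$l))
}

#' Irreps (or feature depth) at each resolution of a U-Net
#' @param config a [unet_config()].
#' @return list of `irreps`, one per resolution 0..levels.
#' @export
unet_level_irreps <- function(config) {
  lapply(0:config$levels, function(d)
    scale_irreps(config$base_irreps, 2^d))
}

new_steerable_block <- function(ir_in, ir_out, config, gated = TRUE,
                               init = TRUE) {
  prof <- radial_profile(config$n_radial, kernel_r_max(config$kernel_size))
  if (gated) {
    spec <- gate_spec(ir_out)
    basis <- sample_kernel_basis(ir_in, spec$irreps_in, config$kernel_size,
                                 prof, config$l_max)
    conv <- layer_steerable_conv(basis)
    if (!init) conv <- zero_block_params(conv)
    list(conv = conv, inorm = layer_norm_inorm(spec$irreps_in),
         act = layer_gate(spec), ir_in = ir_in, ir_out = ir_out)
  } else {
    basis <- sample_kernel_basis(ir_in, ir_out, config$kernel_size,
                                 prof, config$l_max)
    conv <- layer_steerable_conv(basis)
    if (!init) conv <- zero_block_params(conv)
    list(conv = conv, inorm = NULL, act = NULL, ir_in = ir_in,
         ir_out = ir_out)
  }
}

new_reference_block <- function(c_in, c_out, config, act = TRUE,
                                init = TRUE) {
  conv <- layer_conv(c_in, c_out, config$kernel_size)
  if (!init) conv <- zero_block_params(conv)
  list(conv = conv,
       inorm = if (act) layer_inorm(c_out) else NULL,
       act = if (act) layer_lrelu() else NULL,
       ir_in = irreps(data.frame(mul = c_in, l = 0L)),
       ir_out = irreps(data.frame(mul = c_out, l = 0L)))
}

zero_block_params <- function(conv) {
  conv$params <- rapply(conv$params, function(v) if (is.numeric(v)) v * 0
                        else v, classes = "ANY", how = "replace")
  conv
}

#' Build the rotation-equivariant 3D U-Net
#'
#' Encoder: per level two (steerable conv -> norm instance norm -> gate)
#' blocks then norm max-pooling; decoder: trilinear upsampling, order-wise
#' skip concatenation and two blocks; a final steerable convolution emits
#' `n_classes` scalar logits. Every operation commutes exactly with the 24
#' octahedral grid rotations, so the whole network is end-to-end
#' equivariant.
#'
#' @param config a [unet_config()].
#' @param init draw random initial weights (set FALSE when loading).
#' @return a model object.
#' @export
build_equivariant_unet <- function(config, init = TRUE) {
  L <- config$levels
  lv <- unet_level_irreps(config)
  in_ir <- irreps(data.frame(mul = config$in_channels, l = 0L))
  blocks <- list(); ops <- list()
  add_block <- function(name, blk) blocks[[name]] <<- blk
  for (d in 0:(L - 1)) {
    ir_prev <- if (d == 0) in_ir else lv[[d]]
    add_block(sprintf("enc%d_a", d),
              new_steerable_block(ir_prev, lv[[d + 1]], config, init = init))
    add_block(sprintf("enc%d_b", d),
              new_steerable_block(lv[[d + 1]], lv[[d + 1]], config, init = init))
    ops <- c(ops, list(
      list(kind = "block", name = sprintf("enc%d_a", d)),
      list(kind = "block", name = sprintf("enc%d_b", d)),
      list(kind = "push_skip", id = d),
      list(kind = "pool", irreps = lv[[d + 1]])))
  }
  add_block("bot_a", new_steerable_block(lv[[L]], lv[[L + 1]], config,
                                         init = init))
  add_block("bot_b", new_steerable_block(lv[[L + 1]], lv[[L + 1]], config,
                                         init = init))
  ops <- c(ops, list(list(kind = "block", name = "bot_a"),
                     list(kind = "block", name = "bot_b")))
  for (d in (L - 1):0) {
    ir_up <- lv[[d + 2]]
    ir_skip <- lv[[d + 1]]
    ir_cat <- irreps_canonical(irreps_concat(ir_up, ir_skip))
    add_block(sprintf("dec%d_a", d),
              new_steerable_block(ir_cat, lv[[d + 1]], config, init = init))
    add_block(sprintf("dec%d_b", d),
              new_steerable_block(lv[[d + 1]], lv[[d + 1]], config, init = init))
    ops <- c(ops, list(
      list(kind = "up"),
      list(kind = "concat", id = d, ir_a = ir_up, ir_b = ir_skip),
      list(kind = "block", name = sprintf("dec%d_a", d)),
      list(kind = "block", name = sprintf("dec%d_b", d))))
  }
  out_ir <- irreps(data.frame(mul = config$n_classes, l = 0L))
  add_block("final", new_steerable_block(lv[[1]], out_ir, config,
                                         gated = FALSE, init = init))
  ops <- c(ops, list(list(kind = "block", name = "final")))
  structure(list(kind = "equivariant", config = config, blocks = blocks,
                 ops = ops, in_channels = config$in_channels,
                 n_classes = config$n_classes),
            class = "unet_model")
}

#' Build the non-equivariant reference 3D U-Net
#'
#' Standard 3D U-Net mirror of the equivariant architecture: two
#' (convolution -> instance norm -> leaky ReLU) blocks per level, ordinary
#' max-pooling down, trilinear upsampling and skip concatenation up;
#' features double/halve with resolution, `ref_depth` at the top.
#'
#' @inheritParams build_equivariant_unet
#' @return a model object.
#' @export
build_reference_unet <- function(config, init = TRUE) {
  L <- config$levels
  depth <- config$ref_depth * 2^(0:L)
  blocks <- list(); ops <- list()
  add_block <- function(name, blk) blocks[[name]] <<- blk
  for (d in 0:(L - 1)) {
    c_prev <- if (d == 0) config$in_channels else depth[d]
    add_block(sprintf("enc%d_a", d),
              new_reference_block(c_prev, depth[d + 1], config, init = init))
    add_block(sprintf("enc%d_b", d),
              new_reference_block(depth[d + 1], depth[d + 1], config,
                                  init = init))
    ops <- c(ops, list(
      list(kind = "block", name = sprintf("enc%d_a", d)),
      list(kind = "block", name = sprintf("enc%d_b", d)),
      list(kind = "push_skip", id = d),
      list(kind = "pool", irreps = irreps(data.frame(mul = depth[d + 1],
                                                     l = 0L)))))
  }
  add_block("bot_a", new_reference_block(depth[L], depth[L + 1], config,
                                         init = init))
  add_block("bot_b", new_reference_block(depth[L + 1], depth[L + 1], config,
                                         init = init))
  ops <- c(ops, list(list(kind = "block", name = "bot_a"),
                     list(kind = "block", name = "bot_b")))
  for (d in (L - 1):0) {
    c_cat <- depth[d + 2] + depth[d + 1]
    add_block(sprintf("dec%d_a", d),
              new_reference_block(c_cat, depth[d + 1], config, init = init))
    add_block(sprintf("dec%d_b", d),
              new_reference_block(depth[d + 1], depth[d + 1], config,
                                  init = init))
    ops <- c(ops, list(
      list(kind = "up"),
      list(kind = "concat", id = d,
           ir_a = irreps(data.frame(mul = depth[d + 2], l = 0L)),
           ir_b = irreps(data.frame(mul = depth[d + 1], l = 0L))),
      list(kind = "block", name = sprintf("dec%d_a", d)),
      list(kind = "block", name = sprintf("dec%d_b", d))))
  }
  add_block("final", new_reference_block(depth[1], config$n_classes, config,
                                         act = FALSE, init = init))
  ops <- c(ops, list(list(kind = "block", name = "final")))
  structure(list(kind = "reference", config = config, blocks = blocks,
                 ops = ops, in_channels = config$in_channels,
                 n_classes = config$n_classes),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat("<unet_model> ", x$kind, ", levels ", x$config$levels,
      ", kernel ", x$config$kernel_size, "^3, ",
      model_parameter_count(x), " trainable parameters\n", sep = "")
  invisible(x)
}

block_forward <- function(blk, x) {
  r <- layer_forward(blk$conv, x); h <- r$out
  cache <- list(conv = r$cache)
  if (!is.null(blk$inorm)) {
    r <- layer_forward(blk$inorm, h); h <- r$out
    cache$inorm <- r$cache
  }
  if (!is.null(blk$act)) {
    r <- layer_forward(blk$act, h); h <- r$out
    cache$act <- r$cache
  }
  list(out = h, cache = cache)
}

block_backward <- function(blk, cache, gy) {
  if (!is.null(blk$act)) gy <- layer_backward(blk$act, cache$act, gy)$dx
  if (!is.null(blk$inorm)) gy <- layer_backward(blk$inorm, cache$inorm, gy)$dx
  r <- layer_backward(blk$conv, cache$conv, gy)
  list(dx = r$dx, grads = r$grads)
}

#' Forward pass of a U-Net model
#'
#' @param model a built model.
#' @param x input array (in_channels, D, H, W), spatial dims divisible by
#'   `2^levels`; a 3D array is promoted to one channel.
#' @param with_cache keep intermediate activations for a backward pass.
#' @return list with `logits` (n_classes, D, H, W) and (optionally)
#'   `cache`.
#' @export
unet_forward <- function(model, x, with_cache = FALSE) {
  if (length(dim(x)) == 3) x <- array(x, dim = c(1, dim(x)))
  sp <- dim(x)[-1]
  if (any(sp %% 2^model$config$levels != 0))
    stop("spatial dims must be divisible by 2^levels = ",
         2^model$config$levels)
  if (dim(x)[1] != model$in_channels)
    stop("expected ", model$in_channels, " input channels")
  h <- x; skips <- list(); caches <- vector("list", length(model$ops))
  for (k in seq_along(model$ops)) {
    op <- model$ops[[k]]
    if (op$kind == "block") {
      r <- block_forward(model$blocks[[op$name]], h)
      h <- r$out; if (with_cache) caches[[k]] <- r$cache
    } else if (op$kind == "push_skip") {
      skips[[as.character(op$id)]] <- h
    } else if (op$kind == "pool") {
      r <- norm_maxpool_forward(layer_norm_maxpool(op$irreps, 2L), h)
      h <- r$out; if (with_cache) caches[[k]] <- r$cache
    } else if (op$kind == "up") {
      r <- upsample_forward(layer_upsample(2L), h)
      h <- r$out
    } else if (op$kind == "concat") {
      s <- skips[[as.character(op$id)]]
      h <- concat_irrep_fields(irrep_field(op$ir_a, h),
                               irrep_field(op$ir_b, s))$values
    }
  }
  out <- list(logits = h)
  if (with_cache) out$cache <- caches
  out
}

#' Backward pass: gradients of all trainable parameters
#' @param model a model; `fw` the result of `unet_forward(..., with_cache
#'   = TRUE)`; `dlogits` gradient of the loss wrt the logits.
#' @return named list of per-block parameter gradients.
#' @keywords internal
#' @export
unet_backward <- function(model, fw, dlogits) {
  grads <- list()
  g <- dlogits
  skip_grads <- list()
  for (k in rev(seq_along(model$ops))) {
    op <- model$ops[[k]]
    if (op$kind == "block") {
      r <- block_backward(model$blocks[[op$name]], fw$cache[[k]], g)
      grads[[op$name]] <- r$grads
      g <- r$dx
    } else if (op$kind == "push_skip") {
      sg <- skip_grads[[as.character(op$id)]]
      if (!is.null(sg)) g <- g + sg
    } else if (op$kind == "pool") {
      lay <- layer_norm_maxpool(op$irreps, 2L)
      g <- norm_maxpool_backward(lay, fw$cache[[k]], g)$dx
    } else if (op$kind == "up") {
      g <- upsample_backward(layer_upsample(2L), NULL, g)$dx
    } else if (op$kind == "concat") {
      parts <- split_concat_grad(g, op$ir_a, op$ir_b)
      g <- parts$a
      skip_grads[[as.character(op$id)]] <- parts$b
    }
  }
  grads
}

## ---- parameter (un)flattening ---------------------------------------------

flatten_numeric_list <- function(x) {
  if (is.numeric(x)) return(as.vector(x))
  if (is.list(x)) return(unlist(lapply(x, flatten_numeric_list),
                                use.names = FALSE))
  numeric(0)
}

unflatten_numeric_list <- function(template, v, at = 1L) {
  if (is.numeric(template)) {
    n <- length(template)
    template[] <- v[at:(at + n - 1L)]
    return(list(value = template, at = at + n))
  }
  if (is.list(template)) {
    for (i in seq_along(template)) {
      r <- unflatten_numeric_list(template[[i]], v, at)
      template[[i]] <- r$value; at <- r$at
    }
    return(list(value = template, at = at))
  }
  list(value = template, at = at)
}

#' Flatten all trainable parameters of a model into one vector
#' @param model a `unet_model`.
#' @return numeric vector.
#' @export
model_parameters <- function(model) {
  flatten_numeric_list(lapply(model$blocks, function(b) b$conv$params))
}

#' Write a flat parameter vector back into a model
#' @param model a `unet_model`; `v` vector from [model_parameters()].
#' @return the updated model.
#' @export
model_set_parameters <- function(model, v) {
  tmpl <- lapply(model$blocks, function(b) b$conv$params)
  r <- unflatten_numeric_list(tmpl, v)
  if (r$at != length(v) + 1L) stop("parameter vector length mismatch")
  for (nm in names(model$blocks))
    model$blocks[[nm]]$conv$params <- r$value[[nm]]
  model
}

model_gradients <- function(model, grads) {
  flatten_numeric_list(lapply(names(model$blocks), function(nm) grads[[nm]]))
}

#' Number of trainable parameters of a model
#' @param model a `unet_model`.
#' @return integer count of trainable scalars.
#' @export
model_parameter_count <- function(model) length(model_parameters(model))

## ---- save / load -----------------------------------------------------------

#' Save a model as a JSON descriptor plus a raw weight archive
#'
#' Writes `<path>/model.json` (kind + configuration + parameter count)
#' and `<path>/weights.bin` (doubles, native endianness); the round trip
#' through [load_model()] is exact.
#'
#' @param model a `unet_model`; `path` a directory (created).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  v <- model_parameters(model)
  desc <- list(kind = model$kind, config = unclass(model$config),
               n_parameters = length(v), format = "steerable3d-model-v1")
  jsonlite::write_json(desc, file.path(path, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(path, "weights.bin"), "wb")
  writeBin(v, con, size = 8)
  close(con)
  invisible(path)
}

#' Load a model saved by [save_model()]
#' @param path the saved directory.
#' @return the reconstructed `unet_model`.
#' @export
load_model <- function(path) {
  desc <- jsonlite::read_json(file.path(path, "model.json"),
                              simplifyVector = TRUE)
  cfg <- do.call(unet_config, as.list(desc$config))
  model <- if (desc$kind == "equivariant")
    build_equivariant_unet(cfg, init = FALSE)
  else build_reference_unet(cfg, init = FALSE)
  con <- file(file.path(path, "weights.bin"), "rb")
  v <- readBin(con, "double", n = desc$n_parameters, size = 8)
  close(con)
  model_set_parameters(model, v)
}
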