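#' Irrep-valued voxel fields
#'
#' An `irrep_field` carries, at each voxel of a 3D grid, a feature vector
#' laid out as a direct sum of irreps. Values are stored channels-first as
#' an array of dim (feature_dim, D, H, W); within each irreps entry the
#' rows are channel-major with components m = -l..l fastest (see
#' [irreps()]).
#'
#' @param ir the feature type ([irreps()] or string).
#' @param values numeric array (feature_dim, D, H, W); a (D, H, W) array
#'   is promoted to a single scalar channel.
#' @param spacing voxel spacing, informational only.
#' @return an object of class `irrep_field`.
#' @export
irrep_field <- function(ir, values, spacing = c(1, 1, 1)) {
  ir <- irreps(ir)
  if (length(dim(values)) == 3) values <- array(values, dim = c(1, dim(values)))
  stopifnot(length(dim(values)) == 4)
  if (dim(values)[1] != irreps_dim(ir))
    stop("feature dimension ", dim(values)[1], " does not match irreps dim ",
         irreps_dim(ir))
  structure(list(irreps = ir, values = values, spacing = spacing),
            class = "irrep_field")
}

#' @export
print.irrep_field <- function(x, ...) {
  cat("<irrep_field> ", format(x$irreps), " on ",
      paste(dim(x$values)[-1], collapse = "x"), " grid\n", sep = "")
  invisible(x)
}

#' Random irrep field (standard normal entries), for tests and checks
#' @param ir feature type.
#' @param shape length-3 spatial dims.
#' @return an `irrep_field`.
#' @export
random_irrep_field <- function(ir, shape) {
  ir <- irreps(ir)
  irrep_field(ir, array(stats::rnorm(irreps_dim(ir) * prod(shape)),
                        dim = c(irreps_dim(ir), shape)))
}

#' Concatenate two irrep fields order-wise (skip-connection merge)
#'
#' Channels of equal order are made contiguous: for each order l present,
#' the channels of `a` come first, then those of `b`. Both inputs must be
#' in canonical grouped form and share spatial dims.
#'
#' @param a,b `irrep_field`s.
#' @return the merged `irrep_field` with canonical irreps.
#' @export
concat_irrep_fields <- function(a, b) {
  stopifnot(all(dim(a$values)[-1] == dim(b$values)[-1]))
  ls <- sort(unique(c(irreps_orders(a$irreps), irreps_orders(b$irreps))))
  sa <- irreps_slices(a$irreps); sb <- irreps_slices(b$irreps)
  ea <- a$irreps$entries; eb <- b$irreps$entries
  blocks <- list(); mul <- integer(0)
  for (l in ls) {
    m <- 0L
    ia <- which(ea$l == l)
    if (length(ia) == 1) {
      blocks[[length(blocks) + 1L]] <- a$values[sa[[ia]], , , , drop = FALSE]
      m <- m + ea$mul[ia]
    }
    ib <- which(eb$l == l)
    if (length(ib) == 1) {
      blocks[[length(blocks) + 1L]] <- b$values[sb[[ib]], , , , drop = FALSE]
      m <- m + eb$mul[ib]
    }
    mul <- c(mul, m)
  }
  vals <- do.call(function(...) abind4(...), blocks)
  irrep_field(irreps(cbind(mul, ls)), vals)
}

# bind 4D arrays along the first margin
abind4 <- function(...) {
  xs <- list(...)
  sp <- dim(xs[[1]])[-1]
  tot <- sum(vapply(xs, function(x) dim(x)[1], 0L))
  out <- array(0, dim = c(tot, sp))
  at <- 0L
  for (x in xs) {
    out[at + seq_len(dim(x)[1]), , , ] <- x
    at <- at + dim(x)[1]
  }
  out
}

# split a concatenated field back into the two originals' gradients
split_concat_grad <- function(g, ir_a, ir_b) {
  ea <- irreps(ir_a)$entries; eb <- irreps(ir_b)$entries
  ls <- sort(unique(c(ea$l, eb$l)))
  da <- irreps_dim(ir_a); db <- irreps_dim(ir_b)
  sp <- dim(g)[-1]
  ga <- array(0, dim = c(da, sp)); gb <- array(0, dim = c(db, sp))
  sa <- irreps_slices(irreps(ir_a)); sb <- irreps_slices(irreps(ir_b))
  at <- 0L
  for (l in ls) {
    ia <- which(ea$l == l)
    if (length(ia) == 1) {
      n <- length(sa[[ia]])
      ga[sa[[ia]], , , ] <- g[at + seq_len(n), , , , drop = FALSE]
      at <- at + n
    }
    ib <- which(eb$l == l)
    if (length(ib) == 1) {
      n <- length(sb[[ib]])
      gb[sb[[ib]], , , ] <- g[at + seq_len(n), , , , drop = FALSE]
      at <- at + n
    }
  }
  list(a = ga, b = gb)
}
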