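#' Direct sums of SO(3) irreducible representations
#'
#' An `irreps` object is an ordered multiset of `(multiplicity, order)`
#' pairs describing the feature type of an equivariant field: order-l
#' features have dimension 2l+1 (l = 0 scalars, l = 1 vectors, l = 2
#' rank-2 traceless symmetric tensors). The canonical text form is
#' `"8x0+4x1+2x2"`; a trailing parity suffix (`"8x0e"`) is accepted and
#' recorded but not acted on, since only SO(3) (no inversion) is handled.
#'
#' Component ordering convention, used consistently by spherical
#' harmonics, Wigner blocks and Clebsch-Gordan blocks throughout the
#' package: within each order-l block the 2l+1 real components are
#' ordered m = -l, ..., l, and within an entry of multiplicity m the
#' feature rows are channel-major (all components of channel 1, then
#' channel 2, ...).
#'
#' @param x for `irreps()`: a specification string such as `"8x0+4x1+2x2"`,
#'   or a two-column matrix / data.frame of (multiplicity, order), or an
#'   existing `irreps` object.
#' @return an object of class `irreps`.
#' @examples
#' ir <- irreps("8x0+4x1+2x2")
#' irreps_dim(ir)   # 30
#' @export
irreps <- function(x) {
  if (inherits(x, "irreps")) return(x)
  if (is.character(x)) {
    stopifnot(length(x) == 1)
    x <- trimws(x)
    if (identical(x, "") || identical(x, "0")) {
      tab <- data.frame(mul = integer(0), l = integer(0), parity = character(0))
    } else {
      parts <- strsplit(x, "+", fixed = TRUE)[[1]]
      m <- regmatches(parts, regexec("^\\s*([0-9]+)x([0-9]+)([eo]?)\\s*$", parts))
      bad <- vapply(m, length, 1L) != 4L
      if (any(bad)) stop("cannot parse irreps string near: ", parts[bad][1])
      tab <- data.frame(
        mul = as.integer(vapply(m, `[`, "", 2L)),
        l = as.integer(vapply(m, `[`, "", 3L)),
        parity = vapply(m, `[`, "", 4L)
      )
    }
  } else {
    tab <- as.data.frame(x)
    if (ncol(tab) == 2) tab$parity <- ""
    names(tab) <- c("mul", "l", "parity")
    tab$mul <- as.integer(tab$mul)
    tab$l <- as.integer(tab$l)
  }
  if (nrow(tab) > 0 && (any(tab$mul <= 0) || any(tab$l < 0) ||
                        any(is.na(tab$mul)) || any(is.na(tab$l))))
    stop("invalid irreps: multiplicities must be > 0 and orders >= 0")
  structure(list(entries = tab), class = "irreps")
}

#' @export
format.irreps <- function(x, ...) {
  tab <- x$entries
  if (nrow(tab) == 0) return("")
  paste(sprintf("%dx%d%s", tab$mul, tab$l, tab$parity), collapse = "+")
}

#' @export
print.irreps <- function(x, ...) {
  cat("<irreps> ", format(x), "  (dim ", irreps_dim(x), ")\n", sep = "")
  invisible(x)
}

#' Total feature dimension of an irreps object
#'
#' @param ir an [irreps()] object (or anything coercible).
#' @return `sum(mul * (2l + 1))`, an integer.
#' @export
irreps_dim <- function(ir) {
  ir <- irreps(ir)
  tab <- ir$entries
  if (nrow(tab) == 0) return(0L)
  as.integer(sum(tab$mul * (2L * tab$l + 1L)))
}

#' Concatenate two irreps (direct sum, order preserved)
#' @param a,b irreps objects.
#' @return the concatenated `irreps`.
#' @export
irreps_concat <- function(a, b) {
  a <- irreps(a); b <- irreps(b)
  irreps(rbind(a$entries, b$entries))
}

# memoization for the slice/channel tables, keyed by the canonical text
# form (these sit in the hot path of every layer)
.irreps_cache <- new.env(parent = emptyenv())

#' Per-entry feature-row index ranges
#'
#' @param ir an irreps object.
#' @return a list, one integer vector of row indices per entry.
#' @keywords internal
#' @export
irreps_slices <- function(ir) {
  ir <- irreps(ir)
  key <- paste0("sl_", format(ir))
  if (!is.null(.irreps_cache[[key]])) return(.irreps_cache[[key]])
  tab <- ir$entries
  out <- vector("list", nrow(tab))
  at <- 0L
  for (e in seq_len(nrow(tab))) {
    n <- tab$mul[e] * (2L * tab$l[e] + 1L)
    out[[e]] <- at + seq_len(n)
    at <- at + n
  }
  .irreps_cache[[key]] <- out
  out
}

#' Expand an irreps object to a per-channel table
#'
#' Each channel is one copy of an irrep; the table gives, per channel,
#' its order, dimension and the feature rows it occupies.
#'
#' @param ir an irreps object.
#' @return data.frame with columns `chan`, `entry`, `l`, `d`, `start`
#'   (first feature row, 1-based).
#' @keywords internal
#' @export
irreps_channels <- function(ir) {
  ir <- irreps(ir)
  key <- paste0("ch_", format(ir))
  if (!is.null(.irreps_cache[[key]])) return(.irreps_cache[[key]])
  tab <- ir$entries
  rows <- list(); at <- 0L; ch <- 0L
  for (e in seq_len(nrow(tab))) {
    d <- 2L * tab$l[e] + 1L
    for (k in seq_len(tab$mul[e])) {
      ch <- ch + 1L
      rows[[ch]] <- data.frame(chan = ch, entry = e, l = tab$l[e], d = d,
                               start = at + 1L)
      at <- at + d
    }
  }
  out <- if (ch == 0L) data.frame(chan = integer(0), entry = integer(0),
                                  l = integer(0), d = integer(0),
                                  start = integer(0))
         else do.call(rbind, rows)
  .irreps_cache[[key]] <- out
  out
}

#' Canonical grouped form: ascending order, one entry per order
#' @param ir an irreps object.
#' @return an `irreps` with merged multiplicities, sorted by order.
#' @export
irreps_canonical <- function(ir) {
  ir <- irreps(ir)
  tab <- ir$entries
  if (nrow(tab) == 0) return(ir)
  agg <- stats::aggregate(mul ~ l, data = tab, FUN = sum)
  agg <- agg[order(agg$l), c("mul", "l")]
  irreps(agg)
}

#' Multiplicity of a given order in an irreps object
#' @keywords internal
#' @export
irreps_mul_of <- function(ir, l) {
  tab <- irreps(ir)$entries
  as.integer(sum(tab$mul[tab$l == l]))
}

irreps_orders <- function(ir) sort(unique(irreps(ir)$entries$l))
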