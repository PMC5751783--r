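#' Binning configuration for the 3D-SDAR fingerprint space
#'
#' Defines the tessellation of the (shift, shift, distance) space. The
#' default carbon window is -4..+204 PPM (width 208, midpoint 100) and the
#' default nitrogen window -356..-11 PPM (width 345, midpoint -183.5),
#' following the shielding ranges observed for drug-like molecules with the
#' negative-PPM convention for \eqn{^{15}}N. The nitrogen bin width is tied
#' to the carbon bin width by the carbon:nitrogen ratio (default 2.5). Atom
#' pairs are classed CC, CN or NN and each class occupies a disjoint block
#' of bin ids, since the two shift axes have element-specific windows.
#'
#' @param c_window Carbon shift window `c(lo, hi)` in PPM.
#' @param n_window Nitrogen shift window `c(lo, hi)` in PPM.
#' @param w_c Carbon bin width in PPM. The default 8 divides the 208-PPM
#'   carbon window into exactly 26 bins.
#' @param cn_ratio Carbon:nitrogen bin-width ratio; `w_n = cn_ratio * w_c`
#'   (default 2.5, giving 20-PPM nitrogen bins, 18 per axis with the last
#'   truncated at -11 PPM).
#' @param d_window Distance window `c(lo, hi)` in Angstrom.
#' @param w_d Distance bin width in Angstrom.
#' @param occupancy `"count"` (number of atom pairs per bin) or `"binary"`.
#' @param scaling Column scaling for the feature matrix: `"zscore"`,
#'   `"minmax"` or `"none"`.
#' @return An object of class `sdar_binning`.
#' @export
binning_config <- function(c_window = c(-4, 204), n_window = c(-356, -11),
                           w_c = 8, cn_ratio = 2.5,
                           d_window = c(1, 20), w_d = 1,
                           occupancy = c("count", "binary"),
                           scaling = c("zscore", "minmax", "none")) {
  occupancy <- match.arg(occupancy)
  scaling <- match.arg(scaling)
  stopifnot(w_c > 0, cn_ratio > 0, w_d > 0,
            c_window[2] > c_window[1], n_window[2] > n_window[1],
            d_window[2] > d_window[1])
  w_n <- cn_ratio * w_c
  cfg <- list(
    c_window = as.numeric(c_window), n_window = as.numeric(n_window),
    w_c = w_c, w_n = w_n, cn_ratio = cn_ratio,
    d_window = as.numeric(d_window), w_d = w_d,
    occupancy = occupancy, scaling = scaling,
    n_bins_c = as.integer(ceiling(diff(range(c_window)) / w_c)),
    n_bins_n = as.integer(ceiling(diff(range(n_window)) / w_n)),
    n_bins_d = as.integer(ceiling(diff(range(d_window)) / w_d)))
  cfg$block_sizes <- c(
    CC = cfg$n_bins_c * cfg$n_bins_c * cfg$n_bins_d,
    CN = cfg$n_bins_c * cfg$n_bins_n * cfg$n_bins_d,
    NN = cfg$n_bins_n * cfg$n_bins_n * cfg$n_bins_d)
  cfg$block_offsets <- c(CC = 0L, CN = cfg$block_sizes[["CC"]],
                         NN = cfg$block_sizes[["CC"]] + cfg$block_sizes[["CN"]])
  structure(cfg, class = "sdar_binning")
}

#' @export
print.sdar_binning <- function(x, ...) {
  cat(sprintf(
    "<sdar_binning> C %g..%g PPM / %g PPM (%d bins); N %g..%g PPM / %g PPM (%d bins); d %g..%g A / %g A (%d bins)\n  occupancy=%s scaling=%s; %d total bins (CC|CN|NN blocks)\n",
    x$c_window[1], x$c_window[2], x$w_c, x$n_bins_c,
    x$n_window[1], x$n_window[2], x$w_n, x$n_bins_n,
    x$d_window[1], x$d_window[2], x$w_d, x$n_bins_d,
    x$occupancy, x$scaling, sum(x$block_sizes)))
  invisible(x)
}

#' Map a value onto a bin index along one axis
#'
#' Left-closed, right-open bins: index `k` (1-based) covers
#' `[lo + (k-1)*width, lo + k*width)`; a value exactly at the upper window
#' edge maps to the last bin, and values outside the window return
#' `NA_integer_` (out-of-window).
#'
#' @param value Shift (PPM) or distance (Angstrom).
#' @param window `c(lo, hi)`.
#' @param width Bin width (> 0).
#' @return Integer bin index, or `NA_integer_` when out of window.
#'   Vectorized over `value`.
#' @export
bin_axis_index <- function(value, window, width) {
  if (any(!is.finite(value))) {
    sdar_error("bin_axis_index: non-finite value", "sdar_domain_error")
  }
  stopifnot(width > 0)
  n_bins <- as.integer(ceiling(diff(range(window)) / width))
  k <- as.integer(floor((value - window[1]) / width)) + 1L
  k[value == window[2]] <- n_bins
  k[value < window[1] | value > window[2]] <- NA_integer_
  k
}

axis_for <- function(cfg, element) {
  if (element == "C") list(window = cfg$c_window, width = cfg$w_c,
                           n = cfg$n_bins_c)
  else list(window = cfg$n_window, width = cfg$w_n, n = cfg$n_bins_n)
}

#' Encode / decode 3D-SDAR bin ids
#'
#' A bin id identifies one box of the tessellation: the pair class (CC, CN
#' or NN), the two shift-axis bin indices and the distance bin index. Ids
#' are 1-based and the class blocks are disjoint (CC first, then CN, then
#' NN). For CC and NN pairs axis 1 holds the smaller shift; for CN pairs
#' axis 1 is always the carbon.
#'
#' @param class Pair class, one of `"CC"`, `"CN"`, `"NN"`.
#' @param i1,i2 Axis bin indices (1-based).
#' @param k Distance bin index (1-based).
#' @param cfg An [binning_config()] object.
#' @return `encode_bin`: integer bin id. `decode_bin`: a list with the
#'   class, axis indices and the PPM / Angstrom intervals of the box.
#' @export
encode_bin <- function(class, i1, i2, k, cfg) {
  dim2 <- switch(class, CC = cfg$n_bins_c, CN = cfg$n_bins_n,
                 NN = cfg$n_bins_n)
  as.integer(cfg$block_offsets[[class]] +
             ((i1 - 1L) * dim2 + (i2 - 1L)) * cfg$n_bins_d + k)
}

#' @rdname encode_bin
#' @param bin_id Integer bin id to decode.
#' @export
decode_bin <- function(bin_id, cfg) {
  off <- cfg$block_offsets
  class <- if (bin_id <= off[["CN"]]) "CC"
           else if (bin_id <= off[["NN"]]) "CN" else "NN"
  rel <- bin_id - off[[class]] - 1L
  dim2 <- switch(class, CC = cfg$n_bins_c, CN = cfg$n_bins_n,
                 NN = cfg$n_bins_n)
  k <- rel %% cfg$n_bins_d + 1L
  rest <- rel %/% cfg$n_bins_d
  i2 <- rest %% dim2 + 1L
  i1 <- rest %/% dim2 + 1L
  ax1 <- axis_for(cfg, substr(class, 1, 1))
  ax2 <- axis_for(cfg, substr(class, 2, 2))
  list(bin_id = as.integer(bin_id), class = class,
       i1 = i1, i2 = i2, k = k,
       axis1_interval = axis_interval(i1, ax1$window, ax1$width),
       axis2_interval = axis_interval(i2, ax2$window, ax2$width),
       d_interval = axis_interval(k, cfg$d_window, cfg$w_d))
}

axis_interval <- function(i, window, width) {
  c(window[1] + (i - 1) * width, min(window[1] + i * width, window[2]))
}
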