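#' Convolutional layer output size
#'
#' Spatial output side of a convolution with input side `I`, filter side
#' `F`, padding `P` and stride `S`:
#' `floor((I - F + 2 P) / S) + 1`.  Fractional values are floored.
#'
#' @param I input side (pixels).
#' @param F filter side (pixels).
#' @param P zero-padding (pixels, >= 0).
#' @param S stride (>= 1).
#' @return Integer output side.
#' @examples
#' conv_output_size(28, 3, 1, 1)  # 28
#' @export
conv_output_size <- function(I, F, P = 0L, S = 1L) {
  stopifnot(S >= 1, P >= 0, F >= 1, I >= 1)
  out <- (I - F + 2 * P) %/% S + 1L
  if (out <= 0) {
    stop("convolution yields non-positive output size (I=", I, ", F=", F,
         ", P=", P, ", S=", S, ")")
  }
  as.integer(out)
}

#' Pooling layer output size
#'
#' Same arithmetic as [conv_output_size()] with the pool window in place
#' of the filter.  Flooring matters on odd inputs: a 2x2/stride-2 pool
#' maps 28 -> 14 -> 7 -> 3 -> 1 over the default network's four pooling
#' layers.
#'
#' @param I input side (pixels).
#' @param pool pool window side (pixels).
#' @param P padding (pixels, >= 0).
#' @param S stride (>= 1).
#' @return Integer output side.
#' @examples
#' pool_output_size(7, 2, 0, 2)  # 3
#' @export
pool_output_size <- function(I, pool, P = 0L, S = 2L) {
  conv_output_size(I, pool, P, S)
}

#' Parameter count of a convolutional layer
#'
#' `(h * w * c + 1) * n` weights: one `h x w x c` filter plus a bias, for
#' each of the `n` filters.
#'
#' @param h,w filter height and width (pixels).
#' @param c input channels.
#' @param n number of filters.
#' @return Integer parameter count.
#' @examples
#' conv_param_count(3, 3, 1, 16)  # 160
#' @export
conv_param_count <- function(h, w, c, n) {
  stopifnot(h >= 1, w >= 1, c >= 1, n >= 1)
  as.integer((h * w * c + 1) * n)
}
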