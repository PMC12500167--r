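#' Build MADE-style autoregressive masks
#'
#' Constructs the binary masks that turn a one-hidden-layer perceptron into an
#' autoregressive conditioner: under the feature ordering given by `ordering`,
#' the conditioner outputs for feature `i` (its location and log-scale) may
#' depend only on features that precede `i`. The first feature in the ordering
#' receives constant outputs.
#'
#' Hidden units are assigned degrees cycling through `1 .. d-1`; an
#' input-to-hidden connection `j -> k` is kept when `degree(k) >= degree(j)`,
#' and a hidden-to-output connection `k -> i` when `degree(i) > degree(k)`.
#' The composition therefore contains no path from input `j` to output `i`
#' unless `degree(j) < degree(i)`.
#'
#' @param d Number of features (positive integer).
#' @param hidden_features Number of hidden units (positive integer).
#' @param ordering Integer permutation of `1:d` giving each input's
#'   autoregressive degree; defaults to the natural order.
#' @return A list with `input_mask` (`hidden_features x d`), `output_mask`
#'   (`d x hidden_features`), `input_degrees`, and `hidden_degrees`.
#' @examples
#' m <- build_autoregressive_masks(3, 8)
#' # no path from input 3 into output 1 or 2:
#' path <- m$output_mask %*% m$input_mask
#' path[1:2, 3]
#' @export
build_autoregressive_masks <- function(d, hidden_features,
                                       ordering = seq_len(d)) {
  d <- check_positive_int(d, "d")
  hidden_features <- check_positive_int(hidden_features, "hidden_features")
  if (length(ordering) != d || !setequal(ordering, seq_len(d))) {
    stop("`ordering` must be a permutation of 1:d", call. = FALSE)
  }
  in_deg <- as.integer(ordering)
  if (d == 1L) {
    # A single feature has no predecessors: both conditioner outputs are
    # constants, so every path is masked out.
    hid_deg <- rep(1L, hidden_features)
    input_mask <- matrix(0, hidden_features, 1L)
    output_mask <- matrix(0, 1L, hidden_features)
  } else {
    hid_deg <- rep(seq_len(d - 1L), length.out = hidden_features)
    input_mask <- outer(hid_deg, in_deg, FUN = ">=") * 1
    output_mask <- outer(in_deg, hid_deg, FUN = ">") * 1
  }
  list(
    input_mask = input_mask,
    output_mask = output_mask,
    input_degrees = in_deg,
    hidden_degrees = hid_deg
  )
}
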