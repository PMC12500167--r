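# Internal numeric helpers shared across layers.

# Coerce a numeric vector to a 1-row matrix; pass matrices through.
as_row_matrix <- function(x, d = NULL, arg = "x") {
  if (is.null(dim(x))) {
    if (!is.numeric(x)) stop("`", arg, "` must be numeric", call. = FALSE)
    x <- matrix(as.numeric(x), nrow = 1L)
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!is.null(d) && ncol(x) != d) {
    stop("`", arg, "` has ", ncol(x), " columns; expected ", d, call. = FALSE)
  }
  x
}

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# Numerically stable row-wise softmax.
row_softmax <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

check_positive_int <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 1 || x != floor(x)) {
    stop("`", name, "` must be a positive integer", call. = FALSE)
  }
  as.integer(x)
}

# Gaussian noise drawn under a private seed so the caller's RNG stream is
# untouched.
seeded_normal <- function(n, sd, seed) {
  withr::with_seed(seed, stats::rnorm(n, sd = sd))
}
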