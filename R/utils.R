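# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# A binary mask is a 0/1 numeric or logical matrix.
check_binary_mask <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x)) stop(name, " must be a matrix", call. = FALSE)
  v <- as.vector(x)
  if (!all(v %in% c(0, 1))) stop(name, " must be binary (0/1)", call. = FALSE)
  invisible(x)
}

# RGB image: H x W x 3 array with values in [0, 255].
check_rgb_image <- function(x, name = deparse(substitute(x))) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop(name, " must be an H x W x 3 RGB array", call. = FALSE)
  if (min(x) < 0 || max(x) > 255)
    stop(name, " values must lie in [0, 255]", call. = FALSE)
  invisible(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Gaussian blur of a 2-d field; sigma 0 is the identity.
gaussian_blur <- function(x, sigma) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(x)
  EBImage::gblur(x, sigma = sigma)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
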