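# internal helpers shared across modules

# run code with a private RNG stream; restores any prior .Random.seed
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# separable Gaussian blur of a matrix with replicated edges; sigma in pixels
gauss_blur_2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur_1d <- function(x) {  # along rows (first margin)
    n <- nrow(x)
    idx <- pmin(pmax(seq_len(n + 2 * r) - r, 1L), n)
    xp <- x[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(x))
    for (i in seq_along(k)) out <- out + k[i] * xp[(i - 1) + seq_len(n), , drop = FALSE]
    out
  }
  t(blur_1d(t(blur_1d(m))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
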