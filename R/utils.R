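#' @keywords internal
"_PACKAGE"

#' @importFrom stats median rnorm runif sd setNames approx quantile
#'   t.test wilcox.test shapiro.test pchisq pnorm cor complete.cases
#' @importFrom utils head tail read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Run code with a temporary RNG seed, restoring global RNG state afterwards,
# so generators are pure functions of (spec, seed).
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a positive finite scalar", name), call. = FALSE)
  }
}

# Maximal runs of TRUE in a logical vector, as half-open 0-based
# [start, end) frame intervals.
logical_runs <- function(x) {
  x <- as.logical(x)
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start_frame = starts[keep], end_frame = ends[keep])
}

# Bilinear upsample of a coarse matrix to nr x nc (used for bedding texture).
bilinear_upsample <- function(m, nr, nc) {
  ri <- seq(1, nrow(m), length.out = nr)
  ci <- seq(1, ncol(m), length.out = nc)
  r0 <- floor(ri); r1 <- pmin(r0 + 1, nrow(m)); fr <- ri - r0
  c0 <- floor(ci); c1 <- pmin(c0 + 1, ncol(m)); fc <- ci - c0
  a <- m[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
    m[r1, c0, drop = FALSE] * outer(fr, 1 - fc) +
    m[r0, c1, drop = FALSE] * outer(1 - fr, fc) +
    m[r1, c1, drop = FALSE] * outer(fr, fc)
  a
}
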