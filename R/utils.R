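#' Class labels used throughout the pipeline
#'
#' The four frame-level classes, in the fixed order used for probability
#' vectors, confusion matrices and argmax tie-breaking:
#' `Single > Multiple > Death > Empty`.
#'
#' @return Character vector of length 4.
#' @export
well_classes <- function() c("Single", "Multiple", "Death", "Empty")

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.  All generators in the package
# take explicit seeds and go through this helper so that library calls
# never perturb user RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Bilinear resize of a numeric matrix (half-pixel center alignment).
resize_bilinear <- function(img, out_h, out_w = out_h) {
  stopifnot(is.matrix(img), out_h >= 1, out_w >= 1)
  h <- nrow(img); w <- ncol(img)
  sy <- h / out_h; sx <- w / out_w
  yc <- pmin(pmax((seq_len(out_h) - 0.5) * sy + 0.5, 1), h)
  xc <- pmin(pmax((seq_len(out_w) - 0.5) * sx + 0.5, 1), w)
  y0 <- pmin(floor(yc), h - 1L); wy <- yc - y0
  x0 <- pmin(floor(xc), w - 1L); wx <- xc - x0
  # rows first, then columns (separable)
  r <- img[y0, , drop = FALSE] * (1 - wy) + img[y0 + 1, , drop = FALSE] * wy
  r[, x0, drop = FALSE] * rep(1 - wx, each = out_h) +
    r[, x0 + 1, drop = FALSE] * rep(wx, each = out_h)
}

# Separable Gaussian blur via banded convolution matrices (edge-renormalized
# so flat regions stay flat near borders).  sigma in pixels; sigma <= 0 is a
# no-op.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma))
  g <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  band <- function(n) {
    B <- matrix(0, n, n)
    for (k in seq(-half, half)) {
      i <- seq_len(n)
      j <- i + k
      ok <- j >= 1 & j <= n
      B[cbind(i[ok], j[ok])] <- g[k + half + 1]
    }
    B / rowSums(B)
  }
  Br <- band(nrow(img))
  Bc <- if (ncol(img) == nrow(img)) Br else band(ncol(img))
  Br %*% img %*% t(Bc)
}

# Internal assertion with a compact message.
check <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
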