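#' @include AllClasses.R
NULL

# classed conditions so callers can distinguish failure modes
dtcStop <- function(subclass, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(subclass, "dtcmorphError", "error")))
}

# Bilinear interpolation of `img` (matrix, row = y + 1) at 0-based (x, y).
# Out-of-bounds samples return `fill`. Fractional offsets below 1e-9 are
# snapped to the grid so that integer-coordinate sampling is bit-exact.
bilinearSample <- function(img, x, y, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  snap <- fx < 1e-9; fx[snap] <- 0
  snap <- fx > 1 - 1e-9; x0[snap] <- x0[snap] + 1; fx[snap] <- 0
  snap <- fy < 1e-9; fy[snap] <- 0
  snap <- fy > 1 - 1e-9; y0[snap] <- y0[snap] + 1; fy[snap] <- 0
  x1 <- x0 + (fx > 0); y1 <- y0 + (fy > 0)

  px <- function(xi, yi) {
    inside <- xi >= 0 & xi <= w - 1 & yi >= 0 & yi <= h - 1
    v <- rep(fill, length(xi))
    v[inside] <- img[cbind(yi[inside] + 1, xi[inside] + 1)]
    v
  }
  (1 - fx) * (1 - fy) * px(x0, y0) +
    fx * (1 - fy) * px(x1, y0) +
    (1 - fx) * fy * px(x0, y1) +
    fx * fy * px(x1, y1)
}

# provenance step descriptor
provStep <- function(step, ...) c(list(step = step), list(...))

appendProvenance <- function(image, step) {
  image@provenance <- c(image@provenance, list(step))
  image
}

# stable content hash without extra dependencies: md5 of a canonical
# serialization written to a temp file
contentHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}
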