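# Internal numerical helpers shared across modules.

# Bilinear sampling of matrix z at fractional 1-based indices (i1, i2).
# Points outside the index range take `fill` (fill = NA means clamp instead).
.bilinear_idx <- function(z, i1, i2, fill = 0) {
  n1 <- nrow(z); n2 <- ncol(z)
  # tolerate floating-point overshoot at the grid edges
  tol <- 1e-9 * max(n1, n2)
  inside <- i1 >= 1 - tol & i1 <= n1 + tol & i2 >= 1 - tol & i2 <= n2 + tol
  if (is.na(fill)) {
    inside <- rep(TRUE, length(i1))
  }
  i1 <- pmin(pmax(i1, 1), n1)
  i2 <- pmin(pmax(i2, 1), n2)
  out <- rep(if (is.na(fill)) NA_real_ else fill, length(i1))
  if (!any(inside)) return(out)
  a1 <- pmin(pmax(floor(i1[inside]), 1), n1 - 1)
  a2 <- pmin(pmax(floor(i2[inside]), 1), n2 - 1)
  f1 <- i1[inside] - a1
  f2 <- i2[inside] - a2
  v <- (1 - f1) * (1 - f2) * z[cbind(a1, a2)] +
       f1 * (1 - f2) * z[cbind(a1 + 1, a2)] +
       (1 - f1) * f2 * z[cbind(a1, a2 + 1)] +
       f1 * f2 * z[cbind(a1 + 1, a2 + 1)]
  out[inside] <- v
  out
}

# Bilinear sampling of z (dim c(length(x), length(y))) on uniform axes x, y
# at physical points (xi, yi); outside the axes -> fill (NA = clamp).
.bilinear_xy <- function(x, y, z, xi, yi, fill = 0) {
  dx <- if (length(x) > 1) x[2] - x[1] else 1
  dy <- if (length(y) > 1) y[2] - y[1] else 1
  .bilinear_idx(z, (xi - x[1]) / dx + 1, (yi - y[1]) / dy + 1, fill = fill)
}

# Sample a VelocityField at physical points (mm); returns cm/s components.
# Points outside the grid (or outside the mask, velocities being stored as 0
# there) evaluate to ~0 by construction.
.sample_field <- function(field, xi, yi) {
  list(u = .bilinear_xy(field@x, field@y, field@u, xi, yi, fill = 0),
       v = .bilinear_xy(field@x, field@y, field@v, xi, yi, fill = 0))
}

# Deterministic child seed derived from a base seed and a stage label.
.child_seed <- function(seed, ...) {
  lab <- paste(c(seed, ...), collapse = "/")
  h <- sum(utf8ToInt(lab) * (31^(seq_along(utf8ToInt(lab)) %% 8)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Evaluate code with a temporarily fixed RNG state.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

# Uniform grid axes covering a phantom domain.
.phantom_axes <- function(phantom, nx, ny, pad = 0) {
  L <- phantom@domainLength
  R <- phantom@inletRadius + pad
  list(x = seq(-L / 2, L / 2, length.out = nx),
       y = seq(-R, R, length.out = ny))
}
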