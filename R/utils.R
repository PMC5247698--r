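# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_input <- function(...) stop(..., call. = FALSE)

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf, strict_lo = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_input(sprintf("`%s` must be a single finite number", name))
  if ((strict_lo && x <= lo) || (!strict_lo && x < lo) || x > hi)
    stop_input(sprintf("`%s` = %g is outside the allowed range", name, x))
  invisible(x)
}

# Rasterise a filled disc into a logical matrix (row = y, col = x).
# Returns the linear indices of disc pixels; centre and radius in pixels.
disc_pixels <- function(cx, cy, r, nrow, ncol) {
  x0 <- max(1L, floor(cx - r)); x1 <- min(ncol, ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(nrow, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(integer(0))
  xs <- x0:x1; ys <- y0:y1
  dx2 <- (xs - cx)^2
  out <- vector("list", length(xs))
  r2 <- r^2
  for (i in seq_along(xs)) {
    yy <- ys[(ys - cy)^2 <= r2 - dx2[i]]
    out[[i]] <- yy + (xs[i] - 1L) * nrow
  }
  unlist(out, use.names = FALSE)
}

# Pixels within `halfwidth` of the segment (x1,y1)-(x2,y2); a thick ribbon.
segment_pixels <- function(x1, y1, x2, y2, halfwidth, nrow, ncol) {
  xlo <- max(1L, floor(min(x1, x2) - halfwidth)); xhi <- min(ncol, ceiling(max(x1, x2) + halfwidth))
  ylo <- max(1L, floor(min(y1, y2) - halfwidth)); yhi <- min(nrow, ceiling(max(y1, y2) + halfwidth))
  if (xlo > xhi || ylo > yhi) return(integer(0))
  xs <- xlo:xhi; ys <- ylo:yhi
  gx <- rep(xs, each = length(ys)); gy <- rep(ys, length(xs))
  vx <- x2 - x1; vy <- y2 - y1
  len2 <- vx^2 + vy^2
  t <- if (len2 == 0) 0 else clamp(((gx - x1) * vx + (gy - y1) * vy) / len2, 0, 1)
  d2 <- (gx - (x1 + t * vx))^2 + (gy - (y1 + t * vy))^2
  keep <- d2 <= halfwidth^2
  gy[keep] + (gx[keep] - 1L) * nrow
}
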