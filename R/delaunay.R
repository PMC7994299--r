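# Planar Delaunay triangulation (Bowyer-Watson).
#
# Sensor counts are small (<= 64), so an O(n^2) incremental construction is
# ample. Grid-like layouts contain many exactly cocircular quadruples, which
# make the empty-circumcircle test ambiguous; a tiny deterministic,
# index-keyed jitter breaks the ties reproducibly (either diagonal of a
# cocircular quad is an acceptable adjacency).

delaunay_edges <- function(xy) {
  n <- nrow(xy)
  if (n < 3) stop("need at least 3 points for a triangulation")
  i <- seq_len(n)
  jx <- (((i * 2654435761) %% 1009) / 1009 - 0.5) * 1e-7
  jy <- (((i * 40503) %% 997) / 997 - 0.5) * 1e-7
  px <- xy[, 1] + jx
  py <- xy[, 2] + jy

  # super-triangle enclosing everything
  cx <- mean(range(px)); cy <- mean(range(py))
  r <- max(sqrt((px - cx)^2 + (py - cy)^2)) * 4 + 1
  px <- c(px, cx - 2 * r, cx + 2 * r, cx)
  py <- c(py, cy - r, cy - r, cy + 2 * r)
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L

  tri <- matrix(c(s1, s2, s3), ncol = 3)           # vertex index triples
  cc <- circumcircle(tri, px, py)                  # cx, cy, r2 per triangle

  for (p in seq_len(n)) {
    bad <- (px[p] - cc[, 1])^2 + (py[p] - cc[, 2])^2 <= cc[, 3]
    if (!any(bad)) next                            # cannot happen inside super-tri
    badtri <- tri[bad, , drop = FALSE]
    # boundary = edges of the bad-triangle cavity appearing exactly once
    e <- rbind(badtri[, c(1, 2)], badtri[, c(2, 3)], badtri[, c(1, 3)])
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    key <- paste(e[, 1], e[, 2])
    keep <- e[key %in% names(which(table(key) == 1)), , drop = FALSE]
    newtri <- cbind(keep, p)
    tri <- rbind(tri[!bad, , drop = FALSE], newtri)
    cc <- rbind(cc[!bad, , drop = FALSE], circumcircle(newtri, px, py))
  }

  real <- tri[, 1] <= n & tri[, 2] <= n & tri[, 3] <= n
  tri <- tri[real, , drop = FALSE]
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

circumcircle <- function(tri, px, py) {
  ax <- px[tri[, 1]]; ay <- py[tri[, 1]]
  bx <- px[tri[, 2]]; by <- py[tri[, 2]]
  cx <- px[tri[, 3]]; cy <- py[tri[, 3]]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  cbind(ux, uy, (ax - ux)^2 + (ay - uy)^2)
}
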