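# Analytic spherical head model and synthetic parcellation.
#
# The forward model is the exact Legendre-series solution for a current
# dipole inside a homogeneous conducting sphere with an insulating exterior.
# For a dipole with moment q at radius b along unit vector u, the surface
# potential at electrode direction e (|e| = R) is
#
#   V(e) = 1/(4 pi sigma) * sum_{n>=1} (2n+1)/n * b^(n-1)/R^(n+1) *
#          [ n (q.u) P_n(cos g) + ((q.e_hat) - (q.u)(u.e_hat)) P_n'(cos g) ]
#
# with cos g = u . e_hat. The n = 1 term alone gives the closed form for a
# central dipole, V = 3 (q.e_hat) / (4 pi sigma R^2), used as the analytic
# oracle in the tests. The series converges geometrically in (b/R).

sphere_dipole_potential <- function(dipole_pos, dipole_mom, elec, R = 1,
                                    sigma = 1, nterms = 60) {
  b <- sqrt(sum(dipole_pos^2))
  ehat <- elec / R
  qe <- as.numeric(ehat %*% dipole_mom)
  if (b < 1e-12)
    return(3 * qe / (4 * pi * sigma * R^2))
  u <- dipole_pos / b
  qr <- sum(dipole_mom * u)
  cg <- as.numeric(ehat %*% u)
  ue <- cg
  # Legendre P_n and derivative P_n' by recurrence, vectorized over electrodes
  m <- length(cg)
  Pnm1 <- rep(1, m); Pn <- cg                 # P_0, P_1
  dPnm1 <- rep(0, m); dPn <- rep(1, m)        # P_0', P_1'
  V <- numeric(m)
  scale <- 1 / (4 * pi * sigma)
  for (n in 1:nterms) {
    coef <- (2 * n + 1) / n * b^(n - 1) / R^(n + 1)
    V <- V + coef * (n * qr * Pn + (qe - qr * ue) * dPn)
    # advance to P_{n+1}
    Pnp1 <- ((2 * n + 1) * cg * Pn - n * Pnm1) / (n + 1)
    dPnp1 <- ((2 * n + 1) * (Pn + cg * dPn) - n * dPnm1) / (n + 1)
    Pnm1 <- Pn; Pn <- Pnp1
    dPnm1 <- dPn; dPn <- dPnp1
  }
  scale * V
}

#' Build an analytic spherical-head leadfield and a 90-ROI parcellation
#'
#' Gains are exact homogeneous-sphere dipole potentials evaluated at the
#' montage electrodes (average-referenced, matching the preprocessing
#' convention). Grid points are rejection-sampled quasi-uniformly inside a
#' "brain" sphere of radius 0.85 (electrodes at radius 1). The grid is
#' partitioned into 90 Voronoi regions around deterministic Fibonacci-spiral
#' seed directions — a synthetic stand-in for an anatomical atlas — and each
#' region is assigned to one of 7 canonical networks by proximity to fixed
#' network anchor directions.
#'
#' @param montage a `sensor_montage`.
#' @param n_grid number of source grid points (>= 90).
#' @param seed integer seed controlling grid sampling.
#' @return list with `leadfield` (class `leadfield`: `gains`
#'   (n_grid x 3 x n_channels), `grid_positions`, `inside_mask`, `spacing`)
#'   and `parcellation` (class `parcellation`: `roi_of_grid`, `roi_names`,
#'   `network_of_roi`, `centroid_grid_index`).
#' @export
make_leadfield <- function(montage, n_grid, seed = 1) {
  n_roi <- 90L
  if (n_grid < n_roi) stop("n_grid must be at least ", n_roi)
  nch <- length(montage$channel_names)
  grid <- with_seed(seed, {
    pts <- matrix(NA_real_, 0, 3)
    while (nrow(pts) < n_grid) {
      cand <- matrix(runif(3 * n_grid * 2, -1, 1), ncol = 3)
      cand <- cand[rowSums(cand^2) <= 1, , drop = FALSE]
      pts <- rbind(pts, cand * 0.85)
    }
    pts[seq_len(n_grid), , drop = FALSE]
  })
  gains <- array(0, dim = c(n_grid, 3, nch))
  I3 <- diag(3)
  for (g in seq_len(n_grid)) {
    for (o in 1:3) {
      v <- sphere_dipole_potential(grid[g, ], I3[o, ], montage$positions3d)
      gains[g, o, ] <- v - mean(v)       # common-average-referenced forward model
    }
  }
  spacing <- (4 / 3 * pi * 0.85^3 / n_grid)^(1 / 3)
  lf <- structure(list(gains = gains, grid_positions = grid,
                       inside_mask = rep(TRUE, n_grid), spacing = spacing,
                       channel_names = montage$channel_names),
                  class = "leadfield")
  parc <- make_parcellation(grid, n_roi)
  parc <- select_centroids(parc, lf)
  list(leadfield = lf, parcellation = parc)
}

# Voronoi partition of the grid around 90 Fibonacci-spiral seeds; each seed
# first claims its nearest unclaimed grid point so no ROI is empty.
make_parcellation <- function(grid, n_roi = 90L) {
  seeds <- fibonacci_sphere(n_roi) * 0.6
  d <- outer(rowSums(grid^2), rep(1, n_roi)) +
    outer(rep(1, nrow(grid)), rowSums(seeds^2)) - 2 * grid %*% t(seeds)
  roi <- max.col(-d)                       # nearest seed
  # guarantee non-emptiness: repeatedly move the closest grid point from a
  # multi-member ROI into each empty one (terminates since n_grid >= n_roi)
  repeat {
    sizes <- tabulate(roi, n_roi)
    empty <- which(sizes == 0)
    if (!length(empty)) break
    for (r in empty) {
      cand <- order(d[, r])
      pick <- cand[tabulate(roi, n_roi)[roi[cand]] > 1][1]
      roi[pick] <- r
    }
  }
  hemi <- ifelse(seeds[, 1] < 0, "L", "R")
  roi_names <- sprintf("ROI%02d_%s", seq_len(n_roi), hemi)
  anchors <- fibonacci_sphere(7)
  net_d <- seeds %*% t(anchors)
  networks <- c("DMN", "DAN", "FPN", "VAN", "SMN", "VIS", "LIM")
  network_of_roi <- networks[max.col(net_d)]
  structure(list(roi_of_grid = roi, roi_names = roi_names,
                 network_of_roi = network_of_roi,
                 networks = networks,
                 centroid_grid_index = rep(NA_integer_, n_roi)),
            class = "parcellation")
}

# n quasi-uniform unit vectors (golden-angle spiral); deterministic.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(1 - z^2)
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Select ROI centroid grid points
#'
#' The centroid of an ROI is the member grid point minimizing the summed
#' Euclidean distance to all other member points (the discrete geometric
#' median); ties break to the lowest grid index.
#'
#' @param parcellation a `parcellation`.
#' @param leadfield a `leadfield` providing `grid_positions`.
#' @return the parcellation with `centroid_grid_index` filled.
#' @export
select_centroids <- function(parcellation, leadfield) {
  pos <- leadfield$grid_positions
  n_roi <- length(parcellation$roi_names)
  cent <- integer(n_roi)
  for (r in seq_len(n_roi)) {
    idx <- which(parcellation$roi_of_grid == r)
    if (length(idx) == 0) stop("empty ROI: ", r)
    if (length(idx) == 1) { cent[r] <- idx; next }
    p <- pos[idx, , drop = FALSE]
    dsum <- rowSums(as.matrix(stats::dist(p)))
    cent[r] <- idx[which.min(dsum)]      # which.min takes the first (lowest index)
  }
  parcellation$centroid_grid_index <- cent
  parcellation
}

#' Write / read parcellation table as TSV
#' @param parcellation a `parcellation`.
#' @param path file path.
#' @export
write_parcellation_tsv <- function(parcellation, path) {
  df <- data.frame(roi = seq_along(parcellation$roi_names),
                   name = parcellation$roi_names,
                   network = parcellation$network_of_roi,
                   centroid_grid_index = parcellation$centroid_grid_index)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
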