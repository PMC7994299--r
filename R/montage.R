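#' Construct a 10-10 sensor montage
#'
#' Builds a deterministic EEG montage laid out on the extended international
#' 10-10 grid. Channels are named by row (Fp, AF, F, FC, C, CP, P, PO, O)
#' and lateral position; the montage always contains `C3` and `C4` together
#' with their four in-plane neighbours (`C1`/`C5`/`FC3`/`CP3` and mirrored),
#' which the small-Laplacian control-signal filter requires.
#'
#' Positions are defined on a planar 10-10 grid (0.25 per 10% step), clipped
#' radially to the unit disc, and lifted to the unit sphere by the inverse
#' azimuthal equidistant projection (disc radius 1 maps to 90 degrees of
#' inclination from the vertex). `positions2d` is exactly the azimuthal
#' equidistant projection of `positions3d`, the projection later used for
#' sensor adjacency.
#'
#' @param n_channels number of electrodes; 32 or 64.
#' @return an object of class `sensor_montage`: list with `channel_names`,
#'   `positions3d` (n x 3, unit norm), `positions2d` (n x 2).
#' @examples
#' m <- make_montage(64)
#' c("C3", "C4") %in% m$channel_names
#' @export
make_montage <- function(n_channels) {
  if (!n_channels %in% c(32L, 64L))
    stop("unsupported channel count: ", n_channels, " (must be 32 or 64)")
  lay <- montage_layout_64()
  if (n_channels == 32L) {
    keep <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
              "FT7", "FC3", "FC1", "FCz", "FC2", "FC4", "FT8",
              "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
              "CP3", "CP1", "CPz", "CP2", "CP4", "P3", "Pz", "P4", "Oz")
    lay <- lay[match(keep, lay$name), ]
  }
  p2 <- as.matrix(lay[, c("x", "y")])
  rownames(p2) <- lay$name
  p3 <- planar_to_sphere(p2)
  structure(list(channel_names = lay$name, positions3d = p3, positions2d = p2),
            class = "sensor_montage")
}

# The 64-label 10-10 layout on a planar grid: one unit of 0.25 per 10% step;
# points outside the unit circle are compressed onto it (the outer ring).
montage_layout_64 <- function() {
  rows <- list(
    Fp = list(a = 4, labs = c("Fp1", "Fpz", "Fp2"), l = c(-1, 0, 1)),
    AF = list(a = 3, labs = c("AF7", "AF3", "AFz", "AF4", "AF8"), l = c(-3, -1, 0, 1, 3)),
    F  = list(a = 2, labs = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"), l = -4:4),
    FC = list(a = 1, labs = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"), l = -4:4),
    C  = list(a = 0, labs = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"), l = -4:4),
    CP = list(a = -1, labs = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"), l = -4:4),
    P  = list(a = -2, labs = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"), l = -4:4),
    PO = list(a = -3, labs = c("PO7", "PO3", "POz", "PO4", "PO8"), l = c(-3, -1, 0, 1, 3)),
    O  = list(a = -4, labs = c("O1", "Oz", "O2"), l = c(-1, 0, 1))
  )
  nm <- unlist(lapply(rows, `[[`, "labs"), use.names = FALSE)
  x <- unlist(lapply(rows, function(r) 0.25 * r$l), use.names = FALSE)
  y <- unlist(lapply(rows, function(r) rep(0.25 * r$a, length(r$l))), use.names = FALSE)
  # three inferior electrodes complete the 64-set
  nm <- c(nm, "FT9", "FT10", "Iz")
  x <- c(x, -1.25, 1.25, 0)
  y <- c(y, 0.25, 0.25, -1.15)
  r <- sqrt(x^2 + y^2)
  clip <- r > 1 & nm != "Iz"          # Iz sits below the equatorial ring
  x[clip] <- x[clip] / r[clip]
  y[clip] <- y[clip] / r[clip]
  data.frame(name = nm, x = x, y = y, stringsAsFactors = FALSE)
}

# Inverse azimuthal equidistant projection: planar radius r -> inclination
# r * pi/2 from the vertex (+z); azimuth preserved.
planar_to_sphere <- function(p2) {
  r <- sqrt(rowSums(p2^2))
  theta <- r * pi / 2
  u <- p2
  nz <- r > 1e-12
  u[nz, ] <- p2[nz, , drop = FALSE] / r[nz]
  u[!nz, ] <- 0
  cbind(x = sin(theta) * u[, 1], y = sin(theta) * u[, 2], z = cos(theta))
}

# Azimuthal equidistant projection from the vertex (the inverse of
# planar_to_sphere); used to derive positions2d from positions3d.
sphere_to_planar <- function(p3) {
  theta <- acos(pmin(1, pmax(-1, p3[, 3])))
  rho <- sqrt(p3[, 1]^2 + p3[, 2]^2)
  u <- p3[, 1:2, drop = FALSE]
  nz <- rho > 1e-12
  u[nz, ] <- u[nz, , drop = FALSE] / rho[nz]
  u[!nz, ] <- 0
  (theta / (pi / 2)) * u
}

#' Nearest in-plane neighbours of a channel
#'
#' @param montage a `sensor_montage`.
#' @param channel channel name.
#' @param k number of neighbours (default 4, the small-Laplacian set).
#' @return character vector of neighbour names, nearest first.
#' @export
montage_neighbors <- function(montage, channel, k = 4) {
  i <- match(channel, montage$channel_names)
  if (is.na(i)) stop("channel not in montage: ", channel)
  d <- sqrt(rowSums((montage$positions2d -
                       matrix(montage$positions2d[i, ], nrow(montage$positions2d), 2,
                              byrow = TRUE))^2))
  d[i] <- Inf
  montage$channel_names[order(d)[seq_len(k)]]
}

#' Write / read a montage as TSV
#'
#' Four columns: `name`, `x`, `y`, `z` (unit-sphere positions).
#' @param montage a `sensor_montage`.
#' @param path file path.
#' @export
write_montage_tsv <- function(montage, path) {
  df <- data.frame(name = montage$channel_names,
                   x = montage$positions3d[, 1],
                   y = montage$positions3d[, 2],
                   z = montage$positions3d[, 3])
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_montage_tsv
#' @param path file path.
#' @export
read_montage_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  p3 <- as.matrix(df[, c("x", "y", "z")])
  rownames(p3) <- df$name
  p2 <- sphere_to_planar(p3)
  rownames(p2) <- df$name
  structure(list(channel_names = df$name, positions3d = p3, positions2d = p2),
            class = "sensor_montage")
}
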