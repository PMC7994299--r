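# Orthogonalized power-envelope correlation connectivity.

#' Orthogonalize one analytic signal against another
#'
#' Removes the instantaneous zero-lag (spatial leakage) component of `x`
#' from `y`: `y_perp(t) = Im( y(t) * conj(x(t)) / |x(t)| )`. Samples where
#' `|x| = 0` are masked out (dropped) with a count reported as an attribute.
#'
#' @param x,y complex analytic signals of equal length; `x` must not be
#'   identically zero.
#' @return real signal of the same length (`NA` at masked samples).
#' @export
orthogonalize <- function(x, y) {
  if (length(x) != length(y)) stop("signals must have equal length")
  ax <- Mod(x)
  if (all(ax == 0)) stop("x is identically zero")
  out <- rep(NA_real_, length(x))
  ok <- ax > 0
  out[ok] <- Im(y[ok] * Conj(x[ok]) / ax[ok])
  attr(out, "masked") <- sum(!ok)
  out
}

#' Orthogonalized power-envelope correlation
#'
#' Pearson correlation between the log power envelopes of `x` and of `y`
#' orthogonalized to `x`, averaged with the reverse direction — symmetric in
#' `(x, y)` by construction. Identical (fully leaking) signals give r near
#' zero because orthogonalization annihilates the shared component.
#'
#' @param x,y complex analytic signals, length >= 100.
#' @param log_transform correlate log power envelopes (default) or raw
#'   envelopes.
#' @return scalar correlation.
#' @export
envelope_correlation <- function(x, y, log_transform = TRUE) {
  if (length(x) != length(y)) stop("signals must have equal length")
  if (length(x) < 100) stop("need at least 100 samples")
  env <- function(v) {
    a <- abs(v)
    if (log_transform) log(a^2 + .Machine$double.eps) else a^2
  }
  if (sd(Mod(x)) == 0 || sd(Mod(y)) == 0) stop("constant envelope")
  r1 <- env_cor(env(Mod(x)), env(abs(orthogonalize(x, y))))
  r2 <- env_cor(env(Mod(y)), env(abs(orthogonalize(y, x))))
  (r1 + r2) / 2
}

# Pearson correlation of envelope series; a degenerate (all-zero)
# orthogonalized residual carries no shared envelope, so r = 0 by
# convention (perfect leakage suppressed).
env_cor <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sd(a[ok]) == 0 || sd(b[ok]) == 0) return(0)
  cor(a[ok], b[ok])
}

#' All-to-all ROI connectivity matrix
#'
#' Envelope correlation for every unordered ROI pair on trial-concatenated
#' analytic signals (0.1 s trimmed from each trial edge to suppress filter
#' transients). 90 ROIs give 4,005 unique pairs; the matrix is symmetric
#' with a zero diagonal.
#'
#' @param tc a `roi_timecourses` (or a complex rois x samples matrix).
#' @param edge_trim_sec seconds trimmed per trial edge (ignored for plain
#'   matrices).
#' @param log_transform see [envelope_correlation()].
#' @return object of class `connectivity_matrix`: `values` (rois x rois),
#'   `band`, `roi_names`.
#' @export
connectivity_matrix <- function(tc, edge_trim_sec = 0.1, log_transform = TRUE) {
  if (inherits(tc, "roi_timecourses")) {
    d <- dim(tc$signal)
    keep <- seq_len(d[3])
    trim <- round(edge_trim_sec * tc$sampling_rate)
    if (2 * trim < d[3] - 10) keep <- (trim + 1):(d[3] - trim)
    m <- matrix(tc$signal[, , keep], d[1], d[2] * length(keep))
    roi_names <- tc$roi_names
    band <- tc$band
  } else {
    m <- tc
    roi_names <- rownames(m) %||% sprintf("ROI%02d", seq_len(nrow(m)))
    band <- NULL
  }
  n <- nrow(m)
  Tn <- ncol(m)
  # log power envelopes; note log env(y orth x)^2 = log Im(y conj(x))^2 -
  # log|x|^2, so one cross product per pair serves both directions
  eps <- .Machine$double.eps
  le <- log(Mod(m)^2 + eps)
  lec <- le - rowMeans(le)
  len <- sqrt(rowSums(lec^2))
  vals <- matrix(0, n, n)
  rowcor <- function(A, B) {            # rowwise Pearson of two matrices
    Ac <- A - rowMeans(A); Bc <- B - rowMeans(B)
    den <- sqrt(rowSums(Ac^2) * rowSums(Bc^2))
    out <- rowSums(Ac * Bc) / pmax(den, eps)
    out[den == 0] <- 0
    out
  }
  for (i in seq_len(n - 1)) {
    J <- (i + 1):n
    P <- m[J, , drop = FALSE] *
      matrix(Conj(m[i, ]), length(J), Tn, byrow = TRUE)
    L <- log(Im(P)^2 + eps)
    r1 <- rowcor(matrix(le[i, ], length(J), Tn, byrow = TRUE),
                 L - matrix(le[i, ], length(J), Tn, byrow = TRUE))
    r2 <- rowcor(le[J, , drop = FALSE], L - le[J, , drop = FALSE])
    vals[i, J] <- vals[J, i] <- (r1 + r2) / 2
  }
  dimnames(vals) <- list(roi_names, roi_names)
  structure(list(values = vals, band = band, roi_names = roi_names),
            class = "connectivity_matrix")
}

#' Number of unique informative pairs in a connectivity matrix
#' @param cm a `connectivity_matrix` or square matrix.
#' @return integer pair count (`n * (n - 1) / 2`).
#' @export
n_connectivity_pairs <- function(cm) {
  n <- if (inherits(cm, "connectivity_matrix")) nrow(cm$values) else nrow(cm)
  n * (n - 1) / 2
}

#' Long-format export of a connectivity matrix
#' @param cm a `connectivity_matrix`.
#' @param path CSV path.
#' @export
write_connectivity_csv <- function(cm, path) {
  n <- nrow(cm$values)
  idx <- which(upper.tri(cm$values), arr.ind = TRUE)
  df <- data.frame(roi_i = cm$roi_names[idx[, 1]],
                   roi_j = cm$roi_names[idx[, 2]],
                   r = cm$values[idx])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
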