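# Interaction-contrast group statistics: spatial-spectral cluster
# permutation tests and the network-based statistic (NBS).
#
# All tests operate on "interaction samples": one per-subject difference map
# (last session minus first) per row, with a two-level group factor, and use
# full relabeling of subjects across groups (group sizes preserved) with a
# +1-corrected Monte Carlo p so p > 0 always.

#' Spatial-spectral sensor adjacency
#'
#' Spatial links are Delaunay-triangulation edges on the 2-D projected
#' sensor positions; spectral links connect the same channel at frequencies
#' 1 Hz apart. Nodes are (channel, frequency) elements, indexed
#' `channel + (freq_index - 1) * n_channels`.
#'
#' @param montage a `sensor_montage` (>= 3 sensors).
#' @param freqs numeric frequency grid in Hz.
#' @return object of class `adjacency_graph`: `edges` (m x 2 node indices),
#'   `n_nodes`, `node_channel`, `node_freq`, `type = "sensor_freq"`,
#'   `spatial_edges` (channel index pairs).
#' @export
build_sensor_adjacency <- function(montage, freqs = 1:50) {
  nch <- length(montage$channel_names)
  if (nch < 3) stop("need at least 3 sensors")
  se <- delaunay_edges(montage$positions2d)
  nf <- length(freqs)
  node <- function(ch, fi) ch + (fi - 1L) * nch
  spat <- do.call(rbind, lapply(seq_len(nf), function(fi)
    cbind(node(se[, 1], fi), node(se[, 2], fi))))
  adj_f <- which(diff(freqs) == 1)       # spectral neighbours: exactly 1 Hz apart
  spec <- if (length(adj_f))
    do.call(rbind, lapply(adj_f, function(fi)
      cbind(node(seq_len(nch), fi), node(seq_len(nch), fi + 1L))))
  else matrix(integer(), 0, 2)
  structure(list(edges = rbind(spat, spec), n_nodes = nch * nf,
                 node_channel = rep(seq_len(nch), nf),
                 node_freq = rep(freqs, each = nch),
                 n_channels = nch, freqs = freqs,
                 channel_names = montage$channel_names,
                 spatial_edges = se, type = "sensor_freq"),
            class = "adjacency_graph")
}

#' Source-grid spatial adjacency
#'
#' Grid points within `radius_factor` times the nominal grid spacing are
#' adjacent.
#'
#' @param leadfield a `leadfield`.
#' @param radius_factor neighbourhood radius in units of grid spacing
#'   (default 1.25).
#' @return an `adjacency_graph` with `type = "grid"`.
#' @export
build_grid_adjacency <- function(leadfield, radius_factor = 1.25) {
  pos <- leadfield$grid_positions
  n <- nrow(pos)
  r <- radius_factor * leadfield$spacing
  d2 <- as.matrix(stats::dist(pos))^2
  idx <- which(d2 <= r^2 & upper.tri(d2), arr.ind = TRUE)
  structure(list(edges = unname(idx), n_nodes = n,
                 node_channel = seq_len(n), node_freq = rep(1, n),
                 type = "grid"),
            class = "adjacency_graph")
}

#' Element-wise two-sample t map
#'
#' Pooled-variance (Student) two-sample t per element by default, matching
#' conventional neuroimaging toolbox behaviour; Welch optional. Elements
#' with zero variance in both groups get t = 0 (flagged).
#'
#' @param values subjects x elements matrix of difference maps.
#' @param group two-level factor/character of length `nrow(values)`.
#' @param welch use Welch's t.
#' @return list `t`, `p` (two-sided), `df`, `zero_variance` (logical).
#' @export
element_t_map <- function(values, group, welch = FALSE) {
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  a <- values[group == levels(group)[1], , drop = FALSE]
  b <- values[group == levels(group)[2], , drop = FALSE]
  n1 <- nrow(a); n2 <- nrow(b)
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- colSums(a^2) - n1 * m1^2
  v2 <- colSums(b^2) - n2 * m2^2
  if (welch) {
    s1 <- v1 / (n1 - 1); s2 <- v2 / (n2 - 1)
    se2 <- s1 / n1 + s2 / n2
    df <- se2^2 / (pmax(s1 / n1, 1e-300)^2 / (n1 - 1) +
                     pmax(s2 / n2, 1e-300)^2 / (n2 - 1))
  } else {
    sp2 <- (v1 + v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(m1))
  }
  zerov <- se2 <= 0
  tt <- ifelse(zerov, 0, (m1 - m2) / sqrt(pmax(se2, 1e-300)))
  list(t = tt, p = 2 * pt(-abs(tt), df), df = df, zero_variance = zerov,
       group_levels = levels(group))
}

# t maps for a block of permutations at once: perm_idx is a p x n1 matrix of
# row indices assigned to group 1. Returns p x elements matrix of t values.
perm_t_block <- function(values, perm_idx, n1, n2, welch = FALSE) {
  n <- n1 + n2
  tot <- colSums(values)
  tot2 <- colSums(values^2)
  ind <- matrix(0, nrow(perm_idx), n)
  ind[cbind(rep(seq_len(nrow(perm_idx)), ncol(perm_idx)), as.vector(perm_idx))] <- 1
  s1 <- ind %*% values
  q1 <- ind %*% (values^2)
  m1 <- s1 / n1
  m2 <- sweep(-s1, 2, tot, `+`) / n2
  v1 <- q1 - n1 * m1^2
  v2 <- sweep(-q1, 2, tot2, `+`) - n2 * m2^2
  sp2 <- (v1 + v2) / (n - 2)
  se2 <- sp2 * (1 / n1 + 1 / n2)
  tt <- (m1 - m2) / sqrt(pmax(se2, 1e-300))
  tt[se2 <= 0] <- 0
  tt
}

# Connected components of suprathreshold elements of one sign.
# Returns a list of integer vectors (node indices), deterministic order.
sign_components <- function(active_nodes, edges) {
  if (length(active_nodes) == 0) return(list())
  amap <- integer(0)
  amap[active_nodes] <- seq_along(active_nodes)
  keep <- !is.na(match(edges[, 1], active_nodes)) &
    !is.na(match(edges[, 2], active_nodes))
  g <- igraph::make_empty_graph(n = length(active_nodes), directed = FALSE)
  if (any(keep)) {
    el <- cbind(amap[edges[keep, 1]], amap[edges[keep, 2]])
    g <- igraph::add_edges(g, t(el))
  }
  memb <- igraph::components(g)$membership
  comp <- split(active_nodes, memb)
  comp[order(vapply(comp, min, numeric(1)))]
}

# Apply the cluster admissibility rule and compute masses.
admissible_clusters <- function(comps, tvec, adjacency, min_channels,
                                min_freqs, min_size) {
  out <- list()
  for (cp in comps) {
    if (adjacency$type == "sensor_freq") {
      if (length(unique(adjacency$node_channel[cp])) < min_channels) next
      if (length(unique(adjacency$node_freq[cp])) < min_freqs) next
    } else {
      if (length(cp) < min_size) next
    }
    out[[length(out) + 1]] <- list(members = sort(cp), mass = sum(tvec[cp]),
                                   sign = sign(sum(tvec[cp])))
  }
  out
}

max_cluster_mass <- function(tvec, tcrit, adjacency, min_channels, min_freqs,
                             min_size) {
  best <- 0
  for (sgn in c(1, -1)) {
    act <- which(sgn * tvec > tcrit)
    cl <- admissible_clusters(sign_components(act, adjacency$edges), tvec,
                              adjacency, min_channels, min_freqs, min_size)
    if (length(cl))
      best <- max(best, max(vapply(cl, function(x) abs(x$mass), numeric(1))))
  }
  best
}

# Null maxima for a block of permutations at once. Every permutation's
# suprathreshold subgraph is embedded in one big graph with node ids offset
# by permutation, so a single component labeling serves the whole block.
# Isolated suprathreshold nodes are ignored: no admissible cluster (>= 2
# channels and >= 2 frequencies, or >= min_size >= 2 points) is edgeless.
batch_max_cluster_mass <- function(tb, tcrit, adjacency, min_channels,
                                   min_freqs, min_size) {
  P <- nrow(tb); p <- ncol(tb)
  e1 <- adjacency$edges[, 1]; e2 <- adjacency$edges[, 2]
  sensor <- adjacency$type == "sensor_freq"
  best <- numeric(P)
  for (sgn in c(1, -1)) {
    A <- sgn * tb > tcrit
    hit <- which(A[, e1, drop = FALSE] & A[, e2, drop = FALSE],
                 arr.ind = TRUE)
    if (nrow(hit) == 0) next
    gp <- hit[, 1]; ee <- hit[, 2]
    g1 <- (gp - 1) * p + e1[ee]
    g2 <- (gp - 1) * p + e2[ee]
    verts <- sort(unique(c(g1, g2)))
    gr <- igraph::make_graph(rbind(match(g1, verts), match(g2, verts)),
                             n = length(verts), directed = FALSE)
    memb <- igraph::components(gr)$membership
    node <- (verts - 1) %% p + 1
    perm <- (verts - 1) %/% p + 1
    tv <- tb[cbind(perm, node)]
    mass <- abs(rowsum(tv, memb, reorder = TRUE)[, 1])
    size <- rowsum(rep(1, length(memb)), memb, reorder = TRUE)[, 1]
    cperm <- rowsum(perm, memb, reorder = TRUE)[, 1] / size
    if (sensor) {
      ch <- adjacency$node_channel[node]
      fr <- adjacency$node_freq[node]
      u1 <- !duplicated(memb * (p + 1) + ch)
      nch <- rowsum(rep(1, sum(u1)), memb[u1], reorder = TRUE)[, 1]
      u2 <- !duplicated(memb * (p + 51) + fr)
      nfr <- rowsum(rep(1, sum(u2)), memb[u2], reorder = TRUE)[, 1]
      ok <- nch >= min_channels & nfr >= min_freqs
    } else ok <- size >= min_size
    mass[!ok] <- 0
    o <- order(mass)                       # last write per perm wins = max
    res <- numeric(P)
    res[cperm[o]] <- mass[o]
    best <- pmax(best, res)
  }
  best
}

# Same batching for NBS: maximum component size (in edges) per permutation.
batch_max_nbs_size <- function(tb, tcrit, pairs, nroi) {
  P <- nrow(tb)
  best <- numeric(P)
  for (sgn in c(1, -1)) {
    hit <- which(sgn * tb > tcrit, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    gp <- hit[, 1]; ee <- hit[, 2]
    g1 <- (gp - 1) * nroi + pairs[ee, 1]
    g2 <- (gp - 1) * nroi + pairs[ee, 2]
    verts <- sort(unique(c(g1, g2)))
    gr <- igraph::make_graph(rbind(match(g1, verts), match(g2, verts)),
                             n = length(verts), directed = FALSE)
    memb <- igraph::components(gr)$membership
    # every component contains at least one edge, so labels 1..C all occur
    edge_comp <- memb[match(g1, verts)]
    sizes <- rowsum(rep(1, length(edge_comp)), edge_comp, reorder = TRUE)[, 1]
    vperm <- (verts - 1) %/% nroi + 1
    nvert <- rowsum(rep(1, length(memb)), memb, reorder = TRUE)[, 1]
    cperm <- rowsum(vperm, memb, reorder = TRUE)[, 1] / nvert
    o <- order(sizes)                      # last write per perm wins = max
    res <- numeric(P)
    res[cperm[o]] <- sizes[o]
    best <- pmax(best, res)
  }
  best
}

#' Cluster-based permutation test
#'
#' Elements exceeding the two-sided `element_alpha` t threshold are split by
#' sign and grouped into connected components under the adjacency graph.
#' Sensor-frequency clusters must span at least `min_channels` distinct
#' channels and `min_freqs` distinct frequency bins; source-grid clusters at
#' least `min_size` points. Cluster mass is the summed t; the null is the
#' permutation distribution of the maximum absolute admissible cluster mass,
#' and `p = (1 + #{null >= |mass|}) / (1 + n_perm)`.
#'
#' @param values subjects x elements matrix of per-subject difference maps.
#' @param group two-level grouping of length `nrow(values)`.
#' @param adjacency an `adjacency_graph` covering all elements.
#' @param element_alpha element-level threshold (default 0.05, two-sided).
#' @param n_perm number of label permutations (>= 100; default 5000).
#' @param min_channels,min_freqs sensor-frequency admissibility rule.
#' @param min_size minimum grid-cluster size (spatial-only adjacency).
#' @param seed RNG seed.
#' @param alpha family-wise significance level (default 0.05).
#' @param tail_split halve `alpha` per tail (default `FALSE`).
#' @param welch use Welch t statistics.
#' @return object of class `cluster_result`: `clusters` (members, mass,
#'   sign, p_value, significant), `element_t_map`, `t_critical`,
#'   `null_distribution`.
#' @export
cluster_permutation_test <- function(values, group, adjacency,
                                     element_alpha = 0.05, n_perm = 5000,
                                     min_channels = 2, min_freqs = 2,
                                     min_size = 2, seed = 1, alpha = 0.05,
                                     tail_split = FALSE, welch = FALSE) {
  if (n_perm < 100) stop("n_perm below 100 is refused")
  if (ncol(values) != adjacency$n_nodes)
    stop("adjacency does not cover all elements")
  group <- as.factor(group)
  tm <- element_t_map(values, group, welch = welch)
  tcrit <- qt(1 - element_alpha / 2, tm$df[1])
  clusters <- list()
  for (sgn in c(1, -1)) {
    act <- which(sgn * tm$t > tcrit)
    cl <- admissible_clusters(sign_components(act, adjacency$edges), tm$t,
                              adjacency, min_channels, min_freqs, min_size)
    clusters <- c(clusters, cl)
  }
  n <- nrow(values)
  n1 <- sum(group == levels(group)[1]); n2 <- n - n1
  null <- with_seed(seed, {
    perm_idx <- t(replicate(n_perm, sample.int(n, n1)))
    out <- numeric(n_perm)
    chunks <- split(seq_len(n_perm), ceiling(seq_len(n_perm) / 250))
    for (ch in chunks) {
      tb <- if (welch) {
        t(vapply(ch, function(i) {
          g <- rep(levels(group)[2], n); g[perm_idx[i, ]] <- levels(group)[1]
          element_t_map(values, factor(g, levels = levels(group)),
                        welch = TRUE)$t
        }, numeric(ncol(values))))
      } else perm_t_block(values, perm_idx[ch, , drop = FALSE], n1, n2)
      out[ch] <- batch_max_cluster_mass(tb, tcrit, adjacency, min_channels,
                                        min_freqs, min_size)
    }
    out
  })
  thr <- if (tail_split) alpha / 2 else alpha
  clusters <- lapply(clusters, function(cl) {
    cl$p_value <- (1 + sum(null >= abs(cl$mass))) / (1 + n_perm)
    cl$significant <- cl$p_value < thr
    cl
  })
  ord <- order(-vapply(clusters, function(x) abs(x$mass), numeric(1)))
  structure(list(clusters = clusters[ord], element_t_map = tm$t,
                 t_critical = tcrit, null_distribution = null,
                 adjacency_type = adjacency$type, alpha = thr,
                 n_perm = n_perm),
            class = "cluster_result")
}

#' Network-based statistic (NBS)
#'
#' Edge-wise two-sample t tests on Fisher-z transformed connectivity
#' differences over the unique ROI pairs; edges with `p < edge_alpha`
#' (per sign) form a pruned graph whose connected components are scored by
#' edge count and compared with the permutation null of maximum component
#' size.
#'
#' @param diff_mats subjects x rois x rois array of symmetric per-subject
#'   (last - first) connectivity difference matrices.
#' @param group two-level grouping.
#' @param edge_alpha edge threshold (default 0.005, two-sided).
#' @param n_perm permutations (>= 100; default 5000).
#' @param seed RNG seed.
#' @param alpha component-level significance (default 0.05).
#' @param roi_names optional ROI labels.
#'
#' @details Variance stabilization (Fisher z) is applied where the
#'   differences are formed: the pipeline differences `atanh(r)` between
#'   sessions before calling this test. Any symmetric per-subject
#'   difference maps are accepted.
#' @return object of class `nbs_result`: `components` (edges as m x 2 ROI
#'   index pairs, size, p_value, significant), `edge_t_map` (rois x rois),
#'   `null_distribution`.
#' @export
nbs_test <- function(diff_mats, group, edge_alpha = 0.005, n_perm = 5000,
                     seed = 1, alpha = 0.05, roi_names = NULL) {
  if (n_perm < 100) stop("n_perm below 100 is refused")
  d <- dim(diff_mats)
  if (length(d) != 3 || d[2] != d[3]) stop("diff_mats must be subjects x rois x rois")
  nroi <- d[2]
  ut <- which(upper.tri(matrix(0, nroi, nroi)))
  pairs <- arrayInd(ut, c(nroi, nroi))
  values <- t(apply(diff_mats, 1, function(m) m[ut]))
  group <- as.factor(group)
  tm <- element_t_map(values, group)
  tcrit <- qt(1 - edge_alpha / 2, tm$df[1])

  comp_of <- function(tvec) {
    res <- list()
    for (sgn in c(1, -1)) {
      eidx <- which(sgn * tvec > tcrit)
      if (!length(eidx)) next
      nodes <- sort(unique(as.vector(pairs[eidx, ])))
      comps <- sign_components(nodes, pairs[eidx, , drop = FALSE])
      for (cp in comps) {
        inset <- eidx[pairs[eidx, 1] %in% cp & pairs[eidx, 2] %in% cp]
        res[[length(res) + 1]] <- list(edges = pairs[inset, , drop = FALSE],
                                       edge_index = inset,
                                       size = length(inset), sign = sgn,
                                       mean_t = mean(tvec[inset]))
      }
    }
    res
  }
  obs <- comp_of(tm$t)
  n <- nrow(values)
  n1 <- sum(group == levels(group)[1]); n2 <- n - n1
  null <- with_seed(seed, {
    perm_idx <- t(replicate(n_perm, sample.int(n, n1)))
    out <- numeric(n_perm)
    chunks <- split(seq_len(n_perm), ceiling(seq_len(n_perm) / 250))
    for (ch in chunks) {
      tb <- perm_t_block(values, perm_idx[ch, , drop = FALSE], n1, n2)
      out[ch] <- batch_max_nbs_size(tb, tcrit, pairs, nroi)
    }
    out
  })
  obs <- lapply(obs, function(cp) {
    cp$p_value <- (1 + sum(null >= cp$size)) / (1 + n_perm)
    cp$significant <- cp$p_value < alpha
    cp
  })
  ord <- order(-vapply(obs, `[[`, numeric(1), "size"))
  tmat <- matrix(0, nroi, nroi)
  tmat[ut] <- tm$t
  tmat <- tmat + t(tmat)
  if (!is.null(roi_names)) dimnames(tmat) <- list(roi_names, roi_names)
  structure(list(components = obs[ord], edge_t_map = tmat,
                 t_critical = tcrit, null_distribution = null,
                 n_perm = n_perm, alpha = alpha, roi_names = roi_names),
            class = "nbs_result")
}

#' Pearson correlation between neural change and behaviour
#'
#' @param neural_change per-subject scalar neural change (e.g. mean power
#'   change over a significant cluster mask, last - first).
#' @param behavior per-subject scalar (practice minutes or PVC change).
#' @return list `r`, `p` (two-sided t-based), `n`.
#' @export
correlate_neural_behavior <- function(neural_change, behavior) {
  ok <- is.finite(neural_change) & is.finite(behavior)
  if (sum(ok) < 4) stop("need at least 4 complete pairs")
  if (sd(neural_change[ok]) == 0 || sd(behavior[ok]) == 0)
    stop("zero variance")
  ct <- cor.test(neural_change[ok], behavior[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
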