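# Parcellation-level summaries of statistical results and the
# percent-valid-correct (PVC) behavioural metric.

#' Summed significant t values per network
#'
#' For each of the 7 networks, sums the source-level t statistic over the
#' significant grid points whose ROI belongs to that network. The network
#' sums partition the total masked t sum.
#'
#' @param source_t_map t value per grid point.
#' @param significant_mask logical or index mask of significant grid points.
#' @param parcellation a `parcellation`.
#' @return named numeric vector, one entry per network (fixed 7-label
#'   enumeration).
#' @export
summed_t_by_network <- function(source_t_map, significant_mask, parcellation) {
  if (is.logical(significant_mask)) significant_mask <- which(significant_mask)
  nets <- parcellation$networks
  out <- setNames(numeric(length(nets)), nets)
  if (length(significant_mask) == 0) return(out)
  roi <- parcellation$roi_of_grid[significant_mask]
  net <- parcellation$network_of_roi[roi]
  s <- tapply(source_t_map[significant_mask], factor(net, levels = nets), sum)
  out[names(s)] <- ifelse(is.na(s), 0, s)
  out
}

#' Mean degree per network of an NBS component
#'
#' Counts, per network, the edge endpoints falling in that network and
#' divides by the number of ROIs assigned to it (the raw endpoint tally is
#' attached as an attribute so alternative normalizations can be
#' recomputed).
#'
#' @param component m x 2 matrix of ROI index pairs (an NBS component's
#'   edge set).
#' @param parcellation a `parcellation`.
#' @return named numeric vector per network, with attribute `endpoints`.
#' @export
mean_degree_by_network <- function(component, parcellation) {
  nets <- parcellation$networks
  roi_net <- factor(parcellation$network_of_roi, levels = nets)
  n_roi_net <- table(roi_net)
  out <- setNames(numeric(length(nets)), nets)
  ep <- setNames(numeric(length(nets)), nets)
  if (length(component)) {
    endnet <- table(factor(parcellation$network_of_roi[as.vector(component)],
                           levels = nets))
    ep[] <- as.numeric(endnet)
    out[] <- as.numeric(endnet) / pmax(as.numeric(n_roi_net), 1)
  }
  attr(out, "endpoints") <- ep
  out
}

#' Mean connectivity strength over a component, per group and session
#'
#' Averages the connectivity values over the component's edges per subject,
#' then averages within each group x session cell.
#'
#' @param component m x 2 matrix of ROI index pairs (non-empty).
#' @param conn_list list of per-subject-session `connectivity_matrix`
#'   objects (or plain matrices).
#' @param meta data.frame with one row per element of `conn_list`:
#'   `subject`, `group`, `session` (values `"first"`/`"last"`).
#' @return data.frame with `group`, `session`, `mean_r`; per-subject means
#'   attached as attribute `per_subject`.
#' @export
mean_strength_change <- function(component, conn_list, meta) {
  if (is.null(dim(component)) || nrow(component) == 0)
    stop("empty component")
  per <- vapply(conn_list, function(cm) {
    m <- if (inherits(cm, "connectivity_matrix")) cm$values else cm
    mean(m[component])
  }, numeric(1))
  ps <- cbind(meta, mean_r = per)
  agg <- stats::aggregate(mean_r ~ group + session, data = ps, FUN = mean)
  attr(agg, "per_subject") <- ps
  agg
}

#' Percent valid correct (PVC)
#'
#' `PVC = hits / (hits + misses)`: hits over non-timeout trials. Undefined
#' (NA, flagged) when every trial timed out.
#'
#' @param behavior data.frame with columns `hits`, `misses`, `timeouts`
#'   (and any identifier columns, which are carried through).
#' @return the input with a `pvc` column appended.
#' @export
compute_pvc <- function(behavior) {
  h <- behavior$hits; m <- behavior$misses; to <- behavior$timeouts
  if (any(h < 0 | m < 0 | to < 0)) stop("negative counts")
  valid <- h + m
  pvc <- ifelse(valid > 0, h / valid, NA_real_)
  if (any(valid == 0))
    warning(sum(valid == 0), " session(s) with all trials timed out (PVC undefined)")
  behavior$pvc <- pvc
  behavior
}
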