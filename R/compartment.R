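#' Mitochondrial volume density
#'
#' The proportion of a compartment's intracellular volume occupied by
#' mitochondria: `sum(mito_volumes) / compartment_volume`. For somata the
#' denominator is the total soma volume, nucleus included (somatic density
#' panels are normalized to total cellular volume).
#'
#' @param mito_volumes numeric vector of per-organelle volumes, um^3.
#' @param compartment_volume compartment volume, um^3 (> 0).
#' @return a fraction in `[0, 1]`.
#' @export
mitochondrial_volume_density <- function(mito_volumes, compartment_volume) {
  if (!is.finite(compartment_volume) || compartment_volume <= 0)
    stop("compartment volume must be positive", call. = FALSE)
  if (length(mito_volumes) == 0) return(0)
  if (any(mito_volumes < 0)) stop("negative mitochondrial volume", call. = FALSE)
  s <- sum(mito_volumes)
  if (s > compartment_volume * (1 + 1e-9))
    stop("mitochondrial volume exceeds the compartment volume: mis-assigned labels?",
         call. = FALSE)
  min(s / compartment_volume, 1)
}

#' Tube diameter from a distance-transform centerline
#'
#' Measures the diameter of an elongated compartment (axon or dendrite) the
#' way a caliper would: a centerline is traced through the tube, and at
#' `n_points` equally spaced arc-length positions the local diameter is
#' taken as twice the radius of the maximal inscribed ball (the anisotropic
#' Euclidean distance transform, in physical units). The mean of the
#' per-point values is the reported diameter.
#'
#' The centerline is the geodesic between the two mutually farthest
#' foreground voxels, computed with edge costs penalized away from the
#' medial axis so the path hugs the tube center, then trimmed at both ends
#' where the inscribed ball becomes limited by the end caps rather than the
#' tube wall. A structure that is not elongated (trimmed centerline shorter
#' than twice its own width, e.g. a sphere) raises an insufficient-length
#' error.
#'
#' @param mask logical 3D array: one connected tubular component.
#' @param grid a [voxel_grid()].
#' @param n_points number of measurement points along the centerline.
#' @return list with `mean_um`, `points_um` (the per-point diameters),
#'   `length_um` (trimmed centerline length).
#' @export
measure_diameter <- function(mask, grid, n_points = 10) {
  if (!is.array(mask) || length(dim(mask)) != 3)
    stop("`mask` must be a logical 3D array", call. = FALSE)
  mask <- as.logical(mask)
  dim(mask) <- grid$dims
  cc <- cpp_cc_label(mask, grid$dims)
  if (cc$n != 1L)
    stop("diameter is defined for a single connected component (found ", cc$n, ")",
         call. = FALSE)
  sp <- spacing_um(grid)
  r_local <- sqrt(cpp_sqedt(mask, grid$dims, sp))
  fg <- which(mask)
  far <- function(src) {
    g <- cpp_dijkstra(mask, grid$dims, sp, src - 1L, numeric(0))
    d <- g$dist
    d[!is.finite(d)] <- -1
    list(idx = which.max(d), res = g)
  }
  e1 <- far(fg[1])$idx
  e2 <- far(e1)$idx
  rmax <- max(r_local[fg])
  cost <- rep(1, length(mask))
  cost[fg] <- 1 + 20 * (rmax - r_local[fg]) / rmax
  g <- cpp_dijkstra(mask, grid$dims, sp, e1 - 1L, cost)
  path <- integer(0)
  v <- e2
  while (v != 0L) {
    path <- c(path, v)
    v <- g$parent[v]
  }
  if (path[length(path)] != e1)
    stop("no centerline path found", call. = FALSE)
  ijk <- arrayInd(path, grid$dims)
  pts <- sweep(ijk - 0.5, 2, sp, "*")
  steps <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  arc <- c(0, cumsum(steps))
  # the discrete path zigzags within a voxel of the medial axis; taking the
  # neighbourhood max of the distance transform recenters each sample on it
  d <- grid$dims
  rp <- vapply(seq_len(nrow(ijk)), function(t) {
    i <- ijk[t, 1]; j <- ijk[t, 2]; k <- ijk[t, 3]
    ii <- max(1, i - 1):min(d[1], i + 1)
    jj <- max(1, j - 1):min(d[2], j + 1)
    kk <- max(1, k - 1):min(d[3], k + 1)
    nb <- as.vector(outer(ii, outer((jj - 1) * d[1], (kk - 1) * d[1] * d[2], "+"), "+"))
    max(r_local[nb])
  }, numeric(1))
  keep <- which(rp >= 0.9 * max(rp))
  sub <- keep[1]:keep[length(keep)]
  len <- arc[sub[length(sub)]] - arc[sub[1]]
  if (length(sub) < n_points || len < 4 * max(rp))
    stop(structure(class = c("mitomorph_length_error", "error", "condition"),
                   list(message = paste0(
                     "structure is not elongated enough for a diameter profile ",
                     sprintf("(centerline %.3g um vs width %.3g um)", len, 2 * max(rp))),
                     call = NULL)))
  targets <- arc[sub[1]] + (seq_len(n_points) - 0.5) / n_points * len
  d_pts <- 2 * stats::approx(arc[sub], rp[sub], xout = targets, ties = "ordered")$y
  list(mean_um = mean(d_pts), points_um = d_pts, length_um = len)
}

#' Decompose a soma into nucleus, cytoplasm and mitochondria
#'
#' Voxel-exact partition of a soma: the cytoplasmic volume is the soma
#' volume with the nucleus and the mitochondria removed, so
#' `nucleus + cytoplasm + mitochondria = soma` holds exactly in voxel
#' units and the three fractions sum to 1. Containment violations (nucleus
#' or mitochondria outside the soma, or overlapping each other) signal
#' mis-assigned labels and raise a consistency error.
#'
#' @param soma_mask logical 3D array of the whole soma (everything inside
#'   the plasma membrane).
#' @param nucleus_mask logical 3D array, subset of `soma_mask`.
#' @param mito_labels integer 3D array of mitochondrial labels (0
#'   elsewhere), subset of `soma_mask`, disjoint from the nucleus.
#' @param grid a [voxel_grid()].
#' @return list with the four volumes (um^3), the mitochondrion count and
#'   the `fractions` (nucleus, cytoplasm, mitochondria; sum to 1).
#' @export
soma_decomposition <- function(soma_mask, nucleus_mask, mito_labels, grid) {
  soma_mask <- as.logical(soma_mask)
  nucleus_mask <- as.logical(nucleus_mask)
  mito <- mito_labels > 0L
  if (any(nucleus_mask & !soma_mask))
    stop("containment violation: nucleus voxels outside the soma", call. = FALSE)
  if (any(mito & !soma_mask))
    stop("containment violation: mitochondrial voxels outside the soma", call. = FALSE)
  if (any(mito & nucleus_mask))
    stop("containment violation: mitochondria overlap the nucleus", call. = FALSE)
  vox <- voxel_volume_um3(grid)
  n_soma <- sum(soma_mask)
  n_nuc <- sum(nucleus_mask)
  n_mito <- sum(mito)
  vols <- c(soma = n_soma, nucleus = n_nuc, mito = n_mito,
            cytoplasm = n_soma - n_nuc - n_mito) * vox
  fr <- c(nucleus = n_nuc, cytoplasm = n_soma - n_nuc - n_mito, mito = n_mito) / n_soma
  list(soma_volume_um3 = vols[["soma"]],
       nucleus_volume_um3 = vols[["nucleus"]],
       cytoplasm_volume_um3 = vols[["cytoplasm"]],
       mito_volume_um3 = vols[["mito"]],
       n_mito = length(unique(mito_labels[mito])),
       fractions = fr)
}
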