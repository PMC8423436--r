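#' Label connected foreground components
#'
#' 26-connected component labelling of a binary foreground mask (the
#' standard complementary pair: 26 for foreground, 6 for background).
#' Components with any voxel on a grid face are flagged `touches_boundary`,
#' since structures not completely inside the imaged volume are excluded
#' from analysis downstream. An empty mask yields an empty labelling, not an
#' error.
#'
#' @param mask logical 3D array.
#' @param grid a [voxel_grid()] matching `dim(mask)`.
#' @return a [label_volume()]; `attr(, "components")` holds a data frame
#'   with `label`, `n_voxels`, `touches_boundary`.
#' @export
label_components <- function(mask, grid) {
  if (!is.array(mask) || length(dim(mask)) != 3)
    stop("`mask` must be a logical 3D array", call. = FALSE)
  if (!identical(as.integer(dim(mask)), grid$dims))
    stop("mask dimensions do not match the grid", call. = FALSE)
  cc <- cpp_cc_label(as.logical(mask), grid$dims)
  labels <- array(cc$labels, grid$dims)
  roles <- if (cc$n > 0)
    stats::setNames(rep("mitochondrion", cc$n), seq_len(cc$n)) else character(0)
  vol <- label_volume(labels, grid, roles = roles)
  attr(vol, "components") <- data.frame(
    label = seq_len(cc$n),
    n_voxels = cc$counts,
    touches_boundary = cc$touches)
  vol
}

#' Volume of one labeled component
#'
#' Voxel count times the physical voxel volume (`sx sy sz` nm^3), reported
#' in um^3.
#'
#' @param volume a [label_volume()].
#' @param label label id present in the volume.
#' @return volume in um^3.
#' @examples
#' # 200,000 voxels at 10 x 10 x 50 nm are exactly 1 um^3
#' @export
component_volume <- function(volume, label) {
  stopifnot(inherits(volume, "label_volume"))
  n <- sum(volume$labels == as.integer(label))
  if (n == 0L) stop("label ", label, " is not present in the volume", call. = FALSE)
  n * voxel_volume_um3(volume$grid)
}

#' Surface area of one labeled component
#'
#' Extracts the 0.5 iso-surface of the (optionally Gaussian pre-smoothed)
#' binary field with the physical anisotropic spacing applied, and sums the
#' triangle areas. A single isolated voxel has no interior iso-surface and
#' falls back to its physical box area, with a warning.
#'
#' @inheritParams extract_mesh
#' @return surface area in um^2.
#' @export
component_surface_area <- function(volume, label, smooth = TRUE,
                                   sigma_vox = c(1.5, 1.5, 1.5)) {
  stopifnot(inherits(volume, "label_volume"))
  n <- sum(volume$labels == as.integer(label))
  if (n == 0L) stop("label ", label, " is not present in the volume", call. = FALSE)
  if (n == 1L) {
    warning("single-voxel component: reporting the voxel box area")
    s <- spacing_um(volume$grid)
    return(2 * (s[1] * s[2] + s[2] * s[3] + s[1] * s[3]))
  }
  mesh <- extract_mesh(volume, label, smooth = smooth, sigma_vox = sigma_vox)
  mesh_area(mesh)
}

#' Surface mesh metrics
#'
#' `mesh_area()` sums triangle areas (um^2). `mesh_volume()` integrates the
#' enclosed volume by the divergence theorem over the oriented surface
#' (um^3). `mesh_euler()` returns the Euler characteristic
#' `chi = V - E + F`; `mesh_genus()` converts it to the genus
#' `(2 - chi) / 2` of a closed surface, and `is_watertight()` checks that
#' every edge is shared by exactly two faces (genus is undefined otherwise).
#'
#' @param mesh a `surface_mesh` from [extract_mesh()].
#' @return a scalar.
#' @name mesh-metrics
NULL

#' @rdname mesh-metrics
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' @rdname mesh-metrics
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  abs(sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) +
          p1[, 2] * (p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3]) +
          p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1]))) / 6
}

mesh_edge_keys <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  lo <- pmin(e[, 1], e[, 2])
  hi <- pmax(e[, 1], e[, 2])
  as.numeric(lo) * (nrow(mesh$vertices) + 1) + hi
}

#' @rdname mesh-metrics
#' @export
mesh_euler <- function(mesh) {
  n_edges <- length(unique(mesh_edge_keys(mesh)))
  nrow(mesh$vertices) - n_edges + nrow(mesh$faces)
}

#' @rdname mesh-metrics
#' @export
is_watertight <- function(mesh) {
  all(tabulate(match(mesh_edge_keys(mesh), unique(mesh_edge_keys(mesh)))) == 2L)
}

#' @rdname mesh-metrics
#' @export
mesh_genus <- function(mesh) {
  if (!is_watertight(mesh)) return(NA_integer_)
  as.integer((2 - mesh_euler(mesh)) / 2)
}

#' Topology class of an organelle surface
#'
#' Genus of the closed surface mesh; genus >= 1 flags the organelle as a
#' "donut" (toroidal) mitochondrion, an organelle that has looped and fused
#' with itself. Non-watertight meshes have undefined topology and report a
#' missing genus.
#'
#' @param mesh a `surface_mesh`.
#' @return list with `euler`, `genus` (NA if not watertight) and `donut`.
#' @export
classify_topology <- function(mesh) {
  g <- mesh_genus(mesh)
  list(euler = mesh_euler(mesh), genus = g,
       donut = if (is.na(g)) NA else g >= 1L)
}
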