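#' Anisotropic voxel grid
#'
#' Physical geometry of a 3D image stack: voxel spacing in nanometres and
#' voxel counts along x, y and z. Serial block-face stacks are strongly
#' anisotropic (the default spacing, 10 x 10 x 50 nm, has z sections five
#' times thicker than the in-plane pixels), and every measurement in the
#' package carries this spacing through to physical units.
#'
#' The voxel with 1-based array index `(i, j, k)` has its center at
#' `((i - 0.5) sx, (j - 0.5) sy, (k - 0.5) sz)` nm.
#'
#' @param spacing_nm numeric length-3, voxel spacing `(sx, sy, sz)` in nm;
#'   all strictly positive.
#' @param dims integer length-3, voxel counts `(nx, ny, nz)`; all >= 1.
#' @return an object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(10, 10, 50), c(64, 64, 16))
#' voxel_volume_um3(g) * prod(g$dims)  # physical volume of the stack
#' @export
voxel_grid <- function(spacing_nm = c(10, 10, 50), dims) {
  spacing_nm <- as.numeric(spacing_nm)
  if (length(spacing_nm) != 3 || anyNA(spacing_nm) || any(spacing_nm <= 0))
    stop("`spacing_nm` must be three strictly positive values (nm)", call. = FALSE)
  dims <- as.integer(dims)
  if (length(dims) != 3 || anyNA(dims) || any(dims < 1))
    stop("`dims` must be three voxel counts, each >= 1", call. = FALSE)
  structure(list(spacing_nm = spacing_nm, dims = dims), class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels at %g x %g x %g nm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing_nm[1], x$spacing_nm[2], x$spacing_nm[3]))
  invisible(x)
}

#' Physical volume of one voxel in cubic micrometres
#' @param grid a [voxel_grid()].
#' @return scalar, um^3 per voxel.
#' @export
voxel_volume_um3 <- function(grid) prod(grid$spacing_nm) / 1e9

# spacing in um (internal geometry unit)
spacing_um <- function(grid) grid$spacing_nm / 1e3

# voxel-center coordinates (um) along one axis
axis_coords_um <- function(grid, axis) {
  (seq_len(grid$dims[axis]) - 0.5) * grid$spacing_nm[axis] / 1e3
}

#' Labeled volume
#'
#' A 3D integer label field plus its [voxel_grid()]. Label 0 is background.
#' `roles` maps every nonzero label to a structure class: `"mitochondrion"`,
#' `"compartment"` (axon/dendrite shaft or soma cytoplasm) or `"nucleus"`;
#' `meta` carries per-stack metadata (region, compartment type, age group,
#' seed).
#'
#' @param labels integer 3D array (non-negative; 0 = background).
#' @param grid a [voxel_grid()]; dims must match `dim(labels)`.
#' @param roles named character vector, names = label ids as character,
#'   values in `mitochondrion|compartment|nucleus`. Defaults to
#'   `"mitochondrion"` for every label present.
#' @param meta list of free-form stack metadata.
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(labels, grid, roles = NULL, meta = list()) {
  if (!is.array(labels) || length(dim(labels)) != 3)
    stop("`labels` must be a 3D array", call. = FALSE)
  if (!identical(as.integer(dim(labels)), grid$dims))
    stop("label field dimensions do not match the grid", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (any(labels < 0L, na.rm = TRUE) || anyNA(labels))
    stop("labels must be non-negative integers", call. = FALSE)
  present <- sort(unique(labels[labels > 0L]))
  if (is.null(roles)) {
    roles <- stats::setNames(rep("mitochondrion", length(present)), as.character(present))
  } else {
    roles <- unlist(roles)
    bad <- setdiff(roles, c("mitochondrion", "compartment", "nucleus"))
    if (length(bad))
      stop("unknown structure roles: ", paste(unique(bad), collapse = ", "), call. = FALSE)
    missing <- setdiff(as.character(present), names(roles))
    if (length(missing))
      stop("role map does not cover labels: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(grid = grid, labels = labels, roles = roles, meta = meta),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  n <- length(x$roles)
  cat(sprintf("<label_volume> %d labeled structure%s (%s)\n", n,
              if (n == 1) "" else "s",
              paste(names(table(x$roles)), table(x$roles), sep = ":", collapse = ", ")))
  print(x$grid)
  invisible(x)
}

#' Label ids present in a volume, optionally filtered by role
#' @param volume a [label_volume()].
#' @param role optional role filter (`"mitochondrion"`, `"compartment"`,
#'   `"nucleus"`).
#' @return integer vector of label ids.
#' @export
labels_present <- function(volume, role = NULL) {
  ids <- as.integer(names(volume$roles))
  if (!is.null(role)) ids <- ids[volume$roles == role]
  sort(ids)
}
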