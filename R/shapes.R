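#' Shape phantoms with closed-form ground truth
#'
#' Constructors for the implicit solids used as mitochondrial phantoms.
#' Spheres, capsules (cylinder with hemispherical caps) and tori have
#' closed-form volume and surface area, which makes them exact oracles for
#' voxel-based measurement; the branched tube (a trunk capsule with one side
#' branch) emulates branched organelles and reports its volume by voxel
#' count only.
#'
#' All lengths are in micrometres. `center` is the shape center; `axis` its
#' symmetry axis (normalized internally).
#'
#' @param r radius (sphere, capsule tube, torus tube, branched-tube tube), um.
#' @param L capsule cylinder length (caps excluded), um.
#' @param R torus ring (center-line) radius, um; must exceed `r`.
#' @param trunk_length,branch_length branched tube trunk / branch lengths, um.
#' @param branch_angle_deg angle between trunk axis and branch, degrees.
#' @param center numeric length-3 position, um.
#' @param axis numeric length-3 direction (need not be unit length).
#' @return an object of class `shape_spec`.
#' @name shapes
NULL

new_shape <- function(kind, params, center, axis) {
  center <- as.numeric(center)
  axis <- as.numeric(axis)
  if (length(center) != 3 || anyNA(center))
    stop("`center` must be a 3D position", call. = FALSE)
  nrm <- sqrt(sum(axis^2))
  if (length(axis) != 3 || !is.finite(nrm) || nrm == 0)
    stop("`axis` must be a nonzero 3D direction", call. = FALSE)
  if (any(!is.finite(unlist(params))) || any(unlist(params) <= 0))
    stop("all shape dimensions must be strictly positive", call. = FALSE)
  structure(list(kind = kind, params = params, center = center, axis = axis / nrm),
            class = "shape_spec")
}

#' @rdname shapes
#' @export
shape_sphere <- function(r, center = c(0, 0, 0), axis = c(0, 0, 1)) {
  new_shape("sphere", list(r = r), center, axis)
}

#' @rdname shapes
#' @export
shape_capsule <- function(r, L, center = c(0, 0, 0), axis = c(1, 0, 0)) {
  new_shape("capsule", list(r = r, L = L), center, axis)
}

#' @rdname shapes
#' @export
shape_torus <- function(R, r, center = c(0, 0, 0), axis = c(0, 0, 1)) {
  if (R <= r) stop("torus requires R > r (no self-intersection)", call. = FALSE)
  new_shape("torus", list(R = R, r = r), center, axis)
}

#' @rdname shapes
#' @export
shape_branched_tube <- function(r, trunk_length, branch_length = trunk_length / 2,
                                branch_angle_deg = 60,
                                center = c(0, 0, 0), axis = c(1, 0, 0)) {
  if (branch_angle_deg <= 0 || branch_angle_deg >= 180)
    stop("branch angle must lie strictly between 0 and 180 degrees", call. = FALSE)
  new_shape("branched_tube",
            list(r = r, trunk_length = trunk_length, branch_length = branch_length,
                 branch_angle_deg = branch_angle_deg),
            center, axis)
}

#' @export
print.shape_spec <- function(x, ...) {
  cat(sprintf("<shape_spec> %s (%s) at (%.3g, %.3g, %.3g) um\n", x$kind,
              paste(names(x$params), signif(unlist(x$params), 4), sep = "=", collapse = ", "),
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

# a unit vector perpendicular to u (deterministic)
perp_unit <- function(u) {
  ref <- if (abs(u[2]) < 0.9) c(0, 1, 0) else c(1, 0, 0)
  w <- ref - sum(ref * u) * u
  w / sqrt(sum(w^2))
}

# branch direction of a branched tube
branch_axis <- function(shape) {
  a <- shape$params$branch_angle_deg * pi / 180
  u <- shape$axis
  cos(a) * u + sin(a) * perp_unit(u)
}

#' Closed-form volume of a shape phantom
#'
#' Sphere `4/3 pi r^3`; capsule `pi r^2 L + 4/3 pi r^3`; torus
#' `2 pi^2 R r^2`. Branched tubes have no closed form (the trunk/branch
#' union is measured by voxel count) and return `NA`.
#'
#' @param shape a `shape_spec`.
#' @return volume in um^3, or `NA` for branched tubes.
#' @export
analytic_volume <- function(shape) {
  p <- shape$params
  switch(shape$kind,
    sphere = 4 / 3 * pi * p$r^3,
    capsule = pi * p$r^2 * p$L + 4 / 3 * pi * p$r^3,
    torus = 2 * pi^2 * p$R * p$r^2,
    branched_tube = NA_real_)
}

#' Closed-form surface area of a shape phantom
#'
#' Sphere `4 pi r^2`; capsule `2 pi r L + 4 pi r^2`; torus `4 pi^2 R r`.
#' Undefined (`NA`) for branched tubes.
#'
#' @param shape a `shape_spec`.
#' @return surface area in um^2, or `NA` for branched tubes.
#' @export
analytic_surface_area <- function(shape) {
  p <- shape$params
  switch(shape$kind,
    sphere = 4 * pi * p$r^2,
    capsule = 2 * pi * p$r * p$L + 4 * pi * p$r^2,
    torus = 4 * pi^2 * p$R * p$r,
    branched_tube = NA_real_)
}

# nominal volume used for population targeting; approximates the trunk/branch
# union for branched tubes (overlap taken as one ball at the junction)
nominal_volume <- function(shape) {
  v <- analytic_volume(shape)
  if (!is.na(v)) return(v)
  p <- shape$params
  v_trunk <- pi * p$r^2 * p$trunk_length + 4 / 3 * pi * p$r^3
  v_branch <- pi * p$r^2 * p$branch_length + 4 / 3 * pi * p$r^3
  v_trunk + v_branch - 4 / 3 * pi * p$r^3
}

# conservative axis-aligned bounding box (um): 3 x 2 matrix (min, max)
shape_bbox <- function(shape) {
  p <- shape$params
  u <- abs(shape$axis)
  half <- switch(shape$kind,
    sphere = rep(p$r, 3),
    capsule = u * p$L / 2 + p$r,
    torus = {
      s <- sqrt(pmax(0, 1 - u^2))
      (p$R + p$r) * s + p$r * u
    },
    branched_tube = {
      h1 <- u * p$trunk_length / 2 + p$r
      v <- abs(branch_axis(shape))
      h2 <- pmax(v * p$branch_length + p$r, p$r)
      pmax(h1, h2)
    })
  cbind(shape$center - half, shape$center + half)
}

# squared distance from points to a segment a--b (vectorized over points)
dist2_segment <- function(X, Y, Z, a, b) {
  d <- b - a
  len2 <- sum(d^2)
  qx <- X - a[1]; qy <- Y - a[2]; qz <- Z - a[3]
  t <- (qx * d[1] + qy * d[2] + qz * d[3]) / len2
  t[t < 0] <- 0
  t[t > 1] <- 1
  (qx - t * d[1])^2 + (qy - t * d[2])^2 + (qz - t * d[3])^2
}

# inside test on coordinate arrays (um)
shape_inside <- function(shape, X, Y, Z) {
  p <- shape$params
  c0 <- shape$center
  u <- shape$axis
  switch(shape$kind,
    sphere = (X - c0[1])^2 + (Y - c0[2])^2 + (Z - c0[3])^2 <= p$r^2,
    capsule = {
      a <- c0 - u * p$L / 2
      b <- c0 + u * p$L / 2
      dist2_segment(X, Y, Z, a, b) <= p$r^2
    },
    torus = {
      qx <- X - c0[1]; qy <- Y - c0[2]; qz <- Z - c0[3]
      h <- qx * u[1] + qy * u[2] + qz * u[3]
      rho2 <- pmax(0, qx^2 + qy^2 + qz^2 - h^2)
      (sqrt(rho2) - p$R)^2 + h^2 <= p$r^2
    },
    branched_tube = {
      a <- c0 - u * p$trunk_length / 2
      b <- c0 + u * p$trunk_length / 2
      inside <- dist2_segment(X, Y, Z, a, b) <= p$r^2
      v <- branch_axis(shape)
      inside | (dist2_segment(X, Y, Z, c0, c0 + v * p$branch_length) <= p$r^2)
    })
}

# voxelize into a logical sub-array; returns NULL if the shape (with one
# voxel margin) does not fit in the grid
voxelize_submask <- function(shape, grid) {
  bb <- shape_bbox(shape)
  sp <- spacing_um(grid)
  # voxel index range whose centers could fall inside the bbox
  i0 <- floor(bb[, 1] / sp + 0.5) + 1
  i1 <- ceiling(bb[, 2] / sp + 0.5)
  if (any(i0 < 2) || any(i1 > grid$dims - 1)) return(NULL)
  ix <- i0[1]:i1[1]; iy <- i0[2]:i1[2]; iz <- i0[3]:i1[3]
  xs <- (ix - 0.5) * sp[1]; ys <- (iy - 0.5) * sp[2]; zs <- (iz - 0.5) * sp[3]
  nx <- length(ix); ny <- length(iy); nz <- length(iz)
  X <- array(xs, c(nx, ny, nz))
  Y <- array(rep(ys, each = nx), c(nx, ny, nz))
  Z <- array(rep(zs, each = nx * ny), c(nx, ny, nz))
  m <- shape_inside(shape, X, Y, Z)
  if (!any(m)) {
    # degenerate: thinner than the grid can resolve; keep the center voxel
    ci <- pmin(pmax(floor(shape$center / sp) + 1, 1), grid$dims)
    return(list(ix = ci[1], iy = ci[2], iz = ci[3],
                mask = array(TRUE, c(1, 1, 1))))
  }
  list(ix = ix, iy = iy, iz = iz, mask = m)
}

#' Voxelize a shape phantom onto a grid
#'
#' A voxel is assigned to the shape iff its center lies inside the implicit
#' solid (center-point inclusion, matching binary segmentation semantics).
#' The voxel-count volume converges to the closed form as spacing shrinks. A
#' shape thinner than the grid can resolve still sets its center voxel. The
#' shape must fit entirely inside the grid with at least one voxel of
#' background margin on every face; shapes exceeding the bounds raise an
#' error rather than being clipped, because edge-touching structures are
#' excluded from analysis downstream.
#'
#' @param shape a `shape_spec`.
#' @param grid a [voxel_grid()].
#' @param label positive integer label to assign.
#' @return a [label_volume()] with the single labeled object.
#' @examples
#' g <- voxel_grid(c(10, 10, 50), c(120, 120, 24))
#' v <- voxelize_shape(shape_sphere(0.5, center = c(0.6, 0.6, 0.6)), g)
#' component_volume(v, 1)  # close to 4/3 * pi * 0.5^3
#' @export
voxelize_shape <- function(shape, grid, label = 1L) {
  label <- as.integer(label)
  if (is.na(label) || label < 1L) stop("`label` must be a positive integer", call. = FALSE)
  sub <- voxelize_submask(shape, grid)
  if (is.null(sub))
    stop(sprintf("shape does not fit inside the grid with a 1-voxel margin (bbox %s um)",
                 paste(apply(signif(shape_bbox(shape), 4), 1,
                             function(r) paste0("[", r[1], ",", r[2], "]")),
                       collapse = " x ")),
         call. = FALSE)
  labels <- array(0L, grid$dims)
  labels[sub$ix, sub$iy, sub$iz][sub$mask] <- label
  label_volume(labels, grid,
               roles = stats::setNames("mitochondrion", label),
               meta = list(shape = shape))
}
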