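#' Build a synthetic compartment scene
#'
#' Renders one neuronal compartment phantom (a straight tubular axon or
#' dendrite, or an ellipsoidal soma containing one ellipsoidal nucleus) and
#' packs a sampled mitochondrial population into it: every organelle lies
#' fully inside the compartment, outside the nucleus, pairwise
#' non-overlapping (rejection sampling), and never touches a grid face.
#' Axonal and dendritic organelles are oriented roughly along the tube axis
#' (as in tissue); somatic organelles are oriented uniformly.
#'
#' In the emitted label field, label 1 is the plain compartment interior
#' (cytoplasm for a soma), label 2 the nucleus (soma only), and labels 3
#' onward the mitochondria, so the compartment mask is `labels != 0` and the
#' soma partition cytoplasm + nucleus + mitochondria = soma holds voxel
#' exactly by construction.
#'
#' @param compartment `"axon"`, `"dendrite"` or `"soma"`.
#' @param cfg a [population_config()].
#' @param grid a [voxel_grid()].
#' @param seed integer seed (defaults to the config seed).
#' @param region,age free-form group tags recorded in the metadata.
#' @param geometry optional list overriding the compartment geometry:
#'   `radius_um` (tube radius; default 0.5 axon, 0.8 dendrite),
#'   `semi_axes_um` (soma ellipsoid semi-axes; default fits the grid),
#'   `nucleus_scale` (nucleus semi-axes as a fraction of the soma's,
#'   default 0.7, i.e. a nucleus occupying ~1/3 of the soma).
#' @param max_attempts rejection-sampling cap per organelle; exhausting it
#'   raises a packing error reporting the achieved count.
#' @return list with elements `volume` (a [label_volume()]) and `manifest`
#'   (list with per-object ground truth data frame `objects` and compartment
#'   ground truth `compartment`).
#' @examples
#' g <- voxel_grid(c(100, 100, 100), c(160, 24, 24))
#' sc <- build_compartment_scene("axon", population_config(5, 0.12, seed = 1), g)
#' sc$manifest$compartment$diameter_um
#' @export
build_compartment_scene <- function(compartment = c("axon", "dendrite", "soma"),
                                    cfg, grid, seed = cfg$seed,
                                    region = NA_character_, age = NA_character_,
                                    geometry = list(), max_attempts = 10000) {
  compartment <- match.arg(compartment)
  stopifnot(inherits(cfg, "population_config"))
  sp <- spacing_um(grid)
  ext <- grid$dims * sp   # physical extent, um
  xs <- axis_coords_um(grid, 1)
  ys <- axis_coords_um(grid, 2)
  zs <- axis_coords_um(grid, 3)
  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
  X <- array(xs, c(nx, ny, nz))
  Y <- array(rep(ys, each = nx), c(nx, ny, nz))
  Z <- array(rep(zs, each = nx * ny), c(nx, ny, nz))

  nucleus <- NULL
  if (compartment %in% c("axon", "dendrite")) {
    radius <- geometry$radius_um %||% if (compartment == "axon") 0.5 else 0.8
    # axis on a voxel center: keeps the distance-transform caliper unbiased
    cy <- (ceiling(ny / 2) - 0.5) * sp[2]
    cz <- (ceiling(nz / 2) - 0.5) * sp[3]
    if (radius + 2 * max(sp) > min(ext[2], ext[3]) / 2)
      stop("tube radius does not fit the grid cross-section", call. = FALSE)
    x0 <- 1.5 * sp[1]; x1 <- ext[1] - 1.5 * sp[1]
    comp <- (Y - cy)^2 + (Z - cz)^2 <= radius^2 & X >= x0 & X <= x1
    comp_truth <- list(type = compartment, radius_um = radius,
                       diameter_um = 2 * radius, length_um = x1 - x0)
  } else {
    ctr <- ext / 2
    semi <- geometry$semi_axes_um %||% (ext / 2 - 2 * sp) * 0.95
    if (any(semi <= 0) || any(semi + 2 * sp > ext / 2))
      stop("soma semi-axes do not fit the grid", call. = FALSE)
    nuc_scale <- geometry$nucleus_scale %||% 0.7
    comp <- ((X - ctr[1]) / semi[1])^2 + ((Y - ctr[2]) / semi[2])^2 +
      ((Z - ctr[3]) / semi[3])^2 <= 1
    nsemi <- semi * nuc_scale
    # concentric nucleus: keeps the cytoplasmic shell thickness uniform
    nucleus <- ((X - ctr[1]) / nsemi[1])^2 +
      ((Y - ctr[2]) / nsemi[2])^2 +
      ((Z - ctr[3]) / nsemi[3])^2 <= 1
    nucleus <- nucleus & comp
    comp_truth <- list(type = "soma", semi_axes_um = semi,
                       nucleus_scale = nuc_scale)
  }

  specs <- sample_population(cfg, seed = seed)
  if (compartment == "soma") {
    max_r <- geometry$max_object_radius_um %||%
      (0.35 * (1 - (geometry$nucleus_scale %||% 0.7)) * min(comp_truth$semi_axes_um))
    max_hw <- 2.5 * max_r
  } else {
    max_r <- geometry$max_object_radius_um %||% (0.6 * comp_truth$radius_um)
    max_hw <- 0.8 * comp_truth$radius_um
  }
  specs <- lapply(specs, confine_spec, max_r = max_r, max_hw = max_hw)
  ord <- order(vapply(specs, function(s) attr(s, "target_volume_um3"), numeric(1)),
               decreasing = TRUE)
  specs <- specs[ord]

  labels <- array(0L, grid$dims)
  labels[comp] <- 1L
  if (!is.null(nucleus)) labels[nucleus] <- 2L
  allowed <- comp & (if (is.null(nucleus)) TRUE else !nucleus)
  allowed_idx <- which(allowed)
  if (!length(allowed_idx)) stop("compartment has no interior voxels", call. = FALSE)
  # clearance to the compartment wall/nucleus: candidate centers for an
  # organelle of half-width w are drawn where the clearance is >= w, which
  # keeps rejection sampling efficient in narrow tubes
  clearance <- sqrt(cpp_sqedt(allowed, grid$dims, sp))[allowed_idx]

  placed <- vector("list", length(specs))
  with_seed(if (is.null(seed)) NULL else seed + 1L, {
    for (o in seq_along(specs)) {
      s <- specs[[o]]
      lab <- 2L + o
      ok <- FALSE
      wmin <- s$params$r %||% 0
      if (s$kind == "capsule" && compartment == "soma")
        wmin <- wmin + 0.05 * s$params$L   # chord-sagitta allowance
      cand <- allowed_idx[clearance >= wmin]
      if (!length(cand)) cand <- allowed_idx[clearance >= 0.8 * max(clearance)]
      for (att in seq_len(max_attempts)) {
        v <- cand[sample.int(length(cand), 1L)]
        ijk <- arrayInd(v, grid$dims)
        ctr <- (as.numeric(ijk) - 0.5 + stats::runif(3, -0.5, 0.5)) * sp
        ax <- if (compartment == "soma") {
          radial <- ctr - ext / 2
          rn <- sqrt(sum(radial^2))
          if (rn < 1e-9) stats::rnorm(3)
          else if (s$kind == "torus") {
            # ring plane tangent to the shell: donuts lie flat against the
            # nucleus/membrane, so the torus axis points radially
            radial + stats::rnorm(3, 0, 0.05 * rn)
          } else {
            # elongated organelles wrap around the nucleus: axis tangential
            w <- stats::rnorm(3)
            tangent <- w - sum(w * radial) * radial / rn^2
            tangent + stats::rnorm(3, 0, 0.05 * sqrt(sum(tangent^2)))
          }
        } else c(1, stats::rnorm(2, 0, 0.1))
        s$center <- ctr
        s$axis <- ax / sqrt(sum(ax^2))
        sub <- voxelize_submask(s, grid)
        if (is.null(sub)) next
        patch <- labels[sub$ix, sub$iy, sub$iz]
        aok <- allowed[sub$ix, sub$iy, sub$iz]
        if (any(sub$mask & (!aok | patch > 2L))) next
        patch[sub$mask] <- lab
        labels[sub$ix, sub$iy, sub$iz] <- patch
        placed[[o]] <- list(spec = s, label = lab,
                            n_voxels = sum(sub$mask))
        ok <- TRUE
        break
      }
      if (!ok) {
        achieved <- sum(!vapply(placed, is.null, logical(1)))
        stop(structure(class = c("mitomorph_packing_error", "error", "condition"),
                       list(message = sprintf(
                         "packing failed for object %d of %d after %d attempts (%d placed)",
                         o, length(specs), max_attempts, achieved),
                         call = NULL, achieved = achieved)))
      }
    }
  })

  vox <- voxel_volume_um3(grid)
  objects <- do.call(rbind, lapply(placed, function(p) {
    s <- p$spec
    data.frame(label = p$label, kind = s$kind,
               target_volume_um3 = attr(s, "target_volume_um3"),
               analytic_volume_um3 = analytic_volume(s),
               analytic_sa_um2 = analytic_surface_area(s),
               voxel_volume_um3 = p$n_voxels * vox,
               stringsAsFactors = FALSE)
  }))
  roles <- stats::setNames(c("compartment",
                             if (!is.null(nucleus)) "nucleus",
                             rep("mitochondrion", length(placed))),
                           c(1L, if (!is.null(nucleus)) 2L,
                             vapply(placed, `[[`, integer(1), "label")))
  comp_truth$compartment_volume_um3 <- sum(labels != 0L) * vox
  comp_truth$nucleus_volume_um3 <-
    if (is.null(nucleus)) NA_real_ else sum(labels == 2L) * vox
  comp_truth$region <- region
  comp_truth$age <- age
  comp_truth$seed <- if (is.null(seed)) NA_integer_ else seed

  vol <- label_volume(labels, grid, roles = roles,
                      meta = list(compartment = compartment, region = region,
                                  age = age, seed = comp_truth$seed))
  list(volume = vol, manifest = list(objects = objects, compartment = comp_truth))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Organelles wider than the compartment can accommodate are re-solved as
# volume-preserving capsules at the maximal feasible tube radius: narrow
# compartments constrain organelle cross-sections, so large axonal and
# dendritic mitochondria are elongated rather than spherical. `max_r` is the
# largest allowed cross-sectional radius (um).
confine_spec <- function(s, max_r, max_hw = 2.5 * max_r) {
  if (!is.finite(max_r) || max_r <= 0) return(s)
  p <- s$params
  ok <- switch(s$kind,
    sphere = p$r <= max_r,
    capsule = p$r <= max_r,
    torus = p$r <= max_r && (p$R + p$r) <= max_hw,
    branched_tube = p$r <= max_r &&
      p$branch_length * sin(p$branch_angle_deg * pi / 180) + p$r <= max_hw)
  if (ok) return(s)
  V <- attr(s, "target_volume_um3") %||% nominal_volume(s)
  # re-solve at the maximal allowed radius: the shortest capsule of volume V
  # that respects the width limit
  r <- max_r
  L <- V / (pi * r^2) - 4 * r / 3
  out <- if (L > 0) shape_capsule(r = r, L = L, center = s$center, axis = s$axis)
    else shape_sphere(r = (3 * V / (4 * pi))^(1 / 3), center = s$center)
  attr(out, "target_volume_um3") <- attr(s, "target_volume_um3")
  out
}
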