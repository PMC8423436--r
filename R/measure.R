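#' Measure every mitochondrion in a labeled stack
#'
#' Computes the full per-organelle morphometry table for a [label_volume()]:
#' volume (um^3), surface area (um^2), MCI, genus (donut flag) and
#' grid-face contact, tagged with the stack metadata (region, compartment,
#' age). Organelles touching the stack boundary are excluded by default, as
#' structures not completely inside the imaged volume cannot be measured
#' fairly; set `exclude_boundary = FALSE` to keep them (flagged).
#'
#' @param volume a [label_volume()]; labels with role `"mitochondrion"` are
#'   measured.
#' @param smooth,sigma_vox surface pre-smoothing, see [extract_mesh()].
#' @param exclude_boundary drop organelles that touch a grid face.
#' @return data frame, one row per organelle: `label`, `region`,
#'   `compartment`, `age`, `V_um3`, `SA_um2`, `MCI`, `genus`,
#'   `touches_boundary`. The number of boundary-excluded organelles is in
#'   `attr(, "n_excluded")`.
#' @export
measure_stack <- function(volume, smooth = TRUE, sigma_vox = c(1.5, 1.5, 1.5),
                          exclude_boundary = TRUE) {
  stopifnot(inherits(volume, "label_volume"))
  ids <- labels_present(volume, "mitochondrion")
  st <- cpp_label_stats(volume$labels, volume$grid$dims)
  vox <- voxel_volume_um3(volume$grid)
  meta <- volume$meta
  rows <- lapply(ids, function(l) {
    n <- st$count[l]
    touches <- st$touches[l] == 1L
    V <- n * vox
    if (n == 1L) {
      s <- spacing_um(volume$grid)
      SA <- 2 * (s[1] * s[2] + s[2] * s[3] + s[1] * s[3])
      Vmci <- V
      genus <- 0L
    } else {
      mesh <- extract_mesh(volume, l, smooth = smooth, sigma_vox = sigma_vox)
      SA <- mesh_area(mesh)
      # MCI is scale-invariant, so pairing mesh area with mesh-enclosed
      # volume cancels the slight smoothing shrinkage of small organelles
      # (voxel-count V stays the reported volume measurement)
      Vmci <- mesh_volume(mesh)
      genus <- mesh_genus(mesh)
    }
    data.frame(label = l,
               region = meta$region %||% NA_character_,
               compartment = meta$compartment %||% NA_character_,
               age = meta$age %||% NA_character_,
               V_um3 = V, SA_um2 = SA, MCI = mci(SA, Vmci),
               genus = genus, touches_boundary = touches,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), region = character(0), compartment = character(0),
               age = character(0), V_um3 = numeric(0), SA_um2 = numeric(0),
               MCI = numeric(0), genus = integer(0), touches_boundary = logical(0))
  n_excluded <- sum(out$touches_boundary)
  if (exclude_boundary) out <- out[!out$touches_boundary, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- if (exclude_boundary) n_excluded else 0L
  out
}

#' Summarize one compartment stack
#'
#' Produces the compartment-level record for a measured stack: compartment
#' volume, mitochondrion count, mitochondrial volume density, and either
#' the centerline diameter profile (axon/dendrite) or the soma
#' nucleus/cytoplasm decomposition.
#'
#' @param volume a [label_volume()] whose role map contains a
#'   `"compartment"` label (the compartment mask is all nonzero labels).
#' @param organelles per-organelle table from [measure_stack()] (computed if
#'   missing).
#' @param measure_diam compute the tube diameter (axon/dendrite only).
#' @param n_points diameter measurement points.
#' @param ... passed to [measure_stack()] when `organelles` is missing.
#' @return one-row data frame: `region`, `compartment`, `age`,
#'   `compartment_volume_um3`, `n_mito`, `mvd`, `diameter_mean_um`,
#'   `nucleus_volume_um3`, `cytoplasm_volume_um3`, `frac_nucleus`,
#'   `frac_cytoplasm`, `frac_mito`; the diameter per-point values are kept
#'   in `attr(, "diameter_points_um")`.
#' @export
summarize_compartment <- function(volume, organelles = NULL, measure_diam = TRUE,
                                  n_points = 10, ...) {
  stopifnot(inherits(volume, "label_volume"))
  if (is.null(organelles)) organelles <- measure_stack(volume, ...)
  comp_type <- volume$meta$compartment %||% NA_character_
  vox <- voxel_volume_um3(volume$grid)
  comp_mask <- volume$labels != 0L
  comp_vol <- sum(comp_mask) * vox
  mvd <- mitochondrial_volume_density(organelles$V_um3, comp_vol)
  diam <- NA_real_
  diam_pts <- NULL
  nuc_vol <- cyt_vol <- NA_real_
  fr <- c(nucleus = NA_real_, cytoplasm = NA_real_, mito = NA_real_)
  if (identical(comp_type, "soma")) {
    nuc_ids <- labels_present(volume, "nucleus")
    nuc_mask <- if (length(nuc_ids)) array(volume$labels %in% nuc_ids, dim(volume$labels))
      else array(FALSE, dim(volume$labels))
    mito_ids <- labels_present(volume, "mitochondrion")
    mito_lab <- volume$labels
    mito_lab[!(mito_lab %in% mito_ids)] <- 0L
    dec <- soma_decomposition(comp_mask, nuc_mask, mito_lab, volume$grid)
    nuc_vol <- dec$nucleus_volume_um3
    cyt_vol <- dec$cytoplasm_volume_um3
    fr <- dec$fractions
  } else if (measure_diam && comp_type %in% c("axon", "dendrite")) {
    dm <- measure_diameter(comp_mask, volume$grid, n_points = n_points)
    diam <- dm$mean_um
    diam_pts <- dm$points_um
  }
  out <- data.frame(region = volume$meta$region %||% NA_character_,
                    compartment = comp_type,
                    age = volume$meta$age %||% NA_character_,
                    compartment_volume_um3 = comp_vol,
                    n_mito = nrow(organelles),
                    mvd = mvd,
                    diameter_mean_um = diam,
                    nucleus_volume_um3 = nuc_vol,
                    cytoplasm_volume_um3 = cyt_vol,
                    frac_nucleus = fr[["nucleus"]],
                    frac_cytoplasm = fr[["cytoplasm"]],
                    frac_mito = fr[["mito"]],
                    stringsAsFactors = FALSE)
  attr(out, "diameter_points_um") <- diam_pts
  out
}
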