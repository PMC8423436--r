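#' Configuration of a synthetic mitochondrial population
#'
#' Describes the organelle population of one compartment group: how many
#' mitochondria, their volume distribution, and the mix of morphologies.
#' Volumes are drawn from a lognormal law parameterized by its arithmetic
#' mean (um^3) and coefficient of variation; measured mitochondrial volume
#' distributions are right-skewed with rare very large organelles, which the
#' lognormal reproduces. The default CV of 0.8 gives a realistic heavy right
#' tail (a few percent of dendritic-scale organelles above 1 um^3).
#'
#' The shape mix spans simple to complex morphologies: spheres and capsules
#' (the bulk of the population), tori ("donut" mitochondria, rare) and
#' branched tubes. Capsule elongation L/r and torus aspect R/r are drawn
#' uniformly from the configured ranges; the torus default [2, 10] makes the
#' analytic complexity index of donut phantoms (equal to R/r) span the range
#' observed in tissue.
#'
#' @param n number of organelles (>= 1).
#' @param mean_volume_um3 arithmetic mean of the volume law, um^3.
#' @param cv coefficient of variation of the volume law (> 0).
#' @param shape_mix named non-negative weights over
#'   `sphere|capsule|torus|branched_tube`; normalized to sum to 1.
#' @param capsule_aspect range of capsule L/r (uniform draw).
#' @param torus_aspect range of torus R/r (uniform draw), must stay > 1.
#' @param max_volume_um3 upper truncation of the volume law (draws above it
#'   are redrawn); `Inf` disables. Compartments of bounded width cannot
#'   physically host arbitrarily large organelles, and with the default CV
#'   the mass above any cap several-fold beyond the mean is well under 1%
#'   of the total, so the configured mean is preserved to that accuracy.
#' @param seed optional integer seed baked into the config.
#' @return an object of class `population_config`.
#' @export
population_config <- function(n, mean_volume_um3, cv = 0.8,
                              shape_mix = c(sphere = 0.6, capsule = 0.3,
                                            torus = 0.05, branched_tube = 0.05),
                              capsule_aspect = c(2, 8),
                              torus_aspect = c(2, 10),
                              max_volume_um3 = Inf,
                              seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1", call. = FALSE)
  if (!is.finite(mean_volume_um3) || mean_volume_um3 <= 0)
    stop("`mean_volume_um3` must be positive", call. = FALSE)
  if (!is.finite(cv) || cv <= 0) stop("`cv` must be > 0", call. = FALSE)
  kinds <- c("sphere", "capsule", "torus", "branched_tube")
  shape_mix <- unlist(shape_mix)
  if (is.null(names(shape_mix)) || !all(names(shape_mix) %in% kinds))
    stop("`shape_mix` must be named with kinds among: ", paste(kinds, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(shape_mix)) || any(shape_mix < 0) || sum(shape_mix) <= 0)
    stop("`shape_mix` is not normalizable (weights must be non-negative, sum > 0)",
         call. = FALSE)
  mix <- stats::setNames(numeric(length(kinds)), kinds)
  mix[names(shape_mix)] <- shape_mix
  mix <- mix / sum(mix)
  if (length(capsule_aspect) != 2 || any(capsule_aspect <= 0) || diff(capsule_aspect) < 0)
    stop("`capsule_aspect` must be an increasing positive range", call. = FALSE)
  if (length(torus_aspect) != 2 || any(torus_aspect <= 1) || diff(torus_aspect) < 0)
    stop("`torus_aspect` must be an increasing range with both ends > 1", call. = FALSE)
  if (!is.na(max_volume_um3) && max_volume_um3 <= mean_volume_um3)
    stop("`max_volume_um3` must exceed the mean volume", call. = FALSE)
  structure(list(n = n, mean_volume_um3 = mean_volume_um3, cv = cv,
                 shape_mix = mix, capsule_aspect = capsule_aspect,
                 torus_aspect = torus_aspect, max_volume_um3 = max_volume_um3,
                 seed = seed),
            class = "population_config")
}

# run expr under a private RNG state seeded with `seed`, restoring the
# caller's stream afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# solve shape dimensions from a target volume and aspect ratio
shape_from_volume <- function(kind, V, aspect) {
  switch(kind,
    sphere = shape_sphere(r = (3 * V / (4 * pi))^(1 / 3)),
    capsule = {
      r <- (V / (pi * (aspect + 4 / 3)))^(1 / 3)
      shape_capsule(r = r, L = aspect * r)
    },
    torus = {
      r <- (V / (2 * pi^2 * aspect))^(1 / 3)
      shape_torus(R = aspect * r, r = r)
    },
    branched_tube = {
      # nominal volume pi r^3 (1.5 a + 4/3) for branch length = trunk/2
      r <- (V / (pi * (1.5 * aspect + 4 / 3)))^(1 / 3)
      shape_branched_tube(r = r, trunk_length = aspect * r)
    })
}

#' Draw a population of shape specifications
#'
#' Samples `cfg$n` organelle shapes: a target volume from the configured
#' lognormal law, a morphology kind from the shape mix, and an aspect ratio
#' from the kind's aspect law; shape dimensions are then solved so the
#' closed-form (or, for branched tubes, nominal) volume equals the target.
#' Poses are placeholders (`center = 0`, axis = x) until the shapes are
#' placed into a compartment scene. Identical config and seed give an
#' identical spec list.
#'
#' @param cfg a [population_config()].
#' @param seed integer seed; defaults to the seed stored in `cfg`.
#' @return list of `shape_spec`, with per-shape attributes
#'   `target_volume_um3`.
#' @examples
#' specs <- sample_population(population_config(5, 0.27, seed = 7))
#' mean(vapply(specs, function(s) attr(s, "target_volume_um3"), numeric(1)))
#' @export
sample_population <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "population_config"))
  sdlog <- sqrt(log(1 + cfg$cv^2))
  meanlog <- log(cfg$mean_volume_um3) - sdlog^2 / 2
  cap <- cfg$max_volume_um3 %||% Inf
  with_seed(seed, {
    vols <- stats::rlnorm(cfg$n, meanlog, sdlog)
    for (it in 1:100) {
      over <- vols > cap
      if (!any(over)) break
      vols[over] <- stats::rlnorm(sum(over), meanlog, sdlog)
    }
    vols <- pmin(vols, cap)
    kinds <- sample(names(cfg$shape_mix), cfg$n, replace = TRUE, prob = cfg$shape_mix)
    aspects <- ifelse(kinds == "capsule",
                      stats::runif(cfg$n, cfg$capsule_aspect[1], cfg$capsule_aspect[2]),
                      stats::runif(cfg$n, cfg$torus_aspect[1], cfg$torus_aspect[2]))
    mapply(function(v, k, a) {
      s <- shape_from_volume(k, v, a)
      attr(s, "target_volume_um3") <- v
      s
    }, vols, kinds, aspects, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  })
}
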