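# Independent oracles and fixture builders, coded separately from the
# package implementation.

# exact two-sided Mann-Whitney p by enumeration of all rank assignments
# (no ties assumed); U counts pairs with a > b
mw_enumeration_oracle <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  n <- length(pooled)
  u_of <- function(ia) {
    aa <- pooled[ia]
    bb <- pooled[-ia]
    sum(outer(aa, bb, ">"))
  }
  u_obs <- sum(outer(a, b, ">"))
  us <- utils::combn(n, na, u_of)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# literal transcription of the two-stage step-up: BH marks rejections through
# the p-value ordering (not a threshold), then the second pass reruns BH at
# the inflated level
bky_oracle <- function(p, q = 0.05) {
  m <- length(p)
  bh_mark <- function(pv, lev) {
    o <- order(pv)
    s <- pv[o]
    ok <- s <= lev * seq_len(m) / m
    r <- if (any(ok)) max(which(ok)) else 0L
    rej <- rep(FALSE, m)
    if (r > 0) rej[o[seq_len(r)]] <- TRUE
    rej
  }
  q1 <- q / (1 + q)
  r1 <- sum(bh_mark(p, q1))
  if (r1 == 0L) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  bh_mark(p, q1 * m / (m - r1))
}

# analytic-geometry mask builders ---------------------------------------

coord_arrays <- function(grid) {
  d <- grid$dims
  sp <- grid$spacing_nm / 1e3
  xs <- (seq_len(d[1]) - 0.5) * sp[1]
  ys <- (seq_len(d[2]) - 0.5) * sp[2]
  zs <- (seq_len(d[3]) - 0.5) * sp[3]
  list(X = array(xs, d),
       Y = array(rep(ys, each = d[1]), d),
       Z = array(rep(zs, each = d[1] * d[2]), d))
}

# finite cylinder along unit axis u from point a, length L, radius r
cylinder_mask <- function(grid, a, u, L, r) {
  co <- coord_arrays(grid)
  qx <- co$X - a[1]; qy <- co$Y - a[2]; qz <- co$Z - a[3]
  t <- qx * u[1] + qy * u[2] + qz * u[3]
  d2 <- (qx - t * u[1])^2 + (qy - t * u[2])^2 + (qz - t * u[3])^2
  d2 <= r^2 & t >= 0 & t <= L
}

# x-aligned cylinder with its axis on voxel centers in y and z
centered_cylinder <- function(r_um, L_um = 6, spacing_nm = c(10, 10, 50)) {
  sp <- spacing_nm / 1e3
  dims <- c(ceiling((L_um + 0.4) / sp[1]),
            ceiling((2 * r_um + 0.2) / sp[2]),
            ceiling((2 * r_um + 0.3) / sp[3]))
  g <- voxel_grid(spacing_nm, dims)
  cy <- (ceiling(dims[2] / 2) - 0.5) * sp[2]
  cz <- (ceiling(dims[3] / 2) - 0.5) * sp[3]
  list(grid = g,
       mask = cylinder_mask(g, c(0.2, cy, cz), c(1, 0, 0), L_um, r_um))
}

young_dg_config <- function(n = 60) {
  list(mode = "synthetic", seed = 1,
       groups = list(
         list(region = "DG", age = "young", compartment = "axon",
              n_mito = n, mean_volume_um3 = 0.12),
         list(region = "DG", age = "young", compartment = "dendrite",
              n_mito = n, mean_volume_um3 = 0.27),
         list(region = "DG", age = "young", compartment = "soma",
              n_mito = n, mean_volume_um3 = 0.19)))
}

sphere_mci <- 9 / (4 * pi)

`%||%` <- function(a, b) if (is.null(a)) b else a
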