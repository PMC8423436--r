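#' Mitochondrial Complexity Index
#'
#' The MCI is a three-dimensional analog of the form factor used for 2D
#' organelle profiles:
#'
#' \deqn{MCI = \frac{SA^3}{16 \pi^2 V^2}}
#'
#' It is dimensionless and invariant under isotropic scaling of the solid.
#' The sphere minimizes surface area at fixed volume, so the MCI has a hard
#' lower bound of `9 / (4 pi)` (about 0.7162), attained by spheres; for a
#' torus with ring radius R and tube radius r the closed forms collapse to
#' `MCI = R / r`, so donut phantoms double as an analytic MCI oracle.
#'
#' @param SA surface area, um^2 (or any unit, consistently with `V`).
#' @param V volume, um^3.
#' @return the dimensionless MCI; vectorized over `SA` and `V`.
#' @examples
#' mci(4 * pi, 4 * pi / 3)            # unit sphere: 9 / (4 pi)
#' R <- 0.5; r <- 0.1
#' mci(4 * pi^2 * R * r, 2 * pi^2 * R * r^2)  # torus: R / r = 5
#' @export
mci <- function(SA, V) {
  if (any(!is.finite(SA)) || any(!is.finite(V)) || any(SA <= 0) || any(V <= 0))
    stop("MCI requires strictly positive surface area and volume", call. = FALSE)
  SA^3 / (16 * pi^2 * V^2)
}
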