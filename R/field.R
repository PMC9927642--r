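#' Centroid base point
#'
#' The base point anchoring the distance field for organ-end extraction is
#' the arithmetic mean of the cloud. The field is only defined for a base
#' point that is not itself a cloud point, so if the mean coincides exactly
#' (float equality) with some point, a small uniform random offset is added
#' (magnitude at most `perturbation`, drawn with a fixed RNG seed so the
#' pipeline stays reproducible).
#'
#' @param cloud a [point_cloud()].
#' @param perturbation maximum offset magnitude used on collision; default
#'   `1e-6 *` bounding-box diagonal.
#' @param seed RNG seed for the collision offset (default 0).
#' @return numeric length-3 base point.
#' @export
centroid_base_point <- function(cloud, perturbation = NULL, seed = 0L) {
  stopifnot(inherits(cloud, "point_cloud"))
  base <- colMeans(cloud$points)
  if (is.null(perturbation)) perturbation <- 1e-6 * max(bbox_diagonal(cloud), 1e-12)
  collides <- function(b)
    any(cloud$points[, 1] == b[1] & cloud$points[, 2] == b[2] &
        cloud$points[, 3] == b[3])
  if (collides(base)) {
    base <- with_seed(seed, {
      repeat {
        cand <- base + stats::runif(3L, -perturbation, perturbation)
        if (!collides(cand)) break
      }
      cand
    })
  }
  as.numeric(base)
}

#' Minkowski distance field
#'
#' The scalar field driving organ-end extraction: for every cloud point
#' `p_i`, `F(p_i) = ||p_i - base||^alpha` (Euclidean norm, exponent
#' `alpha >= 1`). The exponent changes only the contrast of the field, not
#' the ordering of its values: organ ends far from the base point become
#' sharp local maxima, and larger `alpha` sharpens the relative drop across
#' a local area (which matters through the `beta` level-ratio test in
#' [find_cluster_cores()]).
#'
#' @param cloud a [point_cloud()].
#' @param base numeric length-3 base point; must not coincide with any cloud
#'   point (see [centroid_base_point()]).
#' @param alpha exponent, `>= 1`.
#' @return a `scalar_field`: list with `values` (one positive real per
#'   point), `base_point`, and `alpha`.
#' @export
minkowski_field <- function(cloud, base, alpha = 5) {
  stopifnot(inherits(cloud, "point_cloud"), length(base) == 3L)
  if (alpha < 1) stop("`alpha` must be >= 1", call. = FALSE)
  d2 <- (cloud$points[, 1] - base[1])^2 + (cloud$points[, 2] - base[2])^2 +
    (cloud$points[, 3] - base[3])^2
  if (any(d2 == 0))
    stop("base point coincides with cloud point ", which(d2 == 0)[1L],
         "; perturb the base point (see centroid_base_point)", call. = FALSE)
  structure(list(values = sqrt(d2)^alpha, base_point = as.numeric(base),
                 alpha = alpha),
            class = "scalar_field")
}
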