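#' Euclidean pairwise distance matrix of a point cloud
#'
#' @param cloud Numeric matrix, one point per row.
#' @return Symmetric nonnegative matrix with zero diagonal.
#' @export
pairwise_distances <- function(cloud) {
  cloud <- as.matrix(cloud)
  .assert(nrow(cloud) >= 1L, "need at least one point")
  .assert(all(is.finite(cloud)), "point cloud has non-finite coordinates")
  as.matrix(stats::dist(cloud))
}

#' Dimension-0 Vietoris-Rips persistent homology
#'
#' For a Rips filtration at the pairwise-distance scale, every H0 class is
#' born at 0 and the finite classes die at the single-linkage merge
#' heights, i.e. the edge weights of a Euclidean minimum spanning tree
#' (computed here with Prim's algorithm on the full distance matrix). The
#' one essential (never-dying) component is dropped and flagged.
#'
#' Note: the filtration scale is the pairwise distance itself — the
#' convention of ripser-style software — not the radius at which growing
#' balls touch (which would be distance / 2).
#'
#' @param cloud Numeric point matrix (rows = points), or a precomputed
#'   distance matrix when `distances = TRUE`.
#' @param distances Set `TRUE` if `cloud` is already a distance matrix.
#' @return Object of class `persistence_diagram`: list with `pairs`
#'   (two-column `birth`, `death` matrix, deaths ascending), `dimension`
#'   (0) and `essential_dropped` (`TRUE`). A cloud with fewer than two
#'   points yields an empty `pairs` matrix.
#' @export
rips_h0 <- function(cloud, distances = FALSE) {
  D <- if (distances) as.matrix(cloud) else pairwise_distances(cloud)
  n <- nrow(D)
  deaths <- if (n < 2L) numeric(0) else {
    in_tree <- logical(n)
    in_tree[1L] <- TRUE
    best <- D[1L, ]
    w <- numeric(n - 1L)
    for (k in seq_len(n - 1L)) {
      cand <- best
      cand[in_tree] <- Inf
      j <- which.min(cand)
      w[k] <- cand[j]
      in_tree[j] <- TRUE
      best <- pmin(best, D[j, ])
    }
    sort(w)
  }
  structure(
    list(pairs = cbind(birth = rep(0, length(deaths)), death = deaths),
         dimension = 0L, essential_dropped = TRUE),
    class = "persistence_diagram"
  )
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat(sprintf("<persistence_diagram> H%d, %d finite pair(s)%s\n",
              x$dimension, nrow(x$pairs),
              if (x$essential_dropped) ", essential class dropped" else ""))
  invisible(x)
}

#' Persistence of each diagram pair (death - birth)
#' @param diagram A `persistence_diagram`.
#' @return Numeric vector (possibly empty).
#' @export
persistence_values <- function(diagram) {
  if (nrow(diagram$pairs) == 0L) numeric(0)
  else diagram$pairs[, "death"] - diagram$pairs[, "birth"]
}

#' Automatic persistence-axis bounds for imaging
#'
#' Lower bound 0; upper bound the maximum persistence padded by one pixel
#' width (`max / npix`) so the largest pair's centre falls inside the last
#' pixel. An empty diagram gets the stated fallback `(0, 1)`.
#'
#' @param diagram A `persistence_diagram`, or a numeric vector of
#'   persistence values (a collection may be concatenated to obtain
#'   cohort-wide bounds).
#' @param npix Number of persistence pixels (default 50).
#' @return Numeric `c(p_min, p_max)`.
#' @export
auto_bounds <- function(diagram, npix = 50L) {
  p <- if (inherits(diagram, "persistence_diagram")) persistence_values(diagram)
  else as.numeric(diagram)
  p <- p[is.finite(p)]
  if (length(p) == 0L || max(p) <= 0) return(c(0, 1))
  m <- max(p)
  c(0, m + m / npix)
}

#' Linear persistence image of an H0 diagram
#'
#' Maps the diagram to birth-persistence coordinates and integrates, over
#' `npix` equal persistence bins spanning `bounds`, a sum of isotropic
#' Gaussians (variance `variance`, one per pair) weighted linearly by
#' persistence, `w(p) = p / p_max` with `p_max = bounds[2]` (so the weight
#' vanishes on the diagonal). With birth resolution 1 — all Rips H0 births
#' are 0 — the birth axis integrates out and pixel `k` is
#' `sum_i w(p_i) * (Phi((e[k+1] - p_i)/sigma) - Phi((e[k] - p_i)/sigma))`,
#' the exact Gaussian mass in the bin (not a centre-point evaluation).
#'
#' @param diagram A `persistence_diagram` (or numeric persistence values).
#' @param npix Pixel resolution on the persistence axis (default 50, i.e.
#'   the `[1, 50]` image of the workflow).
#' @param variance Gaussian variance sigma^2 (default 0.005; note this is
#'   a variance, sigma ~= 0.0707).
#' @param bounds Optional `c(p_min, p_max)`; default [auto_bounds()] of
#'   this diagram. Shared (cohort-fitted) bounds make pixel positions
#'   comparable across patients.
#' @return Object of class `persistence_image`: list with `pixels`
#'   (length `npix`, nonnegative), `bounds`, `variance`, `weight`
#'   (`"linear"`) and `breaks` (the `npix + 1` bin edges).
#' @export
persistence_image <- function(diagram, npix = 50L, variance = 0.005,
                              bounds = NULL) {
  .assert(variance > 0, "variance must be positive")
  .assert(npix >= 1L, "need at least one pixel")
  p <- if (inherits(diagram, "persistence_diagram")) persistence_values(diagram)
  else as.numeric(diagram)
  if (is.null(bounds)) bounds <- auto_bounds(p, npix)
  .assert(length(bounds) == 2L && bounds[1] < bounds[2],
          "invalid bounds: need p_min < p_max")
  breaks <- seq(bounds[1], bounds[2], length.out = npix + 1L)
  sigma <- sqrt(variance)
  pixels <- numeric(npix)
  if (length(p) > 0L) {
    w <- p / bounds[2]
    # npix x n matrix of CDF differences, summed over pairs
    cdf <- outer(breaks, p, function(e, pc) stats::pnorm((e - pc) / sigma))
    mass <- cdf[-1L, , drop = FALSE] - cdf[-(npix + 1L), , drop = FALSE]
    pixels <- as.numeric(mass %*% w)
    pixels[pixels < 0] <- 0  # guard tiny negative rounding
  }
  structure(list(pixels = pixels, bounds = bounds, variance = variance,
                 weight = "linear", breaks = breaks),
            class = "persistence_image")
}

#' @export
print.persistence_image <- function(x, ...) {
  cat(sprintf("<persistence_image> %d pixels, bounds [%g, %g], variance %g\n",
              length(x$pixels), x$bounds[1], x$bounds[2], x$variance))
  invisible(x)
}

#' Export a persistence diagram as CSV
#' @param diagram A `persistence_diagram`.
#' @param path Output CSV path (columns `birth,death,dimension`).
#' @export
write_diagram <- function(diagram, path) {
  df <- data.frame(birth = diagram$pairs[, "birth"],
                   death = diagram$pairs[, "death"],
                   dimension = diagram$dimension)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a persistence image as CSV plus JSON sidecar
#' @param image A `persistence_image`.
#' @param path Output CSV path; a `.json` sidecar records bounds,
#'   variance and weight.
#' @export
write_image <- function(image, path) {
  write.csv(matrix(image$pixels, nrow = 1), path, row.names = FALSE)
  side <- sub("\\.csv$", "", path)
  jsonlite::write_json(list(bounds = image$bounds, variance = image$variance,
                            weight = image$weight),
                       paste0(side, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
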