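#' Rasterize polygon annotations into a label mask
#'
#' Produces an integer H x W mask: pixels inside a class polygon receive that
#' class code (1..4 in the order of [tissue_classes()]), pixels inside any
#' exclusion polygon are `-1` (excluded) regardless of class polygons, and
#' pixels in no polygon are `0` (unlabeled). A pixel belongs to a polygon by
#' the even-odd rule applied to its integer (x, y) center, with points on the
#' polygon boundary counted as inside. When class polygons overlap, the later
#' region in `ann$regions` wins.
#'
#' @param ann an [annotation_set()]
#' @param height,width mask dimensions (must match the slide)
#' @return an integer matrix of class `label_mask` with attribute
#'   `codes` naming the integer codes
#' @export
rasterize <- function(ann, height, width) {
  stopifnot(inherits(ann, "annotation_set"), height >= 1, width >= 1)
  grid <- matrix(MASK_UNLABELED, nrow = height, ncol = width)
  for (r in ann$regions) {
    grid[polygon_pixel_idx(r$polygon, height, width)] <- tissue_class_code(r$class)
  }
  for (ex in ann$exclusions) {
    grid[polygon_pixel_idx(ex, height, width)] <- MASK_EXCLUDED
  }
  structure(grid, class = c("label_mask", class(grid)),
            codes = c(excluded = MASK_EXCLUDED, unlabeled = MASK_UNLABELED,
                      stats::setNames(seq_along(tissue_classes()), tissue_classes())))
}

#' Rasterize region identity (biopsy membership)
#'
#' Companion to [rasterize()]: returns the 1-based index of the class region
#' covering each pixel (0 where no region does), with the same later-region-
#' wins rule. Used to attach a biopsy id to sampled patch centers.
#'
#' @inheritParams rasterize
#' @return integer H x W matrix of region indices
#' @export
rasterize_regions <- function(ann, height, width) {
  stopifnot(inherits(ann, "annotation_set"))
  grid <- matrix(0L, nrow = height, ncol = width)
  for (i in seq_along(ann$regions)) {
    grid[polygon_pixel_idx(ann$regions[[i]]$polygon, height, width)] <- i
  }
  grid
}

# Linear indices (into an H x W matrix) of pixel centers inside a polygon:
# even-odd ray casting, boundary points included. Vectorized over the
# polygon's bounding box. Pixel (row, col) is 0-based (y = row, x = col).
polygon_pixel_idx <- function(poly, height, width) {
  xs <- poly[, 1]; ys <- poly[, 2]
  x0 <- max(0L, as.integer(ceiling(min(xs) - 1e-9)))
  x1 <- min(width - 1L, as.integer(floor(max(xs) + 1e-9)))
  y0 <- max(0L, as.integer(ceiling(min(ys) - 1e-9)))
  y1 <- min(height - 1L, as.integer(floor(max(ys) + 1e-9)))
  if (x0 > x1 || y0 > y1) return(integer(0))
  px <- rep(x0:x1, each = y1 - y0 + 1L)
  py <- rep(y0:y1, times = x1 - x0 + 1L)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  n <- length(xs)
  j <- n
  eps <- 1e-9
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    crosses <- (yi > py) != (yj > py)
    if (any(crosses)) {
      xint <- xi + (py[crosses] - yi) * (xj - xi) / (yj - yi)
      hit <- crosses
      hit[crosses] <- px[crosses] < xint
      inside <- xor(inside, hit)
    }
    # boundary: point on segment [i-j]
    d <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    on <- abs(d) <= eps * max(1, abs(xj - xi), abs(yj - yi)) &
      px >= min(xi, xj) - eps & px <= max(xi, xj) + eps &
      py >= min(yi, yj) - eps & py <= max(yi, yj) + eps
    on_edge <- on_edge | on
    j <- i
  }
  keep <- inside | on_edge
  (py[keep] + 1L) + px[keep] * height
}

#' Per-class pixel areas of a label mask
#' @param mask a `label_mask`
#' @return named integer vector of pixel counts per tissue class
#' @export
mask_class_areas <- function(mask) {
  vapply(seq_along(tissue_classes()),
         function(k) sum(mask == k),
         integer(1)) |>
    stats::setNames(tissue_classes())
}
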