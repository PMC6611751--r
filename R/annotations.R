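#' Construct an annotation set
#'
#' An annotation set holds class-labeled polygon regions (each tied to a
#' biopsy identifier) and exclusion polygons covering regions that must not
#' contribute pixels to the study (out-of-focus areas, folds, ink, ...).
#' Polygon vertices are in pixel coordinates: x runs along columns, y along
#' rows, both 0-based.
#'
#' @param regions list of `list(polygon = <n x 2 matrix of (x, y)>,
#'   class = <tissue class code>, biopsy_id = <character>)`
#' @param exclusions list of n x 2 vertex matrices
#' @return an object of class `annotation_set`
#' @export
annotation_set <- function(regions = list(), exclusions = list()) {
  regions <- lapply(seq_along(regions), function(i) {
    r <- regions[[i]]
    r$polygon <- check_polygon(r$polygon, sprintf("region %d", i))
    if (is.null(r$class) || !r$class %in% tissue_classes()) {
      stop("region ", i, " has unknown class '", r$class, "'")
    }
    if (is.null(r$biopsy_id) || !nzchar(r$biopsy_id)) {
      stop("region ", i, " has an empty biopsy_id")
    }
    r[c("polygon", "class", "biopsy_id")]
  })
  exclusions <- lapply(seq_along(exclusions), function(i) {
    check_polygon(exclusions[[i]], sprintf("exclusion %d", i))
  })
  structure(list(regions = regions, exclusions = exclusions),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d region(s), %d exclusion(s), %d biopsy id(s)\n",
              length(x$regions), length(x$exclusions),
              length(unique(vapply(x$regions, `[[`, "", "biopsy_id")))))
  invisible(x)
}

# Validate a polygon vertex matrix: numeric n x 2, >= 3 distinct vertices,
# simple (no self-intersection). A closing vertex equal to the first is
# dropped.
check_polygon <- function(p, what = "polygon") {
  p <- as.matrix(p)
  if (!is.numeric(p) || ncol(p) != 2) {
    stop(what, ": polygon must be an n x 2 numeric matrix of (x, y) vertices")
  }
  if (nrow(p) >= 2 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  if (nrow(p) < 3) stop(what, ": polygon needs at least 3 vertices")
  if (polygon_self_intersects(p)) stop(what, ": polygon is self-intersecting")
  dimnames(p) <- list(NULL, c("x", "y"))
  p
}

seg_intersects <- function(a1, a2, b1, b2) {
  d1 <- a2 - a1; d2 <- b2 - b1
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-12) return(FALSE)  # parallel: adjacency handles shared points
  t <- ((b1[1] - a1[1]) * d2[2] - (b1[2] - a1[2]) * d2[1]) / den
  u <- ((b1[1] - a1[1]) * d1[2] - (b1[2] - a1[2]) * d1[1]) / den
  eps <- 1e-9
  t > eps && t < 1 - eps && u > eps && u < 1 - eps
}

# Simple O(n^2) check over non-adjacent edge pairs; polygons here are small.
polygon_self_intersects <- function(p) {
  n <- nrow(p)
  idx <- c(seq_len(n), 1L)
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 2, n)) {
      if (i == 1 && j == n) next  # adjacent through the closing edge
      if (seg_intersects(p[idx[i], ], p[idx[i + 1], ],
                         p[idx[j], ], p[idx[j + 1], ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' All biopsy identifiers appearing in an annotation set
#' @param ann an [annotation_set()]
#' @return character vector of unique biopsy ids
#' @export
biopsy_ids <- function(ann) {
  stopifnot(inherits(ann, "annotation_set"))
  unique(vapply(ann$regions, `[[`, "", "biopsy_id"))
}

#' Read polygon annotations from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features. Each feature carries the
#' properties `class` (one of `r paste(tissue_classes(), collapse = ", ")`,
#' or `"exclude"` for exclusion regions) and, for class features,
#' `biopsy_id`. Coordinates are pixel units, 0-based, x right / y down.
#' Validation failures report the offending feature index.
#'
#' @param path path to a GeoJSON file
#' @return an [annotation_set()]
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("not a GeoJSON FeatureCollection: ", path)
  }
  regions <- list()
  exclusions <- list()
  for (i in seq_along(gj$features)) {
    f <- gj$features[[i]]
    cls <- f$properties$class
    if (is.null(cls)) stop("feature ", i, ": missing 'class' property")
    if (is.null(f$geometry$type) || f$geometry$type != "Polygon") {
      stop("feature ", i, ": only Polygon geometries are supported")
    }
    ring <- f$geometry$coordinates[[1]]
    poly <- do.call(rbind, lapply(ring, function(v) as.numeric(unlist(v))))
    poly <- tryCatch(check_polygon(poly, sprintf("feature %d", i)),
                     error = function(e) stop(conditionMessage(e), call. = FALSE))
    if (identical(cls, "exclude")) {
      exclusions[[length(exclusions) + 1L]] <- poly
    } else {
      if (!cls %in% tissue_classes()) {
        stop("feature ", i, ": unknown class '", cls, "'")
      }
      bid <- f$properties$biopsy_id
      if (is.null(bid) || !nzchar(bid)) {
        stop("feature ", i, ": missing or empty 'biopsy_id' property")
      }
      regions[[length(regions) + 1L]] <-
        list(polygon = poly, class = cls, biopsy_id = as.character(bid))
    }
  }
  annotation_set(regions, exclusions)
}

#' Write an annotation set to GeoJSON
#'
#' Inverse of [load_annotations()]: class regions become Polygon features with
#' `class` and `biopsy_id` properties, exclusions become features with
#' `class = "exclude"`. Vertex coordinates round-trip exactly.
#'
#' @param ann an [annotation_set()]
#' @param path output path
#' @return `path`, invisibly
#' @export
save_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  close_ring <- function(p) {
    p <- rbind(p, p[1, ])
    lapply(seq_len(nrow(p)), function(i) c(p[i, 1], p[i, 2]))
  }
  feats <- c(
    lapply(ann$regions, function(r) {
      list(type = "Feature",
           properties = list(class = r$class, biopsy_id = r$biopsy_id),
           geometry = list(type = "Polygon",
                           coordinates = list(close_ring(r$polygon))))
    }),
    lapply(ann$exclusions, function(p) {
      list(type = "Feature",
           properties = list(class = "exclude"),
           geometry = list(type = "Polygon",
                           coordinates = list(close_ring(p))))
    })
  )
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
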