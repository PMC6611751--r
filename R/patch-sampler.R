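#' Randomly sample class-balanced patch centers from a labeled slide
#'
#' Draws up to `n_per_class` patch centers per tissue class, uniformly at
#' random (independent draws, so patches may overlap or repeat) from the
#' eligible pixels of that class. A pixel is eligible when the mask carries
#' the class code at that pixel (excluded pixels never qualify) and the full
#' 299 x 299 window fits inside the slide, i.e. the center is at least 149
#' pixels from every edge. The central pixel alone defines the patch label.
#'
#' A class with no eligible pixels contributes zero patches and a warning.
#'
#' @param slide a [slide_image()]
#' @param mask the [rasterize()]d label mask of the slide
#' @param ann the [annotation_set()] (source of biopsy identity per center)
#' @param n_per_class number of patches to draw per class
#' @param seed integer seed (stream-local; does not disturb the global RNG)
#' @return a patch manifest `data.frame` with columns `patch_id`, `slide_id`,
#'   `biopsy_id`, `center_row`, `center_col` (0-based slide coordinates) and
#'   `label`
#' @export
sample_patches <- function(slide, mask, ann, n_per_class, seed) {
  stopifnot(inherits(slide, "slide_image"), n_per_class >= 0)
  d <- slide_dim(slide)
  if (!all(dim(mask) == d)) stop("mask dimensions do not match the slide")
  if (any(d < PATCH_SIZE)) stop("slide is smaller than the patch window")
  regmap <- rasterize_regions(ann, d[1], d[2])
  # 0-based center bounds for a fully interior window
  ok_row <- row(mask) - 1L >= PATCH_HALF & row(mask) - 1L <= d[1] - 1L - PATCH_HALF
  ok_col <- col(mask) - 1L >= PATCH_HALF & col(mask) - 1L <= d[2] - 1L - PATCH_HALF
  window_ok <- ok_row & ok_col
  out <- list()
  with_stream(seed, "sample_patches", {
    for (k in seq_along(tissue_classes())) {
      cls <- tissue_classes()[k]
      eligible <- which(mask == k & window_ok)
      if (length(eligible) == 0) {
        if (n_per_class > 0) {
          warning("no eligible pixels for class '", cls, "' on slide ",
                  slide$slide_id, "; 0 patches drawn", call. = FALSE)
        }
        next
      }
      if (n_per_class == 0) next
      idx <- eligible[sample.int(length(eligible), n_per_class, replace = TRUE)]
      rows0 <- (idx - 1L) %% d[1]
      cols0 <- (idx - 1L) %/% d[1]
      reg <- regmap[idx]
      bid <- vapply(reg, function(i) {
        if (i == 0L) NA_character_ else ann$regions[[i]]$biopsy_id
      }, character(1))
      out[[cls]] <- data.frame(
        slide_id = slide$slide_id, biopsy_id = bid,
        center_row = rows0, center_col = cols0,
        label = cls, stringsAsFactors = FALSE
      )
    }
  })
  df <- if (length(out)) do.call(rbind, out) else {
    data.frame(slide_id = character(), biopsy_id = character(),
               center_row = integer(), center_col = integer(),
               label = character(), stringsAsFactors = FALSE)
  }
  rownames(df) <- NULL
  df <- df[!is.na(df$biopsy_id), , drop = FALSE]
  df <- cbind(patch_id = sprintf("%s_p%05d", slide$slide_id, seq_len(nrow(df))),
              df, stringsAsFactors = FALSE)
  df
}

#' Patch centers on a regular grid over labeled tissue
#'
#' Used at inference time for slide grading: centers lie on a `stride`-spaced
#' grid restricted to pixels that are labeled (not background, not excluded)
#' and whose full patch window fits in the slide, so the resulting patch set
#' samples the biopsy proportionally to area.
#'
#' @inheritParams sample_patches
#' @param stride grid spacing in pixels
#' @return a patch manifest `data.frame` (same columns as [sample_patches()])
#' @export
grid_patches <- function(slide, mask, ann, stride = 50L) {
  stopifnot(inherits(slide, "slide_image"), stride >= 1)
  d <- slide_dim(slide)
  if (!all(dim(mask) == d)) stop("mask dimensions do not match the slide")
  rows0 <- seq(PATCH_HALF, d[1] - 1L - PATCH_HALF, by = stride)
  cols0 <- seq(PATCH_HALF, d[2] - 1L - PATCH_HALF, by = stride)
  if (!length(rows0) || !length(cols0)) {
    stop("slide too small for any interior patch window")
  }
  regmap <- rasterize_regions(ann, d[1], d[2])
  cr <- rep(rows0, times = length(cols0))
  cc <- rep(cols0, each = length(rows0))
  code <- mask[cbind(cr + 1L, cc + 1L)]
  keep <- code >= 1L
  cr <- cr[keep]; cc <- cc[keep]; code <- code[keep]
  reg <- regmap[cbind(cr + 1L, cc + 1L)]
  bid <- vapply(reg, function(i) {
    if (i == 0L) NA_character_ else ann$regions[[i]]$biopsy_id
  }, character(1))
  df <- data.frame(
    patch_id = sprintf("%s_g%05d", slide$slide_id, seq_along(cr)),
    slide_id = slide$slide_id, biopsy_id = bid,
    center_row = cr, center_col = cc,
    label = tissue_classes()[code], stringsAsFactors = FALSE
  )
  df[!is.na(df$biopsy_id), , drop = FALSE]
}

#' Extract the pixel block of a patch
#'
#' Materializes the 299 x 299 x 3 RGB block centered on a (0-based) slide
#' coordinate, optionally applying one of the six dihedral augmentation
#' transforms.
#'
#' @param slide a [slide_image()]
#' @param center_row,center_col 0-based center coordinates
#' @param tag augmentation transform, one of
#'   `c("identity", "rot90", "rot180", "rot270", "mirror_h", "mirror_v")`
#' @return a 299 x 299 x 3 array
#' @export
patch_pixels <- function(slide, center_row, center_col, tag = "identity") {
  d <- slide_dim(slide)
  r <- center_row + 1L; c <- center_col + 1L
  if (r - PATCH_HALF < 1 || r + PATCH_HALF > d[1] ||
      c - PATCH_HALF < 1 || c + PATCH_HALF > d[2]) {
    stop("patch window exceeds slide bounds at center (",
         center_row, ", ", center_col, ")")
  }
  block <- slide$pixels[(r - PATCH_HALF):(r + PATCH_HALF),
                        (c - PATCH_HALF):(c + PATCH_HALF), , drop = FALSE]
  apply_augmentation(block, tag)
}

#' Augmentation transforms
#'
#' The training-set augmentation comprises the identity, rotations by 90, 180
#' and 270 degrees, and horizontal and vertical mirroring - six transforms in
#' total. Augmentation never changes a patch's label, biopsy or size, and is
#' applied to training patches only.
#'
#' @return character vector of the six transform tags
#' @export
augmentation_tags <- function() {
  c("identity", "rot90", "rot180", "rot270", "mirror_h", "mirror_v")
}

rot90_mat <- function(m) t(m[nrow(m):1, , drop = FALSE])  # 90 deg clockwise

per_channel <- function(a, f) {
  first <- f(a[, , 1])
  out <- array(0, dim = c(dim(first), 3))
  out[, , 1] <- first
  for (ch in 2:3) out[, , ch] <- f(a[, , ch])
  out
}

#' Apply one dihedral transform to an RGB block
#' @param block H x W x 3 array (square for rotations)
#' @param tag one of [augmentation_tags()]
#' @return transformed array
#' @export
apply_augmentation <- function(block, tag) {
  switch(tag,
    identity = block,
    rot90 = per_channel(block, rot90_mat),
    rot180 = per_channel(block, function(m) m[nrow(m):1, ncol(m):1, drop = FALSE]),
    rot270 = per_channel(block, function(m) rot90_mat(rot90_mat(rot90_mat(m)))),
    mirror_h = per_channel(block, function(m) m[, ncol(m):1, drop = FALSE]),
    mirror_v = per_channel(block, function(m) m[nrow(m):1, , drop = FALSE]),
    stop("unknown augmentation tag '", tag, "'")
  )
}

#' Augment a single patch into its six dihedral variants
#'
#' @param patch a list with element `pixels` (299 x 299 x 3 array) and
#'   arbitrary metadata fields (`label`, `biopsy_id`, `center`, ...), or a
#'   bare pixel array
#' @return a list of exactly 6 patches; each keeps all metadata of the input
#'   and gains/overwrites `augmentation_tag`
#' @export
augment_patch <- function(patch) {
  if (is.array(patch)) patch <- list(pixels = patch)
  stopifnot(is.list(patch), is.array(patch$pixels))
  lapply(augmentation_tags(), function(tag) {
    out <- patch
    out$pixels <- apply_augmentation(patch$pixels, tag)
    out$augmentation_tag <- tag
    out
  })
}

#' Expand a patch manifest with the six augmentation tags
#'
#' Replicates every manifest row once per transform in [augmentation_tags()],
#' recording the tag in `augmentation_tag`. Used when assembling training
#' sets; test patches stay un-augmented.
#'
#' @param patches a patch manifest `data.frame`
#' @return the expanded manifest
#' @export
expand_augmentations <- function(patches) {
  tags <- augmentation_tags()
  out <- patches[rep(seq_len(nrow(patches)), each = length(tags)), , drop = FALSE]
  out$augmentation_tag <- rep(tags, times = nrow(patches))
  rownames(out) <- NULL
  out
}
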