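# Multi-scale color/texture summary features for a patch.
#
# The central pixel defines a patch's class, so features are computed at
# three nested scales (full 299 window, central 99 and central 33 crops):
# the inner crops make thin structures around the center dominate at least
# one scale even when the full window mostly shows neighboring tissue.
# Per crop and channel: mean and standard deviation; per crop: mean absolute
# horizontal+vertical gradient of the gray image (texture granularity).

FEATURE_SCALES <- c(299L, 99L, 33L)

central_crop <- function(block, side) {
  n <- dim(block)[1]
  if (side >= n) return(block)
  lo <- (n - side) %/% 2 + 1L
  block[lo:(lo + side - 1L), lo:(lo + side - 1L), , drop = FALSE]
}

crop_features <- function(block) {
  gray <- (block[, , 1] + block[, , 2] + block[, , 3]) / 3
  gx <- abs(gray[, -1, drop = FALSE] - gray[, -ncol(gray), drop = FALSE])
  gy <- abs(gray[-1, , drop = FALSE] - gray[-nrow(gray), , drop = FALSE])
  c(vapply(1:3, function(ch) mean(block[, , ch]), numeric(1)),
    vapply(1:3, function(ch) stats::sd(block[, , ch]), numeric(1)),
    mean(gx) + mean(gy),
    stats::sd(gray))
}

#' Summary features of one patch pixel block
#'
#' @param block a 299 x 299 x 3 array (any square RGB block works)
#' @return named numeric feature vector
#' @export
patch_feature_vector <- function(block) {
  out <- unlist(lapply(FEATURE_SCALES, function(s) {
    f <- crop_features(central_crop(block, s))
    names(f) <- sprintf("s%d_%s", s,
                        c("mean_r", "mean_g", "mean_b",
                          "sd_r", "sd_g", "sd_b", "grad", "sd_gray"))
    f
  }))
  out
}

#' Feature matrix for a patch manifest
#'
#' Materializes each patch (honoring an `augmentation_tag` column if present)
#' from its parent slide and computes [patch_feature_vector()] row by row.
#'
#' @param patches patch manifest `data.frame`
#' @param slides named list of [slide_image()]s keyed by `slide_id`
#' @return numeric matrix, one row per manifest row
#' @export
featurize_patches <- function(patches, slides) {
  stopifnot(is.data.frame(patches))
  tags <- if ("augmentation_tag" %in% names(patches)) {
    patches$augmentation_tag
  } else {
    rep("identity", nrow(patches))
  }
  rows <- lapply(seq_len(nrow(patches)), function(i) {
    sl <- slides[[patches$slide_id[i]]]
    if (is.null(sl)) stop("slide '", patches$slide_id[i], "' not supplied")
    patch_feature_vector(
      patch_pixels(sl, patches$center_row[i], patches$center_col[i], tags[i])
    )
  })
  m <- do.call(rbind, rows)
  rownames(m) <- patches$patch_id
  m
}
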