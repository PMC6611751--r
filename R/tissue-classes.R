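#' Tissue classes and fused decision classes
#'
#' The patch classifier distinguishes four tissue classes: unaffected prostate
#' stroma, non-atypical glands (healthy glands and low-grade PIN), Gleason
#' pattern 3, and Gleason pattern >= 4 (patterns 4 and 5 merged, including the
#' affected stroma). Post-classification, stroma and non-atypical glands are
#' fused into a single "non-atypical" decision class, leaving three classes
#' for slide-level grading.
#'
#' @return `tissue_classes()` returns the four class codes in canonical order;
#'   `fused_classes()` the three decision-class codes;
#'   `tissue_class_names()` a named vector of human-readable display names.
#' @export
tissue_classes <- function() {
  c("stroma", "benign_gland", "gp3", "gp4plus")
}

#' @rdname tissue_classes
#' @export
fused_classes <- function() {
  c("non_atypical", "gp3", "gp4plus")
}

#' @rdname tissue_classes
#' @export
tissue_class_names <- function() {
  c(stroma = "Unaffected stroma",
    benign_gland = "Non-atypical gland",
    gp3 = "Gleason pattern 3",
    gp4plus = "Gleason pattern >= 4")
}

# Integer codes used in label masks. 0 = unlabeled, -1 = excluded.
MASK_UNLABELED <- 0L
MASK_EXCLUDED <- -1L

#' Map a tissue class code to its label-mask integer code
#' @param class character vector of tissue class codes
#' @return integer codes (1..4 in the order of [tissue_classes()])
#' @export
tissue_class_code <- function(class) {
  code <- match(class, tissue_classes())
  if (anyNA(code)) {
    stop("unknown tissue class: ", paste(class[is.na(code)], collapse = ", "))
  }
  code
}

#' Merge four-class tissue labels into the three fused decision classes
#'
#' Stroma and non-atypical gland collapse to `non_atypical`; the two malignant
#' patterns map to themselves.
#'
#' @param label character vector of tissue class codes
#' @return character vector of fused class codes
#' @export
fuse_labels <- function(label) {
  stopifnot(all(label %in% tissue_classes()))
  ifelse(label %in% c("stroma", "benign_gland"), "non_atypical", label)
}

# Patch geometry: class is defined by the central pixel of a 299 x 299 window
# (~150 x 150 um at 0.5 um/pixel).
PATCH_SIZE <- 299L
PATCH_HALF <- 149L

#' Patch geometry constants
#'
#' Patches are 299 x 299 pixel RGB blocks; the central pixel defines the
#' class, so an eligible patch center must be at least 149 pixels from every
#' slide edge.
#' @return `patch_size()` the window side in pixels; `patch_half()` the
#'   center-to-edge margin.
#' @export
patch_size <- function() PATCH_SIZE

#' @rdname patch_size
#' @export
patch_half <- function() PATCH_HALF
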