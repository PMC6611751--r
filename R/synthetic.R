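# Procedural pseudo-histology: annotated slides with four visually distinct
# texture classes and controllable Gleason-pattern composition, so the whole
# pipeline is testable end-to-end without any real tissue data.

# H&E-like palette. Class colors interpolate from a common mean toward
# class-specific targets as texture_separation goes 0 -> 1, so separation
# near 0 yields a deliberately hard cohort.
SYNTH_BASE <- c(0.82, 0.62, 0.72)
SYNTH_TARGETS <- list(
  stroma = c(0.96, 0.78, 0.86),   # pale pink fibrous stroma
  benign_gland = c(0.88, 0.68, 0.92),  # light purple glands
  gp3 = c(0.70, 0.45, 0.72),      # mid purple, discrete glands
  gp4plus = c(0.52, 0.32, 0.58)   # dense dark purple
)
# blob geometry per class: radius (px), spacing (px between blob centers),
# darkening applied inside blobs
SYNTH_BLOBS <- list(
  stroma = list(radius = 0, spacing = Inf, delta = 0),
  benign_gland = list(radius = 16, spacing = 42, delta = 0.18),
  gp3 = list(radius = 8, spacing = 20, delta = 0.22),
  gp4plus = list(radius = 4, spacing = 9, delta = 0.25)
)

check_composition <- function(composition) {
  stopifnot(is.numeric(composition))
  if (is.null(names(composition))) names(composition) <- tissue_classes()
  if (!setequal(names(composition), tissue_classes())) {
    stop("composition must be named with the four tissue classes")
  }
  composition <- composition[tissue_classes()]
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-9) {
    stop("composition fractions must be non-negative and sum to 1")
  }
  composition
}

#' Generate one annotated synthetic biopsy slide
#'
#' Draws an elongated tissue band on a white background, split along its
#' length into contiguous class regions with areas proportional to
#' `composition`. Each class is rendered as a distinct procedural texture
#' (class-specific H&E-like base color plus a blob pattern mimicking gland
#' density), with color and pattern contrast scaled by `texture_separation`.
#' Matching rectangular polygon annotations are returned alongside; a region
#' too narrow to contain any eligible patch center is dropped from the
#' annotations (and not rendered) with a warning.
#'
#' Malignant regions are placed in the interior of the band so that even thin
#' regions remain reachable by the interior-window patch sampler.
#'
#' @param composition named fractions over [tissue_classes()], summing to 1
#' @param size slide `c(height, width)` in pixels, each >= 600
#' @param seed integer seed; same seed gives a bit-identical slide
#' @param biopsy_id biopsy identifier recorded in every region
#' @param texture_separation inter-class color/texture distance in `(0, 1]`
#' @return list with elements `slide` (a [slide_image()]) and `ann`
#'   (an [annotation_set()])
#' @export
generate_slide <- function(composition, size = c(600L, 2000L), seed = 1L,
                           biopsy_id = "b1", texture_separation = 1.0) {
  composition <- check_composition(composition)
  stopifnot(length(size) == 2, all(size >= 600),
            texture_separation > 0, texture_separation <= 1)
  H <- as.integer(size[1]); W <- as.integer(size[2])
  y0 <- 60L; y1 <- H - 61L           # band rows (0-based, inclusive)
  x0 <- 20L; x1 <- W - 21L           # band columns
  # malignant stripes sit mid-band: stroma | gp3 | gp4plus | benign
  stripe_order <- c("stroma", "gp3", "gp4plus", "benign_gland")
  fr <- composition[stripe_order]
  bounds <- x0 + round(cumsum(c(0, fr)) * (x1 - x0 + 1L))
  regions <- list()
  for (i in seq_along(stripe_order)) {
    if (fr[i] <= 0) next
    lo <- bounds[i]; hi <- bounds[i + 1] - 1L
    if (hi < lo) next
    # eligible centers need the full patch window inside the slide
    reachable <- hi >= PATCH_HALF && lo <= W - 1L - PATCH_HALF &&
      y1 >= PATCH_HALF && y0 <= H - 1L - PATCH_HALF
    if (!reachable) {
      warning("region '", stripe_order[i], "' of biopsy ", biopsy_id,
              " too small/peripheral for any patch; dropped", call. = FALSE)
      next
    }
    regions[[length(regions) + 1L]] <- list(
      polygon = cbind(x = c(lo, hi, hi, lo), y = c(y0, y0, y1, y1)),
      class = stripe_order[i], biopsy_id = biopsy_id
    )
  }
  ann <- annotation_set(regions)
  mask <- rasterize(ann, H, W)
  s <- texture_separation
  px <- array(1, dim = c(H, W, 3))  # white background
  # blob patterns accumulate into one shared brightness-delta layer, applied
  # to all channels at the end (keeps rendering O(pixels), not O(blobs * HW))
  delta <- matrix(0, H, W)
  with_stream(seed, paste0("render_", biopsy_id), {
    for (k in seq_along(tissue_classes())) {
      cls <- tissue_classes()[k]
      idx <- which(mask == k)
      if (!length(idx)) next
      base <- SYNTH_BASE + s * (SYNTH_TARGETS[[cls]] - SYNTH_BASE)
      for (ch in 1:3) {
        layer <- px[, , ch]
        layer[idx] <- base[ch] + stats::rnorm(length(idx), sd = 0.02)
        px[, , ch] <- layer
      }
      bl <- SYNTH_BLOBS[[cls]]
      if (bl$radius > 0) {
        rows0 <- (idx - 1L) %% H
        cols0 <- (idx - 1L) %/% H
        n_blobs <- max(1L, round(length(idx) / bl$spacing^2))
        pick <- sample.int(length(idx), n_blobs, replace = TRUE)
        for (b in seq_len(n_blobs)) {
          cr <- rows0[pick[b]]; cc <- cols0[pick[b]]
          rr <- max(0L, cr - bl$radius):min(H - 1L, cr + bl$radius)
          cc2 <- max(0L, cc - bl$radius):min(W - 1L, cc + bl$radius)
          subr <- rep(rr, times = length(cc2))
          subc <- rep(cc2, each = length(rr))
          d2 <- (subr - cr)^2 + (subc - cc)^2
          lin <- subr + 1L + subc * H
          ok <- mask[lin] == k
          inside <- d2 <= bl$radius^2 & ok
          # benign glands get a lumen: lighten the blob core instead
          lumen <- cls == "benign_gland" & d2 <= (bl$radius * 0.55)^2 & ok
          delta[lin[inside & !lumen]] <- -s * bl$delta
          delta[lin[lumen]] <- s * 0.12
        }
      }
    }
  })
  if (any(delta != 0)) for (ch in 1:3) px[, , ch] <- px[, , ch] + delta
  px[px < 0] <- 0; px[px > 1] <- 1
  px <- round(px * 255) / 255  # 8-bit grid, so disk round-trips are exact
  list(slide = slide_image(px, slide_id = biopsy_id), ann = ann)
}

#' Default per-biopsy compositions of the synthetic cohort
#'
#' Eight compositions spanning benign slides and adjusted grade groups 1-4,
#' including biopsies whose secondary pattern sits below the 4.5% presence
#' threshold (exercising the doubling rule at both ends of the scale).
#'
#' @return list of named fraction vectors over [tissue_classes()]
#' @export
default_cohort_compositions <- function() {
  list(  # spans benign and adjusted grade groups 1-4
    c(stroma = 0.50, benign_gland = 0.50, gp3 = 0.00, gp4plus = 0.00),
    c(stroma = 0.60, benign_gland = 0.40, gp3 = 0.00, gp4plus = 0.00),
    c(stroma = 0.30, benign_gland = 0.20, gp3 = 0.48, gp4plus = 0.02),
    c(stroma = 0.28, benign_gland = 0.17, gp3 = 0.53, gp4plus = 0.02),
    c(stroma = 0.20, benign_gland = 0.15, gp3 = 0.45, gp4plus = 0.20),
    c(stroma = 0.20, benign_gland = 0.15, gp3 = 0.20, gp4plus = 0.45),
    c(stroma = 0.25, benign_gland = 0.20, gp3 = 0.03, gp4plus = 0.52),
    c(stroma = 0.28, benign_gland = 0.10, gp3 = 0.02, gp4plus = 0.60)
  )
}

#' Specification of a synthetic cohort
#'
#' @param n_biopsies number of biopsies (compositions are recycled)
#' @param compositions list of per-biopsy compositions (named fractions over
#'   [tissue_classes()] summing to 1); the default set spans benign slides
#'   and adjusted grade groups 1-4
#' @param texture_separation inter-class texture distance in `(0, 1]`
#' @param seed integer seed
#' @return a `cohort_spec`
#' @export
cohort_spec <- function(n_biopsies = 8L,
                        compositions = default_cohort_compositions(),
                        texture_separation = 1.0, seed = 1L) {
  stopifnot(n_biopsies >= 1)
  compositions <- lapply(compositions, check_composition)
  structure(list(n_biopsies = as.integer(n_biopsies),
                 compositions = compositions,
                 texture_separation = texture_separation, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with ground-truth grades
#'
#' Generates one slide per biopsy and computes each biopsy's true adjusted
#' grade group by applying the grading rule to its true area fractions.
#' When `out_dir` is given, writes `slide_<id>.png` (+ metadata sidecars),
#' `slide_<id>.geojson` and `ground_truth.csv` there.
#'
#' @param spec a [cohort_spec()]
#' @param out_dir optional output directory
#' @param size per-slide `c(height, width)`
#' @param cfg [grading_config()] used for the ground-truth grades
#' @return list with `slides` (named list of [slide_image()]),
#'   `annotations` (named list of [annotation_set()]) and `truth`
#'   (`data.frame` of true fractions and adjusted grade group per biopsy)
#' @export
generate_cohort <- function(spec = cohort_spec(), out_dir = NULL,
                            size = c(600L, 2000L), cfg = grading_config()) {
  stopifnot(inherits(spec, "cohort_spec"))
  ids <- sprintf("b%02d", seq_len(spec$n_biopsies))
  slides <- list(); anns <- list(); truth <- list()
  for (i in seq_len(spec$n_biopsies)) {
    comp <- spec$compositions[[(i - 1L) %% length(spec$compositions) + 1L]]
    g <- generate_slide(comp, size = size,
                        seed = stream_seed(spec$seed, paste0("cohort_", i)),
                        biopsy_id = ids[i],
                        texture_separation = spec$texture_separation)
    slides[[ids[i]]] <- g$slide
    anns[[ids[i]]] <- g$ann
    truth[[i]] <- assign_adjusted_gg(comp[["gp3"]], comp[["gp4plus"]], cfg,
                                     biopsy_id = ids[i])
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (id in ids) {
      save_slide(slides[[id]], file.path(out_dir, paste0("slide_", id, ".png")))
      save_annotations(anns[[id]], file.path(out_dir, paste0("slide_", id, ".geojson")))
    }
    utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  list(slides = slides, annotations = anns, truth = truth, spec = spec)
}
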