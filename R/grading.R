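#' Configuration of the adjusted grade-group rule
#'
#' A Gleason pattern must cover at least `min_fraction` of a biopsy's
#' classified patches to count as present (default 4.5%, suppressing noise).
#' The adjusted grade groups merge GP4 and GP5, giving a four-level scale
#' keyed by the (majority, minority) pattern pair:
#'
#' | adjusted GG | patterns            |
#' |-------------|---------------------|
#' | 1           | GP3 + GP3           |
#' | 2           | GP3 + GP>=4         |
#' | 3           | GP>=4 + GP3         |
#' | 4           | GP>=4 + GP>=4       |
#'
#' When only one pattern is present it is doubled (counted as both majority
#' and minority); when neither is present the biopsy is benign.
#'
#' @param min_fraction presence threshold in `[0, 1]`
#' @return a `grading_config`
#' @export
grading_config <- function(min_fraction = 0.045) {
  stopifnot(is.numeric(min_fraction), min_fraction >= 0, min_fraction <= 1)
  mapping <- c("gp3+gp3" = 1L, "gp3+gp4plus" = 2L,
               "gp4plus+gp3" = 3L, "gp4plus+gp4plus" = 4L)
  structure(list(min_fraction = min_fraction, mapping = mapping),
            class = "grading_config")
}

#' Grade-group levels, benign included
#'
#' Ordered levels of the slide-level outcome: `benign` (neither pattern
#' reaches the presence threshold) below adjusted grade groups 1-4.
#' @return character vector of the five ordered levels
#' @export
gg_levels <- function() c("benign", "1", "2", "3", "4")

#' Gleason-pattern fractions of one biopsy's patch labels
#'
#' @param labels non-empty vector of fused class labels
#'   (`non_atypical` / `gp3` / `gp4plus`)
#' @return named numeric `c(frac_gp3 = , frac_gp4plus = )`; denominators are
#'   all classified patches, non-atypical ones included
#' @export
compute_fractions <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0) stop("empty label list")
  if (!all(labels %in% fused_classes())) {
    stop("labels outside the fused class set")
  }
  c(frac_gp3 = mean(labels == "gp3"),
    frac_gp4plus = mean(labels == "gp4plus"))
}

#' Adjusted grade group from Gleason-pattern fractions
#'
#' Patterns below the presence threshold are treated as absent. Both absent:
#' benign. One present: that pattern is doubled. Both present: the larger
#' fraction is the majority (an exact tie grades up - GP >= 4 is taken as
#' majority), and the (majority, minority) pair indexes the adjusted
#' grade-group table.
#'
#' @param frac_gp3,frac_gp4plus pattern fractions in `[0, 1]`, sum <= 1
#' @param cfg a [grading_config()]
#' @param biopsy_id optional identifier carried into the result
#' @return a one-row `data.frame`: `biopsy_id`, `frac_gp3`, `frac_gp4plus`,
#'   `majority`, `minority` (NA when benign) and `adjusted_gg` (factor with
#'   [gg_levels()])
#' @export
assign_adjusted_gg <- function(frac_gp3, frac_gp4plus, cfg = grading_config(),
                               biopsy_id = NA_character_) {
  stopifnot(inherits(cfg, "grading_config"))
  if (frac_gp3 < 0 || frac_gp3 > 1 || frac_gp4plus < 0 || frac_gp4plus > 1 ||
      frac_gp3 + frac_gp4plus > 1 + 1e-9) {
    stop("pattern fractions must lie in [0, 1] and sum to at most 1")
  }
  # a pattern is present when it reaches the threshold and actually occurs
  # (a zero threshold must not count absent patterns as present)
  p3 <- frac_gp3 >= cfg$min_fraction && frac_gp3 > 0
  p4 <- frac_gp4plus >= cfg$min_fraction && frac_gp4plus > 0
  if (!p3 && !p4) {
    majority <- minority <- NA_character_
    gg <- "benign"
  } else if (p3 && !p4) {
    majority <- minority <- "gp3"
    gg <- as.character(cfg$mapping[["gp3+gp3"]])
  } else if (!p3 && p4) {
    majority <- minority <- "gp4plus"
    gg <- as.character(cfg$mapping[["gp4plus+gp4plus"]])
  } else {
    if (frac_gp4plus >= frac_gp3) {  # tie grades up
      majority <- "gp4plus"; minority <- "gp3"
    } else {
      majority <- "gp3"; minority <- "gp4plus"
    }
    gg <- as.character(cfg$mapping[[paste(majority, minority, sep = "+")]])
  }
  data.frame(biopsy_id = biopsy_id, frac_gp3 = frac_gp3,
             frac_gp4plus = frac_gp4plus, majority = majority,
             minority = minority,
             adjusted_gg = factor(gg, levels = gg_levels(), ordered = TRUE),
             stringsAsFactors = FALSE)
}

#' Grade every biopsy of a fused patch-label table
#'
#' @param fused `data.frame` with columns `biopsy_id` and `fused_label`
#' @param cfg a [grading_config()]
#' @return a `data.frame` with one row per biopsy (ordered by `biopsy_id`),
#'   the columns of [assign_adjusted_gg()]
#' @export
grade_cohort <- function(fused, cfg = grading_config()) {
  stopifnot(all(c("biopsy_id", "fused_label") %in% names(fused)))
  ids <- sort(unique(fused$biopsy_id))
  out <- lapply(ids, function(b) {
    fr <- compute_fractions(fused$fused_label[fused$biopsy_id == b])
    assign_adjusted_gg(fr[["frac_gp3"]], fr[["frac_gp4plus"]], cfg,
                       biopsy_id = b)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Reference grade group from annotated surface areas
#'
#' The reference standard grades a biopsy from the annotated surface area of
#' each Gleason pattern (rather than from classified patch counts): pattern
#' fractions are pixel areas of the rasterized annotations of that biopsy,
#' divided by its total annotated (non-excluded) area, then passed through
#' the same adjusted grade-group rule.
#'
#' @param ann an [annotation_set()]
#' @param height,width slide dimensions
#' @param cfg a [grading_config()]
#' @return a `data.frame` with one row per biopsy id in `ann`
#' @export
reference_grade_from_annotations <- function(ann, height, width,
                                             cfg = grading_config()) {
  mask <- rasterize(ann, height, width)
  regmap <- rasterize_regions(ann, height, width)
  out <- lapply(sort(biopsy_ids(ann)), function(b) {
    ridx <- which(vapply(ann$regions, `[[`, "", "biopsy_id") == b)
    sel <- regmap %in% ridx & mask > 0
    total <- sum(sel)
    if (total == 0) stop("biopsy '", b, "' has no labeled area")
    assign_adjusted_gg(sum(mask[sel] == tissue_class_code("gp3")) / total,
                       sum(mask[sel] == tissue_class_code("gp4plus")) / total,
                       cfg, biopsy_id = b)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
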