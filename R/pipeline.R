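#' End-to-end whole-slide grading pipeline on a cohort
#'
#' Runs the full method on a cohort of annotated slides: balanced patch
#' sampling, biopsy-exclusive four-fold partitioning with downsampling to the
#' smallest class, four-fold cross-validated patch classification, SVM fusion
#' of the four class probabilities into three decision classes, grid-based
#' slide grading by Gleason-pattern patch fractions, and agreement statistics
#' against the supplied ground truth.
#'
#' Each biopsy's grading patches are predicted by the fold model that held
#' that biopsy out, so slide grades are leakage-free.
#'
#' @param cohort a cohort as returned by [generate_cohort()]: list with
#'   `slides`, `annotations` and `truth` (`truth` needs `biopsy_id` and
#'   `adjusted_gg`)
#' @param n_per_class patches sampled per class per slide for training
#' @param seed integer seed driving every stage
#' @param backend patch-classifier backend (see [classifier_backend()])
#' @param k number of cross-validation partitions
#' @param grid_stride spacing of the grading patch grid in pixels
#' @param cfg [grading_config()]
#' @param map_slides slide ids for which fused probability maps are built
#'   (default none; map building is cheap but rarely needed in batch runs)
#' @param map_stride probability-map cell size in pixels
#' @return list with `cv_table`, `models`, `patch_recall`, `fusion`,
#'   `fused_patches` (grading-grid patches with fused probabilities and
#'   labels), `grades`, `comparison` (truth vs predicted per biopsy),
#'   `agreement` (confusion matrix, concordance, quadratic weighted kappa)
#'   and `maps`
#' @export
run_grading_pipeline <- function(cohort, n_per_class = 40L, seed = 1L,
                                 backend = "multinom", k = 4L,
                                 grid_stride = 50L, cfg = grading_config(),
                                 map_slides = character(),
                                 map_stride = 149L) {
  stopifnot(all(c("slides", "annotations", "truth") %in% names(cohort)))
  slides <- cohort$slides
  anns <- cohort$annotations
  masks <- lapply(names(slides), function(id) {
    d <- slide_dim(slides[[id]])
    rasterize(anns[[id]], d[1], d[2])
  })
  names(masks) <- names(slides)
  # benign slides legitimately lack malignant classes; silence the
  # per-class zero-eligibility warnings for them
  patches <- do.call(rbind, lapply(names(slides), function(id) {
    suppressWarnings(
      sample_patches(slides[[id]], masks[[id]], anns[[id]],
                     n_per_class = n_per_class,
                     seed = stream_seed(seed, paste0("sample_", id)))
    )
  }))
  ps <- build_partitions(patches, k = k, seed = seed)
  ps <- balance_to_smallest_class(ps, seed = seed)
  cv <- cross_validate(ps, slides, seed = seed, backend = backend)
  recall <- patch_recall(cv$table)
  fusion <- fit_fusion(cv$table, seed = seed)

  fused_patches <- do.call(rbind, lapply(names(slides), function(id) {
    grid <- grid_patches(slides[[id]], masks[[id]], anns[[id]],
                         stride = grid_stride)
    if (nrow(grid) == 0) return(NULL)
    out <- lapply(split(grid, grid$biopsy_id), function(gb) {
      fold <- unname(ps$assignment[gb$biopsy_id[1]])
      if (is.na(fold)) {
        stop("biopsy '", gb$biopsy_id[1], "' missing from the partition set")
      }
      p <- predict_patch_proba(cv$models[[fold]], gb, slides)
      q <- fuse(fusion, p)
      lab <- assign_label(q)
      colnames(q) <- paste0("q_", fused_classes())
      cbind(gb, as.data.frame(q), fused_label = lab, fold = fold)
    })
    do.call(rbind, out)
  }))
  rownames(fused_patches) <- NULL

  grades <- grade_cohort(fused_patches, cfg)
  truth <- cohort$truth
  comparison <- merge(
    data.frame(biopsy_id = truth$biopsy_id,
               true_gg = as.character(truth$adjusted_gg)),
    data.frame(biopsy_id = grades$biopsy_id,
               predicted_gg = as.character(grades$adjusted_gg)),
    by = "biopsy_id", all = TRUE
  )
  agreement <- grading_agreement(comparison$true_gg, comparison$predicted_gg)

  maps <- lapply(intersect(map_slides, names(slides)), function(id) {
    rows <- fused_patches[fused_patches$slide_id == id, , drop = FALSE]
    build_probability_map(slides[[id]], rows, stride_pixels = map_stride)
  })
  names(maps) <- intersect(map_slides, names(slides))

  list(cv_table = cv$table, models = cv$models, partition_set = ps,
       patch_recall = recall, fusion = fusion,
       fused_patches = fused_patches, grades = grades,
       comparison = comparison, agreement = agreement, maps = maps)
}
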