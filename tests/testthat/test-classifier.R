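make_four_color_cohort <- function(n_slides_per_class = 2, seed = 10) {
  # one flat-texture slide per (class, replicate); colors well separated
  colors <- list(stroma = c(0.95, 0.78, 0.85), benign_gland = c(0.85, 0.65, 0.9),
                 gp3 = c(0.7, 0.45, 0.72), gp4plus = c(0.5, 0.3, 0.58))
  slides <- list(); manifests <- list()
  i <- 0
  for (cls in tissue_classes()) {
    for (r in seq_len(n_slides_per_class)) {
      i <- i + 1
      id <- sprintf("%s_%d", cls, r)
      sl <- make_color_slide(colors[[cls]], size = 320, seed = seed + i,
                             slide_id = id)
      ann <- annotation_set(list(rect_region(cls, id, 0, 0, 319, 319)))
      mask <- rasterize(ann, 320, 320)
      slides[[id]] <- sl
      # monochrome slides lack the other three classes; the per-class
      # zero-eligibility warnings are expected here
      manifests[[id]] <- suppressWarnings(
        sample_patches(sl, mask, ann, n_per_class = 12, seed = seed + 100 + i)
      )
    }
  }
  list(slides = slides, patches = do.call(rbind, manifests))
}

test_that("reference classifier separates distinct textures and honors the contract", {
  co <- make_four_color_cohort()
  # replicate 1 slides train, replicate 2 slides test: held-out biopsies
  train <- co$patches[grepl("_1$", co$patches$biopsy_id), ]
  test <- co$patches[grepl("_2$", co$patches$biopsy_id), ]
  clf <- fit_reference_classifier(train, co$slides, seed = 1,
                                  backend = "multinom", augment = FALSE)
  p <- predict_patch_proba(clf, test, co$slides)
  # probability contract: 4-vectors summing to 1
  expect_equal(dim(p), c(nrow(test), 4))
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  expect_true(all(p >= 0 & p <= 1))
  # per-class recall on held-out slides
  pred <- tissue_classes()[max.col(p, ties.method = "first")]
  for (cls in tissue_classes()) {
    expect_gte(mean(pred[test$label == cls] == cls), 0.9)
  }
})

test_that("fitting is reproducible under a seed and rejects single-class input", {
  co <- make_four_color_cohort(n_slides_per_class = 1, seed = 30)
  clf1 <- fit_reference_classifier(co$patches, co$slides, seed = 5,
                                   augment = FALSE)
  clf2 <- fit_reference_classifier(co$patches, co$slides, seed = 5,
                                   augment = FALSE)
  probe <- co$patches[seq(1, nrow(co$patches), by = 5), ]
  expect_equal(predict_patch_proba(clf1, probe, co$slides),
               predict_patch_proba(clf2, probe, co$slides))
  single <- co$patches[co$patches$label == "gp3", ]
  expect_error(fit_reference_classifier(single, co$slides, seed = 1),
               "single class")
})

test_that("the nnet backend honors the same contract", {
  co <- make_four_color_cohort(n_slides_per_class = 1, seed = 50)
  clf <- fit_reference_classifier(co$patches, co$slides, seed = 2,
                                  backend = "nnet", augment = FALSE)
  p <- predict_patch_proba(clf, co$patches, co$slides)
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  clf2 <- fit_reference_classifier(co$patches, co$slides, seed = 2,
                                   backend = "nnet", augment = FALSE)
  expect_equal(predict_patch_proba(clf2, co$patches, co$slides), p)
})

test_that("cross-validation bookkeeping: rows, folds, leakage, oracle recall", {
  patches <- fake_manifest(1, sprintf("b%02d", 1:8),
                           labels = tissue_classes())
  patches <- patches[rep(seq_len(nrow(patches)), each = 5), ]
  patches$patch_id <- sprintf("p%04d", seq_len(nrow(patches)))
  ps <- build_partitions(patches, k = 4, seed = 1)
  cv <- cross_validate(ps, slides = list(), seed = 1,
                       feature_fun = label_feature_fun)
  # one output row per un-augmented patch
  expect_equal(nrow(cv$table), nrow(patches))
  expect_true(all(abs(rowSums(cv$table[, paste0("p_", tissue_classes())]) - 1) < 1e-9))
  # fold equals the patch's partition
  expect_equal(cv$table$fold,
               unname(ps$assignment[cv$table$biopsy_id]))
  # leakage: a tested biopsy is never in its fold's training biopsies
  for (f in 1:4) {
    test_b <- unique(cv$table$biopsy_id[cv$table$fold == f])
    train_b <- names(ps$assignment)[ps$assignment != f]
    expect_length(intersect(test_b, train_b), 0)
  }
  # an oracle feature set gives perfect recall in every fold
  expect_true(all(patch_recall(cv$table) == 1))
  # empty partition is an error
  ps_bad <- ps
  ps_bad$patches <- ps_bad$patches[ps_bad$patches$partition != 2, ]
  expect_error(cross_validate(ps_bad, list(), seed = 1,
                              feature_fun = label_feature_fun),
               "empty partition")
})
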