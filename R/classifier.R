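#' Reference patch-classifier backends
#'
#' The patch classifier is pluggable: any object honoring the contract
#' (deterministic `fit(x, y, seed)` returning a state, and
#' `predict_proba(state, x)` returning a row-normalized probability matrix
#' over the four tissue classes) can drive the cross-validation machinery.
#' Two desk-scale reference backends are shipped, both operating on the
#' multi-scale summary features of [featurize_patches()]:
#'
#' * `"multinom"` - a multinomial log-linear model ([nnet::multinom]);
#'   convex fit, fully deterministic, trains in seconds.
#' * `"nnet"` - a single-hidden-layer neural network ([nnet::nnet]),
#'   seeded random initialization, still CPU-friendly.
#'
#' @param backend `"multinom"` or `"nnet"`
#' @param hidden hidden-layer size for the `"nnet"` backend
#' @param decay weight decay for the `"nnet"` backend
#' @return a `classifier_backend` object with elements `descriptor`, `fit`
#'   and `predict_proba`
#' @export
classifier_backend <- function(backend = c("multinom", "nnet"),
                               hidden = 8L, decay = 1e-3) {
  backend <- match.arg(backend)
  if (backend == "multinom") {
    structure(list(
      descriptor = "multinomial log-linear model on summary features",
      fit = function(x, y, seed) {
        df <- data.frame(.y = y, x, check.names = FALSE)
        # mild weight decay keeps separable fits from blowing up along
        # low-variance noise directions
        with_stream(seed, "fit_multinom",
          nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 400,
                         MaxNWts = 5000, decay = 1e-3)
        )
      },
      predict_proba = function(state, x) {
        p <- stats::predict(state, newdata = as.data.frame(x), type = "probs")
        lev <- state$lev
        if (is.null(dim(p))) {
          if (nrow(x) == 1) {  # single-row predictions drop to a vector
            p <- matrix(p, nrow = 1, dimnames = list(NULL, names(p)))
          } else {             # two-class fits return P(second level)
            p <- cbind(1 - p, p)
            colnames(p) <- lev
          }
        }
        p
      }
    ), class = "classifier_backend")
  } else {
    structure(list(
      descriptor = sprintf("single-hidden-layer neural network (%d units)", hidden),
      fit = function(x, y, seed) {
        ymat <- nnet::class.ind(y)
        with_stream(seed, "fit_nnet", {
          fit <- nnet::nnet(x, ymat, size = hidden, decay = decay,
                            maxit = 500, softmax = TRUE, trace = FALSE)
          fit$.levels <- levels(y)
          fit
        })
      },
      predict_proba = function(state, x) {
        p <- stats::predict(state, x)
        colnames(p) <- state$.levels
        p
      }
    ), class = "classifier_backend")
  }
}

# Expand probability columns to all four tissue classes (classes absent from
# training get probability 0), preserving row normalization.
full_class_proba <- function(p, classes_present) {
  p <- as.matrix(p)
  out <- matrix(0, nrow = nrow(p), ncol = length(tissue_classes()),
                dimnames = list(rownames(p), tissue_classes()))
  out[, classes_present] <- p[, classes_present, drop = FALSE]
  out / pmax(rowSums(out), .Machine$double.eps)
}

#' Train a reference patch classifier
#'
#' Fits a four-class patch classifier on a training manifest. Training
#' patches are expanded with the six dihedral augmentation transforms before
#' featurization; features are standardized by training-set mean and sd.
#'
#' @param train patch manifest `data.frame` of training patches
#' @param slides named list of [slide_image()]s
#' @param seed integer seed
#' @param backend a `classifier_backend` or a backend name
#' @param augment apply the six-transform augmentation (default `TRUE`)
#' @param feature_fun function(manifest, slides) -> feature matrix; defaults
#'   to [featurize_patches()]
#' @return a `patch_classifier` with a [predict_patch_proba()] method
#' @export
fit_reference_classifier <- function(train, slides, seed = 1L,
                                     backend = "multinom", augment = TRUE,
                                     feature_fun = featurize_patches) {
  stopifnot(is.data.frame(train), nrow(train) > 0)
  if (length(unique(train$label)) < 2) {
    stop("training set contains a single class; need at least 2")
  }
  if (is.character(backend)) backend <- classifier_backend(backend)
  stopifnot(inherits(backend, "classifier_backend"))
  manifest <- if (augment) expand_augmentations(train) else train
  x <- feature_fun(manifest, slides)
  mu <- colMeans(x)
  # floor the scale so near-constant features are not amplified into
  # high-leverage noise directions
  sg <- pmax(apply(x, 2, stats::sd), 1e-3)
  xs <- scale(x, center = mu, scale = sg)
  y <- factor(manifest$label,
              levels = intersect(tissue_classes(), unique(manifest$label)))
  state <- backend$fit(xs, y, seed)
  structure(list(
    backend = backend, state = state, center = mu, scale = sg,
    classes = levels(y), feature_fun = feature_fun,
    descriptor = backend$descriptor, seed = seed
  ), class = "patch_classifier")
}

#' Predict four-class probabilities for patches
#'
#' @param clf a `patch_classifier` from [fit_reference_classifier()]
#' @param patches patch manifest `data.frame` (un-augmented)
#' @param slides named list of [slide_image()]s
#' @return matrix with one row per patch and one column per tissue class;
#'   rows sum to 1
#' @export
predict_patch_proba <- function(clf, patches, slides) {
  stopifnot(inherits(clf, "patch_classifier"))
  x <- clf$feature_fun(patches, slides)
  xs <- scale(x, center = clf$center, scale = clf$scale)
  p <- clf$backend$predict_proba(clf$state, xs)
  if (is.null(colnames(p))) colnames(p) <- clf$classes
  full_class_proba(p, clf$classes)
}

#' Four-fold cross-validated patch classification
#'
#' For each fold, a classifier is trained on the other partitions (with
#' augmentation) and predicts every un-augmented patch of the held-out
#' partition, so each probability row comes from a model that never saw the
#' patch's biopsy. The biopsy-exclusivity of the partition set is asserted.
#'
#' @param ps a (balanced) `partition_set`
#' @param slides named list of [slide_image()]s
#' @param seed integer seed
#' @param backend backend name or `classifier_backend`
#' @param augment augment the training patches (default `TRUE`)
#' @param feature_fun feature extractor passed through to the classifier
#' @return list with `table` (a `data.frame`: `patch_id`, `slide_id`,
#'   `biopsy_id`, `fold`, `p_stroma`, `p_benign_gland`, `p_gp3`, `p_gp4plus`,
#'   `true_label`) and `models` (one `patch_classifier` per fold)
#' @export
cross_validate <- function(ps, slides, seed = 1L, backend = "multinom",
                           augment = TRUE, feature_fun = featurize_patches) {
  stopifnot(inherits(ps, "partition_set"))
  sizes <- table(factor(ps$patches$partition, levels = seq_len(ps$k)))
  if (any(sizes == 0)) {
    stop("empty partition(s): ", paste(which(sizes == 0), collapse = ", "))
  }
  # every patch (x augmentation tag) appears in three training folds; with
  # the default extractor, featurize once up front and serve folds from the
  # cache instead of recomputing
  if (identical(feature_fun, featurize_patches)) {
    aug <- if (augment) expand_augmentations(ps$patches) else {
      transform(ps$patches, augmentation_tag = "identity")
    }
    Xaug <- featurize_patches(aug, slides)
    keys <- paste(aug$patch_id, aug$augmentation_tag)
    feature_fun <- function(manifest, slides) {
      tags <- if ("augmentation_tag" %in% names(manifest)) {
        manifest$augmentation_tag
      } else rep("identity", nrow(manifest))
      hit <- match(paste(manifest$patch_id, tags), keys)
      if (anyNA(hit)) return(featurize_patches(manifest, slides))
      Xaug[hit, , drop = FALSE]
    }
  }
  models <- vector("list", ps$k)
  rows <- vector("list", ps$k)
  for (f in seq_len(ps$k)) {
    test <- ps$patches[ps$patches$partition == f, , drop = FALSE]
    train <- ps$patches[ps$patches$partition != f, , drop = FALSE]
    overlap <- intersect(unique(test$biopsy_id), unique(train$biopsy_id))
    if (length(overlap)) {
      stop("biopsy leakage across fold ", f, ": ",
           paste(overlap, collapse = ", "))
    }
    clf <- fit_reference_classifier(train, slides,
                                    seed = stream_seed(seed, paste0("fold", f)),
                                    backend = backend, augment = augment,
                                    feature_fun = feature_fun)
    p <- predict_patch_proba(clf, test, slides)
    rows[[f]] <- data.frame(
      patch_id = test$patch_id, slide_id = test$slide_id,
      biopsy_id = test$biopsy_id, fold = f,
      p_stroma = p[, "stroma"], p_benign_gland = p[, "benign_gland"],
      p_gp3 = p[, "gp3"], p_gp4plus = p[, "gp4plus"],
      true_label = test$label, stringsAsFactors = FALSE
    )
    models[[f]] <- clf
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, models = models)
}

#' Per-class recall from a cross-validation probability table
#'
#' Assigns each patch to its highest-probability class among the four tissue
#' classes and computes recall (correct / reference count) per class.
#'
#' @param cv_table the `table` element of a [cross_validate()] result
#' @return named numeric vector of per-class recall
#' @export
patch_recall <- function(cv_table) {
  pcols <- paste0("p_", tissue_classes())
  pred <- tissue_classes()[max.col(as.matrix(cv_table[, pcols]),
                                   ties.method = "first")]
  vapply(tissue_classes(), function(cls) {
    n <- sum(cv_table$true_label == cls)
    if (n == 0) NA_real_ else sum(pred == cls & cv_table$true_label == cls) / n
  }, numeric(1))
}
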