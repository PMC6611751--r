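#' Confusion matrix of reference vs estimated labels
#'
#' @param reference,estimated equal-length label vectors
#' @param class_order the class labels, in order; every label must appear in
#'   this set
#' @return a k x k numeric matrix (reference on rows, estimated on columns)
#' @export
confusion_matrix <- function(reference, estimated, class_order) {
  if (length(reference) != length(estimated)) {
    stop("reference and estimated must have equal length")
  }
  bad <- setdiff(unique(c(as.character(reference), as.character(estimated))),
                 class_order)
  if (length(bad)) stop("label(s) outside class_order: ",
                        paste(bad, collapse = ", "))
  tab <- table(factor(reference, levels = class_order),
               factor(estimated, levels = class_order))
  m <- matrix(as.numeric(tab), nrow = length(class_order),
              dimnames = list(reference = class_order,
                              estimated = class_order))
  m
}

#' Dichotomized agreement metrics from a multi-class confusion matrix
#'
#' Collapses a confusion matrix to 2 x 2 (positive vs negative class groups)
#' and reports sensitivity, specificity, accuracy, precision, recall and the
#' F-measure `F1 = 2 * precision * recall / (precision + recall)`.
#'
#' The matrix may hold raw counts or row percentages. Rows are first
#' normalized to distributions and then weighted by `class_weights`:
#' `NULL` (default) weights rows by their original sums, which on a count
#' matrix reproduces plain count pooling; `"uniform"` weights every reference
#' class equally, appropriate for row-percentage matrices from a balanced
#' test set.
#'
#' Metrics whose denominator is empty are returned as `NA` rather than 0.
#'
#' @param cm confusion matrix (reference rows x estimated columns)
#' @param positive_classes non-empty proper subset of the class names (or
#'   row indices) counted as positive
#' @param class_weights `NULL`, `"uniform"`, or a per-class numeric vector
#' @return an `agreement_report` list
#' @export
dichotomize_metrics <- function(cm, positive_classes, class_weights = NULL) {
  cm <- as.matrix(cm)
  k <- nrow(cm)
  stopifnot(k == ncol(cm), k >= 2)
  cls <- rownames(cm)
  if (is.null(cls)) cls <- as.character(seq_len(k))
  pos <- if (is.character(positive_classes)) {
    match(positive_classes, cls)
  } else as.integer(positive_classes)
  if (anyNA(pos) || length(pos) == 0 || length(pos) >= k) {
    stop("positive_classes must be a non-empty proper subset of the classes")
  }
  w <- if (is.null(class_weights)) {
    rowSums(cm)
  } else if (identical(class_weights, "uniform")) {
    rep(1, k)
  } else {
    stopifnot(length(class_weights) == k)
    as.numeric(class_weights)
  }
  w <- w / sum(w)
  rs <- rowSums(cm)
  rdist <- cm / ifelse(rs == 0, 1, rs)  # empty rows contribute nothing
  m <- sweep(rdist, 1, w, `*`)  # weighted row distributions
  neg <- setdiff(seq_len(k), pos)
  TP <- sum(m[pos, pos]); FN <- sum(m[pos, neg])
  FP <- sum(m[neg, pos]); TN <- sum(m[neg, neg])
  div <- function(a, b) if (b <= 0) NA_real_ else a / b
  sens <- div(TP, TP + FN)
  spec <- div(TN, TN + FP)
  prec <- div(TP, TP + FP)
  acc <- div(TP + TN, TP + TN + FP + FN)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_ else {
    2 * prec * sens / (prec + sens)
  }
  structure(list(
    sensitivity = sens, specificity = spec,
    accuracy = acc, precision = prec, recall = sens, f_measure = f1,
    positive_classes = cls[pos], class_weights = w
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement_report> positive = {%s}\n  sens %.3f  spec %.3f  acc %.3f  prec %.3f  F1 %.3f\n",
    paste(x$positive_classes, collapse = ", "),
    x$sensitivity, x$specificity, x$accuracy, x$precision, x$f_measure))
  invisible(x)
}

#' Exact agreement (concordance) of a square confusion matrix
#' @param cm square count matrix
#' @return trace / total, in `[0, 1]`
#' @export
concordance <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm))
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix has zero total")
  sum(diag(cm)) / total
}

#' Quadratic weighted kappa of an ordinal confusion matrix
#'
#' Chance-corrected agreement for ordinal scales, weighting agreement by
#' `w_ij = 1 - (i - j)^2 / (k - 1)^2`: the observed weighted agreement is
#' compared with the expectation under independent margins,
#' `kappa = (p_o - p_e) / (1 - p_e)`.
#'
#' @param cm square count matrix over an ordered scale (reference rows,
#'   estimated columns, categories in scale order)
#' @return kappa in `[-1, 1]`; `NA` (with a warning) when the margins are
#'   degenerate (chance agreement is already perfect)
#' @export
quadratic_weighted_kappa <- function(cm) {
  cm <- as.matrix(cm)
  k <- nrow(cm)
  stopifnot(k == ncol(cm), k >= 2)
  n <- sum(cm)
  if (n <= 0) stop("confusion matrix has zero total")
  i <- row(cm); j <- col(cm)
  w <- 1 - (i - j)^2 / (k - 1)^2
  po <- sum(w * cm) / n
  expected <- outer(rowSums(cm), colSums(cm)) / n
  pe <- sum(w * expected) / n
  if (abs(1 - pe) < 1e-12) {
    warning("degenerate margins: expected weighted agreement is 1; ",
            "kappa undefined", call. = FALSE)
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Full agreement report for a slide-level grading comparison
#'
#' Convenience wrapper bundling the confusion matrix, concordance and
#' quadratic weighted kappa for two grade vectors on an ordinal scale.
#'
#' @param reference,estimated label vectors on an ordered scale
#' @param class_order ordered scale levels (default [gg_levels()])
#' @return list with `confusion`, `concordance`, `kappa_quadratic`, `n`
#' @export
grading_agreement <- function(reference, estimated, class_order = gg_levels()) {
  cm <- confusion_matrix(reference, estimated, class_order)
  list(confusion = cm,
       concordance = concordance(cm),
       kappa_quadratic = quadratic_weighted_kappa(cm),
       n = length(reference))
}

#' Published benchmark confusion matrices
#'
#' Two confusion matrices shipped as plain-text fixtures for validating the
#' evaluation statistics against published reference values from a four-fold
#' cross-validated Gleason grading study:
#'
#' * `"patch_rowpct"`: 3 x 3 row-percentage matrix of patch-level
#'   classification (non-atypical / GP3 / GP >= 4), balanced test classes.
#' * `"adjusted_gg"`: 4 x 4 count matrix of slide-level adjusted grade groups
#'   over 40 biopsies.
#'
#' @param name which benchmark table to load
#' @return a numeric matrix with class dimnames
#' @export
benchmark_confusion <- function(name = c("patch_rowpct", "adjusted_gg")) {
  name <- match.arg(name)
  f <- system.file("extdata",
                   paste0("benchmark_", name, "_confusion.csv"),
                   package = "gleasonpatch", mustWork = TRUE)
  df <- utils::read.csv(f, check.names = FALSE)
  m <- as.matrix(df[, -1])
  dimnames(m) <- list(reference = df[[1]], estimated = colnames(df)[-1])
  m
}
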