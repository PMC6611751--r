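#' Fit the probability-fusion post-classifier
#'
#' Merges the four patch-class probabilities into three decision classes
#' (non-atypical, GP3, GP >= 4) with a max-margin classifier: a linear-kernel
#' support vector machine trained on the 4-probability vectors against the
#' fused targets (stroma and benign gland collapsed to non-atypical). The
#' regularization cost is chosen by internal 3-fold cross-validation over a
#' small grid; decision values are converted to class probabilities by
#' pairwise coupling with sigmoid calibration, so outputs are valid fused
#' probability vectors.
#'
#' If the input probability vectors are (near-)constant the SVM is degenerate;
#' a warning is raised and a majority-class fallback model is returned.
#'
#' @param prob_table `data.frame` with columns `p_stroma`, `p_benign_gland`,
#'   `p_gp3`, `p_gp4plus` and `true_label` (four-class labels), typically the
#'   cross-validated table from [cross_validate()]
#' @param seed integer seed
#' @param cost_grid candidate SVM cost values
#' @return a `fusion_model`
#' @export
fit_fusion <- function(prob_table, seed = 1L, cost_grid = c(0.1, 1, 10, 100)) {
  pcols <- paste0("p_", tissue_classes())
  stopifnot(all(pcols %in% names(prob_table)), "true_label" %in% names(prob_table))
  x <- as.matrix(prob_table[, pcols])
  y <- factor(fuse_labels(prob_table$true_label), levels = fused_classes())
  missing <- setdiff(fused_classes(), unique(as.character(y)))
  if (length(missing)) {
    stop("fused class(es) absent from training data: ",
         paste(missing, collapse = ", "))
  }
  if (all(apply(x, 2, stats::sd) < 1e-9)) {
    warning("constant input probability vectors; falling back to a ",
            "majority-class fusion model", call. = FALSE)
    maj <- names(which.max(table(y)))
    return(structure(list(type = "majority", majority = maj),
                     class = "fusion_model"))
  }
  best <- with_stream(seed, "fit_fusion", {
    acc <- vapply(cost_grid, function(cc) {
      m <- e1071::svm(x, y, kernel = "linear", cost = cc, cross = 3)
      m$tot.accuracy
    }, numeric(1))
    cost_grid[which.max(acc)]
  })
  svm_fit <- with_stream(seed, "fit_fusion_final",
    e1071::svm(x, y, kernel = "linear", cost = best, probability = TRUE)
  )
  structure(list(type = "svm", svm = svm_fit, cost = best),
            class = "fusion_model")
}

#' @export
print.fusion_model <- function(x, ...) {
  if (x$type == "majority") {
    cat("<fusion_model> degenerate majority fallback ->", x$majority, "\n")
  } else {
    cat(sprintf("<fusion_model> linear SVM, cost = %g, %d support vectors\n",
                x$cost, nrow(x$svm$SV)))
  }
  invisible(x)
}

#' Fuse four-class probabilities into three decision-class probabilities
#'
#' @param model a `fusion_model` from [fit_fusion()]
#' @param cp a 4-vector of class probabilities (order of [tissue_classes()])
#'   or a matrix/data.frame with the four `p_*` columns; rows must sum to 1
#' @return a matrix with columns `non_atypical`, `gp3`, `gp4plus`, rows
#'   summing to 1 (a single input vector yields a 1-row matrix)
#' @export
fuse <- function(model, cp) {
  stopifnot(inherits(model, "fusion_model"))
  pcols <- paste0("p_", tissue_classes())
  if (is.data.frame(cp) && all(pcols %in% names(cp))) {
    x <- as.matrix(cp[, pcols])
  } else {
    x <- if (is.null(dim(cp))) matrix(cp, nrow = 1) else as.matrix(cp)
  }
  if (ncol(x) != 4) stop("expected 4 class probabilities per row")
  bad <- abs(rowSums(x) - 1) > 1e-6 |
    apply(x, 1, function(r) any(r < -1e-9 | r > 1 + 1e-9))
  if (any(bad)) {
    stop("unnormalized class-probability row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }
  colnames(x) <- pcols
  if (model$type == "majority") {
    q <- matrix(0, nrow = nrow(x), ncol = 3,
                dimnames = list(NULL, fused_classes()))
    q[, model$majority] <- 1
    return(q)
  }
  pred <- stats::predict(model$svm, x, probability = TRUE)
  q <- attr(pred, "probabilities")[, fused_classes(), drop = FALSE]
  q <- q / rowSums(q)
  rownames(q) <- rownames(x)
  q
}

#' Assign the decision class of a fused probability vector
#'
#' Highest probability wins; exact ties break to the lowest class index in
#' the fixed order non-atypical < GP3 < GP >= 4.
#'
#' @param fp a fused 3-vector, or matrix with one row per patch (columns in
#'   the order of [fused_classes()])
#' @return character vector of fused class codes
#' @export
assign_label <- function(fp) {
  q <- if (is.null(dim(fp))) matrix(fp, nrow = 1) else as.matrix(fp)
  if (!is.null(colnames(q))) q <- q[, fused_classes(), drop = FALSE]
  stopifnot(ncol(q) == 3)
  fused_classes()[max.col(q, ties.method = "first")]
}
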