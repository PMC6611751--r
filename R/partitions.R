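#' Biopsy-exclusive balanced partitioning of a patch set
#'
#' Groups patches into `k` partitions for cross-validation such that every
#' biopsy lands wholly in one partition (no biopsy ever contributes to both a
#' training and a test fold) and the per-class patch counts are as even as
#' possible across partitions.
#'
#' Assignment uses a greedy longest-processing-time heuristic: biopsies are
#' placed in decreasing order of total patch count, each into the partition
#' minimizing the resulting class-count imbalance (the maximum over classes
#' of the max - min partition count; ties go to the lowest partition index),
#' followed by a deterministic local search (single-biopsy moves and pairwise
#' swaps) from several seeded starting orders. On toy instances this reaches
#' the exhaustive optimum (see [exhaustive_partition_optimum()]).
#'
#' @param patches a patch manifest `data.frame` (needs `biopsy_id`, `label`)
#' @param k number of partitions (default 4)
#' @param seed integer seed
#' @param n_restarts number of seeded restart orders for the heuristic
#' @return a `partition_set`: list with `patches` (manifest plus a
#'   `partition` column), `assignment` (named integer vector biopsy -> index)
#'   and `k`
#' @export
build_partitions <- function(patches, k = 4L, seed = 1L, n_restarts = 15L) {
  stopifnot(is.data.frame(patches), k >= 2)
  if (anyNA(patches$biopsy_id) || any(!nzchar(patches$biopsy_id))) {
    stop("every patch needs a non-empty biopsy_id")
  }
  bids <- unique(patches$biopsy_id)
  if (length(bids) < k) {
    stop("cannot build ", k, " biopsy-exclusive partitions from ",
         length(bids), " biopsies")
  }
  counts <- biopsy_class_counts(patches)
  totals <- rowSums(counts)
  n <- nrow(counts)
  best <- with_stream(seed, "build_partitions", {
    sol <- NULL
    for (r in seq_len(n_restarts)) {
      ord <- if (r == 1) {
        order(totals, decreasing = TRUE)  # classic LPT order
      } else {
        sample(n)
      }
      cand <- lpt_assign(counts, ord, k)
      cand <- refine_assignment(counts, cand, k)
      if (is.null(sol) || cand$obj < sol$obj - 1e-12) sol <- cand
    }
    sol
  })
  assign <- stats::setNames(best$assignment, rownames(counts))
  patches$partition <- assign[patches$biopsy_id]
  structure(list(patches = patches, assignment = assign, k = as.integer(k)),
            class = "partition_set")
}

# one greedy LPT pass: place biopsies in `ord`, each into the partition
# minimizing the resulting imbalance (ties to the lowest index)
lpt_assign <- function(counts, ord, k) {
  assign <- integer(nrow(counts))
  cell <- matrix(0, nrow = k, ncol = ncol(counts))
  for (b in ord) {
    best <- Inf; best_p <- 1L
    for (p in seq_len(k)) {
      trial <- cell
      trial[p, ] <- trial[p, ] + counts[b, ]
      obj <- partition_imbalance(trial)
      if (obj < best - 1e-12) { best <- obj; best_p <- p }
    }
    cell[best_p, ] <- cell[best_p, ] + counts[b, ]
    assign[b] <- best_p
  }
  list(assignment = assign, cell = cell, obj = partition_imbalance(cell))
}

# deterministic local refinement: single-biopsy moves and pairwise swaps,
# accepted when they reduce the imbalance or, at equal imbalance, a
# tie-breaking smoothness score (summed class spreads + tiny variance term)
# that lets the search cross plateaus of the max-spread objective
refine_assignment <- function(counts, sol, k) {
  assign <- sol$assignment; cell <- sol$cell
  n <- nrow(counts)
  smooth <- function(cell) {
    sum(apply(cell, 2, function(x) max(x) - min(x))) +
      1e-6 * sum(sweep(cell, 2, colMeans(cell))^2)
  }
  better <- function(trial, cur) {
    partition_imbalance(trial) < partition_imbalance(cur) - 1e-12 ||
      (partition_imbalance(trial) < partition_imbalance(cur) + 1e-12 &&
         smooth(trial) < smooth(cur) - 1e-9)
  }
  repeat {
    improved <- FALSE
    for (b in seq_len(n)) {
      from <- assign[b]
      for (p in seq_len(k)) {
        if (p == from) next
        trial <- cell
        trial[from, ] <- trial[from, ] - counts[b, ]
        trial[p, ] <- trial[p, ] + counts[b, ]
        if (better(trial, cell)) {
          cell <- trial; assign[b] <- p; from <- p; improved <- TRUE
        }
      }
    }
    if (n >= 2) {
      for (b1 in seq_len(n - 1)) {
        for (b2 in seq(b1 + 1, n)) {
          p1 <- assign[b1]; p2 <- assign[b2]
          if (p1 == p2) next
          trial <- cell
          trial[p1, ] <- trial[p1, ] - counts[b1, ] + counts[b2, ]
          trial[p2, ] <- trial[p2, ] - counts[b2, ] + counts[b1, ]
          if (better(trial, cell)) {
            cell <- trial; assign[b1] <- p2; assign[b2] <- p1
            improved <- TRUE
          }
        }
      }
    }
    if (!improved) break
  }
  list(assignment = assign, cell = cell, obj = partition_imbalance(cell))
}

# biopsies x classes patch-count matrix, over the classes actually present
biopsy_class_counts <- function(patches) {
  lev <- intersect(tissue_classes(), unique(patches$label))
  tab <- table(factor(patches$biopsy_id), factor(patches$label, levels = lev))
  matrix(as.numeric(tab), nrow = nrow(tab), dimnames = dimnames(tab))
}

#' Class-count imbalance of a partition x class count matrix
#'
#' The balance objective for biopsy assignment: the maximum over classes of
#' the spread (max - min) of per-partition counts.
#'
#' @param cell numeric k x C matrix of per-partition per-class patch counts
#' @return a non-negative scalar
#' @export
partition_imbalance <- function(cell) {
  max(apply(cell, 2, function(x) max(x) - min(x)))
}

#' Per-(partition, class) patch counts of a partition set
#' @param ps a `partition_set`
#' @return k x 4 count matrix
#' @export
partition_class_counts <- function(ps) {
  stopifnot(inherits(ps, "partition_set"))
  lev <- intersect(tissue_classes(), unique(ps$patches$label))
  tab <- table(factor(ps$patches$partition, levels = seq_len(ps$k)),
               factor(ps$patches$label, levels = lev))
  matrix(as.integer(tab), nrow = ps$k, dimnames = dimnames(tab))
}

#' @export
print.partition_set <- function(x, ...) {
  cat(sprintf("<partition_set> %d partitions, %d biopsies, %d patches\n",
              x$k, length(x$assignment), nrow(x$patches)))
  print(partition_class_counts(x))
  invisible(x)
}

#' Downsample every (partition, class) cell to the smallest cell
#'
#' After partitioning, the number of patches in each class is reduced (random
#' subsampling without replacement, seeded) so that every partition holds the
#' same number of patches of every class: the global minimum cell count.
#' The biopsy-to-partition assignment is unchanged.
#'
#' @param ps a `partition_set` from [build_partitions()]
#' @param seed integer seed
#' @return a balanced `partition_set`
#' @export
balance_to_smallest_class <- function(ps, seed = 1L) {
  stopifnot(inherits(ps, "partition_set"))
  cell <- partition_class_counts(ps)
  if (any(cell == 0)) {
    empty <- which(cell == 0, arr.ind = TRUE)
    stop("empty (partition, class) cells: ",
         paste(sprintf("(partition %s, %s)", rownames(cell)[empty[, 1]],
                       colnames(cell)[empty[, 2]]), collapse = ", "))
  }
  m <- min(cell)
  keep <- with_stream(seed, "balance_to_smallest_class", {
    idx <- integer(0)
    for (p in seq_len(ps$k)) {
      for (cls in colnames(cell)) {
        rows <- which(ps$patches$partition == p & ps$patches$label == cls)
        idx <- c(idx, sort(rows[sample.int(length(rows), m)]))
      }
    }
    sort(idx)
  })
  out <- ps
  out$patches <- ps$patches[keep, , drop = FALSE]
  rownames(out$patches) <- NULL
  out
}

#' Exact minimum partition imbalance by exhaustive search
#'
#' Reference search used to validate the greedy heuristic on toy instances:
#' enumerates every assignment of biopsies to `k` partitions (first biopsy
#' pinned to partition 1, a harmless symmetry reduction) and returns the
#' minimum achievable [partition_imbalance()]. Exponential in the number of
#' biopsies; intended for at most ~12 biopsies.
#'
#' @param counts biopsies x classes count matrix
#' @param k number of partitions
#' @return minimal imbalance (scalar)
#' @export
exhaustive_partition_optimum <- function(counts, k = 4L) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (nrow(counts) > 14) stop("exhaustive search limited to 14 biopsies")
  partition_oracle(counts, as.integer(k))
}
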