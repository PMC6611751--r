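# Shared fixtures: everything is generated in code at test time.

# A flat-color slide with mild noise; big enough for one patch window.
make_color_slide <- function(color, size = 320L, noise = 0.01, seed = 1L,
                             slide_id = "s1") {
  set.seed(seed)
  px <- array(rep(color, each = size * size), dim = c(size, size, 3))
  px <- px + array(stats::rnorm(size * size * 3, sd = noise),
                   dim = c(size, size, 3))
  px[px < 0] <- 0; px[px > 1] <- 1
  slide_image(px, slide_id = slide_id)
}

# Rectangle polygon with inclusive integer pixel bounds.
rect_poly <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

rect_region <- function(class, biopsy_id, x0, y0, x1, y1) {
  list(polygon = rect_poly(x0, y0, x1, y1), class = class,
       biopsy_id = biopsy_id)
}

# Independent scalar point-in-polygon oracle: even-odd ray casting with
# boundary points counted inside. Deliberately written as a per-point loop,
# sharing no code with the package's vectorized rasterizer.
pip_oracle <- function(px, py, poly) {
  xs <- poly[, 1]; ys <- poly[, 2]
  n <- length(xs)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    x1 <- xs[j]; y1 <- ys[j]; x2 <- xs[i]; y2 <- ys[i]
    # on-segment check
    cr <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    if (abs(cr) < 1e-9 &&
        px >= min(x1, x2) - 1e-9 && px <= max(x1, x2) + 1e-9 &&
        py >= min(y1, y2) - 1e-9 && py <= max(y1, y2) + 1e-9) {
      return(TRUE)
    }
    if ((y2 > py) != (y1 > py)) {
      xint <- x2 + (py - y2) * (x1 - x2) / (y1 - y2)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Simple star-shaped (hence simple) non-convex polygon around a center.
star_polygon <- function(center = c(20, 20), n = 9, rmin = 4, rmax = 16,
                         seed = 5) {
  set.seed(seed)
  ang <- sort(stats::runif(n, 0, 2 * pi))
  rad <- stats::runif(n, rmin, rmax)
  cbind(x = center[1] + rad * cos(ang), y = center[2] + rad * sin(ang))
}

# Independent definitional implementation of Cohen's weighted kappa via
# explicit double sums over disagreement weights, used as the oracle for the
# package implementation.
qwk_oracle <- function(cm) {
  k <- nrow(cm); n <- sum(cm)
  num <- 0; den <- 0
  rm <- rowSums(cm); cmarg <- colSums(cm)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      d <- (i - j)^2 / (k - 1)^2
      num <- num + d * cm[i, j] / n
      den <- den + d * (rm[i] * cmarg[j]) / n^2
    }
  }
  as.numeric(1 - num / den)
}

# Patch manifest without any backing slide, for tests that inject a custom
# feature extractor into the classifier machinery.
fake_manifest <- function(n_per_biopsy, biopsies, labels) {
  rows <- expand.grid(biopsy_id = biopsies, i = seq_len(n_per_biopsy),
                      label = labels, stringsAsFactors = FALSE)
  data.frame(
    patch_id = sprintf("fp%04d", seq_len(nrow(rows))),
    slide_id = rows$biopsy_id, biopsy_id = rows$biopsy_id,
    center_row = 149L, center_col = 149L, label = rows$label,
    stringsAsFactors = FALSE
  )
}

# Feature extractor that encodes the true label (plus tiny jitter so model
# fitting is well-posed); makes any sane backend a perfect oracle classifier.
label_feature_fun <- function(manifest, slides) {
  m <- outer(manifest$label, tissue_classes(), `==`) * 1
  colnames(m) <- paste0("is_", tissue_classes())
  set.seed(99)
  m + matrix(stats::rnorm(length(m), sd = 1e-3), nrow = nrow(m))
}

# A well-separated four-class probability table like a confident classifier
# would produce on held-out patches.
separable_prob_table <- function(n_per_class = 30, seed = 42,
                                 confidence = 0.9) {
  set.seed(seed)
  rows <- lapply(tissue_classes(), function(cls) {
    p <- matrix(stats::runif(n_per_class * 4, 0, 1 - confidence), ncol = 4)
    p[, match(cls, tissue_classes())] <- confidence +
      stats::runif(n_per_class, 0, 0.1)
    p <- p / rowSums(p)
    colnames(p) <- paste0("p_", tissue_classes())
    data.frame(p, true_label = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$biopsy_id <- sprintf("b%02d", seq_len(nrow(out)) %% 6 + 1)
  out
}

# One small cancer-bearing synthetic slide, cached across tests.
cached_small_slide <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- generate_slide(
        c(stroma = 0.3, benign_gland = 0.2, gp3 = 0.35, gp4plus = 0.15),
        size = c(600L, 900L), seed = 31L, biopsy_id = "sm1"
      )
    }
    val
  }
})
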