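#' Build per-class probability maps over a slide
#'
#' Aggregates fused patch probabilities onto a regular grid: cell (i, j)
#' covers slide pixels `[i*stride, (i+1)*stride) x [j*stride, (j+1)*stride)`
#' (0-based) and holds, per decision class, the mean fused probability of all
#' patch centers falling in the cell. Cells containing no center are flagged
#' undefined. On defined cells the three class grids sum to 1.
#'
#' @param slide a [slide_image()] (or a length-2 integer `c(H, W)`)
#' @param centers `data.frame` with `center_row`, `center_col` (0-based) and
#'   the fused probability columns `q_non_atypical`, `q_gp3`, `q_gp4plus`
#' @param stride_pixels cell side in pixels; defaults to 149 (half patch)
#' @return a `probability_map`: list with `grids` (named list of H' x W'
#'   matrices), `defined` (logical matrix), `stride_pixels` and `origin`
#' @export
build_probability_map <- function(slide, centers, stride_pixels = 149L) {
  d <- if (inherits(slide, "slide_image")) slide_dim(slide) else as.integer(slide)
  stopifnot(stride_pixels >= 1, length(d) == 2)
  qcols <- paste0("q_", fused_classes())
  stopifnot(all(c("center_row", "center_col", qcols) %in% names(centers)))
  if (any(centers$center_row < 0 | centers$center_row >= d[1] |
          centers$center_col < 0 | centers$center_col >= d[2])) {
    stop("patch center outside the slide")
  }
  nr <- as.integer(ceiling(d[1] / stride_pixels))
  nc <- as.integer(ceiling(d[2] / stride_pixels))
  ci <- centers$center_row %/% stride_pixels + 1L
  cj <- centers$center_col %/% stride_pixels + 1L
  cell <- (cj - 1L) * nr + ci
  counts <- matrix(0, nr, nc)
  tab <- table(cell)
  counts[as.integer(names(tab))] <- as.integer(tab)
  grids <- lapply(qcols, function(qc) {
    g <- matrix(NA_real_, nr, nc)
    s <- tapply(centers[[qc]], cell, sum)
    g[as.integer(names(s))] <- s / counts[as.integer(names(s))]
    g
  })
  names(grids) <- fused_classes()
  structure(list(grids = grids, defined = counts > 0,
                 stride_pixels = as.integer(stride_pixels),
                 origin = c(0L, 0L)),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map> %d x %d cells, stride %d px, %d defined\n",
              nrow(x$defined), ncol(x$defined), x$stride_pixels,
              sum(x$defined)))
  invisible(x)
}

#' Write a probability map to disk
#'
#' One single-channel 8-bit PNG per decision class (value = round(255 q),
#' undefined cells written as 0), a PNG mask of defined cells, and a JSON
#' sidecar recording stride, origin and the file names.
#'
#' @param map a `probability_map`
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix
#' @return the sidecar path, invisibly
#' @export
write_probability_map <- function(map, dir, prefix = "probmap") {
  stopifnot(inherits(map, "probability_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (cls in names(map$grids)) {
    g <- map$grids[[cls]]
    g[!map$defined] <- 0
    f <- file.path(dir, sprintf("%s_%s.png", prefix, cls))
    png::writePNG(g, target = f)
    files[[cls]] <- basename(f)
  }
  maskf <- file.path(dir, sprintf("%s_defined.png", prefix))
  png::writePNG(map$defined * 1, target = maskf)
  sidecar <- file.path(dir, sprintf("%s.json", prefix))
  jsonlite::write_json(
    list(stride_pixels = map$stride_pixels, origin = map$origin,
         classes = files, defined_mask = basename(maskf)),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(sidecar)
}
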