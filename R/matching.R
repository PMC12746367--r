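#' Per-pixel trajectory container
#'
#' @param data Numeric array of shape (rows, cols, N): the measured or
#'   simulated trajectory at every pixel.
#' @param mask Logical matrix (rows x cols); pixels outside the mask are
#'   ignored.
#' @return A `trajectory_image`.
#' @export
trajectory_image <- function(data, mask = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (is.null(mask)) mask <- matrix(TRUE, dim(data)[1], dim(data)[2])
  stopifnot(is.logical(mask), all(dim(mask) == dim(data)[1:2]))
  structure(list(data = data, mask = mask), class = "trajectory_image")
}

#' Match one trajectory against the dictionary
#'
#' Dot-product matching: returns the grid node maximizing the normalized inner
#' product `<e, d> / (||e|| ||d||)`. Scores live in \[-1, 1\] (no absolute
#' value is taken); ties are broken by the lowest row-major node index.
#'
#' @param e Trajectory (length N, non-zero norm).
#' @param dictionary An `st_dictionary` with matching N.
#' @return One-row tibble: `node`, `fs`, `ksw`, `score`.
#' @export
match_pixel <- function(e, dictionary) {
  if (length(e) != ncol(dictionary$signals))
    abort("trajectory length does not match the dictionary")
  nrm <- sqrt(sum(e^2))
  if (!is.finite(nrm) || nrm == 0)
    abort("zero-norm trajectory is unmatchable")
  scores <- as.numeric(dictionary$signals %*% e) / (dictionary$norms * nrm)
  best <- which.max(scores)
  tibble(node = best,
         fs = dictionary$grid$nodes$fs[best],
         ksw = dictionary$grid$nodes$ksw[best],
         score = scores[best])
}

#' Reconstruct (fs, ksw) maps by dictionary matching
#'
#' Applies dot-product matching to every masked pixel (vectorized over the
#' whole image; the result is order-independent and deterministic). Pixels
#' with a zero-norm trajectory are flagged and left `NA` in the maps.
#'
#' @param image A [trajectory_image()].
#' @param dictionary An `st_dictionary`.
#' @return A `param_maps`: list with matrices `fs_map`, `ksw_map`,
#'   `score_map`, logical `flagged`, the `mask` and a dictionary reference.
#' @export
reconstruct_maps <- function(image, dictionary) {
  dims <- dim(image$data)
  if (dims[3] != ncol(dictionary$signals))
    abort("image trajectory length does not match the dictionary")
  if (!any(image$mask)) abort("empty mask")
  E <- matrix(image$data, dims[1] * dims[2], dims[3])
  sel <- which(as.vector(image$mask))
  E <- E[sel, , drop = FALSE]
  norms <- sqrt(rowSums(E^2))
  ok <- is.finite(norms) & norms > 0

  fs_map <- matrix(NA_real_, dims[1], dims[2])
  ksw_map <- matrix(NA_real_, dims[1], dims[2])
  score_map <- matrix(NA_real_, dims[1], dims[2])
  flagged <- matrix(FALSE, dims[1], dims[2])
  flagged[sel[!ok]] <- TRUE

  if (any(ok)) {
    D <- dictionary$signals / dictionary$norms
    S <- (E[ok, , drop = FALSE] / norms[ok]) %*% t(D) # pixels x nodes
    best <- max.col(S, ties.method = "first")
    idx <- sel[ok]
    fs_map[idx] <- dictionary$grid$nodes$fs[best]
    ksw_map[idx] <- dictionary$grid$nodes$ksw[best]
    score_map[idx] <- S[cbind(seq_along(best), best)]
  }
  structure(list(
    fs_map = fs_map, ksw_map = ksw_map, score_map = score_map,
    flagged = flagged, mask = image$mask, dictionary = dictionary
  ), class = "param_maps")
}

#' @export
print.param_maps <- function(x, ...) {
  cat(sprintf("<param_maps> %d x %d, %d matched pixel(s), %d flagged\n",
              nrow(x$fs_map), ncol(x$fs_map),
              sum(!is.na(x$fs_map)), sum(x$flagged)))
  invisible(x)
}

#' @export
tidy.param_maps <- function(x, ...) {
  dims <- dim(x$fs_map)
  tibble(
    row = rep(seq_len(dims[1]), dims[2]),
    col = rep(seq_len(dims[2]), each = dims[1]),
    mask = as.vector(x$mask),
    fs = as.vector(x$fs_map),
    ksw = as.vector(x$ksw_map),
    score = as.vector(x$score_map)
  )
}

#' Write parameter maps as CSV
#' @param maps A `param_maps`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maps_csv <- function(maps, path) {
  write.csv(as.data.frame(tidy(maps)), path, row.names = FALSE)
  invisible(path)
}
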