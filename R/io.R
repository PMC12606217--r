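#' Write a movie as a multi-page TIFF
#'
#' Stores a frames-first array (`T x H x W`) as one 32-bit page per frame.
#' TIFF pages hold values in \[0, 1\], so intensities are affinely rescaled
#' and the original range is recorded in a small JSON sidecar
#' (`<path>.json`) that [read_movie_tiff()] uses to restore them.
#'
#' @param movie Numeric `T x H x W` array (e.g. from
#'   [gen_calcium_movie()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(length(dim(movie)) == 3L)
  lo <- min(movie)
  hi <- max(movie)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(movie)[1]), function(t) {
    (movie[t, , ] - lo) / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(offset = lo, scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF as a movie array
#'
#' Restores the original intensity range when the sidecar written by
#' [write_movie_tiff()] is present.
#'
#' @param path TIFF file path.
#' @return Numeric `T x H x W` array.
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  out <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (t in seq_along(pages)) out[t, , ] <- pages[[t]]
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::fromJSON(sidecar)
    out <- out * meta$scale + meta$offset
  }
  out
}
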