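#' Save a trained detector to a JSON archive
#'
#' The archive preserves the shape and appearance models, the fixed
#' Jacobian, the wrinkle dictionary and the configuration exactly
#' (types and attributes included).
#'
#' @param models a `wrinkle_detector`
#' @param path output path (conventionally `.json`)
#' @return `path`, invisibly
#' @export
save_detector <- function(models, path) {
  stopifnot(inherits(models, "wrinkle_detector"))
  writeLines(jsonlite::serializeJSON(models, digits = NA), path)
  invisible(path)
}

#' Load a detector saved with [save_detector()]
#'
#' @param path archive path
#' @return a `wrinkle_detector`
#' @export
load_detector <- function(path) {
  models <- jsonlite::unserializeJSON(paste(readLines(path, warn = FALSE),
                                            collapse = "\n"))
  if (!inherits(models, "wrinkle_detector"))
    stop("not a wrinkle_detector archive: ", path)
  models
}

#' Read a fixture dataset from a manifest
#'
#' Loads the images (PNG) and PTS landmark files listed in a
#' `manifest.csv` written by [write_fixtures()].
#'
#' @param manifest_path path to the manifest CSV
#' @param split optional split filter
#' @return list of `list(image =, landmarks =)`
#' @export
read_manifest <- function(manifest_path, split = NULL) {
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!is.null(split)) man <- man[man$split == split, , drop = FALSE]
  base <- dirname(manifest_path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, basename(p))
  lapply(seq_len(nrow(man)), function(i) {
    img <- png::readPNG(resolve(man$image[i]))
    list(image = to_grayscale(img), landmarks = read_pts(resolve(man$landmarks[i])))
  })
}
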