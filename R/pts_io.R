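#' Read an ibug/PTS-style landmark file
#'
#' Parses the plain-text landmark format
#' `version: 1 / n_points: N / { / x y / ... / }` into an n x 2 matrix
#' with columns `x`, `y`. Point order is preserved: for the 88-point
#' annotation used here, rows 1-68 are face feature points and rows 69-88
#' the wrinkle line, nose end first.
#'
#' @param path path to a `.pts` file
#' @return numeric matrix (n x 2), columns `x` and `y`
#' @export
read_pts <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  n_line <- grep("^n_points:", lines, value = TRUE)
  if (length(n_line) != 1L)
    stop("not a PTS file (missing n_points): ", path)
  n <- as.integer(sub("^n_points:\\s*", "", n_line))
  open <- which(lines == "{")
  close <- which(lines == "}")
  if (length(open) != 1L || length(close) != 1L || close <= open)
    stop("malformed PTS braces in ", path)
  body <- lines[(open + 1L):(close - 1L)]
  body <- body[nzchar(body)]
  if (length(body) != n)
    stop("PTS file declares ", n, " points but has ", length(body))
  coords <- do.call(rbind, lapply(strsplit(body, "\\s+"), as.numeric))
  if (ncol(coords) != 2L || anyNA(coords))
    stop("non-numeric coordinates in ", path)
  colnames(coords) <- c("x", "y")
  coords
}

#' Write landmarks to an ibug/PTS-style file
#'
#' Coordinates are written with six decimal places; a file written, read
#' back with [read_pts()] and written again is byte-identical.
#'
#' @param points numeric matrix (n x 2)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pts <- function(points, path) {
  points <- as_landmarks(points)
  body <- sprintf("%.6f %.6f", points[, 1], points[, 2])
  writeLines(c("version: 1",
               sprintf("n_points: %d", nrow(points)),
               "{", body, "}"),
             path)
  invisible(path)
}

# Coerce to an n x 2 numeric landmark matrix, validating finiteness.
as_landmarks <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L)
    stop("landmarks must be an n x 2 matrix")
  if (!all(is.finite(points)))
    stop("landmarks contain non-finite coordinates")
  colnames(points) <- c("x", "y")
  points
}

# Flatten n x 2 landmarks to (x1, y1, x2, y2, ...) and back.
flatten_shape <- function(points) as.vector(t(as_landmarks(points)))

unflatten_shape <- function(v) {
  m <- matrix(v, ncol = 2L, byrow = TRUE)
  colnames(m) <- c("x", "y")
  m
}
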