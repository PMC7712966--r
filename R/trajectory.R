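#' Construct a coordinate trajectory
#'
#' A trajectory is the raw input of the featurization step: `N` frames of the
#' same `P` points in 2- or 3-dimensional space.  Point identity must be
#' stable across frames (point `u` in frame 1 is the same particle as point
#' `u` in frame 1000); the classifier itself never sees coordinates, only the
#' binary contacts derived from them.
#'
#' @param coords numeric array of dimension `N x P x d` (frames, points,
#'   spatial dimensions), `d` in `{2, 3}`.  All values must be finite.
#' @param point_labels optional character/integer vector of `P` point
#'   identifiers (e.g. residue numbers for C-alpha atoms).  Defaults to
#'   `1:P`.
#' @param frame_order optional integer time index per frame; defaults to
#'   `1:N`.  Used only by time-order diagnostics, never by the model.
#' @return An object of class `"trajectory"` with fields `coords`,
#'   `point_labels`, `frame_order`.
#' @seealso [extract_contacts()], [read_xyz()]
#' @export
trajectory <- function(coords, point_labels = NULL, frame_order = NULL) {
  if (!is.array(coords) || length(dim(coords)) != 3L)
    stop("'coords' must be an N x P x d array")
  dm <- dim(coords)
  if (dm[1] < 2L) stop("a trajectory needs at least 2 frames")
  if (dm[2] < 2L) stop("a trajectory needs at least 2 points")
  if (!dm[3] %in% c(2L, 3L)) stop("spatial dimension must be 2 or 3")
  bad <- which(!apply(is.finite(coords), 1L, all))
  if (length(bad))
    stop("non-finite coordinates in frame(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  if (is.null(point_labels)) point_labels <- seq_len(dm[2])
  if (length(point_labels) != dm[2])
    stop("'point_labels' must have one entry per point")
  if (is.null(frame_order)) frame_order <- seq_len(dm[1])
  if (length(frame_order) != dm[1])
    stop("'frame_order' must have one entry per frame")
  structure(list(coords = coords,
                 point_labels = point_labels,
                 frame_order = as.integer(frame_order)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  dm <- dim(x$coords)
  cat(sprintf("<trajectory> %d frames x %d points in %dD\n",
              dm[1], dm[2], dm[3]))
  invisible(x)
}

#' @export
dim.trajectory <- function(x) dim(x$coords)

#' Read a multi-frame XYZ file
#'
#' Plain-text XYZ trajectory format: each frame is an atom count line, a
#' comment line, then one `label x y z` line per atom.  All frames must have
#' the same atom count.  Two-dimensional data can be stored with `z = 0` and
#' recovered with `drop_z = TRUE`.
#'
#' @param path file path.
#' @param drop_z if `TRUE` and the third coordinate is identically zero,
#'   return a 2D trajectory.
#' @return a [trajectory()].
#' @export
read_xyz <- function(path, drop_z = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  i <- 1L
  frames <- list()
  labels <- NULL
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) stop("malformed XYZ: bad atom count at line ", i)
    if (i + 1L + n > length(lines)) stop("malformed XYZ: truncated frame")
    block <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(block), "[[:space:]]+")
    lab <- vapply(toks, `[[`, "", 1L)
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3L)))
    if (is.null(labels)) labels <- lab
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  N <- length(frames)
  P <- nrow(frames[[1L]])
  coords <- array(NA_real_, c(N, P, 3L))
  for (f in seq_len(N)) coords[f, , ] <- frames[[f]]
  if (drop_z && all(coords[, , 3L] == 0)) coords <- coords[, , 1:2, drop = FALSE]
  trajectory(coords, point_labels = labels)
}

#' Write a trajectory as multi-frame XYZ
#'
#' 2D trajectories are padded with `z = 0`.
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @param comment per-frame comment line (recycled).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path, comment = "frame %d") {
  stopifnot(inherits(traj, "trajectory"))
  dm <- dim(traj$coords)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(dm[1])) {
    xyz <- matrix(traj$coords[f, , ], nrow = dm[2])
    if (dm[3] == 2L) xyz <- cbind(xyz, 0)
    writeLines(as.character(dm[2]), con)
    writeLines(sprintf(comment, f), con)
    writeLines(sprintf("%s %.8f %.8f %.8f",
                       as.character(traj$point_labels), xyz[, 1], xyz[, 2],
                       xyz[, 3]), con)
  }
  invisible(path)
}
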