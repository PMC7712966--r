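#' Construct a binary contact feature matrix
#'
#' The sole data input of the mixture model: an `N x M` bit matrix whose
#' entry `x[i, j]` records whether contact `j` (a specific unordered pair of
#' points) is formed in frame `i`.
#'
#' @param x integer/numeric matrix of 0/1 values, frames in rows.
#' @param pairs integer matrix `M x 2` of 1-based point indices, `u < v`,
#'   rows sorted lexicographically; row `j` labels column `j` of `x`.
#' @param cutoff the distance cutoff (length units) that defined the
#'   contacts.
#' @param pruned logical: have constant columns been removed?
#' @param orig_index integer vector mapping the current columns back to the
#'   column positions of the unpruned matrix (identity when unpruned).
#' @param point_labels identifiers of the underlying points.
#' @return an object of class `"feature_matrix"`.
#' @export
feature_matrix <- function(x, pairs, cutoff, pruned = FALSE,
                           orig_index = seq_len(ncol(x)),
                           point_labels = NULL) {
  x <- as.matrix(x)
  if (!all(x %in% c(0, 1))) stop("feature matrix entries must be 0 or 1")
  storage.mode(x) <- "integer"
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (nrow(pairs) != ncol(x)) stop("one pair label per feature column required")
  if (any(pairs[, 1] >= pairs[, 2])) stop("pairs must satisfy u < v")
  if (anyDuplicated(pairs)) stop("pairs must be unique")
  o <- order(pairs[, 1], pairs[, 2])
  if (is.unsorted(o) && any(o != seq_along(o))) {
    x <- x[, o, drop = FALSE]
    pairs <- pairs[o, , drop = FALSE]
    orig_index <- orig_index[o]
  }
  structure(list(x = x, pairs = pairs, cutoff = cutoff, pruned = pruned,
                 orig_index = as.integer(orig_index),
                 point_labels = point_labels),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d frames x %d contacts (cutoff %g, %s)\n",
              nrow(x$x), ncol(x$x), x$cutoff,
              if (x$pruned) "pruned" else "unpruned"))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$x)

#' Extract binary contact features from a trajectory
#'
#' Every unordered pair of points `(u, v)`, `u < v`, becomes one feature
#' column; the bit for frame `i` is 1 exactly when the Euclidean distance
#' between the two points in that frame is strictly below `cutoff`.  Columns
#' are ordered lexicographically in `(u, v)` so matrices are comparable
#' across runs.  No periodic-boundary handling is applied.
#'
#' @param traj a [trajectory()].
#' @param cutoff positive contact distance in the trajectory's length units.
#' @return an unpruned [feature_matrix()] with `M = P(P-1)/2` columns.
#' @seealso [prune_constant_features()]
#' @export
extract_contacts <- function(traj, cutoff) {
  stopifnot(inherits(traj, "trajectory"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("'cutoff' must be a single positive number")
  dm <- dim(traj$coords)
  N <- dm[1]; P <- dm[2]
  M <- P * (P - 1L) / 2L
  x <- matrix(0L, N, M)
  for (f in seq_len(N)) {
    d <- stats::dist(matrix(traj$coords[f, , ], nrow = P))
    x[f, ] <- as.integer(d < cutoff)  # dist() emits pairs in (u,v)-lex order
  }
  u <- rep.int(seq_len(P - 1L), (P - 1L):1L)
  v <- unlist(lapply(seq_len(P - 1L), function(i) (i + 1L):P))
  feature_matrix(x, cbind(u, v), cutoff, pruned = FALSE,
                 point_labels = traj$point_labels)
}

#' Remove constant contact features
#'
#' Contacts that are formed in every frame, or in none, carry no information
#' for classification and are dropped before modelling.  This changes the
#' feature count `M` seen by the algorithm (and therefore the default
#' Dirichlet concentration `alpha = M + 1`), usually reducing it well below
#' `P(P-1)/2`.
#'
#' @param fm an unpruned [feature_matrix()].
#' @return a pruned [feature_matrix()] retaining the pair labels and a map
#'   (`orig_index`) from surviving columns to original column positions.
#' @export
prune_constant_features <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (fm$pruned) return(fm)           # idempotent

  cs <- colSums(fm$x)
  keep <- cs > 0L & cs < nrow(fm$x)
  if (!any(keep)) stop("no informative features: every contact is constant")
  feature_matrix(fm$x[, keep, drop = FALSE], fm$pairs[keep, , drop = FALSE],
                 fm$cutoff, pruned = TRUE,
                 orig_index = fm$orig_index[keep],
                 point_labels = fm$point_labels)
}

#' Contact features from C-alpha positions of standard structure files
#'
#' Reads a protein topology (PDB), keeps only the C-alpha atoms, collects
#' frames from the topology's own MODEL records and/or additional trajectory
#' files (multi-MODEL PDB, DCD, or multi-frame XYZ), and converts the
#' resulting C-alpha trajectory to pruned binary contact features.
#'
#' @param structure_file path to a PDB file carrying the topology (its MODEL
#'   records, if several, are used as frames).
#' @param traj_files optional character vector of trajectory files appended
#'   after the topology frames; format chosen by extension
#'   (`.dcd`, `.pdb`, `.xyz`).
#' @param cutoff contact cutoff in Angstrom; the conventional C-alpha
#'   contact definition uses 5.0.
#' @return a pruned [feature_matrix()]; pair labels refer to C-alpha residue
#'   numbers.
#' @export
extract_ca_contacts <- function(structure_file, traj_files = NULL,
                                cutoff = 5.0) {
  pdb <- bio3d::read.pdb(structure_file, multi = TRUE)
  sel <- bio3d::atom.select(pdb, "calpha", verbose = FALSE)
  if (length(sel$atom) < 2L) stop("fewer than 2 C-alpha atoms found in ",
                                  structure_file)
  xyz <- pdb$xyz[, sel$xyz, drop = FALSE]
  P <- length(sel$atom)
  frames <- list(xyz)
  for (tf in traj_files) {
    ext <- tolower(tools::file_ext(tf))
    fr <- switch(ext,
      dcd = bio3d::read.dcd(tf, verbose = FALSE)[, sel$xyz, drop = FALSE],
      pdb = bio3d::read.pdb(tf, multi = TRUE)$xyz[, sel$xyz, drop = FALSE],
      xyz = {
        tr <- read_xyz(tf)
        if (dim(tr$coords)[2] != P)
          stop("trajectory file ", tf, " has ", dim(tr$coords)[2],
               " atoms; topology has ", P, " C-alphas")
        matrix(aperm(tr$coords, c(3L, 2L, 1L)), ncol = 3L * P, byrow = TRUE)
      },
      stop("unsupported trajectory format: ", tf))
    if (ncol(fr) != 3L * P)
      stop("atom count mismatch between topology and ", tf)
    frames[[length(frames) + 1L]] <- fr
  }
  xyz <- do.call(rbind, frames)
  N <- nrow(xyz)
  if (N < 2L) stop("need at least 2 frames for contact featurization")
  coords <- array(NA_real_, c(N, P, 3L))
  coords[, , 1L] <- xyz[, seq(1L, 3L * P, 3L)]
  coords[, , 2L] <- xyz[, seq(2L, 3L * P, 3L)]
  coords[, , 3L] <- xyz[, seq(3L, 3L * P, 3L)]
  labels <- pdb$atom$resno[sel$atom]
  traj <- trajectory(coords, point_labels = labels)
  prune_constant_features(extract_contacts(traj, cutoff))
}

#' Save or load a feature matrix container
#'
#' The on-disk container is a single serialized R object holding the bit
#' matrix, pair labels, cutoff, prune flag and prune map; the round trip is
#' bit-exact.  [write_pair_labels()] emits an interoperable plain-text
#' sidecar of the pair list.
#'
#' @param fm a [feature_matrix()].
#' @param path file path (conventionally `.rds`).
#' @return `write_features` returns `path` invisibly; `read_features`
#'   returns the restored [feature_matrix()].
#' @export
write_features <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  saveRDS(unclass(fm), path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("no such feature file: ", path)
  obj <- readRDS(path)
  feature_matrix(obj$x, obj$pairs, obj$cutoff, pruned = obj$pruned,
                 orig_index = obj$orig_index, point_labels = obj$point_labels)
}

#' @rdname write_features
#' @details The pair-label sidecar has one `u v` line per feature column,
#'   with 0-based point indices, in column order.
#' @export
write_pair_labels <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  writeLines(sprintf("%d %d", fm$pairs[, 1] - 1L, fm$pairs[, 2] - 1L), path)
  invisible(path)
}
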