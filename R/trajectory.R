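# Frames, trajectories, and periodic geometry queries.

#' Create a single frame
#'
#' Coordinates in angstrom in an orthorhombic box. By convention z is the
#' growth axis: the simulated slab geometry is periodic in x and y and
#' vacuum-terminated (non-periodic) in z.
#'
#' @param positions numeric n x 3 matrix, angstrom.
#' @param box length-3 positive edge lengths, angstrom.
#' @param periodic length-3 logical, per-axis periodicity.
#' @param time frame time in ns.
#' @return object of class `frame`.
#' @export
new_frame <- function(positions, box, periodic = c(TRUE, TRUE, FALSE),
                      time = 0) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, length(box) == 3, all(box > 0),
            length(periodic) == 3)
  structure(list(positions = positions, box = as.numeric(box),
                 periodic = as.logical(periodic), time = as.numeric(time)),
            class = "frame")
}

#' Create a trajectory
#'
#' @param topology a [topology()] matching every frame's atom count.
#' @param frames list of [new_frame()] objects with strictly increasing
#'   times.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(topology, frames) {
  stopifnot(inherits(topology, "topology"), length(frames) >= 1)
  n <- nrow(topology$atoms)
  for (f in frames) {
    if (!inherits(f, "frame")) stop("frames must be `frame` objects")
    if (nrow(f$positions) != n)
      stop("frame has ", nrow(f$positions), " positions but topology has ",
           n, " atoms")
  }
  tt <- vapply(frames, function(f) f$time, 0)
  if (length(tt) > 1 && any(diff(tt) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(topology = topology, frames = frames),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  tt <- vapply(x$frames, function(f) f$time, 0)
  cat(sprintf("trajectory: %d frames (%.3f..%.3f ns), %d atoms\n",
              length(x$frames), min(tt), max(tt), nrow(x$topology$atoms)))
  print(x$topology)
  invisible(x)
}

#' Number of frames
#' @param traj a [trajectory()].
#' @export
n_frames <- function(traj) length(traj$frames)

#' Minimum-image distance between points under a frame's periodicity
#'
#' @param a,b numeric 3-vectors or n x 3 matrices (angstrom).
#' @param frame a [new_frame()] supplying box and periodic flags.
#' @return numeric vector of distances, angstrom.
#' @export
minimum_image_distance <- function(a, b, frame) {
  a <- matrix(a, ncol = 3)
  b <- matrix(b, ncol = 3)
  if (nrow(a) == 1 && nrow(b) > 1) a <- a[rep(1, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1 && nrow(a) > 1) b <- b[rep(1, nrow(a)), , drop = FALSE]
  cpp_min_image_dist(a, b, frame$box, frame$periodic)
}

#' Neighbor list within a cutoff
#'
#' All-pairs search over a subset of atoms under the frame's periodic
#' convention. The cutoff must be below half the smallest periodic box
#' edge so that the minimum-image convention is unambiguous.
#'
#' @param frame a [new_frame()].
#' @param subset integer vector of 1-based atom row indices.
#' @param cutoff distance cutoff, angstrom.
#' @return named list mapping each subset index to an integer vector of
#'   neighboring subset indices (1-based atom rows); symmetric.
#' @export
neighbor_list <- function(frame, subset, cutoff) {
  per_edges <- frame$box[frame$periodic]
  if (length(per_edges) && cutoff >= min(per_edges) / 2)
    stop("cutoff ", cutoff, " must be < half the smallest periodic box edge (",
         min(per_edges), ")")
  pos <- frame$positions[subset, , drop = FALSE]
  pr <- cpp_pair_list(pos, frame$box, frame$periodic, cutoff)
  out <- vector("list", length(subset))
  names(out) <- as.character(subset)
  for (k in seq_along(out)) out[[k]] <- integer(0)
  if (nrow(pr)) {
    for (k in seq_len(nrow(pr))) {
      i <- pr[k, 1]; j <- pr[k, 2]
      out[[i]] <- c(out[[i]], subset[j])
      out[[j]] <- c(out[[j]], subset[i])
    }
  }
  out
}

#' Neighbor pairs within a cutoff (matrix form)
#'
#' Lower-level companion to [neighbor_list()]: returns the unique pairs
#' (i < j) of subset positions within `cutoff`, as 1-based indices into
#' `subset`.
#' @inheritParams neighbor_list
#' @return two-column integer matrix.
#' @export
neighbor_pairs <- function(frame, subset, cutoff) {
  pos <- frame$positions[subset, , drop = FALSE]
  cpp_pair_list(pos, frame$box, frame$periodic, cutoff)
}
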