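# Ice/liquid classification via the neighbour-averaged Steinhardt l=6
# bond-order parameter, seeded-cluster extraction and front tracking.

Q6_CUTOFF <- 3.5   # O-O neighbour cutoff, angstrom
Q6_STAGES <- 4L    # rounds of neighbour vector averaging

#' Neighbour-averaged Steinhardt q6 order parameter
#'
#' For each requested oxygen, the l = 6 Steinhardt bond-order vector is
#' computed over O-O neighbours within `cutoff` and then averaged over
#' {molecule + neighbours} for `stages` rounds (one round is the
#' Lechner-Dellago q6bar) before taking the rotationally invariant
#' magnitude. Each extra averaging round suppresses the incoherent
#' (liquid) tail faster than the coherent crystal signal, which is what
#' makes the i.i.d.-noise synthetic phases separable at the default
#' noise levels. Crystalline environments give values near the lattice
#' reference; disordered ones give low values. Oxygens with no
#' neighbours are assigned 0.
#'
#' @param frame a [new_frame()].
#' @param oxygen_ids integer row indices of water oxygens.
#' @param cutoff neighbour cutoff, angstrom.
#' @param stages rounds of neighbour vector averaging.
#' @return numeric vector in `[0, 1]`, one value per oxygen.
#' @export
local_order_parameter <- function(frame, oxygen_ids, cutoff = Q6_CUTOFF,
                                  stages = Q6_STAGES) {
  pos <- frame$positions[oxygen_ids, , drop = FALSE]
  cpp_qbar6(pos, frame$box, frame$periodic, cutoff, stages)
}

#' Classify water molecules as ice or liquid
#'
#' @inheritParams local_order_parameter
#' @param threshold classification threshold from [calibrate_threshold()].
#' @return logical vector: `TRUE` = ice (q6bar >= threshold).
#' @export
classify_ice <- function(frame, oxygen_ids, threshold,
                         cutoff = Q6_CUTOFF, stages = Q6_STAGES) {
  local_order_parameter(frame, oxygen_ids, cutoff, stages) >= threshold
}

#' Calibrate the ice/liquid threshold from single-phase samples
#'
#' Pools the q6bar distributions of a known-ice and a known-liquid sample
#' and returns the midpoint between the 1st percentile of the ice
#' distribution and the 99th percentile of the liquid distribution.
#' Errors if the two distributions overlap beyond those percentiles, in
#' which case the phases are not separable at the chosen noise/cutoff.
#'
#' @param ice_sample,liquid_sample single-phase [trajectory()] objects
#'   (one or more frames each).
#' @param cutoff O-O neighbour cutoff, angstrom.
#' @return scalar threshold.
#' @export
calibrate_threshold <- function(ice_sample, liquid_sample,
                                cutoff = Q6_CUTOFF) {
  qs <- function(traj) {
    ox <- water_oxygens(traj$topology)
    unlist(lapply(traj$frames, local_order_parameter, oxygen_ids = ox,
                  cutoff = cutoff))
  }
  qi <- qs(ice_sample)
  ql <- qs(liquid_sample)
  lo <- quantile(qi, 0.01, names = FALSE)
  hi <- quantile(ql, 0.99, names = FALSE)
  if (hi >= lo)
    stop("calibration failure: ice and liquid q6 distributions overlap ",
         sprintf("(ice p1 = %.3f <= liquid p99 = %.3f); ", lo, hi),
         "reduce the noise or change the neighbour cutoff")
  (lo + hi) / 2
}

#' Reference calibration samples for a lattice/noise condition
#'
#' Builds a periodic noisy crystal and a periodic random packing at
#' liquid density matching the given spec and noise levels, for use with
#' [calibrate_threshold()].
#'
#' @param spec a [lattice_spec()].
#' @param sigma_ice,sigma_liquid Gaussian noise, angstrom.
#' @param n_frames frames per sample.
#' @param seed RNG seed.
#' @return list with `ice` and `liquid` trajectories.
#' @export
calibration_samples <- function(spec, sigma_ice = 0.25, sigma_liquid = 0.8,
                                n_frames = 5, seed = 99) {
  set.seed(seed)
  lat <- build_ice_lattice(lattice_spec(spec$face, spec$a, spec$c,
                                        spec$nx, spec$ny, spec$nz))
  nw <- nrow(lat$sites)
  box <- lat$frame$box
  ice_frames <- lapply(seq_len(n_frames), function(k)
    new_frame(lat$sites + matrix(rnorm(3 * nw), nw, 3) * sigma_ice,
              box, rep(TRUE, 3), k - 1))
  nl <- round(LIQUID_DENSITY * prod(box))
  liq_frames <- lapply(seq_len(n_frames), function(k) {
    pk <- cpp_pack_points(nl, c(0, 0, 0), box, box, rep(TRUE, 3), 2.4,
                          400 * nl + 4000, matrix(numeric(0), 0, 3))
    new_frame(pk, box, rep(TRUE, 3), k - 1)
  })
  wtop <- function(n) topology(rep("O", n), seq_len(n),
                               rep("water_oxygen", n))
  list(ice = trajectory(wtop(nw), ice_frames),
       liquid = trajectory(wtop(nl), liq_frames))
}

#' Seeded ice cluster of one frame
#'
#' Largest connected component (O-O connectivity within `cutoff`) of the
#' ice-labelled molecules that intersects the seed region. Cluster size
#' is the headline growth observable.
#'
#' @param ice_mask logical ice labels over `oxygen_ids`.
#' @param frame a [new_frame()].
#' @param oxygen_ids integer row indices of water oxygens.
#' @param seed_region z-interval (2-vector) containing the original seed
#'   slab.
#' @param cutoff connectivity cutoff, angstrom.
#' @return list with `members` (logical over `oxygen_ids`) and `size`.
#' @export
seeded_cluster <- function(ice_mask, frame, oxygen_ids, seed_region,
                           cutoff = Q6_CUTOFF) {
  ice_idx <- which(ice_mask)
  if (!length(ice_idx))
    stop("seeded cluster lost: no ice-labelled molecules")
  sub <- oxygen_ids[ice_idx]
  pr <- neighbor_pairs(frame, sub, cutoff)
  lab <- cpp_components(pr, length(sub))
  z <- frame$positions[sub, 3]
  in_seed <- z >= seed_region[1] & z <= seed_region[2]
  if (!any(in_seed))
    stop("seeded cluster lost: no ice-labelled molecules in the seed region")
  seed_labs <- unique(lab[in_seed])
  sizes <- tabulate(lab)
  main <- seed_labs[which.max(sizes[seed_labs])]
  members <- logical(length(ice_mask))
  members[ice_idx[lab == main]] <- TRUE
  list(members = members, size = sum(lab == main))
}

#' Front positions of a cluster
#'
#' Robust per-side front proxy: the 95th-percentile extreme z of the
#' cluster oxygens on each side of the cell midplane (resists single
#' stray molecules, unlike the max).
#'
#' @param members logical cluster membership over `oxygen_ids`.
#' @param frame a [new_frame()].
#' @param oxygen_ids integer row indices of water oxygens.
#' @param midplane z of the cell midplane; defaults to `box_z / 2`.
#' @return named vector `c(z_plus, z_minus)`, angstrom.
#' @export
front_position <- function(members, frame, oxygen_ids,
                           midplane = frame$box[3] / 2) {
  z <- frame$positions[oxygen_ids[members], 3]
  up <- z[z >= midplane]
  dn <- z[z < midplane]
  c(z_plus = if (length(up)) quantile(up, 0.95, names = FALSE) else midplane,
    z_minus = if (length(dn)) quantile(dn, 0.05, names = FALSE) else midplane)
}

#' Majority-vote cleanup of binary phase labels
#'
#' One or more rounds of first-shell majority voting over
#' {self + neighbours}: isolated misclassified molecules inherit the
#' phase of their surroundings. Interface-local (influence radius is one
#' neighbour shell per round), so it does not smear the front.
#'
#' @param mask logical phase labels over `oxygen_ids`.
#' @param frame a [new_frame()].
#' @param oxygen_ids integer row indices of water oxygens.
#' @param cutoff neighbour cutoff, angstrom.
#' @param rounds voting rounds.
#' @return cleaned logical vector.
#' @export
cleanup_labels <- function(mask, frame, oxygen_ids, cutoff = Q6_CUTOFF,
                           rounds = 1L) {
  if (rounds < 1) return(mask)
  pr <- neighbor_pairs(frame, oxygen_ids, cutoff)
  for (r in seq_len(rounds)) {
    votes <- as.numeric(mask)
    cnt <- rep(1, length(mask))
    if (nrow(pr)) for (k in seq_len(nrow(pr))) {
      i <- pr[k, 1]; j <- pr[k, 2]
      votes[i] <- votes[i] + mask[j]
      votes[j] <- votes[j] + mask[i]
      cnt[i] <- cnt[i] + 1
      cnt[j] <- cnt[j] + 1
    }
    mask <- votes / cnt > 0.5
  }
  mask
}

#' Label a whole trajectory
#'
#' Applies [classify_ice()] (plus [cleanup_labels()]),
#' [seeded_cluster()] and [front_position()] frame by frame.
#'
#' @param traj a [trajectory()].
#' @param threshold q6bar threshold from [calibrate_threshold()].
#' @param seed_region z-interval of the original seed slab.
#' @param cutoff O-O neighbour/connectivity cutoff, angstrom.
#' @param cleanup majority-vote rounds applied to the per-frame ice mask.
#' @return object of class `ice_labels`: logical matrices `ice` and
#'   `cluster` (frames x waters), integer `cluster_size`, matrix `front`
#'   (frames x 2), and the parameters used.
#' @export
label_trajectory <- function(traj, threshold, seed_region,
                             cutoff = Q6_CUTOFF, cleanup = 1L) {
  ox <- water_oxygens(traj$topology)
  nf <- n_frames(traj)
  ice <- matrix(FALSE, nf, length(ox))
  clu <- matrix(FALSE, nf, length(ox))
  csz <- integer(nf)
  fro <- matrix(NA_real_, nf, 2, dimnames = list(NULL, c("z_plus", "z_minus")))
  for (k in seq_len(nf)) {
    fr <- traj$frames[[k]]
    m <- classify_ice(fr, ox, threshold, cutoff)
    m <- cleanup_labels(m, fr, ox, cutoff, cleanup)
    cl <- seeded_cluster(m, fr, ox, seed_region, cutoff)
    ice[k, ] <- m
    clu[k, ] <- cl$members
    csz[k] <- cl$size
    fro[k, ] <- front_position(cl$members, fr, ox)
  }
  structure(list(ice = ice, cluster = clu, cluster_size = csz, front = fro,
                 threshold = threshold, cutoff = cutoff,
                 seed_region = seed_region, oxygen_ids = ox),
            class = "ice_labels")
}

#' @export
print.ice_labels <- function(x, ...) {
  cat(sprintf(paste0("ice labels: %d frames, %d waters; cluster size ",
                     "%d -> %d (threshold %.3f)\n"),
              nrow(x$ice), ncol(x$ice), x$cluster_size[1],
              tail(x$cluster_size, 1), x$threshold))
  invisible(x)
}
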