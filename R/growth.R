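# Growth quantification: binding detection, growth rate, overgrowth
# depth and the categorical OG / IRI / no-IRI outcome.

RATE_THRESHOLD <- 0.03  # m/s; inhibition cutoff
DEPTH_THRESHOLD <- 8    # angstrom; ~ two molecular layers

#' Detect the solute-ice binding frame
#'
#' First frame in which any solute heavy atom lies within
#' `contact_cutoff` of a seeded-cluster oxygen; `NA` if never. The rate
#' window conventionally starts here.
#'
#' @param traj a [trajectory()].
#' @param labels an `ice_labels` object from [label_trajectory()].
#' @param contact_cutoff heavy-atom--oxygen contact distance, angstrom.
#' @return 0-based frame index or `NA`.
#' @export
detect_binding <- function(traj, labels, contact_cutoff = 3.5) {
  hv <- solute_heavy_atoms(traj$topology)
  if (!length(hv)) return(NA_integer_)
  ox <- labels$oxygen_ids
  for (k in seq_len(n_frames(traj))) {
    fr <- traj$frames[[k]]
    cl <- ox[labels$cluster[k, ]]
    if (!length(cl)) next
    cpos <- fr$positions[cl, , drop = FALSE]
    for (q in hv) {
      d <- cpp_min_image_dist(matrix(fr$positions[q, ], nrow(cpos), 3,
                                     byrow = TRUE),
                              cpos, fr$box, fr$periodic)
      if (min(d) <= contact_cutoff) return(k - 1L)
    }
  }
  NA_integer_
}

#' Per-molecule volume measured from the seed lattice
#'
#' Median nearest-neighbour O-O distance of the seed cluster, measured
#' on time-averaged positions (molecules in the frame-0 cluster, their
#' coordinates averaged over the first few frames -- lattice molecules
#' are stationary, so averaging suppresses the thermal noise that would
#' otherwise bias pair distances upward and truncate against the
#' neighbour cutoff), with a first-order residual-noise correction
#' (`d <- d - var(d)/d`), converted through the tetrahedral-network
#' relation [vmol_from_nn()]. Self-consistent across synthetic and real
#' input -- no literature ice density is assumed.
#'
#' @param traj a [trajectory()].
#' @param labels an `ice_labels` object.
#' @param avg_frames number of leading frames to average positions over.
#' @return volume per molecule, cubic angstrom.
#' @export
estimate_vmol <- function(traj, labels, avg_frames = 5) {
  K <- min(avg_frames, n_frames(traj))
  keep <- labels$cluster[1, ]
  for (k in seq_len(K)) keep <- keep & labels$cluster[k, ]
  sub <- labels$oxygen_ids[keep]
  fr <- traj$frames[[1]]
  ref <- fr$positions[sub, , drop = FALSE]
  acc <- ref * 0
  for (k in seq_len(K)) {
    # accumulate minimum-image displacements from the reference so that
    # molecules jittering across a periodic boundary average correctly
    disp <- traj$frames[[k]]$positions[sub, , drop = FALSE] - ref
    for (ax in which(fr$periodic))
      disp[, ax] <- disp[, ax] - fr$box[ax] * round(disp[, ax] / fr$box[ax])
    acc <- acc + disp / K
  }
  pos <- ref + acc
  pr <- cpp_pair_list(pos, fr$box, fr$periodic, 3.2)
  if (nrow(pr) < 25)
    stop("too few O-O neighbour pairs in the frame-0 cluster to estimate ",
         "the molecular volume")
  d <- cpp_min_image_dist(pos[pr[, 1], , drop = FALSE],
                          pos[pr[, 2], , drop = FALSE], fr$box, fr$periodic)
  dm <- median(d)
  dm <- dm - var(d) / dm
  vmol_from_nn(dm)
}

#' Growth rate from cluster sizes
#'
#' Converts the seeded-cluster size series into an equivalent slab
#' thickness `h(t) = N(t) v_mol / (fronts * A_xy)` and returns its
#' least-squares slope over the window, in m/s. The default `fronts = 2`
#' reflects the double-interface cell (both fronts grow); set 1 to
#' attribute all growth to a single front.
#'
#' @param cluster_sizes integer per-frame seeded-cluster sizes.
#' @param times frame times, ns.
#' @param window inclusive 0-based frame interval `c(first, last)`;
#'   must span at least 5 frames.
#' @param area in-plane cell area `Lx * Ly`, square angstrom.
#' @param v_mol per-molecule volume, cubic angstrom (see
#'   [estimate_vmol()]).
#' @param fronts number of growing fronts sharing the added molecules.
#' @return growth rate, m/s.
#' @export
growth_rate <- function(cluster_sizes, times, window, area, v_mol,
                        fronts = 2) {
  idx <- (window[1]:window[2]) + 1L
  if (length(idx) < 5)
    stop("rate window must span at least 5 frames, got ", length(idx))
  h <- cluster_sizes[idx] * v_mol / (fronts * area)
  tt <- times[idx]
  angstrom_ns_to_ms(unname(coef(lm(h ~ tt))[2]))
}

#' Overgrowth depth of the solutes at a frame
#'
#' For each solute: the signed distance from the front on the solute's
#' side of the cell to the solute's outermost (water-side) heavy atom,
#' positive when the solute is buried below the front. A solute only
#' counts as buried if ice-labelled cluster molecules actually lie
#' between it and the front (within a 6-angstrom lateral radius).
#' Returns the maximum over solutes, or `-Inf` if there is no solute.
#'
#' @param traj a [trajectory()].
#' @param labels an `ice_labels` object.
#' @param frame_index 1-based frame index (default: final frame).
#' @return depth, angstrom.
#' @export
overgrowth_depth <- function(traj, labels, frame_index = n_frames(traj)) {
  top <- traj$topology
  hv_all <- solute_heavy_atoms(top)
  if (!length(hv_all)) return(-Inf)
  fr <- traj$frames[[frame_index]]
  ox <- labels$oxygen_ids
  cl <- ox[labels$cluster[frame_index, ]]
  zc <- fr$box[3] / 2
  best <- -Inf
  for (m in unique(top$atoms$molecule_id[hv_all])) {
    hv <- hv_all[top$atoms$molecule_id[hv_all] == m]
    z <- fr$positions[hv, 3]
    side <- if (mean(z) >= zc) 1 else -1
    zfront <- if (side > 0) labels$front[frame_index, "z_plus"]
              else labels$front[frame_index, "z_minus"]
    z_ext <- if (side > 0) max(z) else min(z)
    depth <- side * (zfront - z_ext)
    if (depth > 0 && length(cl)) {
      # require ice between the solute and the front
      ctr <- colMeans(fr$positions[hv, , drop = FALSE])
      cp <- fr$positions[cl, , drop = FALSE]
      lat <- cpp_min_image_dist(
        cbind(cp[, 1:2], 0),
        matrix(c(ctr[1], ctr[2], 0), nrow(cp), 3, byrow = TRUE),
        fr$box, fr$periodic)
      between <- if (side > 0) cp[, 3] > z_ext & cp[, 3] <= zfront
                 else cp[, 3] < z_ext & cp[, 3] >= zfront
      if (!any(between & lat <= 6)) depth <- 0
    }
    best <- max(best, depth)
  }
  best
}

#' Categorical growth outcome
#'
#' `OG` if the overgrowth depth reaches `depth_threshold` (overgrown
#' trajectories are excluded from the inhibition count); otherwise `IRI`
#' if the growth rate is below `rate_threshold`; otherwise `no_IRI`.
#' The rate cutoff's robustness range (0.01-0.06 m/s) can be swept via
#' `rate_threshold`.
#'
#' @param growth_rate m/s.
#' @param depth angstrom.
#' @param rate_threshold m/s.
#' @param depth_threshold angstrom.
#' @return one of `"OG"`, `"IRI"`, `"no_IRI"`.
#' @export
classify_outcome <- function(growth_rate, depth,
                             rate_threshold = RATE_THRESHOLD,
                             depth_threshold = DEPTH_THRESHOLD) {
  if (is.finite(depth) && depth >= depth_threshold) return("OG")
  if (growth_rate < rate_threshold) return("IRI")
  "no_IRI"
}

#' Analyse one trajectory end to end
#'
#' Binding detection, rate over the post-binding window (full trajectory
#' when nothing ever binds, e.g. solute-free controls), final-frame
#' overgrowth depth and the categorical outcome.
#'
#' @param traj a [trajectory()].
#' @param labels an `ice_labels` object.
#' @param rate_threshold,depth_threshold outcome thresholds.
#' @param fronts number of growing fronts (see [growth_rate()]).
#' @param v_mol per-molecule volume; estimated from the seed lattice
#'   when `NULL`.
#' @param contact_cutoff binding contact distance, angstrom.
#' @param burn_frac fraction of leading frames excluded from the rate
#'   window: the classifier's interfacial erosion takes roughly one
#'   grown layer to reach its steady-state width, and fitting through
#'   that startup transient biases the slope. The window starts at
#'   whichever is later, the binding frame or the burn-in.
#' @return object of class `growth_result`.
#' @export
analyze_growth <- function(traj, labels,
                           rate_threshold = RATE_THRESHOLD,
                           depth_threshold = DEPTH_THRESHOLD,
                           fronts = 2, v_mol = NULL,
                           contact_cutoff = 3.5, burn_frac = 0.2) {
  nf <- n_frames(traj)
  bind <- detect_binding(traj, labels, contact_cutoff)
  w0 <- if (is.na(bind)) 0L else bind
  w0 <- max(w0, as.integer(ceiling(burn_frac * nf)))
  if (nf - w0 < 5) w0 <- max(0L, nf - 5L)  # keep a minimal window
  window <- c(w0, nf - 1L)
  if (is.null(v_mol)) v_mol <- estimate_vmol(traj, labels)
  fr <- traj$frames[[1]]
  area <- fr$box[1] * fr$box[2]
  times <- vapply(traj$frames, function(f) f$time, 0)
  rate <- growth_rate(labels$cluster_size, times, window, area, v_mol,
                      fronts)
  depth <- overgrowth_depth(traj, labels)
  structure(list(
    binding_frame = bind,
    growth_rate = rate,
    overgrowth_depth = depth,
    outcome = classify_outcome(rate, depth, rate_threshold,
                               depth_threshold),
    rate_window = window,
    v_mol = v_mol,
    n_solutes = length(unique(
      traj$topology$atoms$molecule_id[solute_heavy_atoms(traj$topology)])),
    solute_kind = traj$topology$solute_kind
  ), class = "growth_result")
}

#' @export
print.growth_result <- function(x, ...) {
  cat(sprintf(paste0("growth result: rate %.4f m/s, depth %.1f A, ",
                     "outcome %s (bind frame %s)\n"),
              x$growth_rate, x$overgrowth_depth, x$outcome,
              ifelse(is.na(x$binding_frame), "none", x$binding_frame)))
  invisible(x)
}

#' Aggregate outcomes into a Table-1-style count table
#'
#' @param results list of `growth_result` objects, each optionally
#'   tagged (via attributes or list fields `face`, `n_solutes`,
#'   `solute_kind`).
#' @param face,solute_kind optional character vectors overriding the
#'   per-result tags.
#' @return data.frame with one row per (solute_kind, face, n_solutes)
#'   group and columns `OG`, `IRI`, `no_IRI`, `n`.
#' @export
aggregate_outcomes <- function(results, face = NULL, solute_kind = NULL) {
  if (!length(results))
    return(data.frame(solute_kind = character(), face = character(),
                      n_solutes = integer(), OG = integer(),
                      IRI = integer(), no_IRI = integer(), n = integer()))
  get_tag <- function(r, nmf, override, i)
    if (!is.null(override)) override[i]
    else if (!is.null(r[[nmf]])) r[[nmf]] else "unspecified"
  df <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(solute_kind = as.character(get_tag(r, "solute_kind",
                                                  solute_kind, i)),
               face = as.character(get_tag(r, "face", face, i)),
               n_solutes = r$n_solutes, outcome = r$outcome,
               stringsAsFactors = FALSE)
  }))
  groups <- unique(df[c("solute_kind", "face", "n_solutes")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
    sel <- df$solute_kind == groups$solute_kind[g] &
      df$face == groups$face[g] & df$n_solutes == groups$n_solutes[g]
    data.frame(groups[g, , drop = FALSE],
               OG = sum(df$outcome[sel] == "OG"),
               IRI = sum(df$outcome[sel] == "IRI"),
               no_IRI = sum(df$outcome[sel] == "no_IRI"),
               n = sum(sel))
  }))
  rownames(out) <- NULL
  class(out) <- c("outcome_table", "data.frame")
  out
}

#' @export
print.outcome_table <- function(x, ...) {
  cat("Outcomes (OG / IRI / no-IRI):\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-14s %-20s (%d solute) : %d / %d / %d\n",
                x$solute_kind[i], x$face[i], x$n_solutes[i],
                x$OG[i], x$IRI[i], x$no_IRI[i]))
  invisible(x)
}
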