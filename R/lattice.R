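# Hexagonal ice (Ih) lattice builder with selectable exposed face.

#' Specify an ice Ih lattice
#'
#' The oxygen sublattice of hexagonal ice is built in an orthorhombic
#' representation of the wurtzite arrangement (8 molecules per cell of
#' dimensions `a` x `sqrt(3) a` x `c`) and then oriented so that the
#' requested crystallographic face is normal to z, the growth axis:
#' `basal` = \{0001\}, `primary_prismatic` = \{10-10\},
#' `secondary_prismatic` = \{11-20\}.
#'
#' @param face exposed face.
#' @param a,c hexagonal lattice constants, angstrom. The defaults give a
#'   nearest-neighbour O-O distance of ~2.76 angstrom, appropriate for
#'   ice Ih at strong supercooling.
#' @param nx,ny,nz repeat counts along the (oriented) x, y, z axes.
#' @param proton_model `none` (oxygen-only) or `tetrahedral_random`
#'   (two H per oxygen along randomly chosen tetrahedral bond directions).
#' @return object of class `lattice_spec`.
#' @export
lattice_spec <- function(face = c("basal", "primary_prismatic",
                                  "secondary_prismatic"),
                         a = 4.50, c = 7.34, nx = 3, ny = 3, nz = 3,
                         proton_model = c("none", "tetrahedral_random")) {
  face <- match.arg(face)
  proton_model <- match.arg(proton_model)
  stopifnot(a > 0, c > 0, nx >= 1, ny >= 1, nz >= 1)
  structure(list(face = face, a = a, c = c, nx = as.integer(nx),
                 ny = as.integer(ny), nz = as.integer(nz),
                 proton_model = proton_model),
            class = "lattice_spec")
}

# Axis permutation taking the canonical (basal-up) frame into the
# oriented frame: oriented coordinate k is canonical coordinate perm[k].
face_perm <- function(face) {
  switch(face,
         basal = c(1L, 2L, 3L),
         primary_prismatic = c(1L, 3L, 2L),
         secondary_prismatic = c(2L, 3L, 1L),
         stop("unknown face: ", face))
}

# Oriented unit-cell edge lengths (angstrom).
unit_cell <- function(spec) {
  canon <- c(spec$a, sqrt(3) * spec$a, spec$c)
  canon[face_perm(spec$face)]
}

# 8-molecule oxygen basis of the canonical orthorhombic cell, fractional.
# The internal parameter u is chosen so that the out-of-plane and the
# three in-plane tetrahedral bonds have exactly equal length for the
# given a, c (u = a^2/(3 c^2) + 1/4; u = 3/8 at the ideal c/a ratio).
ih_basis <- function(a, c) {
  u <- a^2 / (3 * c^2) + 1 / 4
  b <- rbind(
    c(0.0, 1 / 3, 0.0), c(0.5, 1 / 6, 0.5),
    c(0.0, 1 / 3, u), c(0.5, 1 / 6, 0.5 + u))
  rbind(b, sweep(b, 2, c(0.5, 0.5, 0.0), `+`) %% 1)
}

#' Build an ice Ih oxygen lattice (optionally protonated)
#'
#' Returns a fully periodic crystal: a single frame whose box is the
#' tiled cell, with one water molecule per oxygen site. With
#' `proton_model = "tetrahedral_random"` each oxygen donates two
#' hydrogens (O-H 1.0 angstrom) along two randomly selected of its four
#' tetrahedral O-O bond directions. This randomised donor choice gives
#' geometrically correct H-bond donors/acceptors without solving the full
#' Bernal-Fowler ice rules; proton placement uses the current RNG state.
#'
#' @param spec a [lattice_spec()].
#' @return list with `topology`, `frame`, `sites` (the n x 3 oxygen site
#'   matrix), and `spec`; class `ice_lattice`.
#' @export
build_ice_lattice <- function(spec) {
  perm <- face_perm(spec$face)
  cell <- unit_cell(spec)
  reps <- c(spec$nx, spec$ny, spec$nz)
  basis <- ih_basis(spec$a, spec$c)[, perm, drop = FALSE]  # oriented fractional
  shifts <- as.matrix(expand.grid(x = seq_len(reps[1]) - 1,
                                  y = seq_len(reps[2]) - 1,
                                  z = seq_len(reps[3]) - 1))
  sites <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(k) {
    sweep(basis, 2, shifts[k, ], `+`)
  }))
  sites <- sweep(sites, 2, cell, `*`)
  # stable ordering: by z, then y, then x
  sites <- sites[order(round(sites[, 3], 6), round(sites[, 2], 6),
                       round(sites[, 1], 6)), , drop = FALSE]
  box <- cell * reps
  n <- nrow(sites)
  if (spec$proton_model == "none") {
    top <- topology(rep("O", n), seq_len(n),
                    rep("water_oxygen", n))
    fr <- new_frame(sites, box, c(TRUE, TRUE, TRUE), 0)
    return(structure(list(topology = top, frame = fr, sites = sites,
                          spec = spec), class = "ice_lattice"))
  }
  hyd <- place_protons(sites, box)
  pos <- matrix(0, 3 * n, 3)
  el <- character(3 * n)
  role <- character(3 * n)
  mol <- integer(3 * n)
  for (i in seq_len(n)) {
    r <- (3 * (i - 1) + 1):(3 * i)
    pos[r, ] <- rbind(sites[i, ], hyd[[i]])
    el[r] <- c("O", "H", "H")
    role[r] <- c("water_oxygen", "water_hydrogen", "water_hydrogen")
    mol[r] <- i
  }
  top <- topology(el, mol, role)
  fr <- new_frame(pos, box, c(TRUE, TRUE, TRUE), 0)
  structure(list(topology = top, frame = fr, sites = sites, spec = spec),
            class = "ice_lattice")
}

# Two H per oxygen, 1.0 angstrom along randomly chosen bond directions.
place_protons <- function(sites, box, oh = 1.0, cutoff = 3.2) {
  n <- nrow(sites)
  pr <- cpp_pair_list(sites, box, rep(TRUE, 3), cutoff)
  nb <- vector("list", n)
  for (k in seq_len(nrow(pr))) {
    i <- pr[k, 1]; j <- pr[k, 2]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  lapply(seq_len(n), function(i) {
    js <- nb[[i]]
    if (length(js) < 2)
      stop("oxygen ", i, " has fewer than 2 lattice neighbours; ",
           "cannot place protons")
    pick <- if (length(js) == 2) js else sample(js, 2)
    t(vapply(pick, function(j) {
      d <- sites[j, ] - sites[i, ]
      d <- d - box * round(d / box)
      sites[i, ] + oh * d / sqrt(sum(d^2))
    }, numeric(3)))
  })
}

#' Molecular-layer structure of a built lattice along z
#'
#' Clusters the distinct oxygen z-levels of a (noiseless) lattice into
#' molecular layers (levels closer than half the maximum level gap are
#' merged) and reports the layer spacing and the span of two molecular
#' layers -- the depth convention used by the overgrowth criterion.
#'
#' @param lattice an `ice_lattice` from [build_ice_lattice()].
#' @return list with `levels`, `layer_centers`, `spacing` and
#'   `two_layer_span` (angstrom).
#' @export
layer_structure <- function(lattice) {
  z <- sort(unique(round(lattice$sites[, 3], 4)))
  if (length(z) < 2) stop("need at least two z-levels")
  Lz <- lattice$frame$box[3]
  # gaps on the periodic ring of z-levels (last entry is the wrap gap)
  gaps <- c(diff(z), z[1] + Lz - z[length(z)])
  thr <- max(gaps) / 2
  splits <- gaps > thr + 0.01
  n_layers <- max(1L, sum(splits))
  # group levels between splits (wrap-aware) for the layer centers
  grp <- cumsum(c(0, head(as.numeric(splits), -1)))
  if (!splits[length(splits)] && n_layers > 1) grp[grp == max(grp)] <- 0
  centers <- sort(as.numeric(tapply(z, grp, mean)))
  spacing <- Lz / n_layers
  list(levels = z, layer_centers = centers, spacing = spacing,
       two_layer_span = 2 * spacing)
}

#' Oxygen number density of an ice Ih lattice
#'
#' For lattice constants a, c the ideal density is `8 / (sqrt(3) a^2 c)`
#' molecules per cubic angstrom.
#' @param spec a [lattice_spec()].
#' @return molecules per cubic angstrom.
#' @export
ih_density <- function(spec) 8 / (sqrt(3) * spec$a^2 * spec$c)

#' Volume per molecule in ice Ih from the nearest-neighbour distance
#'
#' For a tetrahedral (wurtzite) network with bond length d the volume per
#' molecule is `(8 sqrt(3) / 9) d^3`; this converts a measured
#' nearest-neighbour O-O distance into a per-molecule volume without
#' assuming a literature density.
#' @param d nearest-neighbour O-O distance, angstrom.
#' @return cubic angstrom per molecule.
#' @export
vmol_from_nn <- function(d) (8 * sqrt(3) / 9) * d^3
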