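# Readers/writers for extended XYZ, GRO and PDB trajectories.

#' Default residue-role configuration
#'
#' Maps residue names found in GRO/PDB files onto roles. TIP4P-style
#' virtual sites (atom names starting `MW` or `EP`) are dropped on read:
#' every analysis in this package is defined on O/H/N positions only.
#'
#' @param path optional YAML file overriding/extending the defaults, with
#'   keys `water`, `alpha_alanine`, `beta_alanine` (character vectors of
#'   residue names).
#' @return named list of residue-name vectors.
#' @export
role_config <- function(path = NULL) {
  cfg <- list(
    water = c("SOL", "HOH", "WAT", "TIP3", "TIP4", "T4P", "ICE"),
    alpha_alanine = c("AAL", "ALA"),
    beta_alanine = c("BAL", "BALA")
  )
  if (!is.null(path)) {
    usr <- yaml::read_yaml(path)
    for (k in names(usr)) cfg[[k]] <- as.character(usr[[k]])
  }
  cfg
}

element_from_name <- function(nm) {
  sub("^([A-Za-z]).*", "\\1", toupper(trimws(nm)))
}

#' Read a trajectory from a coordinate file
#'
#' Supported formats: extended XYZ (multi-frame, comment line carrying
#' `Lattice=`, `Time=` and `pbc=` fields), GRO (fixed-column, nm, multiple
#' concatenated frames) and PDB (`MODEL`/`ENDMDL` multi-frame, read via
#' bio3d). Roles are assigned from residue names through `config` for
#' GRO/PDB; for plain XYZ (which has no residues) waters are recognised as
#' consecutive O,H,H element triplets and any remaining atoms are taken
#' to be the solute with kind `solute_kind`.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"xyz"`, `"gro"` or `"pdb"`.
#' @param config residue-role mapping from [role_config()].
#' @param solute_kind solute kind used for XYZ input.
#' @param dt frame spacing in ns for formats that carry no time (PDB).
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, format = c("auto", "xyz", "gro", "pdb"),
                            config = role_config(), solute_kind = "none",
                            dt = 1) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xyz = "xyz", gro = "gro", pdb = "pdb",
                     stop("cannot infer format from extension: ", ext))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         xyz = read_xyz(path, solute_kind = solute_kind),
         gro = read_gro(path, config = config),
         pdb = read_pdb_traj(path, config = config, dt = dt))
}

#' Write a trajectory to a coordinate file
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @param format `"xyz"`, `"gro"` or `"pdb"`.
#' @export
write_trajectory <- function(traj, path, format = c("xyz", "gro", "pdb")) {
  format <- match.arg(format)
  switch(format,
         xyz = write_xyz(traj, path),
         gro = write_gro(traj, path),
         pdb = write_pdb_traj(traj, path))
  invisible(path)
}

# ---- extended XYZ ---------------------------------------------------------

parse_kv <- function(line, key) {
  m <- regmatches(line, regexec(paste0(key, '="([^"]*)"'), line))[[1]]
  if (length(m) == 2) return(m[2])
  m <- regmatches(line, regexec(paste0(key, "=([^ ]+)"), line))[[1]]
  if (length(m) == 2) return(m[2])
  NA_character_
}

read_xyz <- function(path, solute_kind = "none") {
  lines <- readLines(path)
  i <- 1L
  frames <- list()
  elements <- NULL
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop("parse error at line ", i, ": expected atom count")
    nat <- as.integer(trimws(lines[i]))
    if (i + 1 + nat > length(lines))
      stop("parse error at line ", i, ": truncated frame")
    comment <- lines[i + 1]
    lat <- parse_kv(comment, "Lattice")
    box <- c(1000, 1000, 1000)
    if (!is.na(lat)) {
      v <- as.numeric(strsplit(trimws(lat), "\\s+")[[1]])
      if (length(v) != 9 || anyNA(v))
        stop("parse error at line ", i + 1, ": bad Lattice field")
      box <- v[c(1, 5, 9)]
    }
    tm <- suppressWarnings(as.numeric(parse_kv(comment, "Time")))
    if (is.na(tm)) tm <- length(frames)
    pbc <- parse_kv(comment, "pbc")
    periodic <- c(TRUE, TRUE, FALSE)
    if (!is.na(pbc))
      periodic <- toupper(strsplit(trimws(pbc), "\\s+")[[1]]) == "T"
    body <- lines[(i + 2):(i + 1 + nat)]
    toks <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(toks, length, 0L) < 4)
    if (length(bad))
      stop("parse error at line ", i + 1 + bad[1], ": need `El x y z`")
    el <- vapply(toks, `[[`, "", 1)
    pos <- matrix(suppressWarnings(
      as.numeric(unlist(lapply(toks, function(t) t[2:4])))),
                  ncol = 3, byrow = TRUE)
    if (anyNA(pos))
      stop("parse error near line ", i + 2, ": non-numeric coordinate")
    if (is.null(elements)) elements <- el
    else if (!identical(elements, el))
      stop("parse error at line ", i, ": atom ordering changed between frames")
    frames[[length(frames) + 1]] <- new_frame(pos, box, periodic, tm)
    i <- i + 2L + nat
  }
  trajectory(xyz_topology(elements, solute_kind), frames)
}

# Infer a topology from bare elements: consecutive O,H,H triplets are
# waters; everything else is solute.
xyz_topology <- function(el, solute_kind) {
  n <- length(el)
  role <- rep(NA_character_, n)
  mol <- integer(n)
  m <- 0L
  i <- 1L
  while (i <= n) {
    if (el[i] == "O" && i + 2 <= n && el[i + 1] == "H" && el[i + 2] == "H") {
      m <- m + 1L
      role[i:(i + 2)] <- c("water_oxygen", "water_hydrogen", "water_hydrogen")
      mol[i:(i + 2)] <- m
      i <- i + 3L
    } else if (el[i] == "O" && (i + 1 > n || el[i + 1] != "H")) {
      # oxygen-only water representation
      m <- m + 1L
      role[i] <- "water_oxygen"
      mol[i] <- m
      i <- i + 1L
    } else {
      break
    }
  }
  if (i <= n) {
    m <- m + 1L
    role[i:n] <- ifelse(el[i:n] == "H", "solute_hydrogen", "solute_heavy")
    mol[i:n] <- m
  }
  topology(el, mol, role, solute_kind = if (i <= n) solute_kind else "none")
}

write_xyz <- function(traj, path) {
  el <- traj$topology$atoms$element
  con <- file(path, "w")
  on.exit(close(con))
  for (f in traj$frames) {
    lat <- sprintf("%.6f 0.0 0.0 0.0 %.6f 0.0 0.0 0.0 %.6f",
                   f$box[1], f$box[2], f$box[3])
    pbc <- paste(ifelse(f$periodic, "T", "F"), collapse = " ")
    writeLines(c(
      as.character(nrow(f$positions)),
      sprintf('Lattice="%s" Properties=species:S:1:pos:R:3 Time=%.6f pbc="%s"',
              lat, f$time, pbc),
      sprintf("%-2s %14.8f %14.8f %14.8f", el,
              f$positions[, 1], f$positions[, 2], f$positions[, 3])
    ), con)
  }
}

# ---- GRO ------------------------------------------------------------------

read_gro <- function(path, config = role_config()) {
  lines <- readLines(path)
  i <- 1L
  frames <- list()
  meta <- NULL
  while (i <= length(lines)) {
    if (i + 1 > length(lines)) break
    title <- lines[i]
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1])))
    if (is.na(nat))
      stop("parse error at line ", i + 1, ": expected atom count")
    if (i + 2 + nat > length(lines))
      stop("parse error at line ", i, ": truncated frame")
    body <- lines[(i + 2):(i + 1 + nat)]
    resname <- trimws(substr(body, 6, 10))
    atname <- trimws(substr(body, 11, 15))
    xs <- suppressWarnings(as.numeric(substr(body, 21, 28)))
    ys <- suppressWarnings(as.numeric(substr(body, 29, 36)))
    zs <- suppressWarnings(as.numeric(substr(body, 37, 44)))
    if (anyNA(xs) || anyNA(ys) || anyNA(zs))
      stop("parse error in frame starting at line ", i,
           ": non-numeric coordinate")
    boxv <- as.numeric(strsplit(trimws(lines[i + 2 + nat]), "\\s+")[[1]])
    tm <- 0
    mt <- regmatches(title, regexec("t=\\s*([0-9.eE+-]+)", title))[[1]]
    if (length(mt) == 2) tm <- as.numeric(mt[2]) / 1000  # ps -> ns
    else tm <- length(frames)
    keep <- !grepl("^(MW|EP)", toupper(atname))
    pos <- unname(cbind(xs, ys, zs))[keep, , drop = FALSE] * 10  # nm -> A
    if (is.null(meta)) {
      resid_num <- as.integer(substr(body, 1, 5))[keep]
      meta <- gro_topology(resname[keep], atname[keep], resid_num, config)
    }
    frames[[length(frames) + 1]] <-
      new_frame(pos, boxv[1:3] * 10, c(TRUE, TRUE, FALSE), tm)
    i <- i + 3L + nat
  }
  trajectory(meta, frames)
}

gro_topology <- function(resname, atname, resid, config) {
  n <- length(resname)
  role <- rep(NA_character_, n)
  el <- element_from_name(atname)
  is_w <- resname %in% config$water
  is_a <- resname %in% config$alpha_alanine
  is_b <- resname %in% config$beta_alanine
  unknown <- unique(resname[!(is_w | is_a | is_b)])
  if (length(unknown))
    stop("role assignment error: unknown residue name(s) ",
         paste(unknown, collapse = ", "),
         " (declare them in the role config)")
  role[is_w & el == "O"] <- "water_oxygen"
  role[is_w & el == "H"] <- "water_hydrogen"
  role[!is_w & el != "H"] <- "solute_heavy"
  role[!is_w & el == "H"] <- "solute_hydrogen"
  kind <- if (any(is_a)) "alpha_alanine" else if (any(is_b)) "beta_alanine"
          else "none"
  # molecule id: consecutive (resid, resname) runs (gro resids wrap at 1e5)
  key <- paste(resid, resname)
  mol <- cumsum(c(TRUE, key[-1] != key[-n]))
  topology(el, mol, role, solute_kind = kind, atom_name = atname)
}

write_gro <- function(traj, path) {
  a <- traj$topology$atoms
  resname <- ifelse(a$role %in% c("water_oxygen", "water_hydrogen"), "SOL",
                    switch(traj$topology$solute_kind,
                           alpha_alanine = "AAL", beta_alanine = "BAL",
                           "LIG"))
  # water atom names by position within the molecule
  atname <- a$atom_name
  w <- a$role == "water_oxygen"
  atname[w] <- "OW"
  for (m in unique(a$molecule_id[a$role == "water_hydrogen"])) {
    idx <- which(a$molecule_id == m & a$role == "water_hydrogen")
    atname[idx] <- paste0("HW", seq_along(idx))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (f in traj$frames) {
    writeLines(sprintf("icetraj t= %.4f", f$time * 1000), con)
    writeLines(sprintf("%5d", nrow(f$positions)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       a$molecule_id %% 100000L, resname,
                       substr(atname, 1, 5),
                       a$atom_id %% 100000L + 1L,
                       f$positions[, 1] / 10, f$positions[, 2] / 10,
                       f$positions[, 3] / 10), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f",
                       f$box[1] / 10, f$box[2] / 10, f$box[3] / 10), con)
  }
}

# ---- PDB (via bio3d) ------------------------------------------------------

read_pdb_traj <- function(path, config = role_config(), dt = 1) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  resname <- trimws(pdb$atom$resid)
  atname <- trimws(pdb$atom$elety)
  keep <- !grepl("^(MW|EP)", toupper(atname))
  top <- gro_topology(resname[keep], atname[keep],
                      as.integer(pdb$atom$resno)[keep], config)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  box <- c(1000, 1000, 1000)
  lines <- readLines(path, n = 200)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl))
    box <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                        substr(cl[1], 25, 33)))
  frames <- lapply(seq_len(nrow(xyz)), function(k) {
    pos <- matrix(xyz[k, ], ncol = 3, byrow = TRUE)[keep, , drop = FALSE]
    new_frame(pos, box, c(TRUE, TRUE, FALSE), (k - 1) * dt)
  })
  trajectory(top, frames)
}

write_pdb_traj <- function(traj, path) {
  a <- traj$topology$atoms
  resname <- ifelse(a$role %in% c("water_oxygen", "water_hydrogen"), "SOL",
                    switch(traj$topology$solute_kind,
                           alpha_alanine = "AAL", beta_alanine = "BAL",
                           "LIG"))
  xyz <- do.call(rbind, lapply(traj$frames, function(f) as.numeric(t(f$positions))))
  b <- traj$frames[[1]]$box
  con <- file(path, "w")
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                     b[1], b[2], b[3]), con)
  close(con)
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$molecule_id,
                   resid = resname, eleno = a$atom_id + 1L,
                   elety = a$atom_name, append = TRUE)
  invisible(path)
}
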