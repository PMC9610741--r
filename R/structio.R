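# Internal unit convention: nanometres everywhere.  PDB and XYZ files are in
# Angstrom on disk and converted on read/write; GRO is natively nm.

#' Default residue-name allow-lists used to classify particles into segments
#'
#' Lipid and solvent classification is by residue name because bead-scale
#' topologies carry no element information.  Anything that is neither lipid
#' nor solvent nor protein-like is labelled "other"; particles with standard
#' amino-acid residue names (or the generic bead names used by the synthetic
#' generators) are labelled "protein".
#'
#' @return Named list with character vectors `lipid` and `solvent`.
#' @export
default_segment_names <- function() {
  list(
    lipid   = c("POPC", "POP", "DPPC", "DOPC", "POPE", "POPS", "LIP"),
    solvent = c("W", "WF", "HOH", "SOL", "TIP3", "NA", "CL", "CA", "ION")
  )
}

.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "PRT", "GLB")

classify_segment <- function(residue_name, names = default_segment_names()) {
  rn <- toupper(trimws(residue_name))
  out <- rep("other", length(rn))
  out[rn %in% toupper(names$lipid)] <- "lipid"
  out[rn %in% toupper(names$solvent)] <- "solvent"
  out[rn %in% .aa3] <- "protein"
  out
}

#' Construct a particle-based structure
#'
#' A structure is an ordered table of particles (atoms or coarse-grained
#' beads) with residue metadata and positions in nm, plus an optional
#' orthorhombic box.
#'
#' @param particles data.frame with columns `index` (1-based, consecutive),
#'   `name`, `residue_index` (>= 1), `residue_name`, `segment` (one of
#'   "protein", "lipid", "solvent", "other"), and positions `x`, `y`, `z`
#'   in nm.
#' @param box optional length-3 numeric, box vectors in nm (all > 0).
#' @return An object of class `md_structure`.
#' @export
md_structure <- function(particles, box = NULL) {
  stopifnot(is.data.frame(particles))
  req <- c("index", "name", "residue_index", "residue_name", "segment",
           "x", "y", "z")
  missing_cols <- setdiff(req, names(particles))
  if (length(missing_cols))
    stop("particles is missing columns: ", paste(missing_cols, collapse = ", "))
  n <- nrow(particles)
  if (n < 1) stop("structure must contain at least one particle")
  if (!identical(as.integer(particles$index), seq_len(n)))
    stop("particle indices must be unique and consecutive from 1")
  if (any(particles$residue_index < 1))
    stop("residue_index must be >= 1")
  if (!all(particles$segment %in% c("protein", "lipid", "solvent", "other")))
    stop("segment must be one of protein/lipid/solvent/other")
  pos <- as.matrix(particles[, c("x", "y", "z")])
  if (!all(is.finite(pos))) stop("particle positions must be finite")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
      stop("box must be three positive finite lengths (nm)")
  }
  structure(list(particles = particles, box = box), class = "md_structure")
}

#' @export
print.md_structure <- function(x, ...) {
  segs <- table(x$particles$segment)
  cat("<md_structure> ", nrow(x$particles), " particles (",
      paste(sprintf("%s: %d", names(segs), as.integer(segs)), collapse = ", "),
      ")", if (!is.null(x$box)) sprintf("; box %.2f x %.2f x %.2f nm",
                                        x$box[1], x$box[2], x$box[3]),
      "\n", sep = "")
  invisible(x)
}

#' Extract particle coordinates as an n x 3 matrix (nm)
#' @param structure an `md_structure`.
#' @export
coords <- function(structure) {
  as.matrix(structure$particles[, c("x", "y", "z")])
}

#' Replace particle coordinates of a structure
#' @param structure an `md_structure`.
#' @param xyz n x 3 coordinate matrix, nm.
#' @export
set_coords <- function(structure, xyz) {
  stopifnot(nrow(xyz) == nrow(structure$particles), ncol(xyz) == 3)
  structure$particles$x <- xyz[, 1]
  structure$particles$y <- xyz[, 2]
  structure$particles$z <- xyz[, 3]
  structure
}

#' Construct a trajectory over a fixed topology
#'
#' @param topology an `md_structure` describing the particles.
#' @param frames list of n x 3 coordinate matrices (nm), one per frame, each
#'   row matching the corresponding topology particle.
#' @param timestep_ns informational time between frames, ns.
#' @return An object of class `md_trajectory` storing coordinates as an
#'   `n_particles x 3 x n_frames` array.
#' @export
md_trajectory <- function(topology, frames, timestep_ns = NA_real_) {
  stopifnot(inherits(topology, "md_structure"))
  if (length(frames) < 1) stop("trajectory needs at least one frame")
  n <- nrow(topology$particles)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f) || nrow(f) != n || ncol(f) != 3)
      stop(sprintf("frame %d has %s coordinates; topology has %d particles",
                   i, if (is.matrix(f)) nrow(f) else "malformed", n))
    if (!all(is.finite(f))) stop(sprintf("frame %d has non-finite coordinates", i))
  }
  arr <- array(unlist(frames), dim = c(n, 3, length(frames)))
  structure(list(topology = topology, coords = arr, timestep_ns = timestep_ns),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("<md_trajectory> ", n_frames(x), " frames x ",
      nrow(x$topology$particles), " particles\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame as an n x 3 coordinate matrix (nm)
#' @param traj an `md_trajectory`.
#' @param i frame index (1-based).
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  traj$coords[, , i, drop = TRUE]
}

#' Construct an AFM-style height field
#'
#' @param heights numeric matrix of heights, nm; rows are the slow scan axis.
#' @param pixel_size_nm lateral size of one pixel, nm.
#' @param origin_nm length-2 physical coordinate of the (1,1) pixel centre.
#' @return Object of class `height_field`.
#' @export
height_field <- function(heights, pixel_size_nm, origin_nm = c(0, 0)) {
  heights <- as.matrix(heights)
  if (length(heights) == 0) stop("height field must be non-empty")
  if (!all(is.finite(heights))) stop("heights must be finite")
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0)
    stop("pixel_size_nm must be > 0")
  origin_nm <- as.numeric(origin_nm)
  if (length(origin_nm) != 2) stop("origin_nm must have length 2")
  structure(list(heights = heights, pixel_size_nm = pixel_size_nm,
                 origin_nm = origin_nm), class = "height_field")
}

#' @export
print.height_field <- function(x, ...) {
  cat("<height_field> ", nrow(x$heights), " x ", ncol(x$heights),
      " px @ ", x$pixel_size_nm, " nm/px\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Readers / writers
# ---------------------------------------------------------------------------

.parse_error <- function(path, line, msg) {
  stop(sprintf("parse error in '%s' at line %d: %s", path, line, msg),
       call. = FALSE)
}

.read_pdb_atoms <- function(lines, path, segment_names) {
  sel <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(sel)
  if (!length(idx)) .parse_error(path, 1L, "no ATOM/HETATM records")
  rec <- lines[idx]
  num <- function(s, from, to, what, ln) {
    v <- suppressWarnings(as.numeric(substr(s, from, to)))
    bad <- which(!is.finite(v))
    if (length(bad)) .parse_error(path, ln[bad[1]], paste("unreadable", what))
    v
  }
  name  <- trimws(substr(rec, 13, 16))
  rname <- trimws(substr(rec, 18, 20))
  rix   <- suppressWarnings(as.integer(substr(rec, 23, 26)))
  bad   <- which(is.na(rix))
  if (length(bad)) .parse_error(path, idx[bad[1]], "unreadable residue number")
  x <- num(rec, 31, 38, "x coordinate", idx)
  y <- num(rec, 39, 46, "y coordinate", idx)
  z <- num(rec, 47, 54, "z coordinate", idx)
  data.frame(index = seq_along(rec), name = name, residue_index = rix,
             residue_name = rname,
             segment = classify_segment(rname, segment_names),
             x = x / 10, y = y / 10, z = z / 10,   # Angstrom -> nm
             stringsAsFactors = FALSE)
}

#' Read a structure from a PDB or GRO file
#'
#' Coordinates are converted to nm (PDB files are Angstrom on disk).  The
#' segment of every particle is classified from its residue name against
#' configurable allow-lists.
#'
#' @param path file path.
#' @param format "pdb" or "gro".
#' @param segment_names allow-lists as returned by [default_segment_names()].
#' @return An `md_structure`.
#' @export
read_structure <- function(path, format = c("pdb", "gro"),
                           segment_names = default_segment_names()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) .parse_error(path, 1L, "empty file")
  if (format == "pdb") {
    particles <- .read_pdb_atoms(lines, path, segment_names)
    md_structure(particles)
  } else {
    .read_gro_frame(lines, 1L, path, segment_names)$structure
  }
}

# Parse one GRO frame starting at line `at`; returns structure + lines used.
.read_gro_frame <- function(lines, at, path, segment_names) {
  if (at + 1 > length(lines)) .parse_error(path, at, "truncated GRO frame")
  n <- suppressWarnings(as.integer(trimws(lines[at + 1])))
  if (is.na(n) || n < 1) .parse_error(path, at + 1L, "bad atom count")
  if (at + 1 + n + 1 > length(lines))
    .parse_error(path, length(lines), "truncated GRO frame (missing atoms or box)")
  rec <- lines[at + 1 + seq_len(n)]
  rix   <- suppressWarnings(as.integer(substr(rec, 1, 5)))
  rname <- trimws(substr(rec, 6, 10))
  aname <- trimws(substr(rec, 11, 15))
  xyz <- matrix(NA_real_, n, 3)
  for (k in 1:3) {
    from <- 21 + (k - 1) * 8
    xyz[, k] <- suppressWarnings(as.numeric(substr(rec, from, from + 7)))
  }
  bad <- which(is.na(rix) | !is.finite(rowSums(xyz)))
  if (length(bad)) .parse_error(path, at + 1L + bad[1], "unreadable atom record")
  boxline <- suppressWarnings(as.numeric(strsplit(trimws(lines[at + n + 2]),
                                                  "\\s+")[[1]]))
  box <- if (length(boxline) >= 3 && all(is.finite(boxline[1:3])) &&
             all(boxline[1:3] > 0)) boxline[1:3] else NULL
  particles <- data.frame(index = seq_len(n), name = aname,
                          residue_index = rix, residue_name = rname,
                          segment = classify_segment(rname, segment_names),
                          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                          stringsAsFactors = FALSE)
  list(structure = md_structure(particles, box = box), lines_used = n + 3L)
}

#' Write a structure to PDB or GRO
#'
#' @param structure an `md_structure`.
#' @param path output file path.
#' @param format "pdb" or "gro".
#' @export
write_structure <- function(structure, path, format = c("pdb", "gro")) {
  format <- match.arg(format)
  if (format == "pdb") {
    writeLines(c(.format_pdb_frame(structure, coords(structure), 0L), "END"),
               path)
  } else {
    writeLines(.format_gro_frame(structure, coords(structure), "memmodes"),
               path)
  }
  invisible(path)
}

.format_pdb_frame <- function(structure, xyz, model) {
  p <- structure$particles
  hdr <- if (model > 0) sprintf("MODEL     %4d", model) else character(0)
  recs <- sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                  p$index %% 100000, substr(p$name, 1, 4),
                  substr(p$residue_name, 1, 3), p$residue_index %% 10000,
                  xyz[, 1] * 10, xyz[, 2] * 10, xyz[, 3] * 10)
  ftr <- if (model > 0) "ENDMDL" else character(0)
  c(hdr, recs, ftr)
}

.format_gro_frame <- function(structure, xyz, title) {
  p <- structure$particles
  box <- if (is.null(structure$box)) c(0, 0, 0) else structure$box
  c(title,
    sprintf("%5d", nrow(p)),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            p$residue_index %% 100000, substr(p$residue_name, 1, 5),
            substr(p$name, 1, 5), p$index %% 100000,
            xyz[, 1], xyz[, 2], xyz[, 3]),
    sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
}

#' Read a multi-frame trajectory
#'
#' Supported dialects: multi-MODEL PDB ("multi-pdb"), concatenated GRO frames
#' ("multi-gro") and XYZ ("xyz", Angstrom on disk, comment line carries the
#' frame index).  Every frame must contain exactly one coordinate per
#' topology particle.
#'
#' @param path file path.
#' @param format one of "multi-pdb", "multi-gro", "xyz".
#' @param topology `md_structure` defining the particle order.
#' @param timestep_ns informational frame spacing, ns.
#' @return An `md_trajectory`.
#' @export
read_trajectory <- function(path, format = c("multi-pdb", "multi-gro", "xyz"),
                            topology, timestep_ns = NA_real_) {
  format <- match.arg(format)
  stopifnot(inherits(topology, "md_structure"))
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) .parse_error(path, 1L, "empty file")
  n <- nrow(topology$particles)
  frames <- list()
  if (format == "multi-pdb") {
    starts <- grep("^(ATOM  |HETATM)", lines)
    if (!length(starts)) .parse_error(path, 1L, "no ATOM records")
    breaks <- grepl("^(ENDMDL|END$|END )", lines)
    grp <- cumsum(breaks)
    atom_grp <- grp[starts]
    for (g in unique(atom_grp)) {
      rec <- lines[starts[atom_grp == g]]
      if (length(rec) != n)
        stop(sprintf("frame %d has %d particles; topology has %d",
                     length(frames) + 1L, length(rec), n))
      xyz <- cbind(as.numeric(substr(rec, 31, 38)),
                   as.numeric(substr(rec, 39, 46)),
                   as.numeric(substr(rec, 47, 54))) / 10
      frames[[length(frames) + 1L]] <- xyz
    }
  } else if (format == "multi-gro") {
    at <- 1L
    while (at <= length(lines)) {
      if (!nzchar(trimws(lines[at])) && at == length(lines)) break
      fr <- .read_gro_frame(lines, at, path, default_segment_names())
      xyz <- coords(fr$structure)
      if (nrow(xyz) != n)
        stop(sprintf("frame %d has %d particles; topology has %d",
                     length(frames) + 1L, nrow(xyz), n))
      frames[[length(frames) + 1L]] <- xyz
      at <- at + fr$lines_used
    }
  } else {
    at <- 1L
    while (at <= length(lines)) {
      if (!nzchar(trimws(lines[at]))) { at <- at + 1L; next }
      cnt <- suppressWarnings(as.integer(trimws(lines[at])))
      if (is.na(cnt)) .parse_error(path, at, "bad XYZ atom count")
      if (cnt != n)
        stop(sprintf("frame %d has %d particles; topology has %d",
                     length(frames) + 1L, cnt, n))
      if (at + 1 + cnt > length(lines))
        .parse_error(path, length(lines), "truncated XYZ frame")
      rec <- lines[at + 1 + seq_len(cnt)]
      parts <- strsplit(trimws(rec), "\\s+")
      xyz <- t(vapply(parts, function(v) as.numeric(v[2:4]), numeric(3))) / 10
      if (!all(is.finite(xyz)))
        .parse_error(path, at + 2L, "unreadable XYZ coordinates")
      frames[[length(frames) + 1L]] <- xyz
      at <- at + 2L + cnt
    }
  }
  md_trajectory(topology, frames, timestep_ns = timestep_ns)
}

#' Write a trajectory
#'
#' @param traj an `md_trajectory`.
#' @param path output path.
#' @param format one of "multi-pdb", "multi-gro", "xyz".
#' @export
write_trajectory <- function(traj, path,
                             format = c("multi-pdb", "multi-gro", "xyz")) {
  format <- match.arg(format)
  top <- traj$topology
  out <- character(0)
  for (i in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, i)
    out <- c(out, switch(format,
      "multi-pdb" = .format_pdb_frame(top, xyz, i),
      "multi-gro" = .format_gro_frame(top, xyz, sprintf("frame %d", i)),
      "xyz" = c(sprintf("%d", nrow(xyz)), sprintf("frame %d", i),
                sprintf("%-5s %12.5f %12.5f %12.5f", top$particles$name,
                        xyz[, 1] * 10, xyz[, 2] * 10, xyz[, 3] * 10))))
  }
  if (format == "multi-pdb") out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

#' Read a height field from headered TSV
#'
#' The dialect is a numeric matrix preceded by two comment lines,
#' `# pixel_size_nm=<v>` and `# origin_nm=<x> <y>`.
#'
#' @param path file path.
#' @return A `height_field`.
#' @export
read_heightfield <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) .parse_error(path, 1L, "need 2 header lines + data")
  getval <- function(key, ln) {
    m <- regmatches(lines[ln], regexec(paste0("^#\\s*", key, "=(.+)$"),
                                       lines[ln]))[[1]]
    if (length(m) < 2) .parse_error(path, ln, paste("missing", key, "header"))
    v <- suppressWarnings(as.numeric(strsplit(trimws(m[2]), "\\s+")[[1]]))
    if (any(!is.finite(v))) .parse_error(path, ln, paste("bad", key, "value"))
    v
  }
  px <- getval("pixel_size_nm", 1L)
  org <- getval("origin_nm", 2L)
  rows <- lapply(lines[-(1:2)], function(l)
    suppressWarnings(as.numeric(strsplit(trimws(l), "[\t ]+")[[1]])))
  rows <- rows[vapply(rows, length, 1L) > 0]
  wid <- vapply(rows, length, 1L)
  if (length(unique(wid)) != 1)
    .parse_error(path, 2L + which(wid != wid[1])[1], "ragged row")
  h <- do.call(rbind, rows)
  if (!all(is.finite(h))) .parse_error(path, 3L, "non-numeric height value")
  height_field(h, pixel_size_nm = px[1], origin_nm = org)
}

#' Write a height field as headered TSV
#'
#' @param field a `height_field`.
#' @param path output path.
#' @param digits decimal digits kept in the text representation.
#' @export
write_heightfield <- function(field, path, digits = 6) {
  stopifnot(inherits(field, "height_field"))
  hdr <- c(sprintf("# pixel_size_nm=%.*f", digits, field$pixel_size_nm),
           sprintf("# origin_nm=%.*f %.*f", digits, field$origin_nm[1],
                   digits, field$origin_nm[2]))
  body <- apply(field$heights, 1, function(r)
    paste(sprintf("%.*f", digits, r), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}
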