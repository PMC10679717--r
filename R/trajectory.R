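# Trajectory container and I/O. Frames are stored as a list of n x 3
# coordinate matrices (Angstrom) with per-frame times (ns) and the TTMD step
# index each frame belongs to.

new_trajectory <- function(coords, times, step = NULL) {
  stopifnot(length(coords) == length(times))
  n <- vapply(coords, nrow, 0L)
  if (length(unique(n)) > 1) abort("frames differ in atom count")
  if (length(times) > 1 && any(diff(times) <= 0))
    abort("frame times must be strictly increasing")
  structure(
    list(coords = coords, times = times,
         step = step %||% rep(1L, length(times)),
         n_atoms = if (length(coords)) nrow(coords[[1]]) else 0L),
    class = "ttmd_trajectory"
  )
}

#' @export
print.ttmd_trajectory <- function(x, ...) {
  cat("<ttmd_trajectory> ", length(x$coords), " frames, ", x$n_atoms,
      " atoms, ", if (length(x$times)) sprintf("%.3f-%.3f ns",
      min(x$times), max(x$times)) else "", "\n", sep = "")
  invisible(x)
}

#' Load a trajectory against a topology
#'
#' Supports DCD (read through bio3d) and multi-model PDB. The topology (a
#' `ttmd_complex` or an atom count) must match the per-frame atom count.
#'
#' @param complex a `ttmd_complex` (or integer atom count) serving as the
#'   topology reference.
#' @param path trajectory file (`.dcd` or multi-model `.pdb`).
#' @param dt time between saved frames in ns (frame times are `dt`, `2 dt`,
#'   ...).
#' @return a `ttmd_trajectory`.
#' @export
read_trajectory <- function(complex, path, dt = 0.1) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  n_top <- if (inherits(complex, "ttmd_complex")) nrow(complex$atoms)
           else as.integer(complex)
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE)
    xyz <- pdb$xyz
  }
  xyz <- as.matrix(xyz)
  if (ncol(xyz) %% 3 != 0) abort("malformed trajectory coordinates")
  n <- ncol(xyz) %/% 3
  if (n != n_top)
    abort(sprintf("atom-count mismatch: topology %d, trajectory %d",
                  n_top, n))
  if (nrow(xyz) == 0) abort("trajectory contains no frames")
  coords <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  new_trajectory(coords, dt * seq_len(nrow(xyz)))
}

#' Write a trajectory
#'
#' Multi-model PDB (text; atom metadata taken from the complex) or a minimal
#' CHARMM-format DCD.
#'
#' @param traj a `ttmd_trajectory`.
#' @param complex the matching `ttmd_complex` (required for PDB output).
#' @param path output path; format chosen by extension (`.dcd` or `.pdb`).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, complex, path) {
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    write_dcd(traj, path)
  } else {
    xyz <- do.call(rbind, lapply(traj$coords, function(m) as.vector(t(m))))
    at <- complex$atoms
    bio3d::write.pdb(file = path, xyz = xyz, type = ifelse(at$is_ligand,
                     "HETATM", "ATOM"), resno = at$resno, resid = at$resname,
                     eleno = at$atom_id, elety = at$name, chain = at$chain,
                     elesy = at$element)
  }
  invisible(path)
}

# Minimal CHARMM DCD writer (no unit cell), sufficient for round-tripping
# through standard readers.
write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nframes <- length(traj$coords)
  natom <- traj$n_atoms
  icntrl <- integer(20)
  icntrl[1] <- nframes; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nframes
  icntrl[20] <- 24L
  writeBin(84L, con, size = 4)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  writeBin(icntrl, con, size = 4)
  writeBin(84L, con, size = 4)
  title <- sprintf("%-80s", "ttmd trajectory")
  writeBin(4L + 80L, con, size = 4)
  writeBin(1L, con, size = 4)
  writeChar(title, con, nchars = 80, eos = NULL)
  writeBin(4L + 80L, con, size = 4)
  writeBin(4L, con, size = 4); writeBin(natom, con, size = 4)
  writeBin(4L, con, size = 4)
  for (m in traj$coords) {
    for (k in 1:3) {
      writeBin(4L * natom, con, size = 4)
      writeBin(as.numeric(m[, k]), con, size = 4)
      writeBin(4L * natom, con, size = 4)
    }
  }
  invisible(path)
}
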