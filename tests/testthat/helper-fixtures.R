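# Fixture builders (all programmatic) and independent oracles used across
# the suite.

# ---- PDB text fixtures -----------------------------------------------------

pdb_line <- function(serial, name, resname, chain, resno, xyz, element,
                     het = FALSE) {
  sprintf("%-6s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          if (het) "HETATM" else "ATOM", serial,
          if (nchar(name) < 4) paste0(" ", name) else name,
          resname, chain, resno, xyz[1], xyz[2], xyz[3], element)
}

write_pdb_fixture <- function(atoms, path) {
  lines <- vapply(seq_len(nrow(atoms)), function(i)
    pdb_line(i, atoms$name[i], atoms$resname[i], atoms$chain[i],
             atoms$resno[i], c(atoms$x[i], atoms$y[i], atoms$z[i]),
             atoms$element[i], het = atoms$is_ligand[i]), "")
  writeLines(c(lines, "END"), path)
  path
}

# A guanine nucleotide (base ring atoms in an idealised plane, phosphate
# group, 2'-OH) plus a small two-atom ligand 3.5 A above the base plane.
guanine_fixture_atoms <- function() {
  hex <- function(r, z = 0, phase = 0) {
    a <- phase + seq(0, by = pi / 3, length.out = 6)
    cbind(r * cos(a), r * sin(a), z)
  }
  ring6 <- hex(1.39)
  base <- tibble::tibble(
    name = c("N1", "C2", "N3", "C4", "C5", "C6"),
    x = ring6[, 1], y = ring6[, 2], z = 0)
  # fused five-membered ring sharing C4-C5; approximate planar positions
  five <- tibble::tibble(
    name = c("N7", "C8", "N9"),
    x = c(2.75, 3.55, 2.80), y = c(1.10, 0.00, -1.10), z = 0)
  subst <- tibble::tibble(
    name = c("O6", "N2", "P", "OP1", "OP2", "O2'"),
    x = c(-1.2, -1.2, -5.0, -6.3, -5.0, -4.0),
    y = c(2.4, -2.4, 0.0, 0.7, -0.7, 2.0),
    z = c(0, 0, 1.0, 1.0, 2.2, 3.0))
  g <- dplyr::bind_rows(base, five, subst)
  g$element <- substr(g$name, 1, 1)
  g$resname <- "G"; g$chain <- "A"; g$resno <- 1L; g$is_ligand <- FALSE
  lig <- tibble::tibble(
    name = c("C1", "O1"), element = c("C", "O"),
    x = c(0, 1.4), y = c(0, 0), z = c(3.5, 3.5),
    resname = "LIG", chain = "A", resno = 9L, is_ligand = TRUE)
  dplyr::bind_rows(g, lig)
}

# Build a complex directly (bypassing file I/O) from an atom tibble.
complex_of <- function(atoms) ttmd:::new_complex(atoms)

# A randomised multi-residue receptor + ligand complex with hand-set
# pharmacophoric flags, used for oracle comparisons. Geometry and flags are
# random but reproducible.
random_flag_complex <- function(seed, n_res = 3, atoms_per_res = 5,
                                n_lig = 6) {
  set.seed(seed)
  rec <- purrr::map_dfr(seq_len(n_res), function(r) {
    centre <- runif(3, -6, 6)
    tibble::tibble(
      name = paste0("X", seq_len(atoms_per_res)),
      element = sample(c("C", "N", "O"), atoms_per_res, replace = TRUE),
      chain = "A", resno = r, resname = "XXX",
      x = centre[1] + runif(atoms_per_res, -1.5, 1.5),
      y = centre[2] + runif(atoms_per_res, -1.5, 1.5),
      z = centre[3] + runif(atoms_per_res, -1.5, 1.5),
      is_ligand = FALSE)
  })
  lig <- tibble::tibble(
    name = paste0("L", seq_len(n_lig)),
    element = sample(c("C", "N", "O", "H"), n_lig, replace = TRUE,
                     prob = c(0.4, 0.2, 0.2, 0.2)),
    chain = "A", resno = 99L, resname = "LIG",
    x = runif(n_lig, -3, 3), y = runif(n_lig, -3, 3),
    z = runif(n_lig, -3, 3), is_ligand = TRUE)
  cx <- suppressWarnings(complex_of(dplyr::bind_rows(rec, lig)))
  heavy <- cx$atoms$element != "H"
  n <- nrow(cx$atoms)
  cx$flags$hb_donor <- heavy & runif(n) < 0.3
  cx$flags$hb_acceptor <- heavy & runif(n) < 0.3
  cx$flags$cation <- heavy & runif(n) < 0.15
  cx$flags$anion <- heavy & runif(n) < 0.15
  cx$flags$hydrophobe <- heavy & runif(n) < 0.4
  cx$flags$halogen <- heavy & cx$atoms$is_ligand & runif(n) < 0.1
  cx
}

# A complex holding two parallel (or tilted) six-membered carbon rings:
# one ligand ring at the origin and one receptor ring offset along z.
ring_pair_complex <- function(centroid_dist, tilt_deg = 0) {
  hexagon <- function(z0, tilt = 0) {
    a <- seq(0, by = pi / 3, length.out = 6)
    pts <- cbind(1.39 * cos(a), 1.39 * sin(a), 0)
    if (tilt != 0) {
      th <- tilt * pi / 180
      rot <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
      pts <- pts %*% t(rot)
    }
    sweep(pts, 2, c(0, 0, z0), `+`)
  }
  rec_pts <- hexagon(0)
  lig_pts <- hexagon(0, tilt_deg)
  lig_pts[, 3] <- lig_pts[, 3] + centroid_dist
  atoms <- tibble::tibble(
    name = paste0("C", 1:12),
    element = "C", chain = "A",
    resno = c(rep(1L, 6), rep(9L, 6)),
    resname = c(rep("XRG", 6), rep("LIG", 6)),
    x = c(rec_pts[, 1], lig_pts[, 1]),
    y = c(rec_pts[, 2], lig_pts[, 2]),
    z = c(rec_pts[, 3], lig_pts[, 3]),
    is_ligand = c(rep(FALSE, 6), rep(TRUE, 6)))
  suppressWarnings(complex_of(atoms))
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(
    c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

# ---- independent oracles ---------------------------------------------------

# Naive O(n^2) re-implementation of every geometric detection rule, written
# with plain loops and scalar arithmetic, independent of the vectorised
# package path.
oracle_detect <- function(coords, cx, residues, rules = geometry_rules()) {
  atoms <- cx$atoms
  fl <- cx$flags
  keys <- ttmd::residue_key(atoms$chain, atoms$resno, atoms$resname)
  dist <- function(i, j) sqrt(sum((coords[i, ] - coords[j, ])^2))
  ang_at <- function(a, b, c) {
    u <- coords[a, ] - coords[b, ]; v <- coords[c, ] - coords[b, ]
    acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  }
  hyd <- function(i) {
    nb <- cx$adjacency[[i]]
    nb[atoms$element[nb] == "H"]
  }
  hits <- character(0)
  put <- function(res, cls) hits <<- c(hits, paste(res, cls))
  lig <- which(atoms$is_ligand)
  rec <- which(!atoms$is_ligand & keys %in% residues)
  for (i in lig) for (j in rec) {
    hj <- atoms$element[j] != "H"; hi <- atoms$element[i] != "H"
    d <- dist(i, j)
    if (fl$hb_donor[i] && fl$hb_acceptor[j] && hj && d <= rules$hb_dist) {
      for (h in hyd(i))
        if (ang_at(i, h, j) >= rules$hb_angle) { put(keys[j], "HBDonor"); break }
    }
    if (fl$hb_acceptor[i] && fl$hb_donor[j] && hi && d <= rules$hb_dist) {
      for (h in hyd(j))
        if (ang_at(j, h, i) >= rules$hb_angle) { put(keys[j], "HBAcceptor"); break }
    }
    if (((fl$cation[i] && fl$anion[j]) || (fl$anion[i] && fl$cation[j])) &&
        d <= rules$ionic_dist) put(keys[j], "Ionic")
    if (fl$hydrophobe[i] && fl$hydrophobe[j] && d <= rules$hydrophobic_dist)
      put(keys[j], "Hydrophobic")
    if (((fl$halogen[i] && fl$hb_acceptor[j] && hj) ||
         (fl$hb_acceptor[i] && hi && fl$halogen[j])) &&
        d <= rules$halogen_dist) put(keys[j], "Halogen")
    if (hi && hj) {
      rsum <- ttmd:::vdw_radius(atoms$element[i]) +
        ttmd:::vdw_radius(atoms$element[j]) + rules$vdw_slack
      if (d <= rsum) put(keys[j], "VdWContact")
    }
  }
  ring_geom <- function(members) {
    m <- coords[members, , drop = FALSE]
    c0 <- colMeans(m)
    cc <- sweep(m, 2, c0)
    list(c = c0, n = svd(cc)$v[, 3])
  }
  fold <- function(a) if (a > 90) 180 - a else a
  vang <- function(u, v)
    acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  ligr <- Filter(function(r) r$side == "ligand", cx$rings)
  recr <- Filter(function(r) r$side != "ligand" && r$residue %in% residues,
                 cx$rings)
  for (a in ligr) for (b in recr) {
    ga <- ring_geom(a$atoms); gb <- ring_geom(b$atoms)
    d <- sqrt(sum((ga$c - gb$c)^2))
    if (d <= rules$pistack_dist) {
      an <- fold(vang(ga$n, gb$n))
      if (an <= rules$pistack_face ||
          (an >= rules$pistack_edge[1] && an <= rules$pistack_edge[2]))
        put(b$residue, "PiStacking")
    }
  }
  for (i in lig[fl$cation[lig]]) for (b in recr) {
    gb <- ring_geom(b$atoms)
    v <- coords[i, ] - gb$c
    if (sqrt(sum(v^2)) <= rules$cationpi_dist &&
        fold(vang(v, gb$n)) <= rules$cationpi_angle)
      put(b$residue, "CationPi")
  }
  for (j in rec[fl$cation[rec]]) for (a in ligr) {
    ga <- ring_geom(a$atoms)
    v <- coords[j, ] - ga$c
    if (sqrt(sum(v^2)) <= rules$cationpi_dist &&
        fold(vang(v, ga$n)) <= rules$cationpi_angle)
      put(keys[j], "PiCation")
  }
  sort(unique(hits))
}

# Horn's closed-form quaternion method for optimal superposition: an
# independent oracle for the SVD-based path. Returns the post-fit RMSD over
# the fit selection.
oracle_quaternion_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  M <- crossprod(A, B)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- rbind(
    c(Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx),
    c(Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz),
    c(Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy),
    c(Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz))
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  ssq <- sum(A^2) + sum(B^2) - 2 * lambda
  sqrt(max(0, ssq) / nrow(mobile))
}

# Stub engine returning scripted coordinates: `coords_for(step, frame)`
# must return an n x 3 matrix. Used for protocol-logic tests.
scripted_engine <- function(coords_for, frames_per_step = 10) {
  counter <- new.env()
  counter$step <- 0L
  ttmd::new_engine(function(config, state) {
    counter$step <- counter$step + 1L
    frames <- lapply(seq_len(frames_per_step), function(f)
      coords_for(counter$step, f))
    list(frames = frames, state = list(coords = frames[[frames_per_step]]))
  }, description = "scripted test engine")
}
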