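#' Interaction classes
#'
#' The closed, stably ordered set of residue-level interaction classes used
#' in fingerprint layouts. `HBDonor` means the ligand donates the hydrogen
#' bond; `CationPi` is a ligand cation over a receptor ring and `PiCation`
#' the converse.
#'
#' @return character vector of the nine class names.
#' @export
interaction_classes <- function() {
  c("HBDonor", "HBAcceptor", "PiStacking", "CationPi", "PiCation",
    "Ionic", "Hydrophobic", "Halogen", "VdWContact")
}

#' Geometric detection rules
#'
#' Distance/angle cutoffs for interaction detection. Defaults follow common
#' fingerprint practice for nucleic-acid-capable interaction typing:
#' hydrogen bond donor-acceptor <= 3.5 A with D-H...A angle >= 130 deg;
#' ionic <= 4.5 A; hydrophobic <= 4.5 A; pi stacking centroid <= 5.5 A with
#' face-to-face (normal-normal <= 30 deg) or edge-to-face (60-90 deg)
#' geometry; cation-pi <= 4.5 A within 30 deg of the ring normal; halogen
#' bond <= 3.5 A; van der Waals contact <= sum of vdW radii + 0.5 A.
#'
#' @param hb_dist,hb_angle,ionic_dist,hydrophobic_dist,pistack_dist
#'   cutoffs (Angstrom, degrees).
#' @param pistack_face,pistack_edge face-to-face normal-angle maximum and
#'   edge-to-face angle window `c(min, max)`.
#' @param cationpi_dist,cationpi_angle,halogen_dist,vdw_slack remaining
#'   cutoffs.
#' @return a `ttmd_geometry` list of cutoffs.
#' @export
geometry_rules <- function(hb_dist = 3.5, hb_angle = 130,
                           ionic_dist = 4.5, hydrophobic_dist = 4.5,
                           pistack_dist = 5.5, pistack_face = 30,
                           pistack_edge = c(60, 90),
                           cationpi_dist = 4.5, cationpi_angle = 30,
                           halogen_dist = 3.5, vdw_slack = 0.5) {
  structure(list(
    hb_dist = hb_dist, hb_angle = hb_angle, ionic_dist = ionic_dist,
    hydrophobic_dist = hydrophobic_dist, pistack_dist = pistack_dist,
    pistack_face = pistack_face, pistack_edge = pistack_edge,
    cationpi_dist = cationpi_dist, cationpi_angle = cationpi_angle,
    halogen_dist = halogen_dist, vdw_slack = vdw_slack
  ), class = "ttmd_geometry")
}

# Angle between two direction vectors folded into [0, 90] degrees
# (ring normals have no sign).
axis_angle <- function(u, v) {
  a <- vec_angle(u, v)
  if (a > 90) 180 - a else a
}

ring_geometry <- function(xyz, members) {
  m <- xyz[members, , drop = FALSE]
  centroid <- colMeans(m)
  centred <- sweep(m, 2, centroid)
  normal <- svd(centred)$v[, 3]
  list(centroid = centroid, normal = normal)
}

#' Detect receptor-ligand interactions in one frame
#'
#' Pure function of coordinates, annotations and geometric rules: returns
#' the set of (residue, class) pairs between the ligand and the given
#' binding-site residues.
#'
#' @param coords n x 3 coordinate matrix covering every atom of the complex.
#' @param complex a `ttmd_complex`.
#' @param residues residue keys (from [select_binding_site()]).
#' @param rules a `ttmd_geometry` object.
#' @return tibble with columns `residue`, `class` (zero rows if no contact).
#' @export
detect_interactions <- function(coords, complex, residues,
                                rules = geometry_rules()) {
  atoms <- complex$atoms
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(atoms)) abort("coords do not cover all atoms")
  flags <- complex$flags
  keys <- residue_key(atoms$chain, atoms$resno, atoms$resname)
  in_site <- keys %in% residues & !atoms$is_ligand
  heavy <- atoms$element != "H"
  adj <- complex$adjacency
  hyd_of <- function(i) {
    nb <- adj[[i]] %||% integer()
    nb[atoms$element[nb] == "H"]
  }
  hits_res <- character(); hits_cls <- character()
  add <- function(res, cls) {
    hits_res <<- c(hits_res, res); hits_cls <<- c(hits_cls, cls)
  }

  pair_scan <- function(lig_idx, rec_idx, cutoff, cls, angle_check = NULL) {
    if (!length(lig_idx) || !length(rec_idx)) return()
    d <- cross_dist(coords[lig_idx, , drop = FALSE],
                    coords[rec_idx, , drop = FALSE])
    hit <- which(d <= cutoff, arr.ind = TRUE)
    for (k in seq_len(nrow(hit))) {
      i <- lig_idx[hit[k, 1]]; j <- rec_idx[hit[k, 2]]
      if (is.null(angle_check) || angle_check(i, j)) add(keys[j], cls)
    }
  }

  lig <- which(atoms$is_ligand)
  # hydrogen bonds, both directions; angle measured at the donated H
  hb_ok <- function(donor, acceptor) {
    hs <- hyd_of(donor)
    length(hs) > 0 && any(vapply(hs, function(h)
      point_angle(coords[donor, ], coords[h, ], coords[acceptor, ]) >=
        rules$hb_angle, TRUE))
  }
  pair_scan(lig[flags$hb_donor[lig]],
            which(in_site & flags$hb_acceptor & heavy),
            rules$hb_dist, "HBDonor", function(i, j) hb_ok(i, j))
  pair_scan(lig[flags$hb_acceptor[lig]],
            which(in_site & flags$hb_donor & heavy),
            rules$hb_dist, "HBAcceptor", function(i, j) hb_ok(j, i))
  # ionic, both charge orders
  pair_scan(lig[flags$cation[lig]], which(in_site & flags$anion),
            rules$ionic_dist, "Ionic")
  pair_scan(lig[flags$anion[lig]], which(in_site & flags$cation),
            rules$ionic_dist, "Ionic")
  pair_scan(lig[flags$hydrophobe[lig]], which(in_site & flags$hydrophobe),
            rules$hydrophobic_dist, "Hydrophobic")
  # halogen bond: ligand halogen to receptor acceptor (and the converse)
  pair_scan(lig[flags$halogen[lig]], which(in_site & flags$hb_acceptor & heavy),
            rules$halogen_dist, "Halogen")
  pair_scan(lig[flags$hb_acceptor[lig]], which(in_site & flags$halogen),
            rules$halogen_dist, "Halogen")
  # van der Waals contact between any heavy-atom pair
  lig_h <- lig[heavy[lig]]
  rec_h <- which(in_site & heavy)
  if (length(lig_h) && length(rec_h)) {
    d <- cross_dist(coords[lig_h, , drop = FALSE],
                    coords[rec_h, , drop = FALSE])
    thr <- outer(vdw_radius(atoms$element[lig_h]),
                 vdw_radius(atoms$element[rec_h]), "+") + rules$vdw_slack
    hit <- which(d <= thr, arr.ind = TRUE)
    for (k in seq_len(nrow(hit))) add(keys[rec_h[hit[k, 2]]], "VdWContact")
  }
  # ring-based classes
  is_lig_ring <- vapply(complex$rings, function(r) r$side == "ligand", TRUE)
  lig_rings <- complex$rings[is_lig_ring]
  rec_rings <- complex$rings[!is_lig_ring &
    vapply(complex$rings, function(r) r$residue %in% residues, TRUE)]
  lg <- lapply(lig_rings, function(r) ring_geometry(coords, r$atoms))
  rg <- lapply(rec_rings, function(r) ring_geometry(coords, r$atoms))
  for (a in seq_along(lig_rings)) {
    for (b in seq_along(rec_rings)) {
      dc <- sqrt(sum((lg[[a]]$centroid - rg[[b]]$centroid)^2))
      if (dc <= rules$pistack_dist) {
        ang <- axis_angle(lg[[a]]$normal, rg[[b]]$normal)
        if (ang <= rules$pistack_face ||
            (ang >= rules$pistack_edge[1] && ang <= rules$pistack_edge[2]))
          add(rec_rings[[b]]$residue, "PiStacking")
      }
    }
  }
  cation_pi <- function(cat_idx, ring_geoms, ring_objs, cls, res_from_ring) {
    for (i in cat_idx) {
      for (b in seq_along(ring_geoms)) {
        v <- coords[i, ] - ring_geoms[[b]]$centroid
        dc <- sqrt(sum(v^2))
        if (dc <= rules$cationpi_dist &&
            axis_angle(v, ring_geoms[[b]]$normal) <= rules$cationpi_angle)
          add(if (res_from_ring) ring_objs[[b]]$residue else keys[i], cls)
      }
    }
  }
  cation_pi(lig[flags$cation[lig]], rg, rec_rings, "CationPi", TRUE)
  cation_pi(which(in_site & flags$cation), lg, lig_rings, "PiCation", FALSE)

  out <- tibble::tibble(residue = hits_res, class = hits_cls)
  dplyr::distinct(out)
}

#' Build a fixed fingerprint layout
#'
#' One slot per (binding-site residue x interaction class); the slot order
#' is deterministic (residues canonically sorted, classes in their stable
#' enumeration order) and fixed for the lifetime of a titration so cosine
#' comparisons stay aligned.
#'
#' @param complex a `ttmd_complex` (recorded for provenance).
#' @param residues residue keys.
#' @param classes interaction classes to include (default: all nine).
#' @return a `ttmd_layout` tibble with columns `slot`, `residue`, `class`.
#' @export
build_layout <- function(complex, residues, classes = interaction_classes()) {
  if (!length(residues)) abort("residues must be non-empty")
  if (!length(classes)) abort("classes must be non-empty")
  classes <- interaction_classes()[interaction_classes() %in% classes]
  residues <- order_residue_keys(as.character(residues))
  grid <- tidyr::expand_grid(residue = residues, class = classes)
  grid$slot <- seq_len(nrow(grid))
  out <- grid[, c("slot", "residue", "class")]
  attr(out, "signature") <- rlang::hash(list(residues, classes))
  class(out) <- c("ttmd_layout", class(out))
  out
}

layout_signature <- function(layout) attr(layout, "signature")

#' Fingerprint one frame
#'
#' Binary fingerprint over the layout slots: bit i is 1 iff
#' [detect_interactions()] reports slot i's (residue, class) pair. Multiple
#' simultaneous contacts of one class to one residue still set a single bit.
#'
#' @param coords n x 3 coordinate matrix for the frame.
#' @param complex a `ttmd_complex`.
#' @param layout a `ttmd_layout`.
#' @param rules a `ttmd_geometry`.
#' @return integer 0/1 vector of length `nrow(layout)` (class `ttmd_fp`).
#' @export
fingerprint <- function(coords, complex, layout, rules = geometry_rules()) {
  det <- detect_interactions(coords, complex, unique(layout$residue), rules)
  bits <- integer(nrow(layout))
  if (nrow(det)) {
    idx <- match(paste(det$residue, det$class),
                 paste(layout$residue, layout$class))
    bits[idx[!is.na(idx)]] <- 1L
  }
  structure(bits, signature = layout_signature(layout), class = "ttmd_fp")
}
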