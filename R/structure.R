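#' Residue keys
#'
#' Residues are identified throughout the package by a `chain:resno:resname`
#' string, ordered deterministically by chain then residue number (numbering
#' is taken verbatim from the input file; no renumbering).
#'
#' @param chain,resno,resname vectors of chain identifiers, residue numbers
#'   and residue names.
#' @return character vector of residue keys.
#' @export
residue_key <- function(chain, resno, resname) {
  paste(chain, resno, resname, sep = ":")
}

# Order residue keys by (chain, resno). `keys` is a character vector of
# residue keys; returns the keys sorted canonically and deduplicated.
order_residue_keys <- function(keys) {
  keys <- unique(keys)
  parts <- strsplit(keys, ":", fixed = TRUE)
  chain <- vapply(parts, `[`, "", 1L)
  resno <- as.numeric(vapply(parts, `[`, "", 2L))
  keys[order(chain, resno)]
}

.backbone_names <- c("P", "OP1", "O1P", "OP2", "O2P", "O5'", "C5'", "C4'",
                     "C3'", "O3'")
.standard_nt <- c("A", "U", "G", "C", "RA", "RU", "RG", "RC",
                  "DA", "DT", "DG", "DC")
.solvent_resnames <- c("HOH", "WAT", "TIP", "TIP3", "SPC", "SOL")
.ion_elements <- c("NA", "K", "MG", "CL", "CA", "ZN")

# Shipped typing table: (resname, atom) -> pharmacophoric flags + ring id.
# resname "ANY" rows cover the sugar-phosphate backbone of all nucleotides.
typing_rules <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "nucleotide_typing.csv", package = "ttmd")
      cache <<- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE,
                                           na.strings = character()))
    }
    cache
  }
})

# ---- bond perception -------------------------------------------------------

# Distance-based covalent bond detection: a pair is bonded when its distance
# is below the sum of covalent radii + 0.4 A tolerance. Returns a two-column
# matrix of atom indices (i < j). Explicit CONECT pairs may be supplied and
# are merged in.
perceive_bonds <- function(atoms, extra_pairs = NULL) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  rcov <- covalent_radius(atoms$element)
  d <- cross_dist(xyz, xyz)
  thr <- outer(rcov, rcov, "+") + 0.4
  hit <- d <= thr & upper.tri(d) & d > 0.1
  idx <- which(hit, arr.ind = TRUE)
  # never bond two hydrogens
  hh <- atoms$element[idx[, 1]] == "H" & atoms$element[idx[, 2]] == "H"
  idx <- idx[!hh, , drop = FALSE]
  if (!is.null(extra_pairs) && nrow(extra_pairs)) {
    ep <- t(apply(extra_pairs, 1, sort))
    idx <- unique(rbind(idx, ep))
  }
  unname(idx)
}

bond_adjacency <- function(bonds, n) {
  adj <- vector("list", n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

# Smallest rings (5- or 6-membered) in the heavy-atom bond graph of the given
# atom indices, found per edge via shortest alternative path.
find_rings <- function(atoms, bonds, indices) {
  heavy <- indices[atoms$element[indices] != "H"]
  sub <- bonds[bonds[, 1] %in% heavy & bonds[, 2] %in% heavy, , drop = FALSE]
  if (!nrow(sub)) return(list())
  sub <- unique(cbind(pmin(sub[, 1], sub[, 2]), pmax(sub[, 1], sub[, 2])))
  verts <- as.character(sort(unique(c(sub))))
  g <- igraph::graph_from_edgelist(cbind(as.character(sub[, 1]),
                                         as.character(sub[, 2])),
                                   directed = FALSE)
  rings <- list()
  for (k in seq_len(nrow(sub))) {
    u <- as.character(sub[k, 1]); v <- as.character(sub[k, 2])
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(u, v)))
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = u, to = v))
    path <- sp$vpath[[1]]
    if (length(path) >= 5 && length(path) <= 6) {
      ring <- sort(as.integer(names(path)))
      rings[[length(rings) + 1L]] <- ring
    }
  }
  unique(rings)
}

# RMS deviation of ring atoms from their best-fit plane (planarity test).
ring_planarity <- function(xyz) {
  centred <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(centred)
  sqrt(mean((centred %*% sv$v[, 3])^2))
}

# ---- annotation ------------------------------------------------------------

annotate_receptor <- function(atoms, adj) {
  rules <- typing_rules()
  n <- nrow(atoms)
  flags <- tibble::tibble(
    atom_id = seq_len(n),
    hb_donor = FALSE, hb_acceptor = FALSE, cation = FALSE,
    anion = FALSE, hydrophobe = FALSE, halogen = FALSE
  )
  rings <- list()
  rec <- which(!atoms$is_ligand)
  res_split <- split(rec, residue_key(atoms$chain[rec], atoms$resno[rec],
                                      atoms$resname[rec]))
  unknown <- character()
  for (key in names(res_split)) {
    ids <- res_split[[key]]
    resname <- atoms$resname[ids[1]]
    if (resname %in% .solvent_resnames) next
    if (length(ids) == 1 && toupper(atoms$element[ids]) %in% .ion_elements) next
    std <- resname %in% .standard_nt
    base_name <- if (std) sub("^[RD]", "", resname) else resname
    hit_any <- match(atoms$name[ids], rules$atom[rules$resname == "ANY"])
    any_rows <- rules[rules$resname == "ANY", ][hit_any[!is.na(hit_any)], ]
    if (nrow(any_rows)) {
      tgt <- ids[!is.na(hit_any)]
      for (col in c("hb_donor", "hb_acceptor", "cation", "anion",
                    "hydrophobe", "halogen"))
        flags[[col]][tgt] <- flags[[col]][tgt] | (any_rows[[col]] == 1)
    }
    if (std) {
      sub_rules <- rules[rules$resname == base_name, ]
      m <- match(atoms$name[ids], sub_rules$atom)
      tgt <- ids[!is.na(m)]
      rows <- sub_rules[m[!is.na(m)], ]
      for (col in c("hb_donor", "hb_acceptor", "cation", "anion",
                    "hydrophobe", "halogen"))
        flags[[col]][tgt] <- flags[[col]][tgt] | (rows[[col]] == 1)
      for (tag in c("ring6", "ring5")) {
        members <- tgt[grepl(tag, rows$ring, fixed = TRUE)]
        if (length(members) >= 5)
          rings[[length(rings) + 1L]] <- list(atoms = sort(members),
                                              residue = key)
      }
    } else {
      # modified / unknown polymer residue: element-based fallback perception
      unknown <- c(unknown, resname)
      fb <- perceive_generic(atoms, adj, ids)
      for (col in names(fb$flags))
        flags[[col]][ids] <- flags[[col]][ids] | fb$flags[[col]]
      for (r in fb$rings)
        rings[[length(rings) + 1L]] <- list(atoms = r, residue = key)
    }
  }
  if (length(unknown))
    warn(paste0("non-standard residue(s) ", paste(unique(unknown),
         collapse = ", "), ": element-based perception fallback applied"))
  list(flags = flags, rings = rings)
}

# Element/connectivity-based perception used for ligands and for modified
# residues lacking typing-table entries. `ids` are atom indices.
# Rules: donor = N/O with a bonded H; acceptor = N/O not positively charged;
# anion = phosphate or carboxylate oxygen; cation = N with four bonds or
# guanidinium N; hydrophobe = C/S with only C/H/S neighbours; halogen =
# Cl/Br/I bonded to carbon. Aromatic rings: planar 5/6-membered C/N/O/S
# cycles.
perceive_generic <- function(atoms, adj, ids) {
  el <- toupper(atoms$element)
  flags <- tibble::tibble(
    hb_donor = logical(length(ids)), hb_acceptor = logical(length(ids)),
    cation = logical(length(ids)), anion = logical(length(ids)),
    hydrophobe = logical(length(ids)), halogen = logical(length(ids))
  )
  nbrs <- function(i) adj[[i]] %||% integer()
  for (k in seq_along(ids)) {
    i <- ids[k]
    nb <- nbrs(i)
    nb_el <- el[nb]
    e <- el[i]
    if (e %in% c("N", "O")) {
      has_h <- any(nb_el == "H")
      if (has_h) flags$hb_donor[k] <- TRUE
      if (e == "N" && length(nb) >= 4) {
        flags$cation[k] <- TRUE
      } else if (e == "N" && length(nb) == 1 && el[nb[1]] == "C") {
        # guanidinium: C bonded to three N
        cn <- nbrs(nb[1])
        if (sum(el[cn] == "N") == 3) flags$cation[k] <- TRUE
      }
      if (e == "O") {
        heavy_nb <- nb[nb_el != "H"]
        if (length(heavy_nb) == 1 && el[heavy_nb] == "P" && !has_h) {
          flags$anion[k] <- TRUE
        } else if (length(heavy_nb) == 1 && el[heavy_nb] == "C" && !has_h) {
          cnb <- nbrs(heavy_nb)
          term_o <- sum(vapply(cnb, function(j) {
            el[j] == "O" && sum(el[nbrs(j)] != "H") == 1
          }, TRUE))
          if (term_o >= 2) flags$anion[k] <- TRUE
        }
      }
      if (!flags$cation[k] && !flags$anion[k]) flags$hb_acceptor[k] <- TRUE
      if (e == "N" && flags$cation[k]) flags$hb_acceptor[k] <- FALSE
    } else if (e %in% c("C", "S")) {
      if (length(nb) && all(nb_el %in% c("C", "H", "S")))
        flags$hydrophobe[k] <- TRUE
    } else if (e %in% c("CL", "BR", "I")) {
      if (any(nb_el == "C")) flags$halogen[k] <- TRUE
    }
  }
  bonds_all <- do.call(rbind, lapply(ids, function(i) {
    nb <- nbrs(i); if (length(nb)) cbind(i, nb) else NULL
  }))
  rings <- list()
  if (!is.null(bonds_all)) {
    cand <- find_rings(atoms, bonds_all, ids)
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    for (r in cand) {
      if (all(el[r] %in% c("C", "N", "O", "S")) &&
          ring_planarity(xyz[r, , drop = FALSE]) < 0.1)
        rings[[length(rings) + 1L]] <- sort(r)
    }
  }
  list(flags = flags, rings = rings)
}

# ---- complex construction --------------------------------------------------

new_complex <- function(atoms, conect = NULL) {
  stopifnot(all(c("name", "element", "chain", "resno", "resname",
                  "x", "y", "z", "is_ligand") %in% names(atoms)))
  atoms <- tibble::as_tibble(atoms)
  atoms$atom_id <- seq_len(nrow(atoms))
  atoms$is_backbone <- atoms$name %in% .backbone_names & !atoms$is_ligand
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) abort("non-finite coordinates in structure")
  bonds <- perceive_bonds(atoms, conect)
  adj <- bond_adjacency(bonds, nrow(atoms))
  rec <- annotate_receptor(atoms, adj)
  flags <- rec$flags
  rings <- lapply(rec$rings, function(r) c(r, side = "receptor"))
  lig_ids <- which(atoms$is_ligand)
  if (length(lig_ids)) {
    lig <- perceive_generic(atoms, adj, lig_ids)
    for (col in names(lig$flags))
      flags[[col]][lig_ids] <- flags[[col]][lig_ids] | lig$flags[[col]]
    for (r in lig$rings) {
      key <- residue_key(atoms$chain[r[1]], atoms$resno[r[1]],
                         atoms$resname[r[1]])
      rings[[length(rings) + 1L]] <- list(atoms = r, residue = key,
                                          side = "ligand")
    }
  }
  structure(
    list(atoms = atoms, flags = flags, rings = rings, bonds = bonds,
         adjacency = adj, reference_coords = xyz),
    class = "ttmd_complex"
  )
}

#' Load an annotated receptor-ligand complex from a PDB file
#'
#' Reads a prepared structure (receptor polymer + ligand as a distinct
#' residue, explicit hydrogens expected for hydrogen-bond geometry), assigns
#' pharmacophoric atom annotations and registers aromatic rings. Nucleotide
#' typing comes from a shipped rules table; ligand atoms and modified
#' residues are perceived from elements and connectivity. Bonds are taken
#' from CONECT records where present and otherwise perceived from covalent
#' radii. The file coordinates become the fingerprint reference snapshot.
#'
#' @param path path to a PDB file.
#' @param ligand residue name identifying the ligand (e.g. `"LIG"`), or a
#'   residue key as produced by [residue_key()], or `NULL` for a
#'   receptor-only structure (as used by [dry_run()]).
#' @return a `ttmd_complex` object: atom table (tibble), per-atom
#'   pharmacophoric flags, aromatic ring registry, bond list and reference
#'   coordinates.
#' @export
read_complex <- function(path, ligand) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  element <- toupper(trimws(at$elesy %||% ""))
  blank <- is.na(element) | element == ""
  element[blank] <- guess_element(at$elety[blank])
  atoms <- tibble::tibble(
    name = trimws(at$elety),
    element = element,
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    resno = at$resno,
    resname = trimws(at$resid),
    x = at$x, y = at$y, z = at$z
  )
  keys <- residue_key(atoms$chain, atoms$resno, atoms$resname)
  if (is.null(ligand)) {
    atoms$is_ligand <- FALSE
  } else {
    if (grepl(":", ligand, fixed = TRUE)) {
      atoms$is_ligand <- keys == ligand
    } else {
      atoms$is_ligand <- atoms$resname == ligand
    }
    if (!any(atoms$is_ligand))
      abort(paste0("ligand not found: no residue matches '", ligand, "'"))
    if (any(atoms$resname[atoms$is_ligand] %in% .standard_nt))
      abort("ligand selector matches receptor polymer residues")
  }
  conect <- read_conect(path, at$eleno)
  new_complex(atoms, conect)
}

# Parse CONECT records into index pairs; `serials` maps file atom serial
# numbers to row indices.
read_conect <- function(path, serials) {
  lines <- grep("^CONECT", readLines(path, warn = FALSE), value = TRUE)
  if (!length(lines)) return(NULL)
  pairs <- list()
  for (ln in lines) {
    f <- as.integer(strsplit(trimws(substring(ln, 7)), "\\s+")[[1]])
    f <- f[!is.na(f)]
    if (length(f) >= 2) {
      i <- match(f[1], serials)
      js <- match(f[-1], serials)
      ok <- !is.na(js) & !is.na(i)
      if (any(ok)) pairs[[length(pairs) + 1L]] <- cbind(i, js[ok])
    }
  }
  if (length(pairs)) do.call(rbind, pairs) else NULL
}

#' @export
print.ttmd_complex <- function(x, ...) {
  nl <- sum(x$atoms$is_ligand)
  res <- unique(residue_key(x$atoms$chain, x$atoms$resno, x$atoms$resname))
  cat("<ttmd_complex> ", nrow(x$atoms), " atoms (", nl, " ligand), ",
      length(res), " residues, ", length(x$rings), " aromatic rings\n",
      sep = "")
  invisible(x)
}

#' Select binding-site residues around the ligand
#'
#' Returns the receptor residues having at least one heavy atom within
#' `radius` of any ligand heavy atom in the reference snapshot, in
#' deterministic (chain, residue number) order. Water and monatomic ions are
#' excluded unless `include_ions = TRUE`.
#'
#' @param complex a `ttmd_complex`.
#' @param radius cutoff in Angstrom. The fingerprint-layout convention is
#'   10.5 (the docking-sphere radius); a smaller 5.0 default is used for the
#'   binding-site RMSD selection.
#' @param include_ions keep monatomic ions and water in the selection.
#' @return character vector of residue keys (class `ttmd_residues`).
#' @export
select_binding_site <- function(complex, radius = 10.5, include_ions = FALSE) {
  stopifnot(radius > 0)
  atoms <- complex$atoms
  xyz <- complex$reference_coords
  lig <- which(atoms$is_ligand & atoms$element != "H")
  rec <- which(!atoms$is_ligand & atoms$element != "H")
  if (!include_ions) {
    drop <- atoms$resname[rec] %in% .solvent_resnames |
      (toupper(atoms$element[rec]) %in% .ion_elements &
         !atoms$resname[rec] %in% .standard_nt)
    rec <- rec[!drop]
  }
  if (!length(lig)) abort("complex has no ligand heavy atoms")
  d <- cross_dist(xyz[rec, , drop = FALSE], xyz[lig, , drop = FALSE])
  near <- rec[apply(d, 1, min) <= radius]
  keys <- order_residue_keys(
    residue_key(atoms$chain[near], atoms$resno[near], atoms$resname[near]))
  if (!length(keys))
    abort("no residues within radius; check ligand selector and radius")
  structure(keys, class = "ttmd_residues")
}

# Atom indices belonging to a set of residue keys.
residue_atoms <- function(complex, keys) {
  all_keys <- residue_key(complex$atoms$chain, complex$atoms$resno,
                          complex$atoms$resname)
  which(all_keys %in% keys)
}
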