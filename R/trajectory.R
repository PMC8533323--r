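# Post-hoc trajectory analytics: per-residue protein-ligand interaction
# occupancy fractions by type (hydrogen bond, hydrophobic, ionic, water
# bridge) and least-squares superposed protein RMSD traces. Simulation
# itself is external; frames are input.

.WATER_RESNAMES <- c("HOH", "WAT", "TIP3", "TIP", "SPC", "SOL", "T3P")
.BOND_H_DIST <- 1.25   # A, H to its heavy atom
.BOND_HEAVY_DIST <- 1.8 # A, heavy-heavy covalent bond inference

#' Geometric interaction criteria
#'
#' Thresholds for contact detection. Hydrogen bond: donor-acceptor heavy
#' atom distance and donor-H-acceptor angle (vertex at H). Hydrophobic:
#' carbon-carbon distance between apolar carbons (carbons with no bonded
#' N/O). Ionic: distance between oppositely formally charged heavy atoms.
#' Water bridges reuse the hydrogen-bond criterion on both legs.
#'
#' @param hbond_dist max donor-acceptor distance, Angstrom (default 3.5).
#' @param hbond_angle min donor-H-acceptor angle, degrees (default 120).
#' @param hydrophobic_dist max apolar C-C distance, Angstrom (default 4.0).
#' @param ionic_dist max charged-group distance, Angstrom (default 3.7).
#' @return a list of class `ivs_criteria`.
#' @export
interaction_criteria <- function(hbond_dist = 3.5, hbond_angle = 120,
                                 hydrophobic_dist = 4.0, ionic_dist = 3.7) {
  structure(list(hbond_dist = hbond_dist, hbond_angle = hbond_angle,
                 hydrophobic_dist = hydrophobic_dist,
                 ionic_dist = ionic_dist),
            class = "ivs_criteria")
}

#' Construct a trajectory frame set
#'
#' @param xyz numeric matrix, one row per frame, `3 * n_atoms` columns in
#'   x1,y1,z1,x2,... order (the convention of crystallographic coordinate
#'   vectors), or a single length-`3n` vector for a one-frame set.
#' @param atoms data.frame with one row per atom: columns `elety` (atom
#'   name), `elem` (element symbol), `resno`, `resid` (residue name),
#'   `chain`, `role` (`"protein"`, `"ligand"` or `"water"`), and optional
#'   `charge` (formal charge, default 0).
#' @param time_step_ns optional time between frames in ns.
#' @return an object of class `ivs_trajectory`.
#' @export
trajectory_frames <- function(xyz, atoms, time_step_ns = NULL) {
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * nrow(atoms))
    .stop_ivs("ivs_trajectory_error",
              "xyz has %d columns but atoms table implies %d",
              ncol(xyz), 3 * nrow(atoms))
  if (nrow(xyz) < 1)
    .stop_ivs("ivs_trajectory_error", "need at least one frame")
  need <- c("elety", "elem", "resno", "resid", "role")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    .stop_ivs("ivs_trajectory_error", "atoms table missing column(s): %s",
              paste(missing_cols, collapse = ", "))
  if (!"chain" %in% names(atoms)) atoms$chain <- "A"
  if (!"charge" %in% names(atoms)) atoms$charge <- 0
  atoms$charge[is.na(atoms$charge)] <- 0
  structure(list(xyz = xyz, atoms = atoms, time_step_ns = time_step_ns),
            class = "ivs_trajectory")
}

#' @export
print.ivs_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frame(s), %d atoms (%d protein, %d ligand, %d water)\n",
              nrow(x$xyz), nrow(x$atoms), sum(x$atoms$role == "protein"),
              sum(x$atoms$role == "ligand"), sum(x$atoms$role == "water")))
  invisible(x)
}

#' Read a multi-model PDB as a trajectory
#'
#' Each MODEL block becomes one frame. Waters are recognized by residue
#' name; HETATM residues named in `ligand_resnames` (or any non-water
#' HETATM residue if `NULL`) become the ligand; everything else is
#' protein. Formal charges for ionic-contact detection are assigned to
#' the standard charged side-chain atoms (Asp/Glu carboxylates negative,
#' Lys/Arg amines positive); ligand charges can be supplied per atom
#' name.
#'
#' @param path multi-model PDB file.
#' @param ligand_resnames character vector of ligand residue names.
#' @param ligand_charges optional named numeric vector mapping ligand
#'   atom names to formal charges.
#' @param time_step_ns optional frame spacing in ns.
#' @return an `ivs_trajectory`.
#' @export
read_multimodel_pdb <- function(path, ligand_resnames = NULL,
                                ligand_charges = NULL, time_step_ns = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(!nzchar(trimws(elem))))
    elem <- substr(trimws(at$elety), 1, 1)
  elem <- trimws(elem)
  role <- rep("protein", nrow(at))
  role[at$resid %in% .WATER_RESNAMES] <- "water"
  if (is.null(ligand_resnames)) {
    role[at$type == "HETATM" & !(at$resid %in% .WATER_RESNAMES)] <- "ligand"
  } else {
    role[at$resid %in% ligand_resnames] <- "ligand"
  }
  charge <- numeric(nrow(at))
  neg <- (at$resid == "ASP" & at$elety %in% c("OD1", "OD2")) |
    (at$resid == "GLU" & at$elety %in% c("OE1", "OE2"))
  pos <- (at$resid == "LYS" & at$elety == "NZ") |
    (at$resid == "ARG" & at$elety %in% c("NH1", "NH2", "NE"))
  charge[neg & role == "protein"] <- -1
  charge[pos & role == "protein"] <- 1
  if (!is.null(ligand_charges)) {
    hit <- role == "ligand" & at$elety %in% names(ligand_charges)
    charge[hit] <- ligand_charges[at$elety[hit]]
  }
  atoms <- data.frame(
    elety = trimws(at$elety), elem = elem, resno = at$resno,
    resid = trimws(at$resid), chain = at$chain, role = role, charge = charge,
    stringsAsFactors = FALSE
  )
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  trajectory_frames(unclass(xyz), atoms, time_step_ns = time_step_ns)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj an `ivs_trajectory`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_multimodel_pdb <- function(traj, path) {
  a <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  for (f in seq_len(nrow(traj$xyz))) {
    bio3d::write.pdb(
      file = tf, xyz = traj$xyz[f, ],
      type = ifelse(a$role == "protein", "ATOM", "HETATM"),
      resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
      elety = a$elety, chain = a$chain, elesy = a$elem, end = FALSE
    )
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(readLines(tf), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# -- contact detection --------------------------------------------------------

# Geometry helpers on one frame's coordinate matrix (n x 3)
.frame_coords <- function(traj, frame) {
  matrix(traj$xyz[frame, ], ncol = 3, byrow = TRUE)
}

.pair_dist <- function(co, i, j) {
  sqrt(sum((co[i, ] - co[j, ])^2))
}

# indices of hydrogens attached to heavy atom i (same role, within bond dist)
.attached_h <- function(co, atoms, i, h_idx) {
  if (length(h_idx) == 0) return(integer(0))
  d2 <- rowSums((co[h_idx, , drop = FALSE] -
                   matrix(co[i, ], length(h_idx), 3, byrow = TRUE))^2)
  h_idx[d2 <= .BOND_H_DIST^2]
}

# TRUE when donor (heavy) i hydrogen-bonds acceptor j; vertex-at-H angle
.is_hbond <- function(co, i, j, h_on_i, crit, have_h) {
  d <- .pair_dist(co, i, j)
  if (d > crit$hbond_dist) return(FALSE)
  if (!have_h) return(TRUE)   # distance-only fallback
  if (length(h_on_i) == 0) return(FALSE)
  for (h in h_on_i) {
    v1 <- co[i, ] - co[h, ]
    v2 <- co[j, ] - co[h, ]
    cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    if (ang >= crit$hbond_angle) return(TRUE)
  }
  FALSE
}

#' Detect protein-ligand contacts in one frame
#'
#' Applies the geometric criteria to one frame and returns the set of
#' (residue, interaction type) contacts between the ligand and the
#' protein. Water bridges report the bridged protein residue. When the
#' structure carries no hydrogen atoms the hydrogen-bond angle test is
#' skipped (distance-only) with a warning.
#'
#' @param traj an `ivs_trajectory`.
#' @param frame frame index (default 1).
#' @param criteria an [interaction_criteria()] object.
#' @return a data.frame with columns `resno`, `resid`, `type` (one of
#'   `"hydrogen_bond"`, `"hydrophobic"`, `"ionic"`, `"water_bridge"`).
#' @export
detect_interactions <- function(traj, frame = 1,
                                criteria = interaction_criteria()) {
  .detect_interactions_impl(traj, frame, criteria, warn_no_h = TRUE)
}

.detect_interactions_impl <- function(traj, frame, crit, warn_no_h) {
  a <- traj$atoms
  co <- .frame_coords(traj, frame)
  is_h <- toupper(a$elem) == "H"
  have_h <- any(is_h)
  if (!have_h && warn_no_h)
    warning("no hydrogen atoms present; hydrogen bonds use the distance-only criterion")

  prot <- which(a$role == "protein" & !is_h)
  lig <- which(a$role == "ligand" & !is_h)
  wat <- which(a$role == "water" & !is_h)
  h_all <- which(is_h)

  polar_elem <- toupper(a$elem) %in% c("N", "O")
  # apolar carbon: C with no bonded N/O heavy atom
  is_c <- toupper(a$elem) == "C"
  apolar <- logical(nrow(a))
  heavy_no <- which(polar_elem & !is_h)
  for (i in which(is_c)) {
    if (length(heavy_no)) {
      d2 <- rowSums((co[heavy_no, , drop = FALSE] -
                       matrix(co[i, ], length(heavy_no), 3, byrow = TRUE))^2)
      apolar[i] <- !any(d2 <= .BOND_HEAVY_DIST^2)
    } else apolar[i] <- TRUE
  }

  h_near <- function(i) .attached_h(co, a, i, h_all)
  donors <- function(idx) idx[polar_elem[idx] &
                                (!have_h | vapply(idx, function(i)
                                  length(h_near(i)) > 0, TRUE))]
  acceptors <- function(idx) idx[polar_elem[idx]]

  contacts <- list()
  add <- function(resno, resid, type) {
    contacts[[length(contacts) + 1]] <<- data.frame(
      resno = resno, resid = resid, type = type, stringsAsFactors = FALSE)
  }

  hb_pair <- function(i, j) {
    # i-j hydrogen bonded in either donor/acceptor direction
    (polar_elem[i] && polar_elem[j]) &&
      (.is_hbond(co, i, j, h_near(i), crit, have_h) ||
         .is_hbond(co, j, i, h_near(j), crit, have_h))
  }

  for (p in prot) {
    for (l in lig) {
      d <- .pair_dist(co, p, l)
      if (d <= crit$hbond_dist && polar_elem[p] && polar_elem[l] &&
          hb_pair(p, l))
        add(a$resno[p], a$resid[p], "hydrogen_bond")
      if (d <= crit$hydrophobic_dist && apolar[p] && apolar[l])
        add(a$resno[p], a$resid[p], "hydrophobic")
      if (d <= crit$ionic_dist && a$charge[p] * a$charge[l] < 0)
        add(a$resno[p], a$resid[p], "ionic")
    }
  }
  # water bridge: one water oxygen H-bonded to ligand and to a residue
  for (w in wat) {
    if (!polar_elem[w]) next
    lig_ok <- any(vapply(lig[polar_elem[lig]], function(l) hb_pair(w, l), TRUE))
    if (!lig_ok) next
    for (p in prot[polar_elem[prot]]) {
      if (hb_pair(w, p)) add(a$resno[p], a$resid[p], "water_bridge")
    }
  }
  if (length(contacts) == 0)
    return(data.frame(resno = integer(0), resid = character(0),
                      type = character(0), stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, contacts))
  rownames(out) <- NULL
  out
}

#' Interaction occupancy fractions over a trajectory
#'
#' For every (residue, interaction type) contact observed in any frame,
#' the fraction of frames in which it is present -- the stacked-bar
#' quantity of a simulation interactions diagram. Fractions for one
#' residue may sum above 1 across types (simultaneous contact types) and
#' are never clamped.
#'
#' @param traj an `ivs_trajectory`.
#' @param criteria an [interaction_criteria()] object.
#' @return a data.frame of class `ivs_occupancy` with columns `resno`,
#'   `resid`, `type`, `fraction`.
#' @export
occupancy_fractions <- function(traj, criteria = interaction_criteria()) {
  n <- nrow(traj$xyz)
  warn_once <- TRUE
  tallies <- new.env(parent = emptyenv())
  meta <- new.env(parent = emptyenv())
  for (f in seq_len(n)) {
    cts <- if (warn_once)
      .detect_interactions_impl(traj, f, criteria, warn_no_h = TRUE)
    else
      .detect_interactions_impl(traj, f, criteria, warn_no_h = FALSE)
    warn_once <- FALSE
    if (nrow(cts) == 0) next
    keys <- paste(cts$resno, cts$type, sep = "\r")
    for (k in seq_along(keys)) {
      key <- keys[k]
      tallies[[key]] <- (if (is.null(tallies[[key]])) 0 else tallies[[key]]) + 1
      meta[[key]] <- c(cts$resno[k], cts$resid[k], cts$type[k])
    }
  }
  keys <- ls(tallies)
  if (length(keys) == 0) {
    out <- data.frame(resno = integer(0), resid = character(0),
                      type = character(0), fraction = numeric(0),
                      stringsAsFactors = FALSE)
  } else {
    m <- t(vapply(keys, function(k) meta[[k]], character(3)))
    out <- data.frame(
      resno = as.integer(m[, 1]), resid = m[, 2], type = m[, 3],
      fraction = vapply(keys, function(k) tallies[[k]], 0) / n,
      stringsAsFactors = FALSE, row.names = NULL
    )
    out <- out[order(out$resno, out$type), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("ivs_occupancy", "data.frame")
  out
}

#' Superposed protein RMSD trace
#'
#' RMSD of a selection (default: protein C-alpha atoms) for every frame
#' against a reference frame, after optimal least-squares superposition
#' (rotation + translation) of each frame onto the reference.
#'
#' @param traj an `ivs_trajectory`.
#' @param selection integer atom indices to superpose and measure;
#'   default protein C-alpha atoms (all protein atoms if no CA present).
#' @param reference reference frame index (default 1; its RMSD is 0).
#' @return numeric vector of per-frame RMSD values in Angstrom.
#' @export
protein_rmsd <- function(traj, selection = NULL, reference = 1) {
  a <- traj$atoms
  if (is.null(selection)) {
    selection <- which(a$role == "protein" & a$elety == "CA")
    if (length(selection) == 0) selection <- which(a$role == "protein")
  }
  if (length(selection) < 3)
    .stop_ivs("ivs_superposition_error",
              "need at least 3 atoms to superpose (got %d)", length(selection))
  inds <- bio3d::atom2xyz(selection)
  ref <- traj$xyz[reference, ]
  # small selections can make bio3d's eigendecomposition emit sqrt(NaN)
  # warnings for numerically negative eigenvalues; the fit itself is fine
  out <- suppressWarnings(
    as.numeric(bio3d::rmsd(ref, traj$xyz, a.inds = inds, b.inds = inds,
                           fit = TRUE))
  )
  if (any(!is.finite(out)))
    .stop_ivs("ivs_superposition_error",
              "superposition failed; selection may be degenerate (e.g. collinear atoms)")
  out
}

#' Write occupancy and RMSD tables
#'
#' @param occupancy an [occupancy_fractions()] result.
#' @param rmsd a [protein_rmsd()] trace.
#' @param path output TSV path.
#' @param time_step_ns optional frame spacing for the `time_ns` column.
#' @return invisibly, the data.frame written.
#' @name md_tsv
NULL

#' @rdname md_tsv
#' @export
write_occupancy_tsv <- function(occupancy, path) {
  utils::write.table(occupancy, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(occupancy)
}

#' @rdname md_tsv
#' @export
write_rmsd_tsv <- function(rmsd, path, time_step_ns = NULL) {
  df <- data.frame(frame = seq_along(rmsd))
  df$time_ns <- if (is.null(time_step_ns)) NA_real_
    else (df$frame - 1) * time_step_ns
  df$rmsd_A <- rmsd
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
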