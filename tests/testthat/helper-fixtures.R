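# Fixtures built in code for the test suite.

# A ~56-molecule candidate library with graded molecular weights and
# donor/acceptor counts: esters, amides, ethers and polyol chains.
toy_candidate_library <- function() {
  smi <- character(0)
  for (a in 1:7) for (b in 1:4) {
    smi <- c(smi, paste0(strrep("C", a), "OC(=O)", strrep("C", b)))        # esters
    smi <- c(smi, paste0(strrep("C", a), "NC(=O)", strrep("C", b), "O"))   # amide-ols
  }
  names(smi) <- sprintf("cand%03d", seq_along(smi))
  smi
}

# Registry rows derived from the shipped worked-example tables: unique
# structures across the two compounds' rankings.
tables_registry <- function() {
  tab <- gentiana_tables()
  key <- paste(tab$pdb_id, tab$conformer)
  u <- tab[!duplicated(key), c("pdb_id", "conformer", "target_name")]
  u$site_mode <- "from_center"
  u$center_x <- 0; u$center_y <- 0; u$center_z <- 0
  rownames(u) <- NULL
  u
}

write_tables_registry <- function(path = tempfile(fileext = ".tsv")) {
  utils::write.table(tables_registry(), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# Per-compound structure-level score rows of the worked-example tables,
# recast as the normalize_scores() output schema.
tables_as_scores <- function(compound) {
  tab <- gentiana_tables(compound)
  data.frame(
    compound_id = compound, pdb_id = tab$pdb_id, conformer = tab$conformer,
    target_name = tab$target_name, v0 = tab$v0, vr = tab$vr,
    v = tab$v0 / tab$vr, valid = TRUE, stringsAsFactors = FALSE
  )
}

# One-frame trajectory whose four interaction types sit at a configurable
# offset from their distance thresholds (for boundary straddling).
boundary_frame <- function(offset, criteria = interaction_criteria()) {
  atoms <- data.frame(
    elety = c("OG", "HG", "CD1", "OD1", "O",
              "OW", "HW1", "HW2",
              "O1", "C1", "N1", "O2"),
    elem = c("O", "H", "C", "O", "O", "O", "H", "H", "O", "C", "N", "O"),
    resno = c(1, 1, 2, 3, 4, 101, 101, 101, 201, 201, 201, 201),
    resid = c("SER", "SER", "LEU", "ASP", "GLY", rep("HOH", 3),
              rep("LIG", 4)),
    chain = c(rep("A", 5), rep("W", 3), rep("L", 4)),
    role = c(rep("protein", 5), rep("water", 3), rep("ligand", 4)),
    charge = c(0, 0, 0, -1, 0, 0, 0, 0, 0, 0, 1, 0),
    stringsAsFactors = FALSE
  )
  co <- rbind(
    c(0, 0, 0), c(0.96, 0, 0),                             # Ser OG-HG donor
    c(20, 0, 0),                                           # Leu apolar C
    c(40, 0, 0),                                           # Asp carboxylate O
    c(0, 20, 0),                                           # backbone O (bridge site)
    c(0, 22.8, 0), c(0, 21.84, 0), c(0, 23.76, 0),         # water
    c(criteria$hbond_dist + offset, 0, 0),                 # ligand acceptor
    c(20 + criteria$hydrophobic_dist + offset, 0, 0),      # ligand apolar C
    c(40 + criteria$ionic_dist + offset, 0, 0),            # ligand cation
    c(0, 22.8 + criteria$hbond_dist + offset, 0)           # bridged ligand O
  )
  trajectory_frames(as.numeric(t(co)), atoms)
}

# Rotation matrix about an arbitrary axis (for rigid-motion tests).
rigid_rotation <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -axis[3], axis[2]),
             c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

apply_rigid <- function(frame_vec, R, t) {
  co <- matrix(frame_vec, ncol = 3, byrow = TRUE)
  as.numeric(t(co %*% t(R) + matrix(t, nrow(co), 3, byrow = TRUE)))
}
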