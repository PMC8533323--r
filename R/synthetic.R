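# Synthetic inputs for every pipeline stage: score campaigns with planted
# targets (to exercise normalization, filtering and ranking end to end)
# and toy complex trajectories with known per-frame interaction geometry
# (to exercise the occupancy and RMSD analytics). Everything is
# deterministic in the spec's seed.

# draw n normals, rejection-resampling any non-negative value so that the
# binding-affinity sign convention holds by construction
.rnorm_neg <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x >= 0)) {
    bad <- x >= 0
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Specification of a synthetic screening campaign
#'
#' Describes the statistical model of a mock inverse-screening campaign:
#' every panel structure gets a "stickiness" `mu_s ~ Normal(base_mean,
#' base_sd)` (kcal/mol, resampled negative); decoy best-pose affinities
#' are `Normal(mu_s, noise_sd)` and query affinities `Normal(mu_s,
#' noise_sd) + shift`, where the shift (negative = stronger binding) is
#' nonzero only for planted (compound, target) pairs. Structures are
#' assigned to target names multinomially after every target is
#' guaranteed one structure, so some targets own several conformers.
#'
#' @param n_compounds number of query compounds (default 2).
#' @param n_structures panel size (default 100).
#' @param n_targets distinct target names (default `n_structures / 5`,
#'   at least 1).
#' @param decoy_count decoys per query (default 10).
#' @param base_mean,base_sd structure stickiness distribution, kcal/mol
#'   (defaults -7.0, 1.0).
#' @param noise_sd per-docking noise, kcal/mol (default 0.3).
#' @param planted optional data.frame with columns `compound_id`,
#'   `target_name`, `shift` (kcal/mol).
#' @param seed integer seed; all generation is deterministic in it.
#' @return a validated list of class `ivs_campaign_spec`.
#' @export
campaign_spec <- function(n_compounds = 2, n_structures = 100,
                          n_targets = NULL, decoy_count = 10,
                          base_mean = -7.0, base_sd = 1.0, noise_sd = 0.3,
                          planted = NULL, seed = 1) {
  if (is.null(n_targets)) n_targets <- max(1L, round(n_structures / 5))
  if (n_structures < n_targets)
    .stop_ivs("ivs_spec_error", "n_structures (%d) must be >= n_targets (%d)",
              n_structures, n_targets)
  if (base_sd <= 0 || noise_sd <= 0)
    .stop_ivs("ivs_spec_error", "standard deviations must be positive")
  if (base_mean >= 0)
    .stop_ivs("ivs_spec_error", "base_mean must be negative (binding affinity)")
  if (!is.null(planted)) {
    need <- c("compound_id", "target_name", "shift")
    if (!all(need %in% names(planted)))
      .stop_ivs("ivs_spec_error", "planted needs columns %s",
                paste(need, collapse = ", "))
  }
  structure(list(
    n_compounds = as.integer(n_compounds),
    n_structures = as.integer(n_structures),
    n_targets = as.integer(n_targets),
    decoy_count = as.integer(decoy_count),
    base_mean = base_mean, base_sd = base_sd, noise_sd = noise_sd,
    planted = planted, seed = as.integer(seed)
  ), class = "ivs_campaign_spec")
}

#' Generate a synthetic screening campaign
#'
#' Produces the three tables the real pipeline ingests: a panel registry,
#' a query score table and a decoy score table, drawn from the model in
#' [campaign_spec()]. Identical specs (same seed) give identical output.
#'
#' @param spec an `ivs_campaign_spec`.
#' @return a list with elements `panel` (registry data.frame),
#'   `query_scores`, `decoy_scores` (data.frames with `compound_id`,
#'   (`query_id`,) `pdb_id`, `conformer`, `v0`) and `spec`.
#' @export
generate_campaign <- function(spec) {
  stopifnot(inherits(spec, "ivs_campaign_spec"))
  .with_local_seed(spec$seed, {
    ns <- spec$n_structures
    nt <- spec$n_targets
    pdb_ids <- sprintf("%04x", 0x1000 + seq_len(ns))
    target_names <- sprintf("target_%03d", seq_len(nt))
    assign_t <- c(seq_len(nt),
                  if (ns > nt) sample.int(nt, ns - nt, replace = TRUE))
    panel <- data.frame(
      pdb_id = pdb_ids, conformer = "",
      target_name = target_names[assign_t],
      site_mode = "from_center",
      center_x = round(stats::runif(ns, 0, 50), 3),
      center_y = round(stats::runif(ns, 0, 50), 3),
      center_z = round(stats::runif(ns, 0, 50), 3),
      site_points = 30L,
      stringsAsFactors = FALSE
    )
    class(panel) <- c("ivs_panel", "data.frame")

    mu <- .rnorm_neg(ns, spec$base_mean, spec$base_sd)
    cmpd_ids <- sprintf("cmpd%02d", seq_len(spec$n_compounds))

    # planted shift per (compound, structure)
    shift <- matrix(0, nrow = spec$n_compounds, ncol = ns)
    if (!is.null(spec$planted)) {
      for (r in seq_len(nrow(spec$planted))) {
        ci <- match(spec$planted$compound_id[r], cmpd_ids)
        ti <- .norm_name(panel$target_name) ==
          .norm_name(spec$planted$target_name[r])
        if (!is.na(ci) && any(ti))
          shift[ci, ti] <- shift[ci, ti] + spec$planted$shift[r]
      }
    }

    qs <- do.call(rbind, lapply(seq_along(cmpd_ids), function(ci) {
      v0 <- .rnorm_neg(ns, mu + shift[ci, ], spec$noise_sd)
      data.frame(compound_id = cmpd_ids[ci], pdb_id = pdb_ids,
                 conformer = "", v0 = v0, stringsAsFactors = FALSE)
    }))
    ds <- do.call(rbind, lapply(seq_along(cmpd_ids), function(ci) {
      do.call(rbind, lapply(seq_len(spec$decoy_count), function(di) {
        v0 <- .rnorm_neg(ns, mu, spec$noise_sd)
        data.frame(
          compound_id = sprintf("%s_decoy%02d", cmpd_ids[ci], di),
          query_id = cmpd_ids[ci], pdb_id = pdb_ids, conformer = "",
          v0 = v0, stringsAsFactors = FALSE
        )
      }))
    }))
    rownames(qs) <- rownames(ds) <- NULL
    list(panel = panel, query_scores = qs, decoy_scores = ds, spec = spec)
  })
}

#' Write a synthetic campaign to disk
#'
#' Emits the registry and score tables in the same TSV dialects the real
#' pipeline ingests ([load_panel()], [read_score_table()]).
#'
#' @param campaign a [generate_campaign()] result.
#' @param dir output directory (created if needed).
#' @return a list of the three file paths (`panel`, `query_scores`,
#'   `decoy_scores`).
#' @export
write_campaign <- function(campaign, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    panel = file.path(dir, "panel_registry.tsv"),
    query_scores = file.path(dir, "query_scores.tsv"),
    decoy_scores = file.path(dir, "decoy_scores.tsv")
  )
  utils::write.table(campaign$panel, paths$panel, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  qs <- campaign$query_scores
  names(qs)[names(qs) == "v0"] <- "affinity"
  utils::write.table(qs, paths$query_scores, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ds <- campaign$decoy_scores
  names(ds)[names(ds) == "v0"] <- "affinity"
  utils::write.table(ds, paths$decoy_scores, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}

# -- toy complex trajectories -------------------------------------------------

# engaged/disengaged ligand-atom positions per interaction type; the
# pocket is three residues (Ser donor site, Leu hydrophobic site, Asp
# charged site) plus a backbone oxygen bridged by one water.
.TOY_GEOMETRY <- list(
  hydrogen_bond = list(atom = "O1", elem = "O", charge = 0,
                       engaged = c(4.0, 0, 0)),
  hydrophobic = list(atom = "C1", elem = "C", charge = 0,
                     engaged = c(24.5, 0, 0)),
  ionic = list(atom = "N1", elem = "N", charge = 1,
               engaged = c(44.5, 0, 0)),
  water_bridge = list(atom = "O2", elem = "O", charge = 0,
                      engaged = c(0, 25.6, 0))
)
.TOY_DISENGAGE <- c(0, 0, 30)

#' Generate a toy protein-ligand complex trajectory
#'
#' Builds a minimal complex -- a three-residue pocket (a serine hydroxyl
#' donor, a leucine hydrophobic carbon, an aspartate carboxylate oxygen,
#' plus a backbone oxygen bridged by one explicit water) and a 5-atom
#' ligand -- in which each requested interaction type is geometrically
#' satisfied in exactly `round(p * n_frames)` frames (a seeded random
#' subset) and cleanly broken otherwise. Gaussian jitter may be applied
#' to the protein atoms to give the RMSD trace structure.
#'
#' @param n_frames number of frames (default 100).
#' @param occupancy named numeric vector of planted occupancies in
#'   `[0, 1]`; names among `"hydrogen_bond"`, `"hydrophobic"`, `"ionic"`,
#'   `"water_bridge"` (default `c(hydrogen_bond = 0.5)`).
#' @param jitter_sd Gaussian jitter applied to protein atom coordinates,
#'   Angstrom (default 0).
#' @param seed integer seed.
#' @param time_step_ns frame spacing metadata (default 0.1).
#' @return an `ivs_trajectory`.
#' @export
generate_complex_trajectory <- function(n_frames = 100,
                                        occupancy = c(hydrogen_bond = 0.5),
                                        jitter_sd = 0, seed = 1,
                                        time_step_ns = 0.1) {
  if (any(occupancy < 0 | occupancy > 1))
    .stop_ivs("ivs_spec_error", "occupancies must lie in [0, 1]")
  bad <- setdiff(names(occupancy), names(.TOY_GEOMETRY))
  if (length(bad))
    .stop_ivs("ivs_spec_error", "unknown interaction type(s): %s",
              paste(bad, collapse = ", "))

  atoms <- data.frame(
    elety = c("CA", "OG", "HG",            # SER 1
              "CA", "CD1",                 # LEU 2
              "CA", "OD1",                 # ASP 3
              "O",                         # backbone O, SER 1 bridge site
              "O", "H1", "H2",             # water
              "O1", "C1", "N1", "O2", "C2" # ligand
    ),
    elem = c("C", "O", "H", "C", "C", "C", "O", "O",
             "O", "H", "H", "O", "C", "N", "O", "C"),
    resno = c(1, 1, 1, 2, 2, 3, 3, 1, 101, 101, 101,
              201, 201, 201, 201, 201),
    resid = c(rep("SER", 3), rep("LEU", 2), rep("ASP", 2), "SER",
              rep("HOH", 3), rep("LIG", 5)),
    chain = c(rep("A", 8), rep("W", 3), rep("L", 5)),
    role = c(rep("protein", 8), rep("water", 3), rep("ligand", 5)),
    charge = c(0, 0, 0, 0, 0, 0, -1, 0, 0, 0, 0,
               0, 0, 1, 0, 0),
    stringsAsFactors = FALSE
  )
  # CA positions are deliberately non-colinear so rigid-body superposition
  # of the C-alpha selection is well conditioned
  base <- rbind(
    c(0, 0, 0), c(1.2, 0, 0), c(2.16, 0, 0),
    c(20, 6, 0), c(21.5, 0, 0),
    c(40, 0, 6), c(41.5, 0, 0),
    c(0, 20, 0),
    c(0, 22.8, 0), c(0, 21.84, 0), c(0, 23.76, 0),
    .TOY_GEOMETRY$hydrogen_bond$engaged,
    .TOY_GEOMETRY$hydrophobic$engaged,
    .TOY_GEOMETRY$ionic$engaged,
    .TOY_GEOMETRY$water_bridge$engaged,
    c(80, 0, 0)
  )
  lig_atom_row <- vapply(names(.TOY_GEOMETRY), function(t)
    which(atoms$elety == .TOY_GEOMETRY[[t]]$atom & atoms$role == "ligand"),
    0L)

  .with_local_seed(seed, {
    engaged <- lapply(names(.TOY_GEOMETRY), function(t) {
      p <- if (t %in% names(occupancy)) occupancy[[t]] else 0
      k <- round(p * n_frames)
      sort(sample.int(n_frames, k))
    })
    names(engaged) <- names(.TOY_GEOMETRY)
    xyz <- matrix(NA_real_, nrow = n_frames, ncol = 3 * nrow(atoms))
    prot <- which(atoms$role == "protein")
    for (f in seq_len(n_frames)) {
      co <- base
      for (t in names(.TOY_GEOMETRY)) {
        if (!(f %in% engaged[[t]]))
          co[lig_atom_row[[t]], ] <- co[lig_atom_row[[t]], ] + .TOY_DISENGAGE
      }
      if (jitter_sd > 0)
        co[prot, ] <- co[prot, ] +
          stats::rnorm(3 * length(prot), 0, jitter_sd)
      xyz[f, ] <- as.numeric(t(co))
    }
    trajectory_frames(xyz, atoms, time_step_ns = time_step_ns)
  })
}
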