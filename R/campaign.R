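# End-to-end campaign orchestration: config, the three-phase screening
# run (scores -> normalization -> analysis), and the MD report. The thin
# command-line wrapper in inst/cli/ivs.R calls these functions.

#' Campaign configuration
#'
#' Builds and validates the configuration of a screening run, either from
#' a named list or from a YAML/JSON file. Required fields: `panel`,
#' `query_scores`, `decoy_scores` (file paths) and `out_dir`. Optional:
#' `threshold` (default 0.9), `strict` (default TRUE: keep V strictly
#' above the threshold), `top_k` (default 10), `decoy_count` (recorded
#' metadata), `seed`.
#'
#' @param x a named list, or the path of a YAML or JSON config file.
#' @return a validated list of class `ivs_config`.
#' @export
campaign_config <- function(x) {
  if (is.character(x) && length(x) == 1) {
    x <- if (grepl("\\.json$", x, ignore.case = TRUE))
      jsonlite::read_json(x, simplifyVector = TRUE)
    else yaml::read_yaml(x)
  }
  if (!is.list(x))
    .stop_ivs("ivs_config_error", "config must be a list or a config file path")
  need <- c("panel", "query_scores", "decoy_scores", "out_dir")
  missing_fields <- setdiff(need, names(x))
  if (length(missing_fields))
    .stop_ivs("ivs_config_error", "config missing field(s): %s",
              paste(missing_fields, collapse = ", "))
  defaults <- list(threshold = 0.9, strict = TRUE, top_k = 10,
                   decoy_count = NA_integer_, seed = NA_integer_)
  for (f in names(defaults)) if (is.null(x[[f]])) x[[f]] <- defaults[[f]]
  if (x$threshold <= 0)
    .stop_ivs("ivs_config_error", "threshold must be positive")
  if (x$top_k < 1)
    .stop_ivs("ivs_config_error", "top_k must be >= 1")
  for (f in c("panel", "query_scores", "decoy_scores"))
    if (!file.exists(x[[f]]))
      .stop_ivs("ivs_config_error", "config path '%s' does not exist: %s",
                f, x[[f]])
  structure(x, class = c("ivs_config", "list"))
}

#' Run an inverse virtual screening campaign
#'
#' The three analysis phases on precomputed docking scores: (1) ingest
#' the per-(compound, structure) best-pose affinities, (2) normalize them
#' against the decoy averages (V = V0/VR), (3) filter by the V threshold,
#' collapse to non-redundant target rankings with occurrence percentages,
#' and intersect the rankings across compounds. Missing (compound,
#' structure) score pairs are reported as gaps in the manifest and the
#' run continues.
#'
#' Outputs per compound: `scores_<id>.tsv` (normalized records),
#' `ranking_<id>.tsv`, `occurrences_<id>.tsv`; across compounds:
#' `intersection.tsv` (when >= 2 compounds); plus `manifest.json`
#' recording version, parameters, seed, counts and gaps. Outputs are a
#' pure function of the inputs and config, so a rerun is byte-identical.
#'
#' @param config an [campaign_config()] (or anything it accepts).
#' @return invisibly, a list with the rankings, the intersection table
#'   and the manifest.
#' @export
run_ivs <- function(config) {
  cfg <- campaign_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- load_panel(cfg$panel)
  qs <- read_score_table(cfg$query_scores)
  ds <- read_score_table(cfg$decoy_scores)

  # structures in the registry with no query score: campaign gaps
  skey <- function(p, c) paste(p, ifelse(is.na(c) | !nzchar(c), "", c),
                               sep = "\r")
  if (!"conformer" %in% names(qs)) qs$conformer <- ""
  compounds <- unique(qs$compound_id)
  gaps <- list()
  for (cid in compounds) {
    have <- skey(qs$pdb_id[qs$compound_id == cid],
                 qs$conformer[qs$compound_id == cid])
    missing_structs <- panel$pdb_id[!skey(panel$pdb_id, panel$conformer)
                                    %in% have]
    if (length(missing_structs))
      gaps[[cid]] <- missing_structs
  }
  if (length(gaps))
    warning(sprintf("%d compound(s) have score gaps; see manifest", length(gaps)))

  norm <- normalize_scores(qs, ds, panel = panel)
  rankings <- list()
  counts <- list()
  for (cid in compounds) {
    sub <- norm[norm$compound_id == cid, , drop = FALSE]
    filtered <- filter_by_threshold(sub, cfg$threshold, strict = cfg$strict)
    ranking <- collapse_non_redundant(filtered, top_k = cfg$top_k,
                                      threshold = cfg$threshold)
    rankings[[cid]] <- ranking
    counts[[cid]] <- list(scored = nrow(sub), filtered = nrow(filtered),
                          ranked = nrow(ranking))
    utils::write.table(sub, file.path(cfg$out_dir,
                                      sprintf("scores_%s.tsv", cid)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_ranking_tsv(ranking, file.path(cfg$out_dir,
                                         sprintf("ranking_%s.tsv", cid)))
    occ <- suppressWarnings(occurrence_percentages(filtered))
    occ$pct <- round(occ$pct, 1)
    utils::write.table(occ, file.path(cfg$out_dir,
                                      sprintf("occurrences_%s.tsv", cid)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  intersection <- NULL
  if (length(rankings) >= 2) {
    intersection <- intersect_rankings(rankings)
    utils::write.table(intersection,
                       file.path(cfg$out_dir, "intersection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    tool = "ivscreen",
    version = as.character(utils::packageVersion("ivscreen")),
    parameters = list(threshold = cfg$threshold, strict = cfg$strict,
                      top_k = cfg$top_k, decoy_count = cfg$decoy_count,
                      seed = cfg$seed),
    inputs = list(panel = cfg$panel, query_scores = cfg$query_scores,
                  decoy_scores = cfg$decoy_scores),
    panel_structures = nrow(panel),
    panel_targets = length(redundancy_groups(panel)),
    compounds = compounds,
    counts = counts,
    gaps = gaps
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(rankings = rankings, intersection = intersection,
                 manifest = manifest))
}

#' Run the MD interaction report
#'
#' Reads a complex trajectory (multi-model PDB, or an in-memory
#' trajectory object), computes the per-residue interaction occupancy
#' fractions and the superposed protein RMSD trace, and writes
#' `occupancy.tsv`, `rmsd.tsv` and `md_manifest.json` to the output
#' directory. The residue with the highest occupancy per interaction
#' type is reported in a message.
#'
#' @param trajectory path to a multi-model PDB, or an `ivs_trajectory`.
#' @param out_dir output directory.
#' @param criteria an [interaction_criteria()] object; defaults recorded
#'   in the manifest.
#' @param ligand_resnames passed to [read_multimodel_pdb()] when reading
#'   from file.
#' @param time_step_ns frame spacing in ns for the RMSD table.
#' @return invisibly, a list with the occupancy table and RMSD trace.
#' @export
run_md_report <- function(trajectory, out_dir,
                          criteria = interaction_criteria(),
                          ligand_resnames = NULL, time_step_ns = NULL) {
  traj <- if (inherits(trajectory, "ivs_trajectory")) trajectory
  else {
    if (!file.exists(trajectory))
      .stop_ivs("ivs_io_error", "trajectory not readable: %s", trajectory)
    read_multimodel_pdb(trajectory, ligand_resnames = ligand_resnames,
                        time_step_ns = time_step_ns)
  }
  if (is.null(time_step_ns)) time_step_ns <- traj$time_step_ns
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  occ <- occupancy_fractions(traj, criteria)
  tr <- protein_rmsd(traj)
  write_occupancy_tsv(occ, file.path(out_dir, "occupancy.tsv"))
  write_rmsd_tsv(tr, file.path(out_dir, "rmsd.tsv"),
                 time_step_ns = time_step_ns)
  for (tp in unique(occ$type)) {
    sub <- occ[occ$type == tp, ]
    best <- sub[which.max(sub$fraction), ]
    message(sprintf("%s: max occupancy %.2f at %s%d",
                    tp, best$fraction, best$resid, best$resno))
  }
  manifest <- list(
    tool = "ivscreen",
    version = as.character(utils::packageVersion("ivscreen")),
    criteria = unclass(criteria),
    n_frames = nrow(traj$xyz),
    n_atoms = nrow(traj$atoms),
    time_step_ns = time_step_ns
  )
  jsonlite::write_json(manifest, file.path(out_dir, "md_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(occupancy = occ, rmsd = tr))
}
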