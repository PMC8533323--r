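# Panel registry, binding-site definitions and docking-box construction.

.MIN_SITE_POINTS <- 15

#' Binding-site definition
#'
#' A binding site is defined either by the coordinates of a co-crystallized
#' ligand (`site_from_ligand()`) or by a precomputed pocket center
#' (`site_from_center()`). A cavity-detection score may report the number
#' of site points supporting the pocket; sites with fewer than 15 points
#' are considered unusable, mirroring the common surface-mapping minimum.
#'
#' @param coords numeric matrix (n x 3) of ligand atom coordinates in
#'   Angstrom.
#' @param center numeric length-3 pocket center in Angstrom.
#' @param site_points optional count of site points supporting the pocket.
#' @return an object of class `ivs_site`.
#' @export
site_from_ligand <- function(coords, site_points = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1 || ncol(coords) != 3 || !is.numeric(coords))
    .stop_ivs("ivs_site_error", "from_ligand site needs an n x 3 coordinate matrix")
  structure(list(mode = "from_ligand", ligand_coords = coords,
                 center = NULL, site_points = site_points),
            class = "ivs_site")
}

#' @rdname site_from_ligand
#' @export
site_from_center <- function(center, site_points = NULL) {
  center <- as.numeric(center)
  if (length(center) != 3 || anyNA(center))
    .stop_ivs("ivs_site_error", "from_center site needs a length-3 center")
  structure(list(mode = "from_center", ligand_coords = NULL,
                 center = center, site_points = site_points),
            class = "ivs_site")
}

#' Read co-crystallized ligand coordinates from a PDB file
#'
#' Extracts the HETATM coordinates of a named residue, to seed a
#' `from_ligand` site definition.
#'
#' @param path PDB file path.
#' @param resname residue name of the ligand (e.g. `"LIG"`).
#' @return numeric matrix (n x 3) of coordinates.
#' @export
read_ligand_coords <- function(path, resname) {
  pdb <- bio3d::read.pdb(path)
  sel <- pdb$atom$resid == resname & pdb$atom$type == "HETATM"
  if (!any(sel))
    .stop_ivs("ivs_site_error", "no HETATM records for residue '%s' in %s",
              resname, path)
  as.matrix(pdb$atom[sel, c("x", "y", "z")])
}

#' Build a docking box around a binding site
#'
#' For a ligand-defined site the box is the axis-aligned bounding box of
#' the ligand, grown by `buffer` Angstrom on every side, centered on the
#' bounding-box midpoint (which guarantees the buffer symmetrically on
#' each axis). For a center-defined site the box is a cube of half-side
#' `buffer` around the center.
#'
#' @param site an `ivs_site`.
#' @param buffer distance buffer in Angstrom added in each direction
#'   (default 10).
#' @param spacing grid spacing in Angstrom (default 1.0).
#' @return an object of class `ivs_box`: list with `center` (length 3),
#'   `extents` (length-3 side lengths) and `spacing`.
#' @examples
#' build_box(site_from_center(c(0, 0, 0)))
#' @export
build_box <- function(site, buffer = 10, spacing = 1.0) {
  if (!inherits(site, "ivs_site"))
    .stop_ivs("ivs_site_error", "site must be an ivs_site")
  if (buffer <= 0 || spacing <= 0)
    .stop_ivs("ivs_site_error", "buffer and spacing must be positive")
  if (!is.null(site$site_points) && site$site_points < .MIN_SITE_POINTS)
    .stop_ivs("ivs_site_error",
              "site has %d site points; at least %d are required",
              site$site_points, .MIN_SITE_POINTS)
  if (site$mode == "from_ligand") {
    lo <- apply(site$ligand_coords, 2, min)
    hi <- apply(site$ligand_coords, 2, max)
    center <- (lo + hi) / 2
    extents <- (hi - lo) + 2 * buffer
  } else {
    center <- site$center
    extents <- rep(2 * buffer, 3)
  }
  structure(list(center = unname(center), extents = unname(extents),
                 spacing = spacing),
            class = "ivs_box")
}

#' @export
print.ivs_box <- function(x, ...) {
  cat(sprintf("Docking box: center (%.2f, %.2f, %.2f) A, extents (%.1f, %.1f, %.1f) A, spacing %.2f A\n",
              x$center[1], x$center[2], x$center[3],
              x$extents[1], x$extents[2], x$extents[3], x$spacing))
  invisible(x)
}

#' Grid points per axis of a docking box
#'
#' @param box an `ivs_box`.
#' @return integer vector of grid point counts per axis
#'   (`extent / spacing + 1`).
#' @export
grid_points <- function(box) {
  as.integer(round(box$extents / box$spacing)) + 1L
}

#' Export a docking box as engine-style configuration text
#'
#' Writes the `center_x/.../size_z` key-value lines understood by
#' grid-based docking engines.
#'
#' @param box an `ivs_box`.
#' @param path output path; if `NULL` the lines are returned invisibly
#'   without writing.
#' @return invisibly, the character vector of config lines.
#' @export
write_box_config <- function(box, path = NULL) {
  lines <- c(
    sprintf("center_x = %.3f", box$center[1]),
    sprintf("center_y = %.3f", box$center[2]),
    sprintf("center_z = %.3f", box$center[3]),
    sprintf("size_x = %.3f", box$extents[1]),
    sprintf("size_y = %.3f", box$extents[2]),
    sprintf("size_z = %.3f", box$extents[3]),
    sprintf("spacing = %.3f", box$spacing)
  )
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

# -- registry -----------------------------------------------------------------

.PANEL_REQUIRED <- c("pdb_id", "target_name")

#' Load a panel registry
#'
#' Reads the tabular registry describing the prepared protein panel. The
#' file must be TSV or CSV (inferred from the extension, or forced with
#' `sep`) with at least columns `pdb_id` and `target_name`; optional
#' columns are `conformer` (tag distinguishing multiple prepared
#' conformations of one crystal structure), `site_mode`
#' (`"from_center"`/`"from_ligand"`), `center_x/y/z`, `site_points`,
#' `ligand_path` and `ligand_resname`. Multiple entries may share a
#' `target_name` (redundant structures of the same protein); the pair
#' `(pdb_id, conformer)` must be unique.
#'
#' @param path registry file path.
#' @param sep field separator; default inferred from extension.
#' @return a data.frame of class `ivs_panel`, one row per panel structure.
#' @export
load_panel <- function(path, sep = NULL) {
  if (!file.exists(path))
    .stop_ivs("ivs_registry_error", "registry file not found: %s", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, comment.char = "",
                          check.names = TRUE)
  missing_cols <- setdiff(.PANEL_REQUIRED, names(df))
  if (length(missing_cols))
    .stop_ivs("ivs_registry_error", "registry missing column(s): %s",
              paste(missing_cols, collapse = ", "))
  if (!"conformer" %in% names(df)) df$conformer <- rep("", nrow(df))
  df$conformer[is.na(df$conformer)] <- ""
  if (!"site_mode" %in% names(df)) df$site_mode <- rep("from_center", nrow(df))
  if (nrow(df) == 0) {
    class(df) <- c("ivs_panel", "data.frame")
    return(df)
  }
  bad_pdb <- which(!grepl("^[0-9][a-z0-9]{3}$", df$pdb_id))
  if (length(bad_pdb))
    .stop_ivs("ivs_registry_error",
              "malformed PDB code '%s' at registry row %d (must be 4 lowercase alphanumerics starting with a digit)",
              df$pdb_id[bad_pdb[1]], bad_pdb[1])
  bad_name <- which(is.na(df$target_name) | !nzchar(trimws(df$target_name)))
  if (length(bad_name))
    .stop_ivs("ivs_registry_error", "empty target_name at registry row %d",
              bad_name[1])
  key <- paste(df$pdb_id, df$conformer, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    .stop_ivs("ivs_registry_error",
              "duplicate (pdb_id, conformer) = ('%s', '%s') at registry row %d",
              df$pdb_id[dup[1]], df$conformer[dup[1]], dup[1])
  bad_mode <- which(!df$site_mode %in% c("from_center", "from_ligand"))
  if (length(bad_mode))
    .stop_ivs("ivs_registry_error", "unknown site_mode '%s' at registry row %d",
              df$site_mode[bad_mode[1]], bad_mode[1])
  rownames(df) <- NULL
  message(sprintf("loaded panel registry: %d structures, %d distinct targets",
                  nrow(df), length(unique(.norm_name(df$target_name)))))
  class(df) <- c("ivs_panel", "data.frame")
  df
}

#' Site definition for one panel entry
#'
#' Materializes the `ivs_site` of a registry row, reading ligand
#' coordinates from the referenced PDB file when `site_mode` is
#' `"from_ligand"`.
#'
#' @param panel an `ivs_panel`.
#' @param row row index.
#' @return an `ivs_site`.
#' @export
panel_site <- function(panel, row) {
  e <- panel[row, ]
  sp <- if ("site_points" %in% names(e) && !is.na(e$site_points))
    e$site_points else NULL
  if (e$site_mode == "from_ligand") {
    if (is.na(e$ligand_path) || is.na(e$ligand_resname))
      .stop_ivs("ivs_site_error",
                "registry row %d: from_ligand site needs ligand_path and ligand_resname", row)
    site_from_ligand(read_ligand_coords(e$ligand_path, e$ligand_resname),
                     site_points = sp)
  } else {
    if (!all(c("center_x", "center_y", "center_z") %in% names(e)) ||
        anyNA(c(e$center_x, e$center_y, e$center_z)))
      .stop_ivs("ivs_site_error",
                "registry row %d: from_center site needs center_x/y/z", row)
    site_from_center(c(e$center_x, e$center_y, e$center_z), site_points = sp)
  }
}

#' Group panel structures by target identity
#'
#' Partitions the panel into redundancy groups: structures sharing a
#' target name (compared case-insensitively with whitespace collapsed)
#' are conformations of the same protein and are later collapsed to one
#' representative in the ranking. Group order follows first appearance.
#'
#' @param panel an `ivs_panel` (or any data.frame with `target_name`).
#' @return a named list mapping each target name (as first seen) to the
#'   integer row indices of its structures.
#' @export
redundancy_groups <- function(panel) {
  keys <- .norm_name(panel$target_name)
  first <- !duplicated(keys)
  groups <- split(seq_len(nrow(panel)), factor(keys, levels = keys[first]))
  names(groups) <- panel$target_name[first]
  groups
}
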