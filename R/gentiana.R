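# Worked-example data: the reported reverse-docking rankings of two
# Gentiana lutea root metabolites against an inflammation/cancer protein
# panel, shipped as plain-text fixtures under extdata.

#' Reported ranking tables for the Gentiana lutea metabolites
#'
#' The top-10 non-redundant target rankings reported for loganic acid and
#' gentiopicroside screened against a 3060-structure inflammation/cancer
#' panel: per structure, the printed V value (2 decimals), the query
#' best-pose affinity `v0`, the decoy average `vr` (kcal/mol) and the
#' printed occurrence percentage. The two 5om7 rows are distinct prepared
#' conformers of the same crystal structure, tagged `a`/`b`. These tables
#' are the package's worked example: re-normalizing their `(v0, vr)`
#' columns reproduces the printed V values to within the tables' own
#' rounding granularity.
#'
#' @param compound optionally restrict to `"loganic_acid"` or
#'   `"gentiopicroside"`.
#' @return a data.frame with columns `compound`, `target_name`, `pdb_id`,
#'   `conformer`, `v_printed`, `v0`, `vr`, `pct_printed`.
#' @examples
#' head(gentiana_tables("loganic_acid"))
#' @export
gentiana_tables <- function(compound = NULL) {
  path <- system.file("extdata", "gentiana_ranking_tables.tsv",
                      package = "ivscreen", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, comment.char = "")
  df$conformer[is.na(df$conformer)] <- ""
  if (!is.null(compound)) {
    stopifnot(compound %in% unique(df$compound))
    df <- df[df$compound == compound, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Structures of the two Gentiana lutea metabolites
#'
#' SMILES of loganic acid (an iridoid glucoside, C16H24O10) and
#' gentiopicroside (a secoiridoid glucoside, C16H20O9), the query
#' compounds of the worked example.
#'
#' @return a data.frame with columns `compound_id`, `smiles`, `role`.
#' @examples
#' nominal_deprotonated_mz(gentiana_metabolites())
#' @export
gentiana_metabolites <- function() {
  path <- system.file("extdata", "gentiana_metabolites.smi",
                      package = "ivscreen", mustWork = TRUE)
  read_smiles(path, role = "query")
}
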