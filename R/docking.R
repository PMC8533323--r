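# Pluggable scoring contract: parse external docking-engine output into
# score records, or generate deterministic mock scores for testing. The
# engine itself is never invoked; only its text output is consumed.
# Affinities are kcal/mol with the more-negative-is-better convention.

#' Construct a score record
#'
#' A score record holds the pose affinities of one (compound, structure)
#' docking run; `v0` is the best (lowest) pose affinity.
#'
#' @param compound_id,pdb_id identifiers.
#' @param poses numeric vector of pose affinities (kcal/mol).
#' @return an object of class `ivs_score`: list with `compound_id`,
#'   `pdb_id`, `poses`, `v0`.
#' @export
score_record <- function(compound_id, pdb_id, poses) {
  if (length(poses) == 0 || !all(is.finite(poses)))
    .stop_ivs("ivs_parse_error",
              "score record for (%s, %s) needs >= 1 finite pose affinity",
              compound_id, pdb_id)
  if (is.unsorted(poses))
    warning(sprintf("pose list for (%s, %s) is not ascending; v0 still taken as the minimum",
                    compound_id, pdb_id))
  structure(list(compound_id = compound_id, pdb_id = pdb_id,
                 poses = as.numeric(poses), v0 = min(poses)),
            class = "ivs_score")
}

#' @export
print.ivs_score <- function(x, ...) {
  cat(sprintf("Score record (%s, %s): v0 = %.2f kcal/mol over %d pose(s)\n",
              x$compound_id, x$pdb_id, x$v0, length(x$poses)))
  invisible(x)
}

#' Parse a docking-engine result table
#'
#' Reads the text output of a grid-docking engine run (the familiar
#' `mode | affinity | rmsd` pose table) and extracts the pose affinities.
#' The best-pose affinity `v0` is the minimum of the listed poses; a
#' non-ascending pose table triggers a warning but is accepted.
#'
#' @param path path to the log file, or a character vector of its lines
#'   via `text =`.
#' @param text character vector of log lines (alternative to `path`).
#' @param compound_id,pdb_id identifiers to attach; default derived from
#'   the file name as `<compound>_<pdb>.log` when possible.
#' @return an `ivs_score`.
#' @export
parse_engine_output <- function(path = NULL, text = NULL,
                                compound_id = NULL, pdb_id = NULL) {
  if (is.null(text)) text <- readLines(path)
  if (is.null(compound_id) || is.null(pdb_id)) {
    stem <- if (!is.null(path))
      sub("\\.[^.]*$", "", basename(path)) else "unknown_unknown"
    parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
    if (is.null(compound_id))
      compound_id <- if (length(parts) >= 2) parts[1] else stem
    if (is.null(pdb_id))
      pdb_id <- if (length(parts) >= 2) parts[length(parts)] else "unknown"
  }
  # pose lines: mode index, affinity, then rmsd columns
  pat <- "^\\s*([0-9]+)\\s+(-?[0-9]+(\\.[0-9]+)?)(\\s+-?[0-9]+(\\.[0-9]+)?)*\\s*$"
  hits <- grep(pat, text, value = TRUE)
  if (length(hits) == 0)
    .stop_ivs("ivs_parse_error", "no pose table found in engine output%s",
              if (is.null(path)) "" else paste0(" ", path))
  poses <- vapply(hits, function(ln) {
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }, 0, USE.NAMES = FALSE)
  score_record(compound_id, pdb_id, poses)
}

#' Parse pose affinities from a PDBQT pose file
#'
#' Honors the `REMARK VINA RESULT:` affinity lines of a multi-pose PDBQT
#' file; pose coordinates are ignored.
#'
#' @inheritParams parse_engine_output
#' @return an `ivs_score`.
#' @export
parse_pdbqt_poses <- function(path = NULL, text = NULL,
                              compound_id = NULL, pdb_id = NULL) {
  if (is.null(text)) text <- readLines(path)
  hits <- grep("^REMARK VINA RESULT:", text, value = TRUE)
  if (length(hits) == 0)
    .stop_ivs("ivs_parse_error", "no REMARK VINA RESULT lines found")
  poses <- vapply(hits, function(ln) {
    as.numeric(strsplit(trimws(sub("^REMARK VINA RESULT:", "", ln)),
                        "\\s+")[[1]][1])
  }, 0, USE.NAMES = FALSE)
  if (is.null(compound_id)) compound_id <- "unknown"
  if (is.null(pdb_id)) pdb_id <- "unknown"
  score_record(compound_id, pdb_id, poses)
}

#' Serialize a score record as an engine-style result table
#'
#' Round-trips with [parse_engine_output()].
#'
#' @param record an `ivs_score`.
#' @return character vector of text lines.
#' @export
format_engine_output <- function(record) {
  c("mode |   affinity | dist from best mode",
    "     | (kcal/mol) | rmsd l.b.| rmsd u.b.",
    "-----+------------+----------+----------",
    sprintf("%5d %12.1f %10.3f %10.3f",
            seq_along(record$poses), record$poses, 0, 0))
}

#' Read a bulk score table
#'
#' Reads a plain TSV of precomputed best-pose affinities with columns
#' `compound_id`, `pdb_id`, `affinity` (kcal/mol), the bulk-campaign
#' ingestion route. Optional `conformer` and `query_id` columns (the
#' latter ties decoy rows to their query) are preserved.
#'
#' @param path TSV path.
#' @return a data.frame with columns `compound_id`, `pdb_id`,
#'   (`conformer`,) `v0`.
#' @export
read_score_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "\"",
                          stringsAsFactors = FALSE)
  need <- c("compound_id", "pdb_id", "affinity")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    .stop_ivs("ivs_parse_error", "score table %s missing column(s): %s",
              path, paste(missing_cols, collapse = ", "))
  out <- data.frame(compound_id = df$compound_id, pdb_id = df$pdb_id,
                    stringsAsFactors = FALSE)
  if ("query_id" %in% names(df)) out$query_id <- df$query_id
  if ("conformer" %in% names(df)) out$conformer <- df$conformer
  out$v0 <- as.numeric(df$affinity)
  if (!all(is.finite(out$v0)))
    .stop_ivs("ivs_parse_error", "non-finite affinity in score table %s", path)
  out
}

#' Deterministic mock scorer
#'
#' Stand-in for an external docking engine in tests and examples: the
#' record is a pure function of `(compound_id, pdb_id, seed)`. The base
#' best-pose affinity is drawn from a Normal(`base_mean`, `base_sd`)
#' using an RNG stream seeded from a hash of the identifiers, and a
#' planted shift (kcal/mol, negative = stronger binding) is added for
#' pairs listed in `planted`. The remaining poses ascend from `v0` by
#' deterministic increments.
#'
#' @param compound_id,pdb_id identifiers.
#' @param seed integer campaign seed.
#' @param planted optional named numeric vector of shifts, names
#'   `"<compound_id>|<pdb_id>"`.
#' @param n_poses number of poses to generate (default 10).
#' @param base_mean,base_sd base affinity distribution (kcal/mol;
#'   defaults -7.0 and 1.0).
#' @return an `ivs_score`.
#' @examples
#' mock_score("cmpd1", "1abc", seed = 1)
#' @export
mock_score <- function(compound_id, pdb_id, seed, planted = NULL,
                       n_poses = 10, base_mean = -7.0, base_sd = 1.0) {
  h <- .str_hash(paste(compound_id, pdb_id, seed, sep = "|"))
  local_seed <- as.integer(h %% 2147483647)
  draws <- .with_local_seed(local_seed, {
    list(base = stats::rnorm(1, base_mean, base_sd),
         gaps = stats::runif(n_poses - 1, 0.05, 0.5))
  })
  shift <- 0
  if (!is.null(planted)) {
    key <- paste(compound_id, pdb_id, sep = "|")
    if (key %in% names(planted)) shift <- planted[[key]]
  }
  v0 <- draws$base + shift
  poses <- v0 + c(0, cumsum(draws$gaps))
  score_record(compound_id, pdb_id, poses)
}
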