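# The IVS core: decoy normalization V = V0/VR, threshold filtering,
# non-redundant collapsing, occurrence statistics and multi-compound
# target intersection.

#' Average decoy binding affinity
#'
#' VR for one panel structure: the arithmetic mean of the decoy
#' compounds' best-pose affinities against that structure.
#'
#' @param decoy_scores a list of [score_record()]s, a data.frame with a
#'   `v0` column (and optionally `pdb_id`), or a bare numeric vector of
#'   best-pose affinities.
#' @return the mean affinity (kcal/mol).
#' @export
aggregate_decoy_affinity <- function(decoy_scores) {
  if (inherits(decoy_scores, "ivs_score")) decoy_scores <- list(decoy_scores)
  if (is.list(decoy_scores) && !is.data.frame(decoy_scores) &&
      all(vapply(decoy_scores, inherits, TRUE, "ivs_score"))) {
    if (length(decoy_scores) == 0)
      .stop_ivs("ivs_aggregation_error", "empty decoy score list")
    pdbs <- unique(vapply(decoy_scores, `[[`, "", "pdb_id"))
    if (length(pdbs) > 1)
      .stop_ivs("ivs_aggregation_error",
                "decoy scores span multiple structures: %s",
                paste(pdbs, collapse = ", "))
    v0 <- vapply(decoy_scores, `[[`, 0, "v0")
  } else if (is.data.frame(decoy_scores)) {
    if (nrow(decoy_scores) == 0)
      .stop_ivs("ivs_aggregation_error", "empty decoy score table")
    if ("pdb_id" %in% names(decoy_scores) &&
        length(unique(decoy_scores$pdb_id)) > 1)
      .stop_ivs("ivs_aggregation_error",
                "decoy scores span multiple structures: %s",
                paste(unique(decoy_scores$pdb_id), collapse = ", "))
    v0 <- decoy_scores$v0
  } else {
    v0 <- as.numeric(decoy_scores)
    if (length(v0) == 0)
      .stop_ivs("ivs_aggregation_error", "empty decoy affinity vector")
  }
  mean(v0)
}

#' The V value: decoy-normalized binding affinity
#'
#' Dimensionless ratio `V = V0 / VR` of the query compound's best-pose
#' affinity to the decoy average against the same structure. Both inputs
#' must be negative (binding, kcal/mol); `V > 1` means the query binds
#' more strongly than its decoy average. Values are returned at full
#' precision; tables round to 2 decimals at reporting time.
#'
#' @param v0 query best-pose affinity, kcal/mol (negative).
#' @param vr mean decoy best-pose affinity, kcal/mol (negative).
#' @return the ratio `v0 / vr` (vectorized).
#' @examples
#' compute_v(-7.7, -5.2) # 1.480769...
#' @export
compute_v <- function(v0, vr) {
  if (any(vr == 0))
    .stop_ivs("ivs_sign_error", "vr is zero; cannot normalize")
  if (any(v0 >= 0))
    .stop_ivs("ivs_sign_error",
              "v0 = %.3f violates the negative-affinity convention",
              v0[v0 >= 0][1])
  if (any(vr >= 0))
    .stop_ivs("ivs_sign_error",
              "vr = %.3f violates the negative-affinity convention",
              vr[vr >= 0][1])
  v0 / vr
}

#' Normalize a query score table against decoy scores
#'
#' Joins the query's best-pose affinities with the per-structure decoy
#' averages and computes V for every (compound, structure) pair. Rows
#' where the sign convention is violated (non-negative `v0` or `vr`) are
#' kept but flagged invalid with `v = NA` and a warning.
#'
#' @param query_scores data.frame with columns `compound_id`, `pdb_id`,
#'   (`conformer`,) `v0`.
#' @param decoy_scores data.frame of decoy best-pose affinities with
#'   columns `compound_id`, `pdb_id`, (`conformer`,) `v0`, and optionally
#'   `query_id` when different queries use different decoy sets.
#' @param panel optional `ivs_panel` used to attach `target_name`.
#' @return a data.frame with columns `compound_id`, `pdb_id`, `conformer`,
#'   `target_name`, `v0`, `vr`, `v`, `valid`.
#' @export
normalize_scores <- function(query_scores, decoy_scores, panel = NULL) {
  q <- query_scores
  d <- decoy_scores
  if (!"conformer" %in% names(q)) q$conformer <- ""
  if (!"conformer" %in% names(d)) d$conformer <- ""
  q$conformer[is.na(q$conformer)] <- ""
  d$conformer[is.na(d$conformer)] <- ""
  skey <- function(x) paste(x$pdb_id, x$conformer, sep = "\r")
  out <- data.frame(
    compound_id = q$compound_id, pdb_id = q$pdb_id, conformer = q$conformer,
    target_name = NA_character_, v0 = q$v0, vr = NA_real_,
    stringsAsFactors = FALSE
  )
  per_query <- "query_id" %in% names(d)
  dkey <- skey(d)
  qkey <- skey(q)
  if (per_query) {
    dkey <- paste(d$query_id, dkey, sep = "\n")
    qkey <- paste(q$compound_id, qkey, sep = "\n")
  }
  means <- tapply(d$v0, dkey, mean)
  out$vr <- as.numeric(means[qkey])
  miss <- is.na(out$vr)
  if (any(miss))
    warning(sprintf("%d (compound, structure) pair(s) lack decoy scores and get vr = NA",
                    sum(miss)))
  out$valid <- !miss & out$v0 < 0 & out$vr < 0
  bad_sign <- !miss & !out$valid
  if (any(bad_sign))
    warning(sprintf("%d record(s) violate the negative-affinity convention and are flagged invalid",
                    sum(bad_sign)))
  out$v <- NA_real_
  out$v[out$valid] <- out$v0[out$valid] / out$vr[out$valid]
  if (!is.null(panel)) {
    pk <- paste(panel$pdb_id, panel$conformer, sep = "\r")
    out$target_name <- panel$target_name[match(skey(out), pk)]
  }
  out
}

#' Filter normalized scores by V threshold
#'
#' Keeps the structures whose V value exceeds the cutoff (strictly by
#' default: "above" the threshold). Invalid rows (`v = NA`) are dropped.
#' Input order is preserved.
#'
#' @param scores data.frame with a `v` column (see [normalize_scores()]).
#' @param threshold V cutoff (default 0.9).
#' @param strict if `TRUE` (default) keep `v > threshold`, else
#'   `v >= threshold`.
#' @return the retained rows.
#' @export
filter_by_threshold <- function(scores, threshold = 0.9, strict = TRUE) {
  if (nrow(scores) == 0) return(scores)
  keep <- !is.na(scores$v) &
    (if (strict) scores$v > threshold else scores$v >= threshold)
  out <- scores[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Occurrence percentage per target
#'
#' Share of post-filter panel structures belonging to each target name:
#' `100 * n_structures(target) / n_structures(all filtered)`. Computed on
#' the structure-level (pre-collapse) filtered set.
#'
#' @param filtered structure-level filtered scores (one compound's
#'   campaign).
#' @return a data.frame with columns `target_name`, `n`, `pct` (full
#'   precision; round at reporting).
#' @export
occurrence_percentages <- function(filtered) {
  if (nrow(filtered) == 0) {
    warning("empty filtered set; occurrence percentages undefined")
    return(data.frame(target_name = character(0), n = integer(0),
                      pct = numeric(0), stringsAsFactors = FALSE))
  }
  keys <- .norm_name(filtered$target_name)
  first <- !duplicated(keys)
  tab <- table(factor(keys, levels = keys[first]))
  data.frame(
    target_name = filtered$target_name[first],
    n = as.integer(tab),
    pct = 100 * as.integer(tab) / nrow(filtered),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Collapse to the non-redundant target ranking
#'
#' Reduces a structure-level filtered score set to one row per target
#' name (the structure with the highest V), attaches occurrence
#' percentages computed on the pre-collapse set, sorts by V descending
#' (ties: `v0` ascending, then `pdb_id`), and keeps the first `top_k`
#' rows.
#'
#' @param filtered structure-level filtered scores for one compound.
#' @param top_k rows retained in the report (default 10; `Inf` keeps all).
#' @param threshold the V cutoff that produced `filtered` (recorded as an
#'   attribute).
#' @return a data.frame of class `ivs_ranking` with columns
#'   `target_name`, `pdb_id`, `conformer`, `v`, `v0`, `vr`, `pct`.
#' @export
collapse_non_redundant <- function(filtered, top_k = 10, threshold = 0.9) {
  occ <- suppressWarnings(occurrence_percentages(filtered))
  keys <- .norm_name(filtered$target_name)
  rows <- integer(0)
  for (k in unique(keys)) {
    idx <- which(keys == k)
    best <- idx[order(-filtered$v[idx], filtered$v0[idx],
                      filtered$pdb_id[idx])[1]]
    rows <- c(rows, best)
  }
  out <- filtered[rows, , drop = FALSE]
  ord <- order(-out$v, out$v0, out$pdb_id)
  out <- out[ord, , drop = FALSE]
  if (is.finite(top_k)) out <- out[seq_len(min(top_k, nrow(out))), , drop = FALSE]
  out$pct <- occ$pct[match(.norm_name(out$target_name),
                           .norm_name(occ$target_name))]
  keep <- intersect(c("target_name", "pdb_id", "conformer", "v", "v0", "vr",
                      "pct"), names(out))
  out <- out[, keep, drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "top_k") <- top_k
  class(out) <- c("ivs_ranking", "data.frame")
  out
}

#' Targets common to several rankings
#'
#' Intersects the target names of two or more rankings (names compared
#' case-insensitively with whitespace collapsed) and orders the common
#' targets by their mean rank across the tables.
#'
#' @param rankings a list of [collapse_non_redundant()] results (>= 2).
#' @return a data.frame with columns `target_name` and `mean_rank`.
#' @export
intersect_rankings <- function(rankings) {
  if (length(rankings) < 2)
    .stop_ivs("ivs_aggregation_error", "need at least two rankings to intersect")
  keysets <- lapply(rankings, function(r) .norm_name(r$target_name))
  common <- Reduce(intersect, keysets)
  if (length(common) == 0)
    return(data.frame(target_name = character(0), mean_rank = numeric(0),
                      stringsAsFactors = FALSE))
  mean_rank <- vapply(common, function(k) {
    mean(vapply(keysets, function(ks) match(k, ks), 0))
  }, 0)
  first <- rankings[[1]]
  nm <- first$target_name[match(common, keysets[[1]])]
  ord <- order(mean_rank, nm)
  data.frame(target_name = nm[ord], mean_rank = unname(mean_rank[ord]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a ranking table as TSV
#'
#' Mirrors the reporting format of published IVS rankings: columns
#' `Target`, `PDB`, `V` (2 decimals), `V0`, `VR`, `pct_occurrences`
#' (1 decimal).
#'
#' @param ranking an `ivs_ranking`.
#' @param path output TSV path.
#' @return invisibly, the formatted data.frame written.
#' @export
write_ranking_tsv <- function(ranking, path) {
  df <- data.frame(
    Target = ranking$target_name,
    PDB = if ("conformer" %in% names(ranking) && any(nzchar(ranking$conformer)))
      paste0(ranking$pdb_id,
             ifelse(nzchar(ranking$conformer), paste0(".", ranking$conformer), ""))
      else ranking$pdb_id,
    V = sprintf("%.2f", ranking$v),
    V0 = ranking$v0,
    VR = ranking$vr,
    pct_occurrences = sprintf("%.1f", ranking$pct),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
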