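# -- element mass tables ------------------------------------------------------

# Integer mass numbers of the most abundant isotope, for nominal-mass
# arithmetic (ESI-MS peak positions).
.NOMINAL_MASS <- c(
  H = 1, B = 11, C = 12, N = 14, O = 16, F = 19, Na = 23, Si = 28,
  P = 31, S = 32, Cl = 35, K = 39, Br = 79, I = 127, Se = 80
)

# -- molecule parsing ---------------------------------------------------------

# Parse a batch of SMILES into internal molecule objects via OpenBabel
# (explicit hydrogens added) and ChemmineR's SDF reader. Returns a list of
# "ivs_mol" objects in input order; unparsable entries raise a structure
# error naming the offending compound_id.
.parse_smiles <- function(ids, smiles) {
  stopifnot(length(ids) == length(smiles))
  if (length(ids) == 0) return(list())
  if (anyDuplicated(ids))
    .stop_ivs("ivs_structure_error", "duplicate compound_id in input: %s",
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
  smi_txt <- paste0(paste(smiles, ids, sep = "\t"), "\n", collapse = "")
  opts <- data.frame(names = c("h", "gen2D"), args = c("", ""))
  sdf_txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", smi_txt, options = opts),
    error = function(e) ""
  )
  can_txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", smi_txt),
    error = function(e) ""
  )
  mols <- .mols_from_sdf_text(sdf_txt)
  if (length(mols) < length(ids) || is.null(names(mols))) {
    ok <- names(mols)
    bad <- setdiff(ids, ok)
    .stop_ivs("ivs_structure_error",
              "unparsable structure for compound_id: %s",
              paste(bad, collapse = ", "))
  }
  mols <- mols[match(ids, names(mols))]
  if (anyNA(names(mols)))
    .stop_ivs("ivs_structure_error", "structure parsing lost records")
  # canonical SMILES per id, used for structure-identity tests
  can <- strsplit(strsplit(can_txt, "\n", fixed = TRUE)[[1]], "\t", fixed = TRUE)
  can_ids <- vapply(can, function(x) if (length(x) >= 2) x[2] else NA_character_, "")
  can_smi <- vapply(can, `[`, "", 1)
  for (i in seq_along(mols)) {
    j <- match(names(mols)[i], can_ids)
    mols[[i]]$canonical <- if (is.na(j)) NA_character_ else can_smi[j]
    mols[[i]]$smiles <- smiles[i]
  }
  mols
}

# Parse multi-record SDF text (explicit hydrogens assumed already present
# or added upstream) into a named list of ivs_mol.
.mols_from_sdf_text <- function(sdf_txt) {
  if (!nzchar(sdf_txt)) return(list())
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(sdf_txt, tf)
  sdfs <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(tf)),
    error = function(e) NULL
  )
  if (is.null(sdfs) || length(sdfs) == 0) return(list())
  recs <- strsplit(sdf_txt, "\\$\\$\\$\\$\n?")[[1]]
  mws <- suppressWarnings(ChemmineR::MW(sdfs))
  out <- vector("list", length(sdfs))
  nms <- character(length(sdfs))
  for (i in seq_along(sdfs)) {
    sdf <- sdfs[[i]]
    title <- ChemmineR::header(sdf)[["Molecule_Name"]]
    charges <- .parse_chg_lines(recs[i])
    out[[i]] <- .build_mol(sdf, mws[[i]], charges)
    nms[i] <- title
  }
  names(out) <- nms
  out
}

# M  CHG lines of one SDF record -> named vector atom_index -> charge
.parse_chg_lines <- function(rec_txt) {
  lines <- grep("^M  CHG", strsplit(rec_txt, "\n", fixed = TRUE)[[1]],
                value = TRUE)
  if (length(lines) == 0) return(integer(0))
  out <- integer(0)
  for (ln in lines) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "[[:space:]]+")[[1]])
    n <- f[1]
    for (k in seq_len(n)) {
      out[as.character(f[2 * k])] <- f[2 * k + 1]
    }
  }
  out
}

# Assemble the heavy-atom graph from ChemmineR atom/bond blocks.
.build_mol <- function(sdf, mw, charges) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  n <- length(elem)
  chg <- integer(n)
  if (length(charges)) chg[as.integer(names(charges))] <- charges
  a1 <- as.integer(bb[, 1]); a2 <- as.integer(bb[, 2])
  order <- as.integer(bb[, 3])
  heavy <- which(elem != "H")
  if (length(heavy) == 0)
    .stop_ivs("ivs_structure_error", "structure has no heavy atoms")
  # hydrogens attached per heavy atom
  nH <- integer(n)
  is_h <- elem == "H"
  for (k in seq_along(a1)) {
    if (is_h[a1[k]] && !is_h[a2[k]]) nH[a2[k]] <- nH[a2[k]] + 1L
    if (is_h[a2[k]] && !is_h[a1[k]]) nH[a1[k]] <- nH[a1[k]] + 1L
  }
  remap <- integer(n); remap[heavy] <- seq_along(heavy)
  keep <- !is_h[a1] & !is_h[a2]
  atoms <- data.frame(
    elem = elem[heavy], nH = nH[heavy], charge = chg[heavy],
    stringsAsFactors = FALSE
  )
  bonds <- data.frame(
    a1 = remap[a1[keep]], a2 = remap[a2[keep]], order = order[keep]
  )
  counts <- table(elem)
  structure(list(
    atoms = atoms, bonds = bonds, mw = unname(mw),
    formula_counts = stats::setNames(as.integer(counts), names(counts))
  ), class = "ivs_mol")
}

# Accept a compounds data.frame, a named character vector of SMILES, or a
# bare character vector (ids invented) and normalize to (compound_id, smiles).
.as_compound_df <- function(x, role = "candidate") {
  if (is.data.frame(x)) {
    if (!all(c("compound_id", "smiles") %in% names(x)))
      .stop_ivs("ivs_structure_error",
                "compound table needs columns compound_id and smiles")
    df <- x[, c("compound_id", "smiles")]
    df$role <- if ("role" %in% names(x)) x$role else role
    return(df)
  }
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- sprintf("cmpd_%d", seq_along(x))
    return(data.frame(compound_id = ids, smiles = unname(x), role = role,
                      stringsAsFactors = FALSE))
  }
  .stop_ivs("ivs_structure_error", "cannot interpret compounds input")
}

#' Read a SMILES file
#'
#' Reads a plain-text SMILES file with one compound per line in
#' `id<TAB>smiles` form. Blank lines and lines starting with `#` are
#' skipped.
#'
#' @param path path to the file.
#' @param role role to assign to every compound (`"query"`, `"decoy"` or
#'   `"candidate"`).
#' @return a data.frame with columns `compound_id`, `smiles`, `role`.
#' @export
read_smiles <- function(path, role = "candidate") {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2)
  if (length(bad))
    .stop_ivs("ivs_structure_error", "malformed SMILES line %d", bad[1])
  data.frame(
    compound_id = vapply(parts, `[`, "", 1),
    smiles = vapply(parts, `[`, "", 2),
    role = role, stringsAsFactors = FALSE
  )
}

#' Read compounds from an SDF file
#'
#' Reads an SDF (V2000) file and returns the compounds as a table of
#' canonical SMILES, using the record title as `compound_id`.
#'
#' @inheritParams read_smiles
#' @return a data.frame with columns `compound_id`, `smiles`, `role`.
#' @export
read_sdf_compounds <- function(path, role = "candidate") {
  txt <- paste(readLines(path), collapse = "\n")
  can <- ChemmineOB::convertFormat("SDF", "CAN", paste0(txt, "\n"))
  rows <- strsplit(strsplit(can, "\n", fixed = TRUE)[[1]], "\t", fixed = TRUE)
  data.frame(
    compound_id = vapply(rows, function(x) if (length(x) >= 2) x[2] else NA, ""),
    smiles = vapply(rows, `[`, "", 1),
    role = role, stringsAsFactors = FALSE
  )
}

# -- features -----------------------------------------------------------------

#' Compute decoy-matching chemical features
#'
#' For each compound, computes the three features used for property-matched
#' decoy selection: molecular weight (average atomic masses, Da) and the
#' Lipinski hydrogen-bond donor and acceptor counts (`hbd` = number of O-H
#' and N-H hydrogens, `hba` = number of nitrogen and oxygen atoms).
#'
#' @param compounds a compounds data.frame (`compound_id`, `smiles`) as
#'   returned by [read_smiles()], or a (optionally named) character vector
#'   of SMILES.
#' @return a data.frame with columns `compound_id`, `mw`, `hbd`, `hba`.
#' @examples
#' compute_features(c(ethanol = "CCO", methane = "C"))
#' @export
compute_features <- function(compounds) {
  df <- .as_compound_df(compounds)
  mols <- .parse_smiles(df$compound_id, df$smiles)
  feat <- function(m) {
    no <- m$atoms$elem %in% c("N", "O")
    c(mw = m$mw, hbd = sum(m$atoms$nH[no]), hba = sum(no))
  }
  v <- t(vapply(mols, feat, c(mw = 0, hbd = 0, hba = 0)))
  data.frame(
    compound_id = df$compound_id,
    mw = v[, "mw"], hbd = as.integer(v[, "hbd"]), hba = as.integer(v[, "hba"]),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Nominal deprotonated ion mass
#'
#' Nominal m/z of the `[M-H]-` ion observed in negative-mode ESI-MS: the
#' sum of the integer mass numbers of each atom's most abundant isotope,
#' minus one for the lost proton. No check is made that the molecule has
#' an acidic hydrogen; the value is the formal one.
#'
#' @inheritParams compute_features
#' @return an integer vector of nominal m/z values, named by compound_id.
#' @examples
#' nominal_deprotonated_mz(c(water = "O")) # 17
#' @export
nominal_deprotonated_mz <- function(compounds) {
  df <- .as_compound_df(compounds)
  mols <- .parse_smiles(df$compound_id, df$smiles)
  out <- vapply(mols, function(m) {
    cts <- m$formula_counts
    unknown <- setdiff(names(cts), names(.NOMINAL_MASS))
    if (length(unknown))
      .stop_ivs("ivs_structure_error",
                "no nominal mass for element(s): %s",
                paste(unknown, collapse = ", "))
    sum(.NOMINAL_MASS[names(cts)] * cts) - 1L
  }, 0)
  stats::setNames(as.integer(out), df$compound_id)
}

# -- circular fingerprint and similarity --------------------------------------

# Morgan-style circular fingerprint on the heavy-atom graph: each atom
# contributes one integer identifier per radius 0..radius, obtained by
# iteratively hashing its previous identifier with the sorted
# (bond order, neighbour identifier) list. The fingerprint is the set of
# all identifiers.
.morgan_fp <- function(mol, radius = 2) {
  atoms <- mol$atoms; bonds <- mol$bonds
  n <- nrow(atoms)
  nb <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$a1[k]; j <- bonds$a2[k]; o <- bonds$order[k]
    nb[[i]] <- rbind(nb[[i]], c(j, o))
    nb[[j]] <- rbind(nb[[j]], c(i, o))
  }
  deg <- vapply(nb, function(x) if (is.null(x)) 0L else nrow(x), 0L)
  ids <- vapply(seq_len(n), function(i) {
    .str_hash(paste(atoms$elem[i], deg[i], atoms$nH[i], atoms$charge[i],
                    sep = "|"))
  }, 0)
  fp <- unique(ids)
  if (radius >= 1) {
    for (r in seq_len(radius)) {
      new_ids <- numeric(n)
      for (i in seq_len(n)) {
        h <- ids[i]
        if (deg[i] > 0) {
          env <- nb[[i]]
          key <- env[, 2] * .HASH_P + ids[env[, 1]]
          for (x in sort(key)) h <- .hash_combine(h, x %% .HASH_P)
        }
        new_ids[i] <- .hash_combine(h, r)
      }
      ids <- new_ids
      fp <- unique(c(fp, ids))
    }
  }
  sort(fp)
}

#' Circular-substructure fingerprint
#'
#' Computes a Morgan-style circular fingerprint (set of hashed atom
#' environments up to the given radius) for one compound.
#'
#' @param smiles a single SMILES string.
#' @param radius maximum environment radius in bonds (default 2).
#' @return a sorted numeric vector of environment identifiers.
#' @export
morgan_fingerprint <- function(smiles, radius = 2) {
  mol <- .parse_smiles("x", smiles)[[1]]
  .morgan_fp(mol, radius)
}

#' Tanimoto structural similarity
#'
#' Symmetric Tanimoto coefficient between the circular fingerprints of two
#' compounds, used to reject decoy candidates structurally related to the
#' query.
#'
#' @param a,b SMILES strings.
#' @param radius fingerprint radius (default 2).
#' @return similarity in `[0, 1]`.
#' @export
structural_similarity <- function(a, b, radius = 2) {
  mols <- .parse_smiles(c("a", "b"), c(a, b))
  fa <- .morgan_fp(mols[[1]], radius)
  fb <- .morgan_fp(mols[[2]], radius)
  inter <- length(intersect(fa, fb))
  uni <- length(union(fa, fb))
  if (uni == 0) return(0)
  inter / uni
}

# -- decoy selection ----------------------------------------------------------

#' Select a property-matched decoy set
#'
#' Picks `n` decoys for a query compound from a candidate library. A
#' candidate is eligible when its molecular weight, hydrogen-bond donor and
#' acceptor counts each lie within the configured window of the query's,
#' and its fingerprint Tanimoto similarity to the query does not exceed
#' `max_similarity` (so decoys share the query's bulk features but not its
#' chemotype). The query itself (same id or same canonical structure) is
#' always excluded. Eligible candidates are ordered by `|mw - mw_query|`
#' ascending with ties broken by `compound_id`, and the first `n` are
#' returned, making selection deterministic.
#'
#' @param query a one-row compounds data.frame or a single named SMILES.
#' @param candidates a compounds data.frame or named SMILES vector.
#' @param n number of decoys (default 10).
#' @param mw_window,hbd_window,hba_window feature tolerances (Da / counts;
#'   defaults 25, 1, 1).
#' @param max_similarity Tanimoto ceiling (default 0.4).
#' @param radius fingerprint radius (default 2).
#' @param seed integer recorded with the set for reproducibility metadata;
#'   the selection rule itself is deterministic.
#' @return an object of class `ivs_decoy_set`: list with `query_id`,
#'   `decoys` (data.frame with features, similarity and `delta_mw`), `n`,
#'   and the parameters used.
#' @export
select_decoys <- function(query, candidates, n = 10,
                          mw_window = 25, hbd_window = 1, hba_window = 1,
                          max_similarity = 0.4, radius = 2, seed = NULL) {
  qdf <- .as_compound_df(query, role = "query")
  if (nrow(qdf) != 1)
    .stop_ivs("ivs_selection_error", "query must be a single compound")
  cdf <- .as_compound_df(candidates, role = "candidate")
  qmol <- .parse_smiles(qdf$compound_id, qdf$smiles)[[1]]
  qfeat <- compute_features(qdf)
  cmols <- .parse_smiles(cdf$compound_id, cdf$smiles)
  cfeat <- compute_features(cdf)

  self <- cdf$compound_id == qdf$compound_id |
    vapply(cmols, function(m) identical(m$canonical, qmol$canonical), TRUE)
  qfp <- .morgan_fp(qmol, radius)
  sim <- vapply(cmols, function(m) {
    f <- .morgan_fp(m, radius)
    u <- length(union(qfp, f))
    if (u == 0) 0 else length(intersect(qfp, f)) / u
  }, 0)

  pass_mw <- abs(cfeat$mw - qfeat$mw) <= mw_window & !self
  pass_hbd <- abs(cfeat$hbd - qfeat$hbd) <= hbd_window & !self
  pass_hba <- abs(cfeat$hba - qfeat$hba) <= hba_window & !self
  pass_sim <- sim <= max_similarity & !self
  eligible <- pass_mw & pass_hbd & pass_hba & pass_sim

  if (sum(eligible) < n)
    .stop_ivs("ivs_selection_error",
              paste0("only %d of %d candidates eligible (need %d): ",
                     "%d pass mw window, %d hbd, %d hba, %d similarity"),
              sum(eligible), nrow(cdf), n,
              sum(pass_mw), sum(pass_hbd), sum(pass_hba), sum(pass_sim))

  sel <- data.frame(
    compound_id = cdf$compound_id, smiles = cdf$smiles,
    mw = cfeat$mw, hbd = cfeat$hbd, hba = cfeat$hba,
    similarity = sim, delta_mw = abs(cfeat$mw - qfeat$mw),
    stringsAsFactors = FALSE
  )[eligible, , drop = FALSE]
  ord <- order(sel$delta_mw, sel$compound_id)
  sel <- sel[ord, , drop = FALSE][seq_len(n), , drop = FALSE]
  rownames(sel) <- NULL
  structure(list(
    query_id = qdf$compound_id, decoys = sel, n = n,
    params = list(mw_window = mw_window, hbd_window = hbd_window,
                  hba_window = hba_window, max_similarity = max_similarity,
                  radius = radius, seed = seed)
  ), class = "ivs_decoy_set")
}

#' @export
print.ivs_decoy_set <- function(x, ...) {
  cat(sprintf("Decoy set for query '%s': %d decoys\n", x$query_id, x$n))
  if (x$n > 0) print(x$decoys[, c("compound_id", "mw", "hbd", "hba",
                                  "similarity")])
  invisible(x)
}

#' Write a decoy set to disk
#'
#' Writes the decoy structures as an SDF file and their features as a TSV.
#'
#' @param decoy_set an [select_decoys()] result.
#' @param sdf_path,features_path output file paths (either may be `NULL`
#'   to skip that file).
#' @return invisibly, the decoy set.
#' @export
write_decoy_set <- function(decoy_set, sdf_path = NULL, features_path = NULL) {
  d <- decoy_set$decoys
  if (!is.null(sdf_path) && nrow(d) > 0) {
    smi_txt <- paste0(paste(d$smiles, d$compound_id, sep = "\t"), "\n",
                      collapse = "")
    opts <- data.frame(names = "gen2D", args = "")
    sdf_txt <- ChemmineOB::convertFormat("SMI", "SDF", smi_txt, options = opts)
    writeLines(sdf_txt, sdf_path)
  }
  if (!is.null(features_path)) {
    utils::write.table(
      d[, c("compound_id", "smiles", "mw", "hbd", "hba", "similarity")],
      features_path, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(decoy_set)
}
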