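# Independent oracles used to cross-check package computations. These are
# deliberately written against ChemmineR/base primitives directly, not the
# package's internals.

# Enumerate canonical circular-environment strings (depth-r unfolding
# trees) of the heavy-atom graph, radius-tagged. Tanimoto over these sets
# is the brute-force counterpart of the hashed fingerprint.
oracle_env_strings <- function(smiles, radius = 2) {
  opts <- data.frame(names = c("h", "gen2D"), args = c("", ""))
  sdf_txt <- ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\tm\n"),
                                       options = opts)
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(sdf_txt, tf)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(tf))
  ab <- ChemmineR::atomblock(sdfs[[1]])
  bb <- ChemmineR::bondblock(sdfs[[1]])
  elem <- sub("_.*$", "", rownames(ab))
  a1 <- as.integer(bb[, 1]); a2 <- as.integer(bb[, 2])
  ord <- as.integer(bb[, 3])
  nH <- integer(length(elem))
  for (k in seq_along(a1)) {
    if (elem[a1[k]] == "H" && elem[a2[k]] != "H") nH[a2[k]] <- nH[a2[k]] + 1L
    if (elem[a2[k]] == "H" && elem[a1[k]] != "H") nH[a1[k]] <- nH[a1[k]] + 1L
  }
  hidx <- which(elem != "H")
  remap <- match(seq_along(elem), hidx)
  adj <- vector("list", length(hidx))
  for (k in seq_along(a1)) {
    if (elem[a1[k]] == "H" || elem[a2[k]] == "H") next
    i <- remap[a1[k]]; j <- remap[a2[k]]
    adj[[i]] <- c(adj[[i]], list(c(j, ord[k])))
    adj[[j]] <- c(adj[[j]], list(c(i, ord[k])))
  }
  inv <- function(i) paste(elem[hidx[i]],
                           if (is.null(adj[[i]])) 0 else length(adj[[i]]),
                           nH[hidx[i]], sep = ",")
  env_str <- function(i, r) {
    if (r == 0) return(inv(i))
    kids <- if (is.null(adj[[i]])) character(0)
      else sort(vapply(adj[[i]],
                       function(e) paste0(e[2], ":", env_str(e[1], r - 1)), ""))
    paste0(inv(i), "(", paste(kids, collapse = "|"), ")")
  }
  unique(unlist(lapply(0:radius, function(r) {
    paste0(r, "~", vapply(seq_along(adj), function(i) env_str(i, r), ""))
  })))
}

oracle_tanimoto <- function(a, b, radius = 2) {
  fa <- oracle_env_strings(a, radius)
  fb <- oracle_env_strings(b, radius)
  u <- length(union(fa, fb))
  if (u == 0) 0 else length(intersect(fa, fb)) / u
}

# Brute-force group-by-max collapse with the ranking tie rule.
oracle_collapse <- function(filtered, top_k = 10) {
  key <- tolower(gsub("[[:space:]]+", " ", trimws(filtered$target_name)))
  reps <- vapply(split(seq_len(nrow(filtered)), key), function(ix) {
    ix[order(-filtered$v[ix], filtered$v0[ix], filtered$pdb_id[ix])[1]]
  }, 0L)
  out <- filtered[reps, , drop = FALSE]
  out <- out[order(-out$v, out$v0, out$pdb_id), , drop = FALSE]
  out <- utils::head(out, top_k)
  rownames(out) <- NULL
  out
}

# Brute-force decoy eligibility filter + ordering rule.
oracle_decoys <- function(qfeat, cfeat, sims, self, n,
                          mw_window = 25, hbd_window = 1, hba_window = 1,
                          max_similarity = 0.4) {
  ok <- !self &
    abs(cfeat$mw - qfeat$mw) <= mw_window &
    abs(cfeat$hbd - qfeat$hbd) <= hbd_window &
    abs(cfeat$hba - qfeat$hba) <= hba_window &
    sims <= max_similarity
  sel <- cfeat[ok, , drop = FALSE]
  sel$delta <- abs(sel$mw - qfeat$mw)
  sel <- sel[order(sel$delta, sel$compound_id), , drop = FALSE]
  utils::head(sel$compound_id, n)
}

# Numerical rigid-body alignment: minimize RMSD over rotations (Euler
# angles) and translations by multi-start quasi-Newton search.
oracle_fit_rmsd <- function(ref, mov) {
  rotmat <- function(a, b, c) {
    Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
    Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
    Rz <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
    Rz %*% Ry %*% Rx
  }
  obj <- function(p) {
    m <- mov %*% t(rotmat(p[1], p[2], p[3]))
    m <- sweep(m, 2, -p[4:6])
    sqrt(mean(rowSums((m - ref)^2)))
  }
  t0 <- colMeans(ref) - colMeans(mov)
  best <- Inf
  for (a in c(0, pi / 2, pi)) for (b in c(0, pi / 2)) for (c in c(0, pi)) {
    fit <- stats::optim(c(a, b, c, t0), obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}
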