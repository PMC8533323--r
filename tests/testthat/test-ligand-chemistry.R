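test_that("feature computation follows the Lipinski MW/HBD/HBA convention", {
  f <- compute_features(c(ethanol = "CCO", methane = "C",
                          glycine = "NCC(=O)O"))
  expect_equal(f$mw[1], 46.07, tolerance = 0.01 / 46.07)
  expect_identical(f$hbd, c(1L, 0L, 3L))  # glycine: N-H2 + O-H
  expect_identical(f$hba, c(1L, 0L, 3L))  # N and O atoms
  expect_true(f$mw[2] > 0)
})

test_that("the iridoid glucoside features are consistent with its ESI-MS ion", {
  met <- gentiana_metabolites()
  f <- compute_features(met)
  loganic <- f[f$compound_id == "loganic_acid", ]
  expect_gte(loganic$mw, 370)
  expect_lte(loganic$mw, 382)
  mz <- nominal_deprotonated_mz(met)
  expect_identical(unname(mz[["loganic_acid"]]), 375L)
  expect_identical(unname(mz[["gentiopicroside"]]), 355L)
})

test_that("nominal deprotonated m/z is the nominal mass minus one", {
  expect_identical(unname(nominal_deprotonated_mz(c(water = "O"))), 17L)
  # methane nominal mass 16
  expect_identical(unname(nominal_deprotonated_mz(c(m = "C"))), 15L)
  # benzoic acid C7H6O2: 7*12 + 6 + 32 = 122 -> 121
  expect_identical(unname(nominal_deprotonated_mz(c(ba = "OC(=O)c1ccccc1"))),
                   121L)
})

test_that("features are invariant under atom reordering of the same molecule", {
  variants <- list(
    c("CCO", "OCC", "C(O)C"),
    c("NCC(=O)O", "OC(=O)CN", "C(N)C(O)=O")
  )
  for (v in variants) {
    f <- compute_features(stats::setNames(v, paste0("v", seq_along(v))))
    expect_true(all(abs(f$mw - f$mw[1]) < 1e-9))
    expect_true(all(f$hbd == f$hbd[1]))
    expect_true(all(f$hba == f$hba[1]))
    fp <- lapply(v, morgan_fingerprint)
    expect_identical(fp[[2]], fp[[1]])
    expect_identical(fp[[3]], fp[[1]])
  }
})

test_that("unparsable structures raise an error naming the compound", {
  expect_error(compute_features(c(good = "CCO", broken = "C1CC")),
               "broken", class = "ivs_structure_error")
})

test_that("similarity is symmetric, 1 on self, 0 on disjoint fingerprints", {
  expect_equal(structural_similarity("CCO", "CCO"), 1.0)
  expect_equal(structural_similarity("CCCC", "O"), 0.0)
  ab <- structural_similarity("CC(=O)Oc1ccccc1C(=O)O", "CC(=O)Nc1ccc(O)cc1")
  ba <- structural_similarity("CC(=O)Nc1ccc(O)cc1", "CC(=O)Oc1ccccc1C(=O)O")
  expect_identical(ab, ba)
  expect_true(ab > 0 && ab < 1)
})

test_that("hashed circular fingerprints agree with brute-force environment enumeration", {
  pairs <- list(
    c("CCO", "CCCO"),
    c("CC(=O)Oc1ccccc1C(=O)O", "CC(=O)Nc1ccc(O)cc1"),
    c("OCC1OC(O)C(O)C(O)C1O", "OCC(O)C(O)C(O)C(O)CO"),
    c("c1ccccc1", "C1CCCCC1")
  )
  for (p in pairs) {
    expect_equal(structural_similarity(p[1], p[2]),
                 oracle_tanimoto(p[1], p[2]),
                 tolerance = 1e-12,
                 label = paste(p, collapse = " vs "))
  }
})

test_that("decoy selection matches the exhaustive filter oracle", {
  cand <- toy_candidate_library()
  query <- c(query = "CCCCOC(=O)CCO")
  ds <- select_decoys(query, cand, n = 5)
  qf <- compute_features(query)
  cf <- compute_features(cand)
  sims <- vapply(cand, function(s) structural_similarity(query[[1]], s), 0)
  expected <- oracle_decoys(qf, cf, sims, self = rep(FALSE, length(cand)),
                            n = 5)
  expect_identical(ds$decoys$compound_id, expected)
  # every decoy satisfies all window predicates
  expect_true(all(abs(ds$decoys$mw - qf$mw) <= 25))
  expect_true(all(abs(ds$decoys$hbd - qf$hbd) <= 1))
  expect_true(all(abs(ds$decoys$hba - qf$hba) <= 1))
  expect_true(all(ds$decoys$similarity <= 0.4))
})

test_that("decoy selection is invariant to candidate order and excludes the query", {
  cand <- toy_candidate_library()
  query <- c(query = "CCCCOC(=O)CCO")
  ds1 <- select_decoys(query, cand, n = 5)
  perm <- rev(cand)
  ds2 <- select_decoys(query, perm, n = 5)
  expect_identical(ds1$decoys$compound_id, ds2$decoys$compound_id)
  # query smuggled into the candidate list under another id is excluded
  cand2 <- c(cand, c(sneaky = "CCCCOC(=O)CCO"))
  ds3 <- select_decoys(query, cand2, n = 5)
  expect_false("sneaky" %in% ds3$decoys$compound_id)
  expect_false("query" %in% ds3$decoys$compound_id)
})

test_that("degenerate and infeasible decoy requests are handled", {
  cand <- toy_candidate_library()
  query <- c(query = "CCCCOC(=O)CCO")
  ds0 <- select_decoys(query, cand, n = 0)
  expect_identical(nrow(ds0$decoys), 0L)
  err <- expect_error(select_decoys(query, cand, n = 50),
                      class = "ivs_selection_error")
  expect_match(conditionMessage(err), "pass mw window")
})

test_that("SMILES files round-trip through read_smiles and decoy output", {
  path <- system.file("extdata", "decoy_candidates.smi", package = "ivscreen")
  lib <- read_smiles(path)
  expect_gte(nrow(lib), 30)
  expect_true(all(nzchar(lib$compound_id)))
  ds <- select_decoys(c(q = "CCCCOC(=O)CCO"), toy_candidate_library(), n = 3)
  sdf <- tempfile(fileext = ".sdf"); tsv <- tempfile(fileext = ".tsv")
  write_decoy_set(ds, sdf, tsv)
  back <- read_sdf_compounds(sdf)
  expect_identical(back$compound_id, ds$decoys$compound_id)
  feats <- utils::read.table(tsv, header = TRUE, sep = "\t")
  expect_identical(nrow(feats), 3L)
})
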