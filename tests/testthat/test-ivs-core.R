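test_that("decoy aggregation is the arithmetic mean over one structure", {
  expect_equal(aggregate_decoy_affinity(c(-8.0)), -8.0)
  expect_equal(aggregate_decoy_affinity(c(-5.0, -5.4)), -5.2)
  recs <- lapply(1:10, function(i)
    score_record(sprintf("d%02d", i), "1abc", -6 - i / 10))
  manual <- sum(vapply(recs, `[[`, 0, "v0")) / 10
  expect_identical(aggregate_decoy_affinity(recs), manual)
  expect_error(aggregate_decoy_affinity(list()),
               class = "ivs_aggregation_error")
  mixed <- list(score_record("d1", "1abc", -6), score_record("d2", "2xyz", -7))
  expect_error(aggregate_decoy_affinity(mixed), "multiple structures",
               class = "ivs_aggregation_error")
})

test_that("V reproduces the worked-example machine values", {
  expect_identical(round(compute_v(-7.7, -5.2), 2), 1.48)
  expect_identical(round(compute_v(-8.5, -7.0), 2), 1.21)
  expect_identical(round(compute_v(-8.7, -8.28), 2), 1.05)
  x <- -6.32
  expect_equal(compute_v(x, x), 1.0)
})

test_that("V enforces the negative-affinity sign convention", {
  expect_error(compute_v(-7, 0), "zero", class = "ivs_sign_error")
  err <- expect_error(compute_v(7.7, -5.2), class = "ivs_sign_error")
  expect_match(conditionMessage(err), "7.700")
  expect_error(compute_v(-7.7, 5.2), class = "ivs_sign_error")
})

test_that("threshold filtering is strictly greater-than by default", {
  df <- data.frame(compound_id = "c", pdb_id = c("1aaa", "1bbb", "1ccc"),
                   target_name = c("X", "Y", "Z"), v0 = c(-9, -9, -9),
                   vr = c(-7.5, -10, -11.25), v = c(1.2, 0.9, 0.8),
                   valid = TRUE)
  kept <- filter_by_threshold(df, 0.9)
  expect_identical(kept$pdb_id, "1aaa")  # 0.9 excluded by strictness
  kept2 <- filter_by_threshold(df, 0.9, strict = FALSE)
  expect_identical(kept2$pdb_id, c("1aaa", "1bbb"))
  empty <- df[0, ]
  expect_identical(nrow(filter_by_threshold(empty, 0.9)), 0L)
})

test_that("every printed top-10 row passes the 0.9 filter", {
  t1 <- tables_as_scores("loganic_acid")
  expect_identical(nrow(filter_by_threshold(t1, 0.9)), 10L)
})

test_that("collapsing keeps the maximum-V structure per target", {
  t2 <- tables_as_scores("gentiopicroside")
  r <- collapse_non_redundant(t2, top_k = 10)
  act <- r[tolower(r$target_name) == "alpha-1-antichymotrypsin", ]
  expect_identical(nrow(act), 1L)
  expect_identical(act$pdb_id, "5om2")
  expect_identical(round(act$v, 2), 1.13)
  # all-distinct names: collapse is identity up to sorting
  t1 <- tables_as_scores("loganic_acid")
  distinct <- t1[!duplicated(t1$target_name), ]
  r1 <- collapse_non_redundant(distinct, top_k = Inf)
  expect_setequal(r1$pdb_id, distinct$pdb_id)
})

test_that("collapsing equals the brute-force group-by-max oracle on random tables", {
  set.seed(303)
  for (case in 1:200) {
    n <- sample(2:25, 1)
    df <- data.frame(
      compound_id = "c",
      pdb_id = sprintf("%04x", sample(0x1000:0x1fff, n)),
      target_name = sample(sprintf("tgt %02d", 1:8), n, replace = TRUE),
      v0 = -round(stats::runif(n, 5, 10), 2),
      stringsAsFactors = FALSE
    )
    df$vr <- -round(stats::runif(n, 5, 10), 2)
    df$v <- df$v0 / df$vr
    df$valid <- TRUE
    got <- collapse_non_redundant(df, top_k = 5)
    want <- oracle_collapse(df, top_k = 5)
    expect_identical(got$pdb_id, want$pdb_id)
    expect_identical(got$target_name, want$target_name)
    expect_identical(got$v, want$v)
  }
})

test_that("occurrence percentages tally structures over the filtered set", {
  df <- data.frame(
    compound_id = "c", pdb_id = sprintf("1a%02d", 1:10),
    target_name = c(rep("A", 3), rep("B", 2), LETTERS[3:7]),
    v0 = -8, vr = -7, v = 8 / 7, valid = TRUE
  )
  occ <- occurrence_percentages(df)
  expect_equal(occ$pct[occ$target_name == "A"], 30.0)
  single <- occurrence_percentages(df[1, ])
  expect_equal(single$pct, 100.0)
  expect_warning(empty <- occurrence_percentages(df[0, ]), "empty")
  expect_identical(nrow(empty), 0L)
})

test_that("occurrence percentages match a brute-force tally and sum to 100", {
  set.seed(99)
  n <- 1000
  df <- data.frame(
    compound_id = "c", pdb_id = sprintf("%04x", 0x1000 + 1:n),
    target_name = sample(sprintf("tgt%03d", 1:40), n, replace = TRUE),
    v0 = -8, vr = -7, v = 8 / 7, valid = TRUE
  )
  occ <- occurrence_percentages(df)
  tally <- table(df$target_name)
  expect_identical(stats::setNames(occ$n, occ$target_name)[names(tally)],
                   stats::setNames(as.integer(tally), names(tally)))
  expect_equal(sum(occ$pct), 100, tolerance = 1e-9)
  # collapsing afterwards does not change the percentages
  r <- collapse_non_redundant(df, top_k = Inf)
  expect_equal(sort(r$pct), sort(occ$pct), tolerance = 1e-12)
})

test_that("ranking intersection handles identical, disjoint and worked-example tables", {
  t1 <- collapse_non_redundant(tables_as_scores("loganic_acid"))
  t2 <- collapse_non_redundant(tables_as_scores("gentiopicroside"))
  expect_identical(intersect_rankings(list(t1, t1))$target_name,
                   t1$target_name)
  fake <- t1
  fake$target_name <- paste0("other ", seq_len(nrow(fake)))
  expect_identical(nrow(intersect_rankings(list(t1, fake))), 0L)

  common <- intersect_rankings(list(t1, t2))
  expect_identical(nrow(common), 4L)
  expect_setequal(tolower(common$target_name), tolower(c(
    "Alpha-1-Acid Glycoprotein 2", "Alpha-1-Antichymotrypsin",
    "Prostaglandin H2 Synthase-2",
    "Tumor Necrosis Factor Ligand Superfamily Member 4")))
  expect_false(is.unsorted(common$mean_rank))
})

test_that("V is scale-invariant and exceeds 1 exactly when v0 < vr", {
  set.seed(77)
  for (i in 1:50) {
    v0 <- -stats::runif(1, 1, 12)
    vr <- -stats::runif(1, 1, 12)
    c_ <- stats::runif(1, 0.1, 10)
    expect_equal(compute_v(c_ * v0, c_ * vr), compute_v(v0, vr),
                 tolerance = 1e-12)
    expect_identical(compute_v(v0, vr) > 1, v0 < vr)
  }
  # scaling all affinities leaves the filtered set and ranking unchanged
  df <- tables_as_scores("loganic_acid")
  scaled <- df
  scaled$v0 <- 1.7 * df$v0
  scaled$vr <- 1.7 * df$vr
  scaled$v <- scaled$v0 / scaled$vr
  r1 <- collapse_non_redundant(filter_by_threshold(df, 0.9))
  r2 <- collapse_non_redundant(filter_by_threshold(scaled, 0.9))
  expect_identical(r1$pdb_id, r2$pdb_id)
  expect_equal(r1$v, r2$v, tolerance = 1e-12)
})

test_that("normalization joins decoy means and flags convention violations", {
  q <- data.frame(compound_id = "c", pdb_id = c("1aaa", "1bbb", "1ccc"),
                  v0 = c(-8, -9, 2))
  d <- data.frame(compound_id = c("d1", "d2", "d1"),
                  pdb_id = c("1aaa", "1aaa", "1ccc"), v0 = c(-6, -8, -7))
  expect_warning(expect_warning(
    norm <- normalize_scores(q, d), "lack decoy"), "flagged invalid")
  expect_equal(norm$vr[norm$pdb_id == "1aaa"], -7)
  expect_equal(norm$v[norm$pdb_id == "1aaa"], 8 / 7)
  expect_true(is.na(norm$v[norm$pdb_id == "1bbb"]))   # no decoys
  expect_false(norm$valid[norm$pdb_id == "1ccc"])     # positive affinity
})

test_that("re-normalizing the printed tables reproduces V within the print granularity", {
  tab <- gentiana_tables()
  v <- round(compute_v(tab$v0, tab$vr), 2)
  expect_true(all(abs(v - tab$v_printed) <= 0.01 + 1e-12))
})
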