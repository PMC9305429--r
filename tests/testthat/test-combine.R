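run_once <- function(seed = 1) {
  run_all(seed = seed, bootstrap = 10L)
}

res <- run_once()

test_that("genetic singletons are resolved by genetics alone", {
  v <- res$verdicts[["CAN"]]
  expect_equal(v$resolution, "species_resolved")
  expect_equal(v$candidate_taxa, "CAN")
  expect_match(paste(v$evidence, collapse = " "), "resolved by genetics")
})

test_that("chemistry splits the White/Abrial chemotype inside group F", {
  v <- res$verdicts[["ANG_W"]]
  expect_equal(v$resolution, "group_only")
  expect_setequal(v$genetic_group, c("ANG_W", "INT_A", "INT_G"))
  expect_equal(sort(v$candidate_taxa), c("ANG_W", "INT_A"))
  # Grosso carries the rosmarinic-acid + cinnamic-pair sub-pattern and is
  # the only group-F member with it: combined evidence resolves it
  vg <- res$verdicts[["INT_G"]]
  expect_equal(vg$resolution, "species_resolved")
  expect_equal(vg$candidate_taxa, "INT_G")
})

test_that("a genetic singleton with unassigned chemistry stays resolved", {
  genetic <- discrimination_summary(c(X = "AAAA", Y = "CCCC"))
  chem <- list(
    X = assign_cluster(c(c1 = TRUE, c2 = FALSE, c3 = TRUE, c4 = FALSE,
                         c5 = TRUE, c6 = FALSE, c7 = TRUE),
                       lav_criteria_key(), max_hamming = 1L,
                       sample_id = "X"),
    Y = assign_cluster(c(c1 = FALSE, c2 = TRUE, c3 = FALSE, c4 = TRUE,
                         c5 = FALSE, c6 = FALSE, c7 = FALSE),
                       lav_criteria_key(), sample_id = "Y")
  )
  expect_true(is.na(chem$X$cluster))
  v <- authenticate(genetic, chem)
  expect_equal(v$X$resolution, "species_resolved")
  expect_match(paste(v$X$evidence, collapse = " "), "low-confidence")
})

test_that("mismatched sample coverage is an error", {
  genetic <- discrimination_summary(c(X = "AAAA", Y = "CCCC"))
  chem <- list(X = assign_cluster(c(c1 = FALSE, c2 = TRUE, c3 = FALSE,
                                    c4 = TRUE, c5 = FALSE, c6 = FALSE,
                                    c7 = FALSE),
                                  lav_criteria_key(), sample_id = "X"))
  expect_error(authenticate(genetic, chem), "Y")
})

test_that("panel counts conserve and residual groups match expectation", {
  rep <- res$report
  expect_equal(rep$n_species_resolved + rep$n_group_only + rep$n_conflict,
               rep$n_samples)
  expect_equal(rep$n_samples, 11L)
  expect_equal(rep$n_resolved_by_genetics, 6L)
  expect_equal(rep$n_conflict, 0L)
  expect_setequal(
    vapply(rep$unresolved_groups, paste, character(1), collapse = ","),
    c("ALL,DEN", "ANG_W,INT_A")
  )
  expect_error(panel_report(list()), "no verdicts")
})

test_that("combined resolution never falls below genetic-only resolution", {
  for (seed in c(2, 5)) {
    r <- run_once(seed)
    expect_gte(r$report$n_species_resolved,
               length(r$genetic$all$fully_differentiated))
  }
})

test_that("repeated zero-noise runs are identical", {
  r2 <- run_once()
  expect_identical(res$amplicons, r2$amplicons)
  expect_identical(res$supports, r2$supports)
  expect_identical(lapply(res$verdicts, unclass),
                   lapply(r2$verdicts, unclass))
})
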