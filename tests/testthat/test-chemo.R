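lib <- lav_compound_library()
key <- lav_criteria_key()
panel <- lavandula_panel()
crit_cols <- paste0("c", 1:7)

zero_noise_tables <- function(seed = 1) {
  cfg <- generator_config(seed = seed, rt_jitter_sd = 0, n_noise_peaks = 0L)
  tabs <- lapply(seq_len(nrow(panel)), function(i)
    make_peak_table(panel[i, ], lib, cfg))
  stats::setNames(tabs, panel$taxon_id)
}

test_that("peaks are matched by retention-time proximity", {
  tb <- data.frame(rt_min = c(3.24, 3.40), area = c(500, 900))
  m <- match_peaks(tb, lib, rt_tolerance = 0.05)
  expect_equal(unname(m[["8"]]), 500) # 3.24 is within 0.05 of 3.23
  tb2 <- data.frame(rt_min = 3.40, area = 900)
  expect_equal(unname(match_peaks(tb2, lib, 0.05)[["8"]]), 0)
  # two peaks within tolerance: larger area wins
  tb3 <- data.frame(rt_min = c(3.21, 3.25), area = c(100, 700))
  expect_equal(unname(match_peaks(tb3, lib, 0.05)[["8"]]), 700)
  # one peak can serve two co-eluting compounds (94 and 95 share 12.85)
  tb4 <- data.frame(rt_min = 12.85, area = 42)
  m4 <- match_peaks(tb4, lib, 0.05)
  expect_equal(unname(m4[["94"]]), 42)
  expect_equal(unname(m4[["95"]]), 42)
  expect_error(match_peaks(tb, lib[0, ], 0.05), "empty")
})

test_that("marker-compound selection flags the seven discriminant compounds", {
  tabs <- zero_noise_tables()
  sel <- select_marker_compounds(tabs, lib)
  expect_setequal(sel, c(8L, 14L, 15L, 16L, 21L, 37L, 53L))
  expect_equal(length(sel), 7L)
  # threshold 0: every compound with any matched peak
  sel0 <- select_marker_compounds(tabs, lib, presence_threshold = 0)
  expect_setequal(sel0, lib$compound_id)
  # a single empty table selects nothing
  empty <- list(s = data.frame(rt_min = numeric(0), area = numeric(0)))
  expect_equal(length(select_marker_compounds(empty, lib)), 0L)
})

test_that("criteria evaluation reproduces the reference key cell-for-cell", {
  tabs <- zero_noise_tables()
  for (tx in names(tabs)) {
    prof <- evaluate_criteria(match_peaks(tabs[[tx]], lib), lib)
    want <- as.logical(key[key$taxon_id == tx, crit_cols])
    names(want) <- crit_cols
    expect_identical(prof, want, label = tx)
  }
})

test_that("criteria semantics: zero matches, mutual exclusion of c3/c4", {
  zero <- stats::setNames(numeric(nrow(lib)), lib$compound_id)
  prof <- evaluate_criteria(zero, lib)
  expect_identical(unname(prof), c(FALSE, FALSE, FALSE, TRUE, FALSE,
                                   FALSE, FALSE))
  tabs <- zero_noise_tables(seed = 9)
  for (tx in names(tabs)) {
    prof <- evaluate_criteria(match_peaks(tabs[[tx]], lib), lib)
    # never both: c4 is the joint absence of the pair whose joint presence
    # is c3; profiles with a single trace member satisfy neither
    expect_false(prof[["c3"]] && prof[["c4"]])
    if (any(as.logical(key[key$taxon_id == tx, c("c3", "c4")]))) {
      expect_true(xor(prof[["c3"]], prof[["c4"]]))
    }
  }
})

test_that("cluster assignment recovers every printed row at distance zero", {
  tabs <- zero_noise_tables()
  clusters <- integer(0)
  for (tx in names(tabs)) {
    prof <- evaluate_criteria(match_peaks(tabs[[tx]], lib), lib)
    assg <- assign_cluster(prof, key, sample_id = tx)
    expect_equal(assg$hamming_distance, 0L, label = tx)
    expect_equal(assg$cluster, key$cluster[key$taxon_id == tx], label = tx)
    clusters <- c(clusters, assg$cluster)
  }
  expect_equal(length(unique(clusters)), 6L)
})

test_that("a profile far from every key row stays unassigned", {
  prof <- c(c1 = TRUE, c2 = FALSE, c3 = TRUE, c4 = FALSE, c5 = TRUE,
            c6 = FALSE, c7 = TRUE)
  dists <- apply(key[, crit_cols], 1, function(r)
    sum(as.logical(r) != prof))
  stopifnot(min(dists) >= 2) # sanity of the crafted profile
  assg <- assign_cluster(prof, key, max_hamming = 1L)
  expect_true(is.na(assg$cluster))
  expect_error(assign_cluster(prof, key[0, ]), "empty")
})

test_that("distant noise peaks never change an assignment", {
  quiet <- assign_samples(zero_noise_tables(), lib, key)
  cfg <- generator_config(seed = 31, rt_jitter_sd = 0, n_noise_peaks = 10L)
  noisy_tabs <- stats::setNames(lapply(seq_len(nrow(panel)), function(i)
    make_peak_table(panel[i, ], lib, cfg)), panel$taxon_id)
  noisy <- assign_samples(noisy_tabs, lib, key)
  for (tx in panel$taxon_id) {
    expect_equal(noisy[[tx]]$cluster, quiet[[tx]]$cluster)
    expect_identical(noisy[[tx]]$criteria, quiet[[tx]]$criteria)
  }
})

test_that("the key loader applies cell overrides", {
  k2 <- lav_criteria_key(override = data.frame(taxon_id = "ANG_W",
                                               c6 = FALSE))
  expect_false(k2$c6[k2$taxon_id == "ANG_W"])
  expect_true(key$c6[key$taxon_id == "ANG_W"])
  expect_error(lav_criteria_key(override = data.frame(taxon_id = "nope",
                                                      c1 = TRUE)),
               "unknown taxon")
})
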