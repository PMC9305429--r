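panel <- lavandula_panel()
markers <- lavandula_markers()

test_that("the panel encodes the study structure", {
  expect_equal(nrow(panel), 11L)
  expect_setequal(panel$taxon_id[panel$class_plastid == "A"],
                  c("ANG_W", "INT_A", "INT_G"))
  expect_setequal(panel$taxon_id[panel$class_plastid == "B"],
                  c("ANG_B", "LAT"))
  expect_setequal(panel$taxon_id[panel$class_plastid == "C"],
                  c("ALL", "DEN"))
  expect_setequal(panel$taxon_id[panel$class_its == "D"],
                  c("ANG_W", "ANG_B", "INT_A", "INT_G"))
  expect_setequal(panel$taxon_id[panel$class_its == "E"],
                  c("ALL", "DEN"))
})

test_that("same seed and inputs give byte-identical references", {
  cfg <- generator_config(seed = 77)
  r1 <- make_marker_references(cfg, panel, markers$B1)
  r2 <- make_marker_references(cfg, panel, markers$B1)
  expect_identical(r1, r2)
  r3 <- make_marker_references(generator_config(seed = 78), panel,
                               markers$B1)
  expect_false(identical(unname(r1), unname(r3)))
})

test_that("class structure holds: identical within, distinct between", {
  for (seed in c(1, 13)) {
    cfg <- generator_config(seed = seed)
    for (m in names(markers)) {
      refs <- make_marker_references(cfg, panel, markers[[m]])
      amps <- vapply(names(refs), function(tx)
        in_silico_pcr(refs[[tx]], markers[[m]])$sequence, character(1))
      cls <- panel[[if (m == "Lav") "class_its" else "class_plastid"]]
      for (cl in unique(cls)) {
        expect_equal(length(unique(amps[cls == cl])), 1L)
      }
      per_class <- tapply(amps, cls, function(x) x[1])
      expect_equal(anyDuplicated(per_class), 0L)
    }
  }
})

test_that("amplicon length below combined primer length is a config error", {
  cfg <- generator_config(seed = 1, amplicon_lengths = c(B1 = 30L))
  expect_error(make_marker_references(cfg, panel, markers$B1),
               "shorter than the combined")
})

test_that("within-class divergence other than zero is rejected", {
  expect_error(generator_config(seed = 1, within_class_divergence = 0.01),
               "fixed at 0")
})

test_that("read pairs are deterministic and overlap sufficiently", {
  cfg <- generator_config(seed = 4, read_error_rate = 0.01)
  set.seed(1)
  ref <- random_dna_string(690)
  p1 <- make_read_pairs(ref, cfg)
  p2 <- make_read_pairs(ref, cfg)
  expect_identical(p1, p2)
  expect_gte(nchar(p1$forward) + nchar(p1$reverse), 690 + 30)
  # errors never fall inside the overlap, so the merge still succeeds
  merged <- merge_reads(p1$forward, p1$reverse)
  expect_equal(nchar(merged), 690L)
})

test_that("zero-noise peak tables sit exactly at library retention times", {
  cfg <- generator_config(seed = 2, rt_jitter_sd = 0, n_noise_peaks = 0L)
  lib <- lav_compound_library()
  for (i in seq_len(nrow(panel))) {
    tb <- make_peak_table(panel[i, ], lib, cfg)
    expect_true(all(tb$rt_min %in% lib$rt_min))
    expect_true(all(tb$area > 0))
  }
})

test_that("noise peaks keep a 3-tolerance guard band around the library", {
  cfg <- generator_config(seed = 6, n_noise_peaks = 8L)
  lib <- lav_compound_library()
  tb <- make_peak_table(panel[panel$taxon_id == "STO", ], lib, cfg)
  matched_rts <- lib$rt_min
  is_noise <- vapply(tb$rt_min, function(rt)
    all(abs(rt - matched_rts) > 2 * cfg$rt_tolerance), logical(1))
  expect_equal(sum(is_noise), 8L)
  noise_rts <- tb$rt_min[is_noise]
  for (rt in noise_rts) {
    expect_true(all(abs(rt - lib$rt_min) >= 3 * cfg$rt_tolerance))
  }
})

test_that("a profile referencing a compound missing from the library fails", {
  cfg <- generator_config(seed = 1)
  lib <- lav_compound_library()
  lib <- lib[lib$compound_id != 53, ]
  expect_error(make_peak_table(panel[panel$taxon_id == "PIN", ], lib, cfg),
               "missing from the library")
})

test_that("simulate_study writes the fixture set and a manifest", {
  outdir <- withr::local_tempdir()
  sim <- simulate_study(seed = 3, outdir = outdir)
  manifest <- jsonlite::read_json(file.path(outdir, "manifest.json"))
  expect_equal(manifest$seed, 3L)
  expect_true(all(file.exists(file.path(outdir, unlist(manifest$files)))))
  refs <- read_fasta(file.path(outdir, "references_B1.fasta"))
  expect_equal(length(refs), 11L)
  expect_identical(as.vector(refs), as.vector(sim$references$B1))
  tb <- read_peak_table(file.path(outdir, "peaks_PER.csv"))
  expect_equal(attr(tb, "sample_id"), "PER")
})
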