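test_that("two taxa form a cherry at half their distance", {
  d <- matrix(c(0, 0.01, 0.01, 0), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  tree <- build_upgma(d)
  expect_equal(length(tree$merges), 1L)
  expect_equal(tree$merges[[1]]$height, 0.005)
  expect_setequal(tree$merges[[1]]$leafset, c("A", "B"))
  expect_equal(unname(tree$phylo$edge.length), c(0.005, 0.005))
})

test_that("a zero-distance pair is joined first at height zero", {
  labels <- c("A", "B", "C")
  d <- matrix(c(0, 0, 0.1, 0, 0, 0.1, 0.1, 0.1, 0), 3, 3,
              dimnames = list(labels, labels))
  tree <- build_upgma(d)
  expect_equal(tree$merges[[1]]$leafset, c("A", "B"))
  expect_equal(tree$merges[[1]]$height, 0)
})

test_that("UPGMA equals the naive from-scratch oracle on random matrices", {
  for (seed in 1:100) {
    n <- 3 + (seed %% 4) # 3..6 taxa
    d <- random_distance_matrix(n, seed)
    got <- lavauth::build_upgma(d)$merges
    want <- oracle_upgma(d)
    expect_identical(merge_keys(got), merge_keys(want))
    expect_equal(merge_heights(got), merge_heights(want),
                 tolerance = 1e-12)
  }
})

test_that("UPGMA agrees with average-linkage hclust on tie-free input", {
  d <- random_distance_matrix(7, 2024)
  tree <- build_upgma(d)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  expect_equal(sort(vapply(tree$merges, function(m) m$height, numeric(1))),
               sort(hc$height / 2), tolerance = 1e-12)
})

test_that("trees are ultrametric with heights non-decreasing toward root", {
  for (seed in c(5, 17, 99)) {
    d <- random_distance_matrix(6, seed)
    tree <- build_upgma(d)
    heights <- vapply(tree$merges, function(m) m$height, numeric(1))
    sizes <- vapply(tree$merges, function(m) length(m$leafset), integer(1))
    # every superset clade is at least as high as its sub-clades
    for (i in seq_along(tree$merges)) {
      for (j in seq_along(tree$merges)) {
        if (all(tree$merges[[i]]$leafset %in% tree$merges[[j]]$leafset) &&
            sizes[i] < sizes[j]) {
          expect_lte(heights[i], heights[j] + 1e-12)
        }
      }
    }
    # ultrametric: all root-to-tip path lengths equal the root height
    phylo <- tree$phylo
    depths <- ape::node.depth.edgelength(phylo)
    tip_depths <- depths[seq_along(phylo$tip.label)]
    expect_true(all(abs(tip_depths - max(heights)) < 1e-9))
  }
})

test_that("adding a constant to all off-diagonal distances keeps topology", {
  for (seed in c(3, 8, 21)) {
    d <- random_distance_matrix(6, seed)
    shifted <- d + 0.3
    diag(shifted) <- 0
    expect_identical(merge_keys(build_upgma(d)$merges),
                     merge_keys(build_upgma(shifted)$merges))
  }
})

test_that("invalid distance matrices are rejected", {
  d <- random_distance_matrix(4, 1)
  d_neg <- d; d_neg[1, 2] <- d_neg[2, 1] <- -0.1
  expect_error(build_upgma(d_neg), "negative")
  d_asym <- d; d_asym[1, 2] <- d_asym[1, 2] + 0.05
  expect_error(build_upgma(d_asym), "symmetric")
})
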