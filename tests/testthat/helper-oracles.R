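# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (no iupac_compat, no Lance-Williams update).

# exhaustive-offset scan for primer binding under IUPAC semantics
oracle_iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_primer_scan <- function(sequence, primer, max_mismatches) {
  s <- strsplit(sequence, "")[[1]]
  p <- strsplit(primer, "")[[1]]
  if (length(p) > length(s)) return(NULL)
  best <- NULL
  for (off in seq_len(length(s) - length(p) + 1L)) {
    mm <- 0L
    for (k in seq_along(p)) {
      if (!s[off + k - 1L] %in% oracle_iupac_sets[[p[k]]]) mm <- mm + 1L
    }
    if (mm <= max_mismatches && (is.null(best) || mm < best$mismatches)) {
      best <- list(start = off, end = off + length(p) - 1L, mismatches = mm)
    }
  }
  best
}

# naive UPGMA: cluster distances recomputed from the original matrix as the
# mean over all cross-cluster pairs; same tie-break contract (lexicographic
# smallest pair of cluster labels, a cluster labelled by its smallest member)
oracle_upgma <- function(d) {
  clusters <- as.list(rownames(d))
  merges <- list()
  while (length(clusters) > 1L) {
    k <- length(clusters)
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        dij <- mean(d[clusters[[i]], clusters[[j]]])
        lab <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        better <- is.null(best) || dij < best$d ||
          (dij == best$d && (lab[1] < best$lab[1] ||
            (lab[1] == best$lab[1] && lab[2] < best$lab[2])))
        if (better) best <- list(i = i, j = j, d = dij, lab = lab)
      }
    }
    newc <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    merges[[length(merges) + 1L]] <- list(leafset = newc,
                                          height = best$d / 2)
    clusters <- c(clusters[-c(best$i, best$j)], list(newc))
  }
  merges
}

merge_keys <- function(merges) {
  vapply(merges, function(m) paste(m$leafset, collapse = "|"), character(1))
}

merge_heights <- function(merges) {
  stats::setNames(vapply(merges, function(m) m$height, numeric(1)),
                  merge_keys(merges))
}

random_distance_matrix <- function(n, seed) {
  set.seed(seed)
  labels <- LETTERS[seq_len(n)]
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  vals <- round(stats::runif(n * (n - 1) / 2, 0.001, 0.2), 4)
  d[upper.tri(d)] <- vals
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# partition encoded in the panel for a given marker-set intersection
panel_partition <- function(panel, cols) {
  split(panel$taxon_id,
        apply(panel[, cols, drop = FALSE], 1, paste, collapse = "/"))
}

partition_key <- function(groups) {
  sorted <- lapply(groups, sort)
  paste(sort(vapply(sorted, paste, character(1), collapse = ",")),
        collapse = ";")
}
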