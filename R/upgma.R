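#' UPGMA clustering of a distance matrix
#'
#' Unweighted pair-group method with arithmetic mean: the pair of clusters at
#' minimal distance is joined iteratively; the distance from a merged cluster
#' to any other is the size-weighted arithmetic mean of its members'
#' distances (equivalently, the mean over all cross-cluster pairs of the
#' original matrix). The node joining two clusters at distance d sits at
#' height d/2, so the result is a rooted, binary, ultrametric tree. Ties on
#' the minimal distance are broken by the lexicographically smallest label
#' pair, where a cluster is labelled by its smallest member label; this makes
#' the output reproducible regardless of input order.
#'
#' @param d Symmetric numeric matrix of pairwise distances with zero diagonal
#'   and unique dimnames (e.g. from \code{\link{p_distance_matrix}}).
#' @return An object of class \code{"upgma_tree"}: a list with
#'   \code{phylo} (an \pkg{ape} tree with branch lengths), \code{merges}
#'   (the clades in join order, each a list with sorted \code{leafset} and
#'   \code{height}) and \code{labels}.
#' @export
#' @examples
#' d <- matrix(c(0, 0.01, 0.01, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
#' build_upgma(d)
build_upgma <- function(d) {
  merges <- upgma_merge(d)
  newick <- paste0(attr(merges, "newick"), ";")
  phylo <- ape::read.tree(text = newick)
  structure(
    list(phylo = phylo, merges = merges, labels = sort(rownames(d))),
    class = "upgma_tree"
  )
}

#' @export
print.upgma_tree <- function(x, ...) {
  root_h <- x$merges[[length(x$merges)]]$height
  cat(sprintf("<UPGMA tree: %d tips, root height %.6g>\n",
              length(x$labels), root_h))
  invisible(x)
}

# core agglomeration; returns the list of merges (leafset, height) in join
# order with the newick string as an attribute
upgma_merge <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("distance input must be a square matrix", call. = FALSE)
  }
  labels <- rownames(d)
  if (is.null(labels) || anyDuplicated(labels) ||
      !identical(labels, colnames(d))) {
    stop("distance matrix needs matching, unique dimnames", call. = FALSE)
  }
  if (nrow(d) < 2L) {
    stop("need at least two taxa", call. = FALSE)
  }
  if (any(d < 0)) {
    stop("negative distances are not allowed", call. = FALSE)
  }
  if (any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal",
         call. = FALSE)
  }

  n <- length(labels)
  cl <- vector("list", 2L * n - 1L)
  for (i in seq_len(n)) {
    cl[[i]] <- list(members = labels[i], label = labels[i], size = 1L,
                    height = 0, newick = labels[i])
  }
  active <- seq_len(n)
  D <- d
  dimnames(D) <- list(as.character(active), as.character(active))
  merges <- vector("list", n - 1L)
  nxt <- n

  for (step in seq_len(n - 1L)) {
    k <- length(active)
    if (k == 1L) break
    Dm <- D
    diag(Dm) <- Inf
    dmin <- min(Dm)
    idx <- which(Dm == dmin, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    # tie-break: lexicographically smallest (sorted) cluster-label pair
    pair_labels <- t(apply(idx, 1, function(ij) {
      sort(c(cl[[active[ij[1]]]]$label, cl[[active[ij[2]]]]$label))
    }))
    ord <- order(pair_labels[, 1], pair_labels[, 2])
    pick <- idx[ord[1], ]
    i <- pick[1]; j <- pick[2]
    ci <- active[i]; cj <- active[j]

    h <- dmin / 2
    nxt <- nxt + 1L
    bl_i <- h - cl[[ci]]$height
    bl_j <- h - cl[[cj]]$height
    children <- c(ci, cj)
    children <- children[order(c(cl[[ci]]$label, cl[[cj]]$label))]
    new_newick <- sprintf(
      "(%s:%.15g,%s:%.15g)",
      cl[[children[1]]]$newick, h - cl[[children[1]]]$height,
      cl[[children[2]]]$newick, h - cl[[children[2]]]$height
    )
    members <- sort(c(cl[[ci]]$members, cl[[cj]]$members))
    cl[[nxt]] <- list(
      members = members, label = min(members),
      size = cl[[ci]]$size + cl[[cj]]$size, height = h, newick = new_newick
    )
    merges[[step]] <- list(leafset = members, height = h)

    # Lance-Williams update, sizes as weights (arithmetic-mean linkage)
    others <- active[-c(i, j)]
    if (length(others) > 0L) {
      wi <- cl[[ci]]$size; wj <- cl[[cj]]$size
      dnew <- (wi * D[as.character(others), as.character(ci)] +
                 wj * D[as.character(others), as.character(cj)]) / (wi + wj)
      keep <- as.character(others)
      D <- D[keep, keep, drop = FALSE]
      D <- rbind(cbind(D, dnew), c(dnew, 0))
      dimnames(D) <- list(c(keep, as.character(nxt)),
                          c(keep, as.character(nxt)))
    } else {
      D <- matrix(0, 1, 1, dimnames = list(as.character(nxt),
                                           as.character(nxt)))
    }
    active <- c(others, nxt)
  }

  attr(merges, "newick") <- cl[[nxt]]$newick
  merges
}

#' Node heights of a UPGMA tree
#'
#' @param tree An \code{"upgma_tree"}.
#' @return Named numeric vector: clade key (sorted leaf labels joined by
#'   \code{"|"}) -> height in substitutions per site.
#' @export
node_heights <- function(tree) {
  stopifnot(inherits(tree, "upgma_tree"))
  vapply(tree$merges, function(m) m$height, numeric(1)) |>
    stats::setNames(vapply(tree$merges, function(m)
      paste(m$leafset, collapse = "|"), character(1)))
}

clade_keys <- function(merges) {
  vapply(merges, function(m) paste(m$leafset, collapse = "|"), character(1))
}

#' Nonparametric bootstrap support for UPGMA clades
#'
#' Columns of the alignment are resampled with replacement (keeping the
#' alignment length), p-distances and the UPGMA tree are recomputed, and the
#' support of each internal clade of the original tree is the percentage of
#' replicates whose tree contains exactly the same leaf set. Deterministic
#' for a given seed; each replicate draws from its own seeded substream.
#'
#' @param alignment Named character vector of equal-length sequences.
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return Named numeric vector of supports in [0, 100]; names are clade keys
#'   (sorted leaf labels joined by \code{"|"}). Attribute
#'   \code{"n_replicates"} records the replicate count.
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000L, seed = 1L) {
  if (length(alignment) < 2L) {
    stop("need at least two sequences", call. = FALSE)
  }
  if (n_replicates < 1L) {
    stop("n_replicates must be >= 1", call. = FALSE)
  }
  enc <- encode_alignment(alignment)
  L <- ncol(enc)
  orig <- upgma_merge(pdist_from_encoded(enc))
  keys <- clade_keys(orig)
  counts <- stats::setNames(integer(length(keys)), keys)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(rep_seeds[r])
    cols <- sample.int(L, L, replace = TRUE)
    rep_keys <- clade_keys(upgma_merge(pdist_from_encoded(
      enc[, cols, drop = FALSE])))
    hit <- keys %in% rep_keys
    counts[hit] <- counts[hit] + 1L
  }
  out <- 100 * counts / n_replicates
  attr(out, "n_replicates") <- as.integer(n_replicates)
  out
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' Attach bootstrap supports to a UPGMA tree as node labels
#'
#' @param tree An \code{"upgma_tree"}.
#' @param supports Output of \code{\link{bootstrap_support}}.
#' @return The tree with \code{phylo$node.label} set to rounded integer
#'   percentages (empty where a clade has no support entry).
#' @export
annotate_supports <- function(tree, supports) {
  stopifnot(inherits(tree, "upgma_tree"))
  phylo <- tree$phylo
  parts <- ape::prop.part(phylo)
  tip_labels <- phylo$tip.label
  labs <- vapply(parts, function(tips) {
    key <- paste(sort(tip_labels[tips]), collapse = "|")
    if (key %in% names(supports)) {
      sprintf("%d", as.integer(round(supports[[key]])))
    } else {
      ""
    }
  }, character(1))
  tree$phylo$node.label <- labs
  tree
}
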