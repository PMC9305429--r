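#' Partition taxa into identical-sequence (haplotype) groups
#'
#' Two taxa fall in the same group if and only if their sequences over the
#' analysed region are bit-identical. An N never matches anything, including
#' another N: an ambiguous base cannot demonstrate identity, so any sequence
#' containing N forms its own singleton group. Taxa in singleton groups are
#' "fully differentiated" by the marker set; multi-member groups are the
#' unresolved clusters.
#'
#' @param sequences Named character vector of equal-length sequences (one per
#'   taxon), e.g. amplicons of one marker or a multi-marker concatenation.
#' @param marker_set Character vector naming the markers the sequences cover
#'   (metadata only).
#' @return An object of class \code{"haplotype_groups"}: list with
#'   \code{marker_set}, \code{groups} (list of sorted taxon-id vectors,
#'   ordered by smallest member), \code{fully_differentiated} (taxa in
#'   singleton groups) and \code{n_taxa}.
#' @export
discrimination_summary <- function(sequences, marker_set = NA_character_) {
  if (length(sequences) == 0L) {
    stop("no sequences supplied", call. = FALSE)
  }
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("sequences must carry unique taxon names", call. = FALSE)
  }
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("sequences have unequal lengths", call. = FALSE)
  }
  seqs <- toupper(sequences)
  has_n <- grepl("[^ACGT]", seqs)
  groups <- list()
  # ambiguous sequences can never be shown identical to anything
  for (tx in names(seqs)[has_n]) {
    groups[[length(groups) + 1L]] <- tx
  }
  clean <- seqs[!has_n]
  if (length(clean) > 0L) {
    for (s in unique(unname(clean))) {
      groups[[length(groups) + 1L]] <- sort(names(clean)[clean == s])
    }
  }
  groups <- groups[order(vapply(groups, min, character(1)))]
  singletons <- unlist(groups[lengths(groups) == 1L], use.names = FALSE)
  structure(
    list(
      marker_set = marker_set,
      groups = groups,
      fully_differentiated = sort(singletons %||% character(0)),
      n_taxa = length(sequences)
    ),
    class = "haplotype_groups"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.haplotype_groups <- function(x, ...) {
  cat(sprintf(
    "<haplotype groups over %s: %d taxa, %d fully differentiated, %d shared group(s)>\n",
    paste(x$marker_set, collapse = "+"), x$n_taxa,
    length(x$fully_differentiated),
    sum(lengths(x$groups) > 1L)
  ))
  for (g in x$groups[lengths(x$groups) > 1L]) {
    cat("  {", paste(g, collapse = ", "), "}\n")
  }
  invisible(x)
}
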