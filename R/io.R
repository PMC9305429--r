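#' Read a FASTA file
#'
#' Thin wrapper over \pkg{Biostrings} enforcing the pipeline's contracts:
#' unique record ids (first whitespace-delimited token of the header),
#' nonempty sequences, uppercase normalization.
#'
#' @param path FASTA file path.
#' @return Named character vector (ids -> sequences); full headers are kept
#'   in attribute \code{"descriptions"}.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA file contains no records: ", path, call. = FALSE)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicate record ids in ", path, call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop("record with blank sequence in ", path, call. = FALSE)
  }
  names(seqs) <- ids
  attr(seqs, "descriptions") <- headers
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param records Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(records, path) {
  if (is.null(names(records)) || any(!nzchar(names(records)))) {
    stop("all records must be named", call. = FALSE)
  }
  if (anyDuplicated(names(records))) {
    stop("duplicate record ids", call. = FALSE)
  }
  if (any(!nzchar(records))) {
    stop("blank sequences cannot be written", call. = FALSE)
  }
  set <- Biostrings::DNAStringSet(toupper(records))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a UPGMA tree to Newick
#'
#' Branch lengths are parent height minus child height (full precision);
#' bootstrap supports, when given, are written as integer internal-node
#' labels.
#'
#' @param tree An \code{"upgma_tree"} (see \code{\link{build_upgma}}).
#' @param path Output path.
#' @param supports Optional output of \code{\link{bootstrap_support}}.
#' @return Invisibly, \code{path}.
#' @export
write_newick <- function(tree, path, supports = NULL) {
  stopifnot(inherits(tree, "upgma_tree"))
  if (is.null(tree$phylo$tip.label) || any(!nzchar(tree$phylo$tip.label))) {
    stop("tree has unnamed leaves", call. = FALSE)
  }
  if (!is.null(supports)) {
    tree <- annotate_supports(tree, supports)
  }
  ape::write.tree(tree$phylo, file = path)
  invisible(path)
}

#' Read a peak-table CSV
#'
#' Expected columns: \code{sample_id}, \code{rt_min}, \code{area} and
#' optionally \code{mz}; comma-separated, header required, '.' decimal.
#'
#' @param path CSV path.
#' @return Data frame of class \code{"lav_peak_table"} with attribute
#'   \code{"sample_id"}.
#' @export
read_peak_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "rt_min", "area")
  if (!all(required %in% names(df))) {
    stop("peak table must have columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  if (length(unique(df$sample_id)) != 1L) {
    stop("peak table must describe exactly one sample", call. = FALSE)
  }
  if (any(df$area < 0)) {
    stop("negative peak areas", call. = FALSE)
  }
  if (any(df$rt_min < 0 | df$rt_min > 20)) {
    stop("retention times outside the 0-20 min run window", call. = FALSE)
  }
  sid <- df$sample_id[1]
  df$sample_id <- NULL
  attr(df, "sample_id") <- sid
  class(df) <- c("lav_peak_table", "data.frame")
  df
}

#' Write a peak table to CSV
#'
#' @param table A peak table with attribute \code{"sample_id"}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_peak_table <- function(table, path) {
  sid <- attr(table, "sample_id")
  if (is.null(sid)) {
    stop("peak table lacks a sample_id attribute", call. = FALSE)
  }
  out <- data.frame(sample_id = sid, rt_min = table$rt_min,
                    area = table$area)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a discrimination report as JSON
#'
#' @param hg A \code{\link{discrimination_summary}} result.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_discrimination_report <- function(hg, path) {
  stopifnot(inherits(hg, "haplotype_groups"))
  jsonlite::write_json(
    list(marker_set = hg$marker_set, groups = hg$groups,
         fully_differentiated = hg$fully_differentiated),
    path, auto_unbox = FALSE, pretty = TRUE
  )
  invisible(path)
}

#' Write per-sample authentication verdicts as JSON
#'
#' @param verdicts Named list from \code{\link{authenticate}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_verdicts <- function(verdicts, path) {
  payload <- lapply(verdicts, function(v) {
    list(
      sample_id = v$sample_id,
      genetic_group = v$genetic_group,
      chemical_cluster = if (is.na(v$chemical_cluster)) "unassigned"
                         else v$chemical_cluster,
      resolution = v$resolution,
      candidate_taxa = v$candidate_taxa,
      evidence = v$evidence
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
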