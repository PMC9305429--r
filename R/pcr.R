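#' Find the best binding site of a (degenerate) primer
#'
#' Scans the plus strand of \code{sequence} for the lowest-mismatch binding
#' site of \code{primer} under IUPAC semantics: a degenerate primer base is
#' compatible with any concrete subject base in its expansion (W matches A or
#' T, R matches A or G, ...). Degenerate positions therefore never count as
#' mismatches when the subject base is in the allowed set. The caller is
#' responsible for reverse-complementing the primer to search the minus
#' strand.
#'
#' @param sequence Subject DNA (A/C/G/T/N), a single string.
#' @param primer Primer sequence, 5'-3', IUPAC codes allowed.
#' @param max_mismatches Maximum number of incompatible positions allowed
#'   (default 2).
#' @return \code{NULL} if no site qualifies (including when the primer is
#'   longer than the sequence); otherwise a list with \code{start},
#'   \code{end} (1-based, closed) and \code{mismatches}. Ties on mismatch
#'   count are broken by the smallest start position.
#' @export
#' @examples
#' match_primer("GGAGACCTATTTGAAGAAGGTTCAGTGG",
#'              "AGACCTWTTTGAAGAAGGTTCWGT", 0)
match_primer <- function(sequence, primer, max_mismatches = 2L) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            is.character(primer), length(primer) == 1L)
  if (max_mismatches < 0) {
    stop("max_mismatches must be >= 0", call. = FALSE)
  }
  sequence <- toupper(sequence)
  primer <- toupper(primer)
  if (nchar(primer) > nchar(sequence) || nchar(primer) == 0L) {
    return(NULL)
  }
  hits <- Biostrings::matchPattern(
    Biostrings::DNAString(primer), Biostrings::DNAString(sequence),
    max.mismatch = max_mismatches, fixed = "subject"
  )
  if (length(hits) == 0L) {
    return(NULL)
  }
  starts <- Biostrings::start(hits)
  compat <- iupac_compat()
  pc <- strsplit(primer, "")[[1]]
  subj <- strsplit(sequence, "")[[1]]
  n_mm <- vapply(starts, function(s) {
    window <- subj[s:(s + length(pc) - 1L)]
    window[!window %in% colnames(compat)] <- "N"
    sum(!compat[cbind(pc, window)])
  }, integer(1))
  keep <- n_mm <= max_mismatches
  if (!any(keep)) {
    return(NULL)
  }
  starts <- starts[keep]
  n_mm <- n_mm[keep]
  best <- which(n_mm == min(n_mm))[1L] # hits are position-ordered
  list(
    start = as.integer(starts[best]),
    end = as.integer(starts[best] + nchar(primer) - 1L),
    mismatches = as.integer(n_mm[best])
  )
}

#' In-silico PCR: extract the amplicon delimited by a primer pair
#'
#' Matches the forward primer on the plus strand, then searches downstream of
#' the forward site for the reverse complement of the reverse primer. The
#' amplicon spans from the first base of the forward-primer site through the
#' last base of the reverse-primer site, primers included, with 1-based
#' closed coordinates on the source sequence.
#'
#' @param sequence Template DNA, a single string.
#' @param marker A \code{\link{marker_definition}}.
#' @param max_mismatches Maximum mismatches allowed per primer (default 2).
#' @param taxon_id Optional identifier carried into the result.
#' @return An object of class \code{"amplicon"} (list with \code{taxon_id},
#'   \code{marker}, \code{sequence}, \code{start}, \code{end},
#'   \code{amplified = TRUE}) or, if either primer fails to bind, an object
#'   of class \code{"no_amplification"} naming the missing primer.
#' @export
in_silico_pcr <- function(sequence, marker, max_mismatches = 2L,
                          taxon_id = NA_character_) {
  stopifnot(inherits(marker, "marker_definition"))
  if (!nzchar(sequence)) {
    stop("empty template sequence", call. = FALSE)
  }
  sequence <- toupper(sequence)
  fwd <- match_primer(sequence, marker$forward_primer, max_mismatches)
  if (is.null(fwd)) {
    return(no_amplification(marker, "forward", taxon_id))
  }
  # search strictly downstream of the forward site so that a reverse site
  # upstream of the forward site is reported as no-amplification
  tail_start <- fwd$end + 1L
  if (tail_start > nchar(sequence)) {
    return(no_amplification(marker, "reverse", taxon_id))
  }
  rc_rev <- reverse_complement(marker$reverse_primer)
  rev <- match_primer(substr(sequence, tail_start, nchar(sequence)),
                      rc_rev, max_mismatches)
  if (is.null(rev)) {
    return(no_amplification(marker, "reverse", taxon_id))
  }
  start <- fwd$start
  end <- tail_start + rev$end - 1L
  structure(
    list(
      taxon_id = taxon_id, marker = marker$name,
      sequence = substr(sequence, start, end),
      start = start, end = end,
      forward_mismatches = fwd$mismatches,
      reverse_mismatches = rev$mismatches,
      amplified = TRUE
    ),
    class = "amplicon"
  )
}

no_amplification <- function(marker, missing_primer, taxon_id) {
  structure(
    list(
      taxon_id = taxon_id, marker = marker$name,
      missing_primer = missing_primer, amplified = FALSE
    ),
    class = "no_amplification"
  )
}

#' Did in-silico PCR produce an amplicon?
#'
#' @param x Result of \code{\link{in_silico_pcr}}.
#' @return \code{TRUE} for an amplicon, \code{FALSE} otherwise.
#' @export
is_amplified <- function(x) isTRUE(x$amplified)

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("<amplicon %s/%s %d-%d (%d bp)>\n",
              x$taxon_id, x$marker, x$start, x$end, nchar(x$sequence)))
  invisible(x)
}

#' @export
print.no_amplification <- function(x, ...) {
  cat(sprintf("<no amplification %s/%s: %s primer not found>\n",
              x$taxon_id, x$marker, x$missing_primer))
  invisible(x)
}

#' Merge a forward/reverse read pair into a consensus sequence
#'
#' The reverse read is reverse-complemented and the highest-identity overlap
#' between the forward read's suffix and the reverse-complemented read's
#' prefix (of length at least \code{min_overlap}) is selected; ties on
#' identity are broken in favour of the longest overlap. Positions that
#' disagree within the overlap are written as N in the consensus.
#'
#' @param forward Forward read (5' portion of the target).
#' @param reverse Reverse read (reverse complement of the 3' portion).
#' @param min_overlap Minimum acceptable overlap length in bases (default 30).
#' @param min_identity Minimum fraction of agreeing positions in the chosen
#'   overlap (default 0.8); below this the merge fails.
#' @return Consensus DNA string.
#' @export
merge_reads <- function(forward, reverse, min_overlap = 30L,
                        min_identity = 0.8) {
  if (!nzchar(forward) || !nzchar(reverse)) {
    stop("reads must be nonempty", call. = FALSE)
  }
  f <- strsplit(toupper(forward), "")[[1]]
  r <- strsplit(reverse_complement(reverse), "")[[1]]
  max_olap <- min(length(f), length(r))
  if (max_olap < min_overlap) {
    stop("reads shorter than the minimum overlap", call. = FALSE)
  }
  best_olap <- 0L
  best_ident <- -1
  for (olap in seq(max_olap, min_overlap)) {
    fs <- f[(length(f) - olap + 1L):length(f)]
    rp <- r[1:olap]
    ident <- sum(fs == rp) / olap
    if (ident > best_ident) {
      best_ident <- ident
      best_olap <- olap
      if (ident == 1) break
    }
  }
  if (best_ident < min_identity) {
    stop(sprintf(
      "read merge failed: best overlap identity %.2f below %.2f",
      max(best_ident, 0), min_identity
    ), call. = FALSE)
  }
  olap <- best_olap
  fs <- f[(length(f) - olap + 1L):length(f)]
  rp <- r[1:olap]
  cons <- ifelse(fs == rp, fs, "N")
  paste0(
    paste(f[seq_len(length(f) - olap)], collapse = ""),
    paste(cons, collapse = ""),
    paste(r[seq_len(length(r) - olap) + olap], collapse = "")
  )
}

#' Concatenate marker sequences per taxon
#'
#' Joins, for each taxon, its sequences for the requested markers in the
#' given order (a "chimeric" multi-marker sequence for combined distance
#' analysis). Marker boundary offsets are attached so positions can be traced
#' back to their source marker.
#'
#' @param per_marker_sequences Named list: marker name -> named character
#'   vector of sequences (names are taxon ids).
#' @param markers Character vector of marker names giving the concatenation
#'   order.
#' @return Named character vector of concatenated sequences, with attribute
#'   \code{"boundaries"}: a named integer vector of cumulative end offsets.
#' @export
concatenate_markers <- function(per_marker_sequences, markers) {
  if (length(markers) == 0L) {
    stop("no markers requested", call. = FALSE)
  }
  missing_markers <- setdiff(markers, names(per_marker_sequences))
  if (length(missing_markers) > 0L) {
    stop("missing marker sequence sets: ",
         paste(missing_markers, collapse = ", "), call. = FALSE)
  }
  taxa <- sort(unique(unlist(lapply(per_marker_sequences[markers], names))))
  gaps <- character(0)
  for (m in markers) {
    absent <- setdiff(taxa, names(per_marker_sequences[[m]]))
    if (length(absent) > 0L) {
      gaps <- c(gaps, paste0("(", absent, ", ", m, ")"))
    }
  }
  if (length(gaps) > 0L) {
    stop("missing sequences: ", paste(gaps, collapse = " "), call. = FALSE)
  }
  out <- vapply(taxa, function(tx) {
    paste(vapply(markers, function(m) per_marker_sequences[[m]][[tx]],
                 character(1)), collapse = "")
  }, character(1))
  lens <- vapply(markers, function(m)
    nchar(per_marker_sequences[[m]][[taxa[1]]]), integer(1))
  attr(out, "boundaries") <- stats::setNames(cumsum(lens), markers)
  out
}
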