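#' Barcode marker definitions for the Lavandula panel
#'
#' Returns the three barcode markers used by the authentication pipeline:
#' two universal plant barcodes, \code{B1} (plastid \emph{rbcL}) and
#' \code{B2} (the plastid \emph{trnH-psbA} intergenic spacer), whose primers
#' carry IUPAC ambiguity codes so that they amplify across a wide range of
#' plant species, and \code{Lav}, a Lavandula-specific marker in the nuclear
#' ITS region with non-degenerate primers.
#'
#' @param name Optional marker name (\code{"B1"}, \code{"B2"} or
#'   \code{"Lav"}); if given, the single definition is returned.
#'
#' @return A named list of marker definitions (or a single definition), each
#'   a list with elements \code{name}, \code{locus}, \code{forward_primer},
#'   \code{reverse_primer} and \code{amplicon_length} (the expected amplicon
#'   size in bp, primers included).
#' @export
#' @examples
#' lavandula_markers()$B1$forward_primer
lavandula_markers <- function(name = NULL) {
  defs <- list(
    B1 = marker_definition(
      name = "B1", locus = "rbcL",
      forward_primer = "AGACCTWTTTGAAGAAGGTTCWGT",
      reverse_primer = "TCGGTYAGAGCRGGCATRTGCCA",
      amplicon_length = 690L
    ),
    B2 = marker_definition(
      name = "B2", locus = "trnH-psbA",
      forward_primer = "GTTATGCATGAACGTAATGCTC",
      reverse_primer = "CGCGCATGGTGGATTCACAATCC",
      amplicon_length = 273L
    ),
    Lav = marker_definition(
      name = "Lav", locus = "ITS",
      forward_primer = "CTGCGGAAGGATCATTGT",
      reverse_primer = "TTGATATGCTTAAACTCAGC",
      amplicon_length = 490L
    )
  )
  if (is.null(name)) {
    return(defs)
  }
  if (!name %in% names(defs)) {
    stop("unknown marker: ", name, call. = FALSE)
  }
  defs[[name]]
}

#' Construct a marker definition
#'
#' @param name Short marker name.
#' @param locus Genetic region the marker targets.
#' @param forward_primer,reverse_primer Primer sequences, 5'-3', IUPAC codes
#'   allowed.
#' @param amplicon_length Expected amplicon length in bp (primers included),
#'   or \code{NA} if unknown.
#' @return A list of class \code{"marker_definition"}.
#' @export
marker_definition <- function(name, locus, forward_primer, reverse_primer,
                              amplicon_length = NA_integer_) {
  forward_primer <- toupper(forward_primer)
  reverse_primer <- toupper(reverse_primer)
  for (p in c(forward_primer, reverse_primer)) {
    if (!grepl("^[ACGTRYSWKMBDHVN]+$", p)) {
      stop("primer contains non-IUPAC characters: ", p, call. = FALSE)
    }
  }
  structure(
    list(
      name = name, locus = locus,
      forward_primer = forward_primer, reverse_primer = reverse_primer,
      amplicon_length = as.integer(amplicon_length)
    ),
    class = "marker_definition"
  )
}

#' @export
print.marker_definition <- function(x, ...) {
  cat(sprintf(
    "<marker %s (%s)>\n  F: %s\n  R: %s\n  expected amplicon: %s bp\n",
    x$name, x$locus, x$forward_primer, x$reverse_primer,
    ifelse(is.na(x$amplicon_length), "?", x$amplicon_length)
  ))
  invisible(x)
}

# IUPAC compatibility lookup: compat[primer_base, subject_base] is TRUE when
# the (possibly degenerate) primer base is compatible with the concrete
# subject base. Subject-side 'N' is never compatible: an unknown base cannot
# demonstrate a match.
iupac_compat_matrix <- function() {
  codes <- Biostrings::IUPAC_CODE_MAP
  subj <- c("A", "C", "G", "T", "N")
  m <- matrix(FALSE, nrow = length(codes), ncol = length(subj),
              dimnames = list(names(codes), subj))
  for (p in names(codes)) {
    allowed <- strsplit(codes[[p]], "")[[1]]
    m[p, intersect(allowed, c("A", "C", "G", "T"))] <- TRUE
  }
  m
}

.lavauth_env <- new.env(parent = emptyenv())

iupac_compat <- function() {
  if (is.null(.lavauth_env$compat)) {
    .lavauth_env$compat <- iupac_compat_matrix()
  }
  .lavauth_env$compat
}

#' Reverse complement of a DNA string
#'
#' IUPAC ambiguity codes are complemented correctly (e.g. R <-> Y, W <-> W).
#'
#' @param x A single DNA string.
#' @return The reverse complement as a character scalar.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
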