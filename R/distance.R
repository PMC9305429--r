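#' Uncorrected p-distance between two aligned sequences
#'
#' The p-distance is the proportion of differing sites among sites where both
#' sequences carry an unambiguous base (A/C/G/T). Positions where either
#' sequence has N (or any other ambiguity) are excluded from both numerator
#' and denominator.
#'
#' @param a,b Aligned DNA strings of equal length.
#' @return Fraction in [0, 1].
#' @export
#' @examples
#' p_distance("ACGT", "ACGA") # 0.25
#' p_distance("ACNT", "ACGA") # one of three comparable sites differs
p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("sequences have unequal lengths; align them first", call. = FALSE)
  }
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  acgt <- c("A", "C", "G", "T")
  valid <- av %in% acgt & bv %in% acgt
  n <- sum(valid)
  if (n == 0L) {
    stop("no comparable (unambiguous) positions", call. = FALSE)
  }
  sum(av[valid] != bv[valid]) / n
}

# integer encoding of an alignment: rows = taxa, NA for ambiguous bases
encode_alignment <- function(sequences) {
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("sequences have unequal lengths; align them first", call. = FALSE)
  }
  chars <- do.call(rbind, strsplit(toupper(sequences), ""))
  enc <- match(chars, c("A", "C", "G", "T"))
  matrix(enc, nrow = length(sequences), ncol = lens[1],
         dimnames = list(names(sequences), NULL))
}

pdist_from_encoded <- function(enc) {
  n <- nrow(enc)
  d <- matrix(0, n, n, dimnames = list(rownames(enc), rownames(enc)))
  for (i in seq_len(n - 1L)) {
    xi <- enc[i, ]
    for (j in seq(i + 1L, n)) {
      xj <- enc[j, ]
      valid <- !is.na(xi) & !is.na(xj)
      m <- sum(valid)
      if (m == 0L) {
        stop("no comparable positions between ", rownames(enc)[i], " and ",
             rownames(enc)[j], call. = FALSE)
      }
      d[i, j] <- d[j, i] <- sum(xi[valid] != xj[valid]) / m
    }
  }
  d
}

#' Pairwise p-distance matrix
#'
#' @param sequences Named character vector of aligned (equal-length)
#'   sequences.
#' @return Symmetric numeric matrix with zero diagonal, labelled by taxon.
#' @export
p_distance_matrix <- function(sequences) {
  if (length(sequences) < 2L) {
    stop("need at least two sequences", call. = FALSE)
  }
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("sequences must carry unique names", call. = FALSE)
  }
  pdist_from_encoded(encode_alignment(sequences))
}
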