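#' Reference compound library
#'
#' The chromatographic reference library used by the chemotaxonomic key: for
#' each compound, its id, name, reference retention time (minutes, on a
#' 20-minute reversed-phase UHPLC gradient) and chemical family. The families
#' drive the family-level criteria: depsides, the monoterpene ester linalyl
#' acetate and the diterpenes. Retention times for compounds 21 and 37 are
#' nominal values consistent with the elution order of their families.
#'
#' @param path Optional path to a CSV with columns \code{compound_id},
#'   \code{name}, \code{rt_min}, \code{family}; defaults to the packaged
#'   library.
#' @return Data frame with one row per compound.
#' @export
lav_compound_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "compound_library.csv",
                        package = "lavauth", mustWork = TRUE)
  }
  lib <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("compound_id", "name", "rt_min", "family")
  if (!all(required %in% names(lib))) {
    stop("compound library must have columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(lib$compound_id)) {
    stop("duplicate compound ids in library", call. = FALSE)
  }
  if (any(lib$rt_min <= 0)) {
    stop("retention times must be positive", call. = FALSE)
  }
  lib$compound_id <- as.integer(lib$compound_id)
  lib
}

#' The chemotaxonomic criteria key
#'
#' The reference presence/absence key for the eleven-taxon panel: one row per
#' authenticated reference sample with its chemotypic cluster (1-6) and the
#' seven criteria. The criteria are: 1 = major presence of coumaric acid
#' hexoside (8) and ferulic acid hexoside (14); 2 = major presence of
#' rosmarinic acid (53); 3 = presence of both cinnamic-acid-derived
#' compounds 15 and 16; 4 = absence of both 15 and 16; 5 = presence of the
#' depside family; 6 = presence of linalyl acetate (93); 7 = presence of the
#' diterpene family. The printed source key carries criterion-6 marks on the
#' four cluster-1 rows whose typography is ambiguous; they are recorded as
#' printed and can be overridden.
#'
#' @param override Optional data frame with columns \code{taxon_id} plus any
#'   of \code{c1}..\code{c7} (logical) to patch individual cells of the key.
#' @return Data frame with columns \code{taxon_id}, \code{species},
#'   \code{cultivar}, \code{cluster} and logical \code{c1}..\code{c7}.
#' @export
lav_criteria_key <- function(override = NULL) {
  path <- system.file("extdata", "criteria_key.csv",
                      package = "lavauth", mustWork = TRUE)
  key <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(cultivar = "character"))
  for (cc in paste0("c", 1:7)) {
    key[[cc]] <- as.logical(key[[cc]])
  }
  if (!is.null(override)) {
    stopifnot("taxon_id" %in% names(override))
    for (i in seq_len(nrow(override))) {
      row <- match(override$taxon_id[i], key$taxon_id)
      if (is.na(row)) {
        stop("override references unknown taxon: ", override$taxon_id[i],
             call. = FALSE)
      }
      for (cc in intersect(paste0("c", 1:7), names(override))) {
        key[row, cc] <- as.logical(override[[cc]][i])
      }
    }
  }
  key
}

#' Match observed peaks to library compounds by retention time
#'
#' Each library compound takes the largest-area observed peak within
#' \code{rt_tolerance} minutes of its reference retention time; one peak may
#' serve several compounds whose reference times collide within tolerance.
#' Unmatched compounds get area 0.
#'
#' @param table A peak table: data frame with columns \code{rt_min} and
#'   \code{area}.
#' @param library Compound library (see \code{\link{lav_compound_library}}).
#' @param rt_tolerance Matching half-window in minutes (default 0.05).
#' @return Named numeric vector: compound id -> matched area.
#' @export
match_peaks <- function(table, library, rt_tolerance = 0.05) {
  if (nrow(library) == 0L) {
    stop("empty compound library", call. = FALSE)
  }
  if (rt_tolerance <= 0) {
    stop("rt_tolerance must be > 0", call. = FALSE)
  }
  out <- stats::setNames(numeric(nrow(library)),
                         as.character(library$compound_id))
  if (nrow(table) == 0L) {
    return(out)
  }
  for (i in seq_len(nrow(library))) {
    hit <- abs(table$rt_min - library$rt_min[i]) <= rt_tolerance
    if (any(hit)) {
      out[i] <- max(table$area[hit])
    }
  }
  out
}

relative_areas <- function(matched) {
  total <- sum(matched)
  if (total <= 0) {
    return(matched * 0)
  }
  matched / total
}

#' Select marker compounds across a sample panel
#'
#' A compound is flagged as a marker when its matched relative area (area
#' divided by the sample's total matched area) exceeds
#' \code{presence_threshold} in at least one sample. Results are ranked by
#' maximal relative area across the panel.
#'
#' @param tables List of peak tables.
#' @param library Compound library.
#' @param presence_threshold Relative-area threshold (default 0.05).
#' @param rt_tolerance Matching tolerance passed to
#'   \code{\link{match_peaks}}.
#' @return Integer vector of compound ids, ranked; empty when nothing
#'   qualifies.
#' @export
select_marker_compounds <- function(tables, library,
                                    presence_threshold = 0.05,
                                    rt_tolerance = 0.05) {
  if (length(tables) == 0L) {
    stop("need at least one peak table", call. = FALSE)
  }
  rel <- vapply(tables, function(tb)
    relative_areas(match_peaks(tb, library, rt_tolerance)),
    numeric(nrow(library)))
  max_rel <- apply(rel, 1L, max)
  keep <- max_rel > presence_threshold
  ids <- library$compound_id[keep]
  ids[order(max_rel[keep], decreasing = TRUE)]
}

#' Evaluate the seven chemotaxonomic criteria for one sample
#'
#' Criteria 1 and 2 are "major presence" tests on the relative matched area
#' (area over the sample's total matched area); criteria 3-7 are simple
#' presence/absence tests (any nonzero match). Criterion 4 is the absence of
#' both compounds whose joint presence is criterion 3, so the two can never
#' both hold.
#'
#' @param matched Named numeric vector from \code{\link{match_peaks}}
#'   covering the library.
#' @param library Compound library (for family membership).
#' @param presence_threshold Relative-area threshold for major presence
#'   (default 0.05).
#' @param min_depsides Number of distinct depside-family compounds required
#'   for criterion 5 (default 2, robust to a single spurious match).
#' @return Named logical vector \code{c1}..\code{c7}.
#' @export
evaluate_criteria <- function(matched, library, presence_threshold = 0.05,
                              min_depsides = 2L) {
  rel <- relative_areas(matched)
  area <- function(id) {
    v <- matched[as.character(id)]
    ifelse(is.na(v), 0, v)
  }
  relarea <- function(id) {
    v <- rel[as.character(id)]
    ifelse(is.na(v), 0, v)
  }
  depside_ids <- library$compound_id[library$family == "depside"]
  diterpene_ids <- library$compound_id[library$family == "diterpene"]
  c(
    c1 = unname(relarea(8) > presence_threshold &
                  relarea(14) > presence_threshold),
    c2 = unname(relarea(53) > presence_threshold),
    c3 = unname(area(15) > 0 & area(16) > 0),
    c4 = unname(area(15) == 0 & area(16) == 0),
    c5 = sum(vapply(depside_ids, area, numeric(1)) > 0) >= min_depsides,
    c6 = unname(area(93) > 0),
    c7 = any(vapply(diterpene_ids, area, numeric(1)) > 0)
  )
}

#' Assign a sample to a chemotypic cluster
#'
#' Nearest-reference classification: the sample's criteria profile is
#' compared to every row of the key by Hamming distance over the seven
#' criteria; ties are broken by lowest cluster number, then key row order.
#' The cluster is assigned only when the best distance does not exceed
#' \code{max_hamming}.
#'
#' @param profile Named logical vector \code{c1}..\code{c7} (from
#'   \code{\link{evaluate_criteria}}).
#' @param key Criteria key (see \code{\link{lav_criteria_key}}).
#' @param max_hamming Maximum acceptable Hamming distance (default 1).
#' @param sample_id Optional sample identifier carried into the result.
#' @return Object of class \code{"chemical_assignment"}: list with
#'   \code{sample_id}, \code{cluster} (integer or \code{NA} if unassigned),
#'   \code{matched_profile_taxon}, \code{hamming_distance} and
#'   \code{criteria}.
#' @export
assign_cluster <- function(profile, key, max_hamming = 1L,
                           sample_id = NA_character_) {
  if (is.null(key) || nrow(key) == 0L) {
    stop("empty criteria key", call. = FALSE)
  }
  crit_cols <- paste0("c", 1:7)
  ref <- as.matrix(key[, crit_cols])
  dist <- rowSums(ref != matrix(profile[crit_cols], nrow(key), 7,
                                byrow = TRUE))
  ord <- order(dist, key$cluster, seq_len(nrow(key)))
  best <- ord[1]
  assigned <- dist[best] <= max_hamming
  structure(
    list(
      sample_id = sample_id,
      cluster = if (assigned) as.integer(key$cluster[best]) else NA_integer_,
      matched_profile_taxon = if (assigned) key$taxon_id[best]
                              else NA_character_,
      hamming_distance = as.integer(dist[best]),
      criteria = profile
    ),
    class = "chemical_assignment"
  )
}

#' @export
print.chemical_assignment <- function(x, ...) {
  cat(sprintf(
    "<chemical assignment %s: cluster %s (nearest %s, Hamming %d)>\n",
    x$sample_id, ifelse(is.na(x$cluster), "unassigned", x$cluster),
    x$matched_profile_taxon, x$hamming_distance
  ))
  invisible(x)
}

#' Run the chemical classification over a panel of peak tables
#'
#' Convenience wrapper: matches peaks, evaluates criteria and assigns a
#' cluster for every sample.
#'
#' @param peak_tables Named list of peak tables (names are sample ids).
#' @param library Compound library.
#' @param key Criteria key.
#' @param rt_tolerance,presence_threshold,max_hamming Passed through to the
#'   stage functions.
#' @return Named list of \code{"chemical_assignment"} objects.
#' @export
assign_samples <- function(peak_tables, library = lav_compound_library(),
                           key = lav_criteria_key(), rt_tolerance = 0.05,
                           presence_threshold = 0.05, max_hamming = 1L) {
  stopifnot(!is.null(names(peak_tables)))
  out <- lapply(names(peak_tables), function(sid) {
    matched <- match_peaks(peak_tables[[sid]], library, rt_tolerance)
    prof <- evaluate_criteria(matched, library, presence_threshold)
    assign_cluster(prof, key, max_hamming, sample_id = sid)
  })
  stats::setNames(out, names(peak_tables))
}
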