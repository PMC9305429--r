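#' Combine genetic and chemical evidence into authentication verdicts
#'
#' Genetics is authoritative: a sample whose three-marker haplotype group is
#' a singleton is resolved by genetics alone, and chemistry can never
#' overrule it. Inside a multi-member genetic group, chemistry refines the
#' candidate list: candidates are the group members whose reference key row
#' carries the sample's assigned chemical cluster and matches any named
#' refinement sub-pattern defined for that cluster. By default one
#' refinement rule is active: within chemical cluster 1, joint major
#' presence of rosmarinic acid and the cinnamic-acid pair (criteria 2 and 3)
#' separates the Blue/Grosso chemotype from the White/Abrial chemotype.
#'
#' @param genetic A \code{\link{discrimination_summary}} over the full
#'   (three-marker) concatenation.
#' @param chemical Named list of \code{"chemical_assignment"} objects (one
#'   per sample, e.g. from \code{\link{assign_samples}}).
#' @param key Criteria key (see \code{\link{lav_criteria_key}}).
#' @param refinements Named list: chemical cluster (as character) -> function
#'   mapping a criteria profile to a comparable signature. Members whose key
#'   signature equals the sample's observed signature stay candidates.
#' @return Named list of \code{"authentication_verdict"} objects: each has
#'   \code{sample_id}, \code{genetic_group}, \code{chemical_cluster},
#'   \code{resolution} (\code{species_resolved}, \code{group_only} or
#'   \code{conflict}), \code{candidate_taxa} (ranked) and \code{evidence}.
#' @export
authenticate <- function(genetic, chemical, key = lav_criteria_key(),
                         refinements = default_refinements()) {
  stopifnot(inherits(genetic, "haplotype_groups"))
  samples <- unlist(genetic$groups, use.names = FALSE)
  missing_chem <- setdiff(samples, names(chemical))
  missing_gen <- setdiff(names(chemical), samples)
  if (length(missing_chem) > 0L || length(missing_gen) > 0L) {
    stop("evidence sets do not cover the same samples; missing: ",
         paste(c(missing_chem, missing_gen), collapse = ", "),
         call. = FALSE)
  }
  crit_cols <- paste0("c", 1:7)

  verdicts <- lapply(samples, function(sid) {
    group <- genetic$groups[[which(vapply(genetic$groups,
                                          function(g) sid %in% g,
                                          logical(1)))]]
    assg <- chemical[[sid]]
    evidence <- character(0)

    if (length(group) == 1L) {
      evidence <- c(evidence, "singleton haplotype group: resolved by genetics")
      if (is.na(assg$cluster)) {
        evidence <- c(evidence,
                      "chemical cluster unassigned: low-confidence chemical corroboration")
      } else {
        evidence <- c(evidence,
                      sprintf("chemical cluster %d (nearest %s, Hamming %d)",
                              assg$cluster, assg$matched_profile_taxon,
                              assg$hamming_distance))
      }
      return(new_verdict(sid, group, assg, "species_resolved", sid, evidence))
    }

    evidence <- c(evidence, sprintf(
      "haplotype group of %d taxa {%s}: genetics alone cannot resolve",
      length(group), paste(group, collapse = ", ")))
    if (is.na(assg$cluster)) {
      evidence <- c(evidence, "chemical cluster unassigned: no refinement")
      return(new_verdict(sid, group, assg, "group_only", sort(group),
                         evidence))
    }

    members <- key[key$taxon_id %in% group, , drop = FALSE]
    cands <- members$taxon_id[members$cluster == assg$cluster]
    rule <- refinements[[as.character(assg$cluster)]]
    if (!is.null(rule) && length(cands) > 0L) {
      sig_sample <- rule(as.list(assg$criteria))
      keep <- vapply(cands, function(tx) {
        row <- key[key$taxon_id == tx, crit_cols]
        identical(rule(as.list(unlist(row))), sig_sample)
      }, logical(1))
      cands <- cands[keep]
      evidence <- c(evidence, sprintf(
        "cluster-%d refinement sub-pattern applied", assg$cluster))
    }
    evidence <- c(evidence, sprintf(
      "chemical cluster %d intersected with genetic group -> {%s}",
      assg$cluster, paste(cands, collapse = ", ")))

    if (length(cands) == 1L) {
      new_verdict(sid, group, assg, "species_resolved", cands, evidence)
    } else if (length(cands) > 1L) {
      # rank by Hamming distance of the key row to the observed profile
      dists <- vapply(cands, function(tx) {
        row <- unlist(key[key$taxon_id == tx, crit_cols])
        sum(row != assg$criteria)
      }, numeric(1))
      ranked <- cands[order(dists, cands)]
      new_verdict(sid, group, assg, "group_only", ranked, evidence)
    } else {
      evidence <- c(evidence,
                    "chemical evidence excludes every genetic candidate")
      new_verdict(sid, group, assg, "conflict", character(0), evidence)
    }
  })
  stats::setNames(verdicts, samples)
}

#' Default chemical refinement rules
#'
#' @return Named list of signature functions keyed by chemical cluster. The
#'   shipped rule splits cluster 1 by joint criteria 2 and 3.
#' @export
default_refinements <- function() {
  list("1" = function(profile) isTRUE(profile$c2) && isTRUE(profile$c3))
}

new_verdict <- function(sample_id, group, assg, resolution, candidates,
                        evidence) {
  structure(
    list(
      sample_id = sample_id,
      genetic_group = sort(group),
      chemical_cluster = assg$cluster,
      resolution = resolution,
      candidate_taxa = candidates,
      evidence = evidence
    ),
    class = "authentication_verdict"
  )
}

#' @export
print.authentication_verdict <- function(x, ...) {
  cat(sprintf("<verdict %s: %s%s>\n", x$sample_id, x$resolution,
              if (length(x$candidate_taxa) > 0)
                paste0(" {", paste(x$candidate_taxa, collapse = ", "), "}")
              else ""))
  invisible(x)
}

#' Panel-level summary of authentication verdicts
#'
#' @param verdicts Named list from \code{\link{authenticate}}.
#' @return List with counts per resolution class
#'   (\code{n_species_resolved}, \code{n_group_only}, \code{n_conflict}),
#'   \code{n_resolved_by_genetics} (singleton haplotype groups) and
#'   \code{unresolved_groups}, the residual indistinguishable candidate
#'   sets.
#' @export
panel_report <- function(verdicts) {
  if (length(verdicts) == 0L) {
    stop("no verdicts supplied", call. = FALSE)
  }
  res <- vapply(verdicts, function(v) v$resolution, character(1))
  by_genetics <- vapply(verdicts, function(v)
    length(v$genetic_group) == 1L, logical(1))
  unresolved <- unique(lapply(
    verdicts[res == "group_only"],
    function(v) sort(v$candidate_taxa)
  ))
  names(unresolved) <- NULL
  list(
    n_samples = length(verdicts),
    n_species_resolved = sum(res == "species_resolved"),
    n_resolved_by_genetics = sum(res == "species_resolved" & by_genetics),
    n_group_only = sum(res == "group_only"),
    n_conflict = sum(res == "conflict"),
    unresolved_groups = unresolved
  )
}
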