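#' Configuration for the synthetic reference panel generator
#'
#' The generator emulates an eleven-accession study panel: per-marker
#' reference sequences whose amplicons realize a prescribed identity
#' structure (taxa in the same haplotype class carry bit-identical
#' amplicons), paired sequencing reads, and per-sample chromatographic peak
#' tables realizing a presence/absence criteria key.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param amplicon_lengths Named integer vector, marker -> amplicon length in
#'   bp (primers included). Defaults: B1 690, B2 273, Lav 490.
#' @param flank_length Length in bp of the non-amplified flank generated on
#'   each side of the amplicon (default 30).
#' @param between_class_divergence Expected substitutions per site between
#'   haplotype classes (default 0.02).
#' @param within_class_divergence Fixed at 0: haplotype groups are defined by
#'   exact sequence identity, so members of a class must be bit-identical
#'   over the amplicon.
#' @param read_error_rate Per-base substitution probability for simulated
#'   reads, applied only outside the read overlap (default 0).
#' @param n_noise_peaks Number of unassigned noise peaks per peak table
#'   (default 0); noise peaks are placed at least three retention-time
#'   tolerance widths away from every library compound.
#' @param rt_jitter_sd Gaussian jitter (sd, minutes) applied to each emitted
#'   peak's retention time (default 0.01).
#' @param rt_tolerance Retention-time matching tolerance in minutes used to
#'   place noise peaks safely (default 0.05, matching the analysis default).
#' @param major_area,extra_area,minor_area Peak areas (arbitrary units) used
#'   for major-presence compounds, additional discriminant compounds and
#'   presence-only family markers respectively.
#' @param noise_area_range Range of noise-peak areas.
#' @return A list of class \code{"lav_generator_config"}.
#' @export
generator_config <- function(seed = 1L,
                             amplicon_lengths = c(B1 = 690L, B2 = 273L,
                                                  Lav = 490L),
                             flank_length = 30L,
                             between_class_divergence = 0.02,
                             within_class_divergence = 0,
                             read_error_rate = 0,
                             n_noise_peaks = 0L,
                             rt_jitter_sd = 0.01,
                             rt_tolerance = 0.05,
                             major_area = 1000,
                             extra_area = 400,
                             minor_area = 30,
                             noise_area_range = c(10, 200)) {
  if (within_class_divergence != 0) {
    stop("within_class_divergence is fixed at 0: haplotype classes are ",
         "defined by exact sequence identity", call. = FALSE)
  }
  if (between_class_divergence <= 0) {
    stop("between_class_divergence must be > 0", call. = FALSE)
  }
  if (read_error_rate < 0 || read_error_rate > 1) {
    stop("read_error_rate must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      seed = as.integer(seed),
      amplicon_lengths = amplicon_lengths,
      flank_length = as.integer(flank_length),
      between_class_divergence = between_class_divergence,
      within_class_divergence = 0,
      read_error_rate = read_error_rate,
      n_noise_peaks = as.integer(n_noise_peaks),
      rt_jitter_sd = rt_jitter_sd,
      rt_tolerance = rt_tolerance,
      major_area = major_area,
      extra_area = extra_area,
      minor_area = minor_area,
      noise_area_range = noise_area_range
    ),
    class = "lav_generator_config"
  )
}

#' The eleven-taxon reference panel
#'
#' Ten Lavandula accessions (including two L. angustifolia and two
#' L. x intermedia cultivars) plus the outgroup Perovskia atriplicifolia,
#' with their haplotype class labels per marker set and their chemotypic
#' criteria profile. Taxa sharing a class label carry identical amplicons
#' for the corresponding markers: classes A-C for the two plastid barcodes
#' (rbcL and trnH-psbA share the same partition), D-E for the ITS marker;
#' all other taxa are singletons.
#'
#' @return A data frame with one row per taxon: \code{taxon_id},
#'   \code{species}, \code{cultivar}, \code{class_plastid},
#'   \code{class_its}, \code{cluster}, criteria \code{c1}..\code{c7} and
#'   \code{extra_compounds} (comma-separated additional discriminant
#'   compound ids emitted into the taxon's peak table).
#' @export
lavandula_panel <- function() {
  key <- lav_criteria_key()
  class_plastid <- c(
    ANG_W = "A", INT_A = "A", INT_G = "A",
    ANG_B = "B", LAT = "B",
    ALL = "C", DEN = "C",
    CAN = "singleton-CAN", PIN = "singleton-PIN",
    STO = "singleton-STO", PER = "singleton-PER"
  )
  class_its <- c(
    ANG_W = "D", ANG_B = "D", INT_A = "D", INT_G = "D",
    ALL = "E", DEN = "E",
    LAT = "singleton-LAT", CAN = "singleton-CAN", PIN = "singleton-PIN",
    STO = "singleton-STO", PER = "singleton-PER"
  )
  extras <- c(
    ANG_W = "21", ANG_B = "21", INT_A = "21", INT_G = "21",
    ALL = "37", DEN = "37", LAT = "37",
    PIN = "", CAN = "", STO = "", PER = ""
  )
  key$class_plastid <- unname(class_plastid[key$taxon_id])
  key$class_its <- unname(class_its[key$taxon_id])
  key$extra_compounds <- unname(extras[key$taxon_id])
  key
}

marker_class_column <- function(marker_name) {
  switch(marker_name,
    B1 = "class_plastid", B2 = "class_plastid", Lav = "class_its",
    stop("no haplotype class column for marker ", marker_name,
         call. = FALSE)
  )
}

with_local_seed <- function(seed, expr) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  expr
}

derive_seed <- function(seed, salt) {
  as.integer((abs(as.numeric(seed)) * 7919 + salt) %% (2^31 - 2)) + 1L
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# one concrete resolution of the degenerate positions of a primer
resolve_primer <- function(primer) {
  codes <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(toupper(primer), "")[[1]]
  resolved <- vapply(chars, function(ch) {
    allowed <- strsplit(codes[[ch]], "")[[1]]
    if (length(allowed) == 1L) allowed else sample(allowed, 1L)
  }, character(1))
  paste(resolved, collapse = "")
}

#' Generate per-taxon reference sequences for one marker
#'
#' Each reference is: 5' flank, an exact forward-primer binding site (one
#' concrete resolution of its degenerate bases), the inter-primer core, the
#' reverse-complemented reverse-primer binding site, 3' flank. Taxa sharing a
#' haplotype class for the marker's partition receive bit-identical
#' amplicons; amplicons of distinct classes are guaranteed to differ at one
#' site or more. Deterministic for a given config seed.
#'
#' @param config A \code{\link{generator_config}}.
#' @param taxa Panel data frame (see \code{\link{lavandula_panel}}).
#' @param marker A \code{\link{marker_definition}}.
#' @return Named character vector taxon_id -> reference sequence, with
#'   attribute \code{"class_amplicons"} (named by class label).
#' @export
make_marker_references <- function(config, taxa, marker) {
  stopifnot(inherits(config, "lav_generator_config"),
            inherits(marker, "marker_definition"))
  amp_len <- config$amplicon_lengths[[marker$name]]
  if (is.null(amp_len)) {
    stop("no amplicon length configured for marker ", marker$name,
         call. = FALSE)
  }
  lf <- nchar(marker$forward_primer)
  lr <- nchar(marker$reverse_primer)
  core_len <- amp_len - lf - lr
  if (core_len < 0L) {
    stop("amplicon length ", amp_len, " is shorter than the combined ",
         "primer lengths (", lf + lr, ")", call. = FALSE)
  }
  class_col <- marker_class_column(marker$name)
  classes <- unique(taxa[[class_col]])

  mseed <- derive_seed(config$seed,
                       match(marker$name, c("B1", "B2", "Lav")))
  with_local_seed(mseed, {
    ancestral <- strsplit(random_dna(core_len), "")[[1]]
    bases <- c("A", "C", "G", "T")
    class_amp <- vapply(classes, function(cl) {
      fwd_site <- resolve_primer(marker$forward_primer)
      rev_site <- reverse_complement(resolve_primer(marker$reverse_primer))
      core <- ancestral
      if (core_len > 0L) {
        mut <- stats::runif(core_len) < config$between_class_divergence
        if (any(mut)) {
          core[mut] <- vapply(core[mut], function(b)
            sample(setdiff(bases, b), 1L), character(1))
        }
      }
      paste0(fwd_site, paste(core, collapse = ""), rev_site)
    }, character(1))
    names(class_amp) <- classes
    # guarantee distinct classes differ at >= 1 amplicon site
    pos <- lf + 1L
    while (anyDuplicated(class_amp) && core_len > 0L) {
      dup <- which(duplicated(class_amp))[1L]
      b <- substr(class_amp[dup], pos, pos)
      substr(class_amp[dup], pos, pos) <- setdiff(bases, b)[1L]
      pos <- pos %% (lf + core_len) + 1L
      if (pos <= lf) pos <- lf + 1L
    }
    refs <- vapply(seq_len(nrow(taxa)), function(i) {
      paste0(random_dna(config$flank_length),
             class_amp[[taxa[[class_col]][i]]],
             random_dna(config$flank_length))
    }, character(1))
    names(refs) <- taxa$taxon_id
    attr(refs, "class_amplicons") <- class_amp
    refs
  })
}

#' Simulate a forward/reverse read pair from a reference
#'
#' Reads cover about 60 percent of the reference from each end (the overlap
#' is forced to at least 30 bp); the reverse read is the reverse complement
#' of the 3' portion. Substitution errors at \code{config$read_error_rate}
#' are injected only outside the overlap, so the overlap alignment stays
#' unambiguous and merging recovers a consensus. Deterministic for a given
#' (seed, reference) pair.
#'
#' @param reference Reference sequence (character scalar).
#' @param config A \code{\link{generator_config}}.
#' @return List with \code{forward} and \code{reverse} read strings.
#' @export
make_read_pairs <- function(reference, config) {
  stopifnot(inherits(config, "lav_generator_config"))
  if (!nzchar(reference)) {
    stop("reference must be nonempty", call. = FALSE)
  }
  L <- nchar(reference)
  fl <- ceiling(0.6 * L)
  if (2L * fl - L < 30L) fl <- ceiling((L + 30L) / 2)
  if (fl > L) {
    stop("reference too short to simulate an overlapping read pair",
         call. = FALSE)
  }
  rl <- fl
  rseed <- derive_seed(config$seed, sum(utf8ToInt(reference)) %% 100000L)
  with_local_seed(rseed, {
    chars <- strsplit(toupper(reference), "")[[1]]
    overlap_start <- L - rl + 1L
    overlap_end <- fl
    fwd <- chars[1:fl]
    rev_region <- chars[(L - rl + 1L):L]
    if (config$read_error_rate > 0) {
      bases <- c("A", "C", "G", "T")
      # forward positions before the overlap
      pre <- seq_len(max(overlap_start - 1L, 0L))
      err <- pre[stats::runif(length(pre)) < config$read_error_rate]
      for (p in err) {
        fwd[p] <- sample(setdiff(bases, fwd[p]), 1L)
      }
      # reverse-region positions after the overlap (relative indexing)
      post <- which((L - rl + seq_len(rl)) > overlap_end)
      err <- post[stats::runif(length(post)) < config$read_error_rate]
      for (p in err) {
        rev_region[p] <- sample(setdiff(bases, rev_region[p]), 1L)
      }
    }
    list(
      forward = paste(fwd, collapse = ""),
      reverse = reverse_complement(paste(rev_region, collapse = ""))
    )
  })
}

#' Generate a synthetic chromatographic peak table for one taxon
#'
#' Emits one peak per compound required present by the taxon's criteria
#' profile (at the library retention time plus Gaussian jitter), with areas
#' chosen so that major-presence compounds dominate the sample's matched
#' area while family-presence markers (depsides, linalyl acetate,
#' diterpenes) stay below the major-presence threshold. Compounds required
#' absent are omitted. Optional noise peaks are placed at least three
#' tolerance widths from every library retention time so they can never be
#' matched to a compound.
#'
#' @param taxon One row of \code{\link{lavandula_panel}}.
#' @param library Compound library (see \code{\link{lav_compound_library}}).
#' @param config A \code{\link{generator_config}}.
#' @return A data frame of class \code{"lav_peak_table"} with columns
#'   \code{rt_min} and \code{area}, ordered by retention time, and attribute
#'   \code{"sample_id"}.
#' @export
make_peak_table <- function(taxon, library, config) {
  stopifnot(inherits(config, "lav_generator_config"), nrow(taxon) == 1L)
  fam_ids <- function(fam) library$compound_id[library$family == fam]
  want <- function(crit) isTRUE(taxon[[crit]])

  ids <- integer(0)
  areas <- numeric(0)
  add <- function(cids, area) {
    ids <<- c(ids, cids)
    areas <<- c(areas, rep(area, length(cids)))
  }
  if (want("c1")) add(c(8L, 14L), config$major_area)
  if (want("c2")) add(53L, config$major_area)
  if (want("c3")) add(c(15L, 16L), config$major_area)
  if (!want("c3") && !want("c4")) {
    # profiles marking neither the joint presence (c3) nor the joint
    # absence (c4) of the cinnamic-acid pair carry a trace of one member
    add(15L, config$minor_area)
  }
  if (want("c5")) add(fam_ids("depside"), config$minor_area)
  if (want("c6")) add(93L, config$minor_area)
  if (want("c7")) add(fam_ids("diterpene"), config$minor_area)
  extras <- taxon$extra_compounds
  if (nzchar(extras)) {
    add(as.integer(strsplit(extras, ",")[[1]]), config$extra_area)
  }
  missing_ids <- setdiff(ids, library$compound_id)
  if (length(missing_ids) > 0L) {
    stop("criteria profile references compounds missing from the library: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }

  pseed <- derive_seed(config$seed,
                       sum(utf8ToInt(taxon$taxon_id)) %% 100000L + 500L)
  with_local_seed(pseed, {
    rts <- library$rt_min[match(ids, library$compound_id)]
    if (config$rt_jitter_sd > 0 && length(rts) > 0L) {
      rts <- rts + stats::rnorm(length(rts), 0, config$rt_jitter_sd)
    }
    rts <- pmin(pmax(rts, 0.01), 19.99)
    if (config$n_noise_peaks > 0L) {
      guard <- 3 * config$rt_tolerance
      noise_rt <- numeric(0)
      while (length(noise_rt) < config$n_noise_peaks) {
        cand <- stats::runif(1, 0.2, 19.8)
        if (all(abs(cand - library$rt_min) >= guard)) {
          noise_rt <- c(noise_rt, cand)
        }
      }
      rts <- c(rts, noise_rt)
      areas <- c(areas, stats::runif(config$n_noise_peaks,
                                     config$noise_area_range[1],
                                     config$noise_area_range[2]))
    }
    out <- data.frame(rt_min = rts, area = areas)
    out <- out[order(out$rt_min), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "sample_id") <- taxon$taxon_id
    class(out) <- c("lav_peak_table", "data.frame")
    out
  })
}

#' Simulate the full study panel
#'
#' Generates, for every taxon of the reference panel: references for all
#' three markers, a paired read set per marker, and a chromatographic peak
#' table; plus the compound library. If \code{outdir} is given, everything
#' is written to disk (per-marker multi-FASTA of references, paired-read
#' FASTA, per-sample peak-table CSV, the library CSV and a manifest JSON).
#'
#' @param seed Integer seed.
#' @param config Optional \code{\link{generator_config}} (defaults to
#'   \code{generator_config(seed)}).
#' @param outdir Optional output directory.
#' @return Invisible list with \code{config}, \code{panel},
#'   \code{references} (marker -> named vector), \code{reads}
#'   (marker -> taxon -> forward/reverse), \code{peak_tables} (named list)
#'   and \code{library}.
#' @export
simulate_study <- function(seed = 1L, config = NULL, outdir = NULL) {
  if (is.null(config)) config <- generator_config(seed = seed)
  panel <- lavandula_panel()
  markers <- lavandula_markers()
  library <- lav_compound_library()

  references <- lapply(markers, function(mk)
    make_marker_references(config, panel, mk))
  reads <- lapply(references, function(refs)
    lapply(refs, make_read_pairs, config = config))
  peak_tables <- lapply(seq_len(nrow(panel)), function(i)
    make_peak_table(panel[i, , drop = FALSE], library, config))
  names(peak_tables) <- panel$taxon_id

  result <- list(config = config, panel = panel, references = references,
                 reads = reads, peak_tables = peak_tables,
                 library = library)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    for (m in names(references)) {
      f <- file.path(outdir, paste0("references_", m, ".fasta"))
      recs <- references[[m]]
      names(recs) <- paste0(names(recs), "|", m)
      write_fasta(recs, f)
      files <- c(files, f)
      f2 <- file.path(outdir, paste0("reads_", m, ".fasta"))
      rd <- reads[[m]]
      flat <- unlist(lapply(names(rd), function(tx)
        stats::setNames(c(rd[[tx]]$forward, rd[[tx]]$reverse),
                        paste0(tx, "|", m, "|", c("F", "R")))))
      write_fasta(flat, f2)
      files <- c(files, f2)
    }
    for (tx in names(peak_tables)) {
      f <- file.path(outdir, paste0("peaks_", tx, ".csv"))
      write_peak_table(peak_tables[[tx]], f)
      files <- c(files, f)
    }
    flib <- file.path(outdir, "compound_library.csv")
    utils::write.csv(library, flib, row.names = FALSE)
    files <- c(files, flib)
    manifest <- list(seed = config$seed, files = basename(files))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(result)
}
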