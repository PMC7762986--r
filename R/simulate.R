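#' Simulation configuration
#'
#' Describes the world the analysis assumes: per marker, identical gap-free
#' conserved anchor blocks flank hypervariable segments whose ungapped lengths
#' carry a per-species effect plus intraspecific indel noise. Defaults mirror
#' a 13-taxon, 35-accession organellar study design with 4 chloroplast-like
#' and 6 mitochondrion-like markers.
#'
#' @param n_species Number of species (terminal taxa).
#' @param accessions_per_species Integer scalar or vector of length
#'   `n_species`. The default for 13 species is the 35-accession allocation
#'   (nine species with 3 accessions, four with 2).
#' @param n_markers Number of markers; default 10 (4 cpDNA-like + 6
#'   mtDNA-like), with names `cp1..cp4, mt1..mt6`.
#' @param marker_names Optional character vector of marker names.
#' @param conserved_blocks_per_marker Scalar or vector (recycled) of anchor
#'   block counts per marker; the default mirrors the study's per-marker
#'   anchor counts (6,5,4,4 for the cpDNA-like and 4,4,5,4,3,5 for the
#'   mtDNA-like markers).
#' @param conserved_block_length Anchor block length in bp.
#' @param hv_base_length_range Range (min, max) of the per-region base
#'   fragment length in bp; organellar spacer segments of 80-300 bp.
#' @param species_length_effect_range Signed range of the per-species length
#'   offset in bp. When the range holds at least `n_species` integers, effects
#'   are drawn without replacement, so species profiles are distinct by
#'   construction.
#' @param intraspecific_indel_prob Probability q that an accession carries a
#'   private indel in a region.
#' @param intraspecific_indel_size_range Size range of that indel in bp
#'   (1-5 bp, the size class reported for organellar spacer indels).
#' @param missing_prob Probability an accession's sequence is absent from a
#'   marker.
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return List of class `spindel_sim_config`.
#' @export
spindel_sim_config <- function(n_species = 13L,
                               accessions_per_species = NULL,
                               n_markers = 10L,
                               marker_names = NULL,
                               conserved_blocks_per_marker = NULL,
                               conserved_block_length = 20L,
                               hv_base_length_range = c(80L, 300L),
                               species_length_effect_range = c(-10L, 10L),
                               intraspecific_indel_prob = 0.1,
                               intraspecific_indel_size_range = c(1L, 5L),
                               missing_prob = 0,
                               seed = 1L) {
  n_species <- as.integer(n_species)
  n_markers <- as.integer(n_markers)
  if (is.null(accessions_per_species)) {
    accessions_per_species <- if (n_species == 13L) {
      rep(c(3L, 2L), c(9L, 4L))  # 35 accessions
    } else 3L
  }
  if (length(accessions_per_species) == 1L) {
    accessions_per_species <- rep(as.integer(accessions_per_species), n_species)
  }
  accessions_per_species <- as.integer(accessions_per_species)
  if (is.null(marker_names)) {
    marker_names <- if (n_markers == 10L) {
      c(paste0("cp", 1:4), paste0("mt", 1:6))
    } else sprintf("m%02d", seq_len(n_markers))
  }
  if (is.null(conserved_blocks_per_marker)) {
    conserved_blocks_per_marker <- if (n_markers == 10L) {
      c(6L, 5L, 4L, 4L, 4L, 4L, 5L, 4L, 3L, 5L)
    } else 4L
  }
  conserved_blocks_per_marker <-
    as.integer(rep_len(conserved_blocks_per_marker, n_markers))
  cfg <- structure(list(
    n_species = n_species,
    accessions_per_species = accessions_per_species,
    n_markers = n_markers,
    marker_names = marker_names,
    conserved_blocks_per_marker = conserved_blocks_per_marker,
    conserved_block_length = as.integer(conserved_block_length),
    hv_base_length_range = as.integer(hv_base_length_range),
    species_length_effect_range = as.integer(species_length_effect_range),
    intraspecific_indel_prob = intraspecific_indel_prob,
    intraspecific_indel_size_range = as.integer(intraspecific_indel_size_range),
    missing_prob = missing_prob,
    seed = as.integer(seed)
  ), class = "spindel_sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_species < 1L || n_markers < 1L || conserved_block_length < 1L) {
      stop("config error: counts must be >= 1")
    }
    if (length(accessions_per_species) != n_species || any(accessions_per_species < 1L)) {
      stop("config error: accessions_per_species must have one entry >= 1 per species")
    }
    if (length(marker_names) != n_markers || anyDuplicated(marker_names)) {
      stop("config error: marker_names must be ", n_markers, " unique names")
    }
    if (any(conserved_blocks_per_marker < 2L)) {
      stop("config error: need >= 2 conserved blocks per marker for interior regions")
    }
    for (r in list(hv_base_length_range, species_length_effect_range,
                   intraspecific_indel_size_range)) {
      if (length(r) != 2L || r[1L] > r[2L]) stop("config error: ranges must be ordered (min, max)")
    }
    for (p in c(intraspecific_indel_prob, missing_prob)) {
      if (p < 0 || p > 1) stop("config error: probabilities must be in [0, 1]")
    }
    if (hv_base_length_range[1L] + species_length_effect_range[1L] < 0L) {
      stop("config error: minimum base length plus most negative species effect is < 0")
    }
  })
  cfg
}

random_dna <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate marker alignments with full ground truth
#'
#' For each marker: one random anchor sequence per conserved block, shared by
#' every sequence; for each interior hypervariable region a base length is
#' drawn, a per-species offset added, and with probability q each accession
#' additionally carries a private indel (one insertion-or-deletion, size
#' uniform on the configured range, sign by fair coin, lengths clamped at 0).
#' Hypervariable segments are realized as random nucleotides, left-aligned and
#' gap-padded to the region's maximum length, so anchors stay gap-free and
#' identical across sequences. With probability `missing_prob` an accession's
#' sequence is dropped from a marker.
#'
#' @param config A [spindel_sim_config()].
#' @return List with `alignments` (named list of `spindel_alignment`),
#'   `metadata` (`sample_metadata`) and `truth`: `anchors`
#'   (`conserved_regions` over all markers), `lengths` (long data.frame:
#'   accession, marker, hv_index, length), `species` (accession -> species
#'   map), `marker_order`.
#' @export
simulate_spindel <- function(config = spindel_sim_config()) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  species <- sprintf("species_%02d", seq_len(cfg$n_species))
  acc_species <- rep(species, cfg$accessions_per_species)
  accessions <- sprintf("acc_%03d", seq_along(acc_species))
  n_acc <- length(accessions)

  alignments <- list()
  anchors_all <- list()
  lengths_all <- list()
  meta_all <- list()

  for (mi in seq_len(cfg$n_markers)) {
    marker <- cfg$marker_names[mi]
    n_blocks <- cfg$conserved_blocks_per_marker[mi]
    n_hv <- n_blocks - 1L
    anchor_seqs <- vapply(seq_len(n_blocks), function(i) {
      random_dna(cfg$conserved_block_length)
    }, character(1))

    # true fragment lengths: base + species effect + optional private indel
    len <- matrix(0L, nrow = n_acc, ncol = n_hv)
    for (h in seq_len(n_hv)) {
      base <- sample(seq(cfg$hv_base_length_range[1L], cfg$hv_base_length_range[2L]), 1L)
      eff_pool <- seq(cfg$species_length_effect_range[1L], cfg$species_length_effect_range[2L])
      effects <- if (length(eff_pool) >= cfg$n_species) {
        sample(eff_pool, cfg$n_species, replace = FALSE)
      } else {
        sample(eff_pool, cfg$n_species, replace = TRUE)
      }
      l <- base + effects[match(acc_species, species)]
      has_indel <- stats::runif(n_acc) < cfg$intraspecific_indel_prob
      if (any(has_indel)) {
        size <- sample(seq(cfg$intraspecific_indel_size_range[1L],
                           cfg$intraspecific_indel_size_range[2L]),
                       sum(has_indel), replace = TRUE)
        sign <- sample(c(-1L, 1L), sum(has_indel), replace = TRUE)
        l[has_indel] <- l[has_indel] + sign * size
      }
      len[, h] <- pmax(l, 0L)
    }

    present <- stats::runif(n_acc) >= cfg$missing_prob
    if (!any(present)) present[1L] <- TRUE  # never emit an empty alignment
    hv_max <- apply(len[present, , drop = FALSE], 2L, max)

    seqs <- vapply(seq_len(n_acc), function(a) {
      if (!present[a]) return(NA_character_)
      parts <- character(2L * n_blocks - 1L)
      parts[seq(1L, length(parts), by = 2L)] <- anchor_seqs
      for (h in seq_len(n_hv)) {
        frag <- random_dna(len[a, h])
        parts[2L * h] <- paste0(frag, strrep("-", hv_max[h] - len[a, h]))
      }
      paste(parts, collapse = "")
    }, character(1))

    ids <- paste(accessions, marker, sep = "_")
    keep <- which(present)
    aln_seqs <- stats::setNames(seqs[keep], ids[keep])
    alignments[[marker]] <- new_alignment(marker, aln_seqs)

    # true anchor intervals from the realized region widths
    starts <- integer(n_blocks); ends <- integer(n_blocks)
    pos <- 0L
    for (b in seq_len(n_blocks)) {
      starts[b] <- pos
      ends[b] <- pos + cfg$conserved_block_length
      pos <- ends[b] + if (b <= n_hv) hv_max[b] else 0L
    }
    anchors_all[[marker]] <- data.frame(
      marker = marker, region_index = seq_len(n_blocks) - 1L,
      start = starts, end = ends, consensus = anchor_seqs,
      stringsAsFactors = FALSE
    )
    lengths_all[[marker]] <- data.frame(
      accession = rep(accessions[keep], each = n_hv),
      marker = marker,
      hv_index = rep(seq_len(n_hv) - 1L, times = length(keep)),
      length = as.integer(t(len[keep, , drop = FALSE])),
      stringsAsFactors = FALSE
    )
    meta_all[[marker]] <- data.frame(
      sequence_id = ids[keep], accession = accessions[keep],
      species = acc_species[keep], subspecies = NA_character_,
      marker = marker, stringsAsFactors = FALSE
    )
  }

  metadata <- validate_metadata(do.call(rbind, meta_all))
  truth <- list(
    anchors = validate_regions(do.call(rbind, anchors_all)),
    lengths = do.call(rbind, lengths_all),
    species = data.frame(accession = accessions, species = acc_species,
                         stringsAsFactors = FALSE),
    marker_order = cfg$marker_names
  )
  rownames(truth$lengths) <- NULL
  list(alignments = alignments, metadata = metadata, truth = truth)
}

#' Profile table built directly from simulation ground truth
#'
#' Bypasses alignment parsing entirely — the oracle for end-to-end tests:
#' pipeline profiles must equal these truth profiles whenever no sequence is
#' missing.
#'
#' @param truth The `truth` element of a [simulate_spindel()] result.
#' @param markers Markers to include, in panel order (default all, in
#'   simulation order).
#' @return A `profile_table` with regions `"<marker>:hv<k>"`; accessions
#'   absent from a marker get `NA` lengths.
#' @export
truth_profiles <- function(truth, markers = truth$marker_order) {
  lg <- truth$lengths[truth$lengths$marker %in% markers, , drop = FALSE]
  acc <- sort(unique(truth$species$accession))
  panel <- unlist(lapply(markers, function(m) {
    hv <- sort(unique(lg$hv_index[lg$marker == m]))
    paste0(m, ":hv", hv)
  }))
  lens <- matrix(NA_integer_, nrow = length(acc), ncol = length(panel),
                 dimnames = list(NULL, panel))
  col <- match(paste0(lg$marker, ":hv", lg$hv_index), panel)
  row <- match(lg$accession, acc)
  lens[cbind(row, col)] <- lg$length
  sp <- truth$species$species[match(acc, truth$species$accession)]
  profile_table(acc, sp, lens)
}

#' Write a simulation to disk (FASTA + TSV)
#'
#' Writes per-marker aligned FASTA, the metadata TSV, the true anchor regions
#' TSV and the true profile table TSV into a directory.
#'
#' @param sim Result of [simulate_spindel()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in names(sim$alignments)) {
    write_alignment(sim$alignments[[m]], file.path(dir, paste0(m, ".fasta")))
  }
  write_metadata(sim$metadata, file.path(dir, "metadata.tsv"))
  write_regions(sim$truth$anchors, file.path(dir, "true_regions.tsv"))
  write_profile_table(truth_profiles(sim$truth), file.path(dir, "true_profiles.tsv"))
  invisible(dir)
}
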