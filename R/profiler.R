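#' Ungapped fragment length within a hypervariable region
#'
#' The length signal is the count of non-gap characters a sequence carries
#' inside the region's alignment columns — the physical fragment length, not
#' the (constant) alignment span. 'N' counts as a residue: ambiguity does not
#' change a fragment's length.
#'
#' @param residues Gapped sequence (single string).
#' @param start,end Region coordinates, 0-based half-open alignment columns.
#' @return Integer count of non-gap characters in `residues[start:end)`;
#'   0 for an empty span.
#' @export
fragment_length <- function(residues, start, end) {
  stopifnot(length(residues) == 1L, start >= 0L, end >= start,
            end <= nchar(residues))
  if (end == start) return(0L)
  span <- substr(residues, start + 1L, end)
  nchar(gsub("-", "", span, fixed = TRUE))
}

#' Build numeric length profiles for one marker
#'
#' Converts an alignment plus hypervariable-region definitions into a
#' [profile_table()]: one row per accession, one integer column per region,
#' each cell the ungapped fragment length. Region identifiers are
#' `"<marker>:hv<hv_index>"`. One sequence per accession per marker is
#' assumed; duplicates are collapsed when their profiles agree and are an
#' error otherwise.
#'
#' @param aln A `spindel_alignment`.
#' @param hv_regions `hv_regions` data.frame for this marker (see
#'   [derive_hypervariable_regions()]).
#' @param meta `sample_metadata`; every alignment sequence id must appear with
#'   this marker.
#' @param level `"species"` labels rows by species; `"subspecies"` treats
#'   subspecies as terminal taxa (label `species/subspecies` where a
#'   subspecies is recorded).
#' @return A `profile_table`, rows sorted by accession.
#' @export
build_profiles <- function(aln, hv_regions, meta,
                           level = c("species", "subspecies")) {
  stopifnot(inherits(aln, "spindel_alignment"))
  level <- match.arg(level)
  hv <- as.data.frame(hv_regions)
  hv <- hv[hv$marker == aln$marker_name, , drop = FALSE]
  if (nrow(hv) == 0L) stop("no hypervariable regions supplied for marker ", aln$marker_name)
  hv <- hv[order(hv$hv_index), , drop = FALSE]
  if (any(hv$end > aln$width)) stop("geometry error: region exceeds alignment width")

  md <- as.data.frame(meta)
  md <- md[md$marker == aln$marker_name, , drop = FALSE]
  ids <- names(aln$sequences)
  missing_ids <- setdiff(ids, md$sequence_id)
  if (length(missing_ids) > 0L) {
    stop("labeling error: sequence(s) missing from metadata for marker ",
         aln$marker_name, ": ", paste(missing_ids, collapse = ", "))
  }
  md <- md[match(ids, md$sequence_id), , drop = FALSE]
  label <- if (level == "subspecies") {
    ifelse(!is.na(md$subspecies) & nzchar(md$subspecies),
           paste(md$species, md$subspecies, sep = "/"), md$species)
  } else md$species

  lens <- vapply(seq_len(nrow(hv)), function(j) {
    vapply(aln$sequences, fragment_length,
           integer(1), start = hv$start[j], end = hv$end[j], USE.NAMES = FALSE)
  }, integer(length(ids)))
  lens <- matrix(as.integer(lens), nrow = length(ids))
  colnames(lens) <- paste0(aln$marker_name, ":hv", hv$hv_index)

  # collapse duplicate sequences for one accession when their profiles agree
  if (anyDuplicated(md$accession)) {
    keep <- !logical(length(ids))
    for (acc in unique(md$accession[duplicated(md$accession)])) {
      rows <- which(md$accession == acc)
      prof <- unique(lapply(rows, function(i) lens[i, ]))
      if (length(prof) > 1L) {
        stop("duplicate accession ", acc, " in marker ", aln$marker_name,
             " with conflicting profiles")
      }
      keep[rows[-1L]] <- FALSE
    }
    lens <- lens[keep, , drop = FALSE]
    md <- md[keep, , drop = FALSE]
    label <- label[keep]
  }
  profile_table(md$accession, label, lens)
}

#' Merge per-marker profile tables into one multi-marker panel
#'
#' Concatenates panels in the given order; each accession's profile is the
#' concatenated length vector. An accession absent from some marker gets
#' missing entries in that marker's columns. Species labels must agree across
#' tables for each accession.
#'
#' @param tables List of `profile_table`s with pairwise-disjoint panels.
#' @return A merged `profile_table` over the union of accessions.
#' @export
merge_panels <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  lapply(tables, function(t) stopifnot(inherits(t, "profile_table")))
  panels <- lapply(tables, panel_of)
  all_panel <- unlist(panels, use.names = FALSE)
  if (anyDuplicated(all_panel)) {
    stop("panel collision: region identifier(s) repeated across tables: ",
         paste(unique(all_panel[duplicated(all_panel)]), collapse = ", "))
  }
  acc <- sort(unique(unlist(lapply(tables, function(t) t$accession))))
  species <- rep(NA_character_, length(acc))
  names(species) <- acc
  for (t in tables) {
    sp <- t$species[match(acc, t$accession)]
    clash <- !is.na(species) & !is.na(sp) & species != sp
    if (any(clash)) {
      stop("metadata-conflict error: accession ", acc[clash][1L],
           " labeled both '", species[clash][1L], "' and '", sp[clash][1L], "'")
    }
    species[!is.na(sp)] <- sp[!is.na(sp)]
  }
  if (any(is.na(species))) stop("accession without species label after merge")
  lens <- matrix(NA_integer_, nrow = length(acc), ncol = length(all_panel),
                 dimnames = list(NULL, all_panel))
  for (t in tables) {
    m <- profile_matrix(t)
    lens[match(t$accession, acc), panel_of(t)] <- m
  }
  profile_table(acc, unname(species), lens)
}
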