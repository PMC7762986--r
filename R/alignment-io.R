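#' Read a marker alignment from aligned FASTA
#'
#' Parses an aligned FASTA file into a `spindel_alignment`. Residues are
#' upper-cased; the only accepted gap character is `'-'` (the `'.'` dialect is
#' rejected so that ungapped length counting stays unambiguous). Characters
#' outside `{A,C,G,T,N,-}` (e.g. IUPAC ambiguity codes from chromatogram-derived
#' data) are accepted but recorded in the validation report attached as the
#' `"flagged"` attribute (see [alignment_validation()]).
#'
#' @param path Path to an aligned FASTA file.
#' @param marker_name Name of the marker (locus) the alignment covers.
#' @return A `spindel_alignment`: list with `marker_name`, `sequences` (named
#'   character vector, names are sequence ids), and `width` (alignment columns).
#' @export
read_alignment <- function(path, marker_name) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty input: no FASTA records in ", path)
  seqs <- toupper(as.character(set))
  # FASTA descriptions: id is the first whitespace-delimited token
  ids <- sub("\\s.*$", "", names(set))
  names(seqs) <- ids
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(grepl(".", seqs, fixed = TRUE))) {
    bad <- ids[grepl(".", seqs, fixed = TRUE)][1L]
    stop("gap dialect error: '.' gaps found (record ", bad,
         "); only '-' is accepted as a gap character")
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    ref <- widths[1L]
    off <- ids[widths != ref][1L]
    stop("alignment-width error: record ", off, " has width ",
         widths[ids == off][1L], " but ", ids[1L], " has width ", ref)
  }
  new_alignment(marker_name, seqs)
}

new_alignment <- function(marker_name, seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L, !is.null(names(seqs)))
  width <- unique(nchar(seqs))
  stopifnot(length(width) == 1L, width > 0L)
  aln <- structure(
    list(marker_name = marker_name, sequences = seqs, width = as.integer(width)),
    class = "spindel_alignment"
  )
  flagged <- alignment_validation(aln)
  if (nrow(flagged) > 0L) {
    message("alignment ", marker_name, ": ", nrow(flagged),
            " sequence(s) carry residues outside {A,C,G,T,N,-} (see alignment_validation())")
  }
  aln
}

#' Report non-canonical residues in an alignment
#'
#' @param aln A `spindel_alignment`.
#' @return data.frame with one row per sequence containing residues outside
#'   `{A,C,G,T,N,-}`: columns `sequence_id`, `residues` (the offending
#'   characters, collapsed), `count`.
#' @export
alignment_validation <- function(aln) {
  stopifnot(inherits(aln, "spindel_alignment"))
  bad <- lapply(aln$sequences, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    ch[!ch %in% c("A", "C", "G", "T", "N", "-")]
  })
  n <- vapply(bad, length, integer(1))
  keep <- n > 0L
  data.frame(
    sequence_id = names(aln$sequences)[keep],
    residues = vapply(bad[keep], function(x) paste(sort(unique(x)), collapse = ""), character(1)),
    count = n[keep],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @export
print.spindel_alignment <- function(x, ...) {
  cat("<spindel_alignment> marker:", x$marker_name,
      "|", length(x$sequences), "sequences x", x$width, "columns\n")
  invisible(x)
}

#' Write an alignment to FASTA
#'
#' Inverse of [read_alignment()]; read-write-read is the identity on
#' (id, residues) pairs.
#'
#' @param aln A `spindel_alignment`.
#' @param path Output file path.
#' @param wrap Line width for sequence wrapping.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(aln, path, wrap = 70L) {
  stopifnot(inherits(aln, "spindel_alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$sequences)) {
    writeLines(paste0(">", names(aln$sequences)[i]), con)
    s <- aln$sequences[[i]]
    starts <- seq(1L, nchar(s), by = wrap)
    writeLines(substring(s, starts, pmin(starts + wrap - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-separated with header columns `sequence_id`, `accession`, `species`,
#' `marker`, and optionally `subspecies` (empty / absent subspecies values are
#' allowed and stored as `NA`).
#'
#' @param path Path to the metadata TSV.
#' @return data.frame of class `sample_metadata` with columns `sequence_id`,
#'   `accession`, `species`, `subspecies`, `marker`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                          check.names = FALSE, na.strings = c("NA", ""))
  required <- c("sequence_id", "accession", "species", "marker")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("schema error: metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("schema error: metadata table has no records")
  if (!"subspecies" %in% names(df)) df$subspecies <- NA_character_
  df <- df[, c("sequence_id", "accession", "species", "subspecies", "marker")]
  validate_metadata(df)
}

validate_metadata <- function(df) {
  key <- paste(df$sequence_id, df$marker, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate-key error: (sequence_id, marker) pair repeated: (",
         d$sequence_id, ", ", d$marker, ")")
  }
  if (any(is.na(df$species) | !nzchar(df$species))) {
    stop("schema error: empty species label in metadata")
  }
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Write a sample metadata table
#' @param meta A `sample_metadata` data.frame.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Construct a profile table
#'
#' A profile table is the accession x hypervariable-region matrix of ungapped
#' fragment lengths (the numeric profiles), plus species labels. Stored as a
#' data.frame with columns `accession`, `species`, then one integer column per
#' panel region; the region identifiers form the panel, kept in the `"panel"`
#' attribute in panel order.
#'
#' @param accession,species Character vectors, one entry per row.
#' @param lengths Integer matrix (rows = accessions, columns = panel regions)
#'   or data.frame; `NA` marks a missing length.
#' @param panel Character vector of region identifiers naming the columns.
#' @return data.frame of class `profile_table`.
#' @export
profile_table <- function(accession, species, lengths, panel = colnames(lengths)) {
  lengths <- as.matrix(lengths)
  storage.mode(lengths) <- "integer"
  stopifnot(length(accession) == nrow(lengths), length(species) == nrow(lengths))
  if (is.null(panel)) panel <- paste0("hv", seq_len(ncol(lengths)) - 1L)
  stopifnot(length(panel) == ncol(lengths), !anyDuplicated(panel))
  if (any(is.na(species) | !nzchar(species))) stop("empty species label in profile table")
  if (any(lengths < 0L, na.rm = TRUE)) stop("negative fragment length in profile table")
  df <- data.frame(accession = as.character(accession),
                   species = as.character(species),
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_along(panel)) df[[panel[j]]] <- lengths[, j]
  df <- df[order(df$accession), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, panel = panel, class = c("profile_table", "data.frame"))
}

#' Panel (region identifiers) of a profile table
#' @param table A `profile_table`.
#' @return Character vector of region identifiers, in panel order.
#' @export
panel_of <- function(table) {
  stopifnot(inherits(table, "profile_table"))
  attr(table, "panel")
}

#' Profile lengths of a table as an integer matrix
#' @param table A `profile_table`.
#' @return Integer matrix, rows named by accession, columns by panel id.
#' @export
profile_matrix <- function(table) {
  p <- panel_of(table)
  m <- as.matrix(as.data.frame(table)[, p, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- table$accession
  m
}

#' Write a profile table to TSV
#'
#' Columns: `accession`, `species`, then one integer-or-NA column per
#' hypervariable region. Missing lengths are written as the literal `NA`.
#' Round-trips losslessly with [read_profile_table()].
#'
#' @param table A `profile_table`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_profile_table <- function(table, path) {
  stopifnot(inherits(table, "profile_table"))
  if (nrow(table) == 0L) stop("profile table is empty")
  ok <- tryCatch({
    utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) stop("write error: ", conditionMessage(e)))
  invisible(path)
}

#' Read a profile table from TSV
#' @param path Path to a TSV written by [write_profile_table()].
#' @return A `profile_table`.
#' @export
read_profile_table <- function(path) {
  if (!file.exists(path)) stop("profile table file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = "NA")
  required <- c("accession", "species")
  if (!all(required %in% names(df)[1:2])) {
    stop("schema error: profile table must start with columns accession, species")
  }
  panel <- setdiff(names(df), required)
  if (length(panel) == 0L) stop("schema error: profile table has no region columns")
  profile_table(df$accession, df$species, df[, panel, drop = FALSE], panel)
}

#' @export
print.profile_table <- function(x, ...) {
  cat("<profile_table> ", nrow(x), " accessions x ", length(attr(x, "panel")),
      " regions [", paste(attr(x, "panel"), collapse = ", "), "]\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}

# Subsetting keeps the class and panel attribute coherent.
#' @export
`[.profile_table` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("accession", "species") %in% names(out))) {
    pan <- intersect(attr(x, "panel"), names(out))
    attr(out, "panel") <- pan
    class(out) <- c("profile_table", "data.frame")
  }
  out
}
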