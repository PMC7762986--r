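#' Detect conserved anchor blocks in a marker alignment
#'
#' A column qualifies as conserved when (a) its gap fraction is at most
#' `max_gap_fraction` and (b) the modal residue frequency among non-gap
#' characters is at least `min_identity`. With `window > 1` both statistics are
#' smoothed by a centered sliding-window mean before thresholding (the window
#' shrinks at the alignment edges). Maximal runs of qualifying columns of
#' length at least `min_width` are reported left to right, with the consensus
#' given by per-column modal residues (ties broken alphabetically).
#'
#' All coordinates are 0-based, half-open alignment columns.
#'
#' @param aln A `spindel_alignment`.
#' @param window Sliding-window width for smoothing the per-column statistics;
#'   the default 1 tests each column on its own.
#' @param min_identity Minimum modal-residue frequency among non-gap characters.
#' @param max_gap_fraction Maximum fraction of gaps tolerated in a column.
#' @param min_width Minimum run length (columns) for a reported block.
#' @return data.frame of class `conserved_regions` with columns `marker`,
#'   `region_index` (0-based, left to right), `start`, `end` (0-based,
#'   half-open), `consensus`. Empty (0-row) when no run qualifies.
#' @export
detect_conserved_regions <- function(aln, window = 1L, min_identity = 1.0,
                                     max_gap_fraction = 0.0, min_width = 15L) {
  stopifnot(inherits(aln, "spindel_alignment"))
  window <- as.integer(window)
  if (window < 1L) stop("parameter error: window must be >= 1")
  if (window > aln$width) stop("parameter error: window exceeds alignment width")
  if (!(min_identity > 0 && min_identity <= 1)) {
    stop("parameter error: min_identity must be in (0, 1]")
  }
  if (max_gap_fraction < 0 || max_gap_fraction > 1) {
    stop("parameter error: max_gap_fraction must be in [0, 1]")
  }
  min_width <- as.integer(min_width)
  if (min_width < 1L) stop("parameter error: min_width must be >= 1")

  chars <- do.call(rbind, strsplit(aln$sequences, "", fixed = TRUE))
  nseq <- nrow(chars)
  gap_frac <- colMeans(chars == "-")
  modal <- apply(chars, 2L, function(col) {
    res <- col[col != "-"]
    if (length(res) == 0L) return(c(freq = 0, residue = "-"))
    tab <- table(res)
    top <- max(tab)
    # alphabetical tie-break for a deterministic consensus
    c(freq = top / length(res), residue = sort(names(tab)[tab == top])[1L])
  })
  modal_freq <- as.numeric(modal["freq", ])
  consensus_res <- as.character(modal["residue", ])

  if (window > 1L) {
    gap_frac <- slide_mean(gap_frac, window)
    modal_freq <- slide_mean(modal_freq, window)
  }
  qualifies <- gap_frac <= max_gap_fraction & modal_freq >= min_identity

  runs <- rle(qualifies)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_width
  out <- data.frame(
    marker = character(0), region_index = integer(0),
    start = integer(0), end = integer(0), consensus = character(0),
    stringsAsFactors = FALSE
  )
  if (any(keep)) {
    s <- starts[keep]; e <- ends[keep]
    out <- data.frame(
      marker = aln$marker_name,
      region_index = seq_along(s) - 1L,
      start = s - 1L,           # to 0-based half-open
      end = e,
      consensus = vapply(seq_along(s), function(i) {
        paste(consensus_res[s[i]:e[i]], collapse = "")
      }, character(1)),
      stringsAsFactors = FALSE
    )
  }
  structure(out, class = c("conserved_regions", "data.frame"))
}

# centered sliding mean; windows shrink at the edges
slide_mean <- function(x, w) {
  n <- length(x)
  half <- (w - 1L) %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (w - 1L - half), n)
  cs <- c(0, cumsum(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

validate_regions <- function(regions) {
  stopifnot(is.data.frame(regions))
  required <- c("marker", "region_index", "start", "end", "consensus")
  if (!all(required %in% names(regions))) {
    stop("schema error: regions table needs columns ", paste(required, collapse = ", "))
  }
  if (any(regions$start >= regions$end)) {
    bad <- which(regions$start >= regions$end)[1L]
    stop("geometry error: region with start >= end (",
         regions$start[bad], " >= ", regions$end[bad], ")")
  }
  regions <- regions[order(regions$marker, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  for (m in unique(regions$marker)) {
    r <- regions[regions$marker == m, , drop = FALSE]
    if (nrow(r) > 1L && any(r$start[-1L] < r$end[-nrow(r)])) {
      stop("geometry error: overlapping conserved regions in marker ", m)
    }
    regions$region_index[regions$marker == m] <- seq_len(nrow(r)) - 1L
  }
  structure(regions, class = c("conserved_regions", "data.frame"))
}

#' Derive hypervariable regions from conserved anchors
#'
#' Interior hypervariable regions span exactly the columns between consecutive
#' conserved blocks (k blocks yield k-1 interior regions). With
#' `include_peripheral = TRUE` the possibly-empty spans before the first and
#' after the last block are also returned, flagged `peripheral`; peripheral
#' spans are excluded from concatenated analyses by default because adjacent
#' markers are not contiguous in the genome.
#'
#' @param regions `conserved_regions` for a single marker, sorted and
#'   non-overlapping.
#' @param aln_width Alignment width in columns.
#' @param include_peripheral Also return the flanks outside the outermost
#'   blocks.
#' @return data.frame of class `hv_regions` with columns `marker`, `hv_index`
#'   (0-based, left to right), `start`, `end` (0-based half-open), `peripheral`.
#' @export
derive_hypervariable_regions <- function(regions, aln_width,
                                         include_peripheral = FALSE) {
  regions <- validate_regions(as.data.frame(regions))
  if (length(unique(regions$marker)) != 1L) {
    stop("derive_hypervariable_regions expects regions of a single marker")
  }
  if (any(regions$end > aln_width)) {
    stop("geometry error: conserved region exceeds alignment width")
  }
  m <- regions$marker[1L]
  k <- nrow(regions)
  starts <- integer(0); ends <- integer(0); peri <- logical(0)
  if (include_peripheral) {
    starts <- c(starts, 0L); ends <- c(ends, regions$start[1L]); peri <- c(peri, TRUE)
  }
  if (k > 1L) {
    starts <- c(starts, regions$end[-k])
    ends <- c(ends, regions$start[-1L])
    peri <- c(peri, rep(FALSE, k - 1L))
  }
  if (include_peripheral) {
    starts <- c(starts, regions$end[k]); ends <- c(ends, aln_width); peri <- c(peri, TRUE)
  }
  ord <- order(starts)
  out <- data.frame(
    marker = if (length(starts)) m else character(0),
    hv_index = seq_along(starts) - 1L,
    start = as.integer(starts[ord]), end = as.integer(ends[ord]),
    peripheral = peri[ord],
    stringsAsFactors = FALSE
  )
  structure(out, class = c("hv_regions", "data.frame"))
}

#' Read / write conserved-region tables
#'
#' TSV with columns `marker`, `region_index`, `start`, `end`, `consensus`;
#' coordinates 0-based half-open. Rows are sorted by (marker, start) on read
#' and region indices renumbered; overlapping or inverted intervals raise a
#' geometry error. Round-trips with [write_regions()].
#'
#' @param path Path to the regions TSV.
#' @return `conserved_regions` data.frame.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("regions file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = "NA")
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$region_index <- as.integer(df$region_index)
  if (any(df$start < 0, na.rm = TRUE)) stop("geometry error: negative start coordinate")
  validate_regions(df)
}

#' @rdname read_regions
#' @param regions `conserved_regions` data.frame to write.
#' @export
write_regions <- function(regions, path) {
  regions <- validate_regions(as.data.frame(regions))
  utils::write.table(regions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
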