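# Profiles are compared as exact length vectors; a missing length is a
# distinct token for grouping but is skipped in pairwise comparisons
# (pairwise-complete).

# pairs x positions indicator matrix over all unordered row pairs:
# 1 = both present and unequal, 0 = both present and equal, NA = either missing
pair_difference_matrix <- function(lens) {
  m <- nrow(lens)
  idx <- utils::combn(m, 2L)
  a <- lens[idx[1L, ], , drop = FALSE]
  b <- lens[idx[2L, ], , drop = FALSE]
  out <- (a != b) * 1L
  dimnames(out) <- list(NULL, colnames(lens))
  out
}

profile_keys <- function(lens) {
  if (ncol(lens) == 0L) return(rep("", nrow(lens)))
  apply(lens, 1L, function(r) paste(ifelse(is.na(r), ".", r), collapse = ","))
}

#' Group identical profiles and mark species-specific ones
#'
#' A profile is species-specific when its carrier species set has size one —
#' it may still be carried by several accessions of that species.
#'
#' @param table A `profile_table`.
#' @return data.frame with one row per distinct profile: `profile` (lengths as
#'   `"l1,l2,..."`, `.` marking a missing value), `n_accessions`, `accessions`,
#'   `n_species`, `species` (comma-separated carrier lists), `complete`
#'   (no missing length), `species_specific`.
#' @export
classify_profiles <- function(table) {
  stopifnot(inherits(table, "profile_table"))
  if (nrow(table) == 0L) stop("profile table is empty")
  lens <- profile_matrix(table)
  key <- profile_keys(lens)
  groups <- split(seq_len(nrow(table)), key)
  out <- data.frame(
    profile = names(groups),
    n_accessions = vapply(groups, length, integer(1)),
    accessions = vapply(groups, function(i) paste(sort(table$accession[i]), collapse = ","), character(1)),
    n_species = vapply(groups, function(i) length(unique(table$species[i])), integer(1)),
    species = vapply(groups, function(i) paste(sort(unique(table$species[i])), collapse = ","), character(1)),
    complete = !grepl(".", names(groups), fixed = TRUE),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out$species_specific <- out$n_species == 1L
  out[order(-out$n_accessions, out$profile), , drop = FALSE]
}

#' Frequency of species-specific profiles (f_sp)
#'
#' Default (`definition = "accession"`): the fraction of accessions with a
#' complete profile whose profile is species-specific. The species-level
#' alternative is the fraction of species all of whose complete-profile
#' accessions carry species-specific profiles.
#'
#' @param table A `profile_table`.
#' @param definition `"accession"` (default) or `"species"`.
#' @return Fraction in `[0, 1]`.
#' @export
species_specific_frequency <- function(table,
                                       definition = c("accession", "species")) {
  definition <- match.arg(definition)
  stopifnot(inherits(table, "profile_table"))
  lens <- profile_matrix(table)
  complete <- !apply(lens, 1L, anyNA)
  if (!any(complete)) stop("undefined statistic: all profiles are incomplete")
  sub <- table[complete, , drop = FALSE]
  key <- profile_keys(profile_matrix(sub))
  n_species_by_key <- vapply(split(sub$species, key),
                             function(s) length(unique(s)), integer(1))
  specific <- n_species_by_key[key] == 1L
  if (definition == "accession") {
    return(sum(specific) / nrow(sub))
  }
  by_sp <- vapply(split(specific, sub$species), all, logical(1))
  sum(by_sp) / length(by_sp)
}

#' Pairwise profile differences and the mismatch distribution
#'
#' For each unordered accession pair, the difference is the number of panel
#' positions where both lengths are present and unequal (pairwise-complete:
#' positions missing in either profile are skipped). Pairs with no comparable
#' position are excluded from the distribution and counted separately.
#'
#' @param table A `profile_table` with at least 2 rows.
#' @return List with `mean` (average difference count), `distribution` (named
#'   integer vector: difference count -> number of pairs), `n_pairs` (pairs in
#'   the distribution) and `n_incomparable`.
#' @export
pairwise_differences <- function(table) {
  stopifnot(inherits(table, "profile_table"))
  if (nrow(table) < 2L) stop("need at least 2 profiles for pairwise differences")
  D <- pair_difference_matrix(profile_matrix(table))
  comparable <- rowSums(!is.na(D)) > 0L
  n_incomparable <- sum(!comparable)
  diffs <- as.integer(rowSums(D[comparable, , drop = FALSE], na.rm = TRUE))
  if (length(diffs) == 0L) {
    return(list(mean = NaN, distribution = integer(0), n_pairs = 0L,
                n_incomparable = n_incomparable))
  }
  tab <- table(factor(diffs, levels = 0:max(diffs)))
  distribution <- stats::setNames(as.integer(tab), names(tab))
  list(mean = mean(diffs), distribution = distribution,
       n_pairs = length(diffs), n_incomparable = n_incomparable)
}

# species are separable on a position subset when no two species share a
# restricted profile
species_separable <- function(lens, species, subset) {
  key <- profile_keys(lens[, subset, drop = FALSE])
  n_sp <- vapply(split(species, key), function(s) length(unique(s)), integer(1))
  all(n_sp == 1L)
}

#' Smallest region subset discriminating all species
#'
#' Exhaustive search over subsets of `pool` in increasing cardinality: the
#' result is the smallest k such that restricting profiles to some k positions
#' makes every species' set of restricted profiles disjoint from every other
#' species' set. All witness subsets of the minimal size are returned in
#' lexicographic order.
#'
#' @param table A `profile_table`.
#' @param pool Panel positions to search over: integer indices or region
#'   identifiers. Defaults to the full panel.
#' @return List with `size` (integer, `NA` when not achievable), `achievable`
#'   (logical) and `witnesses` (list of integer position vectors).
#' @export
min_discriminating_subset <- function(table, pool = NULL) {
  stopifnot(inherits(table, "profile_table"))
  pan <- panel_of(table)
  if (is.null(pool)) pool <- seq_along(pan)
  if (is.character(pool)) pool <- match(pool, pan)
  pool <- sort(unique(as.integer(pool)))
  if (length(pool) == 0L || anyNA(pool) || any(pool < 1L | pool > length(pan))) {
    stop("pool must be a nonempty set of valid panel positions")
  }
  lens <- profile_matrix(table)
  species <- table$species
  if (!species_separable(lens, species, pool)) {
    return(list(size = NA_integer_, achievable = FALSE, witnesses = list()))
  }
  for (k in seq_along(pool)) {
    subs <- utils::combn(pool, k, simplify = FALSE)  # lexicographic order
    hits <- Filter(function(s) species_separable(lens, species, s), subs)
    if (length(hits) > 0L) {
      return(list(size = k, achievable = TRUE, witnesses = hits))
    }
  }
  list(size = NA_integer_, achievable = FALSE, witnesses = list())
}

#' Full per-panel statistics (one summary row per region set)
#'
#' Assembles the marker-level summary: distinct profiles (N), species-specific
#' profiles (Nsp), species-shared profiles (N - Nsp), species carrying shared
#' profiles, f_sp, average pairwise differences with the mismatch
#' distribution, and the minimum discriminating subset size. Profiles with
#' missing lengths are excluded from the N/Nsp/f_sp accounting
#' (complete-profile statistics) and handled pairwise-complete in the
#' difference summaries.
#'
#' @param table A `profile_table`.
#' @param conserved_count Number of conserved anchor blocks (reported
#'   verbatim; `NA` when unknown).
#' @param pool Pool of panel positions for the minimum-subset search
#'   (defaults to the full panel).
#' @param fsp_definition Passed to [species_specific_frequency()].
#' @return List of class `region_stats` with fields `n_conserved`,
#'   `n_hypervariable`, `n_distinct_profiles`, `n_species_specific_profiles`,
#'   `n_species_shared_profiles`, `n_species_with_shared_profiles`, `f_sp`,
#'   `avg_pairwise_differences`, `avg_pairwise_differences_per_region`,
#'   `min_regions_for_discrimination` (integer or `NA` = not achievable),
#'   `min_region_witnesses`, `mismatch_distribution`, `n_pairs`,
#'   `n_incomparable_pairs`.
#' @export
region_stats <- function(table, conserved_count = NA_integer_, pool = NULL,
                         fsp_definition = c("accession", "species")) {
  stopifnot(inherits(table, "profile_table"))
  fsp_definition <- match.arg(fsp_definition)
  pan <- panel_of(table)
  lens <- profile_matrix(table)
  complete <- !apply(lens, 1L, anyNA)
  cls <- classify_profiles(table[complete, , drop = FALSE])
  n_distinct <- nrow(cls)
  n_specific <- sum(cls$species_specific)
  shared <- cls[!cls$species_specific, , drop = FALSE]
  n_species_shared <- if (nrow(shared) == 0L) 0L else {
    length(unique(unlist(strsplit(shared$species, ",", fixed = TRUE))))
  }
  pw <- pairwise_differences(table)
  mds <- min_discriminating_subset(table, pool)
  structure(list(
    n_conserved = as.integer(conserved_count),
    n_hypervariable = length(pan),
    panel = pan,
    n_distinct_profiles = n_distinct,
    n_species_specific_profiles = n_specific,
    n_species_shared_profiles = n_distinct - n_specific,
    n_species_with_shared_profiles = n_species_shared,
    f_sp = species_specific_frequency(table, fsp_definition),
    avg_pairwise_differences = pw$mean,
    avg_pairwise_differences_per_region = pw$mean / length(pan),
    min_regions_for_discrimination = mds$size,
    min_region_witnesses = mds$witnesses,
    mismatch_distribution = pw$distribution,
    n_pairs = pw$n_pairs,
    n_incomparable_pairs = pw$n_incomparable
  ), class = "region_stats")
}

#' @export
print.region_stats <- function(x, ...) {
  cat("<region_stats>\n")
  cat("  conserved blocks:        ", x$n_conserved, "\n")
  cat("  hypervariable regions n: ", x$n_hypervariable, "\n")
  cat("  distinct profiles N:     ", x$n_distinct_profiles, "\n")
  cat("  species-specific Nsp:    ", x$n_species_specific_profiles, "\n")
  cat("  species sharing profiles:", x$n_species_with_shared_profiles, "\n")
  cat("  f_sp:                    ", format(x$f_sp, digits = 4), "\n")
  cat("  avg pairwise diffs p:    ", format(x$avg_pairwise_differences, digits = 4),
      " (", x$n_pairs, " pairs)\n", sep = "")
  cat("  min regions to separate: ",
      if (is.na(x$min_regions_for_discrimination)) "not achievable"
      else x$min_regions_for_discrimination, "\n")
  invisible(x)
}

#' Aggregate per-region summary rows into genome-level means
#'
#' Computes the column means a multi-marker study reports (mean Nsp, mean
#' f_sp, mean pairwise differences, ...) from a table of per-region values —
#' either one assembled from [region_stats()] results or a published summary
#' table read from TSV.
#'
#' @param df data.frame with any of the numeric columns `nsp`, `f_sp`,
#'   `avg_pairwise`, `avg_pairwise_per_region`, `n_shared_species`,
#'   `min_regions`.
#' @param by Optional name of a grouping column (e.g. genome); when given, one
#'   row of means per group is returned.
#' @return data.frame of means (columns prefixed `mean_`).
#' @export
aggregate_region_stats <- function(df, by = NULL) {
  stopifnot(is.data.frame(df))
  cols <- intersect(c("nsp", "f_sp", "avg_pairwise", "avg_pairwise_per_region",
                      "n_shared_species", "min_regions"), names(df))
  if (length(cols) == 0L) stop("no aggregatable columns found")
  agg <- function(d) {
    out <- lapply(d[cols], function(x) mean(as.numeric(x)))
    names(out) <- paste0("mean_", cols)
    as.data.frame(out)
  }
  if (is.null(by)) return(agg(df))
  stopifnot(by %in% names(df))
  parts <- split(df, df[[by]])
  res <- do.call(rbind, lapply(parts, agg))
  res <- cbind(stats::setNames(data.frame(names(parts)), by), res)
  rownames(res) <- NULL
  res
}

#' Write a stats report as JSON (with a TSV mirror)
#'
#' @param stats A `region_stats` object.
#' @param path Output JSON path; a TSV mirror of the summary row is written
#'   alongside with extension `.tsv`.
#' @param params Named list echoed into the report for provenance.
#' @return Invisibly, `path`.
#' @export
write_stats_json <- function(stats, path, params = list()) {
  stopifnot(inherits(stats, "region_stats"))
  body <- unclass(stats)
  body$min_regions_for_discrimination <-
    if (is.na(stats$min_regions_for_discrimination)) "not achievable"
    else stats$min_regions_for_discrimination
  body$min_region_witnesses <- lapply(stats$min_region_witnesses, as.integer)
  body$mismatch_distribution <- as.list(stats$mismatch_distribution)
  report <- c(list(schema_version = "1.0", parameters = params), body)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tsv <- paste0(tools::file_path_sans_ext(path), ".tsv")
  row <- data.frame(
    n_conserved = stats$n_conserved, n_hypervariable = stats$n_hypervariable,
    avg_pairwise = stats$avg_pairwise_differences,
    avg_pairwise_per_region = stats$avg_pairwise_differences_per_region,
    nsp = stats$n_species_specific_profiles, f_sp = stats$f_sp,
    n_shared_profiles = stats$n_species_shared_profiles,
    n_species_with_shared = stats$n_species_with_shared_profiles,
    min_regions = ifelse(is.na(stats$min_regions_for_discrimination), "not achievable",
                         stats$min_regions_for_discrimination)
  )
  utils::write.table(row, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
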