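# Concatenated multi-marker analysis: which region combinations separate the
# most taxa, how different profiles are overall, and which marker pairs carry
# the signal.

subset_fsp <- function(lens, species, subset) {
  sub <- lens[, subset, drop = FALSE]
  complete <- !apply(sub, 1L, anyNA)
  if (!any(complete)) return(NA_real_)
  key <- profile_keys(sub[complete, , drop = FALSE])
  n_sp <- vapply(split(species[complete], key),
                 function(s) length(unique(s)), integer(1))
  sum(n_sp[key] == 1L) / sum(complete)
}

#' Enumerate all hypervariable-region combinations
#'
#' Scores every nonempty subset of the panel: f_sp, number of distinct
#' (complete) profiles, and average pairwise differences computed on profiles
#' restricted to the subset. Exhaustive enumeration is the default because
#' study panels are small (2^n subsets); for larger panels use
#' [greedy_combination()] and treat its result as approximate.
#'
#' @param table A `profile_table`.
#' @param max_panel Guard against exponential blowup; panels larger than this
#'   raise an error advising pool restriction.
#' @return data.frame with one row per subset: `subset` (list column of
#'   integer panel positions), `label` (region ids, comma-separated), `size`,
#'   `f_sp`, `n_distinct_profiles`, `avg_pairwise_differences`; sorted by
#'   f_sp descending, then size ascending, then lexicographic subset order.
#' @export
enumerate_combinations <- function(table, max_panel = 20L) {
  stopifnot(inherits(table, "profile_table"))
  pan <- panel_of(table)
  n <- length(pan)
  if (n > max_panel) {
    stop("panel too large (", n, " regions > max_panel = ", max_panel,
         "): restrict the pool or use greedy_combination()")
  }
  lens <- profile_matrix(table)
  species <- table$species
  D <- pair_difference_matrix(lens)
  subsets <- unlist(lapply(seq_len(n), function(k) {
    utils::combn(seq_len(n), k, simplify = FALSE)
  }), recursive = FALSE)
  out <- data.frame(
    label = vapply(subsets, function(s) paste(pan[s], collapse = ","), character(1)),
    size = vapply(subsets, length, integer(1)),
    f_sp = vapply(subsets, function(s) subset_fsp(lens, species, s), numeric(1)),
    n_distinct_profiles = vapply(subsets, function(s) {
      key <- profile_keys(lens[, s, drop = FALSE])
      length(unique(key[!grepl(".", key, fixed = TRUE)]))
    }, integer(1)),
    avg_pairwise_differences = vapply(subsets, function(s) {
      d <- D[, s, drop = FALSE]
      comp <- rowSums(!is.na(d)) > 0L
      if (!any(comp)) return(NaN)
      mean(rowSums(d[comp, , drop = FALSE], na.rm = TRUE))
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  out$subset <- subsets
  lex <- vapply(subsets, function(s) paste(sprintf("%03d", s), collapse = ""), character(1))
  ord <- order(-out$f_sp, out$size, lex)
  out <- out[ord, c("subset", "label", "size", "f_sp",
                    "n_distinct_profiles", "avg_pairwise_differences")]
  rownames(out) <- NULL
  out
}

#' Greedy (approximate) combination search for large panels
#'
#' Forward selection on f_sp: repeatedly adds the region that most increases
#' f_sp (ties to the lowest position). Approximate — may miss the optimum.
#'
#' @param table A `profile_table`.
#' @param max_size Stop after this many regions (default full panel).
#' @return data.frame like [enumerate_combinations()], one row per greedy step.
#' @export
greedy_combination <- function(table, max_size = length(panel_of(table))) {
  stopifnot(inherits(table, "profile_table"))
  pan <- panel_of(table)
  lens <- profile_matrix(table)
  species <- table$species
  chosen <- integer(0)
  rows <- list()
  while (length(chosen) < max_size) {
    cand <- setdiff(seq_along(pan), chosen)
    gains <- vapply(cand, function(p) subset_fsp(lens, species, sort(c(chosen, p))),
                    numeric(1))
    best <- cand[which.max(gains)]
    chosen <- sort(c(chosen, best))
    sub <- table
    attr(sub, "panel") <- pan[chosen]
    pw <- if (nrow(table) >= 2L) pairwise_differences(sub) else list(mean = NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      label = paste(pan[chosen], collapse = ","), size = length(chosen),
      f_sp = subset_fsp(lens, species, chosen),
      avg_pairwise_differences = pw$mean, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$approximate <- TRUE
  out
}

#' Mismatch distribution over a concatenated panel
#'
#' Same semantics as [pairwise_differences()] applied to the merged
#' multi-marker table (peripheral regions should already have been excluded
#' when the per-marker profiles were built; see
#' [derive_hypervariable_regions()]).
#'
#' @param table A merged `profile_table` (see [merge_panels()]).
#' @return As [pairwise_differences()].
#' @export
concatenated_mismatch <- function(table) {
  pairwise_differences(table)
}

#' Region-by-region discriminatory potential matrix
#'
#' Cell (i, j) holds the average pairwise differences per region computed on
#' the union of the regions of groups i and j (mean difference count divided
#' by the number of regions in the union); the diagonal carries the
#' single-group values, so both "individual" and "pairwise" readings are
#' recoverable from one symmetric matrix.
#'
#' @param table A `profile_table`.
#' @param by_marker Group panel positions by marker (the `"<marker>:"` prefix
#'   of each region id); otherwise every region is its own group.
#' @return Symmetric numeric matrix with group labels on both dimensions.
#' @export
region_pair_matrix <- function(table, by_marker = TRUE) {
  stopifnot(inherits(table, "profile_table"))
  pan <- panel_of(table)
  groups <- if (by_marker) {
    marker <- sub(":.*$", "", pan)
    split(seq_along(pan), factor(marker, levels = unique(marker)))
  } else {
    stats::setNames(as.list(seq_along(pan)), pan)
  }
  if (length(groups) < 2L) stop("need at least 2 region groups")
  g <- length(groups)
  D <- pair_difference_matrix(profile_matrix(table))
  out <- matrix(NA_real_, g, g, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(g)) {
    for (j in seq(i, g)) {
      u <- sort(unique(c(groups[[i]], groups[[j]])))
      d <- D[, u, drop = FALSE]
      comp <- rowSums(!is.na(d)) > 0L
      mean_d <- if (any(comp)) mean(rowSums(d[comp, , drop = FALSE], na.rm = TRUE)) else NaN
      out[i, j] <- out[j, i] <- mean_d / length(u)
    }
  }
  out
}

#' Write a concatenation report as JSON
#'
#' Bundles all combination results, the concatenated mismatch distribution and
#' the region-pair matrix into one machine-readable report.
#'
#' @param table A merged `profile_table`.
#' @param path Output JSON path.
#' @param params Named list echoed for provenance.
#' @return Invisibly, `path`.
#' @export
write_concat_report <- function(table, path, params = list()) {
  comb <- enumerate_combinations(table)
  pw <- concatenated_mismatch(table)
  mat <- if (length(unique(sub(":.*$", "", panel_of(table)))) >= 2L) {
    region_pair_matrix(table, by_marker = TRUE)
  } else NULL
  report <- list(
    schema_version = "1.0",
    parameters = params,
    panel = panel_of(table),
    combinations = data.frame(
      label = comb$label, size = comb$size, f_sp = comb$f_sp,
      n_distinct_profiles = comb$n_distinct_profiles,
      avg_pairwise_differences = comb$avg_pairwise_differences
    ),
    mismatch_distribution = as.list(pw$distribution),
    mean_pairwise_differences = pw$mean,
    n_pairs = pw$n_pairs,
    n_incomparable_pairs = pw$n_incomparable,
    region_pair_matrix = if (is.null(mat)) NULL else {
      list(labels = rownames(mat), values = unname(apply(mat, 1L, as.list)))
    }
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
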