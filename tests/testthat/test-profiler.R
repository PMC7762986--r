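test_that("fragment_length counts non-gap characters in the span", {
  expect_equal(fragment_length("AAAAA--TTG", 5L, 8L), 1L)
  expect_equal(fragment_length("AAAAA--TTG", 0L, 0L), 0L)
  expect_equal(fragment_length("ACGTACGTAC", 2L, 7L), 5L)
  expect_equal(fragment_length("-----", 0L, 5L), 0L)
})

hv_df <- function(marker, start, end, hv_index = seq_along(start) - 1L) {
  data.frame(marker = marker, hv_index = hv_index, start = start, end = end,
             peripheral = FALSE, stringsAsFactors = FALSE)
}

test_that("build_profiles produces one labeled row per accession", {
  # anchors ACGTACGTAC (0,10) and (15,25); hv region (10,15)
  aln <- make_alignment(c(
    x1_m1 = "ACGTACGTACAA---TTGACCTGAA",
    x2_m1 = "ACGTACGTACAAA--TTGACCTGAA",
    x3_m1 = "ACGTACGTAC-----TTGACCTGAA"
  ), "m1")
  meta <- make_metadata(c("x1_m1", "x2_m1", "x3_m1"), c("x1", "x2", "x3"),
                        c("spA", "spA", "spB"))
  hv <- hv_df("m1", 10L, 15L)
  tab <- build_profiles(aln, hv, meta)
  expect_s3_class(tab, "profile_table")
  expect_equal(panel_of(tab), "m1:hv0")
  expect_equal(tab$accession, c("x1", "x2", "x3"))
  expect_equal(unname(profile_matrix(tab)[, 1]), c(2L, 3L, 0L))

  # identical sequences give identical profiles
  aln2 <- make_alignment(c(y1_m1 = "ACGTACGTACAA---TTGACCTGAA",
                           y2_m1 = "ACGTACGTACAA---TTGACCTGAA"), "m1")
  meta2 <- make_metadata(c("y1_m1", "y2_m1"), c("y1", "y2"), c("spA", "spB"))
  tab2 <- build_profiles(aln2, hv, meta2)
  expect_equal(length(unique(profile_matrix(tab2)[, 1])), 1L)

  # sequence absent from metadata is a labeling error naming the id
  expect_error(build_profiles(aln, hv, meta2), "labeling.*x1_m1")
})

test_that("profiles match a per-character oracle and ignore input order", {
  set.seed(99)
  for (rep in 1:20) {
    n_seq <- sample(2:6, 1)
    width <- 30L
    seqs <- vapply(seq_len(n_seq), function(i) {
      paste(sample(c("A", "C", "G", "T", "-"), width, replace = TRUE), collapse = "")
    }, character(1))
    names(seqs) <- sprintf("q%d_m1", seq_len(n_seq))
    aln <- make_alignment(seqs, "m1")
    cuts <- sort(sample(0:width, 4))
    hv <- hv_df("m1", cuts[c(1, 3)], cuts[c(2, 4)])
    meta <- make_metadata(names(seqs), sprintf("q%d", seq_len(n_seq)))
    tab <- build_profiles(aln, hv, meta)
    lens <- profile_matrix(tab)
    for (i in seq_len(n_seq)) {
      acc <- sprintf("q%d", i)
      for (j in 1:2) {
        expect_equal(lens[acc, j],
                     oracle_fragment_length(seqs[[i]], hv$start[j], hv$end[j]))
      }
    }
    shuffled <- make_alignment(seqs[sample(n_seq)], "m1")
    expect_identical(build_profiles(shuffled, hv, meta), tab)
  }
})

test_that("interior lengths plus anchor residues conserve total length", {
  sim <- simulate_spindel(spindel_sim_config(
    n_species = 4, accessions_per_species = 2, n_markers = 1,
    conserved_blocks_per_marker = 4, seed = 21
  ))
  aln <- sim$alignments[[1]]
  r <- detect_conserved_regions(aln)
  hv <- derive_hypervariable_regions(r, aln$width)
  tab <- build_profiles(aln, hv, sim$metadata)
  lens <- profile_matrix(tab)
  for (id in names(aln$sequences)) {
    acc <- sim$metadata$accession[match(id, sim$metadata$sequence_id)]
    anchored <- fragment_length(aln$sequences[[id]], min(r$start), max(r$end))
    in_blocks <- sum(vapply(seq_len(nrow(r)), function(b) {
      fragment_length(aln$sequences[[id]], r$start[b], r$end[b])
    }, integer(1)))
    expect_equal(sum(lens[acc, ]) + in_blocks, anchored)
  }
})

test_that("profiles are invariant to gap-only columns outside the anchors", {
  seqs <- c(z1_m1 = "ACGTACGTACAA---TTGACCTGAA",
            z2_m1 = "ACGTACGTACAAAA-TTGACCTGAA")
  hv <- hv_df("m1", 10L, 15L)
  meta <- make_metadata(names(seqs), c("z1", "z2"))
  base <- build_profiles(make_alignment(seqs, "m1"), hv, meta)
  padded <- build_profiles(
    make_alignment(setNames(paste0(seqs, "--"), names(seqs)), "m1"), hv, meta)
  expect_equal(profile_matrix(padded), profile_matrix(base))
})

test_that("duplicate sequences per accession collapse only when they agree", {
  seqs <- c(d1_m1 = "ACGTACGTACAA---TTGACCTGAA",
            d2_m1 = "ACGTACGTACAA---TTGACCTGAA")
  hv <- hv_df("m1", 10L, 15L)
  meta <- make_metadata(names(seqs), c("d", "d"), c("spA", "spA"))
  tab <- build_profiles(make_alignment(seqs, "m1"), hv, meta)
  expect_equal(nrow(tab), 1L)

  seqs2 <- c(d1_m1 = "ACGTACGTACAA---TTGACCTGAA",
             d2_m1 = "ACGTACGTACAAAA-TTGACCTGAA")
  expect_error(build_profiles(make_alignment(seqs2, "m1"), hv, meta),
               "conflicting profiles")
})

test_that("merge_panels concatenates panels and handles absences", {
  lensA <- matrix(c(1L, 2L, 3L, 4L), nrow = 2)
  tabA <- make_table(lensA, species = c("spA", "spB"),
                     panel = c("mA:hv0", "mA:hv1"))
  tabB <- make_table(lensA + 10L, species = c("spA", "spB"),
                     panel = c("mB:hv0", "mB:hv1"))
  merged <- merge_panels(list(tabA, tabB))
  expect_equal(panel_of(merged), c("mA:hv0", "mA:hv1", "mB:hv0", "mB:hv1"))
  expect_equal(nrow(merged), 2L)

  # a table merged with itself under new panel names doubles the panel
  tabA2 <- tabA
  attr(tabA2, "panel") <- c("mC:hv0", "mC:hv1")
  names(tabA2)[3:4] <- c("mC:hv0", "mC:hv1")
  doubled <- merge_panels(list(tabA, tabA2))
  expect_equal(length(panel_of(doubled)), 4L)

  # panel collision is rejected
  expect_error(merge_panels(list(tabA, tabA)), "collision")

  # accession missing from one marker gets NA there only
  tabB_sub <- tabB[tabB$accession == "a01", ]
  m2 <- merge_panels(list(tabA, tabB_sub))
  expect_equal(unname(is.na(profile_matrix(m2)["a02", ])),
               c(FALSE, FALSE, TRUE, TRUE))

  # conflicting species labels across tables
  tabB_bad <- tabB
  tabB_bad$species <- c("spA", "spX")
  expect_error(merge_panels(list(tabA, tabB_bad)), "metadata-conflict")
})
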