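test_that("classify_profiles groups identical profiles by carrier species", {
  # three distinct single-species profiles
  t1 <- make_table(matrix(c(1L, 2L, 3L), ncol = 1))
  c1 <- classify_profiles(t1)
  expect_equal(nrow(c1), 3L)
  expect_true(all(c1$species_specific))

  # two species sharing one profile: N = 1, Nsp = 0, two sharing species
  t2 <- make_table(matrix(c(5L, 5L), ncol = 1), species = c("spA", "spB"))
  c2 <- classify_profiles(t2)
  expect_equal(nrow(c2), 1L)
  expect_false(any(c2$species_specific))
  expect_equal(c2$n_species, 2L)

  # one profile carried by two accessions of one species stays specific
  t3 <- make_table(matrix(c(5L, 5L, 9L), ncol = 1),
                   species = c("spA", "spA", "spB"))
  c3 <- classify_profiles(t3)
  expect_equal(sum(c3$species_specific), 2L)
})

test_that("f_sp follows the accession-weighted definition", {
  t1 <- make_table(matrix(1:4, ncol = 1))
  expect_equal(species_specific_frequency(t1), 1.0)

  # two species fully sharing one profile, third unique, 3 accessions
  t2 <- make_table(matrix(c(5L, 5L, 9L), ncol = 1),
                   species = c("spA", "spB", "spC"))
  expect_equal(species_specific_frequency(t2), 1 / 3)

  # 35 accessions, 32 with species-specific profiles -> 32/35 (prints 0.91)
  lens <- matrix(c(rep(100L, 3), 200L + seq_len(32)), ncol = 1)
  species <- c("spX", "spX", "spY", sprintf("sp%02d", seq_len(32)))
  t3 <- make_table(lens, species = species)
  f <- species_specific_frequency(t3)
  expect_equal(f, 32 / 35)
  expect_equal(round(f, 2), 0.91)

  # species-level alternative: spX fully shared, spY fully shared
  expect_equal(species_specific_frequency(t3, definition = "species"), 32 / 34)

  # all-incomplete input is undefined
  t4 <- make_table(matrix(NA_integer_, 2, 1), species = c("spA", "spB"))
  expect_error(species_specific_frequency(t4), "undefined")
})

test_that("pairwise differences produce the mismatch distribution", {
  t1 <- make_table(matrix(c(1L, 1L, 1L, 2L, 2L, 2L), nrow = 3, byrow = TRUE))
  pw <- pairwise_differences(t1)
  expect_equal(pw$mean, 4 / 3)
  expect_equal(pw$distribution, c("0" = 0L, "1" = 2L, "2" = 1L))
  expect_equal(pw$n_pairs, 3L)

  # identical rows: all differences zero
  t2 <- make_table(matrix(7L, nrow = 4, ncol = 2),
                   species = rep("spA", 4))
  pw2 <- pairwise_differences(t2)
  expect_equal(pw2$distribution, c("0" = choose(4, 2)))
  expect_equal(pw2$mean, 0)

  # m = 35 accessions -> C(35,2) = 595 pairs
  set.seed(3)
  t3 <- random_table(35, 3)
  expect_equal(sum(pairwise_differences(t3)$distribution), 595L)

  # positions missing in either profile are skipped; fully incomparable
  # pairs are excluded and counted
  lens <- matrix(c(1L, NA, NA, 2L, 1L, 5L), nrow = 3, byrow = TRUE)
  t4 <- make_table(lens)
  pw4 <- pairwise_differences(t4)
  expect_equal(pw4$n_incomparable, 1L)
  expect_equal(pw4$n_pairs, 2L)
  expect_equal(pw4$distribution, c("0" = 1L, "1" = 1L))
})

test_that("Nsp + shared = N and f_sp is order-invariant (random tables)", {
  set.seed(17)
  for (rep in 1:25) {
    tab <- random_table(sample(4:12, 1), sample(1:4, 1))
    cls <- classify_profiles(tab)
    n <- nrow(cls)
    nsp <- sum(cls$species_specific)
    expect_equal(nsp + sum(!cls$species_specific), n)

    st <- region_stats(tab)
    expect_equal(st$n_species_specific_profiles + st$n_species_shared_profiles,
                 st$n_distinct_profiles)
    expect_gte(st$f_sp, 0)
    expect_lte(st$f_sp, 1)
    expect_lte(st$avg_pairwise_differences, st$n_hypervariable)

    # permutation invariance over accession and panel order
    perm <- tab[sample(nrow(tab)), ]
    pan <- panel_of(tab)
    shuf <- sample(pan)
    reordered <- profile_table(perm$accession, perm$species,
                               profile_matrix(perm)[, shuf, drop = FALSE], shuf)
    expect_equal(species_specific_frequency(reordered),
                 species_specific_frequency(tab))
  }
})

test_that("f_sp never decreases when the panel grows", {
  set.seed(23)
  for (rep in 1:20) {
    tab <- random_table(sample(5:10, 1), 4)
    lens <- profile_matrix(tab)
    pan <- panel_of(tab)
    f <- vapply(1:4, function(k) {
      sub <- profile_table(tab$accession, tab$species,
                           lens[, 1:k, drop = FALSE], pan[1:k])
      species_specific_frequency(sub)
    }, numeric(1))
    expect_true(all(diff(f) >= 0))
  }
})

test_that("min_discriminating_subset is exhaustive and reports witnesses", {
  # no single region separates all three species
  t1 <- make_table(cbind(A = c(1L, 1L, 2L), B = c(3L, 4L, 4L)),
                   panel = c("A", "B"))
  r1 <- min_discriminating_subset(t1)
  expect_equal(r1$size, 2L)
  expect_equal(r1$witnesses, list(c(1L, 2L)))

  # one region already separates everything
  t2 <- make_table(cbind(c(1L, 2L, 3L), c(9L, 9L, 9L)))
  r2 <- min_discriminating_subset(t2)
  expect_equal(r2$size, 1L)
  expect_equal(r2$witnesses[[1]], 1L)

  # identical full profiles for two species: not achievable
  t3 <- make_table(matrix(c(1L, 1L), ncol = 1), species = c("spA", "spB"))
  r3 <- min_discriminating_subset(t3)
  expect_false(r3$achievable)
  expect_true(is.na(r3$size))

  # matches an independent full-enumeration oracle on panels of <= 6 regions
  set.seed(31)
  for (rep in 1:15) {
    tab <- random_table(sample(4:8, 1), sample(2:6, 1), values = 0:2)
    got <- min_discriminating_subset(tab)
    want <- oracle_min_subset(tab)
    expect_equal(got$size, want$size)
    if (!is.na(want$size)) expect_equal(got$witnesses, want$witnesses)
  }

  # monotone in the pool: a superset pool never needs more regions
  set.seed(37)
  for (rep in 1:10) {
    tab <- random_table(6, 4, values = 0:2)
    small <- min_discriminating_subset(tab, pool = 1:2)
    big <- min_discriminating_subset(tab, pool = 1:4)
    if (small$achievable) {
      expect_true(big$achievable)
      expect_lte(big$size, small$size)
    }
  }
})

test_that("region_stats assembles a full summary row", {
  tab <- make_table(cbind(c(10L, 11L, 11L), c(5L, 5L, 6L)),
                    species = c("spA", "spB", "spB"))
  st <- region_stats(tab, conserved_count = 3L)
  expect_s3_class(st, "region_stats")
  expect_equal(st$n_conserved, 3L)
  expect_equal(st$n_hypervariable, 2L)
  expect_equal(st$n_distinct_profiles, 3L)
  expect_equal(st$n_species_specific_profiles, 3L)
  expect_equal(st$f_sp, 1.0)
  expect_equal(st$avg_pairwise_differences,
               mean(c(1, 2, 1)))
  expect_equal(st$avg_pairwise_differences_per_region,
               st$avg_pairwise_differences / 2)
  expect_equal(sum(st$mismatch_distribution), choose(3, 2))
  # region 1 alone already separates spA ({10}) from spB ({11})
  expect_equal(st$min_regions_for_discrimination, 1L)
})

test_that("aggregating the published per-region rows reproduces the means", {
  path <- system.file("extdata", "secale_region_summary.tsv", package = "spindelr")
  df <- read.delim(path)
  agg <- aggregate_region_stats(df, by = "genome")
  cp <- agg[agg$genome == "cpDNA", ]
  mt <- agg[agg$genome == "mtDNA", ]
  expect_equal(cp$mean_nsp, 2.5)
  expect_equal(round(cp$mean_f_sp, 2), 0.83)
  expect_equal(round(mt$mean_nsp, 2), 2.67)
  expect_equal(round(mt$mean_f_sp, 2), 0.73)
})

test_that("stats JSON report round-trips the key fields", {
  tab <- make_table(cbind(c(10L, 11L, 11L), c(5L, 5L, 6L)),
                    species = c("spA", "spB", "spB"))
  st <- region_stats(tab, conserved_count = 3L)
  path <- tempfile(fileext = ".json")
  write_stats_json(st, path, params = list(source = "unit-test"))
  rep <- jsonlite::read_json(path)
  expect_equal(rep$schema_version, "1.0")
  expect_equal(rep$parameters$source, "unit-test")
  expect_equal(rep$f_sp, 1.0)
  expect_equal(rep$n_distinct_profiles, 3L)
  expect_true(file.exists(sub("\\.json$", ".tsv", path)))
})
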