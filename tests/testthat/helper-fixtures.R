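# Fixtures are built in code; nothing is read from disk except what a test
# writes itself.

write_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0(">", names(seqs)[i]), seqs[i]), con)
  }
  path
}

make_alignment <- function(seqs, marker = "m1") {
  read_alignment(write_fasta(seqs), marker)
}

make_metadata <- function(sequence_id, accession = sequence_id,
                          species = accession, marker = "m1",
                          subspecies = NA_character_) {
  df <- data.frame(sequence_id = sequence_id, accession = accession,
                   species = species, subspecies = subspecies,
                   marker = marker, stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  read_metadata(path)
}

# profile table straight from a lengths matrix; species defaults to one
# species per accession
make_table <- function(lengths, species = NULL, panel = NULL) {
  lengths <- as.matrix(lengths)
  acc <- sprintf("a%02d", seq_len(nrow(lengths)))
  if (is.null(species)) species <- sprintf("s%02d", seq_len(nrow(lengths)))
  if (is.null(panel)) panel <- sprintf("m:hv%d", seq_len(ncol(lengths)) - 1L)
  colnames(lengths) <- panel
  profile_table(acc, species, lengths, panel)
}

random_table <- function(n_acc, n_regions, n_species = max(2L, n_acc %/% 2L),
                         values = 0:3, na_prob = 0) {
  lens <- matrix(sample(values, n_acc * n_regions, replace = TRUE),
                 nrow = n_acc)
  if (na_prob > 0) lens[runif(length(lens)) < na_prob] <- NA
  species <- sprintf("s%02d", sample(seq_len(n_species), n_acc, replace = TRUE))
  make_table(lens, species = species)
}

# independent per-character oracle for ungapped fragment length
oracle_fragment_length <- function(seq, start, end) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- 0L
  i <- start + 1L
  while (i <= end) {
    if (chars[i] != "-") n <- n + 1L
    i <- i + 1L
  }
  n
}

# independent full-enumeration oracle for the minimum discriminating subset
oracle_min_subset <- function(table, pool = seq_along(panel_of(table))) {
  lens <- profile_matrix(table)
  species <- table$species
  separable <- function(s) {
    keys <- apply(lens[, s, drop = FALSE], 1L, paste, collapse = "|")
    carriers <- lapply(split(species, keys), unique)
    all(vapply(carriers, length, integer(1)) == 1L)
  }
  for (k in seq_along(pool)) {
    subs <- combn(pool, k, simplify = FALSE)
    wit <- Filter(separable, subs)
    if (length(wit) > 0L) return(list(size = k, witnesses = wit))
  }
  list(size = NA_integer_, witnesses = list())
}
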