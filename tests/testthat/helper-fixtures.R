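# Small in-code fixtures shared across test files.

tax_path <- function(...) {
  v <- rep("Unknown", 8)
  names(v) <- PR2_RANKS
  args <- list(...)
  v[names(args)] <- unlist(args)
  v
}

make_taxonomy <- function(ids, genus = "Unknown", order = "Dino-Group-II",
                          division = "Dinoflagellata",
                          class = "Syndiniales") {
  n <- length(ids)
  data.frame(id = ids, kingdom = "Eukaryota", supergroup = "Alveolata",
             division = rep_len(division, n), class = rep_len(class, n),
             order = rep_len(order, n), family = "Unknown",
             genus = rep_len(genus, n), species = "Unknown",
             stringsAsFactors = FALSE)
}

make_records <- function(ids, seqs, dataset = "DS1",
                         short_amplicon = FALSE, identity = 95) {
  data.frame(id = ids, sequence = seqs,
             dataset = rep_len(dataset, length(ids)),
             short_amplicon = rep_len(short_amplicon, length(ids)),
             best_ref_identity = rep_len(identity, length(ids)),
             stringsAsFactors = FALSE)
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# tiny two-dataset input for harmonize()
tiny_datasets <- function() {
  r1 <- make_records(c("a1", "a2"), c(random_dna(400), random_dna(400)))
  t1 <- make_taxonomy(c("a1", "a2"))
  t1$division[1] <- "Metazoa"
  ab1 <- matrix(c(3, 1, 2, 4), 2, 2,
                dimnames = list(c("a1", "a2"), c("s1", "s2")))
  r2 <- make_records(c("b1", "b2"), c(random_dna(400), random_dna(400)),
                     dataset = "DS2")
  t2 <- make_taxonomy(c("b1", "b2"), genus = "Amoebophrya")
  ab2 <- matrix(c(5, 5), 2, 1, dimnames = list(c("b1", "b2"), "s3"))
  list(DS1 = list(records = r1, abundance = ab1, taxonomy = t1),
       DS2 = list(records = r2, abundance = ab2, taxonomy = t2))
}
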