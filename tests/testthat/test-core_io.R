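test_that("read_fasta reads, uppercases and validates records", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "acgt"), f)
  expect_equal(read_fasta(f),
               data.frame(id = "a", sequence = "ACGT",
                          stringsAsFactors = FALSE))

  writeLines(character(0), f)
  expect_equal(nrow(read_fasta(f)), 0L)

  writeLines(c(">a", "ACGT", ">a", "GGGG"), f)
  expect_error(read_fasta(f), "duplicate")

  writeLines(c(">x", "ACGT", ">y", "ACQT"), f)
  expect_error(read_fasta(f), "invalid")

  writeLines(c(">x", "ACGT", ">y", "ACGR"), f)
  expect_error(read_fasta(f), "y")
})

test_that("fasta round-trip preserves ids and sequences", {
  set.seed(1)
  recs <- make_records(sprintf("m%02d", 1:5),
                       vapply(rep(60, 5), random_dna, ""))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f)
  back <- read_fasta(f)
  expect_equal(back$id, recs$id)
  expect_equal(back$sequence, recs$sequence)
})

test_that("read_tables loads a consistent triple and validates cross-references", {
  dir <- withr::local_tempdir()
  ab <- data.frame(id = c("m1", "m2", "m3"), s1 = c(1, 0, 2),
                   s2 = c(0, 3, 1))
  write.table(ab, file.path(dir, "ab.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  md <- data.frame(sample_id = c("s1", "s2"), dataset = "DS1",
                   region = "North Sea", station = "st1",
                   date = "2015-03-05", depth_m = 1, depth_type = "SRF",
                   temperature = c(10.5, NA))
  write.table(md, file.path(dir, "md.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  tx <- make_taxonomy(c("m1", "m2", "m3"))
  write.table(tx, file.path(dir, "tx.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  out <- read_tables(file.path(dir, "ab.tsv"), file.path(dir, "md.tsv"),
                     file.path(dir, "tx.tsv"))
  expect_equal(dim(out$abundance), c(3L, 2L))
  expect_equal(out$abundance["m2", "s2"], 3)
  expect_true(is.na(out$metadata$temperature[2]))
  expect_s3_class(out$metadata$date, "Date")

  ab_bad <- ab; ab_bad$s1[1] <- -1
  write.table(ab_bad, file.path(dir, "ab_bad.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_tables(file.path(dir, "ab_bad.tsv"),
                           file.path(dir, "md.tsv"),
                           file.path(dir, "tx.tsv")), "negative")

  md_short <- md[1, ]
  write.table(md_short, file.path(dir, "md_short.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  expect_error(read_tables(file.path(dir, "ab.tsv"),
                           file.path(dir, "md_short.tsv"),
                           file.path(dir, "tx.tsv")), "s2")
})

test_that("normalize_samples yields unit column sums and is idempotent", {
  m <- matrix(c(10, 30, 60, 5, 0, 0), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  n1 <- normalize_samples(m)
  expect_equal(n1[, "s1"], c(a = 0.1, b = 0.3, c = 0.6))
  expect_equal(unname(colSums(n1)), c(1, 1), tolerance = 1e-9)
  expect_equal(normalize_samples(n1), n1, tolerance = 1e-12)
  expect_identical(n1 == 0, m == 0)

  expect_equal(unname(normalize_samples(matrix(5, 1, 1))[1, 1]), 1)
  z <- matrix(c(1, 0), 1, 2, dimnames = list("a", c("ok", "empty")))
  expect_error(normalize_samples(z), "empty")
})

test_that("rank_status distinguishes assigned, unassigned and gap", {
  p <- tax_path(kingdom = "Eukaryota", supergroup = "Alveolata",
                division = "Dinoflagellata", order = "Dino-Group-II")
  expect_equal(rank_status(p, "class"), "gap")
  expect_equal(rank_status(p, "genus"), "unassigned")
  expect_equal(rank_status(p, "order"), "assigned")
  full <- tax_path(kingdom = "k", supergroup = "s", division = "d",
                   class = "c", order = "o", family = "f", genus = "g",
                   species = "sp")
  expect_equal(rank_status(full, "species"), "assigned")
  expect_error(rank_status(full, "phylum"), "unknown rank")
})

test_that("rank_status never returns gap at species and is consistent", {
  set.seed(42)
  for (rep in 1:50) {
    labels <- ifelse(runif(8) < 0.5, "Unknown",
                     paste0("taxon", seq_len(8)))
    p <- stats::setNames(labels, PR2_RANKS)
    expect_true(rank_status(p, "species") %in% c("assigned", "unassigned"))
    st <- vapply(PR2_RANKS, function(r) rank_status(p, r), "")
    # a rank is a gap exactly when it is Unknown and some lower rank is
    # assigned
    for (i in seq_len(8)) {
      lower_assigned <- i < 8 && any(labels[(i + 1):8] != "Unknown")
      if (labels[i] != "Unknown") {
        expect_equal(unname(st[i]), "assigned")
      } else if (lower_assigned) {
        expect_equal(unname(st[i]), "gap")
      } else {
        expect_equal(unname(st[i]), "unassigned")
      }
    }
  }
})

test_that("depth_layer applies thresholds with DCM flag precedence", {
  expect_equal(depth_layer(3), "SRF")
  expect_equal(depth_layer(5), "SRF")
  expect_equal(depth_layer(1500), "BATHY")
  expect_equal(depth_layer(1000), "BATHY")
  expect_equal(depth_layer(200), "MESO")
  expect_equal(depth_layer(30), "OTHER")
  expect_equal(depth_layer(30, TRUE), "DCM")
  expect_equal(depth_layer(c(3, 500), c(FALSE, FALSE)), c("SRF", "MESO"))
  expect_error(depth_layer(-1), "non-negative")
})

test_that("season_of maps months to meteorological seasons", {
  expect_equal(season_of(as.Date(c("2020-01-15", "2020-12-01",
                                   "2020-04-10", "2020-07-07",
                                   "2020-10-31"))),
               c("DJF", "DJF", "MAM", "JJA", "SON"))
})
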