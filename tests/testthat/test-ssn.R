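test_that("longest_common_substring matches hand cases and the diagonal oracle", {
  expect_equal(longest_common_substring("ACGT", "CGTA"), 3L)
  s <- random_dna(50)
  expect_equal(longest_common_substring(s, s), 50L)
  expect_equal(longest_common_substring("AAAA", "CCCC"), 0L)
  expect_error(longest_common_substring("", "ACGT"), "empty")

  set.seed(11)
  for (k in 1:40) {
    a <- random_dna(sample(10:80, 1))
    b <- if (runif(1) < 0.5) random_dna(sample(10:80, 1)) else {
      # embed a shared segment to exercise long matches
      paste0(random_dna(sample(1:10, 1)),
             substr(a, 3, min(nchar(a), sample(10:60, 1))),
             random_dna(sample(1:10, 1)))
    }
    expect_equal(longest_common_substring(a, b), oracle_lcs(a, b))
  }
})

test_that("pair_edge applies the coverage rule with short-amplicon asymmetry", {
  set.seed(12)
  s400 <- random_dna(400)
  a <- make_records("a", s400)
  b <- make_records("b", s400)
  e <- pair_edge(a, b)
  expect_equal(e$match_len, 400L)
  expect_equal(c(e$coverage_a, e$coverage_b), c(1, 1))

  # 320/400 = 0.8 exactly: inclusive boundary
  sub320 <- make_records("c", substr(s400, 1, 320))
  e2 <- pair_edge(a, sub320)
  expect_equal(c(e2$coverage_a, e2$coverage_b), c(0.8, 1))

  sub319 <- make_records("d", substr(s400, 1, 319))
  expect_null(pair_edge(a, sub319))

  # short amplicon contained in a long sequence: only the short side
  # is coverage-tested
  s430 <- random_dna(430)
  long <- make_records("L", s430)
  short <- make_records("S", substr(s430, 100, 329), short_amplicon = TRUE)
  e3 <- pair_edge(long, short)
  expect_equal(e3$match_len, 230L)
  expect_equal(e3$coverage_b, 1)
  expect_lt(e3$coverage_a, 0.8)
  # two short amplicons fall back to the symmetric rule
  short2 <- make_records("S2", substr(s430, 1, 230), short_amplicon = TRUE)
  expect_null(pair_edge(short, short2))
})

test_that("build_ssn evaluates all pairs without self or duplicate edges", {
  set.seed(13)
  s <- random_dna(400)
  recs <- make_records(c("a", "b", "c"), c(s, s, s))
  edges <- build_ssn(recs)
  expect_equal(nrow(edges), 3L)
  expect_true(all(edges$id_a != edges$id_b))
  expect_equal(anyDuplicated(t(apply(edges[, 1:2], 1, sort))), 0L)

  # one central substitution caps the exact run below 0.8 coverage
  ch <- strsplit(s, "")[[1]]
  ch[200] <- setdiff(c("A", "C", "G", "T"), ch[200])[1]
  recs2 <- make_records(c("a", "b"), c(s, paste(ch, collapse = "")))
  expect_equal(nrow(build_ssn(recs2)), 0L)

  set.seed(14)
  recs3 <- make_records(c("x", "y"), c(random_dna(60), random_dna(60)))
  expect_equal(nrow(build_ssn(recs3)), 0L)
})

test_that("raising min_cov never adds edges", {
  set.seed(15)
  recs <- random_ssn_instance(40)
  recs$dataset <- "DS1"
  e_low <- build_ssn(recs, min_cov = 0.7)
  e_high <- build_ssn(recs, min_cov = 0.9)
  key <- function(e) paste(e$id_a, e$id_b)
  expect_true(all(key(e_high) %in% key(e_low)))
})

test_that("extract_ccs keeps components at the size cutoff and uses connectivity", {
  set.seed(16)
  seqs5 <- rep(random_dna(300), 5)
  seqs6 <- rep(random_dna(300), 6)
  recs <- make_records(c(sprintf("p%d", 1:5), sprintf("q%d", 1:6)),
                       c(seqs5, seqs6))
  edges <- build_ssn(recs)
  ccs <- extract_ccs(edges, recs$id, min_size = 6)
  expect_equal(length(ccs), 1L)
  expect_equal(ccs[[1]], sort(sprintf("q%d", 1:6)))
  expect_equal(length(extract_ccs(edges, recs$id, min_size = 5)), 2L)

  # chain a-b-c: connectivity, not clique
  edges2 <- data.frame(id_a = c("a", "b"), id_b = c("b", "c"),
                       match_len = 1L, coverage_a = 1, coverage_b = 1)
  cc2 <- extract_ccs(edges2, c("a", "b", "c"), min_size = 3)
  expect_equal(cc2[[1]], c("a", "b", "c"))

  empty <- extract_ccs(data.frame(id_a = character(), id_b = character()),
                       character(0))
  expect_equal(length(empty), 0L)
})

test_that("extracted components match the brute-force oracle and partition nodes", {
  set.seed(17)
  for (k in 1:5) {
    recs <- random_ssn_instance(sample(10:30, 1))
    got <- unname(extract_ccs(build_ssn(recs), recs$id, min_size = 2))
    want <- oracle_pipeline(recs, min_size = 2)
    expect_identical(got, want)
    all_cc <- extract_ccs(build_ssn(recs), recs$id, min_size = 1)
    expect_setequal(unlist(all_cc), recs$id)
    expect_equal(sum(lengths(all_cc)), nrow(recs))
  }
})

test_that("genus extrapolation follows the single-assigned-genus rule", {
  tax <- make_taxonomy(c("a", "b", "c"),
                       genus = c("Unknown", "Unknown", "Euduboscquella"))
  expect_equal(extrapolate_genus(c("a", "b", "c"), tax), "Euduboscquella")
  tax2 <- make_taxonomy(c("a", "b"), genus = "Unknown")
  expect_equal(extrapolate_genus(c("a", "b"), tax2), "unknown")
  tax3 <- make_taxonomy(c("a", "b"),
                        genus = c("Amoebophrya", "Euduboscquella"))
  expect_equal(extrapolate_genus(c("a", "b"), tax3), "ambiguous")
  expect_error(extrapolate_genus(c("a", "zz"), tax3), "zz")
})

test_that("cc_abundance sums member rows and checks ids", {
  m <- matrix(c(0.1, 0.2, 0, 0.3), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(cc_abundance(c("a", "b"), m), c(s1 = 0.3, s2 = 0.3))
  expect_equal(cc_abundance("b", m), c(s1 = 0.2, s2 = 0.3))
  expect_error(cc_abundance(c("a", "zz"), m), "zz")
})

test_that("label_ccs ranks components by total abundance", {
  set.seed(18)
  tax <- make_taxonomy(sprintf("m%d", 1:4),
                       genus = c("Unknown", "Unknown", "Amoebophrya",
                                 "Amoebophrya"))
  m <- matrix(c(1, 1, 5, 5), 4, 1,
              dimnames = list(sprintf("m%d", 1:4), "s1"))
  ccs <- list(CC1 = c("m1", "m2"), CC2 = c("m3", "m4"))
  lab <- label_ccs(ccs, tax, m)
  expect_equal(lab$summary$cc_id, c("CC_Amoebophrya_1", "CC_unknown_2"))
  expect_equal(lab$summary$total_abundance, c(10, 2))
  expect_equal(lab$members[["CC_unknown_2"]], c("m1", "m2"))
})
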