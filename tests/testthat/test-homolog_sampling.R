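hit_line <- function(q, s, pid, ev, bs)
  paste(q, s, pid, 200, 10, 1, 1, 200, 1, 200, ev, bs, sep = "\t")

test_that("hit-table reader applies the significance screen", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(hit_line("q", "s1", 90.0, "1e-50", 900),
               hit_line("q", "s2", 80.0, "1e-20", 700),
               hit_line("q", "s3", 70.0, "1e-03", 500),  # fails the cutoff
               hit_line("q", "s4", 60.0, "1e-06", 300),
               hit_line("q", "s5", 50.0, "1e-05", 100)), f)
  h <- read_hits(f)
  expect_equal(nrow(h), 4L)          # 1e-03 row dropped, 1e-05 kept (inclusive)
  expect_false("s3" %in% h$subject_id)

  writeLines(character(0), f)
  expect_equal(nrow(read_hits(f)), 0L)

  writeLines(hit_line("q", "s1", 90.0, "1e-50", "NA"), f)
  expect_error(read_hits(f), "line 1.*bitscore")
})

test_that("top hits are bit-score sorted, id-tiebroken and capped", {
  h <- data.frame(query_id = "q", subject_id = c("b", "a", "c"),
                  identity_pct = c(50, 60, 70), evalue = 1e-30,
                  bitscore = c(300, 500, 300), stringsAsFactors = FALSE)
  out <- top_hits(h, n = 1200)
  expect_equal(out$subject_id, c("a", "b", "c"))  # tie 300: b before c by id
  expect_equal(out$rank, 1:3)

  set.seed(1)
  big <- random_hits(2000)
  big$subject_id <- sprintf("s%04d", 1:2000)  # unique ids
  out <- top_hits(big, n = 1200)
  expect_equal(nrow(out), 1200L)
  expect_true(all(diff(out$bitscore) <= 0))
  expect_equal(out$rank, 1:1200)
})

test_that("representative selection is first-come-first-serve per phylum", {
  tax <- taxonomy_map(sprintf("s%02d", 1:20),
                      phylum = rep(c("P1", "P2"), 10),
                      flags = rep("bacteria", 20))
  one <- data.frame(query_id = "q", subject_id = sprintf("s%02d", seq(1, 19, 2)),
                    identity_pct = 90, evalue = 1e-30, bitscore = 100,
                    stringsAsFactors = FALSE)   # all P1
  expect_equal(select_representatives(one, tax, cap = 6),
               sprintf("s%02d", seq(1, 11, 2)))  # first 6 admitted

  mixed <- data.frame(query_id = "q", subject_id = sprintf("s%02d", 1:20),
                      identity_pct = 90, evalue = 1e-30, bitscore = 100,
                      stringsAsFactors = FALSE)  # interleaved P1/P2
  got <- select_representatives(mixed, tax, cap = 6)
  want <- oracle_select(mixed$subject_id, tax_phylum(tax, mixed$subject_id), 6)
  expect_identical(got, want)
  expect_equal(length(got), 12L)

  # subjects missing from the taxonomy: skipped with a warning by default
  mixed$subject_id[3] <- "unknown"
  expect_warning(got2 <- select_representatives(mixed, tax, cap = 6), "skipping")
  expect_false("unknown" %in% got2)
  expect_error(select_representatives(mixed, tax, cap = 6, unmapped = "error"),
               "missing from taxonomy")
})

test_that("two-pass sample is the union of both pass admissions plus query", {
  tax <- taxonomy_map(c(sprintf("a%d", 1:8), sprintf("b%d", 1:8), "Q"),
                      phylum = c(rep("P1", 8), rep("P2", 8), "Archaeplastida"),
                      flags = c(rep("bacteria", 16), "archaeplastida;query"))

  # orderings coincide -> union equals pass 1
  h <- data.frame(query_id = "Q", subject_id = c(sprintf("a%d", 1:8)),
                  identity_pct = seq(90, 76, -2), evalue = 1e-30,
                  bitscore = seq(900, 760, -20), stringsAsFactors = FALSE)
  s <- build_sample("Q", h, tax, cap = 2)
  expect_equal(s$member_ids, c("Q", "a1", "a2"))

  # identity order promotes a P2 member that bit score leaves out
  h2 <- data.frame(query_id = "Q",
                   subject_id = c("a1", "a2", "b1", "b2", "b3"),
                   identity_pct = c(50, 51, 52, 53, 99),
                   evalue = 1e-30,
                   bitscore = c(900, 880, 860, 840, 10),
                   stringsAsFactors = FALSE)
  s2 <- build_sample("Q", h2, tax, cap = 2)
  pass1 <- oracle_select(c("a1", "a2", "b1", "b2", "b3"),
                         tax_phylum(tax, c("a1", "a2", "b1", "b2", "b3")), 2)
  o2 <- order(-h2$identity_pct, h2$subject_id)
  pass2 <- oracle_select(h2$subject_id[o2], tax_phylum(tax, h2$subject_id[o2]), 2)
  expect_setequal(s2$member_ids, union("Q", union(pass1, pass2)))
  expect_true("b3" %in% s2$member_ids)          # identity pass only
  expect_gt(length(s2$member_ids), length(pass1) + 1)

  # empty hit list -> sample of just the query
  s3 <- build_sample("Q", h2[0, ], tax)
  expect_equal(s3$member_ids, "Q")
})

test_that("bacterial-representation gate counts flagged members", {
  tax <- taxonomy_map(c("Q", "b1", "b2", "b3", "e1"),
                      phylum = c("Archaeplastida", "P1", "P1", "P2", "Viridiplantae"),
                      flags = c("archaeplastida;query", "bacteria", "bacteria",
                                "bacteria", "archaeplastida"))
  smp <- function(ids) structure(list(query_id = "Q", member_ids = ids),
                                 class = "sample_set")
  expect_false(tree_worthy(smp(c("Q", "b1", "b2", "e1")), tax))   # 2 bacteria
  expect_true(tree_worthy(smp(c("Q", "b1", "b2", "b3")), tax))    # 3 bacteria
  expect_false(tree_worthy(smp("Q"), tax))
})

test_that("per-pass per-phylum admissions never exceed the cap (fuzz)", {
  set.seed(123)
  tax <- subject_pool_tax(n_phyla = 5)
  for (i in 1:1000) {
    h <- random_hits(sample(5:40, 1))
    got <- select_representatives(h, tax, cap = 6)
    tab <- table(tax_phylum(tax, got))
    expect_true(all(tab <= 6))
    expect_identical(got, oracle_select(h$subject_id,
                                        tax_phylum(tax, h$subject_id), 6))
  }
})

test_that("sampling output is invariant to shuffling tied rows", {
  set.seed(5)
  tax <- subject_pool_tax()
  h <- random_hits(60)
  h$subject_id <- sprintf("s%03d", sample(500, 60))   # unique
  h$bitscore <- rep(c(800, 700, 600), each = 20)      # heavy ties
  h$identity_pct <- rep(c(90, 80, 70), 20)
  s1 <- build_sample("Q1", h, tax)
  for (k in 1:5) {
    s2 <- build_sample("Q1", h[sample(nrow(h)), ], tax)
    expect_identical(s2$member_ids, s1$member_ids)
    expect_identical(s2$passes, s1$passes)
  }
  # union bound
  n1 <- sum(s1$passes$pass == "bitscore"); n2 <- sum(s1$passes$pass == "identity")
  expect_lte(length(s1$member_ids), n1 + n2 + 1)
})
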