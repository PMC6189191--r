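test_that("Newick parsing captures supports and round-trips", {
  t <- parse_newick("((a,b)95,(c,d)80);")
  expect_equal(length(t$splits$sides), 1L)       # one internal edge, unrooted
  expect_equal(t$splits$sides[[1]], c("a", "b"))
  # the rooted form puts labels 95 and 80 on the same unrooted edge; merged
  expect_equal(t$splits$supports, 95)
  t2 <- parse_newick("((a,b),c,(d,e)70);")
  expect_equal(length(t2$splits$sides), 2L)

  t3 <- parse_newick("((a,b),c,d);")
  expect_true(is.na(t3$splits$supports[1]))

  expect_error(parse_newick("((a,b),(a,c));"), "duplicate")
  expect_error(parse_newick("((a,b,"), "malformed")

  rt <- parse_newick(write_newick(t2))
  expect_equal(rt$splits$sides, t2$splits$sides)
  expect_equal(rt$splits$supports, t2$splits$supports)
})

test_that("support merging on the rooted bipartition keeps the larger label", {
  # both root-child labels annotate the same unrooted edge
  expect_equal(parse_newick("((a,b)95,(c,d)80);")$splits$supports, 95)
  expect_equal(parse_newick("((a,b)80,(c,d)95);")$splits$supports, 95)
})

test_that("anchored clade enumeration walks every internal edge", {
  t4 <- parse_newick("((a,b)90,(c,d)85);")
  cl <- clades(t4, "a")
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$leaves, c("a", "b"))

  star <- parse_newick("(a,b,c,d);")
  expect_length(clades(star, "a"), 0L)

  cat6 <- parse_newick("(((((a,b)90,c)80,d)70,e)60,f);")
  sides <- lapply(clades(cat6, "a"), `[[`, "leaves")
  expect_length(sides, 3L)
  expect_setequal(vapply(sides, paste, "", collapse = ","),
                  c("a,b", "a,b,c", "a,b,c,d"))
  # anchoring at the far end returns the complements
  sides_f <- lapply(clades(cat6, "f"), function(x) sort(x$leaves))
  expect_setequal(vapply(sides_f, paste, "", collapse = ","),
                  c("c,d,e,f", "d,e,f", "e,f"))

  expect_error(clades(cat6, "nope"), "anchor")
})

test_that("the monophyly rules are applied faithfully on hand-built trees", {
  tax <- toy_tax(extra_arch = 5, extra_sec = 1, extra_donor = 2, extra_foreign = 4)

  # clean donor clade: query + 2 donors, supported
  t <- parse_newick("((Q,(D1,D2)97)95,(X1,(X2,X3)80));")
  call <- classify_lgt(t, tax, "Q", "Chlamydiae")
  expect_equal(call$clade_leaves, c("D1", "D2", "Q"))
  expect_equal(call$support, 95)
  expect_equal(call$n_donor, 2); expect_equal(call$n_foreign, 0)

  # single-sequence donor: rejected
  t1 <- parse_newick("((Q,D1)99,(X1,(X2,X3)80));")
  expect_null(classify_lgt(t1, tax, "Q", "Chlamydiae"))

  # three other-bacteria interrupters: rejected; two: tolerated
  t3 <- parse_newick("(((((Q,D1)99,X1)99,(X2,X3)99)99,D2)99,((X4,X5)99,(X6,X7)99));")
  call3 <- classify_lgt(t3, tax, "Q", "Chlamydiae")
  expect_null(call3)   # every 2-donor clade carries >= 3 foreign leaves
  t2f <- parse_newick("((((Q,D1)99,(X1,X2)99)99,D2)99,(A1,(A2,X3)));")
  call2 <- classify_lgt(t2f, tax, "Q", "Chlamydiae")
  expect_equal(call2$n_foreign, 2)
  expect_equal(call2$n_donor, 2)

  # unlimited interruption by Archaeplastida and secondary-plastid lineages
  t5 <- parse_newick("((((((Q,A1)99,(A2,A3)99)99,(S1,A4)99)99,(D1,D2)99)99,A5)99,(X1,(X2,X3)));")
  call5 <- classify_lgt(t5, tax, "Q", "Chlamydiae")
  expect_false(is.null(call5))
  expect_equal(call5$n_exempt, 5)   # A1-A4 + S1 inside the smallest clade
  expect_equal(call5$n_foreign, 0)

  # support threshold is inclusive at 90; 89 fails; missing support fails
  t90 <- parse_newick("((Q,(D1,D2)95)90,(X1,(X2,X3)));")
  expect_false(is.null(classify_lgt(t90, tax, "Q", "Chlamydiae")))
  expect_null(classify_lgt(parse_newick("((Q,(D1,D2)95)89,(X1,(X2,X3)));"),
                           tax, "Q", "Chlamydiae"))
  expect_null(classify_lgt(parse_newick("((Q,(D1,D2)95),(X1,(X2,X3)));"),
                           tax, "Q", "Chlamydiae"))

  expect_error(classify_lgt(t, tax, "missing", "Chlamydiae"), "not a leaf")
})

test_that("classifier equals the exhaustive enumeration oracle on random trees", {
  set.seed(2024)
  for (i in 1:500) {
    r <- random_lgt_tree(sample(6:32, 1))
    donors <- unique(tax_phylum(r$tax, setdiff(tree_leaves(r$tree), r$query)))
    donors <- donors[donors != "Archaeplastida"]
    donor <- sample(donors, 1)
    got <- classify_lgt(r$tree, r$tax, r$query, donor)
    want <- oracle_classify(r$phy, tax_as_df(r$tax), r$query, donor)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_false(is.null(got))
      expect_equal(got$clade_leaves, want$leaves)
      expect_equal(got$support, want$support)
      expect_equal(got$n_donor, want$n_donor)
      expect_equal(got$n_exempt, want$n_exempt)
      expect_equal(got$n_foreign, want$n_foreign)
    }
  }
})

test_that("donor scanning covers every bacterial phylum and flags conflicts", {
  tax <- toy_tax()
  t <- parse_newick("((Q,(D1,D2)97)95,(X1,(X2,X3)));")
  calls <- scan_donors(t, tax, "Q")
  # the X-clade {Q,X1,X2,X3} (support 97) also qualifies for Proteobacteria
  # with the two donors as tolerated interrupters -- an engineered conflict
  expect_length(calls, 2L)
  expect_true(attr(calls, "conflict"))
  expect_setequal(vapply(calls, `[[`, "", "donor_phylum"),
                  c("Chlamydiae", "Proteobacteria"))

  t_lone <- parse_newick("((Q,(D1,D2)97)95,((X1,a1)50,(X2,b1)50));")
  tax2 <- taxonomy_map(c("Q","D1","D2","X1","X2","a1","b1"),
                       phylum = c("Arch","Chlamydiae","Chlamydiae","P1","P2","V","V"),
                       flags = c("archaeplastida;query", rep("chlamydiae;bacteria",2),
                                 "bacteria","bacteria","archaeplastida","archaeplastida"))
  calls2 <- scan_donors(t_lone, tax2, "Q")
  expect_length(calls2, 1L)
  expect_false(attr(calls2, "conflict"))

  tax_nb <- taxonomy_map(c("Q","a","b","c"), phylum = c("Arch","V","V","V"),
                         flags = c("archaeplastida;query", rep("archaeplastida",3)))
  t_nb <- parse_newick("((Q,a)99,(b,c));")
  expect_length(scan_donors(t_nb, tax_nb, "Q"), 0L)
})

test_that("support and foreign-tolerance monotonicity hold", {
  set.seed(77)
  for (i in 1:100) {
    r <- random_lgt_tree(sample(8:20, 1))
    donors <- setdiff(unique(tax_phylum(r$tax, tree_leaves(r$tree))), "Archaeplastida")
    donor <- sample(donors, 1)
    lo <- classify_lgt(r$tree, r$tax, r$query, donor, support_min = 70)
    hi <- classify_lgt(r$tree, r$tax, r$query, donor, support_min = 95)
    if (!is.null(hi)) expect_false(is.null(lo))   # raising threshold never adds
    narrow <- classify_lgt(r$tree, r$tax, r$query, donor, max_foreign = 0)
    wide <- classify_lgt(r$tree, r$tax, r$query, donor, max_foreign = 4)
    if (!is.null(narrow)) expect_false(is.null(wide))
  }
})

test_that("case grouping is single-linkage on homolog-set Jaccard", {
  mkcall <- function(q, donor = "Chlamydiae")
    structure(list(query_id = q, donor_phylum = donor,
                   clade_leaves = q, support = 99,
                   n_donor = 2, n_exempt = 0, n_foreign = 0), class = "lgt_call")
  calls <- list(mkcall("q1"), mkcall("q2"))
  samples <- list(q1 = c("q1", "m1", "m2", "m3"), q2 = c("q2", "m1", "m2", "m3"))
  expect_length(group_cases(calls, samples), 1L)

  samples_dis <- list(q1 = c("q1", "m1", "m2"), q2 = c("q2", "n1", "n2"))
  expect_length(group_cases(calls, samples_dis), 2L)

  # chain a~b, b~c, a!~c merges into one group by single linkage
  calls3 <- list(mkcall("a"), mkcall("b"), mkcall("c"))
  samples3 <- list(a = paste0("m", 1:8),
                   b = paste0("m", 5:12),
                   c = paste0("m", 9:16))
  jac <- function(x, y) length(intersect(x, y)) / length(union(x, y))
  expect_gte(jac(samples3$a, samples3$b), 0.3)
  expect_gte(jac(samples3$b, samples3$c), 0.3)
  expect_lt(jac(samples3$a, samples3$c), 0.3)
  g <- group_cases(calls3, samples3, jaccard_min = 0.3)
  expect_length(g, 1L)
  expect_equal(g[[1]]$member_queries, c("a", "b", "c"))

  # different donors never merge
  calls_d <- list(mkcall("q1"), mkcall("q2", donor = "Proteobacteria"))
  expect_length(group_cases(calls_d, samples), 2L)

  expect_error(group_cases(calls, samples["q1"]), "no sample")
})

test_that("non-redundant counts sum to the number of groups", {
  expect_length(count_nonredundant(list()), 0L)
  g <- function(donor) structure(list(member_queries = "q", donor_phylum = donor,
                                      evidence = list()), class = "lgt_case_group")
  groups <- list(g("Chlamydiae"), g("Chlamydiae"), g("Chlamydiae"), g("Proteobacteria"))
  cnt <- count_nonredundant(groups)
  expect_equal(cnt[["Chlamydiae"]], 3L)
  expect_equal(cnt[["Proteobacteria"]], 1L)
  expect_equal(sum(cnt), length(groups))
})

test_that("congruence gate finds the shared compatible taxon set", {
  a <- parse_newick("(((a,b)99,(c,d)99)99,(e,f)99);")
  b_same <- parse_newick("(((a,b)95,(c,d)95)95,(e,f)95);")
  expect_equal(congruent_taxa(a, b_same), sort(c("a","b","c","d","e","f")))

  # rogue taxon f moves between clades: everything else stays congruent
  b_rogue <- parse_newick("(((a,f)99,b)99,((c,d)99,e)99);")
  got <- congruent_taxa(a, b_rogue)
  orc <- oracle_congruent(a, b_rogue)
  expect_true(any(vapply(orc, function(s) setequal(s, got), NA)))
  expect_equal(got, c("a", "b", "c", "d", "e"))

  # collapsing all weak edges leaves star trees: vacuously congruent
  a_weak <- parse_newick("(((a,b)10,(c,d)20)30,(e,f)40);")
  b_conf <- parse_newick("(((a,c)15,(b,d)25)35,(e,f)45);")
  expect_equal(congruent_taxa(a_weak, b_conf, collapse_below = 50),
               sort(c("a","b","c","d","e","f")))

  small <- parse_newick("((a,b)99,c);")
  expect_error(congruent_taxa(small, small), "fewer than 4")
})

test_that("alignment concatenation joins rows and records the partition", {
  taxa <- paste0("t", 1:8)
  alnA <- setNames(replicate(8, strrep("A", 100)), taxa)
  alnB <- setNames(replicate(8, strrep("D", 120)), taxa)
  cc <- concatenate_alignments(alnA, alnB, taxa)
  expect_length(cc, 8L)
  expect_true(all(nchar(cc) == 220))
  expect_equal(attr(cc, "partition"), c(100, 120))
  expect_error(concatenate_alignments(alnA, alnB, character(0)), "empty")
  expect_error(concatenate_alignments(alnA, alnB, "t1"), "fewer than 4")
  expect_error(concatenate_alignments(alnA[-1], alnB, taxa), "missing")
})

test_that("gap-rich columns are trimmed in place", {
  aln <- c(s1 = "AC-GA-", s2 = "AC-GC-", s3 = "A--GG-", s4 = "AC-G-T")
  # col gap fractions: 0, .25, 1, 0, .25, .75
  out <- trim_alignment(aln, max_gap_fraction = 0.4)
  expect_equal(unname(nchar(out[1])), 4L)
  expect_equal(out[["s1"]], "ACGA")
  expect_equal(trim_alignment(c(a = "AA", b = "AA")), c(a = "AA", b = "AA"))
  expect_error(trim_alignment(c(a = "-", b = "-")), "survive")
})
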