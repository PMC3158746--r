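test_that("the initiation/elongation truth table yields the three states plus the discordant cell", {
  expect_equal(assign_state(TRUE, FALSE), "PAUSED")   # initiation only
  expect_equal(assign_state(TRUE, TRUE), "ACTIVE")    # both
  expect_equal(assign_state(FALSE, FALSE), "SILENT")  # neither
  expect_equal(assign_state(FALSE, TRUE), "DISCORDANT")
  expect_equal(assign_state(c(TRUE, FALSE), c(FALSE, FALSE)),
               c("PAUSED", "SILENT"))
  expect_error(assign_state(NA, TRUE), "non-missing")
})

test_that("transitions map to their named categories with the direct flag on A<->S", {
  expect_equal(classify_transition("PAUSED", "SILENT")$category, "archiving")
  expect_equal(classify_transition("SILENT", "PAUSED")$category, "priming")
  sa <- classify_transition("SILENT", "ACTIVE")
  expect_equal(sa$category, "activation")
  expect_true(sa$direct)
  as_ <- classify_transition("ACTIVE", "SILENT")
  expect_equal(as_$category, "silencing")
  expect_true(as_$direct)
  expect_equal(classify_transition("ACTIVE", "ACTIVE")$category, "stable")
  expect_false(classify_transition("PAUSED", "ACTIVE")$direct)
  # discordant input is an exclusion signal, not an exception
  d <- classify_transition("DISCORDANT", "ACTIVE")
  expect_true(is.na(d$category) && is.na(d$transition))
  expect_error(classify_transition("BOGUS", "ACTIVE"), "unknown state")
})

test_that("a hand-counted ten-locus example tallies exactly", {
  # 4 stable, 3 S->P, 2 P->S, 1 P->A
  before <- setNames(c(rep("ACTIVE", 4), rep("SILENT", 3),
                       rep("PAUSED", 3)), paste0("g", 1:10))
  after <- setNames(c(rep("ACTIVE", 4), rep("PAUSED", 3),
                      rep("SILENT", 2), "ACTIVE"), paste0("g", 1:10))
  tl <- tally_transitions(before, after)
  expect_equal(tl$n_loci, 10L)
  expect_equal(tl$n_changing, 6L)
  expect_equal(unname(tl$category_percent),
               c(16.7, 0, 50.0, 33.3))  # activation/silencing/priming/archiving
  expect_equal(tl$paused_intermediate_percent, 100.0)
  expect_equal(tl$direct_percent, 0.0)
  expect_equal(unname(tl$transition_counts["S->P"]), 3L)
})

test_that("an all-stable cohort reports NA category percentages", {
  s <- setNames(rep(c("ACTIVE", "PAUSED", "SILENT"), 4), paste0("g", 1:12))
  tl <- tally_transitions(s, s)
  expect_equal(tl$n_changing, 0L)
  expect_true(all(is.na(tl$category_percent)))
  expect_true(is.na(tl$paused_intermediate_percent))
  expect_equal(tl$changing_percent, 0)
})

test_that("the nine transitions partition loci and the four categories partition changing loci", {
  set.seed(41)
  for (i in 1:20) {
    v <- random_state_vectors(sample(50:400, 1))
    tl <- tally_transitions(v$before, v$after)
    expect_equal(sum(tl$transition_counts), tl$n_loci)
    expect_equal(sum(tl$category_counts), tl$n_changing)
    expect_equal(tl$n_changing,
                 tl$n_loci - sum(diag(tl$counts)))
    if (tl$n_changing > 0)
      expect_lt(abs(tl$paused_intermediate_percent + tl$direct_percent - 100),
                0.06)  # complementary after half-even rounding
    expect_equal(sum(tl$state_distribution$before), 1)
    expect_equal(sum(tl$state_distribution$after), 1)
  }
})

test_that("swapping conditions exchanges activation with silencing and priming with archiving", {
  set.seed(42)
  for (i in 1:10) {
    v <- random_state_vectors(200)
    fwd <- tally_transitions(v$before, v$after)$category_counts
    rev <- tally_transitions(v$after, v$before)$category_counts
    expect_equal(unname(fwd["activation"]), unname(rev["silencing"]))
    expect_equal(unname(fwd["priming"]), unname(rev["archiving"]))
    expect_equal(unname(fwd["archiving"]), unname(rev["priming"]))
  }
})

test_that("discordant loci are excluded from tallies by default, coercible to active", {
  before <- setNames(c("ACTIVE", "DISCORDANT", "PAUSED"), paste0("g", 1:3))
  after <- setNames(c("ACTIVE", "SILENT", "DISCORDANT"), paste0("g", 1:3))
  rec <- make_transitions(before, after)
  expect_equal(nrow(rec), 1L)
  expect_equal(attr(rec, "n_discordant"), 2L)
  rec2 <- make_transitions(before, after, coerce_discordant = "active")
  expect_equal(nrow(rec2), 3L)
  expect_equal(rec2$transition[rec2$gene_id == "g2"], "A->S")
  expect_error(make_transitions(before, after[1:2]), "identical locus set")
  expect_error(make_transitions(before,
                                setNames(rep("ACTIVE", 3), paste0("x", 1:3))),
               "identical locus set")
})

test_that("state distributions are brute-force count fractions", {
  expect_equal(unname(state_distribution(c("ACTIVE", "ACTIVE", "PAUSED",
                                           "SILENT"))),
               c(0.5, 0.25, 0.25))
  expect_equal(unname(state_distribution(rep("PAUSED", 5))), c(0, 1, 0))
  set.seed(43)
  s <- sample(c("ACTIVE", "PAUSED", "SILENT"), 300, TRUE)
  d <- state_distribution(s)
  for (st in names(d)) expect_equal(unname(d[st]), sum(s == st) / 300)
  expect_error(state_distribution(character(0)), "no non-discordant")
})

test_that("binding and transcript calls combine over the shared platform universe", {
  binding <- data.frame(gene_id = c("G1", "G2", "G3"),
                        bound = c(TRUE, TRUE, FALSE))
  transcripts <- data.frame(gene_id = c("G2", "G3", "G4"),
                            condition = "meso",
                            expressed = c(TRUE, FALSE, TRUE))
  calls <- locus_state_calls(binding, transcripts)
  expect_setequal(calls$gene_id, c("G2", "G3"))  # platform intersection
  expect_equal(calls$state[calls$gene_id == "G2"], "ACTIVE")
  expect_equal(calls$state[calls$gene_id == "G3"], "SILENT")
  expect_equal(unique(calls$condition), "meso")
})
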