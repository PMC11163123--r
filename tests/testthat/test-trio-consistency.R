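test_that("trio point system awards 1 / 0.5 / 0 as defined", {
  # textbook biparental match
  expect_equal(score_trio_locus(c("A*01:01", "A*02:01"),
                                c("A*01:01", "A*03:01"),
                                c("A*02:01", "A*24:02"), 2), 1)
  # homozygous child covered by one parent only: no biparental assignment
  expect_equal(score_trio_locus(c("A*01:01", "A*01:01"),
                                c("A*01:01", "A*03:01"),
                                c("A*02:01", "A*24:02"), 2), 0.5)
  # homozygous child whose allele both parents carry
  expect_equal(score_trio_locus(c("A*01:01", "A*01:01"),
                                c("A*01:01", "A*03:01"),
                                c("A*01:01", "A*24:02"), 2), 1)
  # no child allele in either parent
  expect_equal(score_trio_locus(c("A*11:01", "A*26:01"),
                                c("A*01:01", "A*03:01"),
                                c("A*02:01", "A*24:02"), 1), 0)
  # not-typed members must be excluded upstream, never scored
  expect_error(score_trio_locus(c("A*01:01", NA), c("A*01:01", "A*01:01"),
                                c("A*01:01", "A*01:01"), 1), "exclude")
})

test_that("DRB3/4/5 unit scoring handles variable copy number", {
  # single-allele child: either parent may have transmitted it
  expect_equal(score_trio_unit("DRB4*01:03", "DRB4*01:03", character(0), 2), 1)
  expect_equal(score_trio_unit("DRB4*01:03", character(0), "DRB4*01:03", 2), 1)
  expect_equal(score_trio_unit("DRB4*01:03", "DRB3*01:01", "DRB5*01:01", 2), 0)
  # one allele per parent
  expect_equal(score_trio_unit(c("DRB3*01:01", "DRB4*01:03"),
                               "DRB3*01:01", "DRB4*01:03", 2), 1)
  # two child alleles but only one parent can cover: half a point
  expect_equal(score_trio_unit(c("DRB3*02:02", "DRB5*01:01"),
                               "DRB3*02:02", "DRB3*02:02", 2), 0.5)
  # paralog identity matters: same numeric fields on different genes differ
  expect_equal(score_trio_unit("DRB3*01:01", "DRB4*01:01", character(0), 2), 0)
})

test_that("scoring equals exhaustive assignment enumeration on random trios", {
  set.seed(303)
  for (i in 1:1000) {
    child <- random_genotype(); father <- random_genotype()
    mother <- random_genotype()
    k <- sample(1:3, 1)
    expect_equal(score_trio_locus(child, father, mother, k),
                 oracle_trio(child, father, mother, k),
                 info = paste(c(child, father, mother, k), collapse = " "))
  }
  # and for variable-size units with a mix of paralogs
  unit <- function() {
    n <- sample(0:2, 1)
    vapply(seq_len(n), function(i) random_allele(sample(drb345_loci(), 1)), "")
  }
  for (i in 1:500) {
    child <- unit(); if (length(child) == 0) next
    father <- unit(); mother <- unit()
    k <- sample(1:3, 1)
    expect_equal(score_trio_unit(child, father, mother, k),
                 oracle_trio(child, father, mother, k),
                 info = paste(c(child, "|", father, "|", mother, k),
                              collapse = " "))
  }
})

test_that("trio scores never increase with resolution", {
  set.seed(404)
  for (i in 1:300) {
    child <- random_genotype(); father <- random_genotype()
    mother <- random_genotype()
    s <- vapply(1:3, function(k) score_trio_locus(child, father, mother, k), 0)
    expect_true(all(diff(s) <= 0))
  }
})

test_that("exclusions are per family and per locus", {
  ty <- dplyr::bind_rows(
    make_typing("c1", c("A", "DRB6"), c("A*01:01", "DRB6*01:01"),
                c("A*02:01", "DRB6*01:01")),
    make_typing("f1", c("A", "DRB6"), c("A*01:01", NA), c("A*03:01", NA)),
    make_typing("m1", c("A", "DRB6"), c("A*02:01", "DRB6*01:01"),
                c("A*24:02", "DRB6*01:01")),
    # family 2 has no DOA rows anywhere: not assayed there
    make_typing("c2", "A", "A*01:01", "A*02:01"),
    make_typing("f2", "A", "A*01:01", "A*03:01"),
    make_typing("m2", "A", "A*02:01", "A*24:02")
  )
  ped <- tibble::tibble(family_id = c("T1", "T2"),
                        child_id = c("c1", "c2"),
                        father_id = c("f1", "f2"),
                        mother_id = c("m1", "m2"))
  res <- score_trios(ty, ped, resolutions = 1, drb345_unit = FALSE)
  sc <- res$scores
  # father not typed at DRB6 excludes T1 there but not at A
  drb6 <- sc[sc$locus == "DRB6", ]
  expect_equal(drb6$exclusion_reason[drb6$family_id == "T1"],
               "not_typed_member")
  expect_equal(drb6$exclusion_reason[drb6$family_id == "T2"],
               "locus_not_assayed")
  a <- sc[sc$locus == "A", ]
  expect_true(all(a$included))
  expect_equal(a$score, c(1, 1))
  tab <- consistency_table(res)
  expect_equal(tab$n_families[tab$locus == "DRB6"], 0L)
  expect_true(is.na(tab$first_field_pct[tab$locus == "DRB6"]))
  expect_equal(tab$n_families[tab$locus == "A"], 2L)
})

test_that("worked one-locus decomposition: 3 zero + 6 half + 5 full = 57.14%", {
  ex <- dpb1_worked_example()
  res <- score_trios(ex$typing, ex$pedigree, drb345_unit = FALSE)
  sc <- res$scores[res$scores$resolution == 2, ]
  expect_equal(sum(sc$score == 1), 5)
  expect_equal(sum(sc$score == 0.5), 6)
  expect_equal(sum(sc$score == 0), 3)
  tab <- consistency_table(res)
  expect_equal(tab$n_families, 14L)
  expect_equal(tab$first_field_pct, 100 * 8 / 14)
  expect_equal(round_half_up(tab$second_field_pct, 2), 57.14)
  expect_equal(consistency_percentage(sc$score)$pct, 100 * 8 / 14)
})

test_that("short two-field calls are scored, not excluded, and fail field 3", {
  ty <- dplyr::bind_rows(
    make_typing("c", "A", "A*01:01", "A*02:01:01"),
    make_typing("f", "A", "A*01:01:01", "A*03:01:01"),
    make_typing("m", "A", "A*02:01:01", "A*24:02:01")
  )
  ped <- tibble::tibble(family_id = "T", child_id = "c", father_id = "f",
                        mother_id = "m")
  res <- score_trios(ty, ped, drb345_unit = FALSE)
  sc <- res$scores
  expect_true(all(sc$included))
  expect_equal(sc$score[sc$resolution == 2], 1)
  # at field 3 the two-field child call matches nothing: one parent remains
  expect_equal(sc$score[sc$resolution == 3], 0.5)
})

test_that("noise-free simulated trios are perfectly consistent", {
  cfg <- sim_config(n_families = 100, seed = 9)
  tr <- simulate_trios(cfg)
  ty <- render_typing(tr$truth)
  tab <- consistency_table(score_trios(ty, tr$pedigree))
  pct <- unlist(tab[c("first_field_pct", "second_field_pct",
                      "third_field_pct")])
  expect_true(all(pct[!is.na(pct)] == 100))
  # NA only where no family had complete typing (rare copy-number loci)
  expect_true(all(tab$n_families[is.na(tab$first_field_pct)] == 0))
})
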