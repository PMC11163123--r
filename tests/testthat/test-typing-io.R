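test_that("generic typing TSV round-trips every call including suffixes", {
  ty <- make_typing(
    sample_id = rep(c("s1", "s2"), each = 3),
    locus = rep(c("A", "B", "DRB3"), 2),
    allele1 = c("A*01:01:01", "B*44:02:01N", "DRB3*02:96",
                "A*02:01", NA, "DRB3*01:01:02"),
    allele2 = c("A*02:01:01", "B*08:01", NA,
                "A*02:01", NA, "DRB3*01:01:02")
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_typing_tsv(ty, path)
  back <- read_typing_tsv(path, dataset = "test")
  expect_equal(back, ty)
  # and a second round-trip is byte-stable
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_typing_tsv(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("generic TSV reader rejects malformed input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tlocus\tallele1\tallele2",
               "s1\tA\tA*01:01\tA*02:01",
               "s1\tA\tA*03:01\tA*11:01"), path)
  expect_error(read_typing_tsv(path), "conflicting rows")
  writeLines(c("sample\tlocus\tallele1", "s1\tA\tA*01:01"), path)
  expect_error(read_typing_tsv(path), "allele2")
  writeLines(c("sample\tlocus\tallele1\tallele2",
               "s1\tA\tA*zz:01\tA*02:01"), path)
  expect_error(read_typing_tsv(path), "zz")
})

test_that("HLA-HD dialect: homozygote shorthand, Not typed, and errors", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("A\tHLA-A*02:01:01\tHLA-A*24:02:01",
               "DRB4\tHLA-DRB4*01:03\t-",
               "DRB6\tNot typed\tNot typed"), path)
  ty <- read_hlahd_result(path, sample_id = "s1")
  expect_equal(ty$allele1[ty$locus == "A"], "A*02:01:01")
  expect_equal(ty$allele2[ty$locus == "A"], "A*24:02:01")
  # "-" in slot 2 expands to a homozygous copy in this dialect
  expect_equal(unlist(ty[ty$locus == "DRB4", c("allele1", "allele2")],
                      use.names = FALSE),
               c("DRB4*01:03", "DRB4*01:03"))
  expect_true(all(is.na(ty[ty$locus == "DRB6", c("allele1", "allele2")])))
  # loci absent from the file are absent from the result
  expect_setequal(ty$locus, c("A", "DRB4", "DRB6"))

  writeLines(c("A\tA*02:01\tA*24:02", "A\tA*01:01\tA*03:01"), path)
  expect_error(read_hlahd_result(path), "line 2.*duplicate locus")
  writeLines("A\tA*02:01", path)
  expect_error(read_hlahd_result(path), "line 1")
})

test_that("pedigree reader validates families", {
  path <- withr::local_tempfile(fileext = ".tsv")
  hdr <- "family_id\tchild_id\tfather_id\tmother_id"
  rows <- sprintf("F%02d\tF%02d_c\tF%02d_f\tF%02d_m", 1:14, 1:14, 1:14, 1:14)
  writeLines(c(hdr, rows), path)
  ped <- read_pedigree(path)
  expect_equal(nrow(ped), 14)
  expect_equal(ped$family_id, sprintf("F%02d", 1:14))

  writeLines(c(hdr, "F1\tkid\tkid\tmum"), path)
  expect_error(read_pedigree(path), "distinct")
  writeLines(c(hdr, "F1\ta\tb\tc", "F1\td\te\tf"), path)
  expect_error(read_pedigree(path), "duplicate family_id")
  writeLines(hdr, path)
  expect_equal(nrow(read_pedigree(path)), 0)

  writeLines(c(hdr, "F1\ta\tb\tc"), path)
  expect_error(read_pedigree(path, typing = make_typing("a", "A", NA, NA)),
               "not present.*[bc]")
})

test_that("pairing reader rejects within-dataset pairs", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_a\tdataset_a\tsample_b\tdataset_b",
               "s1\tpanel\ts1x\tpanel"), path)
  expect_error(read_pairs(path), "same dataset")
  writeLines(c("sample_a\tdataset_a\tsample_b\tdataset_b",
               "s1\tpanel\ts1x\texome"), path)
  expect_equal(nrow(read_pairs(path)), 1)
})

test_that("DRB3/4/5 pooling conserves typed-allele multiplicity", {
  ty <- dplyr::bind_rows(
    # DRB3 + DRB4 carrier, one copy each
    make_typing("s1", c("DRB3", "DRB4", "DRB5"),
                c("DRB3*01:01:02", "DRB4*01:03", NA),
                c(NA, NA, NA)),
    # all three loci not typed
    make_typing("s2", c("DRB3", "DRB4", "DRB5"),
                c(NA, NA, NA), c(NA, NA, NA)),
    # homozygous DRB4: the allele is carried twice
    make_typing("s3", "DRB4", "DRB4*01:03", "DRB4*01:03")
  )
  unit <- pool_drb345(ty)
  expect_equal(unit$locus, rep("DRB345", 3))
  expect_setequal(unit$alleles[[match("s1", unit$sample_id)]],
                  c("DRB3*01:01:02", "DRB4*01:03"))
  expect_length(unit$alleles[[match("s2", unit$sample_id)]], 0)
  expect_equal(unit$alleles[[match("s3", unit$sample_id)]],
               c("DRB4*01:03", "DRB4*01:03"))
  # multiplicity equals the count of typed DRB3/4/5 slots
  typed_slots <- sum(!is.na(ty$allele1)) + sum(!is.na(ty$allele2))
  expect_equal(sum(unit$n_alleles), typed_slots)
})

test_that("consistency tables round-trip with NA rows formatted as NA", {
  tab <- tibble::tibble(
    locus = c("A", "DRB6"),
    first_field_pct = c(96.434, NA), second_field_pct = c(67.856, NA),
    third_field_pct = c(64.29, NA), n_families = c(14L, 0L)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_consistency_table(tab, path)
  lines <- readLines(path)
  expect_match(lines[3], "^DRB6\tNA\tNA\tNA\t0$")
  expect_match(lines[2], "^A\t96.43\t67.86\t64.29\t14$")
  back <- read_consistency_table(path)
  expect_equal(back$first_field_pct, c(96.43, NA))
  expect_equal(back$n_families, c(14L, 0L))
})
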