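test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_families = 8, seed = 77, mistyping_rate = 0.1,
                    truncation_rate = 0.1, dropout_rate = 0.1)
  a <- simulate_trios(cfg)
  b <- simulate_trios(cfg)
  expect_identical(a, b)
  na <- apply_noise(render_typing(a$truth), cfg)
  nb <- apply_noise(render_typing(b$truth), cfg)
  expect_identical(na, nb)
  c2 <- simulate_trios(cfg, seed = 78)
  expect_false(identical(a$truth, c2$truth))
})

test_that("configured allele frequencies are recovered from founders", {
  freqs <- c("A*01:01:01" = 0.5, "A*02:01:01" = 0.3, "A*03:01:01" = 0.2)
  cfg <- sim_config(loci = "A", haplotype_frequencies = list(A = freqs),
                    seed = 13)
  pop <- simulate_population(cfg, n_samples = 5000)
  n <- 2 * 5000
  obs <- table(pop$allele)[names(freqs)] / n
  se <- sqrt(freqs * (1 - freqs) / n)
  expect_true(all(abs(obs - freqs) < 3 * se))
})

test_that("DRB3/4/5 carriage follows the DRB1 linkage map", {
  # every DRB1 haplotype in group 15/16 carries DRB5, groups 01/08 carry none
  freqs <- c("DRB1*15:01:01" = 0.5, "DRB1*01:01:01" = 0.5)
  cfg <- sim_config(loci = "DRB1", haplotype_frequencies = list(DRB1 = freqs),
                    seed = 21)
  pop <- simulate_population(cfg, n_samples = 500)
  wide <- tidyr::pivot_wider(pop, names_from = "locus",
                             values_from = "allele")
  expect_setequal(unique(pop$locus), c("DRB1", "DRB5"))
  carries_15 <- grepl("^DRB1\\*15", wide$DRB1)
  expect_identical(!is.na(wide$DRB5), carries_15)

  # a map sending every group to none yields no secondary DRB rows
  cfg0 <- sim_config(loci = "DRB1", haplotype_frequencies = list(DRB1 = freqs),
                     drb_linkage = c("15" = "none", "01" = "none"), seed = 21)
  pop0 <- simulate_population(cfg0, n_samples = 200)
  expect_equal(unique(pop0$locus), "DRB1")
})

test_that("children inherit one whole haplotype per parent", {
  cfg <- sim_config(n_families = 40, seed = 31)
  tr <- simulate_trios(cfg)
  truth <- tr$truth
  for (i in seq_len(nrow(tr$pedigree))) {
    ped <- tr$pedigree[i, ]
    kid <- truth[truth$sample_id == ped$child_id, ]
    dad <- truth[truth$sample_id == ped$father_id, ]
    mum <- truth[truth$sample_id == ped$mother_id, ]
    # child allele multiset within the union of parental alleles, per locus
    for (L in unique(kid$locus)) {
      expect_true(all(kid$allele[kid$locus == L] %in%
                        c(dad$allele[dad$locus == L],
                          mum$allele[mum$locus == L])))
    }
    # child haplotype 1 is exactly one of the father's two haplotypes
    k1 <- sort(paste(kid$locus, kid$allele)[kid$hap == 1])
    d1 <- sort(paste(dad$locus, dad$allele)[dad$hap == 1])
    d2 <- sort(paste(dad$locus, dad$allele)[dad$hap == 2])
    expect_true(identical(k1, d1) || identical(k1, d2))
  }
  # pooled child unit is contained in the pooled parental units
  ty <- render_typing(truth)
  unit <- pool_drb345(ty)
  ua <- function(id) unit$alleles[[match(id, unit$sample_id)]]
  for (i in seq_len(nrow(tr$pedigree))) {
    ped <- tr$pedigree[i, ]
    pooled_parents <- c(ua(ped$father_id), ua(ped$mother_id))
    expect_true(all(ua(ped$child_id) %in% pooled_parents))
  }
})

test_that("noise model: zero rates are silent, rates act per allele call", {
  cfg0 <- sim_config(n_families = 10, seed = 41)
  ty <- render_typing(simulate_trios(cfg0)$truth)
  clean <- apply_noise(ty, cfg0)
  expect_identical(clean$observed, ty)
  expect_equal(nrow(clean$events), 0)

  cfg1 <- sim_config(n_families = 10, seed = 41, dropout_rate = 1)
  wiped <- apply_noise(ty, cfg1)
  expect_true(all(is.na(wiped$observed$allele1)))
  expect_true(all(wiped$events$event == "dropout"))

  # truncation emits two-field calls; mistyping swaps within the pool
  cfgt <- sim_config(n_families = 10, seed = 42, truncation_rate = 1)
  trunc <- apply_noise(ty, cfgt)
  typed <- trunc$observed$allele1[!is.na(trunc$observed$allele1)]
  expect_true(all(grepl("^[A-Z0-9]+\\*[0-9]+:[0-9]+$", typed)))
})

test_that("the event log replays truth into the observed typing exactly", {
  cfg <- sim_config(n_families = 15, seed = 51, dropout_rate = 0.1,
                    truncation_rate = 0.2, mistyping_rate = 0.1)
  ty <- render_typing(simulate_trios(cfg)$truth)
  noisy <- apply_noise(ty, cfg)
  expect_identical(replay_events(ty, noisy$events), noisy$observed)
  # mistyped calls are always replaced by a different pool allele
  mis <- noisy$events[noisy$events$event == "mistyping", ]
  expect_true(all(mis$truth_allele != mis$observed_allele))
})

test_that("duplicate rendering restricts each dataset to its assay design", {
  cfg <- sim_config(n_duplicates = 30, seed = 61)
  d <- simulate_duplicates(cfg)
  expect_setequal(unique(d$typing_a$locus), panel_loci())
  expect_true("DOA" %in% unique(d$typing_b$locus))
  expect_false("DOA" %in% unique(d$typing_a$locus))
  expect_equal(nrow(d$pairs), 30)
  expect_true(all(d$pairs$dataset_a == "panel" & d$pairs$dataset_b == "exome"))
  # noise-free on both sides: perfect concordance everywhere
  res <- score_duplicates(d$typing_a, d$typing_b, d$pairs)
  expect_true(all(res$scores$score == 1))
  expect_setequal(res$loci, panel_loci())
})
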