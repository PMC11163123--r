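# Allele-level concordance between two typings of the same sample.
#
# A genotype has two slots; the pair score at a locus/resolution is the size
# of a maximum matching between the two slot sets divided by two (slot order
# in call files is arbitrary, so positional comparison would be wrong).
# Not-typed slots participate and match only not-typed slots: concordant
# absence counts as agreement, which is why duplicate pairs are never
# excluded for "Not typed" results.  A homozygote against a heterozygote
# sharing one allele scores 0.5: two slots, one agrees.

slot_match <- function(ka, kb, nta, ntb) {
  (nta & ntb) | key_eq(ka, kb)
}

#' Score one duplicate pair at one locus
#'
#' Maximum slot matching between two genotypes of the same sample under
#' [alleles_match()] semantics at the given resolution; not-typed (`NA`)
#' slots match only not-typed slots.
#'
#' @param a,b Character vectors of length 2 (the two allele slots; `NA` =
#'   not typed).
#' @param resolution Integer in 1..3.
#' @return A single score in `{0, 0.5, 1}`.
#' @examples
#' score_pair_locus(c("DRB3*02:96", "DRB3*01:01:01"),
#'                  c("DRB3*02:02:01", "DRB3*01:01:01"), 1)  # 1
#' score_pair_locus(c("DRB3*02:96", "DRB3*01:01:01"),
#'                  c("DRB3*02:02:01", "DRB3*01:01:01"), 2)  # 0.5
#' @export
score_pair_locus <- function(a, b, resolution) {
  resolution <- check_resolution(resolution)
  stopifnot(length(a) == 2, length(b) == 2)
  ka <- match_key(a, resolution); kb <- match_key(b, resolution)
  nta <- is.na(a); ntb <- is.na(b)
  straight <- slot_match(ka[1], kb[1], nta[1], ntb[1]) +
    slot_match(ka[2], kb[2], nta[2], ntb[2])
  crossed <- slot_match(ka[1], kb[2], nta[1], ntb[2]) +
    slot_match(ka[2], kb[1], nta[2], ntb[1])
  max(straight, crossed) / 2
}

#' Score duplicate-sample concordance across two datasets
#'
#' For every pair in `pairs` and every locus assayed in *both* datasets,
#' scores the two genotypes with the maximum-slot-matching rule at each
#' resolution.  Loci absent from one dataset's assay design are skipped
#' entirely (a targeted panel is compared only on its targeted loci); a
#' sample missing a row at a locus its dataset does assay is treated as
#' doubly not typed.
#'
#' @param typing_a,typing_b Typing tibbles for the two datasets/tools.
#' @param pairs Pairing tibble from [read_pairs()] (or with columns
#'   `sample_a, sample_b`).
#' @param resolutions Integer vector of field resolutions (default `1:3`).
#' @param loci Optional restriction; default: loci assayed in both datasets.
#' @return An object of class `hla_dup_scores` with a `scores` tibble
#'   (`sample_a, sample_b, locus, resolution, score`) and metadata.  Use
#'   [concordance_table()], [tidy()], [glance()], [autoplot()].
#' @export
score_duplicates <- function(typing_a, typing_b, pairs, resolutions = 1:3,
                             loci = NULL) {
  resolutions <- sort(unique(vapply(resolutions, check_resolution, 1L)))
  shared <- intersect(unique(typing_a$locus), unique(typing_b$locus))
  loci <- if (is.null(loci)) shared else intersect(loci, shared)
  loci <- intersect(.locus_names(), loci)
  if (length(loci) == 0) {
    stop("the two datasets assay no locus in common", call. = FALSE)
  }
  missing_a <- setdiff(pairs$sample_a, typing_a$sample_id)
  missing_b <- setdiff(pairs$sample_b, typing_b$sample_id)
  if (length(missing_a) + length(missing_b) > 0) {
    stop("paired samples missing from typing data: ",
         paste(c(missing_a, missing_b), collapse = ", "), call. = FALSE)
  }

  grid <- tidyr::expand_grid(
    pairs[intersect(c("sample_a", "sample_b"), names(pairs))], locus = loci)
  ga <- typing_a[typing_a$locus %in% loci,
                 c("sample_id", "locus", "allele1", "allele2")]
  names(ga) <- c("sample_a", "locus", "a1", "a2")
  gb <- typing_b[typing_b$locus %in% loci,
                 c("sample_id", "locus", "allele1", "allele2")]
  names(gb) <- c("sample_b", "locus", "b1", "b2")
  grid <- dplyr::left_join(grid, ga, by = c("sample_a", "locus"))
  grid <- dplyr::left_join(grid, gb, by = c("sample_b", "locus"))

  scores <- dplyr::bind_rows(lapply(resolutions, function(k) {
    ka1 <- match_key(grid$a1, k); ka2 <- match_key(grid$a2, k)
    kb1 <- match_key(grid$b1, k); kb2 <- match_key(grid$b2, k)
    na1 <- is.na(grid$a1); na2 <- is.na(grid$a2)
    nb1 <- is.na(grid$b1); nb2 <- is.na(grid$b2)
    straight <- slot_match(ka1, kb1, na1, nb1) + slot_match(ka2, kb2, na2, nb2)
    crossed <- slot_match(ka1, kb2, na1, nb2) + slot_match(ka2, kb1, na2, nb1)
    tibble::tibble(sample_a = grid$sample_a, sample_b = grid$sample_b,
                   locus = grid$locus, resolution = k,
                   score = pmax(straight, crossed) / 2)
  }))

  structure(
    list(scores = scores,
         dataset = paste(unique(c(typing_a$dataset, typing_b$dataset)),
                         collapse = " vs "),
         n_pairs = nrow(pairs), resolutions = resolutions, loci = loci),
    class = "hla_dup_scores"
  )
}

#' Per-locus concordance percentages for duplicate pairs
#'
#' `100 * sum(score) / n_pairs` per locus and resolution, in the standard
#' report layout.
#'
#' @param x An `hla_dup_scores` object (or its `scores` tibble).
#' @return Tibble `locus, first_field_pct, second_field_pct,
#'   third_field_pct, n_pairs`.
#' @export
concordance_table <- function(x) {
  if (is.data.frame(x)) x <- structure(list(scores = x, dataset = NULL),
                                       class = "hla_dup_scores")
  consistency_table(x)
}
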