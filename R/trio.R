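# Mendelian trio scoring.
#
# Point system per locus and resolution: 1 when the child's two alleles admit
# an assignment (one to each parent) in which each assigned allele matches an
# allele of that parent; 0.5 when no such biparental assignment exists but at
# least one child allele matches at least one parental allele; 0 when neither
# child allele matches either parent.  A parent contributes one transmitted
# haplotype, so one parent can never cover both child alleles.
#
# For the pooled DRB3/4/5 unit a child may legitimately carry a single allele
# (the other haplotype carries no secondary DRB gene): a single-allele child
# scores 1 if its allele matches either parent's unit, 0 otherwise.

key_eq <- function(x, y) !is.na(x) & !is.na(y) & x == y

# vectorized scorer over parallel slot columns (all typed, same locus per row)
score_rows <- function(c1, c2, f1, f2, m1, m2, resolution) {
  kc1 <- match_key(c1, resolution); kc2 <- match_key(c2, resolution)
  kf1 <- match_key(f1, resolution); kf2 <- match_key(f2, resolution)
  km1 <- match_key(m1, resolution); km2 <- match_key(m2, resolution)
  c1F <- key_eq(kc1, kf1) | key_eq(kc1, kf2)
  c2F <- key_eq(kc2, kf1) | key_eq(kc2, kf2)
  c1M <- key_eq(kc1, km1) | key_eq(kc1, km2)
  c2M <- key_eq(kc2, km1) | key_eq(kc2, km2)
  full <- (c1F & c2M) | (c2F & c1M)
  any_match <- c1F | c1M | c2F | c2M
  ifelse(full, 1, ifelse(any_match, 0.5, 0))
}

#' Score one trio genotype for Mendelian consistency
#'
#' Scores a child genotype against both parents at one locus and resolution:
#' 1 point when both child alleles can be assigned to matching parental
#' alleles (one per parent), 0.5 when only one parent can be matched, 0 when
#' neither can.  Alleles are canonical strings as produced by the readers;
#' each argument is the character vector of one member's alleles - exactly
#' two for an ordinary locus, 0-2 for a pooled DRB3/4/5 unit.  A
#' single-allele child unit scores 1 if it matches either parent (the second
#' haplotype may carry no DRB3/4/5 gene), else 0.  Not-typed (`NA`) alleles
#' are not allowed here: such trios are excluded upstream, see
#' [score_trios()].
#'
#' @param child,father,mother Character vectors of alleles.
#' @param resolution Integer in 1..3.
#' @return A single score in `{0, 0.5, 1}`.
#' @examples
#' score_trio_locus(c("A*01:01", "A*02:01"), c("A*01:01", "A*03:01"),
#'                  c("A*02:01", "A*24:02"), 2)  # 1
#' score_trio_locus(c("A*01:01", "A*01:01"), c("A*01:01", "A*03:01"),
#'                  c("A*02:01", "A*24:02"), 2)  # 0.5
#' @export
score_trio_locus <- function(child, father, mother, resolution) {
  resolution <- check_resolution(resolution)
  if (anyNA(child) || anyNA(father) || anyNA(mother)) {
    stop("not-typed alleles cannot be scored; exclude the trio at this locus",
         call. = FALSE)
  }
  if (length(child) > 2) {
    # >2 pooled alleles cannot all be transmitted (one haplotype per parent,
    # each carrying at most one DRB3/4/5 gene): at best a one-parent match
    kc <- match_key(child, resolution)
    kp <- match_key(c(father, mother), resolution)
    return(if (any(outer(kc, kp, key_eq))) 0.5 else 0)
  }
  kf <- match_key(father, resolution)
  km <- match_key(mother, resolution)
  kc <- match_key(child, resolution)
  if (length(child) == 0) {
    stop("child genotype has no alleles; exclude the trio at this locus",
         call. = FALSE)
  }
  if (length(child) == 1) {
    hit <- any(key_eq(kc, kf)) || any(key_eq(kc, km))
    return(if (hit) 1 else 0)
  }
  c1F <- any(key_eq(kc[1], kf)); c2F <- any(key_eq(kc[2], kf))
  c1M <- any(key_eq(kc[1], km)); c2M <- any(key_eq(kc[2], km))
  if ((c1F && c2M) || (c2F && c1M)) return(1)
  if (c1F || c1M || c2F || c2M) return(0.5)
  0
}

#' Alias for [score_trio_locus()] on pooled DRB3/4/5 units
#'
#' The same point system applied to the variable-copy-number unit built by
#' [pool_drb345()]; provided as a named entry point for clarity.
#'
#' @inheritParams score_trio_locus
#' @return A single score in `{0, 0.5, 1}`.
#' @export
score_trio_unit <- function(child, father, mother, resolution) {
  score_trio_locus(child, father, mother, resolution)
}

trio_member_table <- function(typing, ids, role, loci) {
  sub <- typing[typing$sample_id %in% ids & typing$locus %in% loci, ,
                drop = FALSE]
  out <- sub[c("sample_id", "locus", "allele1", "allele2")]
  names(out) <- c(paste0(role, "_id"), "locus",
                  paste0(role, c("1", "2")))
  out
}

#' Score Mendelian consistency for every trio, locus and resolution
#'
#' The pipeline entry point for trio analysis: joins a typing table with a
#' pedigree, applies the exclusion rules, scores every evaluable
#' family/locus/resolution combination, and (optionally) adds the pooled
#' DRB345 unit.
#'
#' Exclusion is per family and per locus: a family is excluded at a locus
#' when any member's genotype there contains a not-typed slot
#' (`not_typed_member`), or when any member lacks the locus entirely
#' (`locus_not_assayed`).  The DRB345 unit row excludes families in which
#' any member's pooled unit is empty, restricting the unit analysis to trios
#' with complete typing across the secondary DRB loci.  Alleles typed to
#' fewer fields than a comparison resolution are *not* excluded - they are
#' scored and simply fail to match at that resolution.
#'
#' @param typing Typing tibble from [read_typing_tsv()] /
#'   [read_hlahd_result()] or the simulator.
#' @param pedigree Pedigree tibble from [read_pedigree()].
#' @param resolutions Integer vector of field resolutions (default `1:3`).
#' @param loci Loci to score; default: all loci present in `typing`.
#' @param drb345_unit Add the pooled DRB345 row (default `TRUE` whenever any
#'   DRB3/4/5 locus is present).
#' @param dataset Label for reporting; default taken from `typing`.
#' @return An object of class `hla_trio_scores`: a list with `scores` (one
#'   row per family x locus x resolution, columns `family_id, locus,
#'   resolution, included, exclusion_reason, score`), and metadata.  Use
#'   [consistency_table()], [tidy()], [glance()], [autoplot()].
#' @export
score_trios <- function(typing, pedigree, resolutions = 1:3, loci = NULL,
                        drb345_unit = TRUE, dataset = NULL) {
  resolutions <- sort(unique(vapply(resolutions, check_resolution, 1L)))
  if (is.null(loci)) loci <- intersect(.locus_names(), unique(typing$locus))
  if (is.null(dataset)) {
    dataset <- if ("dataset" %in% names(typing))
      paste(unique(typing$dataset), collapse = "+") else "typing"
  }
  missing_ids <- setdiff(
    unique(c(pedigree$child_id, pedigree$father_id, pedigree$mother_id)),
    unique(typing$sample_id))
  if (length(missing_ids) > 0) {
    stop("pedigree IDs not present in typing data: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }

  grid <- tidyr::expand_grid(family_id = pedigree$family_id, locus = loci)
  grid <- dplyr::left_join(grid, pedigree, by = "family_id")
  grid <- dplyr::left_join(
    grid, trio_member_table(typing, pedigree$child_id, "child", loci),
    by = c(child_id = "child_id", locus = "locus"))
  grid <- dplyr::left_join(
    grid, trio_member_table(typing, pedigree$father_id, "father", loci),
    by = c(father_id = "father_id", locus = "locus"))
  grid <- dplyr::left_join(
    grid, trio_member_table(typing, pedigree$mother_id, "mother", loci),
    by = c(mother_id = "mother_id", locus = "locus"))

  present <- function(role) {
    ids <- paste(grid[[paste0(role, "_id")]], grid$locus)
    sub <- typing[typing$locus %in% loci, , drop = FALSE]
    ids %in% paste(sub$sample_id, sub$locus)
  }
  assayed <- present("child") & present("father") & present("mother")
  slot_cols <- c("child1", "child2", "father1", "father2", "mother1", "mother2")
  has_nt <- rowSums(is.na(as.matrix(grid[slot_cols]))) > 0
  reason <- dplyr::case_when(
    !assayed ~ "locus_not_assayed",
    has_nt ~ "not_typed_member",
    TRUE ~ NA_character_
  )
  ok <- is.na(reason)

  per_res <- lapply(resolutions, function(k) {
    sc <- rep(NA_real_, nrow(grid))
    if (any(ok)) {
      sc[ok] <- score_rows(grid$child1[ok], grid$child2[ok],
                           grid$father1[ok], grid$father2[ok],
                           grid$mother1[ok], grid$mother2[ok], k)
    }
    tibble::tibble(family_id = grid$family_id, locus = grid$locus,
                   resolution = k, included = ok,
                   exclusion_reason = reason, score = sc)
  })
  scores <- dplyr::bind_rows(per_res)

  if (drb345_unit && any(drb345_loci() %in% loci)) {
    scores <- dplyr::bind_rows(scores,
      score_unit_rows(typing, pedigree, resolutions))
  }

  structure(
    list(scores = scores, dataset = dataset,
         n_families = nrow(pedigree), resolutions = resolutions,
         loci = unique(scores$locus)),
    class = "hla_trio_scores"
  )
}

score_unit_rows <- function(typing, pedigree, resolutions) {
  units <- pool_drb345(typing)
  get <- function(ids, col) units[[col]][match(ids, units$sample_id)]
  assayed <- get(pedigree$child_id, "assayed") &
    get(pedigree$father_id, "assayed") & get(pedigree$mother_id, "assayed")
  assayed[is.na(assayed)] <- FALSE
  empty <- get(pedigree$child_id, "n_alleles") == 0 |
    get(pedigree$father_id, "n_alleles") == 0 |
    get(pedigree$mother_id, "n_alleles") == 0
  reason <- dplyr::case_when(
    !assayed ~ "locus_not_assayed",
    empty ~ "not_typed_member",
    TRUE ~ NA_character_
  )
  ok <- is.na(reason)
  cu <- get(pedigree$child_id, "alleles")
  fu <- get(pedigree$father_id, "alleles")
  mu <- get(pedigree$mother_id, "alleles")
  dplyr::bind_rows(lapply(resolutions, function(k) {
    sc <- rep(NA_real_, nrow(pedigree))
    for (i in which(ok)) sc[i] <- score_trio_locus(cu[[i]], fu[[i]], mu[[i]], k)
    tibble::tibble(family_id = pedigree$family_id, locus = "DRB345",
                   resolution = k, included = ok,
                   exclusion_reason = reason, score = sc)
  }))
}

#' Weighted consistency percentage for one locus/resolution
#'
#' `100 * sum(scores) / n` over the included trios (or duplicate pairs).
#'
#' @param score Numeric vector of scores in `{0, 0.5, 1}` for the included
#'   units; an empty vector yields `NA`.
#' @return One-row tibble `pct, n`.
#' @examples
#' consistency_percentage(c(rep(1, 5), rep(0.5, 6), rep(0, 3)))  # 57.14...
#' @export
consistency_percentage <- function(score) {
  score <- score[!is.na(score)]
  n <- length(score)
  tibble::tibble(pct = if (n == 0) NA_real_ else 100 * sum(score) / n, n = n)
}

res_col <- function(k) paste0(c("first", "second", "third")[k], "_field_pct")

#' Per-locus consistency table
#'
#' Collapses trio or duplicate scores to the familiar report layout: one
#' locus per row, one percentage column per field resolution, and the number
#' of evaluable families (or pairs).  Percentages are unrounded; rounding
#' happens at presentation/writing time.
#'
#' @param x An `hla_trio_scores` or `hla_dup_scores` object, or their
#'   `scores` tibble.
#' @return Tibble `locus, first_field_pct, second_field_pct,
#'   third_field_pct, n_families` (or `n_pairs`), with `NA` percentages
#'   exactly where the count is 0.  Carries the dataset label as attribute
#'   `dataset`.
#' @export
consistency_table <- function(x) {
  n_name <- if (inherits(x, "hla_dup_scores")) "n_pairs" else "n_families"
  dataset <- if (is.list(x) && !is.data.frame(x)) x$dataset else NULL
  scores <- if (is.data.frame(x)) x else x$scores
  if (!"included" %in% names(scores)) scores$included <- !is.na(scores$score)

  agg <- scores |>
    dplyr::group_by(.data$locus, .data$resolution) |>
    dplyr::summarise(
      pct = if (sum(.data$included) == 0) NA_real_ else
        100 * sum(.data$score[.data$included]) / sum(.data$included),
      n = sum(.data$included), .groups = "drop")
  wide <- agg |>
    dplyr::mutate(col = res_col(.data$resolution)) |>
    dplyr::select("locus", "col", "pct") |>
    tidyr::pivot_wider(names_from = "col", values_from = "pct")
  ns <- agg |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(n = max(.data$n), .groups = "drop")
  out <- dplyr::left_join(wide, ns, by = "locus")
  names(out)[names(out) == "n"] <- n_name
  ord <- .locus_names(include_pseudo = TRUE)
  out <- out[order(match(out$locus, ord)), , drop = FALSE]
  attr(out, "dataset") <- dataset
  out
}
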