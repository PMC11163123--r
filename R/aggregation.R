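# Per-resolution and overall averages across loci.
#
# Averages are unweighted across loci: a 2-family DRB5 row counts as much as
# a 25-family HLA-A row.  Loci with no evaluable family (NA rows) are
# excluded from the mean, not zero-filled.  Presentation rounding is
# half-up to two decimals; base R's round() rounds half to even, which would
# disagree with reported percentage tables on exact .005 boundaries.

#' Round half away from zero
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

#' Typing success rate per locus
#'
#' Percentage of samples whose genotype at a locus has both slots typed
#' (after homozygote expansion).  Samples lacking any row at the locus count
#' as failures only if the locus is assayed in the dataset at all; a locus
#' absent from every sample is an error.
#'
#' @param typing Typing tibble.
#' @param loci Loci to report (default: all loci in `typing`).
#' @return Tibble `locus, dataset, pct_typed, n_samples`.
#' @export
success_rate <- function(typing, loci = NULL) {
  if (is.null(loci)) loci <- intersect(.locus_names(), unique(typing$locus))
  absent <- setdiff(loci, unique(typing$locus))
  if (length(absent) > 0) {
    stop("locus not assayed in this dataset: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  samples <- unique(typing$sample_id)
  dataset <- if ("dataset" %in% names(typing))
    paste(unique(typing$dataset), collapse = "+") else "typing"
  sub <- typing[typing$locus %in% loci, , drop = FALSE]
  sub$ok <- !is.na(sub$allele1) & !is.na(sub$allele2)
  agg <- sub |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(n_ok = sum(.data$ok), .groups = "drop")
  out <- tibble::tibble(
    locus = loci,
    dataset = dataset,
    pct_typed = 100 * agg$n_ok[match(loci, agg$locus)] / length(samples),
    n_samples = length(samples)
  )
  out$pct_typed[is.na(out$pct_typed)] <- 0
  out
}

#' Unweighted per-resolution average across loci
#'
#' Arithmetic mean of the per-locus percentages at one field resolution,
#' excluding NA rows (loci with zero evaluable families), rounded half-up to
#' two decimals.
#'
#' @param table Consistency table (from [consistency_table()] or
#'   [read_consistency_table()]).
#' @param resolution Integer in 1..3.
#' @return A single percentage.
#' @export
resolution_average <- function(table, resolution) {
  resolution <- check_resolution(resolution)
  col <- res_col(resolution)
  if (!col %in% names(table)) {
    stop("table has no column for resolution ", resolution, call. = FALSE)
  }
  v <- table[[col]]
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("all loci are NA at resolution ", resolution,
                           call. = FALSE)
  round_half_up(mean(v), 2)
}

#' Overall average across the three field resolutions
#'
#' Arithmetic mean of the field-1..3 means, rounded half-up to two decimals.
#'
#' @param means Numeric vector of exactly three per-resolution means.
#' @return A single percentage.
#' @examples
#' overall_average(c(96.45, 95.27, 94.59))  # 95.44
#' @export
overall_average <- function(means) {
  stopifnot(length(means) == 3, !anyNA(means))
  round_half_up(mean(means), 2)
}

#' One-row summary of a consistency table
#'
#' The per-resolution means, their overall mean and the number of non-NA
#' loci — the quantities usually quoted alongside a per-locus table.
#'
#' @param table Consistency table.
#' @param dataset Optional label (default: the table's `dataset` attribute).
#' @return Tibble `dataset, mean_field1, mean_field2, mean_field3,
#'   overall_mean, n_loci`.
#' @export
summarize_consistency <- function(table, dataset = NULL) {
  if (is.null(dataset)) dataset <- attr(table, "dataset") %||% "dataset"
  means <- vapply(1:3, function(k) resolution_average(table, k), 0)
  nn <- grep("^n_", names(table), value = TRUE)[1]
  n_loci <- sum(!is.na(table[[res_col(1)]]))
  tibble::tibble(
    dataset = dataset,
    mean_field1 = means[1], mean_field2 = means[2], mean_field3 = means[3],
    overall_mean = overall_average(means),
    n_loci = n_loci
  )
}

#' Packaged reference consistency tables
#'
#' Published per-locus consistency percentage tables for four evaluation
#' settings, shipped as plain-text fixtures so the aggregation stage can be
#' exercised and checked against their stated column and overall averages:
#' * `research_exome`: 29-locus table, research-grade whole-exome trios
#'   (14 families; DRB6 has no evaluable family).  The source table lists
#'   DRB9 twice (one row is likely DRB8); kept verbatim.
#' * `clinical_exome`: 29-locus table, clinical-grade whole-exome trios
#'   (25 families).
#' * `panel_trios`: 11-locus table, targeted HLA panel trios (40 families).
#' * `resolution_summaries`: stated per-resolution average concordances for
#'   the duplicate-sample and tool-vs-tool comparisons.
#'
#' @return Named list of tibbles.
#' @export
hla_reference_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "hlaconcord",
                                  mustWork = TRUE)
  list(
    research_exome = read_consistency_table(path("consistency_research_exome.tsv")),
    clinical_exome = read_consistency_table(path("consistency_clinical_exome.tsv")),
    panel_trios = read_consistency_table(path("consistency_panel_trios.tsv")),
    resolution_summaries = {
      df <- read_tsv_commented(path("resolution_summaries.tsv"),
                               c("dataset", "mean_field1", "mean_field2",
                                 "mean_field3"))
      for (cc in c("mean_field1", "mean_field2", "mean_field3"))
        df[[cc]] <- as.numeric(df[[cc]])
      tibble::as_tibble(df)
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
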