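# File formats handled here (all tab-separated, UTF-8, '#' comments ignored):
#   * generic typing TSV:   sample  locus  allele1  allele2   ("-" = not typed)
#   * HLA-HD final result:  locus  allele1  allele2 per line  ("-" in slot 2 =
#     homozygote shorthand, expanded to a copy of slot 1)
#   * pedigree TSV:         family_id  child_id  father_id  mother_id
#   * duplicate pairing:    sample_a  dataset_a  sample_b  dataset_b
#   * consistency table:    locus + per-resolution percentages + n_families
#
# Loci absent from a typing table are "not assayed" — a different state from
# a present locus with not-typed slots, and the two are treated differently
# downstream (assay design vs typing failure).

read_tsv_commented <- function(path, col_names) {
  df <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = "c"),
                        progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(col_names, names(df))
  if (length(missing) > 0) {
    stop("file '", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

normalize_call <- function(raw, locus, path, dash_is_not_typed = TRUE) {
  x <- trimws(raw)
  x[x == "" ] <- NA_character_
  if (dash_is_not_typed) x[x == "-"] <- NA_character_
  x[x %in% NOT_TYPED_SENTINELS] <- NA_character_
  typed <- which(!is.na(x))
  if (length(typed) > 0) {
    parsed <- tryCatch(
      parse_allele(x[typed], locus_hint = locus[typed]),
      error = function(e) stop("in '", path, "': ", conditionMessage(e),
                               call. = FALSE)
    )
    x[typed] <- ifelse(is.na(parsed$suffix), parsed$allele,
                       paste0(parsed$allele, parsed$suffix))
  }
  x
}

#' Read a generic HLA typing table
#'
#' Expects a tab-separated file with a header `sample locus allele1 allele2`
#' (extra columns are kept), one genotype per sample per locus.  `"Not typed"`,
#' `"-"` and empty cells denote untyped slots.  Allele names may or may not
#' carry the `"HLA-"` prefix or the locus; bare field strings are resolved
#' against the `locus` column.
#'
#' @param path File path.
#' @param dataset Label recorded in the `dataset` column (defaults to the
#'   file name without extension).
#' @return A tibble `sample_id, locus, allele1, allele2, dataset` with
#'   canonical allele strings (`NA` = not typed).
#' @export
read_typing_tsv <- function(path, dataset = NULL) {
  df <- read_tsv_commented(path, c("sample", "locus", "allele1", "allele2"))
  if (is.null(dataset)) dataset <- tools::file_path_sans_ext(basename(path))
  assert_known_locus(df$locus)
  dup <- duplicated(df[c("sample", "locus")])
  if (any(dup)) {
    stop("file '", path, "': conflicting rows for sample ",
         df$sample[dup][1], " at locus ", df$locus[dup][1], call. = FALSE)
  }
  tibble::tibble(
    sample_id = df$sample,
    locus = df$locus,
    allele1 = normalize_call(df$allele1, df$locus, path),
    allele2 = normalize_call(df$allele2, df$locus, path),
    dataset = dataset
  )
}

#' Write a typing table in the generic TSV dialect
#'
#' Inverse of [read_typing_tsv()]; not-typed slots are written as
#' `"Not typed"` so the file round-trips without a locus hint ambiguity.
#'
#' @param typing Typing tibble (`sample_id, locus, allele1, allele2, ...`).
#' @param path Output path.
#' @return The input, invisibly.
#' @export
write_typing_tsv <- function(typing, path) {
  out <- tibble::tibble(
    sample = typing$sample_id,
    locus = typing$locus,
    allele1 = ifelse(is.na(typing$allele1), "Not typed", typing$allele1),
    allele2 = ifelse(is.na(typing$allele2), "Not typed", typing$allele2)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(typing)
}

#' Read one sample's HLA-HD final-result file
#'
#' One locus per line: `locus<TAB>allele1<TAB>allele2`, no header.  In this
#' dialect a `"-"` in the second slot alongside a typed first slot is the
#' tool's homozygote shorthand and is expanded to a second copy of the first
#' allele; `"Not typed"` slots become untyped calls.  Loci absent from the
#' file are absent from the result (not assayed).
#'
#' @param path File path.
#' @param sample_id Sample identifier to attach (defaults to file name).
#' @param dataset Dataset label.
#' @return Typing tibble as in [read_typing_tsv()].
#' @export
read_hlahd_result <- function(path, sample_id = NULL,
                              dataset = "hlahd") {
  if (is.null(sample_id)) sample_id <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    stop("'", path, "' line ", bad[1], ": expected locus and two allele slots",
         call. = FALSE)
  }
  locus <- vapply(parts, `[[`, "", 1)
  a1 <- trimws(vapply(parts, `[[`, "", 2))
  a2 <- trimws(vapply(parts, `[[`, "", 3))
  if (anyDuplicated(locus)) {
    i <- which(duplicated(locus))[1]
    stop("'", path, "' line ", i, ": duplicate locus line for ", locus[i],
         call. = FALSE)
  }
  assert_known_locus(locus)
  # homozygote shorthand: "-" in slot 2 copies slot 1 (only when slot 1 typed)
  homo <- a2 == "-" & !(a1 %in% c(NOT_TYPED_SENTINELS, "-", ""))
  a2[homo] <- a1[homo]
  a1 <- normalize_call(a1, locus, path)
  a2 <- normalize_call(a2, locus, path)
  tibble::tibble(sample_id = sample_id, locus = locus,
                 allele1 = a1, allele2 = a2, dataset = dataset)
}

#' Read a pedigree of family trios
#'
#' Tab-separated with header `family_id child_id father_id mother_id`.
#' The three member IDs of a trio must be distinct and family IDs unique.
#'
#' @param path File path.
#' @param typing Optional typing tibble; when given, member IDs that cannot
#'   be resolved against it raise an error naming them.
#' @return Tibble `family_id, child_id, father_id, mother_id` in file order.
#' @export
read_pedigree <- function(path, typing = NULL) {
  df <- read_tsv_commented(path, c("family_id", "child_id", "father_id",
                                   "mother_id"))
  ped <- tibble::as_tibble(df[c("family_id", "child_id", "father_id",
                                "mother_id")])
  if (anyDuplicated(ped$family_id)) {
    stop("duplicate family_id in '", path, "': ",
         ped$family_id[duplicated(ped$family_id)][1], call. = FALSE)
  }
  selfing <- ped$child_id == ped$father_id | ped$child_id == ped$mother_id |
    ped$father_id == ped$mother_id
  if (any(selfing)) {
    stop("family ", ped$family_id[selfing][1],
         " in '", path, "': child, father and mother IDs must be distinct",
         call. = FALSE)
  }
  if (!is.null(typing)) {
    ids <- unique(c(ped$child_id, ped$father_id, ped$mother_id))
    missing <- setdiff(ids, unique(typing$sample_id))
    if (length(missing) > 0) {
      stop("pedigree IDs not present in typing data: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  ped
}

#' Read a duplicate-sample pairing table
#'
#' Tab-separated with header `sample_a dataset_a sample_b dataset_b`, one
#' row per duplicate pair; each row links two typings of the same biological
#' sample from different datasets or tools.
#'
#' @param path File path.
#' @return Tibble `sample_a, dataset_a, sample_b, dataset_b`.
#' @export
read_pairs <- function(path) {
  df <- read_tsv_commented(path, c("sample_a", "dataset_a", "sample_b",
                                   "dataset_b"))
  same <- df$dataset_a == df$dataset_b
  if (any(same)) {
    stop("pair ", df$sample_a[same][1], "/", df$sample_b[same][1],
         " links two typings from the same dataset", call. = FALSE)
  }
  tibble::as_tibble(df[c("sample_a", "dataset_a", "sample_b", "dataset_b")])
}

#' Pool DRB3/4/5 calls into the DRB345 variation unit
#'
#' The secondary DRB loci have variable copy number (0-2 genes per genotype,
#' linked to the DRB1 allele), so they are compared as one pooled unit: per
#' sample, the multiset of all typed alleles across DRB3, DRB4 and DRB5.
#' Not-typed slots contribute nothing; a homozygous genotype contributes its
#' allele twice.  Per-locus rows are untouched — this function returns the
#' unit alongside, it does not replace them.
#'
#' @param typing Typing tibble.
#' @return Tibble `sample_id, locus = "DRB345", alleles` (list-column of
#'   character vectors), `n_alleles`, `assayed` (any DRB3/4/5 row present for
#'   the sample).
#' @examples
#' ty <- tibble::tibble(
#'   sample_id = "s1", locus = c("DRB3", "DRB4"),
#'   allele1 = c("DRB3*01:01:01", "DRB4*01:03"),
#'   allele2 = c(NA, "DRB4*01:03"), dataset = "demo"
#' )
#' pool_drb345(ty)$alleles[[1]]
#' @export
pool_drb345 <- function(typing) {
  drb <- typing[typing$locus %in% drb345_loci(), , drop = FALSE]
  samples <- unique(typing$sample_id)
  long <- tidyr::pivot_longer(drb, c("allele1", "allele2"),
                              names_to = "slot", values_to = "allele")
  long <- long[!is.na(long$allele), , drop = FALSE]
  pooled <- split(long$allele, factor(long$sample_id, levels = samples))
  tibble::tibble(
    sample_id = samples,
    locus = "DRB345",
    alleles = lapply(pooled, function(x) sort(unname(x))),
    n_alleles = lengths(pooled),
    assayed = samples %in% unique(drb$sample_id)
  )
}

#' Write a per-locus consistency table
#'
#' One locus per row with the per-resolution percentages formatted to two
#' decimals (half-up) and `NA` where no family or pair was evaluable.
#'
#' @param table Consistency/concordance tibble: `locus`, percentage columns
#'   (`*_pct`), and a count column (`n_families` or `n_pairs`).
#' @param path Output path.
#' @return The input, invisibly.
#' @export
write_consistency_table <- function(table, path) {
  pct_cols <- grep("_pct$", names(table), value = TRUE)
  out <- table
  for (cc in pct_cols) {
    v <- round_half_up(out[[cc]], 2)
    out[[cc]] <- ifelse(is.na(v), "NA", format(v, nsmall = 2, trim = TRUE,
                                               scientific = FALSE))
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(table)
}

#' Read a consistency table written by [write_consistency_table()]
#'
#' Also reads the packaged reference tables (literal `NA` percentages become
#' `NA`).
#'
#' @param path File path.
#' @return Tibble with numeric percentage columns and integer counts.
#' @export
read_consistency_table <- function(path) {
  df <- read_tsv_commented(path, "locus")
  for (cc in setdiff(names(df), "locus")) {
    suppressWarnings(df[[cc]] <- as.numeric(ifelse(df[[cc]] == "NA", NA,
                                                   df[[cc]])))
  }
  cnt <- grep("^n_", names(df), value = TRUE)
  for (cc in cnt) df[[cc]] <- as.integer(df[[cc]])
  tibble::as_tibble(df)
}
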