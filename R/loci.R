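#' The 29-locus HLA registry
#'
#' Loci typeable by modern NGS HLA callers at up to three-field resolution:
#' the classical class I genes (A, B, C), classical class II genes (DRB1,
#' DQA1, DQB1, DPA1, DPB1), the non-classical / low-polymorphism genes
#' (DMA, DMB, DOA, DOB, DRA, E, F, G, H, J, K, L, V) and the DRB paralogs
#' (DRB2-DRB9).  A pseudo-locus `DRB345` represents the pooled DRB3/DRB4/DRB5
#' variation unit; it is never read from input files but is created by
#' [pool_drb345()].
#'
#' @return A tibble with columns `locus` and `class_group`
#'   (`classical_I`, `classical_II`, `nonclassical`, `DRB_paralog`, `pseudo`).
#' @examples
#' hla_loci()
#' @export
hla_loci <- function() {
  tibble::tibble(
    locus = c(
      "A", "B", "C",
      "DRB1", "DQA1", "DQB1", "DPA1", "DPB1",
      "DMA", "DMB", "DOA", "DOB", "DRA",
      "DRB2", "DRB3", "DRB4", "DRB5", "DRB6", "DRB7", "DRB8", "DRB9",
      "E", "F", "G", "H", "J", "K", "L", "V",
      "DRB345"
    ),
    class_group = c(
      rep("classical_I", 3),
      rep("classical_II", 5),
      rep("nonclassical", 5),
      rep("DRB_paralog", 8),
      rep("nonclassical", 8),
      "pseudo"
    )
  )
}

# registry lookups used on hot paths; computed once at load
.registry <- new.env(parent = emptyenv())

.locus_names <- function(include_pseudo = FALSE) {
  if (is.null(.registry$all)) {
    reg <- hla_loci()
    .registry$all <- reg$locus
    .registry$real <- reg$locus[reg$class_group != "pseudo"]
  }
  if (include_pseudo) .registry$all else .registry$real
}

#' Loci covered by a targeted HLA panel assay
#'
#' The 11 classical loci an amplicon HLA panel types: A, B, C, DRB1, DQA1,
#' DQB1, DPA1, DPB1 and the DRB3/4/5 paralogs.
#'
#' @return Character vector of locus names.
#' @export
panel_loci <- function() {
  c("A", "B", "C", "DRB1", "DQA1", "DQB1", "DPA1", "DPB1",
    "DRB3", "DRB4", "DRB5")
}

#' The DRB3/4/5 paralog loci pooled into the DRB345 unit
#' @return Character vector `c("DRB3", "DRB4", "DRB5")`.
#' @export
drb345_loci <- function() c("DRB3", "DRB4", "DRB5")

assert_known_locus <- function(locus, allow_pseudo = FALSE) {
  known <- .locus_names(include_pseudo = allow_pseudo)
  bad <- setdiff(unique(locus), known)
  if (length(bad) > 0) {
    stop("unknown HLA locus: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(locus)
}
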