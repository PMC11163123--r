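#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom generics tidy glance
NULL

# Allele strings travel through the package in a canonical text form:
# "<LOCUS>*<f1>:<f2>[:<f3>[:<f4>]][suffix]" with numeric, zero-padded field
# tokens and an optional expression suffix (N/L/S/C/A/Q).  A not-typed call
# is NA_character_.  All comparison is string-wise on field tokens, so
# leading zeros are significant ("01" != "1").

NOT_TYPED_SENTINELS <- c("Not typed", "not typed", "NOT TYPED", "Not Typed")

.suffix_re <- "[NLSCAQ]"
.allele_re <- paste0(
  "^(?:HLA-)?([A-Z][A-Z0-9]*)\\*([0-9]+(?::[0-9]+){0,3})(", .suffix_re, ")?$"
)

#' Parse HLA allele names
#'
#' Parses IPD-IMGT/HLA-style allele names such as `"HLA-DRB3*02:02:01"` into
#' their components: locus, ordered field tokens (1-4 numeric, zero-padded
#' strings) and optional expression suffix.  The `"HLA-"` prefix is optional.
#' The sentinels `"Not typed"` and `"-"` (and `NA`) denote an untyped call and
#' require a `locus_hint`.  Bare field strings (`"02:01"`) are accepted only
#' with a `locus_hint`.
#'
#' @param text Character vector of allele names.
#' @param locus_hint Optional locus name (length 1 or `length(text)`); when
#'   given it must agree with any locus parsed from the text.
#' @return A tibble with one row per input: `raw`, `locus`, `status`
#'   (`"typed"`/`"not_typed"`), `allele` (canonical `LOCUS*fields` string
#'   without suffix, `NA` if not typed), `n_fields`, `suffix`.
#' @examples
#' parse_allele(c("HLA-DRB3*02:02:01", "A*01:01:01:01"))
#' parse_allele("Not typed", locus_hint = "DRB6")
#' @export
parse_allele <- function(text, locus_hint = NULL) {
  stopifnot(is.character(text))
  raw <- trimws(text)
  n <- length(raw)
  if (!is.null(locus_hint)) {
    locus_hint <- rep_len(as.character(locus_hint), n)
    assert_known_locus(locus_hint[!is.na(locus_hint)])
  }

  not_typed <- is.na(raw) | raw %in% NOT_TYPED_SENTINELS | raw == "-"
  locus <- rep(NA_character_, n)
  fields <- rep(NA_character_, n)
  suffix <- rep(NA_character_, n)

  if (any(not_typed)) {
    if (is.null(locus_hint) || anyNA(locus_hint[not_typed])) {
      stop("a not-typed sentinel requires a locus_hint", call. = FALSE)
    }
    locus[not_typed] <- locus_hint[not_typed]
  }

  todo <- which(!not_typed)
  if (length(todo) > 0) {
    m <- regmatches(raw[todo], regexec(.allele_re, raw[todo], perl = TRUE))
    ok <- lengths(m) > 0
    # bare "02:01"-style strings need the hint to supply the locus
    bare <- !ok & grepl("^[0-9]+(:[0-9]+){0,3}[NLSCAQ]?$", raw[todo], perl = TRUE)
    if (any(bare) && is.null(locus_hint)) {
      stop("bare allele fields without locus: '", raw[todo][bare][1], "'",
           call. = FALSE)
    }
    bad <- !ok & !bare
    if (any(bad)) {
      stop("malformed HLA allele name: '", raw[todo][bad][1], "'", call. = FALSE)
    }
    for (j in which(ok)) {
      i <- todo[j]
      locus[i] <- m[[j]][2]
      fields[i] <- m[[j]][3]
      sfx <- m[[j]][4]
      suffix[i] <- if (is.na(sfx) || sfx == "") NA_character_ else sfx
    }
    if (any(bare)) {
      bi <- todo[bare]
      body <- raw[bi]
      has_sfx <- grepl(paste0(.suffix_re, "$"), body)
      suffix[bi] <- ifelse(has_sfx, substr(body, nchar(body), nchar(body)),
                           NA_character_)
      fields[bi] <- sub(paste0(.suffix_re, "$"), "", body)
      locus[bi] <- locus_hint[bi]
    }
    typed <- which(!not_typed)
    assert_known_locus(locus[typed])
    if (any(locus[typed] == "DRB345")) {
      stop("pseudo-locus DRB345 cannot appear in allele names", call. = FALSE)
    }
    if (!is.null(locus_hint)) {
      clash <- typed[!is.na(locus_hint[typed]) & locus_hint[typed] != locus[typed]]
      if (length(clash) > 0) {
        stop("allele '", raw[clash[1]], "' does not belong to locus ",
             locus_hint[clash[1]], call. = FALSE)
      }
    }
  }

  tibble::tibble(
    raw = text,
    locus = locus,
    status = ifelse(not_typed, "not_typed", "typed"),
    allele = ifelse(not_typed, NA_character_, paste0(locus, "*", fields)),
    n_fields = ifelse(not_typed, 0L, lengths(strsplit(fields, ":", fixed = TRUE))),
    suffix = suffix
  )
}

# split a canonical allele string into gene and field tokens (suffix dropped);
# returns list(gene=chr, fields=list of chr vectors, n=int, suffix=chr)
split_allele <- function(x) {
  gene <- ifelse(grepl("*", x, fixed = TRUE), sub("\\*.*$", "", x), NA_character_)
  body <- sub("^[^*]*\\*", "", x)
  suffix <- ifelse(grepl(paste0(.suffix_re, "$"), body),
                   substr(body, nchar(body), nchar(body)), NA_character_)
  body <- sub(paste0(.suffix_re, "$"), "", body)
  flds <- strsplit(body, ":", fixed = TRUE)
  flds[is.na(x)] <- list(character(0))
  list(gene = gene, fields = flds, n = lengths(flds), suffix = suffix)
}

#' Truncate an allele name to a field resolution
#'
#' Keeps the first `min(resolution, available)` fields of each allele.
#' Not-typed calls (`NA`) pass through unchanged.  The expression suffix is
#' dropped whenever fields are actually removed, and kept when the allele is
#' already at or below the requested resolution.
#'
#' @param allele Character vector of canonical allele strings
#'   (`"LOCUS*f1:f2[...]"` or bare `"f1:f2[...]"`); `NA` = not typed.
#' @param resolution Integer in 1..3 (a fourth field is tolerated on input
#'   but never a comparison resolution).
#' @return Character vector, same shape as `allele`.
#' @examples
#' truncate_allele("HLA-DRB3*02:02:01", 2)
#' truncate_allele("DRB3*02:96", 3)   # only two fields available, kept as-is
#' @export
truncate_allele <- function(allele, resolution) {
  resolution <- check_resolution(resolution)
  allele <- sub("^HLA-", "", allele)
  p <- split_allele(allele)
  out <- allele
  for (i in seq_along(allele)) {
    if (is.na(allele[i])) next
    f <- p$fields[[i]]
    keep <- min(resolution, length(f))
    body <- paste(f[seq_len(keep)], collapse = ":")
    if (keep == length(f) && !is.na(p$suffix[i])) body <- paste0(body, p$suffix[i])
    out[i] <- if (is.na(p$gene[i])) body else paste0(p$gene[i], "*", body)
  }
  out
}

check_resolution <- function(resolution) {
  resolution <- as.integer(resolution)
  if (length(resolution) != 1 || is.na(resolution) ||
      resolution < 1L || resolution > 3L) {
    stop("resolution must be a single integer in 1..3", call. = FALSE)
  }
  resolution
}

#' Compare two alleles at a field resolution
#'
#' Two typed alleles match at resolution `k` iff both carry at least `k`
#' fields and their first `k` field tokens are equal (string-wise; leading
#' zeros significant).  An allele typed to fewer fields than `k` matches
#' nothing at `k`: a two-field call is counted inconsistent against a
#' three-field call at the third field.  Two not-typed calls (`NA`) match
#' (concordant absence); typed vs not-typed never match.  Expression suffixes
#' are ignored.  When both alleles carry a locus prefix the loci must agree,
#' otherwise an error is thrown (pool DRB3/4/5 upstream, do not compare
#' across paralogs).
#'
#' @param a,b Character vectors of canonical allele strings (`NA` = not
#'   typed), recycled to a common length.
#' @param resolution Integer in 1..3.
#' @return Logical vector.
#' @examples
#' alleles_match("DRB3*02:96", "DRB3*02:02:01", 1)  # TRUE
#' alleles_match("DRB3*02:96", "DRB3*02:02:01", 2)  # FALSE
#' alleles_match("A*02:01", "A*02:01:01", 3)        # FALSE: depth too short
#' @export
alleles_match <- function(a, b, resolution) {
  resolution <- check_resolution(resolution)
  n <- max(length(a), length(b))
  a <- rep_len(sub("^HLA-", "", a), n)
  b <- rep_len(sub("^HLA-", "", b), n)
  pa <- split_allele(a)
  pb <- split_allele(b)
  both_gene <- !is.na(pa$gene) & !is.na(pb$gene)
  if (any(both_gene & pa$gene != pb$gene)) {
    i <- which(both_gene & pa$gene != pb$gene)[1]
    stop("locus mismatch in allele comparison: ", a[i], " vs ", b[i],
         call. = FALSE)
  }
  out <- logical(n)
  for (i in seq_len(n)) {
    if (is.na(a[i]) || is.na(b[i])) {
      out[i] <- is.na(a[i]) && is.na(b[i])
    } else {
      fa <- pa$fields[[i]]
      fb <- pb$fields[[i]]
      out[i] <- length(fa) >= resolution && length(fb) >= resolution &&
        all(fa[seq_len(resolution)] == fb[seq_len(resolution)])
    }
  }
  out
}

# fast path used by the scoring pipelines: map allele strings to a key such
# that two typed alleles match at `resolution` iff both keys are non-NA and
# equal.  Not-typed calls and alleles typed to fewer than `resolution` fields
# get NA (they match nothing via the key; concordant absence is handled by
# the caller where it applies).
match_key <- function(allele, resolution) {
  p <- split_allele(sub("^HLA-", "", allele))
  key <- rep(NA_character_, length(allele))
  for (i in seq_along(allele)) {
    if (is.na(allele[i])) next
    f <- p$fields[[i]]
    if (length(f) >= resolution) {
      key[i] <- paste(c(p$gene[i], f[seq_len(resolution)]), collapse = "|")
    }
  }
  key
}
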