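# Independent brute-force oracles, deliberately written in plain base R with
# no reuse of package internals, so they can cross-check the scoring code.

# token-wise allele match: both typed with >= k fields and first k field
# tokens (plus the gene, when present) equal; two not-typed calls match
oracle_match <- function(a, b, k) {
  if (is.na(a) || is.na(b)) return(is.na(a) && is.na(b))
  strip <- function(x) {
    x <- sub("^HLA-", "", x)
    gene <- if (grepl("*", x, fixed = TRUE)) sub("\\*.*", "", x) else ""
    body <- sub("^[^*]*\\*", "", x)
    body <- sub("[NLSCAQ]$", "", body)
    list(gene = gene, f = strsplit(body, ":", fixed = TRUE)[[1]])
  }
  pa <- strip(a); pb <- strip(b)
  if (nzchar(pa$gene) && nzchar(pb$gene) && pa$gene != pb$gene) return(FALSE)
  length(pa$f) >= k && length(pb$f) >= k &&
    all(pa$f[seq_len(k)] == pb$f[seq_len(k)])
}

# exhaustive enumeration over all assignments of child alleles to parental
# alleles (one child allele to each parent); half point when no biparental
# assignment exists but some child allele matches some parental allele
oracle_trio <- function(child, father, mother, k) {
  if (length(child) == 1) {
    hit <- any(vapply(c(father, mother), oracle_match, TRUE, a = child, k = k))
    return(if (hit) 1 else 0)
  }
  if (length(child) >= 3) {
    any_hit <- FALSE
    for (ca in child) for (p in c(father, mother)) {
      if (oracle_match(ca, p, k)) any_hit <- TRUE
    }
    return(if (any_hit) 0.5 else 0)
  }
  full <- FALSE
  for (p in father) for (q in mother) {
    if ((oracle_match(child[1], p, k) && oracle_match(child[2], q, k)) ||
        (oracle_match(child[2], p, k) && oracle_match(child[1], q, k))) {
      full <- TRUE
    }
  }
  if (full) return(1)
  any_hit <- FALSE
  for (ca in child) for (p in c(father, mother)) {
    if (oracle_match(ca, p, k)) any_hit <- TRUE
  }
  if (any_hit) 0.5 else 0
}

# exhaustive slot-permutation search for the duplicate pair score
oracle_pair <- function(a, b, k) {
  best <- 0
  for (pa in list(a, rev(a))) for (pb in list(b, rev(b))) {
    s <- (oracle_match(pa[1], pb[1], k) + oracle_match(pa[2], pb[2], k)) / 2
    best <- max(best, s)
  }
  best
}

# random toy alleles at one locus: field tokens drawn from a small alphabet,
# depth 2 or 3 so the short-call rule is exercised
random_allele <- function(locus = "A", max_group = 3) {
  f1 <- sprintf("%02d", sample.int(max_group, 1))
  f2 <- sprintf("%02d", sample.int(2, 1))
  depth <- sample(2:3, 1)
  body <- if (depth == 2) paste(f1, f2, sep = ":") else
    paste(f1, f2, sprintf("%02d", sample.int(2, 1)), sep = ":")
  paste0(locus, "*", body)
}

random_genotype <- function(locus = "A") {
  c(random_allele(locus), random_allele(locus))
}

# compact builder for typing tibbles in tests
make_typing <- function(sample_id, locus, allele1, allele2,
                        dataset = "test") {
  tibble::tibble(sample_id = sample_id, locus = locus,
                 allele1 = allele1, allele2 = allele2, dataset = dataset)
}

# the worked single-locus decomposition: 14 trios of which 5 score 1,
# 6 score 0.5 (homozygous child covered by one parent only) and 3 score 0
dpb1_worked_example <- function() {
  rows <- list()
  ped <- tibble::tibble(family_id = sprintf("F%02d", 1:14),
                        child_id = sprintf("F%02d_c", 1:14),
                        father_id = sprintf("F%02d_f", 1:14),
                        mother_id = sprintf("F%02d_m", 1:14))
  add <- function(fam, who, a1, a2) {
    rows[[length(rows) + 1]] <<- make_typing(
      paste0(fam, who), "DPB1", paste0("DPB1*", a1), paste0("DPB1*", a2))
  }
  for (i in 1:14) {
    fam <- sprintf("F%02d", i)
    if (i <= 5) {            # fully Mendelian-consistent
      add(fam, "_c", "01:01:01", "02:01:01")
      add(fam, "_f", "01:01:01", "03:01:01")
      add(fam, "_m", "02:01:01", "04:01:01")
    } else if (i <= 11) {    # one-parent match only (homozygous child)
      add(fam, "_c", "01:01:01", "01:01:01")
      add(fam, "_f", "01:01:01", "03:01:01")
      add(fam, "_m", "02:01:01", "04:01:01")
    } else {                 # neither parent matched
      add(fam, "_c", "05:01:01", "06:01:01")
      add(fam, "_f", "01:01:01", "03:01:01")
      add(fam, "_m", "02:01:01", "04:01:01")
    }
  }
  list(typing = dplyr::bind_rows(rows), pedigree = ped)
}
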