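# End-to-end orchestration: simulate (or load) -> score -> aggregate ->
# report bundle on disk, with a manifest for reproducibility.

#' Run the consistency pipeline from a config
#'
#' Drives the whole analysis from a single YAML file (or equivalent list):
#' either simulates trios/duplicates or loads typing + pedigree + pairing
#' files, scores them, and writes a report bundle to `out_dir`:
#' per-dataset consistency tables (TSV), a per-trio / per-pair audit trail
#' including every exclusion with its reason, success-rate table, a
#' resolution summary, a machine-readable `summary.json` sidecar with
#' unrounded values, and `manifest.json` (config digest, input digests,
#' seed, package version, timestamp).
#'
#' Config schema (all top-level keys optional unless noted):
#' ```yaml
#' seed: 1
#' resolutions: [1, 2, 3]
#' simulate:              # either this ...
#'   n_families: 14
#'   n_duplicates: 100
#'   dropout_rate: 0.0
#'   truncation_rate: 0.0
#'   mistyping_rate: 0.0
#' inputs:                # ... or this
#'   typing: path.tsv
#'   pedigree: ped.tsv
#'   typing_b: other.tsv  # optional, with pairs:
#'   pairs: pairs.tsv
#' ```
#'
#' @param config Path to a YAML config, or a list with the same structure.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the computed tables and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML file path or a list",
                             call. = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  resolutions <- as.integer(unlist(config$resolutions %||% 1:3))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character()
  results <- list()

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    cfg <- sim_config(
      n_families = sim_args$n_families %||% 14,
      n_duplicates = sim_args$n_duplicates %||% 100,
      dropout_rate = sim_args$dropout_rate %||% 0,
      truncation_rate = sim_args$truncation_rate %||% 0,
      mistyping_rate = sim_args$mistyping_rate %||% 0,
      seed = seed
    )
    trios <- simulate_trios(cfg)
    noisy <- apply_noise(render_typing(trios$truth, dataset = "simulated"),
                         cfg, seed = seed + 1L)
    typing <- noisy$observed
    pedigree <- trios$pedigree
    readr::write_tsv(noisy$events, file.path(out_dir, "noise_events.tsv"),
                     progress = FALSE)
    write_typing_tsv(typing, file.path(out_dir, "typing_simulated.tsv"))
    readr::write_tsv(pedigree, file.path(out_dir, "pedigree_simulated.tsv"),
                     progress = FALSE)
    typing_b <- NULL
    pairs <- NULL
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    if (is.null(inp$typing)) stop("config inputs$typing is required",
                                  call. = FALSE)
    typing <- read_typing_tsv(inp$typing)
    inputs <- c(inputs, inp$typing)
    pedigree <- if (!is.null(inp$pedigree)) {
      inputs <- c(inputs, inp$pedigree)
      read_pedigree(inp$pedigree, typing = typing)
    }
    typing_b <- if (!is.null(inp$typing_b)) {
      inputs <- c(inputs, inp$typing_b)
      read_typing_tsv(inp$typing_b)
    }
    pairs <- if (!is.null(inp$pairs)) {
      inputs <- c(inputs, inp$pairs)
      read_pairs(inp$pairs)
    }
  } else {
    stop("config must contain either 'simulate' or 'inputs'", call. = FALSE)
  }

  summaries <- list()
  if (!is.null(pedigree)) {
    trio_res <- score_trios(typing, pedigree, resolutions = resolutions)
    tab <- consistency_table(trio_res)
    write_consistency_table(tab, file.path(out_dir, "trio_consistency.tsv"))
    readr::write_tsv(trio_res$scores, file.path(out_dir, "trio_audit.tsv"),
                     progress = FALSE)
    summaries$trios <- summarize_consistency(tab)
    results$trio_table <- tab
    results$trio_scores <- trio_res
  }
  if (!is.null(typing_b) && !is.null(pairs)) {
    dup_res <- score_duplicates(typing, typing_b, pairs,
                                resolutions = resolutions)
    dtab <- concordance_table(dup_res)
    write_consistency_table(dtab, file.path(out_dir, "dup_concordance.tsv"))
    readr::write_tsv(dup_res$scores, file.path(out_dir, "dup_audit.tsv"),
                     progress = FALSE)
    summaries$duplicates <- summarize_consistency(dtab)
    results$dup_table <- dtab
  }

  sr <- success_rate(typing)
  readr::write_tsv(sr, file.path(out_dir, "success_rate.tsv"), progress = FALSE)
  results$success_rate <- sr

  if (length(summaries) > 0) {
    summary_tbl <- dplyr::bind_rows(summaries, .id = "analysis")
    readr::write_tsv(summary_tbl, file.path(out_dir, "resolution_summary.tsv"),
                     progress = FALSE)
    results$summary <- summary_tbl
    jsonlite::write_json(results$summary,
                         file.path(out_dir, "summary.json"), digits = NA)
  }

  manifest <- list(
    command = "run_pipeline",
    config_digest = digest_of(config_path %||% config),
    input_digests = as.list(stats::setNames(
      vapply(inputs, function(f) unname(tools::md5sum(f)), ""), inputs)),
    seed = seed,
    tool_version = as.character(utils::packageVersion("hlaconcord")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

digest_of <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    return(unname(tools::md5sum(x)))
  }
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(x), tf)
  unname(tools::md5sum(tf))
}

#' Compare two typing tools or assays on shared samples
#'
#' Concordance of two typings of the same samples restricted to the loci both
#' assays cover, plus a discrepancy listing: every pair/locus whose genotypes
#' disagree at the highest requested resolution, with the alleles from both
#' sides (the shape of a manual discrepancy audit).
#'
#' @inheritParams score_duplicates
#' @return List of class `hla_tool_comparison`: `table` (per-locus
#'   concordance), `summary` (one-row resolution summary), `discrepancies`
#'   (tibble `sample_a, sample_b, locus, alleles_a, alleles_b, score`).
#' @export
compare_tools <- function(typing_a, typing_b, pairs, resolutions = 1:3,
                          loci = NULL) {
  res <- score_duplicates(typing_a, typing_b, pairs,
                          resolutions = resolutions, loci = loci)
  tab <- concordance_table(res)
  kmax <- max(res$resolutions)
  disc <- res$scores[res$scores$resolution == kmax & res$scores$score < 1, ,
                     drop = FALSE]
  fmt <- function(typing, ids, loci) {
    i <- match(paste(ids, loci), paste(typing$sample_id, typing$locus))
    paste(ifelse(is.na(typing$allele1[i]), "Not typed", typing$allele1[i]),
          ifelse(is.na(typing$allele2[i]), "Not typed", typing$allele2[i]),
          sep = " / ")
  }
  disc <- tibble::tibble(
    sample_a = disc$sample_a, sample_b = disc$sample_b, locus = disc$locus,
    alleles_a = fmt(typing_a, disc$sample_a, disc$locus),
    alleles_b = fmt(typing_b, disc$sample_b, disc$locus),
    score = disc$score
  )
  structure(list(table = tab, summary = summarize_consistency(tab),
                 discrepancies = disc, resolution = kmax),
            class = "hla_tool_comparison")
}
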