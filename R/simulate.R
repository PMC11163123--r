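# Synthetic populations, trios and duplicate typings.
#
# The generator realises the structure the scoring assumes: founders carry
# two independent haplotypes per locus drawn from categorical allele
# frequencies; a child receives one whole haplotype from each parent (the
# DRB region co-transmits); which secondary DRB gene (DRB3/4/5 or none) a
# haplotype carries is determined by its DRB1 allele group, reproducing the
# copy-number structure the pooled-unit scoring must handle.  Observation
# noise is applied per allele call, independently: dropout (the call becomes
# not typed), field truncation (a three-field call is emitted with two
# fields), and mistyping (the call is replaced by a different pool allele).

default_drb_linkage <- function() {
  c("01" = "none", "08" = "none", "10" = "none",
    "03" = "DRB3", "11" = "DRB3", "12" = "DRB3", "13" = "DRB3", "14" = "DRB3",
    "04" = "DRB4", "07" = "DRB4", "09" = "DRB4",
    "15" = "DRB5", "16" = "DRB5")
}

default_pool <- function(locus, pool_size) {
  if (locus == "DRB1") {
    # groups chosen so all three secondary DRB genes and the no-gene
    # haplotype are common enough to populate every per-locus row
    allele <- paste0("DRB1*", c("03:01:01", "11:01:01", "04:02:01", "07:01:01",
                                "15:01:01", "16:01:01", "01:01:01", "08:01:01"))
    freq <- c(0.20, 0.15, 0.15, 0.10, 0.15, 0.10, 0.10, 0.05)
  } else if (locus == "DRB3") {
    allele <- paste0("DRB3*", c("01:01:02", "02:02:01", "03:01:01"))
    freq <- c(0.5, 0.3, 0.2)
  } else if (locus == "DRB4") {
    allele <- paste0("DRB4*", c("01:03:01", "01:01:01"))
    freq <- c(0.7, 0.3)
  } else if (locus == "DRB5") {
    allele <- paste0("DRB5*", c("01:01:01", "02:02:01"))
    freq <- c(0.7, 0.3)
  } else {
    i <- seq_len(pool_size)
    # paired field-1 groups: pool-mates can share the serological group but
    # differ at field 2, so every resolution level is informative
    allele <- sprintf("%s*%02d:%02d:01", locus, (i + 1) %/% 2, i)
    w <- 1 / i
    freq <- w / sum(w)
  }
  tibble::tibble(allele = allele, freq = freq)
}

#' Configuration for the synthetic typing simulator
#'
#' @param loci Independently simulated loci (default: the full registry
#'   minus DRB3/4/5, whose carriage is driven by DRB1 linkage).
#' @param n_families Number of trios for [simulate_trios()].
#' @param n_duplicates Number of samples for [simulate_duplicates()].
#' @param allele_pool_size Alleles per locus for default pools.
#' @param haplotype_frequencies Optional named list `locus -> named numeric
#'   vector` (names = allele strings, values = frequencies summing to 1)
#'   overriding the default pools; may include DRB3/DRB4/DRB5.
#' @param drb_linkage Named map from DRB1 field-1 group to `"DRB3"`,
#'   `"DRB4"`, `"DRB5"` or `"none"`.
#' @param dropout_rate,truncation_rate,mistyping_rate Per-allele-call noise
#'   probabilities (defaults 0: noise-free Mendelian transmission).
#' @param seed Integer seed; every simulation entry point is deterministic
#'   given the config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(loci = NULL, n_families = 14, n_duplicates = 100,
                       allele_pool_size = 8, haplotype_frequencies = NULL,
                       drb_linkage = default_drb_linkage(),
                       dropout_rate = 0, truncation_rate = 0,
                       mistyping_rate = 0, seed = 1L) {
  if (is.null(loci)) loci <- setdiff(.locus_names(), drb345_loci())
  assert_known_locus(loci)
  loci <- setdiff(loci, drb345_loci())
  rates <- c(dropout_rate = dropout_rate, truncation_rate = truncation_rate,
             mistyping_rate = mistyping_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("noise rates must lie in [0, 1]", call. = FALSE)
  }
  pool_loci <- unique(c(loci, if ("DRB1" %in% loci) drb345_loci()))
  pools <- lapply(pool_loci, function(L) {
    if (!is.null(haplotype_frequencies[[L]])) {
      fr <- haplotype_frequencies[[L]]
      p <- parse_allele(names(fr), locus_hint = L)
      pool <- tibble::tibble(allele = p$allele, freq = unname(fr))
    } else {
      pool <- default_pool(L, allele_pool_size)
    }
    if (nrow(pool) < 2) stop("allele pool for ", L, " needs >= 2 alleles",
                             call. = FALSE)
    if (abs(sum(pool$freq) - 1) > 1e-8 || any(pool$freq < 0)) {
      stop("allele frequencies for ", L, " must be non-negative and sum to 1",
           call. = FALSE)
    }
    pool
  })
  names(pools) <- pool_loci
  if ("DRB1" %in% loci) {
    groups <- sub(":.*$", "", sub("^DRB1\\*", "", pools$DRB1$allele))
    missing <- setdiff(groups, names(drb_linkage))
    if (length(missing) > 0) {
      stop("drb_linkage lacks DRB1 group(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(
    list(loci = loci, n_families = n_families, n_duplicates = n_duplicates,
         pools = pools, drb_linkage = drb_linkage,
         dropout_rate = dropout_rate, truncation_rate = truncation_rate,
         mistyping_rate = mistyping_rate, seed = as.integer(seed)),
    class = "sim_config"
  )
}

draw_pool <- function(pool, n) {
  pool$allele[sample.int(nrow(pool), n, replace = TRUE, prob = pool$freq)]
}

# n_hap haplotypes as a long tibble (hap, locus, allele); secondary DRB rows
# appear only for haplotypes whose DRB1 group carries that gene
simulate_haplotypes <- function(cfg, n_hap) {
  parts <- lapply(cfg$loci, function(L) {
    tibble::tibble(hap = seq_len(n_hap), locus = L,
                   allele = draw_pool(cfg$pools[[L]], n_hap))
  })
  out <- dplyr::bind_rows(parts)
  if ("DRB1" %in% cfg$loci) {
    drb1 <- out$allele[out$locus == "DRB1"]
    group <- sub(":.*$", "", sub("^DRB1\\*", "", drb1))
    carried <- unname(cfg$drb_linkage[group])
    for (P in drb345_loci()) {
      idx <- which(carried == P)
      if (length(idx) > 0) {
        out <- dplyr::bind_rows(out, tibble::tibble(
          hap = idx, locus = P, allele = draw_pool(cfg$pools[[P]], length(idx))))
      }
    }
  }
  out
}

#' Simulate a founder population
#'
#' Each sample carries two independent haplotypes drawn from the configured
#' allele frequencies; DRB3/4/5 carriage follows the DRB1 linkage map.
#' Deterministic under `cfg$seed` (or an explicit `seed`).
#'
#' @param cfg A [sim_config()].
#' @param n_samples Number of founders (default `cfg$n_duplicates`).
#' @param seed Overrides `cfg$seed`.
#' @return Truth tibble `sample_id, hap (1 or 2), locus, allele`; absent
#'   secondary DRB genes have no row.
#' @export
simulate_population <- function(cfg, n_samples = cfg$n_duplicates,
                                seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  haps <- simulate_haplotypes(cfg, 2L * n_samples)
  ids <- sprintf("S%04d", seq_len(n_samples))
  haps$sample_id <- ids[(haps$hap + 1L) %/% 2L]
  haps$hap <- ifelse(haps$hap %% 2L == 1L, 1L, 2L)
  haps[c("sample_id", "hap", "locus", "allele")]
}

#' Simulate family trios with Mendelian transmission
#'
#' Founder parents are drawn as in [simulate_population()]; each child
#' receives one randomly chosen haplotype per parent, co-transmitting every
#' locus on it (including the linked DRB3/4/5 gene).
#'
#' @param cfg A [sim_config()].
#' @param n_families Default `cfg$n_families`.
#' @param seed Overrides `cfg$seed`.
#' @return List with `truth` (tibble `sample_id, hap, locus, allele` for all
#'   members), `pedigree` (tibble `family_id, child_id, father_id,
#'   mother_id`) and `transmitted` (which parental haplotype each child
#'   received).
#' @export
simulate_trios <- function(cfg, n_families = cfg$n_families, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  fam <- sprintf("F%03d", seq_len(n_families))
  ped <- tibble::tibble(
    family_id = fam,
    child_id = paste0(fam, "_ch"),
    father_id = paste0(fam, "_fa"),
    mother_id = paste0(fam, "_mo")
  )
  haps <- simulate_haplotypes(cfg, 4L * n_families)
  # haplotypes 4f-3, 4f-2 belong to the father of family f; 4f-1, 4f mother
  owner_fam <- (haps$hap + 3L) %/% 4L
  is_father <- ((haps$hap - 1L) %% 4L) < 2L
  haps$sample_id <- ifelse(is_father, ped$father_id[owner_fam],
                           ped$mother_id[owner_fam])
  hap_no <- ifelse(((haps$hap - 1L) %% 2L) == 0L, 1L, 2L)

  tf <- sample.int(2L, n_families, replace = TRUE)
  tm <- sample.int(2L, n_families, replace = TRUE)
  from_father <- is_father & hap_no == tf[owner_fam]
  from_mother <- !is_father & hap_no == tm[owner_fam]
  child <- haps[from_father | from_mother, , drop = FALSE]
  child$sample_id <- ped$child_id[(child$hap + 3L) %/% 4L]
  child_hap <- ifelse(is_father[from_father | from_mother], 1L, 2L)

  parents <- haps
  parents$hap <- hap_no
  child$hap <- child_hap
  truth <- dplyr::bind_rows(parents, child)[
    c("sample_id", "hap", "locus", "allele")]
  list(truth = truth,
       pedigree = ped,
       transmitted = tibble::tibble(family_id = fam, father_hap = tf,
                                    mother_hap = tm))
}

#' Render a truth set as an observed-style typing table
#'
#' Converts per-haplotype truth into two-slot genotype calls for an assay
#' covering `loci`: ordinary loci get both haplotype alleles; a
#' copy-number-variable locus carried on one haplotype only gets one typed
#' slot and one not-typed slot, and on no haplotype two not-typed slots.
#' Typed slots are listed first.
#'
#' @param truth Truth tibble from the simulators.
#' @param loci Assay design (default: every locus occurring in `truth` plus
#'   the secondary DRB loci if DRB1 is present).
#' @param dataset Dataset label.
#' @return Typing tibble `sample_id, locus, allele1, allele2, dataset`.
#' @export
render_typing <- function(truth, loci = NULL, dataset = "simulated") {
  if (is.null(loci)) {
    loci <- unique(c(intersect(.locus_names(), unique(truth$locus)),
                     if ("DRB1" %in% truth$locus) drb345_loci()))
  }
  samples <- unique(truth$sample_id)
  grid <- tidyr::expand_grid(sample_id = samples, locus = loci)
  h1 <- truth[truth$hap == 1L, c("sample_id", "locus", "allele")]
  names(h1)[3] <- "h1"
  h2 <- truth[truth$hap == 2L, c("sample_id", "locus", "allele")]
  names(h2)[3] <- "h2"
  grid <- dplyr::left_join(grid, h1, by = c("sample_id", "locus"))
  grid <- dplyr::left_join(grid, h2, by = c("sample_id", "locus"))
  tibble::tibble(
    sample_id = grid$sample_id,
    locus = grid$locus,
    allele1 = dplyr::coalesce(grid$h1, grid$h2),
    allele2 = ifelse(!is.na(grid$h1) & !is.na(grid$h2), grid$h2, NA_character_),
    dataset = dataset
  )
}

#' Apply observation noise to a typing table
#'
#' Each typed allele call independently becomes not typed with
#' `dropout_rate`; otherwise is truncated to two fields with
#' `truncation_rate`; otherwise is replaced by a different allele from the
#' locus pool with `mistyping_rate`.  Every modification is logged, and
#' replaying the log on the input reproduces the output exactly
#' ([replay_events()]).
#'
#' @param typing Typing tibble (truth rendering).
#' @param cfg A [sim_config()] supplying the rates and pools.
#' @param seed Overrides `cfg$seed`.
#' @return List `observed` (typing tibble) and `events` (tibble `sample_id,
#'   locus, slot, event, truth_allele, observed_allele`).
#' @export
apply_noise <- function(typing, cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  obs <- typing
  events <- list()
  for (slot in 1:2) {
    col <- paste0("allele", slot)
    x <- obs[[col]]
    typed <- which(!is.na(x))
    if (length(typed) == 0) next
    u <- matrix(stats::runif(3 * length(typed)), ncol = 3)
    ev <- rep(NA_character_, length(typed))
    ev[u[, 1] < cfg$dropout_rate] <- "dropout"
    ev[is.na(ev) & u[, 2] < cfg$truncation_rate] <- "truncation"
    ev[is.na(ev) & u[, 3] < cfg$mistyping_rate] <- "mistyping"
    new <- x[typed]
    new[ev == "dropout" & !is.na(ev)] <- NA_character_
    tr <- which(ev == "truncation")
    if (length(tr) > 0) new[tr] <- truncate_allele(new[tr], 2)
    mi <- which(ev == "mistyping")
    for (i in mi) {
      locus <- obs$locus[typed[i]]
      pool <- cfg$pools[[locus]]$allele
      alt <- setdiff(pool, new[i])
      new[i] <- alt[sample.int(length(alt), 1L)]
    }
    changed <- which(!is.na(ev))
    if (length(changed) > 0) {
      events[[slot]] <- tibble::tibble(
        sample_id = obs$sample_id[typed[changed]],
        locus = obs$locus[typed[changed]],
        slot = slot,
        event = ev[changed],
        truth_allele = x[typed[changed]],
        observed_allele = new[changed]
      )
    }
    x[typed] <- new
    obs[[col]] <- x
  }
  empty_log <- tibble::tibble(
    sample_id = character(), locus = character(), slot = integer(),
    event = character(), truth_allele = character(),
    observed_allele = character())
  events <- events[!vapply(events, is.null, TRUE)]
  list(observed = obs,
       events = if (length(events) == 0) empty_log else
         dplyr::bind_rows(events))
}

#' Replay a noise event log on a truth typing table
#'
#' @param typing Truth typing tibble.
#' @param events Event log from [apply_noise()].
#' @return The typing tibble with every logged modification applied.
#' @export
replay_events <- function(typing, events) {
  out <- typing
  key <- paste(out$sample_id, out$locus)
  for (i in seq_len(nrow(events))) {
    row <- match(paste(events$sample_id[i], events$locus[i]), key)
    col <- paste0("allele", events$slot[i])
    out[[col]][row] <- events$observed_allele[i]
  }
  out
}

#' Simulate duplicate typings of the same samples under two assays
#'
#' One truth population rendered twice: once per dataset, each with its own
#' assay design (locus list) and noise rates.  Sample IDs are suffixed
#' `.a` / `.b` so the two typings can live in one table if needed.
#'
#' @param cfg A [sim_config()] (population and default rates).
#' @param noise_a,noise_b Named lists overriding `dropout_rate`,
#'   `truncation_rate`, `mistyping_rate` per dataset.
#' @param loci_a,loci_b Assay designs; defaults: a targeted-panel-like
#'   11-locus assay and the full registry.
#' @param labels Dataset labels (length 2).
#' @param n_samples Default `cfg$n_duplicates`.
#' @param seed Overrides `cfg$seed`.
#' @return List `typing_a, typing_b, pairs, truth, events_a, events_b`.
#' @export
simulate_duplicates <- function(cfg, noise_a = list(), noise_b = list(),
                                loci_a = panel_loci(), loci_b = NULL,
                                labels = c("panel", "exome"),
                                n_samples = cfg$n_duplicates,
                                seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  truth <- simulate_population(cfg, n_samples, seed = seed)
  if (is.null(loci_b)) loci_b <- unique(c(cfg$loci, drb345_loci()))
  cfg_a <- override_rates(cfg, noise_a)
  cfg_b <- override_rates(cfg, noise_b)
  seeds <- sample.int(.Machine$integer.max, 2)
  ta <- render_typing(truth, loci = intersect(loci_a, unique(c(cfg$loci, drb345_loci()))),
                      dataset = labels[1])
  tb <- render_typing(truth, loci = loci_b, dataset = labels[2])
  na <- apply_noise(ta, cfg_a, seed = seeds[1])
  nb <- apply_noise(tb, cfg_b, seed = seeds[2])
  ids <- unique(truth$sample_id)
  suffix <- function(ty, sfx) {
    ty$sample_id <- paste0(ty$sample_id, sfx)
    ty
  }
  list(
    typing_a = suffix(na$observed, ".a"),
    typing_b = suffix(nb$observed, ".b"),
    pairs = tibble::tibble(sample_a = paste0(ids, ".a"), dataset_a = labels[1],
                           sample_b = paste0(ids, ".b"), dataset_b = labels[2]),
    truth = truth,
    events_a = na$events,
    events_b = nb$events
  )
}

override_rates <- function(cfg, noise) {
  for (nm in names(noise)) {
    if (!nm %in% c("dropout_rate", "truncation_rate", "mistyping_rate")) {
      stop("unknown noise parameter: ", nm, call. = FALSE)
    }
    cfg[[nm]] <- noise[[nm]]
  }
  cfg
}
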