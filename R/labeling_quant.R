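# Spectral-count quantification of cysteine labeling.
#
# The labeling ratio of a cysteine in one replicate is the number of
# modified spectral counts over the total spectral counts of peptides
# containing that cysteine. Replicates are combined by a count-weighted
# mean: each replicate contributes in proportion to the total number of
# detected peptides it supplied. Three uncertainties are attached:
#   weighted_se       — weighted dispersion of replicate ratios about the mean
#   measurement_error — shot-noise of the pooled count, sqrt(N)/N = 1/sqrt(N)
#   total_error       — the two combined in quadrature (default)

#' Ambiguity policy for multi-cysteine peptides
#'
#' Peptides containing several cysteines may carry a modification whose site
#' assignment is not confident (`localized = FALSE`). Under
#' `"localized_only"` (default) such PSMs are excluded from every site they
#' cover and tracked in `ambiguous_fraction`; under `"fractional"` an
#' unlocalized modification on a k-cysteine peptide contributes 1/k modified
#' count to each contained site (total count 1 to each, as usual). The two
#' policies agree exactly when every PSM is localized.
#'
#' @param mode `"localized_only"` or `"fractional"`.
#' @return The validated mode string, classed `ambiguity_policy`.
#' @export
ambiguity_policy <- function(mode = c("localized_only", "fractional")) {
  mode <- match.arg(mode)
  structure(mode, class = "ambiguity_policy")
}

#' Tally spectral counts per cysteine site
#'
#' Converts PSMs into per-(site, condition, replicate) spectral counts.
#' `sc_total` counts every retained PSM whose peptide contains the site;
#' `sc_mod` counts those where the site carries the modification (possibly
#' fractionally, under the `"fractional"` policy). `n_ambiguous` counts the
#' multi-cysteine, unlocalized PSMs covering the site (excluded under
#' `"localized_only"`, included fractionally otherwise).
#'
#' @param psms A [psm_table()].
#' @param protein The [protein_record()] the PSMs derive from; every peptide
#'   must map uniquely into it.
#' @param policy An [ambiguity_policy()].
#' @return A tibble with columns `protein_id`, `residue_index`, `condition`,
#'   `replicate`, `sc_mod`, `sc_total`, `n_ambiguous`.
#' @export
tally_site_counts <- function(psms, protein,
                              policy = ambiguity_policy("localized_only")) {
  stopifnot(inherits(psms, "psm_table"), inherits(protein, "protein_record"))
  if (!inherits(policy, "ambiguity_policy")) policy <- ambiguity_policy(policy)
  psms <- psms[psms$protein_id == protein$id, , drop = FALSE]
  if (nrow(psms) == 0L) {
    return(tibble::tibble(
      protein_id = character(), residue_index = integer(),
      condition = character(), replicate = character(),
      sc_mod = double(), sc_total = double(), n_ambiguous = integer()
    ))
  }

  # map each distinct peptide once
  peps <- unique(psms$peptide)
  pep_map <- lapply(peps, function(p) {
    m <- map_peptide_to_protein(p, protein)
    sites <- cys_sites_in_peptide(m, protein)
    list(start = m$start, sites = sites, k = length(sites))
  })
  names(pep_map) <- peps

  start_of <- vapply(pep_map, `[[`, integer(1), "start")
  k_of <- vapply(pep_map, `[[`, integer(1), "k")

  rows <- tibble::tibble(
    row_id = seq_len(nrow(psms)),
    condition = psms$condition,
    replicate = psms$replicate,
    peptide = psms$peptide,
    start = start_of[psms$peptide],
    k_cys = k_of[psms$peptide],
    localized = psms$localized,
    mod_offsets = psms$mod_offsets
  )
  rows$is_mod <- nzchar(rows$mod_offsets)
  rows$ambiguous <- rows$k_cys > 1L & !rows$localized
  multi <- grepl(";", rows$mod_offsets, fixed = TRUE)
  rows$n_mods <- as.integer(rows$is_mod)
  rows$n_mods[multi] <- vapply(
    strsplit(rows$mod_offsets[multi], ";", fixed = TRUE),
    function(v) sum(nzchar(v)), integer(1)
  )
  # absolute protein position of a single localized modification (the
  # overwhelmingly common case); multi-modification rows handled per row
  rows$abs_single <- rep(NA_integer_, nrow(rows))
  single <- rows$is_mod & !multi
  rows$abs_single[single] <- rows$start[single] +
    as.integer(rows$mod_offsets[single]) - 1L
  rows$is_multi <- multi

  # (row, site) coverage expansion
  site_tbl <- tibble::tibble(
    peptide = rep(peps, k_of),
    residue_index = unlist(lapply(pep_map, `[[`, "sites"), use.names = FALSE)
  )
  cov <- dplyr::inner_join(rows, site_tbl, by = "peptide",
                           relationship = "many-to-many")

  excluded <- policy == "localized_only" & cov$ambiguous
  cov$w_total <- as.numeric(!excluded)
  # modified contribution per covered site
  cov$w_mod <- 0
  frac <- policy == "fractional" & cov$ambiguous & cov$is_mod
  cov$w_mod[frac] <- cov$n_mods[frac] / cov$k_cys[frac]
  # confidently localized modifications: match absolute position to site
  loc1 <- cov$is_mod & !cov$ambiguous & !cov$is_multi
  cov$w_mod[loc1 & cov$abs_single == cov$residue_index] <- 1
  locm <- which(cov$is_mod & !cov$ambiguous & cov$is_multi)
  if (length(locm) > 0L) {
    hit <- vapply(locm, function(i) {
      offs <- as.integer(strsplit(cov$mod_offsets[i], ";", fixed = TRUE)[[1]])
      cov$residue_index[i] %in% (cov$start[i] + offs - 1L)
    }, logical(1))
    cov$w_mod[locm[hit]] <- 1
  }

  cov |>
    dplyr::group_by(.data$condition, .data$replicate, .data$residue_index) |>
    dplyr::summarise(
      sc_mod = sum(.data$w_mod),
      sc_total = sum(.data$w_total),
      n_ambiguous = sum(.data$ambiguous),
      .groups = "drop"
    ) |>
    dplyr::mutate(protein_id = protein$id, .before = 1L) |>
    dplyr::arrange(.data$residue_index, .data$condition, .data$replicate)
}

#' Labeling ratio from spectral counts
#'
#' @param sc_mod Modified spectral counts (vectorized).
#' @param sc_total Total spectral counts; must be positive where an estimate
#'   is requested.
#' @return `sc_mod / sc_total`, a fraction in `[0, 1]`.
#' @export
labeling_ratio <- function(sc_mod, sc_total) {
  if (any(sc_total <= 0)) {
    stop("site not detected: sc_total must be > 0", call. = FALSE)
  }
  if (any(sc_mod < 0) || any(sc_mod > sc_total)) {
    stop("sc_mod must lie in [0, sc_total]", call. = FALSE)
  }
  sc_mod / sc_total
}

# weighted-mean + error model shared by aggregate_replicates() and
# quantify_sites(); inputs are per-replicate counts for one site+condition
weighted_site_stats <- function(sc_mod, sc_total, total_error_mode) {
  keep <- sc_total > 0
  sc_mod <- sc_mod[keep]
  sc_total <- sc_total[keep]
  m <- length(sc_total)
  if (m == 0L) {
    stop("site not detected: no replicate with positive spectral counts",
         call. = FALSE)
  }
  n_pool <- sum(sc_total)
  w <- sc_total / n_pool
  r <- sc_mod / sc_total
  rbar <- sum(w * r)
  se <- if (m > 1L) sqrt(sum(w * (r - rbar)^2) / (m - 1L)) else 0
  me <- sqrt(n_pool) / n_pool
  te <- switch(total_error_mode,
    quadrature = sqrt(se^2 + me^2),
    rms = sqrt((se^2 + me^2) / 2)
  )
  list(ratio = rbar, weighted_se = se, measurement_error = me,
       total_error = te, n_total = n_pool, n_replicates = m)
}

#' Aggregate replicate counts into a site estimate
#'
#' Combines per-replicate spectral counts for one site and condition into a
#' single labeling-ratio estimate. Replicate i enters the mean with weight
#' `n_i / sum(n_i)` where `n_i` is its total spectral count, so the weighted
#' mean equals the pooled ratio `sum(sc_mod) / sum(sc_total)` exactly. The
#' weighted standard error is `sqrt(sum(w_i (r_i - rbar)^2) / (m - 1))` over
#' the `m` replicates with data (0 when `m = 1`); the measurement error is
#' the shot-noise term `sqrt(N)/N` of the pooled count `N`; the total error
#' combines the two in quadrature by default (`"rms"` divides the sum of
#' squares by 2 before the square root).
#'
#' @param counts Tibble of per-replicate counts for a single site and
#'   condition, with columns `sc_mod`, `sc_total` (and optionally the id
#'   columns produced by [tally_site_counts()], which are carried through).
#' @param total_error_mode `"quadrature"` (default) or `"rms"`.
#' @return One-row tibble with `ratio`, `weighted_se`, `measurement_error`,
#'   `total_error`, `n_total`, `n_replicates` (plus any id columns present).
#' @export
aggregate_replicates <- function(counts,
                                 total_error_mode = c("quadrature", "rms")) {
  total_error_mode <- match.arg(total_error_mode)
  stopifnot(all(c("sc_mod", "sc_total") %in% names(counts)))
  for (idcol in c("protein_id", "residue_index", "condition")) {
    if (idcol %in% names(counts) && length(unique(counts[[idcol]])) > 1L) {
      stop("aggregate_replicates expects counts for a single ", idcol,
           call. = FALSE)
    }
  }
  st <- weighted_site_stats(counts$sc_mod, counts$sc_total, total_error_mode)
  ids <- counts[1, intersect(c("protein_id", "residue_index", "condition"),
                             names(counts)), drop = FALSE]
  amb <- if ("n_ambiguous" %in% names(counts)) {
    sum(counts$n_ambiguous) /
      max(sum(counts$n_ambiguous) + sum(counts$sc_total), 1)
  } else NA_real_
  dplyr::bind_cols(
    tibble::as_tibble(ids),
    tibble::tibble(
      ratio = st$ratio,
      weighted_se = st$weighted_se,
      measurement_error = st$measurement_error,
      total_error = st$total_error,
      n_total = st$n_total,
      n_replicates = st$n_replicates,
      ambiguous_fraction = amb
    )
  )
}

#' Per-site labeling estimates for a whole experiment
#'
#' Tallies spectral counts and aggregates replicates for every cysteine and
#' condition in one call. Sites with no retained spectral counts in a
#' condition are simply absent from the output (they are not estimable).
#'
#' @param psms A [psm_table()].
#' @param protein A [protein_record()].
#' @param policy An [ambiguity_policy()] (or its mode string).
#' @param total_error_mode Passed to the error model; see
#'   [aggregate_replicates()].
#' @return Tibble with one row per (site, condition): `protein_id`,
#'   `residue_index`, `condition`, `ratio`, `weighted_se`,
#'   `measurement_error`, `total_error`, `n_total`, `n_replicates`,
#'   `ambiguous_fraction`.
#' @examples
#' prot <- protein_record("p1", "MKAAACAAAR")
#' psms <- psm_table(data.frame(
#'   condition = "apo", replicate = c(1, 1, 2),
#'   protein_id = "p1", peptide = "AAACAAAR",
#'   mod_offsets = c("4", "", "4")
#' ))
#' quantify_sites(psms, prot)
#' @export
quantify_sites <- function(psms, protein,
                           policy = ambiguity_policy("localized_only"),
                           total_error_mode = c("quadrature", "rms")) {
  total_error_mode <- match.arg(total_error_mode)
  counts <- tally_site_counts(psms, protein, policy)
  if (nrow(counts) == 0L) {
    stop("no site detected: PSM table contributed no cysteine coverage",
         call. = FALSE)
  }
  counts |>
    dplyr::filter(.data$sc_total > 0 | .data$n_ambiguous > 0) |>
    dplyr::group_by(.data$protein_id, .data$residue_index, .data$condition) |>
    dplyr::group_modify(function(g, key) {
      if (all(g$sc_total == 0)) return(tibble::tibble())  # only ambiguous PSMs
      aggregate_replicates(g, total_error_mode = total_error_mode)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$residue_index, .data$condition)
}

#' Extract per-replicate labeling ratios
#'
#' Convenience accessor used by the differential test, which operates on one
#' ratio per replicate rather than on pooled counts.
#'
#' @param counts Output of [tally_site_counts()].
#' @return Tibble `protein_id`, `residue_index`, `condition`, `replicate`,
#'   `ratio`, `sc_total`, restricted to replicates with positive counts.
#' @export
replicate_ratios <- function(counts) {
  counts |>
    dplyr::filter(.data$sc_total > 0) |>
    dplyr::mutate(ratio = .data$sc_mod / .data$sc_total) |>
    dplyr::select(dplyr::any_of(c("protein_id", "residue_index", "condition",
                                  "replicate", "ratio", "sc_total")))
}
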