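# Synthetic PSM tables and toy structures with known ground truth. The
# generator emulates the statistical structure of a spectral-counting
# labeling experiment: per replicate and site, total counts are Poisson
# (acquisition depth varies between runs) and modified counts are binomial
# with the site's true labeling probability. No public MS data accompany
# the original experiments, so simulation with known truth is how the
# quantification pipeline is validated.

#' Cysteine layout of murine alpha-E-catenin
#'
#' The twelve native cysteine positions of murine alpha-E-catenin
#' (1-based residue numbers), the reference site set for the labeling
#' analysis.
#'
#' @return Integer vector of length 12.
#' @export
alpha_catenin_cys_sites <- function() {
  c(116L, 228L, 324L, 337L, 438L, 461L, 526L, 720L, 767L, 772L, 787L, 793L)
}

#' Generate a toy protein with cysteines at chosen positions
#'
#' Draws a random sequence from the 19 non-cysteine residues, places C at
#' the requested positions, and then inserts K/R cleavage anchors around
#' each cysteine so that every site falls inside at least one tryptic
#' peptide within the digest length window. The construction is verified by
#' digestion; an unsatisfiable layout is an error.
#'
#' @param length Protein length (default 900, comfortably containing the
#'   alpha-E-catenin site layout).
#' @param cys_positions 1-based cysteine positions (default the
#'   [alpha_catenin_cys_sites()] layout); must be unique and within range.
#' @param seed Integer seed; the same seed gives an identical protein.
#' @param params [digest_params()] used for the coverage check.
#' @return A [protein_record()] with id `"toyprot"`.
#' @export
make_toy_protein <- function(length = 900L,
                             cys_positions = alpha_catenin_cys_sites(),
                             seed = 1L,
                             params = digest_params()) {
  length <- as.integer(length)
  cys_positions <- as.integer(cys_positions)
  stopifnot(length >= 1L)
  if (anyDuplicated(cys_positions)) {
    stop("cys_positions must be unique", call. = FALSE)
  }
  if (any(cys_positions < 1L | cys_positions > length)) {
    stop("cys_positions out of range 1..", length, call. = FALSE)
  }
  non_cys <- setdiff(AA_STANDARD, "C")
  chars <- with_preserved_seed(seed, {
    sample(non_cys, length, replace = TRUE)
  })
  chars[cys_positions] <- "C"

  place_anchor <- function(chars, candidates, letter) {
    candidates <- candidates[candidates >= 1L & candidates <= length]
    candidates <- candidates[!(candidates %in% cys_positions)]
    for (pos in candidates) {
      chars[pos] <- letter
      nxt <- pos + 1L
      if (nxt <= length && chars[nxt] == "P" && !(nxt %in% cys_positions)) {
        chars[nxt] <- "A"
      }
      return(chars)
    }
    chars
  }
  for (cp in cys_positions) {
    chars <- place_anchor(chars, (cp - 5L):(cp - 12L), "K")
    chars <- place_anchor(chars, (cp + 5L):(cp + 12L), "R")
  }

  prot <- protein_record("toyprot", paste(chars, collapse = ""))
  dig <- tryptic_digest(prot, params)
  covered <- unique(unlist(lapply(seq_len(nrow(dig)), function(i) {
    cys_sites_in_peptide(dig[i, ], prot)
  })))
  missing_sites <- setdiff(cys_positions, covered)
  if (length(missing_sites) > 0L) {
    stop("unsatisfiable placement: cysteine(s) ",
         paste(missing_sites, collapse = ", "),
         " fall in no digest peptide within the length window",
         call. = FALSE)
  }
  prot
}

#' Simulation design for a synthetic labeling experiment
#'
#' Defaults mirror a realistic spectral-counting experiment on the
#' alpha-E-catenin site layout: a handful of technical replicates per
#' condition, a per-site acquisition depth of a couple hundred spectral
#' counts, and an occasional failure to localize a modification on a
#' multi-cysteine peptide.
#'
#' @param protein A [protein_record()]; default [make_toy_protein()].
#' @param site_probs Per-condition true labeling probabilities: a named list
#'   mapping condition label to either a single probability (applied to all
#'   sites) or a numeric vector named by residue index.
#' @param replicates Replicates per condition (default 4).
#' @param mean_depth Expected spectral counts per site per replicate
#'   (Poisson mean; default 200).
#' @param localization_failure_rate Probability that a modified PSM on a
#'   multi-cysteine peptide is emitted with `localized = FALSE`
#'   (default 0.1).
#' @param replicate_sd Standard deviation of an optional per-replicate
#'   logit-normal perturbation of the site probabilities (default 0 = off);
#'   use to exercise between-replicate heterogeneity.
#' @param seed Integer seed.
#' @return List of class `simulation_design`.
#' @export
simulation_design <- function(protein = make_toy_protein(),
                              site_probs = list(apo = 0.4),
                              replicates = 4L,
                              mean_depth = 200,
                              localization_failure_rate = 0.1,
                              replicate_sd = 0,
                              seed = 1L) {
  stopifnot(inherits(protein, "protein_record"),
            is.list(site_probs), length(site_probs) >= 1L,
            !is.null(names(site_probs)), all(nzchar(names(site_probs))),
            replicates >= 1L, mean_depth > 0,
            localization_failure_rate >= 0, localization_failure_rate <= 1,
            replicate_sd >= 0)
  sites <- protein$cys_positions
  site_probs <- lapply(site_probs, function(p) {
    if (length(p) == 1L && is.null(names(p))) {
      p <- stats::setNames(rep(p, length(sites)), sites)
    } else {
      stopifnot(!is.null(names(p)), all(as.character(sites) %in% names(p)))
      p <- p[as.character(sites)]
    }
    stopifnot(all(p >= 0 & p <= 1))
    p
  })
  structure(
    list(protein = protein, site_probs = site_probs,
         replicates = as.integer(replicates), mean_depth = mean_depth,
         localization_failure_rate = localization_failure_rate,
         replicate_sd = replicate_sd, seed = as.integer(seed)),
    class = "simulation_design"
  )
}

# shortest digest peptide containing each site; ties broken by leftmost start
site_carrier_peptides <- function(protein, params = digest_params()) {
  dig <- tryptic_digest(protein, params)
  carriers <- lapply(protein$cys_positions, function(s) {
    cand <- dig[dig$start <= s & dig$end >= s, , drop = FALSE]
    if (nrow(cand) == 0L) return(NULL)
    cand <- cand[order(cand$end - cand$start, cand$start), , drop = FALSE]
    cand[1, , drop = FALSE]
  })
  names(carriers) <- protein$cys_positions
  carriers
}

#' Simulate a PSM table with known ground truth
#'
#' Each cysteine is assigned a carrier peptide, the shortest digest peptide
#' containing it (ties broken leftmost); nearby cysteines may share one
#' carrier, as happens in real digests. For every condition, replicate, and
#' distinct carrier peptide, the total spectral count is drawn from
#' Poisson(`mean_depth`) — acquisition depth varies between runs — and each
#' contained cysteine of each PSM is modified independently with its site's
#' true labeling probability, so the per-site modified count is
#' Binomial(total, p_site). Modified PSMs on multi-cysteine peptides are
#' flagged unlocalized with the design's failure rate. Fully seeded: the
#' same design yields an identical table.
#'
#' @param design A [simulation_design()].
#' @return A [psm_table()] with the true per-condition site probabilities
#'   attached as a tibble in the `"truth"` attribute (`condition`,
#'   `residue_index`, `p`).
#' @export
simulate_psm_table <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  protein <- design$protein
  carriers <- site_carrier_peptides(protein)
  sites <- protein$cys_positions
  usable <- !vapply(carriers, is.null, logical(1))
  if (!all(usable)) {
    stop("site(s) ", paste(sites[!usable], collapse = ", "),
         " have no carrier peptide in the digest window", call. = FALSE)
  }
  # distinct carrier peptides with the sites they report on
  carrier_tbl <- unique(dplyr::bind_rows(carriers))
  carrier_sites <- lapply(seq_len(nrow(carrier_tbl)), function(i) {
    cys_sites_in_peptide(carrier_tbl[i, ], protein)
  })

  out <- with_preserved_seed(design$seed, {
    blocks <- list()
    for (cond in names(design$site_probs)) {
      probs <- design$site_probs[[cond]]
      for (rep_i in seq_len(design$replicates)) {
        for (ci in seq_len(nrow(carrier_tbl))) {
          contained <- carrier_sites[[ci]]
          k <- length(contained)
          p_sites <- unname(probs[as.character(contained)])
          if (design$replicate_sd > 0) {
            in01 <- p_sites > 0 & p_sites < 1
            p_sites[in01] <- stats::plogis(
              stats::qlogis(p_sites[in01]) +
                stats::rnorm(sum(in01), 0, design$replicate_sd)
            )
          }
          n <- stats::rpois(1, design$mean_depth)
          if (n == 0L) next
          offsets <- contained - carrier_tbl$start[ci] + 1L
          mods <- matrix(
            stats::rbinom(n * k, 1L, rep(p_sites, each = n)) == 1L,
            nrow = n, ncol = k
          )
          mod_str <- if (k == 1L) {
            ifelse(mods[, 1], as.character(offsets), "")
          } else {
            apply(mods, 1L, function(m) paste(offsets[m], collapse = ";"))
          }
          localized <- rep(TRUE, n)
          any_mod <- rowSums(mods) > 0L
          if (k > 1L && design$localization_failure_rate > 0 &&
              any(any_mod)) {
            localized[any_mod] <-
              stats::runif(sum(any_mod)) >= design$localization_failure_rate
          }
          blocks[[length(blocks) + 1L]] <- tibble::tibble(
            condition = cond,
            replicate = as.character(rep_i),
            protein_id = protein$id,
            peptide = carrier_tbl$peptide[ci],
            mod_offsets = mod_str,
            localized = localized
          )
        }
      }
    }
    dplyr::bind_rows(blocks)
  })
  tbl <- psm_table(out, provenance = paste0("simulated (seed ", design$seed, ")"))
  truth <- dplyr::bind_rows(lapply(names(design$site_probs), function(cond) {
    tibble::tibble(
      condition = cond,
      residue_index = sites,
      p = unname(design$site_probs[[cond]][as.character(sites)])
    )
  }))
  attr(tbl, "truth") <- truth
  tbl
}

#' Toy sphere fixtures for SASA testing
#'
#' Small synthetic structures with known accessibility: a single isolated
#' atom, a pair of atoms at a stated centre-to-centre distance, or a
#' central atom fully buried inside a cage of neighbours.
#'
#' @param geometry `"isolated"`, `"pair"`, or `"cage"`.
#' @param distance Centre-to-centre separation for `"pair"`, Angstrom.
#' @param element Element symbol for all atoms (default `"C"`).
#' @param cage_size Number of cage atoms (default 26).
#' @return A [structure_model()] of carbon-like spheres; atoms are labelled
#'   as glycine residues purely for format validity.
#' @export
make_sphere_fixture <- function(geometry = c("isolated", "pair", "cage"),
                                distance = 2.0, element = "C",
                                cage_size = 26L) {
  geometry <- match.arg(geometry)
  coords <- switch(geometry,
    isolated = matrix(0, nrow = 1, ncol = 3),
    pair = rbind(c(0, 0, 0), c(distance, 0, 0)),
    cage = rbind(c(0, 0, 0), sphere_points(cage_size) * distance)
  )
  n <- nrow(coords)
  structure_model(tibble::tibble(
    serial = seq_len(n),
    name = "CA",
    residue_name = "GLY",
    chain = "A",
    residue_number = seq_len(n),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    element = element
  ))
}
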