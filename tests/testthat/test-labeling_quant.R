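# protein: ...K CCAAR ... with a single-Cys peptide and a two-Cys peptide
quant_protein <- protein_record("q1", "MKCAAARCCAAKAAAR")
# peptides (0 missed): MK(1-2) CAAAR(3-7) CCAAK(8-12) AAAR(13-16)

psm_rows <- function(n, peptide, offsets, condition = "A", replicate = "1",
                     localized = TRUE) {
  tibble::tibble(
    condition = condition, replicate = replicate, protein_id = "q1",
    peptide = peptide, mod_offsets = offsets,
    localized = localized
  )[rep(1, n), ]
}

test_that("site tallies count covering and modified PSMs per the policy", {
  # 10 PSMs of a single-Cys peptide, 3 modified
  tbl <- psm_table(dplyr::bind_rows(
    psm_rows(3, "CAAAR", "1"),
    psm_rows(7, "CAAAR", "")
  ))
  cnt <- tally_site_counts(tbl, quant_protein)
  expect_equal(cnt$residue_index, 3L)
  expect_equal(cnt$sc_mod, 3)
  expect_equal(cnt$sc_total, 10)

  # two-Cys peptide, localized mod on the first: first site gains the mod,
  # both sites gain a total count
  tbl2 <- psm_table(psm_rows(1, "CCAAK", "1"))
  cnt2 <- tally_site_counts(tbl2, quant_protein)
  expect_equal(cnt2$residue_index, c(8L, 9L))
  expect_equal(cnt2$sc_mod, c(1, 0))
  expect_equal(cnt2$sc_total, c(1, 1))

  # unlocalized mod on a 2-Cys peptide: fractional mode gives each site half
  tbl3 <- psm_table(psm_rows(1, "CCAAK", "1", localized = FALSE))
  cnt3 <- tally_site_counts(tbl3, quant_protein, ambiguity_policy("fractional"))
  expect_equal(cnt3$sc_mod, c(0.5, 0.5))
  expect_equal(cnt3$sc_total, c(1, 1))

  # localized_only mode excludes the PSM entirely and tracks it as ambiguous
  cnt4 <- tally_site_counts(tbl3, quant_protein)
  expect_equal(cnt4$sc_total, c(0, 0))
  expect_equal(cnt4$n_ambiguous, c(1L, 1L))
})

test_that("ambiguity policies agree exactly when every PSM is localized", {
  prot <- make_toy_protein(seed = 3)
  des <- simulation_design(prot, site_probs = list(A = 0.3),
                           replicates = 2, mean_depth = 40,
                           localization_failure_rate = 0, seed = 5)
  psms <- simulate_psm_table(des)
  a <- tally_site_counts(psms, prot, ambiguity_policy("localized_only"))
  b <- tally_site_counts(psms, prot, ambiguity_policy("fractional"))
  expect_equal(a, b)
})

test_that("labeling ratio is the modified fraction with guarded domain", {
  expect_equal(labeling_ratio(0, 10), 0)
  expect_equal(labeling_ratio(10, 10), 1)
  expect_equal(labeling_ratio(3, 12), 0.25)
  expect_error(labeling_ratio(0, 0), "not detected")
  expect_error(labeling_ratio(5, 4), "sc_mod")
})

test_that("replicate aggregation implements the count-weighted error model", {
  # single replicate: no dispersion, only shot noise
  one <- aggregate_replicates(tibble::tibble(sc_mod = 5, sc_total = 10))
  expect_equal(one$ratio, 0.5)
  expect_equal(one$weighted_se, 0)
  expect_equal(one$measurement_error, sqrt(10) / 10)
  expect_equal(one$total_error, sqrt(0 + 1 / 10))
  expect_equal(one$n_replicates, 1L)

  # symmetric counts: plain mean
  sym <- aggregate_replicates(tibble::tibble(sc_mod = c(2, 8),
                                             sc_total = c(10, 10)))
  expect_equal(sym$ratio, 0.5)

  # asymmetric counts: weighted toward the deeper replicate,
  # (0.2*30 + 0.8*10)/40 = 0.35
  asym <- aggregate_replicates(tibble::tibble(sc_mod = c(6, 8),
                                              sc_total = c(30, 10)))
  expect_equal(asym$ratio, 0.35)
  expect_equal(asym$n_total, 40)
  expect_equal(asym$measurement_error, 1 / sqrt(40))
  # weighted SE by direct formula
  w <- c(30, 10) / 40
  r <- c(0.2, 0.8)
  se <- sqrt(sum(w * (r - 0.35)^2) / 1)
  expect_equal(asym$weighted_se, se)
  expect_equal(asym$total_error, sqrt(se^2 + 1 / 40))

  # rms variant halves the sum of squares
  rms <- aggregate_replicates(tibble::tibble(sc_mod = c(6, 8),
                                             sc_total = c(30, 10)),
                              total_error_mode = "rms")
  expect_equal(rms$total_error, sqrt((se^2 + 1 / 40) / 2))

  expect_error(aggregate_replicates(tibble::tibble(sc_mod = 0, sc_total = 0)),
               "not detected")
})

test_that("aggregate ratio is bounded by the replicate ratios and N shrinks error", {
  set.seed(77)
  for (i in 1:25) {
    m <- sample(2:6, 1)
    n <- sample(5:50, m, replace = TRUE)
    k <- rbinom(m, n, runif(1))
    est <- aggregate_replicates(tibble::tibble(sc_mod = k, sc_total = n))
    r <- k / n
    expect_gte(est$ratio, min(r))
    expect_lte(est$ratio, max(r))
    expect_equal(est$measurement_error, 1 / sqrt(sum(n)))
  }
  # measurement error equals 1 at N = 1 and decreases with N
  expect_equal(aggregate_replicates(
    tibble::tibble(sc_mod = 1, sc_total = 1))$measurement_error, 1)
})

test_that("quantify_sites produces one estimate per detected site and condition", {
  tbl <- psm_table(dplyr::bind_rows(
    psm_rows(4, "CAAAR", "1", condition = "A", replicate = "1"),
    psm_rows(6, "CAAAR", "", condition = "A", replicate = "1"),
    psm_rows(5, "CAAAR", "1", condition = "A", replicate = "2"),
    psm_rows(5, "CAAAR", "", condition = "A", replicate = "2"),
    psm_rows(2, "CAAAR", "1", condition = "B", replicate = "1")
  ))
  est <- quantify_sites(tbl, quant_protein)
  expect_equal(nrow(est), 2)
  a <- est[est$condition == "A", ]
  expect_equal(a$ratio, 9 / 20)
  expect_equal(a$n_replicates, 2L)
  b <- est[est$condition == "B", ]
  expect_equal(b$ratio, 1)
  expect_equal(b$n_total, 2)
})
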