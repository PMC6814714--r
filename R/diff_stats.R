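# Differential labeling between two conditions: per-site Welch's t-test on
# replicate-level ratios, significance stars at p <= 0.05 / 0.01 / 0.001,
# and optional Benjamini-Hochberg adjustment.

#' Welch's two-sample t-test on replicate ratios
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom and a
#' two-sided p-value, delegating to [stats::t.test()]. The statistic is
#' `(mean(a) - mean(b)) / sqrt(var(a)/n_a + var(b)/n_b)`. Degenerate inputs
#' with zero variance on both sides are handled explicitly: equal means give
#' `t = 0, p = 1`; unequal means give `t = +/-Inf, p = 0`.
#'
#' @param a,b Numeric vectors of replicate-level labeling ratios, each with
#'   at least 2 values.
#' @return A list with elements `t`, `df`, `p`.
#' @export
welch_test <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("insufficient replicates: Welch's test needs >= 2 values per side",
         call. = FALSE)
  }
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0))
  }
  fit <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = unname(fit$p.value))
}

#' Significance stars for a p-value
#'
#' Inclusive thresholds: three stars for p <= 0.001, two for p <= 0.01, one
#' for p <= 0.05, zero otherwise.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` passes through).
#' @return Integer vector of star counts, 0-3.
#' @export
star_level <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  out <- ifelse(p <= 0.001, 3L, ifelse(p <= 0.01, 2L, ifelse(p <= 0.05, 1L, 0L)))
  as.integer(out)
}

#' Differential labeling between two conditions
#'
#' Pairs per-site estimates from two conditions and tests each shared site
#' with Welch's t-test on the replicate-level ratios. Sites present in only
#' one condition cannot be tested and are returned in the `"unshared"`
#' attribute as presence/absence rows.
#'
#' @param estimates_a,estimates_b Per-site estimates for each condition, as
#'   from [quantify_sites()] (each restricted to a single condition).
#' @param ratios_a,ratios_b Replicate-level ratios for each condition, as
#'   from [replicate_ratios()].
#' @param bh If `TRUE`, add Benjamini-Hochberg adjusted p-values (`q_value`).
#'   Off by default: per-site stars are conventionally reported unadjusted.
#' @return Tibble with one row per shared site: `residue_index`,
#'   `condition_a`, `condition_b`, `ratio_a`, `ratio_b`, `delta`
#'   (`ratio_b - ratio_a`), `t_stat`, `df`, `p_value`, `stars`, and
#'   `q_value` when `bh = TRUE`. Sites with fewer than 2 replicates on
#'   either side keep `NA` statistics. Attribute `"unshared"` holds the
#'   single-condition sites.
#' @export
compare_conditions <- function(estimates_a, estimates_b,
                               ratios_a, ratios_b, bh = FALSE) {
  stopifnot(length(unique(estimates_a$condition)) == 1L,
            length(unique(estimates_b$condition)) == 1L)
  cond_a <- estimates_a$condition[1]
  cond_b <- estimates_b$condition[1]
  shared <- intersect(estimates_a$residue_index, estimates_b$residue_index)
  if (length(shared) == 0L) {
    stop("no shared sites between conditions '", cond_a, "' and '", cond_b,
         "'", call. = FALSE)
  }
  unshared <- dplyr::bind_rows(
    estimates_a[!estimates_a$residue_index %in% shared, , drop = FALSE],
    estimates_b[!estimates_b$residue_index %in% shared, , drop = FALSE]
  )

  res <- lapply(sort(shared), function(site) {
    ra <- ratios_a$ratio[ratios_a$residue_index == site]
    rb <- ratios_b$ratio[ratios_b$residue_index == site]
    w <- if (length(ra) >= 2L && length(rb) >= 2L) {
      welch_test(ra, rb)
    } else {
      list(t = NA_real_, df = NA_real_, p = NA_real_)
    }
    tibble::tibble(
      residue_index = site,
      condition_a = cond_a,
      condition_b = cond_b,
      ratio_a = estimates_a$ratio[estimates_a$residue_index == site],
      ratio_b = estimates_b$ratio[estimates_b$residue_index == site],
      t_stat = w$t, df = w$df, p_value = w$p
    )
  })
  out <- dplyr::bind_rows(res) |>
    dplyr::mutate(
      delta = .data$ratio_b - .data$ratio_a,
      stars = star_level(.data$p_value),
      .after = "ratio_b"
    )
  if (isTRUE(bh)) {
    out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  }
  attr(out, "unshared") <- unshared
  out
}
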