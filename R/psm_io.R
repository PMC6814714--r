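# Peptide-spectrum-match tables. One row is one PSM, i.e. one spectral count;
# quantification downstream is purely count-based, so no intensity columns
# are interpreted. The TSV dialect mirrors a search-engine export reduced to
# what the labeling analysis needs.

PSM_REQUIRED_COLS <- c("condition", "replicate", "protein_id", "peptide",
                       "mod_offsets")

#' Build a PSM table from a data frame
#'
#' Validates the columns and modification offsets of a table of
#' peptide-spectrum matches carrying cysteine-probe (mBBr) localization.
#' `mod_offsets` holds 1-based, peptide-relative positions of modified
#' cysteines as a semicolon-separated string (empty string = unmodified PSM).
#'
#' @param df Data frame with columns `condition`, `replicate`, `protein_id`,
#'   `peptide`, `mod_offsets`, and optionally `localized` (0/1 or logical,
#'   default `TRUE`) and `fdr` (fraction in `[0,1]`, `NA` allowed). Extra
#'   columns (charge, scan number, ...) are carried through untouched.
#' @param provenance Free-text metadata stored as an attribute.
#' @return A tibble of class `psm_table`.
#' @export
psm_table <- function(df, provenance = "") {
  missing_cols <- setdiff(PSM_REQUIRED_COLS, names(df))
  if (length(missing_cols) > 0L) {
    stop("PSM table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  df$condition <- as.character(df$condition)
  df$replicate <- as.character(df$replicate)
  df$protein_id <- as.character(df$protein_id)
  df$peptide <- toupper(as.character(df$peptide))
  df$mod_offsets <- as.character(df$mod_offsets)
  df$mod_offsets[is.na(df$mod_offsets)] <- ""
  if (!"localized" %in% names(df)) {
    df$localized <- TRUE
  } else if (!is.logical(df$localized)) {
    df$localized <- as.integer(df$localized) != 0L
  }
  if (!"fdr" %in% names(df)) df$fdr <- NA_real_
  if (any(!nzchar(df$condition)) || any(!nzchar(df$replicate))) {
    stop("every PSM needs non-empty condition and replicate labels",
         call. = FALSE)
  }
  bad_fdr <- !is.na(df$fdr) & (df$fdr < 0 | df$fdr > 1)
  if (any(bad_fdr)) {
    stop("fdr out of [0,1] on row(s): ",
         paste(utils::head(which(bad_fdr), 5L), collapse = ", "),
         call. = FALSE)
  }
  # validate offsets; the common single-offset case is vectorized
  check_offsets <- function(i, o) {
    if (anyNA(o) || any(o < 1L) || any(o > nchar(df$peptide[i]))) {
      stop("row ", i, ": mod_offsets '", df$mod_offsets[i],
           "' invalid for peptide '", df$peptide[i], "'", call. = FALSE)
    }
    if (anyDuplicated(o)) {
      stop("row ", i, ": duplicate mod_offsets", call. = FALSE)
    }
    res <- substring(df$peptide[i], o, o)
    if (any(res != "C")) {
      stop("row ", i, ": mod_offset ", paste(o[res != "C"], collapse = ";"),
           " does not point at a cysteine in peptide '", df$peptide[i], "'",
           call. = FALSE)
    }
  }
  multi <- grepl(";", df$mod_offsets, fixed = TRUE)
  single <- which(nzchar(df$mod_offsets) & !multi)
  if (length(single) > 0L) {
    o <- suppressWarnings(as.integer(df$mod_offsets[single]))
    ok <- !is.na(o) & o >= 1L & o <= nchar(df$peptide[single]) &
      substring(df$peptide[single], o, o) == "C"
    if (!all(ok)) check_offsets(single[which(!ok)[1]], o[which(!ok)[1]])
  }
  for (i in which(multi)) {
    o <- parse_mod_offsets(df$mod_offsets[i])[[1]]
    check_offsets(i, o)
    # canonical ascending order so round-trips are stable
    df$mod_offsets[i] <- paste(sort(o), collapse = ";")
  }
  attr(df, "provenance") <- provenance
  class(df) <- c("psm_table", class(df))
  df
}

parse_mod_offsets <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE), function(v) {
    v <- v[nzchar(v)]
    as.integer(v)
  })
}

#' Read a PSM table from TSV
#'
#' Expects a UTF-8 tab-separated file with a header naming at least
#' `condition`, `replicate`, `protein_id`, `peptide`, `mod_offsets`
#' (semicolon-separated integers, empty for unmodified), and optionally
#' `localized` (0/1) and `fdr`. Lines starting with `#` are skipped.
#'
#' @param path Path to the TSV file.
#' @return A `psm_table` tibble; file path recorded as provenance.
#' @export
read_psm_table <- function(path) {
  if (!file.exists(path)) {
    stop("PSM table not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(
    path,
    sep = "\t", comment.char = "#", header = TRUE,
    colClasses = "character", check.names = FALSE,
    fileEncoding = "UTF-8"
  )
  if ("fdr" %in% names(df)) df$fdr <- as.numeric(df$fdr)
  tryCatch(
    psm_table(df, provenance = path),
    error = function(e) {
      stop("while reading '", path, "': ", conditionMessage(e), call. = FALSE)
    }
  )
}

#' Write a PSM table to TSV
#'
#' Inverse of [read_psm_table()]; the round trip is lossless for the
#' recognized columns.
#'
#' @param table A `psm_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(table, path) {
  df <- as.data.frame(table)
  df$localized <- as.integer(df$localized)
  if (all(is.na(df$fdr))) df$fdr <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Filter PSMs at an FDR threshold
#'
#' Removes records whose `fdr` exceeds `fdr_max`; records without an FDR
#' value are retained (with a warning if the whole table lacks one). The
#' default threshold of 1% matches common search-engine reporting practice.
#'
#' @param table A `psm_table`.
#' @param fdr_max Maximum tolerated FDR, in `(0, 1]`.
#' @return The filtered `psm_table`. The number of removed records is
#'   reported via `message()`.
#' @export
filter_psms <- function(table, fdr_max = 0.01) {
  stopifnot(inherits(table, "psm_table"))
  stopifnot(is.numeric(fdr_max), length(fdr_max) == 1L,
            fdr_max > 0, fdr_max <= 1)
  if (all(is.na(table$fdr))) {
    warning("PSM table has no fdr values; returning table unchanged",
            call. = FALSE)
    return(table)
  }
  drop <- !is.na(table$fdr) & table$fdr > fdr_max
  message("filter_psms: removed ", sum(drop), " of ", nrow(table),
          " records at fdr_max = ", fdr_max)
  out <- table[!drop, , drop = FALSE]
  attr(out, "provenance") <- attr(table, "provenance")
  class(out) <- class(table)
  out
}
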