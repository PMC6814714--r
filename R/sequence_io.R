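# Protein sequence handling: FASTA input, in-silico tryptic digestion, and
# peptide-to-protein coordinate mapping. Coordinates are 1-based inclusive
# throughout, matching conventional residue numbering (e.g. C116).

AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Construct a protein record
#'
#' A `protein_record` couples a protein identifier with its amino-acid
#' sequence and the 1-based positions of all cysteine residues, the sites
#' interrogated by thiol labeling.
#'
#' @param id Protein identifier (single string).
#' @param sequence Amino-acid sequence using the standard 20-letter alphabet.
#'   Lower case is accepted and upper-cased.
#' @param permissive If `TRUE`, non-standard residue codes (e.g. X, U, B, Z)
#'   are tolerated and treated as non-cleavage, non-cysteine sites; if
#'   `FALSE` (default) they are an error.
#' @return An object of class `protein_record`: a list with elements `id`,
#'   `sequence`, and `cys_positions` (integer vector of 1-based indices of
#'   every C in the sequence).
#' @examples
#' p <- protein_record("p1", "MKCR")
#' p$cys_positions  # 3
#' @export
protein_record <- function(id, sequence, permissive = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) {
    stop("protein '", id, "': sequence is empty", call. = FALSE)
  }
  if (grepl("[[:space:]]", sequence)) {
    stop("protein '", id, "': sequence contains whitespace", call. = FALSE)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), AA_STANDARD)
  if (length(bad) > 0L && !permissive) {
    stop(
      "protein '", id, "': non-standard residue code(s): ",
      paste(bad, collapse = ", "),
      " (use permissive = TRUE to accept)",
      call. = FALSE
    )
  }
  structure(
    list(
      id = id,
      sequence = sequence,
      cys_positions = which(chars == "C")
    ),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat(
    "<protein_record> ", x$id, ": ", nchar(x$sequence), " aa, ",
    length(x$cys_positions), " Cys",
    if (length(x$cys_positions)) {
      paste0(" (", paste0("C", x$cys_positions, collapse = ", "), ")")
    } else "",
    "\n", sep = ""
  )
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file (multi-record; wrapped lines tolerated).
#' @param permissive Passed to [protein_record()]; controls acceptance of
#'   non-standard residue codes.
#' @return A list of [protein_record()] objects in file order.
#' @export
read_fasta <- function(path, permissive = FALSE) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  seqs <- withCallingHandlers(
    tryCatch(
      Biostrings::readAAStringSet(path),
      error = function(e) {
        stop("failed to parse FASTA file '", path, "': ",
             conditionMessage(e), call. = FALSE)
      }
    ),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        lines <- readLines(path)
        bad <- which(!startsWith(lines, ">") &
                       grepl("[^A-Za-z*-]", lines))
        stop("invalid sequence character(s) in FASTA file '", path,
             "' at line ", if (length(bad)) bad[1] else "?", call. = FALSE)
      }
      invokeRestart("muffleWarning")
    }
  )
  if (length(seqs) == 0L) {
    stop("FASTA file '", path, "' contains no sequences", call. = FALSE)
  }
  ids <- vapply(
    strsplit(names(seqs), "[[:space:]]+"), `[[`, character(1), 1L
  )
  lapply(seq_along(seqs), function(i) {
    protein_record(ids[i], as.character(seqs[[i]]), permissive = permissive)
  })
}

#' Digestion parameters
#'
#' @param missed_cleavages Maximum number of internal uncleaved K/R sites per
#'   peptide. Default 2, a common search-engine setting.
#' @param min_length,max_length Retained peptide length window. The defaults
#'   (5, 50) bracket the peptide sizes typically observable by LC-MS.
#' @return A list of class `digest_params`.
#' @export
digest_params <- function(missed_cleavages = 2L, min_length = 5L,
                          max_length = 50L) {
  missed_cleavages <- as.integer(missed_cleavages)
  min_length <- as.integer(min_length)
  max_length <- as.integer(max_length)
  stopifnot(missed_cleavages >= 0L, min_length >= 1L)
  if (min_length > max_length) {
    stop("min_length must be <= max_length", call. = FALSE)
  }
  structure(
    list(
      missed_cleavages = missed_cleavages,
      min_length = min_length,
      max_length = max_length
    ),
    class = "digest_params"
  )
}

# 1-based positions after which trypsin cleaves: after K or R unless the next
# residue is proline. LysC (after K) adds no sites beyond this rule.
tryptic_cleavage_sites <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  kr <- which(chars %in% c("K", "R"))
  kr <- kr[kr < n]                       # C-terminus is a boundary anyway
  kr[chars[kr + 1L] != "P"]
}

#' In-silico trypsin/LysC digestion
#'
#' Cleaves C-terminal to K or R except when the following residue is proline,
#' emits all peptides with up to `params$missed_cleavages` internal uncleaved
#' sites, and applies the peptide length window.
#'
#' @param protein A [protein_record()].
#' @param params A [digest_params()] object.
#' @return A tibble with columns `protein_id`, `start`, `end`, `peptide`,
#'   `missed` (number of internal uncleaved sites), ordered by `start` then
#'   `end`. Coordinates are 1-based inclusive and satisfy
#'   `substr(sequence, start, end) == peptide`.
#' @examples
#' p <- protein_record("p1", "MKCR")
#' tryptic_digest(p, digest_params(0, 1, 50))
#' @export
tryptic_digest <- function(protein, params = digest_params()) {
  stopifnot(inherits(protein, "protein_record"),
            inherits(params, "digest_params"))
  n <- nchar(protein$sequence)
  # segment boundaries: peptide k runs (bounds[k]+1) .. bounds[k+1]
  bounds <- c(0L, tryptic_cleavage_sites(protein$sequence), n)
  bounds <- unique(bounds)
  nseg <- length(bounds) - 1L
  out_start <- integer(0)
  out_end <- integer(0)
  out_missed <- integer(0)
  for (i in seq_len(nseg)) {
    for (mc in 0:params$missed_cleavages) {
      j <- i + mc
      if (j > nseg) break
      out_start <- c(out_start, bounds[i] + 1L)
      out_end <- c(out_end, bounds[j + 1L])
      out_missed <- c(out_missed, mc)
    }
  }
  len <- out_end - out_start + 1L
  keep <- len >= params$min_length & len <= params$max_length
  tibble::tibble(
    protein_id = protein$id,
    start = out_start[keep],
    end = out_end[keep],
    peptide = substring(protein$sequence, out_start[keep], out_end[keep]),
    missed = out_missed[keep]
  ) |>
    dplyr::arrange(.data$start, .data$end)
}

#' Map a peptide sequence onto its parent protein
#'
#' Exact substring matching; isoleucine and leucine are distinct.
#'
#' @param peptide Peptide sequence (non-empty string).
#' @param protein A [protein_record()].
#' @return A one-row tibble with `protein_id`, `start`, `end`, `peptide`.
#' @section Errors: zero occurrences raise an "unmapped peptide" error; two
#'   or more occurrences raise an "ambiguous peptide" error, since the site
#'   coordinates would be undefined.
#' @export
map_peptide_to_protein <- function(peptide, protein) {
  stopifnot(inherits(protein, "protein_record"))
  stopifnot(is.character(peptide), length(peptide) == 1L, nzchar(peptide))
  peptide <- toupper(peptide)
  hits <- gregexpr(peptide, protein$sequence, fixed = TRUE)[[1]]
  if (hits[1] == -1L) {
    stop("unmapped peptide '", peptide, "' in protein '", protein$id, "'",
         call. = FALSE)
  }
  if (length(hits) > 1L) {
    stop("ambiguous peptide '", peptide, "': ", length(hits),
         " occurrences in protein '", protein$id, "'", call. = FALSE)
  }
  start <- as.integer(hits[1])
  tibble::tibble(
    protein_id = protein$id,
    start = start,
    end = start + nchar(peptide) - 1L,
    peptide = peptide
  )
}

#' Cysteine sites covered by a mapped peptide
#'
#' @param match A one-row peptide match (as from [map_peptide_to_protein()]
#'   or a row of [tryptic_digest()] output).
#' @param protein The parent [protein_record()].
#' @return Integer vector of 1-based protein coordinates of every cysteine
#'   within `[start, end]`, ascending (possibly empty).
#' @export
cys_sites_in_peptide <- function(match, protein) {
  stopifnot(inherits(protein, "protein_record"))
  start <- match$start[1]
  end <- match$end[1]
  stopifnot(start >= 1L, end >= start, end <= nchar(protein$sequence))
  protein$cys_positions[protein$cys_positions >= start &
                          protein$cys_positions <= end]
}
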