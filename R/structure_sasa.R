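# Solvent-accessible surface area (Shrake-Rupley sphere-point method) and
# salt-bridge distance series from atomic structures. PDB parsing is
# delegated to bio3d; the SASA algorithm itself is implemented here.

# Bondi-type van der Waals radii (Angstrom); unknown elements fall back to
# the carbon radius with a warning.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
VDW_DEFAULT <- 1.70

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT", "H", "H1", "H2", "H3", "HA")

# side-chain charged-group heavy atoms used for salt-bridge distances
CHARGED_GROUP_ATOMS <- list(
  ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2"),
  ARG = c("NH1", "NH2", "NE"),
  LYS = "NZ",
  HIS = c("ND1", "NE2")
)

assign_vdw_radius <- function(element) {
  element <- toupper(trimws(element))
  r <- unname(VDW_RADII[element])
  unknown <- is.na(r) | !nzchar(element)
  if (any(unknown)) {
    warning("unknown element(s) ",
            paste(unique(element[unknown]), collapse = ", "),
            ": using default vdW radius ", VDW_DEFAULT, " A", call. = FALSE)
    r[unknown] <- VDW_DEFAULT
  }
  r
}

#' Construct a structure model
#'
#' @param atoms Data frame with columns `serial`, `name`, `residue_name`,
#'   `chain`, `residue_number`, `x`, `y`, `z`, `element`; a `vdw_radius`
#'   column is added from the element if absent.
#' @param frames Optional list of `n_atoms x 3` coordinate matrices sharing
#'   the atom list (trajectory-style input). Defaults to the single frame
#'   given by the atom coordinates.
#' @return List of class `structure_model` with elements `atoms` (tibble)
#'   and `frames` (list of coordinate matrices).
#' @export
structure_model <- function(atoms, frames = NULL) {
  need <- c("serial", "name", "residue_name", "chain", "residue_number",
            "x", "y", "z", "element")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atoms table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  atoms <- tibble::as_tibble(atoms)
  if (!"vdw_radius" %in% names(atoms)) {
    atoms$vdw_radius <- assign_vdw_radius(atoms$element)
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates", call. = FALSE)
  stopifnot(all(atoms$vdw_radius > 0))
  if (is.null(frames)) frames <- list(xyz)
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    dimnames(f) <- NULL
    if (nrow(f) != nrow(atoms) || ncol(f) != 3L) {
      stop("every frame must be an n_atoms x 3 coordinate matrix",
           call. = FALSE)
    }
    if (!all(is.finite(f))) stop("non-finite frame coordinates", call. = FALSE)
    f
  })
  structure(list(atoms = atoms, frames = frames), class = "structure_model")
}

#' Read a structure from a PDB file
#'
#' Parses fixed-column ATOM/HETATM records via [bio3d::read.pdb()];
#' multi-model files become multi-frame models sharing one atom list.
#'
#' @param path Path to a PDB file.
#' @param keep_hetero Keep HETATM records (waters are still dropped unless
#'   `keep_water`).
#' @param keep_water Keep water molecules (HOH/WAT).
#' @return A [structure_model()].
#' @export
read_structure <- function(path, keep_hetero = FALSE, keep_water = FALSE) {
  if (!file.exists(path)) stop("PDB file not found: ", path, call. = FALSE)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) {
      stop("failed to parse PDB file '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  at <- pdb$atom
  keep <- rep(TRUE, nrow(at))
  if (!keep_hetero) keep <- keep & at$type == "ATOM"
  if (!keep_water) keep <- keep & !(at$resid %in% c("HOH", "WAT"))
  if (!any(keep)) stop("no atoms retained from '", path, "'", call. = FALSE)
  at <- at[keep, , drop = FALSE]
  element <- toupper(trimws(at$elesy))
  # fall back to the first letter of the atom name when the element column
  # is blank (common in minimal hand-written files)
  blank <- !nzchar(element) | is.na(element)
  element[blank] <- substr(gsub("[0-9]", "", trimws(at$elety[blank])), 1, 1)
  atoms <- tibble::tibble(
    serial = at$eleno,
    name = trimws(at$elety),
    residue_name = trimws(at$resid),
    chain = at$chain,
    residue_number = at$resno,
    x = at$x, y = at$y, z = at$z,
    element = element
  )
  frames <- NULL
  if (!is.null(pdb$xyz) && nrow(pdb$xyz) > 1L) {
    idx <- which(keep)
    cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
    frames <- lapply(seq_len(nrow(pdb$xyz)), function(m) {
      matrix(pdb$xyz[m, cols], ncol = 3L, byrow = TRUE)
    })
  }
  structure_model(atoms, frames)
}

#' Write a structure model to a PDB file
#'
#' Minimal fixed-column writer (multi-frame models become MODEL/ENDMDL
#' blocks); round-trips with [read_structure()].
#'
#' @param model A [structure_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  fmt_frame <- function(xyz) {
    sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      a$serial,
      ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name),
      a$residue_name, a$chain, a$residue_number,
      xyz[, 1], xyz[, 2], xyz[, 3], a$element
    )
  }
  lines <- if (length(model$frames) == 1L) {
    c(fmt_frame(model$frames[[1]]), "END")
  } else {
    unlist(c(lapply(seq_along(model$frames), function(m) {
      c(sprintf("MODEL     %4d", m), fmt_frame(model$frames[[m]]), "ENDMDL")
    }), "END"))
  }
  writeLines(lines, path)
  invisible(path)
}

# deterministic quasi-uniform points on the unit sphere (Fibonacci lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * i        # golden-angle increments
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

# per-atom SASA for one coordinate frame
sasa_frame <- function(xyz, radii, probe_radius, pts) {
  n <- nrow(xyz)
  rexp <- radii + probe_radius
  npts <- nrow(pts)
  # spatial binning: cell size twice the largest expanded radius, so all
  # overlap partners of an atom sit in its 3x3x3 cell neighbourhood
  cell <- 2 * max(rexp)
  ci <- floor(xyz / cell)
  key <- paste(ci[, 1], ci[, 2], ci[, 3], sep = ",")
  cells <- split(seq_len(n), key)
  area <- numeric(n)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in seq_len(n)) {
    nb_keys <- paste(ci[i, 1] + offsets[, 1], ci[i, 2] + offsets[, 2],
                     ci[i, 3] + offsets[, 3], sep = ",")
    cand <- unlist(cells[nb_keys], use.names = FALSE)
    cand <- cand[cand != i]
    if (length(cand) > 0L) {
      d2 <- (xyz[cand, 1] - xyz[i, 1])^2 + (xyz[cand, 2] - xyz[i, 2])^2 +
        (xyz[cand, 3] - xyz[i, 3])^2
      cand <- cand[d2 < (rexp[i] + rexp[cand])^2]
    }
    if (length(cand) == 0L) {
      area[i] <- 4 * pi * rexp[i]^2
      next
    }
    p <- pts * rexp[i]
    p[, 1] <- p[, 1] + xyz[i, 1]
    p[, 2] <- p[, 2] + xyz[i, 2]
    p[, 3] <- p[, 3] + xyz[i, 3]
    covered <- logical(npts)
    for (j in cand) {
      d2j <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      covered <- covered | (d2j < rexp[j]^2)
      if (all(covered)) break
    }
    area[i] <- mean(!covered) * 4 * pi * rexp[i]^2
  }
  area
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' For every atom, `n_points` quasi-uniform test points are placed on a
#' sphere of radius `vdw_radius + probe_radius`; the accessible area is the
#' fraction of points not buried inside any neighbour's expanded sphere,
#' times the full sphere area. Neighbour search uses spatial binning with
#' cell size twice the largest expanded radius.
#'
#' @param model A [structure_model()].
#' @param probe_radius Solvent probe radius, Angstrom (default 1.4, a water
#'   molecule).
#' @param n_points Test points per atom (default 960).
#' @return Object of class `sasa_result`: `atom_area` is an
#'   `n_frames x n_atoms` matrix of areas (Angstrom^2), `residue_area` a
#'   tibble of per-residue totals per frame, plus the parameters.
#' @export
shrake_rupley <- function(model, probe_radius = 1.4, n_points = 960) {
  stopifnot(inherits(model, "structure_model"),
            probe_radius >= 0, n_points >= 12)
  pts <- sphere_points(n_points)
  radii <- model$atoms$vdw_radius
  atom_area <- do.call(rbind, lapply(model$frames, function(xyz) {
    sasa_frame(xyz, radii, probe_radius, pts)
  }))
  a <- model$atoms
  res_key <- paste(a$chain, a$residue_number, a$residue_name, sep = "|")
  residue_area <- dplyr::bind_rows(lapply(seq_len(nrow(atom_area)), function(m) {
    tibble::tibble(
      frame = m, chain = a$chain, residue_number = a$residue_number,
      residue_name = a$residue_name, area = atom_area[m, ]
    ) |>
      dplyr::group_by(.data$frame, .data$chain, .data$residue_number,
                      .data$residue_name) |>
      dplyr::summarise(area = sum(.data$area), .groups = "drop")
  }))
  structure(
    list(atom_area = atom_area, residue_area = residue_area,
         probe_radius = probe_radius, n_points = n_points,
         atoms = a),
    class = "sasa_result"
  )
}

#' Cysteine side-chain SASA
#'
#' Side-chain accessible area (CB, SG and any attached hydrogens; backbone
#' atoms excluded) for every cysteine residue, per frame.
#'
#' @param model A [structure_model()].
#' @param probe_radius,n_points Passed to [shrake_rupley()].
#' @return Tibble `frame`, `chain`, `residue_number`, `sasa` (Angstrom^2),
#'   one row per cysteine per frame; empty (with a warning) if the model has
#'   no cysteines.
#' @export
cys_side_chain_sasa <- function(model, probe_radius = 1.4, n_points = 960) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  is_cys_side <- a$residue_name == "CYS" & !(a$name %in% BACKBONE_ATOMS)
  if (!any(a$residue_name == "CYS")) {
    warning("model contains no cysteine residues", call. = FALSE)
    return(tibble::tibble(frame = integer(), chain = character(),
                          residue_number = integer(), sasa = double()))
  }
  sr <- shrake_rupley(model, probe_radius = probe_radius, n_points = n_points)
  idx <- which(is_cys_side)
  dplyr::bind_rows(lapply(seq_len(nrow(sr$atom_area)), function(m) {
    tibble::tibble(
      frame = m,
      chain = a$chain[idx],
      residue_number = a$residue_number[idx],
      area = sr$atom_area[m, idx]
    ) |>
      dplyr::group_by(.data$frame, .data$chain, .data$residue_number) |>
      dplyr::summarise(sasa = sum(.data$area), .groups = "drop")
  }))
}

find_residue_atoms <- function(model, chain, resno) {
  a <- model$atoms
  sel <- which(a$chain == chain & a$residue_number == resno)
  if (length(sel) == 0L) {
    stop("residue ", chain, ":", resno, " not found in model", call. = FALSE)
  }
  sel
}

#' Salt-bridge distance series
#'
#' Per frame, the minimum distance between the charged-group heavy atoms of
#' two residues (ASP: OD1/OD2; GLU: OE1/OE2; ARG: NH1/NH2/NE; LYS: NZ;
#' HIS: ND1/NE2). A rupture is flagged at the first frame starting a run of
#' at least `dwell` consecutive frames with distance above `cutoff`.
#'
#' @param model A [structure_model()].
#' @param residue_a,residue_b Lists `list(chain =, number =)` naming the two
#'   residues; each must be of a charged-capable type.
#' @param cutoff Rupture distance cutoff, Angstrom (default 4.5).
#' @param dwell Minimum consecutive frames above cutoff to call a rupture.
#' @return Tibble `frame`, `distance` (Angstrom) with attributes
#'   `"rupture_frame"` (integer or `NA`) and `"cutoff"`.
#' @export
salt_bridge_distance <- function(model, residue_a, residue_b,
                                 cutoff = 4.5, dwell = 1L) {
  stopifnot(inherits(model, "structure_model"), cutoff > 0, dwell >= 1L)
  a <- model$atoms
  pick_group <- function(res, label) {
    sel <- find_residue_atoms(model, res$chain, res$number)
    rname <- unique(a$residue_name[sel])[1]
    grp <- CHARGED_GROUP_ATOMS[[rname]]
    if (is.null(grp)) {
      stop("residue ", label, " (", rname, ") is not charged-capable ",
           "(expected ASP/GLU/LYS/ARG/HIS)", call. = FALSE)
    }
    got <- sel[a$name[sel] %in% grp]
    if (length(got) == 0L) {
      stop("residue ", label, " (", rname, ") is missing charged-group ",
           "atom(s): ", paste(grp, collapse = ", "), call. = FALSE)
    }
    got
  }
  ia <- pick_group(residue_a, paste0(residue_a$chain, ":", residue_a$number))
  ib <- pick_group(residue_b, paste0(residue_b$chain, ":", residue_b$number))
  dist_min <- vapply(model$frames, function(xyz) {
    pa <- xyz[ia, , drop = FALSE]
    pb <- xyz[ib, , drop = FALSE]
    d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * tcrossprod(pa, pb)
    sqrt(max(min(d2), 0))
  }, double(1))
  out <- tibble::tibble(frame = seq_along(dist_min), distance = dist_min)
  above <- dist_min > cutoff
  rupture <- NA_integer_
  run <- rle(above)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  hit <- which(run$values & run$lengths >= dwell)
  if (length(hit) > 0L) rupture <- starts[hit[1]]
  attr(out, "rupture_frame") <- rupture
  attr(out, "cutoff") <- cutoff
  out
}

#' Correlation between labeling and structural exposure
#'
#' Pearson and Spearman correlations between per-site labeling ratios and
#' per-site side-chain SASA over the shared site set.
#'
#' @param estimates Per-site estimates with columns `residue_index` and
#'   `ratio` (as from [quantify_sites()]).
#' @param sasa Tibble with columns `residue_number` and `sasa` (as from
#'   [cys_side_chain_sasa()], one frame), or a named numeric vector keyed by
#'   residue number.
#' @return List `pearson_r`, `spearman_rho`, `n`.
#' @export
labeling_sasa_correlation <- function(estimates, sasa) {
  if (is.numeric(sasa) && !is.null(names(sasa))) {
    sasa <- tibble::tibble(residue_number = as.integer(names(sasa)),
                           sasa = unname(sasa))
  }
  stopifnot(all(c("residue_number", "sasa") %in% names(sasa)),
            all(c("residue_index", "ratio") %in% names(estimates)))
  joined <- dplyr::inner_join(
    estimates, sasa,
    by = c(residue_index = "residue_number")
  )
  if (nrow(joined) < 3L) {
    stop("need >= 3 shared sites to correlate (got ", nrow(joined), ")",
         call. = FALSE)
  }
  list(
    pearson_r = stats::cor(joined$ratio, joined$sasa, method = "pearson"),
    spearman_rho = stats::cor(joined$ratio, joined$sasa, method = "spearman"),
    n = nrow(joined)
  )
}
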