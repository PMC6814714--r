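test_that("PDB files round-trip through the reader, including multi-model", {
  m <- make_sphere_fixture("pair", distance = 5)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(m, path)
  back <- read_structure(path)
  expect_equal(nrow(back$atoms), 2)
  expect_equal(back$atoms$element, c("C", "C"))
  expect_equal(back$frames[[1]], m$frames[[1]], tolerance = 1e-3)

  # two frames sharing one atom list
  m2 <- structure_model(m$atoms, frames = list(m$frames[[1]],
                                               m$frames[[1]] + 1))
  write_structure_pdb(m2, path)
  back2 <- read_structure(path)
  expect_length(back2$frames, 2)
  expect_equal(nrow(back2$atoms), 2)
  expect_equal(back2$frames[[2]], m$frames[[1]] + 1, tolerance = 1e-3)
})

test_that("unknown elements get the default radius with a warning", {
  expect_warning(
    m <- structure_model(tibble::tibble(
      serial = 1, name = "X1", residue_name = "UNK", chain = "A",
      residue_number = 1, x = 0, y = 0, z = 0, element = "Q"
    )),
    "default vdW radius"
  )
  expect_equal(m$atoms$vdw_radius, 1.70)
})

test_that("isolated and well-separated spheres match the closed-form area", {
  # carbon, r = 1.70, probe 1.4: area = 4*pi*3.1^2
  iso <- shrake_rupley(make_sphere_fixture("isolated"))
  closed <- 4 * pi * (1.70 + 1.4)^2
  expect_lt(abs(iso$atom_area[1, 1] - closed) / closed, 0.01)

  # beyond the sum of expanded radii (6.2): no interaction
  far <- shrake_rupley(pair_model(10))
  expect_equal(unname(far$atom_area[1, ]), rep(closed, 2), tolerance = 1e-9)

  # accuracy improves with the point count
  coarse <- shrake_rupley(make_sphere_fixture("isolated"), n_points = 96)
  fine <- shrake_rupley(make_sphere_fixture("isolated"), n_points = 4000)
  expect_lte(abs(fine$atom_area[1, 1] - closed),
             abs(coarse$atom_area[1, 1] - closed) + 1e-9)
})

test_that("overlapping pairs agree with a dense brute-force reference", {
  for (d in c(2.0, 3.0, 4.5)) {
    m <- pair_model(d)
    got <- shrake_rupley(m)$atom_area[1, ]
    ref <- brute_force_sasa(m$frames[[1]], m$atoms$vdw_radius,
                            probe = 1.4, n_points = 1e5)
    expect_lt(max(abs(got - ref) / ref), 0.02)
  }
})

test_that("SASA is invariant under rigid motion and unaffected by distant atoms", {
  m <- pair_model(2.5)
  base <- shrake_rupley(m)$atom_area[1, ]

  # rotate + translate all coordinates
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- structure_model(m$atoms,
                           frames = list(m$frames[[1]] %*% rot + 5))
  expect_equal(shrake_rupley(moved)$atom_area[1, ], base, tolerance = 0.01)

  # appending a far-away atom leaves existing areas untouched
  atoms3 <- dplyr::bind_rows(m$atoms, dplyr::mutate(m$atoms[1, ],
                                                    serial = 3,
                                                    residue_number = 3,
                                                    x = 100))
  m3 <- structure_model(atoms3)
  expect_equal(shrake_rupley(m3)$atom_area[1, 1:2], base, tolerance = 1e-12)
})

cys_model <- function() {
  # minimal CYS: backbone N/CA/C/O + side chain CB, SG
  structure_model(tibble::tibble(
    serial = 1:6,
    name = c("N", "CA", "C", "O", "CB", "SG"),
    residue_name = "CYS", chain = "A", residue_number = 1,
    x = c(0, 1.5, 2.2, 2.0, 2.1, 3.0),
    y = c(0, 0, 1.2, 2.3, -1.4, -2.5),
    z = c(0, 0, 0, 0, 0.2, 1.0),
    element = c("N", "C", "C", "O", "C", "S")
  ))
}

test_that("cysteine side-chain SASA sums CB and SG and detects burial", {
  open <- cys_side_chain_sasa(cys_model())
  expect_equal(nrow(open), 1)
  expect_gt(open$sasa, 50)

  # consistency with the atom-level result
  sr <- shrake_rupley(cys_model())
  side <- sr$atoms$name %in% c("CB", "SG")
  expect_equal(open$sasa, sum(sr$atom_area[1, side]))

  # per-frame output length equals the frame count
  m <- cys_model()
  m2 <- structure_model(m$atoms, frames = list(m$frames[[1]],
                                               m$frames[[1]] + 0.1))
  expect_equal(nrow(cys_side_chain_sasa(m2)), 2)

  # no cysteines: empty result with a warning
  expect_warning(none <- cys_side_chain_sasa(make_sphere_fixture("isolated")),
                 "no cysteine")
  expect_equal(nrow(none), 0)
})

salt_bridge_model <- function(distances) {
  # one ASP (OD1 only relevant) and one LYS (NZ), one frame per distance
  atoms <- tibble::tibble(
    serial = 1:4,
    name = c("CB", "OD1", "CB", "NZ"),
    residue_name = c("ASP", "ASP", "LYS", "LYS"),
    chain = "A", residue_number = c(10, 10, 20, 20),
    x = c(-1, 0, 99, 3), y = 0, z = 0,
    element = c("C", "O", "C", "N")
  )
  frames <- lapply(distances, function(d) {
    xyz <- cbind(c(-1, 0, d + 99, d), c(0, 0, 0, 0), c(0, 0, 0, 0))
    xyz
  })
  structure_model(atoms, frames = frames)
}

test_that("salt-bridge distances track the charged-group minimum and flag rupture", {
  m <- salt_bridge_model(3.0)
  d <- salt_bridge_distance(m, list(chain = "A", number = 10),
                            list(chain = "A", number = 20))
  expect_equal(d$distance, 3.0)
  expect_true(is.na(attr(d, "rupture_frame")))

  # series 3, 3, 8, 8 with cutoff 4.5 ruptures at frame 3
  ms <- salt_bridge_model(c(3, 3, 8, 8))
  ds <- salt_bridge_distance(ms, list(chain = "A", number = 10),
                             list(chain = "A", number = 20), cutoff = 4.5)
  expect_equal(ds$distance, c(3, 3, 8, 8))
  expect_equal(attr(ds, "rupture_frame"), 3L)

  # symmetric arguments give the identical series
  rev_ds <- salt_bridge_distance(ms, list(chain = "A", number = 20),
                                 list(chain = "A", number = 10), cutoff = 4.5)
  expect_equal(rev_ds$distance, ds$distance)

  # a dwell longer than the excursion suppresses the flag
  short <- salt_bridge_model(c(3, 8, 3, 3))
  dd <- salt_bridge_distance(short, list(chain = "A", number = 10),
                             list(chain = "A", number = 20), dwell = 2)
  expect_true(is.na(attr(dd, "rupture_frame")))

  # non-charged residues and missing atoms are informative errors
  gly <- make_sphere_fixture("pair", distance = 3)
  expect_error(
    salt_bridge_distance(gly, list(chain = "A", number = 1),
                         list(chain = "A", number = 2)),
    "not charged-capable"
  )
  noatom <- structure_model(tibble::tibble(
    serial = 1:2, name = c("CB", "CB"),
    residue_name = c("ASP", "LYS"), chain = "A", residue_number = c(1, 2),
    x = c(0, 3), y = 0, z = 0, element = "C"
  ))
  expect_error(
    salt_bridge_distance(noatom, list(chain = "A", number = 1),
                         list(chain = "A", number = 2)),
    "OD1"
  )
})

test_that("labeling-SASA correlation reports Pearson and Spearman over shared sites", {
  est <- tibble::tibble(residue_index = c(10L, 20L, 30L, 40L),
                        ratio = c(0.1, 0.4, 0.2, 0.9))
  # sasa proportional to ratio: both coefficients 1
  sasa <- tibble::tibble(residue_number = c(10L, 20L, 30L, 40L),
                         sasa = est$ratio * 100)
  r <- labeling_sasa_correlation(est, sasa)
  expect_equal(r$pearson_r, 1)
  expect_equal(r$spearman_rho, 1)
  expect_equal(r$n, 4L)

  # anti-correlated exposure
  r2 <- labeling_sasa_correlation(est,
    tibble::tibble(residue_number = est$residue_index, sasa = -est$ratio))
  expect_equal(r2$pearson_r, -1)

  # hand-sized check against the direct product-moment formula
  s4 <- c(12, 35, 8, 60)
  r3 <- labeling_sasa_correlation(est,
    tibble::tibble(residue_number = est$residue_index, sasa = s4))
  x <- est$ratio; y <- s4
  pearson_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r3$pearson_r, pearson_hand)
  rx <- rank(x); ry <- rank(y)
  spearman_hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(r3$spearman_rho, spearman_hand)

  # named-vector input and the minimum-size guard
  expect_equal(
    labeling_sasa_correlation(est, setNames(s4, est$residue_index))$pearson_r,
    pearson_hand
  )
  expect_error(
    labeling_sasa_correlation(est[1:2, ],
      tibble::tibble(residue_number = c(10L, 20L), sasa = c(1, 2))),
    ">= 3 shared sites"
  )
})
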