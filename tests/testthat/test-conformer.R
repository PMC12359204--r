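test_that("built conformers reproduce their input torsions", {
  topo <- parse_topology("seq AAAAAAAAAA")
  conf <- build_conformer(topo, cbind(rep(-57, 10), rep(-47, 10)))
  tor <- measure_torsions(conf)
  expect_lt(max(abs(tor$phi + 57)), 1e-6)
  expect_lt(max(abs(tor$psi + 47)), 1e-6)

  set.seed(5)
  pp <- cbind(runif(10, -180, 180), runif(10, -180, 180))
  tor2 <- measure_torsions(build_conformer(topo, pp))
  expect_lt(max(abs(tor2$phi - pp[, 1])), 1e-6)
  expect_lt(max(abs(tor2$psi - pp[, 2])), 1e-6)
})

test_that("the extended chain has the canonical CA-CA spacing", {
  # independent oracle: planar all-trans rebuild of CA(i)->CA(i+1) from the
  # ideal internal coordinates via explicit 2D trigonometry
  b_cac <- 1.525; b_cn <- 1.329; b_nca <- 1.458
  a_cacn <- 116.2; a_cnca <- 121.7
  deg <- pi / 180
  ca0 <- c(0, 0)
  cc <- c(b_cac, 0)
  dir1 <- 180 - a_cacn                       # exterior turn at C
  nn <- cc + b_cn * c(cos(dir1 * deg), sin(dir1 * deg))
  dir2 <- dir1 - (180 - a_cnca)              # alternating turn at N
  ca1 <- nn + b_nca * c(cos(dir2 * deg), sin(dir2 * deg))
  expected <- sqrt(sum((ca1 - ca0)^2))

  topo <- parse_topology("seq AAAAA")
  ext <- build_conformer(topo, cbind(rep(180, 5), rep(180, 5)))
  d <- sqrt(sum((ext$xyz[atom_index(ext, 2, "CA"), ] -
                   ext$xyz[atom_index(ext, 1, "CA"), ])^2))
  expect_equal(d, expected, tolerance = 1e-6)
  expect_equal(d, 3.8, tolerance = 0.02)
})

test_that("empty and mismatched inputs are rejected", {
  topo <- parse_topology("seq AAAAA")
  expect_error(build_conformer(topo, cbind(rep(0, 3), rep(0, 3))), "5 residues")
  expect_error(parse_topology("seq "), "sequence")
})

test_that("chirality and sp2 geometry are honoured at the alpha carbon", {
  l <- build_conformer(parse_topology("seq AAA"), cbind(rep(-60, 3), rep(-40, 3)))
  d <- build_conformer(parse_topology("seq A[D-A]A"), cbind(rep(-60, 3), rep(-40, 3)))
  imp <- function(conf, i) {
    at <- function(a) conf$xyz[atom_index(conf, i, a), ]
    lanthifold:::dihedral_deg(at("C"), at("N"), at("CA"), at("CB"))
  }
  expect_equal(imp(l, 2), -122.6, tolerance = 1e-6)
  expect_equal(imp(d, 2), 122.6, tolerance = 1e-6)

  # Dha: planar CA, CB in the N-CA-C plane at 120-degree angles
  dha <- build_conformer(parse_topology("seq A[DHA]A"),
                         cbind(rep(-60, 3), rep(140, 3)))
  at <- function(a) dha$xyz[atom_index(dha, 2, a), ]
  expect_equal(lanthifold:::angle_deg(at("N"), at("CA"), at("CB")), 120,
               tolerance = 1e-6)
  expect_equal(abs(lanthifold:::dihedral_deg(at("C"), at("N"), at("CA"),
                                             at("CB"))), 180, tolerance = 1e-6)
})

test_that("torsion rotation moves only downstream atoms and preserves bonds", {
  conf <- helix10()
  rot <- rotate_torsion(conf, 5, "phi", 33)
  expect_equal(measure_torsions(rot)$phi[[5]], -57 + 33, tolerance = 1e-9)
  # upstream atoms untouched
  up <- conf$atoms$resno < 5
  expect_equal(rot$xyz[up, ], conf$xyz[up, ])
  # all other torsions unchanged
  t0 <- measure_torsions(conf); t1 <- measure_torsions(rot)
  expect_equal(t1$psi, t0$psi, tolerance = 1e-9)
  expect_equal(t1$phi[-5], t0$phi[-5], tolerance = 1e-9)
  # bonded framework preserved (bond lengths and bond angles; positions of O
  # and H relative to non-bonded atoms legitimately follow their torsions)
  expect_equal(internal_geometry(rot), internal_geometry(conf),
               tolerance = 1e-9)
})
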