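test_that("an exactly-ideal bridge scores zero penalty", {
  conf <- ideal_bridge_conformer()
  rep <- measure_crosslink(conf, ring8_topology()$rings[1, ])
  expect_equal(rep$total, 0, tolerance = 1e-12)
  expect_true(all(rep$terms$deviation < 1e-6))
})

test_that("a stretched C-S bond reports exactly its stretch", {
  conf <- ideal_bridge_conformer()
  ring <- ring8_topology()$rings[1, ]
  i_cb <- atom_index(conf, 2, "CB"); i_sg <- atom_index(conf, 5, "SG")
  u <- conf$xyz[i_sg, ] - conf$xyz[i_cb, ]
  conf$xyz[i_sg, ] <- conf$xyz[i_sg, ] + 0.5 * u / sqrt(sum(u^2))
  rep <- measure_crosslink(conf, ring)
  expect_equal(rep$terms$deviation[rep$terms$term == "bond_CS"], 0.5,
               tolerance = 1e-9)
})

test_that("crosslink penalties equal an independent per-term recomputation", {
  conf <- ring8_closed()
  ring <- ring8_topology()$rings[1, ]
  g <- crosslink_geometry("lanthionine")
  rep <- measure_crosslink(conf, ring, g)
  # brute-force re-measurement with local geometry code
  p <- function(resno, a) conf$xyz[atom_index(conf, resno, a), ]
  ang <- function(a, b, c) {
    u <- (a - b) / sqrt(sum((a - b)^2)); v <- (c - b) / sqrt(sum((c - b)^2))
    acos(pmin(1, pmax(-1, sum(u * v)))) * 180 / pi
  }
  dih <- function(a, b, c, d) {
    b1 <- b - a; b2 <- c - b; b3 <- d - c
    n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
            b1[1] * b2[2] - b1[2] * b2[1])
    n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
            b2[1] * b3[2] - b2[2] * b3[1])
    m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
            n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2 * b2))
    atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  }
  wrap <- function(x) abs(((x + 180) %% 360) - 180)
  expected <- g$bond_weight *
    (sqrt(sum((p(2, "CB") - p(5, "SG"))^2)) - g$cs_bond_length)^2 +
    g$angle_weight * wrap(ang(p(2, "CA"), p(2, "CB"), p(5, "SG")) -
                            g$angle_targets[1])^2 +
    g$angle_weight * wrap(ang(p(2, "CB"), p(5, "SG"), p(5, "CB")) -
                            g$angle_targets[2])^2 +
    g$dihedral_weight * wrap(dih(p(2, "N"), p(2, "CA"), p(2, "CB"),
                                 p(5, "SG")) - 180)^2 +
    g$dihedral_weight * wrap(dih(p(2, "CA"), p(2, "CB"), p(5, "SG"),
                                 p(5, "CB")) - 180)^2 +
    g$dihedral_weight * wrap(dih(p(2, "CB"), p(5, "SG"), p(5, "CB"),
                                 p(5, "CA")) - 180)^2
  expect_equal(rep$total, expected, tolerance = 1e-9)
})

test_that("near-closed rings re-close to a tight C-S gap", {
  base <- ring8_closed()
  ring <- ring8_topology()$rings[1, ]
  set.seed(77)
  hits <- 0
  for (k in 1:20) {
    pert <- base
    for (i in 2:5) {
      pert <- rotate_torsion(pert, i, "phi", rnorm(1, 0, 10))
      pert <- rotate_torsion(pert, i, "psi", rnorm(1, 0, 10))
    }
    out <- close_ring(pert, ring)
    if (is_closed(out) && attr(out, "closure")$gap < 0.02) hits <- hits + 1
  }
  expect_gte(hits, 18)  # 90%
})

test_that("closure is a fixed point on an already-closed ring", {
  conf <- ring8_closed()
  again <- close_ring(conf, ring8_topology()$rings[1, ])
  expect_lt(max(abs(again$xyz - conf$xyz)), 1e-9)
})

test_that("closure changes only torsions, never bonds or angles", {
  topo <- ring8_topology()
  set.seed(15)
  conf <- build_conformer(topo, draw_random_torsions(topo))
  out <- close_ring(conf, topo$rings[1, ])
  # exhaustive internal-coordinate comparison: every bond length and bond
  # angle of the chain is preserved; only torsions may differ
  expect_equal(internal_geometry(out), internal_geometry(conf),
               tolerance = 1e-9)
  # torsions outside the ring span untouched
  t0 <- measure_torsions(conf); t1 <- measure_torsions(out)
  expect_equal(t1$phi[7:8], t0$phi[7:8], tolerance = 1e-9)
  expect_equal(t1$psi[6:8], t0$psi[6:8], tolerance = 1e-9)
})

test_that("degenerate rings are rejected", {
  topo <- parse_topology("seq ACAAA\nring 1-2 lan")
  conf <- build_conformer(topo, cbind(rep(-60, 5), rep(-40, 5)))
  # adjacent-residue ring still has psi/phi dofs; force the degenerate error
  # through the span guard
  expect_error(close_ring(conf, list(donor = 1, acceptor = 1,
                                     type = "lanthionine")),
               "rotatable|span|intervening")
})
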