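# Shared fixtures, built once per test run and cached.

.fix <- new.env(parent = emptyenv())

# 8-residue, one 4-span lanthionine ring
ring8_topology <- function() {
  if (is.null(.fix$ring8)) .fix$ring8 <- parse_topology("seq AAAACAAA\nring 2-5 lan")
  .fix$ring8
}

# a closed conformer of the ring8 topology, deterministic
ring8_closed <- function() {
  if (is.null(.fix$ring8_closed)) {
    set.seed(101)
    topo <- ring8_topology()
    repeat {
      conf <- build_conformer(topo, draw_random_torsions(topo))
      cc <- close_ring(conf, topo$rings[1, ])
      if (is_closed(cc)) { .fix$ring8_closed <- cc; break }
    }
  }
  .fix$ring8_closed
}

draw_random_torsions <- function(topo)
  cbind(runif(nrow(topo$residues), -180, 180),
        runif(nrow(topo$residues), -180, 180))

# helix conformer of 10 Ala, no rings
helix10 <- function() {
  if (is.null(.fix$helix10)) {
    topo <- parse_topology("seq AAAAAAAAAA")
    .fix$helix10 <- build_conformer(topo, cbind(rep(-57, 10), rep(-47, 10)))
  }
  .fix$helix10
}

# pool of 12 random closed ring8 conformers for selector tests
selector_pool <- function() {
  if (is.null(.fix$selpool)) {
    set.seed(202)
    topo <- ring8_topology()
    pool <- list()
    while (length(pool) < 12L) {
      conf <- close_ring(build_conformer(topo, draw_random_torsions(topo)),
                         topo$rings[1, ])
      if (is_closed(conf)) pool[[length(pool) + 1L]] <- conf
    }
    .fix$selpool <- pool
  }
  .fix$selpool
}

# the default two-state fixture with 40 decoys (heaviest shared fixture)
two_state_fixture <- function() {
  if (is.null(.fix$twostate))
    .fix$twostate <- make_two_state_pool(fixture_recipe(seed = 404))
  .fix$twostate
}

random_rotation <- function() {
  axis <- rnorm(3)
  theta <- runif(1, -180, 180)
  u <- axis / sqrt(sum(axis^2))
  t <- theta * pi / 180
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  cos(t) * diag(3) + sin(t) * ux + (1 - cos(t)) * (u %o% u)
}

rigid_copy <- function(conf) {
  R <- random_rotation()
  transform_conformer(conf, R, runif(3, -20, 20))
}

mirror_copy <- function(conf) {
  conf$xyz[, 3] <- -conf$xyz[, 3]
  conf
}

# bonded framework of a conformer: every bond length and the backbone /
# branch bond angles, as one named numeric vector (torsion-free internal
# coordinates -- exactly what torsion moves must leave untouched)
internal_geometry <- function(conf) {
  at <- conf$atoms
  n <- max(at$resno)
  p <- function(i, a) conf$xyz[atom_index(conf, i, a), ]
  has <- function(i, a) any(at$resno == i & at$atom == a)
  dd <- function(a, b) sqrt(sum((a - b)^2))
  ang <- function(a, b, c) {
    u <- (a - b) / sqrt(sum((a - b)^2)); v <- (c - b) / sqrt(sum((c - b)^2))
    acos(pmin(1, pmax(-1, sum(u * v)))) * 180 / pi
  }
  out <- c()
  for (i in seq_len(n)) {
    out <- c(out, dd(p(i, "N"), p(i, "CA")), dd(p(i, "CA"), p(i, "C")),
             dd(p(i, "C"), p(i, "O")), ang(p(i, "N"), p(i, "CA"), p(i, "C")),
             ang(p(i, "CA"), p(i, "C"), p(i, "O")))
    for (a in c("CB", "H", "HA", "HA2", "HA3"))
      if (has(i, a))
        out <- c(out, dd(p(i, if (a %in% c("H")) "N" else "CA"), p(i, a)))
    if (has(i, "CB")) {
      out <- c(out, ang(p(i, "N"), p(i, "CA"), p(i, "CB")))
      for (g in c("SG", "OG", "OG1", "CG", "CG2"))
        if (has(i, g))
          out <- c(out, dd(p(i, "CB"), p(i, g)),
                   ang(p(i, "CA"), p(i, "CB"), p(i, g)))
    }
    if (i < n)
      out <- c(out, dd(p(i, "C"), p(i + 1, "N")),
               ang(p(i, "CA"), p(i, "C"), p(i + 1, "N")),
               ang(p(i, "C"), p(i + 1, "N"), p(i + 1, "CA")))
  }
  out
}

# a tiny torsion table built in code: full 360-degree periodic grid at
# 180-degree spacing = 4 cells
toy_table <- function(energies, mask = matrix(FALSE, 2, 2)) {
  structure(list(code = "TOY", spacing = 180, phi = c(-180, 0),
                 psi = c(-180, 0), energy = energies, mask = mask),
            class = "torsion_table")
}

# Helper: build a conformer and then overwrite the bridge atoms with
# positions constructed to satisfy every crosslink target exactly.
ideal_bridge_conformer <- function() {
  topo <- ring8_topology()
  conf <- build_conformer(topo, cbind(rep(-70, 8), rep(120, 8)))
  g <- crosslink_geometry("lanthionine")
  setxyz <- function(resno, atom, p) {
    conf$xyz[atom_index(conf, resno, atom), ] <<- p
  }
  Nd <- c(0, 0, 0); CAd <- c(1.458, 0, 0)
  CBd <- lanthifold:::place_atom(c(0, 1, 0), Nd, CAd, 1.521, 110.5, -100)
  SG <- lanthifold:::place_atom(Nd, CAd, CBd, g$cs_bond_length,
                                g$angle_targets[[1]], g$dihedral_targets[[1]])
  CBa <- lanthifold:::place_atom(CAd, CBd, SG, 1.808, g$angle_targets[[2]],
                                 g$dihedral_targets[[2]])
  CAa <- lanthifold:::place_atom(CBd, SG, CBa, 1.521, 114,
                                 g$dihedral_targets[[3]])
  setxyz(2, "N", Nd); setxyz(2, "CA", CAd); setxyz(2, "CB", CBd)
  setxyz(5, "SG", SG); setxyz(5, "CB", CBa); setxyz(5, "CA", CAa)
  conf
}
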