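test_that("interpolation is exact at nodes, periodic, and bilinear", {
  tab <- load_torsion_table("dha")
  i <- match(-60, tab$phi); j <- match(135, tab$psi)
  expect_identical(score_torsion(tab, -60, 135), tab$energy[i, j])
  expect_equal(score_torsion(tab, 100, -50), score_torsion(tab, 460, -410),
               tolerance = 1e-12)
  # mid-cell value on a bilinear patch is the mean of the 4 corners
  toy <- toy_table(matrix(c(1, 2, 3, 4), 2, 2))
  expect_equal(score_torsion(toy, -90, -90), mean(c(1, 2, 3, 4)),
               tolerance = 1e-12)
  # and along an edge midpoint, the mean of that edge's corners
  expect_equal(score_torsion(toy, -90, -180), mean(c(1, 2)), tolerance = 1e-12)
})

test_that("sampling respects masks and Boltzmann weights", {
  # single allowed cell -> always that cell
  m <- matrix(TRUE, 2, 2); m[1, 2] <- FALSE
  toy <- toy_table(matrix(0, 2, 2), m)
  set.seed(1)
  s <- sample_torsion(toy, 200)
  expect_true(all(s[, "phi"] < 0 & s[, "psi"] >= 0))

  # two equal-energy cells -> 50/50 within binomial error at n = 1e4
  m2 <- matrix(TRUE, 2, 2); m2[1, 1] <- FALSE; m2[2, 2] <- FALSE
  toy2 <- toy_table(matrix(5, 2, 2), m2)
  set.seed(2)
  s2 <- sample_torsion(toy2, 1e4)
  frac <- mean(s2[, "phi"] < 0)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1e4) + 0.001)

  # fully masked -> error
  expect_error(sample_torsion(toy_table(matrix(0, 2, 2),
                                        matrix(TRUE, 2, 2))),
               "fully masked")
})

test_that("empirical frequencies match Boltzmann weights (chi-square)", {
  E <- matrix(c(0, 0.7, 1.3, 2.1), 2, 2)
  toy <- toy_table(E)
  set.seed(3)
  n <- 1e5
  s <- sample_torsion(toy, n, jitter = FALSE)
  cell <- paste(s[, "phi"], s[, "psi"])
  labels <- as.vector(outer(toy$phi, toy$psi, paste))
  counts <- as.numeric(table(factor(cell, levels = labels)))
  p <- exp(-as.vector(E))
  p <- p / sum(p)
  expect_gt(stats::chisq.test(counts, p = p)$p.value, 0.01)
})

test_that("Dhb never samples its masked steric region", {
  dhb <- load_torsion_table("dhb")
  dha <- load_torsion_table("dha")
  set.seed(4)
  s <- sample_torsion(dhb, 1e5)
  cell_idx <- function(x, grid, spacing)
    ((floor((x - grid[[1]]) / spacing)) %% length(grid)) + 1
  i <- cell_idx(s[, "phi"], dhb$phi, dhb$spacing)
  j <- cell_idx(s[, "psi"], dhb$psi, dhb$spacing)
  expect_false(any(dhb$mask[cbind(i, j)]))
})

test_that("Dhb's allowed region is a strict subset of Dha's", {
  dhb <- load_torsion_table("dhb")
  dha <- load_torsion_table("dha")
  allowed_dhb <- !dhb$mask; allowed_dha <- !dha$mask
  expect_true(all(allowed_dha[allowed_dhb]))
  expect_lt(sum(allowed_dhb), sum(allowed_dha))
})

test_that("D residues score on the mirrored table", {
  g <- load_torsion_table("general")
  f <- flip_torsion_table(g)
  set.seed(6)
  for (k in 1:20) {
    phi <- runif(1, -180, 180); psi <- runif(1, -180, 180)
    expect_equal(score_torsion(f, phi, psi), score_torsion(g, -phi, -psi),
                 tolerance = 1e-9)
  }
  topo <- parse_topology("seq A[D-A]A")
  tab <- residue_torsion_table(topo, 2)
  expect_match(tab$code, "^D-")
})

test_that("table files round-trip through write and read", {
  tab <- load_torsion_table("dhb")
  tmp <- tempfile(fileext = ".tsv")
  write_torsion_table(tab, tmp)
  back <- read_torsion_table(tmp)
  expect_equal(back$energy, tab$energy, tolerance = 1e-4)
  expect_identical(back$mask, tab$mask)
  expect_identical(back$spacing, tab$spacing)
})
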