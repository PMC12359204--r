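test_that("effective distance reduces to Euclidean for single atoms and sums r^-6", {
  conf <- helix10()
  g1 <- resolve_atom_group(conf, 2, "HA")
  g2 <- resolve_atom_group(conf, 5, "HN")
  d_plain <- sqrt(sum((conf$xyz[atom_index(conf, 2, "HA"), ] -
                         conf$xyz[atom_index(conf, 5, "H"), ])^2))
  expect_equal(effective_distance(conf, g1, g2), d_plain, tolerance = 1e-12)

  # constructed two-atom group at pair distances 2.0 and 4.0
  fake <- conf
  fake$xyz[atom_index(fake, 1, "HA"), ] <- c(0, 0, 0)
  fake$xyz[atom_index(fake, 2, "HA"), ] <- c(2, 0, 0)   # at 2.0
  fake$xyz[atom_index(fake, 3, "HA"), ] <- c(0, 4, 0)   # at 4.0
  ga <- data.frame(resno = c(2, 3), atom = "HA")
  gb <- data.frame(resno = 1, atom = "HA")
  expect_equal(effective_distance(fake, ga, gb),
               (2^-6 + 4^-6)^(-1 / 6), tolerance = 1e-12)
  expect_equal((2^-6 + 4^-6)^(-1 / 6), 1.995, tolerance = 1e-3)

  # homogeneity of degree 1: doubling coordinates doubles the distance
  dbl <- conf; dbl$xyz <- 2 * dbl$xyz
  expect_equal(effective_distance(dbl, g1, g2),
               2 * effective_distance(conf, g1, g2), tolerance = 1e-9)
})

test_that("ensemble averaging follows the r^-6 mean over equal states", {
  pool <- selector_pool()
  r <- list(resA = 1, atomA = "HN", resB = 8, atomB = "HA")
  # N = 1: the member's own distance
  g1 <- resolve_atom_group(pool[[1]], 1, "HN")
  g2 <- resolve_atom_group(pool[[1]], 8, "HA")
  expect_equal(ensemble_average_distance(pool[1], r),
               effective_distance(pool[[1]], g1, g2), tolerance = 1e-12)
  # equal distances: d* equals that distance; checked on synthetic geometry
  conf <- helix10()
  mk <- function(d) {
    c2 <- conf
    c2$xyz[atom_index(c2, 1, "HA"), ] <- c(0, 0, 0)
    c2$xyz[atom_index(c2, 5, "HA"), ] <- c(d, 0, 0)
    c2
  }
  rr <- list(resA = 1, atomA = "HA", resB = 5, atomB = "HA")
  expect_equal(ensemble_average_distance(list(mk(3), mk(3), mk(3)), rr), 3,
               tolerance = 1e-12)
  # distances {2, 4}: independent direct evaluation of the formula
  expect_equal(ensemble_average_distance(list(mk(2), mk(4)), rr),
               ((2^-6 + 4^-6) / 2)^(-1 / 6), tolerance = 1e-12)
  expect_equal(((2^-6 + 4^-6) / 2)^(-1 / 6), 2.239, tolerance = 1e-3)
  expect_error(ensemble_average_distance(list(), rr), "empty")
})

test_that("power-mean bounds and short-distance dominance hold", {
  pool <- selector_pool()
  set.seed(21)
  for (k in 1:25) {
    res <- sort(sample(1:8, 2))
    r <- list(resA = res[1], atomA = "HN", resB = res[2], atomB = "HA")
    members <- pool[sample(12, sample(2:6, 1))]
    ga <- resolve_atom_group(members[[1]], r$resA, r$atomA)
    gb <- resolve_atom_group(members[[1]], r$resB, r$atomB)
    di <- vapply(members, effective_distance, numeric(1), ga, gb)
    ds <- ensemble_average_distance(members, r)
    expect_gte(ds, min(di) - 1e-9)
    expect_lte(ds, max(di) + 1e-9)
    # permutation invariance
    expect_equal(ensemble_average_distance(rev(members), r), ds,
                 tolerance = 1e-12)
    # adding a member closer than all others strictly shrinks d*
    closer <- members[[1]]
    u <- closer$xyz[atom_index(closer, r$resB, "HA"), ] -
      closer$xyz[atom_index(closer, r$resA, "H"), ]
    closer$xyz[atom_index(closer, r$resB, "HA"), ] <-
      closer$xyz[atom_index(closer, r$resA, "H"), ] + u / sqrt(sum(u^2)) *
        (0.9 * min(di))
    expect_lt(ensemble_average_distance(c(members, list(closer)), r), ds)
  }
})

test_that("ensemble scoring matches a brute-force oracle", {
  pool <- selector_pool()
  set.seed(22)
  restraints <- make_noe_set(pool[1:3], 15, noise_sd = 0.3, seed = 23)
  sc <- score_ensemble(pool[4:8], restraints)
  # independent recomputation with plain loops
  total <- 0
  for (k in seq_len(nrow(restraints))) {
    d6 <- numeric(0)
    for (m in pool[4:8]) {
      ga <- resolve_atom_group(m, restraints$resA[[k]], restraints$atomA[[k]])
      gb <- resolve_atom_group(m, restraints$resB[[k]], restraints$atomB[[k]])
      s <- 0
      for (i in seq_len(nrow(ga))) for (j in seq_len(nrow(gb)))
        s <- s + sum((m$xyz[atom_index(m, ga$resno[[i]], ga$atom[[i]]), ] -
                        m$xyz[atom_index(m, gb$resno[[j]], gb$atom[[j]]), ])^2)^-3
      d6 <- c(d6, s)
    }
    dstar <- mean((d6)^(1))^(-1 / 6)
    resid <- dstar - restraints$distance[[k]]   # kind = target
    total <- total + resid^2
  }
  expect_equal(sc$total, total, tolerance = 1e-9)
  expect_equal(sum(sc$table$sq_residual), sc$total, tolerance = 1e-12)

  # perfect agreement scores zero; a 0.5 A residual scores 0.25
  exact <- make_noe_set(pool[4:8], 10, noise_sd = 0, seed = 24)
  expect_equal(score_ensemble(pool[4:8], exact)$total, 0, tolerance = 1e-9)
  one <- exact[1, ]; one$distance <- one$distance - 0.5
  expect_equal(score_ensemble(pool[4:8], one)$total, 0.25, tolerance = 1e-9)
})

test_that("upper limits are one-sided in kind mode, two-sided in symmetric", {
  pool <- selector_pool()
  exact <- make_noe_set(pool[1:2], 5, noise_sd = 0, seed = 25,
                        kind = "upper_limit")
  slack <- exact; slack$distance <- slack$distance + 1  # satisfied limits
  expect_equal(score_ensemble(pool[1:2], slack)$total, 0, tolerance = 1e-9)
  expect_equal(score_ensemble(pool[1:2], slack, mode = "symmetric")$total,
               5, tolerance = 1e-6)
  tight <- exact; tight$distance <- tight$distance - 0.3  # violated by 0.3
  expect_equal(score_ensemble(pool[1:2], tight)$total, 5 * 0.09,
               tolerance = 1e-6)
})

test_that("restraint files round-trip and the upl dialect parses", {
  r <- data.frame(resA = c(1, 2), atomA = c("HN", "QB"),
                  resB = c(5, 7), atomB = c("HA", "HN"),
                  distance = c(4.2, 5.0), kind = c("target", "upper_limit"),
                  stringsAsFactors = FALSE)
  tmp <- tempfile(fileext = ".tsv")
  write_restraints(lanthifold:::validate_restraints(r), tmp,
                   remarks = "test set")
  back <- read_restraints(tmp)
  expect_equal(as.data.frame(back), r)

  upl <- tempfile(fileext = ".upl")
  writeLines(c("1 ALA HN 5 ALA HA 4.20", "2 ALA QB 7 ALA HN 5.00"), upl)
  u <- read_restraints(upl)
  expect_equal(u$resA, c(1L, 2L))
  expect_equal(u$atomB, c("HA", "HN"))
  expect_true(all(u$kind == "upper_limit"))

  expect_error(lanthifold:::validate_restraints(
    data.frame(resA = 1, atomA = "HA", resB = 1, atomB = "HA",
               distance = 3, kind = "target")), "itself")
})

test_that("unresolvable atoms are reported by name", {
  conf <- helix10()
  expect_error(resolve_atom_group(conf, 3, "QD"), "QD.*residue 3")
  expect_error(resolve_atom_group(conf, 99, "HA"), "out of range")
})
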