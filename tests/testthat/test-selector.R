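test_that("selection recovers the generating conformer from a tiny pool", {
  pool <- selector_pool()[1:3]
  restraints <- make_noe_set(pool[1], 12, noise_sd = 0, seed = 31)
  # exhaustive oracle over all 7 nonempty subsets
  ex <- exhaustive_select(pool, restraints, 1, 3)
  expect_identical(ex$members, 1L)
  expect_equal(ex$score, 0, tolerance = 1e-9)
  cfg <- selector_config(steps = 3000, size_min = 1, size_max = 3,
                         size_init = 2, seed = 32)
  mc <- select_ensemble(pool, restraints, cfg)
  expect_identical(mc$members, ex$members)
})

test_that("near-greedy selection matches the exhaustive optimum", {
  pool <- selector_pool()
  set.seed(33)
  restraints <- make_noe_set(pool[sample(12, 3)], 10, noise_sd = 0.15,
                             seed = 34)
  ex <- exhaustive_select(pool, restraints, 2, 4)
  cfg <- selector_config(steps = 8000, size_min = 2, size_max = 4,
                         size_init = 3, temperature = 1e-4, seed = 35)
  mc <- select_ensemble(pool, restraints, cfg)
  expect_equal(mc$score, ex$score, tolerance = 1e-9)
})

test_that("the selector is deterministic given a seed", {
  pool <- selector_pool()
  restraints <- make_noe_set(pool[1:2], 10, noise_sd = 0.1, seed = 36)
  cfg <- selector_config(steps = 2000, size_min = 1, size_max = 4,
                         size_init = 2, seed = 37, log_every = 100)
  a <- select_ensemble(pool, restraints, cfg)
  b <- select_ensemble(pool, restraints, cfg)
  expect_identical(a$members, b$members)
  expect_identical(a$score, b$score)
  expect_identical(a$trajectory, b$trajectory)
})

test_that("size bounds are enforced and small pools rejected", {
  pool <- selector_pool()
  restraints <- make_noe_set(pool[1:2], 6, noise_sd = 0.1, seed = 38)
  cfg <- selector_config(steps = 2000, size_min = 2, size_max = 5,
                         size_init = 3, seed = 39)
  st <- select_ensemble(pool, restraints, cfg)
  expect_gte(length(st$members), 2)
  expect_lte(length(st$members), 5)
  expect_error(select_ensemble(pool[1:2], restraints,
                               selector_config(size_min = 2, size_init = 2)),
               "larger than size_min")
  expect_error(selector_config(size_min = 5, size_init = 3), "size_min")
})

test_that("exhaustive enumeration refuses combinatorial blowups", {
  pool <- selector_pool()
  restraints <- make_noe_set(pool[1:2], 5, noise_sd = 0.1, seed = 40)
  expect_error(exhaustive_select(pool, restraints, 1, 12, max_subsets = 100),
               "enumeration bound")
  # empty restraints: any minimal subset scores zero
  empty <- lanthifold:::validate_restraints(
    data.frame(resA = integer(0), atomA = character(0), resB = integer(0),
               atomB = character(0), distance = numeric(0),
               kind = character(0)))
  ex <- exhaustive_select(pool[1:4], empty, 1, 2)
  expect_equal(ex$score, 0)
  expect_equal(length(ex$members), 1L)
})

test_that("two-stage filtering reproduces a hand-computed selection", {
  # crafted 250-model metric tables with a known answer
  set.seed(41)
  rsc <- runif(250); en <- runif(250)
  st <- select_by_filter(rsc, en, n_restraint = 200, n_final = 20)
  # spreadsheet-style recomputation: rank columns independently
  keep1 <- which(rank(rsc, ties.method = "first") <= 200)
  keep2 <- keep1[rank(en[keep1], ties.method = "first") <= 20]
  expect_setequal(st$members, keep2)
  # coinciding rankings: top 20 by either metric
  v <- sort(runif(50))
  st2 <- select_by_filter(v, v, n_restraint = 30, n_final = 20)
  expect_identical(st2$members, 1:20)
  expect_error(select_by_filter(v, v, n_restraint = 10, n_final = 20),
               "n_final")
  expect_error(select_by_filter(v[1:5], v[1:5], 4, 6), "n_final|smaller")
})

test_that("worsening moves are accepted at the Boltzmann rate", {
  set.seed(42)
  delta <- 0.8; temp <- 1.3
  n <- 1e4
  acc <- sum(vapply(seq_len(n), function(i)
    metropolis_accept(delta, temp), logical(1)))
  p <- exp(-delta / temp)
  # binomial 99% bounds
  expect_lt(abs(acc / n - p), 2.58 * sqrt(p * (1 - p) / n))
  # improving moves always accepted
  expect_true(all(vapply(1:100, function(i)
    metropolis_accept(-0.1, temp), logical(1))))
})

test_that("chemical shifts steer selection through the masked mean", {
  pool <- selector_pool()[1:6]
  restraints <- make_noe_set(pool[1:6], 4, noise_sd = 2, seed = 43)
  # observed shifts equal model 2's predictions; prediction tables for all
  topo <- pool[[1]]$topology
  mask <- lanthifold:::shift_inclusion_mask(topo)
  resn <- which(mask)[1:3]
  pred <- do.call(rbind, lapply(seq_along(pool), function(m)
    data.frame(model = m, resno = resn, nucleus = "CA",
               shift = 50 + m + seq_along(resn))))
  obs <- data.frame(resno = resn, nucleus = "CA",
                    shift = 50 + 2 + seq_along(resn))
  cfg <- selector_config(steps = 4000, size_min = 1, size_max = 2,
                         size_init = 1, temperature = 1e-3, seed = 44,
                         shift_weight = 50)
  st <- select_ensemble(pool, restraints, cfg, shifts = list(
    predicted = pred, observed = obs))
  expect_true(2L %in% st$members)
})

test_that("noncanonical neighbourhoods are excluded from the shift mask", {
  topo <- fixture_topology()  # Dha at 8, Cys-acceptors at 6 and 13
  mask <- lanthifold:::shift_inclusion_mask(topo)
  expect_false(mask[[8]])   # Dha itself
  expect_false(mask[[7]])   # neighbours of Dha
  expect_false(mask[[9]])
  expect_true(mask[[4]])    # canonical with canonical neighbours
})
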