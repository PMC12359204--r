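small_cfg <- function(...) sampler_config(burn_in = 20, production = 80,
                                          move_sd = 4, ...)

test_that("unstructured sampling produces closed, scored, sorted pools", {
  topo <- ring8_topology()
  cfg <- small_cfg(n_models = 12, seed = 51)
  pool <- sample_unstructured(topo, cfg)
  expect_gte(length(pool), 10)  # closure succeeds for nearly all models
  g <- crosslink_geometry("lanthionine")
  for (conf in pool) {
    st <- lanthifold:::closure_state(conf, topo$rings[1, ], g)
    expect_lt(st$gap, g$bond_tol)
  }
  sc <- attr(pool, "scores")
  expect_equal(nrow(sc), length(pool))
  expect_true(!is.unsorted(sc$total))
})

test_that("ring-free topologies sample pure torsion chains", {
  topo <- parse_topology("seq AAAAAA")
  pool <- sample_unstructured(topo, small_cfg(n_models = 5, seed = 52))
  expect_length(pool, 5)
})

test_that("sampling is deterministic under a fixed seed", {
  topo <- ring8_topology()
  cfg <- small_cfg(n_models = 4, seed = 53)
  a <- sample_unstructured(topo, cfg)
  b <- sample_unstructured(topo, cfg)
  expect_equal(length(a), length(b))
  for (i in seq_along(a)) expect_identical(a[[i]]$xyz, b[[i]]$xyz)
})

test_that("refinement never worsens the score and fixes nothing at a minimum", {
  topo <- ring8_topology()
  score <- simple_score(topo)
  conf <- ring8_closed()
  s0 <- score$eval(conf)$total
  set.seed(54)
  out <- refine(conf, score, small_cfg())
  expect_lte(attr(out, "refine")$final_score, s0 + 1e-9)
  # zero move magnitude: returned unchanged
  frozen <- refine(conf, score, sampler_config(burn_in = 5, production = 20,
                                               move_sd = 0))
  expect_equal(frozen$xyz, conf$xyz, tolerance = 1e-12)
})

test_that("refinement relieves steric clashes", {
  topo <- parse_topology("seq AAAAAAAA")
  score <- simple_score(topo)
  # a deliberately self-colliding compact chain
  clashing <- build_conformer(topo, cbind(rep(-170, 8), rep(170, 8)))
  clashing <- rotate_torsion(clashing, 4, "phi", 160)
  set.seed(55)
  improved <- 0
  for (k in 1:10) {
    out <- refine(clashing, score, sampler_config(burn_in = 10,
                                                  production = 60,
                                                  move_sd = 8))
    if (score$eval(out)$terms[["clash"]] <=
          score$eval(clashing)$terms[["clash"]]) improved <- improved + 1
  }
  expect_gte(improved, 9)
})

test_that("perturbing a start structure localizes variance at flexible linkers", {
  # helix with a central glycine linker; everything else stays near the start
  topo <- parse_topology("seq AAAAGGAAAA")
  start <- build_conformer(topo, cbind(rep(-57, 10), rep(-47, 10)))
  cfg <- sampler_config(n_models = 6, burn_in = 0, production = 0, seed = 56)
  copies <- sample_from_start(start, topo, cfg)
  for (c in copies) expect_equal(c$xyz, start$xyz, tolerance = 1e-12)

  expect_error(sample_from_start(start, ring8_topology(), cfg), "match")
})

test_that("the two-stage schedule lowers the mean score stage over stage", {
  topo <- ring8_topology()
  cfg <- sampler_config(n_models = 10, burn_in = 10, production = 60,
                        move_sd = 5, top_fraction = 0.3, seed = 57)
  pool <- sample_pipeline(topo, cfg)
  sm <- attr(pool, "stage_means")
  expect_lt(sm[["filtered"]], sm[["sampled"]] + 1e-9)
  expect_lt(sm[["refined"]], sm[["filtered"]] + 1e-9)
})
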