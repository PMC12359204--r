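# Conformer pool generation.
#
# Two pipelines mirror the two lanthipeptide structure classes:
#  * unstructured peptides: backbone torsions drawn from the residue torsion
#    tables, thioether rings closed by CCD (trying ring-order permutations),
#    then Metropolis refinement with small and shear torsion moves;
#  * helical (or otherwise pre-structured) peptides: a user-supplied start
#    conformer perturbed by the same refinement machinery at elevated move
#    magnitudes.
#
# Fragment insertion and backrub moves of full-scale protocols are replaced
# by small/shear moves: they need no fragment library and respect the ring
# constraint through the crosslink score term.

#' Sampler configuration
#'
#' Defaults are scaled for desk-size pools; `n_models` in the hundreds of
#' thousands with `burn_in = 1000` / `production = 9000` reproduces the
#' faithful large-scale schedule.
#'
#' @param n_models models to generate (default 500)
#' @param burn_in Metropolis burn-in steps per refinement (default 1000)
#' @param production production steps per refinement; the best-seen
#'   production conformer is returned (default 9000)
#' @param move_sd small-move magnitude, degrees (sd of the torsion delta)
#' @param shear_prob probability that a move is a shear (compensating
#'   psi(i-1)/phi(i) pair) rather than a single-torsion small move
#' @param top_fraction fraction of the pool passed from the sampling stage to
#'   refinement (default 0.025)
#' @param temperature Metropolis temperature in SimpleScore units
#' @param max_ring_orders cap on ring-closure order permutations tried per
#'   model (default 24; random subsample beyond 4 rings)
#' @param max_attempts_per_model random restarts before a model is dropped
#' @param seed optional RNG seed
#' @return list of class `sampler_config`
#' @export
sampler_config <- function(n_models = 500, burn_in = 1000, production = 9000,
                           move_sd = 10, shear_prob = 0.3,
                           top_fraction = 0.025, temperature = 1,
                           max_ring_orders = 24, max_attempts_per_model = 5,
                           seed = NULL) {
  stopifnot(burn_in >= 0, production >= 0, top_fraction > 0, top_fraction <= 1,
            n_models >= 1)
  structure(list(n_models = n_models, burn_in = burn_in,
                 production = production, move_sd = move_sd,
                 shear_prob = shear_prob, top_fraction = top_fraction,
                 temperature = temperature,
                 max_ring_orders = max_ring_orders,
                 max_attempts_per_model = max_attempts_per_model,
                 seed = seed),
            class = "sampler_config")
}

all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1L))
    for (pos in seq_len(k))
      out <- c(out, list(append(p, k, after = pos - 1L)))
  out
}

ring_orders <- function(n_rings, max_orders) {
  if (n_rings == 0L) return(list(integer(0)))
  if (n_rings <= 4L) {
    perms <- all_permutations(n_rings)
    if (length(perms) > max_orders) perms <- perms[seq_len(max_orders)]
    return(perms)
  }
  lapply(seq_len(max_orders), function(i) sample.int(n_rings))
}

# draw a full backbone torsion set from the residue tables
draw_torsions <- function(topology, temperature = 1) {
  n <- nrow(topology$residues)
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("phi", "psi")))
  for (i in seq_len(n))
    out[i, ] <- sample_torsion(residue_torsion_table(topology, i), 1,
                               temperature = temperature)
  out
}

rings_closed_ok <- function(conf) {
  rings <- conf$topology$rings
  for (k in seq_len(nrow(rings))) {
    g <- crosslink_geometry(rings$type[[k]])
    st <- closure_state(conf, rings[k, ], g)
    if (st$gap >= g$bond_tol || any(st$angle_dev >= g$angle_tol))
      return(FALSE)
  }
  TRUE
}

#' Generate a conformer pool for an unstructured lanthipeptide
#'
#' For each model, backbone torsions are drawn from the residue torsion
#' tables and every ring is closed by CCD, trying ring-closure order
#' permutations until one converges; models whose rings cannot be closed
#' after the configured restarts are dropped. The returned pool is sorted by
#' SimpleScore (best first) and carries the per-model score table as
#' `attr(x, "scores")`.
#'
#' @param topology a `lanthi_topology`
#' @param config a [sampler_config()]
#' @param score optional [simple_score()] (built with defaults if omitted)
#' @return list of `lanthi_conformer`, sorted by total score
#' @export
sample_unstructured <- function(topology, config = sampler_config(),
                                score = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(score)) score <- simple_score(topology)
  n_rings <- nrow(topology$rings)
  pool <- list()
  dropped <- 0L
  for (m in seq_len(config$n_models)) {
    got <- NULL
    for (attempt in seq_len(config$max_attempts_per_model)) {
      conf <- build_conformer(topology, draw_torsions(topology))
      for (ord in ring_orders(n_rings, config$max_ring_orders)) {
        cand <- close_all_rings(conf, order = ord)
        if (attr(cand, "closure")$converged) { got <- cand; break }
      }
      if (!is.null(got)) break
    }
    if (is.null(got)) dropped <- dropped + 1L else pool[[length(pool) + 1L]] <- got
  }
  if (length(pool) == 0L)
    stop(sprintf(
      "no model achieved ring closure (%d attempts each for %d models)",
      config$max_attempts_per_model, config$n_models))
  totals <- vapply(pool, function(c) score$eval(c)$total, numeric(1))
  ord <- order(totals)
  pool <- pool[ord]
  attr(pool, "scores") <- data.frame(model = seq_along(pool),
                                     total = totals[ord])
  attr(pool, "dropped") <- dropped
  pool
}

# one Metropolis torsion move; returns list(conf, delta_desc)
propose_move <- function(conf, move_sd, shear_prob) {
  n <- nrow(conf$topology$residues)
  if (n >= 2L && stats::runif(1) < shear_prob) {
    i <- sample(seq(2L, n), 1L)
    delta <- stats::rnorm(1, 0, move_sd)
    conf <- rotate_torsion(conf, i - 1L, "psi", delta)
    conf <- rotate_torsion(conf, i, "phi", -delta)
  } else {
    i <- sample.int(n, 1L)
    which <- if (stats::runif(1) < 0.5) "phi" else "psi"
    conf <- rotate_torsion(conf, i, which, stats::rnorm(1, 0, move_sd))
  }
  conf
}

#' Metropolis refinement of one conformer
#'
#' Runs `burn_in` then `production` Metropolis steps of small (single
#' torsion) and shear (compensating psi(i-1)/phi(i)) moves against the
#' SimpleScore; the crosslink term keeps rings closed. Returns the
#' lowest-scoring conformer seen during production (or the start, if nothing
#' better was visited), so the returned score never exceeds the input score.
#'
#' @param conf a ring-closed `lanthi_conformer`
#' @param score a [simple_score()]
#' @param config a [sampler_config()] (only the schedule/move fields are
#'   used)
#' @return refined conformer; `attr(x, "refine")` carries start/final scores
#' @export
refine <- function(conf, score, config = sampler_config()) {
  cur <- conf
  cur_score <- score$eval(cur)$total
  best <- cur; best_score <- cur_score
  total_steps <- config$burn_in + config$production
  for (step in seq_len(total_steps)) {
    prop <- propose_move(cur, config$move_sd, config$shear_prob)
    prop_score <- score$eval(prop)$total
    if (metropolis_accept(prop_score - cur_score, config$temperature)) {
      cur <- prop; cur_score <- prop_score
      if (step > config$burn_in && cur_score < best_score) {
        best <- cur; best_score <- cur_score
      }
    }
  }
  attr(best, "refine") <- list(start_score = score$eval(conf)$total,
                               final_score = best_score)
  best
}

#' Generate a pool by perturbing a start structure
#'
#' The helical-pipeline entry point: the caller supplies a start conformer
#' matching the topology (e.g. built from a helical model after mutation to
#' the lanthipeptide sequence and ring closure); each pool member is an
#' independent refinement of the start at the configured move magnitude,
#' with rings re-closed if a trajectory drifts them open.
#'
#' @param start a `lanthi_conformer`
#' @param topology the topology `start` must match
#' @param config a [sampler_config()]
#' @param score optional [simple_score()]
#' @return list of `lanthi_conformer`, sorted by total score, with
#'   `attr(x, "scores")`
#' @export
sample_from_start <- function(start, topology, config = sampler_config(),
                              score = NULL) {
  if (!identical(start$topology$residues$code, topology$residues$code))
    stop("start structure does not match the topology")
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(score)) score <- simple_score(topology)
  pool <- vector("list", config$n_models)
  for (m in seq_len(config$n_models)) {
    conf <- if (config$burn_in + config$production > 0)
      refine(start, score, config) else start
    if (nrow(topology$rings) > 0L && !rings_closed_ok(conf)) {
      conf <- close_all_rings(conf)
      if (!attr(conf, "closure")$converged) conf <- start
    }
    pool[[m]] <- conf
  }
  totals <- vapply(pool, function(c) score$eval(c)$total, numeric(1))
  ord <- order(totals)
  pool <- pool[ord]
  attr(pool, "scores") <- data.frame(model = seq_along(pool),
                                     total = totals[ord])
  pool
}

#' Two-stage sample-filter-refine pipeline
#'
#' Initial sampling, top-fraction filter by SimpleScore, then Metropolis
#' refinement of the survivors; the standard schedule for unstructured
#' lanthipeptides.
#'
#' @param topology a `lanthi_topology`
#' @param config a [sampler_config()]
#' @param score optional [simple_score()]
#' @return refined pool sorted by score, with `attr(x, "scores")` and
#'   `attr(x, "stage_means")` (mean SimpleScore after each stage)
#' @export
sample_pipeline <- function(topology, config = sampler_config(),
                            score = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(score)) score <- simple_score(topology)
  raw <- sample_unstructured(topology, config, score)
  raw_scores <- attr(raw, "scores")$total
  keep <- max(1L, ceiling(config$top_fraction * length(raw)))
  top <- raw[seq_len(keep)]  # already sorted best-first
  refined <- lapply(top, refine, score = score, config = config)
  totals <- vapply(refined, function(c) score$eval(c)$total, numeric(1))
  ord <- order(totals)
  refined <- refined[ord]
  attr(refined, "scores") <- data.frame(model = seq_along(refined),
                                        total = totals[ord])
  attr(refined, "stage_means") <- c(sampled = mean(raw_scores),
                                    filtered = mean(raw_scores[seq_len(keep)]),
                                    refined = mean(totals))
  refined
}
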