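# Monte-Carlo selection of a conformer ensemble that satisfies
# ensemble-averaged NOE restraints.
#
# The search state is a subset of pool indices. Moves add a member, remove a
# member, or swap a member with a non-member; moves that would leave the
# configured size bounds are rejected as invalid. Moves are accepted by the
# Metropolis criterion on the restraint score (sum of squared residuals of
# the ensemble-averaged distances), and the lowest-scoring state ever seen
# is returned.

#' Selector configuration
#'
#' @param steps Monte-Carlo steps (default 500000, the faithful preset; far
#'   fewer suffice for small pools)
#' @param size_min,size_max allowed ensemble size bounds (defaults 10 / 30)
#' @param size_init initial ensemble size (default 20)
#' @param temperature Metropolis temperature in score units (Angstrom^2)
#' @param seed optional RNG seed for a reproducible trajectory
#' @param shift_weight weight of the chemical-shift term when shift tables
#'   are supplied
#' @param allow_duplicates allow the same conformer to occupy several ensemble
#'   slots (up-weighting within the equal-population formalism); off by
#'   default
#' @param mode restraint residual mode, see [score_ensemble()]
#' @param log_every record the trajectory every this many steps (0 = off)
#' @return list of class `selector_config`
#' @export
selector_config <- function(steps = 500000, size_min = 10, size_max = 30,
                            size_init = 20, temperature = 1, seed = NULL,
                            shift_weight = 1, allow_duplicates = FALSE,
                            mode = "kind", log_every = 0) {
  stopifnot(size_min <= size_init, size_init <= size_max, steps > 0,
            temperature > 0)
  structure(list(steps = steps, size_min = size_min, size_max = size_max,
                 size_init = size_init, temperature = temperature,
                 seed = seed, shift_weight = shift_weight,
                 allow_duplicates = allow_duplicates, mode = mode,
                 log_every = log_every),
            class = "selector_config")
}

#' Metropolis acceptance decision
#'
#' Accepts an improving move always and a worsening move with probability
#' `exp(-delta / temperature)`. Uses R's global RNG stream.
#' @param delta score change of the proposed move (positive = worse)
#' @param temperature Metropolis temperature, same units as `delta`
#' @return logical
#' @export
metropolis_accept <- function(delta, temperature) {
  delta <= 0 || stats::runif(1) < exp(-delta / temperature)
}

subset_score <- function(D6, restraints, idx, mode) {
  d_star <- (colSums(D6[idx, , drop = FALSE]) / length(idx))^(-1 / 6)
  sum(restraint_residuals(d_star, restraints, mode)^2)
}

# chemical-shift inclusion mask: canonical residue with canonical sequence
# neighbours (a missing terminal neighbour does not disqualify)
shift_inclusion_mask <- function(topology) {
  res <- topology$residues
  canon <- res$code %in% AA1 & res$chirality == "L"
  n <- length(canon)
  ok <- canon
  for (i in seq_len(n)) {
    if (i > 1L && !canon[[i - 1L]]) ok[[i]] <- FALSE
    if (i < n && !canon[[i + 1L]]) ok[[i]] <- FALSE
  }
  ok
}

# Build the per-model predicted-shift matrix restricted to masked-in
# (residue, nucleus) entries with observations. shifts: list(predicted =
# data.frame(model, resno, nucleus, shift), observed = data.frame(resno,
# nucleus, shift)).
shift_matrices <- function(topology, shifts, n_models) {
  mask <- shift_inclusion_mask(topology)
  obs <- shifts$observed
  obs <- obs[mask[obs$resno], , drop = FALSE]
  if (nrow(obs) == 0L) return(NULL)
  key <- paste(obs$resno, obs$nucleus)
  pred <- shifts$predicted
  P <- matrix(NA_real_, n_models, nrow(obs))
  pk <- paste(pred$resno, pred$nucleus)
  for (j in seq_len(nrow(obs))) {
    rows <- pred[pk == key[[j]], , drop = FALSE]
    P[rows$model, j] <- rows$shift
  }
  keep <- colSums(is.na(P)) == 0
  if (!any(keep)) return(NULL)
  list(P = P[, keep, drop = FALSE], obs = obs$shift[keep])
}

new_ensemble_state <- function(members, score, extra = list()) {
  structure(c(list(members = sort(members), score = score), extra),
            class = "ensemble_state")
}

#' @export
print.ensemble_state <- function(x, ...) {
  cat(sprintf("ensemble of %d members, score %.4f\n  members: %s\n",
              length(x$members), x$score,
              paste(x$members, collapse = " ")))
  invisible(x)
}

#' Monte-Carlo ensemble selection
#'
#' Searches subsets of the conformer pool for the ensemble whose
#' r^-6-averaged distances best satisfy the NOE restraints. Starts from a
#' random subset of `size_init` members; each step proposes (uniformly) an
#' add, remove, or swap move, rejects it outright if it violates the size
#' bounds, and otherwise applies the Metropolis criterion at the configured
#' temperature. The lowest-scoring state seen over the whole trajectory is
#' returned. When predicted/observed chemical-shift tables are supplied, the
#' summed squared deviation of the ensemble-mean predicted shift (shifts
#' average linearly, unlike NOE intensities) over canonical-context residues
#' is added to the score with weight `shift_weight`.
#'
#' @param pool list of `lanthi_conformer`
#' @param restraints restraint data.frame (see [read_restraints()])
#' @param config a [selector_config()]
#' @param shifts optional list with `predicted` (data.frame `model`, `resno`,
#'   `nucleus`, `shift`) and `observed` (data.frame `resno`, `nucleus`,
#'   `shift`)
#' @return an `ensemble_state`: members (pool indices), score, plus the
#'   accepted-move count and optional trajectory log
#' @export
select_ensemble <- function(pool, restraints, config = selector_config(),
                            shifts = NULL) {
  n <- length(pool)
  if (n <= config$size_min)
    stop(sprintf("pool (%d) must be larger than size_min (%d)",
                 n, config$size_min))
  if (!is.null(config$seed)) set.seed(config$seed)
  D6 <- restraint_d6_matrix(pool, restraints)
  SH <- if (!is.null(shifts))
    shift_matrices(pool[[1]]$topology, shifts, n) else NULL
  score_of <- function(idx) {
    s <- subset_score(D6, restraints, idx, config$mode)
    if (!is.null(SH)) {
      mean_pred <- colSums(SH$P[idx, , drop = FALSE]) / length(idx)
      s <- s + config$shift_weight * sum((mean_pred - SH$obs)^2)
    }
    s
  }
  size0 <- min(config$size_init, n - 1L)
  cur <- sample.int(n, size0, replace = config$allow_duplicates)
  cur_score <- score_of(cur)
  best <- cur; best_score <- cur_score
  accepted <- 0L
  traj <- if (config$log_every > 0)
    data.frame(step = 0L, size = length(cur), score = cur_score) else NULL
  for (step in seq_len(config$steps)) {
    move <- sample.int(3L, 1L)
    prop <- NULL
    if (move == 1L && length(cur) < config$size_max) {        # add
      candidates <- if (config$allow_duplicates) seq_len(n)
                    else setdiff(seq_len(n), cur)
      if (length(candidates) > 0L)
        prop <- c(cur, candidates[[sample.int(length(candidates), 1L)]])
    } else if (move == 2L && length(cur) > config$size_min) { # remove
      prop <- cur[-sample.int(length(cur), 1L)]
    } else if (move == 3L) {                                  # swap
      out <- sample.int(length(cur), 1L)
      candidates <- if (config$allow_duplicates) seq_len(n)
                    else setdiff(seq_len(n), cur)
      if (length(candidates) > 0L) {
        prop <- cur
        prop[[out]] <- candidates[[sample.int(length(candidates), 1L)]]
      }
    }
    if (is.null(prop)) next
    prop_score <- score_of(prop)
    if (metropolis_accept(prop_score - cur_score, config$temperature)) {
      cur <- prop; cur_score <- prop_score
      accepted <- accepted + 1L
      if (cur_score < best_score) { best <- cur; best_score <- cur_score }
    }
    if (config$log_every > 0 && step %% config$log_every == 0L)
      traj <- rbind(traj, data.frame(step = step, size = length(cur),
                                     score = cur_score))
  }
  new_ensemble_state(best, best_score,
                     list(accepted = accepted, steps = config$steps,
                          trajectory = traj))
}

#' Exhaustive ensemble selection (test oracle)
#'
#' Enumerates every subset within the size bounds and returns the global
#' optimum of the restraint score. Intended as an independent oracle for
#' small pools; refuses combinatorially large problems.
#'
#' @param pool list of `lanthi_conformer`
#' @param restraints restraint data.frame
#' @param size_min,size_max subset size bounds
#' @param mode residual mode, see [score_ensemble()]
#' @param max_subsets enumeration safety bound (default 1e6)
#' @return an `ensemble_state`
#' @export
exhaustive_select <- function(pool, restraints, size_min = 1,
                              size_max = length(pool), mode = "kind",
                              max_subsets = 1e6) {
  n <- length(pool)
  sizes <- seq(max(1L, size_min), min(n, size_max))
  total <- sum(choose(n, sizes))
  if (total > max_subsets)
    stop(sprintf("%.0f subsets exceed the enumeration bound %g",
                 total, max_subsets))
  D6 <- restraint_d6_matrix(pool, restraints)
  best <- NULL; best_score <- Inf
  for (k in sizes) {
    combos <- utils::combn(n, k)
    for (c in seq_len(ncol(combos))) {
      s <- subset_score(D6, restraints, combos[, c], mode)
      if (s < best_score) { best_score <- s; best <- combos[, c] }
    }
  }
  new_ensemble_state(best, best_score)
}

#' Two-stage filter selection from a scored pool
#'
#' The relax-and-filter alternative to the Monte-Carlo search: keep the
#' `n_restraint` models that best agree with the experimental NOE
#' measurements, then take the `n_final` lowest-energy models among them.
#' Ties are broken by stable input order.
#'
#' @param restraint_scores per-model restraint agreement (lower = better)
#' @param energies per-model energies (lower = better)
#' @param n_restraint size of the restraint-agreement cut (default 200)
#' @param n_final final ensemble size (default 20)
#' @return an `ensemble_state` whose `score` is the summed restraint score of
#'   the chosen members
#' @export
select_by_filter <- function(restraint_scores, energies, n_restraint = 200,
                             n_final = 20) {
  n <- length(restraint_scores)
  if (length(energies) != n)
    stop("restraint_scores and energies must have equal length")
  if (n_final > n_restraint) stop("n_final must be <= n_restraint")
  if (n < n_final) stop(sprintf("pool (%d) smaller than n_final (%d)", n, n_final))
  stage1 <- order(restraint_scores)[seq_len(min(n_restraint, n))]
  stage2 <- stage1[order(energies[stage1])][seq_len(n_final)]
  new_ensemble_state(stage2, sum(restraint_scores[stage2]))
}
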