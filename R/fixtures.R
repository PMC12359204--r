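# Deterministic synthetic fixtures: multi-state conformer pools with known
# ground truth, NOE sets computed from planted mixtures, and ring-flip
# conformers for the atropisomer classifier. Everything is reproducible from
# (recipe, seed) alone.

#' Default synthetic lanthipeptide topology
#'
#' A 15-residue peptide with two adjacent lanthionine rings and one
#' dehydroalanine: small enough for exhaustive ensemble enumeration, rich
#' enough to exercise ring closure, torsion tables and atropisomer probes.
#' @return a `lanthi_topology`
#' @export
fixture_topology <- function() {
  parse_topology(c("seq AAAAACA[DHA]AAAACAA",
                   "ring 2-6 lan", "ring 9-13 lan"))
}

#' Fixture recipe
#'
#' @param topology a `lanthi_topology` (default [fixture_topology()])
#' @param n_states planted ground-truth states (default 2)
#' @param n_decoys decoy conformers (default 40)
#' @param decoy_sd torsion perturbation of decoys relative to a random
#'   planted state, degrees (default 60)
#' @param noise_sd Gaussian noise added to generated NOE distances, Angstrom
#'   (default 0.1)
#' @param n_restraints restraints per generated NOE set (default 50)
#' @param min_state_rmsd minimum pairwise backbone RMSD between planted
#'   states, Angstrom (default 1)
#' @param seed RNG seed fixing every output
#' @return list of class `fixture_recipe`
#' @export
fixture_recipe <- function(topology = fixture_topology(), n_states = 2,
                           n_decoys = 40, decoy_sd = 60, noise_sd = 0.1,
                           n_restraints = 50, min_state_rmsd = 1,
                           seed = 1) {
  structure(list(topology = topology, n_states = n_states,
                 n_decoys = n_decoys, decoy_sd = decoy_sd,
                 noise_sd = noise_sd, n_restraints = n_restraints,
                 min_state_rmsd = min_state_rmsd, seed = seed),
            class = "fixture_recipe")
}

# one ring-closed random conformer, or NULL after `tries` failures
random_closed_conformer <- function(topology, tries = 10) {
  for (t in seq_len(tries)) {
    conf <- build_conformer(topology, draw_torsions(topology))
    for (ord in ring_orders(nrow(topology$rings), 24)) {
      cand <- close_all_rings(conf, order = ord)
      if (attr(cand, "closure")$converged) return(cand)
    }
  }
  NULL
}

#' Multi-state pool with planted ground truth
#'
#' Draws `n_states` ring-closed conformers that are mutually separated by at
#' least `min_state_rmsd` backbone RMSD, then `n_decoys` decoys obtained by
#' perturbing a random state's torsions by `decoy_sd` degrees and re-closing
#' the rings. Labels identify every member's origin.
#'
#' @param recipe a [fixture_recipe()]
#' @return list: `pool` (states first, then decoys), `labels` (character,
#'   `"state<k>"` / `"decoy"`), `state_indices`
#' @export
make_two_state_pool <- function(recipe = fixture_recipe()) {
  set.seed(recipe$seed)
  topo <- recipe$topology
  states <- list()
  for (tries in seq_len(50 * recipe$n_states)) {
    cand <- random_closed_conformer(topo)
    if (is.null(cand)) next
    far <- all(vapply(states, function(s)
      backbone_rmsd(cand, s) > recipe$min_state_rmsd, logical(1)))
    if (far) states[[length(states) + 1L]] <- cand
    if (length(states) == recipe$n_states) break
  }
  if (length(states) < recipe$n_states)
    stop("could not plant states with the required mutual RMSD separation")
  decoys <- list()
  while (length(decoys) < recipe$n_decoys) {
    base <- states[[sample.int(length(states), 1L)]]
    tor <- as.matrix(measure_torsions(base)[, c("phi", "psi")])
    tor <- tor + matrix(stats::rnorm(length(tor), 0, recipe$decoy_sd),
                        nrow(tor), 2)
    conf <- build_conformer(topo, tor)
    for (ord in ring_orders(nrow(topo$rings), 24)) {
      cand <- close_all_rings(conf, order = ord)
      if (attr(cand, "closure")$converged) {
        decoys[[length(decoys) + 1L]] <- cand
        break
      }
    }
  }
  pool <- c(states, decoys)
  labels <- c(sprintf("state%d", seq_along(states)),
              rep("decoy", length(decoys)))
  list(pool = pool, labels = labels, state_indices = seq_along(states))
}

# eligible NOE-visible atom names for one residue of the minimal atom model
eligible_noe_atoms <- function(topology, resno) {
  code <- topology$residues$code[[resno]]
  out <- character(0)
  if (code != "PRO") out <- c(out, "HN")
  out <- c(out, switch(code, GLY = "QA", DHA = NULL, DHB = NULL, "HA"))
  out <- c(out, switch(code, ALA = "QB", ABU = "QG", THR = "QG2", NULL))
  out
}

#' Generate an NOE restraint set from a planted ensemble
#'
#' Candidate restraints are random pairs of amide/alpha/methyl (pseudo)atom
#' groups on different residues whose r^-6 ensemble-averaged distance over
#' the given members is below `max_distance` (an NOE must be observable);
#' `d_obs` is that ensemble-averaged distance plus Gaussian noise, truncated
#' at 0.5 Angstrom.
#'
#' @param members list of `lanthi_conformer` (the planted equal mixture)
#' @param n_restraints number of restraints to draw
#' @param noise_sd Gaussian noise sd, Angstrom
#' @param seed optional RNG seed
#' @param kind `"target"` (default) or `"upper_limit"`
#' @param max_distance observability cutoff on d*, Angstrom (default 7)
#' @return a `noe_restraints` data.frame
#' @export
make_noe_set <- function(members, n_restraints = 50, noise_sd = 0.1,
                         seed = NULL, kind = "target", max_distance = 7) {
  if (length(members) == 0L) stop("empty member set")
  if (!is.null(seed)) set.seed(seed)
  topo <- members[[1]]$topology
  n <- nrow(topo$residues)
  cand <- list()
  for (i in seq_len(n - 1L))
    for (j in seq((i + 1L), n))
      for (a in eligible_noe_atoms(topo, i))
        for (b in eligible_noe_atoms(topo, j))
          cand[[length(cand) + 1L]] <- list(resA = i, atomA = a,
                                            resB = j, atomB = b)
  if (length(cand) == 0L) stop("no eligible atom pairs")
  d_star <- vapply(cand, function(p)
    ensemble_average_distance(members, c(p, distance = 1)), numeric(1))
  ok <- which(d_star <= max_distance)
  if (length(ok) == 0L) stop("no eligible atom pairs within the NOE cutoff")
  pick <- ok[sample.int(length(ok), min(n_restraints, length(ok)))]
  obs <- pmax(0.5, d_star[pick] + stats::rnorm(length(pick), 0, noise_sd))
  out <- data.frame(
    resA = vapply(cand[pick], `[[`, numeric(1), "resA"),
    atomA = vapply(cand[pick], `[[`, character(1), "atomA"),
    resB = vapply(cand[pick], `[[`, numeric(1), "resB"),
    atomB = vapply(cand[pick], `[[`, character(1), "atomB"),
    distance = obs, kind = kind, stringsAsFactors = FALSE)
  validate_restraints(out)
}

#' Ring-flipped conformer (atropisomer fixture)
#'
#' Mirrors the atoms of the ring-span residues through the best-fit plane of
#' the ring atom set, then re-runs ring closure. Mirroring is an isometry of
#' the span, so the thioether bond and all intra-span geometry survive
#' exactly and [close_ring()] is normally a no-op fixed point; the junction
#' bonds to the first residues outside the span absorb the (small) mirror
#' displacement. Atoms outside the span do not move at all. The flip is an
#' involution: flipping twice restores the original. This is a synthetic
#' classifier fixture -- the mirrored span has inverted local chirality and
#' is not claimed to be an accessible conformation.
#'
#' @param conf a ring-closed `lanthi_conformer`
#' @param ring one ring of the topology
#' @return the flipped conformer
#' @export
make_ring_flip <- function(conf, ring) {
  ring <- as.list(ring)
  sel <- ring_atom_selection(ring)
  P <- selection_xyz(conf, sel)
  ctr <- colMeans(P)
  sv <- svd(sweep(P, 2, ctr))
  normal <- sv$v[, 3]
  span <- ring_span(ring)
  rows <- which(conf$atoms$resno >= span[1] & conf$atoms$resno <= span[2])
  disp <- sweep(conf$xyz[rows, , drop = FALSE], 2, ctr)
  conf$xyz[rows, ] <- conf$xyz[rows, , drop = FALSE] -
    2 * (disp %*% normal) %*% t(normal)
  out <- close_ring(conf, ring)
  if (!attr(out, "closure")$converged)
    stop("ring closure failed after the flip")
  out
}

#' Write a self-contained fixture directory
#'
#' Emits a topology file, a multi-model pool PDB, a restraint TSV generated
#' from the planted states, and a labels TSV.
#'
#' @param dir output directory (created if needed)
#' @param recipe a [fixture_recipe()]
#' @return `dir`, invisibly
#' @export
write_fixture_set <- function(dir, recipe = fixture_recipe()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fx <- make_two_state_pool(recipe)
  noe <- make_noe_set(fx$pool[fx$state_indices], recipe$n_restraints,
                      recipe$noise_sd)
  prov <- sprintf("lanthifold fixture seed=%d", recipe$seed)
  write_topology(recipe$topology, file.path(dir, "topology.txt"))
  write_pool_pdb(fx$pool, file.path(dir, "pool.pdb"), remarks = prov)
  write_restraints(noe, file.path(dir, "restraints.tsv"), remarks = prov)
  utils::write.table(
    data.frame(model = seq_along(fx$pool), label = fx$labels),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
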