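# SimpleScore: a deliberately small conformer score standing on four terms --
# soft inverse-power clash repulsion, torsion-table energies, a backbone
# hydrogen-bond reward, and the crosslink deviation penalty. It is NOT a
# physical force field; its job is to rank conformers sensibly (compact,
# clash-free, Ramachandran-plausible, rings closed) during sampling.

#' Build a SimpleScore function for one topology
#'
#' Precomputes the nonbonded pair lists so repeated evaluation over
#' conformers of the same topology is cheap.
#'
#' Terms (all weights >= 0):
#' * clash: `sum((dmin/d)^6 - 1)` over nonbonded atom pairs closer than their
#'   contact distance `dmin` (2.7 Angstrom heavy-heavy, 1.6 when a hydrogen
#'   is involved); pairs within a residue, between sequence neighbours, or
#'   between a ring's donor and acceptor residues (the bridge) are excluded;
#' * torsion: summed per-residue torsion-table energy;
#' * hbond: -1 per backbone amide-H / carbonyl-O contact (d < 2.5 Angstrom,
#'   N-H...O angle > 120 degrees, residues >= 2 apart);
#' * crosslink: summed [measure_crosslink()] penalties over all rings.
#'
#' @param topology a `lanthi_topology`
#' @param clash_weight,torsion_weight,hbond_weight,crosslink_weight term
#'   weights
#' @param clash_cap per-pair cap on the clash term (guards against the
#'   inverse-power blowing up at near-zero distances)
#' @return list of class `simple_score` with an `eval(conf)` function
#'   returning list(`total`, `terms`)
#' @export
simple_score <- function(topology, clash_weight = 1, torsion_weight = 1,
                         hbond_weight = 1, crosslink_weight = 5,
                         clash_cap = 100) {
  stopifnot(clash_weight >= 0, torsion_weight >= 0, hbond_weight >= 0,
            crosslink_weight >= 0)
  template <- build_conformer(topology,
                              cbind(rep(180, nrow(topology$residues)),
                                    rep(180, nrow(topology$residues))))
  at <- template$atoms
  n <- nrow(at)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ri <- at$resno[pr[, 1]]; rj <- at$resno[pr[, 2]]
  keep <- abs(ri - rj) >= 2L
  rings <- topology$rings
  for (k in seq_len(nrow(rings)))
    keep <- keep & !((ri == rings$donor[[k]] & rj == rings$acceptor[[k]]) |
                       (rj == rings$donor[[k]] & ri == rings$acceptor[[k]]))
  pr <- pr[keep, , drop = FALSE]
  isH <- at$element == "H"
  dmin <- ifelse(isH[pr[, 1]] | isH[pr[, 2]], 1.6, 2.7)
  # backbone hbond donors/acceptors
  hs <- which(at$atom == "H"); os <- which(at$atom == "O")
  ns <- vapply(hs, function(h) which(at$resno == at$resno[[h]] &
                                       at$atom == "N"), integer(1))
  geometries <- lapply(seq_len(nrow(rings)), function(k)
    crosslink_geometry(rings$type[[k]]))

  eval_fn <- function(conf) {
    xyz <- conf$xyz
    dd <- sqrt(rowSums((xyz[pr[, 1], , drop = FALSE] -
                          xyz[pr[, 2], , drop = FALSE])^2))
    viol <- dd < dmin
    clash <- if (any(viol))
      sum(pmin((dmin[viol] / pmax(dd[viol], 0.1))^6 - 1, clash_cap)) else 0
    torsion <- torsion_energy(conf)
    hbond <- 0
    for (a in seq_along(hs)) {
      hpos <- xyz[hs[[a]], ]; npos <- xyz[ns[[a]], ]
      for (b in seq_along(os)) {
        if (abs(at$resno[[hs[[a]]]] - at$resno[[os[[b]]]]) < 2L) next
        opos <- xyz[os[[b]], ]
        d <- vnorm(hpos - opos)
        if (d < 2.5 && angle_deg(npos, hpos, opos) > 120) hbond <- hbond - 1
      }
    }
    crosslink <- 0
    for (k in seq_len(nrow(rings)))
      crosslink <- crosslink +
        measure_crosslink(conf, rings[k, ], geometries[[k]])$total
    terms <- c(clash = clash_weight * clash,
               torsion = torsion_weight * torsion,
               hbond = hbond_weight * hbond,
               crosslink = crosslink_weight * crosslink)
    list(total = sum(terms), terms = terms)
  }
  structure(list(topology = topology, eval = eval_fn,
                 weights = c(clash = clash_weight, torsion = torsion_weight,
                             hbond = hbond_weight,
                             crosslink = crosslink_weight)),
            class = "simple_score")
}

#' Score one conformer
#' @param conf a `lanthi_conformer`
#' @param score a [simple_score()] for the conformer's topology (built on the
#'   fly if omitted)
#' @return list with `total` and the named `terms` vector
#' @export
score_conformer <- function(conf, score = NULL) {
  if (is.null(score)) score <- simple_score(conf$topology)
  score$eval(conf)
}
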