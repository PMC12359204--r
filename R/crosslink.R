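# Thioether crosslink geometry: targets, deviation measurement, and
# cyclic-coordinate-descent ring closure.
#
# The crosslink is the new C-S bond between the donor's beta carbon and the
# acceptor cysteine's SG. Its geometry is described by the bond length, the
# two flanking angles (CA_d-CB_d-SG and CB_d-SG-CB_a), and the three
# dihedrals across the bonded path N_d-CA_d-CB_d-SG-CB_a-CA_a. For
# methyllanthionine an improper dihedral at the donor CB (involving the
# beta-methyl CG) pins the stereocentre created by ring formation, and two
# extra angle terms keep the methyl geometry sane.

#' Crosslink geometry targets
#'
#' Target values and per-term weights for measuring (and steering) a
#' thioether crosslink. Defaults are standard small-molecule thioether
#' values: C-S bond 1.81 Angstrom, sp3 carbon flanking angle 109.5 degrees,
#' C-S-C angle 98 degrees, anti (180 degree) dihedral preferences with soft
#' weights, and a tetrahedral improper of -34.2 degrees at the donor CB for
#' methyllanthionine (sign fixed by the bridge chirality). All values are
#' configurable data, not ground truth.
#'
#' @param ring_type `"lanthionine"` or `"methyllanthionine"`
#' @param cs_bond_length target C-S bond length, Angstrom
#' @param angle_targets two flanking-angle targets, degrees
#'   (CA_d-CB_d-SG, CB_d-SG-CB_a)
#' @param dihedral_targets three dihedral targets, degrees
#'   (N_d-CA_d-CB_d-SG, CA_d-CB_d-SG-CB_a, CB_d-SG-CB_a-CA_a)
#' @param improper_target improper dihedral target at the donor CB, degrees
#'   (methyllanthionine only)
#' @param methyl_angle_targets angle targets CA_d-CB_d-CG_d and SG-CB_d-CG_d,
#'   degrees (methyllanthionine only)
#' @param bond_weight,angle_weight,dihedral_weight,improper_weight per-term
#'   penalty weights (penalty = weight * deviation^2; bond deviations in
#'   Angstrom, angular deviations in degrees)
#' @param bond_tol,angle_tol closure tolerances used by [close_ring()]
#' @return a list of class `crosslink_geometry`
#' @export
crosslink_geometry <- function(ring_type = "lanthionine",
                               cs_bond_length = 1.81,
                               angle_targets = c(109.5, 98),
                               dihedral_targets = c(180, 180, 180),
                               improper_target = -34.2,
                               methyl_angle_targets = c(111.5, 109.5),
                               bond_weight = 1,
                               angle_weight = 5e-4,
                               dihedral_weight = 2e-5,
                               improper_weight = 5e-4,
                               bond_tol = 0.02, angle_tol = 20) {
  stopifnot(cs_bond_length > 0, all(angle_targets > 0 & angle_targets < 180),
            bond_tol > 0, angle_tol > 0)
  structure(list(ring_type = ring_type, cs_bond_length = cs_bond_length,
                 angle_targets = angle_targets,
                 dihedral_targets = dihedral_targets,
                 improper_target = improper_target,
                 methyl_angle_targets = methyl_angle_targets,
                 bond_weight = bond_weight, angle_weight = angle_weight,
                 dihedral_weight = dihedral_weight,
                 improper_weight = improper_weight,
                 bond_tol = bond_tol, angle_tol = angle_tol),
            class = "crosslink_geometry")
}

crosslink_atoms <- function(conf, ring) {
  ring <- as.list(ring)
  list(Nd = atom_xyz(conf, ring$donor, "N"),
       CAd = atom_xyz(conf, ring$donor, "CA"),
       CBd = atom_xyz(conf, ring$donor, "CB"),
       CGd = if (ring$type == "methyllanthionine")
         atom_xyz(conf, ring$donor, "CG") else NULL,
       SG = atom_xyz(conf, ring$acceptor, "SG"),
       CBa = atom_xyz(conf, ring$acceptor, "CB"),
       CAa = atom_xyz(conf, ring$acceptor, "CA"))
}

#' Measure a conformer's crosslink geometry against its targets
#'
#' Reports, for every geometric term of the thioether bridge, the target, the
#' observed value, the absolute deviation (angular terms wrapped to the
#' shortest arc) and the weighted harmonic penalty. Methyllanthionine rings
#' additionally report the donor-CB improper and the two methyl angles.
#'
#' @param conf a `lanthi_conformer`
#' @param ring one ring of the conformer's topology (list or one-row
#'   data.frame)
#' @param geometry a [crosslink_geometry()]; defaults per ring type
#' @return list of class `deviation_report`: `terms` (data.frame `term`,
#'   `unit`, `target`, `observed`, `deviation`, `weight`, `penalty`) and
#'   `total` (sum of penalties)
#' @export
measure_crosslink <- function(conf, ring, geometry = NULL) {
  ring <- as.list(ring)
  if (is.null(geometry)) geometry <- crosslink_geometry(ring$type)
  a <- crosslink_atoms(conf, ring)
  g <- geometry
  term <- function(name, unit, target, observed, weight) {
    dev <- if (unit == "deg") angle_diff(observed, target)
           else abs(observed - target)
    data.frame(term = name, unit = unit, target = target, observed = observed,
               deviation = dev, weight = weight, penalty = weight * dev^2,
               stringsAsFactors = FALSE)
  }
  rows <- list(
    term("bond_CS", "A", g$cs_bond_length, vnorm(a$CBd - a$SG), g$bond_weight),
    term("angle_CAd_CBd_SG", "deg", g$angle_targets[[1]],
         angle_deg(a$CAd, a$CBd, a$SG), g$angle_weight),
    term("angle_CBd_SG_CBa", "deg", g$angle_targets[[2]],
         angle_deg(a$CBd, a$SG, a$CBa), g$angle_weight),
    term("dihedral_Nd_CAd_CBd_SG", "deg", g$dihedral_targets[[1]],
         dihedral_deg(a$Nd, a$CAd, a$CBd, a$SG), g$dihedral_weight),
    term("dihedral_CAd_CBd_SG_CBa", "deg", g$dihedral_targets[[2]],
         dihedral_deg(a$CAd, a$CBd, a$SG, a$CBa), g$dihedral_weight),
    term("dihedral_CBd_SG_CBa_CAa", "deg", g$dihedral_targets[[3]],
         dihedral_deg(a$CBd, a$SG, a$CBa, a$CAa), g$dihedral_weight))
  if (ring$type == "methyllanthionine") {
    rows <- c(rows, list(
      term("improper_CBd", "deg", g$improper_target,
           dihedral_deg(a$CAd, a$CGd, a$SG, a$CBd), g$improper_weight),
      term("angle_CAd_CBd_CGd", "deg", g$methyl_angle_targets[[1]],
           angle_deg(a$CAd, a$CBd, a$CGd), g$angle_weight),
      term("angle_SG_CBd_CGd", "deg", g$methyl_angle_targets[[2]],
           angle_deg(a$SG, a$CBd, a$CGd), g$angle_weight)))
  }
  terms <- do.call(rbind, rows)
  structure(list(terms = terms, total = sum(terms$penalty)),
            class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  print(x$terms, digits = 4)
  cat(sprintf("total penalty: %.6g\n", x$total))
  invisible(x)
}

# torsional degrees of freedom available for closing one ring
ring_closure_dofs <- function(conf, ring) {
  ring <- as.list(ring)
  span <- ring_span(ring)
  dofs <- list(list(resno = span[1], which = "psi"))
  for (i in seq(span[1] + 1L, span[2] - 1L))
    if (i > span[1] && i < span[2])
      dofs <- c(dofs, list(list(resno = i, which = "phi"),
                           list(resno = i, which = "psi")))
  dofs <- c(dofs, list(list(resno = span[2], which = "phi")))
  # the thioether S rides on the acceptor sidechain: its chi1 is part of the
  # ring, whichever end of the span the acceptor sits on
  dofs <- c(dofs, list(list(resno = ring$acceptor, which = "chi1")))
  dofs
}

closure_objective <- function(pts, g) {
  gap <- vnorm(pts$CBd - pts$SG) - g$cs_bond_length
  a1 <- angle_diff(angle_deg(pts$CAd, pts$CBd, pts$SG), g$angle_targets[[1]])
  a2 <- angle_diff(angle_deg(pts$CBd, pts$SG, pts$CBa), g$angle_targets[[2]])
  gap^2 + g$angle_weight * (a1^2 + a2^2)
}

closure_state <- function(conf, ring, g) {
  a <- crosslink_atoms(conf, ring)
  list(gap = abs(vnorm(a$CBd - a$SG) - g$cs_bond_length),
       angle_dev = c(
         angle_diff(angle_deg(a$CAd, a$CBd, a$SG), g$angle_targets[[1]]),
         angle_diff(angle_deg(a$CBd, a$SG, a$CBa), g$angle_targets[[2]])))
}

#' Close a thioether ring by cyclic coordinate descent
#'
#' Iteratively adjusts the backbone phi/psi torsions inside the ring span
#' (plus the acceptor's chi1, which carries the SG) to bring the donor-CB to
#' acceptor-SG distance to the target bond length with acceptable flanking
#' angles. Each adjustment is a rigid rotation of the downstream atoms about
#' one bond axis, so bond lengths and bond angles are preserved exactly and
#' torsions outside the ring span are untouched.
#'
#' On success the returned conformer carries `attr(x, "closure")` with
#' `converged = TRUE`; on non-convergence the best conformer found is
#' returned with `converged = FALSE` and the final bond-length gap, so the
#' caller can retry from a new random start.
#'
#' @param conf a `lanthi_conformer`
#' @param ring one ring of the topology
#' @param geometry a [crosslink_geometry()]; defaults per ring type
#' @param max_iter maximum CCD sweeps over the torsion set
#' @param tol convergence tolerance on the C-S bond-length gap, Angstrom
#' @return the (possibly partially) closed conformer with a `closure`
#'   attribute: list `converged`, `gap` (Angstrom), `angle_dev` (degrees),
#'   `sweeps`
#' @export
close_ring <- function(conf, ring, geometry = NULL, max_iter = 100,
                       tol = NULL) {
  ring <- as.list(ring)
  if (is.null(geometry)) geometry <- crosslink_geometry(ring$type)
  g <- geometry
  if (is.null(tol)) tol <- g$bond_tol
  span <- ring_span(ring)
  if (span[2] - span[1] < 1L)
    stop("ring has no intervening rotatable torsions")
  dofs <- ring_closure_dofs(conf, ring)
  if (length(dofs) == 0L)
    stop("ring has no rotatable torsions between donor and acceptor")
  obj_names <- list(c(ring$donor, "N"), c(ring$donor, "CA"),
                    c(ring$donor, "CB"), c(ring$acceptor, "SG"),
                    c(ring$acceptor, "CB"), c(ring$acceptor, "CA"))
  obj_idx <- vapply(obj_names, function(p)
    atom_index(conf, as.integer(p[[1]]), p[[2]]), integer(1))
  names(obj_idx) <- c("Nd", "CAd", "CBd", "SG", "CBa", "CAa")
  pts_of <- function(P) list(Nd = P[1, ], CAd = P[2, ], CBd = P[3, ],
                             SG = P[4, ], CBa = P[5, ], CAa = P[6, ])
  st <- closure_state(conf, ring, g)
  if (st$gap < tol && all(st$angle_dev < g$angle_tol)) {
    attr(conf, "closure") <- list(converged = TRUE, gap = st$gap,
                                  angle_dev = st$angle_dev, sweeps = 0L)
    return(conf)
  }
  coarse <- seq(-180, 165, by = 15)
  prev_obj <- Inf
  for (sweep in seq_len(max_iter)) {
    for (dof in dofs) {
      if (conf$topology$residues$alpha_sp2[[dof$resno]] && dof$which == "chi1")
        next
      ax <- torsion_axis(conf, dof$resno, dof$which)
      mv <- moving_atoms(conf, dof$resno, dof$which)
      mv_rows <- which(obj_idx %in% mv)
      if (length(mv_rows) == 0L || length(mv_rows) == length(obj_idx)) next
      P0 <- conf$xyz[obj_idx, , drop = FALSE]
      eval_theta <- function(theta) {
        P <- P0
        P[mv_rows, ] <- rotate_points(P0[mv_rows, , drop = FALSE],
                                      ax$o, ax$a, theta)
        closure_objective(pts_of(P), g)
      }
      vals <- vapply(coarse, eval_theta, numeric(1))
      best <- coarse[[which.min(vals)]]
      opt <- stats::optimize(eval_theta, c(best - 15, best + 15))
      theta <- if (opt$objective < min(vals)) opt$minimum else best
      if (abs(theta) > 1e-9)
        conf <- rotate_torsion(conf, dof$resno, dof$which, theta)
    }
    st <- closure_state(conf, ring, g)
    if (st$gap < tol && all(st$angle_dev < g$angle_tol)) {
      attr(conf, "closure") <- list(converged = TRUE, gap = st$gap,
                                    angle_dev = st$angle_dev, sweeps = sweep)
      return(conf)
    }
    cur <- closure_objective(pts_of(conf$xyz[obj_idx, , drop = FALSE]), g)
    if (prev_obj - cur < 1e-8) break  # stalled; report failure early
    prev_obj <- cur
  }
  attr(conf, "closure") <- list(converged = FALSE, gap = st$gap,
                                angle_dev = st$angle_dev, sweeps = max_iter)
  conf
}

#' Did the last [close_ring()] call converge?
#' @param conf a conformer returned by [close_ring()]
#' @return logical
#' @export
is_closed <- function(conf) {
  cl <- attr(conf, "closure")
  !is.null(cl) && isTRUE(cl$converged)
}

#' Close every ring of a topology in a given order
#'
#' @param conf a `lanthi_conformer`
#' @param order integer permutation of ring indices (default: input order)
#' @param geometry optional list of [crosslink_geometry()] per ring
#' @param ... passed to [close_ring()]
#' @return conformer with a combined `closure` attribute (`converged` is TRUE
#'   only if every ring converged; `gaps` has the per-ring gaps)
#' @export
close_all_rings <- function(conf, order = NULL, geometry = NULL, ...) {
  rings <- conf$topology$rings
  if (nrow(rings) == 0L) {
    attr(conf, "closure") <- list(converged = TRUE, gaps = numeric(0))
    return(conf)
  }
  if (is.null(order)) order <- seq_len(nrow(rings))
  gaps <- rep(NA_real_, nrow(rings))
  ok <- TRUE
  for (k in order) {
    geo <- if (!is.null(geometry)) geometry[[k]] else NULL
    conf <- close_ring(conf, rings[k, ], geometry = geo, ...)
    cl <- attr(conf, "closure")
    gaps[[k]] <- cl$gap
    ok <- ok && cl$converged
  }
  # earlier rings can be reopened by later closure moves; verify all
  if (ok) {
    for (k in order) {
      geo <- if (!is.null(geometry)) geometry[[k]]
             else crosslink_geometry(rings$type[[k]])
      st <- closure_state(conf, rings[k, ], geo)
      gaps[[k]] <- st$gap
      if (st$gap >= geo$bond_tol || any(st$angle_dev >= geo$angle_tol))
        ok <- FALSE
    }
  }
  attr(conf, "closure") <- list(converged = ok, gaps = gaps)
  conf
}
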