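# Rigid-body superposition and RMSD utilities.

resolve_selection <- function(conf, selection) {
  at <- conf$atoms
  if (is.character(selection) && length(selection) == 1L &&
      selection %in% c("backbone", "heavy", "all")) {
    keep <- switch(selection,
      backbone = at$atom %in% c("N", "CA", "C"),
      heavy = at$element != "H",
      all = rep(TRUE, nrow(at)))
    return(at[keep, c("resno", "atom")])
  }
  if (is.data.frame(selection)) return(selection[, c("resno", "atom")])
  stop("selection must be 'backbone', 'heavy', 'all' or a data.frame(resno, atom)")
}

selection_xyz <- function(conf, sel) {
  idx <- vapply(seq_len(nrow(sel)), function(i)
    atom_index(conf, sel$resno[[i]], sel$atom[[i]]), integer(1))
  conf$xyz[idx, , drop = FALSE]
}

#' Optimal superposition of two conformers
#'
#' Least-squares rigid superposition (Kabsch) of `mobile` onto `reference`
#' over a common atom selection. Only proper rotations are returned, so a
#' mirror image never superposes to zero.
#'
#' @param mobile,reference `lanthi_conformer` objects over the same topology
#' @param selection `"backbone"` (N, CA, C; the default), `"heavy"`, `"all"`,
#'   or a data.frame with columns `resno`, `atom`
#' @return list: `rotation` (3 x 3, det +1), `translation` (length 3; the
#'   fitted coordinates are `xyz %*% t(rotation) + translation`), `rmsd`
#'   (Angstrom)
#' @examples
#' topo <- parse_topology("seq AAAA")
#' a <- build_conformer(topo, cbind(rep(-57, 4), rep(-47, 4)))
#' superpose(a, a)$rmsd
#' @export
superpose <- function(mobile, reference, selection = "backbone") {
  sel <- resolve_selection(mobile, selection)
  if (nrow(sel) < 3L) stop("superposition needs at least 3 atoms")
  kabsch(selection_xyz(mobile, sel), selection_xyz(reference, sel))
}

#' Backbone RMSD between two conformers
#' @inheritParams superpose
#' @return RMSD in Angstrom after optimal superposition
#' @export
backbone_rmsd <- function(mobile, reference, selection = "backbone")
  superpose(mobile, reference, selection)$rmsd

#' Apply a rigid transform to a conformer
#' @param conf a `lanthi_conformer`
#' @param rotation 3 x 3 rotation matrix
#' @param translation length-3 translation
#' @return transformed conformer
#' @export
transform_conformer <- function(conf, rotation, translation = c(0, 0, 0)) {
  conf$xyz <- conf$xyz %*% t(rotation) +
    matrix(translation, nrow(conf$xyz), 3, byrow = TRUE)
  conf
}

# atom set used for per-ring RMSD: backbone N/CA/C over the ring span plus
# the bridge atoms (donor CB, acceptor CB, SG)
ring_atom_selection <- function(ring) {
  ring <- as.list(ring)
  span <- ring_span(ring)
  sel <- do.call(rbind, lapply(seq(span[1], span[2]), function(i)
    data.frame(resno = i, atom = c("N", "CA", "C"), stringsAsFactors = FALSE)))
  rbind(sel,
        data.frame(resno = c(ring$donor, ring$acceptor, ring$acceptor),
                   atom = c("CB", "CB", "SG"), stringsAsFactors = FALSE))
}

#' RMSD over one lanthionine ring
#'
#' Superposes on the ring atom set (backbone N/CA/C of every residue in the
#' ring span, plus donor CB, acceptor CB and SG) and reports the RMSD over
#' that same set, so conformational differences outside the ring do not
#' contribute.
#'
#' @param a,b `lanthi_conformer` objects over the same topology
#' @param ring one ring of the topology
#' @return RMSD in Angstrom
#' @export
ring_rmsd <- function(a, b, ring) {
  sel <- ring_atom_selection(ring)
  kabsch(selection_xyz(a, sel), selection_xyz(b, sel))$rmsd
}
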