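# Conformer construction and torsion bookkeeping.
#
# A conformer holds one set of Cartesian coordinates for a topology. Atoms are
# deliberately minimal: full backbone (N, CA, C, O), amide and alpha
# hydrogens, and the sidechain heavy atoms the method needs (CB everywhere but
# glycine; SG for cysteine; the beta-methyl CG for Abu/Dhb; OG/OG1/CG2 for
# Ser/Thr). Everything else about a sidechain is irrelevant to ring geometry,
# NOE groups and the clash term, and is not modelled.

# internal ideal-geometry parameter set (Angstrom / degrees)
IDEAL <- list(
  b_NCA = 1.458, b_CAC = 1.525, b_CN = 1.329, b_CO = 1.231,
  b_NH = 1.010, b_CAHA = 1.090, b_CACB = 1.521, b_CACB_sp2 = 1.331,
  b_CBSG = 1.808, b_CBCG = 1.521, b_CBOG = 1.417,
  a_NCAC = 111.2, a_NCAC_sp2 = 120.0, a_CACN = 116.2, a_CNCA = 121.7,
  a_CACO = 120.8, a_HNCA = 118.2, a_NCACB = 110.5, a_NCACB_sp2 = 120.0,
  a_CACBSG = 114.0, a_CACBCG = 111.5, a_CACBCG_sp2 = 125.0, a_CACBOG = 110.5,
  # CB / HA placement torsions about the N-CA axis, referenced from C
  # (calibrated once against an embedded L-alanine dipeptide)
  t_CB_L = -122.6, t_HA_L = 118.2,
  omega = 180, chi1_default = -60
)

element_of <- function(atom) substr(atom, 1, 1)

# sidechain gamma-level atoms per residue code: list of (name, bond, angle,
# torsion offset relative to chi1). NULL means CB-only.
gamma_atoms <- function(code) {
  switch(code,
    CYS = list(list(name = "SG", bond = IDEAL$b_CBSG, angle = IDEAL$a_CACBSG, off = 0)),
    ABU = list(list(name = "CG", bond = IDEAL$b_CBCG, angle = IDEAL$a_CACBCG, off = 0)),
    THR = list(list(name = "OG1", bond = IDEAL$b_CBOG, angle = IDEAL$a_CACBOG, off = 0),
               list(name = "CG2", bond = IDEAL$b_CBCG, angle = IDEAL$a_CACBCG, off = 120)),
    SER = list(list(name = "OG", bond = IDEAL$b_CBOG, angle = IDEAL$a_CACBOG, off = 0)),
    NULL)
}

residue_atom_names <- function(code) {
  atoms <- c("N", "CA", "C", "O")
  if (code != "GLY" ) atoms <- c(atoms, "CB")
  for (g in gamma_atoms(code)) atoms <- c(atoms, g$name)
  if (code == "DHB") atoms <- c(atoms, "CG")
  if (code != "PRO") atoms <- c(atoms, "H")
  if (code == "GLY") atoms <- c(atoms, "HA2", "HA3")
  else if (!code %in% c("DHA", "DHB")) atoms <- c(atoms, "HA")
  atoms
}

#' Build a conformer from backbone torsions
#'
#' Standard internal-coordinate (NeRF) chain construction at ideal bond
#' lengths and angles. Dehydrated residues (Dha/Dhb) get a planar sp2 alpha
#' carbon (120 degree angles, in-plane CB at a C=C double-bond length); all
#' other residues are sp3 with the calibrated L (or mirrored D) beta-carbon
#' branch. Rings are NOT closed here; see [close_ring()].
#'
#' @param topology a `lanthi_topology`
#' @param phi_psi an n x 2 matrix or data.frame of backbone torsions in
#'   degrees, one row per residue (`phi`, `psi`)
#' @param chi1 sidechain chi1 torsion in degrees, recycled over residues
#'   (default -60)
#' @return an object of class `lanthi_conformer`: list with `topology`,
#'   `atoms` (data.frame `resno`, `atom`, `element`) and `xyz` (n_atoms x 3,
#'   Angstrom)
#' @examples
#' topo <- parse_topology("seq AAAAA")
#' conf <- build_conformer(topo, cbind(phi = rep(-57, 5), psi = rep(-47, 5)))
#' measure_torsions(conf)
#' @export
build_conformer <- function(topology, phi_psi, chi1 = IDEAL$chi1_default) {
  res <- topology$residues
  n <- nrow(res)
  if (n == 0L) stop("empty topology")
  phi_psi <- as.matrix(as.data.frame(phi_psi))
  if (nrow(phi_psi) != n)
    stop(sprintf("phi_psi has %d rows but topology has %d residues",
                 nrow(phi_psi), n))
  phi <- as.numeric(phi_psi[, 1]); psi <- as.numeric(phi_psi[, 2])
  chi1 <- rep_len(chi1, n)

  acceptors <- topology$rings$acceptor
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    nm <- residue_atom_names(res$code[[i]])
    # ring acceptors are cysteine-derived: attach the thioether SG if the
    # residue code does not already carry one
    if (i %in% acceptors && !"SG" %in% nm)
      nm <- append(nm, "SG", after = which(nm == "CB"))
    data.frame(resno = i, atom = nm,
               element = vapply(nm, element_of, character(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(atoms) <- NULL
  xyz <- matrix(NA_real_, nrow(atoms), 3)
  idx <- function(i, a) which(atoms$resno == i & atoms$atom == a)
  set <- function(i, a, p) xyz[idx(i, a), ] <<- p
  get <- function(i, a) xyz[idx(i, a), ]

  # backbone trace; a virtual pre-N carbonyl carbon anchors phi of residue 1
  c_prev <- c(1.329 * cos(IDEAL$a_CNCA * DEG) + 0, 1.329 * sin(IDEAL$a_CNCA * DEG), 0)
  set(1, "N", c(0, 0, 0))
  set(1, "CA", c(IDEAL$b_NCA, 0, 0))
  for (i in seq_len(n)) {
    sp2 <- res$alpha_sp2[[i]]
    a_ncac <- if (sp2) IDEAL$a_NCAC_sp2 else IDEAL$a_NCAC
    Ni <- get(i, "N"); CAi <- get(i, "CA")
    Cprev <- if (i == 1L) c_prev else get(i - 1L, "C")
    Ci <- place_atom(Cprev, Ni, CAi, IDEAL$b_CAC, a_ncac, phi[[i]])
    set(i, "C", Ci)
    if (i < n) {
      Nn <- place_atom(Ni, CAi, Ci, IDEAL$b_CN, IDEAL$a_CACN, psi[[i]])
      set(i + 1L, "N", Nn)
      CAn <- place_atom(CAi, Ci, Nn, IDEAL$b_NCA, IDEAL$a_CNCA, IDEAL$omega)
      set(i + 1L, "CA", CAn)
    }
  }
  # carbonyl O, hydrogens and sidechains
  for (i in seq_len(n)) {
    code <- res$code[[i]]
    sp2 <- res$alpha_sp2[[i]]
    Ni <- get(i, "N"); CAi <- get(i, "CA"); Ci <- get(i, "C")
    set(i, "O", place_atom(Ni, CAi, Ci, IDEAL$b_CO, IDEAL$a_CACO,
                           psi[[i]] + 180))
    if (code != "PRO")
      set(i, "H", place_atom(Ci, CAi, Ni, IDEAL$b_NH, IDEAL$a_HNCA,
                             phi[[i]] - 180))
    sgn <- if (res$chirality[[i]] == "D") -1 else 1
    if (code == "GLY") {
      set(i, "HA2", place_atom(Ci, Ni, CAi, IDEAL$b_CAHA, IDEAL$a_NCACB,
                               IDEAL$t_CB_L))
      set(i, "HA3", place_atom(Ci, Ni, CAi, IDEAL$b_CAHA, IDEAL$a_NCACB,
                               IDEAL$t_HA_L))
    } else {
      t_cb <- if (sp2) 180 else sgn * IDEAL$t_CB_L
      b_cb <- if (sp2) IDEAL$b_CACB_sp2 else IDEAL$b_CACB
      a_cb <- if (sp2) IDEAL$a_NCACB_sp2 else IDEAL$a_NCACB
      CBi <- place_atom(Ci, Ni, CAi, b_cb, a_cb, t_cb)
      set(i, "CB", CBi)
      if (!sp2)
        set(i, "HA", place_atom(Ci, Ni, CAi, IDEAL$b_CAHA, IDEAL$a_NCACB,
                                sgn * IDEAL$t_HA_L))
      if (code == "DHB") {
        # Z-configured beta-methyl, coplanar with the sp2 CA=CB bond
        set(i, "CG", place_atom(Ni, CAi, CBi, IDEAL$b_CBCG,
                                IDEAL$a_CACBCG_sp2, 0))
      } else {
        for (g in gamma_atoms(code))
          set(i, g$name, place_atom(Ni, CAi, CBi, g$bond, g$angle,
                                    chi1[[i]] + g$off))
        if (i %in% acceptors && code != "CYS")
          set(i, "SG", place_atom(Ni, CAi, CBi, IDEAL$b_CBSG, IDEAL$a_CACBSG,
                                  chi1[[i]] + 120))
      }
    }
  }
  structure(list(topology = topology, atoms = atoms, xyz = xyz),
            class = "lanthi_conformer")
}

#' @export
print.lanthi_conformer <- function(x, ...) {
  cat(sprintf("lanthipeptide conformer: %d residues, %d atoms\n",
              nrow(x$topology$residues), nrow(x$atoms)))
  invisible(x)
}

#' Index of one atom in a conformer
#' @param conf a `lanthi_conformer`
#' @param resno 1-based residue position
#' @param atom atom name (PDB-style, e.g. "CA", "SG")
#' @return integer row index into `conf$atoms` / `conf$xyz`
#' @export
atom_index <- function(conf, resno, atom) {
  i <- which(conf$atoms$resno == resno & conf$atoms$atom == atom)
  if (length(i) != 1L)
    stop(sprintf("atom %s of residue %d not found", atom, resno))
  i
}

atom_xyz <- function(conf, resno, atom) conf$xyz[atom_index(conf, resno, atom), ]

has_atom <- function(conf, resno, atom)
  any(conf$atoms$resno == resno & conf$atoms$atom == atom)

#' Measure backbone torsions of a conformer
#'
#' phi(1) is recovered from the amide hydrogen (placed anti to the virtual
#' preceding carbonyl) and psi(n) from the carbonyl oxygen, so the full
#' torsion set round-trips through [build_conformer()]. phi of an N-terminal
#' proline (no amide H) is `NA`.
#'
#' @param conf a `lanthi_conformer`
#' @return data.frame with columns `resno`, `phi`, `psi` (degrees)
#' @export
measure_torsions <- function(conf) {
  n <- nrow(conf$topology$residues)
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    Ni <- atom_xyz(conf, i, "N"); CAi <- atom_xyz(conf, i, "CA")
    Ci <- atom_xyz(conf, i, "C")
    if (i > 1L) {
      phi[[i]] <- dihedral_deg(atom_xyz(conf, i - 1L, "C"), Ni, CAi, Ci)
    } else if (has_atom(conf, i, "H")) {
      phi[[i]] <- wrap_angle(dihedral_deg(atom_xyz(conf, i, "H"), Ni, CAi, Ci) + 180)
    }
    if (i < n) {
      psi[[i]] <- dihedral_deg(Ni, CAi, Ci, atom_xyz(conf, i + 1L, "N"))
    } else {
      psi[[i]] <- wrap_angle(dihedral_deg(Ni, CAi, Ci, atom_xyz(conf, i, "O")) - 180)
    }
  }
  data.frame(resno = seq_len(n), phi = phi, psi = psi)
}

# Row indices of atoms that move when a given torsion is rotated. Rotating a
# torsion rigidly carries everything downstream of the bond (C-terminal side),
# so bond lengths, bond angles and all other torsions are untouched.
moving_atoms <- function(conf, resno, which) {
  at <- conf$atoms
  later <- at$resno > resno
  if (which == "phi") {
    # about N-CA: residue atoms other than N/H move, plus all later residues
    same <- at$resno == resno & !at$atom %in% c("N", "H")
    which(same | later)
  } else if (which == "psi") {
    # about CA-C: carbonyl O and all later residues
    which((at$resno == resno & at$atom == "O") | later)
  } else if (which == "chi1") {
    # about CA-CB: gamma-level atoms of this residue only
    which(at$resno == resno & at$atom %in% c("SG", "OG", "OG1", "CG", "CG2"))
  } else stop("unknown torsion kind: ", which)
}

torsion_axis <- function(conf, resno, which) {
  switch(which,
    phi = list(o = atom_xyz(conf, resno, "N"),
               a = atom_xyz(conf, resno, "CA") - atom_xyz(conf, resno, "N")),
    psi = list(o = atom_xyz(conf, resno, "CA"),
               a = atom_xyz(conf, resno, "C") - atom_xyz(conf, resno, "CA")),
    chi1 = list(o = atom_xyz(conf, resno, "CA"),
                a = atom_xyz(conf, resno, "CB") - atom_xyz(conf, resno, "CA")),
    stop("unknown torsion kind: ", which))
}

#' Rotate one torsion of a conformer by a delta
#'
#' Applies a rigid rotation of the downstream atom set about the torsion's
#' bond axis; every bond length, bond angle and unrelated torsion is exactly
#' preserved.
#' @param conf a `lanthi_conformer`
#' @param resno residue carrying the torsion
#' @param which `"phi"`, `"psi"` or `"chi1"`
#' @param delta rotation in degrees (positive = increase of the torsion)
#' @return the modified conformer
#' @export
rotate_torsion <- function(conf, resno, which, delta) {
  if (conf$topology$residues$alpha_sp2[[resno]] && which == "chi1")
    stop("sp2 residues have no rotatable chi1")
  ax <- torsion_axis(conf, resno, which)
  mv <- moving_atoms(conf, resno, which)
  if (length(mv) == 0L) return(conf)
  conf$xyz[mv, ] <- rotate_points(conf$xyz[mv, , drop = FALSE], ax$o, ax$a, delta)
  conf
}
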