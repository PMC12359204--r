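# Per-residue-type (phi, psi) torsion potentials.
#
# Tables are periodic grids of energies (arbitrary kcal/mol-like units,
# meaningful up to an additive constant) with a disallowed-cell mask. The
# package ships coarse digitized tables for a generic L residue, glycine,
# proline, and the dehydrated residues Dha and Dhb; the sp2 alpha carbon of
# the dehydrated residues gives them (phi, psi) -> (-phi, -psi) symmetric
# low-energy bands, and Dhb carries an extra masked region where its
# gamma-methyl would clash with the backbone. Users can substitute their own
# (e.g. QM-derived) tables in the same file format.
#
# File format: '#' comments, then 'code <NAME>' and 'spacing <deg>' header
# lines, a column header, and one row per grid cell: phi psi energy mask.

.table_cache <- new.env(parent = emptyenv())

#' Read a torsion table file
#' @param path path to a table file (see the package data files under
#'   `extdata/torsion_tables` for the format)
#' @return object of class `torsion_table`: list with `code`, `spacing`,
#'   `phi`/`psi` grid node vectors, `energy` and `mask` matrices indexed
#'   `[phi, psi]`
#' @export
read_torsion_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1:2]), "\\s+")
  stopifnot(tolower(hdr[[1]][1]) == "code", tolower(hdr[[2]][1]) == "spacing")
  code <- hdr[[1]][2]
  spacing <- as.numeric(hdr[[2]][2])
  body <- utils::read.table(text = lines[-(1:3)], col.names =
                              c("phi", "psi", "energy", "mask"))
  grid <- seq(-180, 180 - spacing, by = spacing)
  n <- length(grid)
  if (nrow(body) != n * n) stop("torsion table has wrong number of rows")
  E <- matrix(NA_real_, n, n)
  M <- matrix(NA, n, n)
  i <- match(body$phi, grid); j <- match(body$psi, grid)
  if (anyNA(i) || anyNA(j)) stop("torsion table nodes off the grid")
  E[cbind(i, j)] <- body$energy
  M[cbind(i, j)] <- body$mask != 0
  if (anyNA(E)) stop("torsion table has missing cells")
  if (!any(!M)) stop("torsion table is fully masked")
  structure(list(code = code, spacing = spacing, phi = grid, psi = grid,
                 energy = E, mask = M), class = "torsion_table")
}

#' Write a torsion table file
#' @param table a `torsion_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_torsion_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# lanthifold torsion table",
               paste("code", table$code),
               paste("spacing", format(table$spacing)),
               "phi\tpsi\tenergy\tmask"), con)
  for (i in seq_along(table$phi))
    for (j in seq_along(table$psi))
      writeLines(sprintf("%g\t%g\t%.4f\t%d", table$phi[[i]], table$psi[[j]],
                         table$energy[i, j], as.integer(table$mask[i, j])),
                 con)
  invisible(path)
}

# map a residue spec to its table name
table_name_for <- function(code) {
  switch(code, DHA = "dha", DHB = "dhb", GLY = "glycine", PRO = "proline",
         "general")
}

#' Load one of the shipped torsion tables
#'
#' @param name `"general"`, `"glycine"`, `"proline"`, `"dha"` or `"dhb"`
#' @return a `torsion_table` (cached across calls)
#' @export
load_torsion_table <- function(name) {
  if (!is.null(.table_cache[[name]])) return(.table_cache[[name]])
  path <- system.file("extdata", "torsion_tables", paste0(name, ".tsv"),
                      package = "lanthifold", mustWork = TRUE)
  tab <- read_torsion_table(path)
  assign(name, tab, envir = .table_cache)
  tab
}

#' Mirror a torsion table for D-amino acids
#'
#' D residues score with the (phi, psi) -> (-phi, -psi) image of the L table.
#' @param table a `torsion_table`
#' @return the mirrored table
#' @export
flip_torsion_table <- function(table) {
  n <- length(table$phi)
  # node at -phi: -(-180) = 180 wraps to -180 (index 1); others reverse
  perm <- c(1L, rev(seq(2L, n)))
  table$energy <- table$energy[perm, perm, drop = FALSE]
  table$mask <- table$mask[perm, perm, drop = FALSE]
  table$code <- paste0("D-", table$code)
  table
}

#' Torsion table for one residue of a topology
#' @param topology a `lanthi_topology`
#' @param resno residue position
#' @return a `torsion_table`, mirrored for D residues
#' @export
residue_torsion_table <- function(topology, resno) {
  r <- topology$residues[resno, ]
  tab <- load_torsion_table(table_name_for(r$code))
  if (r$chirality == "D") flip_torsion_table(tab) else tab
}

# fractional periodic grid position: list(i0, i1, f)
grid_locate <- function(grid, spacing, x) {
  x <- ((x + 180) %% 360) - 180
  u <- (x - grid[[1]]) / spacing
  i0 <- floor(u)
  f <- u - i0
  n <- length(grid)
  list(i0 = (as.integer(i0) %% n) + 1L, i1 = (as.integer(i0 + 1) %% n) + 1L,
       f = f)
}

#' Score a (phi, psi) pair on a torsion table
#'
#' Bilinear interpolation on the periodic grid; exact at grid nodes. Angles
#' are wrapped, so `score_torsion(t, phi + 360, psi - 360)` equals
#' `score_torsion(t, phi, psi)`.
#' @param table a `torsion_table`
#' @param phi,psi torsions in degrees (vectors are recycled together)
#' @return interpolated energy values
#' @export
score_torsion <- function(table, phi, psi) {
  n <- max(length(phi), length(psi))
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  out <- numeric(n)
  for (k in seq_len(n)) {
    gi <- grid_locate(table$phi, table$spacing, phi[[k]])
    gj <- grid_locate(table$psi, table$spacing, psi[[k]])
    E <- table$energy
    out[[k]] <-
      (1 - gi$f) * (1 - gj$f) * E[gi$i0, gj$i0] +
      gi$f * (1 - gj$f) * E[gi$i1, gj$i0] +
      (1 - gi$f) * gj$f * E[gi$i0, gj$i1] +
      gi$f * gj$f * E[gi$i1, gj$i1]
  }
  out
}

#' Sample (phi, psi) pairs from a torsion table
#'
#' Draws grid cells with probability proportional to the Boltzmann weight
#' `exp(-energy / temperature)` of allowed (unmasked) cells, then jitters
#' uniformly within the chosen cell. Masked cells are never returned. Uses
#' R's global RNG stream.
#'
#' @param table a `torsion_table`
#' @param n number of samples
#' @param temperature sampling temperature in table energy units (default 1)
#' @param jitter if `FALSE`, return cell-node values exactly
#' @return an `n` x 2 matrix with columns `phi`, `psi` (degrees)
#' @export
sample_torsion <- function(table, n = 1, temperature = 1, jitter = TRUE) {
  ok <- !table$mask
  if (!any(ok)) stop("torsion table is fully masked")
  w <- exp(-(table$energy - min(table$energy[ok])) / temperature)
  w[!ok] <- 0
  cells <- which(ok)
  pick <- cells[sample.int(length(cells), n, replace = TRUE,
                           prob = w[cells])]
  ij <- arrayInd(pick, dim(table$energy))
  phi <- table$phi[ij[, 1]]
  psi <- table$psi[ij[, 2]]
  if (jitter) {
    s <- table$spacing
    phi <- phi + stats::runif(n, 0, s)
    psi <- psi + stats::runif(n, 0, s)
    phi <- ((phi + 180) %% 360) - 180
    psi <- ((psi + 180) %% 360) - 180
  }
  cbind(phi = phi, psi = psi)
}

#' Total torsion energy of a conformer
#' @param conf a `lanthi_conformer`
#' @return sum over residues of each residue's table energy at its measured
#'   (phi, psi); terminal torsions recovered as in [measure_torsions()]
#' @export
torsion_energy <- function(conf) {
  tor <- measure_torsions(conf)
  total <- 0
  for (i in seq_len(nrow(tor))) {
    if (is.na(tor$phi[[i]]) || is.na(tor$psi[[i]])) next
    tab <- residue_torsion_table(conf$topology, i)
    total <- total + score_torsion(tab, tor$phi[[i]], tor$psi[[i]])
  }
  total
}
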