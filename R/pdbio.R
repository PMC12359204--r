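# Multi-model PDB input/output for conformer pools.
#
# Reading goes through bio3d's PDB parser; writing emits fixed-width
# ATOM/MODEL/ENDMDL records directly (bio3d has no multi-model writer) plus
# LINK records for every thioether bridge (donor CB -- acceptor SG).

#' Write a conformer pool as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per conformer, with LINK records declaring each
#' thioether bond. Dehydrated residues keep their DHA/DHB codes; the
#' methyllanthionine donor is written as ABU and ring acceptors as CYS.
#'
#' @param pool a list of `lanthi_conformer` objects sharing one topology (a
#'   single conformer is accepted too)
#' @param path output file
#' @param remarks optional character vector written as REMARK records (e.g. a
#'   provenance header)
#' @return `path`, invisibly
#' @export
write_pool_pdb <- function(pool, path, remarks = character()) {
  if (inherits(pool, "lanthi_conformer")) pool <- list(pool)
  stopifnot(length(pool) > 0L)
  topo <- pool[[1]]$topology
  con <- file(path, "w")
  on.exit(close(con))
  for (r in remarks)
    writeLines(sprintf("REMARK 250 %s", r), con)
  res <- topo$residues
  for (i in seq_len(nrow(topo$rings))) {
    rg <- topo$rings[i, ]
    writeLines(sprintf(
      "LINK         CB  %-3s A%4d                 SG  %-3s A%4d",
      res$code[[rg$donor]], rg$donor, res$code[[rg$acceptor]], rg$acceptor),
      con)
  }
  for (m in seq_along(pool)) {
    conf <- pool[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    at <- conf$atoms
    for (k in seq_len(nrow(at))) {
      nm <- at$atom[[k]]
      namefield <- if (nchar(nm) >= 4L) substr(nm, 1, 4) else sprintf(" %-3s", nm)
      writeLines(sprintf(
        "ATOM  %5d %4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        k, namefield, res$code[[at$resno[[k]]]], at$resno[[k]],
        conf$xyz[k, 1], conf$xyz[k, 2], conf$xyz[k, 3], 1, 0,
        at$element[[k]]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file as a conformer pool
#'
#' Parses with [bio3d::read.pdb()] and maps atoms onto the supplied topology
#' by residue number and atom name. Atoms in the file that the topology's
#' minimal atom model does not include are ignored; atoms the model requires
#' but the file lacks raise an error.
#'
#' @param path PDB file (possibly multi-model)
#' @param topology the `lanthi_topology` the models belong to
#' @return list of `lanthi_conformer` objects, one per MODEL
#' @export
read_pool_pdb <- function(path, topology) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  template <- build_conformer(topology,
                              cbind(rep(-120, nrow(topology$residues)),
                                    rep(120, nrow(topology$residues))))
  at <- template$atoms
  pat <- pdb$atom
  key_file <- paste(pat$resno, trimws(pat$elety))
  key_want <- paste(at$resno, at$atom)
  idx <- match(key_want, key_file)
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[[1]]
    stop(sprintf("PDB file lacks atom %s of residue %d",
                 at$atom[[miss]], at$resno[[miss]]))
  }
  nmod <- nrow(pdb$xyz)
  lapply(seq_len(nmod), function(m) {
    conf <- template
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    conf$xyz <- xyz[idx, , drop = FALSE]
    conf
  })
}

#' Write a per-model score table
#' @param scores data.frame with a `model` column and score columns
#' @param path output TSV path
#' @param remarks optional provenance lines, written as `#`-prefixed comments
#' @return `path`, invisibly
#' @export
write_score_table <- function(scores, path, remarks = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in remarks) writeLines(paste0("# ", r), con)
  utils::write.table(scores, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
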