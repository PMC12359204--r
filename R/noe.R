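# NOE distance restraints: ambiguous atom groups, r^-6 effective distances,
# ensemble averaging, and restraint scoring.
#
# Two distinct r^-6 combinations are involved and kept deliberately separate:
#  * ambiguity WITHIN one conformer uses the r^-6 SUM over all cross-pairs of
#    the two atom groups (the NMR pseudoatom convention; more equivalent
#    protons -> shorter effective distance);
#  * averaging ACROSS the equally populated members of an ensemble uses the
#    r^-6 MEAN: d* = ( (1/N) * sum_i d_i^-6 )^(-1/6), so short distances in
#    any one member dominate.

.pseudo_cache <- new.env(parent = emptyenv())

pseudoatom_table <- function() {
  if (!is.null(.pseudo_cache$tab)) return(.pseudo_cache$tab)
  path <- system.file("extdata", "pseudoatoms.tsv", package = "lanthifold",
                      mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  .pseudo_cache$tab <- tab
  tab
}

#' Resolve an atom (or pseudoatom) name to an atom group
#'
#' A name that exists as a real atom of the residue resolves to itself; a
#' pseudoatom name (HN, QA, MB/QB, MG/QG, ...) expands through the shipped
#' pseudoatom mapping table. Methyl and methylene pseudoatoms resolve to
#' their carrier heavy atom in this package's minimal-sidechain atom model.
#'
#' @param conf a `lanthi_conformer` (used as the atom-layout template)
#' @param resno residue position
#' @param name atom or pseudoatom name
#' @return data.frame with columns `resno`, `atom` (one row per member atom)
#' @export
resolve_atom_group <- function(conf, resno, name) {
  if (resno < 1 || resno > nrow(conf$topology$residues))
    stop(sprintf("residue %d out of range", resno))
  if (has_atom(conf, resno, name))
    return(data.frame(resno = resno, atom = name, stringsAsFactors = FALSE))
  code <- conf$topology$residues$code[[resno]]
  tab <- pseudoatom_table()
  hit <- tab[tab$pseudo == name &
               (tab$codes == "*" |
                  vapply(strsplit(tab$codes, ","), function(cc) code %in% cc,
                         logical(1))), , drop = FALSE]
  for (k in seq_len(nrow(hit))) {
    atoms <- strsplit(hit$atoms[[k]], ",")[[1]]
    if (all(vapply(atoms, function(a) has_atom(conf, resno, a), logical(1))))
      return(data.frame(resno = resno, atom = atoms, stringsAsFactors = FALSE))
  }
  stop(sprintf("cannot resolve atom '%s' of residue %d (%s)", name, resno, code))
}

group_xyz <- function(conf, group) {
  idx <- vapply(seq_len(nrow(group)), function(i)
    atom_index(conf, group$resno[[i]], group$atom[[i]]), integer(1))
  conf$xyz[idx, , drop = FALSE]
}

#' r^-6-summed effective distance between two atom groups
#'
#' `(sum over all cross-pairs of d^-6)^(-1/6)`; reduces to the plain
#' Euclidean distance when both groups have a single atom.
#'
#' @param conf a `lanthi_conformer`
#' @param group_a,group_b data.frames with columns `resno`, `atom` (as from
#'   [resolve_atom_group()])
#' @return effective distance in Angstrom
#' @export
effective_distance <- function(conf, group_a, group_b) {
  A <- group_xyz(conf, group_a)
  B <- group_xyz(conf, group_b)
  s <- 0
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B))) {
      d2 <- sum((A[i, ] - B[j, ])^2)
      if (d2 < 1e-12) stop("coincident atoms in NOE groups")
      s <- s + d2^(-3)
    }
  s^(-1 / 6)
}

#' Read an NOE restraint file
#'
#' Accepts the package's TSV format (columns `resA`, `atomA`, `resB`,
#' `atomB`, `distance`, optional `kind` = `target` or `upper_limit`) or a
#' CYANA-style `.upl` file (`resnoA resnameA atomA resnoB resnameB atomB
#' distance`), auto-detected from the first data line. Atom fields may be
#' pseudoatom names.
#'
#' @param path restraint file
#' @return data.frame of class `noe_restraints` with columns `resA`, `atomA`,
#'   `resB`, `atomB`, `distance`, `kind`
#' @export
read_restraints <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty restraint file")
  first <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  if (suppressWarnings(!is.na(as.numeric(first[[1]]))) && length(first) >= 7) {
    # CYANA .upl dialect
    df <- utils::read.table(text = lines, stringsAsFactors = FALSE)
    out <- data.frame(resA = as.integer(df[[1]]), atomA = df[[3]],
                      resB = as.integer(df[[4]]), atomB = df[[6]],
                      distance = as.numeric(df[[7]]), kind = "upper_limit",
                      stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(text = lines, header = TRUE,
                            stringsAsFactors = FALSE)
    if (is.null(df$kind)) df$kind <- "upper_limit"
    out <- df[, c("resA", "atomA", "resB", "atomB", "distance", "kind")]
  }
  validate_restraints(out)
}

validate_restraints <- function(x) {
  stopifnot(all(x$distance > 0), all(x$kind %in% c("target", "upper_limit")))
  same <- x$resA == x$resB & x$atomA == x$atomB
  if (any(same)) stop("restraint between an atom group and itself")
  class(x) <- c("noe_restraints", "data.frame")
  x
}

#' Write restraints in the package TSV format
#' @param restraints a restraint data.frame
#' @param path output path
#' @param remarks optional `#`-prefixed header lines
#' @return `path`, invisibly
#' @export
write_restraints <- function(restraints, path, remarks = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in remarks) writeLines(paste0("# ", r), con)
  utils::write.table(restraints, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

resolve_restraint_groups <- function(conf, restraints) {
  lapply(seq_len(nrow(restraints)), function(k)
    list(a = resolve_atom_group(conf, restraints$resA[[k]],
                                restraints$atomA[[k]]),
         b = resolve_atom_group(conf, restraints$resB[[k]],
                                restraints$atomB[[k]])))
}

# n_members x n_restraints matrix of per-member effective d^-6; the basic
# quantity both the selector and the scorer average over
restraint_d6_matrix <- function(members, restraints) {
  groups <- resolve_restraint_groups(members[[1]], restraints)
  out <- matrix(NA_real_, length(members), nrow(restraints))
  for (i in seq_along(members))
    for (k in seq_along(groups))
      out[i, k] <- effective_distance(members[[i]], groups[[k]]$a,
                                      groups[[k]]$b)^(-6)
  out
}

#' Ensemble-averaged NOE distance
#'
#' The r^-6 mean over equally populated members:
#' `d* = ((1/N) * sum_i d_i^-6)^(-1/6)`, with `d_i` the per-member effective
#' distance of the restraint's atom groups. With one member this is that
#' member's distance; shorter members dominate for larger ensembles.
#'
#' @param members list of `lanthi_conformer`
#' @param restraint one restraint row (list or one-row data.frame with
#'   `resA`, `atomA`, `resB`, `atomB`)
#' @return ensemble-averaged distance in Angstrom
#' @export
ensemble_average_distance <- function(members, restraint) {
  if (length(members) == 0L) stop("empty ensemble")
  restraint <- as.list(restraint)
  a <- resolve_atom_group(members[[1]], restraint$resA, restraint$atomA)
  b <- resolve_atom_group(members[[1]], restraint$resB, restraint$atomB)
  d6 <- vapply(members, function(m) effective_distance(m, a, b)^(-6),
               numeric(1))
  mean(d6)^(-1 / 6)
}

restraint_residuals <- function(d_star, restraints, mode) {
  if (mode == "symmetric") return(d_star - restraints$distance)
  ifelse(restraints$kind == "upper_limit",
         pmax(0, d_star - restraints$distance),
         d_star - restraints$distance)
}

#' Score an ensemble against a restraint set
#'
#' Computes the ensemble-averaged distance for every restraint and the sum of
#' squared residuals. In the default kind-aware mode, `upper_limit`
#' restraints contribute only when violated (one-sided residual
#' `max(0, d* - d_obs)`); `target` restraints are two-sided. `mode =
#' "symmetric"` makes every restraint two-sided.
#'
#' @param members list of `lanthi_conformer`
#' @param restraints a restraint data.frame (see [read_restraints()])
#' @param mode `"kind"` (default) or `"symmetric"`
#' @return list of class `restraint_score`: `table` (per-restraint `d_star`,
#'   `residual`, `sq_residual`) and `total` (Angstrom^2)
#' @export
score_ensemble <- function(members, restraints, mode = c("kind", "symmetric")) {
  mode <- match.arg(mode)
  if (length(members) == 0L) stop("empty ensemble")
  if (nrow(restraints) == 0L) stop("empty restraint set")
  D6 <- restraint_d6_matrix(members, restraints)
  d_star <- colMeans(D6)^(-1 / 6)
  resid <- restraint_residuals(d_star, restraints, mode)
  tab <- cbind(as.data.frame(restraints),
               d_star = d_star, residual = resid, sq_residual = resid^2)
  structure(list(table = tab, total = sum(resid^2)),
            class = "restraint_score")
}

#' @export
print.restraint_score <- function(x, ...) {
  cat(sprintf("restraint score over %d restraints: total %.4f A^2\n",
              nrow(x$table), x$total))
  invisible(x)
}
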