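# Ensemble analysis: flexibility profiles and RMSD tables.

circular_variance <- function(deg) {
  deg <- deg[!is.na(deg)]
  if (length(deg) == 0L) return(NA_real_)
  rad <- deg * DEG
  1 - sqrt(mean(cos(rad))^2 + mean(sin(rad))^2)
}

#' Analyze a conformer ensemble
#'
#' Per-member backbone RMSD to a reference member, per-ring RMSD to the same
#' reference, and per-residue circular variance of the backbone torsions
#' across the ensemble (the flexibility profile).
#'
#' The reference policy mirrors standard practice: `"lowest_score"` (for
#' generated ensembles; uses `attr(pool, "scores")` or computes SimpleScore)
#' or `"first"` (model 1, for ensembles read from an external multi-model
#' PDB).
#'
#' @param ensemble list of `lanthi_conformer` (>= 2 members)
#' @param reference `"lowest_score"`, `"first"`, or a member index
#' @param score optional [simple_score()] used when scores must be computed
#' @return list of class `ensemble_report`: `members` (data.frame `model`,
#'   `rmsd_backbone`, one `rmsd_ring_<k>` column per ring), `residues`
#'   (data.frame `resno`, `phi_circvar`, `psi_circvar`), `reference` (index)
#' @export
analyze_ensemble <- function(ensemble, reference = "lowest_score",
                             score = NULL) {
  if (length(ensemble) < 2L) stop("need at least 2 ensemble members")
  topo <- ensemble[[1]]$topology
  ref_idx <- if (is.numeric(reference)) {
    as.integer(reference)
  } else if (identical(reference, "first")) {
    1L
  } else if (identical(reference, "lowest_score")) {
    sc <- attr(ensemble, "scores")
    if (!is.null(sc) && nrow(sc) == length(ensemble)) {
      which.min(sc$total)
    } else {
      if (is.null(score)) score <- simple_score(topo)
      which.min(vapply(ensemble, function(c) score$eval(c)$total, numeric(1)))
    }
  } else stop("reference must be 'lowest_score', 'first' or an index")
  if (ref_idx < 1L || ref_idx > length(ensemble))
    stop("reference index out of range")
  ref <- ensemble[[ref_idx]]
  members <- data.frame(
    model = seq_along(ensemble),
    rmsd_backbone = vapply(ensemble, backbone_rmsd, numeric(1),
                           reference = ref))
  for (k in seq_len(nrow(topo$rings)))
    members[[sprintf("rmsd_ring_%d", k)]] <-
      vapply(ensemble, ring_rmsd, numeric(1), b = ref, ring = topo$rings[k, ])
  tors <- lapply(ensemble, measure_torsions)
  n <- nrow(topo$residues)
  residues <- data.frame(
    resno = seq_len(n),
    phi_circvar = vapply(seq_len(n), function(i)
      circular_variance(vapply(tors, function(t) t$phi[[i]], numeric(1))),
      numeric(1)),
    psi_circvar = vapply(seq_len(n), function(i)
      circular_variance(vapply(tors, function(t) t$psi[[i]], numeric(1))),
      numeric(1)))
  structure(list(members = members, residues = residues,
                 reference = ref_idx),
            class = "ensemble_report")
}

#' @export
print.ensemble_report <- function(x, ...) {
  cat(sprintf("ensemble report: %d members, reference model %d\n",
              nrow(x$members), x$reference))
  cat(sprintf("  backbone RMSD to reference: %.2f - %.2f A (mean %.2f)\n",
              min(x$members$rmsd_backbone), max(x$members$rmsd_backbone),
              mean(x$members$rmsd_backbone)))
  flex <- x$residues$resno[which.max(x$residues$phi_circvar +
                                       x$residues$psi_circvar)]
  cat(sprintf("  most flexible residue: %d\n", flex))
  invisible(x)
}
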