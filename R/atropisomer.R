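# Atropisomer classification: conformers of cyclized peptides can be
# kinetically trapped on one side of a ring plane and cannot interconvert.
# Classes are told apart by plane-side sign tests: three alpha carbons define
# a plane, and the sign of a fourth (probe) alpha carbon against the plane
# normal is a pseudoscalar -- invariant under proper rigid motion, negated by
# mirroring.

#' Define a probe quad
#' @param plane integer vector of three residue positions whose CA atoms form
#'   the plane (order matters: it fixes the normal direction)
#' @param probe residue position of the probe CA
#' @return list of class `probe_quad`
#' @export
probe_quad <- function(plane, probe) {
  plane <- as.integer(plane); probe <- as.integer(probe)
  if (length(plane) != 3L || anyDuplicated(c(plane, probe)))
    stop("a probe quad needs three distinct plane residues and a distinct probe")
  structure(list(plane = plane, probe = probe), class = "probe_quad")
}

#' Plane-side sign of a probe alpha carbon
#'
#' Sign of `(probe - p1) . ((p2 - p1) x (p3 - p1))` over the CA atoms of the
#' quad. Collinear plane residues or a probe within `tolerance` of the plane
#' are degenerate geometry and raise an error rather than returning a sign.
#'
#' @param conf a `lanthi_conformer`
#' @param quad a [probe_quad()]
#' @param tolerance minimum |signed distance| from the plane, Angstrom
#'   (default 0.1)
#' @return `+1` or `-1`
#' @export
probe_sign <- function(conf, quad, tolerance = 0.1) {
  p1 <- atom_xyz(conf, quad$plane[[1]], "CA")
  p2 <- atom_xyz(conf, quad$plane[[2]], "CA")
  p3 <- atom_xyz(conf, quad$plane[[3]], "CA")
  q <- atom_xyz(conf, quad$probe, "CA")
  nrm <- vcross(p2 - p1, p3 - p1)
  nn <- vnorm(nrm)
  if (nn < 1e-6) stop(sprintf("degenerate probe (plane %s): collinear CAs",
                              paste(quad$plane, collapse = ",")))
  signed <- sum((q - p1) * nrm) / nn
  if (abs(signed) < tolerance)
    stop(sprintf(
      "degenerate probe (plane %s, probe %d): |signed distance| %.3f A below tolerance %.3f",
      paste(quad$plane, collapse = ","), quad$probe, abs(signed), tolerance))
  if (signed > 0) 1L else -1L
}

#' Atropisomer key of a conformer
#'
#' Concatenated [probe_sign()] results over a probe list. Identical keys mean
#' the conformers are on the same side of every probe plane; enough probes
#' distinguish all potential atropisomers.
#'
#' @param conf a `lanthi_conformer`
#' @param probes list of [probe_quad()]
#' @param tolerance passed to [probe_sign()]
#' @return integer vector of +1/-1, one entry per probe
#' @export
classify_atropisomer <- function(conf, probes, tolerance = 0.1) {
  vapply(probes, function(q) probe_sign(conf, q, tolerance), integer(1))
}

key_string <- function(key) paste(ifelse(key > 0, "+", "-"), collapse = "")

#' Filter a pool to one atropisomer class
#'
#' Classifies every pool member and keeps those matching the reference key.
#' `reference = "majority"` keeps the modal class (ties raise an error and
#' require an explicit reference key).
#'
#' @param pool list of `lanthi_conformer`
#' @param probes list of [probe_quad()]
#' @param reference `"majority"` or an explicit key (integer vector of +1/-1)
#' @param tolerance passed to [probe_sign()]
#' @return list: `pool` (retained members), `kept` (their indices), `census`
#'   (data.frame `key`, `count`), `reference` (the key used)
#' @export
filter_pool <- function(pool, probes, reference = "majority",
                        tolerance = 0.1) {
  if (length(pool) == 0L) stop("empty pool")
  keys <- lapply(pool, classify_atropisomer, probes = probes,
                 tolerance = tolerance)
  labels <- vapply(keys, key_string, character(1))
  census <- as.data.frame(table(key = labels), stringsAsFactors = FALSE)
  names(census) <- c("key", "count")
  census <- census[order(-census$count, census$key), , drop = FALSE]
  rownames(census) <- NULL
  if (identical(reference, "majority")) {
    top <- census$count == max(census$count)
    if (sum(top) > 1L)
      stop("tie for the majority atropisomer class; pass an explicit reference key")
    ref_label <- census$key[top][[1]]
    reference <- keys[[match(ref_label, labels)]]
  } else {
    ref_label <- key_string(reference)
  }
  kept <- which(labels == ref_label)
  list(pool = pool[kept], kept = kept, census = census, reference = reference)
}

#' Select probe quads that distinguish candidate atropisomers
#'
#' Given conformers representing the potential atropisomer classes, searches
#' plane triples of consecutive CA positions combined with probe residues
#' for quads that are non-degenerate in every candidate and whose signs
#' differ between at least one candidate pair, then greedily keeps quads
#' until every candidate pair is distinguished (or `max_probes` is reached).
#' This mirrors strategic probe selection: quads are chosen with knowledge
#' of the atropisomers they must tell apart.
#'
#' @param confs list of `lanthi_conformer` candidates (>= 2)
#' @param max_probes cap on the returned probe count
#' @param tolerance passed to [probe_sign()]
#' @return list of [probe_quad()]
#' @export
discriminating_probes <- function(confs, max_probes = 4, tolerance = 0.1) {
  if (length(confs) < 2L) stop("need at least two candidate conformers")
  n <- nrow(confs[[1]]$topology$residues)
  pairs <- utils::combn(length(confs), 2)
  chosen <- list(); covered <- rep(FALSE, ncol(pairs))
  for (i in seq_len(n - 2L)) {
    for (m in setdiff(seq_len(n), i:(i + 2L))) {
      quad <- probe_quad(c(i, i + 1L, i + 2L), m)
      signs <- tryCatch(
        vapply(confs, probe_sign, integer(1), quad = quad,
               tolerance = tolerance),
        error = function(e) NULL)
      if (is.null(signs)) next
      splits <- vapply(seq_len(ncol(pairs)), function(k)
        signs[[pairs[1, k]]] != signs[[pairs[2, k]]], logical(1))
      if (any(splits & !covered)) {
        chosen <- c(chosen, list(quad))
        covered <- covered | splits
        if (all(covered) || length(chosen) >= max_probes)
          return(chosen)
      }
    }
  }
  if (length(chosen) == 0L)
    stop("no probe quad distinguishes the candidates")
  chosen
}

#' Heuristic probe suggestion
#'
#' Suggests one probe per ring pair: the plane from three consecutive CA
#' positions inside one ring's span, the probe from the midpoint residue of
#' the other ring. A convenience only -- probe design is the analyst's
#' responsibility.
#'
#' @param topology a `lanthi_topology` with at least two rings
#' @return list of [probe_quad()]
#' @export
suggest_probes <- function(topology) {
  rings <- topology$rings
  if (nrow(rings) < 2L)
    stop("probe suggestion needs at least two rings")
  probes <- list()
  pairs <- utils::combn(nrow(rings), 2)
  for (c in seq_len(ncol(pairs))) {
    sa <- ring_span(rings[pairs[1, c], ])
    sb <- ring_span(rings[pairs[2, c], ])
    plane <- seq(sa[1], min(sa[1] + 2L, sa[2]))
    if (length(unique(plane)) < 3L) next
    probe <- round(mean(sb))
    if (probe %in% plane) next
    probes <- c(probes, list(probe_quad(plane, probe)))
  }
  if (length(probes) == 0L) stop("no usable probe quads found")
  probes
}
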