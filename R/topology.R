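# Lanthipeptide topology: the single source of truth for residue identity and
# thioether connectivity. A topology is parsed from a small line-oriented text
# format:
#
#   # comment
#   seq A[DHA]CGK[ABU]C
#   ring 2-3 lan
#   ring 6-7 melan DL
#
# Sequence letters are one-letter canonical codes; bracketed tokens are
# three-letter codes for noncanonicals (DHA, DHB, ABU), explicit canonical
# three-letter codes, or D-<letter> for D-amino acids (e.g. [D-A] = D-alanine).
# All positions are 1-based.

AA1 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")
NONCANONICAL <- c("DHA", "DHB", "ABU")

residue_spec <- function(position, code, chirality) {
  sp2 <- code %in% c("DHA", "DHB")
  if (sp2 || code == "GLY") chirality <- "achiral"
  list(position = position, code = code, chirality = chirality,
       alpha_sp2 = sp2)
}

parse_residue_token <- function(token, position) {
  if (nchar(token) == 1L) {
    code <- AA1[[toupper(token)]]
    if (is.null(code)) stop(sprintf("unknown residue letter '%s'", token))
    return(residue_spec(position, code, "L"))
  }
  tok <- toupper(token)
  if (grepl("^D-[A-Z]$", tok)) {
    letter <- substr(tok, 3, 3)
    code <- AA1[[letter]]
    if (is.null(code)) stop(sprintf("unknown residue letter in '%s'", token))
    return(residue_spec(position, code, "D"))
  }
  if (tok %in% NONCANONICAL) return(residue_spec(position, tok, "L"))
  if (tok %in% AA1) return(residue_spec(position, tok, "L"))
  stop(sprintf("unknown residue code '[%s]'", token))
}

parse_sequence_string <- function(s) {
  tokens <- character(0)
  i <- 1L; n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (j < 0) stop("unclosed '[' in sequence")
      tokens <- c(tokens, substr(s, i + 1L, i + j - 2L))
      i <- i + j
    } else if (grepl("\\s", ch)) {
      i <- i + 1L
    } else {
      tokens <- c(tokens, ch)
      i <- i + 1L
    }
  }
  tokens
}

#' Parse a lanthipeptide topology specification
#'
#' Reads the line-oriented topology format: a `seq` line giving the modified
#' core peptide (one-letter codes; bracketed three-letter codes such as
#' `[DHA]`, `[DHB]`, `[ABU]` for noncanonicals and `[D-A]` style tokens for
#' D-amino acids) and zero or more `ring` lines, each
#' `ring <donorPos>-<acceptorPos> <lan|melan> [bridgeChirality]` describing a
#' thioether crosslink between the formerly dehydrated donor residue and the
#' cysteine-derived acceptor. Lines starting with `#` are comments. All
#' positions are 1-based.
#'
#' The returned topology is fully validated: ring positions must lie in the
#' sequence, donors must be reacted sp3 residues with a beta carbon
#' (methyllanthionine donors must carry a beta-methyl, i.e. Abu/Thr-derived),
#' acceptors must be cysteine, and no residue may serve in two thioether
#' bridges (the bridge uses the donor's CB and the acceptor's SG, so sharing a
#' residue would share an atom between rings).
#'
#' @param text character scalar (possibly multi-line) or character vector of
#'   lines
#' @return an object of class `lanthi_topology`: a list with `residues`
#'   (data.frame: `position`, `code`, `chirality`, `alpha_sp2`) and `rings`
#'   (data.frame: `donor`, `acceptor`, `type`, `chirality`)
#' @seealso [write_topology()], [classify_ring_pair()], [helix_compatible()]
#' @examples
#' topo <- parse_topology("seq ACDGK\nring 1-3 lan")
#' topo$rings
#' @export
parse_topology <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  residues <- NULL
  rings <- list()
  for (k in seq_along(lines)) {
    line <- trimws(sub("#.*$", "", lines[[k]]))
    if (line == "") next
    parts <- strsplit(line, "\\s+")[[1]]
    head <- tolower(parts[[1]])
    if (head == "seq") {
      if (length(parts) < 2L)
        stop(sprintf("line %d: 'seq' needs a sequence string", k))
      if (!is.null(residues)) stop(sprintf("line %d: duplicate 'seq' line", k))
      tokens <- parse_sequence_string(paste(parts[-1], collapse = ""))
      if (length(tokens) == 0L) stop(sprintf("line %d: empty sequence", k))
      specs <- lapply(seq_along(tokens), function(i)
        tryCatch(parse_residue_token(tokens[[i]], i),
                 error = function(e) stop(sprintf("line %d: %s", k,
                                                  conditionMessage(e)),
                                          call. = FALSE)))
      residues <- data.frame(
        position = vapply(specs, `[[`, integer(1) + 0, "position"),
        code = vapply(specs, `[[`, character(1), "code"),
        chirality = vapply(specs, `[[`, character(1), "chirality"),
        alpha_sp2 = vapply(specs, `[[`, logical(1), "alpha_sp2"),
        stringsAsFactors = FALSE)
    } else if (head == "ring") {
      if (length(parts) < 3L)
        stop(sprintf("line %d: 'ring' needs '<donor>-<acceptor> <lan|melan>'", k))
      m <- regmatches(parts[[2]], regexec("^([0-9]+)-([0-9]+)$", parts[[2]]))[[1]]
      if (length(m) != 3L)
        stop(sprintf("line %d: malformed ring positions '%s'", k, parts[[2]]))
      type <- tolower(parts[[3]])
      if (!type %in% c("lan", "melan"))
        stop(sprintf("line %d: ring type must be 'lan' or 'melan'", k))
      chir <- if (length(parts) >= 4L) toupper(parts[[4]]) else "DL"
      rings[[length(rings) + 1L]] <- list(
        donor = as.integer(m[[2]]), acceptor = as.integer(m[[3]]),
        type = c(lan = "lanthionine", melan = "methyllanthionine")[[type]],
        chirality = chir)
    } else {
      stop(sprintf("line %d: unknown directive '%s'", k, parts[[1]]))
    }
  }
  if (is.null(residues)) stop("topology has no 'seq' line")
  rings_df <- if (length(rings) == 0L) {
    data.frame(donor = integer(0), acceptor = integer(0),
               type = character(0), chirality = character(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(donor = vapply(rings, `[[`, integer(1), "donor"),
               acceptor = vapply(rings, `[[`, integer(1), "acceptor"),
               type = vapply(rings, `[[`, character(1), "type"),
               chirality = vapply(rings, `[[`, character(1), "chirality"),
               stringsAsFactors = FALSE)
  }
  topo <- structure(list(residues = residues, rings = rings_df),
                    class = "lanthi_topology")
  validate_topology(topo)
  topo
}

#' Read a topology file
#' @param path path to a topology spec file
#' @return a `lanthi_topology`
#' @export
read_topology <- function(path) parse_topology(readLines(path, warn = FALSE))

validate_topology <- function(topo) {
  res <- topo$residues
  rings <- topo$rings
  n <- nrow(res)
  for (i in seq_len(nrow(rings))) {
    r <- rings[i, ]
    if (r$donor < 1 || r$donor > n || r$acceptor < 1 || r$acceptor > n)
      stop(sprintf("ring %d: position out of range (sequence has %d residues)",
                   i, n))
    if (r$donor == r$acceptor)
      stop(sprintf("ring %d: donor and acceptor are the same residue", i))
    dcode <- res$code[[r$donor]]
    acode <- res$code[[r$acceptor]]
    if (dcode %in% c("DHA", "DHB"))
      stop(sprintf(
        "ring %d: donor %d is still dehydrated (%s); a ring donor is a reacted sp3 residue",
        i, r$donor, dcode))
    if (dcode == "GLY")
      stop(sprintf("ring %d: donor %d (GLY) has no beta carbon", i, r$donor))
    if (r$type == "methyllanthionine" && !dcode %in% c("ABU", "THR"))
      stop(sprintf(
        "ring %d: methyllanthionine donor %d must be threonine-derived (ABU/THR), got %s",
        i, r$donor, dcode))
    # the acceptor is cysteine-derived; any sp3 residue with a beta carbon is
    # accepted (an SG is attached at build time if the code lacks one)
    if (acode %in% c("DHA", "DHB"))
      stop(sprintf("ring %d: acceptor %d cannot be a dehydrated residue",
                   i, r$acceptor))
    if (acode == "GLY")
      stop(sprintf("ring %d: acceptor %d (GLY) has no beta carbon",
                   i, r$acceptor))
  }
  used <- c(rings$donor, rings$acceptor)
  if (anyDuplicated(used))
    stop(sprintf(
      "residue %d participates in more than one thioether bridge",
      used[duplicated(used)][[1]]))
  invisible(topo)
}

#' Serialize a topology back to its text format
#'
#' The output round-trips: `parse_topology(write_topology(x))` is identical
#' to `x`.
#' @param topo a `lanthi_topology`
#' @param path optional file path; if given the text is written there
#' @return the topology text, invisibly when `path` is given
#' @export
write_topology <- function(topo, path = NULL) {
  res <- topo$residues
  tok <- vapply(seq_len(nrow(res)), function(i) {
    code <- res$code[[i]]
    if (res$chirality[[i]] == "D")
      return(sprintf("[D-%s]", names(AA1)[match(code, AA1)]))
    one <- names(AA1)[match(code, AA1)]
    if (!is.na(one)) one else sprintf("[%s]", code)
  }, character(1))
  lines <- paste0("seq ", paste(tok, collapse = ""))
  short <- c(lanthionine = "lan", methyllanthionine = "melan")
  for (i in seq_len(nrow(topo$rings))) {
    r <- topo$rings[i, ]
    lines <- c(lines, sprintf("ring %d-%d %s %s", r$donor, r$acceptor,
                              short[[r$type]], r$chirality))
  }
  text <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

#' @export
print.lanthi_topology <- function(x, ...) {
  cat(sprintf("lanthipeptide topology: %d residues, %d ring(s)\n",
              nrow(x$residues), nrow(x$rings)))
  cat(" ", write_topology(x), "\n")
  invisible(x)
}

#' Sequence span of a ring
#'
#' Inclusive interval `[min(donor, acceptor), max(donor, acceptor)]`. Rings
#' are direction-agnostic: the acceptor may precede the donor.
#' @param ring one ring: a list or one-row data.frame with `donor`, `acceptor`
#' @return integer vector `c(lo, hi)`
#' @export
ring_span <- function(ring) {
  ring <- as.list(ring)
  c(min(ring$donor, ring$acceptor), max(ring$donor, ring$acceptor))
}

#' Classify the topological relationship of two rings
#'
#' Ring pairs in lanthipeptides fall into three classes by their sequence
#' spans: adjacent (disjoint intervals), nested (one interval strictly
#' contains the other) and overlapping (interleaved). Identical spans are
#' degenerate and raise an error. The classification is symmetric.
#'
#' @param a,b rings (lists or one-row data.frames with `donor`, `acceptor`)
#' @return one of `"adjacent"`, `"overlapping"`, `"nested"`
#' @examples
#' classify_ring_pair(list(donor = 1, acceptor = 5), list(donor = 7, acceptor = 11))
#' @export
classify_ring_pair <- function(a, b) {
  sa <- ring_span(a); sb <- ring_span(b)
  if (sa[1] == sb[1] && sa[2] == sb[2])
    stop("degenerate: rings have identical sequence spans")
  if (sa[2] < sb[1] || sb[2] < sa[1]) return("adjacent")
  if ((sa[1] < sb[1] && sb[2] < sa[2]) || (sb[1] < sa[1] && sa[2] < sb[2]))
    return("nested")
  "overlapping"
}

#' Pairwise ring-class table for a topology
#' @param topo a `lanthi_topology`
#' @return data.frame with columns `ring_a`, `ring_b`, `class`
#' @export
ring_classes <- function(topo) {
  n <- nrow(topo$rings)
  if (n < 2L)
    return(data.frame(ring_a = integer(0), ring_b = integer(0),
                      class = character(0), stringsAsFactors = FALSE))
  pairs <- utils::combn(n, 2)
  data.frame(
    ring_a = pairs[1, ], ring_b = pairs[2, ],
    class = apply(pairs, 2, function(p)
      classify_ring_pair(topo$rings[p[1], ], topo$rings[p[2], ])),
    stringsAsFactors = FALSE)
}

#' Is a ring compatible with an alpha helix?
#'
#' Helical lanthionine rings place the cysteine three or four residues after
#' its conjugation partner, matching one helical turn; rings with other
#' spacings are unlikely to sit inside a helix.
#' @param ring a ring (list or one-row data.frame with `donor`, `acceptor`)
#' @return `TRUE` iff `acceptor - donor` is 3 or 4
#' @export
helix_compatible <- function(ring) {
  ring <- as.list(ring)
  (ring$acceptor - ring$donor) %in% c(3L, 4L)
}
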