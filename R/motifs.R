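#' Adaptation-network motifs
#'
#' A motif is a serial chain or a two-branch parallel arrangement of the
#' three elementary computations: subtractive adaptation (`"S"`), divisive
#' adaptation (`"D"`) and rectification (`"R"`). The generating grammar is
#' `R/0 -> S/D/0 -> R/0 -> S/D/0 -> R/0` for serial chains (`0` = empty
#' node) and, for parallel networks, an input node (`R/0`), two branches
#' each following `R/0 -> S/D/0 -> R/0`, and an output node (`R/0`).
#' Branch outputs are combined by sample-wise summation.
#'
#' @param serial character vector of node labels for a serial motif
#'   (`"S"`, `"D"`, `"R"`; empty vector = identity network).
#' @param input,branch1,branch2,output node label vectors for a parallel
#'   motif (empty vectors allowed).
#' @return object of class `"network_motif"`.
#' @export
network_motif <- function(serial = NULL, input = character(0),
                          branch1 = NULL, branch2 = NULL,
                          output = character(0)) {
  drop0 <- function(x) {
    x <- as.character(x)
    x[x != "0" & x != ""]
  }
  if (!is.null(serial)) {
    m <- structure(list(topology = "serial", nodes = drop0(serial)),
                   class = "network_motif")
  } else {
    if (is.null(branch1) || is.null(branch2))
      stop("parallel motifs need branch1 and branch2")
    m <- structure(list(topology = "parallel", input = drop0(input),
                        branch1 = drop0(branch1), branch2 = drop0(branch2),
                        output = drop0(output)),
                   class = "network_motif")
  }
  ok <- motif_validate(m)
  if (!isTRUE(ok)) stop("invalid motif: ", ok)
  m
}

# node sequences reachable from the 5-slot serial grammar / 3-slot branch
# grammar, used for validation (memoised)
.motif_env <- new.env(parent = emptyenv())

grammar_sequences <- function(kind = c("serial", "branch", "node")) {
  kind <- match.arg(kind)
  key <- paste0("seqs_", kind)
  if (!is.null(.motif_env[[key]])) return(.motif_env[[key]])
  slots <- switch(kind,
    serial = list(c("R", "0"), c("S", "D", "0"), c("R", "0"),
                  c("S", "D", "0"), c("R", "0")),
    branch = list(c("R", "0"), c("S", "D", "0"), c("R", "0")),
    node = list(c("R", "0")))
  grid <- expand.grid(rev(slots), stringsAsFactors = FALSE)[, rev(seq_along(slots)), drop = FALSE]
  seqs <- unique(apply(grid, 1, function(r) paste(r[r != "0"], collapse = "")))
  .motif_env[[key]] <- seqs
  seqs
}

#' Validate a motif against the generating grammar
#'
#' @param motif a `"network_motif"`.
#' @return `TRUE`, or a string naming the offending part.
#' @export
motif_validate <- function(motif) {
  chk <- function(nodes, kind, what) {
    s <- paste(nodes, collapse = "")
    if (!(s %in% grammar_sequences(kind)))
      return(sprintf("%s node sequence '%s' not generated by the grammar",
                     what, s))
    TRUE
  }
  if (motif$topology == "serial") return(chk(motif$nodes, "serial", "serial"))
  for (part in list(c("input", "node"), c("branch1", "branch"),
                    c("branch2", "branch"), c("output", "node"))) {
    ok <- chk(motif[[part[1]]], part[2], part[1])
    if (!isTRUE(ok)) return(ok)
  }
  TRUE
}

collapse_rr <- function(nodes) {
  if (length(nodes) < 2) return(nodes)
  keep <- c(TRUE, !(nodes[-1] == "R" & nodes[-length(nodes)] == "R"))
  nodes[keep]
}

#' Structural canonicalization of a motif
#'
#' Drops empty nodes and collapses adjacent rectifiers (rectification is
#' idempotent). For parallel motifs, a leading branch rectifier directly
#' after a rectifying input node is dropped, and the two branches are put in
#' a canonical order (branch summation is commutative). This is a fast,
#' conservative pre-pass; the arbiter of uniqueness is functional
#' equivalence on a stimulus battery ([dedup_functional()]).
#'
#' @param motif a `"network_motif"`.
#' @return canonicalized `"network_motif"`.
#' @export
motif_canonicalize <- function(motif) {
  if (motif$topology == "serial") {
    motif$nodes <- collapse_rr(motif$nodes)
    return(motif)
  }
  motif$input <- collapse_rr(motif$input)
  fix_branch <- function(b) {
    b <- collapse_rr(b)
    if (length(motif$input) > 0 && length(b) > 0 && b[1] == "R")
      b <- collapse_rr(c("R", b))[-1]  # input already rectifies
    b
  }
  b1 <- fix_branch(motif$branch1)
  b2 <- fix_branch(motif$branch2)
  key <- function(b) paste(b, collapse = "")
  if (key(b2) < key(b1)) { tmp <- b1; b1 <- b2; b2 <- tmp }
  motif$branch1 <- b1
  motif$branch2 <- b2
  motif$output <- collapse_rr(motif$output)
  motif
}

#' @export
format.network_motif <- function(x, ...) {
  pp <- function(n) if (length(n) == 0) "-" else paste(n, collapse = ">")
  if (x$topology == "serial") {
    sprintf("[%s]", pp(x$nodes))
  } else {
    sprintf("[%s|(%s)+(%s)|%s]", pp(x$input), pp(x$branch1), pp(x$branch2),
            pp(x$output))
  }
}

#' @export
print.network_motif <- function(x, ...) {
  cat(sprintf("<network_motif %s> %s\n", x$topology, format(x)))
  invisible(x)
}

#' Enumerate all serial motifs of the grammar
#'
#' Expands every assignment of the five serial slots
#' (`2 * 3 * 2 * 3 * 2 = 72` raw assignments), applies structural
#' canonicalization and returns the distinct structures together with the
#' raw-to-structure mapping.
#'
#' @return list of class `"motif_set"`: `motifs` (list of distinct
#'   canonical motifs), `raw` (data frame mapping each raw slot assignment
#'   to its canonical form), `raw_count`, `structural_count`.
#' @export
enumerate_serial <- function() {
  slots <- expand.grid(r1 = c("R", "0"), a1 = c("S", "D", "0"),
                       r2 = c("R", "0"), a2 = c("S", "D", "0"),
                       r3 = c("R", "0"), stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  slots <- slots[order(apply(slots, 1, paste, collapse = "")), , drop = FALSE]
  canon <- character(nrow(slots))
  motifs <- list()
  for (i in seq_len(nrow(slots))) {
    nodes <- unlist(slots[i, ], use.names = FALSE)
    m <- motif_canonicalize(network_motif(serial = nodes))
    canon[i] <- format(m)
    if (!(canon[i] %in% names(motifs))) motifs[[canon[i]]] <- m
  }
  structure(list(motifs = unname(motifs),
                 canonical = names(motifs),
                 raw = data.frame(assignment = apply(slots, 1, paste,
                                                     collapse = ""),
                                  canonical = canon),
                 raw_count = nrow(slots),
                 structural_count = length(motifs),
                 topology = "serial"),
            class = "motif_set")
}

#' Enumerate all two-branch parallel motifs of the grammar
#'
#' Expands every assignment of input node, two three-slot branches and
#' output node (`2 * 12 * 12 * 2 = 576` raw assignments), canonicalizes
#' (including branch reordering, since branch summation is commutative) and
#' returns the distinct structures.
#'
#' @return a `"motif_set"` (see [enumerate_serial()]).
#' @export
enumerate_parallel <- function() {
  branch_opts <- expand.grid(r1 = c("R", "0"), a = c("S", "D", "0"),
                             r2 = c("R", "0"), stringsAsFactors = FALSE,
                             KEEP.OUT.ATTRS = FALSE)
  bstr <- apply(branch_opts, 1, paste, collapse = "")
  grid <- expand.grid(inp = c("R", "0"), b1 = bstr, b2 = bstr,
                      out = c("R", "0"), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(apply(grid, 1, paste, collapse = "|")), , drop = FALSE]
  canon <- character(nrow(grid))
  motifs <- list()
  for (i in seq_len(nrow(grid))) {
    m <- network_motif(input = grid$inp[i],
                       branch1 = strsplit(grid$b1[i], "")[[1]],
                       branch2 = strsplit(grid$b2[i], "")[[1]],
                       output = grid$out[i])
    m <- motif_canonicalize(m)
    canon[i] <- format(m)
    if (!(canon[i] %in% names(motifs))) motifs[[canon[i]]] <- m
  }
  structure(list(motifs = unname(motifs),
                 canonical = names(motifs),
                 raw = data.frame(assignment = apply(grid, 1, paste,
                                                     collapse = "|"),
                                  canonical = canon),
                 raw_count = nrow(grid),
                 structural_count = length(motifs),
                 topology = "parallel"),
            class = "motif_set")
}

#' @export
print.motif_set <- function(x, ...) {
  cat(sprintf("<motif_set %s> %d raw assignments -> %d structural classes\n",
              x$topology, x$raw_count, x$structural_count))
  invisible(x)
}

#' Stimulus battery for functional motif comparison
#'
#' Covers the signal regimes that distinguish the elementary computations:
#' pure tones of several frequencies, signed smoothed steps, noise with an
#' intensity step, and an offset-plus-tone composite.
#'
#' @param seed integer seed for the noise item.
#' @param sample_rate sampling rate, Hz.
#' @return list of [stimulus()] objects.
#' @export
motif_battery <- function(seed = 1, sample_rate = 10000) {
  noise <- protocol_noise_steps(c(0.25, 2), block = 0.15, seed = seed,
                                sample_rate = sample_rate)
  tone_off <- sinusoid(300, 0.5, 0.3, sample_rate)
  tone_off$samples <- tone_off$samples + c(rep(0, sample_rate * 0.05),
                                           rep(0.44, length(tone_off$samples) -
                                                 sample_rate * 0.05))
  list(
    tone100 = sinusoid(100, 1, 0.25, sample_rate),
    tone300 = sinusoid(300, 2, 0.25, sample_rate),
    tone900 = sinusoid(900, 0.5, 0.25, sample_rate),
    step_up = step_deflection(0.44, 0.05, 0.25, 0.3, sample_rate),
    step_down = step_deflection(-0.44, 0.05, 0.25, 0.3, sample_rate),
    noise_step = noise,
    offset_tone = tone_off)
}

#' Functional deduplication of motifs on a stimulus battery
#'
#' Two motifs are considered equivalent when the maximum absolute
#' difference of their outputs is below `tol` on every battery stimulus at
#' fixed default parameters. Returns equivalence classes built greedily
#' against class representatives; at the default tolerance the classes are
#' well separated, and the equivalence-relation property (transitivity at
#' fixed `tol`) is verified in the test suite.
#'
#' @param motifs list of `"network_motif"` objects (or a `"motif_set"`).
#' @param battery list of stimuli; see [motif_battery()].
#' @param tol absolute output tolerance (inputs are O(1), so this is the
#'   tolerance on the input scale).
#' @param params a [stage_params()].
#' @return list with `classes` (class index per motif), `representatives`
#'   (motif index of each class representative), `motifs`, `n_classes`,
#'   and `signatures` (concatenated battery outputs, one row per motif).
#' @export
dedup_functional <- function(motifs, battery = motif_battery(),
                             tol = 1e-6, params = stage_params()) {
  if (inherits(motifs, "motif_set")) motifs <- motifs$motifs
  if (length(battery) == 0) stop("battery must not be empty")
  sig <- lapply(motifs, function(m) {
    unlist(lapply(battery, function(s) run_motif(m, s, params)$output),
           use.names = FALSE)
  })
  classes <- integer(length(motifs))
  reps <- integer(0)
  for (i in seq_along(motifs)) {
    assigned <- FALSE
    for (ci in seq_along(reps)) {
      if (max(abs(sig[[i]] - sig[[reps[ci]]])) < tol) {
        classes[i] <- ci
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      classes[i] <- length(reps)
    }
  }
  list(classes = classes, representatives = reps, motifs = motifs,
       n_classes = length(reps), signatures = sig)
}
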