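#' Validate a phylogeny as a chronogram
#'
#' A chronogram is a rooted, binary, ultrametric tree whose branch lengths are
#' in units of absolute time (here millions of years, My), so that every tip
#' lies at time 0 (the present) and every internal node has an age measured
#' back from the present. `as_chronogram()` checks these requirements on an
#' [ape::read.tree()]-style `"phylo"` object and returns the tree with class
#' `c("chronogram", "phylo")`.
#'
#' Published chronograms exported from dating software typically carry small
#' rounding errors, so ultrametricity is checked within a relative tolerance:
#' all root-to-tip path lengths must agree within `rel_tol` times the tree
#' height. With `coerce_ultrametric = TRUE`, terminal branches are extended to
#' the maximum tip depth (and a message is emitted) before validation.
#' Polytomies are rejected by default; with `resolve_polytomies = TRUE` they
#' are resolved into zero-length binary splits by [ape::multi2di()] with
#' `random = FALSE` (a deterministic rule), which produces tied branching
#' times downstream. Any root edge is dropped: all analyses in this package
#' are conditioned on the crown.
#'
#' @param phy an object of class `"phylo"`.
#' @param rel_tol ultrametricity tolerance, as a fraction of tree height.
#' @param coerce_ultrametric extend terminal branches to equalise tip depths?
#' @param resolve_polytomies resolve polytomies into zero-length splits?
#' @param quiet suppress validation messages?
#' @return the tree, classed `c("chronogram", "phylo")`, with an attribute
#'   `"chronogram_info"`: a list with `n_tips`, `height` (crown age, My) and
#'   `max_ultrametric_dev` (largest tip-depth deviation, relative to height).
#' @seealso [parse_newick()], [branching_times()]
#' @examples
#' tr <- as_chronogram(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
#' attr(tr, "chronogram_info")$height
#' @export
as_chronogram <- function(phy, rel_tol = 1e-6, coerce_ultrametric = FALSE,
                          resolve_polytomies = FALSE, quiet = FALSE) {
  if (!inherits(phy, "phylo")) stop("'phy' must be a \"phylo\" object")
  say <- function(...) if (!quiet) message(...)
  if (!is.null(phy$root.edge)) {
    phy$root.edge <- NULL
    say("chronogram: root edge ignored (crown-conditioned analyses)")
  }
  n <- length(phy$tip.label)
  if (n < 2L) stop("a chronogram needs at least 2 tips")
  if (anyDuplicated(phy$tip.label)) stop("duplicate tip labels")
  if (any(!nzchar(phy$tip.label))) stop("empty tip labels")
  if (is.null(phy$edge.length) || length(phy$edge.length) != nrow(phy$edge) ||
      anyNA(phy$edge.length))
    stop("all edges must have branch lengths")
  if (any(phy$edge.length < 0)) stop("negative branch lengths")
  # classify by out-degree: a trifurcating "unrooted" root counts as a
  # polytomy here, since all analyses are rooted
  n_children <- tabulate(phy$edge[, 1], nbins = n + phy$Nnode)[(n + 1L):(n + phy$Nnode)]
  if (any(n_children > 2L)) {
    if (!resolve_polytomies)
      stop("tree contains polytomies (or an unresolved root); set ",
           "resolve_polytomies = TRUE to resolve them into zero-length ",
           "binary splits")
    phy <- ape::multi2di(phy, random = FALSE)
    say("chronogram: polytomies resolved into zero-length binary splits; ",
        "branching times will contain ties")
  }
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  depth <- ape::node.depth.edgelength(phy)
  tipd <- depth[seq_len(n)]
  height <- max(tipd)
  if (height <= 0) stop("tree has zero height")
  dev <- (height - min(tipd)) / height
  if (dev > rel_tol) {
    if (!coerce_ultrametric)
      stop(sprintf(paste0("tree is not ultrametric within tolerance: max ",
                          "relative tip-depth deviation %.3g > rel_tol %.3g"),
                   dev, rel_tol))
    term <- match(seq_len(n), phy$edge[, 2])
    phy$edge.length[term] <- phy$edge.length[term] + (height - tipd)
    say(sprintf("chronogram: %d terminal branches extended by up to %.4g My ",
                n, max(height - tipd)), "to restore ultrametricity")
    depth <- ape::node.depth.edgelength(phy)
    dev <- (height - min(depth[seq_len(n)])) / height
  }
  class(phy) <- c("chronogram", "phylo")
  attr(phy, "chronogram_info") <- list(n_tips = n, height = height,
                                       max_ultrametric_dev = dev)
  phy
}

#' Read a chronogram from a Newick string or file
#'
#' Parses standard Newick (branch lengths required on all non-root edges) and
#' validates the result with [as_chronogram()].
#'
#' @param text a Newick string (terminated by `;`).
#' @param file path to a Newick file (alternative to `text`).
#' @param ... passed on to [as_chronogram()] (tolerance, coercion options).
#' @return a validated chronogram.
#' @examples
#' parse_newick("((A:1,B:1):1,C:2);")
#' @export
parse_newick <- function(text = NULL, file = NULL, ...) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' or 'file'")
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) {
    # locate the first structurally broken character for the error message
    bal <- cumsum((strsplit(text, "")[[1]] == "(") -
                    (strsplit(text, "")[[1]] == ")"))
    off <- if (any(bal < 0)) which(bal < 0)[1] else nchar(text)
    stop(sprintf("malformed Newick near character %d", off))
  }
  as_chronogram(phy, ...)
}

#' Write a chronogram as a Newick string
#'
#' Produces standard Newick with branch lengths printed at a fixed decimal
#' precision and a deterministic child ordering: at every node the child
#' subtree containing the lexicographically smallest tip label is written
#' first. Two topologically identical chronograms therefore always serialise
#' to the same string.
#'
#' @param phy a chronogram (or any rooted `"phylo"` with edge lengths).
#' @param file optional path; when given the string is also written to it.
#' @param precision number of decimal places for branch lengths.
#' @return the Newick string, invisibly when `file` is given.
#' @examples
#' write_newick(parse_newick("(B:1,A:1);"))  # "(A:1.000000,B:1.000000);"
#' @export
write_newick <- function(phy, file = NULL, precision = 6L) {
  stopifnot(inherits(phy, "phylo"), precision >= 0)
  n <- length(phy$tip.label)
  m <- n + phy$Nnode
  po <- ape::reorder.phylo(phy, "postorder")
  elen <- numeric(m)
  elen[po$edge[, 2]] <- po$edge.length
  minlab <- character(m)
  minlab[seq_len(n)] <- phy$tip.label
  str <- character(m)
  str[seq_len(n)] <- phy$tip.label
  kids <- split(po$edge[, 2], po$edge[, 1])
  # postorder edge list guarantees children are finished before their parent
  for (v in unique(po$edge[, 1])) {
    ch <- kids[[as.character(v)]]
    ord <- order(minlab[ch], method = "radix")
    ch <- ch[ord]
    minlab[v] <- minlab[ch[1]]
    str[v] <- paste0("(",
                     paste0(str[ch], ":",
                            formatC(elen[ch], format = "f",
                                    digits = precision),
                            collapse = ","),
                     ")")
  }
  root <- n + 1L
  out <- paste0(str[root], ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

# ages (time before present, My) of all nodes; tips forced to 0
node_ages <- function(phy) {
  n <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  age <- max(depth[seq_len(n)]) - depth
  age[seq_len(n)] <- 0
  age
}

#' Prune a chronogram to a set of tips
#'
#' Returns the subtree induced by `keep`: degree-2 nodes created by pruning
#' are suppressed (their branch lengths summed), so the ages of all retained
#' splits are unchanged and the result is again ultrametric.
#'
#' @param phy a chronogram.
#' @param keep character vector of tip labels to retain (at least 2).
#' @param ... passed to [as_chronogram()] for re-validation.
#' @return the induced chronogram.
#' @examples
#' tr <- parse_newick("(((A:1,B:1):1,C:2):1,D:3);")
#' prune_to_tips(tr, c("A", "D"))
#' @export
prune_to_tips <- function(phy, keep, ...) {
  stopifnot(inherits(phy, "phylo"))
  keep <- unique(as.character(keep))
  bad <- setdiff(keep, phy$tip.label)
  if (length(bad)) stop("unknown tip label(s): ", paste(bad, collapse = ", "))
  if (length(keep) < 2L) stop("need at least 2 tips to keep")
  out <- ape::keep.tip(phy, keep)
  as_chronogram(out, quiet = TRUE, ...)
}

#' Extract the clade spanned by a set of tips
#'
#' Returns the subtree rooted at the most recent common ancestor (MRCA) of
#' `tips`, including *all* of its descendants; the crown age of the result is
#' the MRCA's age in the original tree.
#'
#' @param phy a chronogram.
#' @param tips character vector of tip labels (at least 2) whose MRCA defines
#'   the clade.
#' @param ... passed to [as_chronogram()].
#' @return the clade as a chronogram.
#' @examples
#' tr <- parse_newick("(((A:1,B:1):1,C:2):1,D:3);")
#' extract_clade(tr, c("A", "C"))  # 3-tip clade of height 2
#' @export
extract_clade <- function(phy, tips, ...) {
  stopifnot(inherits(phy, "phylo"))
  tips <- unique(as.character(tips))
  bad <- setdiff(tips, phy$tip.label)
  if (length(bad)) stop("unknown tip label(s): ", paste(bad, collapse = ", "))
  if (length(tips) < 2L) stop("need at least 2 tips to define an MRCA")
  if (length(tips) == length(phy$tip.label))
    return(as_chronogram(phy, quiet = TRUE, ...))
  mrca <- ape::getMRCA(phy, tips)
  root <- length(phy$tip.label) + 1L
  if (mrca == root) return(as_chronogram(phy, quiet = TRUE, ...))
  out <- ape::extract.clade(phy, mrca)
  as_chronogram(out, quiet = TRUE, ...)
}
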