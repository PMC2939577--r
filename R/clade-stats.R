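#' Slowinski-Guyer sister-clade richness test
#'
#' Tests whether a sister pair of clades is more uneven in extant species
#' richness than expected under the equal-rates-Markov (ERM) null, in which
#' every way of splitting \eqn{n = r + s} species between two labelled sister
#' clades is equally likely. The one-tailed probability that the specified
#' clade is at least as small as observed is \eqn{p = s/(n - 1)}; the
#' two-tailed value doubles it, capped at 1.
#'
#' @param r species richness of the larger clade (integer >= s).
#' @param s species richness of the smaller clade (integer >= 1).
#' @param tail `"one"` (default; the convention under which a 19,811 / 655
#'   sister pair gives p = 0.032) or `"two"`.
#' @return an object of class `"sg_test"`: list with `r`, `s`, `tail`, `p`.
#' @examples
#' slowinski_guyer(19811, 655)$p   # 655/20465 = 0.032
#' @references Slowinski, J.B. & Guyer, C. (1989) Am. Nat. 134:907-921.
#' @export
slowinski_guyer <- function(r, s, tail = c("one", "two")) {
  tail <- match.arg(tail)
  if (!isTRUE(r >= s) || !isTRUE(s >= 1))
    stop("need r >= s >= 1")
  if (r != round(r) || s != round(s)) stop("richness values must be integers")
  p1 <- s / (r + s - 1)
  p <- if (tail == "one") p1 else min(1, 2 * p1)
  structure(list(r = r, s = s, tail = tail, p = p), class = "sg_test")
}

#' @export
print.sg_test <- function(x, ...) {
  cat(sprintf("Slowinski-Guyer test: r = %d, s = %d, %s-tailed p = %.4f\n",
              x$r, x$s, x$tail, x$p))
  invisible(x)
}

#' Magallon-Sanderson net diversification rate estimator
#'
#' Estimates the net diversification rate \eqn{\hat r = \lambda - \mu} of a
#' clade from its extant species richness `n`, its age `t` (stem or crown,
#' My) and an assumed extinction fraction \eqn{\epsilon = \mu/\lambda}.
#' Stem mode: \eqn{\hat r = \ln[n(1-\epsilon) + \epsilon]/t}. Crown mode
#' (Magallon & Sanderson 2001, eq. 7):
#' \deqn{\hat r = \frac{1}{t}\left\{\ln\left[\tfrac{1}{2} n (1-\epsilon^2) +
#'   2\epsilon + \tfrac{1}{2}(1-\epsilon)
#'   \sqrt{n\,(n\epsilon^2 - 8\epsilon + 2n\epsilon + n)}\right] -
#'   \ln 2\right\}}
#' which reduces to \eqn{(\ln n - \ln 2)/t} at \eqn{\epsilon = 0}. A
#' "2:1 speciation:extinction" assumption corresponds to `epsilon = 0.5`.
#'
#' @param n extant species richness (>= 1 stem; >= 2 crown).
#' @param t clade age in My (> 0).
#' @param epsilon extinction fraction in `[0, 1)`.
#' @param mode `"crown"` or `"stem"`.
#' @return an object of class `"ms_rate"`: list with `n`, `t`, `mode`,
#'   `epsilon` and `r_hat` (per My).
#' @examples
#' ms_rate(19811, 98.5)$r_hat              # 0.0934
#' ms_rate(19811, 98.5, mode = "stem")$r_hat  # 0.1004
#' @references Magallon, S. & Sanderson, M.J. (2001) Evolution 55:1762-1780.
#' @export
ms_rate <- function(n, t, epsilon = 0, mode = c("crown", "stem")) {
  mode <- match.arg(mode)
  if (!isTRUE(t > 0)) stop("'t' must be > 0")
  if (!isTRUE(epsilon >= 0 && epsilon < 1)) stop("'epsilon' must be in [0, 1)")
  if (mode == "stem") {
    if (!isTRUE(n >= 1)) stop("stem mode needs n >= 1")
    r_hat <- log(n * (1 - epsilon) + epsilon) / t
  } else {
    if (!isTRUE(n >= 2)) stop("crown mode needs n >= 2")
    e <- epsilon
    inner <- 0.5 * n * (1 - e^2) + 2 * e +
      0.5 * (1 - e) * sqrt(n * (n * e^2 - 8 * e + 2 * n * e + n))
    r_hat <- (log(inner) - log(2)) / t
  }
  structure(list(n = n, t = t, mode = mode, epsilon = epsilon,
                 r_hat = r_hat), class = "ms_rate")
}

#' @export
print.ms_rate <- function(x, ...) {
  cat(sprintf(
    "Magallon-Sanderson %s rate: n = %g, t = %.4g My, eps = %.2f -> r = %.4f/My\n",
    x$mode, x$n, x$t, x$epsilon, x$r_hat))
  invisible(x)
}

#' Relative cladogenesis (broken-stick) rate-shift test
#'
#' For every branch of a chronogram, asks whether the branch is ancestral to
#' more extant (sampled) descendants than expected by chance among the
#' lineages alive at its origin. With `k` reconstructed lineages present at
#' the branch's origin (the age of its parent node; lineages originating at
#' exactly that age are all counted) and `r` of the tree's `n` tips
#' descending from the branch, the null distributes the `n` tips uniformly
#' over all compositions into `k` positive parts (the ERM "broken stick"),
#' giving the tail probability
#' \deqn{p = \binom{n - r}{k - 1} / \binom{n - 1}{k - 1}.}
#' Bonferroni correction multiplies by the number of branches tested.
#' Because nested clades share descendants, an unusually diverse clade drags
#' its parent branches toward significance ("trickle-down"); the column
#' `sig_descendant` marks, for each significant branch, whether a descendant
#' branch is also significant, supporting the conservative reading that
#' attributes a shift to the shallowest significant branch.
#'
#' If the tree is a subsample of a richer clade (attribute `"subsampled"`,
#' see [subsample_tips()]), the test still operates on the sampled tips only
#' and a caveat is printed.
#'
#' @param phy a chronogram with n >= 3 tips.
#' @param alpha significance level applied to the corrected p (default 0.05).
#' @return a data frame of class `"rc_table"`, one row per branch: `branch`
#'   (id of the child node), `parent`, `slice_My`, `k`, `r_desc`, `n`,
#'   `p_raw`, `p_bonferroni`, `significant`, `sig_descendant`. The Bonferroni
#'   factor (number of branches tested) is in `attr(, "n_tests")`.
#' @examples
#' rc <- rc_test(simulate_yule(16, seed = 1))
#' head(rc[order(rc$p_raw), ])
#' @export
rc_test <- function(phy, alpha = 0.05) {
  stopifnot(inherits(phy, "phylo"))
  phy2 <- if (inherits(phy, "chronogram")) phy else as_chronogram(phy, quiet = TRUE)
  n <- length(phy2$tip.label)
  if (n < 3L) stop("rc_test needs at least 3 tips")
  ages <- node_ages(phy2)
  nint <- phy2$Nnode
  xall <- ages[(n + 1L):(n + nint)]           # internal node ages
  child <- phy2$edge[, 2]
  par <- phy2$edge[, 1]
  slice <- ages[par]
  # lineages alive at the slice: 1 + number of splits at age >= slice
  k <- 1L + vapply(slice, function(s) sum(xall >= s), integer(1))
  # descendant tip counts per node
  ndesc <- integer(n + nint)
  ndesc[seq_len(n)] <- 1L
  po <- ape::reorder.phylo(phy2, "postorder")
  for (i in seq_len(nrow(po$edge)))
    ndesc[po$edge[i, 1]] <- ndesc[po$edge[i, 1]] + ndesc[po$edge[i, 2]]
  r_desc <- ndesc[child]
  p_raw <- exp(lchoose(n - r_desc, k - 1L) - lchoose(n - 1L, k - 1L))
  n_tests <- length(child)
  p_bon <- pmin(1, p_raw * n_tests)
  sig <- p_bon < alpha
  # does any strictly descendant branch also reach significance?
  sig_desc <- logical(n_tests)
  if (any(sig)) {
    # branch j is ancestral to branch i iff the tips under i are a strict
    # subset of those under j
    tipsets <- vector("list", n + nint)
    for (v in seq_len(n)) tipsets[[v]] <- v
    for (i in seq_len(nrow(po$edge)))
      tipsets[[po$edge[i, 1]]] <- c(tipsets[[po$edge[i, 1]]],
                                    tipsets[[po$edge[i, 2]]])
    for (j in which(sig)) {
      mine <- tipsets[[child[j]]]
      for (i in which(sig)) {
        if (i == j) next
        if (r_desc[i] < r_desc[j] && all(tipsets[[child[i]]] %in% mine)) {
          sig_desc[j] <- TRUE
          break
        }
      }
    }
  }
  out <- data.frame(branch = child, parent = par, slice_My = slice,
                    k = k, r_desc = r_desc, n = n, p_raw = p_raw,
                    p_bonferroni = p_bon, significant = sig,
                    sig_descendant = sig_desc)
  attr(out, "n_tests") <- n_tests
  attr(out, "alpha") <- alpha
  if (!is.null(attr(phy, "subsampled")))
    message("rc_test: tree is flagged as a subsample; the test is computed ",
            "on the sampled tips only and rate shifts may reflect sampling")
  class(out) <- c("rc_table", "data.frame")
  out
}

#' @export
print.rc_table <- function(x, ...) {
  cat(sprintf("Relative cladogenesis test: %d branches tested (Bonferroni x%d), alpha = %g\n",
              attr(x, "n_tests"), attr(x, "n_tests"), attr(x, "alpha")))
  NextMethod()
}
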