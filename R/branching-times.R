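#' Branching times of a chronogram
#'
#' Reduces a chronogram to the representation every tempo statistic and
#' diversification likelihood in this package consumes: the ordered internal
#' node ages \eqn{x_2 \ge x_3 \ge \dots \ge x_n} (time before present, My;
#' \eqn{x_2} is the crown age), the internode durations
#' \eqn{g_k = x_k - x_{k+1}} (with \eqn{g_n = x_n}), during which exactly
#' \eqn{k} reconstructed lineages existed, and the total lineage-time
#' \eqn{T = \sum_{k=2}^{n} k\, g_k}, which satisfies the identity
#' \eqn{T = 2 x_2 + \sum_{i \ge 3} x_i}.
#'
#' @param x a chronogram (`"phylo"`), or a numeric vector of internal node
#'   ages (any order; they are sorted).
#' @return an object of class `"branching_times"`: a list with elements `n`
#'   (tip count), `x` (ages, descending), `g` (internode durations, named by
#'   the lineage count k = 2..n) and `total_time` (the lineage-time T, My).
#'   Tied ages (zero-length internal branches) are permitted and flagged in
#'   the `ties` element.
#' @examples
#' bt <- branching_times(parse_newick("(((A:1,B:1):1,C:2):1,D:3);"))
#' bt$x            # 3 2 1
#' bt$total_time   # 2*3 + 2 + 1 = 9
#' @export
branching_times <- function(x) {
  if (inherits(x, "phylo")) {
    n <- length(x$tip.label)
    ages <- node_ages(x)[(n + 1L):(n + x$Nnode)]
  } else if (is.numeric(x)) {
    ages <- x
    n <- length(ages) + 1L
  } else stop("'x' must be a \"phylo\" object or a numeric vector of ages")
  if (length(ages) < 1L) stop("need at least one branching time")
  if (any(!is.finite(ages)) || any(ages < 0)) stop("ages must be finite and >= 0")
  xs <- sort(ages, decreasing = TRUE)
  if (xs[length(xs)] <= 0) stop("youngest branching time must be > 0")
  n <- length(xs) + 1L
  g <- c(-diff(xs), xs[length(xs)])
  names(g) <- 2:n
  k <- 2:n
  total <- sum(k * g)
  out <- list(n = n, x = xs, g = g, total_time = total,
              ties = anyDuplicated(xs) > 0L)
  class(out) <- "branching_times"
  out
}

#' @export
print.branching_times <- function(x, ...) {
  cat(sprintf("Branching times: n = %d tips, crown age %.4g My, T = %.4g My%s\n",
              x$n, x$x[1], x$total_time,
              if (x$ties) " (tied ages present)" else ""))
  invisible(x)
}

#' @export
as.data.frame.branching_times <- function(x, ...) {
  data.frame(index = seq.int(2L, x$n), age_My = x$x)
}

# coerce phylo / numeric / branching_times uniformly
as_branching_times <- function(x) {
  if (inherits(x, "branching_times")) x else branching_times(x)
}
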