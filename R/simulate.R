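# Chronogram simulators.
#
# All simulators work on flat parent/age arrays (no recursion), so trees with
# tens of thousands of tips are cheap; phylo objects are only materialised at
# the end. Node numbering follows ape: tips 1..n, crown node n+1, later
# internal nodes in chronological order n+2 .. 2n-1.

# ERM topology for a set of split ages (descending, ages[1] = crown age).
# Each new lineage attaches to a uniformly chosen existing lineage.
.yule_topology <- function(ages) {
  n <- length(ages) + 1L
  nn <- 2L * n - 1L
  parent <- integer(nn)
  age <- numeric(nn)
  open <- integer(n)            # open[l]: node whose split created lineage l
  age[n + 1L] <- ages[1L]
  open[1L] <- open[2L] <- n + 1L
  if (n > 2L) {
    u <- 1L + as.integer(floor(runif(n - 2L) * (2:(n - 1L))))
    for (k in 3:n) {
      v <- n + k - 1L
      uu <- u[k - 2L]
      parent[v] <- open[uu]
      age[v] <- ages[k - 1L]
      open[uu] <- v
      open[k] <- v
    }
  }
  parent[1:n] <- open
  list(parent = parent, age = age, n = n)
}

# flat arrays -> phylo (tip ages may be > 0, e.g. extinct tips)
.flat_to_phylo <- function(parent, age, n, tip.label = paste0("t", seq_len(n))) {
  nn <- 2L * n - 1L
  child <- seq_len(nn)[-(n + 1L)]
  edge <- cbind(parent[child], child)
  phy <- list(edge = edge,
              edge.length = age[edge[, 1]] - age[edge[, 2]],
              tip.label = tip.label,
              Nnode = n - 1L)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

# Branching times (descending) of the subtree induced by the kept tips of a
# binary flat tree: ages of nodes at which two kept-descendant lineages meet.
.induced_x <- function(parent, age, n, keep) {
  nn <- 2L * n - 1L
  hits <- tabulate(parent[seq_len(n)][keep], nbins = nn)
  if (n > 2L)
    for (v in nn:(n + 2L)) if (hits[v] > 0L) {
      p <- parent[v]
      hits[p] <- hits[p] + 1L
    }
  sort(age[hits >= 2L], decreasing = TRUE)
}

#' Simulate a pure-birth (Yule) chronogram with n tips
#'
#' Forward construction conditioned on the tip count by the waiting-time
#' convention: starting from 2 lineages at the crown, while k lineages exist
#' the wait to the next speciation is exponential with rate \eqn{k\lambda};
#' after the n-th lineage appears, the time from the last speciation to the
#' present is drawn as a full \eqn{Exp(n\lambda)} waiting time (the time to
#' the (n+1)-th event) rather than truncated at a birth, which avoids the
#' length bias of stopping exactly on a speciation. The splitting lineage is
#' chosen uniformly, giving an equal-rates-Markov topology.
#'
#' @param n number of tips (>= 2).
#' @param lam speciation rate, per lineage per My (> 0).
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return a chronogram with `n` tips.
#' @examples
#' tr <- simulate_yule(10, lam = 0.5, seed = 1)
#' branching_times(tr)$n
#' @export
simulate_yule <- function(n, lam = 1, seed = NULL) {
  stopifnot(n >= 2, lam > 0)
  n <- as.integer(n)
  with_seed(seed, {
    g <- rexp(n - 1L, rate = lam * (2:n))     # g_k, k = 2..n
    x <- rev(cumsum(rev(g)))                  # x_k = sum_{j>=k} g_j
    tp <- .yule_topology(x)
    as_chronogram(.flat_to_phylo(tp$parent, tp$age, tp$n), quiet = TRUE)
  })
}

# backward inter-event sampler for a piecewise-constant rate in time before
# present: rate_asc[j] applies on [breaks_asc[j], breaks_asc[j+1]) with
# breaks_asc[1] = 0 and the last segment unbounded. Returns split ages desc.
.piecewise_backward_ages <- function(n, rate_asc, breaks_asc) {
  x <- numeric(n - 1L)
  tau <- 0
  j <- 1L
  nb <- length(breaks_asc)
  for (k in n:2) {
    E <- rexp(1L)
    repeat {
      up <- if (j < nb) breaks_asc[j + 1L] else Inf
      cap <- k * rate_asc[j] * (up - tau)
      if (E <= cap) {
        tau <- tau + E / (k * rate_asc[j])
        break
      }
      E <- E - cap
      tau <- up
      j <- j + 1L
    }
    x[n - k + 1L] <- tau
  }
  rev(x)
}

#' Simulate a piecewise-constant-rate pure-birth chronogram
#'
#' The instantaneous speciation rate is `rates[j]` within segment j of time
#' before present, segments delimited by `shifts` (My before present, oldest
#' first): `rates[1]` applies before `shifts[1]`, `rates[length(rates)]`
#' applies between `shifts[length(shifts)]` and the present. Because the
#' segment boundaries are anchored at the present, the tree is generated
#' backward from the present: while k of the n lineages remain, the age of
#' the next (older) branching is drawn from the inhomogeneous exponential
#' with hazard \eqn{k\lambda(\tau)}; for a constant rate this is exactly the
#' forward construction of [simulate_yule()]. The topology is
#' equal-rates-Markov.
#'
#' @param n number of tips.
#' @param rates positive speciation rates, oldest segment first;
#'   `length(rates) == length(shifts) + 1`.
#' @param shifts shift times in My before present, strictly decreasing.
#' @param seed optional integer seed.
#' @return a chronogram with `n` tips.
#' @examples
#' tr <- simulate_piecewise_yule(50, c(0.08, 0.02), 41, seed = 1)
#' @export
simulate_piecewise_yule <- function(n, rates, shifts = numeric(), seed = NULL) {
  n <- as.integer(n)
  stopifnot(n >= 2, all(rates > 0),
            length(rates) == length(shifts) + 1L)
  if (length(shifts) > 1 && any(diff(shifts) >= 0))
    stop("'shifts' must be strictly decreasing (oldest first)")
  if (length(shifts) && any(shifts <= 0)) stop("'shifts' must be positive")
  with_seed(seed, {
    x <- .piecewise_backward_ages(n, rev(rates), c(0, rev(shifts)))
    tp <- .yule_topology(x)
    as_chronogram(.flat_to_phylo(tp$parent, tp$age, tp$n), quiet = TRUE)
  })
}

# Shared forward birth-death event engine. lam_fun/mu_fun take forward time
# from the crown; bound is an upper bound on lam+mu per lineage. Runs until
# n extant lineages exist (then appends the waiting time to the next event as
# the present) or returns NULL (died out / cap exceeded / t_max exceeded).
.bd_forward_once <- function(n, lam_fun, mu_fun, bound, t_max = Inf,
                             max_events = NULL) {
  if (is.null(max_events)) max_events <- 200L * n + 10000L
  cap <- 4L * n + 16L
  par_ev <- integer(cap)        # parent event of each birth event
  t_ev <- numeric(cap)
  lin_cap <- 2L * n + 16L
  open_ev <- integer(lin_cap)   # event whose node is the lineage's parent-so-far
  tip_ev <- integer(lin_cap)
  tip_t <- numeric(lin_cap)
  alive <- integer(lin_cap)     # stack of extant lineage ids
  open_ev[1L] <- open_ev[2L] <- 0L   # crown event is event 0
  alive[1L] <- 1L; alive[2L] <- 2L
  n_alive <- 2L; n_lin <- 2L; n_ev <- 0L
  t <- 0
  ev <- 0L
  while (TRUE) {
    if (n_alive == 0L) return(NULL)
    if (n_alive == n) {
      # waiting time to the (n+1)-th event = the present
      repeat {
        t <- t + rexp(1L, n_alive * bound)
        if (t > t_max) return(NULL)
        if (runif(1L) <= (lam_fun(t) + mu_fun(t)) / bound) break
      }
      break
    }
    ev <- ev + 1L
    if (ev > max_events) return(NULL)
    t <- t + rexp(1L, n_alive * bound)
    if (t > t_max) return(NULL)
    idx <- sample.int(n_alive, 1L)
    u <- alive[idx]
    lamt <- lam_fun(t); mut <- mu_fun(t)
    acc <- runif(1L) * bound
    if (acc > lamt + mut) next                    # thinned (phantom) event
    if (acc <= lamt) {                            # speciation
      n_ev <- n_ev + 1L
      if (n_ev > cap) {
        cap <- 2L * cap
        length(par_ev) <- cap; length(t_ev) <- cap
      }
      par_ev[n_ev] <- open_ev[u]
      t_ev[n_ev] <- t
      n_lin <- n_lin + 1L
      if (n_lin > lin_cap) {
        lin_cap <- 2L * lin_cap
        length(open_ev) <- lin_cap; length(tip_ev) <- lin_cap
        length(tip_t) <- lin_cap; length(alive) <- lin_cap
      }
      open_ev[u] <- n_ev
      open_ev[n_lin] <- n_ev
      n_alive <- n_alive + 1L
      alive[n_alive] <- n_lin
    } else {                                      # extinction
      tip_ev[u] <- open_ev[u]
      tip_t[u] <- t
      alive[idx] <- alive[n_alive]
      n_alive <- n_alive - 1L
    }
  }
  # close surviving lineages at the present
  for (j in seq_len(n_alive)) {
    u <- alive[j]
    tip_ev[u] <- open_ev[u]
    tip_t[u] <- t
  }
  L <- n_lin; B <- n_ev
  nn <- 2L * L - 1L
  parent <- integer(nn); age <- numeric(nn)
  node_of_ev <- c(L + 1L, L + 1L + seq_len(B))    # event e -> node id
  parent[seq_len(L)] <- node_of_ev[tip_ev[seq_len(L)] + 1L]
  age[seq_len(L)] <- t - tip_t[seq_len(L)]
  if (B > 0L) {
    parent[L + 1L + seq_len(B)] <- node_of_ev[par_ev[seq_len(B)] + 1L]
    age[L + 1L + seq_len(B)] <- t - t_ev[seq_len(B)]
  }
  age[L + 1L] <- t
  survivors <- which(age[seq_len(L)] <= 0 + 1e-12)
  list(parent = parent, age = age, L = L, survivors = survivors)
}

# prune a flat full tree to its surviving tips and return a chronogram
.reconstructed_from_flat <- function(sim) {
  phy <- .flat_to_phylo(sim$parent, sim$age, sim$L)
  keep <- phy$tip.label[sim$survivors]
  out <- ape::keep.tip(phy, keep)
  # clip the numerical fuzz on tip ages
  as_chronogram(out, rel_tol = 1e-8, coerce_ultrametric = TRUE, quiet = TRUE)
}

#' Simulate a reconstructed constant-rate birth-death chronogram
#'
#' Forward simulation with extinction: while k lineages are extant the total
#' event rate is \eqn{k(\lambda+\mu)} and each event is a speciation with
#' probability \eqn{\lambda/(\lambda+\mu)}. When the extant count first
#' reaches `n`, the present is placed at the waiting time to the next event;
#' extinct lineages are then pruned, leaving the reconstructed tree with
#' exactly `n` tips. Simulations that die out are retried up to `max_tries`
#' times.
#'
#' @param n number of surviving tips.
#' @param lam speciation rate (> mu).
#' @param mu extinction rate (>= 0).
#' @param seed optional integer seed.
#' @param max_tries retry cap for whole simulations.
#' @return a chronogram with `n` tips.
#' @examples
#' tr <- simulate_bd(20, lam = 0.2, mu = 0.1, seed = 1)
#' @export
simulate_bd <- function(n, lam, mu = 0, seed = NULL, max_tries = 10000L) {
  n <- as.integer(n)
  stopifnot(n >= 2, lam > mu, mu >= 0)
  with_seed(seed, {
    for (i in seq_len(max_tries)) {
      sim <- .bd_forward_once(n, function(t) lam, function(t) mu, lam + mu)
      if (!is.null(sim) && length(sim$survivors) == n)
        return(.reconstructed_from_flat(sim))
    }
    stop("simulate_bd: no surviving simulation within 'max_tries' attempts")
  })
}

#' Simulate a reconstructed birth-death chronogram with time-varying rates
#'
#' Forward simulation by thinning (rejection sampling against a constant
#' bound on \eqn{\lambda(t)+\mu(t)}): candidate events are generated at the
#' bounding rate and accepted with probability equal to the instantaneous
#' total rate over the bound. Conditioning on `n` surviving tips and pruning
#' of extinct lineages are as in [simulate_bd()]. Rate functions take time
#' measured *forward from the crown*, in My.
#'
#' @param n number of surviving tips.
#' @param lam_fn,mu_fn vectorisable non-negative rate functions of forward
#'   time on `[0, t_max]`.
#' @param t_max horizon (My); simulations still unfinished at `t_max` are
#'   retried.
#' @param seed optional integer seed.
#' @param lam_max,mu_max upper bounds for the rate functions; when `NULL`
#'   they are taken as 1.05 times the maximum over a 2048-point grid on
#'   `[0, t_max]` (exact for monotone rates).
#' @param max_tries retry cap.
#' @return a chronogram with `n` tips.
#' @examples
#' tr <- simulate_time_varying(15, function(t) 0.3 * exp(-0.05 * t),
#'                             function(t) rep(0.02, length(t)),
#'                             t_max = 200, seed = 1)
#' @export
simulate_time_varying <- function(n, lam_fn, mu_fn, t_max, seed = NULL,
                                  lam_max = NULL, mu_max = NULL,
                                  max_tries = 10000L) {
  n <- as.integer(n)
  stopifnot(n >= 2, t_max > 0)
  grid <- seq(0, t_max, length.out = 2048L)
  if (is.null(lam_max)) lam_max <- 1.05 * max(lam_fn(grid))
  if (is.null(mu_max)) mu_max <- 1.05 * max(mu_fn(grid))
  if (!is.finite(lam_max) || !is.finite(mu_max) || lam_max <= 0)
    stop("rate functions must be bounded and lambda positive on [0, t_max]")
  lf <- function(t) lam_fn(t)[1]
  mf <- function(t) mu_fn(t)[1]
  with_seed(seed, {
    for (i in seq_len(max_tries)) {
      sim <- .bd_forward_once(n, lf, mf, lam_max + mu_max, t_max = t_max)
      if (!is.null(sim) && length(sim$survivors) == n)
        return(.reconstructed_from_flat(sim))
    }
    stop("simulate_time_varying: retry cap exceeded ",
         "(process dies out or does not reach n before t_max)")
  })
}

#' Randomly subsample the tips of a chronogram
#'
#' Draws `m` tips (uniformly without replacement by default) and prunes the
#' tree to them, emulating incomplete taxon sampling. A depth-biased option
#' weights each tip by its pendant edge length raised to `depth_bias`,
#' for sensitivity analyses of the uniform-sampling assumption of the MCCR
#' test (real supraspecific sampling tends to oversample deep lineages);
#' `depth_bias = 0` is uniform sampling.
#'
#' @param phy a chronogram.
#' @param m number of tips to retain (2 <= m <= tip count).
#' @param seed optional integer seed.
#' @param depth_bias exponent on the pendant edge length used as a sampling
#'   weight.
#' @return the pruned chronogram, with attribute `"subsampled"` recording
#'   (m, original tip count).
#' @examples
#' tr <- simulate_yule(20, seed = 1)
#' subsample_tips(tr, 5, seed = 2)
#' @export
subsample_tips <- function(phy, m, seed = NULL, depth_bias = 0) {
  stopifnot(inherits(phy, "phylo"))
  n <- length(phy$tip.label)
  m <- as.integer(m)
  if (m < 2L || m > n) stop("'m' must be between 2 and the tip count")
  if (m == n) return(as_chronogram(phy, quiet = TRUE))
  with_seed(seed, {
    if (depth_bias == 0) {
      keep <- sample(phy$tip.label, m)
    } else {
      pend <- phy$edge.length[match(seq_len(n), phy$edge[, 2])]
      keep <- sample(phy$tip.label, m, prob = pend^depth_bias)
    }
    out <- prune_to_tips(phy, keep)
    attr(out, "subsampled") <- c(m = m, n_total = n)
    out
  })
}

# Fast path used by the MCCR test and LTT envelopes: branching times of an
# m-tip uniform subsample of an N-tip unit-rate Yule tree, without building a
# phylo object. Rate 1 is sufficient because gamma is scale invariant.
.yule_subsampled_x <- function(N, m, lam = 1) {
  g <- rexp(N - 1L, rate = lam * (2:N))
  x <- rev(cumsum(rev(g)))
  if (m >= N) return(x)
  tp <- .yule_topology(x)
  keep <- sample.int(N, m)
  .induced_x(tp$parent, tp$age, N, keep)
}

#' Packaged synthetic example emulating a richness-asymmetric sister pair
#'
#' Builds, from a fixed seed, a deterministic bundle emulating the study
#' design this package targets: a hyper-diverse clade of 19,811 species
#' ("harpaline-like", generated as a piecewise-constant pure-birth tree whose
#' rate drops from 0.149 to 0.02 at 41 My and to 0.004 at 12 My before
#' present, giving a crown age near 100 My) sampled down to 193 tips, and its
#' species-poor sister ("brachinine-like", constant-rate Yule at 0.080 per
#' My, 655 species) sampled down to 10 tips, together with the species
#' richness table used by the sister-clade tests.
#'
#' @param seed integer seed; the default is the packaged reference value.
#' @param full_trees also return the two full (pre-subsampling) trees?
#'   They are moderately large (19,811 and 655 tips).
#' @return a list with `harpaline` and `brachinine` sampled chronograms
#'   (193 and 10 tips), optionally `harpaline_full` and `brachinine_full`,
#'   the `richness` table, and `params` documenting every generating
#'   parameter and the seed.
#' @examples
#' \donttest{
#' fx <- harpaline_fixture()
#' length(fx$harpaline$tip.label)  # 193
#' }
#' @export
harpaline_fixture <- function(seed = 20260101L, full_trees = FALSE) {
  params <- list(
    seed = seed,
    harpaline = list(process = "piecewise_yule", n_total = 19811L,
                     rates = c(0.149, 0.02, 0.004), shifts = c(41, 12),
                     m = 193L),
    brachinine = list(process = "yule", n_total = 655L, lam = 0.080, m = 10L)
  )
  with_seed(seed, {
    harp_full <- simulate_piecewise_yule(19811L, c(0.149, 0.02, 0.004),
                                         c(41, 12))
    brach_full <- simulate_yule(655L, 0.080)
    harp <- subsample_tips(harp_full, 193L)
    brach <- subsample_tips(brach_full, 10L)
    out <- list(harpaline = harp, brachinine = brach,
                richness = c(Harpalinae = 19811L, Brachininae = 655L,
                             austral_psydrines = 100L),
                params = params)
    if (full_trees) {
      out$harpaline_full <- harp_full
      out$brachinine_full <- brach_full
    }
    out
  })
}
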