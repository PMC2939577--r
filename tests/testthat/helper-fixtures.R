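# Small reference trees and brute-force oracles used across the suite.

# 4-tip comb with splits at ages 3, 2, 1 (x = (3,2,1), g = (1,1,1), T = 9)
comb4 <- function() parse_newick("(((A:1,B:1):1,C:2):1,D:3);")

# balanced 4-tip tree with splits at 3, 1, 1 (g = (2,0,1), T = 8)
balanced4 <- function() parse_newick("((A:1,B:1):2,(C:1,D:1):2);")

# brute-force ERM oracle: probability that the named clade of a labelled
# sister pair holds at most s of the n species, by enumerating all ordered
# splits (each of the n-1 splits equally likely)
erm_split_p <- function(r, s) {
  n <- r + s
  mean(seq_len(n - 1L) <= s)
}

# brute-force broken-stick oracle: P(first part >= r) over all compositions
# of n into k positive parts, enumerated as bar placements
composition_tail_p <- function(n, k, r) {
  if (k == 1L) return(as.numeric(n >= r))
  bars <- utils::combn(n - 1L, k - 1L)
  mean(bars[1, ] >= r)
}

# join two chronograms below a fresh root at the given age; tips are
# relabelled a1.. / b1.. so clade membership is recoverable by prefix
join_clades <- function(phy1, phy2, root_age) {
  phy1$tip.label <- paste0("a", seq_along(phy1$tip.label))
  phy2$tip.label <- paste0("b", seq_along(phy2$tip.label))
  h1 <- attr(phy1, "chronogram_info")$height
  h2 <- attr(phy2, "chronogram_info")$height
  stopifnot(root_age > max(h1, h2))
  s1 <- sub(";$", "", write_newick(phy1, precision = 10))
  s2 <- sub(";$", "", write_newick(phy2, precision = 10))
  parse_newick(sprintf("(%s:%.10f,%s:%.10f);", s1, root_age - h1,
                       s2, root_age - h2))
}

# random pure-birth branching times, for likelihood property checks
random_bt <- function(n, lam = 0.3) branching_times(simulate_yule(n, lam))
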