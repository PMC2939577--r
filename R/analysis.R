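#' Configuration for a full diversification-tempo analysis
#'
#' Bundles everything [run_full_analysis()] needs: the clades to analyse,
#' their true extant richness (for sampling-corrected tests), sister-pair
#' definitions for the richness tests, and the Monte Carlo settings. Every
#' seed is recorded in the outputs so a run can be reproduced exactly.
#'
#' @param clades named list; each element is either a chronogram or a
#'   character vector of tip labels (a clade is then extracted from `tree`
#'   as the MRCA-spanned subtree).
#' @param richness named integer vector of true extant species richness per
#'   clade label (clades absent from it are treated as completely sampled).
#' @param tree optional chronogram, required when any clade is given as a
#'   tip set.
#' @param sister_pairs list of 2-element character vectors naming clade
#'   labels (or richness entries) to compare with [slowinski_guyer()].
#' @param epsilon extinction fractions for the [ms_rate()] estimates.
#' @param sg_tail tail convention for the sister-clade tests.
#' @param mccr_reps,envelope_reps Monte Carlo replicate counts (>= 100 for
#'   the MCCR test).
#' @param grid_step shift-grid spacing (My) for the piecewise model fits.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param out_dir optional directory; when set, result tables are written as
#'   TSV files with metadata headers.
#' @return an object of class `"analysis_config"`.
#' @seealso [run_full_analysis()]
#' @export
analysis_config <- function(clades, richness = integer(), tree = NULL,
                            sister_pairs = list(), epsilon = c(0, 0.5),
                            sg_tail = "one", mccr_reps = 1000L,
                            envelope_reps = 1000L, grid_step = 1,
                            seed = 1L, out_dir = NULL) {
  stopifnot(is.list(clades), length(clades) >= 1,
            !is.null(names(clades)), all(nzchar(names(clades))))
  if (mccr_reps < 100L) stop("'mccr_reps' must be at least 100")
  for (pr in sister_pairs)
    if (length(pr) != 2L || !all(pr %in% c(names(clades), names(richness))))
      stop("each sister pair must name two known clades")
  structure(list(clades = clades, richness = richness, tree = tree,
                 sister_pairs = sister_pairs, epsilon = epsilon,
                 sg_tail = sg_tail, mccr_reps = as.integer(mccr_reps),
                 envelope_reps = as.integer(envelope_reps),
                 grid_step = grid_step, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "analysis_config")
}

.resolve_clade <- function(config, label) {
  cl <- config$clades[[label]]
  if (inherits(cl, "phylo")) return(as_chronogram(cl, quiet = TRUE))
  if (is.character(cl)) {
    if (is.null(config$tree)) stop("clade '", label,
                                   "' is a tip set but no 'tree' was given")
    return(extract_clade(config$tree, cl))
  }
  stop("clade '", label, "' must be a chronogram or a tip-label vector")
}

.write_block <- function(df, file, meta) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# ", names(meta), " = ", unlist(meta)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full diversification-tempo analysis
#'
#' For every clade in the configuration, computes: the Slowinski-Guyer test
#' against its sister (for configured pairs), Magallon-Sanderson net
#' diversification rates at each extinction fraction, the gamma statistic
#' with CR test, the MCCR test corrected for the clade's sampling fraction,
#' the relative cladogenesis table, the LTT curve with a subsampled-Yule
#' simulation envelope, and the six-model AIC comparison. A failing stage is
#' recorded as an error message in its slot; completed stages are kept.
#'
#' @param config an [analysis_config()].
#' @return a list of class `"divtempo_analysis"`: one entry per clade (each
#'   with elements `sg`, `ms_rates`, `gamma`, `cr`, `mccr`, `rc`, `ltt`,
#'   `envelope`, `models`) plus a `manifest` recording the package version,
#'   seeds and all settings.
#' @examples
#' \donttest{
#' fx <- harpaline_fixture()
#' cfg <- analysis_config(
#'   clades = list(Harpalinae = fx$harpaline, Brachininae = fx$brachinine),
#'   richness = fx$richness,
#'   sister_pairs = list(c("Harpalinae", "Brachininae")),
#'   mccr_reps = 100, envelope_reps = 25, seed = 1)
#' res <- run_full_analysis(cfg)
#' res$Harpalinae$sg
#' }
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  labels <- names(config$clades)
  try_stage <- function(expr) tryCatch(expr, error = function(e)
    structure(list(error = conditionMessage(e)), class = "stage_error"))
  out <- list()
  for (i in seq_along(labels)) {
    lab <- labels[i]
    phy <- .resolve_clade(config, lab)
    bt <- branching_times(phy)
    n_tips <- bt$n
    N_true <- if (lab %in% names(config$richness))
      as.integer(config$richness[[lab]]) else n_tips
    block <- list(label = lab, n_tips = n_tips, richness = N_true,
                  crown_age_My = bt$x[1])
    block$sg <- try_stage({
      pr <- Filter(function(p) p[1] == lab, config$sister_pairs)
      lapply(pr, function(p) {
        n1 <- if (p[1] %in% names(config$richness))
          config$richness[[p[1]]] else length(config$clades[[p[1]]]$tip.label)
        n2 <- if (p[2] %in% names(config$richness))
          config$richness[[p[2]]] else length(config$clades[[p[2]]]$tip.label)
        slowinski_guyer(max(n1, n2), min(n1, n2), tail = config$sg_tail)
      })
    })
    block$ms_rates <- try_stage(
      lapply(config$epsilon, function(e)
        ms_rate(N_true, bt$x[1], epsilon = e, mode = "crown")))
    block$gamma <- try_stage(gamma_stat(bt))
    block$cr <- try_stage(cr_test(block$gamma))
    block$mccr <- try_stage(
      mccr_test(block$gamma, N_total = N_true, m = n_tips,
                reps = config$mccr_reps, seed = config$seed + 1000L * i))
    block$rc <- try_stage(rc_test(phy))
    block$ltt <- try_stage(ltt(bt))
    block$envelope <- try_stage(
      ltt_envelope(N_true, m = n_tips, reps = config$envelope_reps,
                   seed = config$seed + 1000L * i + 1L, empirical = bt))
    block$models <- try_stage(fit_all(bt, grid_step = config$grid_step))
    out[[lab]] <- block
  }
  out$manifest <- list(
    package = "divtempo",
    version = as.character(utils::packageVersion("divtempo")),
    seed = config$seed,
    settings = config[c("epsilon", "sg_tail", "mccr_reps", "envelope_reps",
                        "grid_step")],
    richness = config$richness)
  class(out) <- "divtempo_analysis"
  if (!is.null(config$out_dir)) .write_analysis(out, config)
  out
}

.write_analysis <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  meta0 <- list(package = "divtempo",
                version = as.character(utils::packageVersion("divtempo")),
                seed = config$seed)
  for (lab in setdiff(names(res), "manifest")) {
    bl <- res[[lab]]
    pfx <- file.path(config$out_dir, gsub("[^A-Za-z0-9_]+", "_", lab))
    if (inherits(bl$rc, "rc_table"))
      .write_block(as.data.frame(bl$rc), paste0(pfx, "_rc.tsv"),
                   c(meta0, clade = lab, stage = "rc_test",
                     bonferroni = attr(bl$rc, "n_tests")))
    if (inherits(bl$ltt, "data.frame"))
      .write_block(as.data.frame(bl$ltt), paste0(pfx, "_ltt.tsv"),
                   c(meta0, clade = lab, stage = "ltt"))
    if (inherits(bl$envelope, "data.frame"))
      .write_block(as.data.frame(bl$envelope), paste0(pfx, "_ltt_envelope.tsv"),
                   c(meta0, clade = lab, stage = "ltt_envelope",
                     reps = config$envelope_reps))
    if (inherits(bl$models, "data.frame"))
      .write_block(as.data.frame(bl$models), paste0(pfx, "_models.tsv"),
                   c(meta0, clade = lab, stage = "fit_all",
                     grid_step = config$grid_step))
    if (inherits(bl$mccr, "mccr_result"))
      .write_block(data.frame(null_gamma = bl$mccr$null),
                   paste0(pfx, "_mccr_null.tsv"),
                   c(meta0, clade = lab, stage = "mccr_test",
                     gamma_obs = bl$mccr$gamma_obs, p = bl$mccr$p,
                     p_plain = bl$mccr$p_plain))
    summ <- data.frame(
      clade = lab, n_tips = bl$n_tips, richness = bl$richness,
      crown_age_My = bl$crown_age_My,
      gamma = if (inherits(bl$gamma, "gamma_result")) bl$gamma$gamma else NA,
      cr_p = if (inherits(bl$cr, "cr_test")) bl$cr$p else NA,
      mccr_p = if (inherits(bl$mccr, "mccr_result")) bl$mccr$p else NA)
    .write_block(summ, paste0(pfx, "_summary.tsv"),
                 c(meta0, clade = lab, stage = "summary"))
  }
  invisible(res)
}

#' @export
print.divtempo_analysis <- function(x, ...) {
  labs <- setdiff(names(x), "manifest")
  cat("divtempo analysis of", length(labs), "clade(s):",
      paste(labs, collapse = ", "), "\n")
  for (lab in labs) {
    bl <- x[[lab]]
    cat(sprintf("\n== %s: %d sampled tips of %d species, crown %.4g My\n",
                lab, bl$n_tips, bl$richness, bl$crown_age_My))
    if (inherits(bl$gamma, "gamma_result"))
      cat(sprintf("   gamma = %.4f; CR p = %.4f; MCCR p = %.4f (add-one)\n",
                  bl$gamma$gamma,
                  if (inherits(bl$cr, "cr_test")) bl$cr$p else NA,
                  if (inherits(bl$mccr, "mccr_result")) bl$mccr$p else NA))
    if (length(bl$sg) && inherits(bl$sg[[1]], "sg_test"))
      cat(sprintf("   Slowinski-Guyer vs sister: p = %.4f (%s-tailed)\n",
                  bl$sg[[1]]$p, bl$sg[[1]]$tail))
    if (inherits(bl$models, "model_fit_table"))
      cat("   best model by AIC:",
          bl$models$model[which.min(bl$models$AIC)], "\n")
  }
  invisible(x)
}
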