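#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators.  Defaults describe
#' a small laser-microdissection-style study: a few thousand genes, one to
#' three assembled transcript variants per gene, 25-mer array probes that have
#' diverged slightly from their targets, log-normal array intensities on the
#' log2 scale, and negative-binomial read counts with the dispersion fixed at
#' \code{0.64} (a biological coefficient of variation of 0.8, the value used
#' throughout the differential-expression stage).
#'
#' @param seed integer master seed.  Every generator derives its own
#'   sub-seed deterministically from this value plus a stage offset, so
#'   stages are individually reproducible.
#' @param n_genes number of gene models.
#' @param variants_per_gene either a single integer (every gene gets that
#'   many variants) or an integer vector of candidate counts sampled
#'   uniformly per gene.
#' @param mean_length,sd_length transcript length distribution (bp); lengths
#'   are drawn from a normal and floored at \code{min_length}.
#' @param min_length shortest transcript emitted (bp).
#' @param probe_divergence_rate per-base substitution probability applied to
#'   on-target probes (models cross-species probe/target divergence).
#' @param background_mean,background_sd log2-scale background intensity
#'   distribution for unexpressed and off-target probesets.
#' @param signal_mean,signal_sd log2-scale intensity distribution for
#'   expressed probesets.  The default puts the signal 3 background SDs
#'   above background.
#' @param probe_effect_sd SD of the additive per-probe affinity effect
#'   (mean 0) so that median-polish summarization has structure to remove.
#' @param dispersion negative-binomial dispersion phi; variance =
#'   mu + phi * mu^2.  Default \code{0.8^2 = 0.64}.
#' @param baseline_sd log-scale SD of the per-gene baseline expression
#'   level (0 makes every expressed gene share one mean).
#' @param library_sizes integer vector of per-sample sequencing depths.
#' @param expressed_fraction fraction of genes expressed (array signal,
#'   non-background counts).
#' @param de_fraction fraction of genes given a non-unit fold change.
#' @param fold_change fold change applied to differentially expressed genes.
#' @param samples character vector of sample labels for the count generator.
#'
#' @return an object of class \code{sim_config} (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 50)
#' cfg$dispersion
#' @export
sim_config <- function(seed = 42L,
                       n_genes = 2000L,
                       variants_per_gene = 1:3,
                       mean_length = 1000,
                       sd_length = 200,
                       min_length = 100,
                       probe_divergence_rate = 0.02,
                       background_mean = 6,
                       background_sd = 1,
                       signal_mean = 9,
                       signal_sd = 1,
                       probe_effect_sd = 0.5,
                       dispersion = 0.64,
                       baseline_sd = 1,
                       library_sizes = c(100000L, 100000L, 100000L, 100000L),
                       expressed_fraction = 0.6,
                       de_fraction = 0.1,
                       fold_change = 4,
                       samples = c("focal_cell", "cell_b", "cell_c", "cell_d")) {
  cfg <- list(seed = as.integer(seed),
              n_genes = as.integer(n_genes),
              variants_per_gene = as.integer(variants_per_gene),
              mean_length = mean_length,
              sd_length = sd_length,
              min_length = as.integer(min_length),
              probe_divergence_rate = probe_divergence_rate,
              background_mean = background_mean,
              background_sd = background_sd,
              signal_mean = signal_mean,
              signal_sd = signal_sd,
              probe_effect_sd = probe_effect_sd,
              dispersion = dispersion,
              baseline_sd = baseline_sd,
              library_sizes = as.integer(library_sizes),
              expressed_fraction = expressed_fraction,
              de_fraction = de_fraction,
              fold_change = fold_change,
              samples = samples)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(cfg$seed) != 1L || is.na(cfg$seed))
    stop("sim_config: 'seed' must be a single integer", call. = FALSE)
  if (cfg$n_genes < 1L)
    stop("sim_config: 'n_genes' must be >= 1", call. = FALSE)
  if (length(cfg$variants_per_gene) < 1L || any(cfg$variants_per_gene < 1L) ||
      anyNA(cfg$variants_per_gene))
    stop("sim_config: invalid 'variants_per_gene' distribution spec",
         call. = FALSE)
  if (cfg$probe_divergence_rate < 0 || cfg$probe_divergence_rate > 1)
    stop("sim_config: 'probe_divergence_rate' must lie in [0, 1]",
         call. = FALSE)
  if (cfg$dispersion < 0)
    stop("sim_config: 'dispersion' must be non-negative", call. = FALSE)
  if (any(cfg$library_sizes <= 0L))
    stop("sim_config: 'library_sizes' must be positive", call. = FALSE)
  if (cfg$expressed_fraction < 0 || cfg$expressed_fraction > 1)
    stop("sim_config: 'expressed_fraction' must lie in [0, 1]", call. = FALSE)
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1)
    stop("sim_config: 'de_fraction' must lie in [0, 1]", call. = FALSE)
  if (cfg$fold_change <= 0)
    stop("sim_config: 'fold_change' must be positive", call. = FALSE)
  if (cfg$signal_mean <= cfg$background_mean)
    warning("sim_config: signal_mean <= background_mean; ",
            "presence-call power will be near the nominal FPR")
  if (length(cfg$library_sizes) != length(cfg$samples))
    stop("sim_config: 'library_sizes' and 'samples' lengths differ",
         call. = FALSE)
  cfg
}

# Deterministic per-stage sub-seed so each generator is independently
# reproducible under one master seed.  Kept well below .Machine$integer.max.
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 97L + as.integer(stage) * 7919L) %% 2147483000L
}

# Evaluate `expr` under a stage-local RNG state without disturbing the
# caller's RNG.
with_stage_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stage_seed(seed, stage))
  expr
}
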