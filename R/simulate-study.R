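#' Simulate a complete synthetic study
#'
#' One call generates everything the pipeline consumes: the metallome and
#' phenotype tables, metabolome and proteome matrices with planted set
#' enrichments (plus their GMT-style set databases), and bracketed raw
#' isotope runs — together with the ground truth used, for recovery tests.
#'
#' @param truth A [default_truth()] ground truth.
#' @param cfg A [sim_config()].
#' @param seed Integer seed (defaults to `cfg$seed`); a single RNG stream
#'   drives all generators, so identical `(truth, cfg, seed)` give
#'   bit-identical output.
#' @return A list: `metallome`, `phenotypes`, `metabolome`, `proteome`,
#'   `metabolite_sets`, `protein_sets`, `runs`, `truth`, `cfg`.
#' @export
#' @examples
#' study <- simulate_study(seed = 1)
#' dplyr::count(study$metallome, organ, age_months)
simulate_study <- function(truth = default_truth(), cfg = sim_config(), seed = cfg$seed) {
  if (!is.null(seed)) withr::local_seed(seed)
  mp <- generate_metallome(truth, cfg, seed = NULL)
  met_sets <- default_feature_sets(truth, cfg, "metabolome")
  prot_sets <- default_feature_sets(truth, cfg, "proteome")
  metabolome <- generate_omics(truth, mp$metallome, met_sets, cfg,
    layer = "metabolome", seed = NULL
  )
  proteome <- generate_omics(truth, mp$metallome, prot_sets, cfg,
    layer = "proteome", seed = NULL
  )
  runs <- generate_isotope_runs(truth, cfg, seed = NULL)
  list(
    metallome = mp$metallome, phenotypes = mp$phenotypes,
    metabolome = metabolome, proteome = proteome,
    metabolite_sets = met_sets, protein_sets = prot_sets,
    runs = runs, truth = truth, cfg = cfg
  )
}
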