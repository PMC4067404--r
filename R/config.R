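#' Pipeline configuration
#'
#' Central, validated configuration for end-to-end runs (used by the
#' analysis drivers). Unknown keys — top-level or within a section — are
#' rejected by name, so typos fail loudly instead of being silently
#' ignored.
#'
#' @param seed Integer master seed.
#' @param outdir Output directory for driver scripts.
#' @param n_reads Reads per simulated tissue pool.
#' @param tissues Character vector of tissue preset names (see
#'   [tissue_sim_configs()]).
#' @param annotation Named list overriding [align_params()] arguments.
#' @param filter Named list: `min_length`.
#' @param metrics Named list: `low_mutation_threshold`, `cdr3_short_max`,
#'   `hydrophobic_set`, `charged_set`.
#' @param compare Named list: `min_total`, `min_variance`, `k_top`,
#'   `prior_df`, `dispersion`.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, outdir = "results", n_reads = 2000,
                            tissues = c("peripheral_blood", "small_intestine"),
                            annotation = list(), filter = list(),
                            metrics = list(), compare = list()) {
  check_keys <- function(x, allowed, section) {
    extra <- setdiff(names(x), allowed)
    if (length(extra))
      stop("unknown ", section, " key(s): ", paste(extra, collapse = ", "))
    x
  }
  annotation <- check_keys(annotation, names(formals(align_params)), "annotation")
  filter <- check_keys(filter, "min_length", "filter")
  metrics <- check_keys(metrics, c("low_mutation_threshold", "cdr3_short_max",
                                   "hydrophobic_set", "charged_set"), "metrics")
  compare <- check_keys(compare, c("min_total", "min_variance", "k_top",
                                   "prior_df", "dispersion"), "compare")
  stopifnot(n_reads >= 1, is.character(tissues), length(tissues) >= 1)
  bad <- setdiff(tissues, names(tissue_preset_table))
  if (length(bad)) stop("unknown tissue preset(s): ", paste(bad, collapse = ", "))
  fl <- modifyList(list(min_length = 300), filter)
  me <- modifyList(list(low_mutation_threshold = 5, cdr3_short_max = 14,
                        hydrophobic_set = hydrophobic_residues,
                        charged_set = charged_residues), metrics)
  co <- modifyList(list(min_total = 10, min_variance = 0, k_top = 50,
                        prior_df = 10, dispersion = NULL), compare)
  structure(list(seed = as.integer(seed), outdir = outdir,
                 n_reads = as.integer(n_reads), tissues = tissues,
                 annotation = annotation, filter = fl, metrics = me,
                 compare = co),
            class = "pipeline_config")
}

#' @importFrom utils modifyList
NULL
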