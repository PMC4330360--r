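#' Run configuration for the full analysis pipeline
#'
#' Collects all input paths and stage parameters with their reference
#' defaults: 1000 permutations, switch filters S1 > 0.5,
#' Spearman rho < -0.8, mean TPM > 1, 100 length-matched background
#' genes, 100 subtype subsampling iterations, recurrence cutoff 0.8.
#'
#' @param expression,labels,annotation,mutations,lengths input file
#'   paths (`annotation`, `mutations`, `lengths` optional).
#' @param values `"tpm"` or `"counts"` (the latter requires `lengths`).
#' @param out_dir output directory.
#' @param n_perm,min_s1,max_rho,min_tpm,n_background,n_iter,freq_cutoff
#'   stage parameters (defaults as above).
#' @param k_max largest cross-validation model size.
#' @param tie_policy S1 tie policy, see [score_s1()].
#' @param seed integer RNG seed for all stochastic stages.
#' @return list of class `"RunConfig"`.
#' @export
run_config <- function(expression, labels, out_dir,
                       annotation = NULL, mutations = NULL, lengths = NULL,
                       values = c("tpm", "counts"),
                       n_perm = 1000L, min_s1 = 0.5, max_rho = -0.8,
                       min_tpm = 1.0, n_background = 100L, n_iter = 100L,
                       freq_cutoff = 0.8, k_max = 11L,
                       tie_policy = "strict", seed = 1L) {
  values <- match.arg(values)
  cfg <- list(expression = expression, labels = labels, out_dir = out_dir,
              annotation = annotation, mutations = mutations,
              lengths = lengths, values = values,
              n_perm = as.integer(n_perm), min_s1 = min_s1, max_rho = max_rho,
              min_tpm = min_tpm, n_background = as.integer(n_background),
              n_iter = as.integer(n_iter), freq_cutoff = freq_cutoff,
              k_max = as.integer(k_max), tie_policy = tie_policy,
              seed = as.integer(seed))
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a RunConfig from YAML
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return a `RunConfig`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(run_config, yaml::read_yaml(path))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full switch-detection pipeline
#'
#' Stages, in order: load and filter the dataset; rank isoform pairs;
#' leave-one-pair-out cross-validation and minimal-model selection
#' (skipped without pairing); label-permutation significance; switch
#' detection; mutation association (when annotation and mutations are
#' supplied). Every stage writes a TSV under `out_dir`, and a JSON run
#' manifest records the package version, seed, parameters and input
#' file hashes, making outputs a function of (inputs, config, seed)
#' only.
#'
#' @param config a [run_config()] or path to a YAML config.
#' @return (invisibly) a list with the in-memory stage results:
#'   `dataset`, `ranking`, `crossval`, `model`, `null`, `significant`,
#'   `switches`, `mutation_association`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  ds <- .stage("load", {
    ex <- read_expression(config$expression)
    lb <- read_labels(config$labels)
    lens <- if (!is.null(config$lengths)) read_lengths(config$lengths)
    filter_genes(expression_dataset(ex$expr, ex$gene_of, lb$class_of,
                                    class_levels = lb$class_levels,
                                    pairing = lb$pairing,
                                    values = config$values, lengths = lens,
                                    symbol = ex$symbol_ok))
  })

  ranking <- .stage("score", rank_pairs(ds, config$tie_policy))
  write_tsv(ranking, file.path(config$out_dir, "ranking.tsv"))

  cv <- NULL; model <- NULL
  if (!is.null(ds$pairing) && nrow(ds$pairing) >= 3L) {
    cv <- .stage("crossval", cross_validate(ds, config$k_max,
                                            config$tie_policy))
    write_tsv(data.frame(k = cv$k, mean_accuracy = cv$mean_accuracy),
              file.path(config$out_dir, "crossval.tsv"))
    model <- .stage("model", build_final_model(ds, cv$k_opt, ranking))
    write_tsv(model$rules, file.path(config$out_dir, "model.tsv"))
  }

  null <- .stage("signif", permutation_test(ds, config$n_perm, config$seed,
                                            config$tie_policy))
  write_tsv(data.frame(permutation = seq_len(null$n_perm),
                       max_s1 = null$max_s1, max_ig = null$max_ig),
            file.path(config$out_dir, "permutation_null.tsv"))
  sig <- significant_pairs(ranking, null)
  write_tsv(sig, file.path(config$out_dir, "significant_pairs.tsv"))

  switches <- .stage("switches",
                     detect_switches(sig, ds, config$min_s1, config$max_rho,
                                     config$min_tpm))
  write_tsv(switches, file.path(config$out_dir, "switches.tsv"))

  assoc <- NULL
  if (!is.null(config$annotation) && !is.null(config$mutations) &&
      nrow(switches) > 0L) {
    assoc <- .stage("mutassoc", {
      structures <- read_gtf(config$annotation)
      muts <- read_mutations(config$mutations)
      mutation_association(switches, ds, muts, structures,
                           n_background = config$n_background)
    })
    write_tsv(assoc, file.path(config$out_dir, "mutation_association.tsv"))
  }

  manifest <- list(
    package = "isopair",
    version = as.character(utils::packageVersion("isopair")),
    seed = config$seed,
    parameters = config[setdiff(names(config),
                                c("expression", "labels", "annotation",
                                  "mutations", "lengths", "out_dir"))],
    inputs = lapply(Filter(Negate(is.null),
                           config[c("expression", "labels", "annotation",
                                    "mutations", "lengths")]),
                    function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
    n_significant = nrow(sig),
    n_switches = nrow(switches)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(dataset = ds, ranking = ranking, crossval = cv,
                 model = model, null = null, significant = sig,
                 switches = switches, mutation_association = assoc))
}
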