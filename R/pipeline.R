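#' Pipeline configuration
#'
#' Assembles and validates the configuration driving [run_pipeline()]. A
#' configuration can also be stored as a YAML file with the same field names
#' and loaded with [read_pipeline_config()].
#'
#' @param phenonet path to the primary phenotype network file.
#' @param ppi path to the PPI edge list.
#' @param associations path to the disease-gene association table.
#' @param phenonet_b optional path to a second phenotype network to integrate.
#' @param dialect,dialect_b input dialect of each network: `"dense"` (labeled
#'   square matrix) or `"pairs"` (pairwise score list).
#' @param method,method_b range normalization applied to each network:
#'   `"none"`, `"lin"`, `"sqrt"`, `"maxmin"` or `"tanimoto"`.
#' @param form similarity read direction, see [build_prior()]. With
#'   `form = "symmetric"`, an asymmetric input is symmetrized first.
#' @param proportion mixing weight of the primary network when two networks
#'   are integrated.
#' @param c logistic steepness; ignored when `c_grid` is given.
#' @param c_grid optional numeric vector: run [sweep_c()] instead of a single
#'   calibration.
#' @param mode,alpha,tol,max_iter see [loocv()].
#' @param out_dir optional directory for the TSV/JSON report files.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(phenonet, ppi, associations,
                            phenonet_b = NULL,
                            dialect = c("dense", "pairs"),
                            dialect_b = c("dense", "pairs"),
                            method = "none", method_b = "none",
                            form = c("symmetric", "row", "col"),
                            proportion = 0.5,
                            c = -15, c_grid = NULL,
                            mode = c("all", "monogenic", "polygenic"),
                            alpha = 0.9, tol = 1e-9, max_iter = 100L,
                            out_dir = NULL) {
  dialect <- match.arg(dialect)
  dialect_b <- match.arg(dialect_b)
  form <- match.arg(form)
  mode <- match.arg(mode)
  stopifnot(method %in% c("none", "lin", "sqrt", "maxmin", "tanimoto"),
            method_b %in% c("none", "lin", "sqrt", "maxmin", "tanimoto"),
            proportion >= 0, proportion <= 1)
  for (p in c(phenonet, ppi, associations, phenonet_b)) {
    if (!file.exists(p)) abort(sprintf("Input file not found: %s", p))
  }
  structure(
    list(phenonet = phenonet, ppi = ppi, associations = associations,
         phenonet_b = phenonet_b, dialect = dialect, dialect_b = dialect_b,
         method = method, method_b = method_b, form = form,
         proportion = proportion, c = c, c_grid = c_grid, mode = mode,
         alpha = alpha, tol = tol, max_iter = as.integer(max_iter),
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()]; relative input paths are resolved against the YAML
#'   file's directory.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  base_dir <- dirname(normalizePath(path))
  for (field in c("phenonet", "ppi", "associations", "phenonet_b")) {
    if (!is.null(raw[[field]]) && !file.exists(raw[[field]])) {
      raw[[field]] <- file.path(base_dir, raw[[field]])
    }
  }
  do.call(pipeline_config, raw)
}

read_net_by_dialect <- function(path, dialect) {
  switch(dialect,
         dense = read_dense_matrix(path),
         pairs = read_pair_scores(path))
}

prepare_net <- function(net, method, form) {
  if (form == "symmetric" && !net$symmetric) net <- symmetrize(net)
  if (method != "none") net <- normalize_similarity(net, method)
  net
}

#' Run the full evaluation pipeline
#'
#' Chains the four stages of the benchmark: (1) read the inputs and, when two
#' phenotype networks are given, restrict both to their shared diseases; (2)
#' symmetrize (if the read direction asks for it), range-normalize, and
#' optionally integrate the networks at the configured proportion; (3)
#' logistic-calibrate with a fixed steepness `c`, or sweep a grid of values;
#' (4) leave-one-out cross-validation and summary statistics. The run is
#' fully deterministic.
#'
#' @param config a [pipeline_config()] (or a YAML path accepted by
#'   [read_pipeline_config()]).
#' @return an object of class `phenoprio_pipeline`: list with `report`
#'   (summary tibble; one row per swept `c` when sweeping), `result` (the
#'   `phenoprio_loocv` or `phenoprio_sweep` object), `network` (the calibrated
#'   or pre-calibration `phenotype_net` that entered validation), and
#'   `config`. When `config$out_dir` is set, `report.tsv` and `report.json`
#'   are written there.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))

  gnet <- normalize_adjacency(read_edge_list(config$ppi))
  associations <- read_associations(config$associations)
  net <- read_net_by_dialect(config$phenonet, config$dialect)

  if (!is.null(config$phenonet_b)) {
    net_b <- read_net_by_dialect(config$phenonet_b, config$dialect_b)
    both <- intersect_networks(net, net_b)
    net <- prepare_net(both$a, config$method, config$form)
    net_b <- prepare_net(both$b, config$method_b, config$form)
    net <- combine_networks(net, net_b, config$proportion)
  } else {
    net <- prepare_net(net, config$method, config$form)
  }

  if (!is.null(config$c_grid)) {
    result <- sweep_c(config$c_grid, associations, net, gnet,
                      form = config$form, mode = config$mode,
                      alpha = config$alpha, tol = config$tol,
                      max_iter = config$max_iter)
    report <- result$reports
  } else {
    calibrated <- logistic_transform(net, config$c)
    result <- loocv(associations, calibrated, gnet,
                    form = config$form, mode = config$mode,
                    alpha = config$alpha, tol = config$tol,
                    max_iter = config$max_iter)
    report <- dplyr::bind_cols(tibble(c = config$c),
                               compute_report(result$records))
  }

  out <- structure(
    list(report = report, result = result, network = net, config = config),
    class = "phenoprio_pipeline"
  )
  if (!is.null(config$out_dir)) {
    if (!dir.exists(config$out_dir)) {
      dir.create(config$out_dir, recursive = TRUE)
    }
    utils::write.table(report, file.path(config$out_dir, "report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary <- as.list(report[which.max(report$top_count), , drop = FALSE])
    if (inherits(result, "phenoprio_sweep")) summary$best_c <- result$best_c
    jsonlite::write_json(summary, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.phenoprio_pipeline <- function(x, ...) {
  cat("<phenoprio_pipeline>\n")
  print(x$report, ...)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.phenoprio_pipeline <- function(x, ...) x$report

#' @exportS3Method generics::glance
glance.phenoprio_pipeline <- function(x, ...) {
  if (inherits(x$result, "phenoprio_sweep")) glance(x$result) else x$report
}
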