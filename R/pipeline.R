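#' Validated pipeline configuration
#'
#' Builds the configuration record driving [run_pipeline()] from a YAML file
#' or an R list. Every key is validated before any stage executes; unknown
#' keys are rejected. Defaults mirror the individual functions' defaults.
#'
#' @param config path to a YAML file, or a named list
#' @param overrides named list of values overriding the file (CLI flags)
#' @return a `netkin_config`
#' @export
run_config <- function(config = list(), overrides = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  config[names(overrides)] <- overrides
  defaults <- list(
    network = NULL, network_format = "auto",
    annotations = NULL, annotation_format = "auto",
    min_size = 2L, max_size = Inf, universe = "network",
    algorithm = "louvain", gamma = 1, inflation = 2, seed = 42L,
    test = "hypergeom", alpha = 0.05, correction = "bh",
    permutations = 1000L,
    domain_alpha = NULL, top_k = 3L,
    layout = "fr", layout_seed = 42L, layout_iterations = 500L,
    format = "svg", contour_level = 0.67, dpi = 150L,
    out_dir = "netkin_out")
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$network)) stop("config requires 'network' (input file path)")
  if (is.null(cfg$annotations)) stop("config requires 'annotations' (input file path)")
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) stop("alpha must be in (0, 1)")
  cfg$domain_alpha <- cfg$domain_alpha %||% cfg$alpha
  if (!(cfg$domain_alpha > 0 && cfg$domain_alpha <= 1))
    stop("domain_alpha must be in (0, 1]")
  if (!cfg$correction %in% c("bh", "bonferroni", "none"))
    stop("correction must be bh, bonferroni or none")
  if (!cfg$test %in% c("hypergeom", "permutation", "chisq", "binom"))
    stop("unknown test '", cfg$test, "'")
  if (cfg$permutations < 1) stop("permutations must be >= 1")
  if (!(cfg$contour_level > 0 && cfg$contour_level < 1))
    stop("contour_level must be strictly between 0 and 1")
  structure(cfg, class = "netkin_config")
}

#' Run the full annotation pipeline
#'
#' Chains network import, annotation matrix construction, clustering,
#' overrepresentation testing, domain filtering, layout, evaluation and
#' rendering, writing all artifacts plus a provenance manifest (config,
#' seeds, package version, input checksums) to `cfg$out_dir`. Rerunning
#' with an identical config reproduces the deterministic artifacts
#' byte-for-byte.
#'
#' @param cfg a `netkin_config` (see [run_config()])
#' @param quiet suppress stage messages
#' @return named list of artifact paths: `partition`, `overrep`, `domains`,
#'   `report`, `figure`, `manifest`
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "netkin_config"))
  say <- function(...) if (!quiet) message("[netkin] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  say("reading network: ", cfg$network)
  net <- stage("graph_io", read_network(cfg$network, cfg$network_format))
  say("reading annotations: ", cfg$annotations)
  mapping <- stage("annotation_io", read_annotations(cfg$annotations,
                                                     cfg$annotation_format))
  ann <- stage("annotation_io",
               build_matrix(mapping, net, min_size = cfg$min_size,
                            max_size = cfg$max_size, universe = cfg$universe))

  say("clustering (", cfg$algorithm, ")")
  part <- stage("clustering",
                cluster_network(net, cfg$algorithm, gamma = cfg$gamma,
                                seed = cfg$seed, inflation = cfg$inflation))
  say("testing overrepresentation (", cfg$test, ")")
  tab <- stage("overrep_stats",
               run_overrep(ann, part, test = cfg$test, alpha = cfg$alpha,
                           correction = cfg$correction,
                           R = cfg$permutations, seed = cfg$seed))
  say("building domains at alpha = ", cfg$domain_alpha)
  dm <- stage("significance_domains",
              build_domains(tab, alpha = cfg$domain_alpha, top_k = cfg$top_k))

  say("layout (", cfg$layout, ") and evaluation")
  coords <- stage("visualization",
                  layout_coords(net, cfg$layout, seed = cfg$layout_seed,
                                iterations = cfg$layout_iterations))
  report <- stage("evaluation", evaluate_partition(coords, part))
  uniq <- stage("significance_domains",
                if (length(dm$significant_clusters) > 0)
                  unique_clusters(dm, part, ann) else integer(0))

  paths <- list(partition = file.path(cfg$out_dir, "partition.tsv"),
                overrep = file.path(cfg$out_dir, "overrep.tsv"),
                domains = file.path(cfg$out_dir, "domains.tsv"),
                report = file.path(cfg$out_dir, "report.json"),
                figure = file.path(cfg$out_dir, paste0("figure.", cfg$format)),
                manifest = file.path(cfg$out_dir, "manifest.json"))
  write_partition(part, paths$partition)
  write_overrep(tab, paths$overrep)
  write_domains(dm, paths$domains)
  jsonlite::write_json(list(
    n_nodes = length(net$nodes), n_edges = nrow(net$edges),
    n_terms = length(ann$term_ids), coverage = ann$coverage,
    k_clusters = part$k,
    modularity = modularity_score(net, part, gamma = cfg$gamma),
    significant_clusters = dm$significant_clusters,
    unique_clusters = uniq,
    compactness = as.list(report$per_cluster_compactness),
    separation = report$separation,
    silhouette_mean = report$silhouette_mean),
    paths$report, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("rendering figure (", cfg$format, ")")
  stage("visualization",
        render_network(net, coords, dm, part,
                       spec = plot_spec(layout = cfg$layout,
                                        layout_seed = cfg$layout_seed,
                                        contour_level = cfg$contour_level,
                                        dpi = cfg$dpi, format = cfg$format),
                       path = paths$figure))
  jsonlite::write_json(list(
    config = unclass(cfg),
    package_version = as.character(utils::packageVersion("netkin")),
    input_checksums = as.list(tools::md5sum(c(cfg$network, cfg$annotations)))),
    paths$manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: ", cfg$out_dir)
  invisible(paths)
}
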