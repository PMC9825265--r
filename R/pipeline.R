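#' Default pipeline configuration
#'
#' Every analysis parameter that is not forced by a definition is a config
#' value here, so a run is fully auditable: the adjacency threshold (5 um),
#' polynomial degree (2), confluency anchors (0.15/0.40/0.70), cluster
#' counts (2 superclasses, 3 subclasses where group sizes allow),
#' spheroid thresholds, correlation thresholds (0.8 all-variable graph,
#' 0.3 invasion graph) and the seed.
#'
#' The default `synthetic` block describes the demonstration dataset the
#' pipeline generates when no input images are listed: a panel of clones
#' from two parameter regimes (emulating two parental lines), each imaged
#' across a range of densities, plus replicate spheroids per clone whose
#' planted invasiveness differs by regime.
#'
#' @param seed Integer master seed.
#' @return A nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    adjacency_threshold = 5,
    degree = 2L,
    anchors = c(l = 0.15, m = 0.40, h = 0.70),
    k_super = 2L,
    k_sub = 3L,
    exact_limit = 20L,
    correlation_threshold = 0.8,
    invasion_threshold = 0.3,
    spheroid = list(window = 75, min_area = 50, min_length = 20),
    synthetic = list(
      n_clones_per_line = 3L,
      densities = c(0.08, 0.18, 0.30, 0.42),
      n_cells = 45L,
      axis_um = list(line_A = c(7, 11), line_B = c(10, 17)),
      spheroids_per_clone = 1L,
      protrusions = list(line_A = 2L, line_B = 5L),
      protrusion_length = list(line_A = c(260, 300), line_B = c(300, 380)),
      disseminated = list(line_A = 1L, line_B = 4L),
      disseminated_distance = list(line_A = c(260, 300),
                                   line_B = c(300, 420))
    )
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return For `read_pipeline_config`, a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- unclass(pipeline_config())
  base <- utils::modifyList(base, cfg)
  base$anchors <- unlist(base$anchors)
  structure(base, class = "pipeline_config")
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  out <- unclass(config)
  out$anchors <- as.list(out$anchors)  # YAML drops names of atomic vectors
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the full phenotyping pipeline
#'
#' Generates (or loads) label images per clone across densities, measures
#' cells and network topology per image, fits per-clone density
#' progressions, extracts growth variables, clusters clones, measures
#' spheroids, computes the composite invasion score, and writes Spearman
#' correlation graphs relating 2D growth variables (mid-density anchor) to
#' invasion. All outputs are CSV/GraphML files stamped with the config
#' hash; the run is deterministic given the config seed.
#'
#' @param config A [pipeline_config()] (or YAML path).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the main result tables (`snapshots`,
#'   `growth_variables`, `clusters`, `spheroids`, `invasion`,
#'   `correlations`) and `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.yaml")
  write_pipeline_config(config, cfg_path)
  config_hash <- unname(tools::md5sum(cfg_path))
  log_path <- file.path(out_dir, "run.log")
  logln <- function(...) cat(paste0(format(Sys.time(), "%H:%M:%S "), ...,
                                    "\n"),
                             file = log_path, append = TRUE)
  cat(sprintf("clonemorph run, config %s\n", config_hash), file = log_path)

  syn <- config$synthetic
  lines <- names(syn$axis_um)
  clones <- tibble::tibble(
    clone_id = unlist(lapply(lines, function(l)
      paste0(l, "_c", seq_len(syn$n_clones_per_line)))),
    line = rep(lines, each = syn$n_clones_per_line)
  )

  # --- 2D stage: images per clone per density -> snapshots ---------------
  logln("2D stage: ", nrow(clones), " clones x ", length(syn$densities),
        " densities")
  snapshots <- purrr::map_dfr(seq_len(nrow(clones)), function(i) {
    cl <- clones$clone_id[i]
    ln <- clones$line[i]
    purrr::map_dfr(seq_along(syn$densities), function(d) {
      seed_id <- config$seed * 10000L + i * 100L + d
      spec <- synthetic_population_spec(
        n_cells = syn$n_cells,
        target_confluency = syn$densities[d],
        axis_um = syn$axis_um[[ln]],
        seed = seed_id)
      pop <- tryCatch(
        generate_population(spec, image_id = paste0(cl, "_d", d),
                            clone_id = cl),
        error = function(e) {
          stop("2D stage failed for image ", cl, "_d", d, ": ",
               conditionMessage(e))
        })
      net <- build_network(pop$image,
                           adjacency_threshold = config$adjacency_threshold)
      write_network(net, file.path(out_dir,
                                   paste0("network_", cl, "_d", d,
                                          ".graphml")))
      dplyr::bind_cols(tidy(snapshot(pop$image)),
                       network_metrics(net, img = pop$image,
                                       exact_limit = config$exact_limit))
    })
  })
  utils::write.csv(snapshots, file.path(out_dir, "snapshot_summaries.csv"),
                   row.names = FALSE)

  # --- progression stage: growth variables per clone ---------------------
  logln("progression stage")
  gv <- growth_variable_table(snapshots, degree = config$degree,
                              anchors = config$anchors)
  utils::write.csv(gv, file.path(out_dir, "growth_variables.csv"),
                   row.names = FALSE)

  # --- clustering stage ---------------------------------------------------
  logln("clustering stage")
  n_per_group <- min(table(clones$line))
  clusters <- if (n_per_group >= config$k_sub) {
    two_stage_clustering(gv,
                         superclass_labels = clones$line[
                           match(gv$clone_id, clones$clone_id)],
                         k_super = config$k_super, k_sub = config$k_sub)
  } else {
    cluster_clones(gv, k = min(config$k_super, nrow(gv)))
  }
  utils::write.csv(tidy(clusters), file.path(out_dir, "cluster_labels.csv"),
                   row.names = FALSE)

  # --- 3D stage: spheroids -> invasion score ------------------------------
  logln("3D stage")
  spheroids <- purrr::map_dfr(seq_len(nrow(clones)), function(i) {
    cl <- clones$clone_id[i]
    ln <- clones$line[i]
    purrr::map_dfr(seq_len(syn$spheroids_per_clone), function(s) {
      seed_id <- config$seed * 10000L + 5000L + i * 10L + s
      set.seed(seed_id)
      np <- syn$protrusions[[ln]]
      nc <- syn$disseminated[[ln]]
      spec <- synthetic_spheroid_spec(
        protrusion_lengths = stats::runif(np, syn$protrusion_length[[ln]][1],
                                          syn$protrusion_length[[ln]][2]),
        disseminated_distances = stats::runif(
          nc, syn$disseminated_distance[[ln]][1],
          syn$disseminated_distance[[ln]][2]),
        seed = seed_id)
      sph <- generate_spheroid_stack(spec,
                                     spheroid_id = paste0(cl, "_s", s),
                                     clone_id = cl)
      measure_spheroid_stack(sph$stack, window = config$spheroid$window,
                             min_area = config$spheroid$min_area,
                             min_length = config$spheroid$min_length)
    })
  })
  utils::write.csv(
    spheroids[, setdiff(names(spheroids),
                        c("protrusion_lengths", "region_distances"))],
    file.path(out_dir, "spheroid_metrics.csv"), row.names = FALSE)
  inv <- invasion_score(spheroids)
  utils::write.csv(inv, file.path(out_dir, "invasion_scores.csv"),
                   row.names = FALSE)

  # --- correlation stage --------------------------------------------------
  logln("correlation stage")
  mid_vars <- grep("_m$", names(gv), value = TRUE)
  tab <- dplyr::left_join(gv[, c("clone_id", mid_vars)],
                          inv[, c("clone_id", "invasion3D")],
                          by = "clone_id")
  corr <- spearman_matrix(tab)
  utils::write.csv(corr, file.path(out_dir, "correlation_matrix.csv"))
  graph_all <- correlation_graph(corr,
                                 threshold = config$correlation_threshold)
  inv_graph <- invasion_correlations(tab,
                                     threshold = config$invasion_threshold)
  utils::write.csv(tidy(graph_all),
                   file.path(out_dir, "correlation_edges.csv"),
                   row.names = FALSE)
  utils::write.csv(tidy(inv_graph),
                   file.path(out_dir, "invasion_correlation_edges.csv"),
                   row.names = FALSE)
  igraph::write_graph(as_igraph(graph_all),
                      file.path(out_dir, "correlation_graph.graphml"),
                      format = "graphml")
  logln("done")

  invisible(list(snapshots = snapshots, growth_variables = gv,
                 clusters = clusters, spheroids = spheroids,
                 invasion = inv,
                 correlations = list(matrix = corr, all = graph_all,
                                     invasion = inv_graph),
                 config_hash = config_hash))
}
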