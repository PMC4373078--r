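#' @name pipeline
#' @title Pipeline runners with reproducible outputs
#'
#' @description
#' File-in/file-out wrappers around the analysis stages, suitable for
#' scripting and for the bundled command-line interface
#' (`system.file("cli", "melinvade.R", package = "melinvade")`). Each
#' runner validates its inputs, writes its results as CSV/JSON into
#' `out_dir`, and records a run manifest (`manifest.json`) with the
#' resolved parameters, input file checksums, seeds and package version,
#' sufficient to reproduce the run bit for bit from the same inputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for all randomness in the run.
#' @return Each runner invisibly returns a list of its result objects;
#'   side effect: files under `out_dir`.
NULL

write_manifest <- function(out_dir, command, params, inputs, seed) {
  checksums <- lapply(inputs, function(p) unname(tools::md5sum(p)))
  manifest <- list(command = command, parameters = params,
                   input_md5 = checksums, seed = seed,
                   package = "melinvade",
                   version = as.character(utils::packageVersion("melinvade")),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      "%Y-%m-%dT%H:%M:%SZ"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

ensure_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_dir
}

#' @rdname pipeline
#' @param scores Path to a character-score CSV (see
#'   [read_character_table()]).
#' @param dims,n_starts,metric,range_mode,tuberculata_only Morphospace
#'   options: embedding dimensions, nmMDS starts, distance metric and
#'   Gower range mode (see [mixed_distance()]), and whether to restrict
#'   the ordination to *M. tuberculata* rows when a `species` column is
#'   present.
#' @export
run_morphospace <- function(scores, out_dir, dims = 3, n_starts = 20,
                            seed = 1, metric = "gower",
                            range_mode = "observed",
                            tuberculata_only = FALSE) {
  ensure_dir(out_dir)
  cm <- read_character_table(scores)
  num <- collapse_multistate(cm)
  if (tuberculata_only && "species" %in% names(num)) {
    num <- num[num$species == "Melanoides tuberculata", ]
  }
  d <- mixed_distance(num, metric = metric, range_mode = range_mode)
  ord <- nmmds(d, dims = dims, n_starts = n_starts, seed = seed)
  groups <- num[c("specimen_id", "group")]
  ov <- tryCatch(group_overlap(ord, groups, seed = seed),
                 error = function(e) {
                   inform(paste0("overlap report skipped: ",
                                 conditionMessage(e)))
                   NULL
                 })
  write.csv(as.matrix(d), file.path(out_dir, "distance_matrix.csv"))
  write.csv(dplyr::left_join(tidy(ord), groups, by = "specimen_id"),
            file.path(out_dir, "ordination_coordinates.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    c(as.list(glance(ord)),
      list(start_stress_pct = 100 * ord$start_stress,
           metric = metric, range_mode = range_mode)),
    file.path(out_dir, "stress.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(ov)) {
    jsonlite::write_json(
      list(groups = dplyr::select(ov$groups, -"box_min", -"box_max"),
           pairs = ov$pairs),
      file.path(out_dir, "overlap.json"), auto_unbox = TRUE, digits = NA)
  }
  write_manifest(out_dir, "morphospace",
                 list(dims = dims, n_starts = n_starts, metric = metric,
                      range_mode = range_mode,
                      tuberculata_only = tuberculata_only),
                 list(scores = scores), seed)
  invisible(list(ordination = ord, overlap = ov, distances = d))
}

#' @rdname pipeline
#' @param tree Path to a rooted newick tree with branch lengths.
#' @param regions Path to a tip-region CSV (`tip_label`, `region`).
#' @param focal_region,threshold Invasion-calling options (see
#'   [call_invasions()]).
#' @export
run_ancestry <- function(tree, regions, out_dir, focal_region,
                         threshold = 0.9) {
  ensure_dir(out_dir)
  phy <- read_newick(tree)
  reg <- tibble::as_tibble(read.csv(regions))
  fit <- fit_mk(phy, reg)
  anc <- marginal_ancestral_states(fit)
  calls <- call_invasions(fit, anc, focal_region, threshold)
  write.csv(tidy(anc), file.path(out_dir, "ancestral_states.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(fit = as.list(glance(fit)), calls = calls),
    file.path(out_dir, "invasion_calls.json"), auto_unbox = TRUE,
    digits = NA)
  # annotated newick: argmax state as node label
  phy_out <- phy
  phy_out$node.label <- colnames(anc)[max.col(unclass(anc))]
  write_newick(phy_out, file.path(out_dir, "annotated_tree.nwk"))
  write_manifest(out_dir, "ancestry",
                 list(focal_region = focal_region, threshold = threshold),
                 list(tree = tree, regions = regions), seed = NULL)
  invisible(list(fit = fit, ancestral = anc, calls = calls))
}

#' @rdname pipeline
#' @param grid Path to an ESRI ASCII population grid.
#' @param sites Path to a sites CSV (`locality`, `row`, `col`).
#' @param threshold_density,n_draws Geographic-test options (see
#'   [density_split()] and [resample_null()]).
#' @param cell_area Cell area in km^2 (default 21).
#' @export
run_geotest <- function(grid, sites, out_dir, threshold_density = 100,
                        n_draws = 10000, seed = 1, cell_area = 21) {
  ensure_dir(out_dir)
  g <- read_ascii_grid(grid, cell_area = cell_area)
  st <- validate_sites(g, tibble::as_tibble(read.csv(sites)))
  split <- density_split(g, threshold_density)
  k_in_high <- sum(g$values[cbind(st$row, st$col)] > split$threshold_count)
  test1 <- split_probability(split$n_high, split$n_masked, nrow(st),
                             k_in_high)
  test2 <- resample_null(g, st, n_draws = n_draws, seed = seed)
  jsonlite::write_json(c(as.list(split), as.list(test1)),
                       file.path(out_dir, "split_test.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(k = test2$k, observed_sum = test2$observed_sum,
         count_exceeding = test2$count_exceeding,
         p_empirical = test2$p_empirical, n_draws = test2$n_draws,
         seed = seed, null_fivenum = test2$null_summary),
    file.path(out_dir, "resample_test.json"), auto_unbox = TRUE,
    digits = NA)
  hist_df <- tidy(test2) |>
    dplyr::count(bin = cut(.data$null_sum, breaks = 50, dig.lab = 10))
  write.csv(hist_df, file.path(out_dir, "null_sum_histogram.csv"),
            row.names = FALSE)
  write_manifest(out_dir, "geotest",
                 list(threshold_density = threshold_density,
                      n_draws = n_draws, cell_area = cell_area),
                 list(grid = grid, sites = sites), seed)
  invisible(list(split = split, split_test = test1, resample = test2))
}

#' @rdname pipeline
#' @param config Simulation settings: a JSON file path or a named list
#'   with (all optional) `tree` (`n_tips`, `birth_rate`), `regions`
#'   (`states`, `q_true`, `root_state`, `planted_invasion`), `morphs`
#'   (`n_morphs`, `specimens_per_morph`, `plasticity`), `grid` (`nrows`,
#'   `ncols`, `n_hotspots`, `meanlog`, `sdlog`), `placement` (`k`,
#'   `beta`). The single `seed` governs all stages.
#' @export
run_simulate <- function(config = list(), out_dir, seed = 1) {
  ensure_dir(out_dir)
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  dflt <- list(
    tree = list(n_tips = 200, birth_rate = 8),
    regions = list(states = c("Africa", "Asia", "America"), q_true = 0.1,
                   root_state = NULL, planted_invasion = NULL),
    morphs = list(n_morphs = 6, specimens_per_morph = 8, plasticity = 0.15),
    grid = list(nrows = 60, ncols = 60, n_hotspots = 5,
                meanlog = 4.8, sdlog = 2),
    placement = list(k = 6, beta = 2)
  )
  cfg <- utils::modifyList(dflt, config)
  seeds <- derive_seeds(seed, 5)

  tree <- simulate_yule_tree(cfg$tree$n_tips, cfg$tree$birth_rate, seeds[1])
  sim <- simulate_mk_states(tree, cfg$regions$q_true, cfg$regions$states,
                            seed = seeds[2],
                            planted_invasion = cfg$regions$planted_invasion,
                            root_state = cfg$regions$root_state)
  cm <- simulate_character_matrix(cfg$morphs$n_morphs,
                                  cfg$morphs$specimens_per_morph,
                                  cfg$morphs$plasticity, seed = seeds[3])
  g <- simulate_population_grid(cfg$grid$nrows, cfg$grid$ncols,
                                n_hotspots = cfg$grid$n_hotspots,
                                meanlog = cfg$grid$meanlog,
                                sdlog = cfg$grid$sdlog, seed = seeds[4])
  sites <- place_invasions(g, cfg$placement$k, cfg$placement$beta, seeds[5])

  write_newick(tree, file.path(out_dir, "tree.nwk"))
  write.csv(sim$regions, file.path(out_dir, "regions.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(node_states = sim$node_states, planted = sim$truth$planted,
         planted_node = attr(sim$truth, "planted_node")),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  write.csv(as.data.frame(cm), file.path(out_dir, "scores.csv"),
            row.names = FALSE, na = "na")
  write_ascii_grid(g, file.path(out_dir, "pop.asc"))
  write.csv(sites, file.path(out_dir, "sites.csv"), row.names = FALSE)
  write_manifest(out_dir, "simulate", cfg,
                 if (is.null(cfg_path)) list() else list(config = cfg_path),
                 seed)
  invisible(list(tree = tree, regions = sim$regions, truth = sim$truth,
                 scores = cm, grid = g, sites = sites))
}

#' @rdname pipeline
#' @export
run_all <- function(out_dir, seed = 1, config = list()) {
  sim_dir <- file.path(out_dir, "simulate")
  simres <- run_simulate(config, sim_dir, seed = seed)
  res <- list(simulate = simres)
  res$morphospace <- run_morphospace(file.path(sim_dir, "scores.csv"),
                                     file.path(out_dir, "morphospace"),
                                     seed = seed)
  focal <- if (!is.null(config$regions$states)) {
    config$regions$states[1]
  } else "Africa"
  res$ancestry <- run_ancestry(file.path(sim_dir, "tree.nwk"),
                               file.path(sim_dir, "regions.csv"),
                               file.path(out_dir, "ancestry"),
                               focal_region = focal)
  res$geotest <- run_geotest(file.path(sim_dir, "pop.asc"),
                             file.path(sim_dir, "sites.csv"),
                             file.path(out_dir, "geotest"),
                             seed = seed, n_draws = 2000)
  invisible(res)
}
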