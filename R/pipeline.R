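#' Read a pipeline configuration
#'
#' YAML file mirroring the arguments of [run_pipeline()]: input paths
#' (`injections`, `lengths`, `distances`, `species`, `microstructure`),
#' `seed`, `null_realizations`, an `agranular` list, bin sizes, and
#' `out_dir`.
#'
#' @param file Path to a YAML config.
#' @return Named list of settings with defaults filled in.
#' @export
read_pipeline_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  defaults <- list(seed = 1L, null_realizations = 100L,
                   agranular = character(),
                   bin_log10_fln = 0.5, bin_sln = 0.05,
                   bin_distance_mm = 2, bin_degree = 5,
                   embedding_restarts = 50L, out_dir = NULL)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  for (nm in c("bin_log10_fln", "bin_sln", "bin_distance_mm", "bin_degree"))
    if (cfg[[nm]] <= 0) stop("bin sizes must be positive: ", nm)
  cfg
}

#' Run the full connectome analysis
#'
#' Orchestrates every stage on a set of injection records: connectome
#' assembly and the edge-complete subnetwork; weight-distribution statistics
#' and the FF/FB comparison; binary topology (density, degrees, dyad/triad
#' motifs against a degree-preserving null ensemble, cliques,
#' core-periphery, similarity-distance connection probability); the
#' beta-regression hierarchy and circular embedding; distance distributions
#' and the exponential-distance-rule fit; allometric scaling and
#' microstructure correlations when their tables are supplied. Deterministic
#' given the seed. When `out_dir` is set, each stage is written as JSON
#' (plus CSV series for the figure-like panels) together with a provenance
#' block recording inputs, their MD5 hashes, the seed and package version.
#'
#' @param injections List of [injection_record()]s, or a path to an
#'   injection table readable by [read_injections()].
#' @param distances Optional symmetric wiring-distance matrix (mm) over the
#'   source areas, or a path readable by [read_matrix_csv()].
#' @param lengths Optional numeric vector of per-neuron projection lengths
#'   (mm), or a path to a one-column `length_mm` table.
#' @param species Optional species table for [fit_allometric()], or a path.
#' @param microstructure Optional table for [correlate_spine_hierarchy()],
#'   or a path readable by [read_microstructure()].
#' @param agranular Area codes with undefined SLN.
#' @param sources Optional parcellation source list for
#'   [build_connectome()].
#' @param null_realizations Degree-preserving null ensemble size.
#' @param embedding_restarts Restarts of the circular-embedding optimizer.
#' @param seed Integer seed for every stochastic stage.
#' @param out_dir Optional report directory.
#' @param ground_truth Optional [synthetic_ground_truth()] (or path to a
#'   sidecar JSON) for a recovery report comparing fitted to true values.
#' @return List of per-stage results (class `pipeline_report`).
#' @export
run_pipeline <- function(injections, distances = NULL, lengths = NULL,
                         species = NULL, microstructure = NULL,
                         agranular = character(), sources = NULL,
                         null_realizations = 100L, embedding_restarts = 50L,
                         seed = 1L, out_dir = NULL, ground_truth = NULL) {
  prov <- list(seed = as.integer(seed),
               package_version = as.character(utils::packageVersion("connectoscope")),
               timestamp = NA)
  if (is.character(injections)) {
    prov$inputs <- list(injections = unname(tools::md5sum(injections)))
    injections <- read_injections(injections)
  }
  if (is.character(distances)) distances <- read_matrix_csv(distances)
  if (is.character(lengths))
    lengths <- utils::read.table(lengths, header = TRUE, sep = ",")$length_mm
  if (is.character(species))
    species <- utils::read.table(species, header = TRUE, sep = ",")
  if (is.character(microstructure))
    microstructure <- read_microstructure(microstructure)
  if (is.character(ground_truth)) {
    gtj <- jsonlite::read_json(ground_truth, simplifyVector = TRUE)
    ground_truth <- gtj
  }

  report <- list(provenance = prov)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    out
  }

  cm <- stage("connectome", build_connectome(injections, sources = sources,
                                             agranular = agranular))
  ec <- stage("edge_complete", build_edge_complete(cm))
  report$connectome <- list(
    n_targets = length(cm$targets), n_sources = length(cm$sources),
    coverage_pct = 100 * length(cm$targets) / length(cm$sources),
    possible_connections = length(cm$targets) * length(cm$sources),
    present_connections = sum(cm$presence))

  fln_pos <- cm$fln[cm$presence]
  report$weights <- stage("weights", {
    ln <- fit_log10_normal(fln_pos)
    obs_pairs <- cm$presence & !is.na(cm$sln)
    fffb <- tryCatch(compare_ff_fb(cm$fln[obs_pairs], cm$sln[obs_pairs]),
                     error = function(e) NULL)
    list(lognormal = unclass(ln),
         histogram = density_histogram(log10(fln_pos), 0.5),
         ff_fb = if (!is.null(fffb)) unclass(fffb))
  })

  report$topology <- stage("topology", {
    A <- ec$adjacency
    ens <- degree_preserving_null(A, null_realizations, seed = seed)
    motifs <- motif_ratio(A, ens)
    cliques <- enumerate_cliques(A)
    core <- extract_core(A)
    simfit <- tryCatch(fit_connection_probability(A, mode = "out"),
                       error = function(e) NULL)
    list(density = graph_density(A),
         degrees = degree_sequences(A),
         motifs = motifs, cliques = cliques, core = core,
         similarity = simfit)
  })

  report$hierarchy <- stage("hierarchy", {
    obs <- sln_observations(injections, agranular = agranular)
    fit <- fit_hierarchy(obs, method = "beta")
    emb <- tryCatch(circular_embedding(stats::coef(fit), ec$fln,
                                       n_restarts = embedding_restarts,
                                       seed = seed),
                    error = function(e) NULL)
    list(fit = fit, embedding = emb)
  })

  if (!is.null(distances)) {
    report$spatial <- stage("spatial", {
      src <- intersect(cm$sources, rownames(distances))
      tg <- intersect(cm$targets, rownames(distances))
      all_d <- distances[src, src][upper.tri(distances[src, src])]
      samp_d <- as.vector(distances[tg, src, drop = FALSE])
      samp_d <- samp_d[samp_d > 0]
      pairs_d <- distances[cm$targets, cm$sources]
      keep <- cm$presence & !is.na(pairs_d) & pairs_d > 0
      list(distance_ks = compare_distance_distributions(all_d, samp_d),
           profile = fln_distance_profile(cm$fln[keep], pairs_d[keep]))
    })
  }
  if (!is.null(lengths))
    report$edr <- stage("edr", fit_edr(lengths, bin_size = 2))
  if (!is.null(species))
    report$allometry <- stage("allometry", fit_allometric(species))
  if (!is.null(microstructure)) {
    report$microstructure <- stage("microstructure", {
      h <- stats::coef(report$hierarchy$fit)
      sp <- tryCatch(correlate_spine_hierarchy(microstructure, h),
                     error = function(e) NULL)
      pw <- if ("neural_density" %in% names(microstructure))
        tryCatch(fit_density_powerlaw(microstructure$spine_count,
                                      microstructure$neural_density),
                 error = function(e) NULL)
      rc <- tryCatch(correlate_rostrocaudal(microstructure),
                     error = function(e) NULL)
      list(spine_hierarchy = sp, density_powerlaw = pw, rostrocaudal = rc)
    })
  }
  if (!is.null(ground_truth)) {
    report$recovery <- stage("recovery", {
      h_true <- unlist(ground_truth$h_true)
      h_hat <- stats::coef(report$hierarchy$fit)
      common <- intersect(names(h_true), names(h_hat))
      out <- list(hierarchy_spearman =
                    stats::cor(h_true[common], h_hat[common],
                               method = "spearman"))
      if (!is.null(report$edr) && !is.null(ground_truth$lambda_true)) {
        out$lambda_true <- ground_truth$lambda_true
        out$lambda_hat <- report$edr$lambda
        out$lambda_rel_error <- abs(out$lambda_hat - out$lambda_true) /
          out$lambda_true
      }
      out
    })
  }

  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Connectome analysis report (seed ", x$provenance$seed, ")\n", sep = "")
  cat("  stages: ", paste(setdiff(names(x), "provenance"), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  %d targets x %d sources, edge-complete density %.2f%%\n",
              x$connectome$n_targets, x$connectome$n_sources,
              100 * x$topology$density))
  invisible(x)
}

# Serialize a report bundle: one JSON per stage plus CSV panel series.
write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  to_plain <- function(x) {
    if (is.function(x)) return(NULL)
    if (inherits(x, c("hierarchy_fit", "circular_embedding", "edr_fit",
                      "allometric_fit", "motif_report", "clique_report",
                      "core_report", "similarity_fit")))
      x <- unclass(x)
    if (is.list(x)) {
      x <- lapply(x, to_plain)
      x[!vapply(x, is.null, logical(1))]
    } else x
  }
  for (nm in setdiff(names(report), character())) {
    jsonlite::write_json(to_plain(report[[nm]]),
                         file.path(out_dir, paste0(nm, ".json")),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         na = "null")
  }
  if (!is.null(report$weights$histogram))
    utils::write.table(report$weights$histogram,
                       file.path(out_dir, "fln_histogram.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
  if (!is.null(report$spatial$profile))
    utils::write.table(report$spatial$profile,
                       file.path(out_dir, "fln_distance_profile.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}
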