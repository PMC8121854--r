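#' Default pipeline configuration
#'
#' Returns the configuration list consumed by \code{\link{run_pipeline}}.
#' Every stage's parameters live here: cohort sizes for the ADI-R
#' simulation, the z-threshold sweep, connectome dimensions and planted
#' effects, atlas dimensions, and the enrichment background. Any element
#' can be overridden via \code{...} or by supplying a YAML file to
#' \code{\link{read_pipeline_config}}.
#'
#' @param ... Named overrides of the defaults.
#' @return Configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 17L,
    thresholds = seq(0.5, 1.0, by = 0.1),
    min_group = 20L,
    rho = 1,
    adir = list(n_discovery = 889L, n_replication = 890L, dummy_rate = 0.05),
    connectome = list(K = 19L, group_sizes = default_group_sizes(),
                      planted = default_planted_edges(),
                      n_sites = 3L, site_sd = 0.1),
    atlas = list(networks = c("IC03", "IC07", "IC12", "IC13", "IC17"),
                 n_genes = 1000L, n_coupled = 40L, n_samples = 150L),
    enrichment = list(background_n = 20787L, n_lists = 3L, list_size = 150L,
                      odds_multipliers = c(3, 1, 1))
  )
  dots <- list(...)
  utils::modifyList(cfg, dots)
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys override \code{\link{pipeline_config}}
#'   defaults.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

.write_csv <- function(x, path) utils::write.csv(x, path, row.names = FALSE)

.stage_done <- function(out_dir, files) all(file.exists(file.path(out_dir, files)))

#' Run the full synthetic analysis pipeline
#'
#' Orchestrates the stages in analysis order: simulate and score an ADI-R
#' cohort pair, derive subtype norms and labels across the z-threshold
#' sweep with out-of-sample prediction, simulate a Discovery/Replication
#' connectome and run the edge-wise replication analysis per contrast and
#' threshold, take consensus edges, decode simulated expression atlases
#' against the implicated network maps, build subtype-specific gene sets,
#' and run the enrichment grid. Each stage writes CSV outputs into
#' \code{out_dir} plus a JSON run manifest; stages whose outputs already
#' exist are skipped when \code{resume = TRUE}, and because every stage is
#' seeded from the master seed, regenerated outputs are identical.
#'
#' @param config List from \code{\link{pipeline_config}}.
#' @param out_dir Output directory (created if absent).
#' @param resume Skip stages whose outputs already exist (default TRUE).
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, resume = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- child_seeds(config$seed, 5)
  manifest <- list(config = config, seeds = as.list(seeds),
                   version = as.character(utils::packageVersion("scrrb")),
                   stages = list())
  thr_names <- formatC(config$thresholds, format = "f", digits = 1)

  ## stage 1: ADI-R simulation + scoring -------------------------------
  pair <- simulate_cohort_pair(config$adir$n_discovery, config$adir$n_replication,
                               mode = "items", seed = seeds[1])
  scores <- lapply(pair, function(cohort) score_adir(cohort$records))
  if (!(resume && .stage_done(out_dir, c("scores_discovery.csv", "scores_replication.csv")))) {
    .write_csv(scores$discovery, file.path(out_dir, "scores_discovery.csv"))
    .write_csv(scores$replication, file.path(out_dir, "scores_replication.csv"))
    .write_csv(pair$discovery$truth, file.path(out_dir, "truth_adir_discovery.csv"))
    .write_csv(pair$replication$truth, file.path(out_dir, "truth_adir_replication.csv"))
  }
  manifest$stages$adir <- list(n_discovery = nrow(scores$discovery),
                               n_replication = nrow(scores$replication),
                               dropped = nrow(attr(scores$discovery, "dropped")) +
                                 nrow(attr(scores$replication, "dropped")))

  ## stage 2: subtyping ------------------------------------------------
  norms <- lapply(scores, function(s) compute_norms(s$diff))
  sweep <- lapply(scores, function(s) threshold_sweep(s, compute_norms(s$diff),
                                                      config$thresholds))
  accuracy <- vapply(thr_names, function(th) {
    pred <- predict_out_of_sample(scores$replication, norms$discovery,
                                  as.numeric(th))
    subtype_accuracy(pred, sweep$replication[[th]])$accuracy
  }, numeric(1))
  if (!(resume && .stage_done(out_dir, "subtype_accuracy.csv"))) {
    for (th in thr_names) {
      .write_csv(sweep$discovery[[th]],
                 file.path(out_dir, sprintf("labels_discovery_z%s.csv", th)))
      .write_csv(sweep$replication[[th]],
                 file.path(out_dir, sprintf("labels_replication_z%s.csv", th)))
    }
    .write_csv(data.frame(threshold = as.numeric(thr_names), accuracy = accuracy),
               file.path(out_dir, "subtype_accuracy.csv"))
  }
  manifest$stages$subtype <- list(
    norms = lapply(norms, function(x) x[c("mean", "sd", "n")]),
    accuracy = as.list(accuracy))

  ## stage 3: connectome -----------------------------------------------
  cx <- config$connectome
  conn <- simulate_connectome_dataset(cx$group_sizes, K = cx$K,
                                      planted = cx$planted,
                                      n_sites = cx$n_sites,
                                      site_sd = cx$site_sd, seed = seeds[2])
  contrasts <- setdiff(unique(conn$discovery$pheno$group), "TD")
  group_n <- table(conn$discovery$pheno$group)
  contrasts <- contrasts[group_n[contrasts] >= config$min_group]
  results <- list()
  for (ct in contrasts) {
    per_thr <- list()
    for (th in thr_names) {
      half <- function(h) {
        keep <- h$pheno$group %in% c("TD", ct)
        list(edges = h$edges[keep, , drop = FALSE],
             group = factor(h$pheno$group[keep], levels = c("TD", ct)),
             sex = h$pheno$sex[keep], age = h$pheno$age[keep],
             site = h$pheno$site[keep])
      }
      per_thr[[th]] <- edge_replication_analysis(half(conn$discovery),
                                                 half(conn$replication))
      if (!(resume && .stage_done(out_dir, sprintf("edges_%s_z%s.csv", ct, th)))) {
        .write_csv(per_thr[[th]], file.path(out_dir, sprintf("edges_%s_z%s.csv", ct, th)))
      }
    }
    cons <- consensus_edges(per_thr)
    if (!(resume && .stage_done(out_dir, sprintf("consensus_%s.csv", ct)))) {
      .write_csv(cons, file.path(out_dir, sprintf("consensus_%s.csv", ct)))
    }
    results[[ct]] <- list(per_threshold = per_thr, consensus = cons)
  }
  .write_csv(conn$truth, file.path(out_dir, "truth_edges.csv"))
  manifest$stages$connectome <- list(
    n_edges = ncol(conn$discovery$edges),
    contrasts = as.list(contrasts),
    consensus = lapply(results, function(r) r$consensus$edge))

  ## stage 4: gene decoding --------------------------------------------
  at <- config$atlas
  sim_atlas <- simulate_expression_atlas(networks = at$networks,
                                         n_genes = at$n_genes,
                                         n_coupled = at$n_coupled,
                                         n_samples = at$n_samples,
                                         seed = seeds[3])
  decoded <- lapply(at$networks, function(nw) {
    decode_network(sim_atlas$maps[[nw]], sim_atlas$atlas)
  })
  names(decoded) <- at$networks
  gene_lists <- lapply(decoded, retained_genes)
  sets <- list(
    "SC>RRB" = subtype_specific_genes(gene_lists, targets = "IC17",
                                      exclude = intersect(c("IC03", "IC07", "IC12", "IC13"),
                                                          names(gene_lists))),
    "SC=RRB" = subtype_specific_genes(gene_lists,
                                      targets = intersect(c("IC03", "IC07", "IC13"),
                                                          names(gene_lists)),
                                      exclude = intersect(c("IC12", "IC17"),
                                                          names(gene_lists)))
  )
  if (!(resume && .stage_done(out_dir, "truth_atlas.csv"))) {
    for (nw in at$networks) {
      .write_csv(decoded[[nw]], file.path(out_dir, sprintf("decoded_%s.csv", nw)))
    }
    writeLines(sets[["SC>RRB"]]$gene, file.path(out_dir, "genes_SCgtRRB.txt"))
    writeLines(sets[["SC=RRB"]]$gene, file.path(out_dir, "genes_SCeqRRB.txt"))
    .write_csv(sim_atlas$truth, file.path(out_dir, "truth_atlas.csv"))
  }
  manifest$stages$decode <- list(
    n_retained = lapply(gene_lists, length),
    set_sizes = lapply(sets, nrow))

  ## stage 5: enrichment -----------------------------------------------
  en <- config$enrichment
  list_seeds <- child_seeds(seeds[4], en$n_lists)
  network_sets <- lapply(sets, function(s) s$gene)
  network_sets <- network_sets[vapply(network_sets, length, integer(1)) > 0]
  enrich <- NULL
  if (length(network_sets)) {
    annotations <- lapply(seq_len(en$n_lists), function(i) {
      simulate_gene_lists(network_sets[[1]], background_n = en$background_n,
                          list_size = en$list_size,
                          odds_multiplier = en$odds_multipliers[i],
                          seed = list_seeds[i])$annotation
    })
    names(annotations) <- sprintf("list%02d", seq_len(en$n_lists))
    enrich <- enrichment_grid(network_sets, annotations,
                              background_n = en$background_n)
    if (!(resume && .stage_done(out_dir, "enrichment.csv"))) {
      .write_csv(enrich, file.path(out_dir, "enrichment.csv"))
    }
  }
  manifest$stages$enrichment <- list(
    n_tests = if (is.null(enrich)) 0L else nrow(enrich),
    n_significant = if (is.null(enrich)) 0L else sum(enrich$significant))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(list(scores = scores, norms = norms, sweep = sweep,
                 accuracy = accuracy, connectome = results,
                 decoded = decoded, sets = sets, enrichment = enrich))
}
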