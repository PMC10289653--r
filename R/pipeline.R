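## Pipeline orchestration: simulate -> aggregate -> coverage -> housekeeping
## -> tfactivity -> cci -> report, with a JSON manifest recording parameters
## and file hashes per stage so unchanged stages are skipped on re-runs.

#' Pipeline run configuration
#'
#' @param out_dir output directory of the run.
#' @param seed top-level seed; each stage derives its own stream from it.
#' @param sim a [sim_config()] for the simulate stage (its seed is taken from
#'   `seed`).
#' @param stages character vector of stages to run, in dependency order.
#' @param n_boot bootstrap resamples (aggregate stage).
#' @param coverage_iters down-sampling iterations per size (coverage stage).
#' @param gini_threshold housekeeping candidacy threshold.
#' @param gap,max_dist,ratio,hot_max,folds TF-activity stage parameters.
#' @param n_perm,alpha,rank CCI stage parameters.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1,
                            sim = sim_config(seed = seed),
                            stages = c("simulate", "aggregate", "coverage",
                                       "housekeeping", "tfactivity", "cci",
                                       "report"),
                            n_boot = 1000,
                            coverage_iters = 100,
                            gini_threshold = 0.3,
                            gap = 200, max_dist = 2000, ratio = 1.5,
                            hot_max = 70, folds = 20,
                            n_perm = 1000, alpha = 0.05, rank = 3) {
  sim$seed <- as.integer(derive_seed(seed, "simulate"))
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 stages = stages, n_boot = n_boot,
                 coverage_iters = coverage_iters,
                 gini_threshold = gini_threshold, gap = gap,
                 max_dist = max_dist, ratio = ratio, hot_max = hot_max,
                 folds = folds, n_perm = n_perm, alpha = alpha, rank = rank),
            class = "pipeline_config")
}

.stage_params <- function(config, stage) {
  p <- switch(stage,
    simulate = unclass(config$sim),
    aggregate = list(n_boot = config$n_boot, seed = config$seed),
    coverage = list(iters = config$coverage_iters, seed = config$seed),
    housekeeping = list(gini_threshold = config$gini_threshold),
    tfactivity = list(gap = config$gap, max_dist = config$max_dist,
                      ratio = config$ratio, hot_max = config$hot_max,
                      folds = config$folds, seed = config$seed),
    cci = list(n_perm = config$n_perm, alpha = config$alpha,
               rank = config$rank, seed = config$seed),
    report = list())
  as.character(jsonlite::toJSON(p, auto_unbox = TRUE, digits = NA))
}

.stage_inputs <- list(simulate = character(0),
                      aggregate = "simulate",
                      coverage = "simulate",
                      housekeeping = c("simulate", "aggregate"),
                      tfactivity = c("simulate", "aggregate"),
                      cci = "simulate",
                      report = c("aggregate", "coverage", "housekeeping",
                                 "tfactivity", "cci"))

.hash_dir <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  h <- tools::md5sum(files)
  names(h) <- sub(paste0("^", dir, "/?"), "", names(h))
  as.list(h)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order, writing each stage's
#' outputs under `out_dir/<stage>/` and a JSON manifest (parameters, file
#' hashes, wall-clock) at `out_dir/manifest.json`. A stage whose parameters
#' and upstream file hashes are unchanged since the recorded manifest is
#' skipped.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly (list, one entry per stage).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = FALSE) else list()
  say <- function(...) if (!quiet) message("[wbatlas] ", ...)

  for (stage in c("simulate", "aggregate", "coverage", "housekeeping",
                  "tfactivity", "cci", "report")) {
    if (!stage %in% config$stages) next
    sdir <- file.path(config$out_dir, stage)
    params <- .stage_params(config, stage)
    up <- .stage_inputs[[stage]]
    missing_up <- up[!vapply(up, function(u)
      dir.exists(file.path(config$out_dir, u)), logical(1))]
    if (length(missing_up))
      stop("dependency error: stage '", stage, "' requires outputs of: ",
           paste(missing_up, collapse = ", "))
    in_hashes <- unlist(lapply(up, function(u)
      .hash_dir(file.path(config$out_dir, u))), use.names = TRUE)
    prev <- manifest[[stage]]
    if (!is.null(prev) && identical(prev$params, params) &&
        identical(unlist(prev$input_hashes), in_hashes) &&
        dir.exists(sdir)) {
      say("skipping ", stage, " (up to date)")
      next
    }
    say("running ", stage)
    unlink(sdir, recursive = TRUE)
    dir.create(sdir, recursive = TRUE)
    t0 <- proc.time()[["elapsed"]]
    .run_stage(stage, config, sdir)
    manifest[[stage]] <- list(status = "completed", params = params,
                              input_hashes = as.list(in_hashes),
                              output_hashes = .hash_dir(sdir),
                              elapsed_sec = round(proc.time()[["elapsed"]] - t0, 2))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(manifest)
}

.num_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  write_tsv(df, path)
}

.run_stage <- function(stage, config, sdir) {
  out <- config$out_dir
  load_atlas <- function() read_dataset(file.path(out, "simulate"))
  switch(stage,
    simulate = {
      write_dataset(simulate_atlas(config$sim), sdir)
    },
    aggregate = {
      atlas <- load_atlas()
      prof <- bootstrap_profile(atlas$counts, atlas$cell_labels,
                                n_boot = config$n_boot,
                                seed = derive_seed(config$seed, "aggregate"))
      .num_tsv(prof$scaled_tpm, file.path(sdir, "scaled_tpm.tsv"))
      for (lv in names(prof$ci)) {
        .num_tsv(prof$ci[[lv]]$low, file.path(sdir, sprintf("ci_low_%s.tsv", lv)))
        .num_tsv(prof$ci[[lv]]$high, file.path(sdir, sprintf("ci_high_%s.tsv", lv)))
      }
      .num_tsv(prof$robust_mask * 1L, file.path(sdir, "robust_mask.tsv"))
      .num_tsv(percent_expressed(atlas$counts, atlas$cell_labels),
               file.path(sdir, "pct_expressed.tsv"))
      .num_tsv(aggregate_log1p_cpm(atlas$counts, atlas$cell_labels),
               file.path(sdir, "log1p_cpm.tsv"))
    },
    coverage = {
      atlas <- load_atlas()
      tab <- coverage_table(atlas$counts, atlas$cell_labels,
                            n_iter = config$coverage_iters,
                            seed = derive_seed(config$seed, "coverage"))
      write_tsv(tab, file.path(sdir, "coverage.tsv"))
    },
    housekeeping = {
      agg <- file.path(out, "aggregate")
      stpm <- as.matrix(read_tsv(file.path(agg, "scaled_tpm.tsv"), row_names = 1))
      pct <- as.matrix(read_tsv(file.path(agg, "pct_expressed.tsv"), row_names = 1))
      scores <- gene_consistency_scores(stpm, pct)
      rings <- housekeeping_candidates(scores, config$gini_threshold)
      write_tsv(scores, file.path(sdir, "hk_scores.tsv"))
      jsonlite::write_json(unclass(rings), file.path(sdir, "hk_rings.json"),
                           auto_unbox = FALSE, digits = NA)
    },
    tfactivity = {
      atlas <- load_atlas()
      agg <- file.path(out, "aggregate")
      stpm <- as.matrix(read_tsv(file.path(agg, "scaled_tpm.tsv"), row_names = 1))
      robust <- as.matrix(read_tsv(file.path(agg, "robust_mask.tsv"), row_names = 1)) > 0
      prof <- structure(list(scaled_tpm = stpm, robust_mask = robust,
                             n_cells = table(atlas$cell_labels), n_boot = 0L),
                        class = "cell_type_profile")
      peaks <- normalize_signals(atlas$peaks)
      pc <- cluster_peaks(peaks, gap = config$gap)
      pc <- filter_clusters(pc, max_tfs = config$hot_max)
      pc <- assign_targets(pc, atlas$gene_annotation, max_dist = config$max_dist,
                           ratio = config$ratio)
      X <- build_predictor_matrix(pc)
      fit <- fit_tf_models(X, prof, folds = config$folds,
                           seed = derive_seed(config$seed, "tfactivity"))
      write_tsv(pc$clusters, file.path(sdir, "clusters.tsv"))
      .num_tsv(X, file.path(sdir, "predictor_matrix.tsv"))
      act <- data.frame(tf = rep(rownames(fit$beta), ncol(fit$beta)),
                        cell_type = rep(colnames(fit$beta), each = nrow(fit$beta)),
                        beta_raw = as.vector(fit$beta_raw),
                        beta_clipped = as.vector(fit$beta))
      write_tsv(act, file.path(sdir, "tf_activity.tsv"))
      write_tsv(data.frame(cell_type = names(fit$cv_mse), cv_mse = fit$cv_mse),
                file.path(sdir, "cv_mse.tsv"))
      write_tsv(fit$associations, file.path(sdir, "associations.tsv"))
      ## dendrograms: all genes vs TF activity vs TF expression
      tr_all <- build_dendrogram(log1p(stpm))
      tr_act <- build_dendrogram(fit$beta)
      tf_expr <- log1p(stpm[intersect(rownames(fit$beta), rownames(stpm)), ,
                            drop = FALSE])
      tr_tfx <- build_dendrogram(tf_expr)
      writeLines(.hclust_newick(tr_all), file.path(sdir, "dendrogram_all_genes.nwk"))
      writeLines(.hclust_newick(tr_act), file.path(sdir, "dendrogram_activity.nwk"))
      writeLines(.hclust_newick(tr_tfx), file.path(sdir, "dendrogram_tf_expression.nwk"))
      jsonlite::write_json(list(activity_vs_all_genes = bakers_gamma(tr_all, tr_act),
                                tf_expression_vs_all_genes = bakers_gamma(tr_all, tr_tfx)),
                           file.path(sdir, "gamma.json"), auto_unbox = TRUE,
                           digits = NA)
    },
    cci = {
      atlas <- load_atlas()
      pt <- permutation_test(atlas$counts, atlas$cell_labels, atlas$lr_pairs,
                             n_perm = config$n_perm,
                             seed = derive_seed(config$seed, "cci"))
      tensor <- build_tensor(pt$scores, pt$p_values, alpha = config$alpha,
                             lr_class = atlas$lr_pairs$class)
      sig <- decompose(tensor, rank = config$rank,
                       seed = derive_seed(config$seed, "cci"))
      flatten <- function(a) {
        m <- .unfold(a, 1)
        dn <- dimnames(a)
        dimnames(m) <- list(dn[[1]], paste(rep(dn[[2]], times = length(dn[[3]])),
                                           rep(dn[[3]], each = length(dn[[2]])),
                                           sep = "->"))
        m
      }
      .num_tsv(flatten(tensor$scores), file.path(sdir, "scores_lr_by_sender_receiver.tsv"))
      .num_tsv(flatten(tensor$p_values), file.path(sdir, "pvalues_lr_by_sender_receiver.tsv"))
      dir.create(file.path(sdir, "signatures"))
      .num_tsv(sig$loadings$lr, file.path(sdir, "signatures", "loadings_lr.tsv"))
      .num_tsv(sig$loadings$sender, file.path(sdir, "signatures", "loadings_sender.tsv"))
      .num_tsv(sig$loadings$receiver, file.path(sdir, "signatures", "loadings_receiver.tsv"))
      jsonlite::write_json(list(rank = sig$rank, weights = sig$weights,
                                reconstruction_error = sig$reconstruction_error,
                                relative_error = sig$relative_error,
                                n_retained = tensor$n_retained),
                           file.path(sdir, "signatures", "error.json"),
                           auto_unbox = TRUE, digits = NA)
    },
    report = {
      render_report(out, sdir)
    })
  invisible(NULL)
}

## serialize an hclust tree to Newick with merge heights as branch lengths
.hclust_newick <- function(h) {
  n <- length(h$labels)
  node_str <- character(nrow(h$merge))
  node_h <- h$height
  str_of <- function(id, parent_h) {
    if (id < 0) {
      sprintf("%s:%g", h$labels[-id], parent_h)
    } else {
      sprintf("(%s,%s):%g", str_of(h$merge[id, 1], node_h[id]),
              str_of(h$merge[id, 2], node_h[id]), parent_h - node_h[id])
    }
  }
  root <- nrow(h$merge)
  sprintf("(%s,%s);", str_of(h$merge[root, 1], node_h[root]),
          str_of(h$merge[root, 2], node_h[root]))
}
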