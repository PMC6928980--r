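# End-to-end orchestration: simulate (or read) -> hourly IR -> site x hour
# matrix -> clustering + validation -> MDS + hour ranking -> traffic-flow
# logistic classifier -> CSV report bundle. Intermediates are persisted as
# CSV so every stage can be re-run and audited independently.

#' Pipeline configuration
#'
#' @param out_dir directory for the report bundle.
#' @param input_dir optional directory with monitoring data written by
#'   [write_cohort()] (SPL text files + `flows.csv` + `truth.csv`); when
#'   NULL a synthetic cohort is generated from `sim`.
#' @param offset_c event-emergence offset C, dB.
#' @param min_valid_fraction minimum valid fraction per hour window.
#' @param k number of clusters (the analysis fixes 2).
#' @param methods clustering methods to score.
#' @param neighborhood connectivity neighbourhood size.
#' @param split_ratio train fraction for the classifier.
#' @param seed master seed (simulation, k-means restarts, split).
#' @param hours_for_x `"auto"` (top 3 hours of the Mann-Whitney ranking)
#'   or an explicit vector of three hours.
#' @param sim a [sim_config()] used when `input_dir` is NULL.
#' @param write write the CSV bundle (FALSE = in-memory only).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("noisir_run_"),
                            input_dir = NULL,
                            offset_c = 3, min_valid_fraction = 0.5,
                            k = 2, methods = CLUSTER_METHODS,
                            neighborhood = 10, split_ratio = 0.7,
                            seed = 1, hours_for_x = "auto",
                            sim = NULL, write = TRUE) {
  if (is.null(sim)) sim <- sim_config(seed = seed)
  structure(list(out_dir = out_dir, input_dir = input_dir,
                 offset_c = offset_c,
                 min_valid_fraction = min_valid_fraction, k = k,
                 methods = methods, neighborhood = neighborhood,
                 split_ratio = split_ratio, seed = seed,
                 hours_for_x = hours_for_x, sim = sim, write = write),
            class = "pipeline_config")
}

#' Read a cohort previously written with [write_cohort()]
#'
#' @param dir directory with `<site>_<date>.txt` SPL files, `truth.csv`
#'   (site_id, regime, road_class) and optionally `flows.csv`.
#' @return a cohort list as from [simulate_cohort()] (without `config`).
#' @export
read_cohort <- function(dir) {
  truth_path <- file.path(dir, "truth.csv")
  if (!file.exists(truth_path)) stop("missing truth.csv in ", dir)
  truth <- read.csv(truth_path, stringsAsFactors = FALSE)
  flows_path <- file.path(dir, "flows.csv")
  flows <- if (file.exists(flows_path))
    read.csv(flows_path, stringsAsFactors = FALSE) else NULL
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  if (length(files) == 0) stop("no SPL text files in ", dir)
  series <- lapply(files, function(f) {
    nm <- sub("\\.txt$", "", basename(f))
    site <- sub("_.*$", "", nm)
    rc <- truth$road_class[match(site, truth$site_id)]
    if (is.na(rc)) stop("site ", site, " not in truth.csv")
    read_spl_file(f, rc, site_id = site)
  })
  names(series) <- sub("\\.txt$", "", basename(files))
  list(series = series, flows = flows, truth = truth)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: cohort (simulated or read), hourly IR profiles, site
#' x hour median matrix + column scaling, method validation and
#' selection, site and hour 2-cluster solutions, classical MDS,
#' Mann-Whitney hour ranking, traffic-flow x scores, logistic membership
#' model on a seeded 70/30 split, confusion summaries under both
#' positive-class conventions, analytic and empirical x thresholds. Site
#' cluster ids are canonicalized so Cluster 1 is the group with the lower
#' mean median IR (the "continuous noise" group). When a cluster has
#' fewer than 2 sites the classifier stage is skipped and reported as
#' degenerate instead of failing.
#'
#' @param config a [pipeline_config()].
#' @return An invisible list (`report bundle`) with every stage product;
#'   written as CSV/newick/manifest files under `config$out_dir` when
#'   `config$write` is TRUE.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cohort <- stage("cohort", {
    if (is.null(config$input_dir)) simulate_cohort(config$sim)
    else read_cohort(config$input_dir)
  })

  ir <- stage("ir", {
    profs <- lapply(cohort$series, ir_profile_24h,
                    offset_c = config$offset_c,
                    min_valid_fraction = config$min_valid_fraction)
    list(hours = do.call(rbind, c(lapply(profs, `[[`, "hours"),
                                  make.row.names = FALSE)),
         events = do.call(rbind, c(lapply(profs, `[[`, "events"),
                                   make.row.names = FALSE)))
  })

  agg <- stage("aggregate", {
    by_site <- split(ir$hours, ir$hours$site_id)
    profiles <- lapply(by_site, median_mad_by_hour)
    rc <- NULL
    if (!is.null(cohort$truth))
      rc <- setNames(cohort$truth$road_class, cohort$truth$site_id)
    shm <- build_site_hour_matrix(profiles, road_classes = rc)
    list(shm = shm, scaled = scale_columns(shm))
  })

  clust <- stage("cluster", {
    vr <- validation_report(agg$scaled, k = config$k,
                            methods = config$methods,
                            neighborhood = config$neighborhood,
                            seed = config$seed)
    sel <- if (length(config$methods) >= 2) rank_methods(vr)
           else list(selected = config$methods, ranks = NULL,
                     aggregate = NULL)
    sites <- vr$outcomes[[sel$selected]]
    sites$labels <- canonicalize_site_labels(sites$labels, agg$shm)
    d_hours <- euclidean_distances(agg$scaled, "columns")
    hours <- cluster_with_method(sel$selected, t(unclass(agg$scaled)),
                                 d_hours, config$k, config$seed)
    mds <- classical_mds(euclidean_distances(agg$scaled, "rows"))
    ranking <- if (min(table(sites$labels)) >= 2)
      mannwhitney_hour_ranking(agg$shm, sites) else NULL
    list(validation = vr, selection = sel, sites = sites, hours = hours,
         mds = mds, ranking = ranking)
  })

  classify <- stage("classify", {
    if (is.null(cohort$flows)) {
      list(degenerate = TRUE, reason = "no traffic-flow table")
    } else if (min(table(clust$sites$labels)) < 2) {
      list(degenerate = TRUE,
           reason = "a cluster has fewer than 2 sites; cannot train")
    } else {
      hours_x <- if (identical(config$hours_for_x, "auto")) {
        if (is.null(clust$ranking)) c(15, 13, 11)
        else clust$ranking$hour[1:3]
      } else config$hours_for_x
      xs <- traffic_x(cohort$flows, hours = hours_x)
      xs$cluster <- clust$sites$labels[xs$site_id]
      xs <- xs[!is.na(xs$cluster), ]
      split <- split_train_test(xs, ratio = config$split_ratio,
                                seed = config$seed)
      if (nrow(split$train) < 4 || min(table(split$train$cluster)) < 2 ||
          sd(split$train$x) == 0) {
        list(degenerate = TRUE,
             reason = "training split too small or unbalanced for a logistic fit")
      } else {
        fit <- fit_logistic(split$train$x, split$train$cluster)
        pred <- predict_membership(fit, split$test$x)
        confusion <- confusion_both(pred$cluster, split$test$cluster)
        emp <- empirical_threshold(xs$x, xs$cluster)
        list(degenerate = FALSE, hours_for_x = hours_x, x_scores = xs,
             split = split, fit = fit, test_prediction = pred,
             confusion = confusion,
             analytic_threshold = fit$analytic_threshold,
             empirical_threshold = emp)
      }
    }
  })

  bundle <- list(cohort = cohort, ir = ir, aggregate = agg,
                 cluster = clust, classify = classify, config = config)
  if (config$write) stage("report", write_bundle(bundle))
  invisible(bundle)
}

# Cluster 1 = lower mean median-IR group (continuous-noise sites),
# matching the convention that the eventful sites form Cluster 2.
canonicalize_site_labels <- function(labels, shm) {
  means <- tapply(rowMeans(shm$values)[names(labels)], labels, mean)
  if (length(means) == 2 && means["1"] > means["2"]) {
    labels <- setNames(as.integer(3L - labels), names(labels))
  }
  labels
}

write_bundle <- function(bundle) {
  dir <- bundle$config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, paste0(...))

  ev <- bundle$ir$events
  ev$start_time <- format(ev$start_time, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  write.csv(bundle$ir$hours, p("ir_hours.csv"), row.names = FALSE)
  write.csv(ev, p("ir_events.csv"), row.names = FALSE)

  write_matrix_csv(bundle$aggregate$shm, bundle$aggregate$scaled,
                   p("site_hour"))

  cl <- bundle$cluster
  write.csv(cl$validation$report, p("validation.csv"), row.names = FALSE)
  if (!is.null(cl$selection$ranks)) {
    rk <- data.frame(method = rownames(cl$selection$ranks),
                     cl$selection$ranks,
                     aggregate = cl$selection$aggregate,
                     selected = rownames(cl$selection$ranks) ==
                       cl$selection$selected)
    write.csv(rk, p("method_ranks.csv"), row.names = FALSE)
  }
  write.csv(data.frame(site_id = names(cl$sites$labels),
                       cluster = unname(cl$sites$labels)),
            p("site_clusters.csv"), row.names = FALSE)
  write.csv(data.frame(hour = as.integer(sub("hour_", "",
                                             names(cl$hours$labels))),
                       cluster = unname(cl$hours$labels)),
            p("hour_clusters.csv"), row.names = FALSE)
  write.csv(data.frame(site_id = rownames(cl$mds$coordinates),
                       cl$mds$coordinates),
            p("mds_coordinates.csv"), row.names = FALSE)
  write.csv(mds_variance_summary(cl$mds), p("mds_variance.csv"),
            row.names = FALSE)
  if (!is.null(cl$ranking))
    write.csv(cl$ranking, p("hour_ranking.csv"), row.names = FALSE)
  if (!is.null(cl$sites$tree))
    writeLines(tree_to_newick(cl$sites$tree), p("site_tree.nwk"))
  if (!is.null(cl$hours$tree))
    writeLines(tree_to_newick(cl$hours$tree), p("hour_tree.nwk"))

  # heatmap export: scaled values reordered by the two dendrograms
  hm <- unclass(bundle$aggregate$scaled)
  if (!is.null(cl$sites$tree))
    hm <- hm[stats::as.hclust(cl$sites$tree)$order, , drop = FALSE]
  if (!is.null(cl$hours$tree))
    hm <- hm[, stats::as.hclust(cl$hours$tree)$order, drop = FALSE]
  write.csv(data.frame(site_id = rownames(hm), hm, check.names = FALSE),
            p("heatmap.csv"), row.names = FALSE)

  cf <- bundle$classify
  if (isTRUE(cf$degenerate)) {
    writeLines(paste("classifier skipped:", cf$reason),
               p("classifier_skipped.txt"))
  } else {
    write.csv(cf$x_scores, p("x_scores.csv"), row.names = FALSE)
    write.csv(data.frame(intercept_term = cf$fit$intercept_term,
                         slope_term = cf$fit$slope_term,
                         converged = cf$fit$converged,
                         iterations = cf$fit$iterations,
                         separation = cf$fit$separation,
                         analytic_threshold = cf$analytic_threshold,
                         empirical_threshold = cf$empirical_threshold$threshold,
                         hours_for_x = paste(cf$hours_for_x, collapse = ";")),
              p("logistic_fit.csv"), row.names = FALSE)
    for (nm in names(cf$confusion)) {
      s <- cf$confusion[[nm]]
      write.csv(data.frame(positive_class = s$positive_class,
                           tp = s$table[1, 1], fn = s$table[2, 1],
                           fp = s$table[1, 2], tn = s$table[2, 2],
                           accuracy = s$accuracy, precision = s$precision,
                           recall = s$recall, sensitivity = s$sensitivity,
                           specificity = s$specificity,
                           detection_rate = s$detection_rate,
                           balanced_accuracy = s$balanced_accuracy,
                           kappa = s$kappa),
                p("confusion_", nm, ".csv"), row.names = FALSE)
    }
  }

  writeLines(c(
    paste("noisir version:", as.character(packageVersion("noisir"))),
    paste("R version:", R.version.string),
    paste("generated:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste("seed:", bundle$config$seed),
    paste("offset_c:", bundle$config$offset_c),
    paste("min_valid_fraction:", bundle$config$min_valid_fraction),
    paste("k:", bundle$config$k),
    paste("methods:", paste(bundle$config$methods, collapse = ",")),
    paste("neighborhood:", bundle$config$neighborhood),
    paste("split_ratio:", bundle$config$split_ratio),
    paste("selected_method:", bundle$cluster$selection$selected),
    paste("hours_for_x:",
          if (isTRUE(bundle$classify$degenerate)) "NA"
          else paste(bundle$classify$hours_for_x, collapse = ","))
  ), p("manifest.txt"))
  invisible(dir)
}
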