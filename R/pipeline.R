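# End-to-end pipeline: simulate -> preprocess -> connectivity -> graphs ->
# statistics -> classification, with YAML config and a run directory.

default_config <- function() {
  list(
    seed = 1L,
    states = c("rest", "drawing", "manipulation"),
    simulate = list(n_novice = 5L, n_expert = 3L, fs = 128, noise_sd = 1,
                    rest = NULL, drawing = NULL, manipulation = NULL),
    preprocess = list(low_pass = 45, high_pass = 0.1, notches = c(50, 60),
                      order = 300, notch_halfwidth = 2, amplitude_limit = 100,
                      epoch_len = 2, epoch_gap = 0.5),
    connectivity = list(B = 8L, n_shuffles = 20L),
    graph = list(threshold = 0.001, n_random = 100L),
    classify = list(classifier = "knn", k = 3L, folds = 5L, max_features = 15L,
                    win = 20, step = 1)
  )
}

check_scalar <- function(val, proto, path) {
  if (is.null(val) || is.null(proto)) return(val)
  if (is.numeric(proto) && !is.numeric(val)) {
    stop(sprintf("config error at '%s': expected a number", path), call. = FALSE)
  }
  if (is.character(proto) && !is.character(val)) {
    stop(sprintf("config error at '%s': expected a string", path), call. = FALSE)
  }
  val
}

#' Validate a pipeline configuration
#'
#' Reads a YAML config (or takes a list), rejects unknown keys naming the
#' offending path, type-checks values against the defaults, and injects
#' defaults for everything omitted. An empty file yields the full default
#' configuration.
#'
#' @param config path to a YAML file, a list, or `NULL` for defaults.
#' @return a validated `run_config` list (blocks: `simulate`, `preprocess`,
#'   `connectivity`, `graph`, `classify`, plus `seed` and `states`).
#' @export
validate_config <- function(config = NULL) {
  defaults <- default_config()
  user <- if (is.null(config)) list()
  else if (is.character(config)) yaml::read_yaml(config) %||% list()
  else config
  if (!is.list(user)) stop("config error: top level must be a mapping", call. = FALSE)
  merged <- defaults
  for (key in names(user)) {
    if (!key %in% names(defaults)) {
      stop(sprintf("config error: unknown key '%s'", key), call. = FALSE)
    }
    if (is.list(defaults[[key]])) {
      if (!is.list(user[[key]])) {
        stop(sprintf("config error at '%s': expected a mapping", key), call. = FALSE)
      }
      for (sub in names(user[[key]])) {
        if (!sub %in% names(defaults[[key]])) {
          stop(sprintf("config error: unknown key '%s.%s'", key, sub), call. = FALSE)
        }
        merged[[key]][[sub]] <- check_scalar(user[[key]][[sub]],
                                             defaults[[key]][[sub]],
                                             paste(key, sub, sep = "."))
      }
    } else {
      merged[[key]] <- check_scalar(user[[key]], defaults[[key]], key)
    }
  }
  bad <- setdiff(merged$states, NTEFBN_STATES)
  if (length(bad) > 0) {
    stop(sprintf("config error at 'states': unknown state(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  class(merged) <- "run_config"
  merged
}

config_hash <- function(config) {
  s <- yaml::as.yaml(unclass(config))
  h <- 216613626
  for (b in utf8ToInt(s)) h <- (h * 16777 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline
#'
#' Executes all stages on a synthetic cohort: simulation, preprocessing,
#' NTE connectivity, binary/weighted graph metrics, hemisphere/region
#' statistics, and (when both task states are enabled) classification with
#' sequential forward selection. Outputs land in a run directory
#' (`raw/`, `preprocessed/`, `nte/`, `graphs/`, `stats/`, `classify/`,
#' `logs/`); the validated config is archived next to them and every table
#' carries the config hash. Reruns with the same config and seed reproduce
#' identical numbers.
#'
#' @param config path to YAML, list, or `NULL` (defaults); see
#'   [validate_config()].
#' @param out_dir run directory; default a timestamped directory under
#'   `tempdir()`.
#' @param write_raw write the simulated recordings as CSV. Default TRUE.
#' @param with_classification run the classification stage (requires both
#'   task states). Default TRUE.
#' @return invisibly, a `run_report` list with the per-subject NTE matrices,
#'   metric/statistics tables, classification report and paths.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL, write_raw = TRUE,
                         with_classification = TRUE) {
  cfg <- validate_config(config)
  hash <- config_hash(cfg)
  out_dir <- out_dir %||% file.path(tempdir(),
                                    format(Sys.time(), "ntefbn-run-%Y%m%d-%H%M%S"))
  for (d in c("raw", "preprocessed", "nte", "graphs", "stats", "classify", "logs")) {
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  log_path <- file.path(out_dir, "logs", "run.log")
  logf <- function(fmt, ...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...)),
        file = log_path, append = TRUE)
  }
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  logf("config hash %s", hash)
  stage <- function(name, expr) {
    logf("stage %s: start", name)
    tryCatch(expr, error = function(e) {
      logf("stage %s: FAILED: %s", name, conditionMessage(e))
      writeLines("incomplete", file.path(out_dir, "INCOMPLETE"))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  durations <- cfg$simulate[c("rest", "drawing", "manipulation")]
  cohort <- stage("simulate", {
    co <- make_cohort(cfg$simulate$n_novice, cfg$simulate$n_expert,
                      seed = cfg$seed, fs = cfg$simulate$fs,
                      noise_sd = cfg$simulate$noise_sd)
    if (any(!vapply(durations, is.null, logical(1)))) {
      # fixed durations override the drawn ones (useful for small test runs)
      co <- lapply(co, function(subj) {
        dur <- subj$profile$state_durations
        for (s in names(durations)) if (!is.null(durations[[s]])) dur[s] <- durations[[s]]
        prof <- subj$profile; prof$state_durations <- dur
        list(recording = simulate_subject(prof, subj$coupling, fs = cfg$simulate$fs),
             profile = prof, coupling = subj$coupling)
      })
    }
    if (write_raw) write_cohort(co, file.path(out_dir, "raw"), format = "csv")
    logf("simulated %d subject(s)", length(co))
    co
  })

  pp <- cfg$preprocess
  filtered <- stage("preprocess", {
    lapply(cohort, function(subj) {
      rec <- filter_recording(subj$recording, low_pass = pp$low_pass,
                              high_pass = pp$high_pass, notches = pp$notches,
                              order = pp$order,
                              notch_halfwidth = pp$notch_halfwidth)
      write_recording_csv(rec, file.path(out_dir, "preprocessed",
                                         paste0(subj$profile$subject_id, ".csv")))
      rec
    })
  })

  cc <- cfg$connectivity
  nte <- stage("connectivity", {
    res <- list()
    for (k in seq_along(cohort)) {
      sid <- cohort[[k]]$profile$subject_id
      res[[sid]] <- list()
      for (s in cfg$states) {
        es <- epoch_by_state(filtered[[k]], s, epoch_len = pp$epoch_len,
                             gap = pp$epoch_gap)
        es <- reject_bad_epochs(es, pp$amplitude_limit)
        if (length(es$epochs) == 0) {
          logf("subject %s state %s: all epochs rejected, skipped", sid, s)
          next
        }
        m <- nte_matrix(es, B = cc$B, n_shuffles = cc$n_shuffles,
                        seed = derive_seed(cfg$seed, paste0("nte-", sid, "-", s)),
                        state = s)
        write_nte_tsv(m, file.path(out_dir, "nte", sprintf("%s_%s.tsv", sid, s)))
        res[[sid]][[s]] <- m
      }
    }
    res
  })

  gcfg <- cfg$graph
  metrics <- stage("graphs", {
    rows <- list()
    for (sid in names(nte)) for (s in names(nte[[sid]])) {
      m <- nte[[sid]][[s]]
      g <- binarize(m, gcfg$threshold)
      write_graphml(g, file.path(out_dir, "graphs", sprintf("%s_%s.graphml", sid, s)))
      sw <- small_world_index(g, n_random = gcfg$n_random,
                              seed = derive_seed(cfg$seed, paste0("sw-", sid, "-", s)))
      mc <- motif_census(g)
      cc_i <- clustering_coefficients(g)
      st <- node_strengths(m)
      mif <- mean_information_flow(m)
      add <- function(metric, node, value) {
        rows[[length(rows) + 1L]] <<- data.frame(
          subject = sid, state = s, metric = metric, node = node, value = value,
          stringsAsFactors = FALSE)
      }
      add("connectivity_density", NA, connectivity_density(g))
      add("motif_total", NA, mc$total)
      for (mm in names(mc$counts)) add(mm, NA, mc$counts[[mm]])
      for (ch in names(cc_i)) add("clustering", ch, cc_i[[ch]])
      add("characteristic_path_length", NA, sw$L_d)
      add("C_d", NA, sw$C_d); add("C_rand", NA, sw$C_rand)
      add("L_rand", NA, sw$L_rand); add("sigma", NA, sw$sigma)
      for (ch in names(st)) add("strength", ch, st[[ch]])
      for (ch in names(mif)) add("mean_information_flow", ch, mif[[ch]])
    }
    tab <- do.call(rbind, rows)
    tab$config_hash <- hash
    data.table::fwrite(tab, file.path(out_dir, "graphs", "metrics.csv"))
    tab
  })

  stats_tabs <- stage("stats", {
    flow_rows <- list(); test_rows <- list()
    for (sid in names(nte)) {
      states_here <- names(nte[[sid]])
      for (s in states_here) {
        rf <- region_flows(nte[[sid]][[s]])
        flow_rows[[length(flow_rows) + 1L]] <- data.frame(
          subject = sid, state = s, t(rf$flows), max = rf$max_pair,
          min = rf$min_pair, check.names = FALSE, stringsAsFactors = FALSE)
      }
      if (length(states_here) >= 2) {
        pairs <- utils::combn(states_here, 2, simplify = FALSE)
        for (pr in pairs) {
          # order task-over-baseline so positive differences mean an increase
          pr <- pr[order(match(pr, NTEFBN_STATES), decreasing = TRUE)]
          a <- clustering_coefficients(binarize(nte[[sid]][[pr[1]]], gcfg$threshold))
          b <- clustering_coefficients(binarize(nte[[sid]][[pr[2]]], gcfg$threshold))
          tt <- welch_ttest(a, b)
          test_rows[[length(test_rows) + 1L]] <- data.frame(
            subject = sid, comparison = paste(pr, collapse = " vs "),
            measure = "clustering",
            mean_difference = tt$mean_difference, ci_low = tt$ci_low,
            ci_high = tt$ci_high, df = tt$df, t = tt$t, p = tt$p,
            stars = if (isTRUE(tt$significant)) "*" else "",
            stringsAsFactors = FALSE)
          ha <- unlist(hemisphere_flows(nte[[sid]][[pr[1]]])$outflow)
          hb <- unlist(hemisphere_flows(nte[[sid]][[pr[2]]])$outflow)
          for (blk in names(hemisphere_flows(nte[[sid]][[pr[1]]])$outflow)) {
            bt <- welch_ttest(hemisphere_flows(nte[[sid]][[pr[1]]])$outflow[[blk]],
                              hemisphere_flows(nte[[sid]][[pr[2]]])$outflow[[blk]])
            test_rows[[length(test_rows) + 1L]] <- data.frame(
              subject = sid, comparison = paste(pr, collapse = " vs "),
              measure = paste0("hemisphere_", blk),
              mean_difference = bt$mean_difference, ci_low = bt$ci_low,
              ci_high = bt$ci_high, df = bt$df, t = bt$t, p = bt$p,
              stars = if (isTRUE(bt$significant)) "*" else "",
              stringsAsFactors = FALSE)
          }
        }
        groups <- lapply(states_here, function(s) {
          unname(mean_information_flow(nte[[sid]][[s]]))
        })
        names(groups) <- states_here
        an <- anova_multicompare(groups)
        test_rows[[length(test_rows) + 1L]] <- data.frame(
          subject = sid, comparison = "anova mean_information_flow",
          measure = "F", mean_difference = NA, ci_low = NA, ci_high = NA,
          df = NA, t = an$F, p = an$p,
          stars = if (an$p < 0.05) "*" else "", stringsAsFactors = FALSE)
      }
    }
    flows <- do.call(rbind, flow_rows)
    tests <- do.call(rbind, test_rows)
    flows$config_hash <- hash; tests$config_hash <- hash
    data.table::fwrite(flows, file.path(out_dir, "stats", "region_flows.csv"))
    data.table::fwrite(tests, file.path(out_dir, "stats", "state_tests.csv"))
    list(region_flows = flows, state_tests = tests)
  })

  cl <- cfg$classify
  report <- NULL
  task_states <- intersect(cfg$states, c("drawing", "manipulation"))
  if (with_classification && length(task_states) == 2) {
    report <- stage("classify", {
      ft <- cohort_features(cohort, seed = derive_seed(cfg$seed, "features"),
                            B = cc$B, n_shuffles = cc$n_shuffles,
                            threshold = gcfg$threshold, win = cl$win,
                            step = cl$step, states = task_states,
                            low_pass = pp$low_pass, high_pass = pp$high_pass,
                            notches = pp$notches, order = pp$order,
                            notch_halfwidth = pp$notch_halfwidth)
      write_feature_csv(ft, file.path(out_dir, "classify", "features.csv"))
      sfs <- sequential_forward_search(ft$X, ft$y, classifier = cl$classifier,
                                       cv_folds = cl$folds,
                                       max_features = cl$max_features,
                                       seed = derive_seed(cfg$seed, "sfs"),
                                       knn_k = cl$k)
      ev <- evaluate(ft$X, ft$y, classifier = cl$classifier,
                     feature_subset = sfs$selected, cv_folds = cl$folds,
                     seed = derive_seed(cfg$seed, "cv"), knn_k = cl$k)
      out <- list(classifier = cl$classifier,
                  selected_features = sfs$selected,
                  selected_names = feature_names()[sfs$selected],
                  accuracy_trace = sfs$accuracy_trace, elapsed = sfs$elapsed,
                  accuracy = ev$accuracy, sensitivity = ev$sensitivity,
                  specificity = ev$specificity, precision = ev$precision,
                  f_measure = ev$f_measure, mse = ev$mse,
                  per_fold = ev$per_fold, config_hash = hash)
      jsonlite::write_json(out, file.path(out_dir, "classify", "report.json"),
                           auto_unbox = TRUE, digits = NA)
      logf("classification accuracy %.3f with %d feature(s)",
           ev$accuracy, length(sfs$selected))
      out
    })
  } else {
    logf("classification skipped: task states not both enabled")
  }

  logf("run complete")
  invisible(structure(list(out_dir = out_dir, config = cfg,
                           config_hash = hash, nte = nte, metrics = metrics,
                           stats = stats_tabs, classification = report),
                      class = "run_report"))
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s (config %s)\n", x$out_dir, x$config_hash))
  cat(sprintf("  %d subject(s), %d NTE matrice(s)\n", length(x$nte),
              sum(lengths(x$nte))))
  if (!is.null(x$classification)) {
    cat(sprintf("  classification: %s, accuracy %.3f\n",
                x$classification$classifier, x$classification$accuracy))
  }
  invisible(x)
}
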