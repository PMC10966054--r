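#' Slice the centred window of each state block and re-concatenate
#'
#' For every contiguous label block of length L, keep the `window` frames
#' starting at `floor((L - window) / 2)` (0-based), then concatenate the
#' blocks in their original order with labels preserved. With six 100-frame
#' blocks and the default window of 100 this is the identity; with 210-frame
#' blocks it keeps the middle 100 frames of each.
#'
#' @param series a `labeled_ts`.
#' @param window frames to keep per block (default 100).
#' @return a `labeled_ts` with `6 * window` frames (for six blocks).
#' @export
slice_and_concatenate <- function(series, window = 100L) {
  stopifnot(inherits(series, "labeled_ts"))
  r <- rle(series$labels)
  if (any(duplicated(r$values)))
    .stop2("statemapper_validation_error",
           "state blocks must be contiguous (label '%s' appears twice)",
           r$values[duplicated(r$values)][1L])
  if (any(r$lengths < window))
    .stop2("statemapper_validation_error",
           "state block '%s' has %d frames, shorter than window %d",
           r$values[which.min(r$lengths)], min(r$lengths), window)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- unlist(lapply(seq_along(r$lengths), function(bl) {
    off <- floor((r$lengths[bl] - window) / 2)
    starts[bl] + off + seq_len(window) - 1L
  }))
  out <- series
  out$values <- series$values[keep, , drop = FALSE]
  out$labels <- series$labels[keep]
  out
}

#' Assemble a run configuration
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param params a [cohort_params()] (synthetic mode).
#' @param input_dir directory with per-subject matrices (files mode).
#' @param filter_method,filter_seed filter settings.
#' @param bins,overlap cover settings.
#' @param k,min_neighbors clustering settings.
#' @param window slice window per state block.
#' @param out_dir optional output directory; when set, all result files and
#'   the manifest are written there.
#' @param run_stats run the statistical battery after the per-subject
#'   pipeline (disable for measure-only runs, e.g. power simulations).
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"), params = cohort_params(),
                       input_dir = NULL, filter_method = "linear-projection",
                       filter_seed = 1L, bins = 30L, overlap = 0.5, k = 3L,
                       min_neighbors = 2L, window = 100L, out_dir = NULL,
                       log_level = "info", run_stats = TRUE) {
  mode <- match.arg(mode)
  if (mode == "files" && (is.null(input_dir) || !dir.exists(input_dir)))
    .stop2("statemapper_input_error", "input directory does not exist")
  structure(list(mode = mode, params = params, input_dir = input_dir,
                 filter_method = filter_method,
                 filter_seed = as.integer(filter_seed),
                 bins = as.integer(bins), overlap = overlap,
                 k = as.integer(k), min_neighbors = as.integer(min_neighbors),
                 window = as.integer(window), out_dir = out_dir,
                 log_level = log_level, run_stats = isTRUE(run_stats)),
            class = "run_config")
}

#' Read a flat key: value run-configuration file
#'
#' Minimal YAML-dialect reader: one `key: value` pair per line, `#` comments,
#' numeric values auto-converted. Keys mirror the [run_config()] and
#' [cohort_params()] arguments.
#' @param path configuration file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    .stop2("statemapper_input_error", "config file '%s' not found", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L)
      .stop2("statemapper_input_error", "cannot parse config line: '%s'", ln)
    val <- m[3L]
    num <- suppressWarnings(as.numeric(val))
    kv[[m[2L]]] <- if (!is.na(num)) num else val
  }
  par_names <- names(formals(cohort_params))
  cfg_names <- setdiff(names(formals(run_config)), "params")
  params <- do.call(cohort_params, kv[intersect(names(kv), par_names)])
  do.call(run_config, c(list(params = params),
                        kv[intersect(names(kv), cfg_names)]))
}

.log <- function(config, level, fmt, ...) {
  lv <- c(quiet = 0L, info = 1L, debug = 2L)
  if (lv[[config$log_level]] >= lv[[level]])
    message(sprintf("[statemapper] %s", sprintf(fmt, ...)))
}

#' Run the Mapper pipeline for one subject
#'
#' Slice, filter, cover, cluster, build the shape graph and compute all
#' topological descriptors. Deterministic given the configuration seeds.
#'
#' @param series a `labeled_ts`.
#' @param config a [run_config()].
#' @return list with `graph` (a `shape_graph`) and `row` (MeasureTable row).
#' @export
run_subject <- function(series, config) {
  stopifnot(inherits(series, "labeled_ts"), inherits(config, "run_config"))
  missing_states <- setdiff(MS_LEVELS, unique(series$labels))
  if (length(missing_states) > 0L)
    .stop2("statemapper_validation_error",
           "subject %s is missing state block(s): %s", series$subject_id,
           paste(missing_states, collapse = ", "))
  sliced <- slice_and_concatenate(series, window = config$window)
  graph <- mapper_graph(sliced$values, labels = sliced$labels,
                        filter_method = config$filter_method,
                        seed = config$filter_seed, bins = config$bins,
                        overlap = config$overlap, k = config$k,
                        min_neighbors = config$min_neighbors,
                        levels = MS_LEVELS)
  row <- compute_all_measures(graph, subject_id = series$subject_id,
                              group = series$group)
  list(graph = graph, row = row)
}

# ---- delimited text IO ------------------------------------------------------

#' Write one subject to delimited text files
#'
#' `<id>_values.tsv` (numeric matrix, no header), `<id>_labels.csv`
#' (frame_index, label) and, through [write_psychometrics()], a cohort-level
#' psychometrics CSV.
#' @param series a `labeled_ts`.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_subject <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vf <- file.path(dir, paste0(series$subject_id, "_values.tsv"))
  lf <- file.path(dir, paste0(series$subject_id, "_labels.csv"))
  utils::write.table(series$values, vf, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  write.csv(data.frame(frame_index = seq_along(series$labels),
                       label = series$labels),
            lf, row.names = FALSE, quote = FALSE)
  invisible(c(values = vf, labels = lf))
}

#' Read one subject from delimited text files written by [write_subject()]
#' @param dir directory.
#' @param subject_id subject identifier.
#' @param group group label.
#' @return a `labeled_ts`.
#' @export
read_subject <- function(dir, subject_id, group = NA_character_) {
  vf <- file.path(dir, paste0(subject_id, "_values.tsv"))
  lf <- file.path(dir, paste0(subject_id, "_labels.csv"))
  if (!file.exists(vf) || !file.exists(lf))
    .stop2("statemapper_input_error", "missing files for subject %s", subject_id)
  values <- as.matrix(utils::read.table(vf, sep = "\t"))
  dimnames(values) <- NULL
  labels <- read.csv(lf, stringsAsFactors = FALSE)$label
  structure(list(values = values, labels = labels, subject_id = subject_id,
                 group = group, latent = NA_real_, retreat_gain = NA_real_),
            class = "labeled_ts")
}

#' Write the psychometrics table as CSV
#' @param psychometrics data.frame from [generate_cohort()].
#' @param path output file.
#' @export
write_psychometrics <- function(psychometrics, path) {
  write.csv(psychometrics, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a shape graph to GraphML and JSON
#'
#' GraphML carries node attributes (size and per-label counts); the JSON dump
#' maps each node to its member frame indices.
#' @param graph a `shape_graph`.
#' @param graphml_path,json_path output paths (either may be `NULL`).
#' @export
export_graph <- function(graph, graphml_path = NULL, json_path = NULL) {
  if (!is.null(graphml_path))
    igraph::write_graph(as_igraph(graph), graphml_path, format = "graphml")
  if (!is.null(json_path)) {
    obj <- list(n_frames = graph$n_frames,
                nodes = lapply(seq_along(graph$members), function(v)
                  list(id = v, size = graph$node_size[v],
                       members = graph$members[[v]],
                       label_counts = as.list(graph$label_counts[v, ]))),
                edges = apply(graph$edges, 1L, function(e) list(e[1L], e[2L])))
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(NULL)
}

# ---- cohort orchestration ---------------------------------------------------

.measure_columns <- function() {
  c(paste0("dc_", MS_LEVELS), paste0("cc_", MS_LEVELS),
    paste0("diam_", MS_LEVELS),
    "d_FA1_OM1", "d_FA1_RS1", "d_OM1_RS1",
    "d_FA2_OM2", "d_FA2_RS2", "d_OM2_RS2",
    "d_FA1_FA2", "d_OM1_OM2", "d_RS1_RS2")
}

# long-format helper: one row per subject x session for a condition measure
.to_long <- function(measures, pre_col, post_col) {
  data.frame(subject = rep(measures$subject_id, 2L),
             group = rep(measures$group, 2L),
             session = rep(c("s1", "s2"), each = nrow(measures)),
             value = c(measures[[pre_col]], measures[[post_col]]),
             stringsAsFactors = FALSE)
}

.stats_battery <- function(measures, psychometrics, config) {
  rows <- list()
  add <- function(name, tr, p_corrected = NA_real_, correction = "none") {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, effect = tr$effect, statistic = tr$statistic,
      df1 = tr$df[1L], df2 = if (length(tr$df) > 1L) tr$df[2L] else NA_real_,
      p_raw = tr$p,
      p_corrected = if (is.na(p_corrected)) tr$p else p_corrected,
      correction = correction, stringsAsFactors = FALSE)
  }
  flag <- function(name, why) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, effect = why, statistic = NA_real_, df1 = NA_real_,
      df2 = NA_real_, p_raw = NA_real_, p_corrected = NA_real_,
      correction = "none", stringsAsFactors = FALSE)
  }
  try_test <- function(name, expr) {
    tryCatch(expr, statemapper_error = function(e) {
      flag(name, conditionMessage(e)); NULL
    }, error = function(e) { flag(name, conditionMessage(e)); NULL })
  }

  # mixed ANOVAs on cc/dc/diam per condition, x3 family correction
  for (cond in c("FA", "OM", "RS")) {
    for (meas in c("dc", "cc", "diam")) {
      nm <- sprintf("anova_%s_%s", meas, cond)
      long <- .to_long(measures, sprintf("%s_%s1", meas, cond),
                       sprintf("%s_%s2", meas, cond))
      res <- try_test(nm, mixed_anova(long, "value"))
      if (!is.null(res))
        for (eff in names(res))
          add(paste0(nm, "_", eff), res[[eff]],
              p_corrected = min(1, res[[eff]]$p * 3), correction = "x3")
    }
  }
  # mixed ANOVAs on within-session condition-pair OT distances
  dist_pairs <- list(c("FA", "OM"), c("FA", "RS"), c("OM", "RS"))
  for (pr in dist_pairs) {
    nm <- sprintf("anova_d_%s_%s", pr[1L], pr[2L])
    long <- .to_long(measures, sprintf("d_%s1_%s1", pr[1L], pr[2L]),
                     sprintf("d_%s2_%s2", pr[1L], pr[2L]))
    res <- try_test(nm, mixed_anova(long, "value"))
    if (!is.null(res)) for (eff in names(res)) add(paste0(nm, "_", eff), res[[eff]])
  }
  # post hoc: paired t (retreat) and post-session Welch t (group) per pair,
  # BY-corrected as one family
  posthoc <- list()
  for (pr in dist_pairs) {
    pre <- sprintf("d_%s1_%s1", pr[1L], pr[2L])
    post <- sprintf("d_%s2_%s2", pr[1L], pr[2L])
    nm1 <- sprintf("paired_t_d_%s_%s_retreat", pr[1L], pr[2L])
    r1 <- try_test(nm1, paired_t(measures[[pre]], measures[[post]]))
    if (!is.null(r1)) posthoc[[nm1]] <- r1
    nm2 <- sprintf("welch_t_%s_group", post)
    act <- measures$group == "active"
    r2 <- try_test(nm2, welch_t(measures[[post]][!act], measures[[post]][act]))
    if (!is.null(r2)) posthoc[[nm2]] <- r2
  }
  # cross-session distances: group Welch t only (retreat effect is intrinsic)
  for (cond in c("FA", "OM", "RS")) {
    col <- sprintf("d_%s1_%s2", cond, cond)
    nm <- sprintf("welch_t_%s_group", col)
    act <- measures$group == "active"
    r <- try_test(nm, welch_t(measures[[col]][!act], measures[[col]][act]))
    if (!is.null(r)) posthoc[[nm]] <- r
  }
  if (length(posthoc) > 0L) {
    padj <- by_fdr(vapply(posthoc, `[[`, numeric(1), "p"))
    for (k in seq_along(posthoc))
      add(names(posthoc)[k], posthoc[[k]], p_corrected = padj[k],
          correction = "BY")
  }

  merged <- merge(measures, psychometrics[, c("subject_id",
                                              "positive_derealization",
                                              "insightfulness")],
                  by = "subject_id", sort = TRUE)
  merged <- merged[order(merged$subject_id), , drop = FALSE]

  meas_cols <- intersect(.measure_columns(), colnames(merged))
  complete_cols <- meas_cols[colSums(is.na(merged[meas_cols])) == 0]
  scl <- c("positive_derealization", "insightfulness")
  kendall <- tryCatch(
    correlation_matrix(merged, complete_cols, scl, method = "kendall"),
    error = function(e) NULL)
  pearson <- tryCatch(
    correlation_matrix(merged, complete_cols, method = "pearson"),
    error = function(e) NULL)

  mixed <- tryCatch({
    long <- .to_long(merged, "d_OM1_RS1", "d_OM2_RS2")
    long$positive_derealization <-
      rep(merged$positive_derealization, 2L)
    fit_mixed_lm(long, "value", ~ positive_derealization * session,
                 subject = "subject")
  }, error = function(e) NULL)
  if (!is.null(mixed)) {
    ct <- mixed$coefficients
    for (k in seq_len(nrow(ct)))
      add(paste0("mixedlm_d_OMx_RSx_", gsub("[^A-Za-z0-9_]", "", ct$term[k])),
          .test_result(ct$t[k], NA_real_, ct$p[k], effect = ct$term[k]))
  }

  msplit <- tryCatch(
    median_split_test(merged, "positive_derealization",
                      "d_OM1_RS1", "d_OM2_RS2"),
    error = function(e) NULL)
  if (!is.null(msplit)) {
    for (side in c("low", "high")) {
      if (inherits(msplit[[side]], "test_result"))
        add(paste0("median_split_", side, "_paired_t"), msplit[[side]])
      else flag(paste0("median_split_", side, "_paired_t"), msplit[[side]])
    }
  }

  insight <- tryCatch(insightfulness_model(merged), error = function(e) NULL)
  if (!is.null(insight)) {
    add("insight_full_model_F",
        .test_result(insight$full$f, insight$full$df, insight$full$p,
                     effect = "overall"))
    rows[[length(rows) + 1L]] <- data.frame(
      name = "insight_full_adj_r2", effect = "adj_r2",
      statistic = insight$full$adj_r2, df1 = NA_real_, df2 = NA_real_,
      p_raw = NA_real_, p_corrected = NA_real_, correction = "none",
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      name = "insight_reduced_adj_r2", effect = "adj_r2",
      statistic = insight$reduced$adj_r2, df1 = NA_real_, df2 = NA_real_,
      p_raw = NA_real_, p_corrected = NA_real_, correction = "none",
      stringsAsFactors = FALSE)
  }

  list(tests = do.call(rbind, rows), kendall = kendall, pearson = pearson,
       mixed_model = mixed, median_split = msplit, insight = insight,
       merged = merged)
}

#' Run the full cohort analysis
#'
#' Generates (or loads) the cohort, runs the per-subject Mapper pipeline,
#' assembles the MeasureTable, executes the statistical battery and, when
#' `config$out_dir` is set, writes `measures.csv`, `stats.csv`,
#' `correlations_r.csv`, `correlations_p.csv`, `manifest.json` and per-subject
#' GraphML/JSON graphs. Per-subject failures are logged and excluded with an
#' explicit exclusion list.
#'
#' @param config a [run_config()].
#' @return list with `measures`, `stats` (battery output), `graphs`,
#'   `psychometrics`, `excluded`, `manifest`.
#' @export
run_cohort <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode == "synthetic") {
    coh <- generate_cohort(config$params)
    subjects <- coh$subjects
    psychometrics <- coh$psychometrics
  } else {
    vfiles <- list.files(config$input_dir, pattern = "_values\\.tsv$")
    if (length(vfiles) == 0L)
      .stop2("statemapper_input_error",
             "no subject files in '%s'", config$input_dir)
    psy_path <- file.path(config$input_dir, "psychometrics.csv")
    psychometrics <- if (file.exists(psy_path))
      read.csv(psy_path, stringsAsFactors = FALSE) else NULL
    ids <- sub("_values\\.tsv$", "", vfiles)
    subjects <- lapply(ids, function(id) {
      grp <- if (!is.null(psychometrics) && id %in% psychometrics$subject_id)
        psychometrics$group[match(id, psychometrics$subject_id)]
      else NA_character_
      read_subject(config$input_dir, id, group = grp)
    })
  }

  graphs <- list()
  rows <- list()
  excluded <- character(0)
  for (s in subjects) {
    res <- tryCatch(run_subject(s, config), error = function(e) {
      .log(config, "info", "excluding subject %s: %s", s$subject_id,
           conditionMessage(e))
      NULL
    })
    if (is.null(res)) { excluded <- c(excluded, s$subject_id); next }
    graphs[[s$subject_id]] <- res$graph
    rows[[s$subject_id]] <- res$row
  }
  if (length(rows) == 0L)
    .stop2("statemapper_input_error", "all subjects failed")
  measures <- do.call(rbind, rows)
  rownames(measures) <- NULL

  stats <- if (config$run_stats && !is.null(psychometrics))
    .stats_battery(measures, psychometrics, config) else NULL

  manifest <- list(
    package_version = as.character(packageVersion("statemapper")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config[setdiff(names(config), "params")],
    cohort_params = if (config$mode == "synthetic")
      unclass(config$params) else NULL,
    n_subjects_in = length(subjects),
    excluded = as.list(excluded),
    subjects = lapply(names(graphs), function(id) {
      g <- graphs[[id]]
      r <- measures[measures$subject_id == id, ]
      list(subject_id = id, n_nodes = length(g$members),
           n_edges = nrow(g$edges), n_components = r$n_components,
           discarded_mass = r$discarded_mass)
    }))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(measures, file.path(config$out_dir, "measures.csv"),
              row.names = FALSE)
    if (!is.null(stats)) {
      write.csv(stats$tests, file.path(config$out_dir, "stats.csv"),
                row.names = FALSE)
      if (!is.null(stats$kendall)) {
        write.csv(as.data.frame(stats$kendall$r),
                  file.path(config$out_dir, "correlations_r.csv"))
        write.csv(as.data.frame(stats$kendall$p_corrected),
                  file.path(config$out_dir, "correlations_p.csv"))
      }
    }
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    for (id in names(graphs))
      export_graph(graphs[[id]],
                   graphml_path = file.path(config$out_dir,
                                            paste0(id, ".graphml")),
                   json_path = file.path(config$out_dir, paste0(id, ".json")))
  }
  list(measures = measures, stats = stats, graphs = graphs,
       psychometrics = psychometrics, excluded = excluded,
       manifest = manifest)
}
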