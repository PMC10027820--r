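# End-to-end pipeline runners behind the command-line interface: simulate,
# build networks, compute metrics and statistics, render averaged masked
# networks. Each run writes a manifest (config snapshot + seed) into the
# output directory so deterministic stages reproduce bit-for-bit.

default_config <- function() {
  list(
    paths = list(fixations = NULL, stimulus = NULL, behavioral = NULL,
                 out_dir = "scanpathnet_out"),
    clean = list(min_ms = 40, max_ms = 1000),
    network = list(link_sentences = TRUE),
    mask = list(degree_gt = 5, weight_gt = 0.3),
    metrics = list(n_refs = 20L, seed = 1L, l_mode = "mean_distance",
                   binarize = FALSE),
    simulate = list(n_readers = 52L, n_texts = 1L, n_sentences = 30L,
                    mean_words = 10L, n_topic_words = 2L, seed = 1L),
    render = list(k = 10L, seed = 1L)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a pipeline run configuration
#'
#' Reads a YAML configuration file and fills unspecified keys with package
#' defaults (cleaning window 40-1000 ms, mask degree > 5 / weight > 0.3,
#' 20 random references, mean-distance path-length mode).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Nested configuration list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

write_manifest <- function(cfg, out_dir, stage) {
  manifest <- list(stage = stage, config = cfg,
                   r_version = as.character(getRversion()),
                   package_version = as.character(utils::packageVersion("scanpathnet")))
  jsonlite::write_json(manifest, file.path(out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}

ensure_out_dir <- function(cfg) {
  out <- cfg$paths$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  out
}

#' Simulate a cohort and write its input files
#'
#' Generates synthetic text(s) and a reader cohort, then writes the fixation
#' report, behavioral CSV and stimulus JSON files the downstream stages
#' consume.
#'
#' @param cfg Configuration list from [load_run_config()].
#' @return Invisibly, the generated cohort.
#' @export
run_simulate <- function(cfg = load_run_config()) {
  out <- ensure_out_dir(cfg)
  sim <- cfg$simulate
  texts <- lapply(seq_len(sim$n_texts), function(i) {
    generate_text(n_sentences = sim$n_sentences, mean_words = sim$mean_words,
                  n_topic_words = sim$n_topic_words,
                  text_id = sprintf("text%02d", i), seed = sim$seed + i)
  })
  cohort <- generate_cohort(texts, n_readers = sim$n_readers,
                            seed = sim$seed)
  for (tx in texts) {
    write_text_stimulus(tx, file.path(out, paste0("stimulus_", tx$text_id, ".json")))
  }
  write_fixation_report(cohort$scanpaths, file.path(out, "fixations.csv"))
  write_behavioral_csv(cohort$outcomes, file.path(out, "behavioral.csv"))
  write_manifest(cfg, out, "simulate")
  message(sprintf("simulated %d readers x %d text(s) into %s",
                  sim$n_readers, sim$n_texts, out))
  invisible(cohort)
}

load_stimuli <- function(cfg, out) {
  paths <- cfg$paths$stimulus
  if (is.null(paths)) {
    paths <- list.files(out, pattern = "^stimulus_.*\\.json$", full.names = TRUE)
  }
  if (length(paths) == 0L) stop("no stimulus files found")
  stimuli <- lapply(paths, read_text_stimulus)
  names(stimuli) <- vapply(stimuli, function(s) s$text_id, character(1))
  stimuli
}

build_all_networks <- function(cfg) {
  out <- ensure_out_dir(cfg)
  fix_path <- cfg$paths$fixations %||% file.path(out, "fixations.csv")
  if (!file.exists(fix_path)) stop("fixation report not found: ", fix_path)
  records <- parse_fixation_report(fix_path)
  if (nrow(records) == 0L) stop("fixation report holds no usable records: ", fix_path)
  cleaned <- clean_fixations(records, cfg$clean$min_ms, cfg$clean$max_ms)$kept
  stimuli <- load_stimuli(cfg, out)
  groups <- split(cleaned, list(cleaned$participant_id, cleaned$text_id),
                  drop = TRUE)
  nets <- list()
  for (g in groups) {
    tid <- g$text_id[1]
    if (!tid %in% names(stimuli)) stop("no stimulus for text '", tid, "'")
    sp <- extract_scanpath(g, stimuli[[tid]])
    nets[[paste(sp$participant_id, tid, sep = "::")]] <-
      build_network(sp, link_sentences = cfg$network$link_sentences)
  }
  nets
}

#' Build and export per-reader networks
#'
#' Reads the fixation report and stimuli, cleans fixations, extracts one
#' scanpath per participant-text pair, builds the directed weighted networks,
#' and writes one GraphML, one GEXF and one adjacency CSV per network.
#'
#' @param cfg Configuration list from [load_run_config()].
#' @return Invisibly, the named list of networks.
#' @export
run_build <- function(cfg = load_run_config()) {
  out <- ensure_out_dir(cfg)
  nets <- build_all_networks(cfg)
  net_dir <- file.path(out, "networks")
  if (!dir.exists(net_dir)) dir.create(net_dir)
  for (nm in names(nets)) {
    safe <- gsub("[^A-Za-z0-9_.-]", "_", nm)
    write_graphml(nets[[nm]], file.path(net_dir, paste0(safe, ".graphml")))
    write_gexf(nets[[nm]], file.path(net_dir, paste0(safe, ".gexf")))
    write_adjacency_csv(nets[[nm]], file.path(net_dir, paste0(safe, "_adjacency.csv")))
  }
  write_manifest(cfg, out, "build")
  message(sprintf("built %d network(s) into %s", length(nets), net_dir))
  invisible(nets)
}

#' Compute metrics and reader statistics
#'
#' Computes the five-metric set for every participant-text network, averages
#' metrics across texts per participant, and — when a behavioral file is
#' available — attaches comprehension ability scores, the correlation table,
#' and the skilled vs. less-skilled group comparison.
#'
#' @param cfg Configuration list from [load_run_config()].
#' @return Invisibly, a list with `per_network`, `per_reader`, and (when
#'   behavioral data are present) `correlations` and `group_comparison`.
#' @export
run_metrics <- function(cfg = load_run_config()) {
  out <- ensure_out_dir(cfg)
  nets <- build_all_networks(cfg)
  mcfg <- cfg$metrics
  per_net <- do.call(rbind, lapply(names(nets), function(nm) {
    parts <- strsplit(nm, "::", fixed = TRUE)[[1]]
    ms <- metric_set(nets[[nm]], n_refs = mcfg$n_refs, seed = mcfg$seed,
                     l_mode = mcfg$l_mode, binarize = mcfg$binarize)
    cbind(data.frame(participant_id = parts[1], text_id = parts[2],
                     stringsAsFactors = FALSE), as.data.frame(ms))
  }))
  utils::write.csv(per_net, file.path(out, "metrics_per_network.csv"),
                   row.names = FALSE)
  metric_cols <- c("density", "centralization", "transitivity", "efficiency",
                   "small_worldness")
  per_reader <- stats::aggregate(per_net[metric_cols],
                                 by = list(participant_id = per_net$participant_id),
                                 FUN = mean)
  utils::write.csv(per_reader, file.path(out, "metrics_per_reader.csv"),
                   row.names = FALSE)
  result <- list(per_network = per_net, per_reader = per_reader)

  beh_path <- cfg$paths$behavioral %||% file.path(out, "behavioral.csv")
  if (!file.exists(beh_path) || nrow(per_reader) < 3L) {
    warning("behavioral data missing or cohort too small; statistics skipped")
  } else {
    beh <- utils::read.csv(beh_path, stringsAsFactors = FALSE,
                           colClasses = c(participant_id = "character"))
    beh <- comprehension_score(beh)
    merged <- merge(per_reader, beh, by = "participant_id")
    tab <- metric_score_table(merged)
    write_cor_table(tab, file.path(out, "correlations.csv"))
    groups <- split_groups(merged)
    comps <- lapply(metric_cols, function(mc) {
      gc <- t_test_groups(groups$skilled[[mc]], groups$less_skilled[[mc]],
                          metric = mc)
      unclass(gc)
    })
    names(comps) <- metric_cols
    jsonlite::write_json(comps, file.path(out, "group_comparison.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    result$correlations <- tab
    result$group_comparison <- comps
    result$merged <- merged
  }
  write_manifest(cfg, out, "metrics")
  invisible(result)
}

#' Render averaged masked group networks
#'
#' Averages the networks of the selected reader group (all, top-k or bottom-k
#' by comprehension ability), applies the visualization mask, and writes a
#' PNG rendering (node size proportional to degree, edge width to weight)
#' plus the masked network as GraphML.
#'
#' @param cfg Configuration list from [load_run_config()].
#' @param group `"all"`, `"top_k"` or `"bottom_k"`.
#' @return Invisibly, the masked averaged network.
#' @export
run_render <- function(cfg = load_run_config(), group = c("all", "top_k", "bottom_k")) {
  group <- match.arg(group)
  out <- ensure_out_dir(cfg)
  nets <- build_all_networks(cfg)
  k <- cfg$render$k
  if (group != "all") {
    beh_path <- cfg$paths$behavioral %||% file.path(out, "behavioral.csv")
    if (!file.exists(beh_path)) stop("behavioral file required for top/bottom selection")
    beh <- comprehension_score(utils::read.csv(beh_path, stringsAsFactors = FALSE,
                                               colClasses = c(participant_id = "character")))
    if (k > nrow(beh)) stop("k exceeds cohort size")
    ord <- order(-beh$comprehension_ability)
    sel_ids <- if (group == "top_k") beh$participant_id[ord[seq_len(k)]] else
      beh$participant_id[rev(ord)[seq_len(k)]]
    keep <- vapply(strsplit(names(nets), "::", fixed = TRUE),
                   function(p) p[1] %in% sel_ids, logical(1))
    nets <- nets[keep]
    if (length(nets) == 0L) stop("no networks match the selected readers")
  }
  avg <- average_networks(unname(nets))
  masked <- apply_mask(avg, degree_gt = cfg$mask$degree_gt,
                       weight_gt = cfg$mask$weight_gt)
  stem <- file.path(out, paste0("network_", group))
  write_graphml_safe <- function(net, p) {
    if (length(net$nodes) > 0L) write_graphml(net, p)
  }
  write_graphml_safe(masked, paste0(stem, ".graphml"))
  if (length(masked$nodes) > 0L) {
    grDevices::png(paste0(stem, ".png"), width = 1200, height = 1200, res = 150)
    plot(masked, seed = cfg$render$seed,
         main = paste("Averaged masked scanpath network:", group))
    grDevices::dev.off()
  } else {
    message("masked network is empty; rendering skipped")
  }
  write_manifest(cfg, out, paste0("render_", group))
  invisible(masked)
}

#' Run the full pipeline
#'
#' Simulate (when no fixation input is configured), build, metrics, and the
#' three renderings.
#'
#' @param cfg Configuration list from [load_run_config()].
#' @return Invisibly, the [run_metrics()] result.
#' @export
run_all <- function(cfg = load_run_config()) {
  out <- ensure_out_dir(cfg)
  fix_path <- cfg$paths$fixations %||% file.path(out, "fixations.csv")
  if (!file.exists(fix_path)) run_simulate(cfg)
  run_build(cfg)
  res <- run_metrics(cfg)
  run_render(cfg, "all")
  beh_path <- cfg$paths$behavioral %||% file.path(out, "behavioral.csv")
  if (file.exists(beh_path)) {
    run_render(cfg, "top_k")
    run_render(cfg, "bottom_k")
  }
  invisible(res)
}
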