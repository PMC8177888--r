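#' @title Pipeline driver
#' @description End-to-end stages over a structured run configuration:
#'   `run_simulate()` emits a synthetic connectome, `run_analyze()` the
#'   pathway and hub-score tables, `run_ffn()` the feed-forward activity
#'   tables and `run_dcv()` the dense-core-vesicle tissue fractions. Each
#'   output file carries header comments recording the parameters and package
#'   version; numeric output uses 9 significant digits for reproducible
#'   diffs. The same stages back the `larvaconn` command-line script shipped
#'   under `inst/cli`.
#' @name pipeline
NULL

default_run_config <- function() {
  list(
    io = list(neurons = "neurons.csv", edges = "edges.csv", dcv = "dcv.csv",
              outdir = "."),
    thresholds = list(mono = 3L, sens_to_inter = 2L, inter_to_rpn = 3L,
                      hive = 5L),
    ffn = list(a = 0.05, b = 0.5, activation_factor = 2, max_hops = 2L),
    denominator_policy = "dataset_total",
    seed = 1L,
    simulate = list(),
    groups = NULL,
    origins = NULL
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Load a run configuration
#'
#' Reads a YAML configuration file and merges it over the package defaults;
#' explicit `overrides` (e.g. command-line flags) take precedence over the
#' file, which takes precedence over defaults.
#'
#' @param path optional YAML file path.
#' @param overrides optional named list applied last.
#' @return nested configuration list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_validation("config file not found: %s", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg <- merge_config(cfg, overrides)
  th <- cfg$thresholds
  for (nm in names(th)) assert_scalar_count(th[[nm]], paste0("thresholds$", nm))
  cfg
}

config_ffn_params <- function(cfg) {
  ffn_params(a = cfg$ffn$a, b = cfg$ffn$b,
             activation_factor = cfg$ffn$activation_factor,
             max_hops = cfg$ffn$max_hops)
}

config_generator <- function(cfg) {
  sim <- cfg$simulate %||% list()
  motifs <- lapply(sim$planted_motifs %||% list(),
                   function(m) do.call(pathway_motif, m))
  args <- sim[setdiff(names(sim), "planted_motifs")]
  if (!is.null(args$rpn_census)) args$rpn_census <- unlist(args$rpn_census)
  if (!is.null(args$sensory_census)) {
    args$sensory_census <- unlist(args$sensory_census)
  }
  args$planted_motifs <- motifs
  args$seed <- args$seed %||% cfg$seed
  do.call(generator_config, args)
}

output_header <- function(stage, cfg) {
  c(sprintf("# larvaconn %s | stage: %s",
            as.character(utils::packageVersion("larvaconn")), stage),
    sprintf("# thresholds: mono=%d sens_to_inter=%d inter_to_rpn=%d hive=%d",
            cfg$thresholds$mono, cfg$thresholds$sens_to_inter,
            cfg$thresholds$inter_to_rpn, cfg$thresholds$hive),
    sprintf("# ffn: a=%g b=%g activation_factor=%g max_hops=%d | policy=%s | seed=%d",
            cfg$ffn$a, cfg$ffn$b, cfg$ffn$activation_factor,
            cfg$ffn$max_hops, cfg$denominator_policy, as.integer(cfg$seed)))
}

format_numeric <- function(df) {
  for (col in names(df)) {
    if (is.numeric(df[[col]]) && !is.integer(df[[col]])) {
      df[[col]] <- formatC(df[[col]], digits = 9, format = "g")
    }
  }
  df
}

write_stage_table <- function(df, path, stage, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(stage, cfg), con)
  utils::write.table(format_numeric(df), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_config_inputs <- function(cfg) {
  conn <- read_connectome(cfg$io$neurons, cfg$io$edges)
  wa <- input_fractions(conn, cfg$denominator_policy,
                        declared_totals = unlist(cfg$declared_totals))
  groups <- cfg$groups %||% rpn_groups(conn)
  groups <- lapply(groups, unlist)
  unknown <- setdiff(unlist(groups), conn$neurons$id)
  if (length(unknown)) {
    stop_validation("unknown group member id(s): %s",
                    paste(unknown, collapse = ", "))
  }
  list(conn = conn, wa = wa, groups = groups,
       sensory = neuron_ids(conn, cell_class = "sensory"),
       interneurons = neuron_ids(conn, cell_class = "interneuron"),
       rpns = neuron_ids(conn, cell_class = "rpn"))
}

#' Simulate stage: write a synthetic connectome
#'
#' @param cfg run configuration (see [load_run_config()]); the `simulate`
#'   section configures the generator.
#' @return invisibly, the output file paths.
#' @export
run_simulate <- function(cfg = load_run_config()) {
  gc_ <- config_generator(cfg)
  conn <- simulate_connectome(gc_)
  dir.create(cfg$io$outdir, recursive = TRUE, showWarnings = FALSE)
  np <- file.path(cfg$io$outdir, "neurons.csv")
  ep <- file.path(cfg$io$outdir, "edges.csv")
  write_connectome(conn, np, ep)
  census <- table(conn$neurons$cell_class)
  message("simulated connectome: ",
          paste(sprintf("%s=%d", names(census), census), collapse = " "),
          "; ", nrow(conn$edges), " edges (seed ", gc_$seed, ")")
  invisible(c(np, ep))
}

#' Analyze stage: pathway, profile, hub-score and hive tables
#'
#' Runs the thresholded connectivity analysis end to end and writes
#' `paths.tsv`, `profile.json`, `hub_scores.tsv` and `hive_edges.tsv` to the
#' configured output directory. Validation failures abort before any output
#' is written.
#'
#' @param cfg run configuration.
#' @return invisibly, the output paths.
#' @export
run_analyze <- function(cfg = load_run_config()) {
  inp <- read_config_inputs(cfg)
  dir.create(cfg$io$outdir, recursive = TRUE, showWarnings = FALSE)
  if (!nrow(inp$conn$edges)) warning("connectome has no edges; outputs empty")

  paths <- enumerate_paths(
    inp$conn, inp$sensory, inp$interneurons, inp$rpns,
    mono_threshold = cfg$thresholds$mono,
    sens_to_inter_threshold = cfg$thresholds$sens_to_inter,
    inter_to_rpn_threshold = cfg$thresholds$inter_to_rpn)
  pp <- write_stage_table(paths, file.path(cfg$io$outdir, "paths.tsv"),
                          "analyze/paths", cfg)

  profiles <- lapply(names(inp$groups), function(g) {
    pr <- suppressWarnings(
      sensory_profile(inp$wa, inp$conn$neurons, inp$groups[[g]],
                      basis = "of_sensory_input", label = g))
    list(subject = pr$subject, basis = pr$basis,
         fractions = as.list(pr$fractions))
  })
  names(profiles) <- names(inp$groups)
  jp <- file.path(cfg$io$outdir, "profile.json")
  jsonlite::write_json(profiles, jp, auto_unbox = TRUE, digits = NA)

  hubs <- hub_table(inp$conn, inp$wa, inp$interneurons, inp$groups,
                    inp$sensory)
  hp <- write_stage_table(hubs, file.path(cfg$io$outdir, "hub_scores.tsv"),
                          "analyze/hub_scores", cfg)

  hive <- hive_edge_table(inp$conn, threshold = cfg$thresholds$hive)
  vp <- write_stage_table(hive, file.path(cfg$io$outdir, "hive_edges.tsv"),
                          "analyze/hive_edges", cfg)
  invisible(c(pp, jp, hp, vp))
}

#' FFN stage: propagate each sensory origin and tabulate activity
#'
#' Writes `ffn_activity.tsv` (per-neuron weighted input and activity per
#' origin) and `group_activity.tsv` (mean activity per RPN group per origin).
#'
#' @param cfg run configuration; `cfg$origins` defaults to every sensory
#'   origin present.
#' @return invisibly, the output paths.
#' @export
run_ffn <- function(cfg = load_run_config()) {
  inp <- read_config_inputs(cfg)
  params <- config_ffn_params(cfg)
  ffn <- suppressMessages(
    build_ffn(inp$conn, inp$wa, inp$sensory, inp$rpns, params))
  origins <- cfg$origins %||%
    sort(unique(stats::na.omit(inp$conn$neurons$sensory_origin)))
  dir.create(cfg$io$outdir, recursive = TRUE, showWarnings = FALSE)

  act_rows <- list()
  grp_rows <- list()
  for (org in origins) {
    state <- ffn_propagate(ffn, org, params)
    a <- state$activities
    act_rows[[org]] <- data.frame(origin = org, a, stringsAsFactors = FALSE)
    grp_rows[[org]] <- mean_group_activity(state, inp$groups)
  }
  ap <- write_stage_table(do.call(rbind, act_rows),
                          file.path(cfg$io$outdir, "ffn_activity.tsv"),
                          "ffn/activity", cfg)
  ga <- do.call(rbind, grp_rows)[, c("origin", "group", "mean_activity")]
  rownames(ga) <- NULL
  gp <- write_stage_table(ga, file.path(cfg$io$outdir, "group_activity.tsv"),
                          "ffn/group_activity", cfg)
  invisible(c(ap, gp))
}

#' DCV stage: dense-core-vesicle tissue fractions
#'
#' @param cfg run configuration; reads `cfg$io$dcv` and writes
#'   `dcv_fractions.tsv`.
#' @return invisibly, the output path.
#' @export
run_dcv <- function(cfg = load_run_config()) {
  records <- read_dcv(cfg$io$dcv)
  fr <- dcv_fractions(records)
  dir.create(cfg$io$outdir, recursive = TRUE, showWarnings = FALSE)
  invisible(write_stage_table(fr,
                              file.path(cfg$io$outdir, "dcv_fractions.tsv"),
                              "dcv/fractions", cfg))
}
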