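#' Read a weight set written by [write_weights()]
#'
#' @param path YAML file with at least a `combined` mapping
#' @param schema an [indicator_schema()]
#' @return a `weight_set`
#' @export
read_weights <- function(path, schema) {
  if (!file.exists(path)) stop_regcap("weights file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$combined)) stop_regcap("weights file lacks 'combined': ", path)
  vec <- function(x) if (is.null(x)) NULL else unlist(x)
  combined <- vec(raw$combined)
  combined <- combined / sum(combined)  # absorb 6-decimal serialization
  build_weight_set(combined, schema,
                   subjective = vec(raw$subjective), entropy = vec(raw$entropy))
}

#' Run the full evaluation pipeline
#'
#' Orchestrates interpolation, normalization, weighting, scoring, regional
#' ANOVA, obstacle diagnosis and (optionally) vigilance descriptives, and
#' writes the report bundle: `normalized.csv`, `weights.yaml`,
#' `scores.csv`, `anova.csv`, `obstacles.csv`, `vigilance.csv` (if a
#' series is given), `summary.json` and `run.log`. Re-runs on identical
#' inputs are bit-identical; the log records the scope and an MD5 of every
#' output. Any stage failure is re-signalled with the stage name.
#'
#' @param config list (or path to a YAML file) with elements: `schema`,
#'   `panel` (file paths); exactly one of `experts` (expert-score CSV) or
#'   `weights` (frozen weight YAML, or the string `"printed"` for the
#'   published weight system); optional `vigilance` (CSV); `scope`
#'   (default `"pooled_panel"`); `top_k` (default 2); `out_dir`
#' @return invisibly, a list with the in-memory results (`schema`,
#'   `panel`, `normalized`, `weights`, `scores`, `anova`, `obstacles`,
#'   `summary`)
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop_regcap("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_regcap("stage '", name, "': ", conditionMessage(e)))
  }
  has_experts <- !is.null(config$experts)
  has_weights <- !is.null(config$weights)
  if (has_experts == has_weights)
    stop_regcap("config must give exactly one of 'experts' or 'weights'")
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scope <- config$scope %||% "pooled_panel"
  top_k <- config$top_k %||% 2

  schema <- stage("schema", read_schema(config$schema))
  panel <- stage("panel", read_panel(config$panel, schema))
  panel <- stage("interpolate", interpolate_missing(panel))
  normalized <- stage("normalize",
                      normalize_panel(panel, schema, scope = scope))
  weights <- stage("weights", {
    if (has_experts) {
      compute_weights(normalized, read_expert_scores(config$experts), schema)
    } else if (identical(config$weights, "printed")) {
      printed_weight_set(schema)
    } else {
      read_weights(config$weights, schema)
    }
  })
  scores <- stage("score", score_panel(normalized, weights))
  anova_tab <- stage("anova", anova_by_column(scores))
  obstacles <- stage("obstacles", obstacle_report(normalized, weights))
  regional_obs <- stage("obstacles", regional_obstacle_summary(normalized, weights))
  vig <- NULL
  if (!is.null(config$vigilance))
    vig <- stage("vigilance", vigilance_report(read_vigilance(config$vigilance)))

  latest <- max(scores$year)
  latest_scores <- scores[scores$year == latest, ]
  inds <- names(weights$combined)
  top_latest <- lapply(split(regional_obs[regional_obs$year == latest, ],
                             regional_obs$category[regional_obs$year == latest]),
                       function(row) {
    top <- top_obstacles(stats::setNames(as.numeric(row[1, inds]), inds), top_k)
    stats::setNames(round(top$degree, 6), top$indicator)
  })
  summary <- list(
    years = sort(unique(scores$year)),
    latest_year = latest,
    national_mean_composite = round(mean(latest_scores$composite), 6),
    above_average_count = count_above_mean(latest_scores$composite),
    group_means = group_means(latest_scores),
    trend = trend_table(scores, columns = "composite"),
    top_obstacles = top_latest)

  wr <- function(obj, file) {
    path <- file.path(out_dir, file)
    utils::write.csv(format(obj, digits = 12, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE, na = "")
    path
  }
  paths <- c(
    normalized = wr(as.data.frame(normalized), "normalized.csv"),
    weights = write_weights(weights, file.path(out_dir, "weights.yaml")),
    scores = wr(scores, "scores.csv"),
    anova = wr(anova_tab, "anova.csv"),
    obstacles = wr(obstacles, "obstacles.csv"),
    regional_obstacles = wr(regional_obs, "regional_obstacles.csv"))
  if (!is.null(vig)) paths <- c(paths, vigilance = wr(vig, "vigilance.csv"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 6, dataframe = "rows",
                       pretty = TRUE)
  paths <- c(paths, summary = file.path(out_dir, "summary.json"))
  log <- c(sprintf("regcap %s", as.character(utils::packageVersion("regcap"))),
           sprintf("scope: %s", scope),
           sprintf("top_k: %s", top_k),
           sprintf("weights: %s", if (has_experts) "computed" else "frozen"),
           sprintf("%s: md5=%s", names(paths), tools::md5sum(paths)))
  writeLines(log, file.path(out_dir, "run.log"))

  invisible(list(schema = schema, panel = panel, normalized = normalized,
                 weights = weights, scores = scores, anova = anova_tab,
                 obstacles = obstacles, regional_obstacles = regional_obs,
                 vigilance = vig, summary = summary, paths = paths))
}
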