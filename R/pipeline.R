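# Deterministic per-stage seed derivation from the master seed, so each stage
# can be re-run in isolation. 48271 is the MINSTD multiplier; offsets keep
# stage streams distinct. Kept below 2^31.
derive_seed <- function(seed, stage) {
  offs <- c(simulate = 1L, select = 2L, diagnose = 3L, copas = 4L)
  as.integer((as.double(seed) * 48271 + offs[[stage]]) %% 2147483647)
}

#' Pipeline configuration
#'
#' Validated settings for [run_pipeline()]. Either `person_csv` points to an
#' existing person table, or `n_persons` asks the generator to simulate one.
#'
#' @param seed Master seed; expanded deterministically into per-stage seeds.
#' @param person_csv Optional path to a person-level CSV.
#' @param area_csv Optional path to an area-level CSV; when `NULL` and data
#'   are simulated, the area table is derived from the generator
#'   configuration.
#' @param n_persons Size of the simulated population when no `person_csv` is
#'   given.
#' @param family,link Model specification to fit after (or instead of)
#'   selection; `"auto"` uses the Box-Cox / Park recommendations.
#' @param repetitions Copas repetitions.
#' @param budget Budget to allocate, millions of euros (> 0).
#' @param out_dir Optional output directory for the report bundle.
#' @param sim Optional [sim_config()] overriding the default generator
#'   configuration (its seed is replaced by the derived stage seed).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            person_csv = NULL,
                            area_csv = NULL,
                            n_persons = 100000,
                            family = "auto",
                            link = "auto",
                            repetitions = 10,
                            budget = murcia_budget(),
                            out_dir = NULL,
                            sim = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  if (!is.numeric(budget) || length(budget) != 1 || budget <= 0)
    stop("budget must be a single positive amount")
  if (!is.null(person_csv) && !file.exists(person_csv))
    stop("person_csv does not exist: ", person_csv)
  if (!is.null(area_csv) && !file.exists(area_csv))
    stop("area_csv does not exist: ", area_csv)
  structure(list(seed = as.integer(seed), person_csv = person_csv,
                 area_csv = area_csv, n_persons = n_persons,
                 family = family, link = link, repetitions = repetitions,
                 budget = budget, out_dir = out_dir, sim = sim),
            class = "pipeline_config")
}

#' Run the full capitation analysis pipeline
#'
#' Simulate (or load) the person table, run the selection battery (12-fit
#' information-criteria grid, Box-Cox lambda, Modified Park test), fit the
#' chosen specification, run the diagnostics battery, derive the per-AMG
#' weight table, and allocate the budget across areas by population, adjusted
#' population and historical cost. Every artifact is stamped with the seed, a
#' configuration hash and the package version. With a fixed seed the bundle
#' is byte-identical across runs.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result` with elements `population`,
#'   `group_summary`, `selection` (grid, boxcox, park), `model`,
#'   `diagnostics`, `weights`, `area_summary`, `finance`, `stamp`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop("config must be a pipeline_config")
  stage <- "load data"
  result <- tryCatch({
    if (is.null(config$person_csv)) {
      stage <- "simulate"
      sim <- config$sim
      if (is.null(sim))
        sim <- sim_config(n_persons = config$n_persons,
                          seed = derive_seed(config$seed, "simulate"))
      else
        sim$seed <- derive_seed(config$seed, "simulate")
      records <- generate_population(sim)
      areas_in <- data.frame(
        area_id = sim$areas$area_id,
        covered_population = round(tabulate(
          factor(records$area_id, levels = sim$areas$area_id)) *
            sim$areas$coverage_inflation),
        historical_share = sim$areas$historical_share
      )
    } else {
      records <- read_person_table(config$person_csv)
      areas_in <- NULL
    }
    if (!is.null(config$area_csv)) areas_in <- read_area_table(config$area_csv)
    if (is.null(areas_in)) stop("no area table: supply area_csv")

    stage <- "summarise"
    gs <- summarize_groups(records)

    stage <- "select"
    grid <- selection_grid(records)
    design <- build_design(records)
    bc <- box_cox_lambda(records$cost_eur, design)
    pk <- modified_park_test(records)
    family <- if (identical(config$family, "auto"))
      pk$recommended_family else config$family
    link <- if (identical(config$link, "auto"))
      bc$recommended_link else config$link

    stage <- "fit"
    model <- fit_glm(design, family = family, link = link)

    stage <- "diagnose"
    diag <- diagnostics_report(model, records,
                               repetitions = config$repetitions,
                               seed = derive_seed(config$seed, "copas"))

    stage <- "weights"
    wt <- weight_table(model, records)

    stage <- "allocate"
    asum <- area_cost_summary(records, predict(model, records)$mu)
    ni <- need_index(asum)
    areas_in$need_index <- as.numeric(ni[as.character(areas_in$area_id)])
    if (anyNA(areas_in$need_index))
      stop("no need index for area(s): ",
           paste(areas_in$area_id[is.na(areas_in$need_index)], collapse = ", "))
    fin <- allocate_budget(config$budget, areas_in)

    list(population = records, group_summary = gs,
         selection = list(grid = grid, boxcox = bc, park = pk),
         model = model, diagnostics = diag, weights = wt,
         area_summary = asum, finance = fin)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  result$stamp <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    version = as.character(utils::packageVersion("capamg"))
  )
  class(result) <- "pipeline_result"
  if (!is.null(config$out_dir)) write_report_bundle(result, config$out_dir)
  result
}

# Cheap deterministic checksum of the configuration (polynomial rolling hash
# over its deparsed form).
config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write the pipeline report bundle
#'
#' Emits the group summary, weight table, area cost summary and finance table
#' as CSV, and the selection/diagnostics results plus the run stamp as JSON.
#'
#' @param result A [run_pipeline()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report_bundle <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE,
                     quote = FALSE)
  w(result$group_summary, "group_summary.csv")
  w(as.data.frame(result$weights), "weight_table.csv")
  w(as.data.frame(result$area_summary), "area_cost_summary.csv")
  w(format_area_finance(result$finance), "area_finance.csv")
  sel <- result$selection
  jsonlite::write_json(list(
    stamp = result$stamp,
    grid = as.data.frame(sel$grid),
    boxcox = list(lambda = sel$boxcox$lambda, ci95 = sel$boxcox$ci95,
                  recommended_link = sel$boxcox$recommended_link),
    park = list(slope = sel$park$slope, ci95 = sel$park$ci95,
                recommended_family = sel$park$recommended_family),
    diagnostics = list(
      pregibon_p = result$diagnostics$pregibon_p,
      hl_stat = result$diagnostics$hl_stat,
      hl_p = result$diagnostics$hl_p,
      copas_reps = result$diagnostics$copas_reps,
      copas_p_summary = result$diagnostics$copas_p_summary,
      copas_mean_slope = result$diagnostics$copas_mean_slope,
      r2_aux = result$diagnostics$r2_aux,
      rmse = result$diagnostics$rmse, mae = result$diagnostics$mae,
      rmse_cv = result$diagnostics$rmse_cv,
      mae_cv = result$diagnostics$mae_cv,
      pseudo_r2 = result$diagnostics$pseudo_r2)
  ), file.path(out_dir, "selection_diagnostics.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_model_json(result$model, file.path(out_dir, "model.json"))
  invisible(out_dir)
}
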