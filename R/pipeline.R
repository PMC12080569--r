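#' Default pipeline configuration
#'
#' Returns the fully populated configuration list consumed by
#' [run_pipeline()]; any subset can be overridden via the YAML config file
#' or the `config` argument.
#'
#' @return A nested list: `stages`, `seed`, `output_dir`, `cohort`
#'   (arguments of [cohort_spec()]), `pk`/`pd` (arguments of
#'   [pk_params()]/[pd_params()]), `fit` (arguments of [fit_settings()]),
#'   `vpc` (`n_sim`), `bootstrap` (`n_boot`) and `scenarios` (`doses`,
#'   `n_subjects`, `duration`).
#' @export
default_config <- function() {
  list(
    stages = c("generate", "fit_pk", "fit_pd", "simulate"),
    seed = 1,
    output_dir = "pkpd-run",
    data_file = NULL,
    cohort = list(n_subjects = 85),
    pk = list(),
    pd = list(),
    fit = list(compute_se = TRUE),
    vpc = list(n_sim = 1000),
    bootstrap = list(n_boot = 1000),
    scenarios = list(doses = c(5, 10), n_subjects = 1000, duration = 365)
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

.fit_to_json <- function(fit, path) {
  jsonlite::write_json(
    list(model = fit$model,
         estimates = fit$estimates,
         minus2ll = fit$minus2ll, aic = fit$aic,
         n_obs = fit$n_obs, n_subjects = fit$n_subjects,
         converged = fit$convergence$converged),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order - `generate` (or load
#' a dataset), `fit_pk`, `covsearch`, `fit_pd`, `vpc`, `bootstrap`,
#' `simulate` - writing CSV/JSON artifacts and a manifest (inputs, seeds,
#' package version, output hashes, timings) to the output directory.
#' Identical config and seeds give byte-identical numeric outputs.
#'
#' @param config A configuration list (see [default_config()]) or the path
#'   of a YAML file holding one.
#' @param output_dir Optional override of `config$output_dir`.
#' @return Invisibly, a list with the stage results and the manifest.
#' @examples
#' \dontrun{
#' run_pipeline(list(stages = c("generate", "fit_pk"),
#'                   cohort = list(n_subjects = 30),
#'                   output_dir = tempfile()))
#' }
#' @export
run_pipeline <- function(config = list(), output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path",
                             call. = FALSE)
  cfg <- .merge_config(default_config(), config)
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  stages <- match.arg(cfg$stages,
                      c("generate", "fit_pk", "covsearch", "fit_pd",
                        "vpc", "bootstrap", "simulate"),
                      several.ok = TRUE)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out_path <- function(f) file.path(cfg$output_dir, f)
  manifest <- list(package_version = as.character(utils::packageVersion("dapapkpd")),
                   seed = cfg$seed, stages = stages, outputs = list(),
                   timings = list())
  results <- list()
  log_stage <- function(stage, elapsed, files) {
    manifest$timings[[stage]] <<- round(unname(elapsed), 3)
    for (f in files) {
      manifest$outputs[[basename(f)]] <<-
        unname(tools::md5sum(f))
    }
    message(sprintf("[%s] done in %.1fs", stage, elapsed))
  }

  spec <- do.call(cohort_spec, c(cfg$cohort,
                                 if (is.null(cfg$cohort$seed))
                                   list(seed = cfg$seed)))
  pk <- do.call(pk_params, cfg$pk)
  pd <- do.call(pd_params, cfg$pd)
  settings <- do.call(fit_settings, cfg$fit)

  data <- NULL
  if ("generate" %in% stages) {
    t0 <- proc.time()["elapsed"]
    cohort <- draw_cohort(spec, true_pk = pk, true_pd = pd)
    data <- generate_event_table(cohort, spec, true_pk = pk, true_pd = pd)
    f1 <- out_path("dataset.csv"); f2 <- out_path("truth.csv")
    write_event_table(data, f1)
    readr::write_csv(cohort, f2, progress = FALSE)
    results$cohort <- cohort
    log_stage("generate", proc.time()["elapsed"] - t0, c(f1, f2))
  } else if (!is.null(cfg$data_file)) {
    data <- read_event_table(cfg$data_file, lloq = spec$lloq)
  }

  pk_fit <- NULL
  if ("fit_pk" %in% stages || "fit_pd" %in% stages ||
      "vpc" %in% stages || "bootstrap" %in% stages ||
      "covsearch" %in% stages) {
    if (is.null(data)) stop("stages requiring data need `generate` or ",
                            "`data_file`", call. = FALSE)
    t0 <- proc.time()["elapsed"]
    pk_data <- suppressMessages(exclude_blq(data))
    pk_fit <- fit_pk(pk_data, start = pk, settings = settings)
    f <- out_path("pk_fit.json")
    .fit_to_json(pk_fit, f)
    fe <- out_path("pk_ebe.csv")
    readr::write_csv(pk_fit$ebe, fe, progress = FALSE)
    results$pk_fit <- pk_fit
    log_stage("fit_pk", proc.time()["elapsed"] - t0, c(f, fe))
  }

  if ("covsearch" %in% stages) {
    t0 <- proc.time()["elapsed"]
    sel <- stepwise_select(suppressMessages(exclude_blq(data)),
                           start = pk, settings = settings)
    f <- out_path("covariate_trace.csv")
    readr::write_csv(sel$trace, f, progress = FALSE)
    results$covsearch <- sel
    log_stage("covsearch", proc.time()["elapsed"] - t0, f)
  }

  if ("fit_pd" %in% stages) {
    t0 <- proc.time()["elapsed"]
    pd_fit <- fit_pd(data, pk_fit, start = pd, settings = settings)
    f <- out_path("pd_fit.json")
    .fit_to_json(pd_fit, f)
    fe <- out_path("pd_ebe.csv")
    readr::write_csv(pd_fit$ebe, fe, progress = FALSE)
    results$pd_fit <- pd_fit
    log_stage("fit_pd", proc.time()["elapsed"] - t0, c(f, fe))
  }

  if ("vpc" %in% stages) {
    t0 <- proc.time()["elapsed"]
    vpc <- run_vpc(pk_fit, n_sim = cfg$vpc$n_sim, seed = cfg$seed)
    f <- out_path("vpc_pk.csv")
    readr::write_csv(vpc$stats, f, progress = FALSE)
    results$vpc <- vpc
    log_stage("vpc", proc.time()["elapsed"] - t0, f)
  }

  if ("bootstrap" %in% stages) {
    t0 <- proc.time()["elapsed"]
    bt <- run_bootstrap(suppressMessages(exclude_blq(data)), pk_fit,
                        n_boot = cfg$bootstrap$n_boot, seed = cfg$seed)
    f <- out_path("bootstrap_pk.csv")
    readr::write_csv(bt$summary, f, progress = FALSE)
    results$bootstrap <- bt
    log_stage("bootstrap", proc.time()["elapsed"] - t0, f)
  }

  if ("simulate" %in% stages) {
    t0 <- proc.time()["elapsed"]
    sc_spec <- do.call(cohort_spec,
                       list(n_subjects = cfg$scenarios$n_subjects,
                            seed = cfg$seed))
    files <- character(0)
    results$scenarios <- lapply(cfg$scenarios$doses, function(dmg) {
      sc <- simulate_scenario(dmg, spec = sc_spec, pk = pk, pd = pd,
                              duration = cfg$scenarios$duration)
      f <- out_path(sprintf("scenario_%smg.csv", dmg))
      readr::write_csv(sc$summary, f, progress = FALSE)
      files <<- c(files, f)
      sc
    })
    log_stage("simulate", proc.time()["elapsed"] - t0, files)
  }

  mf <- out_path("manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(results, list(manifest = manifest)))
}
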