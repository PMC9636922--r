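## stable per-stage sub-seed: adding a stage never shifts other streams
.stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(global_seed) * 7919 + h) %% 2147483647)
}

#' Validate a set of pipeline inputs
#'
#' Schema checks on the three CSV tables, year alignment across tables and
#' focal-locus presence. Fatal problems are returned in `errors`; alignment
#' issues are warnings.
#'
#' @param genotypes,loci,catch,flow file paths.
#' @return list with character vectors `errors` and `warnings`.
#' @export
validate_inputs <- function(genotypes, loci, catch, flow) {
  errors <- character(0); warnings <- character(0)
  panel <- tryCatch(suppressWarnings(read_genotypes(genotypes, loci)),
                    error = function(e) {
                      errors <<- c(errors, conditionMessage(e)); NULL
                    })
  ct <- tryCatch(suppressWarnings({
    raw <- utils::read.csv(catch, stringsAsFactors = FALSE)
    if (!all(c("year", "mass_kg") %in% names(raw)))
      stop("catch file needs year and mass_kg columns")
    bad <- which(!is.na(raw$mass_kg) & raw$mass_kg <= 0)
    if (length(bad))
      stop("non-positive mass in catch row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    catch_table(raw)
  }), error = function(e) {
    errors <<- c(errors, conditionMessage(e)); NULL
  })
  fl <- tryCatch(suppressWarnings(read_flow(flow)),
                 error = function(e) {
                   errors <<- c(errors, conditionMessage(e)); NULL
                 })
  if (!is.null(panel)) {
    if (!any(panel$loci$class == "focal"))
      warnings <- c(warnings, "no focal loci in genotype panel")
    if (!is.null(ct)) {
      hit <- panel$info$individual_id %in% ct$individual_id
      if (!any(hit))
        warnings <- c(warnings,
                      "no genotyped individuals found in catch records")
    }
  }
  if (!is.null(ct) && !is.null(fl)) {
    missing_years <- setdiff(ct$year[ct$year >= min(fl$year)], fl$year)
    if (length(missing_years))
      warnings <- c(warnings, paste("catch years outside flow coverage:",
                                    paste(utils::head(missing_years, 5),
                                          collapse = ", ")))
  }
  list(errors = errors, warnings = warnings)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate, drift-test, effects, fit-dynamics and report stages in
#' order, writing each stage's artifacts under `out_dir` together with a
#' manifest (seed, config digest, per-stage seeds) that makes reruns
#' byte-reproducible. Stage settings are scaled by `profile`: `"test"`
#' (small, minutes) or `"full"` (study-scale MCMC settings).
#'
#' @param scenario a [sim_scenario()] (synthetic mode).
#' @param out_dir output directory (created).
#' @param seed global seed; per-stage seeds are derived by stable hashing.
#' @param profile `"test"` or `"full"`.
#' @return invisible list with the stage results (`sim`, `drift`, `focal`,
#'   `effects`, `dynamics`, `report`, `manifest`).
#' @export
run_pipeline <- function(scenario = sim_scenario(), out_dir = tempfile("run"),
                         seed = 1L, profile = c("test", "full")) {
  profile <- match.arg(profile)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message("[pipeline] ", msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(log_lines, file.path(out_dir, "pipeline.log"))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  ## -- simulate ------------------------------------------------------
  scenario$seed <- .stage_seed(seed, "simulate")
  sim <- stage("simulate", simulate_study(scenario))
  write_genotypes(sim$panel, file.path(out_dir, "genotypes.csv"),
                  file.path(out_dir, "loci.csv"))
  write_table_csv(sim$catch, file.path(out_dir, "catch.csv"))
  write_table_csv(sim$flow, file.path(out_dir, "flow.csv"))
  truth <- list(params = unclass(sim$truth$params),
                zeta = sim$truth$zeta,
                effects_a = sim$truth$effects$a,
                effects_d = sim$truth$effects$d)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("simulate: %d genotyped, %d catch records",
      nrow(sim$panel$calls), nrow(sim$catch))

  ## -- drift test ----------------------------------------------------
  cfg <- if (profile == "full")
    drift_config(n_iter = 770000L, burn_in = 370000L, thin = 40L,
                 seed = .stage_seed(seed, "drift"))
  else drift_config(n_iter = 6000L, burn_in = 3000L, thin = 5L,
                    seed = .stage_seed(seed, "drift"))
  panel <- filter_call_rate(sim$panel, 0.7)
  counts <- count_alleles(panel, drop_fixed = TRUE)
  drift <- stage("drift-test", fit_drift_model(counts, cfg))
  focal <- stage("drift-test",
                 focal_posterior(counts, seed = .stage_seed(seed, "focal")))
  drift_rows <- list()
  for (l in names(focal$change))
    for (k in seq_len(ncol(focal$change[[l]]))) {
      p0 <- focal$freq[[l]][, k]
      pr <- drift_probability(focal$change[[l]][, k], p0, drift$zeta[, k],
                              seed = .stage_seed(seed, "driftprob"))
      drift_rows[[length(drift_rows) + 1]] <- data.frame(
        locus_id = l, interval = colnames(focal$change[[l]])[k],
        change_median = stats::median(focal$change[[l]][, k]),
        drift_probability = pr)
    }
  drift_tab <- do.call(rbind, drift_rows)
  utils::write.csv(drift_tab, file.path(out_dir, "drift_summary.csv"),
                   row.names = FALSE)
  grid <- seq(0.05, 0.95, by = 0.05)
  env <- data.frame(p0 = grid)
  for (k in seq_len(ncol(drift$zeta))) {
    zd <- drift$zeta[, k]
    if (length(zd) > 200)    # envelope cost is per-draw; thin deterministically
      zd <- zd[round(seq(1, length(zd), length.out = 200))]
    env[[paste0("envelope_", k)]] <- drift_envelope(grid, zd)
  }
  utils::write.csv(env, file.path(out_dir, "drift_envelope.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(parameter = names(drift$rhat),
                              rhat = unname(drift$rhat)),
                   file.path(out_dir, "drift_diagnostics.csv"),
                   row.names = FALSE)
  say("drift-test: zeta medians %s; converged = %s",
      paste(signif(drift$zeta_summary[, "median"], 3), collapse = ", "),
      drift$converged)

  ## -- effects -------------------------------------------------------
  joined <- join_panel_catch(panel, sim$catch)
  eff_fit <- stage("effects", fit_effect_model(joined))
  eff <- as_locus_effects(eff_fit)
  nd <- if (profile == "full") 50000L else 5000L
  ratios <- do.call(rbind, lapply(rownames(eff$a), function(l)
    do.call(rbind, lapply(c("F", "M"), function(s) {
      r <- genotype_mass_ratio(eff_fit, l, s, n_draws = nd,
                               seed = .stage_seed(seed, "ratios"))
      data.frame(locus = l, sex = s, ratio = r[["ratio"]],
                 lo = r[["lo"]], hi = r[["hi"]])
    }))))
  jsonlite::write_json(list(a = eff$a, d = eff$d, vcov = eff$vcov,
                            ratios = ratios),
                       file.path(out_dir, "effects.json"),
                       digits = NA, pretty = TRUE)
  say("effects: n = %d; a(vgll3, M) = %.3f", eff_fit$n_used,
      eff$a["vgll3", "M"])

  ## -- fit dynamics --------------------------------------------------
  ph <- annual_summary(sim$catch, years = min(scenario$years):max(scenario$years))
  plan <- scenario$sample_plan
  fc <- NULL
  for (t in seq_len(nrow(plan))) {
    if (plan$year[t] < min(scenario$years)) next
    sub <- counts[counts$class == "focal" & counts$period == plan$period[t], ]
    if (nrow(sub))
      fc <- rbind(fc, data.frame(locus = sub$locus_id, year = plan$year[t],
                                 A = sub$T - sub$A, T = sub$T))  # E -> L counts
  }
  dyn <- stage("fit-dynamics", fit_dynamics(
    list(phenotypes = ph, focal_counts = fc, flow = sim$flow),
    constants = dynamics_constants(VP = scenario$VP,
                                   start_year = min(scenario$years)),
    effects = eff,
    n_restarts = if (profile == "full") 10 else 2,
    seed = .stage_seed(seed, "dynamics")))
  utils::write.csv(dyn$trajectory, file.path(out_dir, "trajectory.csv"),
                   row.names = FALSE)
  est <- c(q = dyn$params$q, theta_ref = dyn$params$theta_ref,
           b = dyn$params$b, delta = dyn$params$delta, h2 = dyn$params$h2,
           sigma_e2 = dyn$params$sigma_e2)
  jsonlite::write_json(list(estimates = as.list(est),
                            se = as.list(dyn$se),
                            variance_explained = as.list(variance_explained(dyn)),
                            nll = dyn$nll),
                       file.path(out_dir, "dynamics_fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("fit-dynamics: b = %.3f (SE %.3f), q = %.2f", dyn$params$b,
      dyn$se[["b"]], dyn$params$q)

  ## -- report --------------------------------------------------------
  pre <- sim$catch[sim$catch$year <= 1953, ]
  post <- sim$catch[sim$catch$year >= 1975, ]
  rate <- rate_of_change(mean(log(pre$mass_kg * 1000)),
                         mean(log(post$mass_kg * 1000)), years = 22)
  decomp <- tryCatch(decompose_mass_change(pre, post), error = function(e) NULL)
  report <- list(
    rate = unclass(rate),
    percent_of_original = percent_of_reference(mean(post$mass_kg),
                                               mean(pre$mass_kg))$percent,
    decomposition = if (!is.null(decomp)) unclass(decomp),
    truth_vs_estimate = data.frame(
      parameter = c("q", "b", "h2", "delta"),
      truth = c(scenario$params$q, scenario$params$b, scenario$params$h2,
                scenario$params$delta),
      estimate = c(dyn$params$q, dyn$params$b, dyn$params$h2,
                   dyn$params$delta)))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(package = "salmodyn",
                   version = as.character(utils::packageVersion("salmodyn")),
                   seed = seed, profile = profile,
                   stage_seeds = list(
                     simulate = .stage_seed(seed, "simulate"),
                     drift = .stage_seed(seed, "drift"),
                     focal = .stage_seed(seed, "focal"),
                     ratios = .stage_seed(seed, "ratios"),
                     dynamics = .stage_seed(seed, "dynamics")),
                   scenario_digest = .config_digest(scenario))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  invisible(list(sim = sim, drift = drift, focal = focal, effects = eff_fit,
                 dynamics = dyn, report = report, manifest = manifest,
                 out_dir = out_dir))
}

## deterministic digest of a scenario (no external hash dependency)
.config_digest <- function(x) {
  s <- paste(utils::capture.output(utils::str(x, digits.d = 10)),
             collapse = "\n")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

#' Command-line entry point
#'
#' Thin subcommand dispatcher used by `inst/scripts/salmodyn-cli.R`:
#' `simulate`, `run`, `validate`. Configuration is a YAML file of
#' [sim_scenario()] fields (all optional).
#'
#' @param args character vector of command-line arguments.
#' @return exit status, invisibly.
#' @export
salmodyn_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: salmodyn-cli.R <simulate|run|validate> [--config cfg.yaml] [--out dir] [--seed N]\n       salmodyn-cli.R validate --genotypes g.csv --loci l.csv --catch c.csv --flow f.csv"
  if (!length(args)) { cat(usage, "\n"); return(invisible(1L)) }
  cmd <- args[1]
  opt <- list(out = "salmodyn_run", seed = 1L, config = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  opt$seed <- as.integer(opt$seed)
  scen_args <- if (!is.null(opt$config)) yaml::read_yaml(opt$config) else list()
  scenario <- do.call(sim_scenario, scen_args)
  if (cmd == "simulate") {
    scenario$seed <- opt$seed
    sim <- simulate_study(scenario)
    dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
    write_genotypes(sim$panel, file.path(opt$out, "genotypes.csv"),
                    file.path(opt$out, "loci.csv"))
    write_table_csv(sim$catch, file.path(opt$out, "catch.csv"))
    write_table_csv(sim$flow, file.path(opt$out, "flow.csv"))
    jsonlite::write_json(list(zeta = scenario$zeta,
                              params = unclass(scenario$params)),
                         file.path(opt$out, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (cmd == "run") {
    run_pipeline(scenario, out_dir = opt$out, seed = opt$seed)
  } else if (cmd == "validate") {
    rep <- validate_inputs(opt$genotypes, opt$loci, opt$catch, opt$flow)
    if (length(rep$errors)) {
      cat("errors:\n"); cat(paste(" -", rep$errors), sep = "\n")
      return(invisible(1L))
    }
    if (length(rep$warnings)) {
      cat("warnings:\n"); cat(paste(" -", rep$warnings), sep = "\n")
    }
    cat("inputs OK\n")
  } else {
    cat(usage, "\n"); return(invisible(1L))
  }
  invisible(0L)
}
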