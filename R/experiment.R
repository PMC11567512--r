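# Orchestration: run a scenario under each policy with common random
# numbers across replicates, collect ledgers and logs, and emit the
# comparison report and a reproducibility manifest.

#' Deterministic content hash of a scenario bundle
#'
#' Hashes the bundle's canonical JSON serialisation with the package's
#' 31-bit mixing function; used in run manifests to pin the scenario a
#' report was produced from.
#'
#' @param bundle A `scenario_bundle`.
#' @return Character hash.
#' @export
bundle_hash <- function(bundle) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_scenario(bundle, tmp)
  txt <- readChar(tmp, file.info(tmp)$size, useBytes = TRUE)
  s <- 17
  for (b in utf8ToInt(txt)) s <- .mix(s, b)
  sprintf("%08x", as.integer(s))
}

#' Run a full policy-comparison experiment
#'
#' Runs `replicates` simulations of the bundle under each policy.
#' Replicate `r` uses the same random streams under every policy (common
#' random numbers), so policy contrasts are paired. Aggregates all ledgers
#' into a `comparison_report` and builds a manifest from which the
#' experiment can be reproduced bit-for-bit.
#'
#' @param bundle A validated `scenario_bundle`.
#' @param policies Character vector of policy ids to run (default: all in
#'   the bundle).
#' @param replicates Number of replicates (default: bundle setting).
#' @param horizon_years Optional horizon override.
#' @param out_dir Optional directory; when given, writes `ledgers.csv`,
#'   `report.json` and `manifest.json` there.
#' @param progress Emit per-run progress lines on standard error.
#' @return List of class `experiment_result`: `report`
#'   (a `comparison_report`), `manifest`, `ledgers` (list of
#'   `daly_ledger`), and `runs` (per-run logs: events, deliveries, deaths,
#'   final population).
#' @export
run_experiment <- function(bundle, policies = NULL, replicates = NULL,
                           horizon_years = NULL, out_dir = NULL,
                           progress = FALSE) {
  validate_bundle(bundle)
  if (is.null(policies)) policies <- names(bundle$policies)
  stopifnot(all(policies %in% names(bundle$policies)))
  if (is.null(replicates)) replicates <- bundle$replicates
  if (!is.null(horizon_years))
    bundle$horizon_years <- as.integer(horizon_years)
  ledgers <- list()
  runs <- list()
  for (pid in policies) {
    for (r in seq_len(replicates)) {
      if (progress)
        message(sprintf("running policy=%s replicate=%d", pid, r))
      res <- run_scenario(bundle, pid, r)
      key <- sprintf("%s:%d", pid, r)
      ledgers[[key]] <- res$ledger
      runs[[key]] <- list(events = res$events,
                          deliveries = res$deliveries,
                          deaths = res$deaths,
                          final_population = res$final_population)
    }
  }
  report <- aggregate_replicates(unname(ledgers))
  manifest <- list(
    scenario_hash = bundle_hash(bundle),
    policies = policies,
    replicates = replicates,
    master_seed = bundle$master_seed,
    horizon_years = bundle$horizon_years,
    package_version = as.character(utils::packageVersion("prioritysim")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report$cells, file.path(out_dir, "ledgers.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(totals = report$totals,
                              per_year = report$per_year,
                              per_cause = report$per_cause,
                              benchmark = report$benchmark),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  structure(list(report = report, manifest = manifest, ledgers = ledgers,
                 runs = runs),
            class = "experiment_result")
}

#' Demographic-divergence diagnostic
#'
#' Because capabilities are constant over the horizon while the population
#' grows (and grows differently under policies that deliver different
#' amounts of contraception and life-saving care), final population sizes
#' can diverge across policies. This diagnostic tabulates the final alive
#' count per policy and replicate.
#'
#' @param result An `experiment_result`.
#' @return Data frame `policy`, `replicate`, `final_population`.
#' @export
population_divergence <- function(result) {
  keys <- strsplit(names(result$runs), ":")
  data.frame(
    policy = vapply(keys, `[[`, "", 1),
    replicate = as.integer(vapply(keys, `[[`, "", 2)),
    final_population = vapply(result$runs, `[[`, 1, "final_population"),
    row.names = NULL)
}

#' Minimal command-line interface
#'
#' Subcommands: `make --seed S --out FILE`, `validate FILE`,
#' `run --scenario FILE [--policies A,B] [--replicates N] [--out DIR]`,
#' `report DIR [--horizon H]`, `presets`.
#'
#' @param args Character vector of arguments (default: command line).
#' @return Exit status (0 on success), invisibly.
#' @export
prioritysim_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: prioritysim <command> [options]",
    "  make --seed S --out FILE       write the default scenario bundle",
    "  validate FILE                  validate a scenario bundle",
    "  run --scenario FILE [--policies A,B] [--replicates N] [--out DIR]",
    "  report DIR [--horizon H]       recompute comparison from saved ledgers",
    "  presets                        list shipped policy presets",
    sep = "\n")
  if (!length(args)) { cat(usage, "\n"); return(invisible(1L)) }
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i)) args[i[1] + 1L] else default
  }
  cmd <- args[1]
  if (cmd == "make") {
    seed <- as.integer(opt("seed", 1))
    out <- opt("out")
    if (is.null(out)) stop("make: --out FILE required", call. = FALSE)
    write_scenario(make_default_scenario(seed), out)
    cat(sprintf("wrote scenario (seed %d) to %s\n", seed, out))
  } else if (cmd == "validate") {
    validate_bundle(read_scenario(args[2]))
    cat("ok\n")
  } else if (cmd == "run") {
    b <- read_scenario(opt("scenario"))
    pol <- opt("policies")
    pol <- if (is.null(pol)) NULL else strsplit(pol, ",")[[1]]
    res <- run_experiment(b, policies = pol,
                          replicates = as.integer(opt("replicates",
                                                      b$replicates)),
                          out_dir = opt("out"), progress = TRUE)
    print(res$report$totals)
  } else if (cmd == "report") {
    cells <- utils::read.csv(file.path(args[2], "ledgers.csv"))
    ledgers <- lapply(split(cells, list(cells$policy, cells$replicate),
                            drop = TRUE), function(g)
      daly_ledger(data.frame(cause = g$cause, year = g$year,
                             yll = g$yll, yld = g$yld),
                  policy_id = g$policy[1], replicate_id = g$replicate[1],
                  scale_factor = 1))
    rep <- aggregate_replicates(unname(ledgers))
    h <- opt("horizon")
    if (!is.null(h)) rep <- horizon_view(rep, as.integer(h))
    print(rep$totals)
  } else if (cmd == "presets") {
    for (p in policy_presets())
      cat(sprintf("%-6s excluded: %s | high: %s | fasttracked: %d\n",
                  p$policy_id,
                  if (length(p$excluded))
                    paste(p$excluded, collapse = ",") else "-",
                  paste(names(p$tier_of)[p$tier_of == "high"],
                        collapse = ",") ,
                  length(p$fasttrack)))
  } else {
    cat(usage, "\n"); return(invisible(1L))
  }
  invisible(0L)
}
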