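#' Write a scenario rate table to delimited text
#'
#' Comma-separated output with `#`-prefixed header lines recording the run
#' parameters; every data row carries the full scenario fields (mix, ratios,
#' cell size, variant, strategy, draws, alpha, seed) so the file is
#' self-describing and re-runnable.
#'
#' @param suite a data.frame from [scenario_suite()] (or any data.frame of
#'   scenario rows).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_rate_table <- function(suite, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# balancesim ", as.character(utils::packageVersion("balancesim")),
           " rate table"),
    paste0("# columns: ", paste(names(suite), collapse = ", "))
  ), con)
  utils::write.csv(as.data.frame(suite), con, row.names = FALSE)
  invisible(file)
}

#' Write a p-value histogram to delimited text
#'
#' @param hist_df a [pvalue_histogram()] data.frame.
#' @param file output path.
#' @param spec the generating [scenario_spec()], recorded in the header.
#' @return `file`, invisibly.
#' @export
write_histogram <- function(hist_df, file, spec) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    "# balancesim p-value histogram",
    sprintf("# mix=%s; cell_size=%d; draws=%d; alpha=%g; variant=%s; strategy=%s; seed=%d",
            paste(sprintf("%s=%g", spec$mix$labels, spec$mix$proportions),
                  collapse = ","),
            spec$cell_size, spec$draws, spec$alpha, spec$variant,
            spec$strategy, spec$seed)
  ), con)
  utils::write.csv(hist_df, con, row.names = FALSE)
  invisible(file)
}

#' Export the four reference p-value histograms (panels A-D)
#'
#' Runs the four reference mixtures at 20 subjects per cell and writes one
#' histogram file per panel: (A) two subpopulations, equal ratios; (B) three
#' subpopulations, equal ratios; (C) two subpopulations, 60/40; (D) three
#' subpopulations, 55/35/10. Bin edges include the 0.05 significance
#' threshold, so the mass strictly below 0.05 equals the scenario's
#' unbalanced count exactly.
#'
#' @param out_dir output directory (created if needed).
#' @param cell_size subjects per group, default 20.
#' @param bins histogram bin edges (must include 0.05; default width 0.05).
#' @inheritParams scenario_spec
#' @return A data.frame with one row per panel: panel letter, mix, file,
#'   unbalanced rate and below-threshold count.
#' @export
export_figure_panels <- function(out_dir, cell_size = 20, draws = 10000,
                                 alpha = 0.05, variant = "two-sample-yates",
                                 seed = 20140902,
                                 bins = seq(0, 1, by = 0.05)) {
  if (!any(abs(bins - alpha) < 1e-12))
    stop("'bins' must include the significance threshold ", alpha,
         " as an edge", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panels <- data.frame(panel = c("A", "B", "C", "D"),
                       mix = c("2-equal", "3-equal", "2-unequal", "3-unequal"))
  mixes <- study_mixes()
  rows <- vector("list", nrow(panels))
  for (i in seq_len(nrow(panels))) {
    spec <- scenario_spec(mixes[[panels$mix[i]]], cell_size, draws = draws,
                          alpha = alpha, variant = variant, seed = seed + i)
    res <- run_scenario(spec)
    h <- pvalue_histogram(res, bins)
    path <- file.path(out_dir, paste0("panel_", panels$panel[i], ".csv"))
    write_histogram(h, path, spec)
    rows[[i]] <- data.frame(panel = panels$panel[i], mix = panels$mix[i],
                            file = path,
                            unbalanced_rate = res$unbalanced_rate,
                            below_threshold = sum(h$count[h$bin_hi <= alpha + 1e-12]))
  }
  do.call(rbind, rows)
}

#' Read a run configuration file
#'
#' YAML configuration with optional top-level defaults (`draws`, `alpha`,
#' `variant`, `strategy`, `seed`) and a `scenarios` list; each scenario gives
#' a `mix` mapping (label -> proportion, accepted as fractions summing to 1
#' or percentages summing to 100, see [parse_mix()]), a `cell_size`, and may
#' override any default.
#'
#' @param path YAML file path.
#' @return A list of [scenario_spec()] objects, named by the scenarios'
#'   `name` fields where given.
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines(c("draws: 100", "scenarios:",
#'              "  - name: demo", "    mix: {high: 60, low: 40}",
#'              "    cell_size: 20"), cfg)
#' read_run_config(cfg)
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scenarios) || !length(cfg$scenarios))
    stop("config must contain a non-empty 'scenarios' list", call. = FALSE)
  defaults <- list(draws = 10000, alpha = 0.05, variant = "two-sample-yates",
                   strategy = "random", seed = 20140902)
  for (nm in names(defaults))
    if (!is.null(cfg[[nm]])) defaults[[nm]] <- cfg[[nm]]
  specs <- lapply(seq_along(cfg$scenarios), function(i) {
    sc <- cfg$scenarios[[i]]
    if (is.null(sc$mix))
      stop(sprintf("scenario %d: missing 'mix'", i), call. = FALSE)
    if (is.null(sc$cell_size))
      stop(sprintf("scenario %d: missing 'cell_size'", i), call. = FALSE)
    get <- function(nm) if (!is.null(sc[[nm]])) sc[[nm]] else defaults[[nm]]
    scenario_spec(parse_mix(sc$mix), sc$cell_size, draws = get("draws"),
                  alpha = get("alpha"), variant = get("variant"),
                  strategy = get("strategy"), seed = get("seed"))
  })
  names(specs) <- vapply(seq_along(cfg$scenarios), function(i) {
    nm <- cfg$scenarios[[i]]$name
    if (is.null(nm)) paste0("scenario_", i) else nm
  }, character(1))
  specs
}

#' Run configured scenarios and write all outputs
#'
#' For each configured scenario: runs the Monte Carlo, writes a p-value
#' histogram file, and appends a row to a combined rate table written to
#' `rates.csv` in `out_dir`. Progress and seeds are logged to standard
#' error.
#'
#' @param specs a list of [scenario_spec()]s, e.g. from [read_run_config()].
#' @param out_dir output directory.
#' @return The rate table data.frame, invisibly.
#' @export
run_configured <- function(specs, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    message(sprintf("[balancesim] scenario %s: variant=%s strategy=%s seed=%d",
                    names(specs)[i], spec$variant, spec$strategy, spec$seed))
    res <- run_scenario(spec)
    write_histogram(pvalue_histogram(res),
                    file.path(out_dir, paste0(names(specs)[i], "_pvalues.csv")),
                    spec)
    rows[[i]] <- data.frame(
      scenario = names(specs)[i],
      ratios = paste(sprintf("%s=%g", spec$mix$labels, spec$mix$proportions),
                     collapse = "/"),
      cell_size = spec$cell_size, variant = spec$variant,
      strategy = spec$strategy, draws = spec$draws, alpha = spec$alpha,
      seed = spec$seed, unbalanced_rate = res$unbalanced_rate,
      mc_se = res$mc_se, percent = round(100 * res$unbalanced_rate, 2))
  }
  out <- do.call(rbind, rows)
  write_rate_table(out, file.path(out_dir, "rates.csv"))
  invisible(out)
}
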