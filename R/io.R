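## Delimited-table I/O and the pipeline driver. One table dialect package-
## wide: tab-separated, UTF-8, "." decimal, header row; concentration and
## unit-bearing columns are suffixed (_uM, _RU, _s) so the uM convention is
## explicit at the file boundary. Reports are JSON.

TABLE_SCHEMAS <- list(
  titration = list(
    cols = c("replicate", "protein_uM", "dna_uM", "f0", "f1", "f2", "f3"),
    numeric = c("protein_uM", "dna_uM", "f0", "f1", "f2", "f3")),
  binding_curve = list(
    cols = c("replicate", "x_uM", "y"),
    numeric = c("x_uM", "y")),
  spr = list(
    cols = c("conc_uM", "Req_RU"),
    numeric = c("conc_uM", "Req_RU")),
  decay = list(
    cols = c("time_s", "fraction_complex"),
    numeric = c("time_s", "fraction_complex")),
  footprint = list(
    cols = c("strand", "base_index", "base", "intensity_free",
             "intensity_complex"),
    numeric = c("base_index", "intensity_free", "intensity_complex"))
)

#' Read a typed analysis table
#'
#' Reads one of the package's tab-separated table dialects, validating the
#' header against the schema and coercing numeric columns; validation
#' failures report the offending column and data line.
#'
#' @param path Path to a TSV file with a header row.
#' @param schema One of `"titration"`, `"binding_curve"`, `"spr"`, `"decay"`,
#'   `"footprint"`.
#' @return A validated data frame. For `"titration"`, fraction rows summing
#'   to 1 within 2% are renormalised to exactly 1 (with a warning when any
#'   row needed it); larger deviations are rejected.
#' @export
load_table <- function(path, schema = names(TABLE_SCHEMAS)) {
  schema <- match.arg(schema)
  sch <- TABLE_SCHEMAS[[schema]]
  if (!file.exists(path))
    stop_bindpoly(paste0("file not found: ", path), "bindpoly_io_error")
  raw <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", dec = ".",
                      colClasses = "character", check.names = FALSE,
                      fileEncoding = "UTF-8"),
    error = function(e)
      stop_bindpoly(paste0("cannot parse ", path, ": ", conditionMessage(e)),
                    "bindpoly_io_error"))
  if (nrow(raw) == 0)
    stop_bindpoly(paste0("empty table: ", path), "bindpoly_io_error")
  missing <- setdiff(sch$cols, names(raw))
  if (length(missing))
    stop_bindpoly(paste0(schema, " table is missing column(s): ",
                         paste(missing, collapse = ", ")),
                  "bindpoly_io_error")
  raw <- raw[, sch$cols, drop = FALSE]
  for (col in sch$numeric) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !(raw[[col]] %in% c("NA", "")))
    if (length(bad))
      stop_bindpoly(sprintf("non-numeric value in column '%s' at data line %s",
                            col, paste(bad, collapse = ", ")),
                    "bindpoly_io_error")
    raw[[col]] <- v
  }
  if (schema == "titration") {
    sums <- rowSums(raw[, c("f0", "f1", "f2", "f3")])
    if (any(abs(sums - 1) > 0.02))
      stop_bindpoly(sprintf(
        "fraction rows deviate from sum 1 by more than 2%%: data line %s",
        paste(which(abs(sums - 1) > 0.02), collapse = ", ")),
        "bindpoly_io_error")
    if (any(abs(sums - 1) > 1e-12)) {
      warning("fraction rows renormalised to sum exactly to 1", call. = FALSE)
      raw[, c("f0", "f1", "f2", "f3")] <-
        raw[, c("f0", "f1", "f2", "f3")] / sums
    }
  }
  if (schema == "footprint" &&
      !all(raw$strand %in% c("top", "bottom")))
    stop_bindpoly("footprint strand must be 'top' or 'bottom'",
                  "bindpoly_io_error")
  raw
}

#' Write an analysis table
#'
#' Writes a data frame in the package's TSV dialect (tab-separated, no
#' quoting, no row names). [load_table()] on the result is an identity.
#'
#' @param data A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(data, path) {
  utils::write.table(data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Run one pipeline stage and write its JSON report
#'
#' Thin driver over the analysis functions, for scripted use: executes one
#' stage on a TSV input, writes a JSON report plus a plain-text log into
#' `output_dir`, and returns the report. Identical input, configuration and
#' seed give byte-identical reports (no timestamps; every stochastic stage
#' records its seed).
#'
#' Subcommands:
#' \describe{
#'   \item{`simulate`}{Write a simulated titration (`Ka`, `grid`, `dna_uM`,
#'     `reps`, `noise`).}
#'   \item{`fit-single`}{Hyperbolic fit of a `binding_curve` table.}
#'   \item{`fit-multi`}{Three-site fit of each replicate of a `titration`
#'     table.}
#'   \item{`coop`}{Full cooperativity analysis of a `titration` table:
#'     per-replicate fits, bootstrap, verdicts, Ka/Kd.}
#'   \item{`kinetics`}{Dissociation-chase analysis of a `decay` table
#'     (`background` option).}
#'   \item{`spr`}{Steady-state fit of an `spr` table.}
#'   \item{`footprint`}{Per-base percent change of a `footprint` table
#'     (`threshold` option), per strand.}
#' }
#'
#' @param command Subcommand name (see Details).
#' @param input Path to the input TSV (not used by `simulate`).
#' @param output_dir Directory for the report and log (created if needed).
#' @param seed Integer seed; mandatory for stochastic stages (`simulate`,
#'   `coop`).
#' @param config Named list of stage options: `ligand_conservation`,
#'   `triple_term`, `n_boot`, `threshold`, `background`, `fix_bmax`, `Ka`,
#'   `K`, `grid`, `dna_uM`, `reps`, `noise`.
#' @return The report, a list of class `"run_report"`, invisibly. On stage
#'   failure the error is logged to `output_dir` and re-raised.
#' @export
run_pipeline <- function(command, input = NULL, output_dir, seed = NULL,
                         config = list()) {
  commands <- c("simulate", "fit-single", "fit-multi", "coop", "kinetics",
                "spr", "footprint")
  if (length(command) != 1 || !command %in% commands)
    stop_bindpoly(paste0("unknown command '", command, "'; expected one of: ",
                         paste(commands, collapse = ", ")),
                  "bindpoly_usage_error")
  if (!dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  log_path <- file.path(output_dir, paste0(command, ".log"))
  report_path <- file.path(output_dir, paste0(command, "-report.json"))
  cfg <- function(name, default) config[[name]] %||% default

  result <- tryCatch(
    switch(command,
      "simulate" = {
        sim <- simulate_titration(
          Ka = cfg("Ka", 1.2), K = cfg("K", NULL),
          grid = cfg("grid", seq(0.1, 1.3, length.out = 12)),
          dna_uM = cfg("dna_uM", 0.02), reps = cfg("reps", 1),
          noise = cfg("noise", 300), seed = seed)
        out <- file.path(output_dir, "titration.tsv")
        write_table(sim, out)
        # report the table relative to the run directory so identical runs
        # into different directories produce identical reports
        list(table = "titration.tsv", n_rows = nrow(sim))
      },
      "fit-single" = {
        d <- load_table(input, "binding_curve")
        fit <- fit_hyperbola(d$x_uM, d$y, fix_bmax = cfg("fix_bmax", NULL))
        list(Kd = fit$Kd, Bmax = fit$Bmax, se = as.list(fit$se),
             rss = fit$rss, poorly_constrained = fit$poorly_constrained)
      },
      "fit-multi" = {
        d <- load_table(input, "titration")
        fits <- lapply(split(d, d$replicate), fit_macroscopic,
                       ligand_conservation = cfg("ligand_conservation", "total"))
        lapply(fits, function(f)
          list(K = as.list(coef(f)), se = as.list(f$se), rss = f$rss))
      },
      "coop" = {
        d <- load_table(input, "titration")
        lc <- cfg("ligand_conservation", "total")
        fits <- lapply(split(d, d$replicate), fit_macroscopic,
                       ligand_conservation = lc)
        boot <- bootstrap_uncertainty(d, n_boot = cfg("n_boot", 1000),
                                      seed = seed, ligand_conservation = lc)
        rep <- assess_cooperativity(fits, boot)
        list(K = as.list(rep$K_mean),
             se = lapply(fits, function(f) as.list(f$se)),
             r2 = list(mean = rep$r2_mean, sd = rep$r2_sd,
                       boot_sd = rep$r2_boot_sd),
             r3 = list(mean = rep$r3_mean, sd = rep$r3_sd,
                       boot_sd = rep$r3_boot_sd),
             verdicts = list(event2 = rep$verdict2, event3 = rep$verdict3),
             Ka = list(mean = rep$Ka_mean, sd = rep$Ka_sd),
             Kd = rep$Kd, n_boot = rep$n_bootstrap, seed = seed)
      },
      "kinetics" = {
        d <- load_table(input, "decay")
        fit <- fit_dissociation(d$time_s, d$fraction_complex,
                                background = cfg("background", 0))
        list(koff = fit$koff, t_half_s = fit$t_half,
             is_upper_bound = fit$is_upper_bound,
             background_used = fit$background_used)
      },
      "spr" = {
        d <- load_table(input, "spr")
        fit <- fit_spr_steady_state(d$conc_uM, d$Req_RU)
        list(Kd = fit$Kd, Rmax = fit$Bmax, se = as.list(fit$se),
             rss = fit$rss)
      },
      "footprint" = {
        d <- load_table(input, "footprint")
        thr <- cfg("threshold", 20)
        per_strand <- lapply(split(d, d$strand), function(s) {
          free <- lane_profile(s$base_index, s$intensity_free, s$base,
                               s$strand[1])
          cplx <- lane_profile(s$base_index, s$intensity_complex, s$base,
                               s$strand[1])
          nm <- normalize_profiles(free, cplx)
          rep <- percent_change(nm$free, nm$complexed, threshold = thr)
          list(scale = nm$scale, threshold = thr,
               base_index = rep$base_index,
               percent_change = rep$percent_change,
               classification = rep$classification)
        })
        per_strand
      }),
    error = function(e) {
      writeLines(c(paste0("stage: ", command), paste0("status: error"),
                   paste0("message: ", conditionMessage(e))), log_path)
      stop(e)
    })

  report <- list(
    stage = command,
    package_version = as.character(utils::packageVersion("bindpoly")),
    input = if (is.null(input)) NULL else unname(tools::md5sum(input)),
    parameters = c(config, list(seed = seed)),
    warnings = character(0),
    results = result
  )
  class(report) <- "run_report"
  jsonlite::write_json(unclass(report), report_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  writeLines(c(paste0("stage: ", command), "status: ok",
               paste0("report: ", report_path)), log_path)
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline report: stage '%s' (bindpoly %s)\n",
              x$stage, x$package_version))
  utils::str(x$results, max.level = 2, give.attr = FALSE)
  invisible(x)
}
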