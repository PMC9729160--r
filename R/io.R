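CHILD_COLS <- c("child_id", "source", "sex", "family_history", "hla_group",
                "diagnosis_age_years", "last_followup_age_years")
VISIT_COLS <- c("child_id", "age_years", "iaa_mULN", "gada_mULN", "ia2a_mULN")

#' Read and validate the two cohort tables
#'
#' `children.csv` holds one row per child (`child_id`, `source`, `sex`,
#' `family_history`, `hla_group`, `diagnosis_age_years` with an empty field
#' for no diagnosis, `last_followup_age_years`); `visits.csv` holds one row
#' per antibody-measurement visit (`child_id`, `age_years`, `iaa_mULN`,
#' `gada_mULN`, `ia2a_mULN`). Duplicate child ids, visits of unknown
#' children, duplicated (child, age) pairs, negative levels and a diagnosis
#' after the last follow-up are hard errors naming the offending rows.
#'
#' @param children_path,visits_path CSV file paths.
#' @return List with validated `children` and `visits` data.frames (visits
#'   age-ordered within child), classed `iab_cohort`.
#' @export
read_cohort <- function(children_path, visits_path) {
  for (p in c(children_path, visits_path)) {
    if (!file.exists(p)) stop_input("input file not found: ", p)
  }
  children <- utils::read.csv(children_path, stringsAsFactors = FALSE)
  visits <- utils::read.csv(visits_path, stringsAsFactors = FALSE)
  check_schema(children, CHILD_COLS, children_path)
  check_schema(visits, VISIT_COLS, visits_path)

  children$family_history <- as.logical(children$family_history)
  children$diagnosis_age_years <- as.numeric(children$diagnosis_age_years)

  dup <- duplicated(children$child_id)
  if (any(dup)) {
    stop_input("duplicate child_id in children table: ",
               paste(unique(children$child_id[dup]), collapse = ", "))
  }
  orphan <- !visits$child_id %in% children$child_id
  if (any(orphan)) {
    stop_input("visits reference unknown child_id (rows ",
               paste(utils::head(which(orphan), 10), collapse = ", "), ")")
  }
  dupv <- duplicated(visits[, c("child_id", "age_years")])
  if (any(dupv)) {
    stop_input("duplicated (child_id, age_years) in visits (rows ",
               paste(utils::head(which(dupv), 10), collapse = ", "), ")")
  }
  neg <- visits$iaa_mULN < 0 | visits$gada_mULN < 0 | visits$ia2a_mULN < 0
  if (any(neg, na.rm = TRUE)) {
    stop_input("negative antibody levels in visits (rows ",
               paste(utils::head(which(neg), 10), collapse = ", "), ")")
  }
  bad_dx <- !is.na(children$diagnosis_age_years) &
    children$diagnosis_age_years > children$last_followup_age_years
  if (any(bad_dx)) {
    stop_input("diagnosis after last follow-up for child(ren): ",
               paste(children$child_id[bad_dx], collapse = ", "))
  }
  visits <- visits[order(visits$child_id, visits$age_years), , drop = FALSE]
  rownames(visits) <- NULL
  structure(list(children = children, visits = visits,
                 truth = NULL, config = NULL),
            class = "iab_cohort")
}

check_schema <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  extra <- setdiff(names(df), cols)
  if (length(missing) || length(extra)) {
    stop_input("schema mismatch in ", path,
               if (length(missing)) paste0("; missing columns: ",
                                           paste(missing, collapse = ", ")),
               if (length(extra)) paste0("; unexpected columns: ",
                                         paste(extra, collapse = ", ")))
  }
}

#' Write a cohort to the standard tables
#'
#' Writes `children.csv` and `visits.csv` (plain UTF-8, '.' decimal) and,
#' when generator truth is attached, `truth.json` with the generating
#' parameters and per-child latents.
#'
#' @param cohort `iab_cohort` (or list with `children`/`visits`).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$children[, CHILD_COLS],
                   file.path(dir, "children.csv"), row.names = FALSE)
  utils::write.csv(cohort$visits[, VISIT_COLS],
                   file.path(dir, "visits.csv"), row.names = FALSE)
  if (!is.null(cohort$truth)) {
    jsonlite::write_json(
      list(risk_betas = cohort$truth$risk_betas,
           latents = cohort$truth$latents,
           mode = cohort$config$mode %||% NA,
           seed = cohort$config$seed %||% NA),
      file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE,
      dataframe = "columns")
  }
  invisible(dir)
}

write_manifest <- function(dir, stage, seed, extra = list()) {
  manifest <- c(list(
    stage = stage, seed = seed,
    package_version = as.character(utils::packageVersion("iabhorizon")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
  jsonlite::write_json(manifest, file.path(dir, paste0("manifest_", stage, ".json")),
                       digits = NA, auto_unbox = TRUE)
  invisible(manifest)
}

#' Command-line style entry point
#'
#' Thin dispatcher over the package surface so the pipeline can be driven
#' from a shell wrapper or scripted end to end. Subcommands:
#' \describe{
#'   \item{`simulate`}{`--n N --seed S --out DIR [--mode longitudinal]`;
#'     writes `children.csv`, `visits.csv`, `truth.json`.}
#'   \item{`preprocess`}{`--out DIR`; reads the cohort tables in DIR and
#'     writes `seroconversion.csv`.}
#'   \item{`battery`}{`--out DIR [--T 10 --seed S --B N]`; writes
#'     `results_battery.csv` (nine rows).}
#'   \item{`t-sweep`}{`--out DIR [--seed S --B N]`; writes
#'     `results_t_sweep.csv`.}
#'   \item{`tw-grid`}{`--out DIR [--seed S]`; writes `results_tw_grid.csv`
#'     and the `grid.tsv` matrix (test interval W by follow-up period T).}
#'   \item{`report`}{`--out DIR`; prints a digest of result files found.}
#' }
#' Every stage writes a `manifest_<stage>.json` with the seed and package
#' version, and logs counts (instances, events, censored) via `message()`.
#'
#' @param args Character vector of arguments, e.g.
#'   `c("simulate", "--n", "200", "--seed", "7", "--out", "d")`.
#' @return Integer exit code, 0 on success (invisibly).
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    if (!length(args)) {
      message(cli_usage())
      return(invisible(1L))
    }
    cmd <- args[[1]]
    opts <- parse_cli_flags(args[-1])
    out <- opts$out %||% stop_input("--out DIR is required")
    seed <- as.integer(opts$seed %||% 1L)
    switch(cmd,
      "simulate" = {
        cfg <- cohort_config(n_children = as.integer(opts$n %||% 1500L),
                             seed = seed,
                             mode = opts$mode %||% "longitudinal")
        coh <- generate_cohort(cfg)
        write_cohort(coh, out)
        write_manifest(out, "simulate", seed,
                       list(n_children = cfg$n_children, mode = cfg$mode))
        message(sprintf("simulate: wrote %d children, %d visits to %s",
                        nrow(coh$children), nrow(coh$visits), out))
      },
      "preprocess" = {
        coh <- read_cohort(file.path(out, "children.csv"),
                           file.path(out, "visits.csv"))
        sc <- seroconversion_records(coh$children, coh$visits)
        utils::write.csv(sc, file.path(out, "seroconversion.csv"),
                         row.names = FALSE)
        write_manifest(out, "preprocess", seed,
                       list(n_children = nrow(coh$children),
                            n_retained = nrow(sc)))
        message(sprintf("preprocess: %d of %d children have confirmed seroconversion",
                        nrow(sc), nrow(coh$children)))
      },
      "battery" = {
        coh <- read_cohort(file.path(out, "children.csv"),
                           file.path(out, "visits.csv"))
        res <- covariate_battery(coh, horizon = as.numeric(opts$T %||% 10),
                                 seed = seed, B = as.integer(opts$B %||% 1000L))
        utils::write.csv(res, file.path(out, "results_battery.csv"),
                         row.names = FALSE)
        write_manifest(out, "battery", seed, list(T = as.numeric(opts$T %||% 10)))
        message(sprintf("battery: %d covariate sets evaluated; n = %d, events = %d",
                        nrow(res), res$n[1], res$events[1]))
      },
      "t-sweep" = {
        coh <- read_cohort(file.path(out, "children.csv"),
                           file.path(out, "visits.csv"))
        res <- t_sweep(coh, seed = seed, B = as.integer(opts$B %||% 1000L))
        utils::write.csv(res, file.path(out, "results_t_sweep.csv"),
                         row.names = FALSE)
        write_manifest(out, "t-sweep", seed)
        message(sprintf("t-sweep: %d (model, T) cells evaluated", nrow(res)))
      },
      "tw-grid" = {
        coh <- read_cohort(file.path(out, "children.csv"),
                           file.path(out, "visits.csv"))
        res <- tw_grid(coh, seed = seed)
        utils::write.csv(res, file.path(out, "results_tw_grid.csv"),
                         row.names = FALSE)
        m <- grid_matrix(res)
        utils::write.table(data.frame(W = rownames(m), m, check.names = FALSE),
                           file.path(out, "grid.tsv"), sep = "\t",
                           row.names = FALSE, quote = FALSE)
        write_manifest(out, "tw-grid", seed, list(n_cells = nrow(res)))
        message(sprintf("tw-grid: %d cells evaluated", nrow(res)))
      },
      "report" = {
        files <- list.files(out, pattern = "^results_.*\\.csv$", full.names = TRUE)
        if (!length(files)) stop_input("no result files in ", out)
        for (fp in files) {
          res <- utils::read.csv(fp)
          message(sprintf("%s: %d rows, mean C range %.3f-%.3f",
                          basename(fp), nrow(res),
                          min(res$mean_c, na.rm = TRUE),
                          max(res$mean_c, na.rm = TRUE)))
        }
      },
      stop_input("unknown subcommand '", cmd, "'\n", cli_usage())
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}

cli_usage <- function() {
  paste("usage: iabhorizon <simulate|preprocess|battery|t-sweep|tw-grid|report>",
        "[--n N] [--seed S] [--T YEARS] [--B N] [--mode MODE] --out DIR")
}

parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop_input("unexpected argument '", a, "'\n", cli_usage())
    if (i == length(args)) stop_input("flag '", a, "' needs a value")
    opts[[substring(a, 3)]] <- args[[i + 1L]]
    i <- i + 2L
  }
  opts
}
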