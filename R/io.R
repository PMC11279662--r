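# Dataset and configuration I/O plus pipeline orchestration. Canonical files
# are NONMEM-style CSVs: hours, ug/L, decimal point, comma separator, header
# required; missing DV coded ".". An optional declared-units header line
# ("# units: ug/mL") triggers conversion on import.

.required_cols <- c("ID", "TIME", "AMT", "DV", "EVID", "MDV")

#' Read an analysis-ready PK dataset
#'
#' Validates and sorts a NONMEM-style CSV: required columns `ID`, `TIME`,
#' `AMT`, `DV`, `EVID`, `MDV` plus covariates; `DV` values of `"."` map to
#' missing; every subject must carry exactly one dose record. Concentrations
#' are converted to the internal ug/L scale when the file declares
#' `# units: ug/mL` on its first line (or `conc_units = "ug/mL"` is given).
#'
#' @param path CSV path.
#' @param conc_units Concentration units in the file: `"ug/L"` (default) or
#'   `"ug/mL"`.
#' @return A `pk_dataset` tibble sorted by (`ID`, `TIME`), dose records first.
#' @export
read_pkdataset <- function(path, conc_units = c("ug/L", "ug/mL")) {
  conc_units <- match.arg(conc_units)
  first <- readLines(path, n = 1)
  skip <- 0
  if (grepl("^#", first)) {
    skip <- 1
    if (grepl("ug/mL", first, fixed = TRUE)) conc_units <- "ug/mL"
  }
  raw <- utils::read.csv(path, skip = skip, na.strings = c("NA", ""),
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(.required_cols, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dv <- raw$DV
  if (is.character(dv)) {
    dv[dv == "."] <- NA
    dv <- suppressWarnings(as.numeric(dv))
  }
  bad <- which(raw$EVID == 0 & raw$MDV == 0 & (is.na(dv) & raw$DV != "." | is.na(raw$TIME)))
  raw$DV <- dv
  if (conc_units == "ug/mL") raw$DV <- raw$DV * 1000
  raw$MDV[is.na(raw$DV) & raw$EVID == 0] <- 1L
  if (!"TRUNC" %in% names(raw)) raw$TRUNC <- FALSE
  dat <- tibble::as_tibble(raw)
  # validation
  prob <- character()
  ids <- unique(dat$ID)
  ndose <- table(factor(dat$ID[dat$EVID == 1], levels = ids))
  nodose <- names(ndose)[ndose == 0]
  if (length(nodose)) {
    stop("subject(s) without dose record (EVID=1): ",
         paste(nodose, collapse = ", "), call. = FALSE)
  }
  multidose <- names(ndose)[ndose > 1]
  if (length(multidose)) {
    stop("subject(s) with multiple dose records: ",
         paste(multidose, collapse = ", "), call. = FALSE)
  }
  dat <- dplyr::arrange(dat, .data$ID, .data$TIME, dplyr::desc(.data$EVID))
  dup <- dat |>
    dplyr::filter(.data$EVID == 0) |>
    dplyr::count(.data$ID, .data$TIME) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    warning("duplicate observation times for subject(s): ",
            paste(unique(dup$ID), collapse = ", "))
  }
  class(dat) <- c("pk_dataset", class(tibble::tibble()))
  dat
}

#' Write a PK dataset to CSV
#'
#' Canonical NONMEM-style CSV (hours, ug/L, `"."` for missing DV) with a
#' units header line.
#'
#' @param data A `pk_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pkdataset <- function(data, path) {
  out <- as.data.frame(data)
  out$DV <- ifelse(is.na(out$DV), ".", format(out$DV, digits = 12, trim = TRUE,
                                              scientific = FALSE))
  con <- file(path, "w")
  writeLines("# units: h, ug/L", con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, na = "")
  close(con)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> NCA -> SAEM fit -> covariate selection -> diagnostics
#' in order, writing each stage's artifacts (CSV/JSON) to `out_dir` together
#' with a manifest recording seeds and stage settings. When `config$data`
#' names an existing dataset file the simulate stage is skipped and the file
#' is fitted directly (the external-validation path).
#'
#' @param config Either a list or a YAML file path with (all optional)
#'   entries: `data` (input CSV), `seed`, `n_subjects`, `select` (logical:
#'   run covariate selection), `candidates` (covariate columns), `n_explore`,
#'   `n_smooth`, `n_is`, `k_sim`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the stage results (`data`, `nca`, `fit`,
#'   `selection`, `residuals`, `vpc`, `manifest`).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    data = NULL, seed = 1L, n_subjects = NULL, select = FALSE,
    candidates = c("AGE", "WT", "SEX"), n_explore = 300, n_smooth = 150,
    n_is = 2000, k_sim = 200
  ), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = as.character(utils::packageVersion("salbupop")),
    r_version = R.version.string,
    seed = cfg$seed, settings = cfg,
    design = unclass(default_design()),
    fit_defaults = list(model = "2cmt", fixed = c(V1 = 1),
                        corr = "ka-Q", error = "combined-1",
                        init = "curve-stripping multistart"),
    stages = character())

  if (!is.null(cfg$data)) {
    dat <- read_pkdataset(cfg$data)
    manifest$stages <- c(manifest$stages, "load")
  } else {
    cohort <- if (is.null(cfg$n_subjects)) default_virtual_cohort() else
      sample_cohort(n = cfg$n_subjects, seed = cfg$seed)
    dat <- simulate_dataset(cohort, default_pop_model(), default_design(),
                            seed = cfg$seed)
    write_pkdataset(dat, file.path(out_dir, "simulated_data.csv"))
    manifest$stages <- c(manifest$stages, "simulate")
  }

  nca_res <- nca(dat)
  readr::write_csv(nca_res, file.path(out_dir, "nca.csv"))
  manifest$stages <- c(manifest$stages, "nca")

  settings <- saem_settings(n_explore = cfg$n_explore, n_smooth = cfg$n_smooth,
                            seed = cfg$seed)
  fit <- fit_saem(dat, settings = settings)
  fit <- loglik_importance(fit, n_is = cfg$n_is, seed = cfg$seed + 1L)
  fit <- standard_errors(fit)
  readr::write_csv(tidy(fit), file.path(out_dir, "estimates.csv"))
  readr::write_csv(glance(fit), file.path(out_dir, "fit_summary.csv"))
  manifest$stages <- c(manifest$stages, "fit")

  selection <- NULL
  if (isTRUE(cfg$select)) {
    selection <- stepwise_select(dat, candidates = cfg$candidates,
                                 settings = saem_settings(
                                   n_explore = max(100, cfg$n_explore %/% 3),
                                   n_smooth = max(50, cfg$n_smooth %/% 3),
                                   seed = cfg$seed),
                                 n_is = cfg$n_is %/% 2)
    readr::write_csv(selection$trace, file.path(out_dir, "selection_trace.csv"))
    fit <- selection$fit
    manifest$stages <- c(manifest$stages, "select")
  }

  res <- residual_table(fit, K_sim = cfg$k_sim, seed = cfg$seed + 2L)
  readr::write_csv(res, file.path(out_dir, "residuals.csv"))
  vp <- vpc(fit, K_sim = cfg$k_sim, seed = cfg$seed + 3L)
  readr::write_csv(vp, file.path(out_dir, "vpc.csv"))
  manifest$stages <- c(manifest$stages, "diagnose")

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(data = dat, nca = nca_res, fit = fit, selection = selection,
                 residuals = res, vpc = vp, manifest = manifest))
}
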