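# Dataset dialect: CSV with header and columns
#   ID, TIME (h), AMT (mg), RATE (mg/h), DV (ug/mL), EVID (1 dose / 0
#   observation), BLQ (0/1), WT (kg), COHORT, PART.
# Dose rows carry AMT > 0, EVID = 1 and an empty DV; observation rows carry
# EVID = 0 and an empty AMT. Missing DV is an empty field, never 0 — BLQ is
# a separate flag. All numeric fields use the dot decimal separator.

pk_dialect_cols <- c("ID", "TIME", "AMT", "RATE", "DV", "EVID", "BLQ", "WT",
                     "COHORT", "PART")

#' Write / read a concentration dataset (NONMEM-style CSV)
#'
#' The on-disk dialect has columns `ID, TIME, AMT, RATE, DV, EVID, BLQ, WT,
#' COHORT, PART`; in memory the same data use lower-case names. Reading is
#' strict: unknown or missing columns, malformed numerics (reported with row
#' and column), dose rows with a non-empty DV, duplicated
#' `(ID, TIME, EVID)` rows, negative or out-of-order times all raise errors.
#'
#' @param pk A pk tibble (e.g. the `pk` element of [simulate_trial()]).
#' @param path CSV file path.
#' @return `read_pk_dataset()` returns the validated tibble with columns
#'   `id, time, amt, rate, dv, evid, blq, wt, cohort, part`.
#' @export
write_pk_dataset <- function(pk, path) {
  check_columns(pk, tolower(pk_dialect_cols), "pk data")
  out <- pk[, tolower(pk_dialect_cols)]
  names(out) <- pk_dialect_cols
  out$BLQ <- as.integer(out$BLQ)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

parse_num_col <- function(raw, col, required = FALSE) {
  x <- raw[[col]]
  bad <- which(!is.na(x) & x != "" &
                 !grepl("^[+-]?([0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?)$", x))
  if (length(bad)) {
    stop_phasepk(sprintf("malformed numeric in column %s, row(s) %s", col,
                         paste(head(bad, 5), collapse = ", ")))
  }
  empty <- is.na(x) | x == ""
  if (required && any(empty)) {
    stop_phasepk(sprintf("missing value in required column %s, row(s) %s",
                         col, paste(head(which(empty), 5), collapse = ", ")))
  }
  out <- rep(NA_real_, length(x))
  out[!empty] <- as.numeric(x[!empty])
  out
}

#' @rdname write_pk_dataset
#' @export
read_pk_dataset <- function(path) {
  if (!file.exists(path)) stop_phasepk(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  unknown <- setdiff(names(raw), pk_dialect_cols)
  if (length(unknown)) {
    stop_phasepk(sprintf("unknown column(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(pk_dialect_cols, names(raw))
  if (length(missing)) {
    stop_phasepk(sprintf("missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(
    id = raw$ID,
    time = parse_num_col(raw, "TIME", required = TRUE),
    amt = parse_num_col(raw, "AMT"),
    rate = parse_num_col(raw, "RATE"),
    dv = parse_num_col(raw, "DV"),
    evid = parse_num_col(raw, "EVID", required = TRUE),
    blq = parse_num_col(raw, "BLQ"),
    wt = parse_num_col(raw, "WT"),
    cohort = raw$COHORT, part = raw$PART)
  if (any(!out$evid %in% c(0, 1))) {
    stop_phasepk(sprintf("EVID must be 0 or 1; offending row(s) %s",
                         paste(head(which(!out$evid %in% c(0, 1)), 5),
                               collapse = ", ")))
  }
  out$evid <- as.integer(out$evid)
  if (any(!is.na(out$blq) & !out$blq %in% c(0, 1))) {
    stop_phasepk("BLQ must be 0 or 1")
  }
  out$blq <- !is.na(out$blq) & out$blq == 1
  if (any(out$time < 0)) {
    stop_phasepk(sprintf("negative TIME in row(s) %s",
                         paste(head(which(out$time < 0), 5), collapse = ", ")))
  }
  dose <- out$evid == 1
  if (any(dose & !is.na(out$dv))) {
    stop_phasepk(sprintf("dose rows (EVID=1) must have an empty DV; row(s) %s",
                         paste(head(which(dose & !is.na(out$dv)), 5),
                               collapse = ", ")))
  }
  if (any(dose & (is.na(out$amt) | out$amt <= 0))) {
    stop_phasepk("dose rows must carry AMT > 0")
  }
  if (any(!dose & !is.na(out$amt) & out$amt != 0)) {
    stop_phasepk("observation rows must not carry a dose amount")
  }
  key <- paste(out$id, out$time, out$evid)
  if (anyDuplicated(key)) {
    stop_phasepk(sprintf("duplicated (ID, TIME, EVID) in row(s) %s",
                         paste(head(which(duplicated(key)), 5),
                               collapse = ", ")))
  }
  bad_order <- unlist(lapply(split(seq_len(nrow(out)), out$id), function(ix) {
    ix[c(FALSE, diff(out$time[ix]) < 0)]
  }))
  if (length(bad_order)) {
    stop_phasepk(sprintf("out-of-order TIME within subject, row(s) %s",
                         paste(head(sort(bad_order), 5), collapse = ", ")))
  }
  out
}

write_stream_csv <- function(data, path, upper_cols) {
  out <- data[, tolower(upper_cols)]
  names(out) <- upper_cols
  for (cl in names(out)) {
    if (is.logical(out[[cl]])) out[[cl]] <- as.integer(out[[cl]])
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

read_stream_csv <- function(path, upper_cols, num_cols, logical_cols) {
  if (!file.exists(path)) stop_phasepk(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!setequal(names(raw), upper_cols)) {
    stop_phasepk(sprintf("expected columns %s",
                         paste(upper_cols, collapse = ", ")))
  }
  out <- tibble::as_tibble(raw[, upper_cols])
  names(out) <- tolower(upper_cols)
  for (cl in tolower(num_cols)) out[[cl]] <- parse_num_col(out, cl)
  for (cl in tolower(logical_cols)) {
    out[[cl]] <- !is.na(out[[cl]]) & out[[cl]] == 1
  }
  out
}

ro_cols <- c("ID", "TIME", "ASSAY", "VALUE", "CONC", "ANOMALOUS", "COHORT",
             "PART")
ae_cols <- c("ID", "TERM", "GRADE", "RELATED", "SERIOUS", "WITHDRAWAL",
             "INTERRUPTION", "IMMUNE_RELATED", "COHORT", "PART")
resp_cols <- c("ID", "TIME", "CATEGORY", "COHORT", "PART")

#' Write / read a full synthetic trial (one CSV per stream)
#'
#' `write_trial()` writes `pk.csv` (the dialect of [write_pk_dataset()]),
#' `ro.csv`, `ae.csv`, `response.csv` and `subjects.csv` into `dir`;
#' `read_trial()` reads them back.
#'
#' @param trial A [simulate_trial()] result.
#' @param dir Directory (created if needed).
#' @return `read_trial()` returns a list with elements `pk`, `ro`, `ae`,
#'   `response`, `subjects`.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "trial_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_pk_dataset(trial$pk, file.path(dir, "pk.csv"))
  write_stream_csv(trial$ro, file.path(dir, "ro.csv"), ro_cols)
  write_stream_csv(trial$ae, file.path(dir, "ae.csv"), ae_cols)
  write_stream_csv(trial$response, file.path(dir, "response.csv"), resp_cols)
  readr::write_csv(trial$subjects, file.path(dir, "subjects.csv"), na = "")
  invisible(dir)
}

#' @rdname write_trial
#' @export
read_trial <- function(dir) {
  ae <- read_stream_csv(file.path(dir, "ae.csv"), ae_cols,
                        num_cols = "GRADE",
                        logical_cols = c("RELATED", "SERIOUS", "WITHDRAWAL",
                                         "INTERRUPTION", "IMMUNE_RELATED"))
  ae$grade <- as.integer(ae$grade)
  list(pk = read_pk_dataset(file.path(dir, "pk.csv")),
       ro = read_stream_csv(file.path(dir, "ro.csv"), ro_cols,
                            num_cols = c("TIME", "VALUE", "CONC"),
                            logical_cols = "ANOMALOUS"),
       ae = ae,
       response = read_stream_csv(file.path(dir, "response.csv"), resp_cols,
                                  num_cols = "TIME",
                                  logical_cols = character()),
       subjects = tibble::as_tibble(
         utils::read.csv(file.path(dir, "subjects.csv"))))
}

#' Serialize / read a trial configuration (YAML)
#'
#' The configuration round-trips through YAML; reading re-validates it via
#' [trial_config()], so a file with missing keys fails with the key named.
#'
#' @param config A [trial_config()].
#' @param path YAML file path.
#' @return `read_trial_config()` returns a [trial_config()].
#' @export
write_trial_config <- function(config, path) {
  stopifnot(inherits(config, "trial_config"))
  x <- unclass(config)
  x$cohorts <- lapply(as.list(x$cohorts), as.vector)
  x$typical <- lapply(unclass(x$typical), as.numeric)
  x$omega2 <- as.list(x$omega2)
  x$ae$related <- lapply(as.list(x$ae$related), as.vector)
  x$ae$background <- lapply(as.list(x$ae$background), as.vector)
  # named numeric vectors must go out as maps or YAML drops the names
  x$response$probs <- lapply(x$response$probs, as.list)
  x$omega2 <- as.list(x$omega2)
  # full double precision so a run is exactly reproducible from the snapshot
  yaml::write_yaml(x, path, precision = 17)
  invisible(path)
}

#' @rdname write_trial_config
#' @export
read_trial_config <- function(path) {
  x <- yaml::read_yaml(path)
  needed <- c("cohorts", "typical", "theta_wt", "ref_weight", "omega2",
              "residual", "lloq", "weight", "schedule", "jitter_frac", "ro",
              "ae", "response", "ada", "cycles")
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    stop_phasepk(sprintf("config file is missing key(s): %s",
                         paste(missing, collapse = ", ")))
  }
  ae <- x$ae
  ae$related <- tibble::as_tibble(ae$related)
  ae$background <- tibble::as_tibble(ae$background)
  resp <- x$response
  resp$probs <- lapply(resp$probs, unlist)
  resp$visits <- lapply(resp$visits, unlist)
  trial_config(
    cohorts = tibble::as_tibble(x$cohorts),
    typical = pk_params(x$typical$CL, x$typical$V1, x$typical$Q,
                        x$typical$V2),
    theta_wt = x$theta_wt, ref_weight = x$ref_weight,
    omega2 = unlist(x$omega2),
    residual = residual_error(x$residual$prop, x$residual$add),
    lloq = x$lloq, weight = x$weight, schedule = unlist(x$schedule),
    jitter_frac = x$jitter_frac, ro = x$ro, ae = ae, response = resp,
    ada = x$ada, cycles = unlist(x$cycles))
}

#' Run the full analysis pipeline on a synthetic trial
#'
#' Chains every stage on one generated dataset: simulation, dataset export,
#' per-subject NCA with cohort geometric summaries, dose-proportionality
#' assessment on the part-1 single-dose DLT cohorts, the two-stage
#' population fit with the clearance-weight test, virtual-population trough
#' simulation for both fixed-dose regimens with RO fold-margins, the
#' occupancy threshold summary, and the clinical tabulations. All outputs
#' are written under `dir` together with a YAML run log (config snapshot,
#' seed, package version, row counts) from which the run can be reproduced.
#'
#' @param config A [trial_config()].
#' @param seed Integer seed for the whole run.
#' @param dir Output directory.
#' @param n_sim Virtual-population size for the exposure simulation.
#' @param ro_threshold Full-RO concentration threshold, ug/mL, used for the
#'   exposure margins.
#' @return (Invisibly) a list with every stage result.
#' @export
run_pipeline <- function(config = trial_config(), seed = 1, dir, n_sim = 1000,
                         ro_threshold = 2.44) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  trial <- simulate_trial(config, seed = seed)
  write_trial(trial, file.path(dir, "data"))
  nca_tbl <- nca(trial$pk, meta = cohort_meta())
  readr::write_csv(nca_tbl, file.path(dir, "nca.csv"))
  nca_sum <- nca_summary(nca_tbl)
  readr::write_csv(nca_sum, file.path(dir, "nca_summary.csv"))
  dlt_nca <- dplyr::filter(nca_tbl, .data$cohort %in%
                             c("1 mg/kg DLT", "3 mg/kg DLT", "10 mg/kg DLT"))
  dlt_nca$dose_mg_kg <- dlt_nca$dose_mg / dlt_nca$wt
  dp <- dose_proportionality(dlt_nca, .data$dose_mg_kg)
  readr::write_csv(dp, file.path(dir, "dose_proportionality.csv"))
  model <- fit_poppk(trial$pk, seed = seed)
  write_poppk_model(model, file.path(dir, "poppk_model.yaml"))
  readr::write_csv(model$individual, file.path(dir, "poppk_individual.csv"))
  wtest <- weight_covariate_test(dplyr::filter(nca_tbl, !is.na(.data$cl_l_d)),
                                 .data$cl_l_d, .data$wt)
  readr::write_csv(wtest, file.path(dir, "weight_covariate_test.csv"))
  expo <- purrr::map_dfr(
    list(regimen_q3w(500), regimen_q6w(1000)), function(reg) {
      sim <- simulate_ctrough(model, reg, n = n_sim,
                              weight_dist = config$weight, seed = seed)
      summarize_exposure(sim$ctrough, ro_threshold = ro_threshold,
                         label = reg$label)
    })
  readr::write_csv(expo, file.path(dir, "exposure_summary.csv"))
  ro_sum <- min_full_ro_concentration(trial$ro)
  readr::write_csv(ro_sum$summary, file.path(dir, "ro_summary.csv"))
  aes <- summarize_aes(trial$ae,
                       dplyr::select(trial$subjects, "id", "part",
                                     group = "cohort"))
  readr::write_csv(aes$categories, file.path(dir, "ae_categories.csv"))
  readr::write_csv(aes$related_terms, file.path(dir, "ae_related_terms.csv"))
  bor <- best_overall_response(trial$response)
  part1_ids <- trial$subjects$id[trial$subjects$part == "1"]
  rates <- response_rates(bor$best_response[bor$id %in% part1_ids])
  readr::write_csv(rates, file.path(dir, "response_rates_part1.csv"))
  cfg_path <- file.path(dir, "config.yaml")
  write_trial_config(config, cfg_path)
  yaml::write_yaml(list(
    seed = seed, package = "phasepk",
    version = as.character(utils::packageVersion("phasepk")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_file = "config.yaml", n_sim = n_sim, ro_threshold = ro_threshold,
    rows = list(pk = nrow(trial$pk), ro = nrow(trial$ro),
                ae = nrow(trial$ae), response = nrow(trial$response)),
    outputs = list.files(dir, recursive = TRUE)),
    file.path(dir, "log.yaml"))
  invisible(list(trial = trial, nca = nca_tbl, nca_summary = nca_sum,
                 dose_proportionality = dp, model = model,
                 weight_test = wtest, exposure = expo, ro = ro_sum,
                 ae = aes, response_rates = rates))
}
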