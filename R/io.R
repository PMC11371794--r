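#' Read a simulation configuration from YAML
#'
#' The YAML file holds any subset of [sim_config()]'s arguments; missing
#' entries take the defaults.
#'
#' @param path YAML file path
#' @return a [sim_config()]
#' @export
read_sim_config_yaml <- function(path) {
  vals <- yaml::read_yaml(path) %||% list()
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop(sprintf("unknown sim_config fields in '%s': %s", path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  do.call(sim_config, vals)
}

#' Write a sub-group selection trace as JSON
#'
#' @param subgroup an [sffs_subgroup()] result
#' @param path output path
#' @return `path`, invisibly
#' @export
write_trace_json <- function(subgroup, path) {
  jsonlite::write_json(
    list(members = subgroup$members, cv_auc = subgroup$cv_auc,
         mu = subgroup$mu, trace = subgroup$trace),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write an evaluation report as JSON (plus a per-group CSV)
#'
#' @param report a [run_protocol()] result
#' @param path output JSON path; a CSV of the per-group table is written
#'   alongside with extension `.csv`
#' @return `path`, invisibly
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(
    list(protocol = report$protocol, aggregate = report$aggregate,
         per_user = report$per_user, seed = report$seed,
         config_hash = report$config_hash),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$per_user, sub("\\.json$", ".csv", path),
                   row.names = FALSE)
  invisible(path)
}

#' Write MIMC capability scores as CSV
#'
#' One row per (user, candidate) with `m_in`, `m_co` and the combined `m`.
#'
#' @param scores_list list of [mimc_scores()] results
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_capability_csv <- function(scores_list, path) {
  rows <- do.call(rbind, lapply(scores_list, function(s)
    data.frame(member = s$user_id, candidate = s$candidate_ids,
               m_in = s$m_in, m_co = s$m_co, m = s$m, row.names = NULL)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
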