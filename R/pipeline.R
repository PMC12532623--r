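# Orchestration: a serializable run configuration, cohort synthesis to
# disk, resumable all-pairs scoring to a long-format CSV, evaluation to
# JSON/CSV reports, and reliability summaries. Every command is a pure
# function of (config, seed); a provenance JSON (config hash, seed, package
# version) makes runs auditable.

#' Run configuration
#'
#' All tunable parameters of the pipeline in one serializable list:
#' `method` (akaze, orb or both), the synthesis parameters, both extractor
#' parameter sets, and the root seed. Round-trips through YAML via
#' [save_config()] / [load_config()]; unknown keys are rejected on load.
#'
#' @param method `"akaze"`, `"orb"` or `"both"`.
#' @param seed root seed.
#' @param n_cases cohort size for synthesis.
#' @param synth named list overriding [synth_params()] defaults.
#' @param orb named list overriding [orb_params()] defaults.
#' @param akaze named list overriding [akaze_params()] defaults.
#' @return a `run_config` list.
#' @export
run_config <- function(method = "both", seed = 1L, n_cases = 60L,
                       synth = list(), orb = list(), akaze = list()) {
  if (!method %in% c("akaze", "orb", "both")) stop("method must be akaze, orb or both")
  cfg <- list(method = method, seed = as.integer(seed),
              n_cases = as.integer(n_cases),
              synth = utils::modifyList(unclass(synth_params(seed = seed)), synth),
              orb = utils::modifyList(unclass(orb_params()), orb),
              akaze = utils::modifyList(unclass(akaze_params()), akaze))
  class(cfg) <- "run_config"
  cfg
}

config_methods <- function(cfg) {
  if (cfg$method == "both") c("akaze", "orb") else cfg$method
}

cfg_synth_params <- function(cfg) do.call(synth_params, cfg$synth)
cfg_method_params <- function(cfg, method) {
  if (method == "akaze") do.call(akaze_params, cfg$akaze) else do.call(orb_params, cfg$orb)
}

#' Save a run configuration as YAML
#' @param config a `run_config`.
#' @param path output `.yaml` path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Load a run configuration from YAML
#'
#' Unknown keys (at the top level or inside a parameter block) are rejected,
#' so a typo cannot silently fall back to a default.
#'
#' @param path `.yaml` file written by [save_config()].
#' @return a `run_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ref <- unclass(run_config())
  extra <- setdiff(names(raw), names(ref))
  if (length(extra) > 0L) stop("unknown config key(s): ", paste(extra, collapse = ", "))
  for (blk in c("synth", "orb", "akaze")) {
    extra <- setdiff(names(raw[[blk]]), names(ref[[blk]]))
    if (length(extra) > 0L)
      stop("unknown config key(s) in ", blk, ": ", paste(extra, collapse = ", "))
  }
  run_config(method = raw$method %||% "both", seed = raw$seed %||% 1L,
             n_cases = raw$n_cases %||% 60L,
             synth = raw$synth %||% list(), orb = raw$orb %||% list(),
             akaze = raw$akaze %||% list())
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  unname(tools::md5sum(tmp))
}

write_provenance <- function(config, dir) {
  prov <- list(config_hash = config_hash(config), seed = config$seed,
               package = "sinusid",
               version = as.character(utils::packageVersion("sinusid")))
  writeLines(paste0("{\n",
                    paste(sprintf('  "%s": "%s"', names(prov),
                                  unlist(prov)), collapse = ",\n"),
                    "\n}"), file.path(dir, "provenance.json"))
}

#' Synthesize a cohort to disk
#'
#' Generates the configured cohort and writes silhouette images, the
#' manifest CSV and a provenance JSON into `out_dir`.
#'
#' @param config a `run_config`.
#' @param out_dir output directory.
#' @param force overwrite a non-empty directory.
#' @return the manifest data frame, invisibly.
#' @export
run_synth <- function(config, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !force)
    stop("output directory is not empty (use force = TRUE): ", out_dir)
  cohort <- generate_cohort(config$n_cases, cfg_synth_params(config), dir = out_dir)
  write_provenance(config, out_dir)
  invisible(cohort$manifest)
}

#' Score all AM x PM pairs to a long-format CSV
#'
#' Writes one row per (AM case, PM case, method) with columns `am_id`,
#' `pm_id`, `method`, `score`, `n_matches`, `reason` (empty score plus a
#' reason for pairs where feature extraction failed). With `resume = TRUE`
#' rows already present in `out_csv` are kept and only missing pairs are
#' recomputed; the final file is identical to a clean run.
#'
#' @param manifest manifest data frame or CSV path.
#' @param out_csv output CSV path.
#' @param config a `run_config`.
#' @param resume reuse existing rows of `out_csv`.
#' @return the score data frame, invisibly.
#' @export
run_score <- function(manifest, out_csv, config = run_config(), resume = FALSE) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  missing_files <- manifest$case_id[!file.exists(manifest$am_path) |
                                      !file.exists(manifest$pm_path)]
  if (length(missing_files) > 0L)
    stop("missing image files for case(s): ", paste(missing_files, collapse = ", "))
  prev <- NULL
  if (resume && file.exists(out_csv)) {
    prev <- utils::read.csv(out_csv, stringsAsFactors = FALSE,
                            colClasses = c(reason = "character"))
    prev$reason[is.na(prev$reason)] <- ""
  }
  ids <- manifest$case_id
  rows <- list()
  for (method in config_methods(config)) {
    params <- cfg_method_params(config, method)
    feat_of <- function(path, sil_session) {
      img <- read_silhouette(path, session = sil_session)
      tryCatch(extract_features(img, method, params),
               sinusid_insufficient_features = function(e) conditionMessage(e))
    }
    have <- if (is.null(prev)) character(0) else
      paste(prev$am_id, prev$pm_id, prev$method)
    need_any <- !all(paste(rep(ids, each = length(ids)),
                           rep(ids, length(ids)), method) %in% have)
    fam <- fpm <- NULL
    if (need_any) {
      fam <- lapply(manifest$am_path, feat_of, sil_session = "AM")
      fpm <- lapply(manifest$pm_path, feat_of, sil_session = "PM")
    }
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      key <- paste(ids[i], ids[j], method)
      if (key %in% have) {
        rows[[key]] <- prev[paste(prev$am_id, prev$pm_id, prev$method) == key, ][1L, ]
        next
      }
      if (is.character(fam[[i]]) || is.character(fpm[[j]])) {
        reason <- if (is.character(fam[[i]])) fam[[i]] else fpm[[j]]
        rows[[key]] <- data.frame(am_id = ids[i], pm_id = ids[j], method = method,
                                  score = NA_real_, n_matches = NA_integer_,
                                  reason = reason)
      } else {
        s <- similarity_from_features(fam[[i]], fpm[[j]])
        rows[[key]] <- data.frame(am_id = ids[i], pm_id = ids[j], method = method,
                                  score = s$value, n_matches = s$n_matches,
                                  reason = "")
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$method, out$am_id, out$pm_id), , drop = FALSE]
  rownames(out) <- NULL
  utils::write.csv(out, out_csv, row.names = FALSE)
  invisible(out)
}

#' Evaluate a score table into subgroup reports
#'
#' Runs [tables_from_scores()] over all groupings for each method present
#' and writes a JSON report plus a tables-shaped CSV.
#'
#' @param scores_csv long-format score CSV from [run_score()] (or a
#'   published per-pair score table with the same columns).
#' @param manifest manifest data frame or CSV path.
#' @param out_json,out_csv optional output paths.
#' @return named list of `sinus_eval_report` per method.
#' @export
run_evaluate <- function(scores_csv, manifest, out_json = NULL, out_csv = NULL) {
  scores <- if (is.character(scores_csv))
    utils::read.csv(scores_csv, stringsAsFactors = FALSE) else scores_csv
  if (is.character(manifest)) manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  reports <- tables_from_scores(scores[!is.na(scores$score), , drop = FALSE],
                                manifest)
  all_rows <- do.call(rbind, lapply(names(reports), function(m) {
    cbind(method = m, reports[[m]]$rows)
  }))
  if (!is.null(out_csv)) utils::write.csv(all_rows, out_csv, row.names = FALSE)
  if (!is.null(out_json)) {
    json <- df_to_json(all_rows)
    writeLines(json, out_json)
  }
  reports
}

# minimal data-frame -> JSON records serializer (numbers unquoted)
df_to_json <- function(df) {
  recs <- vapply(seq_len(nrow(df)), function(i) {
    fields <- vapply(names(df), function(nm) {
      v <- df[[nm]][i]
      if (is.numeric(v)) sprintf('"%s": %.10g', nm, v)
      else sprintf('"%s": "%s"', nm, as.character(v))
    }, character(1))
    paste0("  {", paste(fields, collapse = ", "), "}")
  }, character(1))
  paste0("[\n", paste(recs, collapse = ",\n"), "\n]")
}

#' Reliability summary from a repeated-measures CSV
#'
#' @param repeats data frame or CSV with columns subject_id, m1, m2.
#' @param observer `"intra"` or `"inter"`.
#' @param out_json optional JSON output path.
#' @return a `sinus_reliability`.
#' @export
run_reliability <- function(repeats, observer = "intra", out_json = NULL) {
  if (is.character(repeats)) repeats <- utils::read.csv(repeats, stringsAsFactors = FALSE)
  res <- reliability_eval(repeats, observer = observer)
  if (!is.null(out_json)) {
    writeLines(sprintf(
      '{"tem": %.10g, "rtem_percent": %.10g, "R": %.10g, "n": %d, "rtem_pass": %s, "R_pass": %s}',
      res$tem, res$rtem_percent, res$R, res$n,
      tolower(res$rtem_pass), tolower(res$R_pass)), out_json)
  }
  res
}
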