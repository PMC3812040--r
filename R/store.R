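#' Keyword-annotated result store
#'
#' A result store is a directory of JSON index documents plus payload files
#' (CSV/JSON). Every stored result carries keyword tags, a config snapshot
#' and the seeds used, so any document can be reproduced and retrieved by
#' keyword query.
#'
#' @param dir Store directory (created if missing).
#' @return An object of class `result_store`.
#' @export
result_store <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  structure(list(dir = dir), class = "result_store")
}

#' Write a result document
#'
#' @param store A [result_store()].
#' @param stage Stage name (e.g. `"simulate"`, `"features"`, `"stats"`).
#' @param payload A data frame (written as CSV) or a list (written as JSON).
#' @param tags Non-empty character vector of keyword tags.
#' @param config Config snapshot (list), stored with the document.
#' @param seed Seed(s) used to produce the payload.
#' @return The document id, invisibly.
#' @export
store_write <- function(store, stage, payload, tags, config = list(),
                        seed = NA) {
  stopifnot(inherits(store, "result_store"), length(tags) >= 1)
  id <- sprintf("%s-%s", stage,
                format(Sys.time(), "%Y%m%d%H%M%OS3"))
  id <- gsub("[.]", "", id)
  is_df <- is.data.frame(payload)
  payload_file <- file.path(store$dir,
                            paste0(id, if (is_df) ".csv" else ".json"))
  if (is_df) {
    df <- as.data.frame(payload)
    for (cn in names(df)) # list-columns are serialized
      if (is.list(df[[cn]]))
        df[[cn]] <- vapply(df[[cn]], function(x)
          paste(signif(x, 8), collapse = ";"), "")
    utils::write.csv(df, payload_file, row.names = FALSE)
  } else {
    jsonlite::write_json(payload, payload_file, auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  doc <- list(id = id, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              stage = stage, tags = as.character(tags), config = config,
              seed = seed, payload = basename(payload_file))
  jsonlite::write_json(doc, file.path(store$dir, paste0(id, ".doc.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(id)
}

#' Query the store by keyword tags
#'
#' Conjunctive tag match: documents carrying all requested tags are
#' returned. An optional reducer is applied to each matched payload.
#'
#' @param store A [result_store()].
#' @param tags Character vector of required tags (empty = all documents).
#' @param reducer Optional function applied to each loaded payload.
#' @return A list of documents; each has the index fields plus `payload`
#'   (loaded tibble/list, or the reducer's result under `reduced`).
#' @export
query_store <- function(store, tags = character(), reducer = NULL) {
  docs <- list.files(store$dir, pattern = "\\.doc\\.json$",
                     full.names = TRUE)
  out <- list()
  for (f in docs) {
    doc <- jsonlite::read_json(f, simplifyVector = TRUE)
    if (!all(tags %in% doc$tags)) next
    pf <- file.path(store$dir, doc$payload)
    doc$payload_data <- if (grepl("\\.csv$", pf))
      tibble::as_tibble(utils::read.csv(pf)) else
      jsonlite::read_json(pf, simplifyVector = TRUE)
    if (!is.null(reducer)) doc$reduced <- reducer(doc$payload_data)
    out[[doc$id]] <- doc
  }
  out
}

#' Run an analysis pipeline from a config
#'
#' Executes the simulation-driven chain (`simulate` -> `features` ->
#' `stats`) for a set of named conditions and persists every stage in the
#' result store. Conditions are simulated with [simulate_condition()] using
#' the shared baseline cut; length-resolved bootstrap curves are computed
#' per condition; pairwise separation (bootstrapped PCA) and fold changes
#' against the pooled baseline conditions are stored.
#'
#' @param config A list:
#'   \describe{
#'     \item{conditions}{named list mapping condition label to a
#'       [condition_params()] name.}
#'     \item{n_filaments, T_total, dt}{simulation sizes.}
#'     \item{B}{bootstrap replicates per condition.}
#'     \item{range, width, n_windows}{window grid.}
#'     \item{seed}{integer seed for the whole run.}
#'     \item{params}{optional [motor_params()] overriding the defaults.}
#'     \item{stages}{character subset of `c("simulate", "features",
#'       "stats")`.}
#'   }
#' @param store A [result_store()].
#' @return A list with the per-condition records, curve sets, the PC
#'   embedding, the pairwise separation matrix, and fold-change tables.
#' @export
run_pipeline <- function(config, store = result_store(tempfile("store"))) {
  stages <- config$stages %||% c("simulate", "features", "stats")
  seed <- config$seed %||% 1L
  params <- config$params %||% motor_params()
  B <- config$B %||% 200
  n_fil <- config$n_filaments %||% 150
  T_total <- config$T_total %||% 25
  dt <- config$dt %||% (1 / 3)
  range <- config$range %||% c(0.3, 3.25)
  width <- config$width %||% 0.59
  n_windows <- config$n_windows %||% 50
  conditions <- config$conditions %||%
    list(baseline = "baseline")
  set.seed(seed)
  out <- list(store = store)
  if ("simulate" %in% stages) {
    records <- list()
    cut <- NULL
    for (nm in names(conditions)) {
      p <- apply_multipliers(params, condition_params(conditions[[nm]]))
      recs <- simulate_condition(p, n_filaments = n_fil, T_total = T_total,
                                 dt = dt, condition = nm, cut = cut)
      if (is.null(cut)) cut <- attr(recs, "cut") # first condition sets it
      store_write(store, "simulate", recs,
                  tags = c("records", nm, conditions[[nm]]),
                  config = list(n_filaments = n_fil, T_total = T_total,
                                dt = dt, cut = cut), seed = seed)
      records[[nm]] <- recs
    }
    out$records <- records
    out$cut <- cut
  }
  if ("features" %in% stages) {
    stopifnot(!is.null(out$records))
    curves <- lapply(names(out$records), function(nm) {
      cs <- bootstrap_curves(out$records[[nm]], B = B, range = range,
                             width = width, n_windows = n_windows)
      store_write(store, "features", cs$ci,
                  tags = c("curves", nm),
                  config = list(B = B, range = range, width = width,
                                n_windows = n_windows), seed = seed)
      cs
    })
    names(curves) <- names(out$records)
    out$curves <- curves
  }
  if ("stats" %in% stages) {
    stopifnot(!is.null(out$curves))
    cm <- assemble_condition_matrix(out$curves)
    emb <- pca3(cm)
    sep <- pairwise_separation(emb)
    out$embedding <- emb
    out$separation <- sep
    store_write(store, "stats",
                as.data.frame(sep),
                tags = c("separation", "pairwise"),
                config = list(B = B), seed = seed)
    base_names <- names(conditions)[unlist(conditions) == "baseline"]
    if (length(base_names) >= 1) {
      pooled <- do.call(rbind, out$records[base_names])
      pooled_cs <- bootstrap_curves(as_motility_records(pooled), B = B,
                                    range = range, width = width,
                                    n_windows = n_windows)
      folds <- purrr::map_dfr(setdiff(names(conditions), base_names),
        function(nm) {
          purrr::map_dfr(c("v_um_s", "f_mot", "stop_time_s", "run_time_s"),
            function(f) dplyr::mutate(
              fold_changes(out$curves[[nm]], pooled_cs, feature = f),
              condition = nm, .before = 1))
        })
      out$folds <- folds
      if (nrow(folds) > 0)
        store_write(store, "stats", folds, tags = c("folds"),
                    config = list(baseline = base_names), seed = seed)
    }
  }
  out
}
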