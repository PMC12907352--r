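# End-to-end pipeline: preprocess -> transitions/metrics -> (optional)
# coupling -> LCA selection -> clinical association, with a reproducible
# JSON report.

#' Pipeline configuration
#'
#' Collects every path, threshold, seed and tolerance that affects the
#' analysis in one object; the pipeline echoes it verbatim into its report so
#' a run can be reproduced from the report alone.
#'
#' @param events Path to an events CSV (`child_id,session,category,onset_s,offset_s`),
#'   or an [event_log()].
#' @param clinical Path to a clinical CSV (columns of [generate_outcomes()])
#'   or a data frame; `NULL` disables the association stage.
#' @param physio Named list of [physio_signal()]s (or `NULL` to skip
#'   coupling).
#' @param output_dir Directory for result tables (created if needed); `NULL`
#'   writes nothing.
#' @param alphabet_preset `"core6"` or `"full7"`.
#' @param min_interval Merge threshold for [segment_events()] (s).
#' @param gap_threshold Episode gap for sequence metrics (s).
#' @param entropy_support `"bigram"` or `"unigram"`.
#' @param lca List: `kmin`, `kmax`, `restarts`, `seed`, plus the
#'   `binarize_rule` used if indicators must be derived.
#' @param indicators Optional pre-built binary indicator matrix for the LCA
#'   stage (rows named by child id); `NULL` derives median-split indicators
#'   from per-child behavior frequencies.
#' @param coupling List: `category`, `max_lag` (samples), `M` (smoothing
#'   window, samples).
#' @param responder_threshold Relative ADOS-2 decrease defining response.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(events, clinical = NULL, physio = NULL,
                            output_dir = NULL, alphabet_preset = "core6",
                            min_interval = 0.5, gap_threshold = 5,
                            entropy_support = "bigram",
                            lca = list(kmin = 2, kmax = 5, restarts = 20,
                                       seed = 1, binarize_rule = "median"),
                            indicators = NULL,
                            coupling = list(category = "nonverbal_initiation",
                                            max_lag = 50, M = 5),
                            responder_threshold = 0.20) {
  structure(list(events = events, clinical = clinical, physio = physio,
                 output_dir = output_dir, alphabet_preset = alphabet_preset,
                 min_interval = min_interval, gap_threshold = gap_threshold,
                 entropy_support = entropy_support, lca = lca,
                 indicators = indicators, coupling = coupling,
                 responder_threshold = responder_threshold),
            class = "pipeline_config")
}

# internal: fail with the stage name attached
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full behavioral-sequence analysis pipeline
#'
#' Chains preprocessing, transition/sequence metrics, optional physiological
#' coupling, latent class selection and clinical association, writing CSV/TSV
#' tables plus a JSON summary (config echo included) when an output directory
#' is configured.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list with per-stage results and the config
#'   echo.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  alphabet <- behavior_alphabet(config$alphabet_preset)

  log <- .stage("preprocess", {
    lg <- if (inherits(config$events, "event_log")) config$events
    else read_event_log(config$events, alphabet)
    segment_events(lg, config$min_interval)
  })

  transitions <- .stage("transitions", {
    tm <- transition_probabilities(transition_counts(log))
    w <- tabulate(match(log$category, alphabet$code), alphabet_size(alphabet))
    list(matrix = tm, cyclicity = cyclicity(tm, w / sum(w)))
  })

  metrics <- .stage("metrics", {
    per_child <- lapply(split(seq_len(nrow(log)), log$child_id), function(i) {
      lg <- event_log(as.data.frame(log)[i, ], alphabet)
      data.frame(child_id = lg$child_id[1],
                 entropy = behavioral_entropy(lg, config$entropy_support)$H,
                 asl = average_sequence_length(lg, config$gap_threshold),
                 n_events = nrow(lg))
    })
    per_child <- do.call(rbind, per_child)
    rownames(per_child) <- NULL
    list(per_child = per_child,
         chains = mine_chains(log, gap_threshold = config$gap_threshold))
  })

  coupling <- NULL
  if (!is.null(config$physio)) coupling <- .stage("coupling", {
    out <- lapply(names(config$physio), function(id) {
      sig <- moving_average(config$physio[[id]], config$coupling$M)
      lg <- event_log(as.data.frame(log)[log$child_id == id, , drop = FALSE],
                      alphabet)
      if (!nrow(lg)) return(NULL)
      b <- behavior_indicator(lg, config$coupling$category, sig$rate,
                              length(sig$values))
      if (all(b$values == 0) || all(b$values == 1)) return(NULL)
      cc <- cross_correlation(sig, b, config$coupling$max_lag)
      data.frame(child_id = id, peak_lag = cc$peak_lag,
                 peak_cc = cc$cc[which(cc$lag == cc$peak_lag)])
    })
    do.call(rbind, out)
  })

  lca <- .stage("lca", {
    X <- config$indicators
    if (is.null(X)) {
      freqs <- table(log$child_id, log$category)
      X <- binarize_indicators(unclass(as.matrix(freqs)),
                               config$lca$binarize_rule)
    }
    sel <- select_classes(X, kmin = config$lca$kmin, kmax = config$lca$kmax,
                          restarts = config$lca$restarts,
                          seed = config$lca$seed)
    labels <- assign_classes(sel$models[[paste0("k", sel$chosen_k)]])$labels
    list(selection = sel, labels = stats::setNames(labels, rownames(X)))
  })

  association <- NULL
  if (!is.null(config$clinical)) association <- .stage("association", {
    clin <- if (is.data.frame(config$clinical)) config$clinical
    else {
      if (!file.exists(config$clinical))
        stop("clinical file not found: ", config$clinical)
      utils::read.csv(config$clinical, stringsAsFactors = FALSE)
    }
    asd <- clin[!is.na(clin$ados_baseline), , drop = FALSE]
    flags <- response_flags(asd$ados_baseline, asd$ados_post,
                            config$responder_threshold)
    lab <- lca$labels[match(asd$child_id, names(lca$labels))]
    keep <- !is.na(lab)
    rates <- response_rates(lab[keep], flags[keep])
    list(rates = rates, flags = stats::setNames(flags, asd$child_id))
  })

  report <- structure(list(
    n_events = nrow(log), transitions = transitions, metrics = metrics,
    coupling = coupling, lca = lca, association = association,
    config = config, versions = list(
      playseq = as.character(utils::packageVersion("playseq")),
      R = paste(R.version$major, R.version$minor, sep = "."))),
    class = "pipeline_report")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    od <- config$output_dir
    utils::write.table(round(transitions$matrix$probs, 6),
                       file.path(od, "transition_probs.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.csv(metrics$per_child,
                     file.path(od, "sequence_metrics.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(metrics$chains),
                     file.path(od, "chains.csv"), row.names = FALSE)
    utils::write.csv(lca$selection$table,
                     file.path(od, "model_selection.csv"), row.names = FALSE)
    if (!is.null(association))
      utils::write.csv(as.data.frame(association$rates),
                       file.path(od, "response_rates.csv"), row.names = FALSE)
    summ <- list(
      n_events = report$n_events,
      chosen_k = lca$selection$chosen_k,
      cyclicity = transitions$cyclicity$cyclicity,
      mean_entropy = mean(metrics$per_child$entropy),
      mean_asl = mean(metrics$per_child$asl),
      response_rates = if (!is.null(association))
        as.data.frame(association$rates) else NULL,
      config = config[setdiff(names(config), c("physio", "indicators", "events",
                                               "clinical"))],
      versions = report$versions)
    jsonlite::write_json(summ, file.path(od, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report: ", x$n_events, " events after preprocessing\n",
      "  chosen_k = ", x$lca$selection$chosen_k,
      "; mean entropy = ",
      format(mean(x$metrics$per_child$entropy), digits = 4), " bits\n",
      sep = "")
  if (!is.null(x$association)) print(as.data.frame(x$association$rates))
  invisible(x)
}
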