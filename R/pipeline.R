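#' Configuration for the full uncoupling pipeline
#'
#' Either a synthetic-data block or an input directory must be given. All
#' randomness is controlled by \code{seed}; stage seeds are derived from it
#' deterministically.
#'
#' @param synthetic A [synthetic_config()] (or argument list for one), or
#'   NULL when reading data from disk.
#' @param input_dir Directory readable by [read_paired_expression_set()], or
#'   NULL when simulating.
#' @param deg_method \code{"rankprod"} or \code{"ttest"}.
#' @param threshold Significance cutoff: pfp for rank product, BH-adjusted p
#'   for the t-test caller (default 0.2, the study convention for pfp).
#' @param n_permutations Permutations for the pfp estimate.
#' @param fdr FDR level for term enrichment.
#' @param n_iter Bootstrap iterations for the independence tests.
#' @param normalize Quantile-normalize jointly across all arrays first.
#' @param ontology Optional list with \code{graph}, \code{annotations},
#'   \code{slim} (as returned by [generate_toy_ontology()]); enables the
#'   enrichment and semantic stages.
#' @param seed Master integer seed.
#' @return Validated list of class \code{PipelineConfig}.
#' @export
pipeline_config <- function(synthetic = NULL, input_dir = NULL,
                            deg_method = c("rankprod", "ttest"),
                            threshold = 0.2, n_permutations = 1000L,
                            fdr = 0.05, n_iter = 1e4L, normalize = TRUE,
                            ontology = NULL, seed = 1L) {
  deg_method <- match.arg(deg_method)
  if (is.null(synthetic) && is.null(input_dir))
    stop("either a synthetic block or an input_dir is required")
  if (!is.null(synthetic) && !inherits(synthetic, "SyntheticConfig"))
    synthetic <- do.call(synthetic_config, synthetic)
  structure(list(synthetic = synthetic, input_dir = input_dir,
                 deg_method = deg_method, threshold = threshold,
                 n_permutations = as.integer(n_permutations), fdr = fdr,
                 n_iter = as.integer(n_iter), normalize = normalize,
                 ontology = ontology, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Run the full transcriptome-translatome uncoupling analysis
#'
#' Stages: data acquisition (synthetic or from disk), low-signal filtering
#' (when detection calls are present), joint quantile normalization, fold
#' changes, differential-expression calling at both levels, coupling
#' classification and summary, buffering counts, optional term enrichment
#' and semantic specificity, and the three independence tests. A failing
#' stage stops the pipeline but the report retains all completed stages
#' (field \code{failed_stage} names it).
#'
#' @param config A [pipeline_config()].
#' @return List of class \code{PipelineReport} with per-stage results:
#'   \code{truth} (synthetic runs), \code{fold_changes}, \code{deg_tables},
#'   \code{deg_sets}, \code{coupling}, \code{summary}, \code{buffering},
#'   \code{enrichment}, \code{term_overlap}, \code{specificity},
#'   \code{independence}, \code{log} (interpretation notes),
#'   \code{failed_stage}/\code{error} on failure.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  report <- list(config = config, log = character(0),
                 failed_stage = NA_character_)
  note <- function(msg) report$log <<- c(report$log, msg)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      report$failed_stage <<- name
      report$error <<- conditionMessage(e)
      NULL
    })
  }

  # -- data ------------------------------------------------------------
  data <- run_stage("data", {
    if (!is.null(config$synthetic)) {
      generate_paired_dataset(config$synthetic)
    } else {
      list(set = read_paired_expression_set(config$input_dir), truth = NULL)
    }
  })
  if (is.null(data)) return(structure(report, class = "PipelineReport"))
  set <- data$set
  report$truth <- data$truth

  if (!is.null(set$detection)) {
    set <- filter_low_signal(set)
    note(sprintf("low-signal filter removed %d features",
                 attr(set, "n_removed")))
  } else {
    note("no detection calls: low-signal filter skipped")
  }
  if (config$normalize) {
    set <- normalize_paired_set(set)
    note("joint quantile normalization across all arrays of all four groups")
  }
  report$set <- set
  universe <- set$feature_ids

  # -- fold changes and DEG calling ------------------------------------
  report$fold_changes <- run_stage("fold_changes", compute_fold_changes(set))
  if (is.null(report$fold_changes))
    return(structure(report, class = "PipelineReport"))

  degs <- run_stage("deg_calling", {
    one_level <- function(level, seed_offset) {
      ctrl <- set$matrices[[paste0(level, "_control")]]
      trt <- set$matrices[[paste0(level, "_treated")]]
      tab <- if (config$deg_method == "rankprod") {
        rank_product_table(ctrl, trt, config$n_permutations,
                           seed = config$seed + seed_offset)
      } else {
        ttest_bh_caller(ctrl, trt, alpha = config$threshold)
      }
      call_degs(tab, config$threshold)
    }
    note(sprintf("DEG caller: %s (unpaired), threshold %g",
                 config$deg_method, config$threshold))
    list(transcriptome = one_level("transcriptome", 101L),
         translatome = one_level("translatome", 202L))
  })
  if (is.null(degs)) return(structure(report, class = "PipelineReport"))
  report$deg_tables <- degs
  report$deg_sets <- lapply(degs, attr, "degs")

  # -- coupling --------------------------------------------------------
  coup <- run_stage("coupling", {
    tab <- classify_coupling(degs$transcriptome, degs$translatome,
                             fold_changes = report$fold_changes)
    list(table = tab, summary = summarize_uncoupling(tab))
  })
  if (is.null(coup)) return(structure(report, class = "PipelineReport"))
  report$coupling <- coup$table
  report$summary <- coup$summary
  deg_union <- union(report$deg_sets$transcriptome,
                     report$deg_sets$translatome)
  report$buffering <- buffering_counts(report$fold_changes,
                                       genes = if (length(deg_union))
                                         deg_union else NULL)
  note("buffering counted over the union of DEGs (all genes when no DEGs)")

  # -- enrichment + semantics (optional) -------------------------------
  if (!is.null(config$ontology)) {
    enr <- run_stage("enrichment", {
      cat <- annotation_catalog(config$ontology$annotations, universe)
      lapply(report$deg_sets, fisher_enrichment, universe = universe,
             catalog = cat, fdr = config$fdr)
    })
    if (!is.null(enr)) {
      report$enrichment <- enr
      tr_terms <- attr(enr$transcriptome, "enriched_terms")
      tl_terms <- attr(enr$translatome, "enriched_terms")
      report$term_overlap <- term_overlap_summary(tr_terms, tl_terms)
      if (length(tr_terms) && length(tl_terms)) {
        report$specificity <- run_stage("specificity",
          semantic_specificity(tl_terms, tr_terms, config$ontology$graph))
      } else {
        note("semantic specificity undefined: empty enriched-term list")
      }
    }
  }

  # -- independence ----------------------------------------------------
  n1 <- length(report$deg_sets$transcriptome)
  n2 <- length(report$deg_sets$translatome)
  if (n1 == 0L && n2 == 0L) {
    note("independence tests skipped: no DEGs at either level")
  } else {
    report$independence <- run_stage("independence",
      independence_tests(report$deg_sets$transcriptome,
                         report$deg_sets$translatome, universe,
                         n_iter = config$n_iter,
                         seed = config$seed + 303L))
  }
  structure(report, class = "PipelineReport")
}

#' @export
print.PipelineReport <- function(x, ...) {
  cat("PipelineReport\n")
  if (!is.na(x$failed_stage))
    cat("  FAILED at stage:", x$failed_stage, "-", x$error, "\n")
  if (!is.null(x$summary)) {
    s <- x$summary
    cat(sprintf("  DEGs: %d (uncoupled %.1f%%, coupled %.1f%%)\n",
                s$n_degs, s$uncoupled_pct, s$coupled_pct))
  }
  if (!is.null(x$independence)) print(x$independence)
  invisible(x)
}

#' Write a pipeline report to TSV/JSON files
#'
#' @param report A \code{PipelineReport}.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    if (!is.null(df))
      utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                         row.names = FALSE)
  }
  wt(report$fold_changes, "fold_changes.tsv")
  wt(report$deg_tables$transcriptome, "degs_transcriptome.tsv")
  wt(report$deg_tables$translatome, "degs_translatome.tsv")
  wt(report$coupling, "coupling.tsv")
  wt(report$enrichment$transcriptome, "enrichment_transcriptome.tsv")
  wt(report$enrichment$translatome, "enrichment_translatome.tsv")
  coupling_summary <- report$summary
  if (!is.null(coupling_summary)) {
    coupling_summary$counts <- as.list(coupling_summary$counts)
    coupling_summary$pct <- as.list(coupling_summary$pct)
  }
  summary <- list(coupling_summary = coupling_summary,
                  buffering = report$buffering,
                  term_overlap = report$term_overlap,
                  specificity = if (!is.null(report$specificity))
                    report$specificity[c("m", "n", "translatome_specificity",
                                         "transcriptome_specificity")],
                  independence = if (!is.null(report$independence))
                    unclass(report$independence),
                  log = report$log)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}

#' Cross-dataset summary of multiple pipeline reports
#'
#' @param reports Named list (>= 2) of \code{PipelineReport}s.
#' @return List: \code{datasets} (data frame: per-dataset DEG counts,
#'   uncoupled/coupled percentages, uncoupled-majority flag, independence
#'   p-values and MI midrange position) and \code{n_uncoupled_majority}
#'   (datasets where uncoupled DEGs outnumber coupled ones).
#' @export
multi_dataset_report <- function(reports) {
  if (length(reports) < 2L) stop("need >= 2 reports")
  if (is.null(names(reports)))
    names(reports) <- sprintf("dataset_%02d", seq_along(reports))
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    s <- r$summary
    ind <- r$independence
    data.frame(dataset = nm, n_degs = s$n_degs,
               uncoupled_pct = s$uncoupled_pct, coupled_pct = s$coupled_pct,
               uncoupled_majority = !is.na(s$uncoupled_pct) &&
                 s$uncoupled_pct > 50,
               lrt_p = if (is.null(ind)) NA_real_ else ind$lrt_p,
               overlap_p = if (is.null(ind)) NA_real_ else ind$overlap_p,
               mi_observed = if (is.null(ind)) NA_real_ else ind$mi_observed,
               mi_midrange = if (is.null(ind)) NA_real_
                             else ind$mi_midrange_position,
               mi_p = if (is.null(ind)) NA_real_ else ind$mi_p,
               stringsAsFactors = FALSE)
  })
  datasets <- do.call(rbind, rows)
  list(datasets = datasets,
       n_uncoupled_majority = sum(datasets$uncoupled_majority))
}
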