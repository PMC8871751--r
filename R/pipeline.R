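# One-call orchestration of the analysis stages with artifact writing,
# logging, and a reproducibility manifest.

#' Run the MSY lineage-tracing pipeline
#'
#' Executes filter -> polarize -> assign_haplogroups -> impute ->
#' build_haplotypes -> build_tree -> assign_names, optionally followed by
#' backbone panel assignment and by sire-line congruence/summary analysis,
#' writing every artifact plus a manifest (parameters and md5 checksums) to
#' `outdir`. With only `fixture` given, just the genealogy stage runs.
#' The pipeline output is a pure function of its inputs and configuration;
#' re-running with identical inputs reproduces identical checksums.
#'
#' @param input a [call_matrix] or path to a VCF / delimited matrix
#' @param outdir output directory (created if needed)
#' @param outgroup outgroup sample id used for polarization
#' @param filter a [filter_config]
#' @param hg_rules list of [hg_rule] for imputation grouping (optional;
#'   without it imputation is skipped)
#' @param impute_mode `"unanimity"` or `"majority"`
#' @param on_conflict `"fail"` or `"greedy_drop"` for tree building
#' @param registry a [name_registry] of legacy anchors (optional)
#' @param panel,panel_calls a `marker_panel` and an A/D/U/F call grid for
#'   panel-stage placement (optional)
#' @param line_records sire-line records data.frame (see
#'   [read_line_records()]) for the genealogy stage (optional)
#' @param fixture alias for `line_records` when running genealogy only
#' @param haplogroups rollup labels for [summarize_panel()]
#' @param verbose log progress to the console as well as to run.log
#' @return list with `status` (0 on success), `artifacts` (paths) and
#'   `manifest`.
#' @export
run_pipeline <- function(input = NULL, outdir, outgroup = NULL,
                         filter = filter_config(), hg_rules = NULL,
                         impute_mode = "unanimity",
                         on_conflict = "fail", registry = name_registry(),
                         panel = NULL, panel_calls = NULL,
                         line_records = NULL, fixture = NULL,
                         haplogroups = c("Ao-aA", "Ta", "Ao-aD2"),
                         verbose = TRUE) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  logfile <- file.path(outdir, "run.log")
  loglines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    loglines <<- c(loglines, msg)
    if (verbose) message(msg)
  }
  artifacts <- character()
  put <- function(name) { artifacts <<- c(artifacts, file.path(outdir, name)); file.path(outdir, name) }
  params <- list(filter = unclass(filter), impute_mode = impute_mode,
                 on_conflict = on_conflict, haplogroups = haplogroups)
  line_records <- line_records %||% fixture

  status <- 0L
  tryCatch({
    if (!is.null(input)) {
      x <- if (inherits(input, "call_matrix")) input
           else load_call_matrix(input, outgroup = outgroup %||% character())
      say("loaded matrix: %d samples x %d sites", length(x$samples), nrow(x$sites))

      fr <- filter_variants(x, filter)
      x <- fr$matrix
      say("filter: removed %d site(s), retained %d", nrow(fr$report), nrow(x$sites))
      write_filter_report(fr$report, put("filter_report.tsv"))

      if (!is.null(outgroup)) {
        x <- polarize(x, outgroup)
        say("polarized against outgroup '%s' (%d site(s) unknown)",
            outgroup, sum(x$sites$ancestral_state == "unknown"))
      }
      write_call_matrix(x, put("filtered_matrix.tsv"))

      if (!is.null(hg_rules)) {
        groups <- assign_haplogroups(x, hg_rules)
        say("haplogroups: %s",
            paste(sprintf("%s=%d", names(table(groups)), table(groups)), collapse = ", "))
        imp <- impute_by_group(x, groups, mode = impute_mode)
        x <- imp$matrix
        say("imputed %d call(s) by %s consensus", nrow(imp$log), impute_mode)
        if (impute_mode == "majority" && nrow(imp$log))
          say("warning: majority-mode imputations present; review the log")
        write_imputation_log(imp$log, put("imputation_log.tsv"))
      }

      hts <- build_haplotypes(x)
      say("haplotypes: %d distinct over %d sites (%d excluded)",
          length(hts), length(attr(hts, "sites_used")),
          length(attr(hts, "excluded_sites")))
      write_haplotype_table(hts, put("haplotype_table.tsv"))

      bt <- build_tree(x, on_conflict = on_conflict)
      if (length(bt$conflicts$resolution))
        say("warning: dropped conflicting site(s): %s",
            paste(bt$conflicts$resolution, collapse = ", "))
      tree <- assign_names(bt$tree, registry)
      say("tree: %d nodes, root '%s'", nrow(tree$nodes),
          tree$nodes$label[tree$root])
      export_tree(tree, "table", put("tree.tsv"))
      export_tree(tree, "newick", put("tree.nwk"))
      write_registry(registry_of(tree), put("names_registry.tsv"))

      if (!is.null(panel) && !is.null(panel_calls)) {
        asg <- assign_samples(panel_calls, tree, panel)
        say("panel: placed %d sample(s), %d unresolved, %d conflict(s)",
            nrow(asg), sum(!asg$resolved), sum(asg$node_label == "conflict"))
        utils::write.table(asg, put("assignments.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
    }

    if (!is.null(line_records)) {
      summ <- summarize_panel(line_records, haplogroups = haplogroups)
      say("lines: %d samples, %d foundation lines, %d HTs, %d incongruent (%s)",
          summ$total_samples, summ$n_lines, summ$n_distinct_hts,
          summ$n_incongruent, paste(summ$incongruent_lines, collapse = ", "))
      utils::write.table(as.data.frame(summ$congruence),
                         put("congruence_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      txt <- c(sprintf("total samples\t%d", summ$total_samples),
               sprintf("foundation lines\t%d", summ$n_lines),
               sprintf("lines with >1 sample\t%d", summ$n_lines_multi),
               sprintf("distinct haplotypes\t%d", summ$n_distinct_hts),
               sprintf("samples in rollup haplogroups\t%d", summ$hg_total_samples),
               sprintf("subline-HT labels\t%d", summ$n_subline_ht_labels),
               sprintf("incongruent lines\t%d", summ$n_incongruent))
      writeLines(txt, put("panel_summary.txt"))
    }
  }, error = function(e) {
    status <<- 1L
    say("error: %s", conditionMessage(e))
  })

  writeLines(loglines, logfile)
  sums <- tools::md5sum(artifacts[file.exists(artifacts)])
  names(sums) <- basename(names(sums))
  manifest <- list(parameters = params,
                   artifacts = as.list(sums))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (status != 0L) .stopf("pipeline failed; see %s", logfile)
  list(status = status, artifacts = artifacts, manifest = manifest)
}
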