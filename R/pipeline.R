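#' Cohort-level statistics report
#'
#' Applies the group-comparison ladder to every feature of a cohort
#' feature table: two-way (maturation x occlusion) comparisons when both
#' treatments are present, one-way comparisons across maturation groups
#' otherwise, and the Fisher exact battery for the spontaneous-firing
#' proportions.  Cells failing series-resistance QC are excluded from all
#' statistics (their rows remain in the feature table, flagged).
#'
#' @param features a `px_features` data frame.
#' @param alpha family-wise significance level.
#' @return list of class `px_stats_report`.
#' @export
feature_report <- function(features, alpha = 0.05) {
  keep <- is.na(features$qc_pass) | features$qc_pass
  fx <- features[keep, , drop = FALSE]
  numeric_feats <- c("R_i", "C_m", "V_rest", "V_thresh", "V_max", "max_dvdt",
                     "whh", "rheobase", "latency", "fAHP", "max_spike_no",
                     "IF_slope", "SAA_slope", "ISI_CV", "SFA", "SWA",
                     "mAHP", "sag_index")
  numeric_feats <- intersect(numeric_feats, names(fx))
  two_way <- length(unique(fx$treatment[!is.na(fx$treatment)])) >= 2L
  res <- list()
  for (f in numeric_feats) {
    x <- fx[[f]]
    ok <- is.finite(x)
    r <- tryCatch({
      if (two_way) two_way_family(x[ok], fx$group[ok], fx$treatment[ok], alpha)
      else one_way_family(x[ok], fx$group[ok], alpha)
    }, error = function(e) list(error = conditionMessage(e)))
    res[[f]] <- r
  }
  spont <- NULL
  if ("spontaneous" %in% names(fx)) {
    sp <- fx[!is.na(fx$spontaneous), , drop = FALSE]
    ref <- if (two_way) sp[sp$treatment == "sham", , drop = FALSE] else sp
    tab <- stats::aggregate(spontaneous ~ group, data = ref,
                            FUN = function(v) c(s = sum(v), n = length(v)))
    succ <- tab$spontaneous[, "s"]; tot <- tab$spontaneous[, "n"]
    if (length(succ) >= 2L && all(tot > 0)) {
      overall <- fisher_2xk(succ, tot)
      prs <- utils::combn(seq_along(succ), 2)
      pairwise <- data.frame(
        contrast = apply(prs, 2, function(ij)
          paste(tab$group[ij[1]], "-", tab$group[ij[2]])),
        p = apply(prs, 2, function(ij)
          fisher_2x2(succ[ij[1]], tot[ij[1]], succ[ij[2]], tot[ij[2]])))
      spont <- list(groups = tab$group, successes = succ, totals = tot,
                    overall_p = overall, pairwise = pairwise,
                    pairwise_alpha = bonferroni_alpha(alpha, ncol(prs)))
      if (two_way) {
        occl <- lapply(unique(sp$group), function(g) {
          a <- sp$spontaneous[sp$group == g & sp$treatment == "sham"]
          b <- sp$spontaneous[sp$group == g & sp$treatment == "occluded"]
          if (!length(a) || !length(b)) return(NULL)
          data.frame(group = g,
                     p = fisher_2x2(sum(a), length(a), sum(b), length(b)))
        })
        spont$sham_vs_occluded <- do.call(rbind, occl)
      }
    }
  }
  structure(list(features = res, spontaneous = spont, alpha = alpha,
                 design = if (two_way) "two_way" else "one_way",
                 n_cells = nrow(fx), n_excluded_qc = sum(!keep)),
            class = "px_stats_report")
}

#' @export
print.px_stats_report <- function(x, ...) {
  cat(sprintf("<px_stats_report> %s design, %d cell(s), %d excluded by QC\n",
              x$design, x$n_cells, x$n_excluded_qc))
  for (f in names(x$features)) {
    r <- x$features[[f]]
    if (!is.null(r$error)) { cat(sprintf("  %-12s <%s>\n", f, r$error)); next }
    if (!is.null(r$effects))
      cat(sprintf("  %-12s %s [%s]: treatment p = %.3g, interaction p = %.3g\n",
                  f, r$test, r$transform, r$effects["treatment", "p"],
                  r$effects["interaction", "p"]))
    else
      cat(sprintf("  %-12s %s [%s]: p = %.3g\n", f, r$test, r$transform, r$p))
  }
  if (!is.null(x$spontaneous))
    cat(sprintf("  spontaneous  Fisher exact: overall p = %.3g (pairwise alpha %.3g)\n",
                x$spontaneous$overall_p, x$spontaneous$pairwise_alpha))
  invisible(x)
}

report_to_json_list <- function(rep) {
  feats <- lapply(rep$features, function(r) {
    if (!is.null(r$error)) return(list(error = r$error))
    out <- list(test = r$test, transform = r$transform)
    if (!is.null(r$effects)) {
      e <- as.data.frame(r$effects)
      e$effect <- rownames(r$effects)
      out$effects <- e[, c("effect", "SS", "df", "F", "p")]
    } else {
      out$statistic <- r$statistic; out$df <- r$df; out$p <- r$p
    }
    if (!is.null(r$posthoc)) out$posthoc <- r$posthoc
    out
  })
  list(design = rep$design, alpha = rep$alpha, n_cells = rep$n_cells,
       n_excluded_qc = rep$n_excluded_qc, features = feats,
       spontaneous = rep$spontaneous)
}

write_report_md <- function(rep, features, path) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# Intrinsic-properties cohort report")
  w("")
  w("- design: %s", rep$design)
  w("- cells analysed: %d (QC-excluded: %d)", rep$n_cells, rep$n_excluded_qc)
  w("")
  w("| feature | test | transform | p |")
  w("|---|---|---|---|")
  for (f in names(rep$features)) {
    r <- rep$features[[f]]
    if (!is.null(r$error)) { w("| %s | - | - | (%s) |", f, r$error); next }
    p <- if (!is.null(r$effects)) r$effects["treatment", "p"] else r$p
    lab <- if (!is.null(r$effects)) paste0(r$test, " (treatment)") else r$test
    w("| %s | %s | %s | %.4g |", f, lab, r$transform, p)
  }
  if (!is.null(rep$spontaneous)) {
    w("")
    w("Spontaneous firing: overall Fisher exact p = %.4g; pairwise alpha = %.3g",
      rep$spontaneous$overall_p, rep$spontaneous$pairwise_alpha)
  }
  invisible(path)
}

#' Run the end-to-end pipeline
#'
#' Either generates a synthetic cohort (`config$simulate`, a
#' [cohort_spec()] or argument list for one) or reads a cohort directory of
#' CSV/JSON sweeps (`config$input_dir`), extracts one feature record per
#' cell, applies QC, runs the statistics report, and writes
#' `features.csv`, `stats_report.json` and `report.md` into
#' `config$out_dir`.  Fully deterministic given `config$seed`.
#'
#' @param config list with `simulate` or `input_dir`, `out_dir`, and
#'   optionally `seed`, `qc` (arguments for [qc_rule()]), `alpha`.
#' @return list with `features` and `report`, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$out_dir))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  qc <- do.call(qc_rule, if (is.null(config$qc)) list() else config$qc)
  if (!is.null(config$simulate)) {
    spec <- if (inherits(config$simulate, "px_cohort_spec")) config$simulate
            else do.call(cohort_spec, config$simulate)
    if (!is.null(config$seed)) spec$seed <- as.integer(config$seed)
    rows <- list()
    gather <- function(b) {
      rows[[b$cell_id]] <<- extract_cell_features(b, qc)
      TRUE  # drop traces: stream cell by cell
    }
    cohort <- generate_cohort(spec, callback = gather)
    features <- do.call(rbind, c(unname(rows), list(make.row.names = FALSE)))
    class(features) <- c("px_features", "data.frame")
    write_feature_table(cohort$ground_truth,
                        file.path(config$out_dir, "ground_truth.csv"))
  } else if (!is.null(config$input_dir)) {
    cells <- list.dirs(config$input_dir, recursive = FALSE)
    rows <- lapply(cells, function(cd)
      extract_cell_features(read_cell_dir(cd), qc))
    features <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    class(features) <- c("px_features", "data.frame")
  } else stop("config needs either a simulate block or an input_dir")
  write_feature_table(features, file.path(config$out_dir, "features.csv"))
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  rep <- feature_report(features, alpha)
  jsonlite::write_json(report_to_json_list(rep),
                       file.path(config$out_dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = 10, null = "null",
                       pretty = TRUE)
  write_report_md(rep, features, file.path(config$out_dir, "report.md"))
  invisible(list(features = features, report = rep))
}
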