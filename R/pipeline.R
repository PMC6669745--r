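#' @include AllGenerics.R
NULL

.stage <- function(report, name, expr) {
  res <- tryCatch(list(ok = TRUE, value = expr),
                  error = function(e)
                    list(ok = FALSE, error = conditionMessage(e)))
  if (res$ok) {
    report$stages[[name]] <- list(status = "ok")
    report$results[[name]] <- res$value
  } else {
    report$stages[[name]] <- list(status = "failed", error = res$error)
    message("stage '", name, "' failed: ", res$error)
  }
  report
}

#' Run the full variability-analysis pipeline
#'
#' Executes whichever stages the configuration provides inputs for, in
#' dependency order: conservation profiling of an aligned FASTA, ASA
#' table of a reference structure, conservation x ASA x role
#' cross-tabulation, hemolysis trace kinetics / power-law / Hill fits,
#' and melting-temperature extraction. A failed stage is recorded in the
#' report and does not abort the remaining stages. The report is written
#' as `report.json` plus TSV/CSV tables under `outDir`.
#'
#' @param config a named list, or path to a YAML file, with any of the
#'   sections: `alignment` (`file`, `ref_id`), `structure` (`file`,
#'   `chain`), `roles` (`file`), `traces` (character vector of CSVs),
#'   `powerlaw` (CSV with conc_nM, lag_s), `dose_response` (CSV with
#'   conc_nM, hemolysis_pct), `melts` (character vector of CSVs),
#'   `params` (`probe`, `n_points`, `thresholds`, `melt_window`),
#'   `out_dir`.
#' @return The report, an S3 list of class `actinovarReport`, invisibly
#'   when `out_dir` is set.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  p <- config$params
  probe <- if (is.null(p$probe)) 1.4 else p$probe
  npts <- if (is.null(p$n_points)) 960L else as.integer(p$n_points)
  thr <- if (is.null(p$thresholds)) c(0.2, 0.5) else as.numeric(p$thresholds)
  mwin <- if (is.null(p$melt_window)) 10L else as.integer(p$melt_window)
  report <- list(
    package = "actinovar",
    version = as.character(utils::packageVersion("actinovar")),
    parameters = list(probe = probe, n_points = npts, thresholds = thr,
                      melt_window = mwin),
    stages = list(), results = list())
  class(report) <- "actinovarReport"

  consMap <- NULL
  if (!is.null(config$alignment)) {
    report <- .stage(report, "conservation", {
      aln <- readFasta(config$alignment$file, "protein")
      prof <- conservationProfile(aln)
      map <- mapToReference(aln, config$alignment$ref_id)
      consMap <<- map
      list(profile = prof,
           categories = as.list(table(prof$category)),
           map = data.frame(position = map@position,
                            residue = map@residue,
                            category = as.character(map@category)))
    })
  }
  asaTab <- NULL
  if (!is.null(config$structure)) {
    report <- .stage(report, "asa", {
      atoms <- readStructure(config$structure$file,
                             chain = config$structure$chain)
      tab <- asaTable(atoms, probeRadius = probe, nPoints = npts,
                      thresholds = thr)
      asaTab <<- tab
      records(tab)
    })
  }
  if (!is.null(config$roles) && !is.null(consMap) && !is.null(asaTab)) {
    report <- .stage(report, "crosstab", {
      roles <- readRoleTable(config$roles$file)
      prof <- buildRecords(consMap, asaTab, roles)
      list(records = records(prof),
           missing_positions = prof@missing,
           crosstab_all = counts(crosstab(prof, "all")),
           crosstab_none = counts(crosstab(prof, "none")),
           crosstab_lipid = counts(crosstab(prof, "lipid")),
           crosstab_ppi = counts(crosstab(prof, "ppi")),
           identity_fraction = sapply(c("lipid", "ppi", "none"),
             function(r) tryCatch(identityFractionByRole(prof, r),
                                  error = function(e) NA_real_)),
           attribution = variabilityAttribution(prof),
           conserved_summary = conservedSummary(prof))
    })
  }
  if (!is.null(config$traces)) {
    report <- .stage(report, "kinetics", {
      lapply(config$traces, function(f) {
        r <- analyzeTrace(readTraceCsv(f))
        list(file = f, lysed = r@lysed, lag_s = r@lagTime,
             vmax_per_s = r@vmax)
      })
    })
  }
  if (!is.null(config$powerlaw)) {
    report <- .stage(report, "powerlaw", {
      d <- utils::read.csv(config$powerlaw, stringsAsFactors = FALSE)
      fit <- fitPowerLaw(d[[1L]], d[[2L]])
      list(tau = tau(fit), exponent = reactionOrder(fit))
    })
  }
  if (!is.null(config$dose_response)) {
    report <- .stage(report, "hill", {
      d <- utils::read.csv(config$dose_response, stringsAsFactors = FALSE)
      fit <- fitHill(d[[1L]], d[[2L]])
      list(hc50_nM = hc50(fit), hill_n = hillCoef(fit),
           extrapolated = fit@extrapolated)
    })
  }
  if (!is.null(config$melts)) {
    report <- .stage(report, "melting", {
      lapply(config$melts, function(f) {
        r <- meltingTemperature(readMeltCsv(f), window = mwin)
        list(file = f, transition = r@transition, tm_C = r@tm)
      })
    })
  }

  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    strip <- function(x) {
      if (is.matrix(x)) return(apply(x, 1L, as.list, simplify = FALSE))
      if (is.data.frame(x)) return(x)
      if (is.list(x)) return(lapply(x, strip))
      x
    }
    jsonlite::write_json(strip(unclass(report)),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    if (!is.null(report$results$conservation))
      writeConservationTsv(report$results$conservation$profile,
                           file.path(out_dir, "conservation.tsv"))
    if (!is.null(report$results$asa))
      write.table(report$results$asa, file.path(out_dir, "asa.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(report$results$crosstab))
      write.table(report$results$crosstab$records,
                  file.path(out_dir, "records.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(report))
  }
  report
}

#' @export
print.actinovarReport <- function(x, ...) {
  cat("actinovar pipeline report (", length(x$stages), " stage(s))\n",
      sep = "")
  for (nm in names(x$stages))
    cat(sprintf("  %-12s %s\n", nm, x$stages[[nm]]$status))
  invisible(x)
}
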