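.CONFIG_DEFAULTS <- list(
  stages = c("simulate", "normalize", "enrich", "decay", "stability"),
  outdir = ".",
  seed = 1L,
  ## file inputs (unused when the simulate stage provides the tables)
  counts = NULL, spikes = NULL, design = NULL, annotation = NULL,
  timecourse = NULL, mock = NULL, assignments = NULL, features = NULL,
  ## simulate stage
  n_genes = 2000, wc_mean_counts = 1000,
  ## quantify stage
  rpk = TRUE,
  ## normalize stage
  min_reads = 10, min_sample_fraction = 0.75,
  ## enrich stage
  topscore_edges = c(-Inf, 1, 2, 3, Inf),
  dependence_ko = NULL, dependence_control = NULL,
  ## decay stage
  cap_h = 50, alpha = 0.05, floor = 5e-6,
  background_mode = "log_offset", z_reading = "max_then_divide",
  nluc_id = "nLuc",
  ## stability stage
  wt = "WT", ko = "ATG7KO")

.STAGE_ORDER <- c("simulate", "quantify", "normalize", "enrich",
                  "decay", "stability")

#' Assemble and validate a pipeline configuration
#'
#' One flat configuration drives [runPipeline()]. Unknown keys are
#' rejected; referenced input files must exist at load time. Defaults
#' are the package's standard study conditions.
#'
#' @param ... Named configuration values overriding the defaults (see
#'   `lysoseq:::.CONFIG_DEFAULTS` for the full key set).
#' @return A validated named list of class `"lysoseq_config"`.
#' @export
pipelineConfig <- function(...) {
  user <- list(...)
  unknown <- setdiff(names(user), names(.CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(.CONFIG_DEFAULTS, user, keep.null = TRUE)
  bad <- setdiff(cfg$stages, .STAGE_ORDER)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  for (key in c("counts", "spikes", "design", "annotation",
                "timecourse", "mock", "assignments", "features")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop("configured file does not exist: ", key, " = ", cfg[[key]])
  }
  class(cfg) <- "lysoseq_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of flat configuration keys.
#' @return A validated configuration (see [pipelineConfig()]).
#' @export
readPipelineConfig <- function(path) {
  .assertFile(path)
  do.call(pipelineConfig, yaml::read_yaml(path))
}

#' Run the lysoseq pipeline end to end
#'
#' Executes the enabled stages in fixed order: simulate -> quantify ->
#' normalize -> enrich -> decay -> stability. Each stage writes plain
#' TSV outputs under `config$outdir`, and a run report
#' (`report.yaml`) records the effective parameters, gene counts
#' surviving each filter, and output paths. Identical configuration
#' and seed reproduce byte-identical outputs.
#'
#' @param config A configuration from [pipelineConfig()] /
#'   [readPipelineConfig()].
#' @return The run report, invisibly (a nested list, also written as
#'   `report.yaml`).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "lysoseq_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- .STAGE_ORDER[.STAGE_ORDER %in% config$stages]
  report <- list(package_version = as.character(packageVersion("lysoseq")),
                 effective_config = unclass(config)[setdiff(names(config),
                                                            "stages")],
                 stages_run = stages, stages = list())
  state <- list()  # in-memory tables handed between stages
  emit <- function(name, df) {
    p <- file.path(config$outdir, paste0(name, ".tsv"))
    writeTsv(df, p)
    p
  }
  for (stage in stages) {
    rec <- tryCatch(
      switch(stage,
        simulate = {
          cfg <- simConfig(n_genes = config$n_genes,
                           wc_mean_counts = config$wc_mean_counts,
                           seed = config$seed)
          state$truth <- simulateTranscriptome(cfg)
          state$design <- simDesign(cfg)
          fr <- simulateFractionCounts(state$truth, state$design, cfg)
          state$counts <- asCountTable(fr$counts)
          state$spikes <- fr$spikes
          pc <- simulatePulseChase(state$truth, cfg)
          state$timecourse <- pc$timecourse
          state$mock <- pc$mock
          list(params = list(n_genes = config$n_genes,
                             wc_mean_counts = config$wc_mean_counts,
                             seed = config$seed),
               n_genes = nrow(state$truth),
               outputs = c(emit("truth", state$truth),
                           emit("design", state$design),
                           emit("counts", state$counts),
                           emit("spikein_reads", state$spikes),
                           emit("timecourse", state$timecourse),
                           emit("mock", state$mock)))
        },
        quantify = {
          if (is.null(config$assignments)) {
            list(skipped = "no assignment table configured")
          } else {
            asn <- readTsv(config$assignments)
            feats <- if (!is.null(config$features))
              readTsv(config$features) else NULL
            tiers <- sort(unique(asn$reference_tier))
            per <- lapply(tiers, function(t) {
              sub <- asn[asn$reference_tier == t, , drop = FALSE]
              fractionalCount(sub, features = feats)
            })
            cnt <- mergeSequentialReferences(per)
            cnt <- rpkNormalize(cnt, skip = !config$rpk)
            state$counts <- cnt
            list(params = list(rpk = config$rpk),
                 n_reads = length(unique(asn$read_id)),
                 n_genes = nrow(cnt),
                 outputs = emit("counts", cnt))
          }
        },
        normalize = {
          cnt <- state$counts %||% readTsv(config$counts)
          spk <- state$spikes %||% readTsv(config$spikes)
          des <- state$design %||% readTsv(config$design)
          nm <- spikeinNormalize(cnt, spk, design = des,
                                 min_reads = config$min_reads,
                                 min_sample_fraction =
                                   config$min_sample_fraction)
          state$normalized <- nm$normalized
          state$design <- des
          list(params = list(min_reads = config$min_reads,
                             min_sample_fraction =
                               config$min_sample_fraction),
               n_spikes_in = nrow(spk),
               n_spikes_retained = nrow(nm$spikes_normalized),
               n_genes = nrow(nm$normalized),
               outputs = c(emit("normalized", nm$normalized),
                           emit("spike_slopes",
                                data.frame(sample_id = names(nm$slopes),
                                           slope = unname(nm$slopes)))))
        },
        enrich = {
          nrm <- state$normalized %||% readTsv(config$counts)
          des <- state$design %||% readTsv(config$design)
          lx <- countTableToLyso(nrm, design = des)
          SummarizedExperiment::assay(lx, "normalized") <-
            SummarizedExperiment::assay(lx, "counts")
          et <- enrichmentTable(lx)
          if (!is.null(config$dependence_ko) &&
              !is.null(config$dependence_control)) {
            koCol <- sprintf("E_%s_none", config$dependence_ko)
            ctCol <- sprintf("E_%s_none", config$dependence_control)
            if (all(c(koCol, ctCol) %in% names(et)))
              et[[sprintf("D_%s_vs_%s", config$dependence_ko,
                          config$dependence_control)]] <-
                dependenceRatio(setNames(et[[koCol]], et$gene_id),
                                setNames(et[[ctCol]], et$gene_id))
          }
          state$enrichment <- et
          outs <- emit("enrichment", et)
          ann <- if (!is.null(state$truth)) state$truth
                 else if (!is.null(config$annotation))
                   readTsv(config$annotation) else NULL
          if (!is.null(ann) && "class" %in% names(ann)) {
            eCol <- grep("^E_", names(et), value = TRUE)[1]
            sm <- classSummary(setNames(et[[eCol]], et$gene_id), ann,
                               grouping = "class")
            outs <- c(outs, emit("summaries", sm))
          }
          list(params = list(topscore_edges = config$topscore_edges),
               n_genes = nrow(et),
               n_defined = sum(stats::complete.cases(
                 et[, grep("^E_", names(et)), drop = FALSE])),
               outputs = outs)
        },
        decay = {
          tc <- state$timecourse %||% readTsv(config$timecourse)
          mk <- state$mock %||% readTsv(config$mock)
          dk <- fitDecayTable(tc, mk, nluc_id = config$nluc_id,
                              floor = config$floor,
                              cap_h = config$cap_h,
                              alpha = config$alpha,
                              background_mode = config$background_mode,
                              z_reading = config$z_reading)
          state$halflives <- dk$halflives
          list(params = list(cap_h = config$cap_h,
                             alpha = config$alpha,
                             floor = config$floor,
                             background_mode = config$background_mode,
                             z_reading = config$z_reading),
               n_fits = nrow(dk$fits),
               n_retained = nrow(dk$retained),
               n_genes_with_halflife =
                 length(unique(dk$halflives$gene_id)),
               outputs = c(emit("fits", dk$fits),
                           emit("halflives", dk$halflives)))
        },
        stability = {
          hl <- state$halflives
          if (is.null(hl))
            stop("stability stage requires half-lives from the decay stage")
          st <- stabilityTable(hl, wt = config$wt, ko = config$ko)
          list(params = list(wt = config$wt, ko = config$ko),
               n_genes = nrow(st),
               n_defined = sum(is.finite(st$stability)),
               outputs = emit("stability", st))
        }),
      error = function(e)
        stop("pipeline stage '", stage, "' failed: ",
             conditionMessage(e), call. = FALSE))
    report$stages[[stage]] <- rec
  }
  yaml::write_yaml(report, file.path(config$outdir, "report.yaml"))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate pipeline input tables
#'
#' Schema, uniqueness, positivity and design-completeness checks with
#' row-level diagnostics. Nothing is coerced: every violation becomes
#' one finding.
#'
#' @param paths Named character vector / list of file paths; names
#'   among `counts`, `design`, `spikes`, `timecourse`, `mock`,
#'   `annotation`.
#' @return `data.frame` of findings (`table`, `rule`, `message`);
#'   zero rows when everything checks out.
#' @export
validateTables <- function(paths) {
  findings <- list()
  flag <- function(tab, rule, msg)
    findings[[length(findings) + 1L]] <<-
      data.frame(table = tab, rule = rule, message = msg,
                 stringsAsFactors = FALSE)
  requireCols <- function(df, tab, cols) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      flag(tab, "schema", paste("missing column(s):",
                                paste(miss, collapse = ", ")))
    !length(miss)
  }
  tabs <- lapply(paths, readTsv)
  if ("counts" %in% names(tabs)) {
    df <- tabs$counts
    if (requireCols(df, "counts", c("gene_id", "biotype", "length_nt"))) {
      dup <- df$gene_id[duplicated(df$gene_id)]
      if (length(dup))
        flag("counts", "uniqueness",
             paste("duplicated gene_id:",
                   paste(unique(dup), collapse = ", ")))
      if (any(!is.na(df$length_nt) & df$length_nt <= 0))
        flag("counts", "positivity", "nonpositive length_nt")
      samp <- .sampleColumns(df, c("gene_id", "biotype", "length_nt",
                                   "is_spike"))
      for (s in samp)
        if (any(df[[s]] < 0, na.rm = TRUE))
          flag("counts", "positivity",
               paste("negative counts in sample", s))
    }
  }
  if ("design" %in% names(tabs)) {
    df <- tabs$design
    if (requireCols(df, "design",
                    c("sample_id", "genotype", "treatment", "fraction",
                      "replicate", "capture_factor"))) {
      key <- paste(df$genotype, df$treatment, df$fraction,
                   df$replicate)
      if (anyDuplicated(key))
        flag("design", "uniqueness",
             "duplicated genotype/treatment/fraction/replicate")
      if (any(!df$fraction %in% .FRACTIONS))
        flag("design", "schema",
             paste("fraction outside",
                   paste(.FRACTIONS, collapse = "/")))
      if (any(is.na(df$capture_factor) | df$capture_factor <= 0))
        flag("design", "positivity", "nonpositive capture_factor")
      for (gt in unique(df$genotype)) for (tr in unique(df$treatment)) {
        sub <- df[df$genotype == gt & df$treatment == tr, ]
        if (nrow(sub) && (!any(sub$fraction == "whole_cell") ||
                          !any(sub$fraction == "lyso")))
          flag("design", "completeness",
               paste0("condition ", gt, "/", tr,
                      " lacks whole_cell or lyso samples"))
      }
    }
  }
  if ("spikes" %in% names(tabs)) {
    df <- tabs$spikes
    if (requireCols(df, "spikes", c("spike_id", "concentration"))) {
      if (anyDuplicated(df$spike_id))
        flag("spikes", "uniqueness", "duplicated spike_id")
      if (any(df$concentration <= 0))
        flag("spikes", "positivity", "nonpositive concentration")
    }
  }
  if ("timecourse" %in% names(tabs)) {
    df <- tabs$timecourse
    if (requireCols(df, "timecourse",
                    c("gene_id", "genotype", "treatment", "replicate",
                      "time_h", "count"))) {
      if (any(df$time_h < 0))
        flag("timecourse", "positivity", "negative time_h")
      if (any(df$count < 0, na.rm = TRUE))
        flag("timecourse", "positivity", "negative count")
      ser <- unique(df[, c("gene_id", "genotype", "treatment",
                           "replicate")])
      k0 <- paste(df$gene_id, df$genotype, df$treatment,
                  df$replicate)[df$time_h == 0]
      miss <- !paste(ser$gene_id, ser$genotype, ser$treatment,
                     ser$replicate) %in% k0
      if (any(miss))
        flag("timecourse", "completeness",
             paste(sum(miss), "series lack a time-0 observation"))
    }
  }
  if ("mock" %in% names(tabs)) {
    df <- tabs$mock
    if (requireCols(df, "mock", "gene_id")) {
      if (!length(grep("^mock_", names(df))))
        flag("mock", "schema", "no mock_* value columns")
      if (anyDuplicated(df$gene_id))
        flag("mock", "uniqueness", "duplicated gene_id")
    }
  }
  if ("annotation" %in% names(tabs)) {
    df <- tabs$annotation
    if (requireCols(df, "annotation", "gene_id") &&
        anyDuplicated(df$gene_id))
      flag("annotation", "uniqueness", "duplicated gene_id")
  }
  if (length(findings)) do.call(rbind, findings)
  else data.frame(table = character(), rule = character(),
                  message = character(), stringsAsFactors = FALSE)
}
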