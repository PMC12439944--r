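#' Normalize a pulse-chase time course to the nLuc spike-in
#'
#' Every gene's count is divided by the nLuc spike count of the same
#' sample (genotype x treatment x replicate x timepoint), correcting
#' recovery and depth differences between timepoint libraries; the
#' nLuc rows are then removed.
#'
#' @param timecourse Long `data.frame`: `gene_id`, `genotype`,
#'   `treatment`, `replicate`, `time_h`, `count` (including nLuc
#'   rows).
#' @param nluc_id Gene id of the nLuc spike row.
#' @return The time course without nLuc rows, `count` normalized.
#' @export
nlucNormalize <- function(timecourse, nluc_id = "nLuc") {
  need <- c("gene_id", "genotype", "treatment", "replicate", "time_h",
            "count")
  if (!all(need %in% names(timecourse)))
    stop("timecourse must contain columns: ",
         paste(need, collapse = ", "))
  key <- paste(timecourse$genotype, timecourse$treatment,
               timecourse$replicate, timecourse$time_h, sep = "\r")
  isN <- timecourse$gene_id == nluc_id
  if (!any(isN)) stop("no '", nluc_id, "' row present")
  nl <- setNames(timecourse$count[isN], key[isN])
  if (!all(unique(key) %in% names(nl)))
    stop("missing '", nluc_id, "' row in sample(s): ",
         paste(utils::head(gsub("\r", "/", setdiff(unique(key),
                                                   names(nl))), 5),
               collapse = ", "))
  bad <- names(nl)[!is.finite(nl) | nl <= 0]
  if (length(bad))
    stop(nluc_id, " count is zero/invalid in sample(s): ",
         paste(utils::head(gsub("\r", "/", bad), 5), collapse = ", "))
  out <- timecourse[!isN, , drop = FALSE]
  out$count <- out$count / unname(nl[key[!isN]])
  rownames(out) <- NULL
  out
}

#' Normalize each decay series to its timepoint 0
#'
#' Per gene x genotype x treatment x replicate series, all values are
#' divided by the time-0 value so every RNA starts at 1. Series with a
#' zero or missing time-0 value cannot be normalized and are excluded;
#' their keys are returned in the `"excluded"` attribute.
#'
#' @param timecourse Long time course (post [nlucNormalize()]).
#' @return Same layout with `count` t0-normalized and an `"excluded"`
#'   attribute (character vector of dropped series keys).
#' @export
t0Normalize <- function(timecourse) {
  key <- paste(timecourse$gene_id, timecourse$genotype,
               timecourse$treatment, timecourse$replicate, sep = "\r")
  at0 <- timecourse$time_h == 0
  t0 <- setNames(timecourse$count[at0], key[at0])
  have <- key %in% names(t0)
  t0v <- rep(NA_real_, nrow(timecourse))
  t0v[have] <- unname(t0[key[have]])
  drop <- !have | is.na(t0v) | t0v <= 0
  excluded <- unique(gsub("\r", "/", key[drop]))
  out <- timecourse[!drop, , drop = FALSE]
  out$count <- out$count / t0v[!drop]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Background term z for decay fitting
#'
#' The per-gene background of the pulse-chase assay, estimated from
#' the 4 mock-IP samples: the largest mock value (floored at
#' `floor`) divided by the gene's spike-normalized reads at timepoint
#' 0, which places z on the t0-normalized scale of the fitted series.
#' The phrasing of the rule admits a second reading in which only the
#' floor is divided by the t0 reads and the mock values are compared
#' after division; it is available via `reading =
#' "divide_floor_only"`.
#'
#' @param mock_values Numeric vector (typically length 4) of the
#'   gene's mock-IP values, on the same read scale as `t0_reads`.
#' @param t0_reads The gene's spike-normalized reads at timepoint 0
#'   (pre-normalization to nLuc); must be positive.
#' @param floor Lower floor on the background signal.
#' @param reading Which parse of the max/divide rule to use.
#' @return Scalar background term z.
#' @examples
#' backgroundZ(c(0, 0, 0, 0), t0_reads = 0.001)        # 0.005
#' backgroundZ(rep(0.01, 4), t0_reads = 1)             # 0.01
#' @export
backgroundZ <- function(mock_values, t0_reads, floor = 5e-6,
                        reading = c("max_then_divide",
                                    "divide_floor_only")) {
  reading <- match.arg(reading)
  if (!is.finite(t0_reads) || t0_reads <= 0)
    stop("t0_reads must be positive")
  mx <- if (length(mock_values)) max(mock_values, na.rm = TRUE) else 0
  switch(reading,
         max_then_divide = max(mx, floor) / t0_reads,
         divide_floor_only = max(mx, floor / t0_reads))
}

## model predictions in log2 space for the two background readings
.decayPredict <- function(C, k, z, x, background_mode) {
  if (background_mode == "log_offset")
    log2(C * exp(-k * x)) + z
  else
    log2(C * exp(-k * x) + z)
}

#' Fit the background-corrected exponential decay model
#'
#' Least-squares fit of `y = log2(C * exp(-k * x)) + z` to one decay
#' series, where `y` is the log2 t0-normalized signal, `x` the chase
#' time in hours, and `z` the fixed background term from
#' [backgroundZ()]. `C` and `k` are bounded to `[0, Inf)` with
#' starting values `2^max(y)` and 1, and fit by bounded
#' Levenberg-Marquardt least squares. For Torin1-treated series `C`
#' is fixed to the untreated replicate's fitted value via `c_fixed`
#' (the initial level predates the treatment), and only `k` is
#' optimized.
#'
#' Standard errors and two-sided Wald `Pr(>|t|)` p-values come from
#' the asymptotic covariance with `n - n_free` residual degrees of
#' freedom. A `k` estimate stuck at the 0 boundary is not evidence of
#' decay, so its p-value is set to 1. `background_mode =
#' "linear_plateau"` instead fits `y = log2(C * exp(-k*x) + z)`,
#' treating the background as a linear-scale plateau; use it when the
#' data level off at a floor (as mock-IP background produces).
#'
#' @param time_h Chase times (hours), including 0.
#' @param value t0-normalized linear-scale signal (starts at 1).
#' @param z Fixed background term.
#' @param c_fixed Optional fixed value for `C`.
#' @param cap_h Half-life ceiling in hours.
#' @param background_mode `"log_offset"` (literal additive-z model,
#'   default) or `"linear_plateau"`.
#' @return One-row `data.frame`: `C`, `k`, `z`, `se_C`, `se_k`,
#'   `p_C`, `p_k`, `halflife`, `S` (= C*k), `c_was_fixed`,
#'   `converged`, `sse`, `n_points`.
#' @examples
#' t <- c(0, 1, 2, 4, 8, 28)
#' fitDecay(t, exp(-0.3 * t), z = 0)
#' @export
fitDecay <- function(time_h, value, z, c_fixed = NULL, cap_h = 50,
                     background_mode = c("log_offset",
                                         "linear_plateau")) {
  background_mode <- match.arg(background_mode)
  if (any(time_h < 0)) stop("negative timepoints")
  ok <- is.finite(time_h) & is.finite(value) & value > 0
  x <- time_h[ok]
  y <- log2(value[ok])
  n_free <- if (is.null(c_fixed)) 2L else 1L
  fail <- function() data.frame(
    C = if (is.null(c_fixed)) NA_real_ else c_fixed, k = NA_real_,
    z = z, se_C = NA_real_, se_k = NA_real_, p_C = NA_real_,
    p_k = NA_real_, halflife = NA_real_, S = NA_real_,
    c_was_fixed = !is.null(c_fixed), converged = FALSE,
    sse = NA_real_, n_points = length(x))
  if (length(x) < n_free + 1L || all(value[ok] == 0)) return(fail())
  ctl <- minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                    maxiter = 200)
  dat <- data.frame(x = x, y = y)
  ## log2() is written via log()/log(2) so the model is symbolically
  ## differentiable (analytic Jacobian instead of numericDeriv)
  tryFit <- function(k_start) tryCatch({
    if (is.null(c_fixed)) {
      form <- if (background_mode == "log_offset")
        y ~ (log(C) - k * x) / log(2) + z
      else
        y ~ log(C * exp(-k * x) + z) / log(2)
      minpack.lm::nlsLM(form, data = dat,
                        start = list(C = 2^max(y), k = k_start),
                        lower = c(1e-300, 0), upper = c(Inf, Inf),
                        control = ctl)
    } else {
      C0 <- c_fixed
      form <- if (background_mode == "log_offset")
        y ~ (log(C0) - k * x) / log(2) + z
      else
        y ~ log(C0 * exp(-k * x) + z) / log(2)
      minpack.lm::nlsLM(form, data = dat, start = list(k = k_start),
                        lower = 0, upper = Inf, control = ctl)
    }
  }, error = function(e) NULL)
  fit <- tryFit(1)  # standard starting value
  if (is.null(fit)) {
    ## deterministic fallback: start k at the log-linear slope estimate
    ols <- -coef(lm(y ~ x))[[2L]] * log(2)
    fit <- tryFit(max(ols, 1e-3))
  }
  if (is.null(fit)) return(fail())
  cf <- coef(fit)
  sm <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  getrow <- function(p, col) {
    if (is.null(sm) || !p %in% rownames(sm)) NA_real_ else sm[p, col]
  }
  k <- unname(if ("k" %in% names(cf)) cf["k"] else NA_real_)
  C <- if (is.null(c_fixed)) unname(cf["C"]) else c_fixed
  p_k <- getrow("k", 4L)
  if (is.finite(k) && k <= 0) p_k <- 1  # boundary estimate: no decay
  data.frame(
    C = C, k = k, z = z,
    se_C = getrow("C", 2L), se_k = getrow("k", 2L),
    p_C = if (is.null(c_fixed)) getrow("C", 4L) else NA_real_,
    p_k = p_k,
    halflife = halfLife(k, cap_h), S = C * k,
    c_was_fixed = !is.null(c_fixed),
    converged = isTRUE(fit$convInfo$isConv),
    sse = sum(residuals(fit)^2), n_points = length(x))
}

#' Significance filter on decay fits
#'
#' Keeps fits that converged, have `Pr(>|t|) < alpha` for `k`, and --
#' unless `C` was fixed from the untreated series -- `Pr(>|t|) <
#' alpha` for `C` as well.
#'
#' @param fits `data.frame` of [fitDecay()] rows.
#' @param alpha Significance threshold.
#' @return The retained subset.
#' @export
filterFits <- function(fits, alpha = 0.05) {
  keep <- fits$converged &
    is.finite(fits$p_k) & fits$p_k < alpha &
    (fits$c_was_fixed | (is.finite(fits$p_C) & fits$p_C < alpha))
  out <- fits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Half-life from a decay rate, with ceiling
#'
#' `t1/2 = min(ln(2) / k, cap_h)`; a rate of exactly 0 (no measurable
#' decay) reports the ceiling.
#'
#' @param k Decay rate(s), per hour, nonnegative.
#' @param cap_h Ceiling in hours.
#' @return Half-life in hours (vectorized; `NA` propagates).
#' @examples
#' halfLife(log(2))  # 1
#' halfLife(1e-6)    # 50 (capped)
#' @export
halfLife <- function(k, cap_h = 50) {
  if (any(k < 0, na.rm = TRUE)) stop("negative decay rate")
  ifelse(is.na(k), NA_real_, pmin(log(2) / k, cap_h))
}

#' Average half-lives across replicates
#'
#' Downstream analyses use the arithmetic mean of the half-lives
#' fitted independently per biological replicate; only replicates
#' surviving [filterFits()] contribute. Genes with no surviving
#' replicate get no half-life.
#'
#' @param fits Retained fit rows carrying `gene_id`, `halflife` and
#'   optionally grouping columns.
#' @param by Columns defining one averaged series (besides
#'   `gene_id`).
#' @return `data.frame`: grouping columns, `gene_id`, `halflife`
#'   (mean), `n_replicates`.
#' @export
averageReplicates <- function(fits, by = c("genotype", "treatment")) {
  by <- intersect(by, names(fits))
  sp <- fits[, c("gene_id", by, "halflife"), drop = FALSE]
  agg <- stats::aggregate(sp$halflife,
                          by = sp[, c("gene_id", by), drop = FALSE],
                          FUN = mean)
  names(agg)[ncol(agg)] <- "halflife"
  cnt <- stats::aggregate(sp$halflife,
                          by = sp[, c("gene_id", by), drop = FALSE],
                          FUN = length)
  agg$n_replicates <- as.integer(cnt$x)
  agg
}

#' Autophagy-dependent Torin1-induced stability value
#'
#' `A = (t_wt_torin / t_wt) / (t_ko_torin / t_ko)`: how Torin1
#' changes a gene's half-life in autophagy-competent (WT) cells,
#' relative to the same change in autophagy-deficient (e.g. ATG7-KO)
#' cells. Normalizing within genotype removes clonal baseline
#' differences; comparing across genotypes isolates the autophagy
#' contribution from other mTORC1 effects. `A < 1` means autophagy
#' destabilizes the RNA upon mTORC1 inhibition. Undefined (`NA`)
#' unless all four half-lives are present and positive.
#'
#' @param t_wt,t_wt_torin,t_ko,t_ko_torin Half-lives (hours) in the
#'   four conditions (vectorized).
#' @return Stability value(s) A.
#' @examples
#' stabilityMetric(10, 5, 10, 10)  # 0.5
#' @export
stabilityMetric <- function(t_wt, t_wt_torin, t_ko, t_ko_torin) {
  a <- (t_wt_torin / t_wt) / (t_ko_torin / t_ko)
  bad <- !is.finite(t_wt) | !is.finite(t_wt_torin) |
    !is.finite(t_ko) | !is.finite(t_ko_torin) |
    t_wt <= 0 | t_wt_torin <= 0 | t_ko <= 0 | t_ko_torin <= 0
  a[bad] <- NA_real_
  a
}

#' Fit the decay model across a whole pulse-chase experiment
#'
#' Orchestrates the per-gene pipeline on a raw long time course:
#' nLuc normalization, t0 normalization, per-gene background z from
#' the mock-IP table (denominator = the series' raw time-0 reads),
#' untreated fits first, then Torin1 fits with `C` fixed to the same
#' replicate's untreated estimate.
#'
#' @param timecourse Raw long time course including nLuc rows.
#' @param mock Mock-IP table: `gene_id`, `mock_1` .. `mock_4`.
#' @param nluc_id nLuc row id.
#' @param floor,cap_h,alpha,background_mode,z_reading Stage
#'   parameters; see [backgroundZ()], [fitDecay()], [filterFits()].
#' @param share_c If `TRUE` (default, the standard procedure), treated
#'   series are fit with `C` fixed to the untreated replicate's
#'   estimate; `FALSE` fits every series independently (for comparing
#'   the two schemes).
#' @return List: `fits` (all per-replicate fits, with `gene_id`,
#'   `genotype`, `treatment`, `replicate` columns), `retained`
#'   (post-filter), `halflives` (replicate-averaged), `excluded_t0`
#'   (series dropped at t0 normalization).
#' @export
fitDecayTable <- function(timecourse, mock, nluc_id = "nLuc",
                          floor = 5e-6, cap_h = 50, alpha = 0.05,
                          background_mode = c("log_offset",
                                              "linear_plateau"),
                          z_reading = c("max_then_divide",
                                        "divide_floor_only"),
                          share_c = TRUE) {
  background_mode <- match.arg(background_mode)
  z_reading <- match.arg(z_reading)
  raw <- timecourse[timecourse$gene_id != nluc_id, , drop = FALSE]
  rawKey <- paste(raw$gene_id, raw$genotype, raw$treatment,
                  raw$replicate, sep = "\r")
  t0raw <- setNames(raw$count[raw$time_h == 0],
                    rawKey[raw$time_h == 0])
  nn <- nlucNormalize(timecourse, nluc_id)
  tc <- t0Normalize(nn)
  mockMax <- setNames(
    apply(as.matrix(mock[, grep("^mock_", names(mock)), drop = FALSE]),
          1, max),
    mock$gene_id)
  series <- unique(tc[, c("gene_id", "genotype", "treatment",
                          "replicate")])
  key <- paste(tc$gene_id, tc$genotype, tc$treatment, tc$replicate,
               sep = "\r")
  idx <- split(seq_len(nrow(tc)), key)
  fitOne <- function(g, gt, tr, rep_i, c_fixed) {
    rows <- idx[[paste(g, gt, tr, rep_i, sep = "\r")]]
    t0r <- t0raw[[paste(g, gt, tr, rep_i, sep = "\r")]]
    mv <- if (g %in% names(mockMax)) mockMax[[g]] else 0
    zz <- backgroundZ(mv, t0r, floor = floor, reading = z_reading)
    fitDecay(tc$time_h[rows], tc$count[rows], z = zz,
             c_fixed = c_fixed, cap_h = cap_h,
             background_mode = background_mode)
  }
  out <- vector("list", nrow(series))
  untreatedC <- new.env(parent = emptyenv())
  sOrd <- order(series$treatment != "none")  # untreated first
  for (i in sOrd) {
    g <- series$gene_id[i]; gt <- series$genotype[i]
    tr <- series$treatment[i]; rp <- series$replicate[i]
    cfix <- NULL
    if (share_c && tr != "none") {
      ck <- paste(g, gt, rp, sep = "\r")
      if (exists(ck, envir = untreatedC))
        cfix <- get(ck, envir = untreatedC)
    }
    f <- fitOne(g, gt, tr, rp, cfix)
    if (tr == "none" && isTRUE(f$converged) && is.finite(f$C))
      assign(paste(g, gt, rp, sep = "\r"), f$C, envir = untreatedC)
    out[[i]] <- cbind(data.frame(gene_id = g, genotype = gt,
                                 treatment = tr, replicate = rp,
                                 stringsAsFactors = FALSE), f)
  }
  fits <- do.call(rbind, out)
  retained <- filterFits(fits, alpha = alpha)
  halflives <- if (nrow(retained)) averageReplicates(retained)
               else data.frame(gene_id = character(),
                               genotype = character(),
                               treatment = character(),
                               halflife = numeric(),
                               n_replicates = integer())
  list(fits = fits, retained = retained, halflives = halflives,
       excluded_t0 = attr(tc, "excluded"))
}

#' Per-gene stability values from averaged half-lives
#'
#' Joins the four genotype/treatment half-life columns and applies
#' [stabilityMetric()].
#'
#' @param halflives Output of [averageReplicates()] /
#'   `fitDecayTable()$halflives`.
#' @param wt,ko Genotype labels of the autophagy-competent and
#'   autophagy-deficient lines.
#' @param torin_label Treatment label of the Torin1 arm.
#' @return `data.frame`: `gene_id`, the four half-lives, `stability`.
#' @export
stabilityTable <- function(halflives, wt = "WT", ko = "ATG7KO",
                           torin_label = "torin1") {
  pick <- function(gt, tr) {
    sub <- halflives[halflives$genotype == gt &
                     halflives$treatment == tr, ]
    setNames(sub$halflife, sub$gene_id)
  }
  t_wt <- pick(wt, "none"); t_wtT <- pick(wt, torin_label)
  t_ko <- pick(ko, "none"); t_koT <- pick(ko, torin_label)
  genes <- Reduce(union, list(names(t_wt), names(t_wtT), names(t_ko),
                              names(t_koT)))
  g <- function(v) unname(v[match(genes, names(v))])
  data.frame(gene_id = genes,
             halflife_wt = g(t_wt), halflife_wt_torin = g(t_wtT),
             halflife_ko = g(t_ko), halflife_ko_torin = g(t_koT),
             stability = stabilityMetric(g(t_wt), g(t_wtT), g(t_ko),
                                         g(t_koT)),
             row.names = NULL, stringsAsFactors = FALSE)
}
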