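#' Aggregate single-cell measurements into a gradient profile
#'
#' Per-position mean, standard error of the mean (SD/sqrt(n)) and n over
#' cells, for one condition, along either the distance or the time axis.
#' Positions with no measurements are dropped (with a message).
#'
#' @param measurements data frame with columns `cell_id`, `condition`,
#'   `distance_um`, `time_min`, `conc_nM` and optionally `diff_coeff_m2s`
#'   (see [generate_gradient_dataset()]).
#' @param condition condition label to retain.
#' @param axis `"distance"` or `"time"`.
#' @param at for `axis = "distance"`, the time point to hold fixed (default:
#'   latest available); for `axis = "time"`, the distance to hold fixed
#'   (default: smallest available).
#' @return data frame of class `gradient_profile` with columns `condition`,
#'   `axis`, `position`, `mean_conc`, `sem_conc`, `n`, and (when available)
#'   `mean_D`, `sem_D`.
#' @export
build_profile <- function(measurements, condition,
                          axis = c("distance", "time"), at = NULL) {
  axis <- match.arg(axis)
  m <- measurements[measurements$condition == condition, , drop = FALSE]
  if (nrow(m) == 0L) stop("no measurements for condition: ", condition)
  if (axis == "distance") {
    at <- at %||% max(m$time_min)
    m <- m[m$time_min == at, , drop = FALSE]
    pos_col <- "distance_um"
  } else {
    at <- at %||% min(m$distance_um)
    m <- m[m$distance_um == at, , drop = FALSE]
    pos_col <- "time_min"
  }
  if (nrow(m) == 0L) stop("no measurements at the requested fixed position")
  sem <- function(v) if (length(v) > 1L) sd(v) / sqrt(length(v)) else 0
  agg <- function(col, f) {
    a <- aggregate(m[[col]], by = list(position = m[[pos_col]]), FUN = f)
    a$x
  }
  positions <- sort(unique(m[[pos_col]]))
  out <- data.frame(
    condition = condition, axis = axis, position = positions,
    mean_conc = agg("conc_nM", mean),
    sem_conc = agg("conc_nM", sem),
    n = agg("conc_nM", length))
  if ("diff_coeff_m2s" %in% names(m)) {
    out$mean_D <- agg("diff_coeff_m2s", mean)
    out$sem_D <- agg("diff_coeff_m2s", sem)
  }
  class(out) <- c("gradient_profile", "data.frame")
  attr(out, "fixed_at") <- at
  out
}

#' One-sample t-test against a reference concentration
#'
#' Compares measured concentrations to a fixed reference (e.g. the nominal
#' added ligand concentration). Accepts either raw values or a printed
#' summary triple (mean, sem, n); the two routes agree exactly when the
#' summary is computed from the same values. Two-sided p from the t
#' distribution with `n - 1` degrees of freedom, `t = (mean - mu0)/sem`.
#'
#' @param values raw measurement vector (used when `mean`/`sem` are absent).
#' @param mu0 reference value (same units).
#' @param mean,sem,n summary-statistics route: mean, SEM and sample size.
#' @return data frame of class `stat_result` with columns `test`,
#'   `statistic`, `df`, `p_value`, `comparison`, `adjusted`, `flag`.
#' @examples
#' one_sample_ttest(mean = 5.1, sem = 0.8, n = 8, mu0 = 1.8)
#' @export
one_sample_ttest <- function(values = NULL, mu0, mean = NULL, sem = NULL,
                             n = NULL) {
  if (is.null(mean)) {
    if (is.null(values) || length(values) < 2L)
      stop("need raw values (n >= 2) or a (mean, sem, n) summary")
    n <- length(values)
    mean <- base::mean(values)
    sem <- sd(values) / sqrt(n)
  }
  if (n < 2L) stop("n must be at least 2")
  flag <- NA_character_
  if (sem == 0) {
    if (mean == mu0) {
      tstat <- 0; p <- 1
    } else {
      tstat <- Inf * sign(mean - mu0); p <- 0
    }
    flag <- "degenerate: sem = 0"
  } else {
    tstat <- (mean - mu0) / sem
    p <- 2 * pt(-abs(tstat), df = n - 1)
  }
  structure(data.frame(
    test = "one-sample t", statistic = tstat, df = n - 1, p_value = p,
    comparison = sprintf("mean %.4g vs mu0 %.4g", mean, mu0),
    adjusted = FALSE, flag = flag, stringsAsFactors = FALSE),
    class = c("stat_result", "data.frame"))
}

#' Two-way ANOVA on cell-level measurements
#'
#' Fits `response ~ factor_a * factor_b` on cell-level values (each cell is
#' one replicate) and reports Type-II F tests for both main effects and the
#' interaction. The synthetic generator produces balanced designs, where
#' Type-II and Type-I sums of squares coincide for main effects; unbalanced
#' input triggers a warning and documented Type-II behaviour. Both factors
#' are treated as categorical.
#'
#' @param table data frame of measurements.
#' @param response response column name (default `"conc_nM"`).
#' @param factor_a,factor_b factor column names (e.g. `"condition"`,
#'   `"distance_um"`).
#' @return object of class `micropk_anova`: `tests` (a `stat_result` data
#'   frame with one row per term), `fit` (the underlying `lm`), `factors`,
#'   `response`.
#' @export
two_way_anova <- function(table, response = "conc_nM",
                          factor_a = "condition", factor_b = "distance_um") {
  for (col in c(response, factor_a, factor_b))
    if (!col %in% names(table)) stop("missing column: ", col)
  d <- data.frame(y = table[[response]],
                  A = factor(table[[factor_a]]),
                  B = factor(table[[factor_b]]))
  if (nlevels(d$A) < 2L || nlevels(d$B) < 2L)
    stop("each factor needs at least 2 levels")
  counts <- table(d$A, d$B)
  if (length(unique(as.vector(counts))) != 1L)
    warning("unbalanced design: Type-II sums of squares are reported")
  if (var(d$y) == 0) {
    tests <- data.frame(
      test = "two-way ANOVA (II)",
      statistic = NA_real_, df = NA_real_, p_value = NA_real_,
      comparison = c(factor_a, factor_b, paste0(factor_a, ":", factor_b)),
      adjusted = FALSE, flag = "zero variance", stringsAsFactors = FALSE)
    class(tests) <- c("stat_result", "data.frame")
    return(structure(list(tests = tests, fit = NULL,
                          factors = c(factor_a, factor_b), response = response),
                     class = "micropk_anova"))
  }
  fit <- lm(y ~ A * B, data = d)
  aov2 <- car::Anova(fit, type = 2)
  terms <- c("A", "B", "A:B")
  labels <- c(factor_a, factor_b, paste0(factor_a, ":", factor_b))
  idx <- match(terms, rownames(aov2))
  tests <- data.frame(
    test = "two-way ANOVA (II)",
    statistic = aov2[idx, "F value"],
    df = aov2[idx, "Df"],
    p_value = aov2[idx, "Pr(>F)"],
    comparison = labels, adjusted = FALSE, flag = NA_character_,
    stringsAsFactors = FALSE)
  class(tests) <- c("stat_result", "data.frame")
  structure(list(tests = tests, fit = fit, data = d,
                 factors = c(factor_a, factor_b), response = response),
            class = "micropk_anova")
}

#' @export
print.micropk_anova <- function(x, ...) {
  cat("<micropk_anova>\n")
  print(x$tests)
  invisible(x)
}

#' Post-hoc multiple comparisons after a two-way ANOVA
#'
#' Family-wise adjusted comparisons on the estimated marginal means of
#' `factor`: all pairwise with Tukey adjustment, or each level versus a
#' reference with the Dunnett-style adjustment, optionally stratified `by`
#' the other factor (e.g. comparisons between conditions at each distance).
#'
#' @param anova a fitted [two_way_anova()] result.
#' @param method `"tukey"` or `"dunnett"`.
#' @param factor which factor to compare: `"a"` or `"b"` (default `"a"`).
#' @param by if `TRUE` (default), stratify by the other factor.
#' @param reference reference level (required for `dunnett`); its name in
#'   the original coding.
#' @return `stat_result` data frame, one row per comparison, with adjusted
#'   p values.
#' @export
posthoc <- function(anova, method = c("tukey", "dunnett"), factor = "a",
                    by = TRUE, reference = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(anova, "micropk_anova"))
  if (is.null(anova$fit)) stop("ANOVA context is degenerate (zero variance)")
  fac <- if (identical(factor, "a")) "A" else "B"
  other <- setdiff(c("A", "B"), fac)
  spec <- if (by) stats::as.formula(paste0("~ ", fac, " | ", other))
          else stats::as.formula(paste0("~ ", fac))
  emm <- emmeans::emmeans(anova$fit, spec)
  if (method == "tukey") {
    cmp <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "tukey"))
  } else {
    lev <- levels(anova$data[[fac]])
    if (is.null(reference)) stop("dunnett requires a reference level")
    ref_i <- match(as.character(reference), lev)
    if (is.na(ref_i)) stop("reference level not found: ", reference)
    cmp <- summary(emmeans::contrast(emm, method = "trt.vs.ctrl",
                                     ref = ref_i, adjust = "dunnettx"))
  }
  lab <- as.character(cmp$contrast)
  if (!is.null(cmp[[other]])) lab <- paste0(lab, " @ ", cmp[[other]])
  out <- data.frame(
    test = paste0("posthoc ", method),
    statistic = cmp$t.ratio, df = cmp$df, p_value = cmp$p.value,
    comparison = lab, adjusted = TRUE, flag = NA_character_,
    stringsAsFactors = FALSE)
  class(out) <- c("stat_result", "data.frame")
  out
}

#' Micro-pharmacokinetic true-affinity correction
#'
#' Equilibrium affinity estimates assume the receptor sees the bulk ligand
#' concentration. If the local concentration in the receptor's
#' microenvironment (`l_micro`) exceeds the bulk value (`l_bulk`), the
#' apparent Kd understates the true dissociation constant by the same
#' factor: `fold = l_micro / l_bulk`, `kd_true = kd_apparent * fold`.
#'
#' @param kd_apparent apparent equilibrium Kd in nM (> 0).
#' @param l_bulk bulk ligand concentration in nM (> 0).
#' @param l_micro local (near-membrane) ligand concentration in nM (> 0).
#' @return object of class `micropk_result`: `kd_apparent_nM`, `l_bulk_nM`,
#'   `l_micro_nM`, `fold`, `kd_true_nM`.
#' @examples
#' true_affinity(1.8, l_bulk = 1.8, l_micro = 45.7) # ~25-fold, ~45.7 nM
#' @export
true_affinity <- function(kd_apparent, l_bulk, l_micro) {
  if (kd_apparent <= 0 || l_bulk <= 0 || l_micro <= 0)
    stop("all inputs must be positive")
  fold <- l_micro / l_bulk
  structure(list(kd_apparent_nM = kd_apparent, l_bulk_nM = l_bulk,
                 l_micro_nM = l_micro, fold = fold,
                 kd_true_nM = kd_apparent * fold),
            class = "micropk_result")
}

#' @export
print.micropk_result <- function(x, ...) {
  cat(sprintf(
    "<micropk_result> Kd(apparent) = %.4g nM, L_micro/L_bulk = %.3g-fold -> Kd(true) = %.4g nM\n",
    x$kd_apparent_nM, x$fold, x$kd_true_nM))
  invisible(x)
}
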