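#' Kruskal-Wallis test of scores across groups
#'
#' Rank-based test (with tie correction) of whether score distributions
#' differ between groups, e.g. subjects grouped by total SVD score; the
#' statistic is referred to a chi-square with `groups - 1` degrees of
#' freedom.
#'
#' @param x Numeric scores.
#' @param g Group labels (coerced to factor).
#' @return Object of class `kw_result`: list with `chi_square`, `df`,
#'   `p_value`.
#' @export
kw_test <- function(x, g) {
  g <- factor(g)
  g <- droplevels(g[!is.na(x)])
  x <- x[!is.na(x)]
  if (nlevels(g) < 2L)
    stop("need at least two non-empty groups", call. = FALSE)
  if (stats::var(x) == 0)
    stop("degenerate scores: all values identical", call. = FALSE)
  kt <- stats::kruskal.test(x, g)
  structure(list(chi_square = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p_value = kt$p.value),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: chi^2 = %.3f, df = %d, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}

# z-score a numeric vector (binary covariates are standardised the same
# way so every coefficient is comparable)
zscore <- function(x) {
  s <- stats::sd(x)
  if (s == 0) stop("constant covariate cannot be standardised",
                   call. = FALSE)
  (x - mean(x)) / s
}

#' Standardised multiple regression of scores on clinical covariates
#'
#' Fits `score ~ age + WMH fraction + sex + lesion type` by ordinary
#' least squares after z-scoring the response and every predictor
#' (binary predictors included, so each beta is a standardised
#' coefficient).  Sex is coded female = 1, male = 0 and lesion type
#' lacunar = 1, cortical = 0 before standardisation.
#'
#' @param y Numeric response (one score per subject).
#' @param covariates Data.frame with columns `age`, `wmh_fraction`,
#'   `sex` (`"male"`/`"female"`) and `lacunar` (logical).
#' @param predictors Covariate columns to include; the defaults give
#'   one standardised beta each for `Age`, `WMH`, `Sex`, `Lac`.
#' @param condition_threshold Condition-number limit of the
#'   standardised design above which a collinearity error is raised.
#' @return Object of class `std_regression`: list with `beta` and
#'   `p_value` (named `Age`, `WMH`, `Sex`, `Lac`), `adj_r2`, `model_p`
#'   (overall F test), `n`, and the coding used.
#' @export
standardized_regression <- function(y, covariates,
                                    predictors = c("age", "wmh_fraction",
                                                   "sex", "lacunar"),
                                    condition_threshold = 1e8) {
  stopifnot(length(y) == nrow(covariates),
            all(predictors %in% names(covariates)))
  p <- length(predictors)
  if (length(y) <= p + 1L)
    stop("need more subjects than predictors + 1", call. = FALSE)
  label <- c(age = "Age", wmh_fraction = "WMH", sex = "Sex",
             lacunar = "Lac")
  as_num <- function(col, v) switch(col,
    sex = as.numeric(v == "female"),
    lacunar = as.numeric(v),
    as.numeric(v))
  Z <- data.frame(y = zscore(y))
  for (col in predictors) {
    nm <- if (col %in% names(label)) label[[col]] else col
    Z[[nm]] <- zscore(as_num(col, covariates[[col]]))
  }
  X <- as.matrix(Z[, -1L, drop = FALSE])
  if (kappa(crossprod(X), exact = TRUE) > condition_threshold^2)
    stop("collinear predictors: condition number above threshold",
         call. = FALSE)
  fit <- stats::lm(y ~ ., data = Z)
  sm <- summary(fit)
  co <- sm$coefficients
  fstat <- sm$fstatistic
  structure(list(
    beta = stats::setNames(co[-1L, "Estimate"], rownames(co)[-1L]),
    p_value = stats::setNames(co[-1L, "Pr(>|t|)"], rownames(co)[-1L]),
    adj_r2 = sm$adj.r.squared,
    model_p = unname(stats::pf(fstat[1L], fstat[2L], fstat[3L],
                               lower.tail = FALSE)),
    n = length(y),
    coding = c(sex = "female = 1", lacunar = "lacunar = 1")),
    class = "std_regression")
}

#' @export
print.std_regression <- function(x, ...) {
  cat(sprintf("Standardised regression (n = %d): adj. R^2 = %.3f, model p = %.4g\n",
              x$n, x$adj_r2, x$model_p))
  for (nm in names(x$beta))
    cat(sprintf("  beta_%-4s = %+.3f (p = %.4g)\n", nm, x$beta[nm],
                x$p_value[nm]))
  invisible(x)
}

#' Associate a score table with clinical covariates
#'
#' For every (region unit, descriptor) cell of a long-format score
#' table, runs the Kruskal-Wallis test across total-SVD-score groups
#' and the standardised multiple regression on age, WMH fraction, sex
#' and lesion type.  Mirrors a per-cell results layout; no multiplicity
#' correction is applied to the reported p-values, but a
#' Benjamini-Hochberg adjusted column is emitted alongside for
#' reference.  Degenerate cells (e.g. constant scores) are flagged in a
#' `note` column and skipped rather than aborting the run.
#'
#' @param score_table Data.frame with columns `subject_id`, `tier`,
#'   `tissue`, `descriptor`, `score`.
#' @param covariates Covariate table as from [generate_covariates()]
#'   (must cover every subject in `score_table`).
#' @return List with data.frames `kw` (tier, tissue, descriptor,
#'   chi_square, df, p_value, p_bh, note) and `regression` (tier,
#'   tissue, descriptor, adj_r2, model_p, model_p_bh, beta_*, p_*,
#'   note).
#' @export
run_validation <- function(score_table, covariates) {
  need <- c("subject_id", "tier", "tissue", "descriptor", "score")
  stopifnot(all(need %in% names(score_table)))
  miss <- setdiff(score_table$subject_id, covariates$subject_id)
  if (length(miss))
    stop(sprintf("subjects missing from covariate table: %s",
                 paste(utils::head(miss, 3L), collapse = ", ")),
         call. = FALSE)
  cells <- unique(score_table[, c("tier", "tissue", "descriptor")])
  kw_rows <- list(); reg_rows <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    sel <- score_table$tier == cell$tier &
      score_table$tissue == cell$tissue &
      score_table$descriptor == cell$descriptor
    st <- score_table[sel, ]
    cv <- covariates[match(st$subject_id, covariates$subject_id), ]
    kw <- tryCatch(kw_test(st$score, cv$svd_score), error = identity)
    kw_rows[[i]] <- data.frame(
      tier = cell$tier, tissue = cell$tissue,
      descriptor = cell$descriptor,
      chi_square = if (inherits(kw, "error")) NA_real_ else kw$chi_square,
      df = if (inherits(kw, "error")) NA_integer_ else kw$df,
      p_value = if (inherits(kw, "error")) NA_real_ else kw$p_value,
      note = if (inherits(kw, "error")) conditionMessage(kw) else "",
      stringsAsFactors = FALSE)
    rg <- tryCatch(standardized_regression(st$score, cv), error = identity)
    reg_rows[[i]] <- if (inherits(rg, "error")) data.frame(
      tier = cell$tier, tissue = cell$tissue,
      descriptor = cell$descriptor, adj_r2 = NA_real_,
      model_p = NA_real_, beta_Age = NA_real_, beta_WMH = NA_real_,
      beta_Sex = NA_real_, beta_Lac = NA_real_, p_Age = NA_real_,
      p_WMH = NA_real_, p_Sex = NA_real_, p_Lac = NA_real_,
      note = conditionMessage(rg), stringsAsFactors = FALSE)
    else data.frame(
      tier = cell$tier, tissue = cell$tissue,
      descriptor = cell$descriptor, adj_r2 = rg$adj_r2,
      model_p = rg$model_p,
      beta_Age = rg$beta[["Age"]], beta_WMH = rg$beta[["WMH"]],
      beta_Sex = rg$beta[["Sex"]], beta_Lac = rg$beta[["Lac"]],
      p_Age = rg$p_value[["Age"]], p_WMH = rg$p_value[["WMH"]],
      p_Sex = rg$p_value[["Sex"]], p_Lac = rg$p_value[["Lac"]],
      note = "", stringsAsFactors = FALSE)
  }
  kw <- do.call(rbind, kw_rows)
  reg <- do.call(rbind, reg_rows)
  kw$p_bh <- stats::p.adjust(kw$p_value, method = "BH")
  reg$model_p_bh <- stats::p.adjust(reg$model_p, method = "BH")
  list(kw = kw, regression = reg)
}
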