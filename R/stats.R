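#' Mask outlying values by iterated studentized-residual testing
#'
#' Per variable, fits a null model (intercept only, or group means when a
#' group column is present), tests the largest-magnitude studentized
#' residual with a Bonferroni-corrected two-sided p value
#' (\code{car::outlierTest}), masks the offending cell when significant,
#' and repeats until nothing more is flagged.  Masking is cell-wise (the
#' subject's other variables are untouched), so effective n can differ
#' across variables, as is typical in screened physiological tables.
#'
#' @param table data.frame of subjects
#' @param variables character vector of numeric columns to screen
#' @param alpha significance level for the Bonferroni-corrected test
#' @param group_col optional grouping column used in the null model
#' @return list: \code{table} (with masked cells set \code{NA}) and
#'   \code{log} (data.frame variable/row/value for every removal); a
#'   warning is raised for heavy-tailed variables losing > 20\% of values
#' @export
remove_outliers <- function(table, variables, alpha = 0.05,
                            group_col = "group") {
  log_rows <- list()
  for (v in variables) {
    stop_if_not(v %in% names(table), paste("missing variable:", v))
    stop_if_not(sum(is.finite(table[[v]])) >= 10,
                "need at least 10 observations per screened variable")
    n0 <- sum(is.finite(table[[v]]))
    repeat {
      idx <- which(is.finite(table[[v]]))
      if (length(idx) < 4) break
      dat <- data.frame(y = table[[v]][idx])
      has_grp <- !is.null(group_col) && group_col %in% names(table) &&
        length(unique(table[[group_col]][idx])) > 1
      m <- if (has_grp) {
        dat$g <- factor(table[[group_col]][idx])
        lm(y ~ g, data = dat)
      } else lm(y ~ 1, data = dat)
      ot <- car::outlierTest(m, cutoff = Inf, n.max = 1)
      p <- unname(ot$bonf.p[1])
      if (is.na(p)) p <- 1
      if (p >= alpha) break
      bad <- idx[as.integer(names(ot$rstudent)[1])]
      log_rows[[length(log_rows) + 1]] <-
        data.frame(variable = v, row = bad, value = table[[v]][bad],
                   bonf_p = p)
      table[[v]][bad] <- NA
    }
    if (n0 - sum(is.finite(table[[v]])) > 0.2 * n0)
      warning("heavy-tailed variable: more than 20% of '", v, "' masked")
  }
  list(table = table,
       log = if (length(log_rows)) do.call(rbind, log_rows)
             else data.frame(variable = character(), row = integer(),
                             value = numeric(), bonf_p = numeric()))
}

#' Choose between a linear model and a gamma GLM for a response
#'
#' Shapiro-Wilk screening: a sample that rejects normality (p < alpha) and
#' is strictly positive is routed to a gamma GLM (log link); anything else
#' is analysed with an ordinary linear model.  Non-normal samples
#' containing non-positive values fall back to the linear model with a
#' warning, since the gamma family is undefined for them.
#'
#' @param values numeric vector (n >= 3)
#' @param alpha Shapiro-Wilk significance level
#' @return \code{"linear"} or \code{"gamma-glm"}, with attributes
#'   \code{shapiro_p}
#' @export
choose_model <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  stop_if_not(length(values) >= 3, "need at least 3 values")
  sw <- shapiro.test(if (length(values) > 5000) sample(values, 5000)
                     else values)
  model <- "linear"
  if (sw$p.value < alpha) {
    if (all(values > 0)) {
      model <- "gamma-glm"
    } else {
      warning("non-normal response with non-positive values; ",
              "falling back to the linear model")
    }
  }
  structure(model, shapiro_p = sw$p.value)
}

#' Group contrast with covariates and partial eta squared
#'
#' Regresses the variable on group plus covariates, using either ordinary
#' least squares or a gamma GLM with log link (chosen automatically via
#' \code{\link{choose_model}} unless forced).  The reported statistic is
#' the group coefficient's t (Wald t for the GLM), with
#' \eqn{\eta_p^2 = t^2 / (t^2 + df_{res})}.  Before fitting, the design
#' matrix is screened with \code{\link{condition_index}}; a condition index
#' above 30 means harmful collinearity and the covariate set is refused.
#'
#' @param table data.frame with the variable, a \code{group} column (two
#'   levels) and any covariates
#' @param variable response column name
#' @param covariates character vector of numeric covariate columns
#' @param model \code{NULL} for automatic choice, else \code{"linear"} or
#'   \code{"gamma-glm"}
#' @param group_col name of the grouping column
#' @return one-row data.frame: variable, model, t, p, eta_p_sq, df,
#'   n per group
#' @export
group_contrast <- function(table, variable, covariates = "IQ",
                           model = NULL, group_col = "group") {
  stop_if_not(variable %in% names(table), "variable not in table")
  covariates <- covariates[covariates %in% names(table)]
  dat <- data.frame(y = table[[variable]],
                    g = factor(table[[group_col]]))
  for (cv in covariates) dat[[cv]] <- table[[cv]]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  stop_if_not(nlevels(droplevels(dat$g)) == 2,
              "both groups must be represented")
  if (is.null(model)) model <- as.character(choose_model(dat$y))
  fml <- if (length(covariates))
    stats::as.formula(paste("y ~ g +", paste(covariates, collapse = " + ")))
  else y ~ g
  X <- model.matrix(fml, dat)
  if (ncol(X) >= 2) {
    ci <- condition_index(X)
    if (ci$flagged)
      stop("condition index ", round(ci$index, 1),
           " > 30: collinear covariate set refused", call. = FALSE)
  }
  fit <- if (model == "gamma-glm") {
    stop_if_not(all(dat$y > 0), "gamma GLM requires positive response")
    glm(fml, data = dat, family = Gamma(link = "log"))
  } else lm(fml, data = dat)
  sm <- summary(fit)$coefficients
  grow <- grep("^g", rownames(sm))[1]
  tval <- sm[grow, 3]
  df <- df.residual(fit)
  pval <- 2 * pt(-abs(tval), df)
  ns <- tabulate(droplevels(dat$g), nbins = 2)
  data.frame(variable = variable, model = model,
             t = tval, p = pval,
             eta_p_sq = partial_eta_squared(tval, df), df = df,
             n_1 = ns[1], n_2 = ns[2])
}

#' Pooled two-sample t statistic from summary statistics
#'
#' The classic equal-variance two-sample t,
#' \deqn{t = (m_1 - m_2) / (s_p \sqrt{1/n_1 + 1/n_2}),\quad
#'       s_p^2 = \frac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2},}
#' for recomputing printed group-table statistics from their means and SDs.
#'
#' @param m1,s1,n1 mean, SD and size of group 1
#' @param m2,s2,n2 mean, SD and size of group 2
#' @return t statistic with attribute \code{df}
#' @export
pooled_t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  stop_if_not(s1 >= 0 && s2 >= 0, "SDs must be non-negative")
  stop_if_not(n1 >= 2 && n2 >= 2, "group sizes must be at least 2")
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  if (sp2 == 0) {
    if (m1 == m2) return(structure(0, df = n1 + n2 - 2))
    stop("zero pooled variance with unequal means", call. = FALSE)
  }
  structure((m1 - m2) / (sqrt(sp2) * sqrt(1 / n1 + 1 / n2)),
            df = n1 + n2 - 2)
}

#' Partial eta squared from a t statistic
#'
#' \eqn{\eta_p^2 = t^2 / (t^2 + df)}: the effect-size share of variance
#' attributable to one model term.  Invariant to the sign of t.
#'
#' @param t t statistic
#' @param df residual degrees of freedom (> 0)
#' @return partial eta squared in [0, 1]
#' @export
partial_eta_squared <- function(t, df) {
  stop_if_not(df > 0, "df must be positive")
  t^2 / (t^2 + df)
}

#' Largest condition index of a design matrix
#'
#' Columns are scaled to unit Euclidean norm; the index is the square root
#' of the ratio of the largest to the smallest eigenvalue of the scaled
#' cross-product matrix.  Values above 30 indicate harmful
#' multicollinearity.
#'
#' @param design numeric matrix with at least 2 columns
#' @param threshold flag threshold (default 30)
#' @return list: \code{index}, \code{flagged}, \code{eigenvalues}
#' @export
condition_index <- function(design, threshold = 30) {
  stop_if_not(is.matrix(design) && ncol(design) >= 2,
              "design must have at least 2 columns")
  norms <- sqrt(colSums(design^2))
  if (any(norms == 0))
    return(list(index = Inf, flagged = TRUE, eigenvalues = NULL))
  Xs <- sweep(design, 2, norms, "/")
  ev <- eigen(crossprod(Xs), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  idx <- if (min(ev) < max(ev) * 1e-14) Inf else sqrt(max(ev) / min(ev))
  list(index = idx, flagged = idx > threshold, eigenvalues = ev)
}

#' FDR-corrected Spearman correlation network
#'
#' Computes Spearman rank correlations (midranks for ties) for every
#' unique variable pair, Benjamini-Hochberg-adjusts the p values within
#' each group's family of pairs, and flags the edges surviving
#' \code{adjusted p < alpha}.  Constant variables yield undefined r; those
#' edges are reported but excluded from the FDR family.
#'
#' @param table subject data.frame
#' @param variables character vector of numeric columns
#' @param by_group when TRUE (default), a separate correlation network per
#'   level of \code{group_col}
#' @param alpha edge-retention level on the adjusted p
#' @param group_col grouping column name
#' @return data.frame edge list: group, var_i, var_j, n, rho, p, p_adj,
#'   kept
#' @export
spearman_fdr <- function(table, variables, by_group = TRUE, alpha = 0.05,
                         group_col = "group") {
  groups <- if (by_group && group_col %in% names(table))
    split(table, table[[group_col]]) else list(all = table)
  out <- lapply(names(groups), function(gname) {
    tab <- groups[[gname]]
    prs <- utils::combn(variables, 2)
    rows <- lapply(seq_len(ncol(prs)), function(k) {
      vi <- prs[1, k]; vj <- prs[2, k]
      x <- tab[[vi]]; y <- tab[[vj]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 5)
        return(data.frame(group = gname, var_i = vi, var_j = vj,
                          n = sum(ok), rho = NA_real_, p = NA_real_))
      if (sd(x[ok]) == 0 || sd(y[ok]) == 0)
        return(data.frame(group = gname, var_i = vi, var_j = vj,
                          n = sum(ok), rho = NA_real_, p = NA_real_))
      ct <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman",
                                      exact = FALSE))
      data.frame(group = gname, var_i = vi, var_j = vj, n = sum(ok),
                 rho = unname(ct$estimate), p = ct$p.value)
    })
    ed <- do.call(rbind, rows)
    ed$p_adj <- NA_real_
    fam <- is.finite(ed$p)
    ed$p_adj[fam] <- p.adjust(ed$p[fam], method = "BH")
    ed$kept <- !is.na(ed$p_adj) & ed$p_adj < alpha
    ed
  })
  do.call(rbind, out)
}
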