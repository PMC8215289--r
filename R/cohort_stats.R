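# Cohort-level demographic and cognitive statistics: chi-square tests of
# categorical risk factors, one-way ANOVA, ANCOVA group effects, Trail Making
# difference scoring, and MRI-based reclassification totals.

#' Pearson chi-square test of a contingency table
#'
#' Plain Pearson statistic \eqn{\sum (O-E)^2/E} without continuity
#' correction, df = (r-1)(c-1).
#'
#' @param table r x c matrix of nonnegative integer counts.
#' @return list: `chi2`, `df`, `p`.
#' @export
pearsonChiSquare <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0) || sum(m) <= 0) stop("counts must be nonnegative, total > 0")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero row or column margin")
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  chi2 <- sum((m - e)^2 / e)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' One-way analysis of variance
#'
#' Wrapper over `stats::aov` on stacked data. With two groups the F statistic
#' equals the square of the pooled two-sample t.
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 values).
#' @return list: `F`, `df1`, `df2`, `p`.
#' @export
oneWayAnova <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) < 2))
    stop("need >= 2 groups with >= 2 values each")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (all(vapply(groups, var, numeric(1)) == 0))
    stop("zero within-group variance everywhere; ANOVA undefined")
  tab <- summary(stats::aov(y ~ g))[[1]]
  list(F = tab[["F value"]][1], df1 = tab[["Df"]][1], df2 = tab[["Df"]][2],
       p = tab[["Pr(>F)"]][1])
}

#' ANCOVA group effect controlling for covariates
#'
#' F-test comparing the least-squares fit with and without the group factor,
#' covariates always included (Type-III-style single-factor comparison).
#' Exactly collinear covariates are pruned with a warning.
#'
#' @param score numeric response.
#' @param group factor of group membership.
#' @param covariates numeric vector/matrix (e.g. age, VRF count).
#' @return list: `F`, `df1`, `df2`, `p`.
#' @export
ancovaGroupEffect <- function(score, group, covariates) {
  if (var(score) == 0) stop("score has zero variance")
  X <- as.matrix(covariates)
  if (anyNA(X)) stop("missing covariate values")
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    keep <- sort(setdiff(qrX$pivot[seq_len(qrX$rank)], 1)) - 1
    warning("collinear covariates pruned: keeping ",
            paste(keep, collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  g <- factor(group)
  reduced <- lm(score ~ X)
  full <- lm(score ~ X + g)
  cmp <- anova(reduced, full)
  list(F = cmp$F[2], df1 = cmp$Df[2], df2 = cmp$Res.Df[2], p = cmp$`Pr(>F)`[2])
}

#' Trail Making Test difference score
#'
#' Part B time minus Part A time, in seconds; higher = poorer set-shifting.
#'
#' @param partASeconds,partBSeconds positive completion times (vectorised).
#' @return B - A difference score(s).
#' @export
tmtDifference <- function(partASeconds, partBSeconds) {
  if (any(partASeconds <= 0) || any(partBSeconds <= 0))
    stop("completion times must be positive")
  partBSeconds - partASeconds
}

#' Reclassification totals from a clinical-vs-MRI matrix
#'
#' Rows are the original clinical diagnoses (minor stroke, TIA), columns the
#' MRI finding (infarct, no infarct). The reclassified group sizes are the
#' column sums: every patient with an infarct on imaging is a minor stroke,
#' every patient without one a TIA.
#'
#' @param matrix 2 x 2 (or r x 2) nonnegative count matrix.
#' @return named integer vector `c(n_stroke_final=, n_tia_final=)`.
#' @export
reclassificationTotals <- function(matrix) {
  m <- as.matrix(matrix)
  if (any(m < 0) || ncol(m) != 2) stop("need an r x 2 nonnegative count matrix")
  cs <- colSums(m)
  c(n_stroke_final = unname(cs[1]), n_tia_final = unname(cs[2]))
}

#' Table-style cohort summary
#'
#' Per-group mean and SD of the continuous phenotype columns with one-way
#' ANOVA (all groups) and, for each variable, the ANCOVA group effect
#' controlling for age and VRF count (age and VRF themselves get ANOVA only).
#'
#' @param phenotype data.frame with `group`, `age`, `vrf_count` and numeric
#'   score columns.
#' @param variables character; which columns to summarise (default: all
#'   numeric columns except identifiers).
#' @return data.frame, one row per variable.
#' @export
cohortSummaryTable <- function(phenotype, variables = NULL) {
  if (is.null(variables)) {
    num <- vapply(phenotype, is.numeric, logical(1))
    variables <- setdiff(names(phenotype)[num], "subject_id")
  }
  g <- factor(phenotype$group, levels = intersect(
    c("control", "tia", "stroke"), unique(phenotype$group)))
  rows <- lapply(variables, function(v) {
    y <- phenotype[[v]]
    byg <- split(y, g)
    means <- vapply(byg, mean, numeric(1))
    sds <- vapply(byg, sd, numeric(1))
    an <- tryCatch(oneWayAnova(byg), error = function(e)
      list(F = NA_real_, df1 = NA, df2 = NA, p = NA_real_))
    anc <- if (!v %in% c("age", "vrf_count")) {
      tryCatch(ancovaGroupEffect(y, g, cbind(age = phenotype$age,
                                             vrf = phenotype$vrf_count)),
               error = function(e) list(F = NA_real_, p = NA_real_))
    } else list(F = NA_real_, p = NA_real_)
    data.frame(variable = v,
               t(setNames(sprintf("%.1f ± %.1f", means, sds),
                          paste0(names(means), "_mean_sd"))),
               anova_f = an$F, anova_df1 = an$df1, anova_df2 = an$df2,
               anova_p = an$p, ancova_f = anc$F, ancova_p = anc$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
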