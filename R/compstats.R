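# Covariate-adjusted comparative statistics: MANCOVA/ANCOVA with type-III
# tests, estimated marginal means, compact letter displays, assumption
# checks (Box's M, Levene, homogeneity of slopes), repeated-measures ANOVA
# with sphericity, exact r x c contingency tests, one-way ANOVA and Tukey.
#
# Standard model fits go through stats::lm/aov and car; the pieces with no
# installed implementation (Box's M, the exact r x c enumeration, EMM
# contrast machinery, letter displays) are computed here directly.

# ---- multivariate criteria ------------------------------------------------

# Wilks' lambda and Pillai's trace with their F approximations, from
# hypothesis and error SSP matrices. p responses, q hypothesis df, v error df.
.mv_criteria <- function(H, E, q, v) {
  p <- nrow(E)
  HE <- H + E
  lambda <- det(E) / det(HE)
  eig <- Re(eigen(solve(E, H), only.values = TRUE)$values)
  pillai <- sum(eig / (1 + eig))
  # Rao's F for Wilks
  r <- v - (p - q + 1) / 2
  u <- (p * q - 2) / 4
  tt <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  df1_w <- p * q
  df2_w <- r * tt - 2 * u
  F_w <- (1 - lambda^(1 / tt)) / lambda^(1 / tt) * df2_w / df1_w
  # Pillai F
  s <- min(p, q)
  m <- (abs(p - q) - 1) / 2
  nn <- (v - p - 1) / 2
  df1_p <- s * (2 * m + s + 1)
  df2_p <- s * (2 * nn + s + 1)
  F_p <- (2 * nn + s + 1) / (2 * m + s + 1) * pillai / (s - pillai)
  list(
    wilks = list(statistic = lambda, approx_F = F_w, df_num = df1_w,
                 df_den = df2_w, p = stats::pf(F_w, df1_w, df2_w,
                                               lower.tail = FALSE)),
    pillai = list(statistic = pillai, approx_F = F_p, df_num = df1_p,
                  df_den = df2_p, p = stats::pf(F_p, df1_p, df2_p,
                                                lower.tail = FALSE)))
}

# ---- EMM machinery --------------------------------------------------------

# Reference-grid estimated marginal means for one factor of an lm/mlm fit:
# factors crossed at all levels with equal weight, numeric covariates held
# at `at` (default: their mean in the model frame). Returns the contrast
# matrix L (levels x coefficients) so callers can propagate covariances.
.emm_L <- function(fit, factor_name, at = NULL) {
  mf <- stats::model.frame(fit)
  vars <- attr(stats::terms(fit), "term.labels")
  base_vars <- all.vars(stats::delete.response(stats::terms(fit)))
  grid_vars <- list()
  for (v in base_vars) {
    col <- mf[[v]]
    grid_vars[[v]] <- if (is.factor(col)) factor(levels(col), levels(col))
      else if (is.character(col)) unique(col)
      else if (!is.null(at) && v %in% names(at)) at[[v]]
      else mean(col)
  }
  grid <- expand.grid(grid_vars, stringsAsFactors = FALSE)
  X <- stats::model.matrix(stats::delete.response(stats::terms(fit)), grid,
                           contrasts.arg = fit$contrasts)
  lev <- as.character(grid[[factor_name]])
  levels_f <- if (is.factor(mf[[factor_name]])) levels(mf[[factor_name]])
              else unique(lev)
  L <- t(vapply(levels_f,
                function(l) colMeans(X[lev == l, , drop = FALSE]),
                numeric(ncol(X))))
  rownames(L) <- levels_f
  L
}

#' Estimated marginal means for a fitted model
#'
#' Model-adjusted group means: the mean prediction for each level of
#' `factor_name` with numeric covariates held at a fixed value (by default
#' the grand mean of the observations entering the fit) and any other
#' factors averaged over their levels with equal weight. For a
#' common-slope ANCOVA this is the classical adjusted mean
#' `ybar_g + b (xbar - xbar_g)`.
#'
#' @param fit an `lm` (univariate or multivariate) fit, or a
#'   [fit_mancova()] result.
#' @param factor_name the grouping factor whose levels are summarized.
#' @param at optional named list of covariate values at which to evaluate
#'   (e.g. `list(mesosoma = 1.7434)`). A value far outside the observed
#'   covariate range triggers a warning, not an error.
#' @return Data frame with columns `level`, one `emm_*`/`se_*` pair per
#'   response, and the attribute `"evaluation_point"`.
#' @export
estimated_marginal_means <- function(fit, factor_name, at = NULL) {
  if (inherits(fit, "mancova_fit")) fit <- fit$fit
  mf <- stats::model.frame(fit)
  if (!is.null(at)) {
    for (v in names(at)) {
      rng <- range(mf[[v]])
      span <- diff(rng)
      if (at[[v]] < rng[1L] - span || at[[v]] > rng[2L] + span)
        warning(sprintf(
          "covariate %s evaluated at %g, far outside the observed range [%g, %g]",
          v, at[[v]], rng[1L], rng[2L]))
    }
  }
  L <- .emm_L(fit, factor_name, at)
  B <- stats::coef(fit)
  if (is.null(dim(B))) B <- matrix(B, ncol = 1L,
                                   dimnames = list(names(B), "response"))
  XtXinv <- chol2inv(qr.R(fit$qr))
  res <- stats::residuals(fit)
  if (is.null(dim(res))) res <- matrix(res, ncol = 1L)
  sigma2 <- colSums(res^2) / stats::df.residual(fit)
  quad <- rowSums((L %*% XtXinv) * L)   # L (X'X)^-1 L' diagonal
  out <- data.frame(level = rownames(L), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(B))) {
    nm <- colnames(B)[j]
    out[[paste0("emm_", nm)]] <- as.vector(L %*% B[, j])
    out[[paste0("se_", nm)]] <- sqrt(sigma2[j] * quad)
  }
  evalpt <- vapply(mf[vapply(mf, is.numeric, logical(1L))], mean, numeric(1L))
  if (!is.null(at)) evalpt[names(at)] <- unlist(at)
  attr(out, "evaluation_point") <- evalpt
  attr(out, "L") <- L
  attr(out, "XtXinv") <- XtXinv
  attr(out, "sigma2") <- sigma2
  attr(out, "df") <- stats::df.residual(fit)
  out
}

# ---- MANCOVA --------------------------------------------------------------

#' Multivariate analysis of covariance
#'
#' Fits `cbind(responses) ~ group + covariate` and reports, for the group
#' and covariate effects, Wilks' lambda and Pillai's trace with their F
#' approximations (type-III sums of squares and products, sum-to-zero
#' contrasts), per-response type-III between-subject F tests, and
#' estimated marginal means per group and response at the covariate grand
#' mean.
#'
#' @param data data frame of worker-level observations.
#' @param responses character vector of response column names.
#' @param group grouping factor column name (e.g. species).
#' @param covariate numeric covariate column name (e.g. mesosoma length).
#' @param emm_at optional covariate value for the EMM evaluation point;
#'   default is the grand mean of included observations.
#' @return Object of class `mancova_fit`: the underlying `lm` fit,
#'   `multivariate` (per term: wilks and pillai), `between_subjects`
#'   (per response: F, df, p), `emm_table`, `evaluation_point`.
#' @export
fit_mancova <- function(data, responses, group, covariate, emm_at = NULL) {
  data <- stats::na.omit(data[c(responses, group, covariate)])
  g <- factor(data[[group]])
  if (nlevels(g) < 2L) stop_validation("need at least 2 groups")
  if (nrow(data) <= nlevels(g) + length(responses) + 1L)
    stop_validation("too few observations for the requested model")
  if (any(table(g) < 2L))
    stop_validation("rank-deficient design: a group has fewer than 2 observations",
                    class = "ommatidics_rank_error")
  df <- data.frame(.g = g, .x = data[[covariate]])
  Y <- as.matrix(data[responses])
  fit <- stats::lm(Y ~ .g + .x, data = df,
                   contrasts = list(.g = "contr.sum"))
  multivariate <- list()
  if (length(responses) > 1L) {
    man <- car::Manova(fit, type = "III")
    v <- man$error.df
    for (term in setdiff(man$terms, "(Intercept)")) {
      i <- which(man$terms == term)
      crit <- .mv_criteria(man$SSP[[term]], man$SSPE, man$df[i], v)
      nm <- switch(term, ".g" = "group", ".x" = "covariate", term)
      multivariate[[nm]] <- crit
    }
  } else {
    # univariate limit: 1 x 1 SSP matrices from the type-III ANOVA table
    fu <- stats::lm(Y[, 1L] ~ .g + .x, data = df,
                    contrasts = list(.g = "contr.sum"))
    au <- car::Anova(fu, type = "III")
    sse <- matrix(au["Residuals", "Sum Sq"])
    v <- au["Residuals", "Df"]
    for (term in c(".g", ".x")) {
      crit <- .mv_criteria(matrix(au[term, "Sum Sq"]), sse,
                           au[term, "Df"], v)
      nm <- switch(term, ".g" = "group", ".x" = "covariate")
      multivariate[[nm]] <- crit
    }
  }
  # per-response type-III F tests
  between <- lapply(seq_along(responses), function(j) {
    fj <- stats::lm(Y[, j] ~ .g + .x, data = df,
                    contrasts = list(.g = "contr.sum"))
    aj <- car::Anova(fj, type = "III")
    i_g <- which(rownames(aj) == ".g"); i_x <- which(rownames(aj) == ".x")
    i_r <- which(rownames(aj) == "Residuals")
    list(response = responses[j],
         group = list(F = aj$`F value`[i_g], df_num = aj$Df[i_g],
                      df_den = aj$Df[i_r], p = aj$`Pr(>F)`[i_g]),
         covariate = list(F = aj$`F value`[i_x], df_num = aj$Df[i_x],
                          df_den = aj$Df[i_r], p = aj$`Pr(>F)`[i_x]))
  })
  names(between) <- responses
  at <- if (is.null(emm_at)) NULL else list(.x = emm_at)
  emm <- estimated_marginal_means(fit, ".g", at = at)
  evalpt <- if (is.null(emm_at)) mean(df$.x) else emm_at
  structure(list(fit = fit, responses = responses, group = group,
                 covariate = covariate, multivariate = multivariate,
                 between_subjects = between, emm_table = emm,
                 evaluation_point = evalpt, n = nrow(data)),
            class = "mancova_fit")
}

#' @export
print.mancova_fit <- function(x, ...) {
  cat(sprintf("MANCOVA: %s ~ %s + %s (n = %d)\n",
              paste(x$responses, collapse = ","), x$group, x$covariate, x$n))
  for (term in names(x$multivariate)) {
    w <- x$multivariate[[term]]$wilks
    p <- x$multivariate[[term]]$pillai
    cat(sprintf(
      "  %s: Wilks lambda = %.3f, F(%g, %g) = %.2f, p = %.4g | Pillai = %.3f\n",
      term, w$statistic, w$df_num, w$df_den, w$approx_F, w$p, p$statistic))
  }
  cat(sprintf("  EMMs evaluated at %s = %.4f\n", x$covariate,
              x$evaluation_point))
  invisible(x)
}

# ---- ANCOVA ---------------------------------------------------------------

#' Analysis of covariance with type-III tests
#'
#' Fits `dep ~ group + covariate` (optionally with the group x covariate
#' interaction to test homogeneity of regression slopes) and returns
#' type-III F tests using sum-to-zero contrasts.
#'
#' @param data data frame.
#' @param dep,group,covariate column names.
#' @param test_slopes include and test the group x covariate interaction.
#' @return list with per-term `F`, `df_num`, `df_den`, `p`, the fit, and
#'   `perfect_fit` flag (zero residual variance, p reported as 0).
#' @export
ancova <- function(data, dep, group, covariate, test_slopes = FALSE) {
  data <- stats::na.omit(data[c(dep, group, covariate)])
  df <- data.frame(.y = data[[dep]], .g = factor(data[[group]]),
                   .x = data[[covariate]])
  if (nlevels(df$.g) < 2L) stop_validation("need at least 2 groups")
  form <- if (test_slopes) .y ~ .g * .x else .y ~ .g + .x
  fit <- stats::lm(form, data = df, contrasts = list(.g = "contr.sum"))
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((df$.y - mean(df$.y))^2)
  perfect <- tss > 0 && rss < 1e-12 * tss
  if (perfect) {
    # zero residual variance: every F is unbounded; report p = 0 flagged
    k <- nlevels(df$.g)
    dfs <- c(.g = k - 1L, .x = 1L, ".g:.x" = k - 1L)
    term_row <- function(nm) {
      if (nm == ".g:.x" && !test_slopes) return(NULL)
      list(F = Inf, df_num = unname(dfs[nm]),
           df_den = stats::df.residual(fit), p = 0)
    }
  } else {
    a <- car::Anova(fit, type = "III")
    i_r <- which(rownames(a) == "Residuals")
    term_row <- function(nm) {
      i <- which(rownames(a) == nm)
      if (!length(i)) return(NULL)
      list(F = a$`F value`[i], df_num = a$Df[i], df_den = a$Df[i_r],
           p = a$`Pr(>F)`[i])
    }
  }
  out <- list(group = term_row(".g"), covariate = term_row(".x"),
              interaction = term_row(".g:.x"),
              fit = fit, perfect_fit = perfect, n = nrow(df))
  class(out) <- "ancova_fit"
  out
}

#' Two-way ANCOVA (e.g. genus x activity period) with Tukey HSD
#'
#' Fits `dep ~ A * B + covariate` with type-III tests, and runs
#' Tukey-adjusted pairwise comparisons of the estimated marginal means of
#' each factor (Tukey-Kramer via the studentized range distribution).
#'
#' @param data data frame.
#' @param dep,factorA,factorB,covariate column names.
#' @param alpha significance level for the letter displays.
#' @return list with the type-III table entries for A, B, A:B and the
#'   covariate, and per-factor EMMs with Tukey pairwise p-values and
#'   letters.
#' @export
two_way_ancova <- function(data, dep, factorA, factorB, covariate,
                           alpha = 0.05) {
  data <- stats::na.omit(data[c(dep, factorA, factorB, covariate)])
  df <- data.frame(.y = data[[dep]], .a = factor(data[[factorA]]),
                   .b = factor(data[[factorB]]), .x = data[[covariate]])
  if (any(table(df$.a, df$.b) == 0L))
    stop_validation("empty A x B cell: interaction not estimable",
                    class = "ommatidics_estimability_error")
  has_b <- nlevels(df$.b) > 1L
  form <- if (has_b) .y ~ .a * .b + .x else .y ~ .a + .x
  contr <- if (has_b) list(.a = "contr.sum", .b = "contr.sum")
           else list(.a = "contr.sum")
  fit <- stats::lm(form, data = df, contrasts = contr)
  a <- car::Anova(fit, type = "III")
  i_r <- which(rownames(a) == "Residuals")
  row <- function(nm) {
    i <- which(rownames(a) == nm)
    if (!length(i)) return(NULL)
    list(F = a$`F value`[i], df_num = a$Df[i], df_den = a$Df[i_r],
         p = a$`Pr(>F)`[i])
  }
  tukey_for <- function(fname) {
    emm <- estimated_marginal_means(fit, fname)
    L <- attr(emm, "L"); XtXinv <- attr(emm, "XtXinv")
    s2 <- attr(emm, "sigma2")[1L]; dfe <- attr(emm, "df")
    Vemm <- s2 * L %*% XtXinv %*% t(L)
    k <- nrow(emm)
    est <- emm[[2L]]
    pmat <- matrix(NA_real_, k, k, dimnames = list(emm$level, emm$level))
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
      sed <- sqrt(Vemm[i, i] + Vemm[j, j] - 2 * Vemm[i, j])
      tstat <- abs(est[i] - est[j]) / sed
      pmat[i, j] <- pmat[j, i] <-
        stats::ptukey(tstat * sqrt(2), k, dfe, lower.tail = FALSE)
    }
    letters <- .letter_display(est, pmat, alpha, emm$level)
    list(emm = emm, p_matrix = pmat, letters = letters)
  }
  out <- list(A = row(".a"), B = row(".b"),
              interaction = row(".a:.b"), covariate = row(".x"),
              fit = fit,
              tukey_A = tukey_for(".a"),
              tukey_B = if (has_b) tukey_for(".b") else NULL,
              n = nrow(df))
  if (!has_b) { out$group <- out$A }  # collapses to one-way ANCOVA
  out
}

# ---- compact letter displays ----------------------------------------------

# Insert-and-absorb letter assignment from a pairwise significance pattern.
# `est` orders the groups (largest mean gets 'a'); `pmat` is the symmetric
# pairwise p-value matrix.
.letter_display <- function(est, pmat, alpha, labels = NULL) {
  k <- length(est)
  if (is.null(labels)) labels <- rownames(pmat)
  if (is.null(labels)) labels <- as.character(seq_len(k))
  sig <- !is.na(pmat) & pmat < alpha
  cols <- list(rep(TRUE, k))  # start: one column containing every group
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    if (!sig[i, j]) next
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[i] && col[j]) {
        c1 <- col; c1[i] <- FALSE
        c2 <- col; c2[j] <- FALSE
        cols[[ci]] <- c1
        cols[[length(cols) + 1L]] <- c2
      }
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(cols))
    for (ci in seq_along(cols)) for (cj in seq_along(cols)) {
      if (ci != cj && keep[ci] && keep[cj] &&
          all(cols[[ci]] | !cols[[cj]]) && !identical(cols[[ci]], cols[[cj]]))
        keep[cj] <- FALSE
      else if (ci < cj && keep[ci] && keep[cj] &&
               identical(cols[[ci]], cols[[cj]]))
        keep[cj] <- FALSE
    }
    cols <- cols[keep]
  }
  # order columns so 'a' goes to the column holding the largest mean
  colmax <- vapply(cols, function(col) max(est[col]), numeric(1L))
  cols <- cols[order(colmax, decreasing = TRUE)]
  lets <- vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(cols, function(col) col[g], logical(1L)))],
          collapse = "")
  }, character(1L))
  names(lets) <- labels
  # consistency assertion: significant pairs share no letter, and groups
  # sharing no letter are significantly different
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    share <- length(intersect(strsplit(lets[i], "")[[1L]],
                              strsplit(lets[j], "")[[1L]])) > 0L
    if (sig[i, j] && share)
      stop("internal error: significant pair shares a letter")
    if (!sig[i, j] && !share)
      stop("internal error: non-significant pair shares no letter")
  }
  lets
}

#' LSD pairwise comparisons with a letter display
#'
#' Unadjusted pairwise t-tests (Fisher's least significant difference) on
#' a set of estimated marginal means, followed by a compact letter
#' display: letters are assigned in descending order of the means (`a` =
#' largest) and groups sharing a letter are not significantly different
#' at `alpha`.
#'
#' @param emms numeric vector of (marginal) means, optionally named.
#' @param ses standard errors of the means (recycled); ignored when
#'   `vcov` is given.
#' @param df error degrees of freedom.
#' @param alpha significance level (the analysis may lower this to 0.01
#'   when variance homogeneity fails).
#' @param vcov optional covariance matrix of the means; when supplied the
#'   pairwise SE is `sqrt(v_ii + v_jj - 2 v_ij)`.
#' @return list of class `posthoc_result` with `p_matrix`, `letters`,
#'   `alpha`.
#' @examples
#' lsd_letters(c(a = 10, b = 10, c = 2), ses = 0.1, df = 20)
#' @export
lsd_letters <- function(emms, ses = NULL, df, alpha = 0.05, vcov = NULL) {
  k <- length(emms)
  if (k < 2L) stop_validation("need at least 2 groups")
  labels <- names(emms)
  if (is.null(labels)) labels <- as.character(seq_len(k))
  if (is.null(vcov)) {
    if (is.null(ses)) stop_validation("provide `ses` or `vcov`")
    ses <- rep_len(ses, k)
    vcov <- diag(ses^2, k)
  }
  pmat <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    sed <- sqrt(vcov[i, i] + vcov[j, j] - 2 * vcov[i, j])
    tstat <- if (sed == 0) {
      if (emms[i] == emms[j]) 0 else Inf
    } else abs(emms[i] - emms[j]) / sed
    pmat[i, j] <- pmat[j, i] <- 2 * stats::pt(tstat, df, lower.tail = FALSE)
  }
  structure(list(p_matrix = pmat,
                 letters = .letter_display(emms, pmat, alpha, labels),
                 alpha = alpha, means = emms),
            class = "posthoc_result")
}

#' @export
print.posthoc_result <- function(x, ...) {
  ord <- order(x$means, decreasing = TRUE)
  cat(sprintf("Pairwise comparisons (alpha = %g):\n", x$alpha))
  for (i in ord)
    cat(sprintf("  %s: %.4g  %s\n", names(x$letters)[i], x$means[i],
                x$letters[i]))
  invisible(x)
}

#' Tukey HSD pairwise decisions from summary statistics
#'
#' Studentized-range based pairwise comparisons of group means, with the
#' Tukey-Kramer standard error for unbalanced groups, and a compact
#' letter display.
#'
#' @param means group means (named).
#' @param mse error mean square from the ANOVA.
#' @param df error degrees of freedom.
#' @param ns per-group sample sizes (recycled).
#' @param alpha familywise significance level.
#' @return list of class `posthoc_result` with Tukey-adjusted `p_matrix`,
#'   `letters`, `alpha`.
#' @export
tukey_hsd <- function(means, mse, df, ns, alpha = 0.05) {
  k <- length(means)
  if (k < 2L) stop_validation("need at least 2 groups")
  ns <- rep_len(ns, k)
  labels <- names(means)
  if (is.null(labels)) labels <- as.character(seq_len(k))
  pmat <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    # Tukey-Kramer: q = |diff| / sqrt(mse/2 (1/ni + 1/nj))
    sed <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- if (sed == 0) { if (means[i] == means[j]) 0 else Inf }
         else abs(means[i] - means[j]) / sed
    pmat[i, j] <- pmat[j, i] <- stats::ptukey(q, k, df, lower.tail = FALSE)
  }
  structure(list(p_matrix = pmat,
                 letters = .letter_display(means, pmat, alpha, labels),
                 alpha = alpha, means = means),
            class = "posthoc_result")
}

# ---- exact r x c test -----------------------------------------------------

# log multivariate hypergeometric probability of a table given margins
.log_table_prob <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(N + 1) -
    sum(lgamma(tab + 1))
}

#' Fisher's exact test for an r x c table by full enumeration
#'
#' Enumerates every nonnegative integer table with the observed row and
#' column margins, computes the multivariate hypergeometric probability of
#' each, and returns the two-sided p-value as the total probability of
#' tables no more probable than the observed one (the conventional exact
#' two-sided definition for r x c tables).
#'
#' @param table matrix of nonnegative integer counts.
#' @param max_tables guard on the enumeration size; beyond it a resource
#'   error suggests Monte-Carlo simulation instead.
#' @return list with `p`, `log_prob_observed`, `n_tables` enumerated.
#' @examples
#' fisher_exact_rxc(matrix(c(9, 1, 0, 0, 13, 3), 2, byrow = TRUE))$p
#' @export
fisher_exact_rxc <- function(table, max_tables = 1e7) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab)))
    stop_validation("table must hold nonnegative integers")
  rs <- rowSums(tab); cs <- colSums(tab)
  # drop empty rows/columns: they carry no information
  tab <- tab[rs > 0, cs > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    return(list(p = 1, log_prob_observed = 0, n_tables = 1L))
  rs <- rowSums(tab); cs <- colSums(tab)
  # rough bound on the enumeration: product over free cells of (margin+1)
  bound <- prod(pmin(rep(rs[-length(rs)], each = ncol(tab) - 1L) + 1,
                     rep(cs[-length(cs)], nrow(tab) - 1L) + 1))
  if (bound > max_tables)
    stop_validation(
      "table too large for full enumeration; use a Monte-Carlo approach",
      class = "ommatidics_resource_error")
  lp_obs <- .log_table_prob(tab)
  n_tab <- 0L
  total_le <- 0
  r <- nrow(tab); cc <- ncol(tab)
  cur <- matrix(0L, r, cc)
  # recursive fill, row-major over the (r-1) x (c-1) free cells; the last
  # row/column are forced by the margins
  recurse <- function(i, j, row_rem, col_rem) {
    if (i == r) {
      # last row forced
      if (any(col_rem < 0)) return()
      cur[r, ] <<- col_rem
      n_tab <<- n_tab + 1L
      lp <- .log_table_prob(cur)
      if (lp <= lp_obs + 1e-7) total_le <<- total_le + exp(lp)
      return()
    }
    if (j == cc) {
      # last column of row i forced
      if (row_rem < 0 || row_rem > col_rem[cc]) return()
      cur[i, cc] <<- row_rem
      nc <- col_rem; nc[cc] <- nc[cc] - row_rem
      recurse(i + 1L, 1L, rs[i + 1L], nc)
      return()
    }
    hi <- min(row_rem, col_rem[j])
    for (v in 0:hi) {
      cur[i, j] <<- v
      nc <- col_rem; nc[j] <- nc[j] - v
      recurse(i, j + 1L, row_rem - v, nc)
    }
  }
  recurse(1L, 1L, rs[1L], cs)
  list(p = min(1, total_le), log_prob_observed = lp_obs, n_tables = n_tab)
}

# ---- assumption checks ----------------------------------------------------

#' Box's M test for homogeneity of covariance matrices
#'
#' M = (N - k) ln|S_pooled| - sum (n_g - 1) ln|S_g| with the chi-square
#' approximation (Box 1949). Because the test is highly sensitive, the
#' conventional decision threshold in this analysis is alpha = 0.001; when
#' it fails, downstream multivariate tests switch from Wilks' lambda to
#' Pillai's trace.
#'
#' @param data data frame.
#' @param responses response column names.
#' @param group grouping column name.
#' @param alpha decision threshold (default 0.001).
#' @return list with `M`, `chi_square`, `df`, `p`, `violated`.
#' @export
box_m <- function(data, responses, group, alpha = 0.001) {
  data <- stats::na.omit(data[c(responses, group)])
  g <- factor(data[[group]])
  Y <- as.matrix(data[responses])
  p <- ncol(Y); k <- nlevels(g); N <- nrow(Y)
  ns <- as.integer(table(g))
  if (any(ns <= p))
    stop_validation(sprintf(
      "group %s has n <= number of responses; covariance singular",
      levels(g)[which(ns <= p)[1L]]))
  covs <- lapply(levels(g), function(l) stats::cov(Y[g == l, , drop = FALSE]))
  logdets <- vapply(covs, function(S) {
    d <- determinant(S, logarithm = TRUE)
    if (d$sign <= 0) stop_validation("singular within-group covariance")
    as.numeric(d$modulus)
  }, numeric(1L))
  Sp <- Reduce(`+`, Map(function(S, n) (n - 1) * S, covs, ns)) / (N - k)
  dp <- determinant(Sp, logarithm = TRUE)
  if (dp$sign <= 0) stop_validation("singular pooled covariance")
  M <- (N - k) * as.numeric(dp$modulus) - sum((ns - 1) * logdets)
  c1 <- (sum(1 / (ns - 1)) - 1 / (N - k)) *
    (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (k - 1))
  chi <- M * (1 - c1)
  df <- (k - 1) * p * (p + 1) / 2
  pval <- stats::pchisq(chi, df, lower.tail = FALSE)
  list(M = M, chi_square = chi, df = df, p = pval, violated = pval < alpha)
}

#' Levene's test for homogeneity of variance
#'
#' One-way ANOVA on absolute deviations from the group means
#' (`center = mean`, matching the default of the original analysis
#' software). Delegates to [car::leveneTest()].
#'
#' @param data data frame.
#' @param response,group column names.
#' @return list with `F`, `df_num`, `df_den`, `p`.
#' @export
levene <- function(data, response, group) {
  data <- stats::na.omit(data[c(response, group)])
  g <- factor(data[[group]])
  if (nlevels(g) < 2L || any(table(g) < 2L))
    stop_validation("need >= 2 groups with >= 2 observations each")
  lt <- car::leveneTest(data[[response]], g, center = mean)
  Fv <- lt$`F value`[1L]
  if (!is.finite(Fv)) Fv <- 0
  list(F = Fv, df_num = lt$Df[1L], df_den = lt$Df[2L],
       p = lt$`Pr(>F)`[1L])
}

#' Homogeneity-of-slopes check for a MANCOVA
#'
#' Tests the group x covariate interaction on the multivariate responses
#' (Wilks' lambda); a significant interaction means the covariate slopes
#' differ across groups and the common-slope MANCOVA is not appropriate.
#'
#' @inheritParams fit_mancova
#' @return list with `wilks`, `approx_F`, `df_num`, `df_den`, `p`.
#' @export
slopes_homogeneity <- function(data, responses, group, covariate) {
  data <- stats::na.omit(data[c(responses, group, covariate)])
  df <- data.frame(.g = factor(data[[group]]), .x = data[[covariate]])
  Y <- as.matrix(data[responses])
  fit <- stats::lm(Y ~ .g * .x, data = df, contrasts = list(.g = "contr.sum"))
  man <- car::Manova(fit, type = "III")
  i <- which(man$terms == ".g:.x")
  crit <- .mv_criteria(man$SSP[[".g:.x"]], man$SSPE, man$df[i], man$error.df)
  c(list(wilks = crit$wilks$statistic), crit$wilks[-1L])
}

# ---- repeated measures ----------------------------------------------------

#' One-way repeated-measures ANOVA with sphericity assessment
#'
#' For a subjects x levels matrix (e.g. facet diameter in the five eye
#' regions): Mauchly's test of sphericity (W with the chi-square
#' approximation on k(k-1)/2 - 1 df), the sphericity-assumed
#' within-subjects F (df = k-1, (k-1)(n-1)), the multivariate (Wilks /
#' one-sample Hotelling) test on the within-subject difference scores, and
#' unadjusted (LSD) paired comparisons of the level means with letters.
#'
#' @param data numeric matrix or data frame, one row per subject, one
#'   column per repeated level; incomplete rows are dropped with a
#'   warning.
#' @param alpha significance level for the letter display.
#' @return list of class `rm_anova` with `mauchly` (W, chi_square, df, p),
#'   `within` (F, df_num, df_den, p), `multivariate` (wilks, F, df_num,
#'   df_den, p), `level_means`, `lsd`, `n`, and `degenerate` flag.
#' @export
rm_anova <- function(data, alpha = 0.05) {
  Y <- as.matrix(data)
  if (anyNA(Y)) {
    keep <- stats::complete.cases(Y)
    warning(sprintf("dropping %d incomplete subject(s)", sum(!keep)))
    Y <- Y[keep, , drop = FALSE]
  }
  n <- nrow(Y); k <- ncol(Y)
  if (k < 3L) stop_validation("need at least 3 repeated levels")
  if (n < 3L) stop_validation("need at least 3 complete subjects")
  if (is.null(colnames(Y))) colnames(Y) <- paste0("level", seq_len(k))
  levels_k <- colnames(Y)
  # orthonormal contrasts of the repeated factor
  C <- t(stats::contr.helmert(k))
  C <- C / sqrt(rowSums(C^2))
  Yc <- Y %*% t(C)
  Sc <- stats::cov(Yc)
  degenerate <- !all(is.finite(Sc)) || abs(det(Sc)) < 1e-300 ||
    all(abs(Yc) < 1e-12)
  mauchly <- list(W = NA_real_, chi_square = NA_real_,
                  df = k * (k - 1) / 2 - 1, p = NA_real_)
  multiv <- list(wilks = NA_real_, F = NA_real_, df_num = k - 1,
                 df_den = n - k + 1, p = NA_real_)
  if (!degenerate) {
    mfit <- stats::lm(Y ~ 1)
    mt <- stats::mauchly.test(mfit, X = ~1)
    W <- unname(mt$statistic)
    dfm <- k * (k - 1) / 2 - 1
    rho <- 1 - (2 * (k - 1)^2 + (k - 1) + 2) / (6 * (k - 1) * (n - 1))
    mauchly <- list(W = W, chi_square = -(n - 1) * rho * log(W),
                    df = dfm, p = unname(mt$p.value))
    dbar <- colMeans(Yc)
    T2 <- n * drop(t(dbar) %*% solve(Sc, dbar))
    Fm <- (n - k + 1) / ((n - 1) * (k - 1)) * T2
    multiv <- list(wilks = 1 / (1 + T2 / (n - 1)), F = Fm, df_num = k - 1,
                   df_den = n - k + 1,
                   p = stats::pf(Fm, k - 1, n - k + 1, lower.tail = FALSE))
  }
  # sphericity-assumed within-subjects F
  long <- data.frame(y = as.vector(Y),
                     subj = factor(rep(seq_len(n), k)),
                     level = factor(rep(levels_k, each = n), levels_k))
  av <- summary(stats::aov(y ~ level + Error(subj), data = long))
  wtab <- av[["Error: Within"]][[1L]]
  Fw <- wtab["level", "F value"]
  pw <- wtab["level", "Pr(>F)"]
  # identical columns: zero effect and zero residual, report F = 0 flagged
  if (all(abs(Yc) < 1e-9 * max(1, max(abs(Y)))) || !is.finite(Fw)) {
    Fw <- 0; pw <- NA_real_
  }
  within <- list(F = Fw, df_num = wtab["level", "Df"],
                 df_den = wtab["Residuals", "Df"], p = pw)
  # LSD paired comparisons of level means
  means <- colMeans(Y)
  pmat <- matrix(NA_real_, k, k, dimnames = list(levels_k, levels_k))
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    d <- Y[, i] - Y[, j]
    if (stats::sd(d) == 0) {
      pmat[i, j] <- pmat[j, i] <- if (mean(d) == 0) 1 else 0
    } else {
      pmat[i, j] <- pmat[j, i] <- stats::t.test(d)$p.value
    }
  }
  lsd <- structure(list(p_matrix = pmat,
                        letters = .letter_display(means, pmat, alpha, levels_k),
                        alpha = alpha, means = means),
                   class = "posthoc_result")
  structure(list(mauchly = mauchly, within = within, multivariate = multiv,
                 level_means = means, lsd = lsd, n = n, k = k,
                 degenerate = degenerate),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: %d subjects x %d levels\n", x$n, x$k))
  if (x$degenerate) cat("  (degenerate within-subject covariance)\n")
  else cat(sprintf(
    "  Mauchly W = %.3f, chi-square = %.2f (%d df), p = %.3f\n",
    x$mauchly$W, x$mauchly$chi_square, x$mauchly$df, x$mauchly$p))
  cat(sprintf("  Within-subjects F(%d, %d) = %.2f, p = %.4g\n",
              x$within$df_num, x$within$df_den, x$within$F, x$within$p))
  invisible(x)
}

#' One-way ANOVA with LSD letters
#'
#' @param data data frame.
#' @param dep,group column names.
#' @param alpha significance level for the letter display.
#' @return list with `F`, `df_num`, `df_den`, `p`, `group_means`, `lsd`.
#' @export
one_way_anova <- function(data, dep, group, alpha = 0.05) {
  data <- stats::na.omit(data[c(dep, group)])
  g <- factor(data[[group]]); y <- data[[dep]]
  if (nlevels(g) < 2L) stop_validation("need at least 2 groups")
  fit <- stats::aov(y ~ g)
  a <- summary(fit)[[1L]]
  Fv <- a["g", "F value"]
  if (!is.finite(Fv)) Fv <- 0
  mse <- a["Residuals", "Mean Sq"]
  dfe <- a["Residuals", "Df"]
  means <- tapply(y, g, mean)
  ns <- as.integer(table(g))
  k <- nlevels(g)
  pmat <- matrix(NA_real_, k, k, dimnames = list(levels(g), levels(g)))
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    sed <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    tstat <- if (sed == 0) { if (means[i] == means[j]) 0 else Inf }
             else abs(means[i] - means[j]) / sed
    pmat[i, j] <- pmat[j, i] <- 2 * stats::pt(tstat, dfe, lower.tail = FALSE)
  }
  lsd <- structure(list(p_matrix = pmat,
                        letters = .letter_display(means, pmat, alpha,
                                                  levels(g)),
                        alpha = alpha, means = means),
                   class = "posthoc_result")
  list(F = Fv, df_num = a["g", "Df"], df_den = dfe,
       p = a["g", "Pr(>F)"], group_means = means, mse = mse, lsd = lsd)
}
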