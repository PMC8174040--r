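#' Within-subject repeated-measures ANOVA
#'
#' Classical one- or two-way fully-within decomposition on a balanced table
#' of cell means: each effect is tested against its subject-by-effect
#' interaction error term, `F = MS_effect / MS_error` with df `(a - 1)` and
#' `(a - 1)(n - 1)` (analogously for the second factor and the interaction).
#' Implemented through [stats::aov()] with an `Error(subject/...)` stratum.
#' Subjects missing any cell are dropped listwise with a warning; replicate
#' observations per cell are averaged first. When an effect's sum of squares
#' is exactly zero (so is its error term), `F = 0` and `p = 1` are reported.
#'
#' No sphericity correction is applied by default; `gg = TRUE` applies the
#' Greenhouse-Geisser adjustment, with the epsilon for each effect computed
#' from orthonormal contrasts of the subject-level cell covariance.
#'
#' @param data long data frame of (at least) subject, factor and value
#'   columns.
#' @param dv name of the value column.
#' @param within character vector of one or two within-subject factor names.
#' @param subject name of the subject identifier column.
#' @param gg apply the Greenhouse-Geisser correction.
#' @return data frame `effect, F, df_num, df_den, p` (df are the uncorrected
#'   integer df; with `gg = TRUE` an `epsilon` column is added and `p` uses
#'   the corrected df).
#' @examples
#' d <- expand.grid(subject = 1:6, w = 1:4)
#' d$mt <- 3000 + 100 * d$subject - 200 * d$w + rnorm(nrow(d), 0, 10)
#' rm_anova(d, "mt", "w", "subject")
#' @export
rm_anova <- function(data, dv, within, subject = "participant", gg = FALSE) {
  if (length(within) < 1L || length(within) > 2L) {
    stop("'within' must name one or two factors", call. = FALSE)
  }
  d <- data[c(subject, within, dv)]
  names(d) <- c("subj", paste0("f", seq_along(within)), "y")
  d <- d[stats::complete.cases(d), ]
  fac <- paste0("f", seq_along(within))
  d <- stats::aggregate(d["y"], by = d[c("subj", fac)], FUN = mean)
  for (v in c("subj", fac)) d[[v]] <- factor(d[[v]])

  n_cells <- prod(vapply(fac, function(v) nlevels(d[[v]]), 1L))
  cnt <- table(d$subj)
  drop <- names(cnt)[cnt < n_cells]
  if (length(drop)) {
    warning(sprintf("dropping %d subject(s) with missing cells: %s",
                    length(drop), paste(drop, collapse = ", ")))
    d <- droplevels(d[!(d$subj %in% drop), ])
  }
  if (nlevels(d$subj) < 2L) stop("need >= 2 complete subjects", call. = FALSE)
  if (any(vapply(fac, function(v) nlevels(d[[v]]), 1L) < 2L)) {
    stop("every within factor needs >= 2 levels", call. = FALSE)
  }

  tot_ss <- sum((d$y - mean(d$y))^2)
  rhs <- paste(fac, collapse = "*")
  form <- stats::as.formula(
    sprintf("y ~ %s + Error(subj/(%s))", rhs, rhs))
  fit <- stats::aov(form, data = d)
  sm <- summary(fit)

  effects <- c(within, if (length(within) == 2L)
    paste(within, collapse = ":"))
  internal <- c(fac, if (length(fac) == 2L) paste(fac, collapse = ":"))
  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1L]]
    rn <- trimws(rownames(tab))
    for (i in which(rn != "Residuals")) {
      j <- which(rn == "Residuals")
      ss_eff <- tab[i, "Sum Sq"]
      Fv <- tab[i, "F value"]
      pv <- tab[i, "Pr(>F)"]
      if (ss_eff <= 1e-12 * max(tot_ss, 1)) {
        # effect SS is zero to numerical precision (its error term usually
        # is too, so aov's F would be 0/0 noise)
        Fv <- 0
        pv <- 1
      }
      rows[[rn[i]]] <- data.frame(
        effect = effects[match(rn[i], internal)],
        F = Fv, df_num = tab[i, "Df"], df_den = tab[j, "Df"], p = pv)
    }
  }
  out <- do.call(rbind, rows[internal[internal %in% names(rows)]])
  rownames(out) <- NULL

  if (gg) {
    out$epsilon <- NA_real_
    # subject x cell matrix in a fixed cell order
    cell_levels <- do.call(expand.grid, lapply(fac, function(v)
      levels(d[[v]])))                 # first factor varies fastest
    key_d <- do.call(paste, c(d[fac], sep = "\r"))
    key_c <- do.call(paste, c(cell_levels, sep = "\r"))
    subj_lev <- levels(d$subj)
    M <- matrix(NA_real_, length(subj_lev), length(key_c))
    M[cbind(match(d$subj, subj_lev), match(key_d, key_c))] <- d$y
    S <- stats::cov(M)
    orth <- function(k) {
      C <- stats::contr.helmert(k)
      sweep(C, 2, sqrt(colSums(C^2)), "/")
    }
    ks <- vapply(fac, function(v) nlevels(d[[v]]), 1L)
    contr_for <- function(which_fac) {
      Cs <- lapply(seq_along(fac), function(j) {
        if (fac[j] %in% which_fac) t(orth(ks[j])) else
          matrix(1 / ks[j], 1L, ks[j])
      })
      Reduce(`%x%`, rev(Cs))   # matches cell order: first factor fastest
    }
    for (r in seq_len(nrow(out))) {
      wf <- internal[match(out$effect[r], effects)]
      Cm <- contr_for(strsplit(wf, ":", fixed = TRUE)[[1L]])
      V <- Cm %*% S %*% t(Cm)
      dfe <- nrow(V)
      eps <- sum(diag(V))^2 / (dfe * sum(V^2))
      out$epsilon[r] <- eps
      if (out$F[r] > 0 && is.finite(out$F[r])) {
        out$p[r] <- stats::pf(out$F[r], eps * out$df_num[r],
                              eps * out$df_den[r], lower.tail = FALSE)
      }
    }
  }
  out
}

#' Paired, one-sample t tests and Pearson correlation
#'
#' Thin wrappers around [stats::t.test()] and [stats::cor.test()] that return
#' plain named vectors and handle degenerate inputs explicitly: identical
#' paired samples give `t = 0, p = 1`; zero-variance inputs otherwise give
#' `NA` with a warning.
#'
#' @param x,y numeric vectors (paired and equal length for `paired_t`).
#' @param mu null value for the one-sample test.
#' @param two_sided two-sided (default) or greater-tail alternative.
#' @return `paired_t`/`one_sample_t`: named vector `t, df, p, mean_diff`;
#'   `pearson_r`: named vector `r, p, n`.
#' @examples
#' paired_t(c(3, 4, 5), c(1, 2, 2))
#' pearson_r(1:5, c(2, 4, 6, 8, 10))
#' @export
paired_t <- function(x, y, two_sided = TRUE) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  d <- x[ok] - y[ok]
  if (length(d) < 2L) stop("need >= 2 complete pairs", call. = FALSE)
  if (stats::sd(d) <= 1e-10 * (abs(mean(d)) + stats::sd(c(x, y)) + 1e-300)) {
    if (abs(mean(d)) <= 1e-10 * (stats::sd(c(x, y)) + 1e-300)) {
      return(c(t = 0, df = length(d) - 1, p = 1, mean_diff = 0))
    }
    warning("zero variance of differences: t undefined")
    return(c(t = NA_real_, df = length(d) - 1, p = NA_real_,
             mean_diff = mean(d)))
  }
  tt <- stats::t.test(x[ok], y[ok], paired = TRUE,
                      alternative = if (two_sided) "two.sided" else "greater")
  c(t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, mean_diff = unname(tt$estimate))
}

#' @rdname paired_t
#' @export
one_sample_t <- function(x, mu = 0, two_sided = TRUE) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) stop("need >= 2 observations", call. = FALSE)
  if (stats::sd(x) <= 1e-10 * (abs(mean(x) - mu) + abs(mean(x)) + 1e-300)) {
    if (abs(mean(x) - mu) <= 1e-10 * (abs(mean(x)) + 1e-300)) {
      return(c(t = 0, df = length(x) - 1, p = 1, mean_diff = 0))
    }
    warning("zero variance: t undefined")
    return(c(t = NA_real_, df = length(x) - 1, p = NA_real_,
             mean_diff = mean(x) - mu))
  }
  tt <- stats::t.test(x, mu = mu,
                      alternative = if (two_sided) "two.sided" else "greater")
  c(t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, mean_diff = unname(tt$estimate) - mu)
}

#' @rdname paired_t
#' @export
pearson_r <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    if (n >= 3L) warning("zero variance: correlation undefined")
    return(c(r = NA_real_, p = NA_real_, n = n))
  }
  ct <- stats::cor.test(x[ok], y[ok])
  c(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Within-subject standard errors of condition means
#'
#' Removes each subject's mean across conditions (adding back the grand mean)
#' before computing the per-condition SEM, so the error bars reflect the
#' repeated-measures error term rather than between-subject variability.
#' Subjects differing only by an additive offset therefore give SEM = 0.
#'
#' @param cell_means numeric matrix (subjects x conditions) or long data
#'   frame.
#' @param value,condition,subject column names when `cell_means` is a data
#'   frame.
#' @return data frame `condition, mean, sem`.
#' @export
within_subject_sem <- function(cell_means, value = "value",
                               condition = "condition",
                               subject = "participant") {
  if (is.data.frame(cell_means)) {
    d <- cell_means
    agg <- stats::aggregate(d[value], by = d[c(subject, condition)],
                            FUN = mean)
    subj <- factor(agg[[subject]])
    cond <- factor(agg[[condition]])
    M <- matrix(NA_real_, nlevels(subj), nlevels(cond),
                dimnames = list(levels(subj), levels(cond)))
    M[cbind(as.integer(subj), as.integer(cond))] <- agg[[value]]
    cell_means <- M
  }
  M <- cell_means[stats::complete.cases(cell_means), , drop = FALSE]
  centered <- M - rowMeans(M) + mean(M)
  data.frame(
    condition = colnames(M) %||% as.character(seq_len(ncol(M))),
    mean = unname(colMeans(M)),
    sem = unname(apply(centered, 2, stats::sd)) / sqrt(nrow(M)),
    row.names = NULL
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
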