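#' Shapiro-Wilk normality test
#'
#' Normality gate used to route each measure family to a parametric or
#' nonparametric test: valid for 3 <= n <= 2000 (the study's samples are
#' far below the upper bound).
#'
#' @param x Numeric vector.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 2000) {
    stop("Shapiro-Wilk requires 3 <= n <= 2000", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("Shapiro-Wilk is undefined for a constant sample", call. = FALSE)
  }
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Differences `b - a` are computed per pair; zero differences are dropped,
#' absolute differences are mid-ranked, and the two-sided p-value comes
#' from exact enumeration of all sign assignments when the effective n is
#' at most 12 (`method = "auto"`), otherwise from the tie-corrected normal
#' approximation without continuity correction. Sign-group mean ranks are
#' reported alongside the standardised statistic.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @param labels Length-2 character vector naming `a` and `b`.
#' @return Object of class `wilcoxon_result`: `V` (positive-rank sum), `Z`,
#'   `p`, `method`, `mean_rank_pos`, `mean_rank_neg` (mean ranks of the
#'   b > a and b < a groups), `n_effective`.
#' @export
wilcoxon_signed_rank <- function(a, b, method = c("auto", "exact", "normal"),
                                 labels = c("a", "b")) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("unequal pair lengths", call. = FALSE)
  keep <- !(is.na(a) | is.na(b))
  d <- b[keep] - a[keep]
  d <- d[d != 0]
  n <- length(d)
  if (n < 1) stop("no information: all differences are zero", call. = FALSE)

  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  Z <- if (sigma2 > 0) (V - mu) / sqrt(sigma2) else 0

  use_exact <- method == "exact" || (method == "auto" && n <= 12)
  if (use_exact && n > 20) {
    stop("exact enumeration limited to n <= 20", call. = FALSE)
  }
  p <- if (use_exact) {
    # enumerate all 2^n sign assignments of the observed ranks; the null
    # distribution of V is symmetric about mu even under ties
    sums <- 0
    for (ri in r) sums <- c(sums, sums + ri)
    mean(abs(sums - mu) >= abs(V - mu) - 1e-12)
  } else {
    min(1, 2 * stats::pnorm(-abs(Z)))
  }

  structure(
    list(V = V, Z = Z, p = p,
         method = if (use_exact) "exact" else "normal",
         mean_rank_pos = if (any(d > 0)) mean(r[d > 0]) else NA_real_,
         mean_rank_neg = if (any(d < 0)) mean(r[d < 0]) else NA_real_,
         n_effective = n, labels = labels),
    class = "wilcoxon_result"
  )
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon signed-rank (%s): V = %g, Z = %.2f, p = %.4g (n = %d)\n",
    x$method, x$V, x$Z, x$p, x$n_effective))
  cat(sprintf("  mean rank %s>%s: %.2f; %s<%s: %.2f\n",
              x$labels[2], x$labels[1], x$mean_rank_pos,
              x$labels[2], x$labels[1], x$mean_rank_neg))
  invisible(x)
}

#' Paired-samples t test
#'
#' Two-sided paired t on `a - b`: `t = mean(d) / (sd(d) / sqrt(n))` with
#' `n - 1` degrees of freedom.
#'
#' @param a,b Paired numeric vectors.
#' @return List with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("unequal pair lengths", call. = FALSE)
  keep <- !(is.na(a) | is.na(b))
  d <- a[keep] - b[keep]
  if (length(d) < 2) stop("need at least 2 complete pairs", call. = FALSE)
  if (stats::sd(d) == 0) {
    stop("zero variance of the paired differences", call. = FALSE)
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d))
}

#' Two-way repeated-measures ANOVA on a 2 x 2 within design
#'
#' Fits the within-subjects decomposition with subject as the random
#' blocking factor; each effect (identity, modality, their interaction) is
#' tested against its own effect-by-subject error stratum with
#' df = (1, n - 1). Partial eta squared is computed from the stratum sums
#' of squares, `SS_effect / (SS_effect + SS_error)`, and labelled with the
#' conventional cutoffs. Cell means and standard errors are reported.
#'
#' @param table An `amplitude_table` slice holding exactly one component
#'   (or any long data.frame with the named columns).
#' @param subject,identity,modality,dv Column names.
#' @return Object of class `rm_anova_result`: `effects` data.frame (`F`,
#'   `df1`, `df2`, `p`, `eta_p_sq`, `label`), `cell_means`, `cell_ses`,
#'   `n_subjects`.
#' @export
rm_anova_2x2 <- function(table, subject = "subject", identity = "identity",
                         modality = "site", dv = "amplitude_uv") {
  df <- data.frame(subject = factor(table[[subject]]),
                   identity = factor(table[[identity]]),
                   modality = factor(table[[modality]]),
                   y = table[[dv]])
  counts <- table(df$subject, df$identity, df$modality)
  if (any(counts != 1)) {
    bad <- rownames(counts)[apply(counts != 1, 1, any)]
    stop("incomplete 2x2 cells for subject(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- nlevels(df$subject)

  m <- stats::aov(y ~ identity * modality +
                    Error(subject / (identity * modality)), data = df)
  sm <- summary(m)
  pull <- function(stratum, effect) {
    tab <- sm[[stratum]][[1]]
    rn <- trimws(rownames(tab))
    ss_e <- tab[rn == effect, "Sum Sq"]
    ss_r <- tab[rn == "Residuals", "Sum Sq"]
    f <- tab[rn == effect, "F value"]
    p <- tab[rn == effect, "Pr(>F)"]
    data.frame(effect = effect, F = f, df1 = 1, df2 = n - 1, p = p,
               SS_effect = ss_e, SS_error = ss_r,
               eta_p_sq = ss_e / (ss_e + ss_r))
  }
  effects <- rbind(
    pull("Error: subject:identity", "identity"),
    pull("Error: subject:modality", "modality"),
    pull("Error: subject:identity:modality", "identity:modality"))
  effects$effect <- c("identity", "modality", "interaction")
  effects$label <- vapply(effects$eta_p_sq, effect_size_label, "")
  rownames(effects) <- effects$effect

  agg_mean <- tapply(df$y, list(df$identity, df$modality), mean)
  agg_se <- tapply(df$y, list(df$identity, df$modality),
                   function(v) stats::sd(v) / sqrt(length(v)))

  structure(
    list(effects = effects, cell_means = agg_mean, cell_ses = agg_se,
         n_subjects = n),
    class = "rm_anova_result"
  )
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("2x2 repeated-measures ANOVA (n = %d)\n", x$n_subjects))
  for (i in seq_len(nrow(x$effects))) {
    e <- x$effects[i, ]
    cat(sprintf("  %-12s F(%d, %d) = %5.2f, p = %.3f, eta_p^2 = %.3f (%s)\n",
                e$effect, e$df1, e$df2, e$F, e$p, e$eta_p_sq, e$label))
  }
  invisible(x)
}

#' Partial eta squared from an F ratio
#'
#' `eta_p^2 = F * df1 / (F * df1 + df2)`, algebraically identical to
#' `SS_effect / (SS_effect + SS_error)` for the corresponding stratum.
#'
#' @param F F ratio (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom (>= 1).
#' @return Partial eta squared in `[0, 1]`.
#' @examples
#' partial_eta_sq(5.20, 1, 26)  # ~0.17
#' @export
partial_eta_sq <- function(F, df1, df2) {
  if (F < 0) stop("`F` must be >= 0", call. = FALSE)
  if (df1 < 1 || df2 < 1) stop("degrees of freedom must be >= 1", call. = FALSE)
  F * df1 / (F * df1 + df2)
}

#' Effect-size label for partial eta squared
#'
#' Conventional cutoffs on half-open intervals: negligible below 0.01,
#' small in `[0.01, 0.06)`, medium in `[0.06, 0.14)`, large at 0.14 and
#' above.
#'
#' @param eta_p_sq Value in `[0, 1]`.
#' @return One of `"negligible"`, `"small"`, `"medium"`, `"large"`.
#' @export
effect_size_label <- function(eta_p_sq) {
  if (is.na(eta_p_sq) || eta_p_sq < 0 || eta_p_sq > 1) {
    stop("`eta_p_sq` must lie in [0, 1]", call. = FALSE)
  }
  if (eta_p_sq >= 0.14) "large"
  else if (eta_p_sq >= 0.06) "medium"
  else if (eta_p_sq >= 0.01) "small"
  else "negligible"
}

#' Default planned contrasts for the 2 x 2 design
#'
#' The four simple effects: within each identity, P7 versus P8; within each
#' site, human versus AI.
#'
#' @return List of contrasts, each a list with `label`, `cell_a`, `cell_b`
#'   (named character vectors of factor levels).
#' @export
default_contrasts <- function() {
  list(
    list(label = "human: P7 vs P8",
         cell_a = c(identity = "human", site = "P7"),
         cell_b = c(identity = "human", site = "P8")),
    list(label = "AI: P7 vs P8",
         cell_a = c(identity = "AI", site = "P7"),
         cell_b = c(identity = "AI", site = "P8")),
    list(label = "P7: human vs AI",
         cell_a = c(identity = "human", site = "P7"),
         cell_b = c(identity = "AI", site = "P7")),
    list(label = "P8: human vs AI",
         cell_a = c(identity = "human", site = "P8"),
         cell_b = c(identity = "AI", site = "P8"))
  )
}

#' Bonferroni-corrected planned post-hoc contrasts
#'
#' Runs a paired t per planned simple-effect contrast and flags
#' significance against the Bonferroni-corrected criterion
#' `alpha / n_contrasts` (0.0125 for the default four contrasts at
#' alpha = 0.05).
#'
#' @param table One-component `amplitude_table` slice.
#' @param contrasts List of contrasts as in [default_contrasts()].
#' @param alpha Familywise alpha (default 0.05).
#' @return Object of class `posthoc_result`: data.frame with one row per
#'   contrast (`difference`, `t`, `df`, `p`, `alpha_bonf`, `significant`).
#' @export
bonferroni_posthoc <- function(table, contrasts = default_contrasts(),
                               alpha = 0.05) {
  if (length(contrasts) == 0) stop("empty contrast list", call. = FALSE)
  alpha_bonf <- alpha / length(contrasts)
  cell_values <- function(cell) {
    sel <- rep(TRUE, nrow(table))
    for (f in names(cell)) sel <- sel & table[[f]] == cell[[f]]
    v <- table[sel, ]
    v <- v[order(v$subject), ]
    v$amplitude_uv
  }
  rows <- lapply(contrasts, function(ct) {
    a <- cell_values(ct$cell_a)
    b <- cell_values(ct$cell_b)
    tt <- paired_t(a, b)
    data.frame(contrast = ct$label, difference = tt$mean_diff,
               t = tt$t, df = tt$df, p = tt$p,
               alpha_bonf = alpha_bonf, significant = tt$p < alpha_bonf)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("posthoc_result", "data.frame")
  out
}

# normality gate tolerant of tiny cohorts: below n = 3 the Shapiro-Wilk
# statistic is undefined and the parametric default is kept
gate_normality <- function(x) {
  if (length(x) < 3 || stats::sd(x) == 0) {
    return(list(W = NA_real_, p = NA_real_))
  }
  shapiro_wilk(x)
}

#' Analyse the subjective rating tables
#'
#' For each instrument (attitude, naturalness): compute per-subject agent
#' means, gate on Shapiro-Wilk normality of the human-AI differences, and
#' run the Wilcoxon signed-rank test when normality is violated (p < 0.05)
#' or the paired t otherwise.
#'
#' @param ratings A [simulate_ratings()]-shaped data.frame.
#' @param alpha Significance level used downstream.
#' @return Named list per instrument: `normality` (W, p), `test`
#'   (`"wilcoxon"` or `"paired_t"`), `result`, `means`, `sds`.
#' @export
analyze_ratings <- function(ratings, alpha = 0.05) {
  out <- list()
  for (inst in unique(ratings$instrument)) {
    sub <- ratings[ratings$instrument == inst, ]
    wide <- stats::reshape(sub[, c("subject", "agent", "mean_score")],
                           idvar = "subject", timevar = "agent",
                           direction = "wide")
    human <- wide$mean_score.human
    ai <- wide$mean_score.AI
    gate <- gate_normality(ai - human)
    if (!is.na(gate$p) && gate$p < 0.05) {
      res <- wilcoxon_signed_rank(human, ai, labels = c("human", "AI"))
      test <- "wilcoxon"
    } else {
      res <- paired_t(human, ai)
      test <- "paired_t"
    }
    out[[inst]] <- list(
      normality = gate, test = test, result = res,
      means = c(human = mean(human), AI = mean(ai)),
      sds = c(human = stats::sd(human), AI = stats::sd(ai)))
  }
  out
}

#' Analyse the component amplitude table
#'
#' Per component: gate each effect's within-subject contrast scores on
#' Shapiro-Wilk normality, run the 2 x 2 repeated-measures ANOVA, and,
#' when the interaction is significant at `alpha`, the Bonferroni-corrected
#' planned contrasts.
#'
#' @param table An `amplitude_table`.
#' @param alpha Significance level (default 0.05).
#' @return Named list per component: `normality` (per-effect gates),
#'   `anova` ([rm_anova_2x2()] result), `posthoc` (or `NULL`).
#' @export
analyze_amplitudes <- function(table, alpha = 0.05) {
  out <- list()
  for (cmp in unique(table$component)) {
    slice <- table[table$component == cmp, ]
    slice <- slice[order(slice$subject, slice$identity, slice$site), ]
    # contrast scores per effect over the 2x2
    get <- function(id, site) {
      slice$amplitude_uv[slice$identity == id & slice$site == site]
    }
    hp7 <- get("human", "P7"); hp8 <- get("human", "P8")
    ap7 <- get("AI", "P7"); ap8 <- get("AI", "P8")
    gates <- list(
      identity = gate_normality((hp7 + hp8) / 2 - (ap7 + ap8) / 2),
      modality = gate_normality((hp7 + ap7) / 2 - (hp8 + ap8) / 2),
      interaction = gate_normality((hp7 - hp8) - (ap7 - ap8)))
    an <- rm_anova_2x2(slice)
    ph <- if (an$effects["interaction", "p"] < alpha) {
      bonferroni_posthoc(slice, alpha = alpha)
    }
    out[[cmp]] <- list(normality = gates, anova = an, posthoc = ph)
  }
  out
}
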