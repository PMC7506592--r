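test_that("the Shapiro-Wilk gate separates normal from bimodal samples", {
  set.seed(101)
  bimodal <- c(rnorm(25, 0, 1), rnorm(25, 100, 1))
  expect_lt(shapiro_wilk(bimodal)$p, 0.05)

  # type-I behaviour: normal samples rarely fail the gate
  keeps <- vapply(1:100, function(i) {
    set.seed(2000 + i)
    shapiro_wilk(rnorm(20))$p > 0.05
  }, logical(1))
  expect_gte(mean(keeps), 0.90)

  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  expect_error(shapiro_wilk(rnorm(2)), "n")
})

test_that("Wilcoxon exact path matches closed-form enumeration", {
  # six pairs, all differences positive: one-sided 1/64, two-sided 1/32
  a <- 1:6
  b <- 2 * (1:6)
  w <- wilcoxon_signed_rank(a, b)
  expect_identical(w$method, "exact")
  expect_equal(w$p, 1 / 32)
  expect_equal(w$n_effective, 6L)
  expect_equal(w$mean_rank_pos, 3.5)

  # antisymmetric differences carry no signed-rank information
  w0 <- wilcoxon_signed_rank(c(1, 2, 3, 4), c(3, 0, 5, 2))  # d = +2,-2,+2,-2
  expect_equal(w0$Z, 0)
  expect_equal(w0$p, 1)

  expect_error(wilcoxon_signed_rank(1:5, 1:5), "no information")
})

test_that("Wilcoxon normal approximation matches the reference and the oracle", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(15:40, 1)
    a <- rnorm(n)
    b <- a + rnorm(n, 0.3)
    w <- wilcoxon_signed_rank(a, b, method = "normal")
    ref <- stats::wilcox.test(b, a, paired = TRUE, exact = FALSE,
                              correct = FALSE)
    expect_equal(w$p, ref$p.value, tolerance = 1e-10)
    expect_equal(w$V, unname(ref$statistic))
  }
  # exact path agrees with the independent brute-force oracle, ties included
  for (i in 1:25) {
    n <- sample(6:12, 1)
    a <- sample(0:8, n, TRUE)
    b <- sample(0:8, n, TRUE)
    if (all(b - a == 0)) next
    w <- wilcoxon_signed_rank(a, b, method = "exact")
    expect_equal(w$p, oracle_wilcoxon_exact(b - a), tolerance = 1e-12)
  }
})

test_that("Wilcoxon p is invariant under monotone transforms of |d|", {
  set.seed(12)
  a <- rnorm(20)
  b <- a + rnorm(20, 0.4)
  d <- b - a
  # cubing preserves sign and |d| rank order
  w1 <- wilcoxon_signed_rank(rep(0, 20), d, method = "normal")
  w2 <- wilcoxon_signed_rank(rep(0, 20), sign(d) * abs(d)^3,
                             method = "normal")
  expect_equal(w1$p, w2$p, tolerance = 1e-12)
  expect_equal(w1$Z, w2$Z, tolerance = 1e-12)
})

test_that("paired t follows the textbook formula", {
  d <- c(2, -1, 3, 0, 1)
  r <- paired_t(d, rep(0, 5))
  expect_equal(r$t, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  expect_equal(r$t, 1.4142, tolerance = 1e-4)
  expect_equal(r$df, 4)

  # symmetric differences give t = 0, p = 1
  sym <- paired_t(c(1, 2, 3), c(1, 2, 3) - c(-1, 0, 1))
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 1)
  # all-zero (identical columns) and constant nonzero differences both have
  # zero variance and are error paths
  expect_error(paired_t(c(1, 2, 3), c(1, 2, 3)), "zero variance")
  expect_error(paired_t(c(2, 3, 4, 5), c(1, 2, 3, 4)), "zero variance")
})

test_that("the 2x2 RM-ANOVA matches its paired-contrast identity", {
  set.seed(55)
  for (i in 1:10) {
    tab <- simulate_amplitude_cohort(12, seed = 100 + i)
    slice <- tab[tab$component == "P1", ]
    an <- rm_anova_2x2(slice)
    get <- function(id, site) {
      v <- slice[slice$identity == id & slice$site == site, ]
      v$amplitude_uv[order(v$subject)]
    }
    hp7 <- get("human", "P7"); hp8 <- get("human", "P8")
    ap7 <- get("AI", "P7"); ap8 <- get("AI", "P8")
    contrasts <- list(
      identity = (hp7 + hp8) / 2 - (ap7 + ap8) / 2,
      modality = (hp7 + ap7) / 2 - (hp8 + ap8) / 2,
      interaction = (hp7 - hp8) - (ap7 - ap8))
    for (eff in names(contrasts)) {
      tt <- paired_t(contrasts[[eff]], rep(0, length(hp7)))
      expect_equal(an$effects[eff, "F"], tt$t^2, tolerance = 1e-9)
      expect_equal(an$effects[eff, "p"], tt$p, tolerance = 1e-9)
      # SS-based partial eta squared agrees with the F-based formula
      expect_equal(an$effects[eff, "eta_p_sq"],
                   partial_eta_sq(an$effects[eff, "F"], 1, 11),
                   tolerance = 1e-9)
    }
    expect_true(all(an$effects$df2 == 11))
  }
})

test_that("an additively constructed design has a null interaction", {
  set.seed(66)
  subj <- rep(1:10, each = 4)
  id <- rep(c("human", "human", "AI", "AI"), 10)
  site <- rep(c("P7", "P8"), 20)
  # per-subject additive identity and site effects, no interaction term
  a <- rep(2 + rnorm(10, sd = 0.5), each = 4)
  b <- rep(1.5 + rnorm(10, sd = 0.5), each = 4)
  y <- a * (id == "human") + b * (site == "P8") + rep(rnorm(10), each = 4)
  tab <- data.frame(subject = subj, identity = id, site = site,
                    amplitude_uv = y)
  an <- rm_anova_2x2(tab)
  # exactly additive data: the interaction carries no sum of squares (its F
  # is then a ratio of rounding residuals, so assert on SS, not F)
  expect_lt(an$effects["interaction", "SS_effect"], 1e-20)
  expect_gt(an$effects["identity", "F"], 10)
  expect_error(rm_anova_2x2(tab[-1, ]), "incomplete")
})

test_that("cell means and SEs summarise the 2x2 table", {
  tab <- simulate_amplitude_cohort(20, seed = 9)
  slice <- tab[tab$component == "N170", ]
  an <- rm_anova_2x2(slice)
  v <- slice$amplitude_uv[slice$identity == "human" & slice$site == "P8"]
  expect_equal(an$cell_means["human", "P8"], mean(v))
  expect_equal(an$cell_ses["human", "P8"], sd(v) / sqrt(20))
})

test_that("partial eta squared reproduces the printed effect sizes", {
  expect_equal(round(partial_eta_sq(5.20, 1, 26), 2), 0.17)
  expect_equal(round(partial_eta_sq(6.34, 1, 26), 2), 0.20)
  expect_equal(partial_eta_sq(0, 1, 26), 0)
  expect_error(partial_eta_sq(-1, 1, 26), ">= 0")
})

test_that("effect sizes are labelled on half-open intervals", {
  expect_identical(effect_size_label(0.17), "large")
  expect_identical(effect_size_label(0.14), "large")
  expect_identical(effect_size_label(0.06), "medium")
  expect_identical(effect_size_label(0.01), "small")
  expect_identical(effect_size_label(0.002), "negligible")
  expect_error(effect_size_label(1.2), "0, 1")
})

test_that("Bonferroni criterion and flags follow alpha / n_contrasts", {
  tab <- simulate_amplitude_cohort(20, seed = 17)
  slice <- tab[tab$component == "N170", ]
  ph <- bonferroni_posthoc(slice)
  expect_equal(nrow(ph), 4)
  expect_true(all(ph$alpha_bonf == 0.0125))
  expect_equal(ph$significant, ph$p < 0.0125)
  one <- bonferroni_posthoc(slice, contrasts = default_contrasts()[1])
  expect_equal(one$alpha_bonf, 0.05)
  expect_error(bonferroni_posthoc(slice, contrasts = list()), "empty")
})

test_that("each test holds its nominal type-I error under the null", {
  null_pop <- study_population()
  null_pop$p1_means[] <- 5
  null_pop$n170_means[] <- -1.5
  n_rep <- 1000
  rej <- c(wilcoxon = 0, t = 0, anova_identity = 0, anova_interaction = 0)
  for (i in seq_len(n_rep)) {
    set.seed(30000 + i)
    a <- rnorm(27); b <- rnorm(27)
    rej["wilcoxon"] <- rej["wilcoxon"] +
      (wilcoxon_signed_rank(a, b, method = "normal")$p < 0.05)
    rej["t"] <- rej["t"] + (paired_t(a, b)$p < 0.05)
  }
  for (i in seq_len(250)) {
    tab <- simulate_amplitude_cohort(27, seed = 40000 + i,
                                     population = null_pop)
    an <- rm_anova_2x2(tab[tab$component == "P1", ])
    rej["anova_identity"] <- rej["anova_identity"] +
      (an$effects["identity", "p"] < 0.05)
    rej["anova_interaction"] <- rej["anova_interaction"] +
      (an$effects["interaction", "p"] < 0.05)
  }
  expect_gt(rej[["wilcoxon"]] / n_rep, 0.03)
  expect_lt(rej[["wilcoxon"]] / n_rep, 0.07)
  expect_gt(rej[["t"]] / n_rep, 0.03)
  expect_lt(rej[["t"]] / n_rep, 0.07)
  expect_gt(rej[["anova_identity"]] / 250, 0.02)
  expect_lt(rej[["anova_identity"]] / 250, 0.08)
  expect_gt(rej[["anova_interaction"]] / 250, 0.02)
  expect_lt(rej[["anova_interaction"]] / 250, 0.08)
})

test_that("the normality gate routes ratings and amplitudes as intended", {
  prof <- subject_profile()
  ratings <- simulate_ratings(prof, 27, seed = 61)
  rs <- analyze_ratings(ratings)
  for (inst in names(rs)) {
    expect_true(rs[[inst]]$test %in% c("wilcoxon", "paired_t"))
    # the gate decision must match the recorded normality p-value
    expect_identical(rs[[inst]]$test == "wilcoxon",
                     rs[[inst]]$normality$p < 0.05)
  }
  tab <- simulate_amplitude_cohort(27, seed = 62)
  as_ <- analyze_amplitudes(tab)
  expect_named(as_, c("P1", "N170"), ignore.order = TRUE)
  for (cmp in names(as_)) {
    expect_s3_class(as_[[cmp]]$anova, "rm_anova_result")
    expect_length(as_[[cmp]]$normality, 3)
  }
  # posthoc runs exactly when the interaction is significant
  for (cmp in names(as_)) {
    sig <- as_[[cmp]]$anova$effects["interaction", "p"] < 0.05
    expect_identical(!is.null(as_[[cmp]]$posthoc), sig)
  }
})
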