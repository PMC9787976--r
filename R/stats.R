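#' Assemble a time course matrix for permutation testing
#'
#' @param data Numeric array `subjects x trials x timepoints` of per-trial
#'   response time courses (e.g. 0-17 s after CS onset at 10 Hz, 170
#'   points), missing values pre-interpolated.
#' @param condition Character matrix `subjects x trials` of `"CS+"` /
#'   `"CS-"` labels.
#' @param time Optional time grid of the third dimension.
#' @param modality Label carried through to results.
#' @return A `timecourse_matrix`.
#' @export
timecourse_matrix <- function(data, condition, time = NULL, modality = "scr") {
  stopifnot(length(dim(data)) == 3L,
            all(dim(condition) == dim(data)[1:2]),
            all(condition %in% c("CS+", "CS-")),
            all(is.finite(data)))
  structure(list(data = data, condition = condition, time = time,
                 modality = modality),
            class = "timecourse_matrix")
}

# paired t statistics per timepoint from a subjects x timepoints matrix of
# condition differences; zero-variance columns give t = 0
paired_t_cols <- function(D) {
  S <- nrow(D)
  m <- colMeans(D)
  v <- colSums(sweep(D, 2, m)^2) / (S - 1)
  se <- sqrt(v / S)
  t <- ifelse(se > 0, m / se, 0)
  t
}

# maximal runs of supra-threshold same-sign t values and their masses
find_clusters <- function(t, tcrit) {
  lab <- integer(length(t))
  lab[t > tcrit] <- 1L
  lab[t < -tcrit] <- -1L
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  data.frame(start_idx = starts[keep], end_idx = ends[keep],
             sign = r$values[keep],
             mass = vapply(which(keep), function(j) {
               sum(abs(t[starts[j]:ends[j]]))
             }, numeric(1)))
}

max_cluster_mass <- function(t, tcrit) {
  supra <- abs(t) > tcrit
  if (!any(supra)) return(0)
  lab <- integer(length(t))
  lab[t > tcrit] <- 1L
  lab[t < -tcrit] <- -1L
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  if (!any(keep)) return(0)
  max(vapply(which(keep), function(j) sum(abs(t[starts[j]:ends[j]])),
             numeric(1)))
}

#' Cluster-level permutation test on trial-averaged time courses
#'
#' Observed statistic: per-timepoint paired t-test of CS+ versus CS-
#' subject condition means. Clusters are maximal runs of same-sign t
#' values exceeding the two-tailed cluster-forming threshold; the cluster
#' statistic is the mass (sum of |t|). The null distribution is the
#' maximum cluster mass over the time course when trial labels are
#' permuted within each participant (preserving each subject's condition
#' counts), re-averaging and re-testing each time. Cluster p-values use
#' the add-one estimator, so the test is exact-level and p > 0.
#'
#' @param tc A [timecourse_matrix()].
#' @param n_perm Number of label permutations.
#' @param forming_alpha Two-tailed point-wise alpha of the cluster-forming
#'   threshold.
#' @param seed Integer seed (required; the test is deterministic given it).
#' @return A `cluster_result`: observed t values, cluster table with
#'   per-cluster p, the null max-mass distribution, and the settings.
#' @export
cluster_permutation_test <- function(tc, n_perm = 10000, forming_alpha = 0.05,
                                     seed) {
  stopifnot(inherits(tc, "timecourse_matrix"))
  S <- dim(tc$data)[1]
  if (S < 2L) stop("at least 2 subjects required")
  P <- dim(tc$data)[3]
  Tn <- dim(tc$data)[2]
  tcrit <- stats::qt(1 - forming_alpha / 2, df = S - 1)
  # observed: per-subject condition-mean difference
  D <- t(vapply(seq_len(S), function(s) {
    Xs <- matrix(tc$data[s, , ], nrow = Tn)
    plus <- tc$condition[s, ] == "CS+"
    colMeans(Xs[plus, , drop = FALSE]) - colMeans(Xs[!plus, , drop = FALSE])
  }, numeric(P)))
  t_obs <- paired_t_cols(D)
  clusters <- find_clusters(t_obs, tcrit)
  null_max <- withr_seed(seed, {
    sum_d <- matrix(0, n_perm, P)
    sum_d2 <- matrix(0, n_perm, P)
    for (s in seq_len(S)) {
      plus <- tc$condition[s, ] == "CS+"
      n1 <- sum(plus); n2 <- Tn - n1
      w_base <- ifelse(plus, 1 / n1, -1 / n2)
      W <- t(vapply(seq_len(n_perm), function(p) w_base[sample.int(Tn)],
                    numeric(Tn)))
      Ds <- W %*% matrix(tc$data[s, , ], nrow = Tn)
      sum_d <- sum_d + Ds
      sum_d2 <- sum_d2 + Ds^2
    }
    m <- sum_d / S
    v <- (sum_d2 - sum_d^2 / S) / (S - 1)
    v[v < 0] <- 0
    tmat <- ifelse(v > 0, m / sqrt(v / S), 0)
    apply(tmat, 1, max_cluster_mass, tcrit = tcrit)
  })
  clusters$p <- vapply(clusters$mass, function(m) {
    (1 + sum(null_max >= m)) / (1 + n_perm)
  }, numeric(1))
  structure(
    list(t_observed = t_obs, clusters = clusters, null_max = null_max,
         n_permutations = n_perm, cluster_forming_alpha = forming_alpha,
         t_critical = tcrit, df = S - 1, seed = as.integer(seed),
         modality = tc$modality),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s: %d clusters (df = %d, |t| > %.2f, %d permutations)\n",
              x$modality, nrow(x$clusters), x$df, x$t_critical,
              x$n_permutations))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

subject_first_n_means <- function(estimates, n) {
  split_subj <- split(estimates, estimates$subject)
  res <- lapply(split_subj, function(d) {
    d <- d[order(d$trial_index), ]
    mp <- d$amplitude[d$condition == "CS+"][seq_len(n)]
    mm <- d$amplitude[d$condition == "CS-"][seq_len(n)]
    c(mean(mp, na.rm = TRUE), mean(mm, na.rm = TRUE))
  })
  do.call(rbind, res)
}

#' Trial-averaging calibration of retrodictive validity
#'
#' For each `n` from 1 to `n_max`, averages every subject's first `n` CS+
#' and first `n` CS- trials (presentation order within condition) and
#' performs a paired t-test; reports t, df, p, Cohen's d (mean difference
#' over SD of differences) and Hedges' g (small-sample corrected). The
#' average with the highest |d| is recorded as the selected `n`. In
#' confirmation mode (`n_select` given), only that single average is
#' evaluated -- the guard against selection bias on a second dataset.
#' Zero-variance differences flag the row instead of producing a
#' statistic.
#'
#' @param estimates Normalized trial-estimate data frame for one modality,
#'   method, and component.
#' @param n_max Largest average (default 15, the recall trial count).
#' @param n_select If given, evaluate only this `n` (confirmation mode).
#' @return A `calibration_result`: per-n table, `selected_n`, and the
#'   confirmation flag.
#' @export
calibrate_trial_average <- function(estimates, n_max = 15, n_select = NULL) {
  ns <- if (is.null(n_select)) seq_len(n_max) else as.integer(n_select)
  rows <- lapply(ns, function(n) {
    M <- subject_first_n_means(estimates, n)
    diffs <- M[, 1] - M[, 2]
    diffs <- diffs[is.finite(diffs)]
    S <- length(diffs)
    sdd <- stats::sd(diffs)
    if (S < 2L || !is.finite(sdd) || sdd == 0) {
      return(data.frame(n = n, t = NA_real_, df = S - 1, p = NA_real_,
                        cohen_d = NA_real_, hedges_g = NA_real_,
                        zero_variance = TRUE))
    }
    d <- mean(diffs) / sdd
    t <- d * sqrt(S)
    df <- S - 1
    data.frame(n = n, t = t, df = df,
               p = 2 * stats::pt(-abs(t), df),
               cohen_d = d,
               hedges_g = d * (1 - 3 / (4 * df - 1)),
               zero_variance = FALSE)
  })
  tab <- do.call(rbind, rows)
  sel <- if (all(is.na(tab$cohen_d))) NA_integer_
         else tab$n[which.max(abs(tab$cohen_d))]
  structure(list(table = tab, selected_n = sel,
                 confirmation = !is.null(n_select)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result>%s selected n = %s\n",
              if (x$confirmation) " (confirmation)" else "", x$selected_n))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Fit a habituation model to trial estimates
#'
#' Exponential form: ordinary least squares of
#' `a * exp(-lambda * (trial - 1))` to all trials pooled across subjects
#' (lambda by grid search plus local refinement, `a` profiled out).
#' Linear form: OLS slope on trial number. The fitted model records its
#' source dataset and is meant to be frozen: fitted once on a training
#' dataset and reused on evaluation datasets.
#'
#' @param estimates Trial-estimate data frame (uses `trial_index` and
#'   `amplitude`).
#' @param form `"exponential"` or `"linear"`.
#' @param dataset_id Identifier of the training dataset.
#' @param lambda_max Upper bound of the decay-rate search.
#' @return A `habituation_model`.
#' @export
fit_habituation <- function(estimates, form = c("exponential", "linear"),
                            dataset_id = NULL, lambda_max = 1) {
  form <- match.arg(form)
  ok <- is.finite(estimates$amplitude)
  tr <- estimates$trial_index[ok]
  y <- estimates$amplitude[ok]
  if (form == "linear") {
    fit <- stats::lm(y ~ tr)
    mod <- list(form = "linear", slope = unname(stats::coef(fit)[2]),
                intercept = unname(stats::coef(fit)[1]), lambda = NA_real_,
                source_dataset = dataset_id)
  } else {
    rss_of <- function(lam) {
      w <- exp(-lam * (tr - 1))
      a <- sum(w * y) / sum(w^2)
      sum((y - a * w)^2)
    }
    grid <- seq(0, lambda_max, length.out = 101)
    r <- vapply(grid, rss_of, numeric(1))
    best <- grid[which.min(r)]
    step <- grid[2] - grid[1]
    opt <- stats::optimize(rss_of, lower = max(0, best - step),
                           upper = min(lambda_max, best + step))
    lam <- if (opt$objective < rss_of(best)) opt$minimum else best
    w <- exp(-lam * (tr - 1))
    mod <- list(form = "exponential", lambda = max(0, lam),
                intercept = sum(w * y) / sum(w^2), slope = NA_real_,
                source_dataset = dataset_id)
  }
  structure(mod, class = "habituation_model")
}

#' Habituation regressor for a trial index
#'
#' @param model A [fit_habituation()] model.
#' @param trial Trial indices.
#' @return Exponential-decay regressor `exp(-lambda (trial - 1))` or, for
#'   the linear form, the trial index itself.
#' @export
habituation_regressor <- function(model, trial) {
  stopifnot(inherits(model, "habituation_model"))
  if (model$form == "exponential") exp(-model$lambda * (trial - 1))
  else as.numeric(trial)
}

#' Linear mixed-effects test of condition and trial effects
#'
#' Fits `amplitude ~ trial_regressor * condition` with random intercept
#' and random trial slope per subject, where the trial regressor is the
#' habituation transform of trial number (exponential decay or linear,
#' from a frozen training-set fit). Reports F tests for the two main
#' effects and their interaction with partial eta squared. A singular
#' random-effects fit falls back to the random-intercept model with a
#' warning; `random_structure = "select"` picks the structure by AIC (a
#' training-dataset decision).
#'
#' @param estimates Trial-estimate data frame.
#' @param habituation A [fit_habituation()] model. Train/evaluate
#'   separation is the caller's contract: the model carries its source
#'   dataset id.
#' @param random_structure `"intercept_slope"`, `"intercept"`, or
#'   `"select"`.
#' @param ddf Denominator degrees of freedom: `"satterthwaite"` or
#'   `"residual"`.
#' @return An `lme_result`: per-effect table (F, df, p, partial eta
#'   squared), the chosen random structure, and the fitted model.
#' @export
lme_condition_test <- function(estimates, habituation,
                               random_structure = c("intercept_slope",
                                                    "intercept", "select"),
                               ddf = c("satterthwaite", "residual")) {
  random_structure <- match.arg(random_structure)
  ddf <- match.arg(ddf)
  d <- estimates[is.finite(estimates$amplitude), ]
  d$trialreg <- habituation_regressor(habituation, d$trial_index)
  # center the regressor and use sum-to-zero contrasts so the type-3
  # condition test is the average condition effect
  d$trialreg <- d$trialreg - mean(d$trialreg)
  d$condition <- factor(d$condition, levels = c("CS-", "CS+"))
  stats::contrasts(d$condition) <- stats::contr.sum(2)
  d$subject <- factor(d$subject)
  fit_one <- function(slope) {
    form <- if (slope) amplitude ~ trialreg * condition + (1 + trialreg | subject)
            else amplitude ~ trialreg * condition + (1 | subject)
    suppressMessages(lmerTest::lmer(form, data = d,
                                    control = lme4::lmerControl(
                                      check.conv.singular =
                                        lme4::.makeCC(action = "ignore",
                                                      tol = 1e-4))))
  }
  if (random_structure == "select") {
    m1 <- fit_one(TRUE); m0 <- fit_one(FALSE)
    use_slope <- stats::AIC(m1) <= stats::AIC(m0)
    model <- if (use_slope) m1 else m0
    random_structure <- if (use_slope) "intercept_slope" else "intercept"
  } else {
    model <- fit_one(random_structure == "intercept_slope")
    if (random_structure == "intercept_slope" && lme4::isSingular(model)) {
      warning("singular random-effects fit; falling back to random intercept")
      model <- fit_one(FALSE)
      random_structure <- "intercept"
    }
  }
  an <- if (ddf == "satterthwaite") {
    stats::anova(model, type = 3, ddf = "Satterthwaite")
  } else {
    a <- stats::anova(model, type = 3, ddf = "Satterthwaite")
    a$DenDF <- nrow(d) - length(lme4::fixef(model))
    a$`Pr(>F)` <- stats::pf(a$`F value`, a$NumDF, a$DenDF, lower.tail = FALSE)
    a
  }
  eff <- data.frame(
    effect = rownames(an),
    F = an$`F value`, df1 = an$NumDF, df2 = an$DenDF,
    p = an$`Pr(>F)`,
    partial_eta_sq = an$`F value` * an$NumDF /
      (an$`F value` * an$NumDF + an$DenDF),
    stringsAsFactors = FALSE)
  rownames(eff) <- NULL
  structure(list(effects = eff, random_structure = random_structure,
                 ddf = ddf, model = model),
            class = "lme_result")
}

#' @export
print.lme_result <- function(x, ...) {
  cat(sprintf("<lme_result> random structure: %s, ddf: %s\n",
              x$random_structure, x$ddf))
  print(x$effects, row.names = FALSE)
  invisible(x)
}

t_test_power <- function(n, d, design, alpha, tails) {
  if (design == "paired") {
    df <- n - 1
    ncp <- d * sqrt(n)
  } else {
    df <- 2 * n - 2
    ncp <- d * sqrt(n / 2)
  }
  if (df < 1) return(0)
  if (tails == "one") {
    stats::pt(stats::qt(1 - alpha, df), df, ncp = ncp, lower.tail = FALSE)
  } else {
    q <- stats::qt(1 - alpha / 2, df)
    stats::pt(q, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-q, df, ncp = ncp)
  }
}

#' Sample size from exact noncentral-t power
#'
#' Smallest sample size whose t-test power reaches the target, computed
#' from the noncentral t distribution (no normal approximation). Paired
#' design: df = n - 1, noncentrality d * sqrt(n), returns n subjects.
#' Two-sample design with 1:1 allocation: df = 2 n - 2 per-group,
#' noncentrality d * sqrt(n / 2), returns the total across both arms.
#'
#' @param d Standardized effect size (> 0).
#' @param design `"paired"` or `"two_sample"`.
#' @param alpha Significance level.
#' @param power Target power.
#' @param tails `"one"` or `"two"`.
#' @return Integer sample size (total for `two_sample`).
#' @export
sample_size <- function(d, design = c("paired", "two_sample"), alpha = 0.05,
                        power = 0.80, tails = c("one", "two")) {
  design <- match.arg(design)
  tails <- match.arg(tails)
  stopifnot(d > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  n <- 2L
  while (t_test_power(n, d, design, alpha, tails) < power) {
    n <- n + 1L
    if (n > 1e7) stop("sample size search did not converge")
  }
  if (design == "two_sample") 2L * n else n
}

#' Two-sample t and Cohen's d from summary statistics
#'
#' Pooled-variance two-sample t-test and standardized mean difference
#' recomputed from group means, SDs, and sizes.
#'
#' @param mean1,sd1,n1 Summary of group 1.
#' @param mean2,sd2,n2 Summary of group 2.
#' @return List with `t`, `df`, `p` (two-sided), and `cohen_d`.
#' @export
summary_t_and_d <- function(mean1, sd1, n1, mean2, sd2, n2) {
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       cohen_d = (mean1 - mean2) / sqrt(sp2))
}

#' 2x2 chi-square test with Yates continuity correction
#'
#' @param a,b,c,d Cell counts of the 2x2 table (rows are groups).
#' @return List with `chi2`, `df` = 1, and `p`.
#' @export
chi2_2x2_yates <- function(a, b, c, d) {
  n <- a + b + c + d
  num <- n * (max(abs(a * d - b * c) - n / 2, 0))^2
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  if (den == 0) return(list(chi2 = NA_real_, df = 1, p = NA_real_))
  chi2 <- num / den
  list(chi2 = chi2, df = 1, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}
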