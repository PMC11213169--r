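#' Build a 2x2 exposure-by-outcome contingency table from annotations
#'
#' Rows are exposure groups (high, low), columns the outcome (yes, no),
#' counting deletions of the requested target status.
#'
#' @param annotations output of [annotate_deletions()].
#' @param patients patient metadata tibble (see [read_patients()]).
#' @param outcome name of a logical annotation column, e.g.
#'   `"rag_mediated"`, `"full_both"`, `"hept_any"`, `"hept_both"`.
#' @param target which deletions to count (default `"off_target"`; use
#'   `"ig_tcr"` or `"all"`).
#' @return 2x2 integer matrix with dimnames.
#' @export
rag_contingency <- function(annotations, patients,
                            outcome = "rag_mediated",
                            target = "off_target") {
  x <- annotations
  if (target != "all") x <- x[x$target_status == target, ]
  grp <- patients$exposure_group[match(x$patient_id, patients$patient_id)]
  if (any(is.na(grp))) rs_abort("deletion with patient_id absent from patients")
  y <- x[[outcome]]
  tab <- matrix(c(sum(y[grp == "high"]), sum(!y[grp == "high"]),
                  sum(y[grp == "low"]), sum(!y[grp == "low"])),
                nrow = 2, byrow = TRUE,
                dimnames = list(exposure = c("high", "low"),
                                outcome = c("yes", "no")))
  tab
}

check_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) rs_abort("need a 2x2 table")
  if (any(tab < 0)) rs_abort("counts must be nonnegative")
  tab
}

#' Pearson chi-square test on a 2x2 table
#'
#' One degree of freedom, two-sided, without Yates continuity correction
#' (the convention that reproduces the group-comparison p-values this
#' analysis is built around).
#'
#' @param tab 2x2 matrix of counts (rows = groups, columns = outcome).
#' @return tibble with `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(tab) {
  tab <- check_2x2(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    rs_abort("chi-square test needs nonzero margins")
  }
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  if (any(ht$expected <= 0)) rs_abort("expected cell count of 0")
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value as the sum of hypergeometric probabilities, over all
#' tables with the observed margins, of tables no more probable than the
#' observed one (the convention of mainstream statistics libraries).
#'
#' @inheritParams chi_square_test
#' @return tibble with `p_value`.
#' @export
fisher_exact_test <- function(tab) {
  tab <- check_2x2(tab)
  tibble(p_value = fisher.test(tab)$p.value)
}

#' Crude odds ratio with Woolf 95% confidence interval
#'
#' OR = ad/bc; CI = exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)).
#' Tables with a zero cell get the Haldane-Anscombe 0.5 correction in
#' every cell (flagged).
#'
#' @inheritParams chi_square_test
#' @return tibble with `or`, `ci_low`, `ci_high`, `haldane`.
#' @export
odds_ratio <- function(tab) {
  tab <- check_2x2(tab)
  haldane <- any(tab == 0)
  if (haldane) tab <- tab + 0.5
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  se <- sqrt(sum(1 / tab))
  tibble(or = or, ci_low = exp(log(or) - 1.96 * se),
         ci_high = exp(log(or) + 1.96 * se), haldane = haldane)
}

#' Bootstrap percentile confidence interval for a proportion
#'
#' Resamples the per-deletion outcomes with replacement and reports the
#' 2.5/97.5 percentile interval of the resampled proportion.
#'
#' @param outcomes logical (or 0/1) vector, one element per deletion.
#' @param B bootstrap replicates (default 10000).
#' @param seed RNG seed (recorded in the output).
#' @return tibble with `prop`, `ci_low`, `ci_high`, `n`, `B`, `seed`.
#' @export
bootstrap_proportion_ci <- function(outcomes, B = 10000, seed = 1) {
  n <- length(outcomes)
  if (n == 0L) rs_abort("empty outcome vector")
  outcomes <- as.numeric(outcomes)
  props <- withr::with_seed(seed, {
    colMeans(matrix(outcomes[sample.int(n, n * B, replace = TRUE)],
                    nrow = n))
  })
  q <- unname(quantile(props, c(0.025, 0.975)))
  tibble(prop = mean(outcomes), ci_low = q[1], ci_high = q[2], n = n,
         B = B, seed = seed)
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Exact two-sided p-value when there are no ties and the combined sample
#' size is at most 20; otherwise the normal approximation with midranks
#' and tie-corrected variance (no continuity correction).
#'
#' @param x,y numeric vectors (per-patient counts in the two groups).
#' @return tibble with `statistic` (W), `p_value`, `method`.
#' @export
wilcoxon_group_test <- function(x, y) {
  if (!length(x) || !length(y)) rs_abort("both groups must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && (length(x) + length(y)) <= 20
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = FALSE))
  p <- ht$p.value
  if (is.nan(p)) p <- 1   # zero rank variance: identical samples
  tibble(statistic = unname(ht$statistic), p_value = p,
         method = if (exact) "exact" else "normal")
}

#' Linear association with age at diagnosis
#'
#' Ordinary least squares of a per-patient value on age, with the t-test
#' p-value for the slope.
#'
#' @param value numeric per-patient response (count or proportion;
#'   `NA` rows are dropped).
#' @param age age at diagnosis in years.
#' @return tibble with `slope`, `se`, `p_value`, `n`.
#' @export
age_association <- function(value, age) {
  keep <- !is.na(value) & !is.na(age)
  value <- value[keep]; age <- age[keep]
  if (length(value) < 3) rs_abort("need at least 3 patients")
  if (sd(age) == 0) rs_abort("age is constant; slope undefined")
  fit <- lm(value ~ age)
  cf <- summary(fit)$coefficients
  tibble(slope = cf[2, 1], se = cf[2, 2], p_value = cf[2, 4],
         n = length(value))
}

#' Per-patient deletion summaries
#'
#' Counts per patient: total deletions, putatively RAG-mediated
#' deletions, off-target deletions, off-target RAG-mediated deletions,
#' and the within-patient proportion of off-target deletions that are
#' RAG-mediated (undefined, `NA`, for patients with no off-target
#' deletion; such patients are excluded from proportion summaries).
#'
#' @param annotations output of [annotate_deletions()].
#' @param patients patient metadata tibble; every `patient_id` in the
#'   annotations must appear here.
#' @return tibble, one row per patient (patients without deletions get
#'   zero counts).
#' @export
patient_summaries <- function(annotations, patients) {
  orphan <- setdiff(annotations$patient_id, patients$patient_id)
  if (length(orphan)) {
    rs_abort(paste0("deletion(s) with unknown patient_id: ",
                    paste(orphan, collapse = ", ")))
  }
  per <- annotations |>
    group_by(.data$patient_id) |>
    summarise(
      n_deletions = n(),
      n_rag = sum(.data$rag_mediated),
      n_offtarget = sum(.data$target_status == "off_target"),
      n_offtarget_rag = sum(.data$rag_mediated &
                              .data$target_status == "off_target"),
      .groups = "drop"
    )
  out <- patients |>
    left_join(per, by = "patient_id") |>
    mutate(across(c("n_deletions", "n_rag", "n_offtarget",
                    "n_offtarget_rag"),
                  ~ dplyr::coalesce(.x, 0L))) |>
    mutate(prop_offtarget_rag = if_else(.data$n_offtarget > 0,
                                        .data$n_offtarget_rag /
                                          .data$n_offtarget, NA_real_))
  n_undef <- sum(is.na(out$prop_offtarget_rag))
  if (n_undef > 0) {
    inform(sprintf(
      "%d patient(s) with no off-target deletion; proportion undefined",
      n_undef))
  }
  out
}

#' Group medians and IQRs of per-patient summaries
#'
#' @param summaries output of [patient_summaries()].
#' @return tibble with one row per exposure group and summary variable:
#'   `median`, `iqr`, `min`, `max`, `n_patients`.
#' @export
summarise_groups <- function(summaries) {
  summaries |>
    tidyr::pivot_longer(c("n_deletions", "n_rag", "n_offtarget",
                          "n_offtarget_rag", "prop_offtarget_rag"),
                        names_to = "variable") |>
    group_by(.data$exposure_group, .data$variable) |>
    summarise(
      median = median(.data$value, na.rm = TRUE),
      iqr = stats::IQR(.data$value, na.rm = TRUE),
      min = suppressWarnings(min(.data$value, na.rm = TRUE)),
      max = suppressWarnings(max(.data$value, na.rm = TRUE)),
      n_patients = sum(!is.na(.data$value)),
      .groups = "drop"
    )
}

#' Firth-penalised logistic regression (fixed effects only)
#' @noRd
firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  b <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    p <- plogis(eta)
    W <- p * (1 - p)
    XtWX <- crossprod(X * W, X)
    XtWX_inv <- solve(XtWX)
    # hat diagonal of sqrt(W) X (X'WX)^-1 X' sqrt(W)
    h <- rowSums((X %*% XtWX_inv) * X) * W
    U <- crossprod(X, y - p + h * (0.5 - p))
    step <- drop(XtWX_inv %*% U)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  list(coef = b, vcov = XtWX_inv, iter = it)
}

#' Multilevel (random-intercept logistic) model of RAG mediation
#'
#' Per-deletion logistic regression of a binary outcome (default:
#' putatively RAG-mediated) on exposure group, with a per-patient random
#' intercept to absorb within-patient clustering of deletion counts.
#' Estimated by adaptive Gauss-Hermite quadrature (`nAGQ` points),
#' falling back to the Laplace approximation if that fails. Complete
#' separation (a group with all-yes or all-no outcomes) is flagged and
#' handled by a Firth-penalised fixed-effects fit with a warning.
#'
#' @param annotations output of [annotate_deletions()], usually
#'   restricted to off-target deletions.
#' @param patients patient metadata tibble.
#' @param outcome logical annotation column (default `"rag_mediated"`;
#'   `"full_both"` for the full-RSS-at-both-breakpoints model).
#' @param target deletions to include (default `"off_target"`).
#' @param nAGQ quadrature points (default 7).
#' @return object of class `rag_mlfit` with elements `or`, `ci_low`,
#'   `ci_high`, `log_or`, `se`, `random_intercept_var`, `converged`,
#'   `separation`, `method`, `n`, and the underlying `fit`.
#' @export
multilevel_rag_model <- function(annotations, patients,
                                 outcome = "rag_mediated",
                                 target = "off_target", nAGQ = 7) {
  x <- annotations
  if (target != "all") x <- x[x$target_status == target, ]
  d <- tibble(
    y = as.numeric(x[[outcome]]),
    exposure = factor(
      patients$exposure_group[match(x$patient_id, patients$patient_id)],
      levels = c("low", "high")),
    patient = factor(x$patient_id)
  )
  if (any(is.na(d$exposure))) {
    rs_abort("deletion with patient_id absent from patients")
  }
  tab <- table(d$exposure, d$y)
  separation <- any(tab == 0)
  if (separation) {
    warn("complete separation detected; Firth-penalised fixed-effects fit")
    X <- cbind(1, as.numeric(d$exposure == "high"))
    ff <- firth_logistic(X, d$y)
    se <- sqrt(ff$vcov[2, 2])
    return(structure(list(
      or = exp(ff$coef[2]), ci_low = exp(ff$coef[2] - 1.96 * se),
      ci_high = exp(ff$coef[2] + 1.96 * se), log_or = ff$coef[2], se = se,
      random_intercept_var = NA_real_, converged = TRUE,
      separation = TRUE, method = "firth", n = nrow(d), fit = ff
    ), class = "rag_mlfit"))
  }
  fit_once <- function(nagq) {
    lme4::glmer(y ~ exposure + (1 | patient), data = d,
                family = binomial(), nAGQ = nagq)
  }
  method <- sprintf("glmer_agq%d", nAGQ)
  fit <- tryCatch(suppressMessages(fit_once(nAGQ)), error = function(e) NULL)
  if (is.null(fit)) {
    method <- "glmer_laplace"
    fit <- suppressMessages(fit_once(1))
  }
  b <- lme4::fixef(fit)[["exposurehigh"]]
  se <- sqrt(as.matrix(vcov(fit))[2, 2])
  vc <- as.data.frame(lme4::VarCorr(fit))
  converged <- length(fit@optinfo$conv$lme4) == 0 &&
    fit@optinfo$conv$opt == 0
  structure(list(
    or = exp(b), ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
    log_or = b, se = se, random_intercept_var = vc$vcov[1],
    converged = converged, separation = FALSE, method = method,
    n = nrow(d), fit = fit
  ), class = "rag_mlfit")
}

#' @export
print.rag_mlfit <- function(x, ...) {
  cat(sprintf(
    "<rag_mlfit> OR (high vs low) = %.3f [%.3f, %.3f]\n", x$or, x$ci_low,
    x$ci_high))
  cat(sprintf("  random intercept var = %s; method = %s; n = %d%s\n",
              format(x$random_intercept_var, digits = 3), x$method, x$n,
              if (x$separation) "; SEPARATION" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the multilevel fit
#'
#' @param x a `rag_mlfit`.
#' @param ... unused.
#' @return one-row tibble with `term`, `estimate` (odds ratio),
#'   `conf.low`, `conf.high`, `std.error` (log-odds scale).
#' @export
tidy.rag_mlfit <- function(x, ...) {
  tibble(term = "exposure_high", estimate = x$or, conf.low = x$ci_low,
         conf.high = x$ci_high, std.error = x$se)
}

#' One-row model summary of the multilevel fit
#'
#' @param x a `rag_mlfit`.
#' @param ... unused.
#' @return tibble with `n`, `random_intercept_var`, `converged`,
#'   `separation`, `method`.
#' @export
glance.rag_mlfit <- function(x, ...) {
  tibble(n = x$n, random_intercept_var = x$random_intercept_var,
         converged = x$converged, separation = x$separation,
         method = x$method)
}

#' Simulate per-deletion RAG outcomes from the multilevel model
#'
#' Label-level generator for parameter-recovery studies: each patient
#' gets a deletion count from a negative binomial and a normal random
#' intercept; each deletion's outcome is Bernoulli with
#' logit p = logit(`p_low`) + log(`or`) * [high] + b_patient.
#'
#' @param n_high,n_low patients per exposure group.
#' @param or true conditional odds ratio (high vs low).
#' @param p_low baseline outcome probability in the low group (at
#'   b = 0).
#' @param intercept_sd SD of the patient random intercept (logit scale).
#' @param mu_del,nb_size negative-binomial deletion-count parameters
#'   (means per group, dispersion).
#' @param seed RNG seed.
#' @return tibble with `patient_id`, `exposure_group`, `outcome`.
#' @export
simulate_rag_outcomes <- function(n_high = 18, n_low = 17, or = 2.5,
                                  p_low = 0.21, intercept_sd = 0.5,
                                  mu_del = c(high = 12, low = 5.5),
                                  nb_size = 8, seed = 1) {
  withr::with_seed(seed, {
    grp <- c(rep("high", n_high), rep("low", n_low))
    ids <- sprintf("P%02d", seq_along(grp))
    ndel <- rnbinom(length(grp), mu = unname(mu_del[grp]), size = nb_size)
    ndel <- pmax(ndel, 1L)
    b <- rnorm(length(grp), 0, intercept_sd)
    purrr::pmap_dfr(list(ids, grp, ndel, b), function(id, g, nd, bi) {
      eta <- qlogis(p_low) + log(or) * (g == "high") + bi
      tibble(patient_id = id, exposure_group = g,
             outcome = runif(nd) < plogis(eta))
    })
  })
}
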