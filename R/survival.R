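# Survival stratification of gated patients: Kaplan-Meier product-limit
# curves, log-rank test, and multivariate Cox proportional hazards
# (Efron ties, via the survival package).

#' Kaplan-Meier product-limit estimate per group
#'
#' S(t_j) = prod_{i <= j} (1 - d_i / n_i) over distinct event times t_i,
#' with censored subjects leaving the risk set after their time.
#'
#' @param time non-negative survival times (> 0 for valid records).
#' @param event 1 = event observed, 0 = censored.
#' @param group vector of group labels (one curve per level); default a
#'   single group.
#' @return named list of data.frames (one per group), each with columns
#'   `time` (distinct observed times, ascending), `n_risk`, `n_event`,
#'   `n_censor`, `surv`; class `km_curve_set`.
#' @export
km_estimate <- function(time, event, group = rep("all", length(time))) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (any(time <= 0 | is.na(time)) || any(!event %in% c(0, 1)))
    stop("records must be valid for survival (time > 0, event in {0,1})")
  out <- lapply(split(seq_along(time), group), function(i) {
    tt <- time[i]; ev <- event[i]
    ts <- sort(unique(tt))
    n_risk <- vapply(ts, function(u) sum(tt >= u), numeric(1))
    n_event <- vapply(ts, function(u) sum(tt == u & ev == 1), numeric(1))
    n_censor <- vapply(ts, function(u) sum(tt == u & ev == 0), numeric(1))
    surv <- cumprod(1 - n_event / n_risk)
    data.frame(time = ts, n_risk = n_risk, n_event = n_event,
               n_censor = n_censor, surv = surv)
  })
  structure(out, class = "km_curve_set")
}

#' Survival probability / median survival from a KM curve
#'
#' @param curve one element of a [km_estimate()] result.
#' @param t time at which to read the step function.
#' @return `km_surv_at()`: S(t); `km_median()`: smallest observed time
#'   with S <= 0.5, or `NA` if survival never drops that far.
#' @export
km_surv_at <- function(curve, t) {
  i <- findInterval(t, curve$time)
  ifelse(i == 0, 1, curve$surv[pmax(i, 1)])
}

#' @rdname km_surv_at
#' @export
km_median <- function(curve) {
  i <- which(curve$surv <= 0.5)
  if (!length(i)) NA_real_ else curve$time[i[1]]
}

#' Two-group log-rank test
#'
#' At each distinct event time with d pooled events, n at risk and n1 at
#' risk in group 1: E1 = d n1 / n and hypergeometric variance
#' V = d (n1/n) (1 - n1/n) (n - d) / (n - 1). The statistic
#' (sum O1 - sum E1)^2 / sum V is referred to chi-square with 1 df.
#'
#' @inheritParams km_estimate
#' @param group binary group indicator (two levels).
#' @return list of class `logrank_result`: `statistic`, `p_value`,
#'   `observed`, `expected` (per group), `table` of per-time O/E/V.
#' @export
logrank_test <- function(time, event, group) {
  lv <- sort(unique(group))
  if (length(lv) != 2) stop("log-rank test needs exactly two groups")
  g1 <- group == lv[2]
  ts <- sort(unique(time[event == 1]))
  if (!length(ts)) stop("no events observed")
  o1 <- e1 <- v <- numeric(length(ts))
  for (k in seq_along(ts)) {
    u <- ts[k]
    at <- time >= u
    n <- sum(at); n1 <- sum(at & g1)
    d <- sum(time == u & event == 1)
    o1[k] <- sum(time == u & event == 1 & g1)
    e1[k] <- d * n1 / n
    v[k] <- if (n > 1) d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1) else 0
  }
  stat <- (sum(o1) - sum(e1))^2 / sum(v)
  structure(list(statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 observed = c(sum(event[!g1]), sum(o1)),
                 expected = c(sum(event) - sum(e1), sum(e1)),
                 groups = lv,
                 table = data.frame(time = ts, o1 = o1, e1 = e1, v = v)),
            class = "logrank_result")
}

#' Multivariate Cox proportional-hazards fit
#'
#' Maximises the Cox partial likelihood with the Efron tie correction by
#' Newton-Raphson (delegated to `survival::coxph`, the engine the
#' original analysis used). Complete-case: rows with any missing
#' covariate are dropped. Returns per-covariate beta, hazard ratio
#' exp(beta), Wald 95% CI exp(beta +/- 1.96 se) and p-value, plus
#' convergence / separation diagnostics.
#'
#' @param data data.frame with columns `time`, `event` and the covariate
#'   columns.
#' @param covariates character vector of covariate column names.
#' @param max_iter Newton-Raphson iteration cap (default 100).
#' @return list of class `cox_fit`: `table` (data.frame covariate, beta,
#'   hr, lower95, upper95, se, p), `n`, `n_events`, `converged`,
#'   `separable`, `ties` = "efron".
#' @export
cox_fit <- function(data, covariates, max_iter = 100) {
  stopifnot(all(c("time", "event") %in% names(data)),
            all(covariates %in% names(data)))
  cc <- stats::complete.cases(data[, c("time", "event", covariates)])
  df <- data[cc, , drop = FALSE]
  if (sum(df$event) < 1) stop("no events in complete-case data")
  if (nrow(df) < 10 * length(covariates))
    warning(sprintf("only %d complete cases for %d covariates (< 10 per covariate)",
                    nrow(df), length(covariates)))
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron",
                         control = survival::coxph.control(iter.max = max_iter))
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  separable <- any(abs(beta) > 15 | se > 100)
  tab <- data.frame(covariate = names(beta), beta = unname(beta),
                    hr = exp(unname(beta)),
                    lower95 = exp(unname(beta) - 1.96 * se),
                    upper95 = exp(unname(beta) + 1.96 * se),
                    se = unname(se),
                    p = 2 * stats::pnorm(-abs(unname(beta) / se)),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, n = nrow(df), n_events = sum(df$event),
                 converged = fit$iter < max_iter && !separable,
                 iterations = fit$iter,
                 separable = separable, ties = "efron"),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit (Efron ties): n = %d, events = %d%s\n",
              x$n, x$n_events,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(format(x$table, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Build the survival design table for the gated cohort
#'
#' Joins gate calls onto clinical records, keeps records valid for
#' survival, and encodes covariates for the multivariate model: age in
#' decades (continuous), sex male = 1, node_positive binary, stage as
#' ordinal integer 1-4, ILC2 call binary.
#'
#' @param clinical a `clinical_table` from [load_clinical_table()].
#' @param gate a data.frame with `sample_id` and `call` (e.g. from
#'   [gate_cohort()]).
#' @return data.frame with `time`, `event`, `age_decades`, `sex_male`,
#'   `node_positive`, `stage`, `ilc2`.
#' @export
survival_design <- function(clinical, gate) {
  i <- match(clinical$sample_id, gate$sample_id)
  out <- data.frame(
    sample_id = clinical$sample_id,
    time = clinical$time, event = clinical$event,
    age_decades = clinical$age / 10,
    sex_male = ifelse(is.na(clinical$sex), NA_real_,
                      as.numeric(clinical$sex == "male")),
    node_positive = clinical$node_positive,
    stage = clinical$stage,
    ilc2 = gate$call[i],
    stringsAsFactors = FALSE)
  out[clinical$valid_survival & !is.na(out$ilc2), , drop = FALSE]
}
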