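## Synthetic cohort: OSA severity classes, anthropometric sampling.

#' OSA severity class labels
#'
#' Standard apnea-hypopnea-index (AHI) severity classes: Non (<5 events/h),
#' Mild (5-15), Moderate (15-30), Severe (>= 30).
#'
#' @export
severity_levels <- function() c("Non", "Mild", "Moderate", "Severe")

#' AHI bounds (events/hour) for a severity class
#'
#' The four classes partition \[0, Inf): Non \[0,5), Mild \[5,15),
#' Moderate \[15,30), Severe \[30,Inf).
#'
#' @param severity one of `severity_levels()`.
#' @return numeric length-2 vector `c(lo, hi)`.
#' @export
ahi_bounds <- function(severity) {
  switch(match.arg(severity, severity_levels()),
         Non = c(0, 5), Mild = c(5, 15), Moderate = c(15, 30),
         Severe = c(30, Inf))
}

## Reference cohort anthropometrics by severity class: mean/SD of the
## continuous measures, sex counts, and Mallampati score (MPS) counts.
cohort_reference <- function() {
  list(
    Non = list(n = 74, ahi = c(1.2, 1.3), age = c(46.8, 12.9),
               nc = c(38.8, 4.0), bmi = c(30.6, 6.2),
               sex = c(M = 29, F = 45), mps = c(41, 19, 6, 8)),
    Mild = list(n = 35, ahi = c(8.7, 2.6), age = c(52.3, 11.6),
                nc = c(42.1, 6.5), bmi = c(34.3, 8.4),
                sex = c(M = 21, F = 14), mps = c(18, 6, 9, 1)),
    Moderate = list(n = 50, ahi = c(21.5, 4.2), age = c(54.7, 11.3),
                    nc = c(43.1, 3.4), bmi = c(33.8, 6.4),
                    sex = c(M = 36, F = 14), mps = c(17, 17, 8, 8)),
    Severe = list(n = 40, ahi = c(69.5, 33.3), age = c(48.9, 11.1),
                  nc = c(45.3, 3.6), bmi = c(39.7, 8.7),
                  sex = c(M = 30, F = 10), mps = c(5, 13, 14, 8))
  )
}

#' Reference per-class cohort sizes
#'
#' @return named integer vector of subjects per severity class (total 199).
#' @export
reference_class_sizes <- function() {
  vapply(cohort_reference(), function(g) as.integer(g$n), integer(1))
}

## Mean and SD of a normal(mu, sigma) truncated to [a, b].
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  Z <- pnorm(be) - pnorm(al)
  if (Z <= 0) return(c(mean = NA_real_, sd = NA_real_))
  da <- dnorm(al)
  db <- if (is.finite(be)) dnorm(be) else 0
  bdb <- if (is.finite(be)) be * db else 0
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (al * da - bdb) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

## Find (mu, sigma) of the underlying normal so the [a,b]-truncated
## distribution has the target mean/SD; falls back to the least-squares
## optimum when the target is infeasible (e.g. SD too large for the support).
match_truncnorm <- function(target_mean, target_sd, a, b) {
  obj <- function(p) {
    mm <- truncnorm_moments(p[1], exp(p[2]), a, b)
    if (any(!is.finite(mm))) return(1e6)
    sum(((mm - c(target_mean, target_sd)) / c(max(abs(target_mean), 1), target_sd))^2)
  }
  starts <- list(c(target_mean, log(target_sd)),
                 c(target_mean - target_sd, log(2 * target_sd)),
                 c(a + (if (is.finite(b)) (b - a) / 2 else target_sd),
                   log(target_sd)))
  best <- NULL
  for (s in starts) {
    fit <- optim(s, obj, control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  mu <- best$par[1]; sigma <- exp(best$par[2])
  ach <- truncnorm_moments(mu, sigma, a, b)
  list(mu = mu, sigma = sigma, achieved = ach,
       exact = best$value < 1e-8,
       target = c(mean = target_mean, sd = target_sd))
}

## Inverse-CDF sampler for the truncated normal (deterministic given RNG state).
rtruncnorm <- function(n, mu, sigma, a, b) {
  pa <- pnorm((a - mu) / sigma)
  pb <- pnorm((b - mu) / sigma)
  u <- runif(n, pa, pb)
  mu + sigma * qnorm(u)
}

## cache of matched parameters per (severity, variable)
.tbsa_tn_cache <- new.env(parent = emptyenv())

matched_params <- function(severity, variable, target, lo, hi) {
  key <- paste(severity, variable, sep = ".")
  if (!is.null(.tbsa_tn_cache[[key]])) return(.tbsa_tn_cache[[key]])
  p <- match_truncnorm(target[1], target[2], lo, hi)
  .tbsa_tn_cache[[key]] <- p
  p
}

#' Sample synthetic anthropometric records for one severity class
#'
#' Continuous measures (AHI, age, neck circumference, BMI) are drawn from
#' truncated normal distributions whose underlying parameters are
#' moment-matched by numerical optimisation so the *truncated* mean/SD equal
#' the reference-cohort values; AHI is truncated to the class AHI bounds and
#' the other measures to positive support. When a target is infeasible under
#' truncation the squared moment error is minimised and the achieved moments
#' are reported in the `moments` attribute. Sex and Mallampati score are drawn
#' from the reference category proportions.
#'
#' @param severity one of `severity_levels()`.
#' @param n number of records (>= 1).
#' @param seed integer seed; identical seeds give identical records.
#' @return data.frame with columns `subject_id`, `severity`, `ahi`, `age`,
#'   `sex`, `bmi`, `nc`, `mps`, plus a `moments` attribute recording the
#'   matched truncated-normal parameters and achieved moments per variable.
#' @examples
#' rec <- sample_anthropometrics("Severe", 100, seed = 1)
#' mean(rec$ahi)
#' @export
sample_anthropometrics <- function(severity, n, seed = NULL) {
  severity <- match.arg(severity, severity_levels())
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("n must be a positive count", call. = FALSE)
  n <- as.integer(n)
  ref <- cohort_reference()[[severity]]
  bounds <- ahi_bounds(severity)
  specs <- list(
    ahi = list(target = ref$ahi, lo = bounds[1], hi = bounds[2]),
    age = list(target = ref$age, lo = 18, hi = Inf),
    nc  = list(target = ref$nc,  lo = 0,  hi = Inf),
    bmi = list(target = ref$bmi, lo = 10, hi = Inf)
  )
  with_seed(seed, {
    draws <- lapply(names(specs), function(v) {
      s <- specs[[v]]
      p <- matched_params(severity, v, s$target, s$lo, s$hi)
      x <- rtruncnorm(n, p$mu, p$sigma, s$lo, s$hi)
      ## guard against hitting the open upper AHI bound through rounding
      pmin(pmax(x, s$lo), if (is.finite(s$hi)) s$hi - 1e-9 else Inf)
    })
    names(draws) <- names(specs)
    sex <- sample(names(ref$sex), n, replace = TRUE,
                  prob = ref$sex / sum(ref$sex))
    mps <- sample(1:4, n, replace = TRUE, prob = ref$mps / sum(ref$mps))
    out <- data.frame(
      subject_id = sprintf("%s_%04d", severity, seq_len(n)),
      severity = severity,
      ahi = draws$ahi, age = draws$age, sex = sex,
      bmi = draws$bmi, nc = draws$nc, mps = as.integer(mps),
      stringsAsFactors = FALSE
    )
    attr(out, "moments") <- lapply(names(specs), function(v) {
      s <- specs[[v]]
      matched_params(severity, v, s$target, s$lo, s$hi)
    })
    names(attr(out, "moments")) <- names(specs)
    out
  })
}
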