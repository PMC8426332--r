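#' Outcome association statistics
#'
#' Median dichotomization of neoantigen load, Kaplan-Meier product-limit
#' estimation, the two-group log-rank test, Cox proportional-hazards
#' regression (Newton-Raphson on the partial likelihood, Breslow or Efron
#' tie handling), and Spearman rank correlation. All estimators are
#' implemented directly from their formulas; the survival package is used
#' only as an independent cross-check in the test suite.
#'
#' @name cohort_stats
NULL

#' Median split of per-sample loads
#'
#' "High" means strictly above the cohort median; samples at the median go
#' to "low" (values equal to the median are not above it).
#'
#' @param loads data.frame with sample_id and load columns (see
#'   [compute_sample_load()])
#' @param field which load to split on: "neoag_load" or "weighted_load"
#' @return named character vector sample_id -> "high"/"low"
#' @export
dichotomize_load <- function(loads, field = c("neoag_load", "weighted_load")) {
  field <- match.arg(field)
  stopifnot(nrow(loads) >= 2L)
  v <- loads[[field]]
  if (length(unique(v)) == 1L)
    stop("degenerate split: all ", field, " values identical (", v[1], ")")
  med <- median(v)
  setNames(ifelse(v > med, "high", "low"), loads$sample_id)
}

#' Kaplan-Meier product-limit estimate
#'
#' At tied times deaths precede censorings (censored subjects remain at
#' risk for deaths at their own time).
#'
#' @param time,event numeric survival times and 0/1 event indicators
#' @return data.frame: time (distinct event times), n_risk, n_event,
#'   survival (step values of S(t))
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1L,
            all(event %in% c(0, 1)))
  dt <- sort(unique(time[event == 1]))
  if (!length(dt))
    return(data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), survival = numeric(0)))
  n_risk <- vapply(dt, function(t) sum(time >= t), 0)
  n_event <- vapply(dt, function(t) sum(time == t & event == 1), 0)
  data.frame(time = dt, n_risk = n_risk, n_event = n_event,
             survival = cumprod(1 - n_event / n_risk))
}

#' Two-group log-rank test
#'
#' Standard (O - E)^2 / V statistic on the pooled distinct event times,
#' 1 degree of freedom, hypergeometric variance.
#'
#' @param time,event pooled survival data
#' @param group two-level grouping vector
#' @return list: chi_square, p_value, observed/expected for the first group
#' @export
logrank_test <- function(time, event, group) {
  g <- as.factor(group)
  if (nlevels(g) != 2L) stop("log-rank test requires exactly two groups")
  if (sum(event) < 1) stop("log-rank test requires at least one event")
  is1 <- g == levels(g)[1]
  dt <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in dt) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & is1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & is1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- if (V > 0) (O1 - E1)^2 / V else 0
  list(chi_square = chi, p_value = pchisq(chi, df = 1, lower.tail = FALSE),
       observed = O1, expected = E1, variance = V)
}

#' Cox proportional-hazards fit
#'
#' Newton-Raphson maximization of the partial likelihood with Breslow
#' (default) or Efron tie handling. Wald standard errors come from the
#' inverse observed information; 95% CIs are exp(beta +/- 1.96 se).
#' Convergence requires max |score| < 1e-8 within 50 iterations; runaway
#' coefficients (|beta| > 20) are flagged as possible complete separation.
#'
#' @param time,event survival data
#' @param x covariate matrix (or vector for a single covariate)
#' @param ties "breslow" or "efron"
#' @return object of class `cox_fit`: coefficients table (beta,
#'   hazard_ratio, se, wald_p, ci95_low, ci95_high), n, n_events,
#'   converged, separation, loglik, score_stat (score test at beta = 0)
#' @export
cox_ph <- function(time, event, x, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  stopifnot(nrow(x) == length(time), all(event %in% c(0, 1)))
  p <- ncol(x)
  if (sum(event) < p) stop("fewer events than model terms")
  for (j in seq_len(p)) if (length(unique(x[, j])) < 2L)
    stop("covariate ", colnames(x)[j], " is constant")
  deriv <- function(beta) cox_deriv(beta, time, event, x, ties)
  beta <- rep(0, p)
  d0 <- deriv(beta)
  score_stat <- tryCatch(
    drop(t(d0$U) %*% solve(d0$I, d0$U)), error = function(e) NA_real_)
  ll <- d0$loglik; d <- d0
  converged <- FALSE
  for (it in seq_len(50L)) {
    if (max(abs(d$U)) < 1e-8) { converged <- TRUE; break }
    step <- tryCatch(solve(d$I, d$U), error = function(e) NULL)
    if (is.null(step)) break
    new_beta <- beta + step
    d_new <- deriv(new_beta)
    halv <- 0L
    while (d_new$loglik < ll - 1e-12 && halv < 20L) {
      step <- step / 2
      new_beta <- beta + step
      d_new <- deriv(new_beta)
      halv <- halv + 1L
    }
    beta <- new_beta; d <- d_new; ll <- d$loglik
  }
  if (!converged && max(abs(d$U)) < 1e-8) converged <- TRUE
  separation <- any(abs(beta) > 20)
  if (separation) converged <- FALSE
  cov_b <- tryCatch(solve(d$I), error = function(e)
    matrix(NA_real_, p, p))
  se <- sqrt(diag(cov_b))
  z <- beta / se
  coefs <- data.frame(
    term = colnames(x), beta = beta, hazard_ratio = exp(beta), se = se,
    wald_p = 2 * stats::pnorm(-abs(z)),
    ci95_low = exp(beta - 1.96 * se), ci95_high = exp(beta + 1.96 * se),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, n = length(time),
                 n_events = sum(event), converged = converged,
                 separation = separation, loglik = ll,
                 score_stat = score_stat, ties = ties),
            class = "cox_fit")
}

# Partial-likelihood value, score vector and observed information at beta.
# Risk-set sums are suffix sums over times sorted decreasingly, so each
# evaluation is O(n p^2) plus a loop over distinct event times.
cox_deriv <- function(beta, time, event, x, ties) {
  n <- length(time); p <- ncol(x)
  ord <- order(time, decreasing = TRUE)
  tt <- time[ord]; ee <- event[ord]; xx <- x[ord, , drop = FALSE]
  eta <- drop(xx %*% beta)
  eta <- eta - max(eta)                 # guard exp overflow
  w <- exp(eta)
  S0 <- cumsum(w)
  S1 <- apply(xx * w, 2, cumsum)
  if (p == 1L) S1 <- matrix(S1, ncol = 1L)
  # S2 as cumulative sums of w * x_j x_k for the upper triangle
  S2 <- array(0, c(n, p, p))
  for (j in seq_len(p)) for (k in j:p) {
    cs <- cumsum(w * xx[, j] * xx[, k])
    S2[, j, k] <- cs; S2[, k, j] <- cs
  }
  loglik <- 0; U <- rep(0, p); I <- matrix(0, p, p)
  dtimes <- unique(tt[ee == 1])
  for (t in dtimes) {
    idx <- which(tt == t & ee == 1)           # deaths at t
    last <- max(which(tt >= t))               # end of risk set in sorted order
    d <- length(idx)
    s0 <- S0[last]
    s1 <- S1[last, ]
    s2 <- S2[last, , ]
    sum_eta <- sum(eta[idx])
    sum_x <- colSums(xx[idx, , drop = FALSE])
    if (ties == "breslow" || d == 1L) {
      loglik <- loglik + sum_eta - d * log(s0)
      U <- U + sum_x - d * s1 / s0
      I <- I + d * (s2 / s0 - tcrossprod(s1 / s0))
    } else {
      wd <- w[idx]
      d0 <- sum(wd)
      d1 <- colSums(xx[idx, , drop = FALSE] * wd)
      d2 <- matrix(0, p, p)
      for (j in seq_len(p)) for (k in seq_len(p))
        d2[j, k] <- sum(wd * xx[idx, j] * xx[idx, k])
      for (l in seq_len(d) - 1L) {
        a0 <- s0 - l / d * d0
        a1 <- s1 - l / d * d1
        a2 <- s2 - l / d * d2
        loglik <- loglik - log(a0)
        U <- U - a1 / a0
        I <- I + a2 / a0 - tcrossprod(a1 / a0)
      }
      loglik <- loglik + sum_eta
      U <- U + sum_x
    }
  }
  list(loglik = loglik, U = U, I = I)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, ties = %s, converged = %s\n",
              x$n, x$n_events, x$ties, x$converged))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Cox regression on a clinical table
#'
#' Builds the design matrix from named covariate columns: numeric columns
#' enter as-is; character/factor columns are one-hot encoded against their
#' first (reference) level; a load_group column with levels low/high uses
#' low as reference.
#'
#' @param records data.frame with time and event columns plus covariates
#' @param covariates character vector of covariate column names
#' @param time_col,event_col column names for time and status
#' @param ties passed to [cox_ph()]
#' @return a `cox_fit`
#' @export
cox_fit <- function(records, covariates, time_col = "time",
                    event_col = "event", ties = "breslow") {
  mats <- lapply(covariates, function(v) {
    col <- records[[v]]
    if (is.null(col)) stop("covariate column not found: ", v)
    if (is.numeric(col)) {
      m <- matrix(col, ncol = 1L, dimnames = list(NULL, v))
    } else {
      f <- as.factor(col)
      if (all(c("low", "high") %in% levels(f)))
        f <- stats::relevel(f, "low")
      if (nlevels(f) < 2L) stop("covariate ", v, " has a single level")
      lv <- levels(f)[-1L]
      m <- vapply(lv, function(l) as.numeric(f == l), numeric(length(f)))
      if (is.null(dim(m))) m <- matrix(m, ncol = length(lv))
      colnames(m) <- paste0(v, lv)
    }
    m
  })
  cox_ph(records[[time_col]], records[[event_col]], do.call(cbind, mats),
         ties = ties)
}

#' Spearman rank correlation
#'
#' Average ranks for ties; two-sided p-value from the t approximation
#' t = rho * sqrt((n-2)/(1-rho^2)) on n-2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3
#' @return list: rho, p_value, n
#' @export
spearman_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("Spearman correlation undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}
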