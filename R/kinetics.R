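#' @include AllClasses.R AllGenerics.R units.R quantify.R
NULL

#' @rdname tia
setMethod("tia", "FitResult", function(x) x@tia)
#' @rdname tiac
setMethod("tiac", "FitResult", function(x) x@tiac)

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult '%s' [%s]%s: TIA = %.6g MBq h, TIAC = %.6g h\n",
              object@organ, object@model,
              if (object@converged) "" else " (NOT converged)",
              object@tia, object@tiac))
  if (length(object@parameters))
    cat("  parameters:", paste(sprintf("%s = %.6g", names(object@parameters),
                                       object@parameters), collapse = ", "), "\n")
  if (!is.na(object@goodness))
    cat(sprintf("  Spearman goodness = %.4g, RSS = %.4g\n", object@goodness,
                object@rss))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

## Spearman rank correlation between fitted and observed activities; the
## goodness-of-fit statistic reported for every family.
.spearman <- function(obs, fit) {
  if (length(obs) < 2L || stats::sd(obs) == 0 || stats::sd(fit) == 0)
    return(NA_real_)
  suppressWarnings(stats::cor(obs, fit, method = "spearman"))
}

.mkFit <- function(tac, model, parameters, tia, predicted,
                   converged = TRUE, flags = character(),
                   headRule = NA_character_, tailRate = NA_real_) {
  rss <- sum((tac@activities - predicted)^2)
  new("FitResult", organ = tac@organ, model = model,
      parameters = parameters, headRule = headRule, tailRate = tailRate,
      tia = tia, tiac = tia / tac@A0, A0 = tac@A0,
      goodness = .spearman(tac@activities, predicted), rss = rss,
      converged = converged, flags = flags)
}

## log-linear least squares on the positive samples; start values for the
## non-linear fits. Returns c(A, lambda), lambda clamped positive.
.loglinStart <- function(t, a) {
  pos <- a > 0
  if (sum(pos) >= 2L) {
    co <- stats::coef(stats::lm(log(a[pos]) ~ t[pos]))
    A <- exp(co[[1]]); lam <- -co[[2]]
  } else {
    A <- max(a, 1e-12); lam <- 0.01
  }
  c(A = max(A, 1e-12), lambda = max(lam, 1e-9))
}

#' Fit a mono-exponential time-activity model
#'
#' Least-squares fit of `A exp(-lambda t)` on the activity scale
#' (Levenberg-Marquardt, started from a log-linear regression), with
#' `lambda > 0` enforced. The time-integrated activity is the closed-form
#' integral over `[0, Inf)`: `TIA = A / lambda`.
#'
#' @param tac a [TimeActivityCurve] with at least two points.
#' @return a [FitResult]. Non-decaying data are fitted at the rate bound and
#'   flagged `"non_decaying"` rather than rejected.
#' @examples
#' tac <- TimeActivityCurve("liver", c(4, 24, 72, 192),
#'                          50 * exp(-0.02 * c(4, 24, 72, 192)), A0 = 7200)
#' fitMonoexp(tac)
#' @export
fitMonoexp <- function(tac) {
  stopifnot(is(tac, "TimeActivityCurve"))
  t <- tac@times; a <- tac@activities
  if (length(t) < 2L)
    stop("mono-exponential fit needs at least 2 points")
  if (all(a == 0))
    return(.mkFit(tac, "monoexp", c(A = 0, lambda = 1), 0, rep(0, length(t))))
  start <- .loglinStart(t, a)
  flags <- character()
  fit <- tryCatch(
    minpack.lm::nlsLM(a ~ A * exp(-lambda * t),
                      start = as.list(start),
                      lower = c(A = 0, lambda = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    pred <- start[["A"]] * exp(-start[["lambda"]] * t)
    if (a[length(a)] > a[1]) flags <- c(flags, "non_decaying")
    return(.mkFit(tac, "monoexp", start, start[["A"]] / start[["lambda"]],
                  pred, converged = FALSE, flags = c("fit_failed", flags)))
  }
  p <- stats::coef(fit)
  if (p[["lambda"]] <= 1e-8 || a[length(a)] > a[1])
    flags <- c(flags, "non_decaying")
  pred <- stats::predict(fit)
  .mkFit(tac, "monoexp", c(A = p[["A"]], lambda = p[["lambda"]]),
         p[["A"]] / p[["lambda"]], pred, flags = flags)
}

#' Fit a bi-exponential time-activity model
#'
#' Least-squares fit of `A1 exp(-lambda1 t) + A2 exp(-lambda2 t)` by damped
#' (Levenberg-Marquardt) least squares, initialised from a split of the
#' mono-exponential fit: the slow component from a log-linear fit to the
#' tail half of the samples, the fast component from the head residuals.
#' Both amplitudes are constrained non-negative by default (activity cannot
#' be negative); `washIn = TRUE` releases the first amplitude to allow an
#' uptake phase. `TIA = A1/lambda1 + A2/lambda2`. Components are reported
#' fast-first (`lambda1 >= lambda2`).
#'
#' @param tac a [TimeActivityCurve] with at least four points.
#' @param washIn allow a negative fast amplitude (wash-in).
#' @return a [FitResult]; non-convergence is flagged, not an error.
#' @export
fitBiexp <- function(tac, washIn = FALSE) {
  stopifnot(is(tac, "TimeActivityCurve"))
  t <- tac@times; a <- tac@activities
  if (length(t) < 4L)
    stop("bi-exponential fit needs at least 4 points")
  n <- length(t)
  tailIdx <- seq(ceiling(n / 2) + 1L, n)
  slow <- .loglinStart(t[tailIdx], a[tailIdx])
  resid <- a - slow[["A"]] * exp(-slow[["lambda"]] * t)
  headIdx <- seq_len(n - length(tailIdx))
  fastResid <- pmax(resid[headIdx], 1e-12)
  fast <- .loglinStart(t[headIdx], fastResid)
  if (fast[["lambda"]] <= slow[["lambda"]])
    fast[["lambda"]] <- slow[["lambda"]] * 5
  start <- list(A1 = fast[["A"]], l1 = fast[["lambda"]],
                A2 = slow[["A"]], l2 = slow[["lambda"]])
  lowerA1 <- if (washIn) -Inf else 0
  fit <- tryCatch(
    minpack.lm::nlsLM(a ~ A1 * exp(-l1 * t) + A2 * exp(-l2 * t),
                      start = start,
                      lower = c(A1 = lowerA1, l1 = 1e-12, A2 = 0, l2 = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    pred <- start$A1 * exp(-start$l1 * t) + start$A2 * exp(-start$l2 * t)
    p <- unlist(start)
    return(.mkFit(tac, "biexp",
                  c(A1 = p[["A1"]], lambda1 = p[["l1"]],
                    A2 = p[["A2"]], lambda2 = p[["l2"]]),
                  p[["A1"]] / p[["l1"]] + p[["A2"]] / p[["l2"]],
                  pred, converged = FALSE, flags = "fit_failed"))
  }
  p <- stats::coef(fit)
  if (p[["l1"]] < p[["l2"]])  # fast component first
    p <- c(A1 = p[["A2"]], l1 = p[["l2"]], A2 = p[["A1"]], l2 = p[["l1"]])
  tiaVal <- p[["A1"]] / p[["l1"]] + p[["A2"]] / p[["l2"]]
  .mkFit(tac, "biexp",
         c(A1 = p[["A1"]], lambda1 = p[["l1"]],
           A2 = p[["A2"]], lambda2 = p[["l2"]]),
         tiaVal, stats::predict(fit))
}

#' Fit a power-exponential time-activity model
#'
#' Least-squares fit of `f(t) = A t^b exp(-c t^d)` with `c, d > 0` and
#' `b > -1` (required for the integral over `(0, Inf)` to exist),
#' initialised from the mono-exponential fit (`b = 0`, `d = 1`). The TIA is
#' computed by adaptive quadrature of the fitted function on `(0, Inf)` at
#' 1e-8 relative tolerance.
#'
#' @param tac a [TimeActivityCurve] with at least four strictly positive
#'   times.
#' @return a [FitResult].
#' @export
fitPowerexp <- function(tac) {
  stopifnot(is(tac, "TimeActivityCurve"))
  t <- tac@times; a <- tac@activities
  if (length(t) < 4L)
    stop("power-exponential fit needs at least 4 points")
  if (any(t <= 0))
    stop("power-exponential fit needs strictly positive times")
  mono <- fitMonoexp(tac)
  start <- list(A = max(mono@parameters[["A"]], 1e-12), b = 0,
                c = max(mono@parameters[["lambda"]], 1e-9), d = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(a ~ A * t^b * exp(-c * t^d), start = start,
                      lower = c(A = 0, b = -1 + 1e-8, c = 1e-12, d = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    pred <- start$A * t^start$b * exp(-start$c * t^start$d)
    return(.mkFit(tac, "powerexp",
                  c(A = start$A, b = start$b, c = start$c, d = start$d),
                  mono@tia, pred, converged = FALSE, flags = "fit_failed"))
  }
  p <- stats::coef(fit)
  if (p[["b"]] <= -1 + 1e-7)
    stop("power-exponential optimum has b <= -1: TIA integral diverges")
  f <- function(x) p[["A"]] * x^p[["b"]] * exp(-p[["c"]] * x^p[["d"]])
  tiaVal <- stats::integrate(f, 0, Inf, rel.tol = 1e-8,
                             subdivisions = 500L)$value
  .mkFit(tac, "powerexp",
         c(A = p[["A"]], b = p[["b"]], c = p[["c"]], d = p[["d"]]),
         tiaVal, stats::predict(fit))
}

#' Trapezoid integration with head rule and mono-exponential tail
#'
#' `TIA = head + sum of trapezoids between samples + A_last / tail_rate`.
#' The head covers `[0, t1]`: `"zero_line"` draws a straight line from the
#' origin to the first sample (`head = t1 A1 / 2`); `"constant"` holds the
#' first sample's activity constant back to time zero (`head = t1 A1`).
#' The tail extrapolates the last sample mono-exponentially at `tailRate`
#' — by default physical decay only, as used for Lu-177 tail integration.
#'
#' @param tac a [TimeActivityCurve] (a single point is allowed: head + tail).
#' @param headRule `"zero_line"` or `"constant"`.
#' @param tailRate tail decay rate in 1/h; default `ln 2 / 159.53`
#'   (Lu-177 physical decay).
#' @return a [FitResult] with model `"trapezoid_tail"`; the fitted values
#'   used for the goodness statistic are the observations themselves
#'   (the integrator interpolates them exactly).
#' @examples
#' tac <- TimeActivityCurve("kidney", c(4, 24, 72, 192),
#'                          c(90, 70, 40, 10), A0 = 7200)
#' tia(integrateTrapezoidTail(tac))   # ~9721.5 MBq h
#' @export
integrateTrapezoidTail <- function(tac, headRule = c("zero_line", "constant"),
                                   tailRate = log(2) / 159.53) {
  stopifnot(is(tac, "TimeActivityCurve"))
  headRule <- match.arg(headRule)
  if (tailRate <= 0) stop("tailRate must be positive")
  t <- tac@times; a <- tac@activities
  head <- if (headRule == "zero_line") 0.5 * t[1] * a[1] else t[1] * a[1]
  trap <- if (length(t) > 1L)
    sum(diff(t) * (a[-length(a)] + a[-1]) / 2) else 0
  tail <- a[length(a)] / tailRate
  .mkFit(tac, "trapezoid_tail", numeric(), head + trap + tail,
         predicted = a, headRule = headRule, tailRate = tailRate)
}

#' Automatic model selection for a time-activity curve
#'
#' Fits every applicable candidate family and returns the converged fit with
#' the lowest small-sample-corrected Akaike information criterion (AICc),
#' ties broken by fewer parameters. A family whose parameter count `k`
#' leaves no residual degrees of freedom (`n <= k + 1`) cannot be scored and
#' is excluded. Residual sums of squares are floored at a relative epsilon
#' so that two exact (noiseless) fits compare by parsimony alone. If no
#' exponential family converges, trapezoid-with-tail integration is returned
#' with a `"fallback"` flag.
#'
#' @param tac a [TimeActivityCurve].
#' @param candidates character vector of families to consider.
#' @param headRule,tailRate passed to [integrateTrapezoidTail()].
#' @return the selected [FitResult]; the AICc table is attached as
#'   attribute `"selection"`.
#' @export
autoSelect <- function(tac,
                       candidates = c("monoexp", "biexp", "powerexp",
                                      "trapezoid_tail"),
                       headRule = "zero_line",
                       tailRate = log(2) / 159.53) {
  stopifnot(is(tac, "TimeActivityCurve"))
  candidates <- match.arg(candidates, .FIT_FAMILIES, several.ok = TRUE)
  n <- length(tac@times)
  scale2 <- max(mean(tac@activities^2), .Machine$double.xmin)
  fits <- list(); crit <- numeric(); kpar <- integer()
  tryFamily <- function(name, k, fn) {
    if (!name %in% candidates) return()
    f <- tryCatch(fn(), error = function(e) NULL)
    if (is.null(f) || !f@converged) return()
    if (n - k - 1 <= 0) return()
    rss <- max(f@rss, n * scale2 * 1e-20)
    fits[[name]] <<- f
    crit[name] <<- n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
    kpar[name] <<- k
  }
  tryFamily("monoexp", 2L, function() fitMonoexp(tac))
  tryFamily("biexp", 4L, function() fitBiexp(tac))
  tryFamily("powerexp", 4L, function() fitPowerexp(tac))
  if (!length(fits)) {
    out <- integrateTrapezoidTail(tac, headRule, tailRate)
    out@flags <- c(out@flags, "fallback")
    return(out)
  }
  ## lowest AICc; ties (within 1e-9) by fewer parameters, then input order
  best <- names(fits)[1]
  for (nm in names(fits)[-1]) {
    if (crit[nm] < crit[best] - 1e-9 ||
        (abs(crit[nm] - crit[best]) <= 1e-9 && kpar[nm] < kpar[best]))
      best <- nm
  }
  out <- fits[[best]]
  attr(out, "selection") <- data.frame(model = names(fits),
                                       aicc = unname(crit[names(fits)]),
                                       k = unname(kpar[names(fits)]))
  out
}

#' Export fit results as a data.frame / JSON-ready list
#'
#' @param fits list of [FitResult]s.
#' @return data.frame with one row per organ: model, parameters (collapsed),
#'   TIA, TIAC, goodness, convergence.
#' @export
fitSummary <- function(fits) {
  do.call(rbind, lapply(fits, function(f) data.frame(
    organ = f@organ, model = f@model,
    parameters = paste(sprintf("%s=%.8g", names(f@parameters), f@parameters),
                       collapse = ";"),
    tia_MBqh = f@tia, tiac_h = f@tiac, goodness = f@goodness,
    converged = f@converged, stringsAsFactors = FALSE)))
}
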