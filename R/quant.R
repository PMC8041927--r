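#' Fit an exponential-decay half-life
#'
#' Models a transcription- or translation-blockade chase (ActD for mRNA,
#' CHX for protein): relative abundance `y(t) = A * 2^(-t / t_half)`.
#' The default fit is ordinary least squares of `log(y)` on `t` with a
#' free intercept; the decay rate is `k = -slope` (per hour), the
#' half-life `t_half = ln(2) / k`, and its standard error follows from
#' the slope standard error by the delta method,
#' `se(t_half) = ln(2) / k^2 * se(k)`. `method = "nls"` instead fits the
#' single exponential on the response scale by nonlinear least squares;
#' the two agree as noise vanishes. A non-decaying series (slope >= 0)
#' yields an infinite half-life with `decaying = FALSE` rather than an
#' error.
#'
#' @param time Numeric vector of timepoints (hours), or a `data.frame`
#'   with columns `time` and `value`.
#' @param value Relative abundances (positive; conventionally 1 at t = 0).
#' @param method `"ols"` (log-linear, default) or `"nls"`.
#' @return Object of class `"decay_fit"` with elements `k`, `t_half`,
#'   `r2`, `se_k`, `se_thalf`, `decaying`, `method`, the underlying
#'   `fit`, and the `data`.
#' @examples
#' f <- fit_half_life(c(0, 1, 2), c(1, 0.5, 0.25))
#' f$t_half  # 1 hour, r2 = 1
#' @export
fit_half_life <- function(time, value = NULL, method = c("ols", "nls")) {
  method <- match.arg(method)
  if (is.data.frame(time)) {
    value <- time$value
    time <- time$time
  }
  if (length(time) < 3L) stop("need at least 3 timepoints")
  if (any(value <= 0)) stop("abundances must be positive")
  dat <- data.frame(time = time, value = value)
  ols <- stats::lm(log(value) ~ time, data = dat)
  # exact geometric series are legitimate input; silence the
  # "essentially perfect fit" note summary.lm emits for them
  sm <- suppressWarnings(summary(ols))
  slope <- stats::coef(ols)[["time"]]
  se_slope <- sm$coefficients["time", "Std. Error"]
  if (method == "ols") {
    fit <- ols
    k <- -slope
    se_k <- se_slope
    r2 <- sm$r.squared
  } else {
    k0 <- max(-slope, 1e-6)
    # scaleOffset makes the convergence test sound on exact-fit data
    fit <- stats::nls(value ~ A * exp(-k * time), data = dat,
                      start = list(A = exp(stats::coef(ols)[[1]]), k = k0),
                      control = stats::nls.control(maxiter = 100,
                                                   scaleOffset = 1))
    k <- stats::coef(fit)[["k"]]
    se_k <- summary(fit)$coefficients["k", "Std. Error"]
    r2 <- 1 - sum(stats::residuals(fit)^2) /
      sum((value - mean(value))^2)
  }
  decaying <- k > 0
  t_half <- if (decaying) log(2) / k else Inf
  se_thalf <- if (decaying) log(2) / k^2 * se_k else NA_real_
  structure(list(k = k, t_half = t_half, r2 = r2, se_k = se_k,
                 se_thalf = se_thalf, decaying = decaying,
                 method = method, fit = fit, data = dat),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$decaying)
    cat(sprintf("<decay_fit> t1/2 = %.3g h (se %.2g), k = %.3g /h, r2 = %.3f [%s]\n",
                x$t_half, x$se_thalf, x$k, x$r2, x$method))
  else
    cat(sprintf("<decay_fit> non-decaying series (slope >= 0): t1/2 = Inf [%s]\n",
                x$method))
  invisible(x)
}

#' @export
summary.decay_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  %d timepoints over [%g, %g] h\n", nrow(object$data),
              min(object$data$time), max(object$data$time)))
  invisible(object)
}

#' @export
coef.decay_fit <- function(object, ...) {
  c(k = object$k, t_half = object$t_half)
}

#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time
       else if (is.data.frame(newdata)) newdata$time else newdata
  out <- stats::predict(object$fit, data.frame(time = t))
  unname(if (object$method == "ols") exp(out) else out)
}

#' @export
residuals.decay_fit <- function(object, ...) stats::residuals(object$fit)

#' @export
plot.decay_fit <- function(x, ...) {
  graphics::plot(x$data$time, x$data$value, xlab = "time (h)",
                 ylab = "relative abundance", log = "y", pch = 16, ...)
  tt <- seq(min(x$data$time), max(x$data$time), length.out = 100)
  graphics::lines(tt, predict(x, tt))
  if (x$decaying)
    graphics::legend("topright", bty = "n",
                     legend = sprintf("t1/2 = %.2g h", x$t_half))
  invisible(x)
}

#' @export
simulate.decay_fit <- function(object, nsim = 1, seed = NULL, cv = 0.05,
                               ...) {
  if (!object$decaying) stop("cannot simulate from a non-decaying fit")
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim, simulate_decay(object$t_half, object$data$time, cv,
                                 seed = NULL)$value)
}

#' Relative expression by the delta-delta-Cq method
#'
#' Target quantification cycles are normalized against the reference gene
#' (GAPDH in the assays this mirrors) and against the mean of the control
#' condition: `dCq = Cq_target - Cq_ref`, `ddCq = dCq - mean(dCq |
#' control)`, relative expression `= 2^(-ddCq)`. The control-condition
#' mean maps to 1 by construction.
#'
#' @param cq `data.frame` with columns `sample`, `condition`,
#'   `cq_target`, `cq_ref`.
#' @param control_condition The reference condition name.
#' @return `cq` with columns `delta_cq`, `ddcq`, `rel_expr` added.
#' @examples
#' cq <- data.frame(sample = c("c1", "c2", "c3", "t1"),
#'                  condition = c("ctl", "ctl", "ctl", "trt"),
#'                  cq_target = c(25.0, 25.2, 24.8, 24.0),
#'                  cq_ref = rep(20, 4))
#' relative_expression(cq, "ctl")$rel_expr[4]  # 2
#' @export
relative_expression <- function(cq, control_condition) {
  need <- c("sample", "condition", "cq_target", "cq_ref")
  if (!all(need %in% names(cq)))
    stop("cq table needs columns: ", paste(need, collapse = ", "))
  bad <- is.na(cq$cq_ref)
  if (any(bad))
    stop("missing reference Cq for sample(s): ",
         paste(cq$sample[bad], collapse = ", "))
  if (any(is.na(cq$cq_target)))
    stop("missing target Cq for sample(s): ",
         paste(cq$sample[is.na(cq$cq_target)], collapse = ", "))
  if (!control_condition %in% cq$condition)
    stop("control condition '", control_condition, "' not present")
  cq$delta_cq <- cq$cq_target - cq$cq_ref
  ctl <- mean(cq$delta_cq[cq$condition == control_condition])
  cq$ddcq <- cq$delta_cq - ctl
  cq$rel_expr <- 2^(-cq$ddcq)
  cq
}

#' Caliper tumor volume
#'
#' `volume (mm^3) = d^2 * D / 2`, with `d` and `D` the shortest and
#' longest diameters in mm. Supplying `d > D` is an error (diameters
#' swapped upstream).
#'
#' @param d,D Shortest / longest diameters (mm), vectorized.
#' @return Volumes in mm^3.
#' @examples
#' tumor_volume(3, 4)  # 18
#' @export
tumor_volume <- function(d, D) {
  if (any(d <= 0 | D <= 0)) stop("diameters must be positive")
  if (any(d > D))
    stop("shortest diameter exceeds longest; diameters swapped upstream?")
  d^2 * D / 2
}

# all permutations of 1..n as an (n! x n) matrix
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub))
    r <- r + nrow(sub)
  }
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rho is the Pearson correlation of mid-ranks (ties averaged). For
#' `n <= 9` the p-value is exact, from complete enumeration of all `n!`
#' permutations of one rank vector (two-sided: the proportion of
#' permutations with `|rho|` at least the observed); for larger samples
#' the normal approximation `z = rho * sqrt(n - 1)` is used. A constant
#' vector leaves rho undefined (NA, with a warning and flag).
#'
#' @param x,y Paired numeric vectors, `n >= 3`.
#' @return Object of class `"spearman_test"`: `rho`, `p`, `n`, `method`,
#'   `undefined`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not supported")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman rho undefined")
    return(structure(list(rho = NA_real_, p = NA_real_, n = n,
                          method = "undefined", undefined = TRUE),
                     class = "spearman_test"))
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9L) {
    perm <- .permutations(n)
    ry_c <- ry - mean(ry)
    rx_c <- rx - mean(rx)
    s <- as.vector(matrix(ry_c[perm], nrow(perm)) %*% rx_c)
    rho_perm <- s / sqrt(sum(rx_c^2) * sum(ry_c^2))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    z <- rho * sqrt(n - 1)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  structure(list(rho = rho, p = min(p, 1), n = n, method = method,
                 undefined = FALSE),
            class = "spearman_test")
}

#' @export
print.spearman_test <- function(x, ...) {
  if (x$undefined)
    cat("<spearman_test> rho undefined (constant input)\n")
  else
    cat(sprintf("<spearman_test> rho = %.4f, p = %.4g (n = %d, %s)\n",
                x$rho, x$p, x$n, x$method))
  invisible(x)
}
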