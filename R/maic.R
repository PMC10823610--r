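#' Aggregate matching targets for the packaged indirect comparison
#'
#' The thirteen baseline covariates matched in the unanchored indirect
#' comparison, with the aggregate target summaries of the comparator
#' (kallidinogenase) trial population: medians for age, body-mass index,
#' time to treatment and NIHSS; proportions for the binary covariates.
#'
#' @return A tibble with columns `covariate`, `type` (`"median"`,
#'   `"proportion"` or `"mean"`), `value`.
#' @export
maic_targets <- function() {
  tibble::tribble(
    ~covariate,          ~type,         ~value,
    "age",               "median",      62.00,
    "male",              "proportion",  0.6805,
    "bmi",               "median",      24.01,
    "smoker",            "proportion",  0.4330,
    "time_to_treatment", "median",      30.50,
    "previous_stroke",   "proportion",  0.2712,
    "baseline_mrs01",    "proportion",  0.9206,
    "nihss",             "median",      7.00,
    "cardioembolic",     "proportion",  0.0075,
    "hypertension",      "proportion",  0.6631,
    "diabetes",          "proportion",  0.3053,
    "hyperlipidemia",    "proportion",  0.1489,
    "chd",               "proportion",  0.1120
  )
}

#' Build the centered design matrix for moment matching
#'
#' Translates each aggregate target into a column whose weighted mean must
#' vanish: mean targets become `x - target`, proportion targets
#' `indicator - target`, and median targets `I[x <= target] - 0.5` (so the
#' weighted proportion at or below the target median equals one half --
#' first-moment matching cannot constrain a median directly).
#'
#' @param ipd Individual-patient-data data frame; must contain every target
#'   covariate as a column (complete cases, indicators coded 0/1).
#' @param targets A tibble as returned by [maic_targets()].
#' @return A list with `Z` (n x p centered matrix, one column per target)
#'   and `targets`.
#' @export
prepare_matching_matrix <- function(ipd, targets) {
  missing_cov <- setdiff(targets$covariate, names(ipd))
  if (length(missing_cov)) {
    stop("covariate(s) absent from IPD: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(ipd[targets$covariate])) {
    stop("IPD contains missing values; only complete-case tables are supported",
         call. = FALSE)
  }
  cols <- purrr::pmap(targets, function(covariate, type, value) {
    x <- ipd[[covariate]]
    switch(type,
      mean = x - value,
      proportion = {
        if (!all(x %in% c(0, 1))) {
          stop("proportion target `", covariate, "` requires a 0/1 indicator",
               call. = FALSE)
        }
        x - value
      },
      median = as.numeric(x <= value) - 0.5,
      stop("unknown target type: ", type, call. = FALSE)
    )
  })
  Z <- do.call(cbind, cols)
  colnames(Z) <- targets$covariate
  degenerate <- apply(Z, 2, function(z) diff(range(z)) == 0 && any(z != 0))
  if (any(degenerate)) {
    stop("unmatchable covariate(s) (constant in IPD but off target): ",
         paste(colnames(Z)[degenerate], collapse = ", "), call. = FALSE)
  }
  list(Z = Z, targets = targets)
}

#' Estimate matching weights by the method of moments
#'
#' Propensity-style weights `w_i = exp(Z_i b)` with `b` minimising the
#' convex objective `Q(b) = sum_i exp(Z_i b)`; at the optimum the weighted
#' mean of every centered column is zero, i.e. every matched summary equals
#' its aggregate target. Solved by damped Newton iterations with analytic
#' gradient and Hessian, falling back to BFGS if a Newton step fails.
#' Weights are rescaled to mean one (all weighted statistics are
#' scale-invariant).
#'
#' @param Z Centered design matrix from [prepare_matching_matrix()].
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence tolerance on the maximum absolute weighted-mean
#'   gap of the centered columns.
#' @return A numeric weight vector of length `nrow(Z)`, mean 1, with
#'   attributes `b` (coefficients), `iterations`, `max_gap`.
#' @export
#' @examples
#' # one moment, two patients {0, 1}, target mean 0.75: weight ratio 3:1
#' w <- fit_maic_weights(matrix(c(0, 1) - 0.75, ncol = 1))
#' w[2] / w[1]
fit_maic_weights <- function(Z, max_iter = 500, tol = 1e-10) {
  Z <- as.matrix(Z)
  if (!all(is.finite(Z))) stop("non-finite entries in matching matrix", call. = FALSE)
  n <- nrow(Z)
  if (n <= ncol(Z)) {
    stop("need more patients than matched moments", call. = FALSE)
  }
  b <- numeric(ncol(Z))
  Q <- function(b) sum(exp(drop(Z %*% b)))
  gap <- Inf
  for (it in seq_len(max_iter)) {
    w <- exp(drop(Z %*% b))
    g <- drop(crossprod(Z, w))
    gap <- max(abs(g)) / sum(w)         # weighted-mean gap of centered columns
    if (gap <= tol) break
    H <- crossprod(Z * w, Z)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) {
      opt <- stats::optim(b, Q, gr = function(b) drop(crossprod(Z, exp(drop(Z %*% b)))),
                          method = "BFGS", control = list(maxit = 1000, reltol = 1e-14))
      b <- opt$par
      next
    }
    # damped line search on the convex objective
    q0 <- Q(b)
    lambda <- 1
    repeat {
      b_new <- b - lambda * step
      if (Q(b_new) < q0 || lambda < 1e-12) break
      lambda <- lambda / 2
    }
    b <- b_new
    if (max(abs(b)) > 50) {
      stop("separation: a matched moment appears unattainable (unbounded coefficients)",
           call. = FALSE)
    }
  }
  if (gap > 1e-8) {
    stop(sprintf("weight solver did not converge: weighted-mean gap %.3g after %d iterations",
                 gap, it), call. = FALSE)
  }
  w <- exp(drop(Z %*% b))
  w <- w / mean(w)
  attr(w, "b") <- b
  attr(w, "iterations") <- it
  attr(w, "max_gap") <- gap
  w
}

#' Effective sample size of a weighted sample
#'
#' `ESS = (sum w)^2 / sum(w^2)`; equals `n` iff the weights are uniform and
#' shrinks as they concentrate.
#'
#' @param weights Non-negative weights, not all zero.
#' @return The effective sample size (patients).
#' @export
effective_sample_size <- function(weights) {
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  s <- sum(weights)
  if (s == 0) stop("all weights are zero", call. = FALSE)
  s^2 / sum(weights^2)
}

#' Reweighted 90-day outcome distribution
#'
#' The weighted share of patients in each mRS category at day 90:
#' `P(k) = sum of weights with outcome k / sum of weights`.
#'
#' @param ipd IPD data frame with an integer `mrs_d90` outcome column
#'   (values 0..6).
#' @param weights Weight vector aligned to the rows of `ipd`.
#' @return An [mrs_distribution()].
#' @export
weighted_outcome_distribution <- function(ipd, weights) {
  if (length(weights) != nrow(ipd)) {
    stop("length of weights does not match number of patients", call. = FALSE)
  }
  y <- ipd$mrs_d90
  stopifnot(all(y %in% 0:6))
  mass <- vapply(0:6, function(k) sum(weights[y == k]), numeric(1))
  mrs_distribution(mass / sum(mass))
}

#' Unanchored matching-adjusted indirect comparison
#'
#' End-to-end MAIC: centre the IPD on the aggregate targets, estimate
#' method-of-moments weights, and recompute the weighted 90-day mRS
#' distribution, with balance diagnostics and the effective sample size.
#'
#' @param ipd Individual-patient-data data frame (one row per patient;
#'   thirteen baseline covariates plus the `mrs_d90` outcome), e.g. from
#'   [generate_ipd()].
#' @param targets Aggregate targets tibble; defaults to [maic_targets()].
#' @param ... Passed to [fit_maic_weights()].
#' @return A `stroke_maic` object: `weights` (mean 1), `ess`, `balance`
#'   (per-covariate unweighted/weighted summary vs target),
#'   `weighted_outcome` and `unweighted_outcome` distributions.
#' @export
#' @examples
#' \donttest{
#' ipd <- generate_ipd(ipd_generator_spec(n = 400, seed = 7))
#' m <- maic(ipd)
#' glance(m)
#' }
maic <- function(ipd, targets = maic_targets(), ...) {
  prep <- prepare_matching_matrix(ipd, targets)
  w <- fit_maic_weights(prep$Z, ...)
  summarise_at_target <- function(covariate, type, value, weights) {
    x <- ipd[[covariate]]
    ww <- weights / sum(weights)
    switch(type,
      mean = sum(ww * x),
      proportion = sum(ww * x),
      median = sum(ww * (x <= value))  # target scale: share at/below target median is 0.5
    )
  }
  balance <- dplyr::mutate(
    targets,
    unweighted = purrr::pmap_dbl(targets, summarise_at_target,
                                 weights = rep(1, nrow(ipd))),
    weighted = purrr::pmap_dbl(targets, summarise_at_target, weights = w),
    matched_value = ifelse(.data$type == "median", 0.5, .data$value),
    gap = .data$weighted - .data$matched_value
  )
  structure(list(
    weights = as.numeric(w),
    b = attr(w, "b"),
    iterations = attr(w, "iterations"),
    max_gap = attr(w, "max_gap"),
    n = nrow(ipd),
    ess = effective_sample_size(w),
    balance = balance,
    unweighted_outcome = weighted_outcome_distribution(ipd, rep(1, nrow(ipd))),
    weighted_outcome = weighted_outcome_distribution(ipd, as.numeric(w))
  ), class = "stroke_maic")
}

#' @rdname maic
#' @param x A `stroke_maic` object.
#' @return `tidy()`: the per-covariate balance tibble.
#' @exportS3Method
tidy.stroke_maic <- function(x, ...) x$balance

#' @rdname maic
#' @return `glance()`: one-row tibble with `n`, `ess`, `max_gap`,
#'   `iterations`.
#' @exportS3Method
glance.stroke_maic <- function(x, ...) {
  tibble::tibble(n = x$n, ess = x$ess, max_gap = x$max_gap,
                 iterations = x$iterations)
}

#' @export
print.stroke_maic <- function(x, ...) {
  cat(sprintf("<stroke_maic: n = %d, ESS = %.1f>\n", x$n, x$ess))
  cat(sprintf("  max weighted-moment gap: %.2g after %d iterations\n",
              x$max_gap, x$iterations))
  cat("  weighted mRS D90 distribution:\n")
  print(round(unclass(x$weighted_outcome), 4))
  invisible(x)
}
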