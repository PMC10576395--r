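# Behavioural statistical models.
#
# H1: Poisson count model of the number of fish in the lake per minute,
#     with log(total at-risk fish) as offset.
# H2/H3: gamma log-link additive smooth models of activity and depth with
#     factor-by temporal smoothers, a random intercept per fish, and an
#     AR(1) working correlation on within-fish residual sequences, with
#     AIC comparison and collinearity/concurvity screening.

#' Fit the lake-count model
#'
#' Poisson log-link GLM: \code{n_lake ~ day + offset(log(n_total))}.
#' Minutes where no fish is yet at risk (\code{n_total = 0}) are excluded
#' (the offset is undefined there) and counted.
#'
#' @param series output of [lake_count_series()], or any data frame with
#'   \code{n_lake}, \code{n_total} and either \code{day} or
#'   \code{minute_utc} (day of year is then derived).
#' @return object of class \code{"count_fit"}: the glm, a coefficient
#'   table (estimate, SE, z, p), and \code{n_dropped}.
#' @export
fit_count_model <- function(series) {
  if (!"day" %in% names(series)) {
    series$day <- as.numeric(format(series$minute_utc, "%j", tz = "UTC")) +
      (as.numeric(series$minute_utc) %% 86400) / 86400
  }
  drop <- series$n_total == 0
  n_dropped <- sum(drop)
  series <- series[!drop, , drop = FALSE]
  if (any(series$n_lake > series$n_total)) {
    stop("n_lake exceeds n_total; counts are inconsistent")
  }
  fit <- stats::glm(n_lake ~ day + offset(log(n_total)),
                    family = stats::poisson(), data = series)
  ct <- summary(fit)$coefficients
  coef_table <- data.frame(term = rownames(ct), estimate = ct[, 1],
                           se = ct[, 2], z = ct[, 3], p = ct[, 4],
                           row.names = NULL, stringsAsFactors = FALSE)
  structure(list(fit = fit, coef_table = coef_table,
                 n_dropped = n_dropped, n = nrow(series)),
            class = "count_fit")
}

#' @export
print.count_fit <- function(x, ...) {
  cat("Poisson lake-count model: n_lake ~ day + offset(log(n_total))\n")
  cat(sprintf("  n = %d minutes (%d dropped with zero total)\n",
              x$n, x$n_dropped))
  print(x$coef_table, digits = 4)
  invisible(x)
}

#' Smooth term descriptor
#'
#' @param vars covariate name, or two names for a bivariate smooth.
#' @param k basis dimension (>= 3 for univariate smooths).
#' @param by optional factor name for a factor-by smooth (one smooth per
#'   level).
#' @param bs basis type: \code{"cr"} (cubic regression spline, the
#'   univariate default), \code{"cc"} (cyclic, for hour of day),
#'   \code{"tp"} (thin plate, the bivariate default), \code{"re"} (random
#'   intercept).
#' @return list of class \code{"smooth_term"}.
#' @export
sm <- function(vars, k = 10, by = NULL, bs = NULL) {
  bs <- bs %||% if (length(vars) == 2) "tp" else "cr"
  if (length(vars) == 1 && bs %in% c("cr", "cc", "tp") && k < 3) {
    stop("univariate smooths need k >= 3")
  }
  structure(list(vars = vars, k = k, by = by, bs = bs),
            class = "smooth_term")
}

#' Additive model specification
#'
#' @param response response column name (strictly positive for the gamma
#'   family).
#' @param family \code{"gamma_log"} or \code{"poisson_log"}.
#' @param parametric character vector of linear terms.
#' @param smooths list of [sm()] terms.
#' @param rho AR(1) correlation of within-group working residuals; NULL
#'   or 0 for none.
#' @param ar_group column defining the residual sequences (restarts at
#'   each group's first observation); typically the fish id.
#' @param time_col optional column used to order observations within
#'   groups before fitting.
#' @return list of class \code{"model_spec"}.
#' @export
model_spec <- function(response, family = c("gamma_log", "poisson_log"),
                       parametric = character(), smooths = list(),
                       rho = NULL, ar_group = NULL, time_col = NULL) {
  family <- match.arg(family)
  if (!is.null(rho) && (rho <= -1 || rho >= 1)) {
    stop("rho must lie in (-1, 1)")
  }
  structure(list(response = response, family = family,
                 parametric = parametric, smooths = smooths, rho = rho,
                 ar_group = ar_group, time_col = time_col),
            class = "model_spec")
}

smooth_to_text <- function(s, data) {
  k <- s$k
  n_unique <- if (length(s$vars) == 1)
    length(unique(data[[s$vars]])) else
    nrow(unique(data[s$vars]))
  if (s$bs != "re" && k > n_unique) {
    warning(sprintf("k = %d exceeds the %d unique values of %s; reduced",
                    k, n_unique, paste(s$vars, collapse = ",")))
    k <- n_unique
  }
  inner <- paste(s$vars, collapse = ", ")
  args <- sprintf("s(%s, k = %d", inner, k)
  if (s$bs != "tp" || length(s$vars) == 1) {
    args <- paste0(args, sprintf(", bs = \"%s\"", s$bs))
  }
  if (!is.null(s$by)) args <- paste0(args, sprintf(", by = %s", s$by))
  paste0(args, ")")
}

#' Fit a penalised additive smooth model
#'
#' Thin, contract-enforcing front end to \code{mgcv::bam} with
#' \code{method = "fREML"}: gamma or Poisson log link, cubic regression
#' spline smoothers (cyclic for hour-of-day terms), factor-by smoothers
#' (one smooth per habitat level), random intercepts via \code{bs =
#' "re"}, and an AR(1) working correlation on within-group residual
#' sequences restarting at each group's first observation.
#'
#' @param data model frame; ordered internally by \code{(ar_group,
#'   time_col)} when both are given.
#' @param spec a [model_spec()].
#' @return object of class \code{"trout_gam"}: \code{fit} (the bam
#'   object), \code{spec}, \code{aic}, \code{rho_used}, \code{data} (the
#'   ordered frame the model saw).
#' @export
fit_additive_model <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  need <- unique(c(spec$response, spec$parametric,
                   unlist(lapply(spec$smooths, `[[`, "vars")),
                   unlist(lapply(spec$smooths, `[[`, "by")),
                   spec$ar_group, spec$time_col))
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("covariate(s) not in data: ",
                         paste(miss, collapse = ", "))
  if (spec$family == "gamma_log") {
    bad <- which(data[[spec$response]] <= 0)
    if (length(bad)) {
      stop(sprintf("gamma family needs a strictly positive response; %d offending row(s), first: %s",
                   length(bad), paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  if (!is.null(spec$ar_group)) {
    ord <- if (!is.null(spec$time_col)) {
      order(data[[spec$ar_group]], data[[spec$time_col]])
    } else order(data[[spec$ar_group]])
    data <- data[ord, , drop = FALSE]
  }
  terms <- c(spec$parametric,
             vapply(spec$smooths, smooth_to_text, character(1),
                    data = data))
  fml <- stats::as.formula(paste(spec$response, "~",
                                 paste(terms, collapse = " + ")),
                           env = environment())
  fam <- switch(spec$family,
                gamma_log = stats::Gamma(link = "log"),
                poisson_log = stats::poisson(link = "log"))
  rho <- spec$rho %||% 0
  ar_start <- if (!is.null(spec$ar_group) && rho != 0) {
    !duplicated(data[[spec$ar_group]])
  } else NULL
  # discrete fitting is used throughout: it is the path on which the
  # AR(1) working correlation is available for non-gaussian families,
  # and keeping one path makes the rho = 0 fit identical to the plain fit
  fit <- if (is.null(ar_start)) {
    mgcv::bam(fml, data = data, family = fam, method = "fREML",
              discrete = TRUE, rho = rho)
  } else {
    mgcv::bam(fml, data = data, family = fam, method = "fREML",
              discrete = TRUE, rho = rho, AR.start = ar_start)
  }
  structure(list(fit = fit, spec = spec, aic = stats::AIC(fit),
                 rho_used = rho, data = data),
            class = "trout_gam")
}

#' @export
print.trout_gam <- function(x, ...) {
  cat("Additive smooth model (", x$spec$family, ", fREML)\n", sep = "")
  cat("  formula:", deparse(stats::formula(x$fit$formula)), "\n")
  cat(sprintf("  n = %d, AIC = %.1f, AR(1) rho = %.3f\n",
              stats::nobs(x$fit), x$aic, x$rho_used))
  invisible(x)
}

#' @export
summary.trout_gam <- function(object, ...) summary(object$fit, ...)

#' @export
predict.trout_gam <- function(object, ...) stats::predict(object$fit, ...)

#' @export
logLik.trout_gam <- function(object, ...) stats::logLik(object$fit, ...)

#' @export
residuals.trout_gam <- function(object, ...) stats::residuals(object$fit, ...)

unwrap_fit <- function(x) {
  if (inherits(x, "trout_gam")) x$fit
  else if (inherits(x, "count_fit")) x$fit
  else x
}

#' Pooled lag-1 autocorrelation of within-group residuals
#'
#' The AR(1) coefficient is estimated from a model fitted without the
#' autocorrelation term and then passed into the refit: the pooled lag-1
#' autocorrelation of working residuals over consecutive observation
#' pairs within each group (never across group boundaries, so it is
#' invariant to reordering the groups).
#'
#' @param fit a \code{trout_gam} (its \code{ar_group} defines the
#'   sequences), or a numeric residual vector.
#' @param groups grouping vector, required when \code{fit} is a vector.
#' @param type residual type passed to \code{residuals()} for model
#'   objects.
#' @return estimated rho.
#' @export
estimate_rho <- function(fit, groups = NULL, type = "working") {
  if (inherits(fit, "trout_gam")) {
    e <- stats::residuals(fit$fit, type = type)
    groups <- if (!is.null(fit$spec$ar_group))
      fit$data[[fit$spec$ar_group]] else rep(1L, length(e))
  } else {
    e <- as.numeric(fit)
    groups <- groups %||% rep(1L, length(e))
  }
  n <- length(e)
  if (n < 2) stop("need at least two residuals")
  same <- groups[-1] == groups[-n]
  if (!any(same)) {
    stop("no within-group consecutive pairs; rho is undefined")
  }
  num <- sum(e[-1][same] * e[-n][same])
  den <- sum(e^2)
  num / den * n / sum(same)  # scale to a correlation over the pairs used
}

#' Compare fitted models by AIC
#'
#' @param ... named fitted models (\code{trout_gam}, \code{count_fit},
#'   or any object with \code{AIC} and \code{nobs} methods) fitted to the
#'   same response data.
#' @return data frame \code{model, aic, delta_aic}, best first.
#' @export
compare_aic <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) &&
      !inherits(fits[[1]], c("trout_gam", "count_fit", "gam", "glm"))) {
    fits <- fits[[1]]
  }
  nm <- names(fits) %||% paste0("model", seq_along(fits))
  nm[nm == ""] <- paste0("model", which(nm == ""))
  raw <- lapply(fits, unwrap_fit)
  ns <- vapply(raw, function(f) as.integer(stats::nobs(f)), integer(1))
  if (length(unique(ns)) > 1) {
    stop("models were fitted to differing numbers of observations: ",
         paste(ns, collapse = ", "))
  }
  aic <- vapply(raw, stats::AIC, numeric(1))
  out <- data.frame(model = nm, aic = aic,
                    delta_aic = aic - min(aic), stringsAsFactors = FALSE)
  out[order(out$aic), , drop = FALSE] |> `rownames<-`(NULL)
}

#' Worst-case concurvity per smooth term
#'
#' For each smooth term, the squared largest canonical correlation
#' between its basis columns and the span of every other model column
#' (parametric terms and intercept included) -- the most pessimistic
#' measure, in [0, 1].  Values above 0.8 indicate strong concurvity.
#'
#' @param fit a \code{trout_gam} or \code{mgcv} fit with >= 2 smooth
#'   terms.
#' @return named numeric vector, one value per smooth term.
#' @export
concurvity_worst <- function(fit) {
  b <- unwrap_fit(fit)
  if (length(b$smooth) < 2) stop("need at least two smooth terms")
  X <- stats::model.matrix(b)
  orth <- function(M) {
    qrM <- qr(M)
    if (qrM$rank < ncol(M)) {
      warning("rank-deficient basis; concurvity computed on reduced rank")
    }
    qr.Q(qrM)[, seq_len(qrM$rank), drop = FALSE]
  }
  out <- numeric(length(b$smooth))
  names(out) <- vapply(b$smooth, function(s) s$label, character(1))
  for (i in seq_along(b$smooth)) {
    cols <- b$smooth[[i]]$first.para:b$smooth[[i]]$last.para
    Qs <- orth(X[, cols, drop = FALSE])
    Qo <- orth(X[, -cols, drop = FALSE])
    sv <- svd(crossprod(Qs, Qo), nu = 0, nv = 0)$d
    out[i] <- min(1, max(sv)^2)
  }
  out
}

#' Pairwise collinearity screen
#'
#' Pearson correlations among candidate covariates; pairs beyond the
#' threshold are flagged for exclusion (as done here for temperature and
#' downstream-river discharge against day of year).
#'
#' @param data data frame.
#' @param vars columns to screen; default: all numeric columns.
#' @param threshold absolute-correlation flag level (default 0.8).
#' @return data frame \code{var_a, var_b, r, flagged}; a constant
#'   covariate yields \code{r = NA} and is flagged with a warning.
#' @export
screen_collinearity <- function(data, vars = NULL, threshold = 0.8) {
  vars <- vars %||% names(data)[vapply(data, is.numeric, logical(1))]
  if (length(vars) < 2) stop("need at least two covariates")
  const <- vars[vapply(data[vars], function(x)
    stats::sd(x, na.rm = TRUE) == 0, logical(1))]
  if (length(const)) {
    warning("constant covariate(s) with undefined correlation: ",
            paste(const, collapse = ", "))
  }
  cm <- suppressWarnings(stats::cor(data[vars],
                                    use = "pairwise.complete.obs"))
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  out <- data.frame(var_a = vars[idx[, 1]], var_b = vars[idx[, 2]],
                    r = cm[idx], stringsAsFactors = FALSE)
  out$flagged <- is.na(out$r) | abs(out$r) > threshold
  out
}
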