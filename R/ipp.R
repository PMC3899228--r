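# Presence/availability habitat modelling.  Sightings are treated as a
# realisation of an inhomogeneous Poisson point process over the surveyed
# space-time; the process likelihood is approximated by logistic regression
# with very large case weights on uniform availability points (infinitely
# weighted logistic regression, IWLR), whose slope coefficients converge to
# the IPP log-intensity coefficients as the weight grows.

#' Sample availability points for scans
#'
#' For each scan, draws points uniform by area over the sector wedge out to
#' the detection radius (\code{r = R sqrt(u)}, bearing uniform within the
#' sector), timestamps them at the scan start, and samples their covariates.
#' Points landing on missing environmental data are redrawn (at most
#' \code{max_attempts} per point).
#'
#' @param scans Data frame with scan_id, site, start_time, sea_state.
#' @param wedges Named list of [sector_wedge()]s keyed by site; the wedge
#'   radius is overridden per scan by \code{radius_fn} when given.
#' @param env An [environment_bundle()].
#' @param n_per_scan Availability points per scan (default 2).
#' @param seed Integer seed.
#' @param radius_fn Optional function(site, sea_state) returning the
#'   sampling radius (m), typically the inflection radius.
#' @param max_attempts Redraw limit per point (default 100).
#' @return Data frame of availability records with covariates, response 0.
#' @export
sample_availability <- function(scans, wedges, env, n_per_scan = 2, seed,
                                radius_fn = NULL, max_attempts = 100) {
  stopifnot(n_per_scan >= 1)
  .with_seed(seed, {
    n <- nrow(scans) * n_per_scan
    idx <- rep(seq_len(nrow(scans)), each = n_per_scan)
    wl <- wedges[scans$site[idx]]
    if (any(vapply(wl, is.null, TRUE)))
      stop("no sector wedge for site(s): ",
           paste(setdiff(unique(scans$site), names(wedges)), collapse = ", "))
    R <- vapply(seq_len(n), function(i) {
      if (is.null(radius_fn)) wl[[i]]$radius
      else radius_fn(scans$site[idx[i]], scans$sea_state[idx[i]])
    }, 0)
    draw <- function(sel) {
      u <- stats::runif(sum(sel)); a <- stats::runif(sum(sel))
      r <- R[sel] * sqrt(u)
      w <- wl[sel]
      th <- (vapply(w, `[[`, 0, "start") + a * vapply(w, `[[`, 0, "width")) * pi / 180
      list(x = vapply(w, `[[`, 0, "x") + r * sin(th),
           y = vapply(w, `[[`, 0, "y") + r * cos(th))
    }
    pts <- draw(rep(TRUE, n))
    x <- pts$x; y <- pts$y
    times <- as.POSIXct(scans$start_time[idx], tz = "UTC")
    cov <- sample_covariates(x, y, times, env)
    attempt <- 1
    while (any(cov$missing_env) && attempt < max_attempts) {
      sel <- cov$missing_env
      pts <- draw(sel)
      x[sel] <- pts$x; y[sel] <- pts$y
      cov[sel, ] <- sample_covariates(x[sel], y[sel], times[sel], env)
      attempt <- attempt + 1
    }
    if (any(cov$missing_env))
      stop("could not place availability points on valid environment after ",
           max_attempts, " attempts")
    cov$response <- 0L
    cov$scan_id <- scans$scan_id[idx]
    cov$site <- scans$site[idx]
    cov$sea_state <- scans$sea_state[idx]
    cov$day_id <- format(times, "%Y-%m-%d")
    cov
  })
}

#' Assemble a use-availability data set
#'
#' Binds presence records (response 1, case weight 1) and availability
#' records (response 0, case weight W) into the IWLR design.
#'
#' @param presence Data frame of covariate-sampled sightings (response
#'   column added here).
#' @param availability Data frame from [sample_availability()].
#' @param W Availability case weight (default 1000).
#' @return Data frame with \code{response}, \code{case_weight} and the
#'   shared covariate columns.
#' @export
assemble_use_availability <- function(presence, availability, W = 1000) {
  stopifnot(W >= 100)
  presence$response <- 1L
  shared <- intersect(names(presence), names(availability))
  rec <- rbind(presence[shared], availability[shared])
  rec$case_weight <- ifelse(rec$response == 1, 1, W)
  rec
}

#' Screen covariates for collinearity
#'
#' Finds pairs with absolute Pearson correlation at or above the threshold
#' and drops the lower-priority member of each, working through pairs in
#' decreasing order of correlation.
#'
#' @param records Data frame of model records.
#' @param covariates Character vector of numeric covariate columns to screen.
#' @param r_threshold Correlation threshold (default 0.8).
#' @param priority Character vector, most-preferred first; covariates not
#'   listed rank below all listed ones in their column order.
#' @return List with \code{retained}, \code{dropped} and a data frame
#'   \code{pairs} (var1, var2, r, dropped).
#' @export
screen_collinearity <- function(records, covariates, r_threshold = 0.8,
                                priority = c("tidal_stratification",
                                             "mean_stratification")) {
  stopifnot(length(covariates) >= 2, nrow(records) >= 10)
  cm <- stats::cor(records[covariates], use = "pairwise.complete.obs")
  rank_of <- function(v) {
    i <- match(v, priority)
    ifelse(is.na(i), length(priority) + match(v, covariates), i)
  }
  dropped <- character()
  pairs <- data.frame(var1 = character(), var2 = character(),
                      r = numeric(), dropped = character())
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  ord <- ut[order(-abs(cm[ut])), , drop = FALSE]
  for (k in seq_len(nrow(ord))) {
    v1 <- covariates[ord[k, 1]]; v2 <- covariates[ord[k, 2]]
    r <- cm[ord[k, 1], ord[k, 2]]
    if (is.na(r) || abs(r) < r_threshold) next
    if (v1 %in% dropped || v2 %in% dropped) next
    drop <- if (rank_of(v1) <= rank_of(v2)) v2 else v1
    dropped <- c(dropped, drop)
    pairs <- rbind(pairs, data.frame(var1 = v1, var2 = v2, r = r,
                                     dropped = drop))
  }
  list(retained = setdiff(covariates, dropped), dropped = dropped,
       pairs = pairs)
}

#' Specify a model term
#'
#' @param covariate Covariate name (two names for a tensor product).
#' @param basis One of \code{"thin_plate"}, \code{"cyclic_cubic"},
#'   \code{"tensor_product"}, \code{"factor"}, \code{"linear"}.
#' @param k Basis dimension (defaults: thin plate 10, cyclic 8, tensor 5
#'   per margin).
#' @param period Period of a cyclic covariate (required for cyclic_cubic).
#' @return Object of class \code{smooth_term}.
#' @export
smooth_term <- function(covariate,
                        basis = c("thin_plate", "cyclic_cubic",
                                  "tensor_product", "factor", "linear"),
                        k = NULL, period = NULL) {
  basis <- match.arg(basis)
  if (basis == "tensor_product" && length(covariate) != 2)
    stop("tensor_product takes exactly two covariates")
  if (basis == "cyclic_cubic" && is.null(period))
    stop("cyclic_cubic requires a period")
  cyclic_set <- c("lunar_cycle", "tidal_state", "aspect", "current_direction")
  if (basis == "cyclic_cubic" && !covariate %in% cyclic_set)
    warning(covariate, " is not one of the conventional circular covariates")
  if (is.null(k))
    k <- switch(basis, thin_plate = 10, cyclic_cubic = 8,
                tensor_product = 5, NA)
  structure(list(covariate = covariate, basis = basis, k = k,
                 period = period), class = "smooth_term")
}

#' @export
print.smooth_term <- function(x, ...) {
  cat(sprintf("<smooth_term> %s [%s%s]\n", term_label(x), x$basis,
              if (!is.null(x$period)) paste0(", period ", x$period) else ""))
  invisible(x)
}

#' Human-readable label of a term (matches selection-table conventions)
#' @param term A [smooth_term()].
#' @export
term_label <- function(term) {
  switch(term$basis,
         tensor_product = sprintf("te(%s)", paste(term$covariate, collapse = ",")),
         factor = term$covariate,
         linear = term$covariate,
         sprintf("s(%s)", term$covariate))
}

# mgcv formula fragment for a term.
.term_formula <- function(term) {
  switch(term$basis,
         thin_plate = sprintf("s(%s, bs = 'tp', k = %d)", term$covariate, term$k),
         cyclic_cubic = sprintf("s(%s, bs = 'cc', k = %d)", term$covariate, term$k),
         tensor_product = sprintf("te(%s, k = c(%d, %d))",
                                  paste(term$covariate, collapse = ", "),
                                  term$k, term$k),
         factor = sprintf("factor(%s)", term$covariate),
         linear = term$covariate)
}

# knots list entry for cyclic terms so the basis wraps at the period.
.term_knots <- function(terms) {
  kn <- list()
  for (tm in terms)
    if (tm$basis == "cyclic_cubic")
      kn[[tm$covariate]] <- seq(0, tm$period, length.out = tm$k)
  if (length(kn) == 0) NULL else kn
}

# map circular covariates onto [0, period)
.wrap_cyclic <- function(data, terms) {
  for (tm in terms)
    if (tm$basis == "cyclic_cubic")
      data[[tm$covariate]] <- data[[tm$covariate]] %% tm$period
  data
}

#' Default term specifications
#'
#' The standard candidate set: thin-plate smooths of the hydrographic and
#' temporal covariates, cyclic cubic smooths (with their natural periods) of
#' the circular ones, a tensor product of the coordinates, and factors for
#' site and sea state.
#'
#' @return Named list of [smooth_term()]s.
#' @export
default_term_specs <- function() {
  tp <- function(v) smooth_term(v, "thin_plate")
  list(
    sea_state = smooth_term("sea_state", "factor"),
    site = smooth_term("site", "factor"),
    xy = smooth_term(c("x", "y"), "tensor_product"),
    lunar_cycle = smooth_term("lunar_cycle", "cyclic_cubic", period = 14.77),
    tidal_state = smooth_term("tidal_state", "cyclic_cubic", period = 12.42),
    aspect = smooth_term("aspect", "cyclic_cubic", period = 360),
    current_direction = smooth_term("current_direction", "cyclic_cubic",
                                    period = 360),
    mean_stratification = tp("mean_stratification"),
    tidal_stratification = tp("tidal_stratification"),
    day_of_year = tp("day_of_year"),
    hour_of_day = tp("hour_of_day"),
    year = tp("year"),
    depth = tp("depth"),
    slope = tp("slope"),
    sd_slope = tp("sd_slope"),
    sd_current_speed = tp("sd_current_speed"))
}

#' Build the basis and penalty of a smooth term
#'
#' Thin wrapper over \code{mgcv::smoothCon} (cyclic bases get knots spanning
#' one full period so the smooth wraps); factor and linear terms return a
#' model matrix with a zero penalty.
#'
#' @param term A [smooth_term()].
#' @param data Data frame holding the covariate(s).
#' @return List with \code{X} (basis columns) and \code{S} (penalty matrix).
#' @export
build_smooth_basis <- function(term, data) {
  data <- .wrap_cyclic(data, list(term))
  if (term$basis %in% c("factor", "linear")) {
    X <- stats::model.matrix(
      stats::as.formula(paste("~", .term_formula(term))), data)[, -1, drop = FALSE]
    return(list(X = X, S = matrix(0, ncol(X), ncol(X))))
  }
  if (!is.na(term$k) && term$basis != "tensor_product" &&
      term$k >= nrow(data))
    stop("basis dimension must be smaller than the number of observations")
  e <- new.env(parent = baseenv())
  e$s <- mgcv::s; e$te <- mgcv::te
  spec <- eval(parse(text = .term_formula(term)), envir = e)
  sc <- mgcv::smoothCon(spec, data = data, knots = .term_knots(list(term)),
                        absorb.cons = FALSE)[[1]]
  list(X = sc$X, S = if (length(sc$S)) sc$S[[1]] else
    matrix(0, ncol(sc$X), ncol(sc$X)))
}

#' Fit the habitat model by infinitely weighted logistic regression
#'
#' Penalized logistic regression (via \code{mgcv::gam}) with case weight 1
#' on presences and W on availability points.  As W grows the slope
#' coefficients converge to the log-intensity coefficients of the underlying
#' inhomogeneous Poisson process; W = 1000 is ample at survey scale and a
#' doubling check is cheap via [fit_iwlr()] at 2W.  Smoothing parameters are
#' chosen by GCV by default.
#'
#' @param records Use-availability data from [assemble_use_availability()]
#'   (or any data frame with \code{response} and covariates; case weights
#'   are derived from W when absent).
#' @param terms List of [smooth_term()]s.
#' @param W Availability weight (default 1000, >= 100).
#' @param method Smoothing selection criterion passed to \code{mgcv::gam}
#'   (default \code{"GCV.Cp"}).
#' @return Object of class \code{habitat_model} wrapping the gam fit, with
#'   deviance explained (%) and the term list.
#' @export
fit_iwlr <- function(records, terms, W = 1000, method = "GCV.Cp") {
  stopifnot(W >= 100)
  if (!all(c(0, 1) %in% records$response))
    stop("both response classes must be present")
  if (is.null(records$case_weight))
    records$case_weight <- ifelse(records$response == 1, 1, W)
  records <- .wrap_cyclic(records, terms)
  rhs <- if (length(terms) == 0) "1" else
    paste(vapply(terms, .term_formula, ""), collapse = " + ")
  fml <- stats::as.formula(paste("response ~", rhs))
  fit <- mgcv::gam(fml, family = stats::binomial(), data = records,
                   weights = case_weight, method = method,
                   knots = .term_knots(terms))
  dev_expl <- 100 * (1 - fit$deviance / fit$null.deviance)
  # separation check on the parametric (linear / factor) coefficients only
  para <- fit$coefficients
  para <- para[!grepl("Intercept", names(para))]
  para <- para[names(para) %in% names(records) |
                 grepl("^factor\\(", names(para))]
  sdx <- vapply(names(para), function(nm) {
    v <- records[[nm]]
    if (is.numeric(v) && stats::sd(v) > 0) stats::sd(v) else 1
  }, 0)
  if (any(abs(para) * sdx > 20, na.rm = TRUE))
    warning("very large standardized coefficient: possible separation; ",
            "consider a ridge penalty or simpler terms")
  structure(list(fit = fit, terms = terms, W = W,
                 deviance_explained = dev_expl,
                 medians = .covariate_medians(records, terms)),
            class = "habitat_model")
}

.covariate_medians <- function(records, terms) {
  vars <- unique(unlist(lapply(terms, `[[`, "covariate")))
  med <- lapply(vars, function(v) {
    x <- records[[v]]
    if (is.numeric(x)) stats::median(x, na.rm = TRUE)
    else sort(unique(x))[1]
  })
  names(med) <- vars
  med
}

#' @export
print.habitat_model <- function(x, ...) {
  cat(sprintf("<habitat_model> %d terms, W = %g, deviance explained %.1f%%\n",
              length(x$terms), x$W, x$deviance_explained))
  for (tm in x$terms) cat("  ", term_label(tm), "\n")
  invisible(x)
}

#' @export
coef.habitat_model <- function(object, ...) stats::coef(object$fit)

#' Rate ratio of a log-scale coefficient
#'
#' The multiplicative change in sighting rate implied by a log-intensity
#' coefficient: \code{exp(coefficient)}.
#'
#' @param coefficient Numeric vector of coefficients.
#' @param digits Significant digits for reporting (default 3; the raw value
#'   is returned with the rounded one as attribute \code{reported}).
#' @return \code{exp(coefficient)} with attribute \code{reported}.
#' @export
rate_ratio <- function(coefficient, digits = 3) {
  stopifnot(all(is.finite(coefficient)))
  rr <- exp(coefficient)
  structure(rr, reported = signif(rr, digits))
}

#' Day-grouped cross-validated log-likelihood
#'
#' Leave-one-day-out cross-validation of a term set: for each observation
#' day the model is refitted without that day and the held-out (weighted)
#' Bernoulli log-likelihood is accumulated.  Scans within a day are
#' correlated, so whole days are the exchangeable unit.
#'
#' @param records Use-availability data with a \code{day_id} column.
#' @param terms List of [smooth_term()]s.
#' @param W Availability weight.
#' @param weighted Use the case weights in the held-out likelihood (default
#'   TRUE; FALSE gives the unweighted Bernoulli sum).
#' @param method Smoothing selection criterion.
#' @return The summed cross-validated log-likelihood (attribute
#'   \code{n_folds}).
#' @export
cvll_grouped <- function(records, terms, W = 1000, weighted = TRUE,
                         method = "GCV.Cp") {
  days <- sort(unique(records$day_id))
  if (length(days) < 2) stop("need at least 2 distinct days")
  if (is.null(records$case_weight))
    records$case_weight <- ifelse(records$response == 1, 1, W)
  total <- 0; used <- 0L
  for (d in days) {
    hold <- records$day_id == d
    if (!any(records$response[hold] == 0)) {
      warning("fold ", d, " has no availability points; skipped")
      next
    }
    train <- records[!hold, , drop = FALSE]
    if (!all(c(0, 1) %in% train$response)) {
      warning("fold ", d, " leaves a single-class training set; skipped")
      next
    }
    fit <- fit_iwlr(train, terms, W = W, method = method)
    p <- tryCatch(.predict_response(fit, records[hold, , drop = FALSE]),
                  error = function(e) {
                    warning("fold ", d, " not predictable (", conditionMessage(e),
                            "); skipped")
                    NULL
                  })
    if (is.null(p)) next
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    y <- records$response[hold]
    w <- if (weighted) records$case_weight[hold] else rep(1, sum(hold))
    total <- total + sum(w * (y * log(p) + (1 - y) * log(1 - p)))
    used <- used + 1L
  }
  structure(total, n_folds = used)
}

.predict_response <- function(model, newdata) {
  newdata <- .wrap_cyclic(newdata, model$terms)
  as.numeric(mgcv::predict.gam(model$fit, newdata = newdata,
                               type = "response"))
}

.predict_link <- function(model, newdata) {
  newdata <- .wrap_cyclic(newdata, model$terms)
  as.numeric(mgcv::predict.gam(model$fit, newdata = newdata, type = "link"))
}

#' Forward model selection by cross-validated log-likelihood
#'
#' Starting from the intercept (or a fixed base set), repeatedly adds the
#' candidate term that most increases the day-grouped CVLL, stopping when
#' the best remaining candidate no longer improves it.  The returned table
#' lists the accepted steps in order followed by the remaining candidates
#' with their (rejected) change in CVLL relative to the preceding row, in
#' the layout conventional for such selection tables.
#'
#' @param records Use-availability data with \code{day_id}.
#' @param candidates Named list of [smooth_term()]s to consider.
#' @param base_terms Terms always included (default none).
#' @param W,weighted,method Passed to [cvll_grouped()] / [fit_iwlr()].
#' @return List with \code{table} (term, CVLL, dCVLL, retained), the final
#'   \code{model} fitted on all data, and \code{terms}.
#' @export
forward_select <- function(records, candidates, base_terms = list(),
                           W = 1000, weighted = TRUE, method = "GCV.Cp") {
  stopifnot(length(candidates) >= 1)
  selected <- base_terms
  remaining <- candidates
  rows <- list()
  # baseline for the stop rule: intercept-only (or base-terms-only) CVLL
  last_cvll <- as.numeric(suppressWarnings(
    cvll_grouped(records, selected, W = W, weighted = weighted,
                 method = method)))
  first_step <- TRUE
  repeat {
    scores <- vapply(remaining, function(tm)
      as.numeric(suppressWarnings(
        cvll_grouped(records, c(selected, list(tm)), W = W,
                     weighted = weighted, method = method))), 0)
    best <- which.max(scores)  # ties: earliest in candidate order
    delta <- scores[best] - last_cvll
    if (delta <= 0) break
    rows[[length(rows) + 1]] <- data.frame(
      term = term_label(remaining[[best]]), CVLL = scores[best],
      dCVLL = if (first_step) NA_real_ else delta, retained = TRUE)
    first_step <- FALSE
    selected <- c(selected, remaining[best])
    last_cvll <- scores[best]
    remaining <- remaining[-best]
    if (length(remaining) == 0) break
  }
  # report the rejected candidates against the final model, best first,
  # each row's change taken against the row above it
  if (length(remaining) > 0) {
    scores <- vapply(remaining, function(tm)
      as.numeric(suppressWarnings(
        cvll_grouped(records, c(selected, list(tm)), W = W,
                     weighted = weighted, method = method))), 0)
    o <- order(-scores)
    prev <- last_cvll
    for (i in o) {
      rows[[length(rows) + 1]] <- data.frame(
        term = term_label(remaining[[i]]), CVLL = scores[i],
        dCVLL = scores[i] - prev, retained = FALSE)
      prev <- scores[i]
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  model <- fit_iwlr(records, selected, W = W, method = method)
  list(table = tab, model = model, terms = selected)
}

#' Check the internal consistency of a selection table
#'
#' Each change-in-CVLL entry should equal the difference between its row's
#' CVLL and the CVLL of the row above.
#'
#' @param table Data frame with columns CVLL and dCVLL (first dCVLL NA or
#'   blank).
#' @return Maximum absolute discrepancy over the checked rows.
#' @export
selection_delta_consistency <- function(table) {
  cvll <- table$CVLL; d <- table$dCVLL
  max(abs(d[-1] - diff(cvll)), na.rm = TRUE)
}

#' Predict relative sighting rate
#'
#' Exponential of the model's linear predictor.  With \code{vary} set, a
#' one-dimensional effect curve is produced: the named covariate sweeps its
#' observed range (or one full period for circular covariates) while every
#' other covariate is held at its training median (factors at their first
#' level).
#'
#' @param model A [fit_iwlr()] result.
#' @param newdata Data frame of covariates (ignored when \code{vary} given).
#' @param vary Name of the covariate to sweep.
#' @param n Number of grid points for the sweep (default 100).
#' @return Data frame with the covariate values (sweep mode) and
#'   \code{relative_rate}; an attribute \code{extrapolated} flags points
#'   outside the training range.
#' @export
predict_relative_rate <- function(model, newdata = NULL, vary = NULL,
                                  n = 100) {
  fitdata <- model$fit$model
  if (!is.null(vary)) {
    cyc <- NULL
    for (tm in model$terms)
      if (tm$basis == "cyclic_cubic" && tm$covariate == vary) cyc <- tm$period
    xs <- if (!is.null(cyc)) seq(0, cyc, length.out = n)
          else seq(min(fitdata[[vary]]), max(fitdata[[vary]]), length.out = n)
    newdata <- as.data.frame(model$medians[names(model$medians) != vary])
    newdata <- newdata[rep(1, n), , drop = FALSE]
    newdata[[vary]] <- xs
  }
  stopifnot(!is.null(newdata))
  lp <- .predict_link(model, newdata)
  out <- cbind(newdata, relative_rate = exp(lp))
  num <- names(model$medians)[vapply(model$medians, is.numeric, TRUE)]
  extr <- rep(FALSE, nrow(newdata))
  for (v in intersect(num, names(newdata))) {
    rng <- range(fitdata[[v]], na.rm = TRUE)
    if (!is.null(rng)) extr <- extr | newdata[[v]] < rng[1] | newdata[[v]] > rng[2]
  }
  attr(out, "extrapolated") <- extr
  out
}
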