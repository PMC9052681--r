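# Hourly binomial presence model: penalized-spline logistic regression with
# cyclic cubic smooths of day-of-year and hour, natural cubic smooths of
# lunar fraction and chlorophyll-a, fixed effects for sex, maturity and
# active-station count, and a ridge-penalized per-animal random intercept
# (the standard mixed-model-as-penalized-GLM equivalence). Smoothing
# parameters are chosen by coordinate-descent grid search minimizing a
# deviance-based GCV criterion; candidate models (all subsets of the four
# smooths) are ranked by conditional AIC with effective degrees of freedom.

SMOOTH_K <- c(day = 7, hour = 7, moon = 6, chla = 7)

#' Build the hourly observation table
#'
#' One row per animal-hour from 48 h after release to the end of the study
#' window: `y = 1` iff the animal has at least one retained detection in
#' that hour. Covariates: local day-of-year and hour, daily moon fraction
#' and chlorophyll-a (joined by local date), hourly active-receiver count
#' (falling back to the daily value by construction of station intervals),
#' sex and maturity.
#'
#' @param detections filtered detection table.
#' @param deployments deployment table.
#' @param env daily environmental series covering the window.
#' @param stations station table with activity intervals.
#' @param study_end last date included.
#' @param tz_offset local-day offset, hours.
#' @return data.frame of hourly observations.
#' @export
build_hourly_table <- function(detections, deployments, env, stations,
                               study_end = NULL,
                               tz_offset = DEFAULT_TZ_OFFSET) {
  if (is.null(study_end)) {
    study_end <- max(to_calendar_day(detections$timestamp, tz_offset))
  }
  end_ts <- as.POSIXct(as.Date(study_end) + 1, tz = "UTC") - tz_offset * 3600
  rows <- vector("list", nrow(deployments))
  for (i in seq_len(nrow(deployments))) {
    a <- deployments$animal_id[i]
    start <- deployments$release_time[i] + 48 * 3600
    start <- as.POSIXct(ceiling(as.numeric(start) / 3600) * 3600,
                        origin = "1970-01-01", tz = "UTC")
    if (start >= end_ts) next
    hours <- seq(start, end_ts - 3600, by = "hour")
    det <- detections[detections$tag_id %in%
                        c(a, deployments$tag_id[i]), , drop = FALSE]
    hr_key <- floor(as.numeric(det$timestamp) / 3600)
    y <- as.integer(floor(as.numeric(hours) / 3600) %in% unique(hr_key))
    loc <- hours + tz_offset * 3600
    dates <- as.Date(floor(as.numeric(loc) / 86400), origin = "1970-01-01")
    ei <- match(dates, env$date)
    if (anyNA(ei)) stop("environmental series does not cover the window",
                        call. = FALSE)
    rows[[i]] <- data.frame(
      animal_id = a,
      hour_start = hours,
      y = y,
      day_of_year = pmin(as.integer(format(dates, "%j")), 365L),
      hour = as.integer(format(loc, "%H", tz = "UTC")),
      moon_frac = env$moon_frac[ei],
      chla = env$chla[ei],
      n_stations = n_active_stations(stations, hours),
      sex = deployments$sex[i],
      maturity = deployments$maturity[i],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) stop("no observation rows", call. = FALSE)
  rownames(out) <- NULL
  out
}

# Assemble the design for one candidate model. Smooth bases are built once
# on the full table and passed in; `smooths` selects the subset included.
build_design <- function(table, bases, smooths) {
  n <- nrow(table)
  X <- matrix(1, n, 1); colnames(X) <- "(Intercept)"
  blocks <- list()    # per-penalty: columns + penalty matrix + label
  if (length(unique(table$sex)) > 1L) {
    X <- cbind(X, sexM = as.numeric(table$sex == "M"))
  }
  if (length(unique(table$maturity)) > 1L) {
    X <- cbind(X, maturitymature = as.numeric(table$maturity == "mature"))
  }
  if (var(table$n_stations) > 0) {
    X <- cbind(X, n_stations = table$n_stations - mean(table$n_stations))
  }
  for (s in smooths) {
    b <- bases[[s]]
    cols <- ncol(X) + seq_len(ncol(b$X))
    colnames(b$X) <- paste0("s(", s, ").", seq_len(ncol(b$X)))
    X <- cbind(X, b$X)
    blocks[[paste0("s(", s, ")")]] <- list(cols = cols, S = b$S, basis = b,
                                           covariate = s)
  }
  # per-animal random intercept: full indicator block, identity penalty
  an <- factor(table$animal_id)
  if (nlevels(an) > 1L) {
    Zre <- model.matrix(~ an - 1)
    colnames(Zre) <- paste0("re.", levels(an))
    cols <- ncol(X) + seq_len(ncol(Zre))
    X <- cbind(X, Zre)
    blocks[["re(animal)"]] <- list(cols = cols, S = diag(ncol(Zre)),
                                   basis = NULL, covariate = "animal_id")
  }
  list(X = X, blocks = blocks)
}

# Penalized IRLS for binomial/logit with fixed smoothing parameters.
# Returns coefficients, deviance, edf (total and per block), and the
# penalized information matrix pieces needed by GCV/AIC.
pirls_fit <- function(X, y, blocks, lambda, beta0 = NULL,
                      max_iter = 50, tol = 1e-8) {
  n <- nrow(X); p <- ncol(X)
  P <- matrix(0, p, p)
  for (j in seq_along(blocks)) {
    cols <- blocks[[j]]$cols
    P[cols, cols] <- P[cols, cols] + lambda[j] * blocks[[j]]$S
  }
  beta <- beta0 %||% rep(0, p)
  eta <- as.numeric(X %*% beta)
  dev_old <- Inf
  for (it in seq_len(max_iter)) {
    mu <- plogis(eta)
    mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    sw <- sqrt(w)
    Xw <- X * sw
    A <- crossprod(Xw)
    bvec <- crossprod(Xw, z * sw)
    R <- tryCatch(chol(A + P), error = function(e) NULL)
    if (is.null(R)) {
      R <- chol(A + P + diag(1e-8, p))
    }
    beta_new <- backsolve(R, forwardsolve(t(R), bvec))
    eta <- as.numeric(X %*% beta_new)
    dev <- -2 * sum(y * log(pmax(plogis(eta), 1e-12)) +
                      (1 - y) * log(pmax(1 - plogis(eta), 1e-12)))
    beta <- beta_new
    if (abs(dev_old - dev) < tol * (abs(dev) + 0.1)) break
    dev_old <- dev
  }
  if (it == max_iter && abs(dev_old - dev) > 1e-3 * (abs(dev) + 0.1)) {
    stop("penalized IRLS failed to converge", call. = FALSE)
  }
  # influence: F = (A + P)^-1 A ; edf = tr(F), per-column diag for blocks
  Finv <- chol2inv(R)             # (A+P)^-1
  Fdiag <- rowSums(Finv * t(A))   # diag((A+P)^-1 A)
  edf <- sum(Fdiag)
  edf_block <- vapply(blocks, function(b) sum(Fdiag[b$cols]), numeric(1))
  list(beta = as.numeric(beta), deviance = dev, edf = edf,
       edf_block = edf_block, Fdiag = Fdiag, Vb = Finv, A = A,
       eta = eta, iters = it)
}

# Deviance-based GCV score used for smoothing-parameter selection.
gcv_score <- function(fit, n) n * fit$deviance / (n - fit$edf)^2

#' Fit the binomial presence GAMM
#'
#' Penalized IRLS with quadratic curvature penalties per smooth and a ridge
#' penalty on the per-animal intercepts; smoothing parameters selected by
#' coordinate-descent grid search minimizing deviance GCV. AIC is the
#' conditional variant: deviance + 2 x (effective degrees of freedom =
#' trace of the influence matrix).
#'
#' @param table hourly observation table (see [build_hourly_table()]).
#' @param smooths subset of `c("day","hour","moon","chla")` to include.
#' @param k basis dimensions, named as `SMOOTH_K`.
#' @param lambda_grid log10-spaced candidate smoothing parameters.
#' @param sweeps coordinate-descent passes over the penalty set.
#' @param bases precomputed constrained bases (internal reuse).
#' @return `gamm_fit` list: coefficients, lambdas, per-term edf and
#'   approximate Wald p-values, AIC, deviance explained (%), partial-effect
#'   curves on covariate grids (centred, with SE).
#' @export
fit_binomial_gamm <- function(table, smooths = c("day", "hour", "moon", "chla"),
                              k = SMOOTH_K,
                              lambda_grid = 10^seq(-2, 7, by = 1),
                              sweeps = 2, bases = NULL) {
  stopifnot(all(smooths %in% names(SMOOTH_K)))
  y <- table$y
  if (length(unique(y)) < 2L) stop("response is degenerate", call. = FALSE)
  dropped <- character(0)
  covs <- c(day = "day_of_year", hour = "hour", moon = "moon_frac",
            chla = "chla")
  for (s in smooths) {
    if (var(table[[covs[s]]]) == 0) {
      warning("covariate '", covs[s], "' has zero variance; term dropped")
      dropped <- c(dropped, s)
    }
  }
  smooths <- setdiff(smooths, dropped)
  if (is.null(bases)) bases <- build_smooth_bases(table, k, smooths)
  des <- build_design(table, bases, smooths)
  nb <- length(des$blocks)
  lambda <- rep(1, nb)
  fit <- pirls_fit(des$X, y, des$blocks, lambda)
  if (nb > 0) {
    for (sw in seq_len(sweeps)) {
      for (j in seq_len(nb)) {
        best <- Inf; best_l <- lambda[j]
        for (l in lambda_grid) {
          lam <- lambda; lam[j] <- l
          f <- pirls_fit(des$X, y, des$blocks, lam, beta0 = fit$beta)
          sc <- gcv_score(f, nrow(table))
          if (sc < best) { best <- sc; best_l <- l; fit_best <- f }
        }
        lambda[j] <- best_l
        fit <- fit_best
      }
    }
  }
  null_dev <- -2 * sum(y * log(mean(y)) + (1 - y) * log(1 - mean(y)))
  aic <- fit$deviance + 2 * fit$edf
  # approximate Wald tests per penalized block
  pvals <- rep(NA_real_, nb); names(pvals) <- names(des$blocks)
  for (j in seq_len(nb)) {
    cols <- des$blocks[[j]]$cols
    bj <- fit$beta[cols]
    Vj <- fit$Vb[cols, cols, drop = FALSE]
    stat <- tryCatch(as.numeric(t(bj) %*% solve(Vj, bj)),
                     error = function(e) NA_real_)
    df <- max(fit$edf_block[j], 1e-3)
    pvals[j] <- if (is.na(stat)) NA_real_ else
      stats::pchisq(stat, df = df, lower.tail = FALSE)
  }
  partials <- list()
  for (s in smooths) {
    b <- des$blocks[[paste0("s(", s, ")")]]
    grid <- switch(s,
                   day = seq(1, 365, length.out = 200),
                   hour = seq(0, 24, length.out = 200),
                   moon = seq(min(table$moon_frac), max(table$moon_frac),
                              length.out = 200),
                   chla = seq(min(table$chla), max(table$chla),
                              length.out = 200))
    Xg <- eval_basis(b$basis, grid)
    eff <- as.numeric(Xg %*% fit$beta[b$cols])
    Xobs <- eval_basis(b$basis, table[[covs[s]]])
    eff_obs <- as.numeric(Xobs %*% fit$beta[b$cols])
    eff <- eff - mean(eff_obs)    # centred over observed covariate values
    se <- sqrt(pmax(rowSums((Xg %*% fit$Vb[b$cols, b$cols]) * Xg), 0))
    partials[[paste0("s(", s, ")")]] <-
      data.frame(x = grid, effect = eff, se = se)
  }
  structure(list(
    smooths = smooths, dropped = dropped,
    coefficients = setNames(fit$beta, colnames(des$X)),
    lambda = setNames(lambda, names(des$blocks)),
    edf = fit$edf, edf_block = setNames(fit$edf_block, names(des$blocks)),
    p_values = pvals,
    deviance = fit$deviance, null_deviance = null_dev,
    deviance_explained = 100 * (1 - fit$deviance / null_dev),
    aic = aic, gcv = gcv_score(fit, nrow(table)),
    partial_effects = partials, n = nrow(table),
    fitted = plogis(fit$eta), design = des, Vb = fit$Vb),
    class = "gamm_fit")
}

#' @export
print.gamm_fit <- function(x, ...) {
  cat("Binomial presence GAMM (logit link)\n")
  cat(sprintf("  n = %d, smooths: %s\n", x$n,
              if (length(x$smooths)) paste(x$smooths, collapse = ", ")
              else "(none)"))
  cat(sprintf("  AIC = %.1f, edf = %.2f, deviance explained = %.1f%%\n",
              x$aic, x$edf, x$deviance_explained))
  if (length(x$edf_block)) {
    for (nm in names(x$edf_block)) {
      cat(sprintf("  %-12s edf %6.2f  lambda %8.3g  p %.4g\n", nm,
                  x$edf_block[nm], x$lambda[nm], x$p_values[nm]))
    }
  }
  invisible(x)
}

build_smooth_bases <- function(table, k = SMOOTH_K,
                               smooths = names(SMOOTH_K)) {
  covs <- c(day = "day_of_year", hour = "hour", moon = "moon_frac",
            chla = "chla")
  out <- list()
  for (s in smooths) {
    if (var(table[[covs[s]]]) == 0) next   # degenerate covariate: no basis
    out[[s]] <- switch(s,
      day = absorb_constraint(
        cyclic_cubic_basis(table$day_of_year, 365, k[["day"]])),
      hour = absorb_constraint(
        cyclic_cubic_basis(table$hour, 24, k[["hour"]])),
      moon = absorb_constraint(
        natural_cubic_basis(table$moon_frac, k[["moon"]])),
      chla = absorb_constraint(
        natural_cubic_basis(table$chla, k[["chla"]])))
  }
  out
}

#' Enumerate the candidate model set and select by AIC
#'
#' Fits every subset of the four optional smooths (2^4 = 16 candidates when
#' all four covariates are available); fixed effects and the per-animal
#' random intercept are present in every candidate. Candidates whose fit
#' fails are recorded and the ranking proceeds over the successes.
#'
#' @param table hourly observation table.
#' @param smooth_set optional smooths to toggle.
#' @param ... passed to [fit_binomial_gamm()].
#' @return list: `ranking` (data.frame with model label, AIC, dAIC, edf,
#'   deviance explained), `best` (the selected `gamm_fit`), `fits`.
#' @export
enumerate_and_select <- function(table,
                                 smooth_set = c("day", "hour", "moon", "chla"),
                                 ...) {
  bases <- build_smooth_bases(table)
  subsets <- lapply(0:(2^length(smooth_set) - 1), function(m) {
    smooth_set[bitwAnd(m, 2^(seq_along(smooth_set) - 1)) > 0]
  })
  fits <- vector("list", length(subsets))
  rows <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    lab <- if (length(subsets[[i]]))
      paste(paste0("s(", subsets[[i]], ")"), collapse = "+") else "(fixed only)"
    f <- tryCatch(fit_binomial_gamm(table, smooths = subsets[[i]],
                                    bases = bases, ...),
                  error = function(e) e)
    if (inherits(f, "error")) {
      rows[[i]] <- data.frame(model = lab, aic = NA_real_, edf = NA_real_,
                              deviance_explained = NA_real_,
                              error = conditionMessage(f),
                              stringsAsFactors = FALSE)
    } else {
      fits[[i]] <- f
      rows[[i]] <- data.frame(model = lab, aic = f$aic, edf = f$edf,
                              deviance_explained = f$deviance_explained,
                              error = NA_character_, stringsAsFactors = FALSE)
    }
  }
  ranking <- do.call(rbind, rows)
  ranking$daic <- ranking$aic - min(ranking$aic, na.rm = TRUE)
  ok <- which(!is.na(ranking$aic))
  ord <- ok[order(ranking$aic[ok])]
  ranking <- ranking[c(ord, setdiff(seq_len(nrow(ranking)), ord)), ]
  rownames(ranking) <- NULL
  list(ranking = ranking, best = fits[[ord[1]]],
       fits = fits, subsets = subsets)
}

#' @importFrom stats model.matrix pchisq
NULL
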