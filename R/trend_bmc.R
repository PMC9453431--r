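#' Configuration for trend screening and benchmark concentration modeling
#'
#' @param trend_alpha Significance level of the Williams trend gate.
#' @param bmr_factor Benchmark response as a multiple of the reference SD
#'   (default 1.349, the conventional factor equivalent to a 10% change).
#' @param confidence Confidence level for BMDL/BMDU.
#' @param max_iterations Optimizer iteration cap per model fit.
#' @param hill_k_flag_fraction Hill fits with `k` below this fraction of the
#'   lowest positive dose are flagged (default 1/3).
#' @param model_families Ordered model list; earlier families win AIC ties.
#' @param constant_variance Constant-variance assumption (the only mode
#'   implemented; the reference SD is the model residual SD).
#' @param n_permutations Permutations for the Williams test p-value.
#' @param gof_alpha Goodness-of-fit threshold used when a flagged Hill must
#'   be replaced.
#' @param n_boot Parametric bootstrap draws for BMDL/BMDU.
#' @param seed Seed for permutation and bootstrap streams.
#' @return List of class `bmc_config`.
#' @export
bmc_config <- function(trend_alpha = 0.05, bmr_factor = 1.349,
                       confidence = 0.95, max_iterations = 250,
                       hill_k_flag_fraction = 1 / 3,
                       model_families = c("linear", "poly2", "poly3", "poly4",
                                          "power", "hill", "exp2", "exp3",
                                          "exp4", "exp5"),
                       constant_variance = TRUE, n_permutations = 10000,
                       gof_alpha = 0.05, n_boot = 2000, seed = 1) {
  stopifnot(bmr_factor > 0, confidence > 0, confidence < 1)
  structure(list(trend_alpha = trend_alpha, bmr_factor = bmr_factor,
                 confidence = confidence, max_iterations = max_iterations,
                 hill_k_flag_fraction = hill_k_flag_fraction,
                 model_families = model_families,
                 constant_variance = constant_variance,
                 n_permutations = n_permutations, gof_alpha = gof_alpha,
                 n_boot = n_boot, seed = seed), class = "bmc_config")
}

# Williams-type statistics for a matrix of permuted responses.
# X: samples x B; groups ascending by concentration, group 1 = control.
# Amalgamation over treated groups uses the tail-average identity: the
# isotonic (non-decreasing) estimate at the top dose equals the maximum over
# u of the weighted mean of groups u..K.
williams_stats <- function(X, gidx, gsizes) {
  G <- length(gidx); N <- nrow(X)
  M <- matrix(0, G, ncol(X)); SS <- numeric(ncol(X))
  for (g in seq_len(G)) {
    Xg <- X[gidx[[g]], , drop = FALSE]
    M[g, ] <- colMeans(Xg)
    SS <- SS + colSums(Xg^2) - gsizes[g] * M[g, ]^2
  }
  s2 <- SS / (N - G)
  nt <- gsizes[-1]
  Mt <- M[-1, , drop = FALSE]
  W <- Mt * nt
  cn <- apply(W[rev(seq_len(nrow(W))), , drop = FALSE], 2, cumsum)
  cw <- cumsum(rev(nt))
  tails <- cn / cw                      # tail means, top dose first
  iso_up <- apply(tails, 2, max)
  iso_dn <- apply(tails, 2, min)
  sehalf <- sqrt(s2 * (1 / gsizes[G] + 1 / gsizes[1]))
  t_up <- ifelse(sehalf > 0, (iso_up - M[1, ]) / sehalf, 0)
  t_dn <- ifelse(sehalf > 0, (M[1, ] - iso_dn) / sehalf, 0)
  list(t_up = t_up, t_dn = t_dn, s2 = s2)
}

#' Two-sided Williams trend test by permutation
#'
#' Tests for a monotone concentration-response in one gene's normalized
#' expression. Group means are amalgamated under the non-decreasing and
#' non-increasing alternatives (isotonic estimate at the top dose); the
#' statistic compares the amalgamated top-dose mean with the control mean
#' over a pooled within-group SD. Per-direction p-values come from
#' label permutations; the two-sided p is twice the smaller one.
#'
#' @param expr Numeric vector, one value per sample.
#' @param design Experiment design matching `expr`.
#' @param cfg A [bmc_config()].
#' @param seed Permutation seed (default `cfg$seed`).
#' @return List of class `trend_result`: `statistic`, `direction`, `p`,
#'   `passes`.
#' @export
williams_trend <- function(expr, design, cfg = bmc_config(), seed = cfg$seed) {
  concs <- sort(unique(design$concentration))
  if (length(concs) < 3) stop("need >= 3 dose groups including control")
  gidx <- lapply(concs, function(cc) which(design$concentration == cc))
  gsizes <- lengths(gidx)
  if (min(gsizes) < 2) stop("need >= 2 replicates per group")
  obs <- williams_stats(matrix(expr, ncol = 1), gidx, gsizes)
  if (obs$s2 <= 0) {
    return(structure(list(statistic = 0, direction = "up", p = 1,
                          passes = FALSE), class = "trend_result"))
  }
  B <- cfg$n_permutations
  set.seed(seed)
  P <- vapply(seq_len(B), function(b) expr[sample.int(length(expr))],
              numeric(length(expr)))
  perm <- williams_stats(P, gidx, gsizes)
  p_up <- (1 + sum(perm$t_up >= obs$t_up - 1e-12)) / (B + 1)
  p_dn <- (1 + sum(perm$t_dn >= obs$t_dn - 1e-12)) / (B + 1)
  p <- min(1, 2 * min(p_up, p_dn))
  dir <- if (p_up <= p_dn) "up" else "down"
  stat <- if (dir == "up") obs$t_up else obs$t_dn
  structure(list(statistic = as.numeric(stat), direction = dir, p = p,
                 passes = p < cfg$trend_alpha), class = "trend_result")
}

#' Williams trend test for every row of an expression matrix
#'
#' Matrix version of [williams_trend()] sharing one permutation set across
#' genes (the design is common), which keeps large calibration runs fast.
#'
#' @param expr Gene x sample matrix of normalized expression.
#' @param design Experiment design.
#' @param cfg A [bmc_config()].
#' @param seed Permutation seed.
#' @return data.frame: `gene_id`, `statistic`, `direction`, `p`, `passes`.
#' @export
williams_trend_matrix <- function(expr, design, cfg = bmc_config(),
                                  seed = cfg$seed) {
  concs <- sort(unique(design$concentration))
  gidx <- lapply(concs, function(cc) which(design$concentration == cc))
  gsizes <- lengths(gidx)
  B <- cfg$n_permutations
  set.seed(seed)
  perms <- vapply(seq_len(B), function(b) sample.int(ncol(expr)),
                  integer(ncol(expr)))
  out <- data.frame(gene_id = rownames(expr), statistic = NA_real_,
                    direction = NA_character_, p = NA_real_, passes = NA,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(expr))) {
    x <- expr[i, ]
    obs <- williams_stats(matrix(x, ncol = 1), gidx, gsizes)
    if (obs$s2 <= 0) {
      out$statistic[i] <- 0; out$direction[i] <- "up"; out$p[i] <- 1
      next
    }
    X <- matrix(x[perms], nrow = length(x))
    perm <- williams_stats(X, gidx, gsizes)
    p_up <- (1 + sum(perm$t_up >= obs$t_up - 1e-12)) / (B + 1)
    p_dn <- (1 + sum(perm$t_dn >= obs$t_dn - 1e-12)) / (B + 1)
    out$p[i] <- min(1, 2 * min(p_up, p_dn))
    out$direction[i] <- if (p_up <= p_dn) "up" else "down"
    out$statistic[i] <- as.numeric(if (out$direction[i] == "up") obs$t_up else obs$t_dn)
  }
  out$passes <- out$p < cfg$trend_alpha
  out
}

## ---- continuous dose-response model families -------------------------------

drc_n_params <- c(linear = 2, poly2 = 3, poly3 = 4, poly4 = 5, power = 3,
                  hill = 4, exp2 = 2, exp3 = 3, exp4 = 3, exp5 = 4)

#' Predict from a fitted dose-response family
#'
#' @param family Family name (see [bmc_config()]).
#' @param params Named parameter vector as stored in a fit record.
#' @param d Concentrations.
#' @return Predicted responses.
#' @export
predict_drc <- function(family, params, d) {
  p <- params
  switch(family,
    linear = p[["b0"]] + p[["b1"]] * d,
    poly2 = p[["b0"]] + p[["b1"]] * d + p[["b2"]] * d^2,
    poly3 = p[["b0"]] + p[["b1"]] * d + p[["b2"]] * d^2 + p[["b3"]] * d^3,
    poly4 = p[["b0"]] + p[["b1"]] * d + p[["b2"]] * d^2 + p[["b3"]] * d^3 +
      p[["b4"]] * d^4,
    power = p[["g"]] + p[["b"]] * d^p[["delta"]],
    hill = {
      out <- p[["g"]] + p[["v"]] * d^p[["n"]] / (p[["k"]]^p[["n"]] + d^p[["n"]])
      out[d == 0] <- p[["g"]]
      out
    },
    exp2 = p[["a"]] * exp(p[["b"]] * d),
    exp3 = p[["a"]] * exp(p[["sign"]] * (p[["b"]] * d)^p[["c"]]),
    exp4 = p[["a"]] * (p[["c"]] - (p[["c"]] - 1) * exp(-p[["b"]] * d)),
    exp5 = p[["a"]] * (p[["c"]] - (p[["c"]] - 1) * exp(-(p[["b"]] * d)^p[["g"]])),
    stop("unknown family: ", family)
  )
}

# profiled least squares: given a regressor builder xfun(theta) -> matrix,
# the linear coefficients are solved by lm.fit and the RSS returned.
profile_rss <- function(theta, xfun, y) {
  # large finite penalty rather than Inf so optim never warns
  X <- xfun(theta)
  if (any(!is.finite(X))) return(1e300)
  f <- tryCatch(stats::lm.fit(X, y), error = function(e) NULL)
  if (is.null(f)) return(1e300)
  rss <- sum(f$residuals^2)
  if (!is.finite(rss)) 1e300 else rss
}

profile_coefs <- function(theta, xfun, y) {
  X <- xfun(theta)
  f <- stats::lm.fit(X, y)
  list(coefs = unname(ifelse(is.na(f$coefficients), 0, f$coefficients)),
       fitted = f$fitted.values, rss = sum(f$residuals^2))
}

#' Fit one continuous dose-response model family
#'
#' Least-squares fit (Gaussian maximum likelihood under constant variance).
#' Nonlinear shape parameters are optimized by Nelder-Mead over multiple
#' starting points with the linear coefficients profiled out. AIC counts the
#' model parameters plus the variance; the goodness-of-fit p-value is an
#' F-test of the model against the per-group cell-means model.
#'
#' Families (response y at dose d): linear and poly2-4 are polynomials;
#' power `y = g + b d^delta` (delta >= 1); hill
#' `y = g + v d^n / (k^n + d^n)` (n >= 1); exp2 `y = a e^(b d)`;
#' exp3 `y = a e^(s (b d)^c)` (sign s chosen by fit, c >= 1);
#' exp4 `y = a (c - (c-1) e^(-b d))`; exp5 `y = a (c - (c-1) e^(-(b d)^g))`
#' (g >= 1).
#'
#' @param dose Concentrations, one per observation.
#' @param response Observed responses (e.g. log2 normalized expression).
#' @param family Family name.
#' @param cfg A [bmc_config()].
#' @param start Optional internal nonlinear start (used for warm restarts).
#' @return List of class `drc_fit`: `family`, `params`, `theta`, `sigma`,
#'   `loglik`, `aic`, `gof_p`, `fitted`, `converged`, plus the data.
#' @export
fit_family <- function(dose, response, family, cfg = bmc_config(),
                       start = NULL) {
  stopifnot(family %in% names(drc_n_params), length(dose) == length(response))
  n <- length(response)
  dmax <- max(dose); dpos <- dose[dose > 0]
  ctrl <- list(maxit = cfg$max_iterations * 4, reltol = 1e-10)
  fitted <- NULL; params <- NULL; theta <- NULL; rss <- Inf; converged <- TRUE

  if (family %in% c("linear", "poly2", "poly3", "poly4")) {
    deg <- switch(family, linear = 1, poly2 = 2, poly3 = 3, poly4 = 4)
    X <- outer(dose, 0:deg, `^`)
    pc <- profile_coefs(NULL, function(t) X, response)
    params <- setNames(pc$coefs, paste0("b", 0:deg))
    fitted <- pc$fitted; rss <- pc$rss
  } else {
    spec <- switch(family,
      power = list(
        xfun = function(t) cbind(1, dose^(1 + exp(t[1]))),
        starts = if (is.null(start)) list(-4, -1, 0, 1) else list(start),
        pack = function(t, cf) c(g = cf[1], b = cf[2], delta = 1 + exp(t[1]))),
      hill = list(
        xfun = function(t) {
          k <- exp(t[1]); nn <- 1 + exp(t[2])
          cbind(1, dose^nn / (k^nn + dose^nn))
        },
        starts = if (is.null(start)) {
          ks <- log(quantile(dpos, c(0.1, 0.5, 0.9), names = FALSE))
          c(lapply(ks, function(k) c(k, log(0.5))),
            lapply(ks, function(k) c(k, log(2))))
        } else list(start),
        pack = function(t, cf) c(g = cf[1], v = cf[2], k = exp(t[1]),
                                 n = 1 + exp(t[2]))),
      exp2 = list(
        xfun = function(t) cbind(exp(t[1] / dmax * dose)),
        starts = if (is.null(start)) list(-3, -0.5, 0.5, 3) else list(start),
        pack = function(t, cf) c(a = cf[1], b = t[1] / dmax)),
      exp3 = list(
        xfun = function(t) {
          s <- sign(t[3]); b <- exp(t[1]); cc <- 1 + exp(t[2])
          cbind(exp(s * (b * dose)^cc))
        },
        starts = if (is.null(start)) {
          bs <- log(1 / c(median(dpos), dmax))
          out <- list()
          for (s in c(-1, 1)) for (b in bs) for (cc in c(0.2, 1))
            out <- c(out, list(c(b, cc, s)))
          out
        } else list(start),
        pack = function(t, cf) c(a = cf[1], b = exp(t[1]), c = 1 + exp(t[2]),
                                 sign = sign(t[3]))),
      exp4 = list(
        xfun = function(t) {
          b <- exp(t[1]); cc <- exp(t[2])
          cbind(cc - (cc - 1) * exp(-b * dose))
        },
        starts = if (is.null(start)) {
          bs <- log(1 / c(median(dpos), dmax))
          out <- list()
          for (b in bs) for (cc in c(log(0.3), log(3))) out <- c(out, list(c(b, cc)))
          out
        } else list(start),
        pack = function(t, cf) c(a = cf[1], b = exp(t[1]), c = exp(t[2]))),
      exp5 = list(
        xfun = function(t) {
          b <- exp(t[1]); cc <- exp(t[2]); g <- 1 + exp(t[3])
          cbind(cc - (cc - 1) * exp(-(b * dose)^g))
        },
        starts = if (is.null(start)) {
          bs <- log(1 / c(median(dpos), dmax))
          out <- list()
          for (b in bs) for (cc in c(log(0.3), log(3))) for (g in c(-1, 0.7))
            out <- c(out, list(c(b, cc, g)))
          out
        } else list(start),
        pack = function(t, cf) c(a = cf[1], b = exp(t[1]), c = exp(t[2]),
                                 g = 1 + exp(t[3])))
    )
    best <- NULL
    for (s0 in spec$starts) {
      s0 <- as.numeric(s0)
      o <- if (length(s0) == 1L) {
        tryCatch({
          op <- optimize(function(t) profile_rss(t, spec$xfun, response),
                         interval = c(s0 - 6, s0 + 6))
          list(par = op$minimum, value = op$objective, convergence = 0)
        }, error = function(e) NULL)
      } else if (family == "exp3") {
        # keep the sign component fixed during optimization
        tryCatch({
          op <- optim(s0[1:2], function(t)
            profile_rss(c(t, s0[3]), spec$xfun, response),
            method = "Nelder-Mead", control = ctrl)
          list(par = c(op$par, s0[3]), value = op$value,
               convergence = op$convergence)
        }, error = function(e) NULL)
      } else {
        tryCatch(optim(s0, function(t) profile_rss(t, spec$xfun, response),
                       method = "Nelder-Mead", control = ctrl),
                 error = function(e) NULL)
      }
      if (!is.null(o) && is.finite(o$value) &&
          (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best) || !is.finite(best$value) || best$value >= 1e299) {
      return(structure(list(family = family, params = NULL, theta = NULL,
                            sigma = NA_real_, loglik = -Inf, aic = Inf,
                            gof_p = NA_real_, fitted = NULL, converged = FALSE,
                            dose = dose, response = response, n = n),
                       class = "drc_fit"))
    }
    theta <- best$par
    converged <- is.null(best$convergence) || best$convergence == 0
    pc <- profile_coefs(theta, spec$xfun, response)
    params <- spec$pack(theta, pc$coefs)
    fitted <- pc$fitted; rss <- pc$rss
  }

  sigma2 <- max(rss / n, 1e-300)
  loglik <- -n / 2 * (log(2 * pi * sigma2) + 1)
  k <- drc_n_params[[family]]
  aic <- 2 * (k + 1) - 2 * loglik
  # goodness of fit vs the cell-means model
  gm <- ave(response, dose)
  rss_full <- sum((response - gm)^2)
  G <- length(unique(dose))
  gof_p <- if (G - k <= 0 || n - G <= 0) NA_real_
  else if (rss_full < 1e-12) { if (rss - rss_full < 1e-10) 1 else 0 }
  else pf(max(rss - rss_full, 0) / (G - k) / (rss_full / (n - G)),
          G - k, n - G, lower.tail = FALSE)
  structure(list(family = family, params = params, theta = theta,
                 sigma = sqrt(rss / max(n - k, 1)), loglik = loglik, aic = aic,
                 gof_p = gof_p, fitted = fitted, converged = converged,
                 dose = dose, response = response, n = n),
            class = "drc_fit")
}

#' @export
print.drc_fit <- function(x, ...) {
  cat(sprintf("Dose-response fit: %s  (AIC %.2f, gof p %.3g)\n", x$family,
              x$aic, x$gof_p))
  if (!is.null(x$params)) print(signif(x$params, 4))
  invisible(x)
}

#' @export
coef.drc_fit <- function(object, ...) object$params

#' @export
predict.drc_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$dose
       else if (is.data.frame(newdata)) newdata$dose else newdata
  predict_drc(object$family, object$params, d)
}

#' @export
residuals.drc_fit <- function(object, ...) object$response - object$fitted

#' Fit all configured model families to one gene
#'
#' @param dose,response Observations.
#' @param cfg A [bmc_config()].
#' @return Named list of `drc_fit` records in `cfg$model_families` order.
#' @export
fit_all_families <- function(dose, response, cfg = bmc_config()) {
  setNames(lapply(cfg$model_families, function(f)
    fit_family(dose, response, f, cfg)), cfg$model_families)
}

#' Select the best model with the Hill-k flag rule
#'
#' Picks the lowest-AIC fit (ties broken by family order, simpler first).
#' If the winner is a Hill fit whose `k` lies below
#' `hill_k_flag_fraction * lowest_positive_dose`, the next-best fit with
#' goodness-of-fit p above `gof_alpha` is taken instead; if none qualifies
#' the flagged Hill is returned with `hill_flagged = TRUE`.
#'
#' @param fits List of `drc_fit` records (see [fit_all_families()]).
#' @param lowest_positive_dose Smallest nonzero tested concentration.
#' @param cfg A [bmc_config()].
#' @return The selected `drc_fit` with logical fields `hill_flagged` and
#'   `selected`; `selection_undefined = TRUE` if nothing converged.
#' @export
select_model <- function(fits, lowest_positive_dose, cfg = bmc_config()) {
  ord <- order(vapply(fits, function(f) f$aic, numeric(1)),
               match(vapply(fits, function(f) f$family, character(1)),
                     cfg$model_families))
  fits <- fits[ord]
  if (!is.finite(fits[[1]]$aic)) {
    out <- fits[[1]]; out$selection_undefined <- TRUE
    out$selected <- FALSE; out$hill_flagged <- FALSE
    return(out)
  }
  best <- fits[[1]]
  flagged <- best$family == "hill" &&
    is.finite(best$aic) &&
    best$params[["k"]] < lowest_positive_dose * cfg$hill_k_flag_fraction
  if (flagged) {
    for (f in fits[-1]) {
      if (is.finite(f$aic) && !is.na(f$gof_p) && f$gof_p > cfg$gof_alpha) {
        f$hill_flagged <- FALSE; f$selected <- TRUE
        f$selection_undefined <- FALSE
        f$note <- "hill winner flagged (k below one-third lowest positive dose); next best by AIC with adequate fit"
        return(f)
      }
    }
    best$hill_flagged <- TRUE; best$selected <- TRUE
    best$selection_undefined <- FALSE
    return(best)
  }
  best$hill_flagged <- FALSE; best$selected <- TRUE
  best$selection_undefined <- FALSE
  best
}

#' Benchmark concentration for a selected fit
#'
#' Finds the smallest positive concentration at which the fitted curve
#' departs from its control value by `bmr_factor * control_sd`, by a
#' monotone-refined grid plus bisection on `[0, max_dose]`. BMDL/BMDU come
#' from a parametric bootstrap (normal residuals, warm-started refits of the
#' same family) at the configured confidence; the reference SD is
#' re-estimated in each draw when it equals the model residual SD.
#'
#' @param fit Selected `drc_fit`.
#' @param control_sd Reference SD defining the benchmark response (the
#'   pipeline passes the model residual SD, per the constant-variance
#'   assumption).
#' @param cfg A [bmc_config()].
#' @param max_dose Highest tested concentration.
#' @param n_boot Bootstrap draws (default `cfg$n_boot`); 0 skips BMDL/BMDU.
#' @param seed Bootstrap seed.
#' @return `fit` augmented with `bmc`, `bmdl`, `bmdu`, `bmr`,
#'   `removed_above_max`.
#' @export
compute_bmc <- function(fit, control_sd, cfg = bmc_config(), max_dose,
                        n_boot = cfg$n_boot, seed = cfg$seed) {
  stopifnot(is.finite(fit$aic))
  target <- cfg$bmr_factor * control_sd
  fit$bmr <- target
  bmc <- bmc_root(fit$family, fit$params, target, max_dose)
  fit$bmc <- bmc
  fit$removed_above_max <- is.na(bmc)
  fit$bmdl <- NA_real_; fit$bmdu <- NA_real_
  if (!is.na(bmc) && n_boot > 0) {
    rescale <- abs(control_sd - fit$sigma) < 1e-12 * max(control_sd, 1)
    set.seed(seed)
    draws <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      yb <- fit$fitted + rnorm(fit$n, 0, fit$sigma)
      rf <- tryCatch(fit_family(fit$dose, yb, fit$family, cfg,
                                start = fit$theta),
                     error = function(e) NULL)
      if (is.null(rf) || !is.finite(rf$aic)) next
      tb <- if (rescale) cfg$bmr_factor * rf$sigma else target
      draws[b] <- bmc_root(rf$family, rf$params, tb, max_dose)
    }
    ok <- draws[!is.na(draws)]
    if (length(ok) >= 10) {
      qs <- quantile(c(ok, bmc), c((1 - cfg$confidence) / 2,
                                   1 - (1 - cfg$confidence) / 2), names = FALSE)
      fit$bmdl <- min(qs[1], bmc)
      fit$bmdu <- max(qs[2], bmc)
    }
    fit$boot_n_ok <- length(ok)
  }
  fit
}

# smallest d in (0, max_dose] with |f(d) - f(0)| = target, or NA
bmc_root <- function(family, params, target, max_dose, n_grid = 400) {
  f0 <- predict_drc(family, params, 0)
  g <- function(d) abs(predict_drc(family, params, d) - f0) - target
  dd <- seq(0, max_dose, length.out = n_grid + 1)
  vals <- g(dd)
  cross <- which(vals[-1] >= 0 & vals[-length(vals)] < 0)
  if (!length(cross)) return(NA_real_)
  i <- cross[1]
  uniroot(g, c(dd[i], dd[i + 1]), tol = max_dose * 1e-10)$root
}

#' Williams-gated benchmark concentration modeling for a gene panel
#'
#' Runs the full per-gene chain: Williams trend gate, ten-family fit, AIC
#' selection with the Hill-k flag rule, and BMC/BMDL/BMDU estimation at
#' BMR `bmr_factor * residual SD`. Genes failing the trend gate are never
#' fitted.
#'
#' @param expr Gene x sample matrix of normalized log2 expression (e.g.
#'   `log2(normalize_counts(counts) + 1)`).
#' @param design Experiment design.
#' @param cfg A [bmc_config()].
#' @param n_boot Bootstrap draws per gene (default `cfg$n_boot`).
#' @return List of class `bmc_results`: `table` (one row per gene: trend p,
#'   selected family, aic, gof p, bmc, bmdl, bmdu, flags) and `records`
#'   (selected `drc_fit` per modeled gene).
#' @export
bmc_pipeline <- function(expr, design, cfg = bmc_config(),
                         n_boot = cfg$n_boot) {
  trend <- williams_trend_matrix(expr, design, cfg,
                                 seed = derive_seed(cfg$seed, "williams"))
  dose <- design$concentration
  max_dose <- max(dose); lpd <- min(dose[dose > 0])
  tab <- data.frame(gene_id = rownames(expr), trend_p = trend$p,
                    trend_direction = trend$direction, passes = trend$passes,
                    family = NA_character_, aic = NA_real_, gof_p = NA_real_,
                    bmc = NA_real_, bmdl = NA_real_, bmdu = NA_real_,
                    hill_flagged = FALSE, removed_above_max = FALSE,
                    stringsAsFactors = FALSE)
  records <- list()
  for (i in which(trend$passes)) {
    fits <- fit_all_families(dose, expr[i, ], cfg)
    sel <- select_model(fits, lpd, cfg)
    if (isTRUE(sel$selection_undefined)) next
    sel <- compute_bmc(sel, sel$sigma, cfg, max_dose, n_boot = n_boot,
                       seed = derive_seed(cfg$seed, rownames(expr)[i]))
    sel$gene_id <- rownames(expr)[i]
    records[[sel$gene_id]] <- sel
    tab$family[i] <- sel$family; tab$aic[i] <- sel$aic
    tab$gof_p[i] <- sel$gof_p; tab$bmc[i] <- sel$bmc
    tab$bmdl[i] <- sel$bmdl; tab$bmdu[i] <- sel$bmdu
    tab$hill_flagged[i] <- isTRUE(sel$hill_flagged)
    tab$removed_above_max[i] <- isTRUE(sel$removed_above_max)
  }
  structure(list(table = tab, records = records, cfg = cfg),
            class = "bmc_results")
}

#' @export
print.bmc_results <- function(x, ...) {
  t <- x$table
  cat(sprintf("BMC modeling: %d genes, %d passed the trend gate, %d with a BMC within the tested range\n",
              nrow(t), sum(t$passes), sum(!is.na(t$bmc))))
  invisible(x)
}

#' Median benchmark concentration of a gene set
#'
#' Medians of BMC, BMDL and BMDU over set members with a defined BMC not
#' removed for exceeding the top concentration.
#'
#' @param bmc_table The `table` element of [bmc_pipeline()] output (or any
#'   data.frame with `gene_id`, `bmc`, `bmdl`, `bmdu`, `removed_above_max`).
#' @param gene_set Character vector of gene ids.
#' @return List: `median_bmc`, `median_bmdl`, `median_bmdu`, `n_modeled`.
#' @export
geneset_bmc <- function(bmc_table, gene_set) {
  rows <- bmc_table[bmc_table$gene_id %in% gene_set & !is.na(bmc_table$bmc) &
                      !bmc_table$removed_above_max, , drop = FALSE]
  if (nrow(rows) == 0) {
    warning("no gene in the set has a defined BMC")
    return(list(median_bmc = NA_real_, median_bmdl = NA_real_,
                median_bmdu = NA_real_, n_modeled = 0L))
  }
  list(median_bmc = median(rows$bmc), median_bmdl = median(rows$bmdl, na.rm = TRUE),
       median_bmdu = median(rows$bmdu, na.rm = TRUE), n_modeled = nrow(rows))
}
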