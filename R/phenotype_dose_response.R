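#' Incidence ("any effect") table from a phenotype screen
#'
#' Computes per-concentration incidence, pooling endpoints into a single
#' "any_effect" endpoint where that is well-defined. Pooling several endpoint
#' rows requires per-animal data (an `animal_id` column with one row per
#' animal x endpoint and a logical/0-1 `affected` column), because an animal
#' hit on two endpoints must be counted once. A table that already carries
#' one row per concentration/group (single endpoint) is passed through with
#' an `incidence` column added.
#'
#' @param pheno Phenotype table (`concentration`, `endpoint`, `group`,
#'   `n_exposed`, `n_affected`) or a per-animal table (`concentration`,
#'   `group`, `animal_id`, `endpoint`, `affected`).
#' @param endpoints_to_pool Endpoints to pool (default: all present).
#' @return Phenotype table with endpoint `"any_effect"` and an `incidence`
#'   column.
#' @export
incidence_table <- function(pheno, endpoints_to_pool = NULL) {
  if ("animal_id" %in% names(pheno)) {
    if (!is.null(endpoints_to_pool))
      pheno <- pheno[pheno$endpoint %in% endpoints_to_pool, , drop = FALSE]
    hit <- aggregate(affected ~ concentration + group + animal_id, data = pheno,
                     FUN = function(a) as.integer(any(a > 0)))
    out <- aggregate(cbind(n_affected = affected) ~ concentration + group,
                     data = hit, FUN = sum)
    n <- aggregate(cbind(n_exposed = animal_id) ~ concentration + group,
                   data = hit, FUN = length)
    out <- merge(out, n, by = c("concentration", "group"))
    out$endpoint <- "any_effect"
  } else {
    if (!is.null(endpoints_to_pool))
      pheno <- pheno[pheno$endpoint %in% endpoints_to_pool, , drop = FALSE]
    eps <- unique(pheno$endpoint)
    if (length(eps) > 1L)
      stop("cannot pool ", length(eps), " endpoints without per-animal data ",
           "(an animal affected on several endpoints would be double-counted); ",
           "provide an `animal_id` column or a pre-pooled table")
    out <- pheno
    out$endpoint <- "any_effect"
  }
  stopifnot(all(out$n_affected >= 0), all(out$n_affected <= out$n_exposed))
  out$incidence <- out$n_affected / out$n_exposed
  out <- out[order(out$group, out$concentration), ]
  rownames(out) <- NULL
  out[, c("concentration", "endpoint", "group", "n_exposed", "n_affected",
          "incidence")]
}

ll_negloglik <- function(par, d, n, y, bg_max) {
  # par = (logit-scaled bg, log ec50, log slope)
  bg <- bg_max * plogis(par[1])
  p <- loglogistic_incidence(d, exp(par[2]), exp(par[3]), bg)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(dbinom(y, n, p, log = TRUE))
}

#' Fit a binomial log-logistic dose-response curve
#'
#' Maximum-likelihood fit of `P(d) = bg + (1 - bg) / (1 + (ec50/d)^h)` to
#' per-concentration affected/exposed counts, with the background bounded to
#' `[0, bg_max]` (screening backgrounds are small) or fixed. A 95%
#' profile-likelihood confidence interval for the EC50 is reported.
#'
#' @param pheno Phenotype table for one endpoint and group (see
#'   [incidence_table()]); needs >= 3 distinct concentrations with exposed
#'   animals.
#' @param fix_background Optional fixed background probability; `NULL`
#'   (default) estimates it.
#' @param bg_max Upper bound on the estimated background (default 0.2).
#' @param conf_level Confidence level for the EC50 profile interval.
#' @return Object of class `loglogistic_fit` with elements `ec50`,
#'   `hill_slope`, `background`, `loglik`, `ec50_ci`, `extrapolated`,
#'   `converged`, and the data used.
#' @examples
#' ph <- simulate_phenotypes(c(0, 1, 5, 20, 35, 50, 65, 100), seed = 7)
#' fit <- fit_loglogistic(ph)
#' coef(fit)
#' @export
fit_loglogistic <- function(pheno, fix_background = NULL, bg_max = 0.2,
                            conf_level = 0.95) {
  pheno <- pheno[pheno$n_exposed > 0, , drop = FALSE]
  d <- pheno$concentration; n <- pheno$n_exposed; y <- pheno$n_affected
  if (length(unique(d)) < 3) stop("need >= 3 distinct concentrations")
  inc <- y / n
  if (max(inc) - min(inc) < 1e-9)
    stop("incidence is constant across concentrations: EC50 is non-identifiable")
  if (all(inc >= 1 - 1e-9) || (max(inc) <= max(0, inc[d == 0]) + 1e-9))
    stop("no partial response above background: EC50 is non-identifiable")

  fixed_bg <- !is.null(fix_background)
  if (fixed_bg) stopifnot(fix_background >= 0, fix_background < 1)
  nll <- if (fixed_bg) {
    function(par) {  # par = (log ec50, log slope)
      p <- loglogistic_incidence(d, exp(par[1]), exp(par[2]), fix_background)
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      -sum(dbinom(y, n, p, log = TRUE))
    }
  } else {
    function(par) ll_negloglik(par, d, n, y, bg_max)
  }
  # crude EC50 start: concentration where incidence crosses halfway
  pos <- d > 0
  half <- min(inc[d == 0], na.rm = TRUE) + 0.5 * (max(inc) - min(inc))
  ec0 <- if (any(pos & inc >= half)) min(d[pos & inc >= half]) else max(d[pos])
  starts <- expand.grid(log_ec = log(ec0 * c(0.5, 1, 2)), log_h = log(c(1, 2, 4)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- if (fixed_bg) c(starts$log_ec[i], starts$log_h[i])
          else c(-3, starts$log_ec[i], starts$log_h[i])
    fit <- tryCatch(optim(p0, nll, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("optimizer failed for every start")
  converged <- best$convergence == 0
  if (fixed_bg) {
    bg <- fix_background; ec50 <- exp(best$par[1]); h <- exp(best$par[2])
  } else {
    bg <- bg_max * plogis(best$par[1]); ec50 <- exp(best$par[2]); h <- exp(best$par[3])
  }
  loglik <- -best$value

  # profile-likelihood CI for ec50
  cut <- qchisq(conf_level, 1) / 2
  prof <- function(log_ec) {
    pnll <- function(par) {
      bgp <- if (fixed_bg) fix_background else bg_max * plogis(par[1])
      hp <- exp(par[length(par)])
      p <- loglogistic_incidence(d, exp(log_ec), hp, bgp)
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      -sum(dbinom(y, n, p, log = TRUE))
    }
    p0 <- if (fixed_bg) log(h) else c(stats::qlogis(min(max(bg / bg_max, 1e-6), 1 - 1e-6)), log(h))
    o <- optim(p0, pnll, method = if (fixed_bg) "Brent" else "Nelder-Mead",
               lower = if (fixed_bg) log(h) - 10 else -Inf,
               upper = if (fixed_bg) log(h) + 10 else Inf,
               control = list(maxit = 1000))
    o$value - best$value - cut
  }
  ci <- c(NA_real_, NA_real_)
  lo_try <- tryCatch({
    lo_br <- log(ec50); step <- 0.25; v <- prof(lo_br - step)
    while (v < 0 && step < 12) { step <- step * 2; v <- prof(lo_br - step) }
    if (v >= 0) exp(uniroot(prof, c(lo_br - step, lo_br), tol = 1e-4)$root) else 0
  }, error = function(e) NA_real_)
  hi_try <- tryCatch({
    hi_br <- log(ec50); step <- 0.25; v <- prof(hi_br + step)
    while (v < 0 && step < 12) { step <- step * 2; v <- prof(hi_br + step) }
    if (v >= 0) exp(uniroot(prof, c(hi_br, hi_br + step), tol = 1e-4)$root) else Inf
  }, error = function(e) NA_real_)
  ci <- c(lo_try, hi_try)

  structure(list(ec50 = ec50, hill_slope = h, background = bg, loglik = loglik,
                 ec50_ci = ci, conf_level = conf_level,
                 extrapolated = ec50 < min(d[pos]) || ec50 > max(d),
                 converged = converged, fixed_background = fixed_bg,
                 data = data.frame(concentration = d, n_exposed = n,
                                   n_affected = y)),
            class = "loglogistic_fit")
}

#' @export
print.loglogistic_fit <- function(x, ...) {
  cat("Binomial log-logistic dose-response fit\n")
  cat(sprintf("  EC50: %.3g uM  (%.0f%% profile CI %.3g - %.3g)%s\n", x$ec50,
              100 * x$conf_level, x$ec50_ci[1], x$ec50_ci[2],
              if (isTRUE(x$extrapolated)) "  [extrapolated]" else ""))
  cat(sprintf("  slope: %.3g   background: %.3g%s   logLik: %.2f\n",
              x$hill_slope, x$background,
              if (x$fixed_background) " (fixed)" else "", x$loglik))
  if (!x$converged) cat("  WARNING: optimizer did not report convergence\n")
  invisible(x)
}

#' @export
coef.loglogistic_fit <- function(object, ...) {
  c(ec50 = object$ec50, hill_slope = object$hill_slope,
    background = object$background)
}

#' @export
logLik.loglogistic_fit <- function(object, ...) {
  structure(object$loglik, df = if (object$fixed_background) 2 else 3,
            class = "logLik")
}

#' @export
predict.loglogistic_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data$concentration
       else if (is.data.frame(newdata)) newdata$concentration else newdata
  loglogistic_incidence(d, object$ec50, object$hill_slope, object$background)
}

#' @export
plot.loglogistic_fit <- function(x, ...) {
  d <- x$data$concentration
  inc <- x$data$n_affected / x$data$n_exposed
  dmin <- min(d[d > 0]) / 2
  grid <- c(0, exp(seq(log(dmin), log(max(d) * 1.2), length.out = 200)))
  plot(pmax(d, dmin / 2), inc, log = "x", xlab = "concentration (uM)",
       ylab = "incidence", ylim = c(0, 1), pch = 19, ...)
  graphics::lines(pmax(grid, dmin / 2), predict(x, grid), col = "firebrick")
  invisible(x)
}

#' @export
simulate.loglogistic_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object)
  n <- object$data$n_exposed
  out <- replicate(nsim, rbinom(length(n), n, p))
  as.data.frame(out)
}

#' Benchmark concentration of a phenotype dose-response
#'
#' Smallest concentration at which the fitted (or ground-truth) incidence
#' curve rises `bmr_added_risk` above its background: the dichotomous
#' added-risk benchmark dose. For the log-logistic family the closed form is
#' `ec50 / ((1 - bg)/bmr - 1)^(1/h)`; a bisection solver is provided as an
#' independent numerical route. BMDL is the lower profile-likelihood bound on
#' the BMC (fits only).
#'
#' @param fit A `loglogistic_fit` or [phenotype_truth()] object.
#' @param bmr_added_risk Added risk over background defining the BMC
#'   (default 0.10).
#' @param method `"closed_form"` (default) or `"bisection"` (relative
#'   tolerance 1e-6).
#' @param conf_level Confidence level for the BMDL (fits only).
#' @return List with `bmc`, `bmdl` (NA for truth objects), `bmr_added_risk`,
#'   `defined`, and the risk convention used (`"added"`).
#' @export
phenotype_bmc <- function(fit, bmr_added_risk = 0.10,
                          method = c("closed_form", "bisection"),
                          conf_level = 0.95) {
  method <- match.arg(method)
  stopifnot(bmr_added_risk > 0, bmr_added_risk < 1)
  ec50 <- fit$ec50; h <- fit$hill_slope; bg <- fit$background
  max_reach <- 1 - bg  # added risk attainable as d -> Inf
  if (bmr_added_risk >= max_reach - 1e-12) {
    return(list(bmc = NA_real_, bmdl = NA_real_, bmr_added_risk = bmr_added_risk,
                defined = FALSE, risk_convention = "added"))
  }
  if (method == "closed_form") {
    bmc <- ec50 / ((1 - bg) / bmr_added_risk - 1)^(1 / h)
  } else {
    f <- function(d) loglogistic_incidence(d, ec50, h, bg) - bg - bmr_added_risk
    hi <- ec50
    while (f(hi) < 0) hi <- hi * 2
    bmc <- uniroot(f, c(0, hi), tol = 1e-10 * ec50)$root
    # polish to 1e-6 relative tolerance by bisection
    lo <- bmc * (1 - 1e-4); hi2 <- bmc * (1 + 1e-4)
    while (f(lo) > 0) lo <- lo * 0.999
    while (f(hi2) < 0) hi2 <- hi2 * 1.001
    while ((hi2 - lo) / lo > 1e-7) {
      mid <- (lo + hi2) / 2
      if (f(mid) < 0) lo <- mid else hi2 <- mid
    }
    bmc <- (lo + hi2) / 2
  }
  bmdl <- NA_real_
  if (inherits(fit, "loglogistic_fit")) {
    # profile the BMC: ec50 is determined by (bmc, bg, h)
    d <- fit$data$concentration; n <- fit$data$n_exposed; y <- fit$data$n_affected
    cut <- qchisq(conf_level, 1) / 2
    prof_bmc <- function(log_bmc) {
      pnll <- function(par) {
        bgp <- 0.2 * plogis(par[1]); hp <- exp(par[2])
        if (bmr_added_risk >= 1 - bgp - 1e-9) return(1e10)
        ecp <- exp(log_bmc) * ((1 - bgp) / bmr_added_risk - 1)^(1 / hp)
        p <- loglogistic_incidence(d, ecp, hp, bgp)
        p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
        -sum(dbinom(y, n, p, log = TRUE))
      }
      o <- optim(c(stats::qlogis(min(max(bg / 0.2, 1e-6), 1 - 1e-6)), log(h)),
                 pnll, method = "Nelder-Mead", control = list(maxit = 1000))
      o$value - (-fit$loglik) - cut
    }
    bmdl <- tryCatch({
      lb <- log(bmc); step <- 0.25; v <- prof_bmc(lb - step)
      while (v < 0 && step < 12) { step <- step * 2; v <- prof_bmc(lb - step) }
      if (v >= 0) exp(uniroot(prof_bmc, c(lb - step, lb), tol = 1e-4)$root) else 0
    }, error = function(e) NA_real_)
    if (is.finite(bmdl) && is.finite(bmc)) bmdl <- min(bmdl, bmc)
  }
  list(bmc = bmc, bmdl = bmdl, bmr_added_risk = bmr_added_risk, defined = TRUE,
       risk_convention = "added")
}
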