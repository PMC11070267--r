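#' Fit a beta "ANOVA": group means with a common precision
#'
#' Maximum-likelihood fit of the mean/precision beta distribution to grouped
#' proportions: each group `g` has its own mean `mu_g` (logit link) and all
#' groups share a precision `phi` (shape parameters `mu_g * phi` and
#' `(1 - mu_g) * phi`). This is the standard beta-regression construction of
#' an ANOVA for proportion data. The likelihood depends on the data only
#' through per-group sufficient statistics (`n`, `sum log y`,
#' `sum log(1 - y)`), so fits are cheap regardless of sample size.
#'
#' Optimization is BFGS with analytic gradients on
#' `(logit mu_1, ..., logit mu_g, log phi)`, multi-started from
#' method-of-moments means and `phi` in `{MoM, 1, 10, 100}`.
#'
#' @param values proportions strictly inside (0, 1); compress first (see
#'   [compress_proportion()]).
#' @param groups group labels, same length as `values`.
#' @return object of class `beta_group_fit`: list with `mu` (named vector),
#'   `phi`, `logLik`, `n` (per group), `df` (free parameters), `converged`.
#' @examples
#' fit_beta_groups(c(0.3, 0.7, 0.4, 0.6), c("a", "a", "b", "b"))
#' @export
fit_beta_groups <- function(values, groups) {
  if (any(is.na(values))) stop("values must not contain NA", call. = FALSE)
  if (any(values <= 0 | values >= 1)) {
    stop("values must lie strictly in (0, 1); compress proportions first ",
         "(see compress_proportion)", call. = FALSE)
  }
  groups <- as.character(groups)
  stopifnot(length(groups) == length(values))
  lev <- sort(unique(groups))
  g <- length(lev)
  idx <- match(groups, lev)
  n_g <- tabulate(idx, g)
  if (any(n_g < 2)) stop("need >= 2 values per group", call. = FALSE)
  s1 <- vapply(seq_len(g), function(k) sum(log(values[idx == k])), numeric(1))
  s2 <- vapply(seq_len(g), function(k) sum(log1p(-values[idx == k])), numeric(1))

  negll <- function(par) {
    mu <- plogis(par[seq_len(g)])
    phi <- exp(par[g + 1])
    a <- mu * phi
    b <- (1 - mu) * phi
    -sum(n_g * (lgamma(phi) - lgamma(a) - lgamma(b)) +
           (a - 1) * s1 + (b - 1) * s2)
  }
  grad <- function(par) {
    mu <- plogis(par[seq_len(g)])
    phi <- exp(par[g + 1])
    a <- mu * phi
    b <- (1 - mu) * phi
    dmu <- phi * (n_g * (digamma(b) - digamma(a)) + s1 - s2)
    deta <- dmu * mu * (1 - mu)
    dphi <- sum(n_g * (digamma(phi) - mu * digamma(a) -
                         (1 - mu) * digamma(b)) + mu * s1 + (1 - mu) * s2)
    -c(deta, dphi * phi)
  }

  # method-of-moments starting values
  m_g <- vapply(seq_len(g), function(k) mean(values[idx == k]), numeric(1))
  v <- stats::var(values - m_g[idx]) * (length(values) - 1) / length(values)
  mbar <- mean(values)
  phi_mom <- max(0.5, mbar * (1 - mbar) / max(v, 1e-6) - 1)
  eta0 <- qlogis(pmin(0.999, pmax(0.001, m_g)))

  best <- NULL
  for (phi0 in unique(c(phi_mom, 1, 10, 100))) {
    fit <- tryCatch(
      optim(c(eta0, log(phi0)), negll, grad, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("beta fit failed from every start", call. = FALSE)
  structure(
    list(
      mu = setNames(plogis(best$par[seq_len(g)]), lev),
      phi = exp(best$par[g + 1]),
      logLik = -best$value,
      n = setNames(n_g, lev),
      df = g + 1,
      converged = best$convergence == 0
    ),
    class = "beta_group_fit"
  )
}

#' @export
print.beta_group_fit <- function(x, ...) {
  cat("<beta_group_fit> ", length(x$mu), " group(s), common precision\n", sep = "")
  cat("  mu:    ", paste0(names(x$mu), "=", signif(x$mu, 4), collapse = " "), "\n")
  cat("  phi:   ", signif(x$phi, 5), "\n")
  cat("  logLik:", signif(x$logLik, 7),
      if (!x$converged) " (NOT converged)" else "", "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a beta group fit
#' @param x a `beta_group_fit`.
#' @param ... unused.
#' @return tibble with one row per group: `group, estimate, n`.
#' @method tidy beta_group_fit
#' @export
tidy.beta_group_fit <- function(x, ...) {
  tibble::tibble(group = names(x$mu), estimate = unname(x$mu),
                 n = unname(x$n))
}

#' One-row summary of a beta group fit
#' @param x a `beta_group_fit`.
#' @param ... unused.
#' @return tibble: `n_groups, phi, logLik, df, converged`.
#' @method glance beta_group_fit
#' @export
glance.beta_group_fit <- function(x, ...) {
  tibble::tibble(n_groups = length(x$mu), phi = x$phi, logLik = x$logLik,
                 df = x$df, converged = x$converged)
}

#' Omnibus likelihood-ratio test for equal group means
#'
#' Compares the full beta model (one mean per group, common precision) with
#' the null model (a single mean) by a likelihood-ratio test:
#' `2 (l_full - l_null)` on `g - 1` degrees of freedom against the
#' chi-squared upper tail.
#'
#' @inheritParams fit_beta_groups
#' @return one-row tibble `statistic, df, p`.
#' @export
omnibus_test <- function(values, groups) {
  full <- fit_beta_groups(values, groups)
  null <- fit_beta_groups(values, rep("all", length(values)))
  stat <- max(0, 2 * (full$logLik - null$logLik))
  df <- length(full$mu) - 1
  tibble::tibble(statistic = stat, df = df,
                 p = pchisq(stat, df, lower.tail = FALSE))
}

#' Pairwise post-hoc beta-ANOVA tests with Holm correction
#'
#' One two-group likelihood-ratio test per unordered pair of groups, with
#' the effect size reported as the difference of the fitted group means
#' (`mu_a - mu_b`, signed; use the absolute value when direction is
#' irrelevant). P-values are Holm-adjusted within the family of all
#' `choose(g, 2)` pairs.
#'
#' @inheritParams fit_beta_groups
#' @param alpha familywise significance level for the `significant` flag.
#' @return tibble `site_a, site_b, effect_size, p_raw, p_holm, significant`,
#'   one row per unordered pair (`site_a < site_b` lexically).
#' @export
pairwise_posthoc <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) < 2) stop("need >= 2 groups", call. = FALSE)
  pairs <- utils::combn(lev, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    sel <- groups %in% c(a, b)
    full <- fit_beta_groups(values[sel], groups[sel])
    null <- fit_beta_groups(values[sel], rep("all", sum(sel)))
    stat <- max(0, 2 * (full$logLik - null$logLik))
    tibble::tibble(
      site_a = a, site_b = b,
      effect_size = unname(full$mu[a] - full$mu[b]),
      p_raw = pchisq(stat, 1, lower.tail = FALSE)
    )
  })
  res$p_holm <- holm_adjust(res$p_raw)
  res$significant <- res$p_holm < alpha
  res
}

#' Holm step-down adjustment
#'
#' Familywise-error control: the i-th smallest p-value is multiplied by
#' `m - i + 1` with monotonicity enforced and capped at 1; original order is
#' restored. Thin wrapper over [stats::p.adjust()] with `method = "holm"`.
#'
#' @param p p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @examples
#' holm_adjust(c(0.01, 0.02, 0.04))
#' @export
holm_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "holm")
}

#' Beta-ANOVA across sites for each diel phase
#'
#' The site-comparison workflow for one measure: per diel phase, take each
#' site's daily proportions, compress them off the \{0, 1\} boundary with
#' `N` = the number of site-days with values for that phase, run the omnibus
#' likelihood-ratio test across all sites, and all pairwise post-hoc tests
#' with Holm correction (family = the pairs within one phase by default; set
#' `holm_family = "pooled"` in the config to adjust across phases).
#'
#' @param daily_props tibble from [daily_proportions()].
#' @param measure `"intensity"` or `"traffic"`.
#' @param config a [dielflux_config()].
#' @param exclude_sites site ids to drop before testing (e.g. sites whose
#'   coverage does not span the analysis period).
#' @param alpha familywise significance level.
#' @return list with tibbles `omnibus` (`measure, phase, statistic, df, p`)
#'   and `posthoc` (`measure, phase, site_a, site_b, effect_size, p_raw,
#'   p_holm, significant`).
#' @export
diel_site_anova <- function(daily_props, measure = c("intensity", "traffic"),
                            config = dielflux_config(),
                            exclude_sites = character(), alpha = 0.05) {
  measure <- match.arg(measure)
  col <- paste0("prop_", measure)
  dat <- daily_props |>
    dplyr::filter(!.data$site_id %in% exclude_sites,
                  !is.na(.data[[col]])) |>
    dplyr::select(site_id = "site_id", phase = "phase",
                  y = dplyr::all_of(col))
  if (length(unique(dat$site_id)) < 2) {
    # nothing to compare (e.g. a single-site network)
    return(list(
      omnibus = tibble::tibble(measure = character(), phase = character(),
                               statistic = numeric(), df = numeric(),
                               p = numeric()),
      posthoc = tibble::tibble(measure = character(), phase = character(),
                               site_a = character(), site_b = character(),
                               effect_size = numeric(), p_raw = numeric(),
                               p_holm = numeric(), significant = logical())
    ))
  }
  phases <- intersect(diel_phase_levels(), unique(dat$phase))
  per_phase <- purrr::map(phases, function(ph) {
    d <- dat[dat$phase == ph, , drop = FALSE]
    y <- compress_proportion(d$y, nrow(d))
    omni <- omnibus_test(y, d$site_id)
    post <- pairwise_posthoc(y, d$site_id, alpha = alpha)
    list(
      omnibus = dplyr::bind_cols(
        tibble::tibble(measure = measure, phase = ph), omni),
      posthoc = dplyr::bind_cols(
        tibble::tibble(measure = measure, phase = ph,
                       .rows = nrow(post)), post)
    )
  })
  posthoc <- purrr::map_dfr(per_phase, "posthoc")
  if (config$holm_family == "pooled") {
    posthoc$p_holm <- holm_adjust(posthoc$p_raw)
    posthoc$significant <- posthoc$p_holm < alpha
  }
  list(omnibus = purrr::map_dfr(per_phase, "omnibus"), posthoc = posthoc)
}
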