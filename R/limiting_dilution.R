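ld_loglik <- function(f, dose, tested, positive) {
  # single-hit binomial log-likelihood; P(positive) = 1 - exp(-f * dose)
  p <- -expm1(-f * dose)
  sum(positive * log(pmax(p, .Machine$double.xmin)) -
        (tested - positive) * f * dose)
}

#' Fit stem-cell frequency from a limiting-dilution table
#'
#' Single-hit Poisson model: a well is positive with probability
#' `1 - exp(-f * dose)`. The MLE of `log f` comes from a binomial GLM with
#' complementary log-log link, `log(dose)` offset and slope fixed at 1; the
#' 95% CI is Wald on the log-f scale, reported in the conventional
#' "1 in N (lower-upper)" form. Tables with all wells positive or all wells
#' negative have no interior MLE and are returned with a boundary flag and
#' a one-sided 95% bound from the exact binomial likelihood.
#'
#' @param table data.frame with columns dose, tested, positive (one group).
#' @return A `FrequencyEstimate`: `f`, `one_in` (= 1/f), `ci_one_in`
#'   (95% CI on N, lower = more frequent), `loglik`, `boundary` flag.
#' @export
fit_frequency <- function(table) {
  stopifnot(all(c("dose", "tested", "positive") %in% names(table)),
            all(table$dose > 0), all(table$positive >= 0),
            all(table$positive <= table$tested))
  if (length(unique(table$dose)) < 2)
    warning("fewer than 2 distinct doses; the single-hit fit is unverifiable")
  dose <- table$dose; tested <- table$tested; positive <- table$positive

  if (sum(positive) == 0) {
    # likelihood is monotone decreasing in f; exact one-sided 95% bound
    f_up <- -log(0.05) / sum(dose * tested)
    return(structure(list(f = 0, one_in = Inf,
                          ci_one_in = c(lower = 1 / f_up, upper = Inf),
                          loglik = 0, boundary = TRUE,
                          boundary_side = "all_negative"),
                     class = "FrequencyEstimate"))
  }
  if (sum(positive) == sum(tested)) {
    # likelihood increases toward f -> Inf; exact one-sided 95% bound
    lo <- stats::uniroot(function(lf)
      sum(tested * log(-expm1(-exp(lf) * dose))) - log(0.05),
      interval = c(-30, 10), tol = 1e-12)$root
    f_lo <- exp(lo)
    return(structure(list(f = Inf, one_in = 0,
                          ci_one_in = c(lower = 0, upper = 1 / f_lo),
                          loglik = 0, boundary = TRUE,
                          boundary_side = "all_positive"),
                     class = "FrequencyEstimate"))
  }
  fit <- stats::glm(cbind(positive, tested - positive) ~ 1,
                    offset = log(dose),
                    family = stats::binomial(link = "cloglog"))
  logf <- unname(stats::coef(fit)[1])
  se <- sqrt(stats::vcov(fit)[1, 1])
  f <- exp(logf)
  ci_f <- exp(logf + c(-1, 1) * stats::qnorm(0.975) * se)
  structure(list(f = f, one_in = 1 / f,
                 ci_one_in = c(lower = 1 / ci_f[2], upper = 1 / ci_f[1]),
                 ci_f = c(lower = ci_f[1], upper = ci_f[2]),
                 se_logf = se,
                 loglik = ld_loglik(f, dose, tested, positive),
                 boundary = FALSE),
            class = "FrequencyEstimate")
}

#' @export
print.FrequencyEstimate <- function(x, ...) {
  if (x$boundary) {
    cat("FrequencyEstimate (boundary:", x$boundary_side, ")\n")
    cat("  one-sided 95% bound on 1/f: [",
        signif(x$ci_one_in[1], 4), ",", signif(x$ci_one_in[2], 4), "]\n")
  } else {
    cat(sprintf("FrequencyEstimate: 1 in %.1f (95%% CI %.1f-%.1f)\n",
                x$one_in, x$ci_one_in[1], x$ci_one_in[2]))
  }
  invisible(x)
}

#' Compare repopulating frequencies between groups
#'
#' Likelihood-ratio test of one pooled frequency against per-group
#' frequencies, chi-squared with (groups - 1) df. If any group sits on the
#' likelihood boundary (all wells positive or negative), the GLM is
#' replaced by direct profile maximization of the single-hit likelihood,
#' with a warning.
#'
#' @param table data.frame with columns group, dose, tested, positive.
#' @return list: `chisq`, `df`, `p`, per-group `estimates`.
#' @export
compare_frequencies <- function(table) {
  stopifnot(all(c("group", "dose", "tested", "positive") %in% names(table)))
  gs <- unique(as.character(table$group))
  if (length(gs) < 2) stop("need at least 2 groups")
  ests <- lapply(gs, function(g) fit_frequency(table[table$group == g, ]))
  names(ests) <- gs
  boundary <- any(vapply(ests, `[[`, logical(1), "boundary"))

  ll_max <- function(sub) {
    if (sum(sub$positive) == 0 || sum(sub$positive) == sum(sub$tested))
      return(0)  # supremum at the boundary
    opt <- stats::optimize(function(lf)
      ld_loglik(exp(lf), sub$dose, sub$tested, sub$positive),
      interval = c(-30, 5), maximum = TRUE)
    opt$objective
  }
  if (boundary) {
    warning("boundary MLE in at least one group; ",
            "using profile-likelihood comparison")
    ll1 <- sum(vapply(gs, function(g) ll_max(table[table$group == g, ]),
                      numeric(1)))
  } else {
    ll1 <- sum(vapply(ests, `[[`, numeric(1), "loglik"))
  }
  ll0 <- ll_max(table)
  if (sum(table$positive) > 0 && sum(table$positive) < sum(table$tested)) {
    # pooled interior MLE: refine with the GLM for accuracy
    fit0 <- stats::glm(cbind(positive, tested - positive) ~ 1,
                       offset = log(dose),
                       family = stats::binomial(link = "cloglog"),
                       data = table)
    ll0 <- ld_loglik(exp(stats::coef(fit0)[1]), table$dose, table$tested,
                     table$positive)
  }
  chisq <- max(0, 2 * (ll1 - ll0))
  df <- length(gs) - 1
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE),
       estimates = ests)
}
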