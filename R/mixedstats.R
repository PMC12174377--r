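# Factorial mixed-model stage: trial-level power with participant random
# intercepts, type-II Wald chi-square term tests, estimated marginal means
# with Bonferroni-corrected contrast families, and sigma-standardised
# effect sizes.

.factor_levels <- list(
  intensity  = c("sham", "0.5", "1.0", "1.5"),
  time_point = c("pre", "post1", "post2"),
  band       = c("theta", "alpha", "beta", "gamma"),
  region     = c("C3", "C4")
)

#' Assemble the tidy modelling table
#'
#' Binds per-dataset trial-power tables (from [aggregate_power()], plus
#' `subject`, `intensity`, `time_point` identifiers) into one long table
#' with fixed factor-level order, and checks the factorial design is
#' complete. The response column `power` is the positive linear-scale
#' value: raw linear power for resting data, baseline-ratio for
#' event-related data, so a log link is valid.
#'
#' @param tables List of data frames; each needs columns `subject`,
#'   `intensity`, `time_point`, `trial`, `region`, `band`, `value_linear`
#'   (and optionally `period`).
#' @param check_cells Require every subject to fill every
#'   intensity x time x band x region cell (default TRUE).
#' @return Long data frame with factor columns and a `power` response.
#' @export
build_long_table <- function(tables, check_cells = TRUE) {
  tab <- do.call(rbind, lapply(tables, function(t) {
    t[, intersect(c("subject", "intensity", "time_point", "trial", "region",
                    "band", "period", "value_db", "value_linear"),
                  names(t)), drop = FALSE]
  }))
  rownames(tab) <- NULL
  for (f in names(.factor_levels)) {
    bad <- setdiff(unique(tab[[f]]), .factor_levels[[f]])
    if (length(bad)) stop("unknown ", f, " level(s): ",
                          paste(bad, collapse = ", "))
    tab[[f]] <- factor(tab[[f]], levels = .factor_levels[[f]])
  }
  tab$subject <- factor(tab$subject)
  tab$power <- tab$value_linear
  if (any(!is.finite(tab$power)) || any(tab$power <= 0))
    stop("response must be strictly positive and finite")
  if (check_cells) {
    present <- unique(tab[, c("subject", "intensity", "time_point",
                              "band", "region")])
    grid <- expand.grid(subject = levels(tab$subject),
                        intensity = droplevels(unique(tab$intensity)),
                        time_point = droplevels(unique(tab$time_point)),
                        band = droplevels(unique(tab$band)),
                        region = droplevels(unique(tab$region)))
    key <- function(d) do.call(paste, c(d, sep = "|"))
    missing <- setdiff(key(grid), key(present))
    if (length(missing)) stop("missing factor cell(s): ",
                              paste(utils::head(missing, 5), collapse = "; "))
  }
  tab
}

#' Fit the trial-level power model
#'
#' Gaussian generalized linear mixed model with a log link and a
#' participant random intercept (the printed model family of the study this
#' package reproduces), fitted with glmmTMB. Per-term type-II Wald
#' chi-square tests are attached. If the log-link fit fails or does not
#' converge -- or when `backend = "lmer_log"` is requested for speed in
#' repeated simulations -- a linear mixed model on `log(power)` is fitted
#' instead and the substitution is recorded in the descriptor.
#'
#' @param table Output of [build_long_table()] (optionally subset, e.g. to
#'   one movement period).
#' @param fixed One-sided formula of fixed effects, default
#'   `~ intensity * time_point * band * region`.
#' @param backend `"glmmTMB"` (Gaussian, log link) or `"lmer_log"`
#'   (LMM on the log response).
#' @return Object of class `power_model_fit`: `fit`, `backend`,
#'   `term_tests` (term, chisq, df, p), `AIC`, `converged`, `sigma`.
#' @export
fit_power_model <- function(table,
                            fixed = ~ intensity * time_point * band * region,
                            backend = c("glmmTMB", "lmer_log")) {
  backend <- match.arg(backend)
  table <- droplevels(table)
  if (nlevels(table$subject) < 2)
    stop("at least 2 subjects are required")
  rhs <- paste(deparse(fixed[[2]]), collapse = " ")
  fit <- NULL
  converged <- FALSE
  if (backend == "glmmTMB") {
    form <- stats::as.formula(paste("power ~", rhs, "+ (1 | subject)"))
    fit <- tryCatch(
      glmmTMB::glmmTMB(form, data = table,
                       family = stats::gaussian(link = "log")),
      error = function(e) NULL)
    if (!is.null(fit)) {
      converged <- isTRUE(fit$sdr$pdHess) && fit$fit$convergence == 0
    }
    if (is.null(fit) || !converged) {
      tb_log("log-link GLMM failed or did not converge; using lmer on log response")
      backend <- "lmer_log"
    }
  }
  if (backend == "lmer_log") {
    form <- stats::as.formula(paste("log(power) ~", rhs, "+ (1 | subject)"))
    fit <- lme4::lmer(form, data = table, REML = FALSE)
    converged <- length(fit@optinfo$conv$lme4) == 0
  }
  an <- car::Anova(fit, type = "II")
  term_tests <- data.frame(term = rownames(an),
                           chisq = an[["Chisq"]],
                           df = an[["Df"]],
                           p = an[["Pr(>Chisq)"]],
                           stringsAsFactors = FALSE)
  structure(list(fit = fit, backend = backend, fixed = rhs,
                 family = if (backend == "glmmTMB") "gaussian(log)" else
                   "lmm(log response)",
                 term_tests = term_tests,
                 AIC = tryCatch(stats::AIC(fit), error = function(e) NA_real_),
                 converged = converged,
                 sigma = stats::sigma(fit)),
            class = "power_model_fit")
}

#' @export
print.power_model_fit <- function(x, ...) {
  cat(sprintf("<power_model_fit> %s, power ~ %s; AIC %.1f, converged: %s\n",
              x$family, x$fixed, x$AIC, x$converged))
  print(x$term_tests, digits = 3)
  invisible(x)
}

.emm_args <- function(fit) {
  if (fit$backend == "lmer_log") list(lmer.df = "asymptotic") else list()
}

#' Bonferroni-corrected marginal-mean contrast families
#'
#' Pairwise comparisons between estimated marginal means on the link
#' scale, Bonferroni-adjusted within the requested family, with asymptotic
#' z tests and sigma-standardised effect sizes `d = estimate / sigma(fit)`.
#' Because baseline power can differ between stimulation intensities,
#' intensities are never compared directly: the `intensity_change_scores`
#' family compares each intensity against sham on the *change* between two
#' time points (interaction contrasts).
#'
#' @param fit A [fit_power_model()] object.
#' @param family One of `"time_within_intensity"` (pairwise time changes
#'   within each intensity), `"intensity_change_scores"` (time-change
#'   scores, each intensity vs sham), `"region_by_time"` (pairwise region
#'   within each time point).
#' @return Data frame with `family`, `contrast`, grouping columns,
#'   `estimate` (link scale), `se`, `z`, `p_raw`, `p_adj`, `d`.
#' @export
marginal_contrasts <- function(fit,
                               family = c("time_within_intensity",
                                          "intensity_change_scores",
                                          "region_by_time")) {
  family <- match.arg(family)
  stopifnot(inherits(fit, "power_model_fit"))
  ea <- .emm_args(fit)
  mk <- function(specs) do.call(emmeans::emmeans,
                                c(list(fit$fit, specs = specs), ea))
  ct <- switch(family,
    time_within_intensity = emmeans::contrast(
      mk(~ time_point | intensity), method = "pairwise", adjust = "none"),
    intensity_change_scores = emmeans::contrast(
      mk(~ intensity * time_point),
      interaction = list(time_point = "pairwise", intensity = "trt.vs.ctrl"),
      adjust = "none"),
    region_by_time = emmeans::contrast(
      mk(~ region | time_point), method = "pairwise", adjust = "none")
  )
  raw <- as.data.frame(summary(ct, adjust = "none", infer = c(FALSE, TRUE)))
  k <- nrow(raw)
  pcol <- names(raw)[grepl("p\\.value", names(raw))][1]
  zcol <- if ("z.ratio" %in% names(raw)) "z.ratio" else "t.ratio"
  ccol <- intersect(c("contrast", "time_point_pairwise", "intensity_trt.vs.ctrl"),
                    names(raw))
  contrast_lab <- do.call(paste, c(raw[, ccol, drop = FALSE], sep = " : "))
  group_cols <- setdiff(names(raw),
                        c(ccol, "estimate", "SE", "df", zcol, pcol,
                          "null", "lower.CL", "upper.CL", "asymp.LCL",
                          "asymp.UCL"))
  out <- data.frame(family = family, contrast = contrast_lab,
                    stringsAsFactors = FALSE)
  for (g in group_cols) out[[g]] <- raw[[g]]
  out$estimate <- raw$estimate
  out$se <- raw$SE
  out$z <- raw[[zcol]]
  out$p_raw <- raw[[pcol]]
  out$p_adj <- pmin(1, out$p_raw * k)
  out$d <- out$estimate / fit$sigma
  out
}
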