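#' Stack a wide outcome table into long repeated-measures form
#'
#' Band-wise audiological measurements on the same subject are repeated
#' measures; the long form has one row per subject x band, with the band
#' kept as a categorical label and per-subject covariates joined on.
#'
#' @param outcome Wide tibble: `subject` plus one numeric column per band.
#' @param covariates Tibble with `subject` plus covariate columns
#'   (normalized microRNA levels, genotype factors, ...).
#' @return Long tibble: `subject`, `band` (factor in band order), `value`,
#'   covariates.
#' @export
stack_long <- function(outcome, covariates = NULL) {
  stopifnot("subject" %in% names(outcome))
  if (anyDuplicated(outcome$subject)) {
    abort("duplicated subject x band rows in the outcome table")
  }
  bands <- setdiff(names(outcome), "subject")
  long <- outcome %>%
    tidyr::pivot_longer(-"subject", names_to = "band", values_to = "value") %>%
    mutate(band = factor(.data$band, levels = bands))
  if (!is.null(covariates)) {
    stopifnot("subject" %in% names(covariates))
    if (anyDuplicated(covariates$subject)) {
      abort("duplicated subject rows in the covariate table")
    }
    long <- left_join(long, covariates, by = "subject")
  }
  long
}

significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "n.s."
  )
}

#' Band-wise mixed-effects association between an outcome and a microRNA
#'
#' Fits a single linear mixed model per (outcome, microRNA) pair:
#' `value ~ 0 + band + band:mirna + (1 | subject)`, i.e. a band-specific
#' intercept and a band-specific microRNA slope, with a subject random
#' intercept for the repeated measures across bands, fitted by REML.  The
#' per-band slopes reproduce the shape of a band-by-band analysis while
#' honouring the within-subject correlation.  Satterthwaite p values are
#' attached via lmerTest.  A per-band fixed-effects fallback (`per_band =
#' TRUE`) fits an ordinary regression in each band instead.
#'
#' @param data Long tibble from [stack_long()].
#' @param mirna Name of the covariate column holding the microRNA level.
#' @param per_band Fit independent per-band ordinary least squares models
#'   instead of the mixed model.
#' @param extra_terms Character vector of additional fixed-effect columns
#'   (used by [fit_genotype_model()]).
#' @return An object of class `band_fit`; use [tidy()] for the per-band
#'   coefficient report (`band`, `term`, `beta`, `se`, `p`, `stars`) and
#'   [glance()] for fit-level diagnostics (including singular-fit status).
#' @export
fit_band_models <- function(data, mirna, per_band = FALSE,
                            extra_terms = character()) {
  stopifnot(all(c("subject", "band", "value") %in% names(data)))
  if (!mirna %in% names(data)) {
    abort(sprintf("covariate column `%s` not found", mirna))
  }
  if (dplyr::n_distinct(data$band) < 2L) abort("need at least 2 bands")
  if (dplyr::n_distinct(data$subject) < 5L) abort("need at least 5 subjects")
  if (sd(data[[mirna]], na.rm = TRUE) == 0) {
    abort(sprintf("covariate `%s` is constant: slope inestimable", mirna))
  }

  mv <- paste0("`", mirna, "`")
  extra <- if (length(extra_terms) > 0) {
    paste("+", paste(extra_terms, collapse = " + "))
  } else ""

  if (per_band) {
    reports <- purrr::map_dfr(levels(droplevels(factor(data$band))),
                              function(b) {
      sub <- data[data$band == b, ]
      f <- stats::as.formula(paste("value ~", mv, extra))
      fit <- lm(f, data = sub)
      cf <- summary(fit)$coefficients
      rows <- rownames(cf) != "(Intercept)"
      tibble(
        band = b, term = rownames(cf)[rows],
        beta = cf[rows, 1], se = cf[rows, 2], p = cf[rows, 4]
      )
    })
    reports <- mutate(reports,
                      term = gsub("`", "", .data$term),
                      stars = significance_stars(.data$p))
    return(new_band_fit(reports, model = NULL, mirna = mirna,
                        singular = FALSE, per_band = TRUE))
  }

  f <- stats::as.formula(
    paste("value ~ 0 + band + band:", mv, extra, "+ (1 | subject)")
  )
  fit <- lmerTest::lmer(f, data = data, REML = TRUE,
                        control = lme4::lmerControl(
                          check.conv.singular = "ignore",
                          calc.derivs = FALSE
                        ))
  singular <- lme4::isSingular(fit)
  cf <- stats::coef(summary(fit))
  keep <- grepl(":", rownames(cf), fixed = TRUE) |
    (length(extra_terms) > 0 &
       Reduce(`|`, lapply(extra_terms, function(t)
         startsWith(rownames(cf), t)), rep(FALSE, nrow(cf))))
  cf <- cf[keep, , drop = FALSE]
  term <- gsub("`", "", rownames(cf))
  band <- ifelse(
    grepl("^band", term) & grepl(":", term),
    sub("^band([^:]*):.*$", "\\1", term),
    NA_character_
  )
  term <- sub("^band[^:]*:", "", term)
  reports <- tibble(
    band = band, term = term,
    beta = unname(cf[, "Estimate"]), se = unname(cf[, "Std. Error"]),
    p = unname(cf[, "Pr(>|t|)"])
  ) %>% mutate(stars = significance_stars(.data$p))
  new_band_fit(reports, model = fit, mirna = mirna,
               singular = singular, per_band = FALSE)
}

new_band_fit <- function(report, model, mirna, singular, per_band) {
  structure(
    list(report = report, model = model, mirna = mirna,
         singular = singular, per_band = per_band),
    class = "band_fit"
  )
}

#' @export
print.band_fit <- function(x, ...) {
  cat(sprintf("<band_fit> %s model for `%s`%s\n",
              if (x$per_band) "per-band OLS" else "mixed-effects",
              x$mirna,
              if (x$singular) " [singular random-effects fit]" else ""))
  print(x$report)
  invisible(x)
}

#' @export
#' @rdname fit_band_models
#' @param x A `band_fit`.
#' @param ... Unused.
tidy.band_fit <- function(x, ...) x$report

#' @export
#' @rdname fit_band_models
glance.band_fit <- function(x, ...) {
  tibble(
    mirna = x$mirna,
    per_band = x$per_band,
    singular = x$singular,
    n_terms = nrow(x$report),
    sigma = if (is.null(x$model)) NA_real_ else stats::sigma(x$model),
    random_intercept_sd = if (is.null(x$model)) NA_real_ else {
      vc <- as.data.frame(lme4::VarCorr(x$model))
      vc$sdcor[vc$grp == "subject"][1]
    }
  )
}

#' Forest plot of per-band slopes
#'
#' @param object A `band_fit`.
#' @param ... Unused.
#' @export
autoplot.band_fit <- function(object, ...) {
  rep <- object$report %>% filter(!is.na(.data$band))
  ggplot2::ggplot(rep, ggplot2::aes(x = .data$band, y = .data$beta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$beta - 2 * .data$se, ymax = .data$beta + 2 * .data$se
    )) +
    ggplot2::labs(
      x = "frequency band", y = "slope (dB per unit covariate)",
      title = sprintf("Band-wise association with %s", object$mirna)
    ) +
    ggplot2::theme_minimal()
}

#' Mixed-effects association with a genotype factor
#'
#' Adds a base-excision-repair genotype to the fixed effects of the
#' band-wise mixed model, either at variant level (wt/het/mut, reference
#' `ref`, coefficients labelled e.g. `hOGG1mut`, `hOGG1wt`) or pooled into
#' two groups (`grouping = "hOGG1"` pools het+mut vs wt; `grouping =
#' "XRCC1"` pools wt+mut vs het).  Coefficients with p >= 0.05 are starred
#' `"n.s."`.
#'
#' @inheritParams fit_band_models
#' @param genotype Name of the genotype column in `data`.
#' @param grouping `"levels"` (default), `"hOGG1"` or `"XRCC1"` pooling.
#' @param ref Reference level for `grouping = "levels"` (default `"het"`,
#'   so wt and mut effects are reported against it).
#' @return A `band_fit`.
#' @export
fit_genotype_model <- function(data, mirna, genotype = "hOGG1",
                               grouping = c("levels", "hOGG1", "XRCC1"),
                               ref = "het", per_band = FALSE) {
  grouping <- match.arg(grouping)
  if (!genotype %in% names(data)) {
    abort(sprintf("genotype column `%s` not found", genotype))
  }
  g <- factor(data[[genotype]])
  g <- droplevels(g)
  if (grouping == "hOGG1") {
    g <- factor(ifelse(g == "wt", "wt", "mut_het"),
                levels = c("wt", "mut_het"))
  } else if (grouping == "XRCC1") {
    g <- factor(ifelse(g == "het", "het", "wt_mut"),
                levels = c("wt_mut", "het"))
  } else {
    if (!ref %in% levels(g)) {
      abort(sprintf("genotype level `%s` has no subjects", ref))
    }
    g <- stats::relevel(g, ref = ref)
  }
  if (nlevels(g) < 2L) {
    abort("genotype factor has a single level: every subject identical")
  }
  data[[genotype]] <- g
  fit_band_models(data, mirna, per_band = per_band, extra_terms = genotype)
}
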