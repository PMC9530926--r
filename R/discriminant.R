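#' Dichotomize subjects into two groups
#'
#' Splits the cohort either on an audiological summary (mean hearing level
#' across the 11 audiometric frequencies, impaired when strictly above 29
#' dB HL; or mean DPOAE level across the bands, impaired when strictly
#' below 16 dB EPL -- boundary values go to the normal group) or on a
#' genotype pooling (hOGG1: wt vs mut+het; XRCC1: wt+mut vs het).
#'
#' @param subjects Subject tibble (needs `id`, and the genotype columns for
#'   the genotype bases).
#' @param basis One of `"HL_mean"`, `"DPOAE_mean"`, `"hOGG1"`, `"XRCC1"`.
#' @param hl,dpoae Wide audiology tibbles (`subject` + band columns); the
#'   one matching `basis` is required.
#' @param threshold Dichotomy threshold; defaults 29 dB HL / 16 dB EPL.
#' @return Tibble `subject`, `basis`, `value` (the summary, `NA` for
#'   genotype bases), `label`, `threshold`.  Warns when a group is empty.
#' @export
dichotomize <- function(subjects,
                        basis = c("HL_mean", "DPOAE_mean", "hOGG1", "XRCC1"),
                        hl = NULL, dpoae = NULL, threshold = NULL) {
  basis <- match.arg(basis)
  if (basis %in% c("HL_mean", "DPOAE_mean")) {
    tab <- if (basis == "HL_mean") hl else dpoae
    if (is.null(tab)) {
      abort(sprintf("basis `%s` needs the corresponding audiology table", basis))
    }
    missing <- setdiff(subjects$id, tab$subject)
    if (length(missing) > 0L) {
      abort(sprintf("missing audiology for subject(s): %s",
                    paste(missing, collapse = ", ")))
    }
    tab <- tab[match(subjects$id, tab$subject), ]
    value <- rowMeans(as.matrix(tab[setdiff(names(tab), "subject")]))
    if (basis == "HL_mean") {
      threshold <- threshold %||% 29
      label <- ifelse(value > threshold, "impaired", "normal")
    } else {
      threshold <- threshold %||% 16
      label <- ifelse(value < threshold, "impaired", "normal")
    }
  } else {
    g <- as.character(subjects[[basis]])
    value <- rep(NA_real_, nrow(subjects))
    threshold <- threshold %||% NA_real_
    label <- if (basis == "hOGG1") {
      ifelse(g == "wt", "wt", "mut_het")
    } else {
      ifelse(g == "het", "het", "wt_mut")
    }
  }
  if (dplyr::n_distinct(label) < 2L) {
    warn(sprintf("dichotomization on `%s` produced an empty group (all `%s`)",
                 basis, label[1]))
  }
  tibble(subject = subjects$id, basis = basis, value = value,
         label = label, threshold = threshold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sparse PLS discriminant analysis
#'
#' Supervised projection discriminating two groups while selecting at most
#' `keep` variables per component.  The response is the centred +1/-1 group
#' dummy; per component the weight vector `w = X'y` is hard-thresholded to
#' its `keep` largest-magnitude entries, normalised, and the data deflated
#' by regression on the component score before the next component.
#' Variables are centred and (by default) unit-scaled first.  The sign of
#' each component is fixed by forcing its largest-magnitude weight
#' positive, so the fit is deterministic given the input.
#'
#' With `keep` equal to the number of variables the first component
#' coincides with classical PLS-DA.
#'
#' @param x Numeric matrix or data frame, subjects x variables.
#' @param labels Two-level factor/character of group labels, length
#'   `nrow(x)`; both groups need at least 2 subjects.
#' @param n_components Number of components (default 2).
#' @param keep Maximum nonzero weights per component (default 5).
#' @param scale Unit-scale variables (default `TRUE`).
#' @return An object of class `spls_model` with weights, loadings, scores,
#'   selected variables per component, the unit group-centroid
#'   discrimination direction in score space, and variable--score
#'   correlations.  See [tidy.spls_model()], [biplot_tables()],
#'   [autoplot.spls_model()].
#' @export
fit_spls_da <- function(x, labels, n_components = 2L, keep = 5L,
                        scale = TRUE) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  labels <- factor(labels)
  if (nlevels(labels) != 2L) abort("labels must have exactly two levels")
  if (any(table(labels) < 2L)) abort("each group needs at least 2 subjects")
  if (keep > ncol(x)) abort("keep exceeds the number of variables")
  if (nrow(x) != length(labels)) abort("labels must match rows of x")

  keep_sd <- apply(x, 2, sd)
  if (any(keep_sd == 0)) {
    warn(sprintf("dropping constant variable(s): %s",
                 paste(colnames(x)[keep_sd == 0], collapse = ", ")))
    x <- x[, keep_sd > 0, drop = FALSE]
  }
  x0 <- base::scale(x, center = TRUE, scale = scale)
  y <- ifelse(labels == levels(labels)[2], 1, -1)
  y <- y - mean(y)

  p <- ncol(x0)
  h_max <- as.integer(n_components)
  comp_names <- paste0("comp", seq_len(h_max))
  weights <- matrix(0, p, h_max, dimnames = list(colnames(x0), comp_names))
  loadings <- matrix(0, p, h_max, dimnames = list(colnames(x0), comp_names))
  scores <- matrix(0, nrow(x0), h_max,
                   dimnames = list(rownames(x), comp_names))
  selected <- vector("list", h_max)

  e <- x0
  f <- y
  for (h in seq_len(h_max)) {
    w <- drop(crossprod(e, f))
    if (all(abs(w) < 1e-12)) {
      abort(sprintf("component %d is degenerate: no residual covariance", h))
    }
    ord <- order(abs(w), decreasing = TRUE)
    w[-ord[seq_len(keep)]] <- 0
    if (w[ord[1]] < 0) w <- -w  # sign convention
    w <- w / sqrt(sum(w^2))
    t_h <- drop(e %*% w)
    tt <- sum(t_h^2)
    p_h <- drop(crossprod(e, t_h)) / tt
    c_h <- sum(f * t_h) / tt
    e <- e - tcrossprod(t_h, p_h)
    f <- f - t_h * c_h
    weights[, h] <- w
    loadings[, h] <- p_h
    scores[, h] <- t_h
    selected[[h]] <- colnames(x0)[w != 0]
  }

  centroids <- rbind(
    colMeans(scores[labels == levels(labels)[1], , drop = FALSE]),
    colMeans(scores[labels == levels(labels)[2], , drop = FALSE])
  )
  rownames(centroids) <- levels(labels)
  dir <- centroids[2, ] - centroids[1, ]
  dir <- dir / sqrt(sum(dir^2))

  structure(
    list(
      weights = weights, loadings = loadings, scores = scores,
      selected = selected, labels = labels, levels = levels(labels),
      direction = dir, centroids = centroids,
      var_cor = suppressWarnings(cor(x0, scores)),
      explained = apply(scores, 2, var) / sum(apply(x0, 2, var)),
      keep = keep, n_components = h_max, scaled = scale
    ),
    class = "spls_model"
  )
}

#' @export
print.spls_model <- function(x, ...) {
  cat(sprintf(
    "<spls_model> %d components, keep = %d, groups %s (n = %s)\n",
    x$n_components, x$keep, paste(x$levels, collapse = " vs "),
    paste(table(x$labels), collapse = "/")
  ))
  for (h in seq_len(x$n_components)) {
    cat(sprintf("  comp%d: %s\n", h, paste(x$selected[[h]], collapse = ", ")))
  }
  invisible(x)
}

#' Tidy / glance methods for sparse PLS-DA fits
#'
#' `tidy()` returns the sparse weights and loadings in long form (one row
#' per variable x component, zero weights dropped); `glance()` one-row fit
#' summary.
#'
#' @param x An `spls_model`.
#' @param ... Unused.
#' @export
tidy.spls_model <- function(x, ...) {
  as_tibble(x$weights, rownames = "variable") %>%
    setNames(c("variable", paste0("comp", seq_len(x$n_components)))) %>%
    tidyr::pivot_longer(-"variable", names_to = "component",
                        values_to = "weight") %>%
    filter(.data$weight != 0) %>%
    arrange(.data$component, desc(abs(.data$weight)))
}

#' @export
#' @rdname tidy.spls_model
glance.spls_model <- function(x, ...) {
  tibble(
    n = length(x$labels), n_variables = nrow(x$weights),
    n_components = x$n_components, keep = x$keep,
    explained_comp1 = unname(x$explained[1]),
    group_a = x$levels[1], group_b = x$levels[2]
  )
}

#' Plotting-ready biplot tables from a sparse PLS-DA fit
#'
#' Returns the case coordinates in the plane of the first two components,
#' the variable arrows (correlation of each original variable with the two
#' score axes, kept when the correlation-vector norm strictly exceeds
#' `corr_cutoff`), and the unit direction of maximal discrimination (from
#' the first-group centroid to the second-group centroid in score space).
#'
#' @param model An [fit_spls_da()] result with at least 2 components.
#' @param corr_cutoff Correlation filter for the arrows (default 0.75; use
#'   0 to show all variables).
#' @return List of tibbles `cases` (`subject`, `comp1`, `comp2`, `label`),
#'   `arrows` (`variable`, `cor1`, `cor2`, `cor_norm`), `direction`
#'   (`comp1`, `comp2`).
#' @export
biplot_tables <- function(model, corr_cutoff = 0.75) {
  stopifnot(inherits(model, "spls_model"))
  if (model$n_components < 2L) abort("need at least 2 components for a biplot")
  cases <- tibble(
    subject = rownames(model$scores) %||% as.character(seq_along(model$labels)),
    comp1 = model$scores[, 1], comp2 = model$scores[, 2],
    label = as.character(model$labels)
  )
  vc <- model$var_cor[, 1:2, drop = FALSE]
  arrows <- tibble(
    variable = rownames(vc), cor1 = vc[, 1], cor2 = vc[, 2],
    cor_norm = sqrt(vc[, 1]^2 + vc[, 2]^2)
  ) %>%
    filter(!is.na(.data$cor_norm), .data$cor_norm > corr_cutoff) %>%
    arrange(desc(.data$cor_norm))
  direction <- tibble(comp1 = model$direction[1], comp2 = model$direction[2])
  list(cases = cases, arrows = arrows, direction = direction)
}

#' Biplot of a sparse PLS-DA fit
#'
#' Cases in the plane of the first two components, coloured by group, with
#' high-correlation variable arrows and the direction of maximal
#' discrimination.
#'
#' @param object An `spls_model`.
#' @param corr_cutoff Arrow filter passed to [biplot_tables()].
#' @param ... Unused.
#' @export
autoplot.spls_model <- function(object, corr_cutoff = 0.75, ...) {
  tabs <- biplot_tables(object, corr_cutoff = corr_cutoff)
  r <- max(abs(c(tabs$cases$comp1, tabs$cases$comp2)))
  arr <- mutate(tabs$arrows, x = .data$cor1 * r, y = .data$cor2 * r)
  ggplot2::ggplot(tabs$cases,
                  ggplot2::aes(x = .data$comp1, y = .data$comp2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label), size = 2) +
    ggplot2::geom_segment(
      data = arr, colour = "black",
      ggplot2::aes(x = 0, y = 0, xend = .data$x, yend = .data$y),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
    ) +
    ggplot2::geom_text(data = arr, ggplot2::aes(
      x = .data$x * 1.08, y = .data$y * 1.08, label = .data$variable
    ), size = 2.8) +
    ggplot2::geom_segment(
      data = tabs$direction, colour = "blue",
      ggplot2::aes(x = 0, y = 0, xend = .data$comp1 * r,
                   yend = .data$comp2 * r),
      arrow = ggplot2::arrow(length = ggplot2::unit(3, "mm"))
    ) +
    ggplot2::labs(x = "component 1", y = "component 2", colour = NULL) +
    ggplot2::theme_minimal()
}
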