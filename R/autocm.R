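#' Scale variables to [0, 1] and append their complements
#'
#' Prepares a mixed table for auto contractive map training: genotype
#' (factor/character) columns become per-variant indicator columns, every
#' variable is min--max scaled to `[0, 1]`, constant variables are dropped
#' with a warning, and for each scaled variable `x` both `Max_x` (= scaled
#' value) and `Min_x` (= 1 - scaled value) enter the dataset, so that
#' `Max_x + Min_x = 1` exactly per record.  Variable names are sanitised to
#' alphanumerics and underscores (`hsa-miR-122-5p` becomes
#' `Max_hsa_miR_122_5p`).
#'
#' @param data Data frame / tibble, records x variables (numeric, factor or
#'   character columns; an `id`/`subject` column is used for record names).
#' @param provenance Optional named character vector tagging original
#'   variables (`microRNA`, `HL`, `DPOAE`, `polymorphism`, `exposure`).
#' @return An object of class `scaled_dataset`: list with `data` (records x
#'   2p matrix in `[0, 1]`) and `meta` (tibble `variable`, `base`, `kind`,
#'   `provenance`).
#' @export
scale_with_complements <- function(data, provenance = NULL) {
  data <- as.data.frame(data)
  ids <- NULL
  for (idcol in c("id", "subject")) {
    if (idcol %in% names(data)) {
      ids <- as.character(data[[idcol]])
      data[[idcol]] <- NULL
      break
    }
  }
  # expand categorical columns into per-variant indicators
  out_cols <- list()
  prov <- character()
  for (nm in names(data)) {
    col <- data[[nm]]
    tag <- if (!is.null(provenance) && nm %in% names(provenance)) {
      provenance[[nm]]
    } else NA_character_
    if (is.numeric(col)) {
      out_cols[[nm]] <- col
      prov[nm] <- tag
    } else {
      col <- factor(col)
      for (lv in levels(col)) {
        key <- paste0(nm, "_", lv)
        out_cols[[key]] <- as.numeric(col == lv)
        prov[key] <- if (is.na(tag)) "polymorphism" else tag
      }
    }
  }
  mat <- do.call(cbind, out_cols)
  rng <- apply(mat, 2, range)
  const <- rng[1, ] == rng[2, ]
  if (any(const)) {
    warn(sprintf("dropping constant variable(s): %s",
                 paste(colnames(mat)[const], collapse = ", ")))
    mat <- mat[, !const, drop = FALSE]
    prov <- prov[!const]
    rng <- rng[, !const, drop = FALSE]
  }
  if (ncol(mat) == 0L) abort("no non-constant variables to scale")
  scaled <- sweep(sweep(mat, 2, rng[1, ]), 2, rng[2, ] - rng[1, ], `/`)

  base <- gsub("[^[:alnum:]]+", "_", colnames(mat))
  both <- cbind(scaled, 1 - scaled)
  colnames(both) <- c(paste0("Max_", base), paste0("Min_", base))
  rownames(both) <- ids %||% as.character(seq_len(nrow(both)))
  kind <- rep(c("Max", "Min"), each = length(base))
  meta <- tibble(
    variable = colnames(both),
    base = rep(base, 2),
    kind = kind,
    provenance = rep(unname(prov), 2)
  )
  structure(list(data = both, meta = meta), class = "scaled_dataset")
}

#' Train an auto contractive map
#'
#' Three-layer unsupervised network whose trained hidden-to-output
#' connection matrix encodes the pairwise association strength between
#' variables.  Each record `m` (entries in `[0, 1]`) is presented once per
#' epoch; with contraction constant `C`:
#' \deqn{h_i = m_i (1 - v_i/C), \quad \Delta v_i = (m_i - h_i)(1 - v_i/C)}
#' \deqn{Net_j = \sum_i h_i (1 - W_{ij}/C), \quad out_j = h_j (1 - Net_j/C)}
#' \deqn{\Delta W_{ij} = (h_i - out_i)(1 - W_{ij}/C)\, h_j}
#' Training stops when the mean absolute weight update over an epoch drops
#' below `tol` or after `max_epochs`.  For non-negative inputs all weights
#' grow monotonically and stay in `[0, C)`.
#'
#' @param scaled A [scale_with_complements()] result, or a numeric matrix
#'   with entries in `[0, 1]`.
#' @param C Contraction constant (> 0); defaults to the number of records.
#' @param max_epochs,tol Stopping rule.
#' @param init Initial value of all weights (default `C / 1e6`, so early
#'   updates follow raw co-activation).
#' @return An object of class `autocm_model`: mono-connection weights `v`,
#'   full-connection matrix `W`, `C`, `epochs`, per-epoch `history` of mean
#'   absolute updates, variable names and metadata.
#' @export
train_autocm <- function(scaled, C = NULL, max_epochs = 200L, tol = 1e-6,
                         init = NULL) {
  meta <- NULL
  if (inherits(scaled, "scaled_dataset")) {
    meta <- scaled$meta
    scaled <- scaled$data
  }
  scaled <- as.matrix(scaled)
  if (any(!is.finite(scaled)) || any(scaled < 0) || any(scaled > 1)) {
    abort("training data must lie in [0, 1]")
  }
  n <- nrow(scaled)
  p <- ncol(scaled)
  C <- C %||% n
  if (C <= 0) abort("contraction constant C must be positive")
  init <- init %||% (C / 1e6)

  v <- rep(init, p)
  W <- matrix(init, p, p, dimnames = list(colnames(scaled), colnames(scaled)))
  history <- numeric(0)
  epochs <- 0L
  for (epoch in seq_len(max_epochs)) {
    delta_sum <- 0
    for (r in seq_len(n)) {
      m <- scaled[r, ]
      h <- m * (1 - v / C)
      v <- v + (m - h) * (1 - v / C)
      A <- 1 - W / C
      net <- drop(h %*% A)
      out <- h * (1 - net / C)
      dW <- tcrossprod(h - out, h) * A
      W <- W + dW
      delta_sum <- delta_sum + mean(abs(dW))
      if (any(!is.finite(W)) || any(!is.finite(v))) {
        abort(sprintf("non-finite weight update at epoch %d", epoch))
      }
    }
    epochs <- epoch
    history <- c(history, delta_sum / n)
    if (history[epoch] < tol) break
  }
  structure(
    list(v = v, W = W, C = C, epochs = epochs, history = history,
         variables = colnames(scaled), meta = meta),
    class = "autocm_model"
  )
}

#' @export
print.autocm_model <- function(x, ...) {
  cat(sprintf(
    "<autocm_model> %d variables, C = %g, %d epoch(s), final mean |dW| = %.3g\n",
    length(x$variables), x$C, x$epochs, x$history[length(x$history)]
  ))
  invisible(x)
}

#' @export
#' @rdname train_autocm
#' @param x An `autocm_model`.
#' @param ... Unused.
tidy.autocm_model <- function(x, ...) {
  wb <- (x$W + t(x$W)) / 2
  as_tibble(wb, rownames = "from") %>%
    tidyr::pivot_longer(-"from", names_to = "to", values_to = "weight") %>%
    filter(.data$from < .data$to)
}

#' @export
#' @rdname train_autocm
glance.autocm_model <- function(x, ...) {
  tibble(
    n_variables = length(x$variables), C = x$C, epochs = x$epochs,
    converged = x$history[length(x$history)] <
      x$history[max(1, length(x$history) %/% 2)] | x$epochs == 1L,
    final_mean_update = x$history[length(x$history)]
  )
}

#' Convert trained association weights to distances
#'
#' Symmetrises the full-connection matrix and maps connection strength to a
#' distance, `d = 1 - Wbar/C`, in `(0, 1]`: the stronger the association,
#' the shorter the distance.  The diagonal is excluded (`NA`).
#'
#' @param model An [train_autocm()] result.
#' @return Symmetric distance matrix with `NA` diagonal.
#' @export
weights_to_distances <- function(model) {
  stopifnot(inherits(model, "autocm_model"))
  if (any(!is.finite(model$W))) abort("non-finite weights")
  wb <- (model$W + t(model$W)) / 2
  d <- 1 - wb / model$C
  diag(d) <- NA_real_
  d
}

#' Minimum spanning tree of the association distances
#'
#' Kruskal's algorithm with deterministic tie-breaking: candidate edges are
#' sorted by distance, then lexicographically by vertex names, so equal
#' distances always resolve the same way.  The result spans all vertices
#' with `|V| - 1` edges and minimal total distance.
#'
#' @param distances Symmetric numeric matrix with `NA` diagonal (e.g. from
#'   [weights_to_distances()]), or an `autocm_model`.
#' @param meta Optional variable metadata tibble (joined onto vertices).
#' @return An object of class `association_graph`: list with `vertices`
#'   (tibble `name`, plus metadata), `edges` (tibble `from`, `to`,
#'   `distance`, sorted as added) and `total_distance`.
#' @export
minimum_spanning_tree <- function(distances, meta = NULL) {
  if (inherits(distances, "autocm_model")) {
    meta <- meta %||% distances$meta
    distances <- weights_to_distances(distances)
  }
  d <- as.matrix(distances)
  stopifnot(nrow(d) == ncol(d))
  vn <- rownames(d) %||% paste0("V", seq_len(nrow(d)))
  n <- nrow(d)
  if (n < 2L) abort("need at least 2 vertices")

  idx <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[upper.tri(d)]
  ok <- is.finite(w)
  idx <- idx[ok, , drop = FALSE]
  w <- w[ok]
  ord <- order(w, vn[idx[, 1]], vn[idx[, 2]])
  idx <- idx[ord, , drop = FALSE]
  w <- w[ord]

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  from <- to <- character(0)
  dist_out <- numeric(0)
  for (e in seq_along(w)) {
    a <- find(idx[e, 1]); b <- find(idx[e, 2])
    if (a != b) {
      parent[a] <- b
      from <- c(from, vn[idx[e, 1]])
      to <- c(to, vn[idx[e, 2]])
      dist_out <- c(dist_out, w[e])
      if (length(dist_out) == n - 1L) break
    }
  }
  if (length(dist_out) != n - 1L) {
    abort("distance matrix is disconnected: no spanning tree exists")
  }
  vertices <- tibble(name = vn)
  if (!is.null(meta)) {
    vertices <- left_join(vertices, meta,
                          by = c(name = names(meta)[1]))
  }
  structure(
    list(vertices = vertices,
         edges = tibble(from = from, to = to, distance = dist_out),
         total_distance = sum(dist_out)),
    class = "association_graph"
  )
}

#' @export
print.association_graph <- function(x, ...) {
  cat(sprintf("<association_graph> %d vertices, %d MST edges, total distance %.4f\n",
              nrow(x$vertices), nrow(x$edges), x$total_distance))
  invisible(x)
}

#' Spin Net equilibrium query
#'
#' Damped label propagation over the trained association weights: the
#' symmetrised weight matrix is row-normalised (diagonal excluded) into
#' transition weights, the clamped variables are held at activation 1, all
#' others start at 0, and activations are iterated
#' \deqn{a_j \leftarrow \rho \sum_i \tilde w_{ij} a_i}
#' (capped at 1) until the largest change drops below `tol`.  The number of
#' cycles to equilibrium plays the role of the network's hidden layers.
#' Variables close to the clamped ones in the association structure
#' equilibrate just below the damping factor; distant ones lower.
#'
#' @param model An [train_autocm()] result.
#' @param clamped Character vector of variable names to clamp at 1.
#' @param damping Damping factor in (0, 1) (default 0.95).
#' @param tol Convergence tolerance on the max activation change.
#' @param max_iter Iteration cap.
#' @return Tibble `variable`, `activation`, `clamped`, ranked by
#'   descending activation (clamped variables at 1 rank first), with
#'   attribute `cycles`.
#' @export
spinnet_query <- function(model, clamped, damping = 0.95, tol = 1e-6,
                          max_iter = 10000L) {
  stopifnot(inherits(model, "autocm_model"))
  if (length(clamped) == 0L) abort("at least one variable must be clamped")
  unknown <- setdiff(clamped, model$variables)
  if (length(unknown) > 0L) {
    abort(sprintf("clamped variable(s) not in the model: %s",
                  paste(unknown, collapse = ", ")))
  }
  if (damping <= 0 || damping >= 1) abort("damping must lie strictly in (0, 1)")

  wb <- (model$W + t(model$W)) / 2
  diag(wb) <- 0
  rs <- rowSums(wb)
  if (any(rs <= 0)) abort("a variable has no positive connections")
  wt <- wb / rs

  a <- setNames(rep(0, length(model$variables)), model$variables)
  a[clamped] <- 1
  cycles <- 0L
  for (it in seq_len(max_iter)) {
    a_new <- setNames(pmin(1, damping * drop(crossprod(wt, a))), names(a))
    a_new[clamped] <- 1
    delta <- max(abs(a_new - a))
    a <- a_new
    cycles <- it
    if (delta < tol) break
  }
  out <- tibble(
    variable = names(a), activation = unname(a),
    clamped = names(a) %in% clamped
  ) %>%
    arrange(desc(.data$activation), desc(.data$clamped), .data$variable)
  attr(out, "cycles") <- cycles
  out
}
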