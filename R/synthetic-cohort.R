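#' Generate the subject table of a synthetic cohort
#'
#' Draws a cohort of roller painters, spray painters and non-exposed
#' controls: ages, personal noise exposure, urinary solvent metabolites
#' (log-normal around group-scaled medians; spray > roller), exposure
#' durations, cumulative doses (concentration x years), Hardy--Weinberg
#' genotypes for hOGG1 and XRCC1, and the latent cochlear damage variable
#' that drives the audiological outcomes downstream.  Controls carry
#' cotinine but zero solvent dose.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per subject: `id`, `group`, `age`,
#'   `L_ex8h`, `exposure_years`, one column per metabolite, `dose_*`
#'   columns, `hOGG1`, `XRCC1` and the hidden ground truth `damage` (dB).
#' @export
#' @examples
#' subj <- generate_subjects(cohort_config(seed = 1))
#' table(subj$group)
generate_subjects <- function(config) {
  if (!inherits(config, "cohort_config")) {
    config <- do.call(cohort_config, config)
  }
  validate_cohort_config(config)
  set.seed(config$seed)

  groups <- c(
    rep("roller", config$n_roller),
    rep("spray", config$n_spray),
    rep("control", config$n_controls)
  )
  n <- length(groups)
  id <- sprintf(
    "%s%03d",
    c(rep("R", config$n_roller), rep("S", config$n_spray),
      rep("C", config$n_controls)),
    c(seq_len(config$n_roller), seq_len(config$n_spray),
      seq_len(config$n_controls))
  )

  age <- round(runif(n, config$age_range[1], config$age_range[2]))
  noise_mean <- c(
    roller = config$noise_mean_roller,
    spray = config$noise_mean_spray,
    control = config$noise_mean_control
  )[groups]
  L_ex8h <- round(rnorm(n, noise_mean, config$noise_sd), 1)

  exposure_years <- ifelse(
    groups == "control", 0,
    round(runif(n, config$exposure_years_range[1],
                config$exposure_years_range[2]), 1)
  )

  met_names <- names(config$metabolite_medians)
  solvent_mets <- setdiff(met_names, "cotinine")
  scale <- c(roller = 1, spray = config$spray_scale, control = 0)[groups]
  mets <- matrix(0, n, length(met_names), dimnames = list(id, met_names))
  for (m in met_names) {
    med <- config$metabolite_medians[[m]]
    draw <- rlnorm(n, meanlog = log(med) + log(pmax(scale, 1e-12)),
                   sdlog = config$metabolite_sdlog)
    if (m == "cotinine") {
      # controls smoke too: cotinine unscaled by exposure group
      mets[, m] <- rlnorm(n, log(med), config$metabolite_sdlog)
    } else {
      mets[, m] <- ifelse(groups == "control", 0, draw)
    }
  }
  dose <- mets * exposure_years

  hOGG1 <- draw_hwe_genotypes(n, config$allele_freq_hOGG1)
  XRCC1 <- draw_hwe_genotypes(n, config$allele_freq_XRCC1)

  dc <- config$damage_coefficients
  total_dose <- rowSums(dose[, solvent_mets, drop = FALSE])
  dose_term <- log10(1 + total_dose) / 6
  gmult <- dc$genotype[hOGG1]
  damage <- dc$noise * (L_ex8h - 70) +
    dc$dose * dose_term * gmult +
    rnorm(n, 0, dc$sd)

  out <- tibble(
    id = id,
    group = factor(groups, levels = c("roller", "spray", "control")),
    age = age,
    L_ex8h = L_ex8h,
    exposure_years = exposure_years
  )
  for (m in met_names) out[[m]] <- unname(mets[, m])
  for (m in met_names) out[[paste0("dose_", m)]] <- unname(dose[, m])
  out$hOGG1 <- hOGG1
  out$XRCC1 <- XRCC1
  out$damage <- unname(damage)
  out
}

draw_hwe_genotypes <- function(n, q) {
  probs <- c(wt = (1 - q)^2, het = 2 * q * (1 - q), mut = q^2)
  factor(sample(names(probs), n, replace = TRUE, prob = probs),
         levels = c("wt", "het", "mut"))
}

#' Generate audiometry and DPOAE band-level tables
#'
#' For each subject, hearing level is drawn per ear on the 11-frequency
#' audiometric grid as an age baseline plus the latent damage scaled by the
#' low--mid-emphasised frequency profile, plus ear noise; each ear is
#' quantized to 5 dB steps (the audiometer's resolution) and the two-ear
#' average is stored.  DPOAE third-octave band levels start from a healthy
#' baseline and decrease with damage via the band profile, again ear-averaged
#' (no quantization; emission levels are continuous).  Higher damage raises
#' HL and lowers DPOAE level, so the two outcomes are negatively correlated.
#'
#' @param subjects Tibble from [generate_subjects()].
#' @param effects A [planted_effects()].
#' @param seed Integer seed.
#' @param ears Number of ears averaged per subject (default 2; 1 disables
#'   averaging).
#' @param scheme DPOAE [band_scheme()] used to label band columns.
#' @return Named list of two tibbles, `hl` (columns `subject`, `F125` ...
#'   `F8000`, dB HL) and `dpoae` (columns `subject`, `DP1153` ... `DP2904`,
#'   dB EPL).
#' @export
generate_audiology <- function(subjects, effects = planted_effects(),
                               seed = 1L, ears = 2L,
                               scheme = band_scheme()) {
  if (nrow(subjects) == 0L) abort("empty subject list")
  stopifnot(inherits(effects, "planted_effects"), ears >= 1L)
  if (length(effects$dp_profile) != length(scheme$centers)) {
    abort("dp_profile length must match the number of DPOAE bands")
  }
  set.seed(seed)
  n <- nrow(subjects)
  freqs <- hl_frequencies()

  baseline <- outer(subjects$age - 20, effects$hl_baseline_age / 10) + 2
  hl <- matrix(0, n, length(freqs))
  for (e in seq_len(ears)) {
    ear <- baseline +
      outer(subjects$damage, effects$hl_profile) +
      matrix(rnorm(n * length(freqs), 0, effects$hl_noise_sd), n)
    hl <- hl + round(ear / 5) * 5
  }
  hl <- hl / ears
  colnames(hl) <- paste0("F", freqs)

  dp <- matrix(0, n, length(scheme$centers))
  for (e in seq_len(ears)) {
    dp <- dp + effects$dp_baseline -
      outer(subjects$damage, effects$dp_profile) +
      matrix(rnorm(n * length(scheme$centers), 0, effects$dp_noise_sd), n)
  }
  dp <- dp / ears
  colnames(dp) <- paste0("DP", scheme$centers)

  list(
    hl = dplyr::bind_cols(tibble(subject = subjects$id), as_tibble(hl)),
    dpoae = dplyr::bind_cols(tibble(subject = subjects$id), as_tibble(dp))
  )
}

#' Generate a microRNA count matrix with planted effects
#'
#' Simulates negative-binomial sequencing counts for `effects$n_genes`
#' genes across all subjects.  The microRNAs in `effects$de_table` receive
#' the planted exposed-vs-control log2 fold change; microRNAs coupled to an
#' audiological outcome additionally shift their log-mean linearly with each
#' subject's latent damage (centred within condition group, so the planted
#' fold change stays identifiable).  Library sizes vary log-normally around
#' `mean_depth`.
#'
#' @param subjects Tibble from [generate_subjects()] (needs `id`, `group`,
#'   `damage`).
#' @param effects A [planted_effects()].
#' @param mean_depth Mean library size (> 0).
#' @param seed Integer seed.
#' @param libsize_sdlog Log-normal sdlog of library-size variation (0 for
#'   equal depths).
#' @return A [count_matrix()] (genes x samples) with condition labels.
#' @export
generate_counts <- function(subjects, effects = planted_effects(),
                            mean_depth = 1e6, seed = 1L,
                            libsize_sdlog = 0.15) {
  if (nrow(subjects) == 0L) abort("empty subject list")
  if (!is.finite(mean_depth) || mean_depth <= 0) {
    abort("mean_depth must be positive")
  }
  if (any(effects$dispersion < 0)) abort("dispersion must be non-negative")
  set.seed(seed)

  de <- effects$de_table
  n_genes <- max(effects$n_genes, nrow(de))
  genes <- c(de$mirna,
             sprintf("mir-sim-%04d", seq_len(n_genes - nrow(de))))

  n <- nrow(subjects)
  exposed <- subjects$group != "control"
  condition <- factor(ifelse(exposed, "exposed", "control"),
                      levels = c("control", "exposed"))

  w <- rlnorm(n_genes, 0, 1.5)
  # planted genes get a solid baseline; strong upregulation starts low so the
  # exposed-group mean lands in a realistic range
  q80 <- quantile(w, 0.8)
  w[seq_len(nrow(de))] <- q80 * 2^(-pmax(0, de$log2fc))
  w <- w / sum(w)

  lib <- mean_depth * rlnorm(n, 0, libsize_sdlog)

  lfc <- setNames(rep(0, n_genes), genes)
  lfc[de$mirna] <- de$log2fc

  # damage-coupling slope per gene on the log2 scale, sign relative to the
  # audiological variable (DPOAE declines with damage, hence the sign flip)
  slope <- setNames(rep(0, n_genes), genes)
  slope[de$mirna] <- ifelse(de$outcome == "HL", 1, -1) *
    de$corr_sign * effects$coupling_slope

  dmg <- subjects$damage
  dmg_centered <- dmg - stats::ave(dmg, condition)

  phi <- rep_len(effects$dispersion, n_genes)

  counts <- matrix(0L, n_genes, n, dimnames = list(genes, subjects$id))
  log2mu_shift <- outer(lfc, as.numeric(exposed)) +
    outer(slope, dmg_centered)
  mu <- (w * mean_depth) * 2^log2mu_shift
  mu <- sweep(mu, 2, lib / mean_depth, `*`)
  for (g in seq_len(n_genes)) {
    if (phi[g] < 1e-12) {
      counts[g, ] <- stats::rpois(n, mu[g, ])
    } else {
      counts[g, ] <- rnbinom(n, mu = mu[g, ], size = 1 / phi[g])
    }
  }
  storage.mode(counts) <- "integer"
  count_matrix(counts, condition = setNames(as.character(condition),
                                            subjects$id))
}

#' Count matrix container
#'
#' Lightweight container for a genes x samples matrix of non-negative
#' integer counts together with the exposed/control condition labels and,
#' once computed, TMM normalization factors.
#'
#' @param counts Non-negative integer matrix, genes x samples, with
#'   dimnames.
#' @param condition Named character/factor mapping sample ->
#'   `"exposed"`/`"control"`.
#' @param norm_factors Optional per-sample positive factors.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, condition, norm_factors = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("counts must have gene row names and sample column names")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  condition <- condition[colnames(counts)]
  if (anyNA(condition) ||
      !all(condition %in% c("exposed", "control"))) {
    abort("condition must label every sample as exposed or control")
  }
  if (!is.null(norm_factors) && any(norm_factors <= 0)) {
    abort("norm_factors must be positive")
  }
  structure(
    list(
      counts = counts,
      condition = factor(condition, levels = c("control", "exposed")),
      norm_factors = norm_factors
    ),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "<count_matrix> %d genes x %d samples (%d exposed, %d control)%s\n",
    nrow(x$counts), ncol(x$counts),
    sum(x$condition == "exposed"), sum(x$condition == "control"),
    if (is.null(x$norm_factors)) "" else ", TMM-normalized"
  ))
  invisible(x)
}

#' @export
#' @rdname count_matrix
#' @param x A `count_matrix`.
#' @param ... Unused.
tidy.count_matrix <- function(x, ...) {
  as_tibble(x$counts, rownames = "gene") %>%
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "count") %>%
    mutate(condition = as.character(x$condition[.data$sample]))
}

#' Write / read a cohort to a directory of tab-separated tables
#'
#' `write_cohort()` writes `subjects.tsv`, `audiometry.tsv`, `dpoae.tsv` and
#' `counts.tsv` (whichever are present in `tables`); `read_cohort()` reads
#' them back, validates the schema and reconstructs the [count_matrix()].
#' The round trip is an identity on all tables.
#'
#' @param tables Named list with any of `subjects`, `hl`, `dpoae`, `counts`
#'   (a `count_matrix`).
#' @param dir Directory (created if missing).
#' @return `write_cohort()` the directory, invisibly; `read_cohort()` a
#'   named list of tables.
#' @export
write_cohort <- function(tables, dir) {
  stopifnot(is.list(tables))
  known <- intersect(names(tables), c("subjects", "hl", "dpoae", "counts"))
  if (length(known) == 0L) abort("no cohort tables to write")
  for (nm in known) {
    tab <- tables[[nm]]
    empty <- if (inherits(tab, "count_matrix")) ncol(tab$counts) == 0L
             else nrow(tab) == 0L
    if (empty) abort(sprintf("cohort table `%s` is empty; refusing to write", nm))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if ("subjects" %in% known) {
    readr::write_tsv(tables$subjects, file.path(dir, "subjects.tsv"))
  }
  if ("hl" %in% known) {
    readr::write_tsv(tables$hl, file.path(dir, "audiometry.tsv"))
  }
  if ("dpoae" %in% known) {
    readr::write_tsv(tables$dpoae, file.path(dir, "dpoae.tsv"))
  }
  if ("counts" %in% known) {
    cm <- tables$counts
    readr::write_tsv(as_tibble(cm$counts, rownames = "gene"),
                     file.path(dir, "counts.tsv"))
    readr::write_tsv(
      tibble(sample = colnames(cm$counts),
             condition = as.character(cm$condition)),
      file.path(dir, "samples.tsv")
    )
  }
  invisible(dir)
}

subject_schema <- c("id", "group", "age", "L_ex8h", "exposure_years",
                    "hOGG1", "XRCC1")

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir)) abort(sprintf("no such cohort directory: %s", dir))
  out <- list()
  p <- function(f) file.path(dir, f)
  if (file.exists(p("subjects.tsv"))) {
    subj <- readr::read_tsv(p("subjects.tsv"), show_col_types = FALSE)
    missing <- setdiff(subject_schema, names(subj))
    if (length(missing) > 0L) {
      abort(sprintf("subjects.tsv is missing required column(s): %s",
                    paste(missing, collapse = ", ")))
    }
    subj$group <- factor(subj$group, levels = c("roller", "spray", "control"))
    subj$hOGG1 <- factor(subj$hOGG1, levels = c("wt", "het", "mut"))
    subj$XRCC1 <- factor(subj$XRCC1, levels = c("wt", "het", "mut"))
    out$subjects <- subj
  }
  if (file.exists(p("audiometry.tsv"))) {
    out$hl <- read_numeric_table(p("audiometry.tsv"), "subject")
  }
  if (file.exists(p("dpoae.tsv"))) {
    out$dpoae <- read_numeric_table(p("dpoae.tsv"), "subject")
  }
  if (file.exists(p("counts.tsv"))) {
    cts <- read_numeric_table(p("counts.tsv"), "gene")
    mat <- as.matrix(cts[, -1, drop = FALSE])
    rownames(mat) <- cts$gene
    storage.mode(mat) <- "integer"
    if (!file.exists(p("samples.tsv"))) {
      abort("counts.tsv present but samples.tsv (condition labels) missing")
    }
    smp <- readr::read_tsv(p("samples.tsv"), show_col_types = FALSE)
    out$counts <- count_matrix(mat, setNames(smp$condition, smp$sample))
  }
  if (length(out) == 0L) abort(sprintf("no cohort tables found in %s", dir))
  out
}

read_numeric_table <- function(path, key) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (!key %in% names(tab)) {
    abort(sprintf("%s is missing required column: %s", basename(path), key))
  }
  value_cols <- setdiff(names(tab), key)
  bad <- value_cols[!vapply(tab[value_cols], is.numeric, logical(1))]
  if (length(bad) > 0L) {
    abort(sprintf("non-numeric cells in %s column(s): %s",
                  basename(path), paste(bad, collapse = ", ")))
  }
  tab
}
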