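default_stages <- function() {
  c("simulate", "de", "screen", "associate", "discriminate", "graph")
}

#' Pipeline run configuration
#'
#' Plain-list configuration of a full analysis run: either a
#' synthetic-generation block (`cohort` / `effects` override lists handed to
#' [cohort_config()] and [planted_effects()]) or an `input_dir` with an
#' existing cohort; the enabled stages; and every analysis threshold with
#' its documented default.  The configuration round-trips losslessly
#' through its YAML file form ([write_run_config()] / [read_run_config()]).
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param stages Character subset of `simulate`, `dpoae`, `de`, `screen`,
#'   `associate`, `discriminate`, `graph` (order is fixed internally).
#' @param cohort,effects Named override lists for [cohort_config()] /
#'   [planted_effects()] (empty list = defaults).
#' @param input_dir Read an existing cohort directory instead of
#'   simulating (disables `simulate`).
#' @param mean_depth Mean sequencing library size.
#' @param de_alpha Adjusted-p cut for differential expression (0.01).
#' @param screen_threshold,screen_min_bands Correlation screen rule
#'   (|r| > 0.3 in >= 3 bands).
#' @param hl_threshold,dpoae_threshold Dichotomy levels (29 dB HL, 16 dB
#'   EPL).
#' @param spls_keep,spls_ncomp Sparse PLS-DA settings (5 variables, 2
#'   components).
#' @param corr_display Biplot arrow correlation cutoff (0.75).
#' @param autocm_C Contraction constant (`NULL` = number of records).
#' @param autocm_tol,autocm_max_epochs AutoCM stopping rule.
#' @param spinnet_damping,spinnet_tol Spin Net query settings.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       stages = default_stages(),
                       cohort = list(),
                       effects = list(),
                       input_dir = NULL,
                       mean_depth = 1e6,
                       de_alpha = 0.01,
                       screen_threshold = 0.3,
                       screen_min_bands = 3L,
                       hl_threshold = 29,
                       dpoae_threshold = 16,
                       spls_keep = 5L,
                       spls_ncomp = 2L,
                       corr_display = 0.75,
                       autocm_C = NULL,
                       autocm_tol = 1e-6,
                       autocm_max_epochs = 200L,
                       spinnet_damping = 0.95,
                       spinnet_tol = 1e-6) {
  cfg <- list(
    seed = as.integer(seed),
    stages = intersect(c(default_stages(), "dpoae"), stages),
    cohort = cohort, effects = effects, input_dir = input_dir,
    mean_depth = mean_depth, de_alpha = de_alpha,
    screen_threshold = screen_threshold,
    screen_min_bands = as.integer(screen_min_bands),
    hl_threshold = hl_threshold, dpoae_threshold = dpoae_threshold,
    spls_keep = as.integer(spls_keep), spls_ncomp = as.integer(spls_ncomp),
    corr_display = corr_display, autocm_C = autocm_C,
    autocm_tol = autocm_tol,
    autocm_max_epochs = as.integer(autocm_max_epochs),
    spinnet_damping = spinnet_damping, spinnet_tol = spinnet_tol
  )
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  check_range <- function(x, lo, hi, nm, lo_open = FALSE, hi_open = FALSE) {
    bad <- !is.finite(x) ||
      (if (lo_open) x <= lo else x < lo) ||
      (if (hi_open) x >= hi else x > hi)
    if (bad) abort(sprintf("config error: `%s` out of range", nm),
                   class = "otomir_config_error")
  }
  check_range(cfg$de_alpha, 0, 1, "de_alpha")
  check_range(cfg$screen_threshold, 0, 1, "screen_threshold")
  check_range(cfg$spinnet_damping, 0, 1, "spinnet_damping",
              lo_open = TRUE, hi_open = TRUE)
  check_range(cfg$corr_display, 0, 1, "corr_display")
  if (cfg$screen_min_bands < 1L) {
    abort("config error: `screen_min_bands` must be >= 1",
          class = "otomir_config_error")
  }
  if (cfg$spls_keep < 1L || cfg$spls_ncomp < 1L) {
    abort("config error: sPLS-DA settings must be >= 1",
          class = "otomir_config_error")
  }
  invisible(cfg)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

run_log <- function(dir, msg) {
  cat(msg, "\n", sep = "", file = file.path(dir, "log.txt"), append = TRUE)
  invisible(NULL)
}

write_stage_table <- function(dir, name, tab) {
  readr::write_tsv(tab, file.path(dir, name))
  invisible(name)
}

stage_dependency_error <- function(stage, what) {
  abort(
    sprintf("stage `%s`: missing dependency `%s` (enable the producing stage or provide it in the run directory)",
            stage, what),
    class = "otomir_stage_error"
  )
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in fixed order -- simulate (or load), DPOAE
#' spectrum processing (optional), differential expression, correlation
#' screening, mixed-effects association, discriminant analysis, AutoCM
#' graph -- writing every stage's outputs as tab-separated tables into one
#' run directory, together with a log and a manifest (seed, configuration
#' hash, package version, per-file content hashes).  A failure inside a
#' stage halts the run with a stage-named error; a stage whose inputs are
#' missing fails fast the same way.  Two runs with the same configuration
#' produce byte-identical outputs.
#'
#' @param config A [run_config()].
#' @param dir Run directory (created; must be empty or absent unless
#'   `overwrite = TRUE`).
#' @param overwrite Allow writing into a non-empty directory.
#' @return The run directory, invisibly.
#' @export
run_pipeline <- function(config = run_config(), dir, overwrite = FALSE) {
  stopifnot(inherits(config, "run_config"))
  validate_run_config(config)
  if (dir.exists(dir) && length(dir(dir)) > 0 && !overwrite) {
    abort(sprintf("run directory %s exists and is not empty", dir),
          class = "otomir_config_error")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(dir, "log.txt"))

  stages <- config$stages
  state <- list()
  seed <- config$seed

  ## ---- simulate / load --------------------------------------------------
  if (!is.null(config$input_dir)) {
    state <- read_cohort(config$input_dir)
    run_log(dir, sprintf("load: cohort from %s (%d subjects)",
                         config$input_dir, nrow(state$subjects)))
    write_cohort(state, dir)
  } else if ("simulate" %in% stages) {
    cc <- do.call(cohort_config, modifyList(config$cohort,
                                            list(seed = seed)))
    eff <- do.call(planted_effects, config$effects)
    state$subjects <- generate_subjects(cc)
    aud <- generate_audiology(state$subjects, eff, seed = seed + 1L)
    state$hl <- aud$hl
    state$dpoae <- aud$dpoae
    state$counts <- generate_counts(state$subjects, eff,
                                    mean_depth = config$mean_depth,
                                    seed = seed + 2L)
    state$effects <- eff
    write_cohort(state[c("subjects", "hl", "dpoae", "counts")], dir)
    run_log(dir, sprintf(
      "simulate: %d subjects (%d exposed), %d genes",
      nrow(state$subjects), sum(state$subjects$group != "control"),
      nrow(state$counts$counts)
    ))
  }

  need <- function(stage, what) {
    if (is.null(state[[what]])) stage_dependency_error(stage, what)
    state[[what]]
  }

  ## ---- dpoae spectrum demonstration (optional) --------------------------
  if ("dpoae" %in% stages) {
    subjects <- need("dpoae", "subjects")
    dp <- need("dpoae", "dpoae")
    scheme <- band_scheme()
    recovered <- purrr::map_dfr(seq_len(nrow(dp)), function(i) {
      lev <- mean(as.numeric(dp[i, -1]))
      reps <- synthesize_spectrum(
        zl_level = lev, refl_level = lev - 6, noise_level = lev - 25,
        seed = seed + 100L + i
      )
      avg <- coherent_average(reps)
      zl <- unmix_zero_latency(avg$spectrum)
      band_levels(zl, scheme) %>%
        mutate(subject = dp$subject[i], .before = 1)
    })
    write_stage_table(dir, "dpoae_recovered.tsv", recovered)
    run_log(dir, sprintf("dpoae: unmixed spectra for %d subjects", nrow(dp)))
  }

  ## ---- differential expression ------------------------------------------
  if ("de" %in% stages) {
    counts <- need("de", "counts")
    counts <- tmm_factors(counts)
    state$counts <- counts
    de <- de_test(counts)
    sel <- select_de(de, alpha = config$de_alpha)
    state$de <- de
    state$de_selected <- sel
    write_stage_table(dir, "de_results.tsv", de)
    write_stage_table(dir, "de_selected.tsv", sel)
    run_log(dir, sprintf("de: %d/%d genes at adjusted p <= %g",
                         nrow(sel), sum(de$tested), config$de_alpha))
  }

  ## ---- correlation screening --------------------------------------------
  if ("screen" %in% stages) {
    counts <- need("screen", "counts")
    sel <- need("screen", "de_selected")
    subjects <- need("screen", "subjects")
    hl <- need("screen", "hl")
    dp <- need("screen", "dpoae")
    exposed <- subjects$id[subjects$group != "control"]
    expr <- log_cpm(counts)[sel$gene, exposed, drop = FALSE]
    cors <- dplyr::bind_rows(
      correlation_matrix(expr, hl[hl$subject %in% exposed, ]) %>%
        mutate(outcome = "HL"),
      correlation_matrix(expr, dp[dp$subject %in% exposed, ]) %>%
        mutate(outcome = "DPOAE")
    )
    screen <- screen_mirnas(cors, threshold = config$screen_threshold,
                            min_bands = config$screen_min_bands)
    state$correlations <- cors
    state$screen <- screen
    write_stage_table(dir, "correlations.tsv", cors)
    write_stage_table(dir, "screen.tsv", screen)
    run_log(dir, sprintf("screen: %d microRNA-outcome pairs selected",
                         sum(screen$selected)))
  }

  ## ---- mixed-effects association ----------------------------------------
  if ("associate" %in% stages) {
    counts <- need("associate", "counts")
    screen <- need("associate", "screen")
    subjects <- need("associate", "subjects")
    hl <- need("associate", "hl")
    dp <- need("associate", "dpoae")
    exposed <- subjects$id[subjects$group != "control"]
    expr <- log_cpm(counts)
    hits <- screen %>% filter(.data$selected)
    assoc <- purrr::map_dfr(seq_len(nrow(hits)), function(i) {
      mir <- hits$mirna[i]
      out_tab <- if (hits$outcome[i] == "HL") hl else dp
      covars <- tibble(subject = exposed,
                       mirna_level = expr[mir, exposed])
      long <- stack_long(out_tab[out_tab$subject %in% exposed, ], covars)
      fit <- fit_band_models(long, "mirna_level")
      tidy(fit) %>%
        mutate(mirna = mir, outcome = hits$outcome[i], .before = 1)
    })
    state$associations <- assoc
    write_stage_table(dir, "associations.tsv", assoc)

    geno_hits <- hits %>% filter(.data$outcome == "DPOAE")
    geno <- purrr::map_dfr(seq_len(nrow(geno_hits)), function(i) {
      mir <- geno_hits$mirna[i]
      covars <- tibble(
        subject = exposed, mirna_level = expr[mir, exposed],
        hOGG1 = as.character(
          subjects$hOGG1[match(exposed, subjects$id)]
        )
      )
      long <- stack_long(dp[dp$subject %in% exposed, ], covars)
      fit <- tryCatch(
        fit_genotype_model(long, "mirna_level", genotype = "hOGG1"),
        error = function(e) NULL
      )
      if (is.null(fit)) return(tibble())
      tidy(fit) %>%
        mutate(mirna = mir, outcome = "DPOAE", .before = 1)
    })
    state$associations_genotype <- geno
    write_stage_table(dir, "associations_genotype.tsv", geno)
    run_log(dir, sprintf("associate: %d band models over %d microRNAs",
                         nrow(hits), dplyr::n_distinct(hits$mirna)))
  }

  ## ---- discriminant analysis --------------------------------------------
  if ("discriminate" %in% stages) {
    counts <- need("discriminate", "counts")
    sel <- need("discriminate", "de_selected")
    subjects <- need("discriminate", "subjects")
    hl <- need("discriminate", "hl")
    dp <- need("discriminate", "dpoae")
    exposed_tbl <- subjects %>% filter(.data$group != "control")
    groups <- dplyr::bind_rows(
      dichotomize(exposed_tbl, "HL_mean", hl = hl,
                  threshold = config$hl_threshold),
      dichotomize(exposed_tbl, "DPOAE_mean", dpoae = dp,
                  threshold = config$dpoae_threshold),
      dichotomize(exposed_tbl, "hOGG1"),
      dichotomize(exposed_tbl, "XRCC1")
    )
    state$groups <- groups
    write_stage_table(dir, "groups.tsv", groups)

    x <- t(log_cpm(counts)[sel$gene, exposed_tbl$id, drop = FALSE])
    spls <- purrr::map_dfr(unique(groups$basis), function(b) {
      g <- groups %>% filter(.data$basis == b)
      if (dplyr::n_distinct(g$label) < 2L || any(table(g$label) < 2L)) {
        run_log(dir, sprintf(
          "discriminate: basis %s degenerate (single group), skipped", b))
        return(tibble())
      }
      model <- fit_spls_da(x, g$label, n_components = config$spls_ncomp,
                           keep = min(config$spls_keep, ncol(x)))
      tabs <- biplot_tables(model, corr_cutoff = config$corr_display)
      dplyr::bind_rows(
        tidy(model) %>% mutate(basis = b, table = "loadings", .before = 1),
        tabs$cases %>%
          rename(variable = "subject", weight = "comp1") %>%
          mutate(basis = b, table = "cases", component = "comp1",
                 .before = 1) %>%
          select("basis", "table", "variable", "component", "weight"),
        tabs$arrows %>%
          rename(weight = "cor_norm") %>%
          mutate(basis = b, table = "arrows", component = "comp12",
                 .before = 1) %>%
          select("basis", "table", "variable", "component", "weight")
      )
    })
    state$discriminant <- spls
    write_stage_table(dir, "discriminant.tsv", spls)
    run_log(dir, sprintf("discriminate: %d bases analysed",
                         dplyr::n_distinct(groups$basis)))
  }

  ## ---- autocm graph ------------------------------------------------------
  if ("graph" %in% stages) {
    counts <- need("graph", "counts")
    screen <- need("graph", "screen")
    subjects <- need("graph", "subjects")
    hl <- need("graph", "hl")
    dp <- need("graph", "dpoae")
    exposed_tbl <- subjects %>% filter(.data$group != "control")
    hits <- screen %>% filter(.data$selected) %>% distinct(.data$mirna)
    expr <- log_cpm(counts)

    raw <- exposed_tbl %>% select("id", "hOGG1", "XRCC1")
    for (m in hits$mirna) raw[[m]] <- expr[m, exposed_tbl$id]
    raw <- raw %>%
      left_join(hl, by = c(id = "subject")) %>%
      left_join(dp, by = c(id = "subject"))
    prov <- c(
      setNames(rep("polymorphism", 2), c("hOGG1", "XRCC1")),
      setNames(rep("microRNA", nrow(hits)), hits$mirna),
      setNames(rep("HL", 11), paste0("F", hl_frequencies())),
      setNames(rep("DPOAE", 5), paste0("DP", band_scheme()$centers))
    )
    scaled <- scale_with_complements(raw, provenance = prov)
    model <- train_autocm(scaled, C = config$autocm_C,
                          max_epochs = config$autocm_max_epochs,
                          tol = config$autocm_tol)
    mst <- minimum_spanning_tree(model)
    export_graph(mst, file.path(dir, "association_graph.graphml"))
    write_stage_table(dir, "mst_edges.tsv", mst$edges)
    write_stage_table(
      dir, "autocm_weights.tsv",
      as_tibble((model$W + t(model$W)) / 2, rownames = "variable")
    )

    screened <- screen %>% filter(.data$selected) %>%
      group_by(.data$mirna) %>%
      summarise(sign = dplyr::first(.data$dominant_sign), .groups = "drop")
    acts <- purrr::map_dfr(seq_len(nrow(screened)), function(i) {
      base <- gsub("[^[:alnum:]]+", "_", screened$mirna[i])
      prefix <- if (identical(screened$sign[i], "positive")) "Max_" else "Min_"
      clamp <- paste0(prefix, base)
      if (!clamp %in% model$variables) return(tibble())
      q <- spinnet_query(model, clamp, damping = config$spinnet_damping,
                         tol = config$spinnet_tol)
      q %>% mutate(query = clamp, cycles = attr(q, "cycles"), .before = 1)
    })
    state$activations <- acts
    write_stage_table(dir, "activations.tsv", acts)
    run_log(dir, sprintf(
      "graph: autocm on %d variables, %d epochs; %d spinnet queries",
      length(model$variables), model$epochs, dplyr::n_distinct(acts$query)
    ))
  }

  ## ---- manifest ----------------------------------------------------------
  files <- sort(setdiff(dir(dir), c("manifest.json")))
  manifest <- list(
    package = "otomir",
    version = as.character(utils::packageVersion("otomir")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    stages = stages,
    files = lapply(setNames(files, files), function(f) {
      rlang::hash(readBin(file.path(dir, f), "raw",
                          file.size(file.path(dir, f))))
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Assemble report tables from a completed run directory
#'
#' Writes four plain-text report tables: the differential-expression /
#' screening summary (microRNA, regulation, log2 fold change, p values,
#' correlation sign and audiological variable), the band-wise association
#' coefficient report (beta (SE) with significance stars, with and without
#' the hOGG1 factor), the Spin Net activation tables, and the group
#' assignment summary.  Sections whose stage outputs are absent are omitted
#' with a logged notice.  Regeneration is idempotent.
#'
#' @param dir A run directory produced by [run_pipeline()].
#' @return Named list of the report tibbles, invisibly.
#' @export
build_report <- function(dir) {
  if (!dir.exists(dir)) abort(sprintf("no such run directory: %s", dir))
  p <- function(f) file.path(dir, f)
  rd <- function(f) readr::read_tsv(p(f), show_col_types = FALSE)
  out <- list()

  if (file.exists(p("de_selected.tsv")) && file.exists(p("screen.tsv"))) {
    de <- rd("de_selected.tsv")
    sc <- rd("screen.tsv") %>% filter(.data$selected)
    out$de_screen <- sc %>%
      left_join(de, by = c(mirna = "gene")) %>%
      dplyr::transmute(
        mirna = .data$mirna,
        regulation = ifelse(.data$regulation == "up",
                            "Upregulated", "Downregulated"),
        log2fc = round(.data$log2fc, 2),
        p_value = sprintf("%.3g", .data$p),
        p_adjusted = sprintf("%.3g", .data$p_adj),
        correlation_sign = .data$dominant_sign,
        audiological_variable = .data$outcome
      )
    readr::write_tsv(out$de_screen, p("report_de_screen.tsv"))
  } else {
    run_log(dir, "report: DE/screen outputs absent, section omitted")
  }

  if (file.exists(p("associations.tsv"))) {
    assoc <- rd("associations.tsv")
    geno <- if (file.exists(p("associations_genotype.tsv"))) {
      g <- rd("associations_genotype.tsv")
      if (nrow(g) > 0) g else NULL
    } else NULL
    fmt <- function(tab) {
      tab %>%
        filter(!is.na(.data$band)) %>%
        dplyr::transmute(
          outcome = ifelse(.data$outcome == "HL", "AHL", "DP"),
          band = .data$band, mirna = .data$mirna,
          beta_se = sprintf("%.3f%s(%.3f)", .data$beta,
                            ifelse(.data$stars == "n.s.", "",
                                   .data$stars), .data$se),
          significant = .data$stars != "n.s."
        )
    }
    out$beta_report <- fmt(assoc)
    if (!is.null(geno)) {
      out$beta_report_genotype <- dplyr::bind_rows(
        fmt(geno),
        geno %>% filter(is.na(.data$band)) %>%
          dplyr::transmute(
            outcome = "DP", band = NA_character_, mirna = .data$mirna,
            beta_se = sprintf("%s %.3f%s(%.3f)", .data$term, .data$beta,
                              ifelse(.data$stars == "n.s.", "",
                                     .data$stars), .data$se),
            significant = .data$stars != "n.s."
          )
      )
      readr::write_tsv(out$beta_report_genotype,
                       p("report_beta_genotype.tsv"))
    }
    readr::write_tsv(out$beta_report, p("report_beta.tsv"))
  } else {
    run_log(dir, "report: association outputs absent, section omitted")
  }

  if (file.exists(p("activations.tsv"))) {
    acts <- rd("activations.tsv")
    out$activations <- acts %>%
      group_by(.data$query) %>%
      mutate(rank = row_number()) %>%
      ungroup() %>%
      filter(.data$rank <= 18L) %>%
      mutate(activation = round(.data$activation, 3)) %>%
      select("query", "rank", "variable", "activation")
    readr::write_tsv(out$activations, p("report_activations.tsv"))
  } else {
    run_log(dir, "report: Spin Net outputs absent, section omitted")
  }

  if (file.exists(p("groups.tsv"))) {
    out$groups <- rd("groups.tsv") %>%
      count(.data$basis, .data$label, name = "n_subjects")
    readr::write_tsv(out$groups, p("report_groups.tsv"))
  } else {
    run_log(dir, "report: group assignments absent, section omitted")
  }

  invisible(out)
}
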