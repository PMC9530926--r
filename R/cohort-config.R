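#' Standard audiometric frequency grid
#'
#' The 11 octave and inter-octave pure-tone audiometry frequencies spanning
#' 125--8000 Hz at which hearing level is measured in 5 dB steps.
#'
#' @return Integer vector of 11 frequencies in Hz.
#' @export
#' @examples
#' hl_frequencies()
hl_frequencies <- function() {
  c(125L, 250L, 500L, 750L, 1000L, 1500L, 2000L, 3000L, 4000L, 6000L, 8000L)
}

#' Cohort generator configuration
#'
#' Parameters of the synthetic occupational cohort: group sizes (roller
#' painters, spray painters, non-exposed controls), ages, personal A-weighted
#' daily noise exposure, urinary solvent-metabolite medians (micrograms per
#' gram creatinine), exposure durations, minor-allele frequencies of the two
#' base-excision-repair polymorphisms, and the coefficients of the latent
#' cochlear-damage model.
#'
#' The default metabolite medians are the cohort averages for mandelic acid
#' (MA), phenylglyoxylic acid (PGA), methylhippuric acid (MHIPP),
#' S-phenylmercapturic acid (SPMA), S-benzylmercapturic acid (SBMA) and
#' cotinine.  Spray painters receive systematically higher solvent doses than
#' roller painters (`spray_scale`).
#'
#' The latent damage for subject \eqn{i} is
#' \deqn{D_i = a \, (L_{ex,8h,i} - 70) + b \, z_i \, g_i + \epsilon_i}
#' where \eqn{z_i} is a scaled log total solvent dose, \eqn{g_i} the genotype
#' multiplier (mut >= het >= wt) and \eqn{\epsilon_i} Gaussian subject noise.
#'
#' @param n_roller,n_spray,n_controls Group sizes (positive integers).
#' @param age_range Two-element numeric, age bounds in years.
#' @param noise_mean_roller,noise_mean_spray Mean L_ex,8h in dB(A).
#' @param noise_mean_control Mean ambient exposure for controls, dB(A).
#' @param noise_sd Within-group noise-exposure SD, dB(A).
#' @param metabolite_medians Named positive numeric, median urinary
#'   concentrations in ug/g creatinine.
#' @param spray_scale Multiplicative factor for spray-painter metabolites.
#' @param metabolite_sdlog Log-normal sdlog for metabolite variation.
#' @param exposure_years_range Two-element numeric, years of exposure.
#' @param allele_freq_hOGG1,allele_freq_XRCC1 Minor-allele frequencies in
#'   `[0, 1]` (Hardy--Weinberg genotype draws).
#' @param damage_coefficients List with elements `noise` (dB damage per dB(A)
#'   above 70), `dose` (dB damage per unit scaled log dose), `genotype`
#'   (named multipliers `wt`, `het`, `mut`, ordered mut >= het >= wt) and
#'   `sd` (subject noise SD, dB).
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @export
#' @examples
#' cfg <- cohort_config(seed = 7)
#' cfg$n_roller + cfg$n_spray
cohort_config <- function(n_roller = 11L,
                          n_spray = 6L,
                          n_controls = 17L,
                          age_range = c(21, 54),
                          noise_mean_roller = 81.7,
                          noise_mean_spray = 87.2,
                          noise_mean_control = 70,
                          noise_sd = 3,
                          metabolite_medians = c(
                            MA = 7523, PGA = 4441.9, MHIPP = 68974,
                            SPMA = 1.78, SBMA = 14.59, cotinine = 1180.8
                          ),
                          spray_scale = 1.8,
                          metabolite_sdlog = 0.6,
                          exposure_years_range = c(2, 25),
                          allele_freq_hOGG1 = 0.30,
                          allele_freq_XRCC1 = 0.35,
                          damage_coefficients = list(
                            noise = 1.0, dose = 8,
                            genotype = c(wt = 1, het = 1.3, mut = 1.6),
                            sd = 3
                          ),
                          seed = 1L) {
  cfg <- list(
    n_roller = as.integer(n_roller), n_spray = as.integer(n_spray),
    n_controls = as.integer(n_controls),
    age_range = as.numeric(age_range),
    noise_mean_roller = noise_mean_roller,
    noise_mean_spray = noise_mean_spray,
    noise_mean_control = noise_mean_control,
    noise_sd = noise_sd,
    metabolite_medians = metabolite_medians,
    spray_scale = spray_scale,
    metabolite_sdlog = metabolite_sdlog,
    exposure_years_range = as.numeric(exposure_years_range),
    allele_freq_hOGG1 = allele_freq_hOGG1,
    allele_freq_XRCC1 = allele_freq_XRCC1,
    damage_coefficients = damage_coefficients,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  counts <- c(cfg$n_roller, cfg$n_spray, cfg$n_controls)
  if (any(!is.finite(counts)) || any(counts <= 0)) {
    abort("group sizes `n_roller`, `n_spray`, `n_controls` must be positive")
  }
  for (f in c(cfg$allele_freq_hOGG1, cfg$allele_freq_XRCC1)) {
    if (!is.finite(f) || f < 0 || f > 1) {
      abort("allele frequencies must lie in [0, 1]")
    }
  }
  if (any(cfg$metabolite_medians <= 0)) {
    abort("metabolite medians must be positive")
  }
  g <- cfg$damage_coefficients$genotype
  if (!all(c("wt", "het", "mut") %in% names(g))) {
    abort("damage_coefficients$genotype needs named entries wt, het, mut")
  }
  if (!(g["mut"] >= g["het"] && g["het"] >= g["wt"])) {
    abort("genotype multipliers must be ordered mut >= het >= wt")
  }
  invisible(cfg)
}

# The 12 differentially expressed microRNAs carried as defaults, with their
# log2 fold changes (exposed vs control), the audiological variable each is
# correlated with, and the sign of that correlation.
default_de_table <- function() {
  tibble(
    mirna = c(
      "hsa-miR-885-3p", "hsa-miR-122-5p", "hsa-miR-195-5p", "hsa-miR-375",
      "hsa-miR-483-5p", "hsa-miR-193b-5p", "hsa-miR-497-5p", "hsa-miR-206",
      "hsa-miR-486-5p", "hsa-miR-2355-5p", "hsa-miR-873-3p", "hsa-miR-92b-5p"
    ),
    log2fc = c(-3.72, -3.14, -1.82, -2.72, -2.20, -1.81,
               -2.64, -3.01, -1.39, 7.77, 7.74, -1.41),
    outcome = c(rep("HL", 6), rep("DPOAE", 6)),
    corr_sign = c(rep(-1, 6), -1, -1, 1, -1, -1, 1)
  )
}

#' Planted ground-truth effects for the synthetic cohort
#'
#' Defines what the generators plant: which microRNAs are differentially
#' expressed (and by how much, in log2 fold change exposed vs control), which
#' are coupled to the latent cochlear damage (and with which sign, relative
#' to the audiological variable), the negative-binomial dispersion, and the
#' per-frequency damage weights for hearing level and DPOAE band levels.
#'
#' The default differential-expression table carries 12 microRNAs with fold
#' changes between -3.72 and +7.77; six are correlated (all negatively) with
#' hearing level, six with the DPOAE level (four negatively, two positively).
#' The hearing-level damage profile emphasises low--mid frequencies: weights
#' at 6000 Hz and above never exceed those at 2000 Hz and below, matching
#' the predominantly low--mid frequency action of ototoxic solvents.
#'
#' @param de_table Tibble with columns `mirna`, `log2fc`, `outcome`
#'   (`"HL"`/`"DPOAE"`), `corr_sign` (+1/-1, sign of the correlation with the
#'   audiological variable).  Defaults to the 12-microRNA table.
#' @param coupling_slope Absolute log2 expression shift per dB of latent
#'   damage for coupled microRNAs.
#' @param dispersion Negative-binomial dispersion (scalar, recycled per
#'   gene, or per-gene vector at generation time).  Must be >= 0.
#' @param n_genes Total number of genes simulated (planted ones included).
#' @param hl_profile Numeric length 11, damage weights on the audiometric
#'   grid (dB HL per dB damage).
#' @param dp_profile Numeric length 5, damage weights on the DPOAE bands
#'   (dB EPL lost per dB damage).
#' @param hl_baseline_age Numeric length 11, age slopes in dB per decade.
#' @param hl_noise_sd,dp_noise_sd Per-ear measurement noise SD, dB.
#' @param dp_baseline Healthy-ear DPOAE band level, dB EPL.
#'
#' @return An object of class `planted_effects`.
#' @export
#' @examples
#' eff <- planted_effects()
#' eff$de_table[eff$de_table$mirna == "hsa-miR-122-5p", "log2fc"]
planted_effects <- function(de_table = default_de_table(),
                            coupling_slope = 0.08,
                            dispersion = 0.1,
                            n_genes = 2000L,
                            hl_profile = c(1, 1, 1, 1, 0.9, 0.9, 0.8,
                                           0.7, 0.6, 0.4, 0.3),
                            dp_profile = c(0.30, 0.30, 0.25, 0.20, 0.15),
                            hl_baseline_age = c(1, 1, 1, 1, 1.5, 2, 2.5,
                                                3, 4, 5, 6),
                            hl_noise_sd = 3,
                            dp_noise_sd = 2,
                            dp_baseline = 20) {
  stopifnot(
    is.data.frame(de_table),
    all(c("mirna", "log2fc", "outcome", "corr_sign") %in% names(de_table)),
    length(hl_profile) == 11L, length(hl_baseline_age) == 11L
  )
  if (any(dispersion < 0)) abort("dispersion must be non-negative")
  if (max(hl_profile[hl_frequencies() >= 6000]) >
      min(hl_profile[hl_frequencies() <= 2000]) + 1e-12) {
    abort("hl_profile must not weight >= 6000 Hz above <= 2000 Hz (low-mid emphasis)")
  }
  structure(
    list(
      de_table = as_tibble(de_table),
      coupling_slope = coupling_slope,
      dispersion = dispersion,
      n_genes = as.integer(n_genes),
      hl_profile = hl_profile,
      dp_profile = dp_profile,
      hl_baseline_age = hl_baseline_age,
      hl_noise_sd = hl_noise_sd,
      dp_noise_sd = dp_noise_sd,
      dp_baseline = dp_baseline
    ),
    class = "planted_effects"
  )
}
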