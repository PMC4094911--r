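#' Default standardised AD-vs-CTL effect profile
#'
#' Per-feature group-mean shift (AD minus CTL) in population-SD units. The
#' ten regions that dominate AD-vs-control discrimination in the
#' morphometry literature — hippocampus, entorhinal cortex, amygdala,
#' temporal pole, superior temporal gyrus, inferior lateral ventricle,
#' middle temporal gyrus, fusiform gyrus, inferior temporal gyrus,
#' parahippocampal gyrus — carry the largest magnitudes (|shift| 1.0–1.5);
#' atrophic structures are negative and the inferior lateral ventricle is
#' positive (ex-vacuo enlargement). All remaining regions carry small shifts
#' (|shift| <= 0.45). Values are artifact-defined defaults shipped with the
#' population reference fixture.
#'
#' @return named numeric vector of length 57 in canonical feature order.
#' @export
default_effect_profile <- function() {
  reg <- feature_registry()
  stats::setNames(reg$effect_ad_vs_ctl, reg$feature)
}

#' Specify a synthetic morphometry cohort
#'
#' Defines the stated world the generator draws from: group sizes, the
#' standardised AD-vs-CTL effect profile, where the MCI groups sit between
#' CTL and AD, per-group 12-month decline, an APOE e4 severity shift within
#' MCI, the inter-regional correlation model and residual noise.
#'
#' Defaults mirror a multi-centre AD/MCI/CTL study with 348 baseline
#' subjects of whom 214 are followed at 12 months (AD 119 -> 62, CTL
#' 110 -> 79, MCI-c 22 -> 13, MCI-nc 97 -> 60).
#'
#' @param n_ad,n_ctl,n_mci_c,n_mci_nc group sizes at baseline.
#' @param effect_profile named 57-vector of standardised AD-vs-CTL shifts;
#'   default [default_effect_profile()].
#' @param mci_fraction named vector `c(nc = , c = )` in `[0, 1]` placing the
#'   MCI latent-severity means between CTL (0) and AD (1); converters must
#'   sit at least as close to AD as non-converters.
#' @param annual_decline named vector `c(ad = , mci_c = , mci_nc = , ctl = )`
#'   of expected 12-month latent-severity increase per group (index-scale
#'   units; defaults track observed 12-month index shifts: AD ~ +0.16).
#' @param apoe_effect extra latent-severity shift for APOE e4 carriers
#'   within MCI (both timepoints).
#' @param correlation_strength share of residual variance carried by the
#'   shared global-atrophy factor (in `[0, 0.7]`); an additional fixed 0.2
#'   share is carried by within-lobe block factors.
#' @param noise_sd residual SD of each feature in population-SD units.
#' @param severity_sd SD of latent severity within each group.
#' @param followup_fraction named per-group fraction of subjects retained at
#'   12 months.
#' @param followup_noise_sd SD of the fresh 12-month measurement noise
#'   (population-SD units).
#' @param seed integer RNG seed; the cohort is a deterministic function of
#'   the spec including this seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_ad = 119L, n_ctl = 110L, n_mci_c = 22L,
                        n_mci_nc = 97L,
                        effect_profile = default_effect_profile(),
                        mci_fraction = c(nc = 0.45, c = 0.8),
                        annual_decline = c(ad = 0.16, mci_c = 0.10,
                                           mci_nc = 0.06, ctl = 0.10),
                        apoe_effect = 0.3,
                        correlation_strength = 0.3,
                        noise_sd = 0.9,
                        severity_sd = 0.3,
                        followup_fraction = c(ad = 62 / 119, ctl = 79 / 110,
                                              mci_c = 13 / 22,
                                              mci_nc = 60 / 97),
                        followup_noise_sd = 0.15,
                        seed = 1L) {
  counts <- c(n_ad, n_ctl, n_mci_c, n_mci_nc)
  if (any(counts < 0)) stop("group counts must be >= 0")
  feats <- feature_names()
  if (length(effect_profile) != length(feats)) {
    stop("effect_profile must have exactly ", length(feats), " entries")
  }
  if (is.null(names(effect_profile))) names(effect_profile) <- feats
  if (!setequal(names(effect_profile), feats)) {
    stop("effect_profile names must match the canonical feature list")
  }
  effect_profile <- effect_profile[feats]
  if (any(mci_fraction < 0) || any(mci_fraction > 1)) {
    stop("mci_fraction entries must lie in [0, 1]")
  }
  if (mci_fraction[["c"]] < mci_fraction[["nc"]]) {
    stop("mci_fraction for converters must be >= non-converters")
  }
  if (correlation_strength < 0 || correlation_strength > 0.7) {
    stop("correlation_strength must lie in [0, 0.7]")
  }
  structure(list(n_ad = as.integer(n_ad), n_ctl = as.integer(n_ctl),
                 n_mci_c = as.integer(n_mci_c), n_mci_nc = as.integer(n_mci_nc),
                 effect_profile = effect_profile,
                 mci_fraction = mci_fraction,
                 annual_decline = annual_decline,
                 apoe_effect = apoe_effect,
                 correlation_strength = correlation_strength,
                 noise_sd = noise_sd,
                 severity_sd = severity_sd,
                 followup_fraction = followup_fraction,
                 followup_noise_sd = followup_noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Fixed share of residual variance carried by within-lobe block factors.
.block_corr_share <- 0.2

# Group-level constants used by the generator: latent severity means are
# CTL = 0 and AD = 1 by construction (the effect profile is the AD-vs-CTL
# shift); MCI means interpolate via mci_fraction. APOE carrier rates and
# age distributions echo typical memory-clinic cohorts.
.group_constants <- list(
  apoe_rate = c(AD = 0.54, CTL = 0.28, `MCI-c` = 0.59, `MCI-nc` = 0.27),
  age_mean = c(AD = 75.5, CTL = 73.0, `MCI-c` = 72.8, `MCI-nc` = 74.7),
  age_sd = c(AD = 6.0, CTL = 6.5, `MCI-c` = 6.4, `MCI-nc` = 5.4)
)

# Cognitive scores as noisy affine functions of latent severity, anchored to
# typical group means (CTL ~ MMSE 29.1 / CDR-sob 0.1 / ADAS1 3.8; AD ~ 22 /
# 5.9 / 6.5).
.cognitive_scores <- function(severity, n) {
  list(
    mmse = pmin(30, pmax(0, 29.1 - 7.0 * severity + stats::rnorm(n, 0, 1.5))),
    cdr_sob = pmax(0, 0.1 + 5.8 * severity + stats::rnorm(n, 0, 1.0)),
    adas1 = pmin(10, pmax(0, 3.8 + 2.7 * severity + stats::rnorm(n, 0, 1.2)))
  )
}

.icv_reference <- 1.5e6

#' Generate a seeded synthetic morphometry cohort
#'
#' Draws, per subject, a Gaussian latent severity with group means
#' AD = 1 > MCI-c >= MCI-nc > CTL = 0, then builds each standardised feature
#' as `severity * effect + residual`, where the residual combines a shared
#' global-atrophy factor, a within-lobe block factor and independent noise.
#' Features are mapped to their natural scale via the population reference
#' (thickness in mm; volumes in mm^3 additionally multiplied by the
#' subject's ICV relative to the 1.5e6 mm^3 reference, so ICV normalisation
#' is a meaningful preprocessing step). Twelve-month features add the
#' per-group severity decline times the effect profile, plus fresh
#' measurement noise, on top of the retained baseline residual. A random
#' within-group subset is retained at follow-up. Cognitive scores and
#' metadata are derived from severity per timepoint.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `synthetic_cohort`: `data` (one row per
#'   subject x timepoint: `subject_id`, `timepoint`, metadata, 57 features,
#'   `icv`), `spec`, and `truth` (per-subject latent severity at both
#'   timepoints).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  reg <- feature_registry()
  feats <- reg$feature
  groups <- rep(c("AD", "CTL", "MCI-c", "MCI-nc"),
                times = c(spec$n_ad, spec$n_ctl, spec$n_mci_c, spec$n_mci_nc))
  n <- length(groups)
  if (n == 0L) stop("empty cohort")
  sev_mean <- c(AD = 1, CTL = 0,
                `MCI-c` = unname(spec$mci_fraction[["c"]]),
                `MCI-nc` = unname(spec$mci_fraction[["nc"]]))
  decline <- c(AD = unname(spec$annual_decline[["ad"]]),
               CTL = unname(spec$annual_decline[["ctl"]]),
               `MCI-c` = unname(spec$annual_decline[["mci_c"]]),
               `MCI-nc` = unname(spec$annual_decline[["mci_nc"]]))

  withr::with_seed(spec$seed, {
    subject_id <- sprintf("S%04d", seq_len(n))
    apoe <- stats::rbinom(n, 1L, .group_constants$apoe_rate[groups])
    age <- pmax(65, stats::rnorm(n, .group_constants$age_mean[groups],
                                 .group_constants$age_sd[groups]))
    sev0 <- stats::rnorm(n, sev_mean[groups], spec$severity_sd)
    is_mci <- groups %in% c("MCI-c", "MCI-nc")
    sev0 <- sev0 + spec$apoe_effect * apoe * is_mci
    sev12 <- sev0 + decline[groups]

    # residual: shared global factor + within-lobe blocks + independent noise
    rho_g <- spec$correlation_strength
    rho_b <- .block_corr_share
    lobes <- unique(reg$lobe)
    g <- stats::rnorm(n)
    B <- matrix(stats::rnorm(n * length(lobes)), n,
                dimnames = list(NULL, lobes))
    E <- matrix(stats::rnorm(n * length(feats)), n)
    Z_res <- sqrt(rho_g) * g %o% rep(1, length(feats)) +
      sqrt(rho_b) * B[, reg$lobe, drop = FALSE] +
      sqrt(1 - rho_g - rho_b) * E
    Z0 <- sev0 %o% unname(spec$effect_profile) + spec$noise_sd * Z_res
    Z12 <- Z0 + (sev12 - sev0) %o% unname(spec$effect_profile) +
      spec$followup_noise_sd *
        matrix(stats::rnorm(n * length(feats)), n)

    icv <- pmax(1e6, stats::rnorm(n, .icv_reference, 1.5e5))
    to_natural <- function(Z) {
      V <- sweep(sweep(Z, 2L, reg$pop_sd, "*"), 2L, reg$pop_mean, "+")
      V <- pmax(V, 0.01)  # physical scales are positive
      vol <- reg$block == "volume"
      V[, vol] <- V[, vol] * (icv / .icv_reference)
      colnames(V) <- feats
      V
    }
    cog0 <- .cognitive_scores(sev0, n)
    cog12 <- .cognitive_scores(sev12, n)

    followers <- logical(n)
    for (grp in names(spec$followup_fraction)) {
      key <- c(ad = "AD", ctl = "CTL", mci_c = "MCI-c", mci_nc = "MCI-nc")[grp]
      idx <- which(groups == key)
      n_keep <- min(round(length(idx) * spec$followup_fraction[[grp]]),
                    length(idx))
      followers[idx[sample.int(length(idx), n_keep)]] <- TRUE
    }
  })

  mci_status <- ifelse(groups == "MCI-c", "c",
                       ifelse(groups == "MCI-nc", "nc", NA_character_))
  dx <- ifelse(is_mci, "MCI", groups)
  meta0 <- data.frame(subject_id = subject_id, timepoint = "baseline",
                      dx = dx, mci_status = mci_status, apoe_e4 = apoe,
                      age = age, mmse = cog0$mmse, cdr_sob = cog0$cdr_sob,
                      adas1 = cog0$adas1, stringsAsFactors = FALSE)
  meta12 <- meta0[followers, ]
  meta12$timepoint <- "m12"
  meta12$mmse <- cog12$mmse[followers]
  meta12$cdr_sob <- cog12$cdr_sob[followers]
  meta12$adas1 <- cog12$adas1[followers]

  tab0 <- cbind(meta0, as.data.frame(to_natural(Z0)), icv = icv)
  tab12 <- cbind(meta12, as.data.frame(to_natural(Z12)[followers, , drop = FALSE]),
                 icv = icv[followers])
  data <- rbind(tab0, tab12)
  rownames(data) <- NULL

  structure(list(data = data, spec = spec,
                 truth = data.frame(subject_id = subject_id, group = groups,
                                    severity_baseline = sev0,
                                    severity_m12 = sev12,
                                    followed = followers,
                                    stringsAsFactors = FALSE)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$truth$group)
  cat("Synthetic morphometry cohort:",
      sum(tab), "subjects at baseline (",
      paste(names(tab), tab, collapse = ", "), "),",
      sum(x$truth$followed), "followed at 12 months\n")
  invisible(x)
}

#' Extract the training subset (baseline AD and CTL rows) of a cohort table
#'
#' The discriminant model is trained on baseline AD and CTL subjects only;
#' MCI subjects and follow-up rows are never part of training.
#'
#' @param data cohort data.frame with `dx` and `timepoint` columns.
#' @return list with `table` (the training rows) and `y` (CTL = 0, AD = 1).
#' @export
training_subset <- function(data) {
  keep <- data$timepoint == "baseline" & data$dx %in% c("AD", "CTL")
  tab <- data[keep, , drop = FALSE]
  list(table = tab, y = as.numeric(tab$dx == "AD"))
}
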