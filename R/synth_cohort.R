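#' Specification for a synthetic two-group cohort
#'
#' Emulates a case-control resting-state study with simultaneous ECG and
#' 19-channel EEG.  Group effects are injected at the signal level:
#'
#' \itemize{
#'   \item cases have their mean heart rate shifted by \code{effect_hr}
#'     bpm and their respiratory (HF) R-R modulation power multiplied by
#'     \code{effect_hf} (1 = no suppression);
#'   \item cases have their theta-band common-source coupling reduced by
#'     the fraction \code{effect_theta_cpl}, which raises theta
#'     characteristic path length;
#'   \item within the case group, a latent bivariate Gaussian couples each
#'     subject's overall R-R variability scale (which drives SDNN/SDNNi)
#'     to their theta coupling strength, with correlation
#'     \code{-rho_sdnn_cpl_case}; since path length falls as coupling
#'     rises, the induced SDNNi-to-theta-CPL correlation is
#'     \code{rho_sdnn_cpl_case} (negative).  Controls draw the two latents
#'     independently.
#' }
#'
#' Defaults mirror the group sizes and IQ distributions of a 53-case /
#' 58-control young-adult cohort and the reported effect directions
#' (elevated HR, suppressed HF, higher theta CPL, SDNNi-CPL correlation
#' near -0.4 in cases only).
#'
#' @param n_case,n_control group sizes
#' @param effect_hr case-group heart-rate shift in bpm
#' @param effect_hf multiplicative HF-power suppression factor in (0, 1]
#' @param effect_theta_cpl fractional reduction of case theta coupling in
#'   [0, 1)
#' @param rho_sdnn_cpl_case target SDNNi-theta-CPL Spearman correlation in
#'   the case group, in [-1, 0]
#' @param iq_case,iq_control c(mean, sd) of the IQ distributions
#' @param duration_s R-R record length in seconds
#' @param eeg_duration_s EEG record length in seconds (defaults to
#'   \code{duration_s})
#' @param fs_eeg EEG sampling rate in Hz
#' @param ectopic_rate fraction of ectopic-like beats per subject
#' @param seed integer seed; cohorts are byte-identical given the spec
#' @return object of class \code{cohort_spec}
#' @export
cohort_spec <- function(n_case = 53, n_control = 58,
                        effect_hr = 5, effect_hf = 0.5,
                        effect_theta_cpl = 0.25,
                        rho_sdnn_cpl_case = -0.4,
                        iq_case = c(104.78, 17.68),
                        iq_control = c(117.86, 10.96),
                        duration_s = 300, eeg_duration_s = duration_s,
                        fs_eeg = 1000, ectopic_rate = 0.02, seed = NULL) {
  stop_if_not(n_case > 0 && n_control > 0, "group sizes must be positive")
  stop_if_not(effect_hf > 0 && effect_hf <= 1,
              "effect_hf must lie in (0, 1]")
  stop_if_not(effect_theta_cpl >= 0 && effect_theta_cpl < 1,
              "effect_theta_cpl must lie in [0, 1)")
  stop_if_not(rho_sdnn_cpl_case >= -1 && rho_sdnn_cpl_case <= 0,
              "rho_sdnn_cpl_case must lie in [-1, 0]")
  structure(list(n_case = n_case, n_control = n_control,
                 effect_hr = effect_hr, effect_hf = effect_hf,
                 effect_theta_cpl = effect_theta_cpl,
                 rho_sdnn_cpl_case = rho_sdnn_cpl_case,
                 iq_case = iq_case, iq_control = iq_control,
                 duration_s = duration_s, eeg_duration_s = eeg_duration_s,
                 fs_eeg = fs_eeg, ectopic_rate = ectopic_rate, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of simultaneous ECG-EEG subjects
#'
#' Draws per-subject latent parameters per the spec, then renders each
#' subject's R-R series (\code{\link{generate_rr_series}}) and EEG
#' recording (\code{\link{generate_eeg}}).  The returned ground-truth
#' table carries every latent parameter so parameter-recovery tests can
#' compare pipeline estimates against the generating values.
#'
#' @param spec a \code{\link{cohort_spec}}
#' @return list: \code{subjects} (each with \code{id}, \code{group},
#'   \code{rr} (an \code{rr_series}), \code{eeg} (an
#'   \code{eeg_recording})), \code{truth} (data.frame of latent
#'   parameters), \code{spec}
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    groups <- c(rep("case", spec$n_case), rep("control", spec$n_control))
    n <- length(groups)
    ids <- sprintf("S%03d", seq_len(n))

    # latent bivariate Gaussian: z1 drives the R-R variability scale,
    # z2 the theta coupling strength; correlated only in the case group
    rho <- -spec$rho_sdnn_cpl_case
    z1 <- rnorm(n)
    z2_ind <- rnorm(n)
    z2 <- ifelse(groups == "case",
                 rho * z1 + sqrt(1 - rho^2) * z2_ind, z2_ind)

    hr <- rnorm(n, 64, 6) + ifelse(groups == "case", spec$effect_hr, 0)
    hr <- pmax(hr, 40)
    sdnn_scale <- exp(0.25 * z1)
    hf_amp <- exp(rnorm(n, log(30), 0.25)) * sdnn_scale *
      ifelse(groups == "case", sqrt(spec$effect_hf), 1)
    lf_amp <- exp(rnorm(n, log(35), 0.25)) * sdnn_scale
    noise_sd <- 15 * sdnn_scale
    theta_coupling <- exp(0.3 * z2) *
      ifelse(groups == "case", 1 - spec$effect_theta_cpl, 1)
    iq <- ifelse(groups == "case",
                 rnorm(n, spec$iq_case[1], spec$iq_case[2]),
                 rnorm(n, spec$iq_control[1], spec$iq_control[2]))

    subject_seeds <- sample.int(.Machine$integer.max - 1, 2 * n)
    subjects <- vector("list", n)
    for (i in seq_len(n)) {
      rr_spec <- rr_gen_spec(duration_s = spec$duration_s,
                             mean_rr = 60000 / hr[i],
                             lf_amp = lf_amp[i], hf_amp = hf_amp[i],
                             noise_sd = noise_sd[i],
                             ectopic_rate = spec$ectopic_rate,
                             seed = subject_seeds[2 * i - 1])
      sources <- default_band_sources(19)
      for (k in seq_along(sources)) {
        if (sources[[k]]$band == "theta")
          sources[[k]]$weights <- sources[[k]]$weights * theta_coupling[i]
      }
      eeg_spec <- eeg_gen_spec(n_channels = 19, fs = spec$fs_eeg,
                               duration_s = spec$eeg_duration_s,
                               band_sources = sources,
                               seed = subject_seeds[2 * i])
      subjects[[i]] <- list(id = ids[i], group = groups[i],
                            rr = generate_rr_series(rr_spec),
                            eeg = generate_eeg(eeg_spec))
    }
    truth <- data.frame(id = ids, group = groups, IQ = iq,
                        hr_target = hr, hf_amp = hf_amp, lf_amp = lf_amp,
                        noise_sd = noise_sd, sdnn_scale = sdnn_scale,
                        theta_coupling = theta_coupling,
                        z_sdnn = z1, z_coupling = z2)
    list(subjects = subjects, truth = truth, spec = spec)
  })
}
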