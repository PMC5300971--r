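#' Group profile for the synthetic cohort generator
#'
#' A group profile describes one patient stratum: how many patients it
#' contains, the group-median NK population frequencies its members are drawn
#' around, the dispersion of the logistic-normal draw, the clinical metadata
#' distributions, and the T0 to M3 kinetics of the summed CD57+ compartment.
#'
#' @param group_label Group name (canonically "X", "Y" or "Z").
#' @param n_patients Number of patients in the group.
#' @param freq_center Named numeric vector: median percentage of total NK
#'   events per population. Values must be non-negative and sum to <= 100;
#'   any remainder is spread proportionally at draw time.
#' @param freq_spread Logistic-normal dispersion (standard deviation on the
#'   log scale; 0 = no inter-patient variation).
#' @param metadata_centers Named list; each element `c(median, lo, hi)` for a
#'   clinical variable.
#' @param m3_shift Additive change (percentage points) of the summed CD57+
#'   NK frequency between T0 and M3.
#' @param n_acute Number of patients with acute (vs early) infection.
#' @param n_suppressed_m3 Number of patients below 50 HIV-RNA copies/mL at
#'   M3.
#'
#' @return An object of class `nk_group_profile`.
#' @export
group_profile <- function(group_label, n_patients, freq_center,
                          freq_spread = 0.25,
                          metadata_centers = list(),
                          m3_shift = 0,
                          n_acute = 0,
                          n_suppressed_m3 = 0) {
  if (n_patients <= 0) stop("n_patients must be > 0")
  if (any(freq_center < 0)) stop("freq_center values must be >= 0")
  if (sum(freq_center) > 100 + 1e-8) {
    stop("freq_center must sum to <= 100 (got ", round(sum(freq_center), 3), ")")
  }
  if (freq_spread < 0) stop("freq_spread must be >= 0")
  if (n_acute > n_patients || n_suppressed_m3 > n_patients) {
    stop("n_acute and n_suppressed_m3 cannot exceed n_patients")
  }
  structure(
    list(group_label = group_label, n_patients = n_patients,
         freq_center = freq_center, freq_spread = freq_spread,
         metadata_centers = metadata_centers, m3_shift = m3_shift,
         n_acute = n_acute, n_suppressed_m3 = n_suppressed_m3),
    class = "nk_group_profile"
  )
}

# Default group-median population frequencies (% of NK). Populations are the
# thirteen defaults of build_default_phenotypes(); each vector sums to 100.
# The four signature populations carry the study medians (CD56dim NKG2A+:
# 34/13.8/14.3; CD56dim CD57+: 21/2.9/7.2; CD56dim NKG2C+CD57+:
# 17.8/2.9/0.9; CD56dim triple-negative: 12/16/42.6); category totals track
# the per-group medians of the cohort (Progenitors 7.7/4/6.3, Mature
# 6.8/39/8.2, ...), and unconstrained populations absorb the residual mass.
# "CD56neg CD16+CD57+" is kept below 0.5% everywhere so the rare-population
# filter always has work to do.
.default_freq_centers <- function() {
  pops <- names(build_default_phenotypes())
  X <- c(5.7, 2.0, 34.0, 15.2, 12.0, 7.0, 2.9, 2.9, 1.0, 8.0, 0.3, 5.5, 3.5)
  Y <- c(3.0, 1.0, 13.8, 7.0, 16.0, 7.7, 21.0, 17.8, 0.2, 4.0, 0.3, 4.3, 3.9)
  Z <- c(4.3, 2.0, 14.3, 0.5, 42.6, 8.1, 7.2, 0.9, 0.1, 5.0, 0.2, 8.0, 6.8)
  HD <- c(5.8, 2.0, 15.4, 3.0, 27.0, 3.0, 27.0, 9.0, 3.0, 1.0, 0.3, 1.5, 2.0)
  out <- list(X = X, Y = Y, Z = Z, healthy = HD)
  lapply(out, function(v) stats::setNames(v, pops))
}

.default_metadata_centers <- function(group) {
  # c(median, lo, hi); clinical scalars per group, healthy donors for the
  # activation/DC variables only
  tab <- list(
    X = list(hiv_rna = c(5.77, 4.6, 7), hiv_dna = c(3.8, 3.2, 4.7),
             cd4 = c(549, 323, 1012), cd8 = c(2148, 502, 8157),
             il6 = c(2.5, 0.2, 12), ip10 = c(850, 200, 3000),
             pdc_pct = c(0.12, 0.02, 0.3), mdc_pct = c(0.18, 0.05, 0.4),
             cd38 = c(9, 4, 20), cd86 = c(12, 5, 25), pdl1 = c(4, 1.5, 9)),
    Y = list(hiv_rna = c(4.88, 3.2, 5.7), hiv_dna = c(3.5, 2.8, 4.3),
             cd4 = c(584, 368, 864), cd8 = c(1308, 417, 2716),
             il6 = c(0.8, 0.2, 4), ip10 = c(320, 80, 1200),
             pdc_pct = c(0.22, 0.05, 0.45), mdc_pct = c(0.30, 0.1, 0.6),
             cd38 = c(5, 2, 10), cd86 = c(8, 3, 16), pdl1 = c(2.2, 0.8, 5)),
    Z = list(hiv_rna = c(6.05, 5.6, 7), hiv_dna = c(3.9, 3.2, 4.5),
             cd4 = c(430, 341, 513), cd8 = c(1415, 1140, 1966),
             il6 = c(2.0, 0.2, 9), ip10 = c(700, 150, 2500),
             pdc_pct = c(0.12, 0.02, 0.3), mdc_pct = c(0.18, 0.05, 0.4),
             cd38 = c(8, 3.5, 18), cd86 = c(11, 5, 22), pdl1 = c(3.5, 1.2, 8)),
    healthy = list(hiv_rna = NULL, hiv_dna = NULL,
                   cd4 = c(900, 500, 1500), cd8 = c(550, 300, 900),
                   il6 = c(0.6, 0.2, 2), ip10 = c(120, 40, 300),
                   pdc_pct = c(0.35, 0.15, 0.6), mdc_pct = c(0.33, 0.15, 0.6),
                   cd38 = c(2, 1, 4), cd86 = c(5, 2, 9), pdl1 = c(2, 0.8, 4))
  )
  tab[[group]]
}

#' Default patient-group profiles
#'
#' Three strata of 14, 10 and 4 patients whose NK population frequency
#' centers follow the group medians of the modeled cohort: group X dominated
#' by CD56dim NKG2A+ effectors, group Y by mature CD56dim CD57+ (and
#' NKG2C+CD57+) cells, group Z by CD56dim triple-negative cells. Metadata
#' centers give Y the lowest viral load, inflammation and activation. M3
#' kinetics add +6.6 / +1.4 / +7.7 percentage points of summed CD57+ mass.
#'
#' @param freq_spread Logistic-normal dispersion shared by the groups.
#' @return Named list of three [group_profile()] objects.
#' @export
default_group_profiles <- function(freq_spread = 0.25) {
  centers <- .default_freq_centers()
  list(
    X = group_profile("X", 14, centers$X, freq_spread,
                      .default_metadata_centers("X"),
                      m3_shift = 6.6, n_acute = 4, n_suppressed_m3 = 6),
    Y = group_profile("Y", 10, centers$Y, freq_spread,
                      .default_metadata_centers("Y"),
                      m3_shift = 1.4, n_acute = 4, n_suppressed_m3 = 7),
    Z = group_profile("Z", 4, centers$Z, freq_spread,
                      .default_metadata_centers("Z"),
                      m3_shift = 7.7, n_acute = 4, n_suppressed_m3 = 1)
  )
}

#' Cohort generator configuration
#'
#' @param group_profiles List of [group_profile()]s (default
#'   [default_group_profiles()]).
#' @param events_per_sample Events written per patient-timepoint file.
#' @param contaminant_fraction Proportion of dump-positive (non-NK) events
#'   mixed into each file, in `[0, 1)`.
#' @param healthy_donors Number of healthy-donor event files (donors have a
#'   healthy NK frequency profile and metadata but no timepoints).
#' @param phenotypes Phenotype set (default [build_default_phenotypes()]).
#' @param panel Marker panel.
#' @param seed Integer seed; fully determines the generated cohort.
#' @param format `"csv"` or `"fcs"` event-file format.
#' @return An object of class `nk_cohort_config`.
#' @export
cohort_config <- function(group_profiles = default_group_profiles(),
                          events_per_sample = 2000,
                          contaminant_fraction = 0.02,
                          healthy_donors = 1,
                          phenotypes = build_default_phenotypes(),
                          panel = nk_panel(),
                          seed = 1,
                          format = c("csv", "fcs")) {
  format <- match.arg(format)
  if (events_per_sample <= 0) stop("events_per_sample must be > 0")
  if (contaminant_fraction < 0 || contaminant_fraction >= 1) {
    stop("contaminant_fraction must be in [0, 1)")
  }
  pops <- names(phenotypes)
  for (p in group_profiles) {
    if (!all(names(p$freq_center) %in% pops)) {
      stop("group ", p$group_label,
           " has freq_center entries for unknown populations")
    }
  }
  structure(
    list(group_profiles = group_profiles,
         events_per_sample = as.integer(events_per_sample),
         contaminant_fraction = contaminant_fraction,
         healthy_donors = as.integer(healthy_donors),
         phenotypes = phenotypes, panel = panel,
         seed = as.integer(seed), format = format),
    class = "nk_cohort_config"
  )
}

#' Draw one patient's NK population frequency vector
#'
#' Logistic-normal draw around the profile's center: each center is
#' multiplied by `exp(freq_spread * z)` with independent standard-normal
#' `z`, and the vector is renormalized to sum to 100. With `freq_spread = 0`
#' the renormalized center is returned unchanged. Uses the current RNG
#' state.
#'
#' @param profile A [group_profile()].
#' @return Named numeric vector of percentages summing to 100.
#' @export
sample_patient_frequencies <- function(profile) {
  ctr <- profile$freq_center
  w <- ctr * exp(profile$freq_spread * stats::rnorm(length(ctr)))
  if (sum(w) <= 0) stop("degenerate frequency draw: all centers zero")
  100 * w / sum(w)
}

# internal: shift summed CD57+ mass for the M3 timepoint. The added mass is
# split across the CD56dim CD57+ populations proportionally to their T0
# centers and taken from the immature CD56dim pools (triple-negative and
# NKG2A+), again proportionally.
.shift_centers_m3 <- function(center, delta) {
  if (delta == 0) return(center)
  cd57 <- grepl("CD57\\+", names(center)) & grepl("CD56dim", names(center))
  src <- names(center) %in% c("CD56dim NKG2A-NKG2C-CD57-", "CD56dim NKG2A+")
  if (!any(cd57) || !any(src)) return(center)
  delta <- min(delta, sum(center[src]) * 0.95) # never empty the source pools
  center[cd57] <- center[cd57] + delta * center[cd57] / sum(center[cd57])
  center[src] <- center[src] - delta * center[src] / sum(center[src])
  center
}

#' Simulate one cytometry sample
#'
#' Events are a multinomial mixture over the phenotype set in the given
#' frequencies, each phenotype a diagonal Gaussian in the five NK markers on
#' the transformed scale. NK events are dump-negative and viable
#' (dump/viability values near 0); an optional contaminant fraction is
#' dump-positive. Uses the current RNG state.
#'
#' @param frequencies Named percentages per phenotype, summing to 100.
#' @param phenotypes Phenotype set covering `names(frequencies)`.
#' @param panel Marker panel.
#' @param n_events Number of events (>= 0).
#' @param contaminant_fraction Proportion of dump-positive events.
#' @param sample_id Sample identifier stored on the matrix.
#' @return An [event_matrix()] with all panel channels; the planted
#'   per-event phenotype (or `"contaminant"`) is attached as attribute
#'   `"truth"`.
#' @export
simulate_sample <- function(frequencies, phenotypes, panel = nk_panel(),
                            n_events = 2000, contaminant_fraction = 0,
                            sample_id = "S1") {
  if (abs(sum(frequencies) - 100) > 1e-6) {
    stop("frequencies must sum to 100 (got ", sum(frequencies), ")")
  }
  if (n_events < 0) stop("n_events must be >= 0")
  check_phenotype_monotonicity(phenotypes)
  chans <- panel_channels(panel)
  labels <- character(0)
  if (n_events > 0) {
    probs <- c(frequencies / 100 * (1 - contaminant_fraction),
               contaminant = contaminant_fraction)
    labels <- sample(names(probs), n_events, replace = TRUE, prob = probs)
  }
  x <- matrix(0, nrow = n_events, ncol = length(chans),
              dimnames = list(NULL, chans))
  base_sd <- 0.25 # dump/viability channel noise around the planted level
  if (n_events > 0) {
    x[] <- stats::rnorm(length(x), 0, base_sd)
    is_contam <- labels == "contaminant"
    for (nm in names(frequencies)) {
      idx <- which(labels == nm)
      if (!length(idx)) next
      ph <- phenotypes[[nm]]
      for (m in panel$nk_markers) {
        x[idx, m] <- stats::rnorm(length(idx), ph$means[[m]], ph$sds[[m]])
      }
    }
    if (any(is_contam)) {
      idx <- which(is_contam)
      # monocyte/T-cell-like contaminants: one dump channel high, CD16+
      hit <- sample(panel$dump_markers, length(idx), replace = TRUE)
      for (d in panel$dump_markers) {
        sel <- idx[hit == d]
        if (length(sel)) x[sel, d] <- stats::rnorm(length(sel), 4, 0.3)
      }
      x[idx, "CD56"] <- stats::rnorm(length(idx), 0, 0.3)
      x[idx, "CD16"] <- stats::rnorm(length(idx), 4, 0.3)
    }
  }
  em <- event_matrix(x, sample_id = sample_id, transform = "simulated-asinh")
  attr(em, "truth") <- labels
  em
}

#' Simulate a full synthetic cohort
#'
#' Generates one event file per patient-timepoint (T0 and M3) for every
#' group profile, plus optional healthy-donor files, a clinical metadata
#' table and a planted-truth table. The seed in the configuration fully
#' determines the output: re-running with the same configuration writes
#' byte-identical files.
#'
#' Clinical variables are drawn log-normally around the group medians with
#' the stated ranges; HIV-RNA is floored at the assay threshold of 20
#' copies/mL (log10(20) ~ 1.301) and IL-6 below the detection limit is
#' imputed at 0.46 pg/mL. Per group, a planted number of patients is
#' virally suppressed (< 50 copies/mL) at M3.
#'
#' @param config An [cohort_config()].
#' @param dir Output directory for event files and tables; created if
#'   missing. `NULL` keeps everything in memory only.
#' @return List with elements `samples` (named list of [event_matrix()]),
#'   `metadata` (data.frame, one row per patient-timepoint or donor),
#'   `truth` (data.frame of planted group labels and per-sample planted
#'   population percentages), `files` (paths, if written) and `config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(events_per_sample = 200), dir = NULL)
#' nrow(cohort$metadata)
simulate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "nk_cohort_config"))
  withr::with_seed(config$seed, .simulate_cohort_impl(config, dir))
}

.simulate_cohort_impl <- function(config, dir) {
  pops <- names(config$phenotypes)
  samples <- list()
  meta_rows <- list()
  truth_rows <- list()
  pid <- 0L
  for (prof in config$group_profiles) {
    for (i in seq_len(prof$n_patients)) {
      pid <- pid + 1L
      patient <- sprintf("P%02d", pid)
      acute <- i <= prof$n_acute
      suppressed <- i <= prof$n_suppressed_m3
      meta_t0 <- .draw_metadata(prof$metadata_centers, timepoint = "T0")
      for (tp in c("T0", "M3")) {
        sid <- paste0(patient, "_", tp)
        ctr <- prof$freq_center
        if (tp == "M3") ctr <- .shift_centers_m3(ctr, prof$m3_shift)
        prof_tp <- prof
        prof_tp$freq_center <- ctr
        freqs <- stats::setNames(numeric(length(pops)), pops)
        drawn <- sample_patient_frequencies(prof_tp)
        freqs[names(drawn)] <- drawn
        em <- simulate_sample(freqs, config$phenotypes, config$panel,
                              config$events_per_sample,
                              config$contaminant_fraction, sample_id = sid)
        samples[[sid]] <- em
        md <- if (tp == "T0") meta_t0 else {
          .draw_metadata_m3(meta_t0, prof$metadata_centers, suppressed)
        }
        meta_rows[[sid]] <- data.frame(
          sample_id = sid, patient_id = patient, timepoint = tp,
          acute = acute, suppressed_m3 = suppressed, md,
          stringsAsFactors = FALSE)
        truth_rows[[sid]] <- data.frame(
          sample_id = sid, patient_id = patient, timepoint = tp,
          group_label = prof$group_label, t(freqs),
          check.names = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  hd_centers <- .default_freq_centers()$healthy
  hd_meta_ctr <- .default_metadata_centers("healthy")
  for (j in seq_len(config$healthy_donors)) {
    sid <- sprintf("HD%02d", j)
    prof_hd <- group_profile("healthy", 1,
                             hd_centers[intersect(names(hd_centers), pops)],
                             freq_spread = config$group_profiles[[1]]$freq_spread)
    freqs <- stats::setNames(numeric(length(pops)), pops)
    drawn <- sample_patient_frequencies(prof_hd)
    freqs[names(drawn)] <- drawn
    em <- simulate_sample(freqs, config$phenotypes, config$panel,
                          config$events_per_sample,
                          config$contaminant_fraction, sample_id = sid)
    samples[[sid]] <- em
    md <- .draw_metadata(hd_meta_ctr, timepoint = "T0")
    meta_rows[[sid]] <- data.frame(
      sample_id = sid, patient_id = sid, timepoint = "T0",
      acute = FALSE, suppressed_m3 = NA, md, stringsAsFactors = FALSE)
    truth_rows[[sid]] <- data.frame(
      sample_id = sid, patient_id = sid, timepoint = "T0",
      group_label = "healthy", t(freqs),
      check.names = FALSE, stringsAsFactors = FALSE)
  }
  metadata <- do.call(rbind, meta_rows)
  truth <- do.call(rbind, truth_rows)
  rownames(metadata) <- rownames(truth) <- NULL
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    ext <- if (config$format == "csv") ".csv" else ".fcs"
    files <- vapply(names(samples), function(sid) {
      path <- file.path(dir, paste0(sid, ext))
      write_events(samples[[sid]], path, format = config$format)
      path
    }, character(1))
    utils::write.table(metadata, file.path(dir, "metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(samples = samples, metadata = metadata, truth = truth,
       files = files, config = config)
}

# log-normal draw around median within (lo, hi); ~95% of mass inside the
# range. Detection-limit behavior: HIV-RNA floored at 20 copies/mL,
# IL-6 imputed at half the minimal detectable value.
.draw_metadata <- function(centers, timepoint) {
  draw1 <- function(ctr) {
    if (is.null(ctr)) return(NA_real_)
    sd_log <- (log(ctr[3]) - log(ctr[2])) / 4
    ctr[1] * exp(stats::rnorm(1, 0, sd_log))
  }
  hiv_rna <- draw1(centers$hiv_rna) # already on log10 scale
  if (!is.na(hiv_rna)) hiv_rna <- max(hiv_rna, log10(20))
  il6 <- draw1(centers$il6)
  if (!is.na(il6)) il6 <- max(il6, 0.46)
  data.frame(
    hiv_rna = hiv_rna,
    hiv_dna = draw1(centers$hiv_dna),
    cd4 = draw1(centers$cd4),
    cd8 = draw1(centers$cd8),
    il6 = il6,
    ip10 = draw1(centers$ip10),
    pdc_pct = draw1(centers$pdc_pct),
    mdc_pct = draw1(centers$mdc_pct),
    cd38 = draw1(centers$cd38),
    cd86 = draw1(centers$cd86),
    pdl1 = draw1(centers$pdl1)
  )
}

.draw_metadata_m3 <- function(meta_t0, centers, suppressed) {
  md <- meta_t0
  # ~3 log10 viral-load decay; suppressed patients land below 50 copies/mL,
  # with the assay floor at 20 copies/mL
  md$hiv_rna <- if (suppressed) {
    log10(max(20, 10^stats::runif(1, log10(5), log10(49))))
  } else {
    stats::runif(1, log10(51), max(log10(52), min(3.42, md$hiv_rna - 2)))
  }
  md$hiv_dna <- md$hiv_dna - stats::runif(1, 0.5, 1.1)
  md$cd4 <- md$cd4 * stats::runif(1, 1.0, 1.3)
  md$cd8 <- md$cd8 * stats::runif(1, 0.4, 0.8)
  md$il6 <- max(0.46, md$il6 * stats::runif(1, 0.4, 0.9))
  md$ip10 <- md$ip10 * stats::runif(1, 0.3, 0.7)
  md
}
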