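#' Default beat morphology template
#'
#' Each beat is synthesized as a sum of five Gaussian wavelets, one per ECG
#' wave (P, Q, R, S, T), parameterized by amplitude (mV), width (the Gaussian
#' SD, in seconds) and offset of the wave center relative to the R peak
#' (seconds). The default values give a plausible single-lead morphology with
#' distinct P/QRS/T structure that survives downsampling to the 8 Hz symbol
#' rate.
#'
#' @return A data frame with columns `wave`, `amplitude`, `width`, `offset`.
#' @export
#' @examples
#' wave_template()
wave_template <- function() {
  data.frame(
    wave      = c("P", "Q", "R", "S", "T"),
    amplitude = c(0.15, -0.10, 1.00, -0.15, 0.30),
    width     = c(0.025, 0.010, 0.012, 0.012, 0.060),
    offset    = c(-0.200, -0.030, 0.000, 0.030, 0.250),
    stringsAsFactors = FALSE
  )
}

validate_template <- function(template) {
  need <- c("wave", "amplitude", "width", "offset")
  if (!all(need %in% names(template))) {
    stop_("beat template must have columns %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(template$wave)) stop_("beat template wave labels must be unique")
  if (any(template$width <= 0)) stop_("beat template widths must be positive")
  template
}

#' Specification of a synthetic three-group ECG cohort
#'
#' Describes the cohort emulated by [generate_cohort()]: three groups
#' (control, prodromal, prevalent) of 10-second single-lead ECGs. Group heart
#' rate centers follow the published cohort summaries (mean HR about
#' 65.3 / 64.5 / 68.2 bpm and within-subject HR SD about 2.65 / 3.87 /
#' 1.20 bpm for controls / prodromal / prevalent); subject-level spread
#' around those centers is configurable.
#'
#' The disease signature is expressed over a `morph_delta` fraction of the
#' record (0 for controls, 0.5 for the prodromal-like group, 1.0 for the
#' prevalent-like group): within signature segments the record carries a
#' time-locked slow oscillation (`osc_freq` Hz, amplitude `osc_amp` mV,
#' phase on the symbol grid) and a period-2 beat-to-beat T-wave amplitude
#' alternans of relative depth `alt_depth`. Non-signature segments carry a
#' subject-specific slow oscillation (frequency drawn from `own_freq_range`)
#' and a smooth respiratory-like T modulation of the same depth, so that
#' groups differ in shared pattern structure rather than raw variability.
#' R-wave amplitude is never modulated; the signature therefore leaves the
#' R-peak series, and hence all HR characteristics, untouched.
#'
#' @param n_control,n_prodromal,n_prevalent group sizes (default 25/25/10).
#' @param duration record length in seconds.
#' @param fs sampling rate in Hz.
#' @param global_seed integer master seed; every subject's seed is derived
#'   from it, so a spec fully determines the cohort.
#' @param hr_mean,hr_sd per-group centers of the subject HR mean (bpm) and
#'   within-subject HR SD (bpm), in the order control, prodromal, prevalent.
#' @param hr_mean_spread SD (bpm) of subject HR means around the group center.
#' @param hr_sd_spread SD (bpm) of the gamma distribution from which each
#'   subject's within-record HR SD is drawn.
#' @param morph_delta per-group signature duty fraction in `[0, 1]`.
#' @param noise_sd additive white measurement noise SD (mV).
#' @param cal_sd SD of the log-normal per-subject calibration scale factor
#'   (emulates amplitude calibration differences between digitized records).
#' @param alt_depth relative depth of the T-wave alternans.
#' @param osc_amp,osc_freq amplitude (mV) and frequency (Hz) of the shared
#'   signature oscillation; `osc_freq` should divide the symbol rate so the
#'   oscillation has an integer period on the symbol grid.
#' @param seg_len signature segment length in seconds.
#' @param own_freq_range,resp_freq_range frequency ranges (Hz) for the
#'   subject-specific oscillation and the respiratory-like T modulation.
#' @param template beat morphology template, see [wave_template()].
#'
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec(n_control = 2, n_prodromal = 2, n_prevalent = 1)
#' spec
cohort_spec <- function(n_control = 25, n_prodromal = 25, n_prevalent = 10,
                        duration = 10, fs = 500, global_seed = 1L,
                        hr_mean = c(control = 65.30, prodromal = 64.50, prevalent = 68.24),
                        hr_sd = c(control = 2.65, prodromal = 3.87, prevalent = 1.20),
                        hr_mean_spread = 3.0,
                        hr_sd_spread = 2.0,
                        morph_delta = c(control = 0, prodromal = 0.5, prevalent = 1.0),
                        noise_sd = 0.02,
                        cal_sd = 0.15,
                        alt_depth = 0.35,
                        osc_amp = 0.22,
                        osc_freq = 1.6,
                        seg_len = 5,
                        own_freq_range = c(0.5, 1.2),
                        resp_freq_range = c(0.15, 0.45),
                        template = wave_template()) {
  counts <- c(n_control, n_prodromal, n_prevalent)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_("group counts must be non-negative integers")
  }
  if (duration <= 0) stop_("duration must be positive")
  if (fs <= 0) stop_("fs must be positive")
  groups <- c("control", "prodromal", "prevalent")
  named3 <- function(x, what) {
    if (length(x) == 1) x <- rep(x, 3)
    if (length(x) != 3) stop_("%s must have length 1 or 3", what)
    stats::setNames(as.numeric(x), groups)
  }
  spec <- structure(list(
    n_control = as.integer(n_control),
    n_prodromal = as.integer(n_prodromal),
    n_prevalent = as.integer(n_prevalent),
    duration = duration, fs = fs, global_seed = as.integer(global_seed),
    hr_mean = named3(hr_mean, "hr_mean"), hr_sd = named3(hr_sd, "hr_sd"),
    hr_mean_spread = hr_mean_spread, hr_sd_spread = hr_sd_spread,
    morph_delta = named3(morph_delta, "morph_delta"),
    noise_sd = noise_sd, cal_sd = cal_sd,
    alt_depth = alt_depth, osc_amp = osc_amp, osc_freq = osc_freq,
    seg_len = seg_len, own_freq_range = own_freq_range,
    resp_freq_range = resp_freq_range,
    template = validate_template(template)
  ), class = "cohort_spec")
  if (any(spec$hr_mean <= 0) || any(spec$hr_sd < 0)) {
    stop_("hr_mean must be positive and hr_sd non-negative")
  }
  if (any(spec$morph_delta < 0 | spec$morph_delta > 1)) {
    stop_("morph_delta must lie in [0, 1]")
  }
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic ECG cohort spec: %d control / %d prodromal / %d prevalent\n",
              x$n_control, x$n_prodromal, x$n_prevalent))
  cat(sprintf("  %.0f s at %.0f Hz, global seed %d\n", x$duration, x$fs, x$global_seed))
  cat(sprintf("  HR centers (bpm): %s\n",
              paste(sprintf("%s %.2f/%.2f", names(x$hr_mean), x$hr_mean, x$hr_sd),
                    collapse = ", ")))
  cat(sprintf("  signature duty: %s\n",
              paste(sprintf("%s %.2f", names(x$morph_delta), x$morph_delta),
                    collapse = ", ")))
  invisible(x)
}

cohort_groups <- c("control", "prodromal", "prevalent")

#' Draw per-subject simulation parameters
#'
#' Deterministically derives one subject's simulation parameters from the
#' cohort spec: a subject seed is hashed from `(global_seed, group, index)`,
#' and the subject's HR mean (normal around the group center, floored at
#' 40 bpm), within-record HR SD (gamma around the group center, floored at
#' 0.05 bpm), calibration factor and signature duty fraction are drawn under
#' that seed.
#'
#' @param spec a [cohort_spec()].
#' @param group one of `"control"`, `"prodromal"`, `"prevalent"`.
#' @param index 1-based subject index within the group.
#' @return An object of class `subject_sim_params`.
#' @export
#' @examples
#' make_subject_params(cohort_spec(), "control", 1)
make_subject_params <- function(spec, group, index) {
  if (!group %in% cohort_groups) {
    stop_("unknown group label '%s' (expected one of %s)",
          group, paste(cohort_groups, collapse = ", "))
  }
  n_group <- switch(group, control = spec$n_control,
                    prodromal = spec$n_prodromal, prevalent = spec$n_prevalent)
  if (index < 1 || index > max(n_group, 1)) {
    stop_("index %d out of range for group '%s' (n = %d)", index, group, n_group)
  }
  seed <- mix_seed(spec$global_seed, group, index)
  with_seed(seed, {
    hr_mean <- max(40, stats::rnorm(1, spec$hr_mean[[group]], spec$hr_mean_spread))
    c0 <- spec$hr_sd[[group]]; s0 <- spec$hr_sd_spread
    hr_sd <- if (c0 == 0 || s0 == 0) c0 else {
      max(0.05, stats::rgamma(1, shape = (c0 / s0)^2, rate = c0 / s0^2))
    }
    cal <- exp(stats::rnorm(1, 0, spec$cal_sd))
    structure(list(
      subject_id = sprintf("%s_%03d", group, index),
      group = group, index = as.integer(index),
      hr_mean = hr_mean, hr_sd = hr_sd,
      morph_delta = spec$morph_delta[[group]],
      noise_sd = spec$noise_sd, cal = cal, seed = seed
    ), class = "subject_sim_params")
  })
}

#' Generate an RR interval series
#'
#' Instantaneous heart rate is drawn i.i.d. from a normal distribution with
#' the subject's HR mean and SD, truncated below at 20 bpm, and converted to
#' RR intervals (seconds). Intervals are appended until their cumulative sum
#' covers `duration`.
#'
#' @param params a [make_subject_params()] result.
#' @param duration time span to cover, seconds.
#' @param .seed seed the draw from the subject seed (default). Internal
#'   callers that manage the RNG stream themselves pass `FALSE`.
#' @return Numeric vector of RR intervals (seconds), at least one.
#' @export
#' @examples
#' p <- make_subject_params(cohort_spec(), "control", 1)
#' rr <- generate_rr_series(p, 10)
#' sum(rr) >= 10
generate_rr_series <- function(params, duration, .seed = TRUE) {
  if (duration <= 0) stop_("duration must be positive")
  draw <- function() {
    rr <- numeric(0)
    total <- 0
    repeat {
      hr <- max(20, stats::rnorm(1, params$hr_mean, params$hr_sd))
      rr <- c(rr, 60 / hr)
      total <- total + 60 / hr
      if (total >= duration) break
    }
    rr
  }
  rr <- if (.seed) with_seed(mix_seed(params$seed, 1), draw()) else draw()
  if (length(rr) == 1 && rr[1] > duration) {
    warn_("subject %s: mean RR exceeds the record duration; single beat emitted",
          params$subject_id)
  }
  rr
}

#' Synthesize one single-lead ECG record
#'
#' Renders the subject's beat train (sum of Gaussian wavelets per beat,
#' T-wave amplitude modulated as described in [cohort_spec()]), adds the
#' segment-wise slow oscillation, applies the subject calibration factor and
#' additive white noise. The true R-peak times are returned in the record as
#' ground truth for detector tests.
#'
#' @param params a [make_subject_params()] result.
#' @param spec the [cohort_spec()] the parameters were drawn from.
#' @return An object of class `ecg_record` with fields `subject_id`,
#'   `group`, `fs`, `duration`, `samples` (mV) and `r_times` (s).
#' @export
#' @examples
#' spec <- cohort_spec()
#' rec <- synthesize_ecg(make_subject_params(spec, "prevalent", 1), spec)
#' length(rec$samples)
synthesize_ecg <- function(params, spec) {
  n <- round(spec$duration * spec$fs)
  t <- (seq_len(n) - 1) / spec$fs
  with_seed(mix_seed(params$seed, 1), {
    rr <- generate_rr_series(params, spec$duration, .seed = FALSE)
    r_times <- cumsum(rr) - rr[1] / 2 + 0.3
    r_times <- r_times[r_times < spec$duration + 0.5]

    nseg <- ceiling(spec$duration / spec$seg_len)
    nsig <- round(params$morph_delta * nseg)
    sig_seg <- seq_len(nseg) <= nsig
    seg_of <- function(tt) pmin(floor(tt / spec$seg_len) + 1, nseg)

    f_resp <- stats::runif(1, spec$resp_freq_range[1], spec$resp_freq_range[2])
    ph_resp <- stats::runif(1, 0, 2 * pi)

    x <- numeric(n)
    tmpl <- spec$template
    t_row <- match("T", tmpl$wave)
    for (i in seq_along(r_times)) {
      in_sig <- sig_seg[seg_of(r_times[i])]
      mod <- if (in_sig) {
        1 + spec$alt_depth * (-1)^i
      } else {
        1 + spec$alt_depth * sin(2 * pi * f_resp * r_times[i] + ph_resp)
      }
      for (w in seq_len(nrow(tmpl))) {
        a <- tmpl$amplitude[w]
        if (w == t_row) a <- a * mod
        mu <- r_times[i] + tmpl$offset[w]
        sd_w <- tmpl$width[w]
        lo <- max(1L, floor((mu - 5 * sd_w) * spec$fs) + 1L)
        hi <- min(n, ceiling((mu + 5 * sd_w) * spec$fs) + 1L)
        if (lo <= hi) {
          idx <- lo:hi
          x[idx] <- x[idx] + a * exp(-((t[idx] - mu)^2) / (2 * sd_w^2))
        }
      }
    }

    per <- max(2L, round(8 / spec$osc_freq))  # oscillation period in symbols
    osc <- numeric(n)
    seg_id <- seg_of(t)
    for (s in seq_len(nseg)) {
      idx <- which(seg_id == s)
      if (!length(idx)) next
      if (sig_seg[s]) {
        k <- sample(0:(per - 1), 1)
        osc[idx] <- spec$osc_amp * sin(2 * pi * spec$osc_freq * t[idx] + 2 * pi * k / per)
      } else {
        f_own <- stats::runif(1, spec$own_freq_range[1], spec$own_freq_range[2])
        ph_own <- stats::runif(1, 0, 2 * pi)
        osc[idx] <- spec$osc_amp * sin(2 * pi * f_own * t[idx] + ph_own)
      }
    }

    samples <- params$cal * (x + osc)
    if (params$noise_sd > 0) samples <- samples + stats::rnorm(n, 0, params$noise_sd)

    structure(list(
      subject_id = params$subject_id, group = params$group,
      fs = spec$fs, duration = spec$duration,
      samples = samples,
      r_times = r_times[r_times >= 0 & r_times < spec$duration]
    ), class = "ecg_record")
  })
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ECG record %s (%s): %.0f s at %.0f Hz, %d samples, %d R peaks\n",
              x$subject_id, x$group, x$duration, x$fs,
              length(x$samples), length(x$r_times)))
  invisible(x)
}

#' Generate a complete synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `ecg_cohort`: a list with `records` (list of
#'   [synthesize_ecg()] records), `manifest` (data frame with `subject_id`,
#'   `group`, `seed`) and the `spec`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_control = 2, n_prodromal = 2, n_prevalent = 1))
#' coh$manifest
generate_cohort <- function(spec) {
  counts <- c(control = spec$n_control, prodromal = spec$n_prodromal,
              prevalent = spec$n_prevalent)
  records <- list()
  rows <- list()
  for (g in cohort_groups) {
    for (i in seq_len(counts[[g]])) {
      p <- make_subject_params(spec, g, i)
      records[[p$subject_id]] <- synthesize_ecg(p, spec)
      rows[[p$subject_id]] <- data.frame(subject_id = p$subject_id, group = g,
                                         seed = p$seed, stringsAsFactors = FALSE)
    }
  }
  manifest <- if (length(rows)) do.call(rbind, unname(rows)) else {
    data.frame(subject_id = character(), group = character(), seed = integer())
  }
  rownames(manifest) <- NULL
  structure(list(records = records, manifest = manifest, spec = spec),
            class = "ecg_cohort")
}

#' @export
print.ecg_cohort <- function(x, ...) {
  tab <- table(factor(x$manifest$group, levels = cohort_groups))
  cat(sprintf("Synthetic ECG cohort: %d records (%s)\n", nrow(x$manifest),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Write / read an ECG record as CSV
#'
#' Two-column CSV (`time_s`, `amplitude_mv`) preceded by a single comment
#' line carrying the sampling rate, subject id and group.
#'
#' @param record an `ecg_record`.
#' @param path file path.
#' @return `write_ecg_csv` returns `path` invisibly; `read_ecg_csv` returns
#'   the reconstructed `ecg_record` (without ground-truth R times).
#' @export
write_ecg_csv <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g subject_id=%s group=%s duration=%g",
                     record$fs, record$subject_id, record$group, record$duration), con)
  writeLines("time_s,amplitude_mv", con)
  tt <- (seq_along(record$samples) - 1) / record$fs
  writeLines(sprintf("%.6f,%.8g", tt, record$samples), con)
  invisible(path)
}

#' @rdname write_ecg_csv
#' @export
read_ecg_csv <- function(path) {
  header <- readLines(path, n = 1)
  kv <- function(key, default = NA) {
    m <- regmatches(header, regexec(sprintf("%s=([^ ]+)", key), header))[[1]]
    if (length(m) == 2) m[2] else default
  }
  dat <- utils::read.csv(path, comment.char = "#")
  fs <- as.numeric(kv("fs"))
  structure(list(
    subject_id = kv("subject_id", "unknown"), group = kv("group", "unknown"),
    fs = fs, duration = as.numeric(kv("duration", length(dat$amplitude_mv) / fs)),
    samples = dat$amplitude_mv, r_times = NULL
  ), class = "ecg_record")
}

#' Write a cohort to a directory
#'
#' Writes one signal CSV per subject plus `manifest.csv` with columns
#' `subject_id`, `group`, `seed`, `file`.
#'
#' @param cohort an `ecg_cohort`.
#' @param dir output directory (created if missing).
#' @return The manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- cohort$manifest
  manifest$file <- sprintf("%s.csv", manifest$subject_id)
  for (i in seq_len(nrow(manifest))) {
    write_ecg_csv(cohort$records[[manifest$subject_id[i]]],
                  file.path(dir, manifest$file[i]))
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  records <- lapply(seq_len(nrow(manifest)), function(i) {
    rec <- read_ecg_csv(file.path(dir, manifest$file[i]))
    rec$subject_id <- manifest$subject_id[i]
    rec$group <- manifest$group[i]
    rec
  })
  names(records) <- manifest$subject_id
  structure(list(records = records, manifest = manifest, spec = NULL),
            class = "ecg_cohort")
}
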