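#' Specification of a synthetic two-class cohort
#'
#' Describes the stated world the cohort simulator draws from: a case/control
#' blood-transcriptomics study on the log2 scale. Defaults mirror the
#' discovery cohort this package targets: 40 cases vs 20 controls, and
#' differential probes spiked at linear fold changes between 1.2 and 1.5
#' (expression changes of 20-50 % between patients and controls).
#'
#' @param n_cases,n_controls Number of case/control samples (40 / 20).
#' @param n_probes Number of probes on the synthetic array.
#' @param n_spiked Number of truly differential probes (split evenly between
#'   up- and down-regulation in cases).
#' @param fold_change_range Length-2 numeric, linear-scale fold-change range
#'   `c(low, high)` with `1 <= low <= high`, sampled uniformly per spiked
#'   probe.
#' @param baseline_log_mean Grand mean of probe baselines, log2 units.
#' @param between_probe_sd Spread of probe baseline means around
#'   `baseline_log_mean` (log2 units); gives the array a realistic intensity
#'   range so the detection filter has work to do.
#' @param probe_sd Within-probe, between-sample noise sd (log2 units).
#' @param detection_threshold Linear intensity above which a measurement is
#'   called Present (Marginal down to half of it, Absent below).
#' @param seed Integer seed; fixed seed implies bit-identical output.
#'
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_cases = 40, n_controls = 20, n_probes = 2000,
                        n_spiked = 100, fold_change_range = c(1.2, 1.5),
                        baseline_log_mean = 8, between_probe_sd = 1.5,
                        probe_sd = 0.25, detection_threshold = 100,
                        seed = 1L) {
  spec <- list(
    n_cases = check_count(n_cases, "n_cases"),
    n_controls = check_count(n_controls, "n_controls"),
    n_probes = check_count(n_probes, "n_probes"),
    n_spiked = check_count(n_spiked, "n_spiked", min = 0L),
    fold_change_range = fold_change_range,
    baseline_log_mean = check_number(baseline_log_mean, "baseline_log_mean"),
    between_probe_sd = check_number(between_probe_sd, "between_probe_sd", min = 0),
    probe_sd = check_number(probe_sd, "probe_sd", min = 0),
    detection_threshold = check_number(detection_threshold,
                                       "detection_threshold", min = 0,
                                       strict_min = TRUE),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (!is.numeric(fold_change_range) || length(fold_change_range) != 2L ||
      any(is.na(fold_change_range)) || fold_change_range[1] < 1 ||
      fold_change_range[1] > fold_change_range[2]) {
    abort("`fold_change_range` must be c(low, high) with 1 <= low <= high.",
          class = "pdblood_validation_error")
  }
  if (spec$n_spiked > spec$n_probes) {
    abort("`n_spiked` must not exceed `n_probes`.",
          class = "pdblood_validation_error")
  }
  structure(spec, class = "cohort_spec")
}

#' Simulate a two-class expression cohort
#'
#' Draws a log-normal intensity model: each probe has a baseline log2 mean;
#' spiked probes shift their case mean by `log2(fc)` with `fc` uniform over
#' the spec's fold-change range, half up and half down; Gaussian noise with
#' sd `probe_sd` is added on the log2 scale. Detection calls are derived
#' deterministically from linear intensity: Present at or above the
#' detection threshold, Marginal at or above half of it, Absent below.
#'
#' @param spec A [cohort_spec()].
#' @return An [expression_dataset()] with per-probe `truth` flags
#'   (`spiked-up` / `spiked-down` / `null`).
#' @examples
#' ds <- simulate_cohort(cohort_spec(n_probes = 200, n_spiked = 10, seed = 7))
#' glance(ds)
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_cases + spec$n_controls
  with_seed(spec$seed, {
    baseline <- rnorm(spec$n_probes, spec$baseline_log_mean,
                      spec$between_probe_sd)
    truth <- rep("null", spec$n_probes)
    if (spec$n_spiked > 0L) {
      spiked <- sample.int(spec$n_probes, spec$n_spiked)
      n_up <- ceiling(spec$n_spiked / 2)
      truth[spiked[seq_len(n_up)]] <- "spiked-up"
      if (spec$n_spiked > n_up) {
        truth[spiked[(n_up + 1):spec$n_spiked]] <- "spiked-down"
      }
    }
    fc <- runif(spec$n_probes, spec$fold_change_range[1],
                spec$fold_change_range[2])
    shift <- ifelse(truth == "spiked-up", log2(fc),
                    ifelse(truth == "spiked-down", -log2(fc), 0))
    mu <- matrix(baseline, spec$n_probes, n)
    case_cols <- seq_len(spec$n_cases)
    mu[, case_cols] <- mu[, case_cols] + shift
    log_exprs <- mu + matrix(rnorm(spec$n_probes * n, 0, spec$probe_sd),
                             spec$n_probes, n)
    dimnames(log_exprs) <- list(
      sprintf("probe_%05d", seq_len(spec$n_probes)),
      c(sprintf("PD%03d", seq_len(spec$n_cases)),
        sprintf("HC%03d", seq_len(spec$n_controls)))
    )
    lin <- 2^log_exprs
    calls <- matrix("A", spec$n_probes, n, dimnames = dimnames(log_exprs))
    calls[lin >= spec$detection_threshold / 2] <- "M"
    calls[lin >= spec$detection_threshold] <- "P"
    expression_dataset(
      log_exprs = log_exprs,
      calls = calls,
      class_labels = rep(c("case", "control"),
                         c(spec$n_cases, spec$n_controls)),
      gene_ids = sprintf("GENE%05d", seq_len(spec$n_probes)),
      truth = truth
    )
  })
}
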