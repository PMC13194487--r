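#' Synthetic cohort-pair specification
#'
#' Parameters of the synthetic generator that emulates the paired-cohort
#' regime the model is built for: two cohorts with partially overlapping
#' feature sets, ordinal severity driving spirometry, symptoms and
#' functional capacity, configurable missingness and an optional
#' source/target domain shift. Defaults mirror the study conditions:
#' cohort sizes 224 and 101 with stage mixes proportional to
#' 80/60/43/41 (source) and 23/43/27/8 (target).
#'
#' @param n_source,n_target Cohort sizes.
#' @param stage_probs_source,stage_probs_target Stage probability vectors
#'   (length 4, summing to 1).
#' @param signal_strength Separation of the stage-conditional means of the
#'   symptom, exposure and functional-capacity features, in units of their
#'   noise SD. 0 removes all severity signal outside spirometry; 1 (the
#'   default) is a strong, clearly staged cohort.
#' @param noise_sd Multiplier on every feature's measurement-noise SD
#'   (>= 0; 0 gives noiseless measurements).
#' @param missing_rate MCAR probability that any feature cell is missing,
#'   in \[0, 1).
#' @param domain_shift Additive offset applied to the target cohort's
#'   continuous shared features, in units of each feature's noise scale.
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_source = 224L, n_target = 101L,
                     stage_probs_source = c(80, 60, 43, 41) / 224,
                     stage_probs_target = c(23, 43, 27, 8) / 101,
                     signal_strength = 1, noise_sd = 1,
                     missing_rate = 0.1, domain_shift = 0, seed = 1L) {
  check_scalar_number(n_source, "n_source", lower = 1)
  check_scalar_number(n_target, "n_target", lower = 1)
  for (nm in c("stage_probs_source", "stage_probs_target")) {
    p <- get(nm)
    if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-12) {
      abort(sprintf("`%s` must be 4 non-negative probabilities summing to 1.", nm))
    }
  }
  check_scalar_number(signal_strength, "signal_strength", lower = 0)
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  check_scalar_number(missing_rate, "missing_rate", 0, 1, open_upper = TRUE)
  check_scalar_number(domain_shift, "domain_shift")
  check_scalar_number(seed, "seed")
  structure(
    list(
      n_source = as.integer(n_source), n_target = as.integer(n_target),
      stage_probs_source = stage_probs_source,
      stage_probs_target = stage_probs_target,
      signal_strength = signal_strength, noise_sd = noise_sd,
      missing_rate = missing_rate, domain_shift = domain_shift,
      seed = as.integer(seed)
    ),
    class = "sim_spec"
  )
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf(
    "<sim_spec> n = %d source / %d target; signal %.2f, noise %.2f, missing %.0f%%, shift %.2f, seed %d\n",
    x$n_source, x$n_target, x$signal_strength, x$noise_sd,
    100 * x$missing_rate, x$domain_shift, x$seed
  ))
  invisible(x)
}

#' GOLD stage from percent-predicted FEV1
#'
#' The standard spirometric severity bands: stage 1 for FEV1 >= 80% of
#' predicted, stage 2 for \[50, 80), stage 3 for \[30, 50), stage 4 below
#' 30%. Bands are left-closed, so exactly 50% is stage 2.
#'
#' @param fev1_percent_predicted Positive numeric vector.
#' @return Integer stages 1-4.
#' @examples
#' assign_stage_from_fev1pct(c(85, 50, 25)) # 1 2 4
#' @export
assign_stage_from_fev1pct <- function(fev1_percent_predicted) {
  x <- fev1_percent_predicted
  if (anyNA(x) || any(x <= 0)) abort("FEV1 %predicted must be positive.")
  as.integer(ifelse(x >= 80, 1L, ifelse(x >= 50, 2L, ifelse(x >= 30, 3L, 4L))))
}

#' Predicted healthy FEV1 from demographics
#'
#' Simplified linear reference equation used by the generator: the FEV1 a
#' healthy person of the same age and sex would be expected to have, in
#' liters. Percent-predicted FEV1 is `100 * FEV1 / predicted_fev1()`.
#'
#' @param age Age in years.
#' @param sex 0 = female, 1 = male.
#' @return Predicted FEV1 in liters.
#' @export
predicted_fev1 <- function(age, sex) {
  ifelse(sex == 1, 4.2 - 0.028 * (age - 40), 3.0 - 0.022 * (age - 40))
}

# Percent-predicted FEV1 bands used for generation (subranges of the
# staging bands so labels are recoverable in the noiseless limit).
.gen_bands <- list(`1` = c(80, 100), `2` = c(50, 80), `3` = c(30, 50), `4` = c(15, 30))

# Draw one cohort's worth of clinical features for given stages.
simulate_cohort_rows <- function(stage, sig, noise) {
  n <- length(stage)
  s0 <- stage - 1L  # 0-based severity for linear trends

  fev1pp_true <- vapply(stage, function(s) {
    b <- .gen_bands[[as.character(s)]]
    runif(1, b[1], b[2])
  }, numeric(1))

  # Patient-level frailty/effort factor. It depresses measured spirometry
  # (poor effort under-records lung function) and also loads on the walk
  # tests and symptom scores, so the severity signal is only fully
  # decodable by combining the shared and private blocks - the regime the
  # shared-private architecture is built for. All its loadings scale with
  # `noise`, so the noiseless limit keeps labels exactly recoverable from
  # percent-predicted FEV1.
  u <- rnorm(n)
  fev1pp_obs <- pmax(fev1pp_true - 12 * u * noise + rnorm(n, 0, 7 * noise), 5)

  age <- round(clamp(rnorm(n, 62 + 1.8 * (stage - 2.5) * sig, 9), 40, 100))
  sex <- rbinom(n, 1, 0.6)
  smoking <- vapply(seq_len(n), function(i) {
    w <- c(max(0.45 - 0.10 * s0[i] * sig, 0.05), 0.35, 0.20 + 0.10 * s0[i] * sig)
    sample(0:2, 1, prob = w / sum(w))
  }, numeric(1))
  pack_years <- clamp(rnorm(n, 10 + 9 * s0 * sig, 8 * noise + 2), 0, 110)

  # FEV1 in liters is percent-predicted times a demographic reference
  # value, so the informative quantity is a ratio of features - a
  # deliberately nonlinear signal.
  # Truncation to the instrument range preserves the noiseless-limit
  # recoverability of the stage: a clamped FEV1 maps back to a percent-
  # predicted value inside the same severity band.
  fev1 <- clamp(fev1pp_obs / 100 * predicted_fev1(age, sex), 0.4, 4.0)
  ratio <- clamp(0.40 + 0.0030 * fev1pp_true + rnorm(n, 0, 0.06 * noise), 0.25, 0.92)
  fvc <- fev1 / ratio

  tibble(
    age = age, sex = sex, smoking_status = smoking, pack_years = pack_years,
    FEV1 = fev1, FVC = fvc, FEV1_FVC = ratio,
    CAT = clamp(round(4 + 8 * s0 * sig + 2.5 * u * noise +
                        rnorm(n, 0, 3 * noise + 0.5)), 0, 40),
    exacerbations = rpois(n, (0.1 + 0.8 * s0 * sig) * exp(0.25 * u * noise)),
    MWT1 = clamp(580 - 95 * s0 * sig - 25 * u * noise +
                   rnorm(n, 0, 35 * noise + 5), 60, 800),
    .fev1pp_true = fev1pp_true
  ) |>
    dplyr::mutate(MWT2 = clamp(.data$MWT1 - 8 + rnorm(n, 0, 15 * noise + 2), 50, 800))
}

# Per-feature scales used to express domain_shift in noise-SD units.
.shift_scales <- c(age = 9, pack_years = 8, FEV1 = 0.2, FVC = 0.3, FEV1_FVC = 0.05)

#' Generate a paired synthetic source/target cohort
#'
#' Draws GOLD stages from the configured stage mixes, then simulates
#' clinically plausible features: percent-predicted FEV1 uniform inside
#' the stage's spirometric band plus measurement noise, FEV1 / FVC /
#' FEV1:FVC derived consistently from demographics, stage-correlated
#' smoking exposure and demographics, source-private symptom burden (CAT,
#' exacerbations, increasing with stage) and target-private walk-test
#' distances (decreasing with stage). Each non-label cell is then masked
#' missing completely at random at `missing_rate`, and the target cohort's
#' continuous shared features are offset by `domain_shift`.
#'
#' In the noiseless, fully observed limit the stage is a deterministic
#' function of percent-predicted FEV1 (recoverable via
#' `100 * FEV1 / predicted_fev1(age, sex)` and
#' [assign_stage_from_fev1pct()]).
#'
#' @param spec A [sim_spec()].
#' @return A list with `cohort_tbl` elements `source` and `target`.
#' @examples
#' pair <- generate_pair(sim_spec(n_source = 20, n_target = 10, seed = 3))
#' table(pair$target$gold)
#' @export
generate_pair <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, {
    make <- function(n, probs, domain) {
      stage <- sample(1:4, n, replace = TRUE, prob = probs)
      rows <- simulate_cohort_rows(stage, spec$signal_strength, spec$noise_sd)
      rows$.fev1pp_true <- NULL
      keep <- if (domain == "source") {
        c("age", "sex", "smoking_status", "pack_years", "FEV1", "FVC",
          "FEV1_FVC", "CAT", "exacerbations")
      } else {
        c("age", "sex", "smoking_status", "pack_years", "FEV1", "FVC",
          "FEV1_FVC", "MWT1", "MWT2")
      }
      rows <- rows[keep]
      if (domain == "target" && spec$domain_shift != 0) {
        for (f in names(.shift_scales)) {
          rows[[f]] <- rows[[f]] + spec$domain_shift * .shift_scales[[f]]
        }
      }
      if (spec$missing_rate > 0) {
        for (f in names(rows)) {
          drop <- runif(n) < spec$missing_rate
          rows[[f]][drop] <- NA_real_
        }
      }
      rows$GOLD <- stage
      cohort_table(rows, domain = domain)
    }
    list(
      source = make(spec$n_source, spec$stage_probs_source, "source"),
      target = make(spec$n_target, spec$stage_probs_target, "target")
    )
  })
}

#' Write a generated cohort pair to CSV
#'
#' Writes `source.csv` and `target.csv` under `dir` in the exact dialect
#' [read_cohort_csv()] consumes.
#'
#' @param pair A list with `source` and `target` cohort tables.
#' @param dir Output directory (created if needed).
#' @return The two file paths, invisibly.
#' @export
write_pair <- function(pair, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    source = file.path(dir, "source.csv"),
    target = file.path(dir, "target.csv")
  )
  write_cohort_csv(pair$source, paths[["source"]])
  write_cohort_csv(pair$target, paths[["target"]])
  invisible(paths)
}
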