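# Patient-level Monte-Carlo microsimulator. Samples individual
# diagnostic trajectories with the independence structure the closed
# forms assume and accrues per-patient monetary consequences whose
# expectations equal the closed-form terms exactly - an independent
# stochastic oracle for every aggregate.
#
# Random-number policy: one generator seeded once per cohort; each
# patient consumes six uniforms in fixed order (disease status, economic
# burden, AI-arm assignment, AI/MRI read, PET read, auxiliary AI-test
# indicator), so cohorts are bit-reproducible given (params, n, seed).
# The auxiliary indicator exists because the table-consistent MC9/MC11
# terms apply the PD-test sensitivities to the burdened non-PD stratum;
# the simulator draws a dedicated Bernoulli(sens_ai) for that trigger so
# those terms, too, are unbiased for their closed forms.

#' Simulate one patient-level cohort
#'
#' Samples `n` patients - disease status ~ Bernoulli(`pd_dx_rate`),
#' economic burden ~ Bernoulli(`pet_unaffordable`), AI-arm assignment ~
#' Bernoulli(`adoption`), AI/MRI detection ~ Bernoulli(`sens_ai`) for PD
#' and Bernoulli(`1 - spec_ai`) otherwise, PET detection ~
#' Bernoulli(`sens_pet`) for PD - and accrues each term of the model at
#' patient level (benefits positive, costs negative). Patients on the
#' conventional arm accrue nothing, matching the comparator. Aggregates
#' are scaled to the full assessed cohort `n_total`, so they are
#' directly comparable to [evaluate_terms()] and [pd_cba()].
#'
#' @param params A `pd_parameters` object.
#' @param n Number of patients to sample (> 0).
#' @param seed Integer RNG seed.
#' @param adoption Adoption rate; defaults to `params$ai_adoption`.
#' @inheritParams pd_cba
#' @param keep_records If `TRUE`, attach the per-patient table
#'   (trajectory fields, assigned patient type 1-24, and signed
#'   per-category accruals).
#' @return A `pd_microsim` object: list with `seed`, `n`, `n_total`,
#'   `term_totals` (named, unsigned USD, scaled to `n_total`),
#'   `category_totals` (signed), `net_benefit`, `se` (standard error of
#'   the net from per-patient variance), and optionally `records`.
#' @examples
#' korea <- read_parameters(pdcba_example("korea_unrounded.yaml"))
#' sim <- simulate_cohort(korea, n = 20000, seed = 1)
#' sim$net_benefit
#' @export
simulate_cohort <- function(params, n, seed,
                            adoption = params$ai_adoption,
                            variant = c("table_consistent", "as_printed"),
                            aggregation = c("published", "all_terms"),
                            keep_records = FALSE) {
  stopifnot(inherits(params, "pd_parameters"), n > 0)
  variant <- match.arg(variant)
  aggregation <- match.arg(aggregation)
  n <- as.integer(n)
  set.seed(as.integer(seed))
  U <- matrix(stats::runif(n * 6L), nrow = n, byrow = TRUE)

  pd      <- U[, 1] < params$pd_dx_rate
  burden  <- U[, 2] < params$pet_unaffordable
  ai_used <- U[, 3] < adoption
  ai_pos  <- ifelse(pd, U[, 4] < params$sens_ai,
                    U[, 4] < (1 - params$spec_ai))
  # one uniform, two readings: PET sensitivity trigger for accruals, and
  # the realized PET outcome (spec_pet) for non-PD type assignment only
  pet_trig <- U[, 5] < params$sens_pet
  pet_real <- ifelse(pd, pet_trig, U[, 5] < (1 - params$spec_pet))
  aux_ai   <- U[, 6] < params$sens_ai

  tf <- params$persons_per_visit * params$wage_65plus *
    params$employment_65plus * params$hours_pet
  trf <- params$persons_per_visit * params$transport_roundtrip
  hc <- params$perspective == "healthcare_system"
  if (hc) { tf <- 0; trf <- 0 }

  tc <- variant == "table_consistent"
  mc1_trig <- if (tc) !ai_pos else ai_pos
  mcx_trig <- if (tc) (ifelse(pd, ai_pos, aux_ai) & pet_trig)
              else    (ifelse(pd, !ai_pos, !aux_ai) & pet_trig)

  trig <- list(
    MB1  = pd  & !burden & ai_used & !ai_pos,
    MB2  = !pd & !burden & ai_used & !ai_pos,
    MC1  = pd  & burden  & ai_used & mc1_trig,
    MC2  = !pd & burden  & ai_used & ai_pos,
    MC3  = !burden & ai_used,
    MC4  = pd  & burden  & ai_used,
    MC5  = !pd & burden  & ai_used,
    MB3  = pd  & !burden & ai_used & !ai_pos & pet_trig,
    MC6  = pd  & burden  & ai_used & ai_pos  & pet_trig,
    MB4  = pd  & burden  & ai_used & ai_pos  & pet_trig,
    MC7  = pd  & !burden & ai_used & !ai_pos & pet_trig,
    MB5  = pd  & !burden & ai_used & !ai_pos,
    MB6  = !pd & !burden & ai_used & !ai_pos,
    MC8  = pd  & burden  & ai_used & mcx_trig,
    MC9  = !pd & burden  & ai_used & mcx_trig,
    MB7  = !pd & !burden & ai_used & !ai_pos,
    MC10 = pd  & burden  & ai_used & mcx_trig,
    MC11 = !pd & burden  & ai_used & mcx_trig)
  unit <- c(MB1 = params$cost_pet, MB2 = params$cost_pet,
            MC1 = params$cost_pet, MC2 = params$cost_pet,
            MC3 = params$cost_ai, MC4 = params$cost_ai,
            MC5 = params$cost_ai,
            MB3 = params$cost_early, MC6 = params$cost_early,
            MB4 = params$cost_delayed, MC7 = params$cost_delayed,
            MB5 = tf, MB6 = tf, MC8 = tf, MC9 = tf,
            MB7 = trf, MC10 = trf, MC11 = trf)
  role_sign <- ifelse(grepl("^MB", names(trig)), 1, -1)
  names(role_sign) <- names(trig)

  scale <- derived_counts(params)[["n_total"]] / n
  term_totals <- vapply(names(trig),
                        function(id) sum(trig[[id]]) * unit[[id]] * scale,
                        numeric(1))

  included <- names(trig)
  if (aggregation == "published") included <- setdiff(included, "MC10")
  per_patient <- numeric(n)
  for (id in included)
    per_patient <- per_patient + role_sign[[id]] * unit[[id]] * trig[[id]]
  net <- mean(per_patient) * derived_counts(params)[["n_total"]]
  se <- stats::sd(per_patient) / sqrt(n) *
    derived_counts(params)[["n_total"]]

  cat_of <- c(MB1 = "pet_cost", MB2 = "pet_cost", MC1 = "pet_cost",
              MC2 = "pet_cost", MC3 = "ai_cost", MC4 = "ai_cost",
              MC5 = "ai_cost", MB3 = "treatment_cost",
              MC6 = "treatment_cost", MB4 = "treatment_cost",
              MC7 = "treatment_cost", MB5 = "time_cost",
              MB6 = "time_cost", MC8 = "time_cost", MC9 = "time_cost",
              MB7 = "transport_cost", MC10 = "transport_cost",
              MC11 = "transport_cost")
  category_totals <- tapply(role_sign * term_totals, cat_of, sum)

  out <- list(seed = as.integer(seed), n = n,
              n_total = derived_counts(params)[["n_total"]],
              adoption = adoption, variant = variant,
              aggregation = aggregation,
              term_totals = term_totals,
              category_totals = category_totals[unique(cat_of)],
              net_benefit = net, se = se)
  if (keep_records) {
    rec <- data.frame(pd_status = pd, economic_burden = burden,
                      ai_used = ai_used, ai_positive = ai_pos,
                      pet_detected = pet_real)
    rec$patient_type <- .assign_type(pd, burden, ai_pos, pet_real, ai_used)
    for (cg in unique(cat_of)) {
      acc <- numeric(n)
      for (id in intersect(included, names(cat_of)[cat_of == cg]))
        acc <- acc + role_sign[[id]] * unit[[id]] * trig[[id]]
      rec[[paste0("accrual_", cg)]] <- acc
    }
    out$records <- rec
  }
  structure(out, class = "pd_microsim")
}

# Map sampled binaries onto the 24-type classification. Within the
# burdened strata the type table lists a single row per MRI outcome, so
# the PET field is not consulted there.
.assign_type <- function(pd, burden, mri, pet, ai_used) {
  base <- integer(length(pd))
  nb <- !burden
  base[pd & nb &  mri &  pet] <- 1L
  base[pd & nb &  mri & !pet] <- 2L
  base[pd & nb & !mri &  pet] <- 3L
  base[pd & nb & !mri & !pet] <- 4L
  base[pd & burden &  mri]    <- 5L
  base[pd & burden & !mri]    <- 6L
  base[!pd & nb &  mri &  pet] <- 7L
  base[!pd & nb &  mri & !pet] <- 8L
  base[!pd & nb & !mri &  pet] <- 9L
  base[!pd & nb & !mri & !pet] <- 10L
  base[!pd & burden &  mri]    <- 11L
  base[!pd & burden & !mri]    <- 12L
  base + ifelse(ai_used, 0L, 12L)
}

#' @export
print.pd_microsim <- function(x, ...) {
  cat(sprintf("Microsimulated cohort: n = %s sampled (seed %d), scaled to %s\n",
              format(x$n, big.mark = ","), x$seed,
              format(round_half_up(x$n_total), big.mark = ",")))
  cat(sprintf("  net benefit estimate: %s USD (SE %s)\n",
              format(round_half_up(x$net_benefit), big.mark = ","),
              format(round_half_up(x$se), big.mark = ",")))
  cat(sprintf("  variant: %s | aggregation: %s | adoption: %.0f%%\n",
              x$variant, x$aggregation, 100 * x$adoption))
  invisible(x)
}

#' Monte-Carlo net-benefit estimate over replicate cohorts
#'
#' Runs [simulate_cohort()] `replicates` times with seeds derived from
#' `seed` and summarizes the replicate net-benefit estimates (each
#' scaled to the full assessed cohort).
#'
#' @param params A `pd_parameters` object.
#' @param n Patients per replicate cohort.
#' @param replicates Number of replicate cohorts.
#' @param seed Integer seed for the replicate-seed stream.
#' @inheritParams simulate_cohort
#' @return List with `mean`, `se` (standard error over replicates; 0
#'   when every replicate is identical), and `nets` (the replicate
#'   estimates).
#' @examples
#' korea <- read_parameters(pdcba_example("korea_unrounded.yaml"))
#' estimate_net_benefit_mc(korea, n = 5000, replicates = 4, seed = 7)$mean
#' @export
estimate_net_benefit_mc <- function(params, n, replicates, seed,
                                    adoption = params$ai_adoption,
                                    variant = c("table_consistent",
                                                "as_printed"),
                                    aggregation = c("published",
                                                    "all_terms")) {
  stopifnot(n > 0, replicates > 0)
  variant <- match.arg(variant)
  aggregation <- match.arg(aggregation)
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max, replicates)
  nets <- vapply(seeds, function(s)
    simulate_cohort(params, n = n, seed = s, adoption = adoption,
                    variant = variant,
                    aggregation = aggregation)$net_benefit,
    numeric(1))
  se <- if (replicates > 1L) stats::sd(nets) / sqrt(replicates) else NA_real_
  list(mean = mean(nets), se = se, nets = nets)
}
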