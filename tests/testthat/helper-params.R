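# Shared fixtures: bundled parameter sets, a random in-range parameter
# generator, and an independent brute-force term oracle written as
# literal arithmetic products (no shared code with evaluate_terms()).

korea_params <- function() read_parameters(pdcba_example("korea.yaml"))
korea_unrounded_params <- function()
  read_parameters(pdcba_example("korea_unrounded.yaml"))
usa_params <- function() read_parameters(pdcba_example("usa.yaml"))

random_parameters <- function(perspective = "societal") {
  pd_parameters(
    pd_dx_rate = runif(1, 0.2, 0.95),
    n_pd = runif(1, 1e3, 1e5),
    ai_adoption = runif(1),
    pet_unaffordable = runif(1),
    sens_ai = runif(1, 0.5, 1),
    spec_ai = runif(1, 0.5, 1),
    sens_pet = runif(1, 0.5, 1),
    spec_pet = runif(1, 0.5, 1),
    cost_pet = runif(1, 100, 5000),
    cost_ai = runif(1, 1, 500),
    cost_early = runif(1, 1000, 50000),
    cost_delayed = runif(1, 1000, 60000),
    persons_per_visit = sample(1:3, 1),
    hours_pet = runif(1, 1, 8),
    hours_visit = runif(1, 1, 8),
    wage_65plus = runif(1, 5, 40),
    employment_65plus = runif(1),
    transport_roundtrip = runif(1, 1, 60),
    perspective = perspective,
    label = "random")
}

# Literal product transcription of every term (table-consistent and
# as-printed), evaluated with plain arithmetic.
oracle_terms <- function(p, a, variant = "table_consistent") {
  r <- p$pd_dx_rate
  n1 <- p$n_pd
  n0 <- p$n_pd * (1 - r) / r
  nt <- p$n_pd / r
  u <- p$pet_unaffordable
  se <- p$sens_ai; sp <- p$spec_ai; pt <- p$sens_pet
  tfac <- p$persons_per_visit * p$wage_65plus * p$employment_65plus *
    p$hours_pet
  rfac <- p$persons_per_visit * p$transport_roundtrip
  tc <- variant == "table_consistent"
  v <- c(
    MB1 = n1 * (1 - u) * a * (1 - se) * p$cost_pet,
    MB2 = n0 * (1 - u) * a * sp * p$cost_pet,
    MC1 = n1 * u * a * (if (tc) 1 - se else se) * p$cost_pet,
    MC2 = n0 * u * a * (1 - sp) * p$cost_pet,
    MC3 = nt * (1 - u) * a * p$cost_ai,
    MC4 = n1 * u * a * p$cost_ai,
    MC5 = n0 * u * a * p$cost_ai,
    MB3 = n1 * (1 - u) * a * (1 - se) * pt * p$cost_early,
    MC6 = n1 * u * a * se * pt * p$cost_early,
    MB4 = n1 * u * a * se * pt * p$cost_delayed,
    MC7 = n1 * (1 - u) * a * (1 - se) * pt * p$cost_delayed,
    MB5 = n1 * (1 - u) * a * (1 - se) * tfac,
    MB6 = n0 * (1 - u) * a * sp * tfac,
    MC8 = n1 * u * a * (if (tc) se * pt else (1 - se) * pt) * tfac,
    MC9 = n0 * u * a * (if (tc) se * pt else (1 - se) * pt) * tfac,
    MB7 = n0 * (1 - u) * a * sp * rfac,
    MC10 = n1 * u * a * (if (tc) se * pt else (1 - se) * pt) * rfac,
    MC11 = n0 * u * a * (if (tc) se * pt else (1 - se) * pt) * rfac)
  if (p$perspective == "healthcare_system")
    v[c("MB5", "MB6", "MC8", "MC9", "MB7", "MC10", "MC11")] <- 0
  v
}

oracle_net <- function(p, a, variant = "table_consistent",
                       aggregation = "published") {
  v <- oracle_terms(p, a, variant)
  mb <- sum(v[startsWith(names(v), "MB")])
  mc_ids <- grep("^MC", names(v), value = TRUE)
  if (aggregation == "published") mc_ids <- setdiff(mc_ids, "MC10")
  mb - sum(v[mc_ids])
}

modify_params <- function(p, ...) {
  x <- unclass(p)
  for (nm in names(list(...))) x[[nm]] <- list(...)[[nm]]
  do.call(pd_parameters, x[setdiff(names(x), character(0))])
}
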