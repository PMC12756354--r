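# The 18 marginal benefit (MB) / marginal cost (MC) terms of the
# one-year model, in the row order of the published result table.
#
# Two formula variants are carried. `as_printed` transcribes the
# published formula table verbatim. That table, however, does not
# regenerate its own result table for five terms: the tabulated values
# correspond to MC1 with (1 - sens_ai) instead of sens_ai, and to
# MC8-MC11 with sens_ai * sens_pet instead of (1 - sens_ai) * sens_pet.
# `table_consistent` (the default everywhere) applies exactly those five
# corrections and reproduces every tabulated value; the two variants are
# identical on the other thirteen terms. The published term descriptions
# are carried as text only - for the five reconciled terms they describe
# the printed formulas, not the factors actually tabulated.

.term_table <- function(variant = c("table_consistent", "as_printed")) {
  variant <- match.arg(variant)
  tc <- variant == "table_consistent"
  # expressions are evaluated in the environment built by .term_env()
  rows <- list(
    # id     role       category          patient types  expression
    c("MB1", "benefit", "pet_cost",       "3,4",
      "n_pd * (1-u) * a * (1-sens_ai) * cost_pet",
      "avoided PET costs: AI-negative PD patients without economic burden"),
    c("MB2", "benefit", "pet_cost",       "7,8",
      "n_nonpd * (1-u) * a * spec_ai * cost_pet",
      "avoided PET costs: non-PD patients correctly excluded by AI"),
    c("MC1", "cost",    "pet_cost",       "5",
      if (tc) "n_pd * u * a * (1-sens_ai) * cost_pet"
      else    "n_pd * u * a * sens_ai * cost_pet",
      "added PET costs: burdened PD patients routed to PET by the AI arm"),
    c("MC2", "cost",    "pet_cost",       "12",
      "n_nonpd * u * a * (1-spec_ai) * cost_pet",
      "added PET costs: AI false positives among burdened non-PD patients"),
    c("MC3", "cost",    "ai_cost",        "1,2,3,4,7,8,9,10",
      "n_total * (1-u) * a * cost_ai",
      "AI usage cost: patients without economic burden"),
    c("MC4", "cost",    "ai_cost",        "5,6",
      "n_pd * u * a * cost_ai",
      "AI usage cost: burdened PD patients"),
    c("MC5", "cost",    "ai_cost",        "11,12",
      "n_nonpd * u * a * cost_ai",
      "AI usage cost: burdened non-PD patients"),
    c("MB3", "benefit", "treatment_cost", "3",
      "n_pd * (1-u) * a * (1-sens_ai) * sens_pet * cost_early",
      "early-treatment cost saved: AI misses later confirmed by PET"),
    c("MC6", "cost",    "treatment_cost", "5",
      "n_pd * u * a * sens_ai * sens_pet * cost_early",
      "early-treatment cost added: burdened PD patients newly reaching PET"),
    c("MB4", "benefit", "treatment_cost", "5",
      "n_pd * u * a * sens_ai * sens_pet * cost_delayed",
      "delayed-treatment cost avoided: burdened PD patients diagnosed early"),
    c("MC7", "cost",    "treatment_cost", "3",
      "n_pd * (1-u) * a * (1-sens_ai) * sens_pet * cost_delayed",
      "delayed-treatment cost incurred: AI misses diagnosed late"),
    c("MB5", "benefit", "time_cost",      "3,4",
      "n_pd * (1-u) * a * (1-sens_ai) * time_factor",
      "time cost avoided: PD patients spared a PET visit"),
    c("MB6", "benefit", "time_cost",      "7,8",
      "n_nonpd * (1-u) * a * spec_ai * time_factor",
      "time cost avoided: non-PD patients correctly excluded"),
    c("MC8", "cost",    "time_cost",      "5",
      if (tc) "n_pd * u * a * sens_ai * sens_pet * time_factor"
      else    "n_pd * u * a * (1-sens_ai) * sens_pet * time_factor",
      "time cost added: burdened PD patients newly attending PET"),
    c("MC9", "cost",    "time_cost",      "12",
      if (tc) "n_nonpd * u * a * sens_ai * sens_pet * time_factor"
      else    "n_nonpd * u * a * (1-sens_ai) * sens_pet * time_factor",
      "time cost added: burdened non-PD patients attending PET"),
    c("MB7", "benefit", "transport_cost", "7,8",
      "n_nonpd * (1-u) * a * spec_ai * transport_factor",
      "transport cost avoided: non-PD patients correctly excluded"),
    c("MC10", "cost",   "transport_cost", "5",
      if (tc) "n_pd * u * a * sens_ai * sens_pet * transport_factor"
      else    "n_pd * u * a * (1-sens_ai) * sens_pet * transport_factor",
      "transport cost added: burdened PD patients newly attending PET"),
    c("MC11", "cost",   "transport_cost", "12",
      if (tc) "n_nonpd * u * a * sens_ai * sens_pet * transport_factor"
      else    "n_nonpd * u * a * (1-sens_ai) * sens_pet * transport_factor",
      "transport cost added: burdened non-PD patients attending PET"))
  out <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  names(out) <- c("term_id", "role", "category", "patient_types",
                  "expression", "description")
  out$variant <- variant
  out
}

.nonmedical_terms <- c("MB5", "MB6", "MC8", "MC9", "MB7", "MC10", "MC11")

.term_env <- function(params, adoption) {
  dc <- derived_counts(params)
  list2env(list(
    n_pd = dc[["n_pd"]], n_nonpd = dc[["n_nonpd"]],
    n_total = dc[["n_total"]],
    u = params$pet_unaffordable, a = adoption,
    sens_ai = params$sens_ai, spec_ai = params$spec_ai,
    sens_pet = params$sens_pet,
    cost_pet = params$cost_pet, cost_ai = params$cost_ai,
    cost_early = params$cost_early, cost_delayed = params$cost_delayed,
    time_factor = params$persons_per_visit * params$wage_65plus *
      params$employment_65plus * params$hours_pet,
    transport_factor = params$persons_per_visit *
      params$transport_roundtrip),
    parent = baseenv())
}

#' Definitions of the 18 marginal benefit/cost terms
#'
#' Returns the symbolic definition of every term: its role (benefit or
#' cost), cost category, the patient types it prices, and its factor
#' expression over the parameter fields and derived cohort counts
#' (`time_factor` = persons x wage x employment x PET hours;
#' `transport_factor` = persons x round-trip cost).
#'
#' Two variants exist. `"as_printed"` is the published formula table
#' transcribed verbatim. `"table_consistent"` (default) applies the five
#' corrections - MC1 uses `(1 - sens_ai)` in place of `sens_ai`, and
#' MC8-MC11 use `sens_ai * sens_pet` in place of
#' `(1 - sens_ai) * sens_pet` - required to regenerate the published
#' result table; the variants agree on the other thirteen terms.
#'
#' @param variant `"table_consistent"` or `"as_printed"`.
#' @return A data frame with one row per term in published row order.
#' @examples
#' term_definitions()[, c("term_id", "role", "expression")]
#' @export
term_definitions <- function(variant = c("table_consistent",
                                         "as_printed")) {
  .term_table(match.arg(variant))
}

#' Evaluate the 18 terms for a parameter set
#'
#' Evaluates each term's factor product in USD. Under the
#' `healthcare_system` perspective the non-medical terms (MB5-MB7,
#' MC8-MC11) are forced to zero and flagged `excluded`.
#'
#' @param params A `pd_parameters` object.
#' @param adoption AI adoption rate in \[0, 1\]; defaults to
#'   `params$ai_adoption`.
#' @param variant Formula variant, see [term_definitions()].
#' @return The term-definition data frame with columns `value` (USD) and
#'   `excluded` (logical) appended.
#' @examples
#' usa <- read_parameters(pdcba_example("usa.yaml"))
#' evaluate_terms(usa)[, c("term_id", "value")]
#' @export
evaluate_terms <- function(params, adoption = params$ai_adoption,
                           variant = c("table_consistent", "as_printed")) {
  stopifnot(inherits(params, "pd_parameters"),
            is.numeric(adoption), length(adoption) == 1L,
            adoption >= 0, adoption <= 1)
  defs <- term_definitions(match.arg(variant))
  env <- .term_env(params, adoption)
  defs$value <- vapply(defs$expression,
                       function(e) eval(parse(text = e), env), numeric(1),
                       USE.NAMES = FALSE)
  defs$excluded <- params$perspective == "healthcare_system" &
    defs$term_id %in% .nonmedical_terms
  defs$value[defs$excluded] <- 0
  defs
}

#' Aggregate evaluated terms into net benefit and benefit-cost ratio
#'
#' `total_benefit` is the sum of the MB terms. Under the `"published"`
#' aggregation (default) `total_cost` sums the MC terms excluding MC10:
#' at a diagnostic rate of 0.5 the two transportation cost terms MC10 and
#' MC11 are numerically identical, and the published net benefit and B/C
#' ratio are reproduced only when exactly one of the pair is counted.
#' Which of the two is dropped is a convention (they cannot be told apart
#' at that diagnostic rate); `"all_terms"` sums all eleven MC terms.
#'
#' @param terms Output of [evaluate_terms()].
#' @param aggregation `"published"` or `"all_terms"`.
#' @return A list with `total_benefit`, `total_cost`, `net_benefit` and
#'   `bc_ratio` (`NA` when `total_cost` is 0: the ratio is undefined).
#' @export
aggregate_terms <- function(terms,
                            aggregation = c("published", "all_terms")) {
  aggregation <- match.arg(aggregation)
  stopifnot(is.data.frame(terms), nrow(terms) == 18L)
  mb <- sum(terms$value[terms$role == "benefit"])
  cost_ids <- terms$term_id[terms$role == "cost"]
  if (aggregation == "published") cost_ids <- setdiff(cost_ids, "MC10")
  mc <- sum(terms$value[terms$term_id %in% cost_ids])
  list(total_benefit = mb, total_cost = mc, net_benefit = mb - mc,
       bc_ratio = if (mc > 0) mb / mc else NA_real_,
       aggregation = aggregation)
}
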