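# The central model object: evaluate one scenario and carry everything
# needed to reproduce or perturb it.

#' Evaluate the cost-benefit model for one scenario
#'
#' The model prices the switch from a PET-first diagnostic pathway to
#' AI-assisted MRI triage for a one-year national cohort of suspected
#' Parkinson's disease patients. Eighteen additive terms capture the
#' marginal benefits (MB1-MB7) and marginal costs (MC1-MC11) of the AI
#' arm; each is a product of cohort counts, pathway probabilities and a
#' unit cost, and each is linear in the adoption rate. `pd_cba()`
#' evaluates all terms and aggregates them into the net benefit
#' (benefits minus costs) and benefit-cost ratio.
#'
#' @param params A `pd_parameters` object.
#' @param adoption AI adoption rate in \[0, 1\]; defaults to
#'   `params$ai_adoption`.
#' @param variant Formula variant, see [term_definitions()].
#' @param aggregation Cost aggregation rule, see [aggregate_terms()].
#' @return An object of class `pd_cba` with components `params`,
#'   `adoption`, `variant`, `aggregation`, `terms` (the evaluated term
#'   table), `total_benefit`, `total_cost`, `net_benefit`, `bc_ratio`.
#' @seealso [adoption_sweep()], [one_way_sensitivity()],
#'   [break_even_ai_cost()], [simulate_cohort()]
#' @examples
#' korea <- read_parameters(pdcba_example("korea_unrounded.yaml"))
#' fit <- pd_cba(korea, adoption = 0.3)
#' fit
#' coef(fit)[c("MB1", "MC3")]
#' predict(fit, newdata = data.frame(adoption = c(0.3, 0.65, 1)))
#' @export
pd_cba <- function(params, adoption = params$ai_adoption,
                   variant = c("table_consistent", "as_printed"),
                   aggregation = c("published", "all_terms")) {
  variant <- match.arg(variant)
  aggregation <- match.arg(aggregation)
  terms <- evaluate_terms(params, adoption, variant)
  agg <- aggregate_terms(terms, aggregation)
  structure(list(params = params, adoption = adoption, variant = variant,
                 aggregation = aggregation, terms = terms,
                 total_benefit = agg$total_benefit,
                 total_cost = agg$total_cost,
                 net_benefit = agg$net_benefit,
                 bc_ratio = agg$bc_ratio),
            class = "pd_cba")
}

#' @export
print.pd_cba <- function(x, ...) {
  lab <- x$params$label
  cat("AI-triage cost-benefit scenario",
      if (nzchar(lab)) paste0("- ", lab), "\n")
  cat(sprintf("  perspective: %s | adoption: %.0f%% | variant: %s | aggregation: %s\n",
              x$params$perspective, 100 * x$adoption, x$variant,
              x$aggregation))
  cat(sprintf("  Total benefit: %s USD\n",
              format(round_half_up(x$total_benefit), big.mark = ",")))
  cat(sprintf("  Total cost:    %s USD\n",
              format(round_half_up(x$total_cost), big.mark = ",")))
  cat(sprintf("  Net benefit:   %s USD\n",
              format(round_half_up(x$net_benefit), big.mark = ",")))
  cat(sprintf("  B/C ratio:     %s\n",
              if (is.na(x$bc_ratio)) "undefined (zero total cost)"
              else sprintf("%.2f", x$bc_ratio)))
  invisible(x)
}

#' @export
summary.pd_cba <- function(object, ...) {
  structure(object, class = c("summary.pd_cba", "pd_cba"))
}

#' @export
print.summary.pd_cba <- function(x, ...) {
  NextMethod()
  df <- x$terms[, c("term_id", "role", "category", "value")]
  df$value <- format(round_half_up(df$value), big.mark = ",")
  df$value[x$terms$excluded] <- ""
  cat("\nTerms (USD):\n")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Extract evaluated term values
#'
#' @param object A `pd_cba` object.
#' @param ... Unused.
#' @return Named numeric vector of the 18 term values (USD).
#' @export
coef.pd_cba <- function(object, ...) {
  stats::setNames(object$terms$value, object$terms$term_id)
}

#' Re-evaluate a scenario at new inputs
#'
#' Recomputes the model for each row of `newdata`, whose columns may be
#' `adoption` and/or any numeric parameter field (e.g. `cost_ai`,
#' `pet_unaffordable`); unspecified inputs keep the fitted values.
#'
#' @param object A `pd_cba` object.
#' @param newdata Data frame of inputs to vary; defaults to the fitted
#'   scenario.
#' @param type `"net_benefit"` (default), `"bc_ratio"`, or `"terms"`
#'   (matrix of the 18 term values per row).
#' @param ... Unused.
#' @return Numeric vector (or matrix for `type = "terms"`) with one
#'   entry/row per row of `newdata`.
#' @export
predict.pd_cba <- function(object, newdata = NULL,
                           type = c("net_benefit", "bc_ratio", "terms"),
                           ...) {
  type <- match.arg(type)
  if (is.null(newdata))
    newdata <- data.frame(adoption = object$adoption)
  stopifnot(is.data.frame(newdata), nrow(newdata) >= 1L)
  numeric_fields <- names(.param_fields)
  bad <- setdiff(names(newdata), c("adoption", numeric_fields))
  if (length(bad))
    stop("unknown predictor(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  one <- function(i) {
    p <- unclass(object$params)
    a <- object$adoption
    for (nm in names(newdata)) {
      if (nm == "adoption") a <- newdata[[nm]][i]
      else p[[nm]] <- newdata[[nm]][i]
    }
    pd_cba(validate_parameters(p), adoption = a,
           variant = object$variant, aggregation = object$aggregation)
  }
  fits <- lapply(seq_len(nrow(newdata)), one)
  switch(type,
    net_benefit = vapply(fits, `[[`, numeric(1), "net_benefit"),
    bc_ratio    = vapply(fits, `[[`, numeric(1), "bc_ratio"),
    terms       = t(vapply(fits, coef, numeric(18L))))
}

#' Simulate patient-level cohorts matching a fitted scenario
#'
#' Draws `nsim` independent Monte-Carlo cohorts from the patient-level
#' model underlying the closed forms (see [simulate_cohort()]) and
#' returns each replicate's net-benefit estimate scaled to the full
#' assessed cohort.
#'
#' @param object A `pd_cba` object.
#' @param nsim Number of replicate cohorts.
#' @param seed RNG seed (integer); required for reproducibility.
#' @param n Patients sampled per replicate; defaults to the full cohort
#'   size rounded to an integer.
#' @param ... Unused.
#' @return Data frame with one row per replicate: `net_benefit` (USD,
#'   scaled to `n_total`) and `se` (its standard error).
#' @export
simulate.pd_cba <- function(object, nsim = 1, seed = NULL,
                            n = NULL, ...) {
  if (is.null(n))
    n <- as.integer(round_half_up(derived_counts(object$params)[["n_total"]]))
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nsim)
  reps <- lapply(seeds, function(s)
    simulate_cohort(object$params, n = n, seed = s,
                    adoption = object$adoption, variant = object$variant,
                    aggregation = object$aggregation))
  data.frame(sim = seq_len(nsim),
             net_benefit = vapply(reps, `[[`, numeric(1), "net_benefit"),
             se = vapply(reps, `[[`, numeric(1), "se"))
}

#' Bar plot of the evaluated terms
#'
#' Benefits plot upward, costs downward, grouped in published row order;
#' terms zeroed by the healthcare-system perspective are omitted.
#'
#' @param x A `pd_cba` object.
#' @param ... Passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.pd_cba <- function(x, ...) {
  t <- x$terms[!x$terms$excluded, ]
  v <- ifelse(t$role == "benefit", t$value, -t$value) / 1e6
  graphics::barplot(v, names.arg = t$term_id, las = 2,
                    col = ifelse(t$role == "benefit", "steelblue",
                                 "indianred"),
                    ylab = "million USD (benefit +, cost -)",
                    main = sprintf("Marginal terms at %.0f%% adoption",
                                   100 * x$adoption), ...)
  graphics::abline(h = 0)
  invisible(x)
}
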