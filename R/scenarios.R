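# Scenario machinery over the term engine: adoption sweeps, one-way
# deterministic sensitivity, closed-form break-even AI pricing, and the
# multi-year projection.

#' Evaluate the model across AI adoption rates
#'
#' Every term is linear in the adoption rate, so net benefit scales
#' proportionally; the sweep exists to tabulate scenarios side by side.
#'
#' @param params A `pd_parameters` object.
#' @param rates Non-empty vector of adoption rates in \[0, 1\].
#' @inheritParams pd_cba
#' @return A list of `pd_cba` objects (class `pd_sweep`), one per rate.
#' @examples
#' korea <- read_parameters(pdcba_example("korea_unrounded.yaml"))
#' sapply(adoption_sweep(korea, c(0.3, 0.65, 1)), `[[`, "net_benefit")
#' @export
adoption_sweep <- function(params, rates = c(0.3, 0.65, 1),
                           variant = c("table_consistent", "as_printed"),
                           aggregation = c("published", "all_terms")) {
  if (length(rates) == 0L) stop("'rates' must be non-empty", call. = FALSE)
  stopifnot(all(rates >= 0 & rates <= 1))
  variant <- match.arg(variant)
  aggregation <- match.arg(aggregation)
  out <- lapply(rates, function(a)
    pd_cba(params, adoption = a, variant = variant,
           aggregation = aggregation))
  names(out) <- sprintf("%g%%", 100 * rates)
  structure(out, class = c("pd_sweep", "list"))
}

#' One-way deterministic sensitivity analysis
#'
#' Recomputes the net benefit while one parameter moves across a grid,
#' holding everything else at its base-case value, and reports each
#' point's ratio to the base-case net benefit (in percent).
#'
#' @param params A `pd_parameters` object (the base case).
#' @param param_name Name of a numeric parameter field to sweep (e.g.
#'   `"pet_unaffordable"`, `"cost_ai"`).
#' @param grid Strictly increasing numeric grid within the field's valid
#'   range.
#' @param adoption Adoption rate; defaults to `params$ai_adoption`.
#' @inheritParams pd_cba
#' @return A `pd_sensitivity` data frame with columns `value`,
#'   `net_benefit`, `ratio_pct`, plus attributes `param` and
#'   `net_base`.
#' @examples
#' korea <- read_parameters(pdcba_example("korea_unrounded.yaml"))
#' one_way_sensitivity(korea, "pet_unaffordable", c(0, 0.5, 1))
#' @export
one_way_sensitivity <- function(params, param_name, grid,
                                adoption = params$ai_adoption,
                                variant = c("table_consistent",
                                            "as_printed"),
                                aggregation = c("published",
                                                "all_terms")) {
  stopifnot(inherits(params, "pd_parameters"))
  if (!param_name %in% names(.param_fields))
    stop("not a sweepable numeric parameter: ", param_name, call. = FALSE)
  if (length(grid) == 0L || is.unsorted(grid, strictly = TRUE))
    stop("'grid' must be non-empty and strictly increasing", call. = FALSE)
  variant <- match.arg(variant)
  aggregation <- match.arg(aggregation)
  base <- pd_cba(params, adoption, variant, aggregation)
  nets <- vapply(grid, function(v) {
    p <- unclass(params)
    p[[param_name]] <- v
    pd_cba(validate_parameters(p), adoption, variant,
           aggregation)$net_benefit
  }, numeric(1))
  structure(data.frame(value = grid, net_benefit = nets,
                       ratio_pct = 100 * nets / base$net_benefit),
            param = param_name, net_base = base$net_benefit,
            class = c("pd_sensitivity", "data.frame"))
}

#' @export
print.pd_sensitivity <- function(x, ...) {
  cat(sprintf("One-way sensitivity in '%s' (base net benefit %s USD)\n",
              attr(x, "param"),
              format(round_half_up(attr(x, "net_base")),
                     big.mark = ",")))
  df <- data.frame(value = x$value,
                   net_benefit = format(round_half_up(x$net_benefit),
                                        big.mark = ","),
                   ratio = sprintf("%.1f%%", x$ratio_pct))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Break-even AI unit cost
#'
#' The net benefit is affine in the AI unit cost `c` with (negative)
#' slope equal to the AI-applied scan volume
#' `S = a * (n_total (1-u) + n_pd u + n_nonpd u) = a * n_total`
#' (the MC3 + MC4 + MC5 volume). The root of `net(c)` is therefore
#' `c* = (net(c0) + S c0) / S` at any current cost `c0`. The returned
#' value satisfies `net(cost_ai = c*) = 0` to within 1e-9 relative.
#'
#' @param params A `pd_parameters` object.
#' @param adoption Adoption rate; defaults to `params$ai_adoption`.
#' @inheritParams pd_cba
#' @return The break-even AI price per scan (USD), with the verified
#'   residual net benefit attached as attribute `net_at_breakeven`.
#'   `NA` when no one is on the AI arm (`S = 0`): the break-even price
#'   is then undefined.
#' @examples
#' break_even_ai_cost(read_parameters(pdcba_example("usa.yaml")))
#' @export
break_even_ai_cost <- function(params, adoption = params$ai_adoption,
                               variant = c("table_consistent",
                                           "as_printed"),
                               aggregation = c("published",
                                               "all_terms")) {
  stopifnot(inherits(params, "pd_parameters"))
  variant <- match.arg(variant)
  aggregation <- match.arg(aggregation)
  dc <- derived_counts(params)
  u <- params$pet_unaffordable
  S <- adoption * (dc[["n_total"]] * (1 - u) + dc[["n_pd"]] * u +
                     dc[["n_nonpd"]] * u)
  if (S <= 0) return(NA_real_)
  fit <- pd_cba(params, adoption, variant, aggregation)
  cstar <- (fit$net_benefit + S * params$cost_ai) / S
  # the root can be negative (net below zero even at a free AI scan);
  # verify it without the non-negativity constraint on cost_ai
  p <- unclass(params)
  p$cost_ai <- cstar
  check_terms <- evaluate_terms(structure(p, class = "pd_parameters"),
                                adoption, variant)
  check <- aggregate_terms(check_terms, aggregation)$net_benefit
  scale <- max(abs(fit$net_benefit), 1)
  if (abs(check) / scale > 1e-9)
    stop("break-even verification failed: residual net ", check,
         call. = FALSE)
  structure(cstar, net_at_breakeven = check)
}

#' Project annual and cumulative net benefit over a horizon
#'
#' Re-evaluates the one-year model for each calendar year with that
#' year's adoption rate and cohort size. The default adoption ramp is
#' linear from the base-case rate to `ramp_target` over `ramp_years`
#' years, then flat - a transparent diffusion baseline; a logistic
#' (S-curve) ramp reaching the same target is available since real
#' technology uptake is often nonlinear. The default cohort is constant
#' and the default discount rate 0; both are configurable because any
#' realistic long-horizon use has growing prevalence and discounting
#' conventions of its own.
#'
#' @param params A `pd_parameters` object (year-one base case).
#' @param start_year,end_year First and last calendar year (inclusive).
#' @param adoption_ramp `"linear"`, `"logistic"`, or a function of the
#'   0-based year index returning an adoption rate in \[0, 1\].
#' @param ramp_target Adoption rate reached by the built-in ramps.
#' @param ramp_years Years over which the built-in ramps rise.
#' @param cohort_growth Annual growth rate of `n_pd` (scalar), or a
#'   function of the 0-based year index returning that year's `n_pd`,
#'   or a numeric vector of `n_pd` values (one per year).
#' @param discount_rate Annual discount rate applied to year `k` as
#'   `(1 + discount_rate)^-k`; 0 disables discounting.
#' @inheritParams pd_cba
#' @return A `pd_projection` data frame: `year`, `adoption`, `n_pd`,
#'   `annual_net` (discounted USD), `cumulative_net`.
#' @examples
#' korea <- read_parameters(pdcba_example("korea_unrounded.yaml"))
#' proj <- project_long_term(korea, 2025, 2050, cohort_growth = 0.02)
#' tail(proj, 3)
#' @export
project_long_term <- function(params, start_year = 2025, end_year = 2050,
                              adoption_ramp = c("linear", "logistic"),
                              ramp_target = 0.8, ramp_years = 10,
                              cohort_growth = 0, discount_rate = 0,
                              variant = c("table_consistent",
                                          "as_printed"),
                              aggregation = c("published", "all_terms")) {
  stopifnot(inherits(params, "pd_parameters"), start_year <= end_year,
            ramp_target >= 0, ramp_target <= 1, ramp_years > 0,
            discount_rate >= 0)
  variant <- match.arg(variant)
  aggregation <- match.arg(aggregation)
  k <- seq_len(end_year - start_year + 1L) - 1L
  a0 <- params$ai_adoption
  ramp_fun <- if (is.function(adoption_ramp)) adoption_ramp else
    switch(match.arg(adoption_ramp),
      linear = function(k) a0 + (ramp_target - a0) * pmin(k, ramp_years) /
        ramp_years,
      # logistic ramp centred mid-way through the rise, ~same endpoints
      logistic = function(k) a0 + (ramp_target - a0) /
        (1 + exp(-(k - ramp_years / 2) * 8 / ramp_years)))
  adoption <- vapply(k, function(kk) ramp_fun(kk), numeric(1))
  if (any(adoption < 0 | adoption > 1))
    stop("adoption ramp left [0, 1]", call. = FALSE)
  n_pd <- if (is.function(cohort_growth))
    vapply(k, cohort_growth, numeric(1))
  else if (length(cohort_growth) == length(k) && length(k) > 1L)
    cohort_growth
  else if (length(cohort_growth) == 1L)
    params$n_pd * (1 + cohort_growth)^k
  else stop("'cohort_growth' must be a rate, a function, or one n_pd per year",
            call. = FALSE)
  if (any(n_pd <= 0)) stop("cohort growth produced non-positive n_pd",
                           call. = FALSE)
  annual <- vapply(seq_along(k), function(i) {
    p <- unclass(params)
    p$n_pd <- n_pd[i]
    pd_cba(validate_parameters(p), adoption = adoption[i],
           variant = variant, aggregation = aggregation)$net_benefit
  }, numeric(1))
  annual <- annual / (1 + discount_rate)^k
  structure(data.frame(year = start_year + k, adoption = adoption,
                       n_pd = n_pd, annual_net = annual,
                       cumulative_net = cumsum(annual)),
            discount_rate = discount_rate,
            class = c("pd_projection", "data.frame"))
}

#' @export
print.pd_projection <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("Projection %d-%d (discount rate %.1f%%)\n", x$year[1],
              x$year[n], 100 * attr(x, "discount_rate")))
  cat(sprintf("  annual net: %s USD (first) -> %s USD (last)\n",
              format(round_half_up(x$annual_net[1]), big.mark = ","),
              format(round_half_up(x$annual_net[n]), big.mark = ",")))
  cat(sprintf("  cumulative net over %d years: %s USD\n", n,
              format(round_half_up(x$cumulative_net[n]),
                     big.mark = ",")))
  invisible(x)
}
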