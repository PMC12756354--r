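# Model input parameter sets: construction, validation, file I/O and the
# derived cohort denominators.

# field -> c(kind, required). Kinds drive validation; monetary fields are
# the ones a `currency: local` config divides by the exchange rate.
.param_fields <- list(
  pd_dx_rate          = "prob_pos",
  n_pd                = "count_pos",
  ai_adoption         = "prob",
  pet_unaffordable    = "prob",
  sens_ai             = "prob",
  spec_ai             = "prob",
  sens_pet            = "prob",
  spec_pet            = "prob",
  cost_pet            = "money",
  cost_ai             = "money",
  cost_early          = "money",
  cost_delayed        = "money",
  persons_per_visit   = "nonneg",
  hours_pet           = "nonneg",
  hours_visit         = "nonneg",
  wage_65plus         = "money",
  employment_65plus   = "prob",
  transport_roundtrip = "money"
)

.money_fields <- c("cost_pet", "cost_ai", "cost_early", "cost_delayed",
                   "wage_65plus", "transport_roundtrip")

#' Construct a validated model parameter set
#'
#' A `pd_parameters` object holds every input of the cost-benefit model:
#' cohort composition, diagnostic accuracies, unit costs, and the
#' non-medical (time/transport) inputs used under the societal
#' perspective. All monetary values are in USD per unit stated.
#'
#' @param pd_dx_rate PD diagnostic rate among suspected outpatients,
#'   in (0, 1]. The assessed cohort is `n_pd / pd_dx_rate`.
#' @param n_pd PD population aged 65+ entering the pathway (count > 0).
#' @param ai_adoption Fraction of the cohort on the AI arm, in \[0, 1\].
#' @param pet_unaffordable Fraction of patients facing an economic burden
#'   that would make them forgo PET, in \[0, 1\].
#' @param sens_ai,spec_ai Sensitivity and specificity of the AI-read MRI.
#' @param sens_pet,spec_pet Sensitivity and specificity of PET.
#'   `spec_pet` is housed for completeness (the microsimulator can use it
#'   for pathway realism) but enters no closed-form term.
#' @param cost_pet PET cost per scan, USD.
#' @param cost_ai AI usage cost per scan, USD.
#' @param cost_early Annual medical cost after early PD diagnosis, USD.
#' @param cost_delayed Annual medical cost after delayed PD diagnosis, USD.
#' @param persons_per_visit Persons travelling per visit (patient plus
#'   caregiver).
#' @param hours_pet Hours per PET visit.
#' @param hours_visit Hours per outpatient visit (housed; unused by the
#'   closed-form terms).
#' @param wage_65plus Average hourly wage of people aged 65+, USD/h.
#' @param employment_65plus Employment rate of people aged 65+, in \[0, 1\].
#' @param transport_roundtrip Round-trip transportation cost per visit, USD.
#' @param perspective `"societal"` (include time and transport terms) or
#'   `"healthcare_system"` (direct medical costs only; the non-medical
#'   terms are forced to zero).
#' @param exchange_rate Local-currency units per USD; only used when a
#'   config file declares `currency: local`.
#' @param label Free-text label, e.g. a country name.
#'
#' @return An object of class `pd_parameters` (a named list).
#' @seealso [read_parameters()], [derived_counts()], [pd_cba()]
#' @examples
#' p <- read_parameters(pdcba_example("korea.yaml"))
#' derived_counts(p)
#' @export
pd_parameters <- function(pd_dx_rate, n_pd, ai_adoption, pet_unaffordable,
                          sens_ai, spec_ai, sens_pet, spec_pet,
                          cost_pet, cost_ai, cost_early, cost_delayed,
                          persons_per_visit = 0, hours_pet = 0,
                          hours_visit = 0, wage_65plus = 0,
                          employment_65plus = 0, transport_roundtrip = 0,
                          perspective = c("societal", "healthcare_system"),
                          exchange_rate = NULL, label = "") {
  perspective <- match.arg(perspective)
  p <- list(pd_dx_rate = pd_dx_rate, n_pd = n_pd,
            ai_adoption = ai_adoption, pet_unaffordable = pet_unaffordable,
            sens_ai = sens_ai, spec_ai = spec_ai,
            sens_pet = sens_pet, spec_pet = spec_pet,
            cost_pet = cost_pet, cost_ai = cost_ai,
            cost_early = cost_early, cost_delayed = cost_delayed,
            persons_per_visit = persons_per_visit, hours_pet = hours_pet,
            hours_visit = hours_visit, wage_65plus = wage_65plus,
            employment_65plus = employment_65plus,
            transport_roundtrip = transport_roundtrip,
            perspective = perspective,
            exchange_rate = exchange_rate, label = label)
  validate_parameters(p)
}

validate_parameters <- function(p) {
  for (f in names(.param_fields)) {
    v <- p[[f]]
    if (is.null(v)) stop(sprintf("missing parameter '%s'", f), call. = FALSE)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("parameter '%s' must be a single finite number", f),
           call. = FALSE)
    kind <- .param_fields[[f]]
    ok <- switch(kind,
      prob      = v >= 0 && v <= 1,
      prob_pos  = v > 0 && v <= 1,
      count_pos = v > 0,
      money     = ,
      nonneg    = v >= 0)
    if (!ok)
      stop(sprintf("parameter '%s' out of range (%s): %g", f, kind, v),
           call. = FALSE)
  }
  if (!p$perspective %in% c("societal", "healthcare_system"))
    stop("parameter 'perspective' must be 'societal' or 'healthcare_system'",
         call. = FALSE)
  if (!is.null(p$exchange_rate) &&
      (!is.numeric(p$exchange_rate) || p$exchange_rate <= 0))
    stop("parameter 'exchange_rate' must be a positive number", call. = FALSE)
  structure(p, class = "pd_parameters")
}

#' Read a parameter set from a YAML or JSON config file
#'
#' Keys are exactly the argument names of [pd_parameters()]. An optional
#' `currency` key (`"USD"`, the default, or `"local"`) states the currency
#' of the monetary fields; with `currency: local` every monetary field is
#' divided once by `exchange_rate` at load, so all internal arithmetic is
#' in USD.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `pd_parameters` object.
#' @examples
#' usa <- read_parameters(pdcba_example("usa.yaml"))
#' usa$cost_pet
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported parameter file extension: .", ext, call. = FALSE))
  if (!is.list(raw)) stop("parameter file did not parse to a mapping",
                          call. = FALSE)
  currency <- raw$currency %||% "USD"
  if (!currency %in% c("USD", "local"))
    stop("parameter 'currency' must be 'USD' or 'local'", call. = FALSE)
  if (currency == "local") {
    if (is.null(raw$exchange_rate))
      stop("currency 'local' requires parameter 'exchange_rate'",
           call. = FALSE)
    for (f in .money_fields)
      if (!is.null(raw[[f]])) raw[[f]] <- raw[[f]] / raw$exchange_rate
  }
  raw$currency <- NULL
  known <- c(names(.param_fields), "perspective", "exchange_rate", "label")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  raw$perspective <- raw$perspective %||% "societal"
  raw$label <- raw$label %||% ""
  do.call(pd_parameters, raw)
}

#' Write a parameter set to YAML or JSON
#'
#' The inverse of [read_parameters()]: values are written at full double
#' precision so a load/write/load round trip reproduces every field
#' bit-identically. Output is always in USD (no `currency` key).
#'
#' @param params A `pd_parameters` object.
#' @param path Destination `.yaml`/`.yml` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "pd_parameters"))
  x <- unclass(params)
  x <- x[!vapply(x, is.null, logical(1))]
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::write_yaml(x, path, precision = 17),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE,
                                digits = I(17), pretty = TRUE),
    stop("unsupported parameter file extension: .", ext, call. = FALSE))
  invisible(path)
}

#' Derived cohort denominators
#'
#' The model's closed forms scale three cohort sizes from `n_pd` and the
#' diagnostic rate: the non-PD count `n_nonpd = n_pd (1 - r)/r` and the
#' total assessed cohort `n_total = n_pd / r`, where `r` is `pd_dx_rate`.
#' Values are real (no rounding).
#'
#' @param params A `pd_parameters` object.
#' @return Named numeric vector with elements `n_pd`, `n_nonpd`, `n_total`.
#' @examples
#' derived_counts(read_parameters(pdcba_example("korea.yaml")))
#' @export
derived_counts <- function(params) {
  stopifnot(inherits(params, "pd_parameters"))
  r <- params$pd_dx_rate
  c(n_pd = params$n_pd,
    n_nonpd = params$n_pd * (1 - r) / r,
    n_total = params$n_pd / r)
}

#' Path to a bundled example parameter file
#'
#' @param file One of `"korea.yaml"`, `"korea_unrounded.yaml"`,
#'   `"usa.yaml"`; with no argument, lists the bundled files.
#' @return A file path (or a character vector of file names).
#' @export
pdcba_example <- function(file = NULL) {
  dir <- system.file("extdata", package = "pdcba")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("no bundled parameter file: ", file,
                               call. = FALSE)
  path
}

#' @export
print.pd_parameters <- function(x, ...) {
  cat("Model parameter set", if (nzchar(x$label)) paste0("- ", x$label),
      "\n")
  cat("  perspective:", x$perspective, "\n")
  dc <- derived_counts(x)
  cat(sprintf("  cohort: n_pd = %s, n_nonpd = %s, n_total = %s\n",
              format(dc[["n_pd"]], big.mark = ","),
              format(dc[["n_nonpd"]], big.mark = ","),
              format(dc[["n_total"]], big.mark = ",")))
  num <- names(.param_fields)
  vals <- vapply(num, function(f) x[[f]], numeric(1))
  print(vals)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Presentation rounding used for printed counts and monetary tables
#' (half-up, unlike [round()]'s round-half-even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
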