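# The 24 mutually exclusive patient types and the cohort partitions
# derived from them.

#' Enumerate the 24 patient types
#'
#' Each member of the assessed cohort belongs to exactly one of 24 types
#' defined by five binaries: true PD status, economic burden for PET,
#' MRI detection outcome, PET detection outcome (detected, not detected,
#' or not performed), and whether the MRI was read with AI. Types 1-12
#' are the AI arm; types 13-24 repeat the same clinical patterns on the
#' conventional PET-first arm, where the AI strategy changes nothing
#' ("same as comparator").
#'
#' @return A data frame with 24 rows and columns `type_id`, `pd_status`
#'   (logical), `economic_burden` (`"yes"`/`"no"`), `mri_detection`
#'   (`"detected"`/`"not_detected"`), `pet_detection` (`"detected"`,
#'   `"not_detected"`, `"not_performed"`), `ai_usage` (`"yes"`/`"no"`),
#'   `note`.
#' @examples
#' patient_types()[5, ]
#' @export
patient_types <- function() {
  det <- c(O = "detected", X = "not_detected", N = "not_performed")
  # the 12 clinical patterns (pd, burden, mri, pet) shared by both arms
  pat <- data.frame(
    pd_status       = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                        FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    economic_burden = c("no", "no", "no", "no", "yes", "yes",
                        "no", "no", "no", "no", "yes", "yes"),
    mri_detection   = det[c("O", "O", "X", "X", "O", "X",
                            "O", "O", "X", "X", "O", "X")],
    pet_detection   = det[c("O", "X", "O", "X", "O", "N",
                            "O", "X", "O", "X", "N", "O")],
    stringsAsFactors = FALSE)
  ai_notes <- c(
    "additional AI cost",
    "additional AI cost",
    "additional AI cost; missed case incurs delayed-diagnosis costs",
    "additional AI cost; missed case incurs delayed-diagnosis costs",
    "additional AI cost; additional PET cost; early-treatment cost saving",
    "additional AI cost",
    "additional AI cost; PET cost saved by triage",
    "additional AI cost; PET cost saved by triage",
    "additional AI cost",
    "additional AI cost",
    "additional AI cost",
    "additional AI cost")
  out <- rbind(
    cbind(type_id = 1:12, pat, ai_usage = "yes", note = ai_notes,
          stringsAsFactors = FALSE),
    cbind(type_id = 13:24, pat, ai_usage = "no",
          note = "same as comparator (conventional PET strategy)",
          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Expected cohort counts across the eight reporting subgroups
#'
#' Partitions the full assessed cohort (`n_total`, no adoption factor) by
#' PD status, economic burden and AI-read MRI outcome. Letters denote the
#' stratum (A = PD without burden, B = non-PD without burden, C = PD with
#' burden, D = non-PD with burden); suffix 1 means the AI call matched the
#' truth, suffix 2 that it did not. B1 is the triage payoff (avoided PET
#' scans in correctly excluded non-PD patients), C1 the access payoff
#' (burdened PD patients the AI flags for reimbursable PET), A2 the missed
#' PD cases and D2 the unnecessary PET scans from false positives.
#'
#' Counts are expected values and stay real-valued; use
#' [round_half_up()] (as the `print` method does) for presentation.
#'
#' @param params A `pd_parameters` object.
#' @return A `pd_subgroups` object: named numeric vector of the eight
#'   counts with attributes `n_total` and `label`.
#' @examples
#' subgroup_counts(read_parameters(pdcba_example("korea.yaml")))
#' @export
subgroup_counts <- function(params) {
  stopifnot(inherits(params, "pd_parameters"))
  dc <- derived_counts(params)
  u <- params$pet_unaffordable
  se <- params$sens_ai
  sp <- params$spec_ai
  x <- c(A1 = dc[["n_pd"]]    * (1 - u) * se,
         A2 = dc[["n_pd"]]    * (1 - u) * (1 - se),
         B1 = dc[["n_nonpd"]] * (1 - u) * sp,
         B2 = dc[["n_nonpd"]] * (1 - u) * (1 - sp),
         C1 = dc[["n_pd"]]    * u * se,
         C2 = dc[["n_pd"]]    * u * (1 - se),
         D1 = dc[["n_nonpd"]] * u * sp,
         D2 = dc[["n_nonpd"]] * u * (1 - sp))
  structure(x, n_total = dc[["n_total"]], label = params$label,
            class = "pd_subgroups")
}

#' @export
print.pd_subgroups <- function(x, ...) {
  nt <- attr(x, "n_total")
  cat("Cohort subgroups", if (nzchar(attr(x, "label")))
    paste0("- ", attr(x, "label")), "\n")
  cat(sprintf("  total assessed: %s\n",
              format(round_half_up(nt), big.mark = ",")))
  df <- data.frame(count = format(round_half_up(unclass(x)),
                                  big.mark = ","),
                   pct_of_total = sprintf("%.1f%%", 100 * x / nt))
  print(df)
  invisible(x)
}

#' @export
as.data.frame.pd_subgroups <- function(x, ...) {
  data.frame(subgroup = names(x), count = as.numeric(x),
             pct_of_total = 100 * as.numeric(x) / attr(x, "n_total"))
}

#' Expected counts over all 24 patient types
#'
#' Splits the cohort over the full 24-type classification at a given AI
#' adoption rate. The three MRI/burden/status margins follow the model's
#' closed forms; PET outcomes, which the closed forms never resolve at
#' this granularity, are factorized with `sens_pet` (PD) and `spec_pet`
#' (non-PD) under independence. This PET factorization is an
#' extrapolation beyond the aggregate model: only the 8-way collapse of
#' [subgroup_counts()] is constrained by published results.
#'
#' @param params A `pd_parameters` object.
#' @param adoption AI adoption rate; defaults to `params$ai_adoption`.
#' @return `patient_types()` with an `expected_count` column appended;
#'   the column sums to `n_total`.
#' @export
expected_type_counts <- function(params, adoption = params$ai_adoption) {
  stopifnot(inherits(params, "pd_parameters"),
            adoption >= 0, adoption <= 1)
  types <- patient_types()
  dc <- derived_counts(params)
  u <- params$pet_unaffordable
  n <- ifelse(types$pd_status, dc[["n_pd"]], dc[["n_nonpd"]])
  pburden <- ifelse(types$economic_burden == "yes", u, 1 - u)
  pmri <- ifelse(types$pd_status,
                 ifelse(types$mri_detection == "detected",
                        params$sens_ai, 1 - params$sens_ai),
                 ifelse(types$mri_detection == "detected",
                        1 - params$spec_ai, params$spec_ai))
  # PET outcome resolved only where the type table distinguishes it
  # within a (status, burden, MRI) stratum; N/A and singleton rows get 1.
  ppet <- rep(1, nrow(types))
  split_pet <- types$economic_burden == "no"   # burdened strata collapse
  ppet[split_pet] <- ifelse(types$pd_status[split_pet],
    ifelse(types$pet_detection[split_pet] == "detected",
           params$sens_pet, 1 - params$sens_pet),
    ifelse(types$pet_detection[split_pet] == "detected",
           1 - params$spec_pet, params$spec_pet))
  parm <- ifelse(types$ai_usage == "yes", adoption, 1 - adoption)
  types$expected_count <- n * pburden * pmri * ppet * parm
  types
}
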