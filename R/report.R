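# Presentation-format renderers: the side-by-side term table and the
# reproducibility bundle written by the command-line `reproduce` verb.

#' Render scenarios as a side-by-side term table
#'
#' Lays out one column per scenario in the published row order (MB1,
#' MB2, MC1, MC2, MC3, MC4, MC5, MB3, MC6, MB4, MC7, MB5, MB6, MC8,
#' MC9, MB7, MC10, MC11, then Net benefit and B/C ratio). Money is
#' rounded half-up to integer USD; the B/C ratio is shown to two
#' decimals; cells for terms zeroed by the healthcare-system perspective
#' are left blank.
#'
#' @param results A list of `pd_cba` objects sharing one variant and one
#'   aggregation rule (mixing them is refused - the rows would not be
#'   comparable).
#' @return A character data frame, rows as above, one column per
#'   scenario (named `<label> <adoption>%`).
#' @examples
#' korea <- read_parameters(pdcba_example("korea_unrounded.yaml"))
#' render_table4(adoption_sweep(korea, c(0.3, 1)))
#' @export
render_table4 <- function(results) {
  stopifnot(is.list(results), length(results) >= 0L)
  results <- unclass(results)
  row_ids <- term_definitions()$term_id
  if (length(results) == 0L) {
    out <- data.frame(row.names = c(row_ids, "Net benefit", "B/C ratio"))
    return(out)
  }
  stopifnot(all(vapply(results, inherits, logical(1), "pd_cba")))
  if (length(unique(vapply(results, `[[`, character(1), "variant"))) > 1L ||
      length(unique(vapply(results, `[[`, character(1),
                           "aggregation"))) > 1L)
    stop("refusing to tabulate scenarios with mixed variants or aggregations",
         call. = FALSE)
  cols <- lapply(results, function(r) {
    v <- r$terms$value[match(row_ids, r$terms$term_id)]
    cell <- format(round_half_up(v), big.mark = ",", scientific = FALSE,
                   trim = TRUE)
    cell[r$terms$excluded[match(row_ids, r$terms$term_id)]] <- ""
    c(cell,
      format(round_half_up(r$net_benefit), big.mark = ",",
             scientific = FALSE, trim = TRUE),
      if (is.na(r$bc_ratio)) "undefined" else sprintf("%.2f", r$bc_ratio))
  })
  names(cols) <- vapply(results, function(r)
    trimws(sprintf("%s %.0f%%", r$params$label, 100 * r$adoption)),
    character(1))
  out <- as.data.frame(cols, check.names = FALSE, optional = TRUE)
  rownames(out) <- c(row_ids, "Net benefit", "B/C ratio")
  out
}

# Full published analysis: both countries at three adoption levels,
# the subgroup partition, sensitivity endpoints and the U.S. break-even,
# plus metadata sufficient to re-run bit-identically.
reproduce_bundle <- function(out_dir,
                             korea = pdcba_example("korea_unrounded.yaml"),
                             korea_printed = pdcba_example("korea.yaml"),
                             usa = pdcba_example("usa.yaml"),
                             rates = c(0.3, 0.65, 1), seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pk <- read_parameters(korea)
  pu <- read_parameters(usa)
  scenarios <- c(adoption_sweep(pk, rates), adoption_sweep(pu, rates))
  tab <- render_table4(scenarios)
  utils::write.csv(cbind(term = rownames(tab), tab),
                   file.path(out_dir, "term_table.csv"),
                   row.names = FALSE)
  sg <- subgroup_counts(read_parameters(korea_printed))
  utils::write.csv(as.data.frame(sg),
                   file.path(out_dir, "subgroups_korea.csv"),
                   row.names = FALSE)
  sens <- one_way_sensitivity(pk, "pet_unaffordable", c(0, 0.5, 1))
  utils::write.csv(as.data.frame(sens),
                   file.path(out_dir, "sensitivity_unaffordability.csv"),
                   row.names = FALSE)
  meta <- list(
    variant = "table_consistent", aggregation = "published",
    adoption_rates = rates, seed = seed,
    reconciled_terms = c("MC1", "MC8", "MC9", "MC10", "MC11"),
    breakeven_ai_cost_usa = as.numeric(break_even_ai_cost(pu)),
    breakeven_ai_cost_korea = as.numeric(break_even_ai_cost(pk)),
    parameter_files = list(
      korea = unname(tools::md5sum(korea)),
      korea_printed = unname(tools::md5sum(korea_printed)),
      usa = unname(tools::md5sum(usa))))
  jsonlite::write_json(meta, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
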