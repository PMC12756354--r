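test_that("the rendered term table follows the published layout", {
  k <- korea_unrounded_params()
  u <- usa_params()
  tab <- render_table4(c(adoption_sweep(k, c(0.3, 1)),
                         adoption_sweep(u, c(0.3, 1))))
  expect_equal(rownames(tab),
               c(term_definitions()$term_id, "Net benefit", "B/C ratio"))
  expect_equal(ncol(tab), 4L)
  # money half-up to integer; B/C to two decimals
  expect_equal(tab["MB1", 3], "2,786,975")
  expect_equal(tab["MC3", 3], "3,780,000")
  expect_equal(tab["B/C ratio", 1], "1.48")
  expect_equal(tab["B/C ratio", 3], "1.36")
  # non-medical cells blank for the healthcare-system column
  expect_equal(tab["MB5", 3], "")
  expect_equal(tab["MC11", 4], "")
  expect_true(nzchar(tab["MB5", 1]))
  # rendered net equals re-rounding the unrendered float
  fit <- pd_cba(k, 0.3)
  expect_equal(tab["Net benefit", 1],
               format(round_half_up(fit$net_benefit), big.mark = ",",
                      scientific = FALSE, trim = TRUE))
})

test_that("mixed variants are refused and empty input gives a header-only table", {
  k <- korea_unrounded_params()
  a <- pd_cba(k, 0.3, variant = "table_consistent")
  b <- pd_cba(k, 0.3, variant = "as_printed")
  expect_error(render_table4(list(a, b)), "mixed")
  empty <- render_table4(list())
  expect_equal(nrow(empty), 20L)
  expect_equal(ncol(empty), 0L)
})

test_that("CLI subcommands run on bundled configs and fail usefully", {
  kf <- pdcba_example("korea_unrounded.yaml")
  uf <- pdcba_example("usa.yaml")

  expect_equal(suppressMessages(run_cli(character(0))), 2L)
  expect_equal(suppressMessages(run_cli("frobnicate")), 2L)
  expect_equal(suppressMessages(run_cli(c("run"))), 2L)  # missing --params

  out <- withr::local_tempfile(fileext = ".csv")
  expect_equal(suppressMessages(
    run_cli(c("run", "--params", kf, "--out", out))), 0L)
  got <- utils::read.csv(out, check.names = FALSE)
  expect_equal(nrow(got), 20L)

  expect_equal(suppressMessages(
    run_cli(c("subgroups", "--params", kf, "--out", out))), 0L)
  expect_equal(nrow(utils::read.csv(out)), 8L)

  expect_equal(suppressMessages(
    run_cli(c("sweep", "--params", kf, "--var", "pet_unaffordable",
              "--grid", "0:1:0.5", "--out", out))), 0L)
  expect_equal(utils::read.csv(out)$value, c(0, 0.5, 1))

  expect_equal(suppressMessages(
    run_cli(c("project", "--params", kf, "--years", "2025:2030",
              "--out", out))), 0L)
  expect_equal(nrow(utils::read.csv(out)), 6L)

  # breakeven prints the same value the closed form returns
  txt <- capture.output(status <- suppressMessages(
    run_cli(c("breakeven", "--params", uf))))
  expect_equal(status, 0L)
  expect_match(txt, "1506.62", fixed = TRUE, all = FALSE)
})

test_that("the reproduce bundle is complete and re-runnable", {
  dir <- withr::local_tempdir()
  expect_equal(suppressMessages(
    run_cli(c("reproduce", "--out", dir))), 0L)
  expect_true(file.exists(file.path(dir, "term_table.csv")))
  expect_true(file.exists(file.path(dir, "subgroups_korea.csv")))
  expect_true(file.exists(file.path(dir,
                                    "sensitivity_unaffordability.csv")))
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$variant, "table_consistent")
  expect_equal(round(meta$breakeven_ai_cost_usa), 1507)
  sg <- utils::read.csv(file.path(dir, "subgroups_korea.csv"))
  expect_equal(round_half_up(sg$count[sg$subgroup == "B1"]), 31381)

  # metadata re-runs to bit-identical outputs
  dir2 <- withr::local_tempdir()
  suppressMessages(run_cli(c("reproduce", "--out", dir2,
                             "--seed", as.character(meta$seed))))
  expect_identical(readLines(file.path(dir, "term_table.csv")),
                   readLines(file.path(dir2, "term_table.csv")))
})
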