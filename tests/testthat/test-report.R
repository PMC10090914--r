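noncomp_cfg <- list(
  design_kind = "noncomparative",
  parameters = list(target_lower_primary = 90, target_lower_alternative = 80,
                    level = 0.95, prevalence = 0.6,
                    override_n = c(150L, 63L)))

test_that("non-comparative config reproduces the worked report numbers", {
  rep <- run_design(noncomp_cfg)
  expect_equal(rep$numbers$n_total, 213)
  expect_equal(rep$numbers$n_cases, 128L)
  expect_equal(rep$numbers$n_controls, 85L)
  txt <- render_report(rep, "text")
  expect_match(txt, "n_total = 213")
  expect_match(txt, "n_cases = 128")
})

test_that("rct non-inferiority config reports per-group and doubled total", {
  rep <- run_design(list(
    design_kind = "rct-noninf",
    parameters = list(p_control = 0.80, p_new = 0.80, margin = 0.05,
                      alpha = 0.05, power = 0.90)))
  expect_equal(rep$numbers$n_per_group, 1097L)
  expect_equal(rep$numbers$n_total, 2194L)
  txt <- render_report(rep, "text")
  expect_match(txt, "n_per_group = 1097")
  expect_match(txt, "alpha = 0.05")
  expect_match(txt, "power = 0.9")
})

test_that("invalid configs fail with the offending field named", {
  bad <- noncomp_cfg
  bad$parameters$prevalence <- 1.2
  expect_error(run_design(bad), "prevalence")
  expect_error(run_design(list(design_kind = "nope", parameters = list())),
               "design_kind")
  expect_error(run_design(list(design_kind = "rct-sup",
                               parameters = list(p_control = 0.8))),
               "p_new")
  expect_error(run_design(list(design_kind = "diag-noninf",
                               parameters = list(p_control = 0.8,
                                                 p_new = 0.8))),
               "margin")
  expect_error(run_design(list(parameters = list())), "design_kind")
})

test_that("JSON report round-trips and agrees with the text report", {
  rep <- run_design(noncomp_cfg)
  parsed <- jsonlite::fromJSON(render_report(rep, "json"))
  expect_equal(parsed$design_kind, rep$design_kind)
  txt <- render_report(rep, "text")
  for (nm in names(rep$numbers)) {
    val <- rep$numbers[[nm]]
    if (is.na(val)) next
    expect_equal(parsed$numbers[[nm]], as.numeric(val), tolerance = 1e-15,
                 label = nm)
    # every number in the text report appears identically in the JSON one
    expect_match(txt, sprintf("%s = %s", nm,
                              jsonlite::toJSON(val, auto_unbox = TRUE,
                                               digits = NA)),
                 fixed = TRUE)
  }
  expect_error(render_report(rep, "xml"), "arg")
  expect_error(render_report(list(), "text"), "design_report")
})

test_that("warnings surface in the rendered report", {
  cfg <- noncomp_cfg
  cfg$parameters$prevalence <- 0.001
  rep <- suppressWarnings(run_design(cfg))
  expect_gt(length(rep$warnings), 0)
  expect_match(render_report(rep, "text"), "warnings:")
  expect_match(render_report(rep, "text"), "degenerate")
})

test_that("percent convention rescales proportion-type parameters", {
  rep <- run_design(list(
    design_kind = "diag-sup", percent_convention = TRUE,
    parameters = list(p_control = 80, p_new = 90, alpha = 5, power = 90)))
  expect_equal(rep$numbers$n_per_group, 263L)
  expect_equal(rep$numbers$n_total, 263L)  # paired-diagnostic framing
})

test_that("configs load from JSON and YAML files identically", {
  json_path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(noncomp_cfg, json_path, auto_unbox = TRUE)
  cfg_json <- read_design_config(json_path)
  expect_equal(run_design(cfg_json)$numbers$n_total, 213)

  yaml_path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(noncomp_cfg, yaml_path)
  cfg_yaml <- read_design_config(yaml_path)
  expect_equal(run_design(cfg_yaml)$numbers, run_design(cfg_json)$numbers)

  expect_error(read_design_config("no-such-file.json"), "not found")
  bad_path <- withr::local_tempfile(fileext = ".txt")
  writeLines("x", bad_path)
  expect_error(read_design_config(bad_path), "extension")
})

test_that("report pipeline is deterministic for closed-form designs", {
  r1 <- run_design(noncomp_cfg)
  r2 <- run_design(noncomp_cfg)
  expect_equal(r1$numbers, r2$numbers)
  expect_equal(r1$inputs, r2$inputs)
})
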