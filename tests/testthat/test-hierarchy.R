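test_that("BMI bands assign fine labels with inclusive lower bounds", {
  expect_equal(bmi_label(1.70, 49.0), "Insufficient weight")   # BMI 16.96
  expect_equal(bmi_label(1.70, 130.0), "Obesity type III")     # BMI 44.98
  expect_equal(bmi_label(2.0, 74.0), "Normal weight")          # BMI exactly 18.5
  expect_equal(bmi_label(1.0, 25.0), "Overweight level I")     # boundary 25.0
  expect_equal(bmi_label(1.0, 40.0), "Obesity type III")       # boundary 40.0
  expect_error(bmi_label(0, 70), "positive")
  expect_error(bmi_label(1.7, -1), "positive")
})

test_that("fine labels merge into the three coarse groups", {
  expect_equal(coarsen("Normal weight"), "Lean")
  expect_equal(coarsen("Overweight level II"), "Overweight")
  expect_equal(coarsen("Obesity type II"), "Obese")
  expect_equal(coarsen(c("Insufficient weight", "Obesity type I")),
               c("Lean", "Obese"))
  expect_error(coarsen("Skinny"), "unknown")
})

test_that("label scheme validates totality, surjectivity and threshold order", {
  expect_error(label_scheme(c("a", "b"), c("g"), c(a = "g"), 1), "every fine label")
  expect_error(label_scheme(c("a", "b"), c("g", "h"), c(a = "g", b = "g"), 1),
               "surjective")
  expect_error(label_scheme(c("a", "b", "c"), c("g"), c(a = "g", b = "g", c = "g"),
                            c(2, 1)), "increasing")
  expect_error(obesity_scheme(overweight_split = 31), "inside")
})

test_that("hierarchical rule counts sum module-wise and beat the flat count", {
  expect_equal(hierarchical_rule_count(c(2, 3, 3, 4), 3), 144)
  expect_equal(hierarchical_rule_count(c(1), 2), 2)
  expect_equal(hierarchical_rule_count(c(6), 3), 729)
  expect_lt(hierarchical_rule_count(c(2, 3, 3, 4), 3), rule_count(6, 3))
})

test_that("routing follows the coarse argmax and hard-constrains fine labels", {
  fx <- fixture_trained()
  model <- fx$model
  te <- fx$ds$records[fx$split$test, ]
  p <- predict(model, te)
  # routing equals an independently recomputed coarse argmax
  co <- infer_batch(model$coarse, te[, model$coarse$frame$attribute_names])
  expect_equal(p$coarse,
               model$coarse$class_labels[apply(co$masses, 1, which.max)])
  # the fine label always belongs to the routed group
  scheme <- model$scheme
  for (i in seq_along(p$fine)) {
    expect_equal(unname(scheme$merge_map[p$fine[i]]), p$coarse[i])
  }
  # single-record path agrees with the batch path
  one <- dbrb_predict(model, as.list(te[3, ]))
  expect_equal(one$fine_label, p$fine[3])
  expect_equal(one$coarse_label, p$coarse[3])
})

test_that("coarse accuracy dominates fine accuracy on held-out synthetic data", {
  fx <- fixture_trained()
  te <- fx$ds$records[fx$split$test, ]
  yte <- fx$ds$fine_labels[fx$split$test]
  p <- predict(fx$model, te)
  coarse_acc <- mean(p$coarse == coarsen(yte))
  fine_acc <- mean(p$fine == yte)
  expect_gte(coarse_acc, fine_acc)
  expect_gt(coarse_acc, 0.9)  # height/weight separate the groups cleanly
})

test_that("noiseless records with unambiguous BMI get their BMI-derived label", {
  fx <- fixture_trained()
  ds <- fx$ds
  te <- ds$records[fx$split$test, ]
  yte <- ds$fine_labels[fx$split$test]
  p <- predict(fx$model, te)
  # restrict to records well inside their BMI band (no boundary ambiguity)
  bmi <- te$weight / te$height^2
  edges <- c(10, ds$scheme$bmi_thresholds, 50)
  band <- findInterval(bmi, ds$scheme$bmi_thresholds) + 1
  depth <- pmin(bmi - edges[band], edges[band + 1] - bmi) /
    (edges[band + 1] - edges[band])
  core <- depth > 0.25
  # well above chance (1/7) and the per-group majority rate; exact agreement
  # is capacity-limited: three reference values per attribute cannot carve
  # the curved within-group BMI boundaries perfectly
  expect_gt(mean(p$fine[core] == yte[core]), 0.5)
})

test_that("model construction enforces the submodule label partition", {
  sch <- obesity_scheme()
  ds <- fixture_cohort()
  expect_error(
    dbrb_model(brb_rulebase(frame_from_data(ds$records, c("height", "weight")),
                            sch$coarse_labels),
               list(Lean = brb_rulebase(frame_from_data(ds$records, "ncp"),
                                        c("Normal weight", "Insufficient weight")),
                    Overweight = brb_rulebase(frame_from_data(ds$records, "age"),
                                              c("Overweight level I", "Overweight level II")),
                    Obese = brb_rulebase(frame_from_data(ds$records, "fcvc"),
                                         c("Obesity type I", "Obesity type II", "Obesity type III"))),
               sch),
    "must classify exactly")
})

test_that("hierarchy configuration round-trips through YAML", {
  sch <- obesity_scheme(overweight_split = 27.0)
  fs <- default_feature_subsets(sch)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_hierarchy_config(sch, fs, 3, path)
  cfg <- read_hierarchy_config(path)
  expect_equal(cfg$scheme$fine_labels, sch$fine_labels)
  expect_equal(cfg$scheme$merge_map, sch$merge_map)
  expect_equal(cfg$scheme$bmi_thresholds, sch$bmi_thresholds)
  expect_equal(cfg$feature_subsets, fs)
  expect_equal(cfg$n_refs, 3)
})
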