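baseVals <- c(shape = "oval", margin = "circumscribed",
              orientation = "parallel", echogenicity = "hypoechoic",
              posterior = "none", halo = "absent",
              suggestivity = "no_clear_suggestivity")

test_that("the two fine-tuning rules fire with malignancy-dominant precedence", {
  ## round nodules lose their orientation
  v <- baseVals; v["shape"] <- "round"
  out <- applyRules(descriptorSet(v), "3")
  expect_identical(descriptorValues(out$descriptors)[["orientation"]], "none")

  ## special-case suggestivities override the regression category
  v <- baseVals
  v[c("echogenicity", "posterior", "suggestivity")] <-
    c("anechoic", "enhancement", "simple_cyst")
  expect_identical(applyRules(descriptorSet(v), "3")$category, "2")
  v <- baseVals
  v[c("echogenicity", "suggestivity")] <- c("heterogeneous", "complex_cyst")
  expect_identical(applyRules(descriptorSet(v), "3")$category, "4A")
  v <- baseVals; v["margin"] <- "spiculated"
  expect_identical(applyRules(descriptorSet(v), "3")$category, "5")

  ## spiculated beats a cyst-like suggestivity (malignancy-dominant order)
  v <- baseVals
  v[c("margin", "suggestivity")] <- c("spiculated", "complex_cyst")
  expect_identical(applyRules(descriptorSet(v), "3")$category, "5")

  ## everything else passes through
  out <- applyRules(descriptorSet(baseVals), "4B")
  expect_identical(out$category, "4B")
  expect_identical(descriptorValues(out$descriptors), baseVals)
})

test_that("rules are idempotent and consistent over the full combination table", {
  voc <- descriptorVocabularies()
  for (sh in voc$shape) for (mg in voc$margin) for (sg in voc$suggestivity)
    for (cat in voc$birads) {
      v <- baseVals
      v[c("shape", "margin", "suggestivity")] <- c(sh, mg, sg)
      if (sg == "simple_cyst")
        v[c("echogenicity", "posterior", "margin")] <-
          c("anechoic", "enhancement", mg)
      r1 <- applyRules(descriptorSet(v), cat)
      r2 <- applyRules(r1$descriptors, r1$category)
      expect_identical(r2$category, r1$category)
      expect_identical(descriptorValues(r2$descriptors),
                       descriptorValues(r1$descriptors))
      if (sh == "round")
        expect_identical(descriptorValues(r1$descriptors)[["orientation"]],
                         "none")
      if (mg == "spiculated") expect_identical(r1$category, "5")
      else if (sg == "simple_cyst") expect_identical(r1$category, "2")
      else if (sg == "complex_cyst") expect_identical(r1$category, "4A")
      else expect_identical(r1$category, cat)
    }
})

test_that("the intervention table covers the full category scale", {
  expect_identical(intervention("0"), "Additional evaluation")
  expect_identical(intervention("1"), "Normal procedure")
  expect_identical(intervention("2"), "Normal procedure")
  expect_identical(intervention("3"), "Control in 6 months")
  for (cat in c("4A", "4B", "4C", "5"))
    expect_identical(intervention(cat), "Biopsy")
  expect_identical(intervention("6"), "Treatment")
  expect_error(intervention("7"), "unknown")
})

test_that("reports render deterministically and round-trip losslessly", {
  rep1 <- renderReport(descriptorSet(baseVals), "3", malignancyProb = 0.12)
  rep2 <- renderReport(descriptorSet(baseVals), "3", malignancyProb = 0.12)
  expect_identical(rep1@narrative, rep2@narrative)
  expect_match(rep1@narrative, "parallel orientation")
  expect_match(rep1@narrative, "Control in 6 months")

  ## a round nodule's narrative has no orientation phrase
  v <- baseVals; v[c("shape", "orientation")] <- c("round", "none")
  repR <- renderReport(descriptorSet(v), "3", 0.2)
  expect_false(grepl("orientation", repR@narrative))

  ## serialize -> parse -> serialize is byte-identical
  js1 <- serializeReport(rep1)
  js2 <- serializeReport(parseReport(js1))
  expect_identical(js1, js2)

  ## every retained descriptor value is mentioned exactly once
  for (val in c("oval", "circumscribed", "hypoechoic"))
    expect_equal(lengths(regmatches(rep1@narrative,
      gregexpr(val, rep1@narrative))), 1)

  expect_error(renderReport(descriptorSet(baseVals), "3",
                            template = "The nodule {missing_slot}."),
               "slot")
})
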