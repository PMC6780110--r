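# Per-layer trainable parameter counts of the published layer tables,
# verified by hand arithmetic (kh*kw*cin + 1)*cout and 2*cout. The decoder
# table leaves one conv cell blank; 295040 + 256 is the derived value.
published_counts <- list(
  "ECon-1_1" = c(1792, 128),    "ECon-1_2" = c(36928, 128),
  "ECon-2_1" = c(73856, 256),   "IRSP-1" = c(8320, 256),
  "ECon-2_2" = c(147584, 256),
  "ECon-3_1" = c(295168, 512),  "IRSP-2" = c(33024, 512),
  "ECon-3_2" = c(590080, 512),
  "ECon-4_1" = c(1180160, 1024), "IRSP-3" = c(131584, 1024),
  "ECon-4_2" = c(2359808, 1024),
  "DCon-4_2" = c(2359808, 1024), "IRSP-4" = c(131328, 512),
  "DCon-4_1" = c(1179904, 512),
  "DCon-3_2" = c(590080, 512),  "IRSP-5" = c(32896, 256),
  "DCon-3_1" = c(295040, 256),
  "DCon-2_2" = c(147584, 256),  "IRSP-6" = c(8256, 128),
  "DCon-2_1" = c(73792, 128),
  "DConv-1_2" = c(36928, 128),  "DConv-1_1" = c(1154, 4))

test_that("generated plan reproduces every published parameter cell", {
  plan <- plan_vessnet(c(447, 447, 3), 2)
  specs <- conv_specs(plan)
  expect_setequal(names(specs), names(published_counts))
  for (nm in names(published_counts)) {
    expect_identical(as.integer(conv_param_count(specs[[nm]])),
                     as.integer(published_counts[[nm]][1]), label = nm)
    expect_identical(as.integer(bn_param_count(specs[[nm]])),
                     as.integer(published_counts[[nm]][2]), label = nm)
  }
})

test_that("plan has 16 3x3 convs, 6 projection and 4 identity links", {
  plan <- plan_vessnet(c(447, 447, 3), 2)
  main <- conv_specs(plan, include_projections = FALSE)
  expect_length(main, 16L)
  expect_true(all(vapply(main, function(s) all(s$kernel == 3L), logical(1))))
  proj <- Filter(function(l) l$kind == "projection", plan$links)
  iden <- Filter(function(l) l$kind == "identity", plan$links)
  expect_length(proj, 6L)
  expect_length(iden, 4L)
  expect_true(all(vapply(proj, function(l)
    all(l$projection$kernel == 1L), logical(1))))
  expect_identical(sum(vapply(plan$blocks, function(b)
    b$pool_or_unpool == "pool", logical(1))), 4L)
  # first encoder and terminal decoder block carry no inner projection
  expect_false(plan$blocks[[1]]$has_irsp)
  expect_false(plan$blocks[[8]]$has_irsp)
  # terminal conv produces one filter per class
  expect_identical(main[["DConv-1_1"]]$out_channels, 2L)
})

test_that("shape schedule matches the published tables and mirrors back", {
  sh <- infer_shapes(plan_vessnet(c(447, 447, 3), 2))
  enc <- sapply(sprintf("Pool-%d", 1:4), function(n) sh[[n]][1])
  expect_equal(unname(enc), c(223, 111, 55, 27))
  expect_equal(unname(sh[["Pool-4"]]), c(27, 27, 512))
  expect_equal(unname(sh[["DConv-1_1"]]), c(447, 447, 2))
  expect_equal(unname(sh[["Unpool-1"]]), c(447, 447, 64))
  # even input halves and mirrors exactly too
  sh2 <- infer_shapes(plan_vessnet(c(448, 448, 3), 2))
  expect_equal(sapply(sprintf("Pool-%d", 1:4), function(n) sh2[[n]][1]),
               c(`Pool-1` = 224, `Pool-2` = 112, `Pool-3` = 56, `Pool-4` = 28))
  expect_equal(unname(sh2[["DConv-1_1"]][1:2]), c(448, 448))
  # deepest spatial side for a 64-pixel input: 64 -> 32 -> 16 -> 8 -> 4
  sh3 <- infer_shapes(plan_vessnet(c(64, 64, 3), 2, base_filters = 8))
  expect_equal(sh3[["Pool-4"]][1], 4)
})

test_that("invalid plans are rejected", {
  expect_error(plan_vessnet(c(0, 447, 3), 2), "positive")
  expect_error(plan_vessnet(c(447, 447, 1), 2), "3 channels")
  expect_error(plan_vessnet(c(8, 8, 3), 2), "at least 16")
  expect_error(plan_vessnet(c(64, 64, 3), 1), "num_classes")
})

test_that("architecture table prints published rows and totals", {
  tab <- describe_plan(plan_vessnet(c(447, 447, 3), 2))
  txt <- paste(capture.output(print(tab)), collapse = "\n")
  expect_match(txt, "ECon-4_2.*2,359,808 \\+\\s+1,024")
  expect_match(txt, "IRSP-4.*131,328 \\+\\s+512")
  expect_match(txt, "27 × 27 × 512")
  tot <- attr(tab, "totals")
  expect_equal(unname(tot["conv"]),
               sum(vapply(published_counts, `[`, numeric(1), 1)))
  expect_equal(unname(tot["bn"]),
               sum(vapply(published_counts, `[`, numeric(1), 2)))
})
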