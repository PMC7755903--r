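test_that("hinge span arithmetic reproduces the wingspan anchors", {
  p <- geometry_params()
  expect_equal(hinge_span(10, "relaxed", "both", p), 42)
  expect_equal(hinge_span(10, "tense", "both", p), 63)
  expect_equal(hinge_span(0, "relaxed", "both", p), 0)
  expect_equal(hinge_span(0, "tense", "one", p), 0)
  expect_equal(hinge_span(7, "tense", "both", p), 44.1)
  expect_equal(hinge_span(13, "relaxed", "both", p), 54.6)
  expect_error(hinge_span(-1, "relaxed"), "negative")
})

test_that("hinge span is linear in n and tense dominates relaxed", {
  p <- geometry_params()
  n <- 0:25
  rel <- hinge_span(n, "relaxed", "both", p)
  ten <- hinge_span(n, "tense", "both", p)
  expect_equal(rel, 2 * p$L_ref / p$n_ref * n)
  expect_true(all(ten >= rel))
  # linearity: span(a + b) = span(a) + span(b)
  expect_equal(hinge_span(7, "tense", "both", p) + hinge_span(3, "tense", "both", p),
               hinge_span(10, "tense", "both", p))
})

test_that("span assessment brackets the anchor distance correctly", {
  a10 <- assess_span(10)
  expect_equal(a10$relaxed_both, 42)
  expect_equal(a10$tense_both, 63)
  expect_true(a10$reach_ok && a10$strain_ok)
  expect_equal(a10$strain_ratio, (51 - 42) / (63 - 42), tolerance = 1e-12)

  a13 <- assess_span(13)  # +GGS-like insertion
  expect_false(a13$strain_ok)
  expect_true(a13$reach_ok)

  a7 <- assess_span(7)    # -KTH-like deletion
  expect_false(a7$reach_ok)
  expect_true(a7$strain_ok)

  # ratio undefined when d_req falls outside [relaxed, tense]
  a8 <- assess_span(8)
  expect_true(a8$reach_ok)
  expect_true(is.na(a8$strain_ratio))
})

test_that("variant loading strips gaps, computes n, and rejects bad rows", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,upper_seq,constrained,scaffold",
               "IgG1.v2,EPKSCDKTH---------T,false,IgG1",
               "G1-KTH,EPKSCD------------T,false,IgG1",
               "X,,false,IgG1"), tmp)
  vars <- load_variants(tmp)
  expect_length(vars, 3)
  expect_equal(vars[[1]]$n, 10)
  expect_equal(vars[[1]]$upper_seq, "EPKSCDKTHT")
  expect_equal(vars[[2]]$n, 7)
  expect_true(vars[[3]]$degenerate)
  expect_equal(vars[[3]]$n, 0)

  bad_seq <- data.frame(name = "B", upper_seq = "EPKZ", constrained = "false",
                        scaffold = "IgG1")
  expect_error(load_variants(bad_seq), "row 1")
  bad_bool <- data.frame(name = "B", upper_seq = "EPKS", constrained = "maybe",
                         scaffold = "IgG1")
  expect_error(load_variants(bad_bool), "boolean")
})

test_that("constraint inference flags extra cysteines beyond the scaffold baseline", {
  tab <- data.frame(name = c("WT", "CC"),
                    upper_seq = c("EPKSCDKTHT", "EPKSCDKCCT"),
                    constrained = c("false", "false"), scaffold = "IgG1")
  vars <- load_variants(tab, infer_constraint = TRUE)
  expect_false(vars[[1]]$constrained)
  expect_true(vars[[2]]$constrained)
})

test_that("inhibition prediction follows the reach/strain/constraint logic", {
  wt <- hinge_variant("WT", "EPKSCDKTHT")
  expect_equal(predict_inhibition(wt)$class, "full")

  igg2 <- hinge_variant("IgG2", "ERKCCVE", constrained = TRUE, scaffold = "IgG2")
  p2 <- predict_inhibition(igg2)
  expect_equal(p2$class, "none")
  expect_equal(p2$reason, "constrained")

  long <- hinge_variant("+(GGS)3", "EPKSCDKTHGGSGGSGGST")
  pl <- predict_inhibition(long)
  expect_equal(pl$class, "none")
  expect_equal(pl$reason, "no_strain")

  short <- hinge_variant("-KTH", "EPKSCDT")
  ps <- predict_inhibition(short)
  expect_equal(ps$class, "none")
  expect_equal(ps$reason, "no_reach")

  gg <- hinge_variant("+GG", "EPKSCDKTHGGT")
  expect_equal(predict_inhibition(gg)$class, "partial")

  igg4 <- hinge_variant("IgG4", "ESKYGPP", scaffold = "IgG4")
  p4 <- predict_inhibition(igg4)
  expect_true(is.na(p4$class))
  expect_equal(p4$reason, "unsupported_scaffold")
})

test_that("prediction is monotone in hinge length with no re-entry", {
  scan <- scan_active_window(n_range = 0:30)
  act <- scan$active
  # the active region is a single contiguous block
  runs <- rle(act)
  expect_lte(sum(runs$values), 1)
  # below the block: no_reach; above: no_strain
  first_active <- min(which(act))
  last_active <- max(which(act))
  expect_true(all(scan$reason[seq_len(first_active - 1)] == "no_reach"))
  expect_true(all(scan$reason[seq(last_active + 1, nrow(scan))] == "no_strain"))
})

test_that("default parameters recover the 8-12 residue active window", {
  scan <- scan_active_window(n_range = 4:20)
  expect_setequal(scan$n[scan$active], 8:12)
  # one-arm relaxed spans at the window edges match ~17-26 A within 1 A
  expect_gte(hinge_span(8, "relaxed", "one"), 17 - 1)
  expect_lte(hinge_span(12, "relaxed", "one"), 26 + 1)
})

test_that("d_req = 0 makes every length reach, and the window shrinks with eps", {
  p0 <- geometry_params(d_req = 0)
  scan0 <- scan_active_window(p0, n_range = 0:20)
  expect_true(all(scan0$reason != "no_reach"))

  eps_grid <- c(2, 1, 0.5, 0)
  sets <- lapply(eps_grid, function(e) {
    s <- scan_active_window(geometry_params(eps = e), n_range = 4:20)
    s$n[s$active]
  })
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})
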