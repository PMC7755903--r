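make_uptake <- function(apo, holo, times = 10, start = 1, end = 10,
                        pep = "pep1") {
  rows <- list()
  for (ti in seq_along(times)) {
    for (r in seq_along(apo[[ti]])) {
      rows[[length(rows) + 1L]] <- data.frame(
        peptide_id = pep, sequence = "AAAAAAAAAA", start = start, end = end,
        state = "apo", time_min = times[ti], replicate = r, D = apo[[ti]][r])
    }
    for (r in seq_along(holo[[ti]])) {
      rows[[length(rows) + 1L]] <- data.frame(
        peptide_id = pep, sequence = "AAAAAAAAAA", start = start, end = end,
        state = "holo", time_min = times[ti], replicate = r, D = holo[[ti]][r])
    }
  }
  do.call(rbind, rows)
}

test_that("the duplicate-range differential criterion matches worked arithmetic", {
  up <- make_uptake(list(c(2.0, 2.2)), list(c(1.4, 1.5)))
  dm <- differential_map(up)
  tp <- dm$per_timepoint
  expect_equal(tp$delta, 0.65, tolerance = 1e-12)
  expect_equal(tp$range_apo, 0.2, tolerance = 1e-12)
  expect_equal(tp$range_holo, 0.1, tolerance = 1e-12)
  expect_true(tp$significant)
  expect_true(dm$per_peptide$significant)
  expect_equal(dm$per_peptide$direction, 1)  # slower exchange when bound

  # wide duplicate ranges keep even sizeable spreads non-significant
  up2 <- make_uptake(list(c(2.0, 3.0)), list(c(2.4, 2.6)))
  dm2 <- differential_map(up2)
  expect_lte(dm2$per_timepoint$delta,
             dm2$per_timepoint$range_apo + dm2$per_timepoint$range_holo)
  expect_false(dm2$per_peptide$significant)

  up3 <- make_uptake(list(c(2.0, 2.2)), list(c(2.0, 2.2)))
  expect_false(differential_map(up3)$per_peptide$significant)
})

test_that("differential significance is symmetric under state relabeling", {
  up <- make_uptake(list(c(2.0, 2.2), c(4.0, 4.1)),
                    list(c(1.4, 1.5), c(2.0, 2.2)), times = c(1, 10))
  fwd <- differential_map(up, "apo", "holo")
  rev <- differential_map(up, "holo", "apo")
  expect_equal(fwd$per_peptide$significant, rev$per_peptide$significant)
  expect_equal(fwd$per_peptide$direction, -rev$per_peptide$direction)
  expect_equal(fwd$per_timepoint$delta, rev$per_timepoint$delta)
})

test_that("unmatched peptides are reported and skipped", {
  up <- make_uptake(list(c(2.0, 2.2)), list(c(1.4, 1.5)))
  lone <- up[up$state == "apo", ]
  lone$peptide_id <- "pep_lonely"
  expect_warning(dm <- differential_map(rbind(up, lone)), "pep_lonely")
  expect_equal(nrow(dm$per_peptide), 1)
})

test_that("intrinsic rates obey the base-catalysed pD law and exclusions", {
  r7 <- intrinsic_rates("AAAAAAAA", pD = 7)
  r8 <- intrinsic_rates("AAAAAAAA", pD = 8)
  mid <- 4:6
  expect_equal(r8$k_int[mid] / r7$k_int[mid], rep(10, 3), tolerance = 0.01)
  expect_true(all(is.na(r7$k_int[1:2])))
  rp <- intrinsic_rates("AAAPAAAA")
  expect_true(is.na(rp$k_int[4]))
  expect_error(intrinsic_rates("AAXB"), "unknown residue")
  expect_error(intrinsic_rates("AAAA", pD = 20), "pD")
})

test_that("poly-alanine interior rate matches the reference constants", {
  # direct arithmetic from the reference constants at pD 7, 20 C
  k_expected <- 10^1.62 * 1e-7 + 10^10.05 * 10^(7 - 15.05) + 10^-1.5
  r <- intrinsic_rates("AAAAAAAA", pD = 7, temperature_C = 20)
  expect_equal(r$k_int[5], k_expected, tolerance = 0.05)
  # Arrhenius: rates increase with temperature
  r30 <- intrinsic_rates("AAAAAAAA", pD = 7, temperature_C = 30)
  expect_true(all(r30$k_int[4:6] > r$k_int[4:6]))
})

test_that("empirical protection factors are recovered from uptake curves", {
  k <- intrinsic_rates("GAKLVSTIEF")$k_int
  times <- c(0.5, 2.3, 10, 48, 218, 1000)
  curve <- function(pf, noise = 0, seed = 1) {
    kk <- k[is.finite(k)]
    D <- vapply(times, function(t) sum(1 - exp(-kk * t / pf)), numeric(1))
    set.seed(seed)
    do.call(rbind, lapply(1:2, function(r) {
      data.frame(time_min = times, replicate = r,
                 D = D * (1 + rnorm(length(times), 0, noise)))
    }))
  }
  # noiseless PF = 1
  fit1 <- empirical_pf(curve(1), k)
  expect_equal(fit1$PF, 1, tolerance = 0.01)
  expect_equal(fit1$flag, "ok")
  # PF = 100 with 2% duplicate noise: within a factor of 1.25
  fit100 <- empirical_pf(curve(100, noise = 0.02, seed = 42), k)
  expect_lt(abs(log(fit100$PF / 100)), log(1.25))
  expect_true(fit100$sigma_PF > 0 && is.finite(fit100$sigma_PF))
  # zero uptake: upper-bound sentinel, flagged
  zero <- curve(1)
  zero$D <- 0
  fit0 <- empirical_pf(zero, k)
  expect_equal(fit0$flag, "no_uptake")
  expect_equal(fit0$PF, 1e8)
})

test_that("residue consolidation applies the set-subtraction rule", {
  pp <- data.frame(start = c(10, 10), end = c(20, 15),
                   significant = c(TRUE, FALSE))
  expect_equal(consolidate_residues(pp), 16:20)
  none <- data.frame(start = 10, end = 20, significant = FALSE)
  expect_equal(consolidate_residues(none), integer(0))
  bad <- data.frame(start = 10, end = 5, significant = TRUE)
  expect_error(consolidate_residues(bad), "conflicting")
})

test_that("state annotation distinguishes shared and unique protection", {
  ann <- annotate_states(c(70:75), c(73:78), labels = c("v1", "v2"))
  expect_equal(ann$state[ann$residue == 70], "v1-only")
  expect_equal(ann$state[ann$residue == 74], "both")
  expect_equal(ann$state[ann$residue == 78], "v2-only")
})
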