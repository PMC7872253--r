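# Donor-recipient pairing, mirroring, deviations, and the paired test.

test_that("pairing honours the 1-4 mm window on simple cases", {
  tab <- pair_donors(c(A = 24), c(B = 22))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$size_difference, 2)

  none <- pair_donors(c(A = 24), c(B = 24))  # 0 mm is outside 1-4
  expect_equal(nrow(none), 0L)
  expect_equal(attr(none, "unmatched_recipients"), "A")

  tab2 <- pair_donors(c(A = 24, B = 26), c(X = 21.5, Y = 23))
  expect_true(all(tab2$size_difference >= 1 & tab2$size_difference <= 4))
})

test_that("4x4 assignments equal exhaustive enumeration", {
  set.seed(101)
  for (i in 1:20) {
    r <- round(runif(4, 20, 26), 1)
    d <- round(runif(4, 18, 24), 1)
    names(r) <- paste0("R", 1:4); names(d) <- paste0("D", 1:4)
    tab <- pair_donors(r, d)
    orc <- oracle_pairing(r, d)
    expect_equal(nrow(tab), orc$matches)
    if (nrow(tab)) {
      cost <- sum(abs(tab$size_difference - 2.5))
      expect_equal(cost, orc$cost, tolerance = 1e-9)
    }
  }
})

test_that("every emitted pair satisfies the window over many random instances", {
  set.seed(202)
  for (i in 1:1000) {
    nr <- sample(2:6, 1L); nd <- sample(2:6, 1L)
    r <- stats::setNames(runif(nr, 19, 27), paste0("R", seq_len(nr)))
    d <- stats::setNames(runif(nd, 17, 25), paste0("D", seq_len(nd)))
    tab <- pair_donors(r, d)
    if (nrow(tab)) {
      expect_true(all(tab$size_difference >= 1 - 1e-12 &
                        tab$size_difference <= 4 + 1e-12))
      expect_false(any(duplicated(tab$donor_id)))
      expect_false(any(duplicated(tab$recipient_id)))
    }
  }
})

test_that("mirroring is an involution preserving landmark distances", {
  fem <- generate_femur(femur_params())
  sag <- plane(c(3, -2, 1), unitize(c(0.2, 1, 0.1)))
  lm <- fem$landmarks
  m1 <- mirror_plan(lm, sag)
  m2 <- mirror_plan(m1, sag)
  for (nm in c("craniomedial", "craniolateral", "caudomedial", "caudolateral")) {
    expect_lt(vnorm(m2[[nm]] - lm[[nm]]), 1e-9)
  }
  expect_identical(m1$side, "left")
  expect_identical(m2$side, "right")
  d0 <- dist(rbind(lm$craniomedial, lm$craniolateral, lm$caudomedial,
                   lm$caudolateral))
  d1 <- dist(rbind(m1$craniomedial, m1$craniolateral, m1$caudomedial,
                   m1$caudolateral))
  expect_lt(max(abs(d0 - d1)), 1e-9)

  plan <- chevron_planes(lm)
  plan2 <- mirror_plan(mirror_plan(plan, sag), sag)
  expect_lt(vnorm(plan2$plane_a$normal - plan$plane_a$normal), 1e-9)
  expect_equal(plan2$dihedral_angle, plan$dihedral_angle)
})

test_that("a mirrored anteverted femur re-measures with the same |version|", {
  fem <- generate_femur(femur_params(version = 20, side = "right"))
  sag <- plane(c(0, 0, 0), c(0, 1, 0))
  mr0 <- measure_femur(fem$mesh, fem$landmarks$condyle_medial,
                       fem$landmarks$condyle_lateral, "right")
  mirrored <- mirror_plan(mr0, sag)
  expect_identical(mirrored$side, "left")
  expect_equal(abs(mirrored$version), 20, tolerance = 1e-6)
  expect_equal(mirrored$neck_length, mr0$neck_length)  # isometry
  # recompute on the mirrored mesh: the measured |version| is unchanged
  mm <- reflect_across(sag, fem$mesh)
  mlm <- mirror_plan(fem$landmarks, sag)
  mr1 <- measure_femur(mm, mlm$condyle_medial, mlm$condyle_lateral, "left")
  expect_equal(abs(mr1$version), 20, tolerance = 1e-6)
  expect_equal(mr1$version, mirrored$version, tolerance = 1e-6)
})

test_that("deviation records are absolute differences with side checking", {
  fem <- generate_femur(femur_params())
  mr <- measure_femur(fem$mesh, fem$landmarks$condyle_medial,
                      fem$landmarks$condyle_lateral, "right")
  z <- deviation_from_plan(mr, mr, "S1", "guide")
  expect_equal(z$abs_dev_version, 0)
  expect_equal(z$abs_dev_inclination, 0)
  expect_equal(z$abs_dev_neck_length, 0)

  shifted <- mr
  shifted$version <- mr$version + 7
  shifted$neck_length <- mr$neck_length - 2
  dv <- deviation_from_plan(shifted, mr)
  expect_equal(dv$abs_dev_version, 7)
  expect_equal(dv$abs_dev_neck_length, 2)

  other <- mirror_plan(mr, plane(c(0, 0, 0), c(0, 1, 0)))
  expect_error(deviation_from_plan(other, mr), "side mismatch")
})

test_that("the paired one-tailed t matches the closed form to 1e-9", {
  a <- c(1, 2, 4, 3, 5); b <- c(0, 1, 1, 2, 2)
  res <- paired_one_tailed_t(a, b, "a_greater")
  d <- a - b
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  p_oracle <- 1 - pt(t_oracle, df = length(d) - 1)
  expect_equal(res$t_statistic, t_oracle, tolerance = 1e-9)
  expect_equal(res$p_one_tailed, p_oracle, tolerance = 1e-9)
  expect_equal(res$shapiro_p, shapiro.test(d)$p.value, tolerance = 1e-9)

  # swapping groups and direction leaves p unchanged
  sw <- paired_one_tailed_t(b, a, "a_less")
  expect_equal(sw$p_one_tailed, res$p_one_tailed, tolerance = 1e-12)

  expect_error(paired_one_tailed_t(a, a, "a_less"), "zero variance")
  expect_error(paired_one_tailed_t(a, b[1:3], "a_less"), "equal-length")
})
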