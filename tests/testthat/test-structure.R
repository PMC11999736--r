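test_that("structure constraints derive counts and validate positions", {
  hh <- fixture_structure("hammerhead-like")
  expect_identical(c(hh$Lstr, hh$s, hh$b, hh$M), c(39L, 13L, 8L, 3L))
  tw <- fixture_structure("twister-like")
  expect_identical(c(tw$Lstr, tw$s, tw$b, tw$M), c(54L, 11L, 17L, 3L))
  tri <- fixture_structure("triphosphorylation-like")
  expect_identical(c(tri$Lstr, tri$s, tri$b, tri$M), c(44L, 13L, 11L, 2L))
  expect_true(tri$anchored5)

  empty <- structure_constraint(5)
  expect_identical(c(empty$s, empty$b, empty$M), c(0L, 0L, 1L))

  expect_error(structure_constraint(4, conserved = c(`0` = "G")), "1..Lstr")
  expect_error(structure_constraint(4, conserved = c(`2` = "G"),
                                    pairs = rbind(c(2, 4))), "conserved and paired")
  expect_error(structure_constraint(6, pairs = rbind(c(1, 4), c(2, 4))),
               "two pairs")
  expect_error(structure_constraint(4, pairs = rbind(c(1, 9))), "1..Lstr")
  expect_error(structure_constraint(3, conserved = c(`1` = "G", `2` = "C"),
                                    pairs = rbind(c(3, 3))), "itself")
  expect_error(structure_constraint(4, breaks = 4), "break")
  # T accepted and normalised to U
  st <- structure_constraint(2, conserved = c(`1` = "T"))
  expect_identical(unname(st$conserved), "U")
})

test_that("structure files round-trip bit-exactly", {
  dir <- withr::local_tempdir()
  for (nm in c("hammerhead-like", "triphosphorylation-like", "toy-two-module")) {
    st <- fixture_structure(nm)
    f1 <- file.path(dir, "a.structure")
    f2 <- file.path(dir, "b.structure")
    write_structure(st, f1)
    st2 <- read_structure(f1)
    expect_equal(st2, st)
    write_structure(st2, f2)
    expect_identical(readLines(f1), readLines(f2))
  }
  bad <- file.path(dir, "bad.structure")
  writeLines(c("LENGTH 4", "CONS 0=G"), bad)
  expect_error(read_structure(bad), "1-based")
  writeLines(c("LENGTH 4", "WOBBLE 1"), bad)
  expect_error(read_structure(bad), "unknown directive")
})

test_that("single-frame exact-match probability is (1/4)^s (3/8)^b", {
  expect_equal(signif(exact_match_probability(13, 8), 2), 5.8e-12)
  expect_equal(signif(exact_match_probability(11, 17), 2), 1.4e-14)
  expect_equal(signif(exact_match_probability(13, 11), 2), 3.1e-13)
  expect_equal(exact_match_probability(0, 0), 1)
  expect_equal(exact_match_probability(fixture_structure("hammerhead-like")),
               0.25^13 * 0.375^8)
})

test_that("frame counts follow the gap-composition formula", {
  expect_equal(frame_count(80, 39, M = 3), 13244)
  expect_equal(frame_count(80, 54, M = 3), 3654)
  expect_equal(frame_count(80, 39, M = 1), 42)
  expect_equal(frame_count(80, 44, M = 2, anchored5 = TRUE), 37)
  expect_equal(frame_count(80, fixture_structure("triphosphorylation-like")), 37)
  expect_error(frame_count(30, 39), "at least")
  for (Lran in c(10, 25, 80)) {
    for (Lstr in c(4, 10)) {
      expect_equal(frame_count(Lran, Lstr, M = 1), Lran - Lstr + 1)
    }
  }
  # anchoring forces the leading gap to zero
  expect_equal(frame_count(20, 10, M = 1, anchored5 = TRUE), 1)
  expect_equal(frame_count(20, 10, M = 2, anchored5 = TRUE),
               frame_count(20, 10, M = 1))
})

test_that("multi-frame exact probability and its Wq approximation agree when small", {
  hh <- multi_frame_exact_probability(exact_match_probability(13, 8),
                                      frame_count(80, 39, M = 3))
  expect_equal(signif(hh$Wq, 2), 7.7e-8)
  expect_equal(hh$PW, hh$Wq, tolerance = 1e-3)
  tri <- multi_frame_exact_probability(exact_match_probability(13, 11), 37)
  expect_equal(signif(tri$Wq, 2), 1.1e-11)
  expect_equal(multi_frame_exact_probability(0, 10)$PW, 0)
})

test_that("mismatch joint distribution is a product of binomials", {
  expect_equal(mismatch_joint_probability(0, 0, 13, 8),
               exact_match_probability(13, 8))
  expect_equal(mismatch_joint_probability(1, 0, 2, 0), 0.375)
  grid <- expand.grid(m1 = 0:5, m2 = 0:3)
  expect_equal(sum(mismatch_joint_probability(grid$m1, grid$m2, 5, 3)), 1,
               tolerance = 1e-12)
  expect_error(mismatch_joint_probability(3, 0, 2, 0), "m1")
})

test_that("single-frame distance distribution convolves the two mismatch types", {
  expect_equal(single_frame_distribution(1, 0)$probability, c(0.25, 0.75))
  hh <- single_frame_distribution(13, 8)
  expect_equal(hh$probability[1], exact_match_probability(13, 8))
  expect_equal(sum(hh$probability), 1, tolerance = 1e-12)
  expect_identical(hh$m, 0:21)
  # matches direct summation over (m1, m2)
  for (m in c(0, 3, 10, 21)) {
    direct <- sum(vapply(0:m, function(m1) {
      if (m1 <= 13 && (m - m1) <= 8) {
        mismatch_joint_probability(m1, m - m1, 13, 8)
      } else 0
    }, numeric(1)))
    expect_equal(hh$probability[m + 1], direct, tolerance = 1e-14)
  }
})

test_that("multi-frame distribution is the minimum over independent frames", {
  single <- single_frame_distribution(13, 8)
  expect_identical(multi_frame_distribution(single, 1), single)
  W <- frame_count(80, 39, M = 3)
  multi <- multi_frame_distribution(single, W)
  expect_equal(sum(multi$probability), 1, tolerance = 1e-12)
  q <- exact_match_probability(13, 8)
  expect_equal(multi$probability[1], 1 - (1 - q)^W, tolerance = 1e-9)
  # near-matches are orders of magnitude more frequent than exact matches
  expect_true(all(multi$probability[2:4] > 10 * multi$probability[1]))
  # g(m) = P(distance >= m) is nonincreasing
  g <- rev(cumsum(rev(single$probability)))
  expect_true(all(diff(g) <= 1e-15))
  # the minimum over frames stochastically dominates toward smaller m
  cdf_single <- cumsum(single$probability)
  cdf_multi <- cumsum(multi$probability)
  expect_true(all(cdf_multi >= cdf_single - 1e-12))
})
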