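test_that("min-distance scan handles planted, violated and hand-checked cases", {
  toy <- fixture_structure("toy-hairpin") # G at 1, pair 2:4
  expect_identical(min_distance_scan("GACU", toy), 0L) # A-U pairs
  expect_identical(min_distance_scan("GACG", toy), 1L) # A-G does not
  # every constraint violated: all-A sequence, no constraint satisfiable by A-A
  expect_identical(min_distance_scan("AAAA", toy), 2L)
  # hand enumeration at Lran = 6 (3 frames):
  # GACGAA -> offsets 0,1,2 give 1, 2, 2 -> min 1
  expect_identical(min_distance_scan("GACGAA", toy), 1L)
  # planted exact match for the hammerhead-like motif, with inserted gaps
  hh <- fixture_structure("hammerhead-like")
  seq <- rep("A", 80)
  gap <- function(pos) pos + ifelse(pos <= 13, 5, ifelse(pos <= 26, 8, 11))
  seq[gap(as.integer(names(hh$conserved)))] <- hh$conserved
  seq[gap(hh$pairs[, 1])] <- "U"
  seq[gap(hh$pairs[, 2])] <- "G" # U-G wobble counts as canonical
  expect_identical(min_distance_scan(paste(seq, collapse = ""), hh), 0L)
  expect_error(min_distance_scan("GAXU", toy), "invalid base")
  expect_error(min_distance_scan("GG", toy), "shorter")
  # T is accepted as U
  expect_identical(min_distance_scan("GACT", toy), 0L)
})

test_that("scan agrees with a plain-R placement enumeration", {
  withr::local_seed(101)
  structs <- list(fixture_structure("toy-hairpin"),
                  fixture_structure("toy-two-module"),
                  fixture_structure("triphosphorylation-like"))
  Lrans <- c(9, 11, 48)
  for (i in seq_along(structs)) {
    for (rep in 1:25) {
      s <- random_rna(Lrans[i])
      ref <- ref_min_distance(s, structs[[i]])
      expect_identical(min_distance_scan(s, structs[[i]]),
                       as.integer(ref$min_distance))
    }
  }
})

test_that("the scan enumerates exactly frame_count placements", {
  cases <- list(
    list(st = fixture_structure("toy-hairpin"), Lran = 4),
    list(st = fixture_structure("toy-hairpin"), Lran = 9),
    list(st = fixture_structure("toy-two-module"), Lran = 10),
    list(st = fixture_structure("triphosphorylation-like"), Lran = 50)
  )
  for (cs in cases) {
    n <- selexdyn:::scan_enumerate(strrep("A", cs$Lran), cs$st)$n_placements
    expect_equal(n, frame_count(cs$Lran, cs$st))
  }
})

test_that("cross-module pairs are scored from both modules' offsets", {
  # pair 2:6 spans the two modules; its status depends on the gap inserted
  st <- structure_constraint(6, conserved = c(`1` = "G"),
                             pairs = rbind(c(2, 6)), breaks = 4)
  withr::local_seed(7)
  for (rep in 1:40) {
    s <- random_rna(9)
    expect_identical(min_distance_scan(s, st),
                     as.integer(ref_min_distance(s, st)$min_distance))
  }
})

test_that("exhaustive enumeration equals the single-frame formula at Lran = Lstr", {
  toy <- fixture_structure("toy-hairpin")
  ex <- exhaustive_distance_distribution(toy, 4)
  th <- single_frame_distribution(toy)
  expect_equal(ex$probability, th$probability, tolerance = 1e-12)
  expect_equal(sum(ex$count), 4^4)
  toy2 <- fixture_structure("toy-two-module")
  ex2 <- exhaustive_distance_distribution(toy2, 6)
  th2 <- single_frame_distribution(toy2)
  expect_equal(ex2$probability, th2$probability, tolerance = 1e-12)
  # no constraints: all mass at zero
  free <- structure_constraint(3)
  exf <- exhaustive_distance_distribution(free, 5)
  expect_equal(exf$probability, 1)
  expect_error(exhaustive_distance_distribution(toy, 13), "<= 12")
})

test_that("overlapping frames make the independence formula an upper bound at m = 0", {
  # Lran > Lstr: enumerate the truth and compare with the W-frame formula.
  # Frames sharing modules are positively associated, so the independent-
  # frames result overestimates the exact-match probability; the gap at
  # m = 0 stays well within a factor of two here.
  toy <- fixture_structure("toy-hairpin")
  for (Lran in c(6, 8)) {
    ex <- exhaustive_distance_distribution(toy, Lran)
    th <- multi_frame_distribution(single_frame_distribution(toy),
                                   frame_count(Lran, toy))
    expect_equal(sum(ex$probability), 1, tolerance = 1e-12)
    expect_lte(ex$probability[1], th$probability[1] * (1 + 1e-12))
    expect_gte(ex$probability[1], th$probability[1] * 0.5)
  }
})

test_that("Monte Carlo sampling reproduces exhaustive enumeration on a toy", {
  toy <- fixture_structure("toy-hairpin")
  ex <- exhaustive_distance_distribution(toy, 6)
  n <- 1e5
  mc <- sample_min_distance_distribution(toy, 6, n_samples = n, seed = 5)
  expect_equal(sum(mc$count), n)
  for (m in ex$m) {
    p <- ex$probability[m + 1]
    sigma <- sqrt(n * p * (1 - p))
    expect_lt(abs(mc$count[m + 1] - n * p), 3 * sigma + 1)
  }
  # reproducible per seed
  mc2 <- sample_min_distance_distribution(toy, 6, n_samples = 1000, seed = 11)
  mc3 <- sample_min_distance_distribution(toy, 6, n_samples = 1000, seed = 11)
  expect_identical(mc2$count, mc3$count)
})

test_that("Monte Carlo matches the exact single-frame theory at Lran = Lstr", {
  # with exactly one frame there is no independence approximation, so the
  # sampled distribution must agree with the formula everywhere it is
  # resolvable
  hh <- fixture_structure("hammerhead-like")
  n <- 2e5
  mc <- sample_min_distance_distribution(hh, 39, n_samples = n, seed = 9)
  th <- single_frame_distribution(hh)
  for (m in th$m) {
    expected <- n * th$probability[m + 1]
    if (expected >= 100) {
      sigma <- sqrt(expected * (1 - th$probability[m + 1]))
      expect_lt(abs(mc$count[m + 1] - expected), 4 * sigma)
    }
  }
})

test_that("multi-frame theory matches sampling in the rare-tail regime", {
  # where matches are rare the union-bound/independence treatment is
  # accurate even though frames overlap: cumulative P(min <= 2) for the
  # hammerhead-like motif in an 80-mer
  hh <- fixture_structure("hammerhead-like")
  n <- 2e5
  mc <- sample_min_distance_distribution(hh, 80, n_samples = n, seed = 13)
  th <- multi_frame_distribution(single_frame_distribution(hh),
                                 frame_count(80, hh))
  p_tail <- sum(th$probability[1:3])
  obs <- sum(mc$count[1:3])
  expect_lt(abs(obs - n * p_tail), 3 * sqrt(n * p_tail) + 1)
})

test_that("random pools are reproducible and FASTA round-trips", {
  p1 <- random_pool(5, 20, seed = 3)
  p2 <- random_pool(5, 20, seed = 3)
  expect_identical(p1, p2)
  expect_true(all(nchar(p1) == 20))
  skip_if_not_installed("Biostrings")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_pool_fasta(p1, f)
  back <- read_pool_fasta(f)
  expect_identical(unname(back), unname(p1))
})
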